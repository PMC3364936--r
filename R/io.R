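#' Load the packaged anesthetic binding tables
#'
#' Returns the packaged table of per-ligand, per-site free-energy
#' components, total binding free energies with standard errors,
#' dissociation constants (micromolar), predicted IC50 ranges and the
#' experimental IC50s used as comparison annotations. The ethanol
#' dissociation constant is absent (its published value is ambiguous) and
#' left `NA`.
#'
#' @param path Optional path to an alternative TSV with the same columns.
#' @return Data frame, one row per anesthetic/site/conformation.
#' @export
load_binding_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "glic_binding_tables.tsv",
                        package = "poreblock", mustWork = TRUE)
  }
  utils::read.delim(path, na.strings = "NA", stringsAsFactors = FALSE)
}

#' Parse an IC50 range string like "2.8-86"
#'
#' @param x Character vector of `low-high` strings (or `NA`).
#' @return Two-column numeric matrix `low`, `high`.
#' @export
parse_ic50_range <- function(x) {
  out <- t(vapply(x, function(s) {
    if (is.na(s)) return(c(NA_real_, NA_real_))
    parts <- as.numeric(strsplit(s, "-", fixed = TRUE)[[1]])
    if (length(parts) != 2L || anyNA(parts)) {
      stop("malformed range string: ", s, call. = FALSE)
    }
    parts
  }, numeric(2)))
  dimnames(out) <- list(NULL, c("low", "high"))
  out
}

#' Read per-window FEP samples from a TSV file
#'
#' Long format with columns `lambda_low`, `lambda_high`, `direction`
#' (`forward`/`backward`) and `delta_u` (kcal/mol); rows are grouped into
#' one [window_samples()] per (`lambda_low`, `lambda_high`) pair.
#'
#' @param path Path to the TSV file.
#' @return List of [window_samples()] ordered by `lambda_low`.
#' @export
read_window_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lambda_low", "lambda_high", "direction", "delta_u")
  if (!all(need %in% names(df))) {
    stop("window sample file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(df$direction %in% c("forward", "backward"))) {
    stop("direction must be 'forward' or 'backward'", call. = FALSE)
  }
  key <- paste(df$lambda_low, df$lambda_high)
  windows <- lapply(split(df, key), function(d) {
    window_samples(d$lambda_low[1], d$lambda_high[1],
                   forward_du = d$delta_u[d$direction == "forward"],
                   backward_du = d$delta_u[d$direction == "backward"])
  })
  windows <- windows[order(vapply(windows, `[[`, numeric(1), "lambda_low"))]
  names(windows) <- NULL
  windows
}

#' Write window samples to the TSV dialect read by [read_window_samples()]
#'
#' @param windows List of [window_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_samples <- function(windows, path) {
  rows <- lapply(windows, function(w) {
    rbind(
      if (length(w$forward_du))
        data.frame(lambda_low = w$lambda_low, lambda_high = w$lambda_high,
                   direction = "forward", delta_u = w$forward_du),
      if (length(w$backward_du))
        data.frame(lambda_low = w$lambda_low, lambda_high = w$lambda_high,
                   direction = "backward", delta_u = w$backward_du))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one window from a two-column (time, delta-U) file
#'
#' Lenient reader for the minimal per-window dialect emitted by
#' simulation engines: whitespace-separated lines of time and energy
#' difference (kcal/mol); lines starting with `#` are ignored, as is any
#' leading label column that is non-numeric.
#'
#' @param path Path to the file.
#' @param lambda_low,lambda_high Window bounds.
#' @param direction `"forward"` or `"backward"`.
#' @return A [window_samples()] with one populated direction.
#' @export
read_fepout_window <- function(path, lambda_low, lambda_high,
                               direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  du <- vapply(strsplit(trimws(lines), "\\s+"), function(f) {
    v <- suppressWarnings(as.numeric(f))
    v <- v[!is.na(v)]
    if (length(v) < 2L) {
      stop("expected at least two numeric columns (time, delta_u)",
           call. = FALSE)
    }
    v[2]
  }, numeric(1))
  if (direction == "forward") {
    window_samples(lambda_low, lambda_high, forward_du = du)
  } else {
    window_samples(lambda_low, lambda_high, backward_du = du)
  }
}

#' Read a ligand center-of-mass trajectory from CSV
#'
#' Expects columns `frame`, `ligand_id`, `x`, `y`, `z` (angstroms), or a
#' single-column file of pore-axis z values.
#'
#' @param path CSV path.
#' @return Data frame with the columns above, or with a single `z` column.
#' @export
read_ligand_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) == 1L) {
    names(df) <- "z"
    return(df)
  }
  need <- c("frame", "ligand_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         " or a single z column", call. = FALSE)
  }
  df[need]
}

#' Project trajectory coordinates onto a pore axis
#'
#' @param xyz Matrix or data frame with columns `x`, `y`, `z` (angstroms).
#' @param center Pore center from [pore_center()] (the z origin).
#' @param axis Unit axis vector from [pore_axis()].
#' @return Numeric vector of axial coordinates.
#' @export
project_onto_axis <- function(xyz, center, axis) {
  m <- as.matrix(xyz[, c("x", "y", "z")])
  as.numeric((sweep(m, 2, center)) %*% (axis / sqrt(sum(axis^2))))
}

#' Write a 1D profile as TSV
#'
#' @param profile A `free_energy_profile` or `density_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  if (inherits(profile, "free_energy_profile")) {
    df <- data.frame(center = profile$centers, value = profile$values)
  } else if (inherits(profile, "density_profile")) {
    df <- data.frame(center = profile$centers, value = profile$rho)
  } else {
    stop("profile must be a free_energy_profile or density_profile",
         call. = FALSE)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a binding result (with provenance) as JSON
#'
#' @param result A `binding_result` from [combine_binding_free_energy()].
#' @param path Output path.
#' @param provenance Optional named list recorded verbatim under
#'   `"provenance"` (e.g. input file hashes, seeds, component origins).
#' @return `path`, invisibly.
#' @export
write_binding_result_json <- function(result, path, provenance = list()) {
  stopifnot(inherits(result, "binding_result"))
  obj <- list(
    delta_g_bind_1 = result$delta_g_bind_1,
    delta_g_bind_1_err = result$delta_g_bind_1_err,
    kd1_molar = result$kd1,
    temperature_K = result$temperature,
    units = list(free_energy = "kcal/mol", kd = "M"))
  if (!is.null(result$delta_g_bind_2)) {
    obj$delta_g_bind_2 <- result$delta_g_bind_2
    obj$delta_g_bind_2_err <- result$delta_g_bind_2_err
    obj$kd2_molar <- result$kd2
  }
  obj$provenance <- provenance
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
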