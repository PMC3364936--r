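#' Structure model for a pentameric channel
#'
#' A light atom table: one row per atom with chain id, residue number,
#' residue name, atom name and coordinates in angstroms. `subunit_order`
#' lists the five chains as arranged consecutively around the pore; it
#' defaults to the sorted unique chain ids, which matches conventionally
#' lettered pentamers (A-E around the ring).
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` (bio3d column naming: `resid` is the residue name,
#'   `elety` the atom name).
#' @param subunit_order Optional character vector of 5 chain ids.
#' @return An object of class `structure_model`.
#' @seealso [read_structure()] to build one from a PDB file.
#' @export
structure_model <- function(atoms, subunit_order = NULL) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms))) {
    stop("atoms must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) ||
      any(!is.finite(atoms$z))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  chains <- sort(unique(as.character(atoms$chain)))
  if (is.null(subunit_order)) {
    subunit_order <- chains
  } else if (!setequal(subunit_order, chains)) {
    stop("subunit_order must name exactly the chains present", call. = FALSE)
  }
  structure(list(atoms = atoms, subunit_order = as.character(subunit_order)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, %d chain(s) [%s]\n",
              nrow(x$atoms), length(x$subunit_order),
              paste(x$subunit_order, collapse = " ")))
  invisible(x)
}

#' Read a structure model from a PDB file
#'
#' Parses ATOM records (1-based residue numbering as in the PDB) via
#' `bio3d::read.pdb` and returns a [structure_model()].
#'
#' @param path Path to a PDB file.
#' @param subunit_order Optional chain ordering around the pore.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, subunit_order = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM",
                 c("chain", "resno", "resid", "elety", "x", "y", "z")]
  structure_model(at, subunit_order = subunit_order)
}

# Ca coordinates for one residue number in each listed chain; errors name
# the first missing chain/residue.
ca_coords <- function(model, resno, chains = model$subunit_order) {
  at <- model$atoms
  out <- matrix(NA_real_, nrow = length(chains), ncol = 3,
                dimnames = list(chains, c("x", "y", "z")))
  for (i in seq_along(chains)) {
    sel <- at$chain == chains[i] & at$resno == resno & at$elety == "CA"
    if (sum(sel) != 1L) {
      stop(sprintf("expected one CA atom for chain %s residue %d, found %d",
                   chains[i], resno, sum(sel)), call. = FALSE)
    }
    out[i, ] <- as.numeric(at[sel, c("x", "y", "z")])
  }
  out
}

#' Center of the pore
#'
#' The pore center is the unweighted mean of the ten alpha-carbon positions
#' of the two pore-lining tyrosines (residues 226 and 244) over the five
#' subunits.
#'
#' @param model A [structure_model()] of the pentamer.
#' @param anchor_residues The two anchor residue numbers.
#' @return Named numeric vector `c(x, y, z)` in angstroms.
#' @export
pore_center <- function(model, anchor_residues = c(226, 244)) {
  stopifnot(inherits(model, "structure_model"))
  if (length(model$subunit_order) != 5L) {
    stop("pore operations require a pentamer (5 chains)", call. = FALSE)
  }
  xyz <- do.call(rbind, lapply(anchor_residues, ca_coords, model = model))
  colMeans(xyz)
}

#' Pore axis by principal component of the anchor carbons
#'
#' The axis is the leading principal direction of the ten anchor
#' alpha-carbons (residues 226/244), oriented so that positive z points
#' toward the extracellular side (the residue-244 ring).
#'
#' @inheritParams pore_center
#' @return Unit vector of length 3.
#' @export
pore_axis <- function(model, anchor_residues = c(226, 244)) {
  stopifnot(inherits(model, "structure_model"))
  lower <- ca_coords(model, anchor_residues[1])
  upper <- ca_coords(model, anchor_residues[2])
  xyz <- rbind(lower, upper)
  v <- stats::prcomp(xyz, center = TRUE)$rotation[, 1]
  if (sum(v * (colMeans(upper) - colMeans(lower))) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Pairwise M2-helix distances across the pentamer
#'
#' For each subunit, the geometric center of the alpha carbons in the
#' extracellular half of the M2 helix (residues 232-245) is computed; the
#' five distances between centers of non-adjacent subunits
#' (1-3, 1-4, 2-4, 2-5, 3-5 in ring order) describe pore constriction.
#'
#' @param model A [structure_model()] pentamer (one frame).
#' @param residues Residue span defining the M2 extracellular half.
#' @return An object of class `distance_series`: a named numeric vector of
#'   the five distances (angstroms) for a single frame.
#' @export
m2_pair_distances <- function(model, residues = 232:245) {
  stopifnot(inherits(model, "structure_model"))
  chains <- model$subunit_order
  if (length(chains) != 5L) {
    stop("pore operations require a pentamer (5 chains)", call. = FALSE)
  }
  centers <- t(vapply(chains, function(ch) {
    colMeans(do.call(rbind, lapply(residues, function(r) {
      ca_coords(model, r, chains = ch)
    })))
  }, numeric(3)))
  pairs <- non_adjacent_pairs()
  d <- apply(pairs, 1, function(p) {
    sqrt(sum((centers[p[1], ] - centers[p[2], ])^2))
  })
  names(d) <- apply(pairs, 1, paste, collapse = "-")
  structure(d, class = "distance_series")
}

#' The five non-adjacent subunit pairs of a pentagon
#'
#' @return Integer matrix with rows 1-3, 1-4, 2-4, 2-5, 3-5 (ring indices).
#' @export
non_adjacent_pairs <- function() {
  matrix(c(1, 3, 1, 4, 2, 4, 2, 5, 3, 5), ncol = 2, byrow = TRUE)
}

#' One-dimensional free-energy profile container
#'
#' @param centers Bin centers (angstroms), strictly increasing, equal width.
#' @param values Profile values in kcal/mol; `NA` marks unsampled bins.
#' @param bin_width Bin width (angstroms).
#' @return An object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(centers, values, bin_width) {
  stopifnot(is.numeric(centers), is.numeric(values),
            length(centers) == length(values), bin_width > 0)
  if (length(centers) > 1L &&
      max(abs(diff(centers) - bin_width)) > 1e-6 * bin_width) {
    stop("bin centers must be evenly spaced by bin_width", call. = FALSE)
  }
  structure(list(centers = centers, values = values, bin_width = bin_width),
            class = "free_energy_profile")
}

#' Boltzmann-transform a sampled coordinate into a free-energy profile
#'
#' Histograms the samples and applies \eqn{G(d) = -kT \ln \rho(d)}, shifting
#' the minimum to zero. Bins with no samples are flagged as `NA`
#' (the profile is undefined there), never zero-filled.
#'
#' @param samples Numeric samples of the coordinate (angstroms).
#' @param bin_width Histogram bin width, > 0 (default 0.5).
#' @param ctx A [thermo_context()].
#' @return A [free_energy_profile()].
#' @export
boltzmann_profile <- function(samples, bin_width = 0.5,
                              ctx = thermo_context()) {
  stopifnot(is.numeric(samples), length(samples) >= 1L)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  h <- bin_samples(samples, bin_width)
  g <- ifelse(h$counts > 0, -ctx$kT * log(h$counts), NA_real_)
  g <- g - min(g, na.rm = TRUE)
  free_energy_profile(h$centers, g, bin_width)
}

# shared binning: grid aligned to multiples of bin_width
bin_samples <- function(samples, bin_width) {
  lo <- floor(min(samples) / bin_width) * bin_width
  hi <- ceiling(max(samples) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  # guard against numeric shortfall at the top edge
  if (breaks[length(breaks)] < max(samples)) {
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  }
  counts <- graphics::hist(samples, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  list(centers = breaks[-length(breaks)] + bin_width / 2, counts = counts)
}

#' Flat-bottom wall restraint specification
#'
#' A one-sided harmonic wall on a distance coordinate: zero for
#' \eqn{d \ge d_0} and \eqn{(k/2)(d - d_0)^2} below, continuous and
#' once-differentiable at the wall.
#'
#' @param d0 Wall position (angstroms).
#' @param k Force constant, kcal/mol/A^2, > 0.
#' @param target Optional label for the restrained distance definition.
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(d0, k = 10, target = NULL) {
  stopifnot(is.numeric(d0), length(d0) == 1L, is.finite(d0))
  if (!is.numeric(k) || k <= 0) stop("k must be positive", call. = FALSE)
  structure(list(d0 = d0, k = k, target = target), class = "restraint_spec")
}

#' Evaluate a flat-bottom restraint
#'
#' @param spec A [restraint_spec()].
#' @param d Distance value(s), angstroms.
#' @return Data frame with columns `d`, `energy` (kcal/mol) and `force`
#'   (kcal/mol/A, \eqn{-dU/dd}).
#' @export
restraint_energy <- function(spec, d) {
  stopifnot(inherits(spec, "restraint_spec"), is.numeric(d))
  below <- d < spec$d0
  energy <- ifelse(below, 0.5 * spec$k * (d - spec$d0)^2, 0)
  force <- ifelse(below, -spec$k * (d - spec$d0), 0)
  data.frame(d = d, energy = energy, force = force)
}

#' Design a flat-bottom restraint from a free-energy profile
#'
#' Places the wall at the barrier-side edge of the open basin: the largest
#' distance below the basin center where the profile exceeds the basin
#' minimum by `margin`. The wall then reinforces the barrier against
#' collapse while leaving the landscape within the open basin untouched
#' (the potential is zero for all d at or above the wall).
#'
#' The profile must actually show a barrier below the basin - a local
#' maximum separating the open basin from a collapsed state; a single-well
#' profile is rejected.
#'
#' @param profile A [free_energy_profile()] of the pore distance.
#' @param open_basin_center Approximate location of the open-basin minimum
#'   (angstroms).
#' @param k Wall force constant, kcal/mol/A^2 (default 10).
#' @param margin Height above the basin minimum at which the wall is placed,
#'   kcal/mol (default 1 kT at the profile's implied temperature is a
#'   sensible choice; the numeric default is 1 kT at 300 K).
#' @param basin_window Half-width (angstroms) of the search window around
#'   `open_basin_center` for the basin minimum; must be narrow enough to
#'   exclude the collapsed basin.
#' @param target Optional label passed to [restraint_spec()].
#' @return A [restraint_spec()].
#' @export
design_flat_bottom_restraint <- function(profile, open_basin_center,
                                         k = 10,
                                         margin = thermo_context()$kT,
                                         basin_window = 1,
                                         target = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"),
            is.numeric(open_basin_center), margin > 0, basin_window > 0)
  centers <- profile$centers
  values <- profile$values
  ok <- which(!is.na(values))
  if (length(ok) < 3L) stop("profile has too few sampled bins", call. = FALSE)
  # basin minimum: lowest sampled bin near the stated center
  near <- ok[abs(centers[ok] - open_basin_center) <= basin_window]
  if (length(near) == 0L) {
    stop("no sampled bins near open_basin_center", call. = FALSE)
  }
  imin <- near[which.min(values[near])]
  below <- ok[ok < imin]
  if (length(below) == 0L) {
    stop("no sampled profile below the open basin; cannot design a wall",
         call. = FALSE)
  }
  # require a barrier: the collapsed basin is the minimum below the open
  # basin, and the barrier is the maximum between the two minima
  icol <- below[which.min(values[below])]
  between <- ok[ok > icol & ok < imin]
  ibar <- if (length(between) > 0L) between[which.max(values[between])]
          else icol
  barrier_height <- values[ibar] - values[imin]
  if (barrier_height < margin || values[ibar] <= values[icol] + 1e-9) {
    stop("no barrier below the open basin (single-well profile?); ",
         "flat-bottom design not applicable", call. = FALSE)
  }
  crossing <- below[below >= ibar & values[below] >= values[imin] + margin]
  if (length(crossing) == 0L) {
    stop("profile never exceeds the basin minimum by the requested margin ",
         "between barrier and basin", call. = FALSE)
  }
  d0 <- centers[max(crossing)]
  restraint_spec(d0 = d0, k = k, target = target)
}

#' Axial ligand density profile
#'
#' Bins the pore-axis positions of the ligand center(s) of mass and scales
#' to a number density \eqn{\rho(z) = n \, P(z) / \Delta z}, where `n` is
#' the number of ligands in the pore and `P(z)` the probability of
#' observing a ligand center of mass in the bin at `z` (positions of both
#' ligands are pooled when two are present). The profile is then smoothed
#' by a three-bin running average whose window shrinks at the edges so that
#' the integral \eqn{\sum \rho \Delta z = n} is preserved exactly.
#'
#' @param ligand_z Numeric vector (or matrix with one column per ligand) of
#'   per-frame positions along the pore axis, angstroms.
#' @param n_ligands Number of ligands in the pore, 1 or 2.
#' @param bin_width Bin width, angstroms (default 0.5).
#' @param smooth Apply the three-bin running average (default TRUE).
#' @return An object of class `density_profile` with fields `centers`,
#'   `rho`, `n_ligands`, `bin_width`.
#' @export
axial_density <- function(ligand_z, n_ligands, bin_width = 0.5,
                          smooth = TRUE) {
  z <- as.numeric(ligand_z)
  if (length(z) == 0L || any(!is.finite(z))) {
    stop("ligand_z must be non-empty and finite", call. = FALSE)
  }
  if (!n_ligands %in% c(1L, 2L)) {
    stop("n_ligands must be 1 or 2", call. = FALSE)
  }
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  h <- bin_samples(z, bin_width)
  # pad with one empty bin per side so edge mass has somewhere to smooth to
  centers <- c(h$centers[1] - bin_width, h$centers,
               h$centers[length(h$centers)] + bin_width)
  counts <- c(0, h$counts, 0)
  h <- list(centers = centers, counts = counts)
  rho <- n_ligands * (h$counts / length(z)) / bin_width
  if (smooth) rho <- running_mean3(rho)
  structure(list(centers = h$centers, rho = rho,
                 n_ligands = as.integer(n_ligands), bin_width = bin_width),
            class = "density_profile")
}

#' Mass-preserving three-bin running average
#'
#' Each bin exports one third of its content to each existing neighbour;
#' thirds with no neighbour (at the two edges) stay in place. In the
#' interior this is the ordinary centered three-bin running mean; at the
#' edges the window shrinks without losing mass, so the sum is conserved
#' exactly.
#'
#' @param x Numeric vector.
#' @return Smoothed vector of the same length and sum.
#' @export
running_mean3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  s <- x / 3
  out <- s
  out[1] <- 2 * s[1] + s[2]
  out[n] <- s[n - 1] + 2 * s[n]
  if (n > 2L) {
    mid <- 2:(n - 1)
    out[mid] <- s[mid - 1] + s[mid] + s[mid + 1]
  }
  out
}

#' Prime-notation index of an M2 residue
#'
#' Pore positions are compared across the channel family in prime notation,
#' counting from 0' at the intracellular end of M2. For this channel the
#' mapping is `prime = residue - 223`, fixed by the gate isoleucines
#' 232 (9') and 239 (16').
#'
#' @param resno Residue number(s) within the M2 span (223-245).
#' @return Integer prime index (9 for 9', etc.).
#' @examples
#' prime_index(c(232, 239))  # 9, 16
#' @export
prime_index <- function(resno) {
  stopifnot(is.numeric(resno))
  if (any(resno < 223 | resno > 245)) {
    stop("residue outside the M2 span (223-245)", call. = FALSE)
  }
  as.integer(resno - 223)
}

#' Pore site definitions
#'
#' Non-overlapping z-intervals for the primary site (between the gate
#' isoleucines, 9'-16') and the two secondary sites below (6'-9') and above
#' (16'-20') it.
#'
#' @param labels Character vector of site labels.
#' @param z_low,z_high Interval bounds on the pore axis, angstroms.
#' @return A data frame of class `site_definition`.
#' @export
site_definition <- function(labels, z_low, z_high) {
  stopifnot(length(labels) == length(z_low),
            length(z_low) == length(z_high), all(z_high > z_low))
  ord <- order(z_low)
  if (any(z_low[ord][-1] < z_high[ord][-length(ord)] - 1e-9)) {
    stop("site intervals must not overlap", call. = FALSE)
  }
  structure(data.frame(label = labels, z_low = z_low, z_high = z_high,
                       stringsAsFactors = FALSE),
            class = c("site_definition", "data.frame"))
}

#' Expected ligand count per pore site
#'
#' Integrates an axial density profile over each site interval (bins are
#' assigned by their centers), or, given raw z samples, uses the sample
#' fraction times the ligand count.
#'
#' @param x A `density_profile` from [axial_density()], or a numeric vector
#'   of raw z samples.
#' @param sites A [site_definition()].
#' @param n_ligands Required when `x` is a raw sample vector.
#' @return Named numeric vector of per-site expected occupancies.
#' @export
site_occupancy <- function(x, sites, n_ligands = NULL) {
  stopifnot(inherits(sites, "site_definition"))
  if (inherits(x, "density_profile")) {
    centers <- x$centers
    mass <- x$rho * x$bin_width
    n <- x$n_ligands
  } else {
    if (is.null(n_ligands)) {
      stop("n_ligands is required for raw samples", call. = FALSE)
    }
    z <- as.numeric(x)
    centers <- z
    mass <- rep(n_ligands / length(z), length(z))
    n <- n_ligands
  }
  occ <- vapply(seq_len(nrow(sites)), function(i) {
    sum(mass[centers >= sites$z_low[i] & centers < sites$z_high[i]])
  }, numeric(1))
  names(occ) <- sites$label
  occ
}
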