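#' Build a coupling-parameter (lambda) schedule
#'
#' Alchemical decoupling is staged over a grid of coupling values in
#' \[0, 1\], sampled more finely where the integrand changes fastest. The
#' grid uses `fine_step` inside `fine_region` and `coarse_step` elsewhere.
#' The default fine region \[0, 0.25\] yields 25 windows per stage
#' (10 fine + 15 coarse intervals), i.e. 25 ns per decoupling or recoupling
#' stage at 1 ns of sampling per window.
#'
#' @param fine_region Numeric length-2 interval inside \[0, 1\], or `NULL`
#'   for a uniform coarse grid.
#' @param fine_step Spacing inside `fine_region` (default 0.025).
#' @param coarse_step Spacing outside it (default 0.05).
#' @return An object of class `lambda_schedule` with fields `values`
#'   (ordered grid from 0 to 1), `fine_region`, `fine_step`, `coarse_step`
#'   and `n_windows` (number of intervals).
#' @examples
#' sched <- make_lambda_schedule()
#' sched$n_windows  # 25
#' @export
make_lambda_schedule <- function(fine_region = c(0, 0.25),
                                 fine_step = 0.025,
                                 coarse_step = 0.05) {
  stopifnot(fine_step > 0, coarse_step > 0)
  divisible <- function(len, step) {
    len <= 1e-12 || abs(len / step - round(len / step)) < 1e-9
  }
  seg_grid <- function(a, b, step) {
    if (b - a <= 1e-12) return(numeric(0))
    a + step * seq_len(round((b - a) / step))
  }
  if (is.null(fine_region) || length(fine_region) == 0L ||
      diff(range(fine_region)) <= 1e-12) {
    if (!divisible(1, coarse_step)) {
      stop("coarse_step must divide [0, 1]", call. = FALSE)
    }
    values <- c(0, seg_grid(0, 1, coarse_step))
    fine_region <- NULL
  } else {
    a <- min(fine_region); b <- max(fine_region)
    if (a < -1e-12 || b > 1 + 1e-12) {
      stop("fine_region must lie within [0, 1]", call. = FALSE)
    }
    if (!divisible(a, coarse_step) || !divisible(b - a, fine_step) ||
        !divisible(1 - b, coarse_step)) {
      stop("steps must divide the segment lengths (to 1e-9)", call. = FALSE)
    }
    values <- c(0, seg_grid(0, a, coarse_step), seg_grid(a, b, fine_step),
                seg_grid(b, 1, coarse_step))
    fine_region <- c(a, b)
  }
  values <- round(values, 12)
  stopifnot(!is.unsorted(values, strictly = TRUE),
            abs(values[1L]) < 1e-9, abs(values[length(values)] - 1) < 1e-9)
  structure(
    list(values = values, fine_region = fine_region, fine_step = fine_step,
         coarse_step = coarse_step, n_windows = length(values) - 1L),
    class = "lambda_schedule"
  )
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("Lambda schedule: %d windows, %d values\n",
              x$n_windows, length(x$values)))
  if (!is.null(x$fine_region)) {
    cat(sprintf("  fine step %g in [%g, %g], coarse step %g elsewhere\n",
                x$fine_step, x$fine_region[1], x$fine_region[2],
                x$coarse_step))
  } else {
    cat(sprintf("  uniform step %g\n", x$coarse_step))
  }
  invisible(x)
}

#' Per-window bidirectional energy-difference samples
#'
#' Holds the potential-energy differences \eqn{\Delta U = U(\lambda_{high})
#' - U(\lambda_{low})} (kcal/mol) for one alchemical window, sampled in the
#' ensemble at `lambda_low` (forward) and at `lambda_high` (backward).
#'
#' @param lambda_low,lambda_high Coupling values bounding the window.
#' @param forward_du Energy differences sampled at `lambda_low`.
#' @param backward_du Energy differences sampled at `lambda_high`.
#' @param direction_label Optional stage label, `"decoupling"` or
#'   `"recoupling"`.
#' @return An object of class `window_samples`.
#' @export
window_samples <- function(lambda_low, lambda_high,
                           forward_du = numeric(0),
                           backward_du = numeric(0),
                           direction_label = NULL) {
  stopifnot(is.numeric(lambda_low), is.numeric(lambda_high),
            lambda_low < lambda_high,
            is.numeric(forward_du), is.numeric(backward_du))
  if (length(forward_du) == 0L && length(backward_du) == 0L) {
    stop("at least one of forward_du/backward_du must be non-empty",
         call. = FALSE)
  }
  if (!is.null(direction_label)) {
    direction_label <- match.arg(direction_label,
                                 c("decoupling", "recoupling"))
  }
  structure(
    list(lambda_low = lambda_low, lambda_high = lambda_high,
         forward_du = as.numeric(forward_du),
         backward_du = as.numeric(backward_du),
         direction_label = direction_label),
    class = "window_samples"
  )
}

#' A free-energy estimate with uncertainty
#'
#' @param delta_g Estimate, kcal/mol.
#' @param stderr Standard error, kcal/mol (>= 0).
#' @param method `"exp"`, `"bar"` or `"combined"`.
#' @param n_windows Number of windows entering the estimate.
#' @param lambda_low,lambda_high Optional window bounds carried along for
#'   contiguity checks in [combine_windows()].
#' @param overlap_warning Logical flag set when forward/backward sample
#'   ranges do not overlap (poor phase-space overlap).
#' @return An object of class `free_energy_estimate`.
#' @export
free_energy_estimate <- function(delta_g, stderr, method,
                                 n_windows = 1L,
                                 lambda_low = NULL, lambda_high = NULL,
                                 overlap_warning = FALSE) {
  stopifnot(is.numeric(delta_g), is.finite(delta_g),
            is.numeric(stderr), stderr >= 0)
  method <- match.arg(method, c("exp", "bar", "combined"))
  structure(
    list(delta_g = delta_g, stderr = stderr, method = method,
         n_windows = as.integer(n_windows),
         lambda_low = lambda_low, lambda_high = lambda_high,
         overlap_warning = isTRUE(overlap_warning)),
    class = "free_energy_estimate"
  )
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("dG = %.4f +/- %.4f kcal/mol  [%s, %d window%s]%s\n",
              x$delta_g, x$stderr, x$method, x$n_windows,
              if (x$n_windows == 1L) "" else "s",
              if (x$overlap_warning) "  (overlap warning)" else ""))
  invisible(x)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  ifelse(x > 35, x + exp(-x), log1p(exp(pmin(x, 35))))
}

# log(mean(exp(x))) without overflow
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Exponential-averaging (Zwanzig) free-energy estimator
#'
#' One-sided free-energy perturbation for a single window:
#' forward, \eqn{\Delta G = -kT \ln \langle e^{-\Delta U/kT}\rangle_{low}};
#' backward, \eqn{\Delta G = +kT \ln \langle e^{+\Delta U/kT}\rangle_{high}}.
#' Both converge to the same window free energy; the backward sign follows
#' from evaluating the same \eqn{\Delta U = U_{high} - U_{low}} in the
#' high-\eqn{\lambda} ensemble. The standard error is first-order
#' (delta-method) in the sample mean of the Boltzmann factor.
#'
#' @param samples A [window_samples()] object.
#' @param direction `"forward"` or `"backward"`.
#' @param ctx A [thermo_context()].
#' @return A [free_energy_estimate()] with `method = "exp"`.
#' @export
exp_estimator <- function(samples, direction = c("forward", "backward"),
                          ctx = thermo_context()) {
  stopifnot(inherits(samples, "window_samples"))
  direction <- match.arg(direction)
  u <- if (direction == "forward") samples$forward_du else samples$backward_du
  if (length(u) < 2L) {
    stop("exp_estimator needs >= 2 samples in the requested direction",
         call. = FALSE)
  }
  kT <- ctx$kT
  s <- if (direction == "forward") -1 else 1
  x <- s * u / kT
  # work on exp(x - max) to avoid overflow; ratios are scale-free
  y <- exp(x - max(x))
  m <- mean(y)
  dg <- s * kT * (max(x) + log(m))
  se <- kT * stats::sd(y) / (m * sqrt(length(y)))
  free_energy_estimate(dg, se, "exp",
                       lambda_low = samples$lambda_low,
                       lambda_high = samples$lambda_high)
}

#' Bennett acceptance ratio (BAR) estimator
#'
#' Statistically optimal two-state estimator combining forward and backward
#' energy-difference samples. The estimate solves the self-consistency
#' condition
#' \deqn{\sum_{i \in F} f\!\big((\Delta U_i - C)/kT\big) =
#'       \sum_{j \in B} f\!\big((C - \Delta U_j)/kT\big)}
#' with \eqn{f(x) = 1/(1+e^x)} and \eqn{C = \Delta G - kT\ln(n_F/n_B)},
#' solved for \eqn{\Delta G} by bracketed root finding on
#' \[-50, +50\] kcal/mol (the condition is monotone in \eqn{\Delta G}).
#' The standard error is the standard BAR asymptotic variance evaluated at
#' the solution. If the forward and backward sample ranges do not overlap
#' the estimate is flagged (`overlap_warning`), since the variance formula
#' is then unreliable.
#'
#' @param samples A [window_samples()] object with both directions non-empty.
#' @param ctx A [thermo_context()].
#' @param tol Convergence tolerance on \eqn{\Delta G}, kcal/mol.
#' @param max_iter Maximum root-finder iterations.
#' @return A [free_energy_estimate()] with `method = "bar"`.
#' @export
bar_estimator <- function(samples, ctx = thermo_context(),
                          tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(samples, "window_samples"))
  uF <- samples$forward_du
  uB <- samples$backward_du
  if (length(uF) == 0L || length(uB) == 0L) {
    stop("bar_estimator needs samples in both directions", call. = FALSE)
  }
  kT <- ctx$kT
  wF <- uF / kT
  wB <- uB / kT
  M <- log(length(wF) / length(wB))
  # monotone increasing in g = dG/kT; log-sum form for numerical stability;
  # C is Bennett's variance-optimal shift C = dG - kT ln(nF/nB)
  h <- function(g) {
    C <- g - M
    log_mean_exp(-log1pexp(wF - C)) + log(length(wF)) -
      log_mean_exp(-log1pexp(C - wB)) - log(length(wB))
  }
  lo <- -50 / kT; hi <- 50 / kT
  if (h(lo) * h(hi) > 0) {
    stop("BAR self-consistency equation has no root in [-50, 50] kcal/mol ",
         "(no phase-space overlap?)", call. = FALSE)
  }
  root <- withCallingHandlers(
    stats::uniroot(h, c(lo, hi), tol = tol / kT,
                   maxiter = as.integer(max_iter)),
    warning = function(w) {
      stop(sprintf("BAR root finding did not converge in %d iterations (%s)",
                   max_iter, conditionMessage(w)), call. = FALSE)
    })
  g <- root$root
  C <- g - M
  fF <- 1 / (1 + exp(wF - C))
  fB <- 1 / (1 + exp(C - wB))
  var_g <- (mean(fF^2) / mean(fF)^2 - 1) / length(fF) +
    (mean(fB^2) / mean(fB)^2 - 1) / length(fB)
  overlap <- !(max(wF) >= min(wB) && max(wB) >= min(wF))
  free_energy_estimate(g * kT, kT * sqrt(max(var_g, 0)), "bar",
                       lambda_low = samples$lambda_low,
                       lambda_high = samples$lambda_high,
                       overlap_warning = overlap)
}

#' Sum per-window free energies along a lambda path
#'
#' Stagewise total over contiguous windows: free energies add, standard
#' errors combine in quadrature under window independence. Windows must tile
#' the lambda path without gaps or overlaps.
#'
#' @param per_window List of [free_energy_estimate()]s, each carrying its
#'   window bounds.
#' @return A [free_energy_estimate()] for the whole path.
#' @export
combine_windows <- function(per_window) {
  stopifnot(is.list(per_window), length(per_window) >= 1L)
  ok <- vapply(per_window, inherits, logical(1), "free_energy_estimate")
  if (!all(ok)) {
    stop("per_window must be a list of free_energy_estimate objects",
         call. = FALSE)
  }
  lo <- vapply(per_window, function(e) {
    if (is.null(e$lambda_low)) NA_real_ else e$lambda_low
  }, numeric(1))
  hi <- vapply(per_window, function(e) {
    if (is.null(e$lambda_high)) NA_real_ else e$lambda_high
  }, numeric(1))
  if (anyNA(lo) || anyNA(hi)) {
    stop("window estimates must carry lambda bounds for contiguity checking",
         call. = FALSE)
  }
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  if (length(lo) > 1L && any(abs(hi[-length(hi)] - lo[-1L]) > 1e-9)) {
    stop("windows do not tile the lambda path (gap or overlap)",
         call. = FALSE)
  }
  dg <- sum(vapply(per_window, `[[`, numeric(1), "delta_g"))
  se <- sqrt(sum(vapply(per_window, `[[`, numeric(1), "stderr")^2))
  warn <- any(vapply(per_window, `[[`, logical(1), "overlap_warning"))
  methods <- unique(vapply(per_window, `[[`, character(1), "method"))
  free_energy_estimate(dg, se,
                       if (length(methods) == 1L) methods else "combined",
                       n_windows = length(per_window),
                       lambda_low = lo[1L], lambda_high = hi[length(hi)],
                       overlap_warning = warn)
}

#' Combine decoupling and recoupling stage totals
#'
#' The two stages of a double-annihilation protocol estimate the same
#' transformation in opposite orientations (the recoupling total is assumed
#' already sign-normalized to the binding direction). The combined estimate
#' is their mean, and the quoted standard error is half the absolute
#' difference between the two stages.
#'
#' @param decoupling,recoupling [free_energy_estimate()]s for the two stages.
#' @return A [free_energy_estimate()] with `method = "combined"`.
#' @examples
#' d <- free_energy_estimate(-8.5, 0.1, "bar")
#' r <- free_energy_estimate(-8.9, 0.1, "bar")
#' bidirectional_combine(d, r)  # -8.7 +/- 0.2
#' @export
bidirectional_combine <- function(decoupling, recoupling) {
  stopifnot(inherits(decoupling, "free_energy_estimate"),
            inherits(recoupling, "free_energy_estimate"))
  free_energy_estimate(
    (decoupling$delta_g + recoupling$delta_g) / 2,
    abs(decoupling$delta_g - recoupling$delta_g) / 2,
    "combined",
    n_windows = max(decoupling$n_windows, recoupling$n_windows),
    overlap_warning = decoupling$overlap_warning || recoupling$overlap_warning
  )
}

#' Estimate a stage total from a list of window samples
#'
#' Convenience wrapper: applies [bar_estimator()] (or [exp_estimator()]) to
#' every window and sums with [combine_windows()]. Replicate runs of the
#' same stage may be pooled beforehand with [pool_window_samples()].
#'
#' @param windows List of [window_samples()].
#' @param method `"bar"` (default), `"exp-forward"` or `"exp-backward"`.
#' @param ctx A [thermo_context()].
#' @return A [free_energy_estimate()] for the stage.
#' @export
estimate_stage <- function(windows,
                           method = c("bar", "exp-forward", "exp-backward"),
                           ctx = thermo_context()) {
  method <- match.arg(method)
  per <- lapply(windows, function(w) {
    switch(method,
           "bar" = bar_estimator(w, ctx),
           "exp-forward" = exp_estimator(w, "forward", ctx),
           "exp-backward" = exp_estimator(w, "backward", ctx))
  })
  combine_windows(per)
}

#' Pool replicate runs of the same windows
#'
#' Concatenates forward and backward samples of matching windows across
#' k >= 1 replicate runs before estimation, the convention for combining
#' repeated decoupling (or recoupling) stages into one data set.
#'
#' @param runs List of window lists; windows are matched by
#'   (`lambda_low`, `lambda_high`).
#' @return A single list of pooled [window_samples()].
#' @export
pool_window_samples <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  key <- function(w) sprintf("%.9f_%.9f", w$lambda_low, w$lambda_high)
  pooled <- list()
  for (run in runs) {
    for (w in run) {
      k <- key(w)
      if (is.null(pooled[[k]])) {
        pooled[[k]] <- w
      } else {
        pooled[[k]]$forward_du <- c(pooled[[k]]$forward_du, w$forward_du)
        pooled[[k]]$backward_du <- c(pooled[[k]]$backward_du, w$backward_du)
      }
    }
  }
  pooled <- pooled[order(vapply(pooled, `[[`, numeric(1), "lambda_low"))]
  names(pooled) <- NULL
  pooled
}
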