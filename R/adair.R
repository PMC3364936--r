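#' Parameters of the two-site pore-block model
#'
#' The pore holds up to two anesthetic molecules, binding sequentially with
#' stepwise dissociation constants `kd1` (empty pore -> one bound) and `kd2`
#' (one bound -> two bound). A bound dimer always blocks conduction; a
#' monomer blocks with probability `alpha`, the model's free parameter for
#' the unknown relationship between single occupancy and function.
#'
#' @param kd1,kd2 Stepwise dissociation constants, in the same unit as the
#'   dose axis; > 0.
#' @param alpha Monomer block probability, in \[0, 1\].
#' @return An object of class `pore_block_params`.
#' @examples
#' pore_block_params(2.9, 83, alpha = 1)  # closed-pore isoflurane, uM
#' @export
pore_block_params <- function(kd1, kd2, alpha = 1) {
  stopifnot(is.numeric(kd1), is.numeric(kd2), is.numeric(alpha),
            length(kd1) == 1L, length(kd2) == 1L, length(alpha) == 1L)
  if (!is.finite(kd1) || kd1 <= 0 || !is.finite(kd2) || kd2 <= 0) {
    stop("kd1 and kd2 must be positive and finite", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  structure(list(kd1 = kd1, kd2 = kd2, alpha = alpha),
            class = "pore_block_params")
}

#' @export
print.pore_block_params <- function(x, ...) {
  cat(sprintf("Pore-block parameters: Kd1 = %g, Kd2 = %g, alpha = %g\n",
              x$kd1, x$kd2, x$alpha))
  invisible(x)
}

#' Adair occupancy distribution at one concentration
#'
#' Probabilities of finding 0, 1 or 2 ligands in the pore at free ligand
#' concentration `conc`, from the sequential-binding partition function
#' \eqn{Z = 1 + x/K_{d1} + x^2/(K_{d1} K_{d2})}.
#'
#' @param params A [pore_block_params()].
#' @param conc Ligand concentration(s), same unit as the constants; >= 0.
#' @return A data frame with columns `conc`, `p0`, `p1`, `p2`
#'   (rows sum to 1).
#' @export
occupancy <- function(params, conc) {
  stopifnot(inherits(params, "pore_block_params"), is.numeric(conc))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("conc must be non-negative and finite", call. = FALSE)
  }
  t1 <- conc / params$kd1
  t2 <- conc^2 / (params$kd1 * params$kd2)
  z <- 1 + t1 + t2
  data.frame(conc = conc, p0 = 1 / z, p1 = t1 / z, p2 = t2 / z)
}

#' Fractional inhibition by pore block
#'
#' The modified Adair dose-response: a dimer blocks with probability 1, a
#' monomer with probability `alpha`, so the fractional inhibition is
#' \eqn{I = \alpha p_1 + p_2}. It is 0 at zero concentration, increases
#' strictly with concentration, and saturates at 1.
#'
#' @inheritParams occupancy
#' @return Numeric vector of inhibition fractions in \[0, 1\].
#' @examples
#' p <- pore_block_params(2.9, 83, alpha = 1)
#' inhibition(p, c(0, 2.8, 1e5))
#' @export
inhibition <- function(params, conc) {
  occ <- occupancy(params, conc)
  params$alpha * occ$p1 + occ$p2
}

#' Closed-form IC50 at the extreme monomer-block probabilities
#'
#' At the bounds of the monomer block probability the half-inhibition
#' condition reduces to a quadratic with one positive root:
#' \eqn{\alpha = 1}: \eqn{x^2 + K_{d2} x - K_{d1} K_{d2} = 0};
#' \eqn{\alpha = 0}: \eqn{x^2 - K_{d2} x - K_{d1} K_{d2} = 0}.
#'
#' @param params A [pore_block_params()] whose `alpha` is exactly 0 or 1.
#' @return IC50 in the unit of the dissociation constants.
#' @examples
#' ic50_closed_form(pore_block_params(2.9, 83, alpha = 1))  # ~2.8
#' ic50_closed_form(pore_block_params(2.9, 83, alpha = 0))  # ~86
#' @export
ic50_closed_form <- function(params) {
  stopifnot(inherits(params, "pore_block_params"))
  if (params$alpha != 0 && params$alpha != 1) {
    stop("closed forms exist only for alpha exactly 0 or 1; ",
         "use ic50_exact() for intermediate alpha", call. = FALSE)
  }
  k1 <- params$kd1; k2 <- params$kd2
  disc <- sqrt(k2^2 + 4 * k1 * k2)
  if (params$alpha == 1) (-k2 + disc) / 2 else (k2 + disc) / 2
}

#' IC50 by root finding for any monomer-block probability
#'
#' Solves `inhibition(conc) = 1/2` by bracketed bisection. A root always
#' exists and is unique because the inhibition curve rises continuously and
#' strictly from 0 to 1. The upper bracket is grown geometrically (factor
#' 10) from `kd1` until the curve exceeds one half.
#'
#' @param params A [pore_block_params()].
#' @param tol Relative tolerance on the root.
#' @return IC50 in the unit of the dissociation constants.
#' @export
ic50_exact <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "pore_block_params"), tol > 0)
  f <- function(x) inhibition(params, x) - 0.5
  lo <- 1e-12 * params$kd1
  hi <- params$kd1
  while (f(hi) < 0) hi <- hi * 10
  stats::uniroot(f, c(lo, hi), tol = tol * params$kd1)$root
}

#' Predicted IC50 range over the physical span of alpha
#'
#' The monomer block probability is bounded by 0 and 1; the corresponding
#' IC50s bound the model's prediction. `alpha = 1` gives the lower end
#' (monomers already block), `alpha = 0` the upper (a dimer is required).
#'
#' @param kd1,kd2 Stepwise dissociation constants, > 0.
#' @return Named numeric vector `c(low = ..., high = ...)`, `low < high`.
#' @examples
#' ic50_range(2.9, 83)   # ~ (2.8, 86): closed-pore isoflurane
#' ic50_range(1.5, 2.9)  # ~ (1.1, 4.0): open-pore propofol
#' @export
ic50_range <- function(kd1, kd2) {
  c(low = ic50_closed_form(pore_block_params(kd1, kd2, alpha = 1)),
    high = ic50_closed_form(pore_block_params(kd1, kd2, alpha = 0)))
}

#' Dose-response observations
#'
#' @param concentrations Strictly increasing positive concentrations.
#' @param inhibition Observed inhibition fractions in \[0, 1\], same length.
#' @return An object of class `dose_response` (also a data frame).
#' @export
dose_response <- function(concentrations, inhibition) {
  stopifnot(is.numeric(concentrations), is.numeric(inhibition),
            length(concentrations) == length(inhibition))
  if (any(concentrations <= 0) || is.unsorted(concentrations,
                                              strictly = TRUE)) {
    stop("concentrations must be positive and strictly increasing",
         call. = FALSE)
  }
  if (any(inhibition < 0 | inhibition > 1)) {
    stop("inhibition values must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(concentrations = concentrations,
                       inhibition = inhibition),
            class = c("dose_response", "data.frame"))
}

#' Fit the pore-block model to a dose-response curve
#'
#' Least-squares estimation of (Kd1, Kd2, alpha) from
#' concentration/inhibition pairs, by Levenberg-Marquardt on log-scaled
#' dissociation constants (alpha on a clamped linear scale). A
#' deterministic multistart grid guards against local minima; the best
#' converged start is returned.
#'
#' @param data A [dose_response()] or data frame with columns
#'   `concentrations`, `inhibition`.
#' @param fix_alpha Optional: hold alpha fixed at this value.
#' @param kd_bounds Positive length-2 bounds on both constants
#'   (default spans 1e-4 to 1e4 times the median concentration).
#' @param n_starts Grid points per dimension for the multistart.
#' @return A [pore_block_params()] with extra fields `residual_norm`
#'   (root-mean-square residual), `converged`, and `n_obs`.
#' @examples
#' truth <- pore_block_params(2.9, 83, alpha = 1)
#' conc <- 10^seq(log10(0.1), log10(1000), length.out = 12)
#' fit <- fit_dose_response(dose_response(conc, inhibition(truth, conc)))
#' @export
fit_dose_response <- function(data, fix_alpha = NULL, kd_bounds = NULL,
                              n_starts = 3L) {
  if (!is.data.frame(data) ||
      !all(c("concentrations", "inhibition") %in% names(data))) {
    stop("data must have columns 'concentrations' and 'inhibition'",
         call. = FALSE)
  }
  x <- data$concentrations
  y <- data$inhibition
  if (length(x) < 4L) {
    stop("need at least 4 dose-response points", call. = FALSE)
  }
  if (all(y < 1e-6) || all(y > 1 - 1e-6)) {
    stop("degenerate dose-response data (all ~0 or all ~1); ",
         "the curve is uninformative", call. = FALSE)
  }
  if (is.null(kd_bounds)) {
    med <- stats::median(x)
    kd_bounds <- c(1e-4 * med, 1e4 * med)
  }
  stopifnot(length(kd_bounds) == 2L, all(kd_bounds > 0),
            kd_bounds[1] < kd_bounds[2])
  lb <- log(kd_bounds)
  clamp01 <- function(a) pmin(1, pmax(0, a))
  resid_fn <- function(par) {
    p <- pore_block_params(exp(min(max(par[1], lb[1]), lb[2])),
                           exp(min(max(par[2], lb[1]), lb[2])),
                           if (is.null(fix_alpha)) clamp01(par[3])
                           else fix_alpha)
    inhibition(p, x) - y
  }
  # deterministic multistart: log-spaced kd grid around the dose span
  kd_grid <- exp(seq(lb[1] + 0.1 * diff(lb), lb[2] - 0.1 * diff(lb),
                     length.out = n_starts))
  alpha_grid <- if (is.null(fix_alpha)) c(0.25, 0.75) else fix_alpha
  best <- NULL
  for (k1 in kd_grid) for (k2 in kd_grid) for (a in alpha_grid) {
    start <- if (is.null(fix_alpha)) c(log(k1), log(k2), a)
             else c(log(k1), log(k2))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || ss < best$ss - 1e-15) {
      best <- list(par = fit$par, ss = ss,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    stop("dose-response fit failed from every start", call. = FALSE)
  }
  out <- pore_block_params(
    exp(min(max(best$par[1], lb[1]), lb[2])),
    exp(min(max(best$par[2], lb[1]), lb[2])),
    if (is.null(fix_alpha)) clamp01(best$par[3]) else fix_alpha)
  out$residual_norm <- sqrt(best$ss / length(x))
  out$converged <- best$converged
  out$n_obs <- length(x)
  out
}
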