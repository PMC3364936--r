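#' Ground truth for synthetic FEP window samples
#'
#' Defines a per-window true free-energy profile along a lambda schedule,
#' with Gaussian work fluctuations of standard deviation `sigma` per
#' window. By default the total true free energy is spread evenly over the
#' 25 windows of the default schedule.
#'
#' @param total_delta_g Total true free energy over the path, kcal/mol.
#' @param schedule A [make_lambda_schedule()].
#' @param sigma Per-window work standard deviation, kcal/mol, > 0.
#' @param n_samples Samples per direction per window.
#' @param seed Integer seed.
#' @return An object of class `fep_ground_truth` with a `delta_g_profile`
#'   of one value per window.
#' @export
fep_ground_truth <- function(total_delta_g = -7.6,
                             schedule = make_lambda_schedule(),
                             sigma = 1, n_samples = 5000, seed = 1) {
  stopifnot(inherits(schedule, "lambda_schedule"), sigma > 0,
            n_samples >= 2)
  structure(
    list(delta_g_profile = rep(total_delta_g / schedule$n_windows,
                               schedule$n_windows),
         schedule = schedule, sigma = sigma,
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "fep_ground_truth"
  )
}

#' Generate Crooks-consistent FEP window samples
#'
#' For each window with true free energy \eqn{\Delta G} the forward energy
#' differences are drawn from \eqn{N(\Delta G + \sigma^2/2kT, \sigma^2)}
#' and the backward ones from \eqn{N(\Delta G - \sigma^2/2kT, \sigma^2)}.
#' This Gaussian pair satisfies the Crooks fluctuation relation exactly, so
#' both one-sided exponential averages and the Bennett estimator converge
#' to \eqn{\Delta G}; recovery of the known truth is therefore a valid test
#' of the whole estimation pipeline.
#'
#' @param truth A [fep_ground_truth()].
#' @param ctx A [thermo_context()].
#' @return List of [window_samples()], one per window of the schedule.
#' @export
gen_fep_samples <- function(truth, ctx = thermo_context()) {
  stopifnot(inherits(truth, "fep_ground_truth"))
  set.seed(truth$seed)
  lam <- truth$schedule$values
  shift <- truth$sigma^2 / (2 * ctx$kT)
  lapply(seq_len(truth$schedule$n_windows), function(i) {
    dg <- truth$delta_g_profile[i]
    window_samples(
      lambda_low = lam[i], lambda_high = lam[i + 1],
      forward_du = stats::rnorm(truth$n_samples, dg + shift, truth$sigma),
      backward_du = stats::rnorm(truth$n_samples, dg - shift, truth$sigma)
    )
  })
}

#' Toy pore model for ligand-hopping trajectories
#'
#' A one-dimensional multi-well potential along the pore axis: Gaussian
#' wells at the site centers with given depths and widths, hard walls at
#' the pore ends, and (for two ligands) a soft Gaussian excluded-volume
#' repulsion.
#'
#' @param site_centers Well centers on z, angstroms.
#' @param well_depths Well depths, kcal/mol (positive = attractive).
#' @param well_widths Gaussian widths of the wells, angstroms.
#' @param pore_span Length-2 interval of allowed z.
#' @param n_ligands 1 or 2.
#' @param n_frames Number of recorded frames.
#' @param repulsion_height Height of the pair repulsion, kcal/mol.
#' @param repulsion_width Width of the pair repulsion, angstroms.
#' @param seed Integer seed.
#' @return An object of class `pore_toy_model`.
#' @export
pore_toy_model <- function(site_centers = c(0, 7),
                           well_depths = c(3, 3),
                           well_widths = c(1.5, 1.5),
                           pore_span = c(-8, 15),
                           n_ligands = 1, n_frames = 20000,
                           repulsion_height = 5, repulsion_width = 2.5,
                           seed = 1) {
  stopifnot(length(site_centers) == length(well_depths),
            length(well_depths) == length(well_widths),
            all(well_widths > 0), n_ligands %in% c(1L, 2L),
            n_frames >= 100)
  if (any(site_centers < pore_span[1]) || any(site_centers > pore_span[2])) {
    stop("site centers must lie within the pore span", call. = FALSE)
  }
  structure(
    list(site_centers = site_centers, well_depths = well_depths,
         well_widths = well_widths, pore_span = pore_span,
         n_ligands = as.integer(n_ligands), n_frames = as.integer(n_frames),
         repulsion_height = repulsion_height,
         repulsion_width = repulsion_width, seed = as.integer(seed)),
    class = "pore_toy_model"
  )
}

# potential energy of the toy pore (kcal/mol) for a vector of z positions
toy_pore_energy <- function(model, z) {
  u <- 0
  for (zi in z) {
    u <- u - sum(model$well_depths *
                   exp(-(zi - model$site_centers)^2 /
                         (2 * model$well_widths^2)))
  }
  if (length(z) == 2L) {
    u <- u + model$repulsion_height *
      exp(-((z[1] - z[2]) / model$repulsion_width)^2)
  }
  u
}

#' Sample ligand positions in the toy pore by Metropolis Monte Carlo
#'
#' Samples the Boltzmann distribution of the toy pore potential with
#' single-particle moves and hard walls at the pore ends. Proposals mix
#' local displacements with occasional uniform long-range jumps
#' (probability `jump_prob`); both are symmetric, so plain Metropolis
#' acceptance targets the Boltzmann distribution, and the jumps decorrelate
#' hopping between well-separated sites. The local step size is auto-tuned
#' toward 30-50% acceptance during a burn-in of 10% of `n_frames`, which
#' is then discarded. Deterministic under the model's seed.
#'
#' @param model A [pore_toy_model()].
#' @param ctx A [thermo_context()].
#' @param jump_prob Probability of proposing a uniform jump across the
#'   pore span instead of a local step.
#' @return Matrix of z positions, `n_frames` rows by `n_ligands` columns;
#'   attribute `acceptance` records the post-burn-in acceptance rate of
#'   the local moves.
#' @export
gen_pore_trajectory <- function(model, ctx = thermo_context(),
                                jump_prob = 0.1) {
  stopifnot(inherits(model, "pore_toy_model"))
  set.seed(model$seed)
  kT <- ctx$kT
  nl <- model$n_ligands
  span <- model$pore_span
  z <- seq(span[1], span[2], length.out = nl + 2)[2:(nl + 1)]
  u <- toy_pore_energy(model, z)
  step <- 1.0
  burn <- max(100L, as.integer(0.1 * model$n_frames))
  out <- matrix(NA_real_, nrow = model$n_frames, ncol = nl)
  acc <- 0L; tries <- 0L
  for (it in seq_len(burn + model$n_frames)) {
    for (j in seq_len(nl)) {
      znew <- z
      jump <- stats::runif(1) < jump_prob
      znew[j] <- if (jump) {
        stats::runif(1, span[1], span[2])
      } else {
        z[j] + stats::runif(1, -step, step)
      }
      if (!jump) tries <- tries + 1L
      if (znew[j] >= span[1] && znew[j] <= span[2]) {
        unew <- toy_pore_energy(model, znew)
        if (unew <= u || stats::runif(1) < exp(-(unew - u) / kT)) {
          z <- znew; u <- unew
          if (!jump) acc <- acc + 1L
        }
      }
    }
    if (it <= burn) {
      # retune every 50 sweeps toward the 30-50% acceptance band
      if (it %% 50L == 0L && tries > 0L) {
        rate <- acc / tries
        if (rate < 0.30) step <- step * 0.8
        if (rate > 0.50) step <- step * 1.25
        acc <- 0L; tries <- 0L
      }
      if (it == burn) { acc <- 0L; tries <- 0L }
    } else {
      out[it - burn, ] <- z
    }
  }
  attr(out, "acceptance") <- if (tries > 0) acc / tries else NA_real_
  attr(out, "step") <- step
  out
}

#' Generate a Gaussian-mixture pore-distance series
#'
#' Emulates the bimodal distribution of M2 pair distances from an
#' unrestrained trajectory: a metastable open basin (around 20 A) and a
#' more populated collapsed state (below 19 A).
#'
#' @param open_center,collapsed_center Mode locations, angstroms.
#' @param weights Length-2 mixture weights (collapsed, open), summing to 1.
#' @param sigmas Length-2 mode standard deviations, angstroms.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Numeric vector of distance samples.
#' @export
gen_distance_series <- function(open_center = 20, collapsed_center = 18.5,
                                weights = c(0.7, 0.3),
                                sigmas = c(0.3, 0.25),
                                n = 1e5, seed = 1) {
  stopifnot(length(weights) == 2L, abs(sum(weights) - 1) < 1e-9,
            all(weights >= 0), all(sigmas > 0), n >= 1)
  set.seed(seed)
  comp <- stats::rbinom(n, 1, weights[2])  # 1 = open mode
  mu <- ifelse(comp == 1, open_center, collapsed_center)
  sd <- ifelse(comp == 1, sigmas[2], sigmas[1])
  stats::rnorm(n, mu, sd)
}

#' Generate a noisy dose-response curve from known parameters
#'
#' Evaluates the pore-block model on a log-spaced concentration grid and
#' adds truncated Gaussian noise (clipped to \[0, 1\]).
#'
#' @param params A [pore_block_params()] ground truth.
#' @param n_points Number of concentrations.
#' @param conc_span Length-2 span of the grid; must cover the model's IC50.
#' @param noise_sd Noise standard deviation on the inhibition fraction.
#' @param seed Integer seed.
#' @return A [dose_response()].
#' @export
gen_dose_response <- function(params, n_points = 12,
                              conc_span = NULL, noise_sd = 0, seed = 1) {
  stopifnot(inherits(params, "pore_block_params"), n_points >= 2,
            noise_sd >= 0)
  ic50 <- ic50_exact(params)
  if (is.null(conc_span)) conc_span <- c(ic50 / 30, ic50 * 30)
  if (conc_span[1] > ic50 || conc_span[2] < ic50) {
    stop("conc_span must cover the model's IC50", call. = FALSE)
  }
  set.seed(seed)
  conc <- 10^seq(log10(conc_span[1]), log10(conc_span[2]),
                 length.out = n_points)
  y <- inhibition(params, conc)
  if (noise_sd > 0) {
    y <- pmin(1, pmax(0, y + stats::rnorm(n_points, 0, noise_sd)))
  }
  dose_response(conc, y)
}

#' Build an idealized pentameric M2 helix bundle
#'
#' Synthetic C5-symmetric alpha-carbon model of the five pore-lining M2
#' helices (residues 223-245), for testing geometric operations: helices
#' are vertical rods on a ring of the given radius, with the two anchor
#' tyrosine positions (226/244) included. Coordinates are exact, so
#' centers and distances have closed-form values.
#'
#' @param radius Ring radius of the helix axes, angstroms.
#' @param rise Vertical rise per residue, angstroms.
#' @param z0 z of residue 223.
#' @param chains Five chain ids in ring order.
#' @param perturb Optional named list `list(chain =, dx =, dy =, dz =)`
#'   displacing one whole subunit (to emulate local collapse).
#' @return A [structure_model()].
#' @export
synthetic_pentamer <- function(radius = 10, rise = 1.5, z0 = 0,
                               chains = c("A", "B", "C", "D", "E"),
                               perturb = NULL) {
  stopifnot(length(chains) == 5L, radius > 0)
  resnos <- 223:245
  resnames <- ifelse(resnos %in% c(226, 244), "TYR",
                     ifelse(resnos %in% c(232, 239), "ILE", "ALA"))
  rows <- list()
  for (i in seq_along(chains)) {
    theta <- 2 * pi * (i - 1) / 5
    x <- radius * cos(theta)
    y <- radius * sin(theta)
    rows[[i]] <- data.frame(
      chain = chains[i], resno = resnos, resid = resnames, elety = "CA",
      x = x, y = y, z = z0 + rise * (resnos - min(resnos)),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(perturb)) {
    sel <- atoms$chain == perturb$chain
    atoms$x[sel] <- atoms$x[sel] + (perturb$dx %||% 0)
    atoms$y[sel] <- atoms$y[sel] + (perturb$dy %||% 0)
    atoms$z[sel] <- atoms$z[sel] + (perturb$dz %||% 0)
  }
  structure_model(atoms, subunit_order = chains)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
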