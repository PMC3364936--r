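# Independent reference implementations used as oracles. These stay
# deliberately separate from the package's code paths: bar_reference solves
# Bennett's identity by damped fixed-point iteration (the package uses
# bracketed root finding on the log-sum form).

bar_reference <- function(uF, uB, kT, tol = 1e-13, max_iter = 50000) {
  M <- log(length(uF) / length(uB))
  dg <- 0
  for (i in seq_len(max_iter)) {
    C <- dg - kT * M
    mF <- mean(1 / (1 + exp((uF - C) / kT)))
    mB <- mean(1 / (1 + exp((C - uB) / kT)))
    dg_new <- C - kT * (log(mF) - log(mB))
    if (abs(dg_new - dg) < tol) return(dg_new)
    dg <- dg_new
  }
  dg
}

# Crooks-consistent Gaussian sample pair with known true free energy
crooks_window <- function(truth, sigma, n, seed,
                          kT = thermo_context()$kT) {
  set.seed(seed)
  window_samples(0, 1,
                 forward_du = rnorm(n, truth + sigma^2 / (2 * kT), sigma),
                 backward_du = rnorm(n, truth - sigma^2 / (2 * kT), sigma))
}

# batch-means standard error for a (possibly autocorrelated) MCMC series
batch_se <- function(x, n_batches = 40) {
  bm <- tapply(x, cut(seq_along(x), n_batches), mean)
  stats::sd(bm) / sqrt(n_batches)
}

# Calibrate the second well depth of a two-well toy pore so the true
# Boltzmann population of the first site region is exactly `split`.
# Independent oracle: direct numerical integration of exp(-U/kT).
calibrate_two_well_depth <- function(split = 0.7, depth1 = 4, width = 1,
                                     centers = c(0, 7), span = c(-8, 15),
                                     divide = 3.5,
                                     kT = thermo_context()$kT) {
  pop1_frac <- function(depth2) {
    u <- function(z) {
      -(depth1 * exp(-(z - centers[1])^2 / (2 * width^2)) +
          depth2 * exp(-(z - centers[2])^2 / (2 * width^2)))
    }
    w <- function(z) exp(-u(z) / kT)
    a <- stats::integrate(w, span[1], divide)$value
    b <- stats::integrate(w, divide, span[2])$value
    a / (a + b)
  }
  stats::uniroot(function(d2) pop1_frac(d2) - split,
                 c(0.2, depth1), tol = 1e-10)$root
}

# minimal hand-rolled PDB ATOM writer (fixed-width columns) so the package
# reader is exercised against externally produced standard-format text
write_minimal_pdb <- function(model, path) {
  at <- model$atoms
  lines <- vapply(seq_len(nrow(at)), function(i) {
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, sprintf(" %-3s", at$elety[i]), at$resid[i], at$chain[i],
            at$resno[i], at$x[i], at$y[i], at$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
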