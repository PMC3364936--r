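#' Thermodynamic context for binding free-energy bookkeeping
#'
#' Bundles the temperature, Boltzmann constant and standard-state volume used
#' throughout the package. The standard-state volume is the free volume per
#' molecule in a 1 M ideal solution (1661 \eqn{\text{\AA}^3}), the reference
#' against which restraint-volume corrections are taken.
#'
#' @param temperature Simulation/assay temperature in kelvin. Default 300 K,
#'   the usual thermostat setting for membrane-protein simulations.
#' @param boltzmann_constant Boltzmann constant in kcal/(mol K).
#' @param standard_volume Standard-state volume in \eqn{\text{\AA}^3} per
#'   molecule at 1 M.
#' @return An object of class `thermo_context` with fields `temperature`,
#'   `boltzmann_constant`, `standard_volume` and the derived `kT` (kcal/mol).
#' @examples
#' ctx <- thermo_context()
#' ctx$kT  # ~0.5962 kcal/mol at 300 K
#' @export
thermo_context <- function(temperature = 300,
                           boltzmann_constant = 1.9872e-3,
                           standard_volume = 1661) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature))
  if (temperature <= 0) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  if (abs(boltzmann_constant - 1.9872e-3) > 1e-6) {
    stop("boltzmann_constant must equal 1.9872e-3 kcal/(mol K) to 4 ",
         "significant figures", call. = FALSE)
  }
  if (standard_volume <= 0) {
    stop("standard_volume must be positive", call. = FALSE)
  }
  structure(
    list(temperature = temperature,
         boltzmann_constant = boltzmann_constant,
         standard_volume = standard_volume,
         kT = boltzmann_constant * temperature),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat("Thermodynamic context\n")
  cat(sprintf("  T            : %g K\n", x$temperature))
  cat(sprintf("  kT           : %.4g kcal/mol\n", x$kT))
  cat(sprintf("  V0 (1 M std) : %g A^3/molecule\n", x$standard_volume))
  invisible(x)
}

#' Entropic restraint-volume correction
#'
#' Free-energy cost of confining a ligand to the volume enclosed by a
#' flat-bottom ("square-well") binding-site restraint, relative to the free
#' volume it would have in a 1 M standard-state solution:
#' \deqn{\Delta G_V = -kT \ln(V_{site}/V_0).}
#' Negative when the restraint volume exceeds the standard-state volume
#' (the restraint is then less confining than 1 M solution).
#'
#' @param site_volume Volume enclosed by the restraint, \eqn{\text{\AA}^3}.
#' @param ctx A [thermo_context()].
#' @return Correction in kcal/mol.
#' @examples
#' ctx <- thermo_context()
#' restraint_volume_term(1661, ctx)                # 0: equals V0
#' restraint_volume_term(pi * 5^2 * 35, ctx)       # cylindrical pore restraint
#' @export
restraint_volume_term <- function(site_volume, ctx = thermo_context()) {
  stopifnot(is.numeric(site_volume))
  if (any(!is.finite(site_volume)) || any(site_volume <= 0)) {
    stop("site_volume must be positive and finite", call. = FALSE)
  }
  -ctx$kT * log(site_volume / ctx$standard_volume)
}

#' Symmetry-number correction to a binding free energy
#'
#' Penalty for the loss of orientational symmetry upon binding,
#' \eqn{+kT \ln \sigma} for a ligand of symmetry number \eqn{\sigma}.
#' For a twofold-symmetric ligand (propofol, ethanol) this contributes
#' about 0.4 kcal/mol at 300 K, i.e. a factor of two in affinity; an
#' asymmetric ligand (isoflurane, \eqn{\sigma = 1}) contributes nothing.
#'
#' @param sigma_ligand Integer symmetry number, >= 1.
#' @param ctx A [thermo_context()].
#' @return Penalty in kcal/mol (non-negative).
#' @export
symmetry_term <- function(sigma_ligand, ctx = thermo_context()) {
  stopifnot(is.numeric(sigma_ligand))
  if (any(sigma_ligand < 1) || any(sigma_ligand != round(sigma_ligand))) {
    stop("sigma_ligand must be an integer >= 1", call. = FALSE)
  }
  ctx$kT * log(sigma_ligand)
}

#' Per-site free-energy components of absolute binding
#'
#' Container for the terms entering the total microscopic binding free
#' energies: the ligand solvation free energy, the symmetry penalty, the
#' restraint-volume correction, and the alchemical insertion free energies
#' into the unoccupied site (first ligand) and, optionally, into the
#' singly-occupied site (second ligand).
#'
#' @param solvation Solvation free energy of the ligand, kcal/mol.
#' @param symmetry Symmetry penalty, kcal/mol (see [symmetry_term()]).
#' @param restraint_volume Restraint-volume correction, kcal/mol
#'   (see [restraint_volume_term()]).
#' @param site_insertion_1 Free energy of moving one ligand from vacuum into
#'   the unoccupied site, kcal/mol.
#' @param site_insertion_1_err Standard error of `site_insertion_1` (>= 0).
#' @param site_insertion_2 Optional: insertion into the singly-occupied site.
#' @param site_insertion_2_err Standard error of `site_insertion_2`.
#' @return An object of class `free_energy_components`.
#' @export
free_energy_components <- function(solvation, symmetry, restraint_volume,
                                   site_insertion_1,
                                   site_insertion_1_err = 0,
                                   site_insertion_2 = NULL,
                                   site_insertion_2_err = NULL) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(nm, " must be a single finite number", call. = FALSE)
    }
    x
  }
  solvation <- num1(solvation, "solvation")
  symmetry <- num1(symmetry, "symmetry")
  restraint_volume <- num1(restraint_volume, "restraint_volume")
  site_insertion_1 <- num1(site_insertion_1, "site_insertion_1")
  site_insertion_1_err <- num1(site_insertion_1_err, "site_insertion_1_err")
  if (site_insertion_1_err < 0) {
    stop("site_insertion_1_err must be >= 0", call. = FALSE)
  }
  if (!is.null(site_insertion_2)) {
    site_insertion_2 <- num1(site_insertion_2, "site_insertion_2")
    if (is.null(site_insertion_2_err)) site_insertion_2_err <- 0
    site_insertion_2_err <- num1(site_insertion_2_err, "site_insertion_2_err")
    if (site_insertion_2_err < 0) {
      stop("site_insertion_2_err must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(solvation = solvation, symmetry = symmetry,
         restraint_volume = restraint_volume,
         site_insertion_1 = site_insertion_1,
         site_insertion_1_err = site_insertion_1_err,
         site_insertion_2 = site_insertion_2,
         site_insertion_2_err = site_insertion_2_err),
    class = "free_energy_components"
  )
}

#' Convert a binding free energy to a dissociation constant
#'
#' Standard-state relation \eqn{K_d = (1\,\mathrm{M}) \exp(\Delta G / kT)}:
#' a more favourable (more negative) binding free energy gives a smaller
#' dissociation constant. Strictly increasing in `delta_g`.
#'
#' @param delta_g Binding free energy, kcal/mol.
#' @param ctx A [thermo_context()].
#' @return Dissociation constant in molar.
#' @examples
#' kd_from_free_energy(-7.6)  # ~2.9e-6 M at 300 K
#' @export
kd_from_free_energy <- function(delta_g, ctx = thermo_context()) {
  stopifnot(is.numeric(delta_g), all(is.finite(delta_g)))
  exp(delta_g / ctx$kT)
}

#' Convert a dissociation constant to a binding free energy
#'
#' Inverse of [kd_from_free_energy()]: \eqn{\Delta G = kT \ln(K_d / 1 M)}.
#'
#' @param kd Dissociation constant in molar, > 0.
#' @param ctx A [thermo_context()].
#' @return Binding free energy, kcal/mol.
#' @export
free_energy_from_kd <- function(kd, ctx = thermo_context()) {
  stopifnot(is.numeric(kd))
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop("kd must be positive and finite (molar)", call. = FALSE)
  }
  ctx$kT * log(kd)
}

#' Assemble total binding free energies and dissociation constants
#'
#' Combines the per-site components into the total microscopic free energies
#' of binding the first and (optionally) second ligand:
#' \deqn{\Delta G_{bind,n} = \Delta G_{FEP,n} - \Delta G_{solv}
#'   + \Delta G_V + \Delta G_{sym}}
#' where \eqn{\Delta G_{FEP,n}} is the vacuum-to-site insertion free energy.
#' The correction terms are treated as exact, so the standard error of each
#' total equals the standard error of its insertion term. Dissociation
#' constants follow from [kd_from_free_energy()].
#'
#' @param components A [free_energy_components()] object.
#' @param ctx A [thermo_context()].
#' @return An object of class `binding_result` with fields `delta_g_bind_1`,
#'   `delta_g_bind_1_err`, `kd1` (molar) and, when a second insertion term is
#'   present, `delta_g_bind_2`, `delta_g_bind_2_err`, `kd2`.
#' @export
combine_binding_free_energy <- function(components, ctx = thermo_context()) {
  if (!inherits(components, "free_energy_components")) {
    stop("components must be a free_energy_components object", call. = FALSE)
  }
  corr <- -components$solvation + components$restraint_volume +
    components$symmetry
  dg1 <- components$site_insertion_1 + corr
  out <- list(delta_g_bind_1 = dg1,
              delta_g_bind_1_err = components$site_insertion_1_err,
              kd1 = kd_from_free_energy(dg1, ctx),
              delta_g_bind_2 = NULL, delta_g_bind_2_err = NULL, kd2 = NULL,
              temperature = ctx$temperature)
  if (!is.null(components$site_insertion_2)) {
    dg2 <- components$site_insertion_2 + corr
    out$delta_g_bind_2 <- dg2
    out$delta_g_bind_2_err <- components$site_insertion_2_err
    out$kd2 <- kd_from_free_energy(dg2, ctx)
  }
  structure(out, class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat("Binding result (", x$temperature, " K)\n", sep = "")
  cat(sprintf("  dG_bind,1 = %.2f +/- %.2f kcal/mol   Kd1 = %s\n",
              x$delta_g_bind_1, x$delta_g_bind_1_err,
              format_concentration(x$kd1)))
  if (!is.null(x$delta_g_bind_2)) {
    cat(sprintf("  dG_bind,2 = %.2f +/- %.2f kcal/mol   Kd2 = %s\n",
                x$delta_g_bind_2, x$delta_g_bind_2_err,
                format_concentration(x$kd2)))
  }
  invisible(x)
}

#' Human-readable concentration with auto-scaled unit
#'
#' Values are stored in molar throughout; this picks M, mM or uM for display.
#'
#' @param x Concentration in molar.
#' @param digits Significant digits.
#' @return Character scalar, e.g. `"2.9 uM"`.
#' @export
format_concentration <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 0)
  if (x >= 0.1) {
    sprintf("%s M", signif(x, digits))
  } else if (x >= 1e-4) {
    sprintf("%s mM", signif(x * 1e3, digits))
  } else {
    sprintf("%s uM", signif(x * 1e6, digits))
  }
}

#' Classify binding cooperativity from stepwise dissociation constants
#'
#' Sequential binding of two ligands is negatively cooperative when the
#' second stepwise dissociation constant exceeds the first by more than the
#' stated tolerance, positively cooperative in the opposite case, and
#' non-cooperative otherwise.
#'
#' @param kd1,kd2 Stepwise dissociation constants (any common unit), > 0.
#' @param tolerance Relative tolerance defining the non-cooperative band.
#' @return One of `"negative"`, `"non-cooperative"`, `"positive"`.
#' @examples
#' cooperativity(2.9, 83)    # closed-pore isoflurane: negative
#' cooperativity(620, 530)   # open-pore isoflurane: non-cooperative
#' @export
cooperativity <- function(kd1, kd2, tolerance = 0.5) {
  stopifnot(kd1 > 0, kd2 > 0, tolerance > 0)
  if (kd2 > kd1 * (1 + tolerance)) {
    "negative"
  } else if (kd2 < kd1 / (1 + tolerance)) {
    "positive"
  } else {
    "non-cooperative"
  }
}
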