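#' Extrapolate a sensing free energy to the reference length of 24 residues
#'
#' The relative curvature-sensing free energy \eqn{\Delta\Delta F} scales
#' linearly with peptide length, so a value measured (or predicted) for an
#' L-residue peptide is extrapolated to the 24-residue reference via
#' \deqn{\Delta\Delta F_{L24} = \frac{a_L \cdot 24 + b_L}{a_L \cdot L + b_L}
#'       \, \Delta\Delta F}
#' which enables fair comparison between peptides of different lengths.
#' The factor is 1 at L = 24 and grows as L shrinks (about 5.5 at L = 7),
#' which is why predictions for short peptides deserve extra caution.
#'
#' @param ddf Relative sensing free energy \eqn{\Delta\Delta F} (kJ/mol);
#'   vectorized.
#' @param length Peptide length in residues, between 7 and 24.
#' @param constants A [pmi_constants()] object.
#' @return \eqn{\Delta\Delta F_{L24}} (kJ/mol).
#' @export
length_extrapolate <- function(ddf, length, constants = pmi_constants()) {
  stopifnot(is.numeric(ddf), is.numeric(length))
  if (any(!is.finite(ddf))) stop("ddf must be finite", call. = FALSE)
  if (any(length < 7 | length > 24))
    stop("peptide length must be between 7 and 24 residues", call. = FALSE)
  num <- constants$a_l * constants$ref_length + constants$b_l
  den <- constants$a_l * length + constants$b_l
  if (any(abs(den) < 1e-12))
    stop("inconsistent constants: a_l * L + b_l vanishes in the admissible length range",
         call. = FALSE)
  (num / den) * ddf
}

#' Adjust a sensing free energy for peptide net charge on anionic membranes
#'
#' Most biomembranes carry net negative charge while the reference membrane
#' is neutral; each unit of positive peptide charge strengthens binding by
#' |c_z| = 0.93 kJ/mol: \eqn{\Delta\Delta F_{adj} = \Delta\Delta F_{L24} +
#' c_z z}. The correction was calibrated on peptides with charges between
#' -1 and +4; outside that range a caution is emitted.
#'
#' @param ddf24 Length-extrapolated free energy (kJ/mol); vectorized.
#' @param charge Net integer charge z of the peptide.
#' @param constants A [pmi_constants()] object.
#' @return \eqn{\Delta\Delta F_{adj}} (kJ/mol).
#' @export
charge_adjust <- function(ddf24, charge, constants = pmi_constants()) {
  stopifnot(is.numeric(ddf24), is.numeric(charge))
  if (any(!is.finite(ddf24))) stop("ddf24 must be finite", call. = FALSE)
  if (any(charge != round(charge)))
    stop("charge must be an integer", call. = FALSE)
  if (any(charge > 4 | charge < -1))
    message("note: charge correction was calibrated for charges in [-1, +4]; ",
            "interpret values outside this range with caution")
  ddf24 + constants$c_z * charge
}

#' Relative elastic strain of a vesicle of radius R
#'
#' The curvature correction uses the dimensionless strain
#' \eqn{\epsilon(R) = 1/R^2 + 2/R} (R in nm), which vanishes for a flat
#' membrane. Flat membranes are passed as `radius = Inf`.
#'
#' @param radius Vesicle radius in nm (> 0), or `Inf` for a flat membrane;
#'   vectorized.
#' @return Dimensionless strain, strictly decreasing in R.
#' @export
vesicle_strain <- function(radius) {
  stopifnot(is.numeric(radius))
  if (any(is.na(radius) | radius <= 0))
    stop("radius must be positive (use Inf for a flat membrane)", call. = FALSE)
  ifelse(is.infinite(radius), 0, 1 / radius^2 + 2 / radius)
}

#' Membrane-binding free energy of a peptide to a vesicle of radius R
#'
#' Maps the (adjusted) relative sensing free energy onto the absolute
#' membrane-binding free energy via a fitted affine relation plus a
#' strain-scaled curvature term:
#' \deqn{\Delta F_{sm}(R) = \alpha \, \Delta\Delta F_{eff} + \beta +
#'       \frac{\Delta\Delta F_{eff}}{\epsilon_{ref}}
#'       \left(\frac{1}{R^2} + \frac{2}{R}\right)}
#' At \eqn{\Delta\Delta F_{eff} = 0} on a flat membrane this reduces to the
#' intercept \eqn{\beta}.
#'
#' @param ddf_eff Effective sensing free energy (length-extrapolated, charge
#'   adjusted when the membrane is anionic), kJ/mol; vectorized.
#' @param radius Vesicle radius in nm, or `Inf` for flat.
#' @param constants A [pmi_constants()] object.
#' @return \eqn{\Delta F_{sm}(R)} (kJ/mol).
#' @export
binding_free_energy <- function(ddf_eff, radius, constants = pmi_constants()) {
  stopifnot(is.numeric(ddf_eff))
  if (any(!is.finite(ddf_eff))) stop("ddf_eff must be finite", call. = FALSE)
  strain <- vesicle_strain(radius)
  constants$alpha * ddf_eff + constants$beta +
    (ddf_eff / constants$eps_ref) * strain
}

#' Membrane-binding probability from the binding free energy
#'
#' A sigmoid-like switch function with a prefactor counting the ratio of
#' peptide realizations in solvent versus on the membrane:
#' \deqn{P_m = \frac{1}{1 + (N_s/N_m)\, e^{\Delta F_{sm}/RT}}}
#' \eqn{P_m \to 0} for non-binders, \eqn{\approx 0.5} in the sensing regime,
#' and \eqn{\to 1} for binders. The exponent is clamped at +/-700 before
#' exponentiation so extreme inputs saturate to 0/1 without overflow.
#'
#' @param dfsm Binding free energy \eqn{\Delta F_{sm}} (kJ/mol); vectorized.
#' @param constants A [pmi_constants()] object.
#' @return Probability in (0, 1), strictly decreasing in `dfsm`.
#' @export
binding_probability <- function(dfsm, constants = pmi_constants()) {
  stopifnot(is.numeric(dfsm))
  if (any(!is.finite(dfsm))) stop("dfsm must be finite", call. = FALSE)
  expo <- pmin(pmax(dfsm / constants$thermal_energy, -700), 700)
  1 / (1 + constants$ns_over_nm * exp(expo))
}

#' Classify a peptide as non-binder, curvature sensor, or membrane binder
#'
#' Thresholds act on the effective sensing free energy: non-binder above
#' -6.4 kJ/mol, sensor in the closed interval [-10.0, -6.4], binder below
#' -10.0 kJ/mol. Both sensor boundaries are inclusive, so ties classify as
#' sensor. These thresholds are the \eqn{P_m = 0.05} and \eqn{0.95}
#' crossings of the binding-probability curve at a 50 nm vesicle (see
#' [derive_class_boundaries()]).
#'
#' @param ddf_eff Effective sensing free energy (kJ/mol); vectorized.
#' @param constants A [pmi_constants()] object.
#' @return A factor with levels `non-binder`, `sensor`, `binder`.
#' @export
classify_ddf <- function(ddf_eff, constants = pmi_constants()) {
  stopifnot(is.numeric(ddf_eff))
  if (any(!is.finite(ddf_eff))) stop("ddf_eff must be finite", call. = FALSE)
  lab <- ifelse(ddf_eff > constants$sensor_hi, "non-binder",
         ifelse(ddf_eff < constants$sensor_lo, "binder", "sensor"))
  factor(lab, levels = c("non-binder", "sensor", "binder"))
}

#' Binding probability as a function of vesicle radius
#'
#' Evaluates the composed model \eqn{P_m(\Delta F_{sm}(\Delta\Delta F_{eff},
#' R))} on a grid of radii, giving the curve that distinguishes the three
#' activity regimes: flat near 0 (non-binders), flat near 1 (binders), and
#' strongly radius-dependent in between (curvature sensors).
#'
#' @param ddf_eff Effective sensing free energy (kJ/mol), scalar.
#' @param radii Vesicle radii in nm (all > 0; `Inf` allowed for flat).
#' @param constants A [pmi_constants()] object.
#' @return A data.frame with columns `radius`, `dfsm`, `pm`.
#' @export
pm_radius_curve <- function(ddf_eff, radii, constants = pmi_constants()) {
  stopifnot(length(ddf_eff) == 1)
  dfsm <- binding_free_energy(ddf_eff, radii, constants)
  data.frame(radius = radii, dfsm = dfsm,
             pm = binding_probability(dfsm, constants))
}

#' Recover the classification boundaries from the probability model
#'
#' Root-finds the effective sensing free energies at which the
#' membrane-binding probability at radius R equals `p_low` and `p_high`.
#' With the default probabilities (0.05, 0.95) at R = 50 nm and the default
#' constants, the results round (one decimal) to the classification
#' thresholds -6.4 and -10.0 kJ/mol, tying the free-energy map, the
#' probability sigmoid, and the thresholds together.
#'
#' @param p_low,p_high Probabilities with `0 < p_low < p_high < 1`.
#' @param radius Vesicle radius in nm (default 50).
#' @param constants A [pmi_constants()] object.
#' @return Named numeric vector `c(at_p_low = ..., at_p_high = ...)`
#'   (kJ/mol); `at_p_low` is the non-binder/sensor boundary, `at_p_high` the
#'   sensor/binder boundary.
#' @export
derive_class_boundaries <- function(p_low = 0.05, p_high = 0.95, radius = 50,
                                    constants = pmi_constants()) {
  if (!(p_low > 0 && p_low < p_high && p_high < 1))
    stop("need 0 < p_low < p_high < 1", call. = FALSE)
  f <- function(x, p) binding_probability(
    binding_free_energy(x, radius, constants), constants) - p
  solve_one <- function(p) {
    lo <- -80; hi <- 40
    if (f(lo, p) * f(hi, p) > 0)
      stop("root not bracketed on [-80, 40] kJ/mol", call. = FALSE)
    stats::uniroot(f, c(lo, hi), p = p, tol = 1e-10)$root
  }
  c(at_p_low = solve_one(p_low), at_p_high = solve_one(p_high))
}
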