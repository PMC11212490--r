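#' Physical constants of the membrane-interaction model
#'
#' Bundles the fitted and assumed constants of the free-energy model: the
#' linear length dependence of the relative curvature-sensing free energy
#' \eqn{\Delta\Delta F}, the per-charge correction for anionic membranes, the
#' affine map from \eqn{\Delta\Delta F} to the absolute membrane-binding free
#' energy \eqn{\Delta F_{sm}(R)} with its strain-scaled curvature term, the
#' solvent/membrane state-count ratio entering the binding-probability
#' sigmoid, and the classification thresholds separating non-binders,
#' curvature sensors, and membrane binders.
#'
#' All free energies are in kJ/mol; vesicle radii in nm. The thermal energy
#' default corresponds to RT at 298.15 K.
#'
#' @param a_l Slope of \eqn{\Delta\Delta F} vs peptide length (kJ/mol per
#'   residue).
#' @param b_l Intercept of the length relation (kJ/mol).
#' @param c_z Free-energy shift per unit of positive net charge on anionic
#'   membranes (kJ/mol).
#' @param alpha Slope of the flat-membrane part of the
#'   \eqn{\Delta\Delta F \rightarrow \Delta F_{sm}} map (dimensionless).
#' @param beta Intercept of that map (kJ/mol).
#' @param eps_ref Relative strain of the reference stretched membrane
#'   (dimensionless).
#' @param ns_over_nm Ratio of peptide realizations in solvent vs on the
#'   membrane (dimensionless).
#' @param thermal_energy RT (kJ/mol).
#' @param sensor_hi Non-binder/sensor boundary on \eqn{\Delta\Delta F}
#'   (kJ/mol).
#' @param sensor_lo Sensor/binder boundary (kJ/mol).
#' @param ref_radius Default vesicle radius (nm).
#' @param ref_length Reference peptide length (residues).
#' @return An object of class `pmi_constants` (a named list).
#' @examples
#' cst <- pmi_constants()
#' cst$alpha
#' @export
pmi_constants <- function(a_l = -1.03,
                          b_l = 3.28,
                          c_z = -0.93,
                          alpha = 3.83,
                          beta = 12.27,
                          eps_ref = 0.165,
                          ns_over_nm = 5.2e3,
                          thermal_energy = 2.478,
                          sensor_hi = -6.4,
                          sensor_lo = -10.0,
                          ref_radius = 50,
                          ref_length = 24L) {
  cst <- list(
    a_l = a_l, b_l = b_l, c_z = c_z,
    alpha = alpha, beta = beta, eps_ref = eps_ref,
    ns_over_nm = ns_over_nm, thermal_energy = thermal_energy,
    sensor_hi = sensor_hi, sensor_lo = sensor_lo,
    ref_radius = ref_radius, ref_length = as.integer(ref_length)
  )
  if (!all(vapply(cst, is.numeric, logical(1))))
    stop("all constants must be numeric", call. = FALSE)
  if (cst$a_l >= 0) stop("a_l must be negative", call. = FALSE)
  if (cst$eps_ref <= 0) stop("eps_ref must be positive", call. = FALSE)
  if (cst$ns_over_nm <= 1) stop("ns_over_nm must exceed 1", call. = FALSE)
  if (cst$thermal_energy <= 0) stop("thermal_energy must be positive", call. = FALSE)
  if (!(cst$sensor_lo < cst$sensor_hi && cst$sensor_hi < 0))
    stop("thresholds must satisfy sensor_lo < sensor_hi < 0", call. = FALSE)
  if (cst$ref_length != 24L)
    stop("ref_length must be 24 (the model's reference peptide length)", call. = FALSE)
  structure(cst, class = "pmi_constants")
}

#' @export
print.pmi_constants <- function(x, ...) {
  cat("Membrane-interaction model constants:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read model constants from a key=value configuration file
#'
#' Lines of the form `name = value`; blank lines and `#` comments ignored.
#' Unknown keys are an error; missing keys keep their defaults.
#'
#' @param path Path to the configuration file.
#' @return A [pmi_constants()] object.
#' @export
read_constants_file <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed constants line (expected key = value): ", ln, call. = FALSE)
    key <- trimws(kv[1])
    if (!key %in% names(formals(pmi_constants)))
      stop("unknown constant '", key, "'; valid keys: ",
           paste(names(formals(pmi_constants)), collapse = ", "), call. = FALSE)
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for constant '", key, "'", call. = FALSE)
    args[[key]] <- val
  }
  do.call(pmi_constants, args)
}
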