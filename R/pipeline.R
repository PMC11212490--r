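# End-to-end workflows wiring the predictor, the physics layer and the
# reporting together, plus run manifests for reproducibility.

#' Default radius grid for binding-probability curves
#'
#' Logarithmic grid from 10 to 500 nm (50 points), covering typical
#' vesicle sizes.
#' @return Numeric vector of radii (nm).
#' @export
default_radius_grid <- function() exp(seq(log(10), log(500), length.out = 50))

#' Predict membrane interaction for a single peptide
#'
#' Composes the full peptide workflow: sequence validation, free-energy
#' prediction, length extrapolation to the 24-residue reference, charge
#' adjustment when the target membrane is anionic, the binding free energy
#' and probability at the reference vesicle radius (50 nm), activity
#' classification, physicochemical descriptors, and the binding-probability
#' curve over a radius grid.
#'
#' @param sequence Peptide sequence, 7-24 natural residues.
#' @param membrane `"neutral"` or `"anionic"`.
#' @param predictor A predictor accepted by [predict_ddf()].
#' @param constants A [pmi_constants()] object.
#' @param radii Radius grid for the probability curve (nm).
#' @return An object of class `peptide_report`: sequence, membrane, the
#'   free-energy chain (`ddf`, `ddf_l24`, `ddf_adj` when anionic,
#'   `ddf_eff`), `dfsm_ref` and `pm_ref` at the reference radius, the class
#'   `label`, the descriptor row, and the `pm_curve` data.frame.
#' @examples
#' rep <- run_peptide("FLLWLLFSETWF", predictor = constant_predictor(-8))
#' @export
run_peptide <- function(sequence, membrane = c("neutral", "anionic"),
                        predictor, constants = pmi_constants(),
                        radii = default_radius_grid()) {
  membrane <- match.arg(membrane)
  seq <- validate_sequence(sequence)
  ddf <- predict_ddf(predictor, seq)
  ddf_l24 <- length_extrapolate(ddf, nchar(seq), constants)
  z <- net_charge(seq)
  ddf_adj <- charge_adjust(ddf_l24, z, constants)
  ddf_eff <- if (membrane == "anionic") ddf_adj else ddf_l24
  dfsm_ref <- binding_free_energy(ddf_eff, constants$ref_radius, constants)
  pm_ref <- binding_probability(dfsm_ref, constants)
  structure(list(
    sequence = seq, membrane = membrane,
    ddf = ddf, ddf_l24 = ddf_l24,
    ddf_adj = if (membrane == "anionic") ddf_adj else NULL,
    ddf_eff = ddf_eff,
    dfsm_ref = dfsm_ref, pm_ref = pm_ref,
    label = classify_ddf(ddf_eff, constants),
    descriptors = peptide_descriptors(seq),
    pm_curve = pm_radius_curve(ddf_eff, radii, constants),
    constants = constants
  ), class = "peptide_report")
}

#' @export
print.peptide_report <- function(x, ...) {
  cat("Peptide membrane-interaction report\n")
  cat(sprintf("  sequence            %s  (%d residues)\n", x$sequence,
              nchar(x$sequence)))
  cat(sprintf("  target membrane     %s\n", x$membrane))
  cat(sprintf("  ddF (predicted)     %8.2f kJ/mol\n", x$ddf))
  cat(sprintf("  ddF_L24             %8.2f kJ/mol\n", x$ddf_l24))
  if (!is.null(x$ddf_adj))
    cat(sprintf("  ddF_adj             %8.2f kJ/mol\n", x$ddf_adj))
  cat(sprintf("  dFsm (R = %g nm)    %8.2f kJ/mol\n",
              x$constants$ref_radius, x$dfsm_ref))
  cat(sprintf("  Pm   (R = %g nm)    %s\n", x$constants$ref_radius,
              signif(x$pm_ref, 3)))
  cat(sprintf("  class               %s\n", as.character(x$label)))
  d <- x$descriptors
  cat(sprintf("  charge %+d | mean hydrophobicity %.3f | hydrophobic moment %.3f\n",
              d$charge, d$mean_hydrophobicity, d$hydrophobic_moment))
  invisible(x)
}

#' Machine-readable row for a peptide report
#'
#' Flattens a `peptide_report` to a one-row data.frame carrying exactly
#' the numbers the printed report shows (at full precision).
#'
#' @param report A `peptide_report`.
#' @return One-row data.frame.
#' @export
peptide_report_row <- function(report) {
  stopifnot(inherits(report, "peptide_report"))
  d <- report$descriptors
  data.frame(sequence = report$sequence, membrane = report$membrane,
             length = d$length, charge = d$charge,
             mean_hydrophobicity = d$mean_hydrophobicity,
             hydrophobic_moment = d$hydrophobic_moment,
             ddf = report$ddf, ddf_l24 = report$ddf_l24,
             ddf_adj = ifelse(is.null(report$ddf_adj), NA_real_,
                              report$ddf_adj),
             dfsm_ref = report$dfsm_ref, pm_ref = report$pm_ref,
             label = as.character(report$label), stringsAsFactors = FALSE)
}

predictor_fingerprint <- function(predictor) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(predictor, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(path, ...) {
  entries <- list(...)
  entries$package <- "memsense"
  entries$version <- as.character(utils::packageVersion("memsense"))
  entries$r_version <- as.character(getRversion())
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the structure-screening workflow and write its output bundle
#'
#' Screens a structure file and writes four artifacts to `out_dir`: the
#' B-factor-annotated PDB (`annotated.pdb`), the per-residue table
#' (`residues.tsv`), the per-segment table (`segments.tsv`), and a run
#' manifest (`manifest.json`) recording the configuration, constants,
#' input checksum and predictor fingerprint. Reruns with identical inputs
#' produce byte-identical tables.
#'
#' @param structure_path Path to a PDB or mmCIF file.
#' @param out_dir Output directory (created if absent).
#' @param config A [screen_config()].
#' @param predictor A predictor accepted by [predict_ddf()].
#' @param constants A [pmi_constants()] object.
#' @return The `screen_result`, invisibly; paths in
#'   `attr(result, "paths")`.
#' @export
run_screen <- function(structure_path, out_dir, config = screen_config(),
                       predictor, constants = pmi_constants()) {
  if (!file.exists(structure_path))
    stop("structure file not found: ", structure_path, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- annotate_structure(structure_path, config, predictor, constants)
  paths <- list(
    pdb = file.path(out_dir, "annotated.pdb"),
    residues = file.path(out_dir, "residues.tsv"),
    segments = file.path(out_dir, "segments.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_annotated_pdb(structure_path, result, paths$pdb)
  utils::write.table(result$residues, paths$residues, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$segments, paths$segments, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(paths$manifest,
                 workflow = "screen",
                 config = unclass(config),
                 constants = unclass(constants),
                 input = basename(structure_path),
                 input_md5 = unname(tools::md5sum(structure_path)),
                 predictor_class = class(predictor)[1],
                 predictor_md5 = predictor_fingerprint(predictor))
  attr(result, "paths") <- paths
  invisible(result)
}

#' Train a regressor from a dataset file and write its artifacts
#'
#' Reads (or takes) a (sequence, ddf) dataset, trains the attention
#' regressor, and writes the checkpoint (`model.rds`), the per-epoch
#' history (`history.tsv`) and a manifest to `out_dir`.
#'
#' @param data A dataset data.frame or a path readable by
#'   [read_peptide_dataset()].
#' @param out_dir Output directory.
#' @param config A [model_config()].
#' @param verbose Print training progress.
#' @return The trained `ddf_model`, invisibly.
#' @export
run_train <- function(data, out_dir, config = model_config(),
                      verbose = FALSE) {
  if (is.character(data)) data <- read_peptide_dataset(data)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- train_ddf_model(data, config, verbose = verbose)
  save_ddf_model(model, file.path(out_dir, "model.rds"))
  utils::write.table(model$history, file.path(out_dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  test <- data[model$split$test, , drop = FALSE]
  test_rmse <- if (nrow(test) > 0) evaluate_rmse(model, test)$rmse else NA
  write_manifest(file.path(out_dir, "manifest.json"),
                 workflow = "train", config = unclass(config),
                 n_examples = nrow(data), test_rmse = test_rmse,
                 best_epoch = model$best_epoch)
  invisible(model)
}

#' Benchmark a screened structure against reference regions and report
#'
#' @param residues_path Path to a per-residue table (`residues.tsv` from
#'   [run_screen()]) or a compatible data.frame.
#' @param regions_path Path to a reference-region file (see
#'   [read_reference_regions()]) or a compatible data.frame.
#' @param out_dir Optional output directory for the per-fragment table and
#'   summary.
#' @param fragment_size,min_hits,include_sensors See [benchmark_screen()].
#' @return The benchmark list (summary + fragments), invisibly when
#'   writing, visibly otherwise.
#' @export
run_benchmark <- function(residues_path, regions_path, out_dir = NULL,
                          fragment_size = 15L, min_hits = 1L,
                          include_sensors = TRUE) {
  residues <- if (is.character(residues_path)) {
    if (!file.exists(residues_path))
      stop("residue table not found: ", residues_path, call. = FALSE)
    utils::read.table(residues_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else residues_path
  regions <- if (is.character(regions_path))
    read_reference_regions(regions_path) else regions_path
  bench <- benchmark_screen(residues, regions, fragment_size, min_hits,
                            include_sensors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(bench$fragments, file.path(out_dir, "fragments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    s <- bench$summary
    write_manifest(file.path(out_dir, "benchmark.json"),
                   workflow = "benchmark", fragment_size = fragment_size,
                   min_hits = min_hits, include_sensors = include_sensors,
                   tp = s$tp, fp = s$fp, tn = s$tn, fn = s$fn,
                   mcc = s$mcc, fdr = s$fdr, for_ = s$for_)
    return(invisible(bench))
  }
  bench
}
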