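test_that("sliding windows cover L - w + 1 positions with stride 1", {
  s20 <- paste(rep("A", 20), collapse = "")
  segs <- sliding_segments(s20, 15)
  expect_identical(nrow(segs), 6L)
  expect_identical(segs$start, 1:6)
  expect_identical(segs$end, 15:20)
  expect_true(all(nchar(segs$sequence) == 15))
  one <- sliding_segments(strrep("A", 15), 15)
  expect_identical(nrow(one), 1L)
  expect_warning(none <- sliding_segments("AAAAAA", 15), "skipped")
  expect_identical(nrow(none), 0L)
  expect_message(short <- sliding_segments(strrep("A", 10), 15), "single segment")
  expect_identical(short$end, 10L)
})

test_that("per-residue averaging pools exactly the covering windows", {
  # constant conservation: same score everywhere
  for (L in c(15, 20, 40)) {
    segs <- sliding_segments(strrep("G", L), 15)
    segs$ddf_eff <- -7.3
    expect_equal(per_residue_score(segs, L), rep(-7.3, L))
  }
  # L = 17, w = 15, scores (0, -3, -6): hand-averaged expectations
  segs <- sliding_segments(strrep("G", 17), 15)
  segs$ddf_eff <- c(0, -3, -6)
  pr <- per_residue_score(segs, 17)
  expect_equal(pr[1], 0)
  expect_equal(pr[2], -1.5)
  expect_equal(pr[9], -3)
  expect_equal(pr[17], -6)
  expect_equal(pr[16], -4.5)
})

test_that("screening classifies on the length-extrapolated scale, gated by exposure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(list(A = list(sequence = strrep("L", 24))), f)
  # stub -15: binder everywhere that is exposed
  res <- annotate_structure(f, screen_config(sasa_threshold = 0.3),
                            constant_predictor(-15))
  expect_true(all(res$residues$label == "binder"))
  expect_true(all(res$residues$bfactor == 1.0))
  # impossible threshold: everything inaccessible, B-factor 0
  res2 <- annotate_structure(f, screen_config(sasa_threshold = 99),
                             constant_predictor(-15))
  expect_true(all(res2$residues$label == "not accessible"))
  expect_true(all(res2$residues$bfactor == 0))
  # order of operations: a window score of -8 at w = 15 extrapolates to
  # -14.09 (binder), NOT sensor as the raw score would suggest
  res3 <- annotate_structure(f, screen_config(sasa_threshold = 0.3),
                             constant_predictor(-8))
  expect_equal(res3$segments$ddf_eff[1],
               length_extrapolate(-8, 15), tolerance = 1e-12)
  expect_true(all(res3$residues$label == "binder"))
})

test_that("anionic screening applies the per-window charge correction", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(list(A = list(sequence = strrep("K", 20))), f)
  neutral <- annotate_structure(f, screen_config(sasa_threshold = 0.3),
                                constant_predictor(-5))
  anionic <- annotate_structure(f, screen_config(sasa_threshold = 0.3,
                                                 membrane = "anionic"),
                                constant_predictor(-5))
  # each 15-mer of lysines carries charge +15
  expect_equal(anionic$segments$ddf_eff,
               neutral$segments$ddf_eff + (-0.93) * 15,
               tolerance = 1e-12)
})

test_that("segment labels stay consistent with the physics classifier", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(list(A = list(sequence = strrep("G", 30))), f)
  res <- annotate_structure(f, screen_config(sasa_threshold = 0.3),
                            constant_predictor(-4.5))
  expect_identical(as.character(res$segments$label),
                   as.character(classify_ddf(res$segments$ddf_eff)))
})

test_that("annotated PDB output carries class-coded B-factors and preserves columns", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(list(A = list(sequence = strrep("L", 24))), f)
  out <- withr::local_tempfile(fileext = ".pdb")
  res <- annotate_structure(f, screen_config(sasa_threshold = 0.3),
                            constant_predictor(-2))  # all non-binder
  write_annotated_pdb(f, res, out)
  lines <- readLines(out)
  atom <- lines[startsWith(lines, "ATOM")]
  expect_true(all(trimws(substr(atom, 61, 66)) == "0.00"))
  # every other column is preserved byte-for-byte
  orig <- readLines(f)
  orig_atom <- orig[startsWith(orig, "ATOM")]
  expect_identical(substr(atom, 1, 60), substr(orig_atom, 1, 60))
  expect_identical(trimws(substr(atom, 67, 80)),
                   trimws(substr(orig_atom, 67, 80)))
  # mixed classes produce exactly the three canonical values
  res$residues$bfactor <- rep(c(0, 0.5, 1), length.out = 24)
  write_annotated_pdb(f, res, out)
  reparsed <- read_structure(out)
  expect_identical(sort(unique(reparsed$atom$b)), c(0, 0.5, 1))
  expect_equal(reparsed$atom$b, res$residues$bfactor[match(
    reparsed$atom$resno, res$residues$resno)])
})
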