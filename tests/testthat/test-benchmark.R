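test_that("sequences are cut into consecutive fragments, remainder dropped", {
  fr <- suppressMessages(fragment_sequence(100, 15))
  expect_identical(nrow(fr), 6L)
  expect_identical(fr$start[1], 1L)
  expect_identical(fr$end[6], 90L)
  expect_identical(nrow(fragment_sequence(15, 15)), 1L)
  expect_warning(fr0 <- fragment_sequence(14, 15), "no fragment")
  expect_identical(nrow(fr0), 0L)
  expect_identical(nrow(suppressMessages(fragment_sequence(strrep("A", 31), 15))), 2L)
})

test_that("fragment labelling counts hit residues against min_hits", {
  fr <- fragment_sequence(30, 15)
  expect_identical(label_fragments(rep(TRUE, 30), fr), c(TRUE, TRUE))
  expect_identical(label_fragments(rep(FALSE, 30), fr), c(FALSE, FALSE))
  one_hit <- c(rep(FALSE, 7), TRUE, rep(FALSE, 22))
  expect_identical(label_fragments(one_hit, fr), c(TRUE, FALSE))
  expect_identical(label_fragments(one_hit, fr, min_hits = 2), c(FALSE, FALSE))
  expect_error(label_fragments(rep(TRUE, 20), fr), "misaligned")
})

test_that("confusion statistics match hand-computed values", {
  perfect <- confusion_stats(c(TRUE, TRUE, FALSE, FALSE),
                             c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$fdr, 0)
  expect_equal(perfect$for_, 0)
  expect_length(perfect$degenerate, 0)
  # TP 5, FP 5, TN 85, FN 5: MCC = 400/900, FDR = 0.5, FOR = 5/90
  pred <- c(rep(TRUE, 10), rep(FALSE, 90))
  ref <- c(rep(TRUE, 5), rep(FALSE, 5), rep(FALSE, 85), rep(TRUE, 5))
  cs <- confusion_stats(pred, ref)
  expect_identical(c(cs$tp, cs$fp, cs$tn, cs$fn), c(5L, 5L, 85L, 5L))
  expect_equal(cs$mcc, 400 / 900)
  expect_equal(cs$fdr, 0.5)
  expect_equal(cs$for_, 5 / 90)
  # all-positive predictions on a mixed set: FOR denominator degenerates
  cs2 <- confusion_stats(rep(TRUE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(cs2$for_, 0)
  expect_true("for" %in% cs2$degenerate)
  expect_error(confusion_stats(logical(), logical()), "no fragments")
  expect_error(confusion_stats(c(TRUE), c(TRUE, FALSE)), "equal length")
})

test_that("MCC is symmetric, sign-flips under inversion, and stays bounded", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ref <- sample(c(TRUE, FALSE), n, replace = TRUE)
    cs <- confusion_stats(pred, ref)
    expect_gte(cs$mcc, -1); expect_lte(cs$mcc, 1)
    expect_gte(cs$fdr, 0); expect_lte(cs$fdr, 1)
    expect_gte(cs$for_, 0); expect_lte(cs$for_, 1)
    # symmetry under swapping prediction and reference
    expect_equal(confusion_stats(ref, pred)$mcc, cs$mcc)
    # inversion negates MCC when both classes occur on both sides
    if (length(unique(pred)) == 2 && length(unique(ref)) == 2)
      expect_equal(confusion_stats(!pred, ref)$mcc, -cs$mcc)
  }
})

test_that("the end-to-end benchmark scores fragments per chain", {
  residues <- data.frame(
    chain = "A", resno = 1:45,
    label = c(rep("binder", 15), rep("non-binder", 15),
              rep("sensor", 8), rep("not accessible", 7)),
    stringsAsFactors = FALSE)
  regions <- data.frame(chain = "A", start = 1, end = 15)
  b <- benchmark_screen(residues, regions)
  # fragment 1: predicted + reference positive; 2: both negative;
  # 3: sensor hits predicted positive, no reference -> FP
  expect_identical(c(b$summary$tp, b$summary$fp, b$summary$tn, b$summary$fn),
                   c(1L, 1L, 1L, 0L))
  b2 <- benchmark_screen(residues, regions, include_sensors = FALSE)
  expect_identical(b2$summary$fp, 0L)
  # reference file reader
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tstart\tend", "A\t1\t15"), f)
  expect_identical(read_reference_regions(f),
                   data.frame(chain = "A", start = 1L, end = 15L))
  writeLines(c("chain\tstart\tend", "A\t20\t10"), f)
  expect_error(read_reference_regions(f), "end < start")
})
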