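test_that("analytic gradients match finite differences on a tiny encoder", {
  set.seed(42)
  cfg <- model_config(embed_dim = 8, n_heads = 2, n_layers = 1, ff_dim = 16,
                      max_length = 6, seed = 3)
  params <- memsense:::init_params(cfg)
  toks <- rbind(tokenize("ACDEF", 6), tokenize("KLMNPQ", 6),
                tokenize("WWY", 6))
  y <- c(-2, 1, 0.5)
  loss_fn <- function(p) {
    f <- memsense:::model_fwd(p, toks, cfg)
    mean((f$yhat - y)^2)
  }
  fwd <- memsense:::model_fwd(params, toks, cfg, keep_cache = TRUE)
  dyhat <- matrix(2 * (fwd$yhat - y) / length(y), ncol = 1)
  g <- memsense:::model_bwd(params, fwd, dyhat, cfg)
  worst <- 0
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      eps <- 1e-6
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
      ana <- g[[nm]][i]
      if (abs(num) + abs(ana) > 1e-10)
        worst <- max(worst, abs(num - ana) / (abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the encoder can memorize a small noise-free dataset", {
  d <- tiny_dataset(n = 50, seed = 5, noise_sd = 0)
  cfg <- model_config(epochs = 120, patience = 120, batch_size = 16,
                      learning_rate = 4e-3, seed = 2,
                      splits = c(1, 0, 0))
  m <- train_ddf_model(d, cfg)
  expect_lt(tail(m$history$train_rmse, 1), 0.5)
})

test_that("training is reproducible and divergence is reported by epoch", {
  d <- tiny_dataset(n = 120, seed = 8, noise_sd = 1)
  cfg <- model_config(epochs = 3, seed = 21)
  m1 <- train_ddf_model(d, cfg)
  m2 <- train_ddf_model(d, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # an absurd learning rate must fail loudly, naming the epoch
  expect_error(
    train_ddf_model(d, model_config(epochs = 5, seed = 21,
                                    learning_rate = 1e300)),
    "epoch")
})

test_that("inference is deterministic and model files round-trip bit-identically", {
  d <- tiny_dataset(n = 120, seed = 8, noise_sd = 1)
  m <- train_ddf_model(d, model_config(epochs = 2, seed = 21))
  seqs <- d$sequence[1:10]
  p1 <- predict_ddf(m, seqs)
  p2 <- predict_ddf(m, seqs)
  expect_identical(p1, p2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_ddf_model(m, f)
  m2 <- load_ddf_model(f)
  expect_identical(predict_ddf(m2, seqs), p1)
  expect_error(load_ddf_model(withr::local_tempfile()), "not found")
  f2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, f2)
  expect_error(load_ddf_model(f2), "checkpoint")
})

test_that("short-peptide predictions carry a caution note", {
  d <- tiny_dataset(n = 120, seed = 8, noise_sd = 1)
  m <- train_ddf_model(d, model_config(epochs = 1, seed = 21))
  expect_message(predict_ddf(m, "GIGAVLKV"), "caution")
  expect_silent(invisible(predict_ddf(m, strrep("A", 15))))
})

test_that("RMSE evaluation matches closed forms", {
  data0 <- data.frame(sequence = rep(strrep("A", 10), 4), ddf = rep(-3, 4))
  expect_equal(evaluate_rmse(constant_predictor(-3), data0)$rmse, 0)
  # constant offset of +1
  data1 <- data.frame(sequence = rep(strrep("A", 10), 4), ddf = rep(-4, 4))
  expect_equal(evaluate_rmse(constant_predictor(-3), data1)$rmse, 1)
  # residuals {+1, -1, +1, -1}
  data2 <- data.frame(sequence = rep(strrep("A", 10), 4),
                      ddf = c(-4, -2, -4, -2))
  ev <- evaluate_rmse(constant_predictor(-3), data2)
  expect_equal(ev$rmse, 1)
  expect_equal(ev$residual_mean, 0)
  expect_error(evaluate_rmse(constant_predictor(0),
                             data.frame(sequence = character(),
                                        ddf = numeric())),
               "empty")
})

test_that("predictor dispatch covers stubs, baselines, and rejects the rest", {
  expect_identical(predict_ddf(constant_predictor(-7), c("AAA", "WWW")),
                   c(-7, -7))
  d <- generate_peptide_dataset(synthetic_spec(n_examples = 200, seed = 3,
                                               noise_sd = 0))
  bl <- fit_additive_baseline(d)
  coefs <- attr(d, "coefficients")
  expect_equal(predict_ddf(bl, "WWLLKK"),
               2 * coefs[["W"]] + 2 * coefs[["L"]] + 2 * coefs[["K"]],
               tolerance = 1e-5)
  expect_error(predict_ddf(list(), "AAA"), "no predictor")
})
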