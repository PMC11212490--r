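# Sequence -> free-energy regressor: a small pre-LN multi-head
# self-attention encoder with a pooled linear head, trained by Adam on
# mean-squared error. Forward and backward passes are written out
# explicitly in base R matrix algebra (gradient-checked in the test suite
# against finite differences).

#' Configuration for the attention-based free-energy regressor
#'
#' Defaults are a deliberately small capacity (2 encoder layers, 4 heads,
#' 32-dim embeddings) adequate for learning residue-additive structure from
#' synthetic data on a single CPU; every field can be overridden.
#'
#' @param embed_dim Embedding dimension (divisible by `n_heads`).
#' @param n_heads Number of attention heads.
#' @param n_layers Number of encoder layers.
#' @param ff_dim Hidden width of the position-wise feed-forward block.
#' @param dropout Dropout rate on attention/feed-forward outputs during
#'   training (default 0; training is then fully deterministic given the
#'   seed).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation RMSE (epochs).
#' @param seed RNG seed governing initialization, splits and shuffling.
#' @param splits Train/validation/test fractions (must sum to 1).
#' @param max_length Maximum (padded) sequence length.
#' @return An object of class `model_config`.
#' @export
model_config <- function(embed_dim = 32L, n_heads = 4L, n_layers = 2L,
                         ff_dim = 64L, dropout = 0, learning_rate = 3e-3,
                         batch_size = 64L, epochs = 20L, patience = 4L,
                         seed = 1L, splits = c(0.8, 0.1, 0.1),
                         max_length = 24L) {
  if (embed_dim %% n_heads != 0)
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  if (abs(sum(splits) - 1) > 1e-8 || length(splits) != 3 || any(splits < 0))
    stop("splits must be three non-negative fractions summing to 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(embed_dim = as.integer(embed_dim), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), ff_dim = as.integer(ff_dim),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 splits = splits, max_length = as.integer(max_length)),
            class = "model_config")
}

LN_EPS <- 1e-5

init_params <- function(cfg) {
  d <- cfg$embed_dim; ff <- cfg$ff_dim
  gauss <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))),
                                   nr, nc)
  p <- list(
    E = matrix(stats::rnorm(21 * d, sd = 0.02), 21, d),
    P = matrix(stats::rnorm(cfg$max_length * d, sd = 0.02), cfg$max_length, d)
  )
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d_", l)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- rep(0, d)
    p[[paste0(pre, "Wq")]] <- gauss(d, d)
    p[[paste0(pre, "Wk")]] <- gauss(d, d)
    p[[paste0(pre, "Wv")]] <- gauss(d, d)
    p[[paste0(pre, "Wo")]] <- gauss(d, d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    p[[paste0(pre, "W1")]] <- gauss(d, ff)
    p[[paste0(pre, "b1")]] <- rep(0, ff)
    p[[paste0(pre, "W2")]] <- gauss(ff, d)
    p[[paste0(pre, "b2")]] <- rep(0, d)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- rep(0, d)
  p$w_head <- matrix(stats::rnorm(d, sd = 0.02), d, 1)
  p$b_head <- 0
  p
}

softmax_rows <- function(S) {
  m <- S[, 1]
  for (q in 2:ncol(S)) m <- pmax(m, S[, q])
  E <- exp(S - m)
  E / rowSums(E)
}

ln_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  inv <- 1 / sqrt(rowMeans(Xc^2) + LN_EPS)
  xhat <- Xc * inv
  list(out = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dOut, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dOut, 2, g, "*")
  dX <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX,
       dg = colSums(dOut * xhat),
       db = colSums(dOut))
}

# Attention is vectorized across the batch: scores are held as a
# (B*L) x L matrix (row = query position within its sample, column = key
# position), and the per-sample matrix products become a short loop over
# the L key positions with whole-batch vector operations inside.
attn_fwd <- function(X, Wq, Wk, Wv, Wo, B, L, nh, mask) {
  d <- ncol(X); dh <- d %/% nh; scale <- 1 / sqrt(dh)
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  base <- rep(seq(0L, (B - 1L) * L, by = L), each = L)
  group <- rep(seq_len(B), each = L)
  keymask_rows <- !mask[group, , drop = FALSE]
  O <- matrix(0, B * L, d)
  A_all <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- Q[, cols, drop = FALSE]
    Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    S <- matrix(0, B * L, L)
    for (q in seq_len(L))
      S[, q] <- rowSums(Qh * Kh[base + q, , drop = FALSE]) * scale
    S[keymask_rows] <- -1e9
    A <- softmax_rows(S)
    A_all[[h]] <- A
    Oh <- matrix(0, B * L, dh)
    for (q in seq_len(L))
      Oh <- Oh + A[, q] * Vh[base + q, , drop = FALSE]
    O[, cols] <- Oh
  }
  list(out = O %*% Wo, Q = Q, K = K, V = V, O = O, A = A_all,
       base = base, group = group)
}

attn_bwd <- function(dOut, X, Wq, Wk, Wv, Wo, cache, B, L, nh, mask) {
  d <- ncol(X); dh <- d %/% nh; scale <- 1 / sqrt(dh)
  base <- cache$base; group <- cache$group
  base1 <- seq(0L, (B - 1L) * L, by = L)
  dWo <- crossprod(cache$O, dOut)
  dO <- dOut %*% t(Wo)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Qh <- cache$Q[, cols, drop = FALSE]
    Kh <- cache$K[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- matrix(0, nrow(X), L)
    for (q in seq_len(L))
      dA[, q] <- rowSums(dOh * Vh[base + q, , drop = FALSE])
    dS <- A * (dA - rowSums(dA * A))
    dQh <- matrix(0, nrow(X), dh)
    for (q in seq_len(L)) {
      dQh <- dQh + dS[, q] * Kh[base + q, , drop = FALSE] * scale
      dV[base1 + q, cols] <- dV[base1 + q, cols, drop = FALSE] +
        rowsum(A[, q] * dOh, group)
      dK[base1 + q, cols] <- dK[base1 + q, cols, drop = FALSE] +
        rowsum(dS[, q] * Qh, group) * scale
    }
    dQ[, cols] <- dQh
  }
  list(dX = dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv),
       dWq = crossprod(X, dQ), dWk = crossprod(X, dK),
       dWv = crossprod(X, dV), dWo = dWo)
}

# Forward pass over a batch. tokens: B x L integer matrix. Returns
# predictions and (optionally) all caches needed for the backward pass.
model_fwd <- function(params, tokens, cfg, keep_cache = FALSE,
                      drop_masks = NULL) {
  B <- nrow(tokens); L <- ncol(tokens)
  tok_flat <- as.vector(t(tokens))
  mask <- tokens != PAD_TOKEN
  mvec <- as.vector(t(mask))
  group <- rep(seq_len(B), each = L)
  X <- params$E[tok_flat, , drop = FALSE] +
    params$P[rep(seq_len(L), B), , drop = FALSE]
  caches <- list()
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d_", l)
    c1 <- ln_fwd(X, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]])
    at <- attn_fwd(c1$out, params[[paste0(pre, "Wq")]], params[[paste0(pre, "Wk")]],
                   params[[paste0(pre, "Wv")]], params[[paste0(pre, "Wo")]],
                   B, L, cfg$n_heads, mask)
    a_out <- at$out
    if (!is.null(drop_masks)) a_out <- a_out * drop_masks[[l]]$attn
    X1 <- X + a_out
    c2 <- ln_fwd(X1, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]])
    H_pre <- c2$out %*% params[[paste0(pre, "W1")]] +
      rep(params[[paste0(pre, "b1")]], each = nrow(X))
    H <- pmax(H_pre, 0)
    f_out <- H %*% params[[paste0(pre, "W2")]] +
      rep(params[[paste0(pre, "b2")]], each = nrow(X))
    if (!is.null(drop_masks)) f_out <- f_out * drop_masks[[l]]$ffn
    X2 <- X1 + f_out
    if (keep_cache)
      caches[[l]] <- list(Xin = X, c1 = c1, at = at, X1 = X1, c2 = c2, H = H)
    X <- X2
  }
  cf <- ln_fwd(X, params$lnf_g, params$lnf_b)
  n_real <- rowSums(mask)
  pooled <- rowsum(cf$out * mvec, group) / n_real
  yhat <- as.vector(pooled %*% params$w_head) + params$b_head
  res <- list(yhat = yhat)
  if (keep_cache)
    res <- c(res, list(caches = caches, cf = cf, pooled = pooled, Xlast = X,
                       tok_flat = tok_flat, mvec = mvec, group = group,
                       n_real = n_real, B = B, L = L, mask = mask))
  res
}

# Backward pass from d(loss)/d(yhat); returns gradient list parallel to params.
model_bwd <- function(params, fwd, dyhat, cfg, drop_masks = NULL) {
  B <- fwd$B; L <- fwd$L
  g <- list()
  g$w_head <- crossprod(fwd$pooled, dyhat)
  g$b_head <- sum(dyhat)
  dpooled <- dyhat %*% t(params$w_head)
  dXf <- dpooled[fwd$group, , drop = FALSE] * (fwd$mvec / fwd$n_real[fwd$group])
  bf <- ln_bwd(dXf, fwd$cf, params$lnf_g)
  g$lnf_g <- bf$dg; g$lnf_b <- bf$db
  dX <- bf$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("L%d_", l)
    ca <- fwd$caches[[l]]
    d_fout <- dX
    if (!is.null(drop_masks)) d_fout <- d_fout * drop_masks[[l]]$ffn
    # feed-forward block
    g[[paste0(pre, "W2")]] <- crossprod(ca$H, d_fout)
    g[[paste0(pre, "b2")]] <- colSums(d_fout)
    dH <- d_fout %*% t(params[[paste0(pre, "W2")]])
    dH_pre <- dH * (ca$H > 0)
    g[[paste0(pre, "W1")]] <- crossprod(ca$c2$out, dH_pre)
    g[[paste0(pre, "b1")]] <- colSums(dH_pre)
    dZ <- dH_pre %*% t(params[[paste0(pre, "W1")]])
    b2 <- ln_bwd(dZ, ca$c2, params[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- b2$dg; g[[paste0(pre, "ln2_b")]] <- b2$db
    dX1 <- dX + b2$dX
    # attention block
    d_aout <- dX1
    if (!is.null(drop_masks)) d_aout <- d_aout * drop_masks[[l]]$attn
    ab <- attn_bwd(d_aout, ca$c1$out, params[[paste0(pre, "Wq")]],
                   params[[paste0(pre, "Wk")]], params[[paste0(pre, "Wv")]],
                   params[[paste0(pre, "Wo")]], ca$at, B, L, cfg$n_heads,
                   fwd$mask)
    g[[paste0(pre, "Wq")]] <- ab$dWq; g[[paste0(pre, "Wk")]] <- ab$dWk
    g[[paste0(pre, "Wv")]] <- ab$dWv; g[[paste0(pre, "Wo")]] <- ab$dWo
    b1 <- ln_bwd(ab$dX, ca$c1, params[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- b1$dg; g[[paste0(pre, "ln1_b")]] <- b1$db
    dX <- dX1 + b1$dX
  }
  dE_rows <- rowsum(dX, fwd$tok_flat)
  dE <- matrix(0, 21, ncol(dX))
  dE[as.integer(rownames(dE_rows)), ] <- dE_rows
  g$E <- dE
  dP_rows <- rowsum(dX, rep(seq_len(L), B))
  dP <- matrix(0, cfg$max_length, ncol(dX))
  dP[as.integer(rownames(dP_rows)), ] <- dP_rows
  g$P <- dP
  g[names(params)]
}

adam_step <- function(state, params, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    gm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gm^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

tokens_matrix <- function(sequences, max_length) {
  t(vapply(sequences, tokenize, integer(max_length), max_length = max_length))
}

#' Train the attention-based free-energy regressor
#'
#' Splits the dataset into train/validation/test per the config, trains the
#' encoder with Adam on mean-squared error, and keeps the checkpoint with
#' the best validation RMSE (early stopping). Everything — initialization,
#' split, shuffling, dropout — is driven by `config$seed`, so the same data
#' and config reproduce the identical training history.
#'
#' @param data A data.frame with columns `sequence` and `ddf` (sequences up
#'   to 24 residues; shorter ones are padded and masked).
#' @param config A [model_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `ddf_model`: best parameters, config,
#'   per-epoch `history` (train/val RMSE), and the row indices of the
#'   train/validation/test split.
#' @export
train_ddf_model <- function(data, config = model_config(), verbose = FALSE) {
  stopifnot(all(c("sequence", "ddf") %in% names(data)))
  n <- nrow(data)
  if (n < 10) stop("need at least 10 examples to train", call. = FALSE)
  toks <- tokens_matrix(data$sequence, config$max_length)
  y <- data$ddf
  out <- local_seed(config$seed, {
    perm <- sample.int(n)
    n_tr <- max(1L, floor(config$splits[1] * n))
    n_va <- max(1L, floor(config$splits[2] * n))
    idx_tr <- perm[seq_len(n_tr)]
    idx_va <- perm[n_tr + seq_len(min(n_va, n - n_tr))]
    idx_te <- setdiff(perm, c(idx_tr, idx_va))
    params <- init_params(config)
    state <- list(m = lapply(params, function(x) x * 0),
                  v = lapply(params, function(x) x * 0))
    best <- list(val = Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_rmse = numeric(),
                       val_rmse = numeric())
    t_adam <- 0L
    n_batches <- ceiling(length(idx_tr) / config$batch_size)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(idx_tr)
      sse <- 0
      for (b in seq_len(n_batches)) {
        rows <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size,
                                                            length(ord))]
        tb <- toks[rows, , drop = FALSE]
        dm <- NULL
        if (config$dropout > 0) {
          keep <- 1 - config$dropout
          dm <- lapply(seq_len(config$n_layers), function(l) list(
            attn = matrix(stats::rbinom(length(rows) * ncol(tb) * config$embed_dim,
                                        1, keep) / keep,
                          length(rows) * ncol(tb), config$embed_dim),
            ffn = matrix(stats::rbinom(length(rows) * ncol(tb) * config$embed_dim,
                                       1, keep) / keep,
                         length(rows) * ncol(tb), config$embed_dim)))
        }
        fwd <- model_fwd(params, tb, config, keep_cache = TRUE, drop_masks = dm)
        resid <- fwd$yhat - y[rows]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
               call. = FALSE)
        sse <- sse + sum(resid^2)
        dyhat <- matrix(2 * resid / length(rows), ncol = 1)
        grads <- model_bwd(params, fwd, dyhat, config, drop_masks = dm)
        t_adam <- t_adam + 1L
        upd <- adam_step(state, params, grads, config$learning_rate, t_adam)
        state <- upd$state; params <- upd$params
      }
      tr_rmse <- sqrt(sse / length(idx_tr))
      va_rmse <- if (length(idx_va) > 0)
        sqrt(mean((batched_fwd(params, toks[idx_va, , drop = FALSE], config) -
                     y[idx_va])^2)) else NA_real_
      hist <- rbind(hist, data.frame(epoch = ep, train_rmse = tr_rmse,
                                     val_rmse = va_rmse))
      if (verbose)
        message(sprintf("epoch %3d  train RMSE %.3f  val RMSE %.3f",
                        ep, tr_rmse, va_rmse))
      track <- if (is.na(va_rmse)) tr_rmse else va_rmse
      if (track < best$val - 1e-6) {
        best <- list(val = track, params = params, epoch = ep)
      } else if (ep - best$epoch >= config$patience) break
    }
    list(best = best, hist = hist, idx = list(train = idx_tr, val = idx_va,
                                              test = idx_te))
  })
  structure(list(params = out$best$params, config = config,
                 history = out$hist, best_epoch = out$best$epoch,
                 split = out$idx),
            class = "ddf_model")
}

batched_fwd <- function(params, toks, cfg, batch = 256L) {
  n <- nrow(toks)
  yhat <- numeric(n)
  for (b in seq_len(ceiling(n / batch))) {
    rows <- ((b - 1L) * batch + 1L):min(b * batch, n)
    yhat[rows] <- model_fwd(params, toks[rows, , drop = FALSE], cfg)$yhat
  }
  yhat
}

#' @export
print.ddf_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Attention-based free-energy regressor ",
                     "(%d layers, %d heads, %d-dim embeddings)\n"),
              cfg$n_layers, cfg$n_heads, cfg$embed_dim))
  cat(sprintf("  trained %d epochs, best validation RMSE %.3f kJ/mol at epoch %d\n",
              nrow(x$history), min(x$history$val_rmse, na.rm = TRUE),
              x$best_epoch))
  invisible(x)
}

#' Predict sensing free energies for peptide sequences
#'
#' Generic over the package's predictor implementations: the trained
#' attention model (`ddf_model`), the additive baseline (`additive_model`),
#' and the constant stub ([constant_predictor()]). Inference is
#' deterministic. Predictions for short peptides (<= 12 residues) carry a
#' caution because the downstream length extrapolation amplifies them
#' strongly.
#'
#' @param object A predictor.
#' @param sequences Character vector of validated peptide sequences (7-24
#'   residues for direct queries; the structure-screening module may pass
#'   shorter terminal fragments).
#' @param ... Unused.
#' @return Numeric vector of \eqn{\Delta\Delta F} predictions (kJ/mol).
#' @export
predict_ddf <- function(object, sequences, ...) UseMethod("predict_ddf")

#' @rdname predict_ddf
#' @export
predict_ddf.ddf_model <- function(object, sequences, ...) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (any(nchar(sequences) <= 12))
    message("note: predictions for short peptides (<= 12 residues) are ",
            "amplified by length extrapolation; interpret with caution")
  toks <- tokens_matrix(sequences, object$config$max_length)
  batched_fwd(object$params, toks, object$config)
}

#' @rdname predict_ddf
#' @export
predict_ddf.additive_model <- function(object, sequences, ...) {
  coefs <- object$coefficients
  coefs[is.na(coefs)] <- 0
  vapply(sequences, function(s) sum(coefs[strsplit(s, "")[[1]]]), numeric(1),
         USE.NAMES = FALSE)
}

#' Constant stub predictor
#'
#' Returns the same \eqn{\Delta\Delta F} for every sequence. Useful for
#' exercising and testing the downstream physics and screening machinery
#' without a trained model.
#'
#' @param value The constant prediction (kJ/mol).
#' @return An object of class `constant_predictor`.
#' @export
constant_predictor <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(value = value), class = "constant_predictor")
}

#' @rdname predict_ddf
#' @export
predict_ddf.constant_predictor <- function(object, sequences, ...) {
  rep(object$value, length(sequences))
}

#' @rdname predict_ddf
#' @export
predict_ddf.default <- function(object, sequences, ...) {
  stop("no predictor loaded: expected a ddf_model, additive_model, or ",
       "constant_predictor", call. = FALSE)
}

#' Root-mean-square prediction error on a test set
#'
#' @param object A predictor accepted by [predict_ddf()].
#' @param data A data.frame with columns `sequence` and `ddf` (>= 1 row).
#' @return List with `rmse`, `residual_mean`, `residual_sd` (all kJ/mol)
#'   and `n`.
#' @export
evaluate_rmse <- function(object, data) {
  stopifnot(all(c("sequence", "ddf") %in% names(data)))
  if (nrow(data) < 1) stop("test set is empty", call. = FALSE)
  resid <- predict_ddf(object, data$sequence) - data$ddf
  list(rmse = sqrt(mean(resid^2)),
       residual_mean = mean(resid),
       residual_sd = stats::sd(resid),
       n = nrow(data))
}

#' Save / load a trained regressor
#'
#' The checkpoint embeds the full configuration and the package version; a
#' reloaded model predicts bit-identically to the in-memory one.
#'
#' @param model A `ddf_model`.
#' @param path Checkpoint file path.
#' @return `load_ddf_model` returns the model.
#' @export
save_ddf_model <- function(model, path) {
  stopifnot(inherits(model, "ddf_model"))
  model$package_version <- as.character(utils::packageVersion("memsense"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ddf_model
#' @export
load_ddf_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "ddf_model"))
    stop("file does not contain a ddf_model checkpoint", call. = FALSE)
  model
}
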