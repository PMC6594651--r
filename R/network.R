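# The interaction network: trainable residue embedding -> per-window-size 1D
# convolutions (stride 1) -> masked global max-pooling -> batch-normalised
# ELU dense stack for the protein; fingerprint -> dense stack for the drug;
# concatenation -> joint dense stack -> sigmoid output. Forward and backward
# passes are implemented directly in matrix code; the convolution is
# evaluated as a sum of shifted embedding-slice products, which is the
# literal double sum (x*w)_j = sum_a sum_b w[a,b] x[a, j+b] batched over
# filters and sequences.

#' Exponential linear unit
#'
#' `alpha * (exp(x) - 1)` for `x < 0`, `x` otherwise; continuous at 0.
#'
#' @param x Numeric vector/matrix.
#' @param alpha Negative-side scale; default 1.
#' @return Same shape as `x`.
#' @examples elu(c(-1, 0, 2))
#' @export
elu <- function(x, alpha = 1) {
  ifelse(x >= 0, x, alpha * (exp(x) - 1))
}

.elu_grad <- function(x, alpha = 1) {
  ifelse(x >= 0, 1, alpha * exp(x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Model hyperparameter configuration
#'
#' Assembles and validates the architecture/training hyperparameters. The
#' full-scale reference configuration uses 128 filters per window size, a
#' maximum protein length (MPL) of 2500, learning rate 1e-4, Morgan
#' fingerprints of width 2048, and ELU activations; window sizes, embedding
#' size and dense widths are grid-search material rather than constants,
#' so the defaults below are simply usable multi-scale settings.
#'
#' @param window_sizes Integer vector of convolution window sizes.
#' @param filters_per_window Filters per window size; default 128.
#' @param embedding_size Residue embedding dimension; default 20.
#' @param mpl Maximum (padded) protein length; default 2500.
#' @param protein_dense_sizes,drug_dense_sizes,joint_dense_sizes Hidden
#'   widths of the three dense stacks.
#' @param n_bits Drug fingerprint width; default 2048.
#' @param elu_alpha ELU negative-side scale; default 1.
#' @param l2_lambda L2 penalty weight on dense and convolution kernels
#'   (embedding, biases and batch-norm parameters are exempt).
#' @param spatial_dropout_rate Spatial dropout on the embedding layer:
#'   whole embedding channels are zeroed per sample during training.
#' @param dense_dropout_rate Ordinary dropout after dense activations.
#' @param learning_rate Adam learning rate; default 1e-4.
#' @param batch_size Minibatch size; default 32.
#' @param epochs Training epochs; default 10.
#' @param mask_padding If `TRUE` (default), window positions that reach
#'   into the pad margin are excluded from global max-pooling (set to -Inf
#'   before the max); `FALSE` reproduces the unmasked behaviour in which
#'   pooling alone is trusted to filter pad convolutions.
#' @param conv_bias Include a per-filter bias; disable for formula-exact
#'   convolution checks.
#' @param pad_zero Pin the pad embedding row at zeros.
#' @param seed Integer seed used for initialisation and training streams.
#' @return A `model_config` list.
#' @export
model_config <- function(window_sizes = c(8L, 16L, 24L, 32L),
                         filters_per_window = 128L,
                         embedding_size = 20L,
                         mpl = 2500L,
                         protein_dense_sizes = c(128L),
                         drug_dense_sizes = c(128L),
                         joint_dense_sizes = c(32L),
                         n_bits = 2048L,
                         elu_alpha = 1,
                         l2_lambda = 1e-6,
                         spatial_dropout_rate = 0.2,
                         dense_dropout_rate = 0,
                         learning_rate = 1e-4,
                         batch_size = 32L,
                         epochs = 10L,
                         mask_padding = TRUE,
                         conv_bias = TRUE,
                         pad_zero = FALSE,
                         seed = 1L) {
  cfg <- list(window_sizes = as.integer(window_sizes),
              filters_per_window = as.integer(filters_per_window),
              embedding_size = as.integer(embedding_size),
              mpl = as.integer(mpl),
              protein_dense_sizes = as.integer(protein_dense_sizes),
              drug_dense_sizes = as.integer(drug_dense_sizes),
              joint_dense_sizes = as.integer(joint_dense_sizes),
              n_bits = as.integer(n_bits),
              elu_alpha = elu_alpha,
              l2_lambda = l2_lambda,
              spatial_dropout_rate = spatial_dropout_rate,
              dense_dropout_rate = dense_dropout_rate,
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              mask_padding = isTRUE(mask_padding),
              conv_bias = isTRUE(conv_bias),
              pad_zero = isTRUE(pad_zero),
              seed = as.integer(seed))
  if (length(cfg$window_sizes) == 0) stop("window_sizes must be non-empty", call. = FALSE)
  if (any(c(cfg$window_sizes, cfg$filters_per_window, cfg$embedding_size,
            cfg$mpl, cfg$protein_dense_sizes, cfg$drug_dense_sizes,
            cfg$joint_dense_sizes, cfg$n_bits, cfg$batch_size) < 1)) {
    stop("all sizes must be positive integers", call. = FALSE)
  }
  if (cfg$mpl < max(cfg$window_sizes)) {
    stop("mpl must be at least the largest window size", call. = FALSE)
  }
  if (cfg$spatial_dropout_rate < 0 || cfg$spatial_dropout_rate >= 1 ||
      cfg$dense_dropout_rate < 0 || cfg$dense_dropout_rate >= 1) {
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "model_config")
}

.glorot <- function(fan_in, fan_out, n = fan_in * fan_out) {
  stats::rnorm(n, sd = sqrt(2 / (fan_in + fan_out)))
}

.init_dense_stack <- function(sizes, input_dim) {
  layers <- list()
  d <- input_dim
  for (h in sizes) {
    layers[[length(layers) + 1]] <- list(
      W = matrix(.glorot(d, h), d, h),
      b = numeric(h), gamma = rep(1, h), beta = numeric(h))
    d <- h
  }
  layers
}

.init_running_stack <- function(sizes) {
  lapply(sizes, function(h) list(mean = numeric(h), var = rep(1, h)))
}

#' Initialise an untrained interaction model
#'
#' Draws all parameters (embedding table, per-window convolution kernels,
#' dense weights) from the Xavier/Glorot normal scheme, reproducibly from
#' the seed; biases start at 0, batch-norm scales at 1.
#'
#' @param config A [model_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A `dti_model`: list with `config`, `vocabulary`, `params`
#'   (nested parameter tree), `running` (batch-norm running statistics).
#' @export
init_dti_model <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "model_config"))
  vocab <- aa_vocabulary()
  v <- length(vocab$tokens)
  es <- config$embedding_size
  nf <- config$filters_per_window
  with_seed(seed, {
    params <- list(
      emb = {
        e <- matrix(.glorot(v, es), v, es)
        if (config$pad_zero) e[vocab$pad_index, ] <- 0
        e
      },
      conv = stats::setNames(lapply(config$window_sizes, function(ws) {
        list(W = matrix(.glorot(es * ws, nf), nf, es * ws, byrow = TRUE),
             b = numeric(nf))
      }), as.character(config$window_sizes)),
      bn_pool = {
        d <- nf * length(config$window_sizes)
        list(gamma = rep(1, d), beta = numeric(d))
      },
      protein = .init_dense_stack(config$protein_dense_sizes,
                                  nf * length(config$window_sizes)),
      drug = .init_dense_stack(config$drug_dense_sizes, config$n_bits),
      joint = .init_dense_stack(
        config$joint_dense_sizes,
        utils::tail(config$protein_dense_sizes, 1) +
          utils::tail(config$drug_dense_sizes, 1)),
      out = list(
        W = matrix(.glorot(utils::tail(config$joint_dense_sizes, 1), 1),
                   ncol = 1),
        b = 0)
    )
    running <- list(
      pool = list(mean = numeric(nf * length(config$window_sizes)),
                  var = rep(1, nf * length(config$window_sizes))),
      protein = .init_running_stack(config$protein_dense_sizes),
      drug = .init_running_stack(config$drug_dense_sizes),
      joint = .init_running_stack(config$joint_dense_sizes))
    structure(list(config = config, vocabulary = vocab,
                   params = params, running = running),
              class = "dti_model")
  })
}

#' Number of trainable parameters of a model
#' @param model A `dti_model` (or `dti_fit`).
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  if (inherits(model, "dti_fit")) model <- model$model
  sum(unlist(.tree_map(length, model$params)))
}

# Apply f leaf-wise over one or more identically shaped parameter trees.
.tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i) {
      do.call(.tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

.bn_eps <- 1e-3
.bn_momentum <- 0.9

# Batch normalisation over columns. In training mode uses batch statistics
# and reports updated running statistics; in inference mode uses the frozen
# running statistics.
.bn_forward <- function(Z, par, run, training) {
  if (training && nrow(Z) > 1) {
    mu <- colMeans(Z)
    v <- pmax(colMeans(Z * Z) - mu * mu, 0)
    new_run <- list(mean = .bn_momentum * run$mean + (1 - .bn_momentum) * mu,
                    var = .bn_momentum * run$var + (1 - .bn_momentum) * v)
  } else {
    mu <- run$mean
    v <- run$var
    new_run <- run
  }
  invstd <- 1 / sqrt(v + .bn_eps)
  m <- nrow(Z)
  xhat <- (Z - matrix(mu, m, ncol(Z), byrow = TRUE)) *
    matrix(invstd, m, ncol(Z), byrow = TRUE)
  A <- xhat * matrix(par$gamma, m, ncol(Z), byrow = TRUE) +
    matrix(par$beta, m, ncol(Z), byrow = TRUE)
  list(A = A, cache = list(xhat = xhat, invstd = invstd, gamma = par$gamma),
       run = new_run)
}

.bn_backward <- function(dA, cache) {
  m <- nrow(dA)
  dgamma <- colSums(dA * cache$xhat)
  dbeta <- colSums(dA)
  dxhat <- dA * matrix(cache$gamma, m, ncol(dA), byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dZ <- (dxhat - matrix(s1 / m, m, ncol(dA), byrow = TRUE) -
           cache$xhat * matrix(s2 / m, m, ncol(dA), byrow = TRUE)) *
    matrix(cache$invstd, m, ncol(dA), byrow = TRUE)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

# Forward through one linear -> batch-norm -> ELU (-> dropout) stack.
.stack_forward <- function(H, layers, run_stack, training, alpha,
                           dropout_rate = 0) {
  caches <- vector("list", length(layers))
  new_run <- run_stack
  for (l in seq_along(layers)) {
    L <- layers[[l]]
    Z <- H %*% L$W + matrix(L$b, nrow(H), length(L$b), byrow = TRUE)
    bn <- .bn_forward(Z, L, run_stack[[l]], training)
    new_run[[l]] <- bn$run
    A <- bn$A
    H_out <- elu(A, alpha)
    mask <- NULL
    if (training && dropout_rate > 0) {
      mask <- matrix(stats::rbinom(length(H_out), 1, 1 - dropout_rate),
                     nrow(H_out)) / (1 - dropout_rate)
      H_out <- H_out * mask
    }
    caches[[l]] <- list(input = H, A = A, bn = bn$cache, mask = mask)
    H <- H_out
  }
  list(H = H, caches = caches, run = new_run)
}

.stack_backward <- function(dH, layers, caches, alpha, l2_lambda) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    cc <- caches[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dA <- dH * .elu_grad(cc$A, alpha)
    bb <- .bn_backward(dA, cc$bn)
    dW <- crossprod(cc$input, bb$dZ) + 2 * l2_lambda * layers[[l]]$W
    db <- colSums(bb$dZ)
    dH <- bb$dZ %*% t(layers[[l]]$W)
    grads[[l]] <- list(W = dW, b = db, gamma = bb$dgamma, beta = bb$dbeta)
  }
  list(dH = dH, grads = grads)
}

# Protein convolution trunk: embedding lookup (+ spatial dropout), the
# per-window convolutions, masking, and global max-pooling with argmax
# bookkeeping. `labels` is B x MPL (MPL may differ from config$mpl as long
# as it is >= every true length; with masking on the result is invariant to
# it). Returns pooled B x D values, per-window argmax start positions, and
# the cache needed for backprop.
.conv_trunk_forward <- function(cfg, params, labels, tl, training) {
  B <- nrow(labels)
  mpl <- ncol(labels)
  es <- cfg$embedding_size
  nf <- cfg$filters_per_window
  lab_vec <- as.vector(t(labels))
  E_all <- t(params$emb[lab_vec, , drop = FALSE])   # es x (B*mpl)
  drop_exp <- NULL
  if (training && cfg$spatial_dropout_rate > 0) {
    M <- matrix(stats::rbinom(es * B, 1, 1 - cfg$spatial_dropout_rate),
                es, B) / (1 - cfg$spatial_dropout_rate)
    drop_exp <- M[, rep(seq_len(B), each = mpl), drop = FALSE]
    E_all <- E_all * drop_exp
  }
  pooled <- matrix(0, B, nf * length(cfg$window_sizes))
  argmax <- matrix(NA_integer_, B, nf * length(cfg$window_sizes))
  conv_cache <- list()
  for (wi in seq_along(cfg$window_sizes)) {
    ws <- cfg$window_sizes[wi]
    if (ws > mpl) stop(sprintf("window size %d exceeds padded length %d", ws, mpl),
                       call. = FALSE)
    p_w <- mpl - ws + 1
    Wc <- params$conv[[as.character(ws)]]$W
    C <- if (cfg$conv_bias) {
      matrix(params$conv[[as.character(ws)]]$b, nf, B * p_w)
    } else {
      matrix(0, nf, B * p_w)
    }
    base <- rep((seq_len(B) - 1) * mpl, each = p_w) + rep(seq_len(p_w), B)
    for (b in 0:(ws - 1)) {
      Wb <- Wc[, (b * es + 1):((b + 1) * es), drop = FALSE]
      C <- C + Wb %*% E_all[, base + b, drop = FALSE]
    }
    if (cfg$mask_padding) {
      pos_in_block <- rep(seq_len(p_w), B)
      seq_of_col <- rep(seq_len(B), each = p_w)
      invalid <- pos_in_block > (tl[seq_of_col] - ws + 1)
      if (any(invalid)) C[, invalid] <- -Inf
    }
    cols <- matrix(NA_integer_, nf, B)   # argmax column in E_all coordinates
    off <- (wi - 1) * nf
    for (i in seq_len(B)) {
      block <- C[, ((i - 1) * p_w + 1):(i * p_w), drop = FALSE]
      if (cfg$mask_padding && tl[i] < ws) next   # no valid window: pooled 0
      am <- max.col(block, ties.method = "first")
      pooled[i, off + seq_len(nf)] <- block[cbind(seq_len(nf), am)]
      argmax[i, off + seq_len(nf)] <- am
      cols[, i] <- (i - 1L) * mpl + am
    }
    conv_cache[[as.character(ws)]] <- list(cols = cols, p_w = p_w)
  }
  list(pooled = pooled, argmax = argmax,
       cache = list(E_all = E_all, lab_vec = lab_vec, drop_exp = drop_exp,
                    conv = conv_cache, B = B, mpl = mpl))
}

.conv_trunk_backward <- function(cfg, params, dPooled, cache) {
  es <- cfg$embedding_size
  nf <- cfg$filters_per_window
  B <- cache$B
  E_all <- cache$E_all
  dE <- matrix(0, nrow(E_all), ncol(E_all))
  conv_grads <- list()
  for (wi in seq_along(cfg$window_sizes)) {
    ws <- cfg$window_sizes[wi]
    key <- as.character(ws)
    cols <- cache$conv[[key]]$cols            # nf x B (NA where no window)
    off <- (wi - 1) * nf
    G <- t(dPooled[, off + seq_len(nf), drop = FALSE])   # nf x B
    G[is.na(cols)] <- 0
    colsvec <- as.vector(cols)
    keep <- !is.na(colsvec)
    colsvec <- colsvec[keep]
    Gvec <- as.vector(G)[keep]
    fidx <- rep(seq_len(nf), B)[keep]
    Wc <- params$conv[[key]]$W
    dWc <- matrix(0, nf, es * ws)
    if (length(colsvec) > 0) {
      Gexp <- matrix(Gvec, es, length(Gvec), byrow = TRUE)
      for (b in 0:(ws - 1)) {
        Xb <- E_all[, colsvec + b, drop = FALSE]         # es x k
        dWb <- rowsum(t(Xb * Gexp), fidx)                # (<=nf) x es
        dWc[as.integer(rownames(dWb)), (b * es + 1):((b + 1) * es)] <-
          dWc[as.integer(rownames(dWb)), (b * es + 1):((b + 1) * es)] + dWb
        Wb <- Wc[, (b * es + 1):((b + 1) * es), drop = FALSE]
        contrib <- t(Wb)[, fidx, drop = FALSE] * Gexp    # es x k
        agg <- rowsum(t(contrib), colsvec + b)
        tgt <- as.integer(rownames(agg))
        dE[, tgt] <- dE[, tgt] + t(agg)
      }
    }
    dWc <- dWc + 2 * cfg$l2_lambda * Wc
    db <- if (cfg$conv_bias) rowSums(G) else numeric(nf)
    conv_grads[[key]] <- list(W = dWc, b = db)
  }
  if (!is.null(cache$drop_exp)) dE <- dE * cache$drop_exp
  demb_rows <- rowsum(t(dE), cache$lab_vec)
  demb <- matrix(0, nrow(params$emb), ncol(params$emb))
  demb[as.integer(rownames(demb_rows)), ] <- demb_rows
  if (cfg$pad_zero) demb[1, ] <- 0
  list(conv = conv_grads, demb = demb)
}

# Full forward pass over a batch. Returns probabilities, every intermediate
# needed for backprop (when want_cache), pooled/argmax traces, and the
# updated running statistics.
.forward <- function(model, labels, tl, FP, training = FALSE,
                     want_cache = FALSE) {
  cfg <- model$config
  params <- model$params
  trunk <- .conv_trunk_forward(cfg, params, labels, tl, training)
  bn0 <- .bn_forward(trunk$pooled, params$bn_pool, model$running$pool, training)
  H0 <- elu(bn0$A, cfg$elu_alpha)
  pstack <- .stack_forward(H0, params$protein, model$running$protein,
                           training, cfg$elu_alpha, cfg$dense_dropout_rate)
  dstack <- .stack_forward(FP, params$drug, model$running$drug,
                           training, cfg$elu_alpha, cfg$dense_dropout_rate)
  Hj <- cbind(pstack$H, dstack$H)
  jstack <- .stack_forward(Hj, params$joint, model$running$joint,
                           training, cfg$elu_alpha, cfg$dense_dropout_rate)
  logit <- as.vector(jstack$H %*% params$out$W) + params$out$b
  prob <- sigmoid(logit)
  running <- list(pool = bn0$run, protein = pstack$run,
                  drug = dstack$run, joint = jstack$run)
  out <- list(prob = prob, pooled = trunk$pooled, argmax = trunk$argmax,
              protein_latent = pstack$H, drug_latent = dstack$H,
              running = running)
  if (want_cache) {
    out$cache <- list(trunk = trunk$cache, bn0 = bn0$cache, A0 = bn0$A,
                      pooled = trunk$pooled, H0 = H0,
                      pstack = pstack$caches, dstack = dstack$caches,
                      jstack = jstack$caches, Hj = Hj, Hjoint = jstack$H,
                      prob = prob)
  }
  out
}

# Backward pass: gradients of the mean penalized BCE loss wrt every
# parameter, mirroring the params tree.
.backward <- function(model, fwd, y) {
  cfg <- model$config
  params <- model$params
  cache <- fwd$cache
  B <- length(y)
  dlogit <- matrix((fwd$prob - y) / B, ncol = 1)
  dW_out <- crossprod(cache$Hjoint, dlogit) + 2 * cfg$l2_lambda * params$out$W
  db_out <- sum(dlogit)
  dHj_out <- dlogit %*% t(params$out$W)
  jb <- .stack_backward(dHj_out, params$joint, cache$jstack,
                        cfg$elu_alpha, cfg$l2_lambda)
  dp_dim <- length(params$protein[[length(params$protein)]]$b)
  dHp <- jb$dH[, seq_len(dp_dim), drop = FALSE]
  dHd <- jb$dH[, (dp_dim + 1):ncol(jb$dH), drop = FALSE]
  pb <- .stack_backward(dHp, params$protein, cache$pstack,
                        cfg$elu_alpha, cfg$l2_lambda)
  db_ <- .stack_backward(dHd, params$drug, cache$dstack,
                         cfg$elu_alpha, cfg$l2_lambda)
  dA0 <- pb$dH * .elu_grad(cache$A0, cfg$elu_alpha)
  bn0b <- .bn_backward(dA0, cache$bn0)
  trunkb <- .conv_trunk_backward(cfg, params, bn0b$dZ, cache$trunk)
  list(
    emb = trunkb$demb,
    conv = trunkb$conv,
    bn_pool = list(gamma = bn0b$dgamma, beta = bn0b$dbeta),
    protein = pb$grads,
    drug = db_$grads,
    joint = jb$grads,
    out = list(W = dW_out, b = db_out)
  )
}

#' Reference single-filter convolution (the double sum)
#'
#' Convolution of one filter over one embedding matrix, stride 1: entry `j`
#' is `sum_a sum_b w[a, b] * E[a, j + b]` for `b = 0..WS-1` (1-based `j`).
#' This is the definitional form used by the oracle tests; the batched
#' trunk computes the same quantity via shifted matrix products.
#'
#' @param E Embedding matrix, `ES x MPL` (rows = embedding dimensions).
#' @param w Filter, `ES x WS` matrix.
#' @param bias Optional scalar added to every output entry.
#' @return Numeric vector of length `MPL - WS + 1`.
#' @export
convolve_window <- function(E, w, bias = 0) {
  stopifnot(is.matrix(E), is.matrix(w), nrow(E) == nrow(w))
  ws <- ncol(w)
  if (ws > ncol(E)) stop("window size exceeds embedding length", call. = FALSE)
  p <- ncol(E) - ws + 1
  out <- rep(bias, p)
  for (b in 0:(ws - 1)) {
    out <- out + colSums(w[, b + 1] * E[, (1 + b):(p + b), drop = FALSE])
  }
  out
}

#' Global max-pooling over valid window positions
#'
#' Returns the maximum of a convolution output over the valid start
#' positions, and the earliest position attaining it (deterministic
#' tie-break, needed for attribution). With an empty valid set (window
#' longer than the sequence) the pooled value is defined as 0 with no
#' position and `degenerate = TRUE`.
#'
#' @param conv_out Numeric vector of convolution outputs.
#' @param valid_positions Integer vector of valid 1-based start positions;
#'   defaults to all positions.
#' @return List with `value`, `position` (NA when degenerate), `degenerate`.
#' @export
global_max_pool <- function(conv_out, valid_positions = seq_along(conv_out)) {
  stopifnot(length(conv_out) > 0,
            all(valid_positions >= 1 & valid_positions <= length(conv_out)))
  if (length(valid_positions) == 0) {
    return(list(value = 0, position = NA_integer_, degenerate = TRUE))
  }
  vals <- conv_out[valid_positions]
  k <- which.max(vals)
  list(value = vals[k], position = as.integer(valid_positions[k]),
       degenerate = FALSE)
}

#' Penalized binary cross-entropy loss
#'
#' Mean BCE `-(1/n) sum [y log p + (1-y) log(1-p)]` plus an L2 penalty
#' `lambda * sum ||W||^2` over dense and convolution weight matrices
#' (embedding, biases and batch-norm parameters are exempt). Probabilities
#' are clipped to `[1e-7, 1 - 1e-7]` for stability.
#'
#' @param probabilities Predicted probabilities in (0,1).
#' @param labels 0/1 labels, same length.
#' @param model Optional `dti_model` supplying the penalized weights.
#' @param l2_lambda Penalty weight; default 0.
#' @return Scalar loss.
#' @export
bce_loss <- function(probabilities, labels, model = NULL, l2_lambda = 0) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must have the same length", call. = FALSE)
  }
  assert_binary_labels(labels)
  p <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  j <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  if (!is.null(model) && l2_lambda > 0) {
    j <- j + l2_lambda * .l2_weight_sum(model$params)
  }
  j
}

.l2_weight_sum <- function(params) {
  s <- sum(vapply(params$conv, function(cv) sum(cv$W^2), numeric(1)))
  for (st in list(params$protein, params$drug, params$joint)) {
    s <- s + sum(vapply(st, function(L) sum(L$W^2), numeric(1)))
  }
  s + sum(params$out$W^2)
}

#' Forward trace for one drug-protein pair
#'
#' Runs the network in inference mode on a single pair and exposes the
#' intermediates used by attribution and inspection: per-(window, filter)
#' pooled values with their argmax window start positions, both latent
#' vectors, and the interaction probability.
#'
#' @param model A `dti_model` or `dti_fit`.
#' @param protein An `encoded_protein` (or `encoded_proteins` of size 1).
#' @param fingerprint Binary vector of length `config$n_bits`.
#' @return A `forward_trace`: list with `probability`, `pooled` (tibble:
#'   `window_size`, `filter`, `value`, `argmax_start`, `degenerate`),
#'   `protein_latent`, `drug_latent`.
#' @export
forward_trace <- function(model, protein, fingerprint) {
  if (inherits(model, "dti_fit")) model <- model$model
  stopifnot(inherits(model, "dti_model"))
  enc <- .as_single_encoded(protein)
  if (length(fingerprint) != model$config$n_bits) {
    stop(sprintf("fingerprint must have length %d", model$config$n_bits),
         call. = FALSE)
  }
  fwd <- .forward(model, matrix(enc$labels, nrow = 1), enc$true_length,
                  matrix(as.numeric(fingerprint), nrow = 1),
                  training = FALSE)
  cfg <- model$config
  nf <- cfg$filters_per_window
  pooled <- tibble::tibble(
    window_size = rep(cfg$window_sizes, each = nf),
    filter = rep(seq_len(nf), length(cfg$window_sizes)),
    value = as.vector(fwd$pooled[1, ]),
    argmax_start = as.integer(fwd$argmax[1, ]))
  pooled$degenerate <- is.na(pooled$argmax_start)
  structure(list(probability = fwd$prob[1], pooled = pooled,
                 protein_latent = as.vector(fwd$protein_latent),
                 drug_latent = as.vector(fwd$drug_latent)),
            class = "forward_trace")
}

.as_single_encoded <- function(protein) {
  if (inherits(protein, "encoded_protein")) return(protein)
  if (inherits(protein, "encoded_proteins")) {
    if (nrow(protein$labels) != 1) {
      stop("expected a single encoded protein", call. = FALSE)
    }
    return(structure(list(labels = protein$labels[1, ],
                          true_length = unname(protein$true_length[1]),
                          vocabulary = protein$vocabulary),
                     class = "encoded_protein"))
  }
  stop("`protein` must be an encoded protein", call. = FALSE)
}
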