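# Independent oracle: the convolution double sum evaluated literally,
# element by element.
brute_conv <- function(E, w, bias = 0) {
  es <- nrow(E); ws <- ncol(w); p <- ncol(E) - ws + 1
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- bias
    for (a in seq_len(es)) {
      for (b in 0:(ws - 1)) acc <- acc + w[a, b + 1] * E[a, j + b]
    }
    out[j] <- acc
  }
  out
}

test_that("ELU matches its closed form and is continuous at zero", {
  expect_equal(elu(0), 0)
  expect_equal(elu(2), 2)
  expect_equal(elu(-1), exp(-1) - 1, tolerance = 1e-12)
  expect_equal(elu(-1, alpha = 2), 2 * (exp(-1) - 1))
  x <- seq(-3, 3, by = 0.25)
  expect_true(all(diff(elu(x)) > 0))    # monotone
})

test_that("convolve_window equals the brute-force double sum", {
  # hand-checked toy: ES=2, WS=2
  E <- rbind(c(1, 2, 3), c(0, 1, 0))
  w <- rbind(c(1, 0), c(0, 1))
  expect_equal(convolve_window(E, w), c(2, 2))
  expect_equal(convolve_window(E, matrix(0, 2, 2)), c(0, 0))
  # identity filter
  expect_equal(convolve_window(matrix(1:5, 1), matrix(1, 1, 1)), 1:5)

  set.seed(9)
  for (i in 1:100) {
    es <- sample(1:8, 1); ws <- sample(1:6, 1); mpl <- sample(ws:50, 1)
    E <- matrix(rnorm(es * mpl), es)
    w <- matrix(rnorm(es * ws), es)
    b <- rnorm(1)
    expect_equal(convolve_window(E, w, b), brute_conv(E, w, b),
                 tolerance = 1e-6)
  }
})

test_that("the batched convolution trunk agrees with the per-filter oracle", {
  cfg <- tiny_config(conv_bias = TRUE)
  model <- init_dti_model(cfg)
  set.seed(4)
  seqs <- tibble::tibble(protein_id = c("a", "b"),
                         sequence = c(random_sequence(20), random_sequence(33)))
  enc <- encode_proteins(seqs, mpl = cfg$mpl)
  trunk <- convdti:::.conv_trunk_forward(cfg, model$params, enc$labels,
                                         unname(enc$true_length), FALSE)
  nf <- cfg$filters_per_window
  for (i in 1:2) {
    E <- t(model$params$emb[enc$labels[i, ], ])
    for (wi in seq_along(cfg$window_sizes)) {
      ws <- cfg$window_sizes[wi]
      for (f in seq_len(nf)) {
        w <- matrix(model$params$conv[[as.character(ws)]]$W[f, ],
                    nrow = cfg$embedding_size)   # offset-major columns
        cv <- brute_conv(E, w, model$params$conv[[as.character(ws)]]$b[f])
        valid <- valid_window_positions(enc$true_length[i], ws)
        gm <- global_max_pool(cv, valid)
        expect_equal(trunk$pooled[i, (wi - 1) * nf + f], gm$value,
                     tolerance = 1e-9)
        expect_equal(trunk$argmax[i, (wi - 1) * nf + f], gm$position)
      }
    }
  }
})

test_that("global max-pooling respects masks and breaks ties earliest", {
  expect_equal(global_max_pool(c(3, 7, 7, 1)),
               list(value = 7, position = 2L, degenerate = FALSE))
  expect_equal(global_max_pool(c(5, 9), valid_positions = 1L),
               list(value = 5, position = 1L, degenerate = FALSE))
  expect_true(global_max_pool(c(1, 2), integer(0))$degenerate)
  set.seed(5)
  for (i in 1:50) {
    v <- rnorm(sample(3:30, 1))
    valid <- sort(sample(seq_along(v), sample(seq_along(v), 1)))
    gm <- global_max_pool(v, valid)
    expect_equal(gm$value, max(v[valid]))
    expect_equal(gm$position, valid[which.max(v[valid])])
  }
})

test_that("the BCE loss matches hand evaluation and the L2 scope", {
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(1 - 1e-9, 1e-9), c(1, 0)), 1e-6)   # clipping limit
  expect_error(bce_loss(0.5, c(1, 0)), "same length")

  cfg <- tiny_config()
  model <- init_dti_model(cfg)
  zeroed <- convdti:::.tree_map(function(x) x * 0, model$params)
  model$params <- zeroed
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0), model, l2_lambda = 1),
               log(2))  # all-zero weights: zero penalty
})

test_that("forward output has the documented geometry and range", {
  cfg <- tiny_config(window_sizes = c(8L, 16L), filters_per_window = 128L,
                     mpl = 60L)
  model <- init_dti_model(cfg)
  enc <- encode_sequence(random_sequence(50), mpl = cfg$mpl)
  set.seed(6)
  fp <- rbinom(cfg$n_bits, 1, 0.3)
  tr <- forward_trace(model, enc, fp)
  expect_equal(nrow(tr$pooled), 128 * 2)  # filters x windows
  expect_equal(sum(tr$pooled$window_size == 8), 128)
  expect_gt(tr$probability, 0)
  expect_lt(tr$probability, 1)
  valid8 <- valid_window_positions(50, 8)
  expect_true(all(tr$pooled$argmax_start[tr$pooled$window_size == 8] %in% valid8))
})

test_that("with masking on the trace is invariant to the padded length", {
  cfg <- tiny_config(mpl = 45L)
  model <- init_dti_model(cfg)
  s <- random_sequence(30)
  set.seed(8)
  fp <- rbinom(cfg$n_bits, 1, 0.3)
  t1 <- forward_trace(model, encode_sequence(s, mpl = 45), fp)
  t2 <- forward_trace(model, encode_sequence(s, mpl = 120), fp)
  t3 <- forward_trace(model, encode_sequence(s, mpl = 30), fp)
  expect_equal(t1$probability, t2$probability, tolerance = 1e-12)
  expect_equal(t1$pooled, t2$pooled, tolerance = 1e-12)
  expect_equal(t1$pooled, t3$pooled, tolerance = 1e-12)
})

test_that("a motif-matched filter pools identically wherever the motif sits", {
  cfg <- tiny_config(window_sizes = 3L, filters_per_window = 2L, mpl = 40L)
  model <- init_dti_model(cfg)
  v <- model$vocabulary
  motif <- "CDE"
  model$params$conv[["3"]]$W[1, ] <- 5 * motif_filter(motif, model$params$emb, v)
  model$params$conv[["3"]]$b[] <- 0
  vals <- vapply(c(1, 10, 25, 28), function(off) {
    chars <- rep("A", 30)
    chars[off:(off + 2)] <- strsplit(motif, "")[[1]]
    enc <- encode_sequence(paste(chars, collapse = ""), mpl = cfg$mpl)
    trunk <- convdti:::.conv_trunk_forward(cfg, model$params,
                                           matrix(enc$labels, nrow = 1),
                                           enc$true_length, FALSE)
    expect_equal(trunk$argmax[1, 1], as.integer(off))
    trunk$pooled[1, 1]
  }, numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_config(window_sizes = c(2L, 3L), filters_per_window = 3L,
                     embedding_size = 4L, mpl = 12L, protein_dense_sizes = 5L,
                     drug_dense_sizes = 4L, joint_dense_sizes = 3L,
                     n_bits = 6L, l2_lambda = 1e-3)
  model <- init_dti_model(cfg)
  set.seed(3)
  seqs <- tibble::tibble(protein_id = paste0("p", 1:4),
                         sequence = replicate(4, random_sequence(sample(6:10, 1))))
  enc <- encode_proteins(seqs, mpl = cfg$mpl)
  FP <- matrix(rbinom(4 * cfg$n_bits, 1, 0.5), 4)
  y <- c(1, 0, 1, 0)
  lossfn <- function(m) {
    fwd <- convdti:::.forward(m, enc$labels, unname(enc$true_length), FP,
                              training = TRUE)
    bce_loss(fwd$prob, y, m, cfg$l2_lambda)
  }
  fwd <- convdti:::.forward(model, enc$labels, unname(enc$true_length), FP,
                            training = TRUE, want_cache = TRUE)
  grads <- convdti:::.backward(model, fwd, y)

  flatten <- function(tree, path = character()) {
    if (is.list(tree)) {
      out <- list()
      for (nm in names(tree)) out <- c(out, flatten(tree[[nm]], c(path, nm)))
      out
    } else list(list(path = path, val = tree))
  }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1) tree[[path]] <- val
    else tree[[path[1]]] <- set_leaf(tree[[path[1]]], path[-1], val)
    tree
  }
  get_leaf <- function(tree, path) { for (p in path) tree <- tree[[p]]; tree }
  eps <- 1e-5
  for (lf in flatten(model$params)) {
    n <- length(lf$val)
    for (i in unique(c(1, max(1, n %/% 2), n))) {
      for (sgn in c(1, -1)) {
        v <- lf$val; v[i] <- v[i] + sgn * eps
        m2 <- model; m2$params <- set_leaf(model$params, lf$path, v)
        if (sgn > 0) up <- lossfn(m2) else dn <- lossfn(m2)
      }
      num <- (up - dn) / (2 * eps)
      ana <- get_leaf(grads, lf$path)[i]
      if (abs(num) + abs(ana) > 1e-10) {
        expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4)
      }
    }
  }
})
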