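# Independent step-up oracle for the BH adjustment.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

test_that("window coverage counts events and residues as specified", {
  expect_equal(window_coverage(1, 3, c(2, 5)), 1L)
  expect_equal(window_coverage(1, 3, c(2, 5), mode = "residues"), 1L)
  expect_equal(window_coverage(c(1, 1), 3, 2), 2L)                 # multiset
  expect_equal(window_coverage(c(1, 1), 3, 2, mode = "residues"), 1L)
  expect_equal(window_coverage(10, 2, c(1, 2)), 0L)
  expect_error(window_coverage(1, 3, integer(0)), "empty residue")

  # brute-force cross-check on random geometries
  set.seed(30)
  for (i in 1:30) {
    len <- sample(20:60, 1); ws <- sample(2:8, 1)
    starts <- sample(seq_len(len - ws + 1), sample(1:20, 1), replace = TRUE)
    resid <- sort(sample(len, sample(1:10, 1)))
    events <- sum(vapply(starts, function(s) {
      sum(resid >= s & resid <= s + ws - 1)
    }, numeric(1)))
    covered <- sum(vapply(resid, function(r) {
      any(starts <= r & starts + ws - 1 >= r)
    }, logical(1)))
    expect_equal(window_coverage(starts, ws, resid), as.integer(events))
    expect_equal(window_coverage(starts, ws, resid, mode = "residues"),
                 as.integer(covered))
  }
})

test_that("the Monte-Carlo null matches closed-form expectations", {
  # annotation covering the whole sequence: every window covers exactly WS
  n0 <- sample_null(40, 5, residues = 1:40, n_results = 16, n_reps = 200,
                    seed = 2)
  expect_equal(n0$mean, 16 * 5)
  expect_equal(n0$sd, 0)

  # single valid start: degenerate support
  n1 <- sample_null(6, 6, residues = c(2, 4), n_results = 8, n_reps = 100,
                    seed = 3)
  expect_equal(n1$sd, 0)
  expect_equal(n1$mean, 8 * 2)   # the only window covers both residues

  # closed form: E[events] = n_results * sum_r (#starts covering r) / #starts
  set.seed(31)
  for (i in 1:5) {
    len <- sample(50:150, 1); ws <- sample(3:9, 1)
    resid <- sort(sample(len, sample(3:12, 1)))
    n_starts <- len - ws + 1
    cover_r <- vapply(resid, function(r) {
      sum(pmax(1, r - ws + 1):min(n_starts, r) > 0)
    }, numeric(1))
    expected <- 64 * sum(pmin(cover_r, n_starts)) / n_starts
    nd <- sample_null(len, ws, resid, n_results = 64, n_reps = 4000, seed = i)
    se <- nd$sd / sqrt(nd$n_reps)
    expect_lt(abs(nd$mean - expected), 3 * se + 1e-9)
  }

  expect_error(sample_null(10, 12, residues = 2), "exceeds sequence length")
  expect_error(sample_null(50, 5, residues = 60), "residue indices exceed")
  # reproducibility
  expect_equal(sample_null(80, 5, 1:10, seed = 9),
               sample_null(80, 5, 1:10, seed = 9))
})

test_that("right-tailed p-values follow the fitted normal and its degeneracies", {
  null <- structure(list(window_size = 5L, n_results = 128L, n_reps = 10000L,
                         mode = "events", mean = 10, sd = 2),
                    class = "null_distribution")
  expect_equal(right_tailed_p(10, null), 0.5)
  expect_equal(right_tailed_p(10 + 1.6449 * 2, null), 0.05, tolerance = 1e-3)
  expect_gt(right_tailed_p(0, null), 0.999)

  deg <- structure(list(window_size = 5L, n_results = 1L, n_reps = 10L,
                        mode = "events", mean = 4, sd = 0),
                   class = "null_distribution")
  expect_equal(as.numeric(right_tailed_p(4, deg)), 1)
  expect_equal(as.numeric(right_tailed_p(5, deg)), 0)
  expect_true(attr(right_tailed_p(5, deg), "degenerate"))
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(32)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("entry attribution ties observed statistics to their own nulls", {
  cfg <- tiny_config(window_sizes = c(3L, 5L), filters_per_window = 6L,
                     mpl = 60L)
  model <- init_dti_model(cfg)
  enc <- encode_sequence(random_sequence(50), mpl = 60)
  res <- attribute_entry(model, enc, residues = c(10, 11, 12, 30),
                         n_reps = 500, seed = 4)
  expect_equal(res$window_size, c(3, 5))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  expect_equal(attr(res, "min_adjusted_p"), min(res$p_adjusted))
  expect_named(attr(res, "significant"), c("0.01", "0.05", "0.1"))
  # observed equals the coverage of the trace's argmax starts
  st <- convdti:::.argmax_starts(model, enc)
  expect_equal(res$observed[1],
               window_coverage(st[["3"]], 3, c(10, 11, 12, 30)))
  expect_error(attribute_entry(model, enc, residues = 55), "exceed")
})

test_that("significance summaries are monotone and flag-consistent", {
  res <- tibble::tibble(entry_id = rep(c("a", "b", "c"), each = 2),
                        window_size = rep(c(3, 5), 3),
                        p_adjusted = c(0.001, 0.2, 0.04, 0.9, 0.5, 0.6))
  summ <- attribution_summary(res)
  expect_equal(summ$min_adjusted_p, c(0.001, 0.04, 0.5))
  expect_equal(summ$sig_05, c(TRUE, TRUE, FALSE))
  fr <- summarize_significance(res)
  expect_equal(fr$fraction, c(1 / 3, 2 / 3, 2 / 3))
  expect_true(all(diff(fr$fraction) >= 0))
  all_small <- dplyr::mutate(res, p_adjusted = 0.001)
  expect_equal(summarize_significance(all_small)$fraction, rep(1, 3))
  all_half <- dplyr::mutate(res, p_adjusted = 0.5)
  expect_equal(summarize_significance(all_half)$fraction, rep(0, 3))
})

test_that("top-k coverage follows the single-window geometry and accounting", {
  cfg <- tiny_config(window_sizes = 4L, filters_per_window = 5L, mpl = 40L)
  model <- init_dti_model(cfg)
  enc <- encode_sequence(random_sequence(30), mpl = 40)

  cov1 <- top_k_coverage(model, enc, k = 1)
  expect_equal(nrow(cov1), 4)                     # one contiguous run of WS
  expect_equal(cov1$residue, min(cov1$residue) + 0:3)
  expect_equal(cov1$n_windows, rep(1L, 4))

  cov_all <- top_k_coverage(model, enc, k = 5)
  trunk <- convdti:::.conv_trunk_forward(cfg, model$params,
                                         matrix(enc$labels, nrow = 1),
                                         enc$true_length, FALSE)
  expected_sum <- sum(vapply(trunk$argmax[1, ], function(s) {
    min(30, s + 3) - s + 1
  }, numeric(1)))
  expect_equal(sum(cov_all$n_windows), expected_sum)
  expect_warning(capped <- top_k_coverage(model, enc, k = 10), "capped")
  expect_equal(capped, cov_all)
})
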