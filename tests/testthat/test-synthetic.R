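test_that("the generator is deterministic and records exact truth sites", {
  spec <- synthetic_spec(n_proteins = 30L, n_drugs = 8L, seed = 41L)
  d1 <- generate_synthetic(spec)
  d2 <- generate_synthetic(spec)
  expect_identical(d1$proteins, d2$proteins)
  expect_identical(d1$drugs, d2$drugs)
  expect_identical(d1$interactions$pairs, d2$interactions$pairs)

  # truth sites hold exactly the implanted motif text
  for (pid in names(d1$truth_sites)) {
    sites <- d1$truth_sites[[pid]]
    if (length(sites) == 0) next
    seqc <- strsplit(d1$proteins$sequence[d1$proteins$protein_id == pid],
                     "")[[1]]
    expect_true(all(sites <= length(seqc)))
    motifs <- d1$truth_motifs[[pid]]
    found <- vapply(motifs, function(m) {
      grepl(m, d1$proteins$sequence[d1$proteins$protein_id == pid],
            fixed = TRUE)
    }, logical(1))
    expect_true(all(found))
  }
})

test_that("noiseless labels equal the motif-bit rule predicate exactly", {
  spec <- synthetic_spec(n_proteins = 40L, n_drugs = 10L, label_noise = 0,
                         seed = 42L)
  d <- generate_synthetic(spec)
  fp_of <- stats::setNames(d$drugs$fingerprint, d$drugs$drug_id)
  pred <- mapply(function(did, pid) {
    motifs <- d$truth_motifs[[pid]]
    bits <- d$truth_rule[names(d$truth_rule) %in% motifs]
    as.integer(length(bits) > 0 && any(fp_of[[did]][bits] == 1L))
  }, d$interactions$pairs$drug_id, d$interactions$pairs$protein_id)
  expect_equal(d$interactions$pairs$label, unname(pred))
})

test_that("label noise flips at the specified rate within binomial tolerance", {
  spec0 <- synthetic_spec(n_proteins = 200L, n_drugs = 10L, label_noise = 0,
                          seed = 43L)
  spec1 <- synthetic_spec(n_proteins = 200L, n_drugs = 10L, label_noise = 0.1,
                          seed = 43L)
  d1 <- generate_synthetic(spec1)
  fp_of <- stats::setNames(d1$drugs$fingerprint, d1$drugs$drug_id)
  pred <- mapply(function(did, pid) {
    motifs <- d1$truth_motifs[[pid]]
    bits <- d1$truth_rule[names(d1$truth_rule) %in% motifs]
    as.integer(length(bits) > 0 && any(fp_of[[did]][bits] == 1L))
  }, d1$interactions$pairs$drug_id, d1$interactions$pairs$protein_id)
  n <- length(pred)
  expect_gt(n, 1000)
  flips <- mean(d1$interactions$pairs$label != pred)
  ci <- stats::qbinom(c(0.0005, 0.9995), n, 0.1) / n
  expect_gt(flips, ci[1]); expect_lt(flips, ci[2])
  expect_equal(nrow(generate_synthetic(spec0)$interactions$pairs), n)
})

test_that("the positive fraction tracks 1 / (1 + negative_ratio)", {
  fracs <- vapply(1:10, function(s) {
    d <- generate_synthetic(synthetic_spec(n_proteins = 60L, n_drugs = 10L,
                                           seed = s))
    mean(d$interactions$pairs$label)
  }, numeric(1))
  n_tot <- 10 * 250   # conservative lower bound on pairs per generation
  expect_lt(abs(mean(fracs) - 0.5), 3 * sqrt(0.25 / n_tot) + 0.02)
})

test_that("spec validation rejects infeasible settings", {
  expect_error(synthetic_spec(motif_set = "ACDE"), "k in 5..15")
  expect_error(synthetic_spec(length_range = c(6L, 20L)), "shortest protein")
  expect_error(synthetic_spec(rule = c(NOPE = 1L)), "outside motif_set")
  expect_error(synthetic_spec(rule = c(WYWHKCF = 4000L)), "1..fingerprint_dim")
  expect_error(synthetic_spec(label_noise = 0.7), "0, 0.5")
  expect_error(synthetic_spec(n_proteins = 0L), "at least one")
})

test_that("recovery evaluation separates motif-bearing from control entries", {
  summ <- tibble::tibble(entry_id = c("a", "b", "c", "d"),
                         min_adjusted_p = c(0.001, 0.2, 0.03, 0.8))
  truth <- list(a = 1:7, b = 5:11, c = integer(0), d = integer(0))
  out <- evaluate_recovery(summ, truth, level = 0.05)
  expect_equal(out$recovery, 0.5)
  expect_equal(out$calibration, 0.5)
  expect_equal(out$n_motif, 2)
  expect_error(evaluate_recovery(summ[0, ], truth), "empty")
  expect_error(evaluate_recovery(
    tibble::tibble(entry_id = "zz", min_adjusted_p = 0.1), truth),
    "without truth sites")
})
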