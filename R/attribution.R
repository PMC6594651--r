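# Binding-site attribution: do the argmax windows of the pooled convolution
# results cover annotated binding residues more than random window
# placement would? For each window size, the observed coverage of the
# annotation by all filters' argmax windows is compared against a
# Monte-Carlo null (128 uniformly placed windows, 10,000 replicates,
# normal fit, right-tailed test), p-values are Benjamini-Hochberg adjusted
# across window sizes within the entry, and the entry is summarised by its
# minimum adjusted p-value.

#' Coverage of binding residues by a set of windows
#'
#' A window starting at `j` covers residues `j .. j + window_size - 1`
#' inclusive. In `events` mode (default) the statistic is the total number
#' of (window, residue) covering pairs — repeated starts count multiply,
#' and this form has a closed-form null expectation. In `residues` mode it
#' is the number of distinct binding residues covered by at least one
#' window.
#'
#' @param starts Integer multiset of 1-based window start positions.
#' @param window_size Window size.
#' @param residues Non-empty set of 1-based binding residue indices.
#' @param mode `"events"` or `"residues"`.
#' @return Integer coverage count.
#' @examples
#' window_coverage(c(1, 1), 3, c(2, 5))
#' @export
window_coverage <- function(starts, window_size, residues,
                            mode = c("events", "residues")) {
  mode <- match.arg(mode)
  if (length(residues) == 0) stop("empty residue set", call. = FALSE)
  stopifnot(window_size >= 1, all(starts >= 1), all(residues >= 1))
  if (length(starts) == 0) return(0L)
  if (mode == "events") {
    n <- 0L
    for (r in residues) {
      n <- n + sum(starts <= r & starts + window_size - 1 >= r)
    }
    as.integer(n)
  } else {
    covered <- vapply(residues, function(r) {
      any(starts <= r & starts + window_size - 1 >= r)
    }, logical(1))
    as.integer(sum(covered))
  }
}

# Per-start-position coverage contribution c(j) = number of annotated
# residues covered by a window starting at j (events mode); lets replicate
# statistics be computed as sums of table lookups.
.coverage_profile <- function(n_starts, window_size, residues) {
  prof <- integer(n_starts)
  for (r in residues) {
    lo <- max(1L, r - window_size + 1L)
    hi <- min(n_starts, r)
    if (lo <= hi) prof[lo:hi] <- prof[lo:hi] + 1L
  }
  prof
}

#' Monte-Carlo null distribution of the coverage statistic
#'
#' Each replicate places `n_results` windows uniformly with replacement
#' over the valid start positions `1 .. true_length - window_size + 1` and
#' computes the coverage of `residues`; the sample mean and standard
#' deviation over `n_reps` replicates parameterise the fitted normal null.
#'
#' @param true_length Protein length.
#' @param window_size Window size; must not exceed `true_length`.
#' @param residues 1-based binding residue indices, all within
#'   `true_length`.
#' @param n_results Windows per replicate (the filter count); default 128.
#' @param n_reps Replicates; default 10000.
#' @param mode Coverage mode as in [window_coverage()].
#' @param seed Integer seed.
#' @return A `null_distribution`: list with `window_size`, `n_results`,
#'   `n_reps`, `mode`, `mean`, `sd`.
#' @export
sample_null <- function(true_length, window_size, residues,
                        n_results = 128L, n_reps = 10000L,
                        mode = c("events", "residues"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_results >= 1, n_reps >= 1)
  if (length(residues) == 0) stop("empty residue set", call. = FALSE)
  if (window_size > true_length) {
    stop(sprintf("window size %d exceeds sequence length %d",
                 window_size, true_length), call. = FALSE)
  }
  if (any(residues > true_length)) {
    stop("residue indices exceed sequence length", call. = FALSE)
  }
  n_starts <- true_length - window_size + 1L
  stats_vec <- with_seed(seed, {
    draws <- matrix(sample.int(n_starts, n_results * n_reps, replace = TRUE),
                    nrow = n_reps)
    if (mode == "events") {
      prof <- .coverage_profile(n_starts, window_size, residues)
      rowSums(matrix(prof[draws], nrow = n_reps))
    } else {
      apply(draws, 1, function(st) {
        window_coverage(st, window_size, residues, mode = "residues")
      })
    }
  })
  structure(list(window_size = as.integer(window_size),
                 n_results = as.integer(n_results),
                 n_reps = as.integer(n_reps),
                 mode = mode,
                 mean = mean(stats_vec),
                 sd = stats::sd(stats_vec)),
            class = "null_distribution")
}

#' Right-tailed p-value against a fitted normal null
#'
#' Upper-tail probability of the null's fitted normal at the observed
#' coverage. With 10,000 replicates the t-correction is negligible, so the
#' normal tail is used directly. A degenerate null (`sd = 0`, e.g. a single
#' valid start position) yields p = 1 when the observation does not exceed
#' the mean and p = 0 when it does, flagged via the `degenerate` attribute.
#'
#' @param observed Observed coverage count.
#' @param null A [sample_null()] result.
#' @return p-value in [0, 1].
#' @export
right_tailed_p <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$sd == 0) {
    return(structure(if (observed > null$mean) 0 else 1, degenerate = TRUE))
  }
  stats::pnorm(observed, mean = null$mean, sd = null$sd, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (sort ascending, multiply by `m/i`,
#' enforce monotonicity from the largest down, cap at 1, return in input
#' order).
#'
#' @param pvalues Numeric vector in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Argmax window starts of every filter for each window size, from the
# protein-side trunk only (the drug does not enter the pooled protein
# features). Returns a list window_size -> integer starts (multiset over
# filters; NA-free).
.argmax_starts <- function(model, encoded) {
  if (inherits(model, "dti_fit")) model <- model$model
  enc <- .as_single_encoded(encoded)
  trunk <- .conv_trunk_forward(model$config, model$params,
                               matrix(enc$labels, nrow = 1),
                               enc$true_length, training = FALSE)
  nf <- model$config$filters_per_window
  out <- list()
  for (wi in seq_along(model$config$window_sizes)) {
    ws <- model$config$window_sizes[wi]
    st <- trunk$argmax[1, (wi - 1) * nf + seq_len(nf)]
    out[[as.character(ws)]] <- st[!is.na(st)]
  }
  out
}

#' Attribute one binding-site entry
#'
#' For each window size: the observed statistic is the coverage of the
#' annotated residues by the argmax window starts of all filters of that
#' window (a multiset by default; set `unique_starts = TRUE` to count
#' repeated argmax positions once); its p-value comes from that window's
#' own Monte-Carlo null; p-values are BH-adjusted across window sizes
#' within the entry.
#'
#' @param model A `dti_fit` or `dti_model`.
#' @param encoded An `encoded_protein` for the annotated protein.
#' @param residues 1-based binding residue indices (within the true
#'   length).
#' @param entry_id Identifier carried into the output.
#' @param n_reps Null replicates per window; default 10000.
#' @param mode Coverage mode; default `"events"`.
#' @param unique_starts Deduplicate argmax positions before counting.
#' @param seed Integer seed for the nulls.
#' @return Tibble, one row per window size: `entry_id`, `window_size`,
#'   `observed`, `null_mean`, `null_sd`, `p_value`, `p_adjusted`;
#'   attributes `min_adjusted_p` and `significant` (named logical at
#'   levels 0.01/0.05/0.10).
#' @export
attribute_entry <- function(model, encoded, residues, entry_id = "entry",
                            n_reps = 10000L, mode = c("events", "residues"),
                            unique_starts = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(model, "dti_fit")) model <- model$model
  enc <- .as_single_encoded(encoded)
  if (length(residues) == 0) stop("empty residue set", call. = FALSE)
  if (any(residues > enc$true_length)) {
    stop("annotation residues exceed the protein's length", call. = FALSE)
  }
  starts_by_ws <- .argmax_starts(model, enc)
  nf <- model$config$filters_per_window
  rows <- list()
  for (wi in seq_along(model$config$window_sizes)) {
    ws <- model$config$window_sizes[wi]
    if (ws > enc$true_length) next   # no valid windows for this size
    st <- starts_by_ws[[as.character(ws)]]
    if (unique_starts) st <- unique(st)
    obs <- window_coverage(st, ws, residues, mode = mode)
    null <- sample_null(enc$true_length, ws, residues,
                        n_results = length(st), n_reps = n_reps,
                        mode = mode, seed = child_seed(seed, wi))
    rows[[length(rows) + 1]] <- tibble::tibble(
      entry_id = entry_id, window_size = ws, observed = obs,
      null_mean = null$mean, null_sd = null$sd,
      p_value = as.numeric(right_tailed_p(obs, null)))
  }
  if (length(rows) == 0) {
    stop("no window size fits within the protein", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  attr(out, "min_adjusted_p") <- min(out$p_adjusted)
  attr(out, "significant") <- stats::setNames(
    min(out$p_adjusted) < c(0.01, 0.05, 0.10),
    c("0.01", "0.05", "0.1"))
  out
}

#' Attribute a set of annotated entries
#'
#' Runs [attribute_entry()] for every row of an annotation table and binds
#' the per-window results. Entries whose protein is not in `encoded` are
#' skipped with a message.
#'
#' @param model A `dti_fit` or `dti_model`.
#' @param encoded An `encoded_proteins` object covering the annotated
#'   proteins.
#' @param annotations Tibble from [read_binding_sites()] (`entry_id`,
#'   `protein_id`, `residues` list-column).
#' @inheritParams attribute_entry
#' @return Tibble: per-window rows for every attributed entry (columns as
#'   in [attribute_entry()] plus `protein_id`).
#' @export
attribute_dataset <- function(model, encoded, annotations,
                              n_reps = 10000L, mode = c("events", "residues"),
                              unique_starts = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(encoded, "encoded_proteins"))
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    pid <- annotations$protein_id[i]
    if (!(pid %in% rownames(encoded$labels))) {
      message(sprintf("skipping entry '%s': protein '%s' not encoded",
                      annotations$entry_id[i], pid))
      next
    }
    enc <- structure(list(labels = encoded$labels[pid, ],
                          true_length = unname(encoded$true_length[pid]),
                          vocabulary = encoded$vocabulary),
                     class = "encoded_protein")
    res <- attribute_entry(model, enc, annotations$residues[[i]],
                           entry_id = annotations$entry_id[i],
                           n_reps = n_reps, mode = mode,
                           unique_starts = unique_starts,
                           seed = child_seed(seed, i))
    res$protein_id <- pid
    rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) stop("no entries could be attributed", call. = FALSE)
  dplyr::bind_rows(rows)
}

#' Per-entry attribution summary
#'
#' Collapses per-window attribution rows to one row per entry with the
#' minimum BH-adjusted p-value and significance flags.
#'
#' @param results Per-window tibble from [attribute_dataset()].
#' @param levels Significance levels; default 0.01/0.05/0.10.
#' @return Tibble: `entry_id`, `min_adjusted_p`, one logical column
#'   `sig_<level>` per level.
#' @export
attribution_summary <- function(results, levels = c(0.01, 0.05, 0.10)) {
  out <- results |>
    dplyr::group_by(.data$entry_id) |>
    dplyr::summarise(min_adjusted_p = min(.data$p_adjusted), .groups = "drop")
  for (lv in levels) {
    out[[paste0("sig_", sub("^0\\.", "", format(lv)))]] <- out$min_adjusted_p < lv
  }
  out
}

#' Fraction of significant entries per level
#'
#' The per-entry minimum adjusted p-value is compared to each significance
#' level; fractions are monotone non-decreasing in the level.
#'
#' @param results Per-window tibble from [attribute_dataset()] (or a
#'   summary from [attribution_summary()]).
#' @param levels Significance levels.
#' @return Tibble: `level`, `n_significant`, `fraction`.
#' @export
summarize_significance <- function(results, levels = c(0.01, 0.05, 0.10)) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  minp <- if ("min_adjusted_p" %in% names(results)) {
    results$min_adjusted_p
  } else {
    attribution_summary(results)$min_adjusted_p
  }
  tibble::tibble(
    level = levels,
    n_significant = vapply(levels, function(lv) sum(minp < lv), integer(1)),
    fraction = vapply(levels, function(lv) mean(minp < lv), numeric(1)))
}

#' Residue coverage by the top-k pooled filters
#'
#' For each window size, takes the `k` filters with the largest pooled
#' values and counts, per residue, how many of those argmax windows cover
#' it — the simplified view used to highlight candidate binding regions on
#' a structure. `k` greater than the filter count is capped with a
#' warning.
#'
#' @param model A `dti_fit` or `dti_model`.
#' @param encoded An `encoded_protein`.
#' @param k Filters per window size; default 5.
#' @return Tibble: `residue`, `n_windows` (covering count, over residues
#'   with non-zero count).
#' @export
top_k_coverage <- function(model, encoded, k = 5L) {
  if (inherits(model, "dti_fit")) model <- model$model
  enc <- .as_single_encoded(encoded)
  stopifnot(k >= 1)
  nf <- model$config$filters_per_window
  if (k > nf) {
    warning(sprintf("k = %d exceeds the filter count %d; capped", k, nf),
            call. = FALSE)
    k <- nf
  }
  trunk <- .conv_trunk_forward(model$config, model$params,
                               matrix(enc$labels, nrow = 1),
                               enc$true_length, training = FALSE)
  counts <- integer(enc$true_length)
  for (wi in seq_along(model$config$window_sizes)) {
    ws <- model$config$window_sizes[wi]
    idx <- (wi - 1) * nf + seq_len(nf)
    vals <- trunk$pooled[1, idx]
    st <- trunk$argmax[1, idx]
    ok <- !is.na(st)
    if (!any(ok)) next
    top <- order(vals[ok], decreasing = TRUE)[seq_len(min(k, sum(ok)))]
    for (s in st[ok][top]) {
      hi <- min(enc$true_length, s + ws - 1L)
      counts[s:hi] <- counts[s:hi] + 1L
    }
  }
  tibble::tibble(residue = which(counts > 0),
                 n_windows = counts[counts > 0])
}
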