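# Synthetic motif-implantation benchmark: random amino-acid sequences with
# implanted k-mer "binding" motifs at recorded positions, random binary
# drug fingerprints carrying designated rule bits, and interaction labels
# driven by (motif presence x fingerprint bit) rules with optional label
# noise. Stands in for large curated DTI collections so every pipeline
# stage is testable without downloads; the recorded truth sites play the
# role of structural binding-site annotations.

#' Specification of a synthetic DTI benchmark
#'
#' @param n_proteins,n_drugs Entity counts; defaults 300 proteins and 10
#'   drugs — protein-rich so that held-out-protein validation measures
#'   sequence generalisation rather than protein memorisation.
#' @param length_range Protein length range (uniform); default c(100, 300).
#' @param motif_set Character vector of k-mer motifs (k in 5..15); default
#'   three 7-mers.
#' @param motifs_per_protein_range How many motifs (drawn with replacement
#'   from `motif_set`) each protein carries; default 0..2, so some
#'   proteins are motif-free controls.
#' @param fingerprint_dim Fingerprint width; default 2048.
#' @param bits_per_drug Random background bits per drug; default 30.
#' @param rule Named integer vector mapping motif -> fingerprint bit
#'   (1-based); defaults to one distinct bit per motif.
#' @param rule_bit_prob Probability that a drug carries each rule bit;
#'   default 0.4.
#' @param label_noise Probability of flipping a pair's label; in [0, 0.5);
#'   default 0.02.
#' @param negative_ratio Sampled negatives per positive; default 1.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins = 300L,
                           length_range = c(100L, 300L),
                           motif_set = c("WYWHKCF", "MHFRDYW", "CKYDNHM"),
                           motifs_per_protein_range = c(0L, 2L),
                           n_drugs = 10L,
                           fingerprint_dim = 2048L,
                           bits_per_drug = 30L,
                           rule = NULL,
                           rule_bit_prob = 0.4,
                           label_noise = 0.02,
                           negative_ratio = 1,
                           seed = 1L) {
  if (is.null(rule)) {
    rule <- stats::setNames(seq_along(motif_set), motif_set)
  }
  spec <- list(n_proteins = as.integer(n_proteins),
               length_range = as.integer(length_range),
               motif_set = motif_set,
               motifs_per_protein_range = as.integer(motifs_per_protein_range),
               n_drugs = as.integer(n_drugs),
               fingerprint_dim = as.integer(fingerprint_dim),
               bits_per_drug = as.integer(bits_per_drug),
               rule = rule,
               rule_bit_prob = rule_bit_prob,
               label_noise = label_noise,
               negative_ratio = negative_ratio,
               seed = as.integer(seed))
  ks <- nchar(spec$motif_set)
  if (length(spec$motif_set) == 0 || any(ks < 5 | ks > 15)) {
    stop("motifs must be k-mers with k in 5..15", call. = FALSE)
  }
  if (max(ks) > spec$length_range[1]) {
    stop("motifs must fit within the shortest protein", call. = FALSE)
  }
  if (!all(names(spec$rule) %in% spec$motif_set)) {
    stop("rule references motifs outside motif_set", call. = FALSE)
  }
  if (any(spec$rule < 1 | spec$rule > spec$fingerprint_dim)) {
    stop("rule bits must lie in 1..fingerprint_dim", call. = FALSE)
  }
  if (spec$label_noise < 0 || spec$label_noise >= 0.5) {
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  }
  if (spec$n_proteins < 1 || spec$n_drugs < 1) {
    stop("need at least one protein and one drug", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

.residues20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Implant motifs at uniform non-overlapping positions (overwriting the
# background so recorded positions are exact). Returns sequence, implanted
# motif names, and the residue indices they occupy.
.implant <- function(background, motifs) {
  chars <- strsplit(background, "", fixed = TRUE)[[1]]
  n <- length(chars)
  occupied <- logical(n)
  placed <- character(0)
  sites <- integer(0)
  for (m in motifs) {
    k <- nchar(m)
    cand <- which(vapply(seq_len(n - k + 1), function(s) {
      !any(occupied[s:(s + k - 1)])
    }, logical(1)))
    if (length(cand) == 0) next   # no room left; skip this motif
    s <- cand[sample.int(length(cand), 1)]
    chars[s:(s + k - 1)] <- strsplit(m, "", fixed = TRUE)[[1]]
    occupied[s:(s + k - 1)] <- TRUE
    placed <- c(placed, m)
    sites <- c(sites, s:(s + k - 1))
  }
  list(sequence = paste(chars, collapse = ""), motifs = placed,
       sites = sort(sites))
}

#' Generate a synthetic DTI dataset
#'
#' Proteins are uniform random sequences over the 20 canonical residues
#' with motifs implanted at uniform non-overlapping positions (positions
#' recorded as truth sites). Drugs get `bits_per_drug` random fingerprint
#' bits plus each rule bit independently with probability `rule_bit_prob`.
#' The noiseless label of a pair is 1 iff some motif in the protein has
#' its rule bit set in the drug's fingerprint; the dataset contains all
#' rule-positives plus `negative_ratio` as many rule-negatives sampled
#' uniformly, and finally each included label is flipped with probability
#' `label_noise`. Fully reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset`: list with `proteins` (tibble),
#'   `drugs` (tibble with `fingerprint` list-column), `interactions`
#'   (an [interaction_dataset()]), `truth_sites` (named list of residue
#'   index vectors), `truth_motifs` (named list of motif names per
#'   protein), `truth_rule`, and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    lens <- sample(spec$length_range[1]:spec$length_range[2],
                   spec$n_proteins, replace = TRUE)
    n_mot <- sample(spec$motifs_per_protein_range[1]:spec$motifs_per_protein_range[2],
                    spec$n_proteins, replace = TRUE)
    prot_rows <- lapply(seq_len(spec$n_proteins), function(i) {
      bg <- paste(sample(.residues20, lens[i], replace = TRUE), collapse = "")
      motifs <- if (n_mot[i] > 0) {
        sample(spec$motif_set, n_mot[i], replace = TRUE)
      } else character(0)
      imp <- .implant(bg, motifs)
      list(protein_id = sprintf("P%03d", i), sequence = imp$sequence,
           motifs = unique(imp$motifs), sites = imp$sites)
    })
    proteins <- tibble::tibble(
      protein_id = vapply(prot_rows, `[[`, character(1), "protein_id"),
      sequence = vapply(prot_rows, `[[`, character(1), "sequence"))
    proteins$length <- nchar(proteins$sequence)
    truth_sites <- stats::setNames(lapply(prot_rows, `[[`, "sites"),
                                   proteins$protein_id)
    truth_motifs <- stats::setNames(lapply(prot_rows, `[[`, "motifs"),
                                    proteins$protein_id)

    fps <- lapply(seq_len(spec$n_drugs), function(j) {
      fp <- integer(spec$fingerprint_dim)
      fp[sample.int(spec$fingerprint_dim, spec$bits_per_drug)] <- 1L
      carry <- stats::runif(length(spec$rule)) < spec$rule_bit_prob
      fp[spec$rule[carry]] <- 1L
      fp
    })
    drugs <- tibble::tibble(
      drug_id = sprintf("D%03d", seq_len(spec$n_drugs)),
      smiles = NA_character_,
      fingerprint = fps)

    # noiseless rule labels over the full grid
    has_bit <- vapply(fps, function(fp) fp[spec$rule] == 1L,
                      logical(length(spec$rule)))  # n_rules x n_drugs
    has_bit <- matrix(has_bit, nrow = length(spec$rule))
    rule_label <- matrix(0L, spec$n_drugs, spec$n_proteins)
    for (i in seq_len(spec$n_proteins)) {
      mots <- truth_motifs[[i]]
      ri <- which(names(spec$rule) %in% mots)
      if (length(ri) > 0) {
        rule_label[, i] <- as.integer(colSums(
          has_bit[ri, , drop = FALSE]) > 0)
      }
    }
    pos_idx <- which(rule_label == 1L)
    neg_idx <- which(rule_label == 0L)
    n_neg <- min(length(neg_idx), round(spec$negative_ratio * length(pos_idx)))
    neg_sel <- if (n_neg > 0) sample(neg_idx, n_neg) else integer(0)
    sel <- c(pos_idx, neg_sel)
    di <- ((sel - 1L) %% spec$n_drugs) + 1L
    pi_ <- ((sel - 1L) %/% spec$n_drugs) + 1L
    label <- c(rep(1L, length(pos_idx)), rep(0L, length(neg_sel)))
    if (spec$label_noise > 0) {
      flip <- stats::runif(length(label)) < spec$label_noise
      label[flip] <- 1L - label[flip]
    }
    pairs <- tibble::tibble(drug_id = drugs$drug_id[di],
                            protein_id = proteins$protein_id[pi_],
                            label = label)
    structure(list(proteins = proteins, drugs = drugs,
                   interactions = interaction_dataset(pairs, proteins, drugs),
                   truth_sites = truth_sites,
                   truth_motifs = truth_motifs,
                   truth_rule = spec$rule,
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d proteins, %d drugs, %d pairs (%d positive), %d motifs\n",
    nrow(x$proteins), nrow(x$drugs), nrow(x$interactions$pairs),
    sum(x$interactions$pairs$label == 1), length(x$spec$motif_set)))
  invisible(x)
}

#' Split a synthetic dataset's pairs into train and validation sets
#'
#' `by = "pair"` holds out random pairs; `by = "protein"` (the default)
#' holds out whole proteins, so validation measures generalisation to
#' unseen sequences — the analogue of validating on an external dataset.
#' Reproducible from the seed; both resulting datasets share the entity
#' tables.
#'
#' @param data A `synthetic_dataset`.
#' @param val_fraction Fraction held out; default 0.2.
#' @param by `"protein"` or `"pair"`.
#' @param seed Integer seed.
#' @return List with `train` and `val` interaction datasets.
#' @export
split_pairs <- function(data, val_fraction = 0.2, by = c("protein", "pair"),
                        seed = 1L) {
  by <- match.arg(by)
  pairs <- data$interactions$pairs
  in_val <- with_seed(seed, {
    if (by == "pair") {
      seq_len(nrow(pairs)) %in% sample.int(nrow(pairs),
                                           round(val_fraction * nrow(pairs)))
    } else {
      ids <- data$proteins$protein_id
      held <- sample(ids, round(val_fraction * length(ids)))
      pairs$protein_id %in% held
    }
  })
  make <- function(p) {
    structure(list(pairs = p, proteins = data$proteins, drugs = data$drugs),
              class = "interaction_dataset")
  }
  list(train = make(pairs[!in_val, , drop = FALSE]),
       val = make(pairs[in_val, , drop = FALSE]))
}

#' Attribution recovery on synthetic truth
#'
#' Given per-entry attribution results for synthetic proteins, reports the
#' fraction of motif-bearing entries significant at `level` (the recovery
#' rate) and the fraction of motif-free control entries significant at the
#' same level (the calibration rate).
#'
#' @param results Attribution results for proteins of a synthetic dataset
#'   (per-window tibble from [attribute_dataset()] or a summary from
#'   [attribution_summary()]); `entry_id` must equal the protein id.
#' @param truth_sites Named list of truth-site vectors from the dataset
#'   (empty vector = motif-free).
#' @param level Significance level; default 0.05.
#' @return One-row tibble: `level`, `n_motif`, `recovery`, `n_control`,
#'   `calibration`.
#' @export
evaluate_recovery <- function(results, truth_sites, level = 0.05) {
  if (nrow(results) == 0) stop("empty results", call. = FALSE)
  summ <- if ("min_adjusted_p" %in% names(results)) results else {
    attribution_summary(results)
  }
  if (!all(summ$entry_id %in% names(truth_sites))) {
    stop("results reference proteins without truth sites", call. = FALSE)
  }
  has_motif <- lengths(truth_sites[summ$entry_id]) > 0
  sig <- summ$min_adjusted_p < level
  tibble::tibble(
    level = level,
    n_motif = sum(has_motif),
    recovery = if (any(has_motif)) mean(sig[has_motif]) else NA_real_,
    n_control = sum(!has_motif),
    calibration = if (any(!has_motif)) mean(sig[!has_motif]) else NA_real_)
}
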