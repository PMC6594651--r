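# Readers/writers for the external plain-text formats (FASTA proteins, TSV
# drug and interaction tables, TSV binding-site annotations, prediction and
# attribution outputs), dataset assembly with referential checks, negative
# sampling, and novelty partitioning of test pairs.

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `sequence` (uppercased,
#'   whitespace-free), `length`, in file order.
#' @details Duplicate identifiers and empty sequence entries are errors; the
#'   error message reports the positions involved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  seq_chr <- toupper(gsub("\\s", "", as.character(seqs)))
  empty <- which(!nzchar(seq_chr))
  if (length(empty) > 0) {
    stop(sprintf("empty sequence for entries at positions: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    pos <- vapply(unique(dup), function(d) {
      paste(which(ids == d), collapse = " and ")
    }, character(1))
    stop(sprintf("duplicate protein ids: %s",
                 paste(sprintf("'%s' (entries %s)", unique(dup), pos),
                       collapse = "; ")), call. = FALSE)
  }
  tibble::tibble(protein_id = ids, sequence = unname(seq_chr),
                 length = unname(nchar(seq_chr)))
}

#' Write a protein table to FASTA
#'
#' @param proteins Data frame with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$protein_id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a drug table (TSV: drug_id, smiles)
#'
#' @param path Path to a tab-separated file with header `drug_id`, `smiles`.
#' @return Tibble with `drug_id`, `smiles` and an empty `fingerprint`
#'   list-column (filled by [featurize_drugs()] or supplied directly).
#' @export
read_drugs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("drug_id", "smiles") %in% names(tab))) {
    stop("drug table must have columns drug_id, smiles", call. = FALSE)
  }
  dup <- unique(tab$drug_id[duplicated(tab$drug_id)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate drug ids: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(drug_id = tab$drug_id, smiles = tab$smiles,
                 fingerprint = vector("list", nrow(tab)))
}

#' Assemble a validated interaction dataset
#'
#' Binds a pair table to its drug and protein tables, enforcing the dataset
#' invariants: every pair references an existing drug and protein, labels
#' are binary, and no (drug_id, protein_id) pair occurs twice.
#'
#' @param pairs Data frame with columns `drug_id`, `protein_id`, `label`.
#' @param proteins Protein tibble (`protein_id`, `sequence`).
#' @param drugs Drug tibble (`drug_id`, plus `smiles` and/or `fingerprint`).
#' @return An `interaction_dataset`: list with `pairs` (tibble), `proteins`,
#'   `drugs`.
#' @export
interaction_dataset <- function(pairs, proteins, drugs) {
  stopifnot(is.data.frame(pairs),
            all(c("drug_id", "protein_id", "label") %in% names(pairs)))
  bad_label <- which(!(pairs$label %in% c(0, 1)))
  if (length(bad_label) > 0) {
    stop(sprintf("non-binary label in rows: %s",
                 paste(bad_label, collapse = ", ")), call. = FALSE)
  }
  unknown_d <- which(!(pairs$drug_id %in% drugs$drug_id))
  unknown_p <- which(!(pairs$protein_id %in% proteins$protein_id))
  if (length(unknown_d) > 0 || length(unknown_p) > 0) {
    msg <- c(
      if (length(unknown_d) > 0)
        sprintf("unknown drug_id in rows: %s", paste(unknown_d, collapse = ", ")),
      if (length(unknown_p) > 0)
        sprintf("unknown protein_id in rows: %s", paste(unknown_p, collapse = ", ")))
    stop(paste(msg, collapse = "; "), call. = FALSE)
  }
  key <- paste(pairs$drug_id, pairs$protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup_keys <- unique(key[duplicated(key)])
    rows <- vapply(dup_keys, function(k) paste(which(key == k), collapse = " and "),
                   character(1))
    stop(sprintf("duplicate pairs at rows: %s", paste(rows, collapse = "; ")),
         call. = FALSE)
  }
  structure(
    list(pairs = tibble::as_tibble(pairs[c("drug_id", "protein_id", "label")]),
         proteins = tibble::as_tibble(proteins),
         drugs = tibble::as_tibble(drugs)),
    class = "interaction_dataset"
  )
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf(
    "<interaction_dataset> %d pairs (%d positive), %d drugs, %d proteins\n",
    nrow(x$pairs), sum(x$pairs$label == 1), nrow(x$drugs), nrow(x$proteins)))
  invisible(x)
}

#' Read an interaction pair table (TSV: drug_id, protein_id, label)
#'
#' @param path Path to a TSV file with header `drug_id`, `protein_id`,
#'   `label` (0/1).
#' @inheritParams interaction_dataset
#' @return An [interaction_dataset()].
#' @export
read_interactions <- function(path, drugs, proteins) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  if (!all(c("drug_id", "protein_id", "label") %in% names(tab))) {
    stop("interaction table must have columns drug_id, protein_id, label",
         call. = FALSE)
  }
  tab$label <- suppressWarnings(as.numeric(tab$label))
  interaction_dataset(tab, proteins, drugs)
}

#' Sample negative interaction sets from the non-positive grid
#'
#' Given a dataset of positive pairs only, draws `n_sets` negative sets
#' uniformly without replacement from the non-positive cells of the
#' drug x protein grid (restricted to entities present in the positive set)
#' and returns, for each, the positives plus the sampled negatives labelled
#' 0. Multiple sets reduce the bias any single random negative draw would
#' introduce. Negatives are guaranteed disjoint from the positives; with
#' `disjoint_sets = TRUE` they are additionally pairwise disjoint across
#' sets.
#'
#' @param dataset An [interaction_dataset()] whose pairs all have label 1.
#' @param n_sets Number of negative sets; default 10.
#' @param ratio Negatives per positive; default 1.
#' @param seed Integer seed; sampling is reproducible.
#' @param disjoint_sets Force negatives to be disjoint across sets.
#' @return List of `n_sets` interaction datasets.
#' @export
sample_negative_sets <- function(dataset, n_sets = 10L, ratio = 1,
                                 seed = 1L, disjoint_sets = FALSE) {
  stopifnot(inherits(dataset, "interaction_dataset"), n_sets >= 1, ratio > 0)
  if (any(dataset$pairs$label != 1)) {
    stop("`dataset` must contain only positive pairs", call. = FALSE)
  }
  drugs <- unique(dataset$pairs$drug_id)
  prots <- unique(dataset$pairs$protein_id)
  grid <- expand.grid(drug_id = drugs, protein_id = prots,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pos_key <- paste(dataset$pairs$drug_id, dataset$pairs$protein_id, sep = "\r")
  grid_key <- paste(grid$drug_id, grid$protein_id, sep = "\r")
  complement <- which(!(grid_key %in% pos_key))
  n_neg <- round(ratio * nrow(dataset$pairs))
  needed <- if (disjoint_sets) n_neg * n_sets else n_neg
  if (needed > length(complement)) {
    stop(sprintf(
      "requested %d negatives but only %d non-positive drug x protein pairs exist",
      needed, length(complement)), call. = FALSE)
  }
  idx_sets <- with_seed(seed, {
    if (disjoint_sets) {
      all_idx <- sample(complement, needed)
      split(all_idx, rep(seq_len(n_sets), each = n_neg))
    } else {
      lapply(seq_len(n_sets), function(i) sample(complement, n_neg))
    }
  })
  lapply(idx_sets, function(idx) {
    neg <- grid[idx, , drop = FALSE]
    neg$label <- 0
    pairs <- rbind(as.data.frame(dataset$pairs),
                   neg[c("drug_id", "protein_id", "label")])
    interaction_dataset(pairs, dataset$proteins, dataset$drugs)
  })
}

#' Partition test pairs by novelty relative to the training set
#'
#' Splits a test dataset into the four evaluation subsets used for
#' generalisation analysis: all pairs; pairs whose compound is unseen in
#' training; pairs whose protein is unseen; and pairs where both are unseen.
#' The subsets overlap by construction: unseen-both is contained in each
#' single-novelty subset, and every subset is contained in "all".
#'
#' @param train,test [interaction_dataset()] objects.
#' @return Named list of four interaction datasets: `all`,
#'   `unseen_compound`, `unseen_protein`, `unseen_both`.
#' @export
split_by_novelty <- function(train, test) {
  stopifnot(inherits(train, "interaction_dataset"),
            inherits(test, "interaction_dataset"))
  new_drug <- !(test$pairs$drug_id %in% train$pairs$drug_id)
  new_prot <- !(test$pairs$protein_id %in% train$pairs$protein_id)
  subset_ds <- function(keep) {
    structure(list(pairs = test$pairs[keep, , drop = FALSE],
                   proteins = test$proteins, drugs = test$drugs),
              class = "interaction_dataset")
  }
  list(all = subset_ds(rep(TRUE, nrow(test$pairs))),
       unseen_compound = subset_ds(new_drug),
       unseen_protein = subset_ds(new_prot),
       unseen_both = subset_ds(new_drug & new_prot))
}

#' Read binding-site annotations (TSV: entry_id, protein_id, residues)
#'
#' Residue indices are 1-based inclusive, comma-separated; duplicates are
#' collapsed and indices sorted. A protein may carry several annotation
#' entries (one per structure/ligand complex).
#'
#' @param path TSV path with header `entry_id`, `protein_id`, `residues`.
#' @return Tibble with columns `entry_id`, `protein_id`, `residues`
#'   (list-column of sorted integer vectors).
#' @export
read_binding_sites <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  if (!all(c("entry_id", "protein_id", "residues") %in% names(tab))) {
    stop("binding-site table must have columns entry_id, protein_id, residues",
         call. = FALSE)
  }
  res <- lapply(seq_len(nrow(tab)), function(i) {
    r <- suppressWarnings(as.integer(strsplit(tab$residues[i], ",")[[1]]))
    if (length(r) == 0 || anyNA(r)) {
      stop(sprintf("row %d: empty or unparseable residue list", i), call. = FALSE)
    }
    if (any(r <= 0)) {
      stop(sprintf("row %d: residue indices must be >= 1 (1-based)", i),
           call. = FALSE)
    }
    sort(unique(r))
  })
  tibble::tibble(entry_id = tab$entry_id, protein_id = tab$protein_id,
                 residues = res)
}

#' Write binding-site annotations
#' @param annotations Tibble as returned by [read_binding_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_binding_sites <- function(annotations, path) {
  tab <- data.frame(
    entry_id = annotations$entry_id,
    protein_id = annotations$protein_id,
    residues = vapply(annotations$residues, paste, character(1), collapse = ","))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a predictions table (TSV: drug_id, protein_id, score, call)
#' @param predictions Tibble with those columns (see [predict_dti()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- intersect(c("drug_id", "protein_id", "score", "call", "label"),
                    names(predictions))
  utils::write.table(as.data.frame(predictions[cols]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write attribution results (CSV: entry_id, window_size, p_value, p_adjusted)
#' @param results Per-window attribution tibble (see [attribute_dataset()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(results, path) {
  utils::write.csv(
    as.data.frame(results[c("entry_id", "window_size", "observed",
                            "p_value", "p_adjusted")]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
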