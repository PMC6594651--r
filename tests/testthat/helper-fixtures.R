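# Shared fixtures: all built in code at test time.

RESIDUES20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(len) {
  paste(sample(RESIDUES20, len, replace = TRUE), collapse = "")
}

# A deliberately small architecture for fast unit tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(window_sizes = c(3L, 5L), filters_per_window = 4L,
         embedding_size = 6L, mpl = 40L,
         protein_dense_sizes = 8L, drug_dense_sizes = 8L,
         joint_dense_sizes = 6L, n_bits = 16L,
         spatial_dropout_rate = 0, dense_dropout_rate = 0,
         learning_rate = 1e-3, batch_size = 8L, epochs = 2L, seed = 7L),
    list(...))
  do.call(model_config, args)
}

# A tiny labelled dataset with direct fingerprints (no chemistry needed).
tiny_dataset <- function(n_prot = 12, n_drug = 6, n_bits = 16, seed = 3) {
  set.seed(seed)
  proteins <- tibble::tibble(
    protein_id = sprintf("p%02d", seq_len(n_prot)),
    sequence = replicate(n_prot, random_sequence(sample(15:35, 1))))
  drugs <- tibble::tibble(
    drug_id = sprintf("d%02d", seq_len(n_drug)),
    smiles = NA_character_,
    fingerprint = replicate(n_drug,
                            as.integer(stats::rbinom(n_bits, 1, 0.3)),
                            simplify = FALSE))
  pairs <- expand.grid(drug_id = drugs$drug_id, protein_id = proteins$protein_id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs$label <- stats::rbinom(nrow(pairs), 1, 0.5)
  interaction_dataset(pairs, proteins, drugs)
}

# Embedding-pattern filter matched to a motif: returns the conv-kernel row
# (offset-major layout) whose dot product is maximal at the motif.
motif_filter <- function(motif, emb, vocab) {
  toks <- vocab$index[strsplit(motif, "", fixed = TRUE)[[1]]]
  as.vector(vapply(seq_along(toks), function(b) emb[toks[b], ],
                   numeric(ncol(emb))))
}
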