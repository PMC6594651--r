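# Protein sequence encoding: residue vocabulary, fixed-length integer label
# vectors with pad margins, window-validity masks, and the trainable
# embedding table the convolution layer looks up.

#' Amino-acid vocabulary with pad and unknown tokens
#'
#' The encoder vocabulary holds the 20 canonical amino-acid letters plus a
#' pad token (written `$`, reserved at index 1) used to fill the margin
#' beyond a sequence's true length, and an unknown token (`X`) to which any
#' non-canonical residue letter (B, Z, U, O, ...) is mapped. Pad and unknown
#' are deliberately distinct: absence of sequence is not the same as an
#' ambiguous residue.
#'
#' @return An object of class `aa_vocab`: a list with `tokens` (ordered
#'   character vector), `index` (named integer vector, a bijection onto
#'   `1..length(tokens)`), `pad_index`, and `unknown_index`.
#' @examples
#' v <- aa_vocabulary()
#' v$tokens[v$pad_index]
#' @export
aa_vocabulary <- function() {
  residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  tokens <- c("$", residues, "X")
  structure(
    list(
      tokens = tokens,
      index = stats::setNames(seq_along(tokens), tokens),
      pad_index = 1L,
      unknown_index = length(tokens)
    ),
    class = "aa_vocab"
  )
}

#' Encode one amino-acid sequence as a padded integer label vector
#'
#' Residues are mapped through the vocabulary; positions past the sequence's
#' true length carry the pad index. Non-canonical letters map to the unknown
#' token. Sequences longer than `mpl` (maximum protein length) are truncated
#' to their first `mpl` residues with a warning (the N-terminal prefix is
#' kept); set `on_overflow = "error"` to reject instead.
#'
#' @param sequence Non-empty amino-acid string.
#' @param vocabulary An [aa_vocabulary()] object.
#' @param mpl Maximum protein length; default 2500.
#' @param on_overflow `"truncate"` (default, warns) or `"error"`.
#' @return An `encoded_protein`: list with `labels` (integer vector of
#'   length `mpl`), `true_length`, and `vocabulary`.
#' @examples
#' ep <- encode_sequence("MKV", mpl = 5)
#' ep$labels
#' @export
encode_sequence <- function(sequence, vocabulary = aa_vocabulary(),
                            mpl = 2500L, on_overflow = c("truncate", "error")) {
  on_overflow <- match.arg(on_overflow)
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("`sequence` must be a single non-empty string", call. = FALSE)
  }
  stopifnot(mpl >= 1)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) > mpl) {
    if (on_overflow == "error") {
      stop(sprintf("sequence length %d exceeds mpl = %d", length(chars), mpl),
           call. = FALSE)
    }
    warning(sprintf("sequence of length %d truncated to first %d residues",
                    length(chars), mpl), call. = FALSE)
    chars <- chars[seq_len(mpl)]
  }
  idx <- unname(vocabulary$index[chars])
  idx[is.na(idx) | chars == "$"] <- vocabulary$unknown_index
  labels <- rep(vocabulary$pad_index, mpl)
  labels[seq_along(idx)] <- idx
  structure(
    list(labels = as.integer(labels),
         true_length = length(idx),
         vocabulary = vocabulary),
    class = "encoded_protein"
  )
}

#' Decode an encoded protein back to its residue string
#'
#' Inverse of [encode_sequence()] up to truncation and unknown-residue
#' mapping: canonical sequences of length at most `mpl` round-trip exactly.
#'
#' @param encoded An `encoded_protein`.
#' @return Character string of length `true_length`.
#' @export
decode_sequence <- function(encoded) {
  stopifnot(inherits(encoded, "encoded_protein"))
  v <- encoded$vocabulary
  paste(v$tokens[encoded$labels[seq_len(encoded$true_length)]], collapse = "")
}

#' Encode a protein table
#'
#' Vectorised encoder over a tibble of proteins (as returned by
#' [read_fasta()] or generated by [generate_synthetic()]).
#'
#' @param proteins Data frame with columns `protein_id`, `sequence`.
#' @inheritParams encode_sequence
#' @return An `encoded_proteins` object: list with `labels` (n x mpl integer
#'   matrix, rownames = protein ids), `true_length` (named integer vector),
#'   and `vocabulary`.
#' @export
encode_proteins <- function(proteins, vocabulary = aa_vocabulary(),
                            mpl = 2500L, on_overflow = c("truncate", "error")) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  on_overflow <- match.arg(on_overflow)
  encs <- lapply(proteins$sequence, encode_sequence,
                 vocabulary = vocabulary, mpl = mpl, on_overflow = on_overflow)
  labels <- do.call(rbind, lapply(encs, `[[`, "labels"))
  rownames(labels) <- proteins$protein_id
  structure(
    list(labels = labels,
         true_length = stats::setNames(
           vapply(encs, `[[`, integer(1), "true_length"),
           proteins$protein_id),
         vocabulary = vocabulary),
    class = "encoded_proteins"
  )
}

#' Valid convolution window start positions for a sequence
#'
#' A window of size `window_size` starting at 1-based position `j` covers
#' residues `j .. j + window_size - 1`; it is valid when it lies entirely
#' within the true (un-padded) sequence. Windows reaching into the pad
#' margin are excluded from global max-pooling when masking is enabled.
#'
#' @param true_length Sequence length before padding.
#' @param window_size Window size (>= 1).
#' @return Integer vector `1:(true_length - window_size + 1)`, or
#'   `integer(0)` when the window is longer than the sequence.
#' @examples
#' valid_window_positions(10, 4)
#' @export
valid_window_positions <- function(true_length, window_size) {
  stopifnot(window_size >= 1, true_length >= 0)
  n <- true_length - window_size + 1
  if (n < 1) integer(0) else seq_len(n)
}

#' Initialise the residue embedding table
#'
#' Draws a `|V| x embedding_size` table from the Xavier/Glorot normal
#' scheme: entries are normal with variance `2 / (fan_in + fan_out)` where
#' fan-in is the vocabulary size and fan-out the embedding size. The table
#' is trainable downstream. Optionally the pad row is pinned to zeros.
#'
#' @param vocabulary An [aa_vocabulary()].
#' @param embedding_size Embedding dimension (>= 1); default 20.
#' @param seed Integer seed; the draw is reproducible.
#' @param pad_zero If `TRUE`, the pad token's row is set to zeros.
#' @return Numeric matrix `|V| x embedding_size`.
#' @export
init_embedding <- function(vocabulary = aa_vocabulary(), embedding_size = 20L,
                           seed = 1L, pad_zero = FALSE) {
  stopifnot(embedding_size >= 1)
  v <- length(vocabulary$tokens)
  sd <- sqrt(2 / (v + embedding_size))
  emb <- with_seed(seed, matrix(stats::rnorm(v * embedding_size, sd = sd),
                                nrow = v, ncol = embedding_size))
  if (pad_zero) emb[vocabulary$pad_index, ] <- 0
  rownames(emb) <- vocabulary$tokens
  emb
}
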