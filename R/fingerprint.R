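# Morgan/circular fingerprint featurization of drugs. SMILES strings are
# canonicalized and parsed with the OpenBabel-backed ChemmineR toolkit; the
# circular-substructure iterative hashing (ECFP-style) is implemented here,
# folding hashed atom environments up to the given radius into a fixed-width
# binary vector. Bit positions are deterministic for this package's hash
# (fingerprints from other toolkits use different hashes and are not
# bit-compatible, which does not matter for learning: only presence/absence
# patterns do).

# Deterministic polynomial hash of an integer vector onto 0..2^31-2.
# All intermediates stay below 2^53 so double arithmetic is exact.
.hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  h
}

.default_valence <- c("6" = 4, "7" = 3, "8" = 2, "16" = 2, "15" = 3,
                      "9" = 1, "17" = 1, "35" = 1, "53" = 1, "5" = 3)

# Parse a SMILES string into atom/bond tables via ChemmineOB/ChemmineR.
.parse_smiles <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES parsing requires the ChemmineR and ChemmineOB packages; ",
         "supply precomputed fingerprints instead", call. = FALSE)
  }
  canon <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                               paste0(smiles, "\n"))),
    error = function(e) "")
  canon <- sub("\\s.*$", "", canon)
  if (!nzchar(canon)) {
    stop(sprintf("unparseable SMILES: '%s'", smiles), call. = FALSE)
  }
  sdf <- ChemmineR::smiles2sdf(canon)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  n_atoms <- length(elements)
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    matrix(numeric(0), ncol = 3)
  } else {
    cbind(bb[, 1], bb[, 2], bb[, 3])
  }
  list(elements = elements, n_atoms = n_atoms, bonds = bonds)
}

#' Morgan/circular fingerprint of a molecule
#'
#' Computes a hashed circular-substructure fingerprint from a SMILES string:
#' every atom starts from an invariant tuple (atomic number, heavy-atom
#' degree, total bond order, implicit-hydrogen estimate), and for each
#' iteration up to `radius` the invariant is re-hashed together with the
#' sorted (bond order, neighbour invariant) pairs, so each atom's hash
#' describes its circular environment of that radius. Every hash from every
#' iteration sets one bit of the folded binary vector. Chemically identical
#' inputs written as different SMILES yield identical fingerprints (inputs
#' are canonicalized first and the hashing is neighbour-order independent).
#'
#' @param smiles A single SMILES string.
#' @param radius Environment radius; default 2.
#' @param n_bits Fingerprint width; default 2048.
#' @return A `fingerprint`: integer 0/1 vector of length `n_bits` with
#'   attributes `radius` and `n_bits`.
#' @examples
#' \dontrun{
#' fp <- morgan_fingerprint("CCO")
#' sum(fp)
#' }
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }
  stopifnot(radius >= 0, n_bits >= 1)
  mol <- .parse_smiles(smiles)
  z <- vapply(mol$elements, function(e) {
    i <- match(e, .element_symbols)
    if (is.na(i)) 0L else i
  }, integer(1))

  nb <- vector("list", mol$n_atoms)        # neighbour indices
  nb_order <- vector("list", mol$n_atoms)  # matching bond orders
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[k, 1]; b <- mol$bonds[k, 2]; o <- mol$bonds[k, 3]
      nb[[a]] <- c(nb[[a]], b); nb_order[[a]] <- c(nb_order[[a]], o)
      nb[[b]] <- c(nb[[b]], a); nb_order[[b]] <- c(nb_order[[b]], o)
    }
  }
  degree <- lengths(nb)
  bond_sum <- vapply(seq_len(mol$n_atoms),
                     function(i) sum(nb_order[[i]]), numeric(1))
  hcount <- pmax(0, .default_valence[as.character(z)] - bond_sum)
  hcount[is.na(hcount)] <- 0

  inv <- vapply(seq_len(mol$n_atoms), function(i) {
    .hash_ints(c(z[i], degree[i], bond_sum[i], hcount[i]))
  }, numeric(1))

  hashes <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(mol$n_atoms), function(i) {
      if (degree[i] == 0) return(.hash_ints(c(r, inv[i])))
      pairs <- cbind(nb_order[[i]], inv[nb[[i]]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .hash_ints(c(r, inv[i], as.vector(t(pairs))))
    }, numeric(1))
    hashes <- c(hashes, inv)
  }

  bits <- integer(n_bits)
  bits[(hashes %% n_bits) + 1] <- 1L
  structure(bits, radius = as.integer(radius), n_bits = as.integer(n_bits),
            class = "fingerprint")
}

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe")

#' Build the drug feature matrix
#'
#' Converts a drug table into an n x `n_bits` binary matrix, row order
#' matching input order. Records with a precomputed `fingerprint` entry are
#' passed through verbatim (after a dimension check); others must carry a
#' parseable SMILES.
#'
#' @param drugs Tibble with `drug_id` and `smiles` and/or a `fingerprint`
#'   list-column of 0/1 vectors.
#' @param radius,n_bits Morgan parameters for records featurized from
#'   SMILES; defaults 2 and 2048.
#' @return Binary matrix with rownames `drug_id`.
#' @export
featurize_drugs <- function(drugs, radius = 2L, n_bits = 2048L) {
  stopifnot(is.data.frame(drugs), "drug_id" %in% names(drugs))
  has_fp <- if ("fingerprint" %in% names(drugs)) {
    !vapply(drugs$fingerprint, is.null, logical(1))
  } else rep(FALSE, nrow(drugs))
  rows <- lapply(seq_len(nrow(drugs)), function(i) {
    if (has_fp[i]) {
      fp <- drugs$fingerprint[[i]]
      if (length(fp) != n_bits) {
        stop(sprintf(
          "drug '%s': precomputed fingerprint has length %d, expected %d",
          drugs$drug_id[i], length(fp), n_bits), call. = FALSE)
      }
      if (!all(fp %in% c(0, 1))) {
        stop(sprintf("drug '%s': fingerprint entries must be 0/1",
                     drugs$drug_id[i]), call. = FALSE)
      }
      as.numeric(fp)
    } else {
      smi <- drugs$smiles[i]
      if (is.null(smi) || is.na(smi) || !nzchar(smi)) {
        stop(sprintf("drug '%s': no SMILES and no precomputed fingerprint",
                     drugs$drug_id[i]), call. = FALSE)
      }
      as.numeric(morgan_fingerprint(smi, radius = radius, n_bits = n_bits))
    }
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- drugs$drug_id
  mat
}
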