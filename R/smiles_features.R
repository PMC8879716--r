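MAX_SMILES_LENGTH <- 250L
UNKNOWN_SYMBOL <- "<unk>"

#' Read a drug_id/SMILES table
#'
#' @param path CSV or TSV file with header columns `drug_id` and `smiles`
#'   (separator inferred from the extension, `.tsv` means tab).
#' @return data.frame with character columns `drug_id`, `smiles`.
#' @export
read_smiles_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("drug_id", "smiles") %in% names(df))) {
    stop_smilegnn("SMILES table must have columns drug_id, smiles")
  }
  if (anyDuplicated(df$drug_id)) stop_smilegnn("duplicate drug_id in SMILES table")
  df[, c("drug_id", "smiles")]
}

# SMILES longer than 250 characters are excluded from featurisation
smiles_retained <- function(smiles) {
  nzchar(smiles) & nchar(smiles) <= MAX_SMILES_LENGTH
}

#' Build the character vocabulary of a SMILES corpus
#'
#' SMILES strings longer than 250 characters are excluded first. The
#' vocabulary contains every character occurring in the retained strings,
#' truncated to the `cap - 1` most frequent (frequency descending, ties by
#' codepoint ascending), plus a reserved unknown-symbol slot that pools all
#' characters outside the kept set.
#'
#' @param records data.frame with columns `drug_id`, `smiles`.
#' @param cap maximum vocabulary size including the unknown slot (default 251).
#' @return an object of class `char_vocab`: `symbols` (last one is the unknown
#'   slot) and `size`.
#' @export
build_char_vocabulary <- function(records, cap = 251L) {
  stopifnot(cap >= 2)
  keep <- smiles_retained(records$smiles)
  if (!any(keep)) stop_smilegnn("empty corpus: no SMILES retained after the length rule")
  chars <- unlist(strsplit(records$smiles[keep], "", fixed = TRUE), use.names = FALSE)
  tab <- table(chars)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  syms <- names(tab)[ord]
  if (length(syms) > cap - 1L) syms <- syms[seq_len(cap - 1L)]
  structure(list(symbols = c(syms, UNKNOWN_SYMBOL),
                 size = length(syms) + 1L),
            class = "char_vocab")
}

#' @export
print.char_vocab <- function(x, ...) {
  cat(sprintf("<char_vocab> %d symbols incl. unknown slot: %s%s\n", x$size,
              paste(utils::head(x$symbols, 12), collapse = " "),
              if (x$size > 12) " ..." else ""))
  invisible(x)
}

#' Encode one SMILES string as a character-count vector
#'
#' @param smiles a single SMILES string of length at most 250 characters.
#' @param vocab a `char_vocab`.
#' @return integer vector of length `vocab$size`; characters outside the
#'   vocabulary are pooled into the final unknown slot.
#' @export
encode_smiles <- function(smiles, vocab) {
  stopifnot(length(smiles) == 1L)
  if (nchar(smiles) > MAX_SMILES_LENGTH) {
    stop_smilegnn("SMILES longer than %d characters is excluded, not encoded",
                  MAX_SMILES_LENGTH)
  }
  counts <- integer(vocab$size)
  if (nzchar(smiles)) {
    ch <- strsplit(smiles, "", fixed = TRUE)[[1]]
    i <- match(ch, vocab$symbols[-vocab$size])
    i[is.na(i)] <- vocab$size
    tab <- tabulate(i, nbins = vocab$size)
    counts <- as.integer(tab)
  }
  counts
}

#' Encode a SMILES corpus as a count matrix
#'
#' @param records data.frame with `drug_id`, `smiles`; over-long records are
#'   dropped (they fail the length rule).
#' @param vocab a `char_vocab`.
#' @return integer matrix (retained drugs x vocab size) with rownames the
#'   drug ids.
#' @export
encode_corpus <- function(records, vocab) {
  keep <- smiles_retained(records$smiles)
  recs <- records[keep, , drop = FALSE]
  m <- t(vapply(recs$smiles, encode_smiles, integer(vocab$size), vocab = vocab))
  rownames(m) <- recs$drug_id
  m
}

#' Reduce SMILES count vectors with PCA
#'
#' Projects the mean-centered count matrix onto its top `d_struct` principal
#' components. The sign of each component is fixed deterministically by making
#' its largest-magnitude loading positive, so results do not depend on the
#' underlying eigensolver's sign convention.
#'
#' @param raw numeric matrix (drugs with SMILES x vocabulary size), rownames
#'   are drug ids.
#' @param d_struct target dimension.
#' @param seed unused (the projection is deterministic); kept so all feature
#'   constructors share a uniform signature.
#' @return list with `scores` (n x d_struct), `rotation`, `center`, `sdev`.
#' @export
reduce_dimensions <- function(raw, d_struct, seed = 0L) {
  n <- nrow(raw); p <- ncol(raw)
  dmax <- min(n, p)
  if (d_struct > dmax) {
    stop_smilegnn("d_struct = %d exceeds achievable maximum %d (min of %d drugs with SMILES and %d vocabulary columns)",
                  d_struct, dmax, n, p)
  }
  pc <- stats::prcomp(raw, center = TRUE, scale. = FALSE, rank. = d_struct)
  rot <- pc$rotation
  if (ncol(rot) < d_struct) { # pad zero-variance directions if rank-deficient
    rot <- cbind(rot, matrix(0, p, d_struct - ncol(rot)))
  }
  flip <- apply(rot, 2, function(v) {
    k <- which.max(abs(v))
    if (v[k] < 0) -1 else 1
  })
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(raw, 2, pc$center) %*% rot
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(d_struct))
  list(scores = scores, rotation = rot, center = pc$center,
       sdev = pc$sdev[seq_len(min(d_struct, length(pc$sdev)))])
}

#' Build the per-drug structural feature matrix
#'
#' Full structural pipeline: length filter, character vocabulary, count
#' encoding, PCA reduction. Drugs without a (retained) SMILES get an all-zero
#' row and are flagged in `missing_mask`, so a topology-only prediction still
#' works for them.
#'
#' @param records data.frame `drug_id`, `smiles` (drugs with structures).
#' @param drug_ids character vector of all drugs the matrix must cover, in
#'   output row order.
#' @param d_struct reduced dimension (default 64).
#' @param cap vocabulary cap (default 251).
#' @param seed passed to [reduce_dimensions()].
#' @return object of class `structural_features`: `drug_ids`, `features`
#'   (n_drugs x d_struct), `missing_mask`, `vocab`, `pca`.
#' @export
structural_features <- function(records, drug_ids, d_struct = 64L,
                                cap = 251L, seed = 0L) {
  vocab <- build_char_vocabulary(records, cap = cap)
  raw <- encode_corpus(records, vocab)
  raw <- raw[rownames(raw) %in% drug_ids, , drop = FALSE]
  red <- reduce_dimensions(raw, d_struct, seed = seed)
  feats <- matrix(0, length(drug_ids), d_struct,
                  dimnames = list(drug_ids, colnames(red$scores)))
  hit <- match(rownames(raw), drug_ids)
  feats[hit, ] <- red$scores
  missing <- rep(TRUE, length(drug_ids))
  missing[hit] <- FALSE
  structure(list(drug_ids = drug_ids, features = feats,
                 missing_mask = missing, vocab = vocab,
                 pca = red[c("rotation", "center", "sdev")]),
            class = "structural_features")
}

#' @export
print.structural_features <- function(x, ...) {
  cat(sprintf("<structural_features> %d drugs x %d dims (%d without SMILES)\n",
              length(x$drug_ids), ncol(x$features), sum(x$missing_mask)))
  invisible(x)
}

#' Persist a structural feature matrix with its vocabulary/PCA sidecar
#'
#' Writes `<path>` as TSV (drug_id + numeric columns) and `<path>.json` with
#' the vocabulary and PCA parameters needed to re-project new SMILES.
#'
#' @param x a `structural_features` object.
#' @param path output TSV path.
#' @export
write_structural_features <- function(x, path) {
  df <- data.frame(drug_id = x$drug_ids, x$features, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(symbols = x$vocab$symbols,
               center = unname(x$pca$center),
               rotation = unname(x$pca$rotation))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA)
  invisible(path)
}
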