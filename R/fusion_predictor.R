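#' Labeled drug-pair dataset
#'
#' Validates and canonicalises a table of labeled drug pairs: labels must be
#' 0/1, self-pairs are forbidden, and each unordered pair may appear once.
#'
#' @param drug1,drug2 character vectors of drug ids.
#' @param label integer 0/1 vector.
#' @return a data.frame of class `pair_dataset` with columns `drug1`, `drug2`,
#'   `label` and attribute `drugs` (the sorted drug index set).
#' @export
pair_dataset <- function(drug1, drug2, label) {
  drug1 <- as.character(drug1); drug2 <- as.character(drug2)
  label <- as.integer(label)
  stopifnot(length(drug1) == length(drug2), length(drug1) == length(label))
  if (!all(label %in% c(0L, 1L))) stop_smilegnn("labels must be 0/1")
  if (any(drug1 == drug2)) stop_smilegnn("self-pairs are not allowed")
  key <- pair_key(drug1, drug2)
  if (anyDuplicated(key)) stop_smilegnn("duplicate unordered pair(s) in dataset")
  out <- data.frame(drug1 = drug1, drug2 = drug2, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "drugs") <- sort(unique(c(drug1, drug2)))
  class(out) <- c("pair_dataset", "data.frame")
  out
}

#' Read a labeled pair file (3-column TSV with header drug1, drug2, label)
#' @param path file path.
#' @return a `pair_dataset`.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  pair_dataset(df[[1]], df[[2]], df[[3]])
}

#' Write a labeled pair file
#' @param pairs a `pair_dataset`.
#' @param path output TSV path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs)[, c("drug1", "drug2", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_fusion_dims <- function(A, B, W, b, method) {
  d_topo <- ncol(A); d_struct <- ncol(B)
  if (nrow(A) != nrow(B)) {
    stop_smilegnn("row mismatch: %d topological vs %d structural rows",
                  nrow(A), nrow(B))
  }
  need <- if (method == "sum") d_topo else d_topo + d_struct
  if (method == "sum" && d_struct != d_topo) {
    stop_smilegnn("sum fusion needs d_struct = d_topo, got %d vs %d",
                  d_struct, d_topo)
  }
  if (nrow(W) != need || ncol(W) != d_topo || length(b) != d_topo) {
    stop_smilegnn("fusion weights must be %d x %d (bias %d), got %d x %d (bias %d)",
                  need, d_topo, d_topo, nrow(W), ncol(W), length(b))
  }
}

#' Fuse topological and structural features by superposition
#'
#' Computes `tanh((A + B) %*% W + b)`: the two per-drug feature matrices are
#' added elementwise (they must share the same dimension) and projected by a
#' learned weight matrix.
#'
#' @param A topological feature matrix (n_drugs x d_topo).
#' @param B structural feature matrix (n_drugs x d_topo).
#' @param W weight matrix (d_topo x d_topo).
#' @param b bias vector of length d_topo.
#' @return the fused comprehensive feature matrix, entries in (-1, 1).
#' @export
fuse_sum <- function(A, B, W, b) {
  A <- as.matrix(A); B <- as.matrix(B); W <- as.matrix(W)
  check_fusion_dims(A, B, W, b, "sum")
  tanh(sweep((A + B) %*% W, 2, b, `+`))
}

#' Fuse topological and structural features by concatenation
#'
#' Computes `tanh(cbind(A, B) %*% W + b)`. Unlike [fuse_sum()] this places no
#' constraint on the structural dimension; the output width is always the
#' topological dimension `ncol(A)`.
#'
#' @param A topological feature matrix (n_drugs x d_topo).
#' @param B structural feature matrix (n_drugs x d_struct).
#' @param W weight matrix ((d_topo + d_struct) x d_topo).
#' @param b bias vector of length d_topo.
#' @return the fused comprehensive feature matrix, entries in (-1, 1).
#' @export
fuse_concat <- function(A, B, W, b) {
  A <- as.matrix(A); B <- as.matrix(B); W <- as.matrix(W)
  check_fusion_dims(A, B, W, b, "concat")
  tanh(sweep(cbind(A, B) %*% W, 2, b, `+`))
}

#' Score a drug pair from its two comprehensive feature vectors
#'
#' The interaction score is the sigmoid of the inner product of the two fused
#' drug vectors; a pair is predicted interacting when the score strictly
#' exceeds 0.5.
#'
#' @param f1,f2 numeric vectors of equal length.
#' @return list with `score` in (0, 1) and `predicted_label` (0/1).
#' @export
score_pair <- function(f1, f2) {
  if (length(f1) != length(f2)) {
    stop_smilegnn("feature length mismatch: %d vs %d", length(f1), length(f2))
  }
  s <- sigmoid(sum(f1 * f2))
  list(score = s, predicted_label = as.integer(s > 0.5))
}

#' Binary cross-entropy loss over a set of scored pairs
#'
#' Scores are clipped to `[eps, 1 - eps]` for numerical stability. Returns the
#' sum over pairs of `-(y * log(p) + (1 - y) * log(1 - p))`; divide by the
#' number of pairs for the per-pair mean.
#'
#' @param labels 0/1 vector.
#' @param scores predicted probabilities, same length.
#' @param eps clipping constant (default 1e-7).
#' @param mean if TRUE return the mean instead of the sum.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(labels, scores, eps = 1e-7, mean = FALSE) {
  if (length(labels) != length(scores)) {
    stop_smilegnn("length mismatch: %d labels vs %d scores",
                  length(labels), length(scores))
  }
  p <- pmin(pmax(scores, eps), 1 - eps)
  tot <- -sum(labels * log(p) + (1 - labels) * log(1 - p))
  if (mean) tot / length(labels) else tot
}

#' Write scored predictions as TSV
#'
#' Columns: drug1, drug2, score (6 decimals), predicted_label.
#'
#' @param pairs data.frame with `drug1`, `drug2`.
#' @param scores numeric vector of pair scores.
#' @param path output path.
#' @export
write_predictions <- function(pairs, scores, path) {
  out <- data.frame(drug1 = pairs$drug1, drug2 = pairs$drug2,
                    score = sprintf("%.6f", scores),
                    predicted_label = as.integer(scores > 0.5))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
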