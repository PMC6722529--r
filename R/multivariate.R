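# Principal component analysis of RSCU profiles.

#' PCA of RSCU vectors
#'
#' Each sequence is a point in the 59-dimensional RSCU space (AUG, UGG and
#' stops excluded).  The matrix is column-centred (not scaled) and
#' decomposed by singular values; the inertia of axis k is its eigenvalue
#' divided by the total.  Undefined RSCU entries (families absent from a
#' sequence) are imputed with the column mean so they are inert after
#' centring.  Axis signs follow a deterministic convention: the loading
#' with the largest absolute value on each axis is made positive, so score
#' tables are reproducible bit-for-bit regardless of input order.
#'
#' @param vectors list of `rscu_vector` (or a numeric matrix with 59
#'   columns, rows = sequences).
#' @param n_axes number of axes to report (truncated to the rank with a
#'   warning when larger).
#' @return Object of class `pca_rscu`: `inertia` (fraction per positive
#'   axis), `scores` (n x n_axes), `loadings` (59 x n_axes), `n_axes`,
#'   `degenerate` (TRUE when total variance is zero).
#' @export
pca_rscu <- function(vectors, n_axes = 2L) {
  m <- if (is.matrix(vectors)) vectors else .as_rscu_matrix(vectors)
  if (nrow(m) < 3L) stop("need at least 3 sequences for PCA")
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (all(nas)) m[, j] <- 0
    else if (any(nas)) m[nas, j] <- mean(m[!nas, j])
  }
  centred <- scale(m, center = TRUE, scale = FALSE)
  total_var <- sum(centred^2)
  if (total_var < 1e-12) {
    return(structure(list(inertia = numeric(0),
                          scores = matrix(0, nrow(m), 0),
                          loadings = matrix(0, ncol(m), 0),
                          n_axes = 0L, degenerate = TRUE),
                     class = "pca_rscu"))
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  pos <- ev > max(ev) * 1e-12
  ev <- ev[pos]
  inertia <- ev / sum(ev)
  rank <- length(ev)
  if (n_axes > rank) {
    warning("n_axes = ", n_axes, " exceeds rank ", rank, "; truncated")
    n_axes <- rank
  }
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  for (k in seq_len(n_axes)) {
    # smallest index whose |loading| is within tolerance of the maximum,
    # so near-ties cannot flip the sign under input permutation
    pivot <- which(abs(loadings[, k]) >= max(abs(loadings[, k])) - 1e-8)[1L]
    if (loadings[pivot, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("axis", seq_len(n_axes))
  rownames(loadings) <- colnames(m)
  structure(list(inertia = inertia, scores = scores, loadings = loadings,
                 n_axes = as.integer(n_axes), degenerate = FALSE),
            class = "pca_rscu")
}

#' @export
print.pca_rscu <- function(x, ...) {
  if (x$degenerate) {
    cat("<pca_rscu> degenerate (zero variance)\n")
  } else {
    cat("<pca_rscu> ", length(x$inertia), " positive axes; axis1 inertia = ",
        sprintf("%.3f", x$inertia[1L]), "\n", sep = "")
  }
  invisible(x)
}

#' Per-sequence PCA score table
#'
#' @param seqs list of [coding_sequence()] records.
#' @param n_axes number of axes.
#' @return List with `scores` (data frame id, host, group, axis1..) and
#'   `inertia` (data frame axis, inertia, cumulative).
#' @export
pca_score_table <- function(seqs, n_axes = 2L) {
  vecs <- lapply(seqs, function(s) rscu(count_codons(s)))
  pc <- pca_rscu(vecs, n_axes = n_axes)
  ids <- vapply(seqs, `[[`, "", "id")
  hosts <- vapply(seqs, function(s) as.character(s$host), "")
  groups <- vapply(seqs, function(s) as.character(s$group), "")
  scores <- data.frame(id = ids, host = hosts, group = groups,
                       stringsAsFactors = FALSE)
  if (!pc$degenerate)
    scores <- cbind(scores, as.data.frame(pc$scores))
  inertia <- data.frame(axis = seq_along(pc$inertia), inertia = pc$inertia,
                        cumulative = cumsum(pc$inertia))
  list(scores = scores, inertia = inertia, pca = pc)
}
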