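# Relative synonymous codon usage: per-sequence vectors, group means and
# Table-1-style summaries.

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon i in an amino-acid family is its observed count divided by
#' the mean count over the family's synonymous codons, i.e. the ratio of
#' observed to expected usage under equal synonymous choice.  A value of 1
#' means no bias; by convention values > 1.6 are "overrepresented" and
#' values < 0.6 "underrepresented".  Families with zero observations are
#' flagged undefined (NA), never imputed as 0.
#'
#' @param counts a `codon_counts` with `exclude_nonbias = TRUE`.
#' @param over,under classification thresholds.
#' @return An object of class `rscu_vector`: list with `rscu` (named
#'   numeric over the 59-codon universe, NA for undefined families),
#'   `classification` (factor-like character vector: overrepresented /
#'   normal / underrepresented / undefined) and `n_per_aa` (family totals).
#' @examples
#' cc <- count_codons(c("TTT", "TTT", "TTT", "TTC"))
#' rscu(cc)$rscu[c("TTT", "TTC")]  # 1.5, 0.5
#' @export
rscu <- function(counts, over = 1.6, under = 0.6) {
  stopifnot(inherits(counts, "codon_counts"))
  if (!counts$exclude_nonbias)
    stop("rscu requires counts with exclude_nonbias = TRUE")
  vals <- stats::setNames(rep(NA_real_, length(BIAS_CODONS)), BIAS_CODONS)
  for (aa in DEGENERATE_AA) {
    fam <- SYN_FAMILIES[[aa]]
    g <- counts$g[fam]
    n <- sum(g)
    if (n > 0) vals[fam] <- g / mean(g)
  }
  cls <- ifelse(is.na(vals), "undefined",
         ifelse(vals > over, "overrepresented",
         ifelse(vals < under, "underrepresented", "normal")))
  structure(list(rscu = vals,
                 classification = stats::setNames(cls, BIAS_CODONS),
                 n_per_aa = counts$n_per_aa[DEGENERATE_AA]),
            class = "rscu_vector")
}

#' @export
print.rscu_vector <- function(x, ...) {
  def <- sum(!is.na(x$rscu))
  cat("<rscu_vector> ", def, "/", length(x$rscu), " codons defined\n", sep = "")
  invisible(x)
}

.as_rscu_matrix <- function(group) {
  vecs <- lapply(group, function(v) {
    if (inherits(v, "rscu_vector")) v$rscu
    else if (inherits(v, "codon_counts")) rscu(v)$rscu
    else stop("group elements must be rscu_vector or codon_counts")
  })
  do.call(rbind, vecs)
}

#' Group mean RSCU with preferred-codon calls
#'
#' The default group RSCU is the arithmetic mean of per-sequence RSCU
#' values, taken per codon over the sequences where that codon's family is
#' defined (undefined entries are excluded, not treated as 0).  The
#' alternative `mode = "pooled"` computes RSCU of the summed codon counts;
#' the two differ in general.  Within each family the most-used codon (the
#' largest mean RSCU) is marked; ties are broken lexicographically and
#' flagged.
#'
#' @param group non-empty list of `rscu_vector` (either mode) or
#'   `codon_counts` (required for `mode = "pooled"`).
#' @param mode `"sequences"` (mean of per-sequence vectors, default) or
#'   `"pooled"`.
#' @return Data frame with one row per codon: `codon` (RNA), `codon_dna`,
#'   `aa`, `rscu`, `n_seqs` (sequences contributing), `preferred`
#'   (logical), `tie` (logical).
#' @export
mean_rscu <- function(group, mode = c("sequences", "pooled")) {
  mode <- match.arg(mode)
  if (length(group) == 0L) stop("empty group")
  if (mode == "pooled") {
    if (!all(vapply(group, inherits, logical(1), "codon_counts")))
      stop("pooled mode requires codon_counts inputs")
    vals <- rscu(pool_codon_counts(group))$rscu
    nseq <- ifelse(is.na(vals), 0L, length(group))
  } else {
    m <- .as_rscu_matrix(group)
    nseq <- colSums(!is.na(m))
    vals <- suppressWarnings(colMeans(m, na.rm = TRUE))
    vals[nseq == 0L] <- NA_real_
  }
  aa <- AA_OF_CODON[BIAS_CODONS]
  preferred <- tie <- stats::setNames(rep(FALSE, length(BIAS_CODONS)),
                                      BIAS_CODONS)
  for (fam_aa in DEGENERATE_AA) {
    fam <- SYN_FAMILIES[[fam_aa]]
    v <- vals[fam]
    if (all(is.na(v))) next
    top <- max(v, na.rm = TRUE)
    winners <- sort(fam[!is.na(v) & v == top])
    preferred[winners[1L]] <- TRUE
    if (length(winners) > 1L) tie[winners] <- TRUE
  }
  data.frame(codon = codon_to_rna(BIAS_CODONS), codon_dna = BIAS_CODONS,
             aa = unname(aa), rscu = unname(vals),
             n_seqs = unname(nseq), preferred = unname(preferred),
             tie = unname(tie), stringsAsFactors = FALSE)
}

#' Table-1-style RSCU comparison across groups
#'
#' @param groups named list; each element is a list of `rscu_vector` (one
#'   per sequence in that group).  An `"All"` column pooling every sequence
#'   is appended.
#' @param mode passed to [mean_rscu()].
#' @return Data frame: codon, aa, one RSCU column per group plus `All`, and
#'   a `<group>_preferred` marker column per group.
#' @export
rscu_table <- function(groups, mode = c("sequences", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(groups) > 0L, !is.null(names(groups)))
  all_seqs <- unlist(groups, recursive = FALSE)
  cols <- c(groups, list(All = all_seqs))
  out <- data.frame(codon = codon_to_rna(BIAS_CODONS),
                    aa = unname(AA_OF_CODON[BIAS_CODONS]),
                    stringsAsFactors = FALSE)
  for (gname in names(cols)) {
    mr <- mean_rscu(cols[[gname]], mode = mode)
    out[[gname]] <- mr$rscu
    out[[paste0(gname, "_preferred")]] <- ifelse(mr$preferred, "*", "")
  }
  out
}
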