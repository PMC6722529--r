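# Mutation-vs-selection analyses: parity rule 2, neutrality regression and
# the Spearman correlation matrix of protein indices against bias measures.

#' Parity rule 2 (PR2) coordinates
#'
#' Under mutation pressure alone and no strand bias, A = U and G = C at the
#' third position of fourfold-degenerate families, placing a gene at
#' (0.5, 0.5) in the plot of A3/(A3+U3) against G3/(G3+C3).  The default
#' uses only the five strictly fourfold families (Ala, Gly, Pro, Thr, Val);
#' `mode = "include6fold"` adds the fourfold codon boxes of Leu (CUN), Ser
#' (UCN) and Arg (CGN).
#'
#' @param counts a `codon_counts`.
#' @param mode `"strict4"` (default) or `"include6fold"`.
#' @return List: `at_bias` = A3/(A3+U3), `gc_bias` = G3/(G3+C3) (NA with a
#'   flag when a denominator is zero), third-position tallies `a3`, `u3`,
#'   `g3`, `c3`, `n` and `mode`.
#' @export
pr2_point <- function(counts, mode = c("strict4", "include6fold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "codon_counts"))
  boxes <- unlist(SYN_FAMILIES[FOURFOLD_AA], use.names = FALSE)
  if (mode == "include6fold")
    boxes <- c(boxes, unlist(SIXFOLD_BOXES, use.names = FALSE))
  g <- counts$g[boxes]
  if (sum(g) == 0) stop("no fourfold-family codons observed")
  third <- substr(boxes, 3L, 3L)
  a3 <- sum(g[third == "A"]); u3 <- sum(g[third == "T"])
  g3 <- sum(g[third == "G"]); c3 <- sum(g[third == "C"])
  list(at_bias = if (a3 + u3 > 0) a3 / (a3 + u3) else NA_real_,
       gc_bias = if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_,
       a3 = a3, u3 = u3, g3 = g3, c3 = c3, n = sum(g), mode = mode)
}

#' PR2 table over a set of sequences
#'
#' @param seqs list of [coding_sequence()] records.
#' @param mode passed to [pr2_point()].
#' @return Data frame with one row per sequence.
#' @export
pr2_table <- function(seqs, mode = c("strict4", "include6fold")) {
  mode <- match.arg(mode)
  if (length(seqs) == 0L) stop("no sequences")
  rows <- lapply(seqs, function(s) {
    p <- pr2_point(count_codons(s), mode = mode)
    data.frame(id = s$id, host = s$host, group = s$group,
               at_bias = p$at_bias, gc_bias = p$gc_bias, n = p$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean G+C at codon positions 1 and 2) on
#' GC3.  The slope estimates the share of directional mutation pressure:
#' points on the diagonal (slope 1) indicate mutation pressure alone, while
#' shallower slopes indicate selection constraining positions 1-2.  The
#' selection share is defined as 100 - 100*slope, so the two percentages
#' always sum to 100.
#'
#' @param gc12,gc3 numeric vectors (same scale, percent or fraction), or a
#'   data frame with columns `gc12` and `gc3` as the first argument.
#' @return Object of class `neutrality_fit`: slope, intercept, r2, p
#'   (two-sided t-test of slope = 0), mutation_pct, selection_pct, n.
#' @export
neutrality_fit <- function(gc12, gc3 = NULL) {
  if (is.data.frame(gc12)) {
    gc3 <- gc12$gc3
    gc12 <- gc12$gc12
  }
  stopifnot(length(gc12) == length(gc3))
  keep <- !is.na(gc12) & !is.na(gc3)
  gc12 <- gc12[keep]; gc3 <- gc3[keep]
  n <- length(gc12)
  if (n < 3L) stop("need at least 3 points for a neutrality fit")
  if (stats::sd(gc3) == 0) stop("degenerate regression: GC3 is constant")
  fit <- stats::lm(gc12 ~ gc3)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = sm$r.squared, p = p,
                 mutation_pct = 100 * slope,
                 selection_pct = 100 - 100 * slope,
                 n = n),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(paste0("<neutrality_fit> slope = %.4f (r2 = %.4f, p = %.3g, ",
                     "n = %d)\n  mutation %.2f%% / selection %.2f%%\n"),
              x$slope, x$r2, x$p, x$n, x$mutation_pct, x$selection_pct))
  invisible(x)
}

#' Per-host neutrality fits
#'
#' @param tab per-sequence table with columns `gc12s`, `gc3s` and a
#'   grouping column (from [composition_table()]).
#' @param by grouping column, default `"host"`; a fit over all rows is
#'   labelled `"All"` and prepended.
#' @return Data frame of fits (group, n, slope, intercept, r2, p,
#'   mutation_pct, selection_pct); groups whose fit fails (too few points,
#'   constant GC3) are reported with NA estimates.
#' @export
neutrality_by_group <- function(tab, by = "host") {
  stopifnot(all(c("gc12s", "gc3s") %in% names(tab)))
  grp <- c(list(All = seq_len(nrow(tab))),
           split(seq_len(nrow(tab)), as.character(tab[[by]])))
  rows <- lapply(names(grp), function(gname) {
    ix <- grp[[gname]]
    fit <- tryCatch(neutrality_fit(tab$gc12s[ix], tab$gc3s[ix]),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(group = gname, n = length(ix), slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_, p = NA_real_,
                        mutation_pct = NA_real_, selection_pct = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(group = gname, n = fit$n, slope = fit$slope,
               intercept = fit$intercept, r2 = fit$r2, p = fit$p,
               mutation_pct = fit$mutation_pct,
               selection_pct = fit$selection_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.spearman_one <- function(x, y, exact_max_n = 10L) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, flag = "constant"))
  rho <- stats::cor(x, y, method = "spearman")
  has_ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= exact_max_n && !has_ties) {
    p <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = TRUE)$p.value)
  } else {
    # t approximation on rho with n - 2 df (mid-ranks for ties)
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, flag = "")
}

.stars <- function(p) {
  if (is.na(p)) "na" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Spearman correlation matrix with significance stars
#'
#' Correlates each row variable (typically GRAVY and aromaticity) against
#' each column variable (typically ENC, GC3s, GC and the first two PCA
#' axes) using Spearman's rank correlation with mid-rank tie handling.
#' P-values use the t approximation (exact for n <= 10 without ties);
#' stars follow the convention ** p < 0.01, * 0.01 <= p < 0.05, ns
#' otherwise.
#'
#' @param tab per-sequence data frame holding all variables.
#' @param row_vars,col_vars column names to correlate.
#' @return Long data frame: var1, var2, rho, p, stars, n, flag
#'   ("constant" when a variable has zero variance).
#' @export
correlation_matrix <- function(tab,
                               row_vars = c("gravy", "aroma"),
                               col_vars = c("enc", "gc3s", "gc_pct",
                                            "axis1", "axis2")) {
  missing_vars <- setdiff(c(row_vars, col_vars), names(tab))
  if (length(missing_vars) > 0L)
    stop("missing column(s): ", paste(missing_vars, collapse = ", "))
  if (nrow(tab) < 5L) stop("need at least 5 sequences for correlations")
  rows <- list()
  for (rv in row_vars) for (cv in col_vars) {
    res <- .spearman_one(tab[[rv]], tab[[cv]])
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = rv, var2 = cv, rho = res$rho, p = res$p,
      stars = .stars(res$p), n = nrow(tab), flag = res$flag,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
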