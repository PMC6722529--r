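# Wright's effective number of codons (ENC) and the GC3s expected curve
# used in ENC-plot analysis.

#' Codon homozygosity of one amino-acid family
#'
#' For a family observed n times with per-codon counts n_i, the codon
#' homozygosity estimator is F = (nS - 1)/(n - 1) with S = sum((n_i/n)^2).
#' F ranges from 1/k (equal use, large n) to 1 (a single codon used).
#' Families observed fewer than twice are undefined.
#'
#' @param g numeric vector of codon counts for one family.
#' @return List with `F`, `S` and `n` (`F` is NA when n < 2).
#' @examples
#' family_F(c(3, 1))$F  # 0.5
#' @export
family_F <- function(g) {
  stopifnot(is.numeric(g), all(g >= 0))
  n <- sum(g)
  if (n < 2) return(list(F = NA_real_, S = NA_real_, n = n))
  S <- sum((g / n)^2)
  list(F = (n * S - 1) / (n - 1), S = S, n = n)
}

#' Effective number of codons (ENC)
#'
#' Wright's summary of how far a gene departs from uniform synonymous
#' usage: ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, where Fk is the mean codon
#' homozygosity over the k-fold degenerate families (9 two-fold families,
#' Ile as the single three-fold family, 5 four-fold and 3 six-fold
#' families; the leading 2 accounts for Met and Trp).  ENC ranges from 20
#' (a single codon per family, extreme bias) to 61 (uniform usage, no
#' bias); values <= 35 conventionally indicate significant codon bias.
#'
#' Families with undefined F (n < 2) or F <= 0 are excluded from their
#' class mean with a diagnostic.  A missing three-fold class (no Ile) is
#' imputed as (F2 + F4)/2 (Wright's correction); a missing six-fold class
#' is imputed as F4 and flags the result unusable.  A missing two-fold or
#' four-fold class is an error.  Sampling noise can push ENC slightly above
#' 61; such values are clamped to 61 and flagged.
#'
#' @param counts a `codon_counts` with `exclude_nonbias = TRUE`.
#' @return Object of class `enc_result`: `enc` (clamped), `enc_raw`,
#'   `fbar` (named by class "2","3","4","6"), `families` (per-family data
#'   frame with aa, k, n, S, F, used), `gc3s` (fraction in 0-1), `clamped`,
#'   `imputed` (character vector of imputed classes), `usable`, `biased`
#'   (ENC <= 35).
#' @export
enc <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  if (!counts$exclude_nonbias)
    stop("enc requires counts with exclude_nonbias = TRUE")
  fams <- lapply(DEGENERATE_AA, function(aa) {
    f <- family_F(counts$g[SYN_FAMILIES[[aa]]])
    data.frame(aa = aa, k = DEGENERACY[[aa]], n = f$n, S = f$S, F = f$F,
               stringsAsFactors = FALSE)
  })
  fams <- do.call(rbind, fams)
  fams$used <- !is.na(fams$F) & fams$F > 0
  fbar <- vapply(c(2, 3, 4, 6), function(k) {
    f <- fams$F[fams$k == k & fams$used]
    if (length(f) == 0L) NA_real_ else mean(f)
  }, numeric(1))
  names(fbar) <- c("2", "3", "4", "6")
  imputed <- character(0)
  usable <- TRUE
  if (is.na(fbar[["2"]]) || is.na(fbar[["4"]]))
    stop("sequence too short for ENC (no usable two-fold or four-fold family)")
  if (is.na(fbar[["3"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
    imputed <- c(imputed, "3")
  }
  if (is.na(fbar[["6"]])) {
    fbar[["6"]] <- fbar[["4"]]
    imputed <- c(imputed, "6")
    usable <- FALSE
  }
  enc_raw <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] +
    5 / fbar[["4"]] + 3 / fbar[["6"]]
  clamped <- enc_raw > 61
  enc_val <- if (clamped) 61 else enc_raw

  syn <- BIAS_CODONS
  third <- substr(syn, 3L, 3L)
  n_syn <- sum(counts$g[syn])
  gc3s <- sum(counts$g[syn][third %in% c("G", "C")]) / n_syn

  structure(list(enc = enc_val, enc_raw = enc_raw, fbar = fbar,
                 families = fams, gc3s = gc3s, clamped = clamped,
                 imputed = imputed, usable = usable,
                 biased = enc_val <= 35),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("<enc_result> ENC = %.3f (GC3s = %.3f)%s%s\n", x$enc, x$gc3s,
              if (x$clamped) " [clamped]" else "",
              if (length(x$imputed)) paste0(" [imputed F",
                                            paste(x$imputed, collapse = ",F"),
                                            "]") else ""))
  invisible(x)
}

#' Expected ENC under mutation pressure alone
#'
#' The null curve of the ENC-GC3s plot: the ENC a gene would have if codon
#' usage were determined only by its third-position G+C content s,
#' ENC_expected = 2 + s + 29/(s^2 + (1-s)^2).  Genes falling below the
#' curve are read as shaped by selection beyond mutation pressure.
#'
#' @param s GC3s fraction(s) in \[0, 1\].
#' @return Numeric vector of expected ENC values.
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(s) {
  if (any(s < 0 | s > 1)) stop("GC3s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' ENC-plot table: observed vs expected ENC per sequence
#'
#' @param seqs non-empty list of [coding_sequence()] records.
#' @return Data frame: id, host, group, gc3s (fraction), enc, expected_enc,
#'   below_curve (enc < expected), biased (enc <= 35).
#' @export
enc_plot_table <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences")
  rows <- lapply(seqs, function(s) {
    e <- enc(count_codons(s))
    data.frame(id = s$id, host = s$host, group = s$group,
               gc3s = e$gc3s, enc = e$enc,
               expected_enc = enc_expected(e$gc3s),
               below_curve = e$enc < enc_expected(e$gc3s),
               biased = e$biased, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
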