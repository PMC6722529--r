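# Shared fixtures and independent brute-force oracles.  The oracles are
# literal transcriptions of the defining formulas, kept separate from the
# package's implementation paths.

GCT <- genetic_code_table()
SENSE <- GCT$codon[GCT$aa != "*"]
AA_OF <- setNames(GCT$aa, GCT$codon)[SENSE]
FAMS <- split(SENSE, AA_OF)
DEGEN_FAMS <- FAMS[vapply(FAMS, length, 1L) >= 2L]
BIAS59 <- unlist(DEGEN_FAMS, use.names = FALSE)

random_seq <- function(n, seed) {
  set.seed(seed)
  coding_sequence(paste0("rnd", seed), sample(SENSE, n, replace = TRUE))
}

random_counts <- function(seed, lambda = 5, min_count = 0L) {
  set.seed(seed)
  g <- rpois(length(SENSE), lambda) + min_count
  cc <- count_codons(rep(SENSE, 2L))  # template with the right shape
  cc$g[] <- as.numeric(setNames(g, SENSE))
  cc$g[c("ATG", "TGG")] <- 0
  cc$n_per_aa <- tapply(cc$g, AA_OF[SENSE], sum)
  cc$n_per_aa <- setNames(as.numeric(cc$n_per_aa),
                          names(table(AA_OF[SENSE])))
  cc$n_total <- sum(cc$g)
  cc
}

random_host_counts <- function(seed, min_count = 1) {
  set.seed(seed)
  setNames(rpois(length(SENSE), 20) + min_count, SENSE)
}

# Host table with near-deterministic preferences: one codon per family
# carries count 1000, the rest count 1 (no zeros, so no smoothing).
strong_host <- function() {
  counts <- setNames(rep(1, length(SENSE)), SENSE)
  for (fam in FAMS) counts[sort(fam)[1L]] <- 1000
  host_usage_table(counts, name = "strong")
}

# RSCU by the direct definition: g_ij * n_i / sum_j g_ij.
oracle_rscu <- function(g) {
  out <- setNames(rep(NA_real_, length(BIAS59)), BIAS59)
  for (fam in DEGEN_FAMS) {
    tot <- sum(g[fam])
    if (tot > 0) out[fam] <- g[fam] * length(fam) / tot
  }
  out
}

# ENC by straight-line evaluation of Wright's formulas.
oracle_enc <- function(g) {
  Fk <- list("2" = c(), "3" = c(), "4" = c(), "6" = c())
  for (fam in DEGEN_FAMS) {
    n <- sum(g[fam])
    if (n < 2) next
    S <- sum((g[fam] / n)^2)
    Fv <- (n * S - 1) / (n - 1)
    if (Fv <= 0) next
    k <- as.character(length(fam))
    Fk[[k]] <- c(Fk[[k]], Fv)
  }
  fbar <- vapply(Fk, function(v) if (length(v)) mean(v) else NA_real_, 1)
  if (is.na(fbar[["3"]])) fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  if (is.na(fbar[["6"]])) fbar[["6"]] <- fbar[["4"]]
  val <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  min(val, 61)
}

# Spearman rho: mid-ranks then the Pearson product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

oracle_cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# PCA inertia fractions via an explicit eigendecomposition of the centred
# cross-product matrix.
oracle_pca_inertia <- function(m) {
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (all(nas)) m[, j] <- 0 else if (any(nas)) m[nas, j] <- mean(m[!nas, j])
  }
  centred <- sweep(m, 2, colMeans(m))
  ev <- eigen(crossprod(centred), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  ev / sum(ev)
}
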