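# Nucleotide composition (overall and at synonymous third positions) and
# protein-level hydropathy / aromaticity indices.

.pct <- function(x, total) if (total > 0) 100 * x / total else NA_real_

#' Nucleotide composition profile of a coding sequence
#'
#' Overall A/C/G/U percentages (and AU, GC totals) are computed over the
#' full CDS nucleotides.  Positional statistics (A3s..U3s, GC1s, GC2s,
#' GC3s) are computed over synonymous codons only, i.e. the 59-codon
#' universe that excludes AUG, UGG and stops, following the CodonW
#' convention.  GC12s is the arithmetic mean of GC1s and GC2s.
#'
#' @param seq a [coding_sequence()].
#' @return One-row data frame with columns `id`, `host`, `group`,
#'   `a_pct`..`u_pct`, `gc_pct`, `au_pct`, `a3s`..`u3s`, `gc1s`, `gc2s`,
#'   `gc3s`, `gc12s`, `length_codons`.  Percentages are on the 0-100 scale.
#' @export
composition_profile <- function(seq) {
  stopifnot(inherits(seq, "coding_sequence"))
  codons <- seq$codons
  nt <- unlist(strsplit(codons, ""), use.names = FALSE)
  ntot <- length(nt)
  base_pct <- vapply(c(A = "A", C = "C", G = "G", U = "T"),
                     function(b) .pct(sum(nt == b), ntot), numeric(1))

  syn <- codons[codons %in% BIAS_CODONS]
  if (length(syn) == 0L) stop("no synonymous codons in sequence '", seq$id, "'")
  p1 <- substr(syn, 1L, 1L); p2 <- substr(syn, 2L, 2L); p3 <- substr(syn, 3L, 3L)
  n_syn <- length(syn)
  third_pct <- vapply(c(A = "A", C = "C", G = "G", U = "T"),
                      function(b) .pct(sum(p3 == b), n_syn), numeric(1))
  gc1s <- .pct(sum(p1 %in% c("G", "C")), n_syn)
  gc2s <- .pct(sum(p2 %in% c("G", "C")), n_syn)
  gc3s <- .pct(sum(p3 %in% c("G", "C")), n_syn)

  data.frame(id = seq$id, host = seq$host, group = seq$group,
             a_pct = base_pct[["A"]], c_pct = base_pct[["C"]],
             g_pct = base_pct[["G"]], u_pct = base_pct[["U"]],
             gc_pct = base_pct[["G"]] + base_pct[["C"]],
             au_pct = base_pct[["A"]] + base_pct[["U"]],
             a3s = third_pct[["A"]], c3s = third_pct[["C"]],
             g3s = third_pct[["G"]], u3s = third_pct[["U"]],
             gc1s = gc1s, gc2s = gc2s, gc3s = gc3s,
             gc12s = (gc1s + gc2s) / 2,
             length_codons = length(codons),
             stringsAsFactors = FALSE)
}

#' GRAVY and aromaticity of a protein sequence
#'
#' GRAVY is the mean Kyte-Doolittle hydropathy per residue (scale extremes
#' -4.5 for Arg, +4.5 for Ile); aromaticity is the fraction of Phe, Tyr and
#' Trp residues.
#'
#' @param protein single string over the 20 one-letter amino-acid codes.
#' @return List with numeric elements `gravy` and `aroma`.
#' @examples
#' protein_indices("RF")  # gravy (-4.5 + 2.8)/2, aroma 0.5
#' @export
protein_indices <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  aa <- strsplit(toupper(protein), "")[[1]]
  unknown <- setdiff(aa, names(KD_HYDROPATHY))
  if (length(unknown) > 0L)
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  list(gravy = mean(KD_HYDROPATHY[aa]),
       aroma = mean(aa %in% AROMATIC_AA))
}

#' Per-sequence composition and protein-index table
#'
#' @param seqs list of [coding_sequence()] records.
#' @return Data frame, one row per sequence, combining
#'   [composition_profile()] with GRAVY and aromaticity of the encoded
#'   protein.
#' @export
composition_table <- function(seqs) {
  stopifnot(length(seqs) > 0L)
  rows <- lapply(seqs, function(s) {
    prof <- composition_profile(s)
    pi <- protein_indices(translate_codons(s))
    prof$gravy <- pi$gravy
    prof$aroma <- pi$aroma
    prof
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group summary (mean and SD) of a per-sequence table
#'
#' @param tab data frame from [composition_table()] or any per-sequence
#'   table with numeric columns.
#' @param by grouping column name (e.g. `"host"`); `NULL` summarises all
#'   rows as one group `"All"`.
#' @param sd `"population"` (divisor n, the default) or `"sample"`
#'   (divisor n-1).
#' @return Data frame with one row per group and `<var>_mean` /
#'   `<var>_sd` columns.
#' @export
group_summary <- function(tab, by = NULL, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  grp <- if (is.null(by)) rep("All", nrow(tab)) else as.character(tab[[by]])
  sdfun <- function(x) {
    n <- sum(!is.na(x))
    if (n < 1L) return(NA_real_)
    if (sd == "population") sqrt(sum((x - mean(x, na.rm = TRUE))^2,
                                     na.rm = TRUE) / n)
    else stats::sd(x, na.rm = TRUE)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(tab)), grp), function(ix) {
    row <- data.frame(group = grp[ix[1L]], n = length(ix),
                      stringsAsFactors = FALSE)
    for (v in num) {
      row[[paste0(v, "_mean")]] <- mean(tab[[v]][ix], na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- sdfun(tab[[v]][ix])
    }
    row
  }))
  rownames(out) <- NULL
  out
}
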