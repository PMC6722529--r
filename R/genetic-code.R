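# Standard genetic code tables shared by every module.  Codons are stored
# internally in the DNA alphabet (T); reporting helpers convert to RNA (U),
# which is how codon-usage tables are conventionally printed.

.build_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(p3 = bases, p2 = bases, p1 = bases,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1), USE.NAMES = FALSE)
  data.frame(codon = codons, aa = aa, stringsAsFactors = FALSE)
}

CODON_TABLE <- .build_codon_table()

STOP_CODONS <- CODON_TABLE$codon[CODON_TABLE$aa == "*"]
SENSE_CODONS <- CODON_TABLE$codon[CODON_TABLE$aa != "*"]
AA_OF_CODON <- stats::setNames(CODON_TABLE$aa, CODON_TABLE$codon)[SENSE_CODONS]

# Met and Trp are encoded by a single codon each, so they carry no
# information about synonymous choice ("non-bias" codons); together with the
# three stops they are excluded from all bias statistics.
NONBIAS_CODONS <- c("ATG", "TGG")
BIAS_CODONS <- setdiff(SENSE_CODONS, NONBIAS_CODONS)  # the 59-codon universe

# Synonymous families over the sense codons (all 20 amino acids) and the
# degeneracy class k of each family; 18 families have k >= 2.
SYN_FAMILIES <- split(SENSE_CODONS, AA_OF_CODON[SENSE_CODONS])
DEGENERACY <- vapply(SYN_FAMILIES, length, integer(1))
DEGENERATE_AA <- names(DEGENERACY)[DEGENERACY >= 2L]

# The five strictly fourfold-degenerate amino acids used by PR2 analysis,
# and the fourfold codon boxes of the three sixfold families.
FOURFOLD_AA <- c("A", "G", "P", "T", "V")
SIXFOLD_BOXES <- list(
  L = c("CTT", "CTC", "CTA", "CTG"),
  S = c("TCT", "TCC", "TCA", "TCG"),
  R = c("CGT", "CGC", "CGA", "CGG")
)

# Kyte-Doolittle hydropathy scale keyed by one-letter amino-acid code,
# taken from seqinr's aaindex compilation (entry KYTJ820101).
.build_kd_scale <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  kd <- env$aaindex[["KYTJ820101"]]$I
  stats::setNames(as.numeric(kd),
                  vapply(names(kd), seqinr::a, character(1)))
}
KD_HYDROPATHY <- .build_kd_scale()

AROMATIC_AA <- c("F", "Y", "W")

#' Sense codons of the standard genetic code
#'
#' @param universe `"sense"` for all 61 sense codons, `"bias"` for the
#'   59-codon universe that excludes the single-codon families Met (ATG)
#'   and Trp (TGG).
#' @param alphabet `"dna"` (T) or `"rna"` (U).
#' @return Character vector of codons.
#' @examples
#' length(sense_codons())           # 61
#' length(sense_codons("bias"))     # 59
#' @export
sense_codons <- function(universe = c("sense", "bias"),
                         alphabet = c("dna", "rna")) {
  universe <- match.arg(universe)
  alphabet <- match.arg(alphabet)
  out <- if (universe == "sense") SENSE_CODONS else BIAS_CODONS
  if (alphabet == "rna") codon_to_rna(out) else out
}

#' Convert codons between DNA and RNA alphabets
#'
#' @param codons character vector of codons.
#' @return Character vector with T replaced by U (or vice versa).
#' @export
codon_to_rna <- function(codons) gsub("T", "U", codons, fixed = TRUE)

#' @rdname codon_to_rna
#' @export
codon_to_dna <- function(codons) gsub("U", "T", toupper(codons), fixed = TRUE)

#' Standard genetic code as a data frame
#'
#' @return Data frame with columns `codon` (DNA alphabet), `aa` (one-letter
#'   code, `*` for stop) and `degeneracy` (NA for stops).
#' @export
genetic_code_table <- function() {
  tab <- CODON_TABLE
  tab$degeneracy <- ifelse(tab$aa == "*", NA_integer_,
                           DEGENERACY[tab$aa])
  tab
}
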