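# Reading and validating coding sequences, codon tallies and translation.

#' Construct a coding sequence record
#'
#' A `coding_sequence` holds an ordered codon vector (DNA alphabet; U on
#' input is normalised to T), an identifier and optional host / group
#' labels.  The nucleotide length must be a multiple of three, every codon
#' must be an unambiguous triplet over A, C, G, T, and internal stop codons
#' are fatal; a terminal stop is stripped and recorded.
#'
#' @param id character identifier.
#' @param codons character vector of triplets, or a single nucleotide string.
#' @param host,group optional categorical labels.
#' @param terminal_stop logical, whether a terminal stop was stripped.
#' @return An object of class `coding_sequence`.
#' @examples
#' cds <- coding_sequence("x", "ATGGCTGCATAA")
#' cds$codons   # ATG GCT GCA; the terminal TAA is stripped
#' @export
coding_sequence <- function(id, codons, host = NA_character_,
                            group = NA_character_, terminal_stop = FALSE) {
  stopifnot(is.character(id), length(id) == 1L)
  if (length(codons) == 1L && nchar(codons) > 3L) {
    nt <- toupper(gsub("U", "T", codons, fixed = FALSE))
    if (nchar(nt) %% 3L != 0L)
      stop("sequence '", id, "': length not multiple of 3")
    codons <- substring(nt, seq(1L, nchar(nt), by = 3L),
                        seq(3L, nchar(nt), by = 3L))
  } else {
    codons <- toupper(gsub("U", "T", codons, fixed = FALSE))
  }
  if (length(codons) == 0L) stop("sequence '", id, "': empty")
  if (any(nchar(codons) != 3L))
    stop("sequence '", id, "': codons must be triplets")
  bad <- grepl("[^ACGT]", codons)
  if (any(bad))
    stop("sequence '", id, "': ambiguous or invalid codon(s): ",
         paste(unique(codons[bad]), collapse = ", "))
  is_stop <- codons %in% STOP_CODONS
  if (any(is_stop)) {
    if (sum(is_stop) == 1L && is_stop[length(codons)]) {
      codons <- codons[-length(codons)]
      terminal_stop <- TRUE
      if (length(codons) == 0L) stop("sequence '", id, "': empty after stop strip")
    } else {
      stop("sequence '", id, "': internal stop codon at codon ",
           which(is_stop)[1L])
    }
  }
  structure(list(id = id, codons = codons, host = host, group = group,
                 terminal_stop = terminal_stop),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence> ", x$id, ": ", length(x$codons), " codons",
      if (!is.na(x$host)) paste0(", host=", x$host),
      if (!is.na(x$group)) paste0(", group=", x$group),
      if (x$terminal_stop) " (terminal stop stripped)", "\n", sep = "")
  invisible(x)
}

#' @export
length.coding_sequence <- function(x) length(x$codons)

#' Read coding sequences from a FASTA file
#'
#' Each record is validated as a CDS: length divisible by three, no internal
#' stop codons, terminal stop stripped if present.  Codons containing
#' ambiguity codes (N, R, ...) are dropped (`ambiguity = "drop"`) or cause
#' the whole record to be rejected (`"reject"`).  Invalid records are
#' skipped with a warning (`on_invalid = "skip"`) or abort the read
#' (`"abort"`).
#'
#' @param path FASTA file path.
#' @param ambiguity how to treat codons with ambiguity codes.
#' @param on_invalid what to do with records that fail validation.
#' @param metadata optional data frame with columns `id`, `host`, `group`
#'   (e.g. from [read_metadata()]); labels are attached by id.
#' @return Named list of [coding_sequence()] records, in file order.
#' @export
read_cds_fasta <- function(path, ambiguity = c("drop", "reject"),
                           on_invalid = c("skip", "abort"),
                           metadata = NULL) {
  ambiguity <- match.arg(ambiguity)
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  out <- list()
  for (i in seq_along(recs)) {
    id <- names(recs)[i]
    nt <- toupper(gsub("U", "T", as.character(recs[[i]])))
    res <- tryCatch({
      if (nchar(nt) %% 3L != 0L)
        stop("sequence '", id, "': length not multiple of 3")
      codons <- substring(nt, seq(1L, nchar(nt), by = 3L),
                          seq(3L, nchar(nt), by = 3L))
      amb <- grepl("[^ACGT]", codons)
      if (any(amb)) {
        if (ambiguity == "reject")
          stop("sequence '", id, "': ", sum(amb), " ambiguous codon(s)")
        codons <- codons[!amb]
        if (length(codons) == 0L)
          stop("sequence '", id, "': no unambiguous codons")
      }
      coding_sequence(id, codons)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_invalid == "abort") stop(conditionMessage(res), call. = FALSE)
      warning("skipping record: ", conditionMessage(res), call. = FALSE)
    } else {
      out[[id]] <- res
    }
  }
  if (!is.null(metadata)) out <- attach_metadata(out, metadata)
  out
}

#' Read a sequence metadata table
#'
#' @param path TSV file with columns `id`, `host`, `group` (extra columns
#'   are kept).
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(md)) stop("metadata must have an 'id' column")
  md
}

#' Attach host/group labels from a metadata table
#'
#' @param seqs list of [coding_sequence()] records.
#' @param metadata data frame with columns `id` and optionally `host`,
#'   `group`.
#' @return The list with labels filled in.
#' @export
attach_metadata <- function(seqs, metadata) {
  idx <- match(vapply(seqs, `[[`, "", "id"), metadata$id)
  for (i in seq_along(seqs)) {
    if (is.na(idx[i])) next
    if ("host" %in% names(metadata)) seqs[[i]]$host <- metadata$host[idx[i]]
    if ("group" %in% names(metadata)) seqs[[i]]$group <- metadata$group[idx[i]]
  }
  seqs
}

#' Tally codon usage of a coding sequence
#'
#' Counts each of the 61 sense codons.  With `exclude_nonbias = TRUE` (the
#' default used by all bias statistics) the single-codon families AUG (Met)
#' and UGG (Trp) are zeroed and excluded from the total, leaving the
#' 59-codon universe; stop codons are never counted.
#'
#' @param x a [coding_sequence()] or a character vector of codons.
#' @param exclude_nonbias logical.
#' @return An object of class `codon_counts` with elements `g` (named count
#'   vector over the 61 sense codons), `n_per_aa` (per-family totals),
#'   `n_total` and `exclude_nonbias`.
#' @examples
#' cc <- count_codons(coding_sequence("x", c("ATG", "GCT", "GCT", "TGG")))
#' cc$n_total  # 2: only the GCT codons are informative
#' @export
count_codons <- function(x, exclude_nonbias = TRUE) {
  codons <- if (inherits(x, "coding_sequence")) x$codons else codon_to_dna(x)
  if (length(codons) == 0L) stop("empty sequence")
  if (!all(codons %in% SENSE_CODONS))
    stop("non-sense codon(s) in input: ",
         paste(unique(setdiff(codons, SENSE_CODONS)), collapse = ", "))
  g <- table(factor(codons, levels = SENSE_CODONS))
  g <- stats::setNames(as.numeric(g), SENSE_CODONS)
  if (exclude_nonbias) g[NONBIAS_CODONS] <- 0
  fam_aa <- AA_OF_CODON[SENSE_CODONS]
  n_per_aa <- tapply(g, fam_aa, sum)
  structure(list(g = g,
                 n_per_aa = stats::setNames(as.numeric(n_per_aa),
                                            names(n_per_aa)),
                 n_total = sum(g),
                 exclude_nonbias = exclude_nonbias),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("<codon_counts> ", x$n_total, " codons",
      if (x$exclude_nonbias) " (AUG/UGG excluded)", "\n", sep = "")
  invisible(x)
}

#' Pool codon counts over several sequences
#'
#' Summing tallies is equivalent to tallying the concatenation.
#'
#' @param counts list of `codon_counts` sharing the same `exclude_nonbias`
#'   setting.
#' @return A pooled `codon_counts`.
#' @export
pool_codon_counts <- function(counts) {
  stopifnot(length(counts) > 0L)
  flags <- vapply(counts, `[[`, logical(1), "exclude_nonbias")
  if (length(unique(flags)) != 1L)
    stop("cannot pool counts with different exclude_nonbias settings")
  g <- Reduce(`+`, lapply(counts, `[[`, "g"))
  fam_aa <- AA_OF_CODON[SENSE_CODONS]
  n_per_aa <- tapply(g, fam_aa, sum)
  structure(list(g = g,
                 n_per_aa = stats::setNames(as.numeric(n_per_aa),
                                            names(n_per_aa)),
                 n_total = sum(g),
                 exclude_nonbias = flags[1L]),
            class = "codon_counts")
}

#' Translate a coding sequence to protein
#'
#' @param x a [coding_sequence()] or character vector of codons (stops not
#'   allowed; the terminal stop is already stripped on input).
#' @return Single amino-acid string.
#' @examples
#' translate_codons(c("ATG", "TTT"))  # "MF"
#' @export
translate_codons <- function(x) {
  codons <- if (inherits(x, "coding_sequence")) x$codons else codon_to_dna(x)
  aa <- AA_OF_CODON[codons]
  if (anyNA(aa)) stop("cannot translate codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  paste(aa, collapse = "")
}
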