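# Host-adaptation statistics: CAI, RCDI and SiD against host reference
# codon-usage tables.

#' Build a host codon-usage table from raw counts
#'
#' Derives, per codon: the per-thousand frequency, the within-family
#' relative frequency, the relative adaptedness w = count / max(count in
#' family), and the host RSCU vector over the 59-codon universe.  If any
#' sense codon has a zero count, a pseudocount of 0.5 is added to every
#' count before normalisation so that log(w) and frequency ratios stay
#' finite (the result is flagged `smoothed`).
#'
#' @param counts named numeric vector covering all 61 sense codons (DNA or
#'   RNA alphabet); stop-codon entries are ignored.  Values may be counts
#'   or per-thousand frequencies (all derived quantities are
#'   scale-invariant).
#' @param name host label.
#' @return Object of class `host_usage_table`: `name`, `counts`, `freq`
#'   (per thousand), `rel_freq` (within-family), `w`, `rscu` (an
#'   `rscu_vector`), `smoothed`.
#' @export
host_usage_table <- function(counts, name = "host") {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  names(counts) <- codon_to_dna(names(counts))
  counts <- counts[names(counts) %in% SENSE_CODONS]
  missing_cod <- setdiff(SENSE_CODONS, names(counts))
  if (length(missing_cod) > 0L)
    stop("host table is missing codon(s): ",
         paste(codon_to_rna(missing_cod), collapse = ", "))
  counts <- counts[SENSE_CODONS]
  if (any(counts < 0)) stop("negative host codon counts")
  if (sum(counts) == 0) stop("all-zero host table")
  smoothed <- any(counts == 0)
  if (smoothed) counts <- counts + 0.5
  freq <- 1000 * counts / sum(counts)
  rel_freq <- w <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    rel_freq[fam] <- counts[fam] / sum(counts[fam])
    w[fam] <- counts[fam] / max(counts[fam])
  }
  g_bias <- counts
  g_bias[NONBIAS_CODONS] <- 0
  n_per_aa <- tapply(g_bias, AA_OF_CODON[SENSE_CODONS], sum)
  host_counts <- structure(
    list(g = g_bias,
         n_per_aa = stats::setNames(as.numeric(n_per_aa), names(n_per_aa)),
         n_total = sum(g_bias), exclude_nonbias = TRUE),
    class = "codon_counts")
  structure(list(name = name, counts = counts, freq = freq,
                 rel_freq = rel_freq, w = w, rscu = rscu(host_counts),
                 smoothed = smoothed),
            class = "host_usage_table")
}

#' @export
print.host_usage_table <- function(x, ...) {
  cat("<host_usage_table> ", x$name,
      if (x$smoothed) " (zero counts smoothed with +0.5)", "\n", sep = "")
  invisible(x)
}

#' Load a host codon-usage table from a file
#'
#' Supports the Kazusa codon-usage-database layout, in which codons appear
#' as `GCU 17.6 ( 12345)` (several per line, RNA alphabet, per-thousand
#' frequency followed by a raw count in parentheses), and a plain
#' two-column TSV of codon and count.  Counts are preferred over
#' per-thousand values when both are present.
#'
#' @param path file path.
#' @param format `"kazusa"` or `"counts_tsv"`.
#' @param name host label (defaults to the file name).
#' @return A [host_usage_table()].
#' @export
load_host_table <- function(path, format = c("kazusa", "counts_tsv"),
                            name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "kazusa") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    m <- gregexpr("([AUCGTaucgt]{3})\\s+([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]+)\\s*\\)",
                  txt, perl = TRUE)
    hits <- regmatches(txt, m)[[1]]
    if (length(hits) == 0L) stop("no Kazusa-style codon entries in ", path)
    parts <- regmatches(hits,
      regexec("([AUCGTaucgt]{3})\\s+([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]+)\\s*\\)",
              hits))
    codons <- vapply(parts, `[`, "", 2L)
    vals <- as.numeric(vapply(parts, `[`, "", 4L))  # raw counts
    counts <- stats::setNames(vals, codon_to_dna(codons))
  } else {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("codon", "count") %in% names(tab)))
      stop("counts_tsv format needs columns 'codon' and 'count'")
    counts <- stats::setNames(as.numeric(tab$count),
                              codon_to_dna(tab$codon))
  }
  host_usage_table(counts, name = name)
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of relative adaptedness w over the counted codons:
#' CAI = exp(sum(g_c log w_c) / sum(g_c)).  Values range over (0, 1]; 1
#' means every codon is the host's family-preferred one.  Met, Trp and
#' stops are excluded (their w is identically 1 and carries no
#' information).
#'
#' @param counts a `codon_counts` with `exclude_nonbias = TRUE`.
#' @param host a `host_usage_table`.
#' @return CAI value in (0, 1].
#' @export
cai <- function(counts, host) {
  stopifnot(inherits(counts, "codon_counts"),
            inherits(host, "host_usage_table"))
  if (!counts$exclude_nonbias)
    stop("cai requires counts with exclude_nonbias = TRUE")
  g <- counts$g[BIAS_CODONS]
  n <- sum(g)
  if (n == 0) stop("no informative codons for CAI")
  w <- host$w[BIAS_CODONS]
  exp(sum(g * log(w)) / n)
}

#' Relative codon deoptimization index (RCDI)
#'
#' Usage-weighted mean ratio of the query's within-family codon frequencies
#' to the host's: RCDI = sum_i (CiFa / ChFh) * N_i / N, where CiFa and
#' ChFh are the within-family relative frequencies of codon i in the query
#' and host, N_i the query count of codon i and N the total counted
#' codons.  RCDI = 1 when the query matches the host's synonymous usage
#' exactly; larger values indicate deoptimization.
#'
#' @inheritParams cai
#' @return RCDI value (>= 1, with equality iff frequencies match).
#' @export
rcdi <- function(counts, host) {
  stopifnot(inherits(counts, "codon_counts"),
            inherits(host, "host_usage_table"))
  if (!counts$exclude_nonbias)
    stop("rcdi requires counts with exclude_nonbias = TRUE")
  if (counts$n_total == 0) stop("no informative codons for RCDI")
  if (host$smoothed)
    warning("host table had zero-count codons; frequencies were smoothed")
  total <- 0
  for (aa in DEGENERATE_AA) {
    fam <- SYN_FAMILIES[[aa]]
    g <- counts$g[fam]
    n_fam <- sum(g)
    if (n_fam == 0) next
    cifa <- g / n_fam
    chfh <- host$rel_freq[fam]
    total <- total + sum((cifa / chfh) * g)
  }
  total / counts$n_total
}

#' Similarity index (SiD) between virus and host codon usage
#'
#' R(A,B) is the cosine similarity between the virus's and the host's
#' 59-dimensional RSCU vectors; SiD transforms it into a distance read as
#' the host's influence on viral codon usage.  The default convention is
#' SiD = (1 - R)/2 (0 for identical usage); `convention =
#' "one-minus-half"` gives the alternative reading SiD = 1 - R/2.
#' Undefined RSCU entries are dropped pairwise.
#'
#' @param virus_rscu an `rscu_vector` for the virus gene (or group mean).
#' @param host a `host_usage_table`.
#' @param convention `"half-diff"` (default) or `"one-minus-half"`.
#' @return List: `r_cos`, `sid`, `convention`, `n_codons` used.
#' @export
sid <- function(virus_rscu, host, convention = c("half-diff", "one-minus-half")) {
  convention <- match.arg(convention)
  stopifnot(inherits(host, "host_usage_table"))
  a <- if (inherits(virus_rscu, "rscu_vector")) virus_rscu$rscu
       else virus_rscu
  b <- host$rscu$rscu
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (sum(a^2) == 0 || sum(b^2) == 0) stop("all-zero RSCU vector")
  r_cos <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sid_val <- if (convention == "half-diff") (1 - r_cos) / 2 else 1 - r_cos / 2
  list(r_cos = r_cos, sid = sid_val, convention = convention,
       n_codons = sum(keep))
}

#' The host-preferred codon of each amino-acid family
#'
#' @param host a `host_usage_table`.
#' @return Named character vector, one codon (DNA alphabet) per amino
#'   acid; ties broken lexicographically.
#' @export
preferred_codons <- function(host) {
  stopifnot(inherits(host, "host_usage_table"))
  vapply(SYN_FAMILIES, function(fam) {
    w <- host$w[fam]
    sort(fam[w == max(w)])[1L]
  }, character(1))
}

#' Per-sequence adaptation table against one or more hosts
#'
#' @param seqs list of [coding_sequence()] records.
#' @param hosts list of `host_usage_table` (or a single one).
#' @param sid_convention passed to [sid()].
#' @return Data frame: id, host (label of the sequence), group,
#'   host_table, cai, rcdi, r_cos, sid.
#' @export
adaptation_table <- function(seqs, hosts,
                             sid_convention = c("half-diff", "one-minus-half")) {
  sid_convention <- match.arg(sid_convention)
  if (inherits(hosts, "host_usage_table")) hosts <- list(hosts)
  if (length(seqs) == 0L) stop("no sequences")
  rows <- list()
  for (s in seqs) {
    cc <- count_codons(s)
    rv <- rscu(cc)
    for (h in hosts) {
      sd_res <- sid(rv, h, convention = sid_convention)
      rows[[length(rows) + 1L]] <- data.frame(
        id = s$id, host = s$host, group = s$group, host_table = h$name,
        cai = cai(cc, h), rcdi = rcdi(cc, h),
        r_cos = sd_res$r_cos, sid = sd_res$sid, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
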