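# Synthetic coding-sequence generator: controllable mutational
# third-position bias, host-directed translational selection, and
# host/group labels.  Used for fixtures, property tests and parameter
# recovery; real analyses read FASTA input instead.

#' Specification for the synthetic CDS generator
#'
#' Codons are generated by a two-route mixture.  At each position an amino
#' acid is drawn from `aa_profile`; with probability `w_sel` the codon is
#' the host table's preferred codon for that amino acid (translational
#' selection), otherwise a synonym is chosen by drawing the third-position
#' nucleotide from the mutational distribution `pi3` (restricted and
#' renormalised to the third positions available in the family) and then
#' uniformly among synonyms sharing that third position (this handles the
#' two codon boxes of the sixfold families).  Optional substitution noise
#' replaces each codon with a uniformly random sense codon at rate
#' `noise_rate`.
#'
#' @param n_sequences number of sequences.
#' @param length_codons codons per sequence (>= 30 for ENC stability).
#' @param pi3 named numeric c(A=,C=,G=,U=), the mutational third-position
#'   distribution; must sum to 1.
#' @param w_sel selection weight in \[0, 1\]; requires `host_table` when
#'   positive.
#' @param host_table a `host_usage_table` supplying preferred codons.
#' @param aa_profile named amino-acid frequencies (default uniform over
#'   the 20 amino acids).
#' @param noise_rate per-codon substitution probability in \[0, 1\].
#' @param seed integer random seed (mandatory; the generator never uses
#'   global random state implicitly).
#' @param host_labels,group_labels label(s) stamped on the output,
#'   recycled over sequences.
#' @param id_prefix sequence id prefix.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_sequences, length_codons,
                           pi3 = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                           w_sel = 0, host_table = NULL, aa_profile = NULL,
                           noise_rate = 0, seed,
                           host_labels = NA_character_,
                           group_labels = NA_character_,
                           id_prefix = "syn") {
  stopifnot(n_sequences >= 1L, length_codons >= 30L,
            w_sel >= 0, w_sel <= 1, noise_rate >= 0, noise_rate <= 1)
  if (missing(seed)) stop("a seed is mandatory")
  if (!setequal(names(pi3), c("A", "C", "G", "U")))
    stop("pi3 must be named A, C, G, U")
  pi3 <- pi3[c("A", "C", "G", "U")]
  if (any(pi3 < 0) || abs(sum(pi3) - 1) > 1e-8)
    stop("pi3 must be a probability distribution")
  if (w_sel > 0 && is.null(host_table))
    stop("w_sel > 0 requires a host_table")
  if (is.null(aa_profile)) {
    aas <- names(SYN_FAMILIES)
    aa_profile <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  }
  unknown <- setdiff(names(aa_profile), names(SYN_FAMILIES))
  if (length(unknown) > 0L)
    stop("unknown amino acid(s) in profile: ", paste(unknown, collapse = ", "))
  if (any(aa_profile < 0) || sum(aa_profile) <= 0)
    stop("invalid amino-acid profile")
  aa_profile <- aa_profile / sum(aa_profile)
  structure(list(n_sequences = as.integer(n_sequences),
                 length_codons = as.integer(length_codons),
                 pi3 = pi3, w_sel = w_sel, host_table = host_table,
                 aa_profile = aa_profile, noise_rate = noise_rate,
                 seed = as.integer(seed), host_labels = host_labels,
                 group_labels = group_labels, id_prefix = id_prefix),
            class = "generator_spec")
}

# Per-family lookup: available third-position bases (DNA alphabet) and the
# synonyms carrying each base.
.family_third_map <- function() {
  lapply(SYN_FAMILIES, function(fam) {
    third <- substr(fam, 3L, 3L)
    split(fam, third)
  })
}
.THIRD_MAP <- .family_third_map()

.draw_codons_for_aa <- function(aa, n, pi3_dna) {
  boxes <- .THIRD_MAP[[aa]]
  avail <- names(boxes)
  p <- pi3_dna[avail]
  p <- p / sum(p)
  tb <- if (length(avail) == 1L) rep(avail, n)
        else sample(avail, n, replace = TRUE, prob = p)
  out <- character(n)
  for (b in unique(tb)) {
    ix <- which(tb == b)
    syn <- boxes[[b]]
    out[ix] <- if (length(syn) == 1L) syn
               else sample(syn, length(ix), replace = TRUE)
  }
  out
}

#' Generate synthetic coding sequences
#'
#' @param spec a [generator_spec()].
#' @return List with `sequences` (list of [coding_sequence()]) and `truth`
#'   (the generating parameters: w_sel, pi3, host table name, seed).
#' @export
generate_cds <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  pi3_dna <- stats::setNames(spec$pi3[c("A", "C", "G", "U")],
                             c("A", "C", "G", "T"))
  pref <- if (!is.null(spec$host_table)) preferred_codons(spec$host_table)
  hosts <- rep_len(spec$host_labels, spec$n_sequences)
  groups <- rep_len(spec$group_labels, spec$n_sequences)
  seqs <- vector("list", spec$n_sequences)
  for (i in seq_len(spec$n_sequences)) {
    len <- spec$length_codons
    aa <- sample(names(spec$aa_profile), len, replace = TRUE,
                 prob = spec$aa_profile)
    codons <- character(len)
    sel <- if (spec$w_sel > 0) stats::runif(len) < spec$w_sel
           else rep(FALSE, len)
    if (any(sel)) codons[sel] <- pref[aa[sel]]
    mut_ix <- which(!sel)
    if (length(mut_ix) > 0L) {
      for (a in unique(aa[mut_ix])) {
        ix <- mut_ix[aa[mut_ix] == a]
        codons[ix] <- .draw_codons_for_aa(a, length(ix), pi3_dna)
      }
    }
    if (spec$noise_rate > 0) {
      hit <- stats::runif(len) < spec$noise_rate
      if (any(hit))
        codons[hit] <- sample(SENSE_CODONS, sum(hit), replace = TRUE)
    }
    id <- sprintf("%s_%03d", spec$id_prefix, i)
    seqs[[i]] <- coding_sequence(id, codons, host = hosts[i],
                                 group = groups[i])
  }
  names(seqs) <- vapply(seqs, `[[`, "", "id")
  truth <- list(w_sel = spec$w_sel, pi3 = spec$pi3,
                host = if (!is.null(spec$host_table)) spec$host_table$name
                       else NA_character_,
                noise_rate = spec$noise_rate, seed = spec$seed,
                n_sequences = spec$n_sequences,
                length_codons = spec$length_codons)
  list(sequences = seqs, truth = truth)
}

.write_fixture <- function(seqs, dir, stem) {
  fasta <- file.path(dir, paste0(stem, ".fasta"))
  meta <- file.path(dir, paste0(stem, "_metadata.tsv"))
  lines <- unlist(lapply(seqs, function(s) {
    nt <- paste(s$codons, collapse = "")
    c(paste0(">", s$id),
      substring(nt, seq(1L, nchar(nt), by = 60L),
                pmin(seq(60L, nchar(nt) + 59L, by = 60L), nchar(nt))))
  }), use.names = FALSE)
  writeLines(lines, fasta)
  md <- data.frame(id = vapply(seqs, `[[`, "", "id"),
                   host = vapply(seqs, function(s) as.character(s$host), ""),
                   group = vapply(seqs, function(s) as.character(s$group), ""),
                   stringsAsFactors = FALSE)
  utils::write.table(md, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  c(fasta = fasta, metadata = meta)
}

#' GC-rich (coat-protein-like) fixture
#'
#' Thirty 300-codon sequences generated under a GC-rich mutational
#' third-position distribution, targeting a mean total GC content around
#' 53% with host labels pepino/potato/tomato and groups GP1/GP2.
#'
#' @param dir output directory.
#' @param seed random seed (default 101).
#' @return Named character vector with the `fasta` and `metadata` paths.
#' @export
cp_like_fixture <- function(dir, seed = 101L) {
  spec <- generator_spec(
    n_sequences = 30L, length_codons = 300L,
    pi3 = c(A = 0.11, C = 0.30, G = 0.44, U = 0.15),
    w_sel = 0, seed = seed,
    host_labels = rep(c("pepino", "potato", "tomato"), each = 10L),
    group_labels = rep(c("GP1", "GP2"), length.out = 30L),
    id_prefix = "cp")
  gen <- generate_cds(spec)
  .write_fixture(gen$sequences, dir, "cp_like")
}

#' AU-rich (nucleic-acid-binding-protein-like) fixture
#'
#' Thirty 300-codon sequences generated under an AU-rich mutational
#' third-position distribution, targeting a mean total AU content around
#' 54%.
#'
#' @inheritParams cp_like_fixture
#' @export
nabp_like_fixture <- function(dir, seed = 202L) {
  spec <- generator_spec(
    n_sequences = 30L, length_codons = 300L,
    pi3 = c(A = 0.26, C = 0.20, G = 0.24, U = 0.30),
    w_sel = 0, seed = seed,
    host_labels = rep(c("pepino", "potato", "tomato"), each = 10L),
    group_labels = rep(c("GP1", "GP2"), length.out = 30L),
    id_prefix = "nabp")
  gen <- generate_cds(spec)
  .write_fixture(gen$sequences, dir, "nabp_like")
}

#' Pure-mutation gene series for neutrality analysis
#'
#' Generates one gene per mutational GC level drawn uniformly from
#' `gc3_range`, with zero selection weight.  The neutrality plot's null
#' model assumes directional mutation pressure acts on all three codon
#' positions; with a fixed amino-acid profile, positions 1-2 could not
#' respond and the GC12-on-GC3 slope would be attenuated by construction.
#' Here every codon is therefore drawn from the full mutational model:
#' codon probability proportional to the product of its three
#' per-position nucleotide probabilities, restricted to the 61 sense
#' codons.  The amino-acid composition then covaries with the mutational
#' distribution, GC12 tracks the mutational GC level, and the fitted
#' slope estimates the mutational share, approaching 1 under pure
#' mutation (a small residual attenuation, about 0.97 analytically,
#' comes from excluding the stop codons).
#'
#' @param n_genes number of genes.
#' @param length_codons codons per gene.
#' @param gc3_range range of mutational GC levels (fractions).
#' @param seed integer random seed.
#' @return List with `sequences` and `gc_levels` (the true mutational GC
#'   per gene).
#' @export
neutrality_series <- function(n_genes, length_codons = 2000L,
                              gc3_range = c(0.25, 0.75), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(as.integer(seed))
  gc_levels <- stats::runif(n_genes, gc3_range[1L], gc3_range[2L])
  gene_seeds <- sample.int(.Machine$integer.max, n_genes)
  seqs <- vector("list", n_genes)
  codon_nt <- strsplit(SENSE_CODONS, "")
  for (i in seq_len(n_genes)) {
    g <- gc_levels[i]
    p_nt <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
    w <- vapply(codon_nt, function(chs) prod(p_nt[chs]), numeric(1))
    set.seed(gene_seeds[i])
    codons <- sample(SENSE_CODONS, length_codons, replace = TRUE,
                     prob = w / sum(w))
    seqs[[i]] <- coding_sequence(sprintf("neut_%03d", i), codons)
  }
  names(seqs) <- vapply(seqs, `[[`, "", "id")
  list(sequences = seqs, gc_levels = gc_levels)
}
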