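# One-command pipeline: runs every analysis stage on a FASTA + metadata +
# host tables and writes plot-ready TSVs.

.fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

# Write a TSV with numeric columns printed at `digits` decimals plus a
# full-precision `<col>_raw` companion column.
.write_table <- function(df, path, digits = 4L, raw_columns = TRUE) {
  out <- df
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  for (v in num) {
    out[[v]] <- .fmt_num(df[[v]], digits)
    if (raw_columns) out[[paste0(v, "_raw")]] <- sprintf("%.17g", df[[v]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full codon-usage analysis pipeline
#'
#' Reads coding sequences (with optional metadata) and host codon-usage
#' tables, runs every analysis stage — composition and protein indices,
#' RSCU with group means, ENC and the ENC-GC3s plot table, PR2, neutrality
#' regressions (overall and per host), CAI/RCDI/SiD against each host
#' table, PCA of RSCU vectors, and the Spearman correlation matrix — and
#' writes one TSV per stage plus a manifest and run log.  Numeric columns
#' are printed at 4 decimals with a full-precision `_raw` companion
#' column.  Outputs are deterministic for a fixed config and seed.
#'
#' @param fasta path to a CDS FASTA file.
#' @param metadata optional path to a TSV with columns id, host, group.
#' @param host_tables named character vector of host-table paths, or a
#'   list of `host_usage_table` objects.
#' @param out_dir output directory (created if absent).
#' @param host_format format of host-table files, see [load_host_table()].
#' @param group_by metadata column used for grouped summaries ("host" or
#'   "group").
#' @param rscu_over,rscu_under RSCU classification thresholds.
#' @param enc_bias_threshold ENC at or below which a gene is called
#'   significantly biased.
#' @param pr2_mode passed to [pr2_point()].
#' @param sid_convention passed to [sid()].
#' @param rscu_mode passed to [mean_rscu()].
#' @param ambiguity,on_invalid passed to [read_cds_fasta()].
#' @param seed integer; recorded in the log and set before any stage that
#'   could resample (the standard stages are deterministic).
#' @param digits printed decimals.
#' @param raw_columns write full-precision companion columns.
#' @return Invisibly, a manifest data frame (file, stage, rows).
#' @export
run_codon_pipeline <- function(fasta, metadata = NULL, host_tables = NULL,
                               out_dir,
                               host_format = c("kazusa", "counts_tsv"),
                               group_by = "host",
                               rscu_over = 1.6, rscu_under = 0.6,
                               enc_bias_threshold = 35,
                               pr2_mode = c("strict4", "include6fold"),
                               sid_convention = c("half-diff",
                                                  "one-minus-half"),
                               rscu_mode = c("sequences", "pooled"),
                               ambiguity = c("drop", "reject"),
                               on_invalid = c("skip", "abort"),
                               seed = NULL, digits = 4L,
                               raw_columns = TRUE) {
  host_format <- match.arg(host_format)
  pr2_mode <- match.arg(pr2_mode)
  sid_convention <- match.arg(sid_convention)
  rscu_mode <- match.arg(rscu_mode)
  ambiguity <- match.arg(ambiguity)
  on_invalid <- match.arg(on_invalid)
  stopifnot(rscu_over > 0, rscu_under > 0, enc_bias_threshold > 0)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  manifest <- data.frame(file = character(0), stage = character(0),
                         rows = integer(0), stringsAsFactors = FALSE)
  emit <- function(df, name, stage) {
    path <- file.path(out_dir, name)
    .write_table(df, path, digits = digits, raw_columns = raw_columns)
    manifest <<- rbind(manifest,
                       data.frame(file = name, stage = stage,
                                  rows = nrow(df), stringsAsFactors = FALSE))
  }
  stage <- "load"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  md <- if (!is.null(metadata)) {
    if (is.character(metadata)) read_metadata(metadata) else metadata
  }
  seqs <- run_stage("read_fasta",
    read_cds_fasta(fasta, ambiguity = ambiguity, on_invalid = on_invalid,
                   metadata = md))
  hosts <- run_stage("load_host_table", {
    if (is.null(host_tables)) list()
    else if (is.list(host_tables)) host_tables
    else lapply(seq_along(host_tables), function(i)
      load_host_table(host_tables[i], format = host_format,
                      name = names(host_tables)[i]))
  })

  comp <- run_stage("composition", composition_table(seqs))
  emit(comp, "composition.tsv", "composition")

  run_stage("rscu", {
    by <- as.character(comp[[group_by]])
    by[is.na(by) | by == ""] <- "unlabelled"
    rv <- lapply(seqs, function(s)
      rscu(count_codons(s), over = rscu_over, under = rscu_under))
    groups <- split(rv, by)
    emit(rscu_table(groups, mode = rscu_mode), "rscu_table1.tsv", "rscu")
  })

  ep <- run_stage("enc", enc_plot_table(seqs))
  run_stage("enc", {
    ep$biased <- ep$enc <= enc_bias_threshold
    enc_tab <- ep[, c("id", "host", "group", "enc", "gc3s", "biased")]
    emit(enc_tab, "enc.tsv", "enc")
    emit(ep, "enc_plot.tsv", "enc")
  })

  run_stage("pr2", emit(pr2_table(seqs, mode = pr2_mode), "pr2.tsv", "pr2"))

  run_stage("neutrality",
    emit(neutrality_by_group(comp, by = group_by), "neutrality.tsv",
         "neutrality"))

  if (length(hosts) > 0L) {
    adapt <- run_stage("adaptation",
      adaptation_table(seqs, hosts, sid_convention = sid_convention))
    emit(adapt[, c("id", "host", "group", "host_table", "cai", "rcdi")],
         "cai_rcdi.tsv", "adaptation")
    emit(adapt[, c("id", "host", "group", "host_table", "r_cos", "sid")],
         "sid.tsv", "adaptation")
  }

  pca <- run_stage("pca", pca_score_table(seqs, n_axes = 2L))
  emit(pca$inertia, "pca_inertia.tsv", "pca")
  emit(pca$scores, "pca_scores.tsv", "pca")

  run_stage("correlations", {
    tab <- comp
    tab$enc <- ep$enc[match(tab$id, ep$id)]
    if (!pca$pca$degenerate) {
      tab$axis1 <- pca$scores$axis1[match(tab$id, pca$scores$id)]
      tab$axis2 <- if ("axis2" %in% names(pca$scores))
        pca$scores$axis2[match(tab$id, pca$scores$id)] else NA_real_
    } else {
      tab$axis1 <- tab$axis2 <- NA_real_
    }
    emit(correlation_matrix(tab), "correlations_table2.tsv", "correlations")
  })

  log_lines <- c(
    paste0("codonbias version: ",
           as.character(utils::packageVersion("codonbias"))),
    paste0("R version: ", R.version.string),
    paste0("fasta: ", fasta),
    paste0("metadata: ", if (is.null(metadata)) "none" else "provided"),
    paste0("host_tables: ",
           if (length(hosts) == 0L) "none"
           else paste(vapply(hosts, `[[`, "", "name"), collapse = ", ")),
    paste0("group_by: ", group_by),
    paste0("rscu_thresholds: over=", rscu_over, " under=", rscu_under),
    paste0("enc_bias_threshold: ", enc_bias_threshold),
    paste0("pr2_mode: ", pr2_mode),
    paste0("sid_convention: ", sid_convention),
    paste0("rscu_mode: ", rscu_mode),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    paste0("sequences: ", length(seqs))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
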