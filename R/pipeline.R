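#' Pipeline run configuration
#'
#' Thresholds and seeds for a full pipeline run. All thresholds are applied as
#' strict inequalities. The configuration round-trips through YAML unchanged
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param fdr FDR threshold for deregulation and switch significance
#'   (default 0.05).
#' @param dif absolute differential-isoform-fraction threshold (default 0.10).
#' @param ridd_prob stem-loop probability threshold for RIDD sites
#'   (default 0.9).
#' @param pwm_p exact p-value threshold for promoter PWM hits (default 5e-4).
#' @param phi per-gene |phi| reporting threshold (default 0.5).
#' @param protein_p protein-level significance threshold on the raw p-value
#'   (default 0.05).
#' @param quantiles number of quantile bins for the IRE1 score (default 4).
#' @param n_perm label permutations for the switch test (default 10000).
#' @param n_sim Monte-Carlo draws for the chi-squared null (default 1e5).
#' @param seed master seed; stage seeds are derived from it by fixed offsets.
#' @param synthetic named list of [cohort_config()] overrides for synthetic
#'   runs.
#' @return a `run_config` list.
#' @export
run_config <- function(fdr = 0.05, dif = 0.10, ridd_prob = 0.9, pwm_p = 5e-4,
                       phi = 0.5, protein_p = 0.05, quantiles = 4L,
                       n_perm = 10000L, n_sim = 1e5L, seed = 1L,
                       synthetic = list()) {
  stopifnot(fdr > 0, fdr < 1, dif >= 0, dif < 1, ridd_prob >= 0,
            pwm_p > 0, pwm_p < 1, phi >= 0, phi <= 1,
            protein_p > 0, protein_p < 1, quantiles >= 2)
  structure(list(fdr = fdr, dif = dif, ridd_prob = ridd_prob, pwm_p = pwm_p,
                 phi = phi, protein_p = protein_p,
                 quantiles = as.integer(quantiles),
                 n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
                 seed = as.integer(seed), synthetic = synthetic),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full IRE1/RIDD analysis pipeline
#'
#' Executes the stages in dependency order: RIDD site scanning, isoform
#' fractions and switch testing, consequence classification and event
#' fractions, transcript- and protein-level differential expression, IRE1
#' activity scoring with categorical association to condition, per-gene and
#' global splice-event × RIDD associations, promoter PWM scanning, shared
#' RIDD/XBP1s targets, and the cross-omics overlap. Progress is logged to
#' `stderr`; results go to the returned report (and to files when `outdir` is
#' given).
#'
#' @param cohort a cohort as returned by [make_cohort()], or an equivalent
#'   list built from real data (`models`, `sequences`, `expr`, `proteome`,
#'   `promoters`, `pwm`, optionally `truth` and `panel`).
#' @param cfg a [run_config()].
#' @param outdir optional output directory; when given, stage TSVs and
#'   `report.json` are written with a seed/threshold provenance header.
#' @return the report: a named list aggregating every stage's results.
#' @export
run_pipeline <- function(cohort, cfg = run_config(), outdir = NULL) {
  log_msg <- function(...) message("[ire1ridd] ", ...)

  log_msg("scanning ", length(cohort$models), " transcripts for RIDD sites")
  sp <- scan_params(prob_threshold = cfg$ridd_prob)
  sites <- scan_transcriptome(cohort$models, sp)
  direc <- differential_recognizability(sites, cohort$models)

  log_msg("testing isoform switches")
  ifs <- isoform_fractions(cohort$expr, cohort$models)
  records <- test_switches(ifs, n_perm = cfg$n_perm,
                           seed = child_seed(cfg$seed, 11L),
                           fdr_threshold = cfg$fdr, dif_threshold = cfg$dif,
                           expr = cohort$expr)
  calls <- call_consequences(records, cohort$models)
  fractions <- if (nrow(calls)) event_fractions(calls) else NULL

  log_msg("differential expression (transcript and protein level)")
  tx_stats <- diff_expression(cohort$expr)
  tx_stats$gene_id <- unname(
    vapply(cohort$models, function(m) m$gene_id, "")[tx_stats$feature_id])
  prot_stats <- diff_expression(cohort$proteome)
  prot_stats$gene_id <- prot_stats$feature_id

  log_msg("IRE1 activity scoring")
  ire1 <- NULL
  if (!is.null(cohort$panel)) {
    scores <- categorize(score_samples(cohort$expr, cohort$panel,
                                       Q = cfg$quantiles))
    assoc <- association_test(scores$category, scores$condition,
                              n_sim = cfg$n_sim,
                              seed = child_seed(cfg$seed, 12L))
    ire1 <- list(scores = scores, chi2 = assoc$chi2, df = assoc$df,
                 p = assoc$p, cramers_v = assoc$cramers_v,
                 monte_carlo = assoc$monte_carlo)
  }

  log_msg("splice-event x RIDD associations")
  flags <- isoform_flags(cohort$models, sites, records)
  candidates <- ridd_candidates(flags, fdr_threshold = cfg$fdr)
  events <- c("A3_gain", "A5_gain", "domain_loss", "transcript_noncoding")
  per_gene <- do.call(rbind, lapply(events, function(e) {
    per_gene_correlation(flags, e, phi_threshold = cfg$phi)
  }))
  global <- lapply(stats::setNames(events, events), function(e) {
    ga <- global_association(flags, e, n_sim = cfg$n_sim,
                             seed = child_seed(cfg$seed, 13L))
    ga[c("chi2", "df", "p", "cramers_v", "mi_bits")]
  })

  log_msg("promoter PWM scan")
  hits <- scan_promoters(cohort$pwm, cohort$promoters, threshold_p = cfg$pwm_p)
  xbp1_genes <- sort(unique(hits$promoter_id))
  ridd_genes <- sort(unique(sites$gene_id))
  shared <- shared_targets(ridd_genes, xbp1_genes, tx_stats, prot_stats)
  overlap <- cross_omics_overlap(tx_stats, prot_stats, calls,
                                 ridd_genes, xbp1_genes)

  report <- list(
    config = unclass(cfg),
    n_transcripts = length(cohort$models),
    sites = sites, differential_recognizability = direc,
    switches = records, consequences = calls, event_fractions = fractions,
    tx_stats = tx_stats, prot_stats = prot_stats,
    ire1 = ire1,
    ridd_candidates = candidates, per_gene_assoc = per_gene,
    global_assoc = global,
    pwm_hits = hits, shared_targets = shared,
    overlap_counts = overlap$counts)
  if (!is.null(outdir)) write_report(report, cohort, outdir)
  report
}

#' Run the pipeline on a freshly generated synthetic cohort
#'
#' @param cfg a [run_config()]; `cfg$synthetic` entries override
#'   [cohort_config()] defaults, and the cohort seed is derived from
#'   `cfg$seed`.
#' @param outdir optional output directory.
#' @return list with `report` and the generated `cohort`.
#' @export
run_synthetic <- function(cfg = run_config(), outdir = NULL) {
  ccfg <- do.call(cohort_config,
                  utils::modifyList(list(seed = child_seed(cfg$seed, 1L)),
                                    cfg$synthetic))
  cohort <- make_cohort(ccfg)
  list(report = run_pipeline(cohort, cfg, outdir = outdir), cohort = cohort)
}

write_report <- function(report, cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# ire1ridd seed=%d fdr=%g dif=%g ridd_prob=%g pwm_p=%g phi=%g",
                    report$config$seed, report$config$fdr, report$config$dif,
                    report$config$ridd_prob, report$config$pwm_p,
                    report$config$phi)
  dump <- function(df, name) {
    path <- file.path(outdir, name)
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  dump(report$sites, "sites.tsv")
  dump(report$switches, "switches.tsv")
  dump(report$consequences, "consequences.tsv")
  if (!is.null(report$event_fractions)) {
    dump(report$event_fractions, "event_fractions.tsv")
  }
  if (!is.null(report$ire1)) dump(report$ire1$scores, "ire1_scores.tsv")
  dump(report$per_gene_assoc, "per_gene_assoc.tsv")
  dump(report$pwm_hits, "pwm_hits.tsv")
  jsonlite::write_json(report_summary(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Machine-readable summary of a pipeline report
#'
#' Flattens the report into plain lists/vectors suitable for JSON
#' serialization (used for the on-disk `report.json` and the determinism
#' check).
#'
#' @param report output of [run_pipeline()].
#' @return a nested list of plain values.
#' @export
report_summary <- function(report) {
  list(
    config = report$config,
    n_transcripts = report$n_transcripts,
    n_sites = nrow(report$sites),
    sites = report$sites,
    n_significant_switches = sum(report$switches$significant, na.rm = TRUE),
    event_fractions = report$event_fractions,
    ire1 = if (is.null(report$ire1)) NULL else list(
      scores = report$ire1$scores, chi2 = report$ire1$chi2,
      df = report$ire1$df, p = report$ire1$p,
      cramers_v = report$ire1$cramers_v,
      monte_carlo = report$ire1$monte_carlo),
    ridd_candidates = report$ridd_candidates$transcript_id,
    per_gene_assoc = report$per_gene_assoc,
    global_assoc = report$global_assoc,
    n_pwm_hits = nrow(report$pwm_hits),
    xbp1_genes = sort(unique(report$pwm_hits$promoter_id)),
    shared_targets = report$shared_targets,
    overlap_counts = report$overlap_counts)
}
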