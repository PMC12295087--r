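#' Per-sample isoform fractions
#'
#' `IF(t, sample) = TPM(t) / sum over the gene's isoforms`. Samples where a
#' gene's total is zero get `NA` for all of that gene's isoforms (the sample is
#' excluded for that gene).
#'
#' @param expr transcript-level [expression_matrix()].
#' @param tx2gene named character vector mapping transcript id → gene id, or a
#'   list of [transcript_model()]s. Every matrix feature must be mapped.
#' @return list with `IF` (matrix, same dim as `expr$values`), `tx2gene`,
#'   `condition`, `batch`.
#' @export
isoform_fractions <- function(expr, tx2gene) {
  if (is.list(tx2gene) && !is.null(tx2gene[[1]]$gene_id)) {
    tx2gene <- vapply(tx2gene, function(m) m$gene_id, "",
                      USE.NAMES = FALSE) |>
      stats::setNames(vapply(tx2gene, function(m) m$transcript_id, ""))
  }
  tx <- rownames(expr$values)
  if (!all(tx %in% names(tx2gene))) {
    stop("transcripts without gene mapping: ",
         paste(utils::head(setdiff(tx, names(tx2gene)), 5), collapse = ", "))
  }
  genes <- tx2gene[tx]
  totals <- rowsum(expr$values, genes)        # genes x samples
  denom <- totals[genes, , drop = FALSE]
  IF <- expr$values / denom
  IF[denom == 0] <- NA_real_
  list(IF = IF, tx2gene = genes, condition = expr$condition, batch = expr$batch)
}

#' Test isoform switches between conditions
#'
#' For each isoform, `dIF = mean IF(disease) - mean IF(control)` (over samples
#' where the IF is defined). Significance comes from a two-sided permutation
#' test on the difference of mean IF (condition labels permuted within batch
#' when batch labels exist), or from a linear model on arcsine-square-root
#' transformed IF with a batch covariate (`method = "lm"`). P-values are
#' BH-adjusted across all isoforms; an isoform switches significantly iff
#' `fdr < 0.05` and `|dIF| > 0.10` (both strict).
#'
#' @param ifs result of [isoform_fractions()].
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param method `"permutation"` (default) or `"lm"`.
#' @param fdr_threshold,dif_threshold significance thresholds (strict).
#' @param expr optional transcript [expression_matrix()]; when given,
#'   isoform- and gene-level log2 fold changes (pseudocount 1) are attached.
#' @return data.frame of switch records: `gene_id`, `transcript_id`,
#'   `IF_control`, `IF_disease`, `dIF`, `p_value`, `fdr`, `significant`, and
#'   (with `expr`) `iso_log2fc`, `gene_log2fc`.
#' @export
test_switches <- function(ifs, n_perm = 10000L, seed = 1L,
                          method = c("permutation", "lm"),
                          fdr_threshold = 0.05, dif_threshold = 0.10,
                          expr = NULL) {
  method <- match.arg(method)
  IF <- ifs$IF
  cond <- ifs$condition
  if (any(table(cond) < 2L)) stop("need >= 2 samples per condition")
  is_d <- cond == levels(cond)[2]
  dIF <- apply(IF, 1, function(v) {
    mean(v[is_d], na.rm = TRUE) - mean(v[!is_d], na.rm = TRUE)
  })
  pv <- switch(method,
    permutation = perm_pvalues(IF, is_d, ifs$batch, n_perm, seed),
    lm = lm_pvalues(IF, cond, ifs$batch))
  fdr <- stats::p.adjust(pv, method = "BH")
  rec <- data.frame(
    gene_id = unname(ifs$tx2gene), transcript_id = rownames(IF),
    IF_control = rowMeans(IF[, !is_d, drop = FALSE], na.rm = TRUE),
    IF_disease = rowMeans(IF[, is_d, drop = FALSE], na.rm = TRUE),
    dIF = dIF, p_value = pv, fdr = fdr,
    significant = fdr < fdr_threshold & abs(dIF) > dif_threshold,
    row.names = NULL)
  if (!is.null(expr)) {
    pm <- function(m) log2((rowMeans(m[, is_d, drop = FALSE]) + 1) /
                           (rowMeans(m[, !is_d, drop = FALSE]) + 1))
    rec$iso_log2fc <- unname(pm(expr$values)[rec$transcript_id])
    gl <- pm(rowsum(expr$values, ifs$tx2gene))
    rec$gene_log2fc <- unname(gl[rec$gene_id])
  }
  rec
}

## two-sided permutation p-values on difference of mean IF, all isoforms at
## once via one matrix multiply; isoforms with NAs fall back to a loop
perm_pvalues <- function(IF, is_d, batch, n_perm, seed) {
  n <- ncol(IF)
  contrast <- function(d) d / sum(d) - (!d) / sum(!d)
  perm_labels <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      if (is.null(batch)) {
        sample(is_d)
      } else {
        out <- logical(n)
        for (b in levels(batch)) {
          ix <- which(batch == b)
          out[ix] <- sample(is_d[ix])
        }
        out
      }
    }, logical(n))
  })
  U <- apply(perm_labels, 2, contrast)              # n x n_perm
  obs_u <- contrast(is_d)
  has_na <- rowSums(is.na(IF)) > 0
  pv <- numeric(nrow(IF))
  if (any(!has_na)) {
    M <- IF[!has_na, , drop = FALSE]
    obs <- as.numeric(M %*% obs_u)
    stats_mat <- M %*% U                            # features x n_perm
    pv[!has_na] <- (1 + rowSums(abs(stats_mat) >= abs(obs) - 1e-12)) / (n_perm + 1)
    ## a constant isoform has obs = 0 and every permutation stat = 0 -> p = 1
  }
  if (any(has_na)) {
    for (i in which(has_na)) {
      v <- IF[i, ]
      ok <- !is.na(v)
      if (sum(ok & is_d) < 1 || sum(ok & !is_d) < 1) { pv[i] <- NA_real_; next }
      cstat <- function(d) mean(v[ok & d]) - mean(v[ok & !d])
      obs <- cstat(is_d)
      ps <- apply(perm_labels, 2, cstat)
      pv[i] <- (1 + sum(abs(ps) >= abs(obs) - 1e-12)) / (n_perm + 1)
    }
  }
  pv
}

lm_pvalues <- function(IF, cond, batch) {
  apply(IF, 1, function(v) {
    ok <- !is.na(v)
    if (length(unique(v[ok])) == 1L) return(1)
    y <- asin(sqrt(pmin(pmax(v[ok], 0), 1)))
    df <- data.frame(y = y, condition = cond[ok])
    form <- y ~ condition
    if (!is.null(batch) && nlevels(droplevels(batch[ok])) > 1L) {
      df$batch <- droplevels(batch[ok])
      form <- y ~ condition + batch
    }
    fit <- stats::lm(form, data = df)
    co <- summary(fit)$coefficients
    row <- grep("^condition", rownames(co))
    if (!length(row)) 1 else co[row[1], "Pr(>|t|)"]
  })
}

#' Classify the consequence of one gene's isoform switch
#'
#' Compares the most-upregulated against the most-downregulated isoform:
#' `A3_gain`/`A3_loss` when the up-isoform's 3'UTR is longer/shorter,
#' `A5_gain`/`A5_loss` for the 5'UTR, `domain_loss`/`domain_gain` when one
#' isoform's domain set strictly contains the other's, and
#' `transcript_noncoding`/`transcript_coding` for a biotype change. Several
#' events may co-occur; `none` when no event applies. UTR events require both
#' isoforms to be coding (UTRs are undefined otherwise).
#'
#' @param rec_up,rec_down switch records (rows of [test_switches()] output)
#'   for the same gene with `rec_up$dIF > 0 > rec_down$dIF`.
#' @param models named list of [transcript_model()]s.
#' @return data.frame: `gene_id`, `up_isoform`, `down_isoform`, `events`
#'   (comma-joined).
#' @export
classify_consequences <- function(rec_up, rec_down, models) {
  if (rec_up$transcript_id == rec_down$transcript_id) {
    stop("up and down records refer to the same isoform")
  }
  if (rec_up$gene_id != rec_down$gene_id) stop("records from different genes")
  if (!(rec_up$dIF > 0 && rec_down$dIF < 0)) {
    stop("expected rec_up$dIF > 0 > rec_down$dIF")
  }
  up <- models[[rec_up$transcript_id]]
  dn <- models[[rec_down$transcript_id]]
  ev <- character()
  if (up$biotype == "coding" && dn$biotype == "coding") {
    uu <- utr_lengths(up); ud <- utr_lengths(dn)
    if (uu["utr3"] > ud["utr3"]) ev <- c(ev, "A3_gain")
    if (uu["utr3"] < ud["utr3"]) ev <- c(ev, "A3_loss")
    if (uu["utr5"] > ud["utr5"]) ev <- c(ev, "A5_gain")
    if (uu["utr5"] < ud["utr5"]) ev <- c(ev, "A5_loss")
  }
  dup <- unique(up$domains$domain); ddn <- unique(dn$domains$domain)
  if (all(dup %in% ddn) && length(ddn) > length(dup)) ev <- c(ev, "domain_loss")
  if (all(ddn %in% dup) && length(dup) > length(ddn)) ev <- c(ev, "domain_gain")
  if (up$biotype == "non_coding" && dn$biotype == "coding") {
    ev <- c(ev, "transcript_noncoding")
  }
  if (up$biotype == "coding" && dn$biotype == "non_coding") {
    ev <- c(ev, "transcript_coding")
  }
  if (!length(ev)) ev <- "none"
  data.frame(gene_id = rec_up$gene_id, up_isoform = rec_up$transcript_id,
             down_isoform = rec_down$transcript_id,
             events = paste(ev, collapse = ","))
}

#' Consequence calls for all switching genes
#'
#' For each gene with at least one significantly up- and one significantly
#' down-switching isoform, pairs the most-increased with the most-decreased
#' isoform and classifies the consequence.
#'
#' @param records output of [test_switches()].
#' @param models named list of [transcript_model()]s.
#' @return data.frame of [classify_consequences()] rows (possibly empty).
#' @export
call_consequences <- function(records, models) {
  sig <- records[records$significant, , drop = FALSE]
  out <- list()
  for (g in unique(sig$gene_id)) {
    sub <- sig[sig$gene_id == g, , drop = FALSE]
    ups <- sub[sub$dIF > 0, , drop = FALSE]
    dns <- sub[sub$dIF < 0, , drop = FALSE]
    if (!nrow(ups) || !nrow(dns)) next
    out[[g]] <- classify_consequences(ups[which.max(ups$dIF), ],
                                      dns[which.min(dns$dIF), ], models)
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), up_isoform = character(),
                      down_isoform = character(), events = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of switching genes per consequence event, with 95% CIs
#'
#' @param calls output of [call_consequences()].
#' @param n_switch_genes denominator: number of genes with a significant
#'   switch (default `nrow(calls)`).
#' @param events event types to tabulate.
#' @return data.frame: `event`, `n`, `fraction`, `ci_lower`, `ci_upper`
#'   (Wilson score interval at 95%).
#' @export
event_fractions <- function(calls, n_switch_genes = nrow(calls),
                            events = c("A3_gain", "A5_gain", "domain_loss",
                                       "transcript_noncoding")) {
  stopifnot(n_switch_genes >= 1)
  evlist <- strsplit(calls$events, ",", fixed = TRUE)
  do.call(rbind, lapply(events, function(e) {
    x <- sum(vapply(evlist, function(v) e %in% v, logical(1)))
    ci <- wilson_ci(x, n_switch_genes)
    data.frame(event = e, n = x, fraction = ci[["estimate"]],
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
  }))
}

#' Differential expression between conditions
#'
#' Minimal two-condition pipeline: drop features that are zero in more than
#' half the samples, transform `log2(x + 1)`, median-centre each sample,
#' remove per-batch feature means (batch centring preserves within-batch
#' condition contrasts), then a Welch two-sample t-test per feature with BH
#' adjustment. `log2fc` is the mean difference (disease − control) of the
#' transformed values. Features with fewer than two usable samples per group
#' are skipped (recorded in `note`).
#'
#' @param expr an [expression_matrix()] (gene, transcript or protein level).
#' @return data.frame of feature statistics: `feature_id`, `log2fc`,
#'   `p_value`, `fdr`, `note`.
#' @export
diff_expression <- function(expr) {
  vals <- expr$values
  keep <- rowMeans(vals == 0) <= 0.5
  vals <- vals[keep, , drop = FALSE]
  lv <- log2(vals + 1)
  lv <- sweep(lv, 2, apply(lv, 2, stats::median))
  if (!is.null(expr$batch) && nlevels(expr$batch) > 1L) {
    for (b in levels(expr$batch)) {
      ix <- expr$batch == b
      lv[, ix] <- lv[, ix] - rowMeans(lv[, ix, drop = FALSE])
    }
  }
  is_d <- expr$condition == levels(expr$condition)[2]
  res <- apply(lv, 1, function(v) {
    a <- v[is_d]; b <- v[!is_d]
    if (sum(!is.na(a)) < 2 || sum(!is.na(b)) < 2) {
      return(c(NA_real_, NA_real_))
    }
    fc <- mean(a) - mean(b)
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (fc == 0) 1 else 0
    } else {
      stats::t.test(a, b)$p.value
    }
    c(fc, p)
  })
  out <- data.frame(feature_id = rownames(lv), log2fc = res[1, ],
                    p_value = res[2, ],
                    fdr = stats::p.adjust(res[2, ], method = "BH"),
                    note = ifelse(is.na(res[2, ]), "insufficient samples", ""),
                    row.names = NULL)
  out
}

#' Cross-omics feature overlap
#'
#' Per-gene binary flags across analysis tracks (deregulated transcript,
#' deregulated protein, consequence events, RIDD recognizability, XBP1s
#' promoter hit) plus the Venn-style counts of every flag combination.
#'
#' @param tx_stats transcript/gene [diff_expression()] output with a `gene_id`
#'   column (`fdr < 0.05` defines `deg_tx`).
#' @param prot_stats protein [diff_expression()] output keyed by gene
#'   (`p_value < 0.05` defines `deg_prot`, matching the protein-level rule).
#' @param calls [call_consequences()] output.
#' @param ridd_genes character vector of RIDD-recognizable genes.
#' @param xbp1_genes character vector of genes with an XBP1s promoter hit.
#' @return list with `flags` (one row per gene) and `counts` (per flag-set
#'   combination).
#' @export
cross_omics_overlap <- function(tx_stats, prot_stats, calls,
                                ridd_genes = character(),
                                xbp1_genes = character()) {
  if (!"gene_id" %in% names(tx_stats)) tx_stats$gene_id <- tx_stats$feature_id
  if (!"gene_id" %in% names(prot_stats)) prot_stats$gene_id <- prot_stats$feature_id
  genes <- sort(unique(c(tx_stats$gene_id, prot_stats$gene_id, calls$gene_id,
                         ridd_genes, xbp1_genes)))
  evlist <- strsplit(calls$events, ",", fixed = TRUE)
  has_event <- function(g, e) {
    ix <- which(calls$gene_id == g)
    length(ix) > 0 && any(vapply(evlist[ix], function(v) e %in% v, logical(1)))
  }
  flags <- data.frame(
    gene_id = genes,
    deg_tx = vapply(genes, function(g) {
      any(tx_stats$gene_id == g & tx_stats$fdr < 0.05, na.rm = TRUE)
    }, logical(1)),
    deg_prot = vapply(genes, function(g) {
      any(prot_stats$gene_id == g & prot_stats$p_value < 0.05, na.rm = TRUE)
    }, logical(1)),
    A3_gain = vapply(genes, has_event, logical(1), e = "A3_gain"),
    A5_gain = vapply(genes, has_event, logical(1), e = "A5_gain"),
    domain_loss = vapply(genes, has_event, logical(1), e = "domain_loss"),
    noncoding = vapply(genes, has_event, logical(1), e = "transcript_noncoding"),
    ridd_recognizable = genes %in% ridd_genes,
    xbp1_promoter_hit = genes %in% xbp1_genes,
    row.names = NULL)
  combo <- apply(flags[, -1, drop = FALSE], 1, function(r) {
    paste(names(r)[as.logical(r)], collapse = "&")
  })
  combo[combo == ""] <- "(none)"
  counts <- as.data.frame(table(combo), stringsAsFactors = FALSE)
  names(counts) <- c("flag_set", "n_genes")
  list(flags = flags, counts = counts[order(-counts$n_genes), ])
}
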