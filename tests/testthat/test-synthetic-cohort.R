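small_cfg <- function(...) {
  cohort_config(n_genes = 10, n_control = 4, n_disease = 4,
                promoter_length = 200, ...)
}

test_that("the cohort is bit-for-bit reproducible under a fixed seed", {
  a <- make_cohort(small_cfg(seed = 5))
  b <- make_cohort(small_cfg(seed = 5))
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$proteome$values, b$proteome$values)
  expect_identical(a$truth, b$truth)
  c <- make_cohort(small_cfg(seed = 6))
  expect_false(identical(a$sequences, c$sequences))
})

test_that("with no RIDD genes no sequence matches the consensus (regex oracle)", {
  tx <- make_transcriptome(small_cfg(frac_ridd_genes = 0, seed = 2))
  hits <- vapply(tx$sequences, function(s) length(oracle_motif_starts(s)),
                 integer(1))
  expect_true(all(hits == 0))
})

test_that("all-RIDD cohorts have every planted site verifiable by an independent regex+pairing check", {
  cfg <- cohort_config(n_genes = 12, frac_ridd_genes = 1,
                       frac_switch_genes = 0, n_control = 4, n_disease = 4,
                       seed = 8)
  tx <- make_transcriptome(cfg)
  tr <- tx$truth[tx$truth$planted_event == "ridd_site", ]
  expect_equal(nrow(tr), 12)
  params <- scan_params()
  for (i in seq_len(nrow(tr))) {
    seq <- tx$sequences[[tr$isoform[i]]]
    # regex: exactly one consensus match inside the planted span
    st <- oracle_motif_starts(seq)
    inside <- st[st >= tr$planted_site_start[i] & st < tr$planted_site_end[i]]
    expect_equal(length(inside), 1L, info = tr$isoform[i])
    # pairing: the enumeration oracle confirms a dominant stem-loop there
    ws <- max(0, inside - params$flank)
    we <- min(nchar(seq), inside + 10 + params$flank)
    win <- substring(seq, ws + 1, we)
    p <- oracle_hairpin_prob(win, inside + 2 - ws, params)
    expect_gt(p, 0.9)
  }
  # and sequences outside planted spans carry no other match
  for (i in seq_len(nrow(tx$truth))) {
    iso <- tx$truth$isoform[i]
    if (is.na(iso)) next
    st <- oracle_motif_starts(tx$sequences[[iso]])
    span <- tr[tr$isoform == iso, ]
    outside <- if (nrow(span)) {
      st[st < span$planted_site_start - 2 | st >= span$planted_site_end]
    } else st
    expect_equal(length(outside), 0L, info = iso)
  }
})

test_that("noiseless expression carries the planted effects exactly", {
  cfg <- small_cfg(noise_cv = 0, seed = 3, frac_ridd_genes = 0.4,
                   frac_switch_genes = 0.4, switch_effect_dIF = 0.3)
  tx <- make_transcriptome(cfg)
  expr <- make_expression(cfg, tx, tpm = FALSE)
  is_d <- expr$condition == "disease"

  # RIDD isoform: disease/control mean ratio exactly 1/fold
  ridd <- tx$truth$isoform[tx$truth$planted_event == "ridd_site"]
  expect_gt(length(ridd), 0)
  for (iso in ridd) {
    expect_equal(mean(expr$values[iso, is_d]) / mean(expr$values[iso, !is_d]),
                 1 / cfg$ridd_downreg_fold)
  }

  # planted switch: dIF exactly +0.30 for the up isoform (scale-invariant, so
  # it also holds after TPM rescaling)
  tpm <- make_expression(cfg, tx, tpm = TRUE)
  ifs <- isoform_fractions(tpm, tx$models)
  sw <- tx$truth$isoform[tx$truth$planted_event == "switch_up"]
  expect_gt(length(sw), 0)
  for (iso in sw) {
    dif <- mean(ifs$IF[iso, is_d]) - mean(ifs$IF[iso, !is_d])
    expect_equal(dif, 0.3, tolerance = 1e-12)
  }

  # TPM columns sum to 1e6
  expect_equal(unname(colSums(tpm$values)), rep(1e6, ncol(tpm$values)))
})

test_that("gene-level expression is the sum of its isoforms in every sample", {
  cfg <- small_cfg(seed = 4)
  co <- make_cohort(cfg)
  genes <- vapply(co$models, function(m) m$gene_id, "")
  gsum <- rowsum(co$expr$values, genes[rownames(co$expr$values)])
  # the proteome at noise 0 / exponent 1 equals exactly this gene matrix
  cfg0 <- small_cfg(seed = 4, proteome_noise_cv = 0)
  tx <- make_transcriptome(cfg0)
  expr <- make_expression(cfg0, tx)
  prot <- make_proteome(cfg0, expr, tx)
  genes0 <- vapply(tx$models, function(m) m$gene_id, "")
  expect_equal(prot$values,
               rowsum(expr$values, genes0[rownames(expr$values)]))
  expect_true(all(gsum >= 0))
})

test_that("flip genes get a protein effect with the opposite sign", {
  tx <- make_transcriptome(small_cfg(seed = 9, frac_ridd_genes = 0.4))
  ridd_iso <- tx$truth$isoform[tx$truth$planted_event == "ridd_site"][1]
  flip_gene <- tx$truth$gene[tx$truth$isoform == ridd_iso &
                               tx$truth$planted_event == "ridd_site"]
  cfg <- small_cfg(seed = 9, frac_ridd_genes = 0.4, noise_cv = 0,
                   proteome_noise_cv = 0, flip_genes = flip_gene)
  tx <- make_transcriptome(cfg)
  expr <- make_expression(cfg, tx, tpm = FALSE)
  prot <- make_proteome(cfg, expr, tx)
  is_d <- expr$condition == "disease"
  iso_fc <- log2(mean(expr$values[ridd_iso, is_d]) /
                   mean(expr$values[ridd_iso, !is_d]))
  prot_fc <- log2(mean(prot$values[flip_gene, is_d]) /
                    mean(prot$values[flip_gene, !is_d]))
  expect_lt(iso_fc, 0)
  expect_gt(prot_fc, 0)
})

test_that("planted promoter instances score maximally when they are the consensus", {
  pw <- xbp1s_pwm()
  cons <- pwm_consensus(pw)
  smax <- score_window(pw, cons)
  # consensus attains the per-position maximum
  expect_equal(smax, sum(apply(pw$scores, 2, max)))
  # planted instances are recovered by the scanner at the recorded offset
  cfg <- small_cfg(seed = 12, promoter_plant_frac = 0.5)
  tx <- make_transcriptome(cfg)
  prom <- make_promoters(cfg, tx)
  hits <- scan_promoters(pw, prom$promoters)
  for (i in seq_len(nrow(prom$truth))) {
    g <- prom$truth$gene[i]
    expect_true(any(hits$promoter_id == g &
                      hits$offset == prom$truth$planted_site_start[i] &
                      hits$strand == "+"), info = g)
  }
})

test_that("background promoters yield hits at the exact-p-value rate (binomial oracle)", {
  cfg <- cohort_config(n_genes = 40, n_control = 2, n_disease = 2,
                       promoter_plant_frac = 0, promoter_length = 600,
                       seed = 21)
  tx <- make_transcriptome(cfg)
  prom <- make_promoters(cfg, tx)
  expect_null(prom$truth)
  pw <- xbp1s_pwm()
  hits <- scan_promoters(pw, prom$promoters, threshold_p = 5e-4)
  # per-window hit probability = largest attainable tail below the threshold
  dist <- pwm_score_distribution(pw)
  pstar <- max(c(0, dist$tail[dist$tail < 5e-4]))
  n_windows <- 2 * sum(nchar(prom$promoters) - pw$width + 1)
  expected <- n_windows * pstar
  se <- sqrt(n_windows * pstar * (1 - pstar))
  expect_lt(abs(nrow(hits) - expected), 3 * se + 1)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(ridd_downreg_fold = 1), "> 1")
  expect_error(cohort_config(frac_ridd_genes = 1.2), "<= 1")
  expect_error(cohort_config(n_genes = 10, frac_ridd_genes = 0.9,
                             frac_switch_genes = 0.9), "<= 1")
})
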