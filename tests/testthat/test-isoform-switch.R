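# helper: a transcript-level matrix with explicit gene structure
make_if_fixture <- function(vals, genes, conditions) {
  expr <- expression_matrix(vals, conditions)
  list(expr = expr, tx2gene = stats::setNames(genes, rownames(vals)))
}

test_that("isoform fractions divide by the gene total per sample", {
  vals <- matrix(c(8, 2, 5,
                   4, 6, 1), nrow = 3,
                 dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  fx <- make_if_fixture(vals, c("g1", "g1", "g2"), c("control", "disease"))
  ifs <- isoform_fractions(fx$expr, fx$tx2gene)
  expect_equal(ifs$IF["t1", "s1"], 0.8)
  expect_equal(ifs$IF["t2", "s1"], 0.2)
  expect_equal(ifs$IF["t3", "s1"], 1)      # single-isoform gene
  expect_equal(unname(colSums(ifs$IF[c("t1", "t2"), ])), c(1, 1))
})

test_that("zero-total samples are excluded for that gene and means use the rest", {
  vals <- matrix(c(8, 2,
                   0, 0,
                   6, 2,
                   9, 3), nrow = 2,
                 dimnames = list(c("t1", "t2"), c("s1", "s2", "s3", "s4")))
  fx <- make_if_fixture(vals, c("g1", "g1"),
                        c("control", "control", "disease", "disease"))
  ifs <- isoform_fractions(fx$expr, fx$tx2gene)
  expect_true(all(is.na(ifs$IF[, "s2"])))
  # hand value: control mean IF(t1) over s1 only = 0.8
  rec <- test_switches(ifs, n_perm = 200, seed = 1)
  expect_equal(rec$IF_control[rec$transcript_id == "t1"], 0.8)
  expect_equal(rec$IF_disease[rec$transcript_id == "t1"], 0.75)
})

test_that("a transcript without a gene mapping is an error", {
  vals <- matrix(1:4, 2, dimnames = list(c("t1", "tX"), c("s1", "s2")))
  fx <- make_if_fixture(vals, c("g1", "g1"), c("control", "disease"))
  expect_error(isoform_fractions(fx$expr, fx$tx2gene["t1"]), "tX")
})

noiseless_switch_fixture <- function(dif = 0.3, n = 6) {
  # two-isoform gene, IF 0.5/0.5 in control, (0.5+dif)/(0.5-dif) in disease;
  # a filler gene keeps the FDR machinery honest
  tot <- 100
  conditions <- rep(c("control", "disease"), each = n)
  t1 <- c(rep(0.5 * tot, n), rep((0.5 + dif) * tot, n))
  t2 <- tot - t1
  t3 <- rep(50, 2 * n)
  vals <- rbind(t1 = t1, t2 = t2, t3 = t3)
  colnames(vals) <- sprintf("s%02d", seq_len(2 * n))
  make_if_fixture(vals, c("g1", "g1", "g2"), conditions)
}

test_that("a noiseless planted switch is recovered exactly with the smallest attainable p", {
  fx <- noiseless_switch_fixture(0.3)
  ifs <- isoform_fractions(fx$expr, fx$tx2gene)
  rec <- test_switches(ifs, n_perm = 1000, seed = 1)
  expect_equal(rec$dIF[rec$transcript_id == "t1"], 0.3)
  expect_equal(rec$dIF[rec$transcript_id == "t2"], -0.3)
  # p at the permutation resolution: only label permutations reproducing the
  # split attain |stat| >= obs
  expect_lt(rec$p_value[rec$transcript_id == "t1"], 0.01)
  # constant isoform -> p = 1
  expect_equal(rec$p_value[rec$transcript_id == "t3"], 1)
})

test_that("|dIF| exactly at the threshold is not significant (strict inequality)", {
  fx <- noiseless_switch_fixture(0.10)
  ifs <- isoform_fractions(fx$expr, fx$tx2gene)
  rec <- test_switches(ifs, n_perm = 2000, seed = 1)
  r1 <- rec[rec$transcript_id == "t1", ]
  expect_equal(abs(r1$dIF), 0.10)
  expect_false(r1$significant)            # dIF must exceed 0.10 strictly
  # just above the threshold it is significant
  fx2 <- noiseless_switch_fixture(0.11)
  rec2 <- test_switches(isoform_fractions(fx2$expr, fx2$tx2gene),
                        n_perm = 2000, seed = 1)
  expect_true(rec2$significant[rec2$transcript_id == "t1"])
})

test_that("swapping condition labels negates every dIF", {
  fx <- noiseless_switch_fixture(0.2)
  ifs <- isoform_fractions(fx$expr, fx$tx2gene)
  rec <- test_switches(ifs, n_perm = 100, seed = 1)
  swapped <- fx$expr
  swapped$condition <- factor(
    ifelse(swapped$condition == "control", "disease", "control"),
    levels = c("control", "disease"))
  ifs2 <- isoform_fractions(swapped, fx$tx2gene)
  rec2 <- test_switches(ifs2, n_perm = 100, seed = 1)
  expect_equal(rec2$dIF, -rec$dIF)
})

test_that("permutation p-values are invariant to global TPM rescaling", {
  withr::with_seed(31, {
    vals <- matrix(rlnorm(8 * 10, 3, 1), nrow = 8,
                   dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  })
  genes <- rep(paste0("g", 1:4), each = 2)
  conditions <- rep(c("control", "disease"), each = 5)
  fx <- make_if_fixture(vals, genes, conditions)
  rec <- test_switches(isoform_fractions(fx$expr, fx$tx2gene),
                       n_perm = 500, seed = 2)
  fx2 <- make_if_fixture(vals * 37.5, genes, conditions)
  rec2 <- test_switches(isoform_fractions(fx2$expr, fx2$tx2gene),
                        n_perm = 500, seed = 2)
  expect_equal(rec$p_value, rec2$p_value)
  expect_equal(rec$dIF, rec2$dIF)
})

test_that("batch-aware testing is available in both permutation and lm modes", {
  withr::with_seed(13, {
    vals <- matrix(rlnorm(6 * 12, 3, 0.5), nrow = 6,
                   dimnames = list(paste0("t", 1:6), sprintf("s%02d", 1:12)))
  })
  genes <- rep(paste0("g", 1:3), each = 2)
  expr <- expression_matrix(vals, rep(c("control", "disease"), each = 6),
                            batch = rep(c("b1", "b2"), 6))
  ifs <- isoform_fractions(expr, stats::setNames(genes, rownames(vals)))
  rec_p <- test_switches(ifs, n_perm = 500, seed = 3)
  rec_l <- test_switches(ifs, method = "lm")
  expect_true(all(rec_p$p_value > 0 & rec_p$p_value <= 1))
  expect_true(all(rec_l$p_value > 0 & rec_l$p_value <= 1))
})

test_that("consequence classification follows the UTR/domain/biotype definitions", {
  models <- fixture_models()  # t2 has a 200 nt longer 3'UTR and lacks D2
  up <- data.frame(gene_id = "gA", transcript_id = "t2", dIF = 0.4)
  down <- data.frame(gene_id = "gA", transcript_id = "t1", dIF = -0.4)
  call <- classify_consequences(up, down, models)
  ev <- strsplit(call$events, ",")[[1]]
  expect_true(all(c("A3_gain", "domain_loss") %in% ev))
  expect_false("A5_gain" %in% ev)

  # reversed direction: loss events
  call2 <- classify_consequences(transform(down, dIF = 0.4),
                                 transform(up, dIF = -0.4), models)
  ev2 <- strsplit(call2$events, ",")[[1]]
  expect_true(all(c("A3_loss", "domain_gain") %in% ev2))

  # non-coding up-isoform
  nc <- transcript_model("t4", "gA", strand = "+",
                         exons = data.frame(start = 100, end = 550))
  models$t4 <- nc
  call3 <- classify_consequences(
    data.frame(gene_id = "gA", transcript_id = "t4", dIF = 0.3),
    down, models)
  expect_match(call3$events, "transcript_noncoding")

  expect_error(classify_consequences(up, transform(up, dIF = -1), models),
               "same isoform")
})

test_that("event fractions use the Wilson score interval (closed-form oracle)", {
  calls <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      up_isoform = "u", down_isoform = "d",
                      events = c(rep("A3_gain", 13), rep("none", 87)))
  ef <- event_fractions(calls, 100)
  row <- ef[ef$event == "A3_gain", ]
  expect_equal(row$fraction, 0.13)
  w <- oracle_wilson(13, 100)
  expect_equal(row$ci_lower, unname(w["lower"]), tolerance = 1e-9)
  expect_equal(row$ci_upper, unname(w["upper"]), tolerance = 1e-9)
  # boundary cases
  ef0 <- event_fractions(calls[calls$events == "none", ], 87)
  expect_equal(ef0$fraction[ef0$event == "A3_gain"], 0)
  expect_equal(ef0$ci_lower[ef0$event == "A3_gain"], 0)
  efall <- event_fractions(
    data.frame(gene_id = "g", up_isoform = "u", down_isoform = "d",
               events = rep("A3_gain", 5))[rep(1, 5), ], 5)
  expect_equal(efall$fraction[efall$event == "A3_gain"], 1)
  expect_equal(efall$ci_upper[efall$event == "A3_gain"], 1)
})

test_that("differential expression recovers a planted fold change and applies BH", {
  n <- 6
  withr::with_seed(17, {
    vals <- matrix(rlnorm(50 * 2 * n, log(1000), 0.0001), nrow = 50)
  })
  rownames(vals) <- paste0("f", 1:50)
  colnames(vals) <- sprintf("s%02d", 1:(2 * n))
  vals["f1", (n + 1):(2 * n)] <- vals["f1", (n + 1):(2 * n)] * 2
  expr <- expression_matrix(vals, rep(c("control", "disease"), each = n))
  de <- diff_expression(expr)
  # log2(x+1) and median-centring keep the 2-fold change within 1% of 1
  expect_equal(de$log2fc[de$feature_id == "f1"], 1, tolerance = 0.01)
  expect_lt(de$fdr[de$feature_id == "f1"], 0.05)
  expect_true(all(de$fdr >= de$p_value - 1e-12, na.rm = TRUE))
})

test_that("features with majority zeros are filtered out", {
  vals <- matrix(c(0, 0, 0, 5, 1, 2, 3, 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("fz", "fk"), paste0("s", 1:4)))
  expr <- expression_matrix(vals, c("control", "control", "disease", "disease"))
  de <- diff_expression(expr)
  expect_false("fz" %in% de$feature_id)
  expect_true("fk" %in% de$feature_id)
})

test_that("cross-omics overlap flags and counts match brute-force set logic", {
  tx <- data.frame(feature_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                   log2fc = c(-1, 1), p_value = c(0.001, 0.5),
                   fdr = c(0.01, 0.8))
  prot <- data.frame(feature_id = c("g1", "g3"), log2fc = c(1, 0.2),
                     p_value = c(0.01, 0.9),
                     fdr = c(0.04, 0.95))
  calls <- data.frame(gene_id = "g1", up_isoform = "a", down_isoform = "b",
                      events = "A3_gain,domain_loss")
  ov <- cross_omics_overlap(tx, prot, calls, ridd_genes = "g1",
                            xbp1_genes = c("g1", "g2"))
  f1 <- ov$flags[ov$flags$gene_id == "g1", ]
  expect_true(all(unlist(f1[, c("deg_tx", "deg_prot", "A3_gain",
                                "domain_loss", "ridd_recognizable",
                                "xbp1_promoter_hit")])))
  expect_false(f1$A5_gain)
  # g1 sits in the all-layers intersection
  full <- ov$counts$flag_set[which.max(nchar(ov$counts$flag_set))]
  expect_true(grepl("deg_tx", full) && grepl("xbp1_promoter_hit", full))
  # disjoint fixture: empty intersection
  ov2 <- cross_omics_overlap(tx[2, ], prot[2, ], calls[0, ])
  expect_true(all(!ov2$flags$deg_prot | !ov2$flags$deg_tx))
  # counts equal a brute-force scan
  expect_equal(sum(ov$counts$n_genes), nrow(ov$flags))
})
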