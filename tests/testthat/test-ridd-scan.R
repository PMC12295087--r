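test_that("find_motifs matches direct instances and rejects non-matches", {
  m <- find_motifs("AACAGCAGAA")
  expect_equal(m$start, 0L)
  expect_equal(m$motif, "AACAGCAGAA")
  expect_equal(nrow(find_motifs("AAAAAAAAAAAA")), 0L)
  expect_equal(nrow(find_motifs("ACGT")), 0L)          # shorter than 10
  # N never matches a fixed position, but matches wildcards
  expect_equal(nrow(find_motifs("AANAGCAGAA")), 0L)    # N at fixed C
  expect_equal(find_motifs("NNCAGCAGNN")$start, 0L)    # N at wildcards is fine
})

test_that("find_motifs equals the regex oracle on a random 10 kb sequence", {
  seq <- withr::with_seed(7, random_dna(10000))
  expect_identical(find_motifs(seq)$start, oracle_motif_starts(seq))
})

test_that("overlapping motif matches are all reported in ascending order", {
  # CAGCAGCAGCAG gives shifted overlapping instances
  seq <- paste0("AA", strrep("CAG", 6), "AA")
  st <- find_motifs(seq)$start
  expect_identical(st, sort(st))
  expect_identical(st, oracle_motif_starts(seq))
  expect_gt(length(st), 1)
})

test_that("hairpin probability is 0 without any admissible stem", {
  seq <- paste0(strrep("A", 15), "AACAGCAGAA", strrep("A", 15))
  expect_equal(as.numeric(hairpin_probability(seq, 15, scan_params())), 0)
})

test_that("hairpin probability equals exhaustive enumeration on the planted example", {
  seq <- paste0("GGGGGG", "AAACAGCAGAA", "CCCCCC")
  params <- scan_params()
  p <- hairpin_probability(seq, find_motifs(seq)$start[1], params)
  # whole sequence fits in one window: h1 is the hexamer start
  expect_equal(as.numeric(p), oracle_hairpin_prob(seq, 9, params),
               tolerance = 1e-12)
  expect_gt(as.numeric(p), 0.9)
})

test_that("large beta drives the probability to 1 when the best structure is loop-compatible", {
  seq <- paste0("GGGGGG", "AAACAGCAGAA", "CCCCCC")
  p <- hairpin_probability(seq, find_motifs(seq)$start[1], scan_params(beta = 30))
  expect_equal(as.numeric(p), 1, tolerance = 1e-6)
})

test_that("windows too short for a stem score 0", {
  params <- scan_params()
  expect_equal(ire1ridd:::hairpin_probability_window("ACGTACGTAC", 2, params), 0)
})

test_that("hairpin probability equals the enumeration oracle on random windows", {
  params <- scan_params()
  for (s in 1:25) {
    withr::with_seed(s, {
      L <- sample(12:30, 1)
      win <- random_dna(L)
      h1 <- sample(0:(L - 6), 1)
      expect_equal(ire1ridd:::hairpin_probability_window(win, h1, params),
                   oracle_hairpin_prob(win, h1, params), tolerance = 1e-9,
                   info = paste("seed", s))
    })
  }
})

test_that("lengthening a complementary stem never decreases hairpin probability", {
  # A/T-only stems around an N-padded CCGCCG loop in an N background: N never
  # pairs, so every admissible structure's loop still contains the hexamer and
  # extending the stem adds structures without removing any
  params <- scan_params()
  loop <- "NCCGCCGN"
  probs <- vapply(4:9, function(s) {
    seq <- paste0(strrep("N", 10 - (s - 4)), strrep("A", s), loop,
                  strrep("T", s), strrep("N", 10 - (s - 4)))
    m <- find_motifs(seq)
    expect_equal(nrow(m), 1L)
    as.numeric(hairpin_probability(seq, m$start[1], params))
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_gt(probs[1], 0)
})

test_that("planted synthetic sites are recovered at the planted coordinates", {
  cfg <- cohort_config(n_genes = 12, frac_ridd_genes = 0.5, seed = 42)
  tx <- make_transcriptome(cfg)
  sites <- scan_transcriptome(tx$models)
  tr <- tx$truth[tx$truth$planted_event == "ridd_site", ]
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    hit <- sites[sites$transcript_id == tr$isoform[i], , drop = FALSE]
    expect_true(any(hit$motif_start >= tr$planted_site_start[i] &
                      hit$motif_start < tr$planted_site_end[i]),
                info = tr$isoform[i])
  }
})

test_that("an unattainable probability threshold yields no sites", {
  cfg <- cohort_config(n_genes = 8, frac_ridd_genes = 0.5, seed = 3)
  tx <- make_transcriptome(cfg)
  sites <- scan_transcriptome(tx$models, scan_params(prob_threshold = 1.01))
  expect_equal(nrow(sites), 0L)
})

test_that("sites on non-coding transcripts are annotated non_coding", {
  cfg <- cohort_config(n_genes = 12, frac_ridd_genes = 1,
                       frac_switch_genes = 0, seed = 11)
  tx <- make_transcriptome(cfg)
  sites <- scan_transcriptome(tx$models)
  nc <- vapply(tx$models, function(m) m$biotype == "non_coding", logical(1))
  on_nc <- sites$transcript_id %in% names(tx$models)[nc]
  expect_gt(sum(on_nc), 0)
  expect_true(all(sites$region[on_nc] == "non_coding"))
  expect_true(all(sites$region[!on_nc] %in% c("5UTR", "CDS", "3UTR")))
})

test_that("overlapping-window sites are deduplicated to the best one", {
  sites <- data.frame(
    transcript_id = "t", gene_id = "g",
    motif_start = c(5L, 8L, 60L), motif_seq = "NNCNGCNGNN",
    window_start = c(0L, 3L, 55L), window_end = c(35L, 38L, 90L),
    hairpin_prob = c(0.95, 0.99, 0.92), region = "3UTR")
  out <- ire1ridd:::dedup_overlapping_sites(sites)
  expect_equal(out$motif_start, c(8L, 60L))
})

test_that("differential recognizability requires a mixed-isoform gene", {
  models <- fixture_models()
  site_row <- function(tx) data.frame(
    transcript_id = tx, gene_id = "gA", motif_start = 0L, motif_seq = "x",
    window_start = 0L, window_end = 10L, hairpin_prob = 1, region = "CDS")
  # one isoform with a site, one without -> differential
  d <- differential_recognizability(site_row("t1"), models)
  expect_true(d$differential[d$gene_id == "gA"])
  # both isoforms with sites -> not differential
  d2 <- differential_recognizability(rbind(site_row("t1"), site_row("t2")), models)
  expect_false(d2$differential[d2$gene_id == "gA"])
  # no sites -> not differential; single-isoform gene flagged
  d3 <- differential_recognizability(site_row("t1")[0, ], models)
  expect_false(any(d3$differential))
  expect_match(d3$note[d3$gene_id == "gB"], "single-isoform")
})
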