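#' Configuration of the synthetic study cohort
#'
#' Describes a two-condition bulk-transcriptomics study with planted IRE1
#' biology: multi-isoform genes whose alternative isoforms differ by exactly
#' one splice consequence, RIDD stem-loop sites planted in a subset of genes
#' (with the carrying isoform degraded in disease), an XBP1-like two-isoform
#' gene whose spliced/unspliced usage shifts in disease, isoform switches of a
#' fixed effect size, promoters with planted transcription-factor motifs, and
#' a protein layer correlated with gene expression. Defaults emulate a
#' 12-control vs 12-patient brain cohort with moderate biological noise.
#'
#' @param n_control,n_disease samples per condition (defaults 12 and 12).
#' @param n_genes number of genes (default 60).
#' @param isoforms_per_gene inclusive range of isoform counts per gene
#'   (default `c(2, 3)`).
#' @param frac_ridd_genes fraction of genes carrying a planted RIDD site in
#'   one isoform (default 0.3).
#' @param frac_switch_genes fraction of genes with a planted isoform switch
#'   (default 0.3).
#' @param ridd_downreg_fold fold by which RIDD-carrying isoforms are divided
#'   in disease (default 2; must exceed 1).
#' @param xbp1s_upreg_fold fold applied to the XBP1s-like isoform in disease,
#'   with the XBP1u-like partner reduced to conserve the gene total
#'   (default 2).
#' @param switch_effect_dIF isoform-fraction shift planted in switch genes
#'   (default 0.3).
#' @param noise_cv coefficient of variation of multiplicative expression noise
#'   (default 0.2).
#' @param batch_levels number of batches (default 1 = no batch structure).
#' @param batch_sd log2 standard deviation of per-feature batch effects
#'   (default 0.3, used only when `batch_levels > 1`).
#' @param stem_range planted stem lengths, base pairs (default `c(6, 8)`).
#' @param loop_range planted loop lengths, nucleotides (default `c(7, 10)`).
#' @param plant_min_prob planted stem-loops are rejection-sampled until their
#'   ensemble probability under default scan parameters reaches this value
#'   (default 0.95), so a planted site genuinely presents the consensus in a
#'   dominant stem-loop rather than burying it in an alternative pairing
#'   register.
#' @param promoter_length promoter length in nt (default 1000).
#' @param promoter_plant_frac fraction of genes receiving a planted PWM
#'   instance (default 0.3).
#' @param proteome_exponent power `a` in `protein = gene^a × noise`
#'   (default 1).
#' @param proteome_noise_cv CV of the protein noise (default 0.2).
#' @param flip_genes genes whose protein-level effect is sign-flipped relative
#'   to the transcript level (default none).
#' @param max_attempts cap on rejection/repair sampling per sequence
#'   (default 10000).
#' @param seed master seed; fixes every output bit-for-bit.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_control = 12L, n_disease = 12L, n_genes = 60L,
                          isoforms_per_gene = c(2L, 3L),
                          frac_ridd_genes = 0.3, frac_switch_genes = 0.3,
                          ridd_downreg_fold = 2, xbp1s_upreg_fold = 2,
                          switch_effect_dIF = 0.3, noise_cv = 0.2,
                          batch_levels = 1L, batch_sd = 0.3,
                          stem_range = c(6L, 8L), loop_range = c(7L, 10L),
                          plant_min_prob = 0.95,
                          promoter_length = 1000L, promoter_plant_frac = 0.3,
                          proteome_exponent = 1, proteome_noise_cv = 0.2,
                          flip_genes = character(), max_attempts = 10000L,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_control >= 2, n_disease >= 2, n_genes >= 3,
            length(isoforms_per_gene) == 2, isoforms_per_gene[1] >= 1,
            diff(isoforms_per_gene) >= 0,
            frac_ridd_genes >= 0, frac_ridd_genes <= 1,
            frac_switch_genes >= 0, frac_switch_genes <= 1,
            frac_ridd_genes + frac_switch_genes <= 1,
            ridd_downreg_fold > 1, xbp1s_upreg_fold > 1,
            switch_effect_dIF >= 0, switch_effect_dIF <= 1,
            noise_cv >= 0, batch_levels >= 1,
            stem_range[1] >= 4, loop_range[1] >= 7, loop_range[2] <= 12,
            promoter_length >= 50,
            promoter_plant_frac >= 0, promoter_plant_frac <= 1,
            max_attempts >= 1)
  structure(cfg, class = "cohort_config")
}

## replace a fixed motif position of each NNCNGCNGNN match until none remain,
## leaving the protected interval untouched; bounded by max_attempts
clean_motifs <- function(seq, protect = NULL, max_attempts = 10000L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (it in seq_len(max_attempts)) {
    m <- find_motifs(paste(ch, collapse = ""))
    if (!is.null(protect)) {
      m <- m[m$start < protect[1] - 2L | m$start > protect[2], , drop = FALSE]
    }
    if (!nrow(m)) return(paste(ch, collapse = ""))
    for (s in m$start) {
      fixed_pos <- s + c(2L, 4L, 5L, 7L) + 1L    # 1-based fixed positions
      ok <- if (is.null(protect)) fixed_pos else {
        fixed_pos[fixed_pos <= protect[1] | fixed_pos > protect[2]]
      }
      if (!length(ok)) next                       # fully inside protected span
      ch[ok[1]] <- "A"
    }
  }
  stop("could not clear motif matches within ", max_attempts, " attempts")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## build a stem-loop insert: complementary arms of `stem` bp around a loop of
## `loop_len` nt whose centre holds a CNGCNG hexamer. Returns the insert and
## the motif start (0-based) relative to the insert.
build_hairpin_insert <- function(stem, loop_len) {
  hex <- c("C", sample(c("A","C","G","T"), 1), "G",
           "C", sample(c("A","C","G","T"), 1), "G")
  pad <- loop_len - 6L
  lpad <- sample(0:pad, 1)
  loop <- c(sample(c("A","C","G","T"), lpad, replace = TRUE), hex,
            sample(c("A","C","G","T"), pad - lpad, replace = TRUE))
  arm5 <- sample(c("A","C","G","T"), stem, replace = TRUE)
  arm3 <- rev(chartr("ACGT", "TGCA", arm5))
  insert <- paste(c(arm5, loop, arm3), collapse = "")
  list(insert = insert, hex_start = stem + lpad)   # 0-based within insert
}

## plant a stem-loop at `pos` (0-based) in `seq`. The insert and its local
## flanks are rejection-sampled until (a) the only motif match near the site
## is the planted one and (b) the site's stem-loop ensemble probability under
## the default scan parameters is at least `min_prob` — i.e. until the insert
## genuinely presents the consensus in a dominant stem-loop rather than
## burying it in an alternative register.
plant_ridd_site <- function(seq, pos, stem, loop_len, max_attempts = 10000L,
                            min_prob = 0.95, params = scan_params()) {
  n <- nchar(seq)
  fl <- params$flank
  stopifnot(pos >= fl, pos + 2L * stem + loop_len + fl <= n)
  for (att in seq_len(max_attempts)) {
    hp <- build_hairpin_insert(stem, loop_len)
    ins_len <- nchar(hp$insert)
    region <- paste0(random_seq(fl), hp$insert, random_seq(fl))
    cand <- paste0(substring(seq, 1, pos - fl),
                   region,
                   substring(seq, pos + ins_len + fl + 1L, n))
    motif_start <- pos + hp$hex_start - 2L
    lo <- max(0L, pos - fl - 10L); hi <- min(n, pos + ins_len + fl + 10L)
    local <- find_motifs(substring(cand, lo + 1L, hi))
    if (!(nrow(local) == 1L && local$start[1] + lo == motif_start)) next
    if (as.numeric(hairpin_probability(cand, motif_start, params)) < min_prob) next
    return(list(seq = cand, motif_start = motif_start,
                site_start = pos, site_end = pos + ins_len))
  }
  stop("could not plant an unambiguous stem-loop within ", max_attempts,
       " attempts")
}

#' Generate the synthetic transcriptome
#'
#' Builds transcript models and spliced sequences for every gene in the
#' configuration. Each gene has a canonical coding isoform; alternative
#' isoforms differ from it by exactly one planted event (3'UTR gain, 5'UTR
#' gain, domain loss, loss of coding potential, or none). In RIDD genes
#' exactly one alternative isoform carries a planted stem-loop (complementary
#' stem of `stem_range` bp around a `loop_range` nt loop with a central
#' CNGCNG) in its 3' region; every other sequence is scrubbed of NNCNGCNGNN
#' matches.
#'
#' @param cfg a [cohort_config()].
#' @return list: `models` (named list of [transcript_model()]s), `sequences`
#'   (named character vector), `truth` (planted-truth data.frame).
#' @export
make_transcriptome <- function(cfg) {
  with_seed(child_seed(cfg$seed, 1L), make_transcriptome_impl(cfg))
}

make_transcriptome_impl <- function(cfg) {
  ng <- cfg$n_genes
  n_ridd <- round(cfg$frac_ridd_genes * ng)
  n_switch <- round(cfg$frac_switch_genes * ng)
  classes <- rep("null", ng)
  pick <- sample(ng)
  classes[pick[seq_len(n_ridd)]] <- "ridd"
  if (n_switch > 0) classes[pick[n_ridd + seq_len(n_switch)]] <- "switch"
  ## the XBP1-like gene occupies a slot only when one is free
  if (n_ridd + n_switch < ng) classes[pick[n_ridd + n_switch + 1L]] <- "xbp1"
  event_types <- c("a3_gain", "a5_gain", "domain_loss", "transcript_noncoding")

  models <- list()
  truth <- list()
  add_truth <- function(gene, iso, event, s = NA_integer_, e = NA_integer_,
                        effect = NA_real_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      gene = gene, isoform = iso, planted_event = event,
      planted_site_start = s, planted_site_end = e, effect = effect)
  }

  for (gi in seq_len(ng)) {
    g <- sprintf("g%03d", gi)
    strand <- if (gi %% 2L == 0L) "-" else "+"
    gstart <- (gi - 1L) * 10000L + 1000L
    utr5 <- sample(40:80, 1)
    cds_len <- 3L * sample(60:100, 1)
    utr3 <- sample(140:240, 1)
    tlen <- utr5 + cds_len + utr3
    n_iso <- sample(cfg$isoforms_per_gene[1]:cfg$isoforms_per_gene[2], 1)
    cls <- classes[gi]
    if (cls %in% c("ridd", "switch", "xbp1")) n_iso <- max(n_iso, 2L)

    mk <- function(id, u5, clen, u3, coding = TRUE, domains = c("D1", "D2"),
                   sequence) {
      len <- u5 + clen + u3
      ## two exons split inside the CDS; genomic layout from transcript lengths
      ex1 <- u5 + clen %/% 2L
      ex2 <- len - ex1
      intron <- 500L
      if (strand == "+") {
        exons <- data.frame(start = c(gstart, gstart + ex1 + intron),
                            end = c(gstart + ex1, gstart + ex1 + intron + ex2))
      } else {
        exons <- data.frame(start = c(gstart + ex2 + intron, gstart),
                            end = c(gstart + ex2 + intron + ex1, gstart + ex2))
      }
      cds <- NULL
      if (coding) {
        ## CDS spans [u5, u5+clen) in transcript coords, across both exons
        if (strand == "+") {
          cds <- data.frame(start = c(gstart + u5, gstart + ex1 + intron),
                            end = c(gstart + ex1,
                                    gstart + ex1 + intron + (clen - (ex1 - u5))))
        } else {
          cds <- data.frame(start = c(gstart + ex2 + intron,
                                      gstart + ex2 - (clen - (ex1 - u5))),
                            end = c(gstart + ex2 + intron + ex1 - u5,
                                    gstart + ex2))
        }
      }
      dom <- if (coding && length(domains)) {
        data.frame(domain = paste0(g, "_", domains),
                   start = u5 + 3L * seq_along(domains),
                   end = u5 + 3L * seq_along(domains) + 30L)
      } else NULL
      transcript_model(id, g, chrom = "chr1", strand = strand, exons = exons,
                       cds = cds, biotype = if (coding) "coding" else "non_coding",
                       domains = dom, sequence = sequence)
    }

    ref_id <- paste0(g, ".t1")
    ref_seq <- clean_motifs(random_seq(tlen), max_attempts = cfg$max_attempts)
    models[[ref_id]] <- mk(ref_id, utr5, cds_len, utr3, sequence = ref_seq)
    add_truth(g, ref_id, "reference")

    if (n_iso >= 2L) {
      alt_id <- paste0(g, ".t2")
      if (cls == "xbp1") {
        ## XBP1u-like: reference-style; XBP1s-like: alternative with a short
        ## internal difference (26 nt shorter 5'UTR, mimicking excision)
        u5s <- max(20L, utr5 - 26L)
        alt_seq <- clean_motifs(random_seq(u5s + cds_len + utr3),
                                max_attempts = cfg$max_attempts)
        models[[alt_id]] <- mk(alt_id, u5s, cds_len, utr3, sequence = alt_seq)
        add_truth(g, alt_id, "xbp1s", effect = cfg$xbp1s_upreg_fold)
        add_truth(g, ref_id, "xbp1u")
      } else {
        ev <- sample(event_types, 1)
        u5 <- utr5; u3 <- utr3; coding <- TRUE; doms <- c("D1", "D2")
        if (ev == "a3_gain") u3 <- utr3 + 200L
        if (ev == "a5_gain") u5 <- utr5 + 150L
        if (ev == "domain_loss") doms <- "D1"
        if (ev == "transcript_noncoding") { coding <- FALSE; doms <- character() }
        alen <- u5 + cds_len + u3
        alt_seq <- clean_motifs(random_seq(alen), max_attempts = cfg$max_attempts)
        site <- NULL
        if (cls == "ridd") {
          stem <- sample(cfg$stem_range[1]:cfg$stem_range[2], 1)
          loop <- sample(cfg$loop_range[1]:cfg$loop_range[2], 1)
          pos <- alen - 2L * stem - loop - 25L     # inside the 3' region
          planted <- plant_ridd_site(alt_seq, pos, stem, loop,
                                     max_attempts = cfg$max_attempts,
                                     min_prob = cfg$plant_min_prob)
          alt_seq <- planted$seq
          site <- planted
        }
        models[[alt_id]] <- mk(alt_id, u5, if (coding) cds_len else 0L,
                               if (coding) u3 else alen - u5, coding = coding,
                               domains = doms, sequence = alt_seq)
        add_truth(g, alt_id, ev)
        if (!is.null(site)) {
          add_truth(g, alt_id, "ridd_site", site$site_start, site$site_end,
                    effect = cfg$ridd_downreg_fold)
        }
        if (cls == "switch") {
          add_truth(g, alt_id, "switch_up", effect = cfg$switch_effect_dIF)
        }
      }
    }
    if (n_iso >= 3L && cls != "xbp1") {
      ex_id <- paste0(g, ".t3")
      ex_seq <- clean_motifs(random_seq(tlen), max_attempts = cfg$max_attempts)
      models[[ex_id]] <- mk(ex_id, utr5, cds_len, utr3, sequence = ex_seq)
      add_truth(g, ex_id, "none")
    }
  }
  truth <- do.call(rbind, truth)
  sequences <- vapply(models, function(m) m$sequence, "")
  list(models = models, sequences = sequences, truth = truth)
}

#' Generate the synthetic expression matrix
#'
#' Baseline isoform abundances are lognormal (log2 mean 5, sd 2). Disease
#' samples receive the planted effects: RIDD-carrying isoforms divided by
#' `ridd_downreg_fold`; the XBP1s-like isoform multiplied by
#' `xbp1s_upreg_fold` with its XBP1u-like partner reduced so the gene total is
#' conserved; switch genes shift `switch_effect_dIF` of the gene total from
#' the canonical to the event isoform. Multiplicative lognormal noise with
#' `CV = noise_cv` is applied, then optional per-batch per-feature
#' multipliers, then (optionally) per-sample rescaling of columns to 1e6
#' (TPM).
#'
#' @param cfg a [cohort_config()].
#' @param tx output of [make_transcriptome()].
#' @param tpm rescale columns to sum to 1e6 (default `TRUE`).
#' @return an [expression_matrix()] at transcript level.
#' @export
make_expression <- function(cfg, tx, tpm = TRUE) {
  with_seed(child_seed(cfg$seed, 2L), make_expression_impl(cfg, tx, tpm))
}

make_expression_impl <- function(cfg, tx, tpm) {
  truth <- tx$truth
  ids <- names(tx$models)
  genes <- vapply(tx$models, function(m) m$gene_id, "")
  n_iso <- length(ids)
  nc <- cfg$n_control; nd <- cfg$n_disease
  samples <- c(sprintf("C%02d", seq_len(nc)), sprintf("P%02d", seq_len(nd)))
  cond <- rep(c("control", "disease"), c(nc, nd))

  base <- 2^stats::rnorm(n_iso, mean = 5, sd = 2)
  names(base) <- ids
  ## switch genes get fixed baseline fractions so the planted dIF is feasible
  sw_iso <- truth$isoform[truth$planted_event == "switch_up"]
  for (iso in sw_iso) {
    g <- genes[[iso]]
    members <- ids[genes == g]
    tot <- sum(base[members])
    fr <- if (length(members) == 2L) c(0.7, 0.3) else c(0.5, 0.3, 0.2)
    canon <- setdiff(members, iso)[1]
    others <- setdiff(members, c(canon, iso))
    base[canon] <- fr[1] * tot
    base[iso] <- fr[2] * tot
    if (length(others)) base[others] <- fr[3] * tot / length(others)
  }
  ## XBP1-like pair: unspliced dominant at baseline
  xs <- truth$isoform[truth$planted_event == "xbp1s"]
  xu <- truth$isoform[truth$planted_event == "xbp1u"]
  if (length(xs)) {
    tot <- base[xs] + base[xu]
    base[xu] <- 0.8 * tot
    base[xs] <- 0.2 * tot
  }

  ctrl <- matrix(base, n_iso, nc)
  dis <- matrix(base, n_iso, nd)
  rownames(ctrl) <- rownames(dis) <- ids
  ridd_iso <- truth$isoform[truth$planted_event == "ridd_site"]
  dis[ridd_iso, ] <- dis[ridd_iso, ] / cfg$ridd_downreg_fold
  if (length(xs)) {
    pair_tot <- base[xs] + base[xu]
    new_xs <- min(base[xs] * cfg$xbp1s_upreg_fold, 0.95 * pair_tot)
    dis[xs, ] <- new_xs
    dis[xu, ] <- pair_tot - new_xs
  }
  for (iso in sw_iso) {
    g <- genes[[iso]]
    members <- ids[genes == g]
    tot <- sum(base[members])
    canon <- setdiff(members, iso)[1]
    dis[iso, ] <- base[iso] + cfg$switch_effect_dIF * tot
    dis[canon, ] <- base[canon] - cfg$switch_effect_dIF * tot
  }
  vals <- cbind(ctrl, dis)
  colnames(vals) <- samples

  if (cfg$noise_cv > 0) {
    s <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- matrix(stats::rlnorm(length(vals), meanlog = -s^2 / 2, sdlog = s),
                    nrow(vals), ncol(vals))
    vals <- vals * noise
  }
  batch <- NULL
  if (cfg$batch_levels > 1L) {
    ## balanced assignment: round-robin within each condition
    batch <- integer(length(cond))
    batch[cond == "control"] <- rep_len(seq_len(cfg$batch_levels), nc)
    batch[cond == "disease"] <- rep_len(seq_len(cfg$batch_levels), nd)
    eff <- matrix(2^stats::rnorm(n_iso * cfg$batch_levels, 0, cfg$batch_sd),
                  n_iso, cfg$batch_levels)
    vals <- vals * eff[, batch]
    batch <- paste0("b", batch)
  }
  if (tpm) vals <- sweep(vals, 2, colSums(vals), "/") * 1e6
  expression_matrix(vals, cond, batch = batch)
}

#' Generate synthetic promoters with planted PWM instances
#'
#' A configured fraction of genes receives one high-scoring instance sampled
#' from the PWM (rejection-sampled until its exact p-value is below
#' `threshold_p`) at a recorded offset; the remaining promoters are uniform
#' background.
#'
#' @param cfg a [cohort_config()].
#' @param tx output of [make_transcriptome()].
#' @param pwm a [pwm()] object (default: the packaged synthetic XBP1s-like
#'   matrix, see [xbp1s_pwm()]).
#' @param threshold_p planted instances must beat this exact p-value
#'   (default 5e-4).
#' @return list: `promoters` (named by gene), `truth` (planted offsets).
#' @export
make_promoters <- function(cfg, tx, pwm = xbp1s_pwm(), threshold_p = 5e-4) {
  with_seed(child_seed(cfg$seed, 3L),
            make_promoters_impl(cfg, tx, pwm, threshold_p))
}

make_promoters_impl <- function(cfg, tx, pwm, threshold_p) {
  genes <- unique(vapply(tx$models, function(m) m$gene_id, ""))
  n_plant <- round(cfg$promoter_plant_frac * length(genes))
  planted <- sort(sample(genes, n_plant))
  dist <- pwm_score_distribution(pwm)
  L <- cfg$promoter_length
  proms <- character(length(genes)); names(proms) <- genes
  truth <- list()
  for (g in genes) {
    proms[[g]] <- random_seq(L)
    if (g %in% planted) {
      inst <- pwm_consensus(pwm)
      for (att in seq_len(cfg$max_attempts)) {
        cand <- paste(vapply(seq_len(pwm$width), function(j) {
          sample(c("A", "C", "G", "T"), 1, prob = pwm$probs[, j])
        }, ""), collapse = "")
        if (exact_pvalue(pwm, score_window(pwm, cand), dist) < threshold_p) {
          inst <- cand
          break
        }
      }
      off <- sample.int(L - pwm$width + 1L, 1) - 1L
      proms[[g]] <- paste0(substring(proms[[g]], 1, off), inst,
                           substring(proms[[g]], off + pwm$width + 1L, L))
      truth[[g]] <- data.frame(gene = g, isoform = NA_character_,
                               planted_event = "promoter_motif",
                               planted_site_start = off,
                               planted_site_end = off + pwm$width,
                               effect = NA_real_)
    }
  }
  list(promoters = proms,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Generate the synthetic protein abundance matrix
#'
#' `protein = gene^a × lognormal noise` at gene level (isoform expression
#' summed). Genes in `cfg$flip_genes` get a sign-flipped disease effect
#' (transcript down, protein up) to emulate discordant shared targets.
#'
#' @param cfg a [cohort_config()].
#' @param expr transcript-level [expression_matrix()].
#' @param tx output of [make_transcriptome()] (for the transcript→gene map).
#' @return a gene-level protein [expression_matrix()].
#' @export
make_proteome <- function(cfg, expr, tx) {
  with_seed(child_seed(cfg$seed, 4L), make_proteome_impl(cfg, expr, tx))
}

make_proteome_impl <- function(cfg, expr, tx) {
  genes <- vapply(tx$models, function(m) m$gene_id, "")[rownames(expr$values)]
  gvals <- rowsum(expr$values, genes)
  prot <- gvals^cfg$proteome_exponent
  is_d <- expr$condition == levels(expr$condition)[2]
  for (g in intersect(cfg$flip_genes, rownames(prot))) {
    mc <- mean(gvals[g, !is_d]); md <- mean(gvals[g, is_d])
    if (mc > 0 && md > 0) {
      ## invert the systematic disease effect on the protein scale
      prot[g, is_d] <- prot[g, is_d] * (mc / md)^(2 * cfg$proteome_exponent)
    }
  }
  if (cfg$proteome_noise_cv > 0) {
    s <- sqrt(log(1 + cfg$proteome_noise_cv^2))
    prot <- prot * matrix(stats::rlnorm(length(prot), -s^2 / 2, s),
                          nrow(prot), ncol(prot))
  }
  expression_matrix(prot, as.character(expr$condition),
                    batch = if (is.null(expr$batch)) NULL else
                      as.character(expr$batch))
}

#' The packaged synthetic XBP1s-like PWM
#'
#' An 8-wide count matrix with an ACGT-core consensus resembling a UPR-element
#' binding preference. It is a synthetic fixture for testing and simulation,
#' not a database matrix.
#'
#' @inheritParams pwm
#' @return a [pwm()] object.
#' @export
xbp1s_pwm <- function(background = rep(0.25, 4), pseudocount = 0.1) {
  read_jaspar(system.file("extdata", "xbp1s_synthetic.jaspar",
                          package = "ire1ridd"),
              background = background, pseudocount = pseudocount)
}

#' Generate the full synthetic cohort
#'
#' Runs [make_transcriptome()], [make_expression()], [make_promoters()] and
#' [make_proteome()] under one master seed and assembles the combined truth
#' table and the IRE1 panel implied by the planted biology (all RIDD-carrying
#' isoforms plus the XBP1s/XBP1u-like pair).
#'
#' @param cfg a [cohort_config()].
#' @param tpm passed to [make_expression()].
#' @return list: `models`, `sequences`, `expr`, `proteome`, `promoters`,
#'   `pwm`, `truth`, `panel`, `config`.
#' @export
make_cohort <- function(cfg = cohort_config(), tpm = TRUE) {
  tx <- make_transcriptome(cfg)
  expr <- make_expression(cfg, tx, tpm = tpm)
  prom <- make_promoters(cfg, tx)
  prot <- make_proteome(cfg, expr, tx)
  truth <- rbind(tx$truth, prom$truth)
  panel <- ire1_panel(
    ridd_targets = truth$isoform[truth$planted_event == "ridd_site"],
    xbp1s_id = c(truth$isoform[truth$planted_event == "xbp1s"], NA)[1],
    xbp1u_id = c(truth$isoform[truth$planted_event == "xbp1u"], NA)[1])
  list(models = tx$models, sequences = tx$sequences, expr = expr,
       proteome = prot, promoters = prom$promoters, pwm = xbp1s_pwm(),
       truth = truth, panel = panel, config = cfg)
}

#' Write a cohort's files to a directory
#'
#' Emits the standard formats: `transcripts.gtf`, `transcripts.fa`,
#' `promoters.fa`, `tx_tpm.tsv` + `meta.tsv`, `protein.tsv` +
#' `protein_meta.tsv`, and `truth_table.tsv`.
#'
#' @param cohort output of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(cohort$models, file.path(dir, "transcripts.gtf"))
  write_fasta(cohort$sequences, file.path(dir, "transcripts.fa"))
  write_fasta(cohort$promoters, file.path(dir, "promoters.fa"))
  write_matrix(cohort$expr, file.path(dir, "tx_tpm.tsv"),
               file.path(dir, "meta.tsv"))
  write_matrix(cohort$proteome, file.path(dir, "protein.tsv"),
               file.path(dir, "protein_meta.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate an IRE1 activity panel cohort
#'
#' Lightweight generator for calibration and power studies of the IRE1
#' activity score: a panel of RIDD-target features plus the XBP1 isoform pair
#' under a two-condition design. Under the alternative, disease samples have
#' RIDD targets and XBP1u divided by `effect_fold` and XBP1s multiplied by
#' it; `effect_fold = 1` gives the null. Multiplicative lognormal noise with
#' the given CV.
#'
#' @param n_control,n_disease samples per condition (defaults 12, 12).
#' @param n_ridd number of RIDD-target features (default 18, giving a
#'   20-feature panel with the XBP1 pair).
#' @param effect_fold planted fold effect (default 2; 1 = null).
#' @param noise_cv noise CV (default 0.2).
#' @param seed RNG seed.
#' @return list: `expr` ([expression_matrix()]), `panel` ([ire1_panel()]).
#' @export
simulate_ire1_panel <- function(n_control = 12L, n_disease = 12L,
                                n_ridd = 18L, effect_fold = 2,
                                noise_cv = 0.2, seed = 1L) {
  with_seed(seed, {
    feats <- c(sprintf("ridd%02d", seq_len(n_ridd)), "XBP1s", "XBP1u")
    base <- 2^stats::rnorm(length(feats), 5, 2)
    vals <- matrix(base, length(feats), n_control + n_disease)
    rownames(vals) <- feats
    colnames(vals) <- c(sprintf("C%02d", seq_len(n_control)),
                        sprintf("P%02d", seq_len(n_disease)))
    d <- n_control + seq_len(n_disease)
    vals[c(sprintf("ridd%02d", seq_len(n_ridd)), "XBP1u"), d] <-
      vals[c(sprintf("ridd%02d", seq_len(n_ridd)), "XBP1u"), d] / effect_fold
    vals["XBP1s", d] <- vals["XBP1s", d] * effect_fold
    if (noise_cv > 0) {
      s <- sqrt(log(1 + noise_cv^2))
      vals <- vals * matrix(stats::rlnorm(length(vals), -s^2 / 2, s),
                            nrow(vals), ncol(vals))
    }
    expr <- expression_matrix(vals, rep(c("control", "disease"),
                                        c(n_control, n_disease)))
    list(expr = expr,
         panel = ire1_panel(sprintf("ridd%02d", seq_len(n_ridd)),
                            xbp1s_id = "XBP1s", xbp1u_id = "XBP1u"))
  })
}

#' Evaluate RIDD site recovery against a planted truth table
#'
#' A planted site is recovered when some predicted site on the same transcript
#' has a window overlapping the planted stem-loop span. A predicted site is a
#' false discovery when it overlaps no planted span on its transcript.
#'
#' @param sites predicted sites from [scan_transcriptome()].
#' @param truth truth table (rows with `planted_event == "ridd_site"`).
#' @return list: `sensitivity`, `fdr`, `n_planted`, `n_predicted`.
#' @export
evaluate_site_recovery <- function(sites, truth) {
  tr <- truth[truth$planted_event == "ridd_site", , drop = FALSE]
  overlaps <- function(iso, s, e) {
    any(sites$transcript_id == iso & sites$window_start < e & sites$window_end > s)
  }
  recovered <- mapply(overlaps, tr$isoform, tr$planted_site_start,
                      tr$planted_site_end)
  tp_pred <- vapply(seq_len(nrow(sites)), function(i) {
    any(tr$isoform == sites$transcript_id[i] &
          tr$planted_site_start < sites$window_end[i] &
          tr$planted_site_end > sites$window_start[i])
  }, logical(1))
  list(sensitivity = if (nrow(tr)) mean(recovered) else NA_real_,
       fdr = if (nrow(sites)) mean(!tp_pred) else 0,
       n_planted = nrow(tr), n_predicted = nrow(sites))
}
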