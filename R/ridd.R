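#' Parameters for RIDD target-site scanning
#'
#' @param flank nucleotides of context added on each side of a motif match to
#'   form the folding window; also the maximum stem length (default 15).
#' @param min_stem minimum stem length, in base pairs (default 4).
#' @param min_loop,max_loop admissible hairpin loop lengths (defaults 4 and 12).
#' @param beta per-base-pair energy weight: each admissible hairpin is weighted
#'   `exp(beta * pairs)` against the open chain's weight 1 (default 1).
#' @param prob_threshold a motif is called a site when its stem-loop ensemble
#'   probability is strictly greater than this (default 0.9).
#' @return a `scan_params` list.
#' @export
scan_params <- function(flank = 15L, min_stem = 4L, min_loop = 4L,
                        max_loop = 12L, beta = 1, prob_threshold = 0.9) {
  stopifnot(flank >= 1, min_stem >= 1, min_loop >= 1, max_loop >= min_loop,
            beta >= 0, prob_threshold >= 0)
  structure(list(flank = as.integer(flank), min_stem = as.integer(min_stem),
                 min_loop = as.integer(min_loop), max_loop = as.integer(max_loop),
                 beta = beta, prob_threshold = prob_threshold),
            class = "scan_params")
}

#' Find RIDD consensus motif matches
#'
#' Scans a sequence for the degenerate 10-mer NNCNGCNGNN (a CNGCNG core with
#' two flanking positions on each side). Fixed positions are 3, 5, 6 and 8
#' (1-based): C, G, C, G. `N` in the sequence never matches a fixed position;
#' wildcard positions match any base. Matches may overlap.
#'
#' @param seq a nucleotide string (ACGT/U, N allowed).
#' @return data.frame with 0-based `start` and the matched `motif` 10-mer,
#'   in ascending start order.
#' @export
find_motifs <- function(seq) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), motif = character())
  if (n < 10L) return(empty)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  i <- seq_len(n - 9L)                         # 1-based candidate starts
  hit <- ch[i + 2L] == "C" & ch[i + 4L] == "G" &
         ch[i + 5L] == "C" & ch[i + 7L] == "G"
  starts <- i[hit]
  if (!length(starts)) return(empty)
  data.frame(start = starts - 1L,
             motif = substring(seq, starts, starts + 9L))
}

#' Stem-loop ensemble probability of a motif window
#'
#' The folding window is the 10-nt motif extended by `params$flank` on each
#' side (clipped to the sequence). The structural ensemble contains the open
#' chain (weight 1) and every single hairpin placeable in the window: a stem of
#' `s` contiguous base pairs (`params$min_stem <= s <= params$flank`) directly
#' enclosing a loop of length `l` (`min_loop <= l <= max_loop`), with pairs
#' drawn from {AU/UA, GC/CG, GU/UG} (T read as U; N pairs with nothing) and
#' Boltzmann weight `exp(beta * s)`. The returned probability is
#' `Z_loop / Z_total`, where `Z_loop` sums only hairpins whose loop fully
#' contains the CNGCNG hexamer (motif positions 3–8) — i.e. the probability
#' that the cleavage consensus is presented unpaired in a stem-loop.
#'
#' Windows too short for any hairpin (`< 2*min_stem + min_loop`) score 0.
#' Computation groups hairpins by loop placement and extends the stem outward,
#' summing the geometric series of admissible stem lengths in log space, so it
#' is exact and overflow-safe for large `beta`.
#'
#' @param seq transcript sequence.
#' @param motif_start 0-based start of a 10-mer motif match in `seq`.
#' @param params a [scan_params()] object.
#' @return probability in `[0, 1]`, plus window bounds as attributes
#'   `window_start`/`window_end` (0-based half-open in transcript coordinates).
#' @export
hairpin_probability <- function(seq, motif_start, params = scan_params()) {
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  stopifnot(motif_start >= 0, motif_start + 10L <= n)
  ws <- max(0L, motif_start - params$flank)
  we <- min(n, motif_start + 10L + params$flank)
  win <- substring(seq, ws + 1L, we)
  h1 <- motif_start + 2L - ws                 # 0-based hexamer start in window
  p <- hairpin_probability_window(win, h1, params)
  attr(p, "window_start") <- ws
  attr(p, "window_end") <- we
  p
}

## can two bases pair? (RNA rules on the DNA alphabet; N pairs nothing)
.pair_ok <- local({
  ok <- matrix(FALSE, 5, 5, dimnames = list(c("A","C","G","T","N"),
                                            c("A","C","G","T","N")))
  ok["A","T"] <- ok["T","A"] <- TRUE
  ok["G","C"] <- ok["C","G"] <- TRUE
  ok["G","T"] <- ok["T","G"] <- TRUE
  ok
})

## core ensemble computation on an extracted window; h1 = 0-based start of the
## hexamer that must sit inside the loop
hairpin_probability_window <- function(win, h1, params) {
  L <- nchar(win)
  ms <- params$min_stem
  if (L < 2L * ms + params$min_loop) return(0)
  ch <- strsplit(win, "", fixed = TRUE)[[1]]
  ch[!ch %in% c("A", "C", "G", "T")] <- "N"
  beta <- params$beta
  log_terms_all <- numeric(0)
  log_terms_loop <- numeric(0)
  ## enumerate loop placements; q = 0-based loop start, l = loop length
  for (l in params$min_loop:params$max_loop) {
    if (2L * ms + l > L) break
    for (q in ms:(L - l - ms)) {
      ## maximal contiguous stem extending outward from the loop boundary
      kmax <- min(params$flank, q, L - q - l)
      m <- 0L
      while (m < kmax && .pair_ok[ch[q - m], ch[q + l + 1L + m]]) m <- m + 1L
      if (m < ms) next
      ## sum_{s=ms..m} exp(beta*s), in log space
      lt <- logsumexp(beta * (ms:m))
      log_terms_all <- c(log_terms_all, lt)
      if (q <= h1 && q + l >= h1 + 6L) {
        log_terms_loop <- c(log_terms_loop, lt)
      }
    }
  }
  if (!length(log_terms_loop)) return(0)
  logZ_loop <- logsumexp(log_terms_loop)
  logZ_total <- logsumexp(c(0, log_terms_all))   # 0 = log weight of open chain
  exp(logZ_loop - logZ_total)
}

#' Scan a transcript for RIDD target sites
#'
#' Finds all NNCNGCNGNN matches, computes each match's stem-loop ensemble
#' probability, keeps those with probability strictly above
#' `params$prob_threshold`, and annotates the transcript region of the hexamer
#' (5UTR/CDS/3UTR from the CDS boundaries, or non_coding). Among retained sites
#' whose windows overlap, only the highest-probability one is kept (ties go to
#' the leftmost) so downstream associations do not double-count one hairpin.
#'
#' @param tm a [transcript_model()] with a sequence, or a plain sequence string
#'   (then `transcript_id` is taken from `names()` or `"seq"` and region is
#'   `NA`).
#' @param params a [scan_params()] object.
#' @return data.frame of sites: `transcript_id`, `gene_id`, `motif_start`
#'   (0-based), `motif_seq`, `window_start`, `window_end`, `hairpin_prob`,
#'   `region`. A transcript is RIDD-recognizable iff this has at least one row.
#' @export
scan_transcript <- function(tm, params = scan_params()) {
  if (is.character(tm)) {
    id <- if (!is.null(names(tm))) names(tm)[1] else "seq"
    seq <- tm[[1]]; gene <- NA_character_; model <- NULL
  } else {
    stopifnot(inherits(tm, "transcript_model"))
    if (is.null(tm$sequence)) stop("transcript ", tm$transcript_id, " has no sequence")
    id <- tm$transcript_id; seq <- tm$sequence; gene <- tm$gene_id; model <- tm
  }
  seq <- normalize_seq(seq)
  mot <- find_motifs(seq)
  out <- data.frame(transcript_id = character(), gene_id = character(),
                    motif_start = integer(), motif_seq = character(),
                    window_start = integer(), window_end = integer(),
                    hairpin_prob = numeric(), region = character())
  if (!nrow(mot)) return(out)
  probs <- numeric(nrow(mot)); wst <- integer(nrow(mot)); wen <- integer(nrow(mot))
  for (k in seq_len(nrow(mot))) {
    p <- hairpin_probability(seq, mot$start[k], params)
    probs[k] <- as.numeric(p)
    wst[k] <- attr(p, "window_start"); wen[k] <- attr(p, "window_end")
  }
  keep <- probs > params$prob_threshold
  if (!any(keep)) return(out)
  sites <- data.frame(
    transcript_id = id, gene_id = gene,
    motif_start = mot$start[keep], motif_seq = mot$motif[keep],
    window_start = wst[keep], window_end = wen[keep],
    hairpin_prob = probs[keep],
    region = if (is.null(model)) NA_character_ else
      vapply(mot$start[keep] + 2L, function(p) position_region(model, p), ""))
  dedup_overlapping_sites(sites)
}

## among sites with overlapping windows keep the max-probability one
dedup_overlapping_sites <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  sites <- sites[order(sites$window_start), , drop = FALSE]
  grp <- integer(nrow(sites)); grp[1] <- 1L; gmax <- sites$window_end[1]
  for (i in 2:nrow(sites)) {
    if (sites$window_start[i] < gmax) {
      grp[i] <- grp[i - 1L]
      gmax <- max(gmax, sites$window_end[i])
    } else {
      grp[i] <- grp[i - 1L] + 1L
      gmax <- sites$window_end[i]
    }
  }
  keep <- unlist(lapply(split(seq_len(nrow(sites)), grp), function(ix) {
    ix[which.max(sites$hairpin_prob[ix])]
  }), use.names = FALSE)
  out <- sites[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many transcripts for RIDD target sites
#'
#' @param models list of [transcript_model()]s (with sequences) or a named
#'   character vector of sequences.
#' @param params a [scan_params()] object.
#' @return one data.frame of sites, rbind of [scan_transcript()] results.
#' @export
scan_transcriptome <- function(models, params = scan_params()) {
  if (is.character(models)) {
    models <- lapply(seq_along(models), function(i) {
      stats::setNames(models[i], names(models)[i])
    })
  }
  do.call(rbind, c(lapply(models, scan_transcript, params = params),
                   list(make.row.names = FALSE)))
}

#' Differential RIDD recognizability per gene
#'
#' A multi-isoform gene is differentially RIDD-recognizable when at least one
#' isoform carries a predicted site and at least one carries none. Genes with a
#' single isoform are `FALSE` (noted in the `note` column).
#'
#' @param sites site table from [scan_transcriptome()].
#' @param models list of `transcript_model`s defining the gene→isoform map
#'   (needed so isoforms with zero sites are counted).
#' @return data.frame: `gene_id`, `n_isoforms`, `n_recognizable`,
#'   `differential` (logical), `note`.
#' @export
differential_recognizability <- function(sites, models) {
  tx2gene <- vapply(models, function(m) m$gene_id, "")
  tx <- vapply(models, function(m) m$transcript_id, "")
  rec <- tx %in% unique(sites$transcript_id)
  out <- do.call(rbind, lapply(split(seq_along(tx), tx2gene), function(ix) {
    n <- length(ix); r <- sum(rec[ix])
    data.frame(gene_id = tx2gene[ix[1]], n_isoforms = n, n_recognizable = r,
               differential = n >= 2L && r >= 1L && r < n,
               note = if (n < 2L) "single-isoform gene" else "")
  }))
  rownames(out) <- NULL
  out
}
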