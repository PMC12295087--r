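#' Position weight matrix
#'
#' Builds a PWM from a 4 × width count (or probability) matrix with rows
#' A, C, G, T. Counts are regularized per column with
#' `p = (count + pseudocount * bg) / (colsum + pseudocount)` and scored as
#' log2 odds against the background.
#'
#' @param counts numeric 4 × width matrix, rownames A/C/G/T (any row order).
#' @param background length-4 background probabilities (default uniform).
#' @param pseudocount regularization mass (default 0.1).
#' @param name optional matrix name.
#' @return object of class `pwm` with elements `probs`, `scores` (log2-odds
#'   bits), `width`, `background`, `name`.
#' @export
pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.1,
                name = "pwm") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0)) stop("negative counts")
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount > 0)
  background <- background / sum(background)
  tot <- colSums(counts)
  probs <- vapply(seq_len(ncol(counts)), function(j) {
    (counts[, j] + pseudocount * background) / (tot[j] + pseudocount)
  }, numeric(4))
  dimnames(probs) <- list(c("A", "C", "G", "T"), NULL)
  scores <- log2(probs / background)
  structure(list(probs = probs, scores = scores, width = ncol(probs),
                 background = background, name = name), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n", x$name, x$width,
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence (max-probability base per position) of a PWM
#' @param pwm a [pwm()] object.
#' @return character string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Read a JASPAR-format count matrix
#'
#' Accepts the standard four-row JASPAR text format: an optional `>` header
#' followed by lines like `A [ 3 12 0 ... ]` (brackets optional).
#'
#' @param path file path.
#' @inheritParams pwm
#' @return a [pwm()] object.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- "jaspar"
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  rows <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([ACGT])\\s*\\[?\\s*([0-9. \t]+?)\\s*\\]?\\s*$", ln))[[1]]
    if (length(m) != 3L) stop("unparseable JASPAR line: ", ln)
    rows[[m[2]]] <- as.numeric(strsplit(m[3], "\\s+")[[1]])
  }
  if (!setequal(names(rows), c("A", "C", "G", "T"))) {
    stop("JASPAR matrix must have rows A, C, G, T")
  }
  counts <- do.call(rbind, rows[c("A", "C", "G", "T")])
  pwm(counts, background = background, pseudocount = pseudocount, name = name)
}

#' Score one window against a PWM
#'
#' @param pwm a [pwm()] object.
#' @param window string of length `pwm$width` over ACGT (windows containing N
#'   are not scorable and raise an error; the scanner skips them).
#' @return log2-odds score in bits.
#' @export
score_window <- function(pwm, window) {
  window <- normalize_seq(window)
  if (nchar(window) != pwm$width) stop("window length must equal PWM width")
  idx <- match(strsplit(window, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("window contains non-ACGT characters")
  sum(pwm$scores[cbind(idx, seq_len(pwm$width))])
}

## integer-discretized per-position scores (units of `granularity` bits),
## shifted so the minimum per column is 0; used by both the DP null and the
## scanner so scores and p-values are mutually consistent
pwm_int_scores <- function(pwm, granularity = 1 / 1000) {
  s <- round(pwm$scores / granularity)
  offset <- apply(s, 2, min)
  list(mat = sweep(s, 2, offset), offset = sum(offset), granularity = granularity)
}

#' Exact null distribution of PWM scores
#'
#' Dynamic programme over integer-discretized scores (default granularity
#' 1/1000 bit): the exact distribution of the log2-odds score of a random
#' window drawn from the background model.
#'
#' @param pwm a [pwm()] object (width ≤ 20).
#' @param granularity discretization step in bits.
#' @return list with `score` (ascending attainable scores, bits), `prob`, and
#'   `tail` (`P(S >= score)`).
#' @export
pwm_score_distribution <- function(pwm, granularity = 1 / 1000) {
  if (pwm$width > 20L) stop("width > 20 not supported by the exact DP")
  is <- pwm_int_scores(pwm, granularity)
  dist <- 1                      # prob vector over shifted integer scores, 0-based
  for (j in seq_len(pwm$width)) {
    col <- is$mat[, j]
    newlen <- length(dist) + max(col)
    nd <- numeric(newlen)
    for (b in 1:4) {
      sh <- col[b]
      nd[(sh + 1):(sh + length(dist))] <-
        nd[(sh + 1):(sh + length(dist))] + dist * pwm$background[b]
    }
    dist <- nd
  }
  keep <- dist > 0
  ints <- which(keep) - 1L
  prob <- dist[keep]
  tail <- rev(cumsum(rev(prob)))
  list(score = (ints + is$offset) * granularity, prob = prob, tail = tail,
       granularity = granularity)
}

#' Exact p-value of a PWM score
#'
#' `P(score(random background window) >= score)`, from the discretized exact
#' null of [pwm_score_distribution()]. Scores above the maximum attainable
#' score return the smallest representable positive double (a p of exactly 0
#' is never reported).
#'
#' @param pwm a [pwm()] object.
#' @param score log2-odds score in bits (vectorized).
#' @param dist optional precomputed [pwm_score_distribution()].
#' @return p-values in `(0, 1]`.
#' @export
exact_pvalue <- function(pwm, score, dist = NULL) {
  if (is.null(dist)) dist <- pwm_score_distribution(pwm)
  ## match on the discretized grid: p = tail at the first attainable score
  ## >= requested score (minus half a bin for roundoff)
  vapply(score, function(s) {
    i <- findInterval(s - dist$granularity / 2, dist$score) + 1L
    if (i > length(dist$score)) .Machine$double.xmin else dist$tail[i]
  }, numeric(1))
}

#' Scan promoters for PWM hits with exact p-values
#'
#' Slides the PWM over every promoter on both strands, scores each N-free
#' window, and reports windows with exact p-value strictly below
#' `threshold_p`. Minus-strand hits are reported with the 0-based offset of
#' the window on the forward sequence. Promoters shorter than the PWM width
#' are skipped with a warning. All overlapping hits are reported.
#'
#' @param pwm a [pwm()] object.
#' @param promoters named character vector of promoter sequences.
#' @param threshold_p p-value threshold (default 5e-4, strict `<`).
#' @return data.frame: `promoter_id`, `offset`, `strand`, `score` (bits),
#'   `p_value`.
#' @export
scan_promoters <- function(pwm, promoters, threshold_p = 5e-4) {
  dist <- pwm_score_distribution(pwm)
  out <- list()
  for (id in names(promoters)) {
    seq <- normalize_seq(promoters[[id]])
    L <- nchar(seq)
    if (L < pwm$width) {
      warning("promoter ", id, " shorter than PWM width; skipped")
      next
    }
    for (str in c("+", "-")) {
      s <- if (str == "+") seq else revcomp(seq)
      sc <- score_all_windows(pwm, s)
      hit <- which(!is.na(sc))
      if (!length(hit)) next
      pv <- exact_pvalue(pwm, sc[hit], dist = dist)
      sig <- pv < threshold_p
      if (!any(sig)) next
      off <- hit[sig] - 1L                       # 0-based on scanned strand
      if (str == "-") off <- L - off - pwm$width # mirror to forward coords
      out[[length(out) + 1L]] <- data.frame(
        promoter_id = id, offset = off, strand = str,
        score = sc[hit][sig], p_value = pv[sig])
    }
  }
  if (!length(out)) {
    return(data.frame(promoter_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$promoter_id, res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## vectorized scores of every window of a sequence; NA where the window
## contains a non-ACGT character. Scores are computed on the same discretized
## grid as the DP null so p-value lookups are consistent.
score_all_windows <- function(pwm, seq) {
  L <- nchar(seq)
  w <- pwm$width
  if (L < w) return(numeric(0))
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  is <- pwm_int_scores(pwm)
  n <- L - w + 1L
  tot <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n - 1L)]
    bad <- bad | is.na(b)
    v <- is$mat[, j][b]
    v[is.na(v)] <- 0
    tot <- tot + v
  }
  sc <- (tot + is$offset) * is$granularity
  sc[bad] <- NA_real_
  sc
}

#' Genes targeted by both RIDD and XBP1s
#'
#' Intersects RIDD-recognizable genes with XBP1s promoter-hit genes and
#' annotates transcript- and protein-level log2 fold changes. A gene is
#' flagged `discordant` when some isoform is significantly down at the
#' transcript level while its protein is up — the pattern seen for shared
#' targets whose protein abundance rises despite RIDD-driven transcript decay.
#'
#' @param ridd_genes character vector of RIDD-recognizable gene ids.
#' @param xbp1_genes character vector of genes with ≥1 promoter PWM hit.
#' @param tx_stats data.frame with `gene_id`, `log2fc`, `fdr` at the
#'   transcript level (one row per isoform; `feature_id` optional).
#' @param prot_stats data.frame with `gene_id` (or `feature_id`), `log2fc`,
#'   `p_value` at the protein level.
#' @return data.frame: `gene_id`, `iso_log2fc_min`, `prot_log2fc`,
#'   `discordant`.
#' @export
shared_targets <- function(ridd_genes, xbp1_genes, tx_stats, prot_stats) {
  shared <- sort(intersect(unique(ridd_genes), unique(xbp1_genes)))
  if (!"gene_id" %in% names(prot_stats) && "feature_id" %in% names(prot_stats)) {
    prot_stats$gene_id <- prot_stats$feature_id
  }
  rows <- lapply(shared, function(g) {
    tx <- tx_stats[tx_stats$gene_id == g, , drop = FALSE]
    pr <- prot_stats[prot_stats$gene_id == g, , drop = FALSE]
    iso_min <- if (nrow(tx)) min(tx$log2fc) else NA_real_
    iso_dn <- nrow(tx) && any(tx$log2fc < 0 & tx$fdr < 0.05)
    prot_fc <- if (nrow(pr)) pr$log2fc[1] else NA_real_
    data.frame(gene_id = g, iso_log2fc_min = iso_min, prot_log2fc = prot_fc,
               discordant = isTRUE(iso_dn && !is.na(prot_fc) && prot_fc > 0))
  })
  if (!length(rows)) {
    return(data.frame(gene_id = character(), iso_log2fc_min = numeric(),
                      prot_log2fc = numeric(), discordant = logical()))
  }
  do.call(rbind, rows)
}
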