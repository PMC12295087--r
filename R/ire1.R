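#' IRE1 activity feature panel
#'
#' Names the features entering the per-sample IRE1 activity score: known RIDD
#' target transcripts plus the two XBP1 isoforms. RIDD targets and XBP1u are
#' scored inverted (RIDD degrades its targets and IRE1 consumes XBP1u, so
#' lower expression means higher activity); XBP1s is scored directly.
#'
#' @param ridd_targets character vector of transcript ids.
#' @param xbp1s_id,xbp1u_id XBP1 isoform transcript ids (either may be `NA` to
#'   omit).
#' @return object of class `ire1_panel` with a `direction` vector (+1 direct,
#'   -1 inverted) named by feature id.
#' @export
ire1_panel <- function(ridd_targets, xbp1s_id = NA, xbp1u_id = NA) {
  dir <- c(stats::setNames(rep(-1, length(ridd_targets)), ridd_targets))
  if (!is.na(xbp1s_id)) dir[xbp1s_id] <- +1
  if (!is.na(xbp1u_id)) dir[xbp1u_id] <- -1
  if (!length(dir)) stop("empty panel")
  if (anyDuplicated(names(dir))) stop("duplicate panel feature ids")
  structure(list(direction = dir), class = "ire1_panel")
}

#' @export
print.ire1_panel <- function(x, ...) {
  cat(sprintf("<ire1_panel> %d feature(s): %d inverted, %d direct\n",
              length(x$direction), sum(x$direction < 0), sum(x$direction > 0)))
  invisible(x)
}

## quantile bin of each sample for one feature: rank samples, map position i
## (of n) to bin ceiling(i*Q/n); tied samples share the mean of their
## positions' bins, rounded half up. direction -1 ranks descending.
quantile_bins <- function(x, Q, direction = +1) {
  n <- length(x)
  key <- direction * x
  pos_bins <- ceiling(seq_len(n) * Q / n)
  ## a tied group occupies rank positions rmin..rmax; all its members get the
  ## mean of the bins over that span, rounded half up
  rmin <- rank(key, ties.method = "min")
  rmax <- rank(key, ties.method = "max")
  vapply(seq_len(n), function(i) {
    floor(mean(pos_bins[rmin[i]:rmax[i]]) + 0.5)
  }, numeric(1))
}

#' Per-sample IRE1 activity scores
#'
#' For every panel feature, samples are ranked by that feature's expression
#' and assigned quantile bins `1..Q` (inverted features rank low expression
#' into high bins). A sample's score is the mean bin over the panel:
#' the sum of quantiles divided by the number of features, so scores lie in
#' `[1, Q]`. All-zero features are dropped with a warning, as are panel ids
#' absent from the matrix.
#'
#' @param expr TPM-normalized transcript [expression_matrix()].
#' @param panel an [ire1_panel()].
#' @param Q number of quantile bins (default 4; must not exceed the sample
#'   count).
#' @return data.frame: `sample_id`, `score`, `condition`.
#' @export
score_samples <- function(expr, panel, Q = 4L) {
  n <- ncol(expr$values)
  if (Q > n) stop("Q (", Q, ") exceeds the number of samples (", n, ")")
  ids <- names(panel$direction)
  missing <- setdiff(ids, rownames(expr$values))
  if (length(missing)) {
    warning("panel feature(s) absent from matrix, dropped: ",
            paste(missing, collapse = ", "))
    ids <- setdiff(ids, missing)
  }
  vals <- expr$values[ids, , drop = FALSE]
  allzero <- rowSums(vals) == 0
  if (any(allzero)) {
    warning("all-zero panel feature(s) dropped: ",
            paste(ids[allzero], collapse = ", "))
    ids <- ids[!allzero]
    vals <- vals[ids, , drop = FALSE]
  }
  if (!length(ids)) stop("no usable panel features")
  bins <- vapply(ids, function(f) {
    quantile_bins(vals[f, ], Q, panel$direction[[f]])
  }, numeric(n))                                  # samples x features
  data.frame(sample_id = colnames(expr$values),
             score = rowMeans(bins),
             condition = as.character(expr$condition),
             row.names = NULL)
}

#' Categorize IRE1 scores into low/medium/high tertiles
#'
#' Samples are sorted by score (ties broken by sample id, lexically, for
#' determinism) and split into three contiguous groups whose sizes differ by
#' at most one. With fewer than three distinct scores the split is degenerate
#' and flagged via the `degenerate` attribute.
#'
#' @param scores data.frame from [score_samples()].
#' @return `scores` with a `category` factor column (`low < medium < high`);
#'   attribute `degenerate` is `TRUE` when score ties make the categories
#'   arbitrary.
#' @export
categorize <- function(scores) {
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 samples to form tertiles")
  ord <- order(scores$score, scores$sample_id)
  grp <- ceiling(3 * seq_len(n) / n)
  category <- factor(c("low", "medium", "high")[grp[order(ord)]],
                     levels = c("low", "medium", "high"))
  scores$category <- category
  attr(scores, "degenerate") <- length(unique(scores$score)) < 3L
  if (attr(scores, "degenerate")) {
    warning("fewer than 3 distinct scores; tertile categories are degenerate")
  }
  scores
}

#' Chi-squared association between categories and condition
#'
#' Pearson chi-squared without continuity correction on the categories ×
#' condition contingency table. When any expected count is below 5 the
#' asymptotic p-value is replaced by a Monte-Carlo p-value (tables drawn with
#' both margins fixed; `(1 + #{X² ≥ X²_obs}) / (B + 1)`) and flagged. Rows or
#' columns with zero total are collapsed away with a warning. Cramér's V is
#' `sqrt(chi2 / (n * min(r - 1, c - 1)))`.
#'
#' @param categories factor/character of per-sample categories, or a
#'   pre-tabulated contingency `table`/`matrix` (then `condition` is ignored).
#' @param condition factor/character of per-sample condition labels.
#' @param n_sim Monte-Carlo draws (default 1e5).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return list: `chi2`, `df`, `p`, `cramers_v`, `monte_carlo` (logical),
#'   `table`.
#' @export
association_test <- function(categories, condition = NULL, n_sim = 1e5L,
                             seed = 1L) {
  tab <- if (is.matrix(categories) || is.table(categories)) {
    as.matrix(categories)
  } else {
    table(category = as.character(categories),
          condition = as.character(condition))
  }
  empty_r <- rowSums(tab) == 0
  empty_c <- colSums(tab) == 0
  if (any(empty_r) || any(empty_c)) {
    warning("empty category/condition level(s) collapsed")
    tab <- tab[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("association needs at least a 2x2 table after collapsing")
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  mc <- any(expected < 5)
  p <- if (mc) {
    with_seed(seed, suppressWarnings(
      stats::chisq.test(tab, simulate.p.value = TRUE, B = n_sim)$p.value))
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  v <- sqrt(chi2 / (n * min(nrow(tab) - 1L, ncol(tab) - 1L)))
  list(chi2 = chi2, df = df, p = as.numeric(p), cramers_v = v,
       monte_carlo = mc, table = tab)
}
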