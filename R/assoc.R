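#' Per-isoform event and RIDD-recognizability flags
#'
#' Builds the binary isoform table used by the splice-event × RIDD association
#' analysis. Event flags are assigned relative to each gene's canonical
#' isoform (the isoform with the highest mean isoform fraction in controls,
#' falling back to the first isoform): an isoform is flagged `A3_gain` when
#' its 3'UTR is longer than the canonical one's, `A5_gain` for the 5'UTR,
#' `domain_loss` when its domain set is a strict subset of the canonical
#' one's, and `transcript_noncoding` when it is non-coding while the canonical
#' isoform codes. `ridd_flag` marks isoforms with at least one predicted site.
#'
#' @param models named list of [transcript_model()]s.
#' @param sites site table from [scan_transcriptome()].
#' @param records optional [test_switches()] output; contributes `iso_log2fc`
#'   and `fdr` columns (as `iso_fdr`) and the control isoform fractions used
#'   to pick the canonical isoform.
#' @return data.frame: `gene_id`, `transcript_id`, the four event flags (0/1),
#'   `ridd_flag`, and (when available) `iso_log2fc`, `iso_fdr`.
#' @export
isoform_flags <- function(models, sites, records = NULL) {
  tx <- vapply(models, function(m) m$transcript_id, "")
  gene <- vapply(models, function(m) m$gene_id, "")
  rec <- tx %in% unique(sites$transcript_id)
  rows <- list()
  for (g in unique(gene)) {
    ix <- which(gene == g)
    canon <- ix[1]
    if (!is.null(records)) {
      sub <- records[match(tx[ix], records$transcript_id), ]
      if (!all(is.na(sub$IF_control))) canon <- ix[which.max(sub$IF_control)]
    }
    cm <- models[[canon]]
    cu <- utr_lengths(cm)
    cdom <- unique(cm$domains$domain)
    for (i in ix) {
      m <- models[[i]]
      u <- utr_lengths(m)
      dom <- unique(m$domains$domain)
      both_coding <- m$biotype == "coding" && cm$biotype == "coding"
      rows[[tx[i]]] <- data.frame(
        gene_id = g, transcript_id = tx[i],
        A3_gain = as.integer(both_coding && u[["utr3"]] > cu[["utr3"]]),
        A5_gain = as.integer(both_coding && u[["utr5"]] > cu[["utr5"]]),
        domain_loss = as.integer(all(dom %in% cdom) && length(cdom) > length(dom)),
        transcript_noncoding = as.integer(m$biotype == "non_coding" &&
                                            cm$biotype == "coding"),
        ridd_flag = as.integer(rec[i]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(records)) {
    j <- match(out$transcript_id, records$transcript_id)
    if ("iso_log2fc" %in% names(records)) out$iso_log2fc <- records$iso_log2fc[j]
    out$iso_fdr <- records$fdr[j]
  }
  out
}

#' RIDD candidate transcripts
#'
#' Retains isoforms that are potential RIDD targets *and* significantly
#' downregulated: `ridd_flag == 1`, `iso_log2fc < 0`, `iso_fdr < 0.05`.
#'
#' @param flags [isoform_flags()] output with `iso_log2fc` and `iso_fdr`
#'   columns.
#' @param fdr_threshold significance threshold (strict; default 0.05).
#' @return the retained subset of `flags`.
#' @export
ridd_candidates <- function(flags, fdr_threshold = 0.05) {
  stopifnot(all(c("iso_log2fc", "iso_fdr") %in% names(flags)))
  keep <- flags$ridd_flag == 1 & flags$iso_log2fc < 0 &
    flags$iso_fdr < fdr_threshold
  keep[is.na(keep)] <- FALSE
  out <- flags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phi coefficient between two binary vectors
#'
#' Pearson correlation of two 0/1 vectors; on a 2×2 table this equals
#' `±sqrt(chi2/n)`. Undefined (NA) when either vector has zero variance.
#'
#' @param x,y binary vectors of equal length.
#' @return phi in `[-1, 1]`, or `NA` when undefined.
#' @export
phi_coefficient <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Per-gene correlation of a splice event with RIDD recognizability
#'
#' For each gene with at least two isoforms, differential RIDD
#' recognizability, and the event present in at least one isoform, computes
#' the phi coefficient between the isoform event flags and RIDD flags. Genes
#' where either flag has zero variance are excluded with a note. A pair is
#' `reported` when `|phi|` strictly exceeds the threshold.
#'
#' @param flags [isoform_flags()] output.
#' @param event one of the event flag column names.
#' @param phi_threshold reporting threshold on `|phi|` (strict; default 0.5).
#' @return data.frame: `gene_id`, `event`, `phi`, `reported`, `note`.
#' @export
per_gene_correlation <- function(flags, event = "A3_gain", phi_threshold = 0.5) {
  stopifnot(event %in% names(flags))
  out <- list()
  for (g in unique(flags$gene_id)) {
    sub <- flags[flags$gene_id == g, , drop = FALSE]
    if (nrow(sub) < 2L) next
    r <- sub$ridd_flag
    e <- sub[[event]]
    if (!(any(r == 1) && any(r == 0))) next     # not differentially recognizable
    if (!any(e == 1)) next                      # event absent from the gene
    phi <- phi_coefficient(e, r)
    note <- if (is.na(phi)) "zero variance; excluded" else ""
    out[[g]] <- data.frame(gene_id = g, event = event, phi = phi,
                           reported = !is.na(phi) && abs(phi) > phi_threshold,
                           note = note)
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), event = character(),
                      phi = numeric(), reported = logical(), note = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plug-in mutual information of a contingency table, in bits
#'
#' `MI = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` with `0 log 0 = 0`; no
#' small-sample bias correction is applied (the plug-in estimator is biased
#' upward for small tables).
#'
#' @param tab contingency table or matrix of counts.
#' @return mutual information in bits (≥ 0).
#' @export
mutual_information <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

#' Global splice-event × RIDD association over all isoforms
#'
#' Pools all isoform rows into one 2×2 table of event flag × RIDD flag and
#' reports Pearson chi-squared (as in [association_test()]), Cramér's V, and
#' plug-in mutual information in bits. An empty margin (event or RIDD flag
#' constant) makes the association undefined: all statistics are `NA`.
#'
#' @param flags [isoform_flags()] output.
#' @param event event flag column name.
#' @param ... passed to [association_test()] (`n_sim`, `seed`).
#' @return list: `table`, `chi2`, `df`, `p`, `cramers_v`, `mi_bits`.
#' @export
global_association <- function(flags, event = "A3_gain", ...) {
  stopifnot(event %in% names(flags))
  tab <- table(factor(flags[[event]], levels = 0:1),
               factor(flags$ridd_flag, levels = 0:1))
  dimnames(tab) <- list(event = c("no_event", "event"),
                        ridd = c("no_site", "site"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                cramers_v = NA_real_, mi_bits = NA_real_))
  }
  at <- association_test(tab, ...)
  list(table = tab, chi2 = at$chi2, df = at$df, p = at$p,
       cramers_v = at$cramers_v, mi_bits = mutual_information(tab))
}
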