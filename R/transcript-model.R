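#' Transcript model
#'
#' A `transcript_model` describes one isoform: its exon (and optional CDS)
#' structure in genomic coordinates, biotype, any domain annotations in
#' transcript-relative coordinates, and optionally its spliced sequence.
#'
#' Internal coordinates are 0-based half-open throughout the package; GTF I/O
#' converts to/from the 1-based inclusive convention at the boundary. Exons are
#' stored sorted 5'→3' in *transcript* orientation, i.e. genomically ascending
#' on the plus strand and descending on the minus strand.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with integer columns `start`, `end`
#'   (0-based half-open, genomic), one row per exon.
#' @param cds optional data.frame like `exons` for the coding region;
#'   `NULL` for non-coding transcripts.
#' @param biotype `"coding"` or `"non_coding"`; defaults to `"coding"` iff
#'   `cds` is given. Supplying an inconsistent value is an error.
#' @param domains data.frame with columns `domain`, `start`, `end`
#'   (transcript-relative, 0-based half-open), possibly empty.
#' @param sequence optional spliced sequence (sense strand, 5'→3'); normalized
#'   to uppercase ACGT (U accepted). Length must equal the spliced length.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom = "chr1",
                             strand = c("+", "-"), exons, cds = NULL,
                             biotype = NULL, domains = NULL, sequence = NULL) {
  strand <- match.arg(strand)
  exons <- check_intervals(exons, "exons")
  ## sort into transcript orientation
  ord <- order(exons$start, decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  gen_sorted <- sort(exons$start)
  gen_end <- sort(exons$end)
  if (any(gen_end[-length(gen_end)] > gen_sorted[-1])) {
    stop("exons overlap in transcript ", transcript_id)
  }
  if (!is.null(cds)) {
    cds <- check_intervals(cds, "cds")
    cds <- cds[order(cds$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(cds) <- NULL
    for (i in seq_len(nrow(cds))) {
      ok <- any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
      if (!ok) stop("cds interval outside exons in transcript ", transcript_id)
    }
  }
  if (is.null(biotype)) biotype <- if (is.null(cds)) "non_coding" else "coding"
  biotype <- match.arg(biotype, c("coding", "non_coding"))
  if ((biotype == "non_coding") != is.null(cds) && biotype == "coding" && is.null(cds)) {
    stop("biotype 'coding' requires a cds")
  }
  if (biotype == "non_coding" && !is.null(cds)) {
    stop("biotype 'non_coding' is incompatible with a cds")
  }
  if (is.null(domains)) {
    domains <- data.frame(domain = character(), start = integer(), end = integer())
  }
  slen <- sum(exons$end - exons$start)
  if (!is.null(sequence)) {
    sequence <- normalize_seq(sequence)
    if (nchar(sequence) != slen) {
      stop("sequence length (", nchar(sequence), ") does not match spliced length (",
           slen, ") for ", transcript_id)
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds, biotype = biotype,
         domains = domains, sequence = sequence),
    class = "transcript_model")
}

check_intervals <- function(df, what) {
  df <- as.data.frame(df)
  if (!all(c("start", "end") %in% names(df)) || nrow(df) == 0L) {
    stop(what, " must be a non-empty data.frame with 'start' and 'end'")
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 0L) || any(df$start >= df$end)) {
    stop(what, " intervals must satisfy 0 <= start < end")
  }
  df[, c("start", "end"), drop = FALSE]
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s%s  %d exon(s), %s, %d nt%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$biotype, spliced_length(x),
              if (is.null(x$sequence)) ", no sequence" else ""))
  invisible(x)
}

#' Spliced length of a transcript model
#' @param tm a `transcript_model`.
#' @return integer, sum of exon lengths.
#' @export
spliced_length <- function(tm) sum(tm$exons$end - tm$exons$start)

#' UTR and CDS lengths of a transcript model
#'
#' Lengths are measured along the spliced transcript, so
#' `utr5 + cds + utr3 == spliced_length(tm)` for coding transcripts. For
#' non-coding transcripts UTRs are undefined: `utr5` and `utr3` are `NA` and
#' `cds` is 0.
#'
#' @param tm a `transcript_model`.
#' @return named numeric vector `c(utr5, cds, utr3)`.
#' @export
utr_lengths <- function(tm) {
  if (is.null(tm$cds)) return(c(utr5 = NA_real_, cds = 0, utr3 = NA_real_))
  cds_len <- sum(tm$cds$end - tm$cds$start)
  ## transcript-relative offset of the CDS 5' end
  first <- tm$cds[1, ]     # exons and cds are both in transcript orientation
  off <- 0
  for (i in seq_len(nrow(tm$exons))) {
    ex <- tm$exons[i, ]
    if (first$start >= ex$start && first$end <= ex$end) {
      off <- off + if (tm$strand == "+") first$start - ex$start else ex$end - first$end
      break
    }
    off <- off + (ex$end - ex$start)
  }
  c(utr5 = off, cds = cds_len, utr3 = spliced_length(tm) - off - cds_len)
}

## Transcript-relative region of a 0-based position: 5UTR / CDS / 3UTR,
## or non_coding for transcripts without a CDS.
position_region <- function(tm, pos) {
  if (tm$biotype == "non_coding") return("non_coding")
  u <- utr_lengths(tm)
  if (pos < u["utr5"]) "5UTR" else if (pos < u["utr5"] + u["cds"]) "CDS" else "3UTR"
}

#' Convert between GTF (1-based inclusive) and internal (0-based half-open)
#' coordinates
#'
#' The two functions are mutual inverses.
#'
#' @param start,end interval bounds in the source convention.
#' @return data.frame with converted `start`, `end`.
#' @export
gtf_to_internal <- function(start, end) data.frame(start = start - 1L, end = end)

#' @rdname gtf_to_internal
#' @export
internal_to_gtf <- function(start, end) data.frame(start = start + 1L, end = end)
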