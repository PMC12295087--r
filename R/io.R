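#' Read transcript models from a GTF file
#'
#' Parses `exon` and `CDS` features (via [rtracklayer::import()]) into one
#' [transcript_model()] per `transcript_id`. GTF 1-based inclusive coordinates
#' are converted to the internal 0-based half-open convention and minus-strand
#' exons are reordered 5'→3' in transcript orientation. Transcripts with no
#' exon feature are skipped with a warning.
#'
#' @param path GTF file path.
#' @param sequences optional named character vector (e.g. from [read_fasta()])
#'   attaching spliced sequences by transcript id.
#' @return named list of `transcript_model` objects.
#' @export
read_gtf <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## cheap structural validation so malformed lines are reported by number;
  ## the actual parsing is rtracklayer's
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon/CDS features in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop("GTF features must carry transcript_id attributes")
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    biotype = if (!is.null(gr$transcript_biotype)) gr$transcript_biotype else NA_character_,
    stringsAsFactors = FALSE)

  models <- list()
  for (tx in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tx, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) {
      warning("transcript ", tx, " has zero exons; skipped")
      next
    }
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    seq <- if (!is.null(sequences) && tx %in% names(sequences)) sequences[[tx]] else NULL
    models[[tx]] <- transcript_model(
      transcript_id = tx, gene_id = ex$gene_id[1], chrom = ex$chrom[1],
      strand = ex$strand[1],
      exons = ex[, c("start", "end")],
      cds = if (nrow(cds)) cds[, c("start", "end")] else NULL,
      biotype = if (!is.na(ex$biotype[1])) ex$biotype[1] else NULL,
      sequence = seq)
  }
  models
}

#' Write transcript models to a GTF file
#'
#' Emits exon and CDS features with `gene_id`, `transcript_id` and
#' `transcript_biotype` attributes; internal 0-based half-open coordinates are
#' converted back to GTF 1-based inclusive. `read_gtf(write_gtf(models))`
#' reproduces the structural fields (exons, cds, strand, ids, biotype); domain
#' annotations and sequences are carried in their own files.
#'
#' @param models list of `transcript_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  rows <- lapply(models, function(tm) {
    feat <- rbind(
      cbind(tm$exons, type = "exon"),
      if (!is.null(tm$cds)) cbind(tm$cds, type = "CDS"))
    data.frame(chrom = tm$chrom, start = feat$start, end = feat$end,
               strand = tm$strand, type = feat$type, gene_id = tm$gene_id,
               transcript_id = tm$transcript_id, biotype = tm$biotype,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$source <- "ire1ridd"
  gr$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  gr$gene_id <- df$gene_id
  gr$transcript_id <- df$transcript_id
  gr$transcript_biotype <- df$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and U is normalized to T (one internal alphabet;
#' scanners treat sequences as the mRNA sense strand). Ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- normalize_seq(as.character(ss))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id: ", ids[nchar(seqs) == 0L][1])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Expression matrix with sample metadata
#'
#' Container for a features × samples abundance matrix (TPM or protein
#' abundance) with per-sample condition and optional batch labels.
#'
#' @param values numeric matrix, features in rows (rownames) and samples in
#'   columns (colnames); finite and non-negative.
#' @param condition character/factor of length `ncol(values)` with levels
#'   `control` and `disease` (any two labels accepted; the first sorted level
#'   is taken as reference unless a `control` level is present).
#' @param batch optional per-sample batch labels.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition, batch = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("negative values not allowed")
  if (length(condition) != ncol(values)) {
    stop("condition must have one label per sample")
  }
  if (anyNA(condition)) stop("every sample needs a condition label")
  lev <- unique(as.character(condition))
  if ("control" %in% lev) lev <- c("control", setdiff(lev, "control"))
  condition <- factor(as.character(condition), levels = lev)
  if (!is.null(batch)) {
    if (length(batch) != ncol(values)) stop("batch must have one label per sample")
    batch <- factor(as.character(batch))
  }
  structure(list(values = values, condition = condition, batch = batch),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", levels(x$condition), table(x$condition)),
                    collapse = ", "),
              if (is.null(x$batch)) "" else
                sprintf("; %d batch level(s)", nlevels(x$batch))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata from TSV files
#'
#' @param path TSV with feature ids in the first column and one column per
#'   sample.
#' @param metadata TSV with columns `sample_id`, `condition` and optionally
#'   `batch`. Samples must match the matrix columns as a set (extra metadata
#'   rows are dropped with a warning); metadata is reordered to the matrix
#'   column order.
#' @return an [expression_matrix()].
#' @export
read_matrix <- function(path, metadata) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(metadata)) stop("no such file: ", metadata)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("non-numeric or missing values in ", path)
  meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(meta))) {
    stop("metadata must have sample_id and condition columns")
  }
  missing <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing)) {
    stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(meta$sample_id, colnames(vals))
  if (length(extra)) {
    warning("metadata rows for unknown sample(s) ignored: ",
            paste(extra, collapse = ", "))
    meta <- meta[meta$sample_id %in% colnames(vals), , drop = FALSE]
  }
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
  expression_matrix(vals, meta$condition,
                    batch = if ("batch" %in% names(meta)) meta$batch else NULL)
}

#' Write an expression matrix and its metadata to TSV files
#' @param expr an [expression_matrix()].
#' @param path output TSV for the matrix.
#' @param metadata output TSV for sample metadata.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(expr, path, metadata) {
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(expr$values),
                     condition = as.character(expr$condition))
  if (!is.null(expr$batch)) meta$batch <- as.character(expr$batch)
  utils::write.table(meta, metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
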