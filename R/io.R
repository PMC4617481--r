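#' Read a GFF3 or GTF annotation into a transcript_set
#'
#' Parses exon features from a GFF3 or GTF file (via rtracklayer) and builds
#' the internal transcript models. File coordinates (1-based inclusive) are
#' converted to internal 0-based half-open intervals. For GFF3 input a gene
#' is flagged protein-coding when any of its transcripts carries a CDS
#' feature; for GTF input the optional `gene_biotype "protein_coding"`
#' attribute is honoured and genes default to non-coding.
#'
#' Transcripts without any exon feature are dropped with a warning.
#'
#' @param path path to a `.gff3`/`.gff` or `.gtf` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"gtf"`.
#' @return a [transcript_set()]
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gtf") "gtf" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  if (format == "gtf") {
    is_exon <- type == "exon"
    tx_id <- as.character(md$transcript_id)
    gene_id <- as.character(md$gene_id)
    coding <- character(0)
    if ("gene_biotype" %in% names(md)) {
      coding <- unique(gene_id[!is.na(md$gene_biotype) &
                                 md$gene_biotype == "protein_coding"])
    }
    ex <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
      start = GenomicRanges::start(gr)[is_exon] - 1L,
      end = GenomicRanges::end(gr)[is_exon],
      strand = as.character(GenomicRanges::strand(gr))[is_exon],
      transcript_id = tx_id[is_exon], gene_id = gene_id[is_exon],
      stringsAsFactors = FALSE)
    declared <- unique(stats::na.omit(tx_id[type %in%
                                              c("transcript", "mRNA")]))
  } else {
    id <- as.character(md$ID)
    parent <- vapply(as.list(md$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
    is_tx <- type %in% c("mRNA", "transcript", "ncRNA", "lnc_RNA")
    tx2gene <- stats::setNames(parent[is_tx], id[is_tx])
    is_exon <- type == "exon"
    tx_of_exon <- parent[is_exon]
    gene_of_exon <- unname(tx2gene[tx_of_exon])
    # exons attached directly to a gene (no transcript level)
    orphan <- is.na(gene_of_exon)
    gene_of_exon[orphan] <- tx_of_exon[orphan]
    coding_tx <- unique(parent[type == "CDS"])
    coding <- unique(stats::na.omit(unname(tx2gene[coding_tx])))
    ex <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
      start = GenomicRanges::start(gr)[is_exon] - 1L,
      end = GenomicRanges::end(gr)[is_exon],
      strand = as.character(GenomicRanges::strand(gr))[is_exon],
      transcript_id = tx_of_exon, gene_id = gene_of_exon,
      stringsAsFactors = FALSE)
    declared <- id[is_tx]
  }
  empty <- setdiff(declared, unique(ex$transcript_id))
  if (length(empty)) {
    warning("dropping ", length(empty),
            " transcript(s) with zero exons: ",
            paste(utils::head(empty, 5L), collapse = ", "))
  }
  ex$strand[ex$strand == "."] <- "*"
  transcript_set(ex, coding_genes = coding)
}

#' Write a transcript_set as GTF
#'
#' Emits one `exon` line per exon with `gene_id` and `transcript_id`
#' attributes (1-based inclusive coordinates). An optional named vector of
#' class codes is written as a `class_code` attribute.
#'
#' @param ts a [transcript_set()]
#' @param path output path
#' @param class_codes optional named character vector
#'   (names = transcript ids)
#' @param source source field (column 2)
#' @return `path`, invisibly
#' @export
write_gtf <- function(ts, path, class_codes = NULL, source = "lncsieve") {
  tr <- ts$transcripts
  lines <- character(0)
  for (i in seq_len(nrow(tr))) {
    id <- tr$transcript_id[i]
    m <- ts$exons[[id]]
    strand <- tr$strand[i]
    if (strand == "*") strand <- "."
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        tr$gene_id[i], id)
    if (!is.null(class_codes) && id %in% names(class_codes)) {
      attr_str <- paste0(attr_str,
                         sprintf(' class_code "%s";', class_codes[[id]]))
    }
    lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tr$chrom[i], source, m[, 1L] + 1L, m[, 2L],
                              strand, attr_str))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference annotation as GFF3
#'
#' Writes gene/mRNA/exon features (plus CDS features for transcripts listed
#' in `cds`) in 1-based inclusive coordinates.
#'
#' @param ts a [transcript_set()]
#' @param path output path
#' @param cds optional named list (by transcript id) of two-column 0-based
#'   half-open CDS interval matrices in genomic coordinates
#' @return `path`, invisibly
#' @export
write_gff3 <- function(ts, path, cds = NULL) {
  tr <- ts$transcripts
  sp <- gene_spans(ts)
  lines <- "##gff-version 3"
  for (g in seq_len(nrow(sp))) {
    st <- sp$strand[g]
    if (st == "*") st <- "."
    lines <- c(lines, sprintf(
      "%s\tlncsieve\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      sp$chrom[g], sp$start[g] + 1L, sp$end[g], st, sp$gene_id[g]))
    sub <- tr[tr$gene_id == sp$gene_id[g], , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      id <- sub$transcript_id[i]
      st_i <- sub$strand[i]
      if (st_i == "*") st_i <- "."
      ftype <- if (!is.null(cds) && id %in% names(cds)) "mRNA" else "transcript"
      lines <- c(lines, sprintf(
        "%s\tlncsieve\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        sub$chrom[i], ftype, sub$start[i] + 1L, sub$end[i], st_i, id,
        sp$gene_id[g]))
      m <- ts$exons[[id]]
      lines <- c(lines, sprintf(
        "%s\tlncsieve\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        sub$chrom[i], m[, 1L] + 1L, m[, 2L], st_i, id, seq_len(nrow(m)), id))
      if (!is.null(cds) && id %in% names(cds)) {
        cm <- cds[[id]]
        lines <- c(lines, sprintf(
          "%s\tlncsieve\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
          sub$chrom[i], cm[, 1L] + 1L, cm[, 2L], st_i, id,
          seq_len(nrow(cm)), id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export class codes as TSV
#'
#' @param codes named character vector of class codes (names = transcript
#'   ids)
#' @param ts the [transcript_set()] the codes refer to (for gene ids)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_class_codes <- function(codes, ts, path) {
  tr <- ts$transcripts
  df <- data.frame(transcript_id = tr$transcript_id, gene_id = tr$gene_id,
                   class_code = unname(codes[tr$transcript_id]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# FASTA helpers: thin wrappers over Biostrings, returning plain named
# character vectors which the string-level algorithms operate on.
#' @noRd
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @noRd
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' @noRd
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
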