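#' Transcript model container
#'
#' A `transcript_set` holds a collection of transcript models: per-transcript
#' metadata plus sorted exon intervals in internal 0-based half-open
#' coordinates. It is the common currency between the annotation reader, the
#' class-code assignment, the filter cascade and the synthetic-data
#' generator.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`, `"-"` or `"*"` for unknown),
#'   `transcript_id`, `gene_id`; one row per exon.
#' @param coding_genes character vector of gene ids flagged as
#'   protein-coding (used for reference annotations).
#' @return an object of class `transcript_set` with elements
#'   `transcripts` (data.frame: transcript_id, gene_id, chrom, strand,
#'   n_exons, start, end, exonic_length) and `exons` (named list of
#'   two-column start/end matrices), plus `coding_genes`.
#' @examples
#' ex <- data.frame(chrom = "chr1", start = c(100L, 300L), end = c(200L, 400L),
#'                  strand = "+", transcript_id = "t1", gene_id = "g1")
#' ts <- transcript_set(ex)
#' exonic_lengths(ts)
#' @export
transcript_set <- function(exons, coding_genes = character(0)) {
  stopifnot(is.data.frame(exons),
            all(c("chrom", "start", "end", "strand", "transcript_id",
                  "gene_id") %in% names(exons)))
  if (nrow(exons) == 0L) {
    obj <- list(
      transcripts = data.frame(transcript_id = character(0),
                               gene_id = character(0), chrom = character(0),
                               strand = character(0), n_exons = integer(0),
                               start = integer(0), end = integer(0),
                               exonic_length = integer(0),
                               stringsAsFactors = FALSE),
      exons = list(), coding_genes = coding_genes)
    class(obj) <- "transcript_set"
    return(obj)
  }
  if (any(exons$start < 0L) || any(exons$start >= exons$end)) {
    stop("invalid exon interval: need 0 <= start < end")
  }
  if (!all(exons$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  ex_list <- split(seq_len(nrow(exons)), exons$transcript_id)
  exon_mats <- vector("list", length(ex_list))
  names(exon_mats) <- names(ex_list)
  meta <- vector("list", length(ex_list))
  for (k in seq_along(ex_list)) {
    idx <- ex_list[[k]]
    sub <- exons[idx, , drop = FALSE]
    if (length(unique(sub$chrom)) != 1L || length(unique(sub$strand)) != 1L ||
        length(unique(sub$gene_id)) != 1L) {
      stop("transcript ", names(ex_list)[k],
           ": exons must share chrom, strand and gene_id")
    }
    m <- cbind(start = as.integer(sub$start), end = as.integer(sub$end))
    if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L] + 1L)) {
      stop("transcript ", names(ex_list)[k],
           ": exons must be non-overlapping and separated by >= 1 bp introns")
    }
    exon_mats[[k]] <- m
    meta[[k]] <- data.frame(
      transcript_id = names(ex_list)[k], gene_id = sub$gene_id[1L],
      chrom = sub$chrom[1L], strand = sub$strand[1L], n_exons = nrow(m),
      start = m[1L, 1L], end = m[nrow(m), 2L],
      exonic_length = sum(m[, 2L] - m[, 1L]), stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, meta)
  rownames(tr) <- NULL
  obj <- list(transcripts = tr, exons = exon_mats,
              coding_genes = unique(coding_genes))
  class(obj) <- "transcript_set"
  obj
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes,",
      length(x$coding_genes), "coding genes\n")
  invisible(x)
}

#' Exonic length of every transcript
#' @param ts a `transcript_set`
#' @return named integer vector of summed exon widths (bp)
#' @export
exonic_lengths <- function(ts) {
  stats::setNames(ts$transcripts$exonic_length, ts$transcripts$transcript_id)
}

#' Gene spans of a transcript set
#'
#' Collapses transcripts to per-gene genomic spans (0-based half-open),
#' used for neighbor finding and intergenic ("u") calls.
#'
#' @param ts a `transcript_set`
#' @return data.frame: gene_id, chrom, strand, start, end, coding
#' @export
gene_spans <- function(ts) {
  tr <- ts$transcripts
  if (nrow(tr) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), coding = logical(0)))
  }
  sp <- do.call(rbind, lapply(split(tr, tr$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               strand = g$strand[1L], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp$coding <- sp$gene_id %in% ts$coding_genes
  sp[order(sp$chrom, sp$start), , drop = FALSE]
}

# Subset a transcript_set by transcript ids.
#' @noRd
subset_transcripts <- function(ts, ids) {
  keep <- ts$transcripts$transcript_id %in% ids
  obj <- list(transcripts = ts$transcripts[keep, , drop = FALSE],
              exons = ts$exons[ts$transcripts$transcript_id[keep]],
              coding_genes = ts$coding_genes)
  rownames(obj$transcripts) <- NULL
  class(obj) <- "transcript_set"
  obj
}
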