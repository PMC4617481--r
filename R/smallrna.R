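# Small-RNA association: read filtering, perfect-match mapping to lncRNA
# sequences, multimapper removal, per-locus counting and the
# "> 10 mapped reads = generates small RNAs" call.

#' Filter and collapse small-RNA reads
#'
#' Keeps reads of 18-30 nt, drops non-ACGT reads (tallied as rejects),
#' drops low-complexity reads in which a tandem repeat of a 1-3 nt motif
#' covers at least 80 % of the read as one contiguous run, and collapses
#' identical reads into one record with a copy count. Copy counts already
#' present on the input (collapsed-FASTA `>id_count` dialect, see
#' [read_smallrna_fasta()]) are preserved and summed.
#'
#' @param raw_reads character vector of read sequences; an optional
#'   `copy_count` attribute-style numeric vector may be given via
#'   `copy_counts`
#' @param copy_counts per-read multiplicities (default 1)
#' @param min_len,max_len length window
#' @param simple_cov coverage fraction above which a tandem-repeat run
#'   classifies the read as a simple repeat
#' @return list with `reads` (data.frame: sequence, copy_count) and
#'   `rejects` (named integer vector: non_acgt, length, simple_repeat)
#' @export
filter_reads <- function(raw_reads, copy_counts = NULL, min_len = 18L,
                         max_len = 30L, simple_cov = 0.8) {
  if (is.null(copy_counts)) copy_counts <- rep(1L, length(raw_reads))
  stopifnot(length(copy_counts) == length(raw_reads))
  raw_reads <- toupper(raw_reads)
  rejects <- c(non_acgt = 0L, length = 0L, simple_repeat = 0L)
  ok_acgt <- !grepl("[^ACGT]", raw_reads)
  rejects["non_acgt"] <- sum(!ok_acgt)
  len <- nchar(raw_reads)
  ok_len <- len >= min_len & len <= max_len
  rejects["length"] <- sum(ok_acgt & !ok_len)
  keep <- ok_acgt & ok_len
  simple <- vapply(raw_reads[keep], is_simple_repeat, logical(1),
                   max_period = 3L, min_cov = simple_cov)
  rejects["simple_repeat"] <- sum(simple)
  seqs <- raw_reads[keep][!simple]
  cc <- copy_counts[keep][!simple]
  if (!length(seqs)) {
    return(list(reads = data.frame(sequence = character(0),
                                   copy_count = integer(0),
                                   stringsAsFactors = FALSE),
                rejects = rejects))
  }
  agg <- tapply(cc, seqs, sum)
  reads <- data.frame(sequence = names(agg),
                      copy_count = as.integer(agg),
                      stringsAsFactors = FALSE)
  reads <- reads[order(reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads, rejects = rejects)
}

# Longest contiguous run with period k covers >= min_cov of the read for
# some k <= max_period?
#' @noRd
is_simple_repeat <- function(s, max_period = 3L, min_cov = 0.8) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1L]]
  for (k in seq_len(min(max_period, n - 1L))) {
    eq <- ch[seq_len(n - k)] == ch[(k + 1L):n]
    r <- rle(eq)
    runs <- r$lengths[r$values]
    if (length(runs) && (max(runs) + k) / n >= min_cov) return(TRUE)
  }
  FALSE
}

#' Read a (possibly collapsed) small-RNA FASTA
#'
#' Headers of the form `>id_count` (count = trailing integer after the last
#' underscore) carry a collapsed multiplicity; other headers count once.
#'
#' @param path FASTA path
#' @return list with `sequences` and `copy_counts`
#' @export
read_smallrna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- names(x)
  cc <- suppressWarnings(as.integer(sub("^.*_(\\d+)$", "\\1", ids)))
  cc[!grepl("_\\d+$", ids) | is.na(cc)] <- 1L
  list(sequences = as.character(x), copy_counts = cc)
}

#' Map reads to lncRNA sequences by perfect match
#'
#' A read maps to a locus when the read or its reverse complement is an
#' exact substring of the lncRNA sequence; all loci per read are recorded.
#'
#' @param reads data.frame from [filter_reads()] (`sequence`, `copy_count`)
#' @param lncrna_sequences named character vector
#' @return list with `reads` (the input) and `loci` (list, per read, of
#'   matched lncRNA ids)
#' @export
map_perfect <- function(reads, lncrna_sequences) {
  subj <- unlist(lncrna_sequences)
  loci <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    pat <- reads$sequence[i]
    hit <- grepl(pat, subj, fixed = TRUE) |
      grepl(revcomp(pat), subj, fixed = TRUE)
    loci[[i]] <- names(subj)[hit]
  }
  list(reads = reads, loci = loci)
}

#' Remove multimapping reads
#'
#' Reads mapping to more than `max_loci` loci are removed entirely
#' (a read at exactly `max_loci` loci is kept).
#'
#' @param alignments result of [map_perfect()]
#' @param max_loci multimapper threshold
#' @return filtered alignments (same structure)
#' @export
multimap_filter <- function(alignments, max_loci = 20L) {
  keep <- vapply(alignments$loci, length, integer(1)) <= max_loci
  list(reads = alignments$reads[keep, , drop = FALSE],
       loci = alignments$loci[keep])
}

#' Per-lncRNA small-RNA association
#'
#' Sums mapped reads per lncRNA (copy-count-weighted by default; set
#' `weighted = FALSE` to count distinct collapsed reads) together with an
#' 18-30 nt read-length histogram, and calls a locus "generating" when its
#' mapped-read count is strictly greater than `min_reads` (a count of
#' exactly `min_reads` is not generating). Multimapped reads that survived
#' [multimap_filter()] contribute to every retained locus.
#'
#' @param alignments result of [map_perfect()] / [multimap_filter()]
#' @param lncrna_ids ids to report (loci with zero mapped reads included)
#' @param weighted use collapsed copy counts as weights
#' @param min_reads generating threshold (strict `>`)
#' @return data.frame: lncrna_id, mapped_read_count, generating, and
#'   columns `len18` ... `len30`
#' @export
associate_smallrna <- function(alignments, lncrna_ids, weighted = TRUE,
                               min_reads = 10L) {
  lens <- 18:30
  counts <- stats::setNames(numeric(length(lncrna_ids)), lncrna_ids)
  hist <- matrix(0, nrow = length(lncrna_ids), ncol = length(lens),
                 dimnames = list(lncrna_ids, paste0("len", lens)))
  reads <- alignments$reads
  for (i in seq_along(alignments$loci)) {
    loci <- intersect(alignments$loci[[i]], lncrna_ids)
    if (!length(loci)) next
    w <- if (weighted) reads$copy_count[i] else 1L
    counts[loci] <- counts[loci] + w
    lcol <- paste0("len", nchar(reads$sequence[i]))
    hist[loci, lcol] <- hist[loci, lcol] + w
  }
  out <- data.frame(lncrna_id = lncrna_ids,
                    mapped_read_count = unname(counts),
                    generating = unname(counts) > min_reads,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(hist, optional = TRUE))
}
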