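STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a nucleotide sequence for ORFs
#'
#' Finds every ATG-to-stop open reading frame in the three forward frames of
#' the given sequence and, with `strand_policy = "both"`, also in the three
#' frames of its reverse complement. An ORF requires both an ATG start and
#' an in-frame stop codon inside the sequence; each ATG is paired with the
#' nearest downstream in-frame stop. Codons containing `N` are neither
#' starts nor stops.
#'
#' @param sequence a single A/C/G/T/N string
#' @param strand_policy `"sense"` (forward frames only) or `"both"`
#' @return data.frame with columns `strand` (`"+"`/`"-"`), `frame` (0-2),
#'   `start`, `end` (0-based half-open offsets on the scanned orientation,
#'   ATG through stop codon inclusive) and `aa_len` (codons excluding the
#'   stop). For minus-strand hits the offsets refer to the
#'   reverse-complemented sequence.
#' @examples
#' scan_orfs("ATGAAATAG")
#' @export
scan_orfs <- function(sequence, strand_policy = c("sense", "both")) {
  strand_policy <- match.arg(strand_policy)
  empty <- data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_len = integer(0), stringsAsFactors = FALSE)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3L) return(empty)
  res <- list(scan_one_strand(sequence, "+"))
  if (strand_policy == "both") {
    res[[2L]] <- scan_one_strand(revcomp(sequence), "-")
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) empty else out
}

#' @noRd
scan_one_strand <- function(s, strand_label) {
  n <- nchar(s)
  hits <- list()
  for (frame in 0:2) {
    if (frame + 1L > n - 2L) next
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (!length(atg) || !length(stp)) next
    # nearest downstream in-frame stop for each ATG
    pos <- findInterval(atg, stp) + 1L
    ok <- pos <= length(stp)
    if (!any(ok)) next
    a <- atg[ok]
    st <- stp[pos[ok]]
    hits[[length(hits) + 1L]] <- data.frame(
      strand = strand_label, frame = frame,
      start = starts[a] - 1L, end = starts[st] + 2L,
      aa_len = st - a, stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

#' @noRd
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Translate an in-frame nucleotide string; codons containing N become "X".
#' @noRd
translate_nt <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  codons <- substring(s, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Call the coding potential of a transcript
#'
#' Labels a transcript `coding` or `noncoding`, either from an external
#' per-transcript coding-potential score table (noncoding when
#' `score < cutoff`, default cutoff -1) or from a transparent built-in ORF
#' heuristic (noncoding when the longest ORF is shorter than `orf_aa_max`
#' amino acids AND covers less than `orf_cov_max` of the transcript).
#'
#' Strand handling in heuristic mode: transcripts with a known strand are
#' evaluated on the sense strand only; unknown-strand transcripts are
#' evaluated in both orientations and labeled noncoding only when both
#' orientations are noncoding.
#'
#' @param transcript_id transcript identifier
#' @param sequence the transcript sequence (sense orientation when the
#'   strand is known)
#' @param strand `"+"`, `"-"` or `"*"` (unknown)
#' @param external_scores optional named numeric vector of external coding
#'   scores; when supplied the transcript must be present (a missing id is
#'   an error, never a silent fallback)
#' @param cutoff external-score noncoding cutoff (strict `<`)
#' @param orf_aa_max,orf_cov_max heuristic-mode thresholds
#' @return list with `transcript_id`, `mode` (`"external"`/`"heuristic"`),
#'   `label`, and either `score` or `aa_len`/`orf_coverage`
#' @export
coding_call <- function(transcript_id, sequence, strand = "*",
                        external_scores = NULL, cutoff = -1,
                        orf_aa_max = 100L, orf_cov_max = 0.5) {
  if (!is.null(external_scores)) {
    if (!transcript_id %in% names(external_scores)) {
      stop("transcript '", transcript_id,
           "' missing from the external coding-score table")
    }
    score <- unname(external_scores[[transcript_id]])
    return(list(transcript_id = transcript_id, mode = "external",
                score = score,
                label = if (score < cutoff) "noncoding" else "coding"))
  }
  orientations <- if (strand == "*") c("+", "-") else "+"
  worst_aa <- 0L
  worst_cov <- 0
  label <- "noncoding"
  for (o in orientations) {
    s <- if (o == "+") sequence else revcomp(sequence)
    orfs <- scan_orfs(s, "sense")
    aa <- if (nrow(orfs)) max(orfs$aa_len) else 0L
    cov <- if (nrow(orfs)) max(orfs$end - orfs$start) / nchar(sequence) else 0
    worst_aa <- max(worst_aa, aa)
    worst_cov <- max(worst_cov, cov)
    if (!(aa < orf_aa_max && cov < orf_cov_max)) label <- "coding"
  }
  list(transcript_id = transcript_id, mode = "heuristic",
       aa_len = worst_aa, orf_coverage = worst_cov, label = label)
}
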