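# Repeat-fraction classification: a simplified frequent-l-mer
# seed-and-extend de novo repeat finder plus library-based masking through
# the shared similarity engine, implementing the "< 10 % repetitive
# sequence = no repeat" rule.

#' De novo repeat discovery by frequent l-mer seed and extension
#'
#' Counts strand-collapsed (canonical) l-mers over the input sequences;
#' every l-mer occurring at least `min_count` times seeds a consensus that
#' is greedily extended left and right one base at a time while at least
#' half of the occurrences agree on the extended base. Overlapping consensi
#' are deduplicated: a seed already covered by (occurring within) a
#' previously built consensus is skipped.
#'
#' This is a deliberately transparent analog of heavier de novo repeat
#' finders, adequate for flagging interspersed elements in a candidate
#' transcript set; external repeat libraries remain first-class inputs of
#' [mask_fraction()].
#'
#' @param sequences named character vector
#' @param l seed length
#' @param min_count minimum occurrences for a seed
#' @return named character vector of consensus sequences (possibly empty),
#'   names `denovo_1`, `denovo_2`, ...
#' @export
find_denovo_repeats <- function(sequences, l = 16L, min_count = 10L) {
  if (!length(sequences) || sum(nchar(sequences)) < l) {
    return(stats::setNames(character(0), character(0)))
  }
  occ_seq <- integer(0)
  occ_pos <- integer(0)
  occ_kmer <- character(0)
  occ_rc <- logical(0)
  for (i in seq_along(sequences)) {
    n <- nchar(sequences[[i]])
    if (n < l) next
    starts <- seq_len(n - l + 1L)
    words <- substring(sequences[[i]], starts, starts + l - 1L)
    rcw <- revcomp(words)
    canon <- ifelse(words <= rcw, words, rcw)
    occ_seq <- c(occ_seq, rep(i, length(starts)))
    occ_pos <- c(occ_pos, starts)
    occ_kmer <- c(occ_kmer, canon)
    occ_rc <- c(occ_rc, words > rcw)
  }
  counts <- table(occ_kmer)
  seeds <- names(counts)[counts >= min_count]
  if (!length(seeds)) return(stats::setNames(character(0), character(0)))
  seeds <- seeds[order(-as.integer(counts[seeds]), seeds)]
  consensi <- character(0)
  for (sd in seeds) {
    if (length(consensi) &&
        any(vapply(consensi, function(cs) {
          grepl(sd, cs, fixed = TRUE) || grepl(revcomp(sd), cs, fixed = TRUE)
        }, logical(1)))) next
    sel <- which(occ_kmer == sd)
    cons <- extend_consensus(sequences, sd, occ_seq[sel], occ_pos[sel],
                             occ_rc[sel], l)
    consensi <- c(consensi, cons)
  }
  stats::setNames(consensi, paste0("denovo_", seq_along(consensi)))
}

# Greedy left/right extension of one seed's occurrence set. Occurrences
# where the canonical k-mer matched the reverse strand are walked in the
# opposite direction with complemented bases.
#' @noRd
extend_consensus <- function(sequences, seed, seq_i, pos, is_rc, l) {
  n_occ <- length(seq_i)
  oriented_base <- function(offset) {
    # base at oriented position `offset` relative to the seed (0 = first
    # seed base); NA when outside the sequence
    vapply(seq_len(n_occ), function(k) {
      s <- sequences[[seq_i[k]]]
      if (!is_rc[k]) {
        p <- pos[k] + offset
        if (p < 1L || p > nchar(s)) return(NA_character_)
        substr(s, p, p)
      } else {
        p <- pos[k] + (l - 1L) - offset
        if (p < 1L || p > nchar(s)) return(NA_character_)
        unname(COMPLEMENT[substr(s, p, p)])
      }
    }, character(1))
  }
  left <- character(0)
  off <- -1L
  repeat {
    b <- oriented_base(off)
    tab <- table(b[!is.na(b)])
    if (!length(tab) || max(tab) < n_occ / 2) break
    left <- c(names(tab)[which.max(tab)], left)
    off <- off - 1L
    if (length(left) > 5000L) break
  }
  right <- character(0)
  off <- l
  repeat {
    b <- oriented_base(off)
    tab <- table(b[!is.na(b)])
    if (!length(tab) || max(tab) < n_occ / 2) break
    right <- c(right, names(tab)[which.max(tab)])
    off <- off + 1L
    if (length(right) > 5000L) break
  }
  paste0(paste(left, collapse = ""), seed, paste(right, collapse = ""))
}

#' Mask a transcript against a repeat library
#'
#' Runs the shared [similarity_search()] engine (both strands) of the
#' transcript against every library consensus, keeps hits with raw score at
#' least `min_score`, merges the hit intervals on the transcript and
#' reports the masked fraction.
#'
#' @param sequence one transcript sequence
#' @param library named character vector of repeat consensi (de novo,
#'   external, or a concatenation of both)
#' @param min_score raw-score hit threshold (the 20-nt-exact equivalent by
#'   default)
#' @return list with `masked_intervals` (merged two-column matrix, 0-based
#'   half-open transcript coordinates) and `masked_fraction`
#' @export
mask_fraction <- function(sequence, library, min_score = 20) {
  n <- nchar(sequence)
  if (!length(library)) {
    return(list(masked_intervals = merge_intervals(NULL),
                masked_fraction = 0))
  }
  hits <- similarity_search(c(q = sequence), library, e_cutoff = Inf,
                            min_score = min_score)
  if (!nrow(hits)) {
    return(list(masked_intervals = merge_intervals(NULL),
                masked_fraction = 0))
  }
  # minus-strand hit coordinates refer to the reverse complement; map back
  qs <- ifelse(hits$strand == "+", hits$q_start, n - hits$q_end)
  qe <- ifelse(hits$strand == "+", hits$q_end, n - hits$q_start)
  merged <- merge_intervals(cbind(start = qs, end = qe))
  list(masked_intervals = merged,
       masked_fraction = interval_span(merged) / n)
}

#' Classify repeat association from a masked fraction
#'
#' `no_repeat` when the masked fraction is strictly below the threshold;
#' `repeat_associated` at or above it (a fraction of exactly 0.10 is
#' repeat-associated).
#'
#' @param masked_fraction value in `[0, 1]`
#' @param threshold classification threshold
#' @return `"no_repeat"` or `"repeat_associated"`
#' @export
classify_repeat_association <- function(masked_fraction, threshold = 0.10) {
  stopifnot(masked_fraction >= 0, masked_fraction <= 1)
  if (masked_fraction < threshold) "no_repeat" else "repeat_associated"
}
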