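# Ungapped seed-and-extend nucleotide similarity search with
# Karlin-Altschul-style E-values. This is the shared engine behind the
# housekeeping-RNA removal filter and library-based repeat masking; it is a
# deliberately small, self-contained analog of an ungapped blastn pass
# (exact-word seeding, X-drop extension, extreme-value significance), not a
# re-implementation of gapped BLAST.

#' Karlin-Altschul statistics for a match/mismatch scoring scheme
#'
#' Solves for the scale parameter lambda from
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` at the given background base
#' frequencies (bisection via [stats::uniroot()]), and estimates the
#' prefactor K from the stationary tail of the Lindley-recursion maximum of
#' the per-diagonal score walk: `P(M >= y) ~ K exp(-lambda y)`. Treating
#' every query/subject position pair as an independent diagonal start, the
#' expected number of alignments scoring at least S is then
#' `E = K * m * n * exp(-lambda * S)`. Counting all starts slightly
#' overstates the number of independent trials, so the E-value is
#' conservative (never too small).
#'
#' @param match,mismatch integer match reward and mismatch penalty
#' @param p_match background probability that two random bases match (1/4
#'   at uniform base frequencies)
#' @return list with `lambda` and `K`
#' @export
karlin_altschul_params <- function(match = 1, mismatch = -2,
                                   p_match = 0.25) {
  stopifnot(match > 0, mismatch < 0)
  f <- function(l) {
    p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  }
  lambda <- stats::uniroot(f, c(1e-8, 10), tol = 1e-12)$root
  # Lindley recursion: distribution of M_{t+1} = max(0, M_t + X) on a grid,
  # iterated to stationarity; X = +match w.p. p_match, mismatch otherwise.
  grid_max <- 120L
  pr <- c(1, rep(0, grid_max))            # P(M = 0..grid_max)
  for (iter in 1:4000) {
    new <- rep(0, grid_max + 1L)
    idx <- 0:grid_max
    up <- idx + match
    dn <- idx + mismatch
    up[up > grid_max] <- grid_max
    dn[dn < 0L] <- 0L
    for (k in seq_along(idx)) {
      new[up[k] + 1L] <- new[up[k] + 1L] + p_match * pr[k]
      new[dn[k] + 1L] <- new[dn[k] + 1L] + (1 - p_match) * pr[k]
    }
    if (max(abs(new - pr)) < 1e-14) { pr <- new; break }
    pr <- new
  }
  tail_p <- rev(cumsum(rev(pr)))          # P(M >= y)
  ys <- 20:40                              # well into the geometric tail
  K <- mean(tail_p[ys + 1L] * exp(lambda * ys))
  list(lambda = lambda, K = K)
}

#' Seed-and-extend similarity search
#'
#' Searches one or more queries (both strands) against a FASTA-style
#' subject library using exact `word_size`-mer seeds extended ungapped in
#' both directions under an X-drop rule. Hit significance is
#' `E = K * m * n * exp(-lambda * S)` with m the query length and n the
#' total library length; hits with `e_value < e_cutoff` are returned.
#'
#' @param queries named character vector of query sequences
#' @param subjects named character vector of subject sequences
#' @param word_size exact seed length
#' @param match,mismatch scoring scheme
#' @param xdrop stop extension when the running score falls this far below
#'   its maximum
#' @param e_cutoff E-value threshold (strict `<`); `Inf` returns all hits
#'   with score >= `min_score`
#' @param min_score optional raw-score floor applied after extension
#' @return data.frame: query_id, subject_id, strand (of the query),
#'   q_start, q_end, s_start, s_end (0-based half-open), score, e_value
#' @export
similarity_search <- function(queries, subjects, word_size = 11L,
                              match = 1, mismatch = -2, xdrop = 20,
                              e_cutoff = 0.001, min_score = 0) {
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      strand = character(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), score = numeric(0),
                      e_value = numeric(0), stringsAsFactors = FALSE)
  if (!length(subjects) || !length(queries)) return(empty)
  ka <- karlin_altschul_params(match, mismatch)
  n_db <- sum(nchar(subjects))
  sub_index <- lapply(subjects, index_words, w = word_size)
  out <- vector("list", 0L)
  for (qi in seq_along(queries)) {
    qname <- names(queries)[qi]
    for (qstrand in c("+", "-")) {
      qseq <- if (qstrand == "+") queries[[qi]] else revcomp(queries[[qi]])
      m <- nchar(qseq)
      if (m < word_size) next
      qwords <- substring(qseq, seq_len(m - word_size + 1L),
                          seq_len(m - word_size + 1L) + word_size - 1L)
      for (si in seq_along(subjects)) {
        hits <- extend_seeds(qseq, subjects[[si]], qwords, sub_index[[si]],
                             word_size, match, mismatch, xdrop)
        if (is.null(hits)) next
        hits$e_value <- ka$K * m * n_db * exp(-ka$lambda * hits$score)
        hits <- hits[hits$e_value < e_cutoff & hits$score >= min_score, ,
                     drop = FALSE]
        if (!nrow(hits)) next
        hits$query_id <- qname
        hits$subject_id <- names(subjects)[si]
        hits$strand <- qstrand
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[, c("query_id", "subject_id", "strand", "q_start", "q_end",
                 "s_start", "s_end", "score", "e_value")]
  rownames(res) <- NULL
  res
}

# Word -> positions lookup for one subject (1-based start positions).
#' @noRd
index_words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(list(words = character(0), pos = integer(0)))
  starts <- seq_len(n - w + 1L)
  words <- substring(s, starts, starts + w - 1L)
  split(starts, words)
}

# Extend all seed matches of one query (fixed orientation) against one
# subject; returns best hit per diagonal region or NULL.
#' @noRd
extend_seeds <- function(qseq, sseq, qwords, sindex, w, match, mismatch,
                         xdrop) {
  hit_q <- match(qwords, names(sindex))
  seed_qpos <- which(!is.na(hit_q))
  if (!length(seed_qpos)) return(NULL)
  qv <- charToRaw(qseq)
  sv <- charToRaw(sseq)
  m <- length(qv)
  n <- length(sv)
  done_diag <- new.env(hash = TRUE, parent = emptyenv())
  rows <- list()
  for (qp in seed_qpos) {
    for (sp in sindex[[hit_q[qp]]]) {
      diag_id <- as.character(qp - sp)
      covered <- get0(diag_id, envir = done_diag, ifnotfound = NULL)
      if (!is.null(covered) && qp >= covered[1L] && qp <= covered[2L]) next
      # right extension from the seed end
      len_r <- min(m - (qp + w - 1L), n - (sp + w - 1L))
      r_gain <- 0
      r_len <- 0L
      if (len_r > 0L) {
        eq <- qv[(qp + w):(qp + w - 1L + len_r)] ==
          sv[(sp + w):(sp + w - 1L + len_r)]
        sc <- cumsum(ifelse(eq, match, mismatch))
        run_max <- cummax(sc)
        stop_at <- which(run_max - sc >= xdrop)[1L]
        lim <- if (is.na(stop_at)) len_r else stop_at - 1L
        if (lim > 0L) {
          best <- which.max(sc[seq_len(lim)])
          if (sc[best] > 0) { r_gain <- sc[best]; r_len <- best }
        }
      }
      # left extension from the seed start
      len_l <- min(qp - 1L, sp - 1L)
      l_gain <- 0
      l_len <- 0L
      if (len_l > 0L) {
        eq <- qv[(qp - 1L):(qp - len_l)] == sv[(sp - 1L):(sp - len_l)]
        sc <- cumsum(ifelse(eq, match, mismatch))
        run_max <- cummax(sc)
        stop_at <- which(run_max - sc >= xdrop)[1L]
        lim <- if (is.na(stop_at)) len_l else stop_at - 1L
        if (lim > 0L) {
          best <- which.max(sc[seq_len(lim)])
          if (sc[best] > 0) { l_gain <- sc[best]; l_len <- best }
        }
      }
      score <- w * match + r_gain + l_gain
      q_start <- qp - l_len
      q_end <- qp + w - 1L + r_len
      assign(diag_id, c(q_start, q_end), envir = done_diag)
      rows[[length(rows) + 1L]] <- data.frame(
        q_start = q_start - 1L, q_end = q_end,
        s_start = sp - l_len - 1L, s_end = sp + w - 1L + r_len,
        score = score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
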