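# Internal interval arithmetic on 0-based half-open [start, end) integer
# intervals, stored as two-column matrices (start, end). All public
# coordinates in GTF/GFF3 files are 1-based inclusive; conversion happens at
# the I/O boundary only.

#' Merge overlapping or touching intervals
#'
#' @param mat two-column integer matrix of (start, end) pairs, 0-based
#'   half-open.
#' @return matrix with overlapping/adjacent intervals unioned, sorted by
#'   start.
#' @keywords internal
#' @noRd
merge_intervals <- function(mat) {
  if (is.null(mat) || nrow(mat) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  mat <- mat[order(mat[, 1L], mat[, 2L]), , drop = FALSE]
  out_s <- mat[1L, 1L]
  out_e <- mat[1L, 2L]
  res_s <- integer(0)
  res_e <- integer(0)
  if (nrow(mat) > 1L) {
    for (i in 2L:nrow(mat)) {
      if (mat[i, 1L] <= out_e) {
        out_e <- max(out_e, mat[i, 2L])
      } else {
        res_s <- c(res_s, out_s)
        res_e <- c(res_e, out_e)
        out_s <- mat[i, 1L]
        out_e <- mat[i, 2L]
      }
    }
  }
  res_s <- c(res_s, out_s)
  res_e <- c(res_e, out_e)
  cbind(start = res_s, end = res_e)
}

# Total bases covered by a (merged) interval set.
#' @noRd
interval_span <- function(mat) {
  if (nrow(mat) == 0L) return(0L)
  sum(mat[, 2L] - mat[, 1L])
}

# Width of base-level overlap between two interval sets (each a 2-col matrix).
#' @noRd
overlap_width <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    w <- pmin(a[i, 2L], b[, 2L]) - pmax(a[i, 1L], b[, 1L])
    tot <- tot + sum(w[w > 0L])
  }
  tot
}

# TRUE when two single intervals [s1,e1) and [s2,e2) share >= 1 base.
#' @noRd
overlaps1 <- function(s1, e1, s2, e2) {
  s1 < e2 && s2 < e1
}

# Introns implied by a sorted exon matrix: gaps between consecutive exons.
#' @noRd
intron_matrix <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = exons[seq_len(n - 1L), 2L], end = exons[2L:n, 1L])
}
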