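# Candidate target discovery by expression correlation: cis (10-kb
# neighbor) and trans (genome-wide) Pearson screens over tissue-averaged
# FPKM profiles, Student-t significance, and hub detection.

#' Pearson correlation of two tissue-averaged profiles
#'
#' A thin validating wrapper around [stats::cor()]: profiles must have
#' equal length >= 3 and non-zero variance (constant profiles are
#' undefined and an error; screening functions skip them).
#'
#' @param x,y numeric profiles
#' @return the correlation coefficient
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined for constant profiles")
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Student-t transform: `t = |r| sqrt(n - 2) / sqrt(1 - r^2)` referred to a
#' t distribution with `n - 2` degrees of freedom; `r = +/-1` gives p = 0.
#'
#' @param r correlation coefficient
#' @param n number of (tissue) observations
#' @return two-sided p-value
#' @export
cor_pvalue <- function(r, n) {
  stopifnot(n >= 3L, abs(r) <= 1 + 1e-12)
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0,
              2 * stats::pt(abs(r) * sqrt(n - 2) / sqrt(1 - r^2),
                            df = n - 2, lower.tail = FALSE))
  unname(p)
}

#' Cis correlation screen over neighbor pairs
#'
#' Correlates each lncRNA locus with its 10-kb protein-coding neighbors
#' (from [find_neighbors()]) over tissue-averaged FPKM and keeps pairs with
#' `|r|` strictly above the cutoff, split by sign. Pairs with a constant
#' profile on either side are skipped (and counted in the `skipped`
#' attribute).
#'
#' @param lnc_profiles,pc_profiles features x tissues matrices of
#'   tissue-averaged FPKM
#' @param neighbor_pairs data.frame from [find_neighbors()]
#' @param abs_r_cutoff strict absolute-correlation cutoff
#' @return data.frame: lncrna_id, pc_gene_id, side, r, p, relation
#'   (`"cis"`), sign (`"positive"`/`"negative"`)
#' @export
cis_screen <- function(lnc_profiles, pc_profiles, neighbor_pairs,
                       abs_r_cutoff = 0.5) {
  n_t <- ncol(lnc_profiles)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(neighbor_pairs))) {
    lid <- neighbor_pairs$lncrna_locus_id[i]
    gid <- neighbor_pairs$pc_gene_id[i]
    x <- lnc_profiles[lid, ]
    y <- pc_profiles[gid, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      skipped <- skipped + 1L
      next
    }
    r <- stats::cor(x, y)
    if (abs(r) > abs_r_cutoff) {
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lid, pc_gene_id = gid,
        side = neighbor_pairs$side[i], r = r, p = cor_pvalue(r, n_t),
        relation = "cis",
        sign = if (r > 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(0), pc_gene_id = character(0),
               side = character(0), r = numeric(0), p = numeric(0),
               relation = character(0), sign = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Trans correlation screen
#'
#' Correlates every lncRNA locus with every protein-coding gene except its
#' known 10-kb neighbors, over tissue-averaged FPKM, and preserves only
#' strongly negative pairs (`r` strictly below the cutoff, -0.7 by
#' default), with Student-t p-values. Computed blockwise to bound memory.
#'
#' @param lnc_profiles,pc_profiles features x tissues matrices
#' @param neighbor_pairs data.frame from [find_neighbors()]; these pairs
#'   are excluded from the candidate set
#' @param r_cutoff strict negative cutoff
#' @param block_size number of lncRNA rows correlated per block
#' @return data.frame: lncrna_id, pc_gene_id, r, p, relation (`"trans"`),
#'   sign (`"negative"`)
#' @export
trans_screen <- function(lnc_profiles, pc_profiles, neighbor_pairs,
                         r_cutoff = -0.7, block_size = 500L) {
  n_t <- ncol(lnc_profiles)
  excl <- paste(neighbor_pairs$lncrna_locus_id, neighbor_pairs$pc_gene_id)
  empty <- data.frame(lncrna_id = character(0), pc_gene_id = character(0),
                      r = numeric(0), p = numeric(0),
                      relation = character(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(lnc_profiles) == 0L || nrow(pc_profiles) == 0L) return(empty)
  sd_l <- apply(lnc_profiles, 1L, stats::sd)
  sd_p <- apply(pc_profiles, 1L, stats::sd)
  lnc_ok <- rownames(lnc_profiles)[sd_l > 0]
  pc_ok <- rownames(pc_profiles)[sd_p > 0]
  if (!length(lnc_ok) || !length(pc_ok)) return(empty)
  rows <- list()
  for (b in split(lnc_ok, ceiling(seq_along(lnc_ok) / block_size))) {
    cm <- stats::cor(t(lnc_profiles[b, , drop = FALSE]),
                     t(pc_profiles[pc_ok, , drop = FALSE]))
    hit <- which(cm < r_cutoff, arr.ind = TRUE)
    if (!nrow(hit)) next
    lid <- b[hit[, 1L]]
    gid <- pc_ok[hit[, 2L]]
    keep <- !(paste(lid, gid) %in% excl)
    if (!any(keep)) next
    r <- cm[hit][keep]
    rows[[length(rows) + 1L]] <- data.frame(
      lncrna_id = lid[keep], pc_gene_id = gid[keep], r = r,
      p = cor_pvalue(r, n_t), relation = "trans", sign = "negative",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(0), pc_gene_id = character(0),
               r = numeric(0), p = numeric(0), relation = character(0),
               sign = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect hub lncRNAs
#'
#' A hub is an lncRNA negatively correlated (trans pairs) with strictly
#' more than `min_targets` protein-coding genes. Hubs are ranked by target
#' count, ties broken by id.
#'
#' @param trans_pairs data.frame from [trans_screen()]
#' @param min_targets hub threshold (strict `>`: 11 targets qualify, 10 do
#'   not)
#' @return data.frame: lncrna_id, target_count, targets (comma-separated)
#' @export
find_hubs <- function(trans_pairs, min_targets = 10L) {
  if (!nrow(trans_pairs)) {
    return(data.frame(lncrna_id = character(0), target_count = integer(0),
                      targets = character(0), stringsAsFactors = FALSE))
  }
  tl <- split(trans_pairs$pc_gene_id, trans_pairs$lncrna_id)
  cnt <- vapply(tl, function(x) length(unique(x)), integer(1))
  keep <- cnt > min_targets
  out <- data.frame(
    lncrna_id = names(cnt)[keep], target_count = unname(cnt[keep]),
    targets = vapply(tl[keep], function(x)
      paste(sort(unique(x)), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$target_count, out$lncrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
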