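# Expression statistics: FPKM, the > 2 FPKM expressed filter, per-tissue
# Z-scores, Jensen-Shannon tissue specificity, pairwise differential
# expression between successive stages, distribution comparison, and qPCR
# relative quantification.

#' Construct a sample design
#'
#' @param samples data.frame with columns `sample`, `tissue`, `replicate`;
#'   the design must have exactly two replicates per tissue
#' @return validated design (class `sample_design`)
#' @export
sample_design <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "tissue", "replicate") %in% names(samples)))
  reps <- table(samples$tissue)
  if (any(reps != 2L)) {
    stop("design requires exactly 2 replicates per tissue; offending: ",
         paste(names(reps)[reps != 2L], collapse = ", "))
  }
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  samples <- samples[, c("sample", "tissue", "replicate")]
  class(samples) <- c("sample_design", "data.frame")
  samples
}

#' @noRd
design_tissues <- function(design) unique(design$tissue)

#' FPKM from a fragment-count matrix
#'
#' `fpkm[i, s] = counts[i, s] * 1e9 / (length_i * libsize_s)` with
#' `libsize_s` the column sum of counts. Satisfies the conservation
#' identity `sum_i fpkm * length * libsize / 1e9 = libsize` per sample.
#'
#' @param counts non-negative matrix (features x samples)
#' @param exonic_lengths named (or positionally matched) vector of feature
#'   lengths in bp, all > 0
#' @return FPKM matrix with the same dimnames
#' @export
fpkm <- function(counts, exonic_lengths) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (!is.null(names(exonic_lengths)) && !is.null(rownames(counts))) {
    exonic_lengths <- exonic_lengths[rownames(counts)]
  }
  stopifnot(length(exonic_lengths) == nrow(counts),
            all(exonic_lengths > 0))
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("zero library size in sample(s): ",
                              paste(colnames(counts)[libsize == 0],
                                    collapse = ", "))
  sweep(counts / exonic_lengths, 2L, libsize, "/") * 1e9
}

#' Tissue-averaged expression
#'
#' Averages the two replicates of every tissue.
#'
#' @param mat features x samples matrix (FPKM or counts)
#' @param design a [sample_design()]
#' @return features x tissues matrix
#' @export
tissue_mean <- function(mat, design) {
  tissues <- design_tissues(design)
  out <- matrix(NA_real_, nrow(mat), length(tissues),
                dimnames = list(rownames(mat), tissues))
  for (t in tissues) {
    cols <- design$sample[design$tissue == t]
    out[, t] <- rowMeans(mat[, cols, drop = FALSE])
  }
  out
}

#' Expressed-feature filter
#'
#' A feature is expressed when some tissue has FPKM strictly above the
#' threshold in BOTH replicates.
#'
#' @param fpkm_mat FPKM matrix (features x samples)
#' @param design a [sample_design()]
#' @param threshold FPKM threshold (strict `>`)
#' @return named logical vector
#' @export
expressed_filter <- function(fpkm_mat, design, threshold = 2) {
  tissues <- design_tissues(design)
  ok <- matrix(FALSE, nrow(fpkm_mat), length(tissues))
  for (k in seq_along(tissues)) {
    cols <- design$sample[design$tissue == tissues[k]]
    sub <- fpkm_mat[, cols, drop = FALSE]
    ok[, k] <- rowSums(sub > threshold) == length(cols)
  }
  stats::setNames(rowSums(ok) > 0, rownames(fpkm_mat))
}

#' Per-tissue expression Z-scores
#'
#' Replicates are averaged per tissue, then each feature's profile is
#' standardised across tissues (`(x - mean) / sd`, sample sd). Features
#' with zero variance get an all-zero row.
#'
#' @param fpkm_mat FPKM matrix (features x samples)
#' @param design a [sample_design()]
#' @return features x tissues Z-score matrix
#' @export
tissue_zscore <- function(fpkm_mat, design) {
  tm <- tissue_mean(fpkm_mat, design)
  mu <- rowMeans(tm)
  sd <- apply(tm, 1L, stats::sd)
  z <- (tm - mu) / sd
  z[sd == 0, ] <- 0
  z
}

#' Jensen-Shannon tissue-specificity score
#'
#' The tissue-averaged profile of each feature is normalised to a
#' probability vector p and compared with the single-tissue indicator
#' distribution of every tissue t: the specificity for t is
#' `1 - sqrt(JSD(p, e_t))`, with the Jensen-Shannon divergence taken in log
#' base 2 so it lives in `[0, 1]`. A feature expressed exclusively in one
#' tissue scores exactly 1 there. The maximum over tissues and the argmax
#' tissue are returned; all-zero profiles are undefined and reported NA.
#'
#' @param profiles features x tissues matrix of tissue-averaged expression
#'   (e.g. from [tissue_mean()])
#' @return data.frame: feature_id, js_score, js_tissue
#' @export
js_specificity <- function(profiles) {
  stopifnot(is.matrix(profiles))
  tissues <- colnames(profiles)
  n <- nrow(profiles)
  score <- rep(NA_real_, n)
  argt <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tot <- sum(profiles[i, ])
    if (!is.finite(tot) || tot <= 0) next
    p <- profiles[i, ] / tot
    s <- js_score_vs_indicators(p)
    j <- which.max(s)
    score[i] <- s[j]
    argt[i] <- tissues[j]
  }
  data.frame(feature_id = rownames(profiles), js_score = score,
             js_tissue = argt, stringsAsFactors = FALSE)
}

# Specificity scores of a probability vector against every single-tissue
# indicator. With m = (p + e_t)/2, the divergence collapses to a closed
# form in p_t:
#   JSD_t = 0.5 * [ (1 - p_t) + p_t * log2(2 p_t / (1 + p_t)) ]
#         + 0.5 * [ -log2((1 + p_t) / 2) ]
# (terms with p_i = 0 contribute 0).
#' @noRd
js_score_vs_indicators <- function(p) {
  pt <- p
  term_p <- (1 - pt) + ifelse(pt > 0, pt * log2(2 * pt / (1 + pt)), 0)
  term_e <- -log2((1 + pt) / 2)
  jsd <- 0.5 * term_p + 0.5 * term_e
  jsd[jsd < 0] <- 0      # numeric guard
  1 - sqrt(jsd)
}

#' Successive-stage comparisons implied by tissue names
#'
#' Tissues named `<type>_<stage>` (stage an integer) yield one comparison
#' per consecutive stage pair within each type.
#'
#' @param design a [sample_design()]
#' @return data.frame: tissue_a, tissue_b
#' @export
successive_stage_comparisons <- function(design) {
  tissues <- design_tissues(design)
  parts <- regmatches(tissues, regexec("^(.*)_(\\d+)$", tissues))
  ok <- lengths(parts) == 3L
  df <- data.frame(tissue = tissues[ok],
                   type = vapply(parts[ok], `[`, "", 2L),
                   stage = as.integer(vapply(parts[ok], `[`, "", 3L)),
                   stringsAsFactors = FALSE)
  out <- list()
  for (ty in unique(df$type)) {
    sub <- df[df$type == ty, ]
    sub <- sub[order(sub$stage), ]
    if (nrow(sub) < 2L) next
    out[[ty]] <- data.frame(tissue_a = sub$tissue[-nrow(sub)],
                            tissue_b = sub$tissue[-1L],
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(tissue_a = character(0), tissue_b = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise differential expression
#'
#' For each comparison (two tissues, two replicates each) the test operates
#' on `log2(FPKM + 1)`. The per-feature within-group variance is stabilised
#' by taking the maximum of the feature's own pooled variance, the mean
#' pooled variance across all features in the comparison, and a fixed
#' floor; with only two replicates per side a purely per-feature variance
#' has 2 degrees of freedom and essentially no resolving power, so the
#' cross-feature pooling carries the degrees of freedom (the reference
#' distribution is t with the summed residual df). Fold change is computed
#' on `(mean FPKM + 1)` to stabilise zeros; q-values are Benjamini-Hochberg
#' within each comparison; a feature is differentially expressed when
#' `q < q_max` and its fold change exceeds `fc_min` in either direction
#' (strict).
#'
#' @param fpkm_mat FPKM matrix (features x samples)
#' @param design a [sample_design()]
#' @param comparisons data.frame with columns `tissue_a`, `tissue_b`
#' @param q_max,fc_min significance and fold-change thresholds
#' @param var_floor variance floor on the log2 scale
#' @return data.frame: feature_id, comparison, log2fc, t, p, q, is_de
#' @export
pairwise_de <- function(fpkm_mat, design, comparisons, q_max = 0.01,
                        fc_min = 2, var_floor = 0.01) {
  res <- list()
  for (ci in seq_len(nrow(comparisons))) {
    ta <- comparisons$tissue_a[ci]
    tb <- comparisons$tissue_b[ci]
    if (!all(c(ta, tb) %in% design$tissue)) {
      stop("comparison references unknown tissue: ", ta, " vs ", tb)
    }
    ca <- design$sample[design$tissue == ta]
    cb <- design$sample[design$tissue == tb]
    ya <- log2(fpkm_mat[, ca, drop = FALSE] + 1)
    yb <- log2(fpkm_mat[, cb, drop = FALSE] + 1)
    ma <- rowMeans(ya)
    mb <- rowMeans(yb)
    va <- apply(ya, 1L, stats::var)
    vb <- apply(yb, 1L, stats::var)
    vg <- (va + vb) / 2
    vstar <- pmax(vg, mean(vg, na.rm = TRUE), var_floor)
    tstat <- (ma - mb) / sqrt(vstar)
    df_total <- 2L * nrow(fpkm_mat)
    p <- 2 * stats::pt(-abs(tstat), df = df_total)
    q <- stats::p.adjust(p, method = "BH")
    fa <- rowMeans(fpkm_mat[, ca, drop = FALSE]) + 1
    fb <- rowMeans(fpkm_mat[, cb, drop = FALSE]) + 1
    fc <- fa / fb
    res[[ci]] <- data.frame(
      feature_id = rownames(fpkm_mat),
      comparison = paste0(ta, "_vs_", tb),
      log2fc = log2(fc), t = tstat, p = p, q = q,
      is_de = q < q_max & (fc > fc_min | fc < 1 / fc_min),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic Kolmogorov p-value
#' (delegated to [stats::ks.test()]).
#'
#' @param a,b numeric samples
#' @return list with `D` and `p`
#' @export
ks_two_sample <- function(a, b) {
  k <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(k$statistic), p = unname(k$p.value))
}

#' Pfaffl relative expression (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_reference` per sample,
#' `ddCt = dCt_sample - dCt_calibrator`, fold = `2^-ddCt`.
#'
#' @param ct_target,ct_reference named numeric vectors of Ct values over
#'   the same samples
#' @param calibrator_sample name (or index) of the calibrator sample
#' @return named numeric vector of fold changes (calibrator = 1)
#' @export
pfaffl_relative_expression <- function(ct_target, ct_reference,
                                       calibrator_sample) {
  stopifnot(length(ct_target) == length(ct_reference))
  dct <- ct_target - ct_reference
  ddct <- dct - dct[[calibrator_sample]]
  out <- 2^(-ddct)
  names(out) <- names(ct_target)
  out
}
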