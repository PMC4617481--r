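# Shared builders and independent oracles for the test suite.

# quick transcript_set builder: exons given as list of 2-col matrices
make_ts <- function(exon_list, chrom = "chr1", strand = "+",
                    gene_ids = NULL, coding = character(0)) {
  ids <- names(exon_list)
  if (is.null(ids)) ids <- paste0("t", seq_along(exon_list))
  if (is.null(gene_ids)) gene_ids <- sub("^t", "g", ids)
  strand <- rep_len(strand, length(exon_list))
  chrom <- rep_len(chrom, length(exon_list))
  rows <- lapply(seq_along(exon_list), function(i) {
    m <- exon_list[[i]]
    data.frame(chrom = chrom[i], start = m[, 1], end = m[, 2],
               strand = strand[i], transcript_id = ids[i],
               gene_id = gene_ids[i], stringsAsFactors = FALSE)
  })
  transcript_set(do.call(rbind, rows), coding_genes = coding)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# ---------------------------------------------------------------------
# Independent brute-force class-code oracle. Works on per-base occupancy
# vectors over a small chromosome and re-derives introns from run-length
# encodings, following the documented priority ladder.
oracle_class_code <- function(q, refs, chrom_len = 1000L) {
  base_mask <- function(ex) {
    v <- logical(chrom_len)
    for (i in seq_len(nrow(ex))) v[(ex[i, 1] + 1L):ex[i, 2]] <- TRUE
    v
  }
  intron_runs <- function(ex) {
    span <- logical(chrom_len)
    span[(ex[1, 1] + 1L):ex[nrow(ex), 2]] <- TRUE
    intr <- span & !base_mask(ex)
    r <- rle(intr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values] - 1L, end = ends[r$values])
  }
  compat <- function(a, b) a == "*" || b == "*" || a == b
  qm <- base_mask(q$exons)
  q_introns <- intron_runs(q$exons)
  q_junc <- if (nrow(q_introns)) paste(q_introns[, 1], q_introns[, 2])
            else character(0)
  # "="
  for (r in refs) {
    if (!compat(q$strand, r$strand)) next
    if (nrow(q$exons) == 1 && nrow(r$exons) == 1) {
      if (all(q$exons == r$exons)) return("=")
    } else if (nrow(q$exons) > 1) {
      ri <- intron_runs(r$exons)
      rj <- if (nrow(ri)) paste(ri[, 1], ri[, 2]) else character(0)
      if (length(rj) == length(q_junc) && all(rj == q_junc)) return("=")
    }
  }
  # "j"
  if (length(q_junc) && q$strand != "*") {
    for (r in refs) {
      if (r$strand != q$strand) next
      ri <- intron_runs(r$exons)
      rj <- if (nrow(ri)) paste(ri[, 1], ri[, 2]) else character(0)
      if (any(q_junc %in% rj)) return("j")
    }
  }
  sense <- FALSE
  anti <- FALSE
  for (r in refs) {
    if (any(qm & base_mask(r$exons))) {
      if (q$strand != "*" && r$strand != "*" && q$strand != r$strand) {
        anti <- TRUE
      } else {
        sense <- TRUE
      }
    }
  }
  if (sense) return("o")
  if (anti) return("x")
  qlo <- min(which(qm)) - 1L
  qhi <- max(which(qm))
  for (r in refs) {
    ri <- intron_runs(r$exons)
    if (nrow(ri) && any(ri[, 1] <= qlo & qhi <= ri[, 2])) return("i")
  }
  "u"
}

# random sorted exon structure inside [lo, hi)
rand_exons <- function(lo, hi, max_exons = 3L) {
  repeat {
    n <- sample.int(max_exons, 1L)
    cuts <- sort(sample(seq.int(lo, hi), 2L * n))
    m <- cbind(start = cuts[seq(1, 2 * n, 2)], end = cuts[seq(2, 2 * n, 2)])
    ok <- all(m[, 2] > m[, 1]) &&
      (n == 1 || all(m[-1, 1] >= m[-n, 2] + 2L))
    if (ok) return(m)
  }
}

# one fuzzed query/reference instance on a toy chromosome
rand_classcode_case <- function(chrom_len = 1000L) {
  n_ref <- sample.int(2L, 1L)
  refs <- lapply(seq_len(n_ref), function(i) {
    list(exons = rand_exons(0L, chrom_len - 2L),
         strand = sample(c("+", "-"), 1L))
  })
  mode <- sample(c("free", "copy", "share_junction"), 1L,
                 prob = c(0.6, 0.2, 0.2))
  r1 <- refs[[1L]]
  if (mode == "copy") {
    q <- list(exons = r1$exons,
              strand = sample(c(r1$strand, "*", "+", "-"), 1L))
  } else if (mode == "share_junction" && nrow(r1$exons) > 1L) {
    ex <- r1$exons
    ex[1L, 1L] <- max(0L, ex[1L, 1L] - sample.int(20L, 1L))
    keep <- seq_len(sample.int(nrow(ex), 1L))
    q <- list(exons = ex[keep, , drop = FALSE], strand = r1$strand)
  } else {
    q <- list(exons = rand_exons(0L, chrom_len - 2L),
              strand = sample(c("+", "-", "*"), 1L))
  }
  list(query = q, refs = refs)
}

# package-side evaluation of a fuzz case
package_class_code <- function(case) {
  refs_df <- do.call(rbind, lapply(seq_along(case$refs), function(i) {
    r <- case$refs[[i]]
    data.frame(chrom = "chr1", start = r$exons[, 1], end = r$exons[, 2],
               strand = r$strand, transcript_id = paste0("r", i),
               gene_id = paste0("rg", i), stringsAsFactors = FALSE)
  }))
  idx <- classcode_index(transcript_set(refs_df))
  assign_class_code(list(chrom = "chr1", strand = case$query$strand,
                         exons = case$query$exons), idx)
}

# ---------------------------------------------------------------------
# Cached synthetic fixture + pipeline run (built once per test session).
fixture_env <- new.env()

get_fixture <- function() {
  if (!is.null(fixture_env$fx)) return(fixture_env$fx)
  dir_sim <- file.path(tempdir(), "lncsieve_fixture")
  dir_out <- file.path(tempdir(), "lncsieve_pipeout")
  cfg <- simulate_config(seed = 20240915)
  sim <- simulate_dataset(cfg, dir_sim)
  inputs <- as.list(sim$paths[c("reference", "assembled", "transcripts",
                                "housekeeping", "mirna", "motifs",
                                "repeat_library", "counts", "design",
                                "smallrna")])
  res <- run_pipeline(inputs, dir_out)
  fixture_env$fx <- list(cfg = cfg, sim = sim, inputs = inputs,
                         res = res, dir_sim = dir_sim, dir_out = dir_out)
  fixture_env$fx
}
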