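# Expression and small-RNA layers of the synthetic dataset, plus the
# top-level writer that emits every file the pipeline consumes together
# with the ground-truth manifest.

#' Generate the planted expression matrix
#'
#' Builds the 37-tissue x 2-replicate design and a fragment-count matrix
#' over all planted features (protein-coding genes and assembled loci).
#' Tissue-mean intensities follow log-normal baselines with log-normal
#' tissue variation; tissue-exclusive lncRNAs get exactly zero intensity
#' outside their hot tissue; cis pairs and trans hubs are planted through
#' shared latent tissue factors with exact-sample-correlation loadings
#' ([latent_correlated_profiles()]); counts are negative binomial at the
#' configured dispersion with per-sample library-size factors. FPKM is
#' never generated directly — it derives downstream via [fpkm()].
#'
#' @param cfg a [simulate_config()]
#' @param plan the `plan` element of [generate_genome_and_annotation()]
#' @return list with `counts` (integer matrix features x samples),
#'   `design` ([sample_design()]), `lengths` (named bp vector) and
#'   `intensity` (the planted tissue-mean intensity matrix)
#' @export
generate_expression <- function(cfg, plan) {
  set.seed(cfg$seed + 1L)
  tissues <- all_tissues(cfg)
  n_t <- length(tissues)
  design <- sample_design(data.frame(
    sample = paste0(rep(tissues, each = cfg$replicates), "_r",
                    seq_len(cfg$replicates)),
    tissue = rep(tissues, each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), n_t),
    stringsAsFactors = FALSE))

  lnc <- plan$lnc
  pc <- plan$pc
  feat <- c(pc$gene_id, lnc$locus_id)
  lengths <- stats::setNames(c(pc$length, lnc$length), feat)
  FF <- matrix(0, length(feat), n_t, dimnames = list(feat, tissues))

  # independent baselines
  for (i in seq_len(nrow(pc))) {
    base <- exp(stats::rnorm(1L, log(cfg$pc_base_fpkm), 0.4))
    FF[pc$gene_id[i], ] <- base * exp(stats::rnorm(n_t, 0,
                                                   cfg$tissue_noise_sd))
  }
  for (i in seq_len(nrow(lnc))) {
    row <- lnc[i, ]
    FF[row$locus_id, ] <- switch(
      row$role,
      exclusive = {
        v <- numeric(n_t)
        v[match(row$exclusive_tissue, tissues)] <- cfg$exclusive_hot_fpkm
        v
      },
      low = cfg$low_fpkm * exp(stats::rnorm(n_t, 0, 0.1)),
      # cis/hub latent profiles are overwritten below
      exp(stats::rnorm(1L, log(cfg$lnc_base_fpkm), 0.3)) *
        exp(stats::rnorm(n_t, 0, cfg$tissue_noise_sd)))
  }

  latent_profile <- function(z, base) pmax(base * (1 + cfg$corr_cv * z),
                                           0.02 * base)
  # cis pairs: lncRNA anchor, partner gene at the target correlation
  for (ci in seq_len(cfg$n_cis)) {
    lp <- latent_correlated_profiles(n_t, cfg$cis_target_r[ci])
    lid <- lnc$locus_id[!is.na(lnc$cis_index) & lnc$cis_index == ci]
    gid <- pc$gene_id[!is.na(pc$cis_index) & pc$cis_index == ci]
    FF[lid, ] <- latent_profile(lp$anchor, cfg$corr_lnc_base_fpkm)
    FF[gid, ] <- latent_profile(lp$partners[1L, ], cfg$pc_base_fpkm)
  }
  # hubs: lncRNA anchor, every target at the (negative) target correlation
  for (h in seq_along(cfg$hub_targets)) {
    gids <- pc$gene_id[!is.na(pc$hub_index) & pc$hub_index == h]
    lp <- latent_correlated_profiles(
      n_t, rep(cfg$hub_target_r, length(gids)))
    lid <- lnc$locus_id[!is.na(lnc$hub_index) & lnc$hub_index == h]
    FF[lid, ] <- latent_profile(lp$anchor, cfg$corr_lnc_base_fpkm)
    for (k in seq_along(gids)) {
      FF[gids[k], ] <- latent_profile(lp$partners[k, ],
                                      cfg$hub_target_fpkm)
    }
  }

  libsize <- stats::runif(nrow(design), cfg$library_size_range[1L],
                          cfg$library_size_range[2L])
  counts <- matrix(0L, length(feat), nrow(design),
                   dimnames = list(feat, design$sample))
  for (s in seq_len(nrow(design))) {
    mu <- FF[, design$tissue[s]] * lengths
    mu <- mu * libsize[s] / sum(mu)    # calibrate to the library size
    counts[, s] <- stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$nb_dispersion)
  }
  list(counts = counts, design = design, lengths = lengths,
       intensity = FF)
}

#' Generate the planted small-RNA read set
#'
#' Source loci emit collapsed reads (copy-weighted total
#' `reads_per_source`, the majority 21 nt) drawn as exact substrings of
#' their transcript; the background contributes multimapping reads drawn
#' from the shared repeat element (present in > 20 repeat-associated
#' loci), low-complexity reads, out-of-range lengths, a non-ACGT read and
#' unmappable random reads. Every emitted source read is checked to map
#' only to its source locus.
#'
#' @param cfg a [simulate_config()]
#' @param plan generator plan
#' @param sequences assembled transcript sequences
#' @param libraries generator libraries (for the repeat element)
#' @return data.frame: read_id, sequence, copy_count, label, source_locus
#' @export
generate_smallrna <- function(cfg, plan, sequences, libraries) {
  set.seed(cfg$seed + 2L)
  lnc <- plan$lnc
  surv <- lnc[lnc$survives, ]
  surv_seqs <- sequences[surv$transcript_id]
  names(surv_seqs) <- surv$locus_id
  src <- surv$locus_id[surv$smallrna_source]
  rows <- list()
  emit <- function(sequence, copy, label, source = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sequence = sequence, copy_count = copy, label = label,
      source_locus = source, stringsAsFactors = FALSE)
  }
  # copy plan per source: 12 x 21-nt reads carrying most copies + 8 others
  copies21 <- c(3L, 2L, 2L, 2L, rep(1L, 8L))
  other_len <- c(19L, 20L, 22L, 22L, 23L, 24L, 20L, 24L)
  stopifnot(sum(copies21) + length(other_len) == cfg$reads_per_source)
  for (locus in src) {
    s <- surv_seqs[[locus]]
    lens <- c(rep(21L, length(copies21)), other_len)
    cps <- c(copies21, rep(1L, length(other_len)))
    taken <- character(0)
    for (k in seq_along(lens)) {
      for (try in seq_len(80L)) {
        at <- sample.int(nchar(s) - lens[k] + 1L, 1L)
        rd <- substr(s, at, at + lens[k] - 1L)
        n_hits <- sum(vapply(surv_seqs, function(x)
          grepl(rd, x, fixed = TRUE) || grepl(revcomp(rd), x, fixed = TRUE),
          logical(1)))
        if (n_hits == 1L && !is_simple_repeat(rd) && !(rd %in% taken)) break
        if (try == 80L) stop("could not place a unique source read")
      }
      taken <- c(taken, rd)
      emit(rd, cps[k], "source", locus)
    }
  }
  element <- libraries$repeat_element[[1L]]
  emit(substr(element, 11L, 32L), 4L, "multimapper")
  emit(substr(element, 61L, 81L), 2L, "multimapper")
  emit(strrep("A", 21L), 5L, "low_complexity")
  emit(strrep("AT", 11L), 1L, "low_complexity")
  emit(strrep("CAG", 7L), 1L, "low_complexity")
  emit(random_dna(17L), 2L, "too_short")
  emit(random_dna(31L), 1L, "too_long")
  emit(paste0(random_dna(10L), "N", random_dna(10L)), 1L, "non_acgt")
  for (k in seq_len(10L)) {
    for (try in seq_len(40L)) {
      rd <- random_dna(sample(18:26, 1L))
      hit <- any(vapply(surv_seqs, function(x)
        grepl(rd, x, fixed = TRUE) || grepl(revcomp(rd), x, fixed = TRUE),
        logical(1)))
      if (!hit) break
    }
    emit(rd, 1L, "unmapped")
  }
  out <- do.call(rbind, rows)
  out$read_id <- sprintf("sr%04d_%d", seq_len(nrow(out)), out$copy_count)
  out[, c("read_id", "sequence", "copy_count", "label", "source_locus")]
}

#' Write a complete synthetic dataset with ground truth
#'
#' Runs [generate_genome_and_annotation()], [generate_expression()] and
#' [generate_smallrna()] and writes every file the pipeline consumes:
#' `genome.fasta`, `reference.gff3`, `assembled.gtf`, `transcripts.fasta`,
#' the library FASTAs (`housekeeping.fasta`, `mirna.fasta`,
#' `motifs.fasta`, `repeat_library.fasta`), `counts.tsv`, `design.tsv`,
#' `smallrna_reads.fasta` (collapsed `>id_count` dialect),
#' `cpc_scores.tsv` (planted external coding scores) and the ground-truth
#' `manifest.json`.
#'
#' @param cfg a [simulate_config()]
#' @param outdir output directory (created if needed)
#' @return invisibly, a list with the in-memory dataset (`genome_ann`,
#'   `expression`, `smallrna`, `manifest`) and `paths`
#' @export
simulate_dataset <- function(cfg = simulate_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ga <- generate_genome_and_annotation(cfg)
  expr <- generate_expression(cfg, ga$plan)
  sr <- generate_smallrna(cfg, ga$plan, ga$sequences, ga$libraries)

  p <- function(f) file.path(outdir, f)
  write_fasta(ga$genome, p("genome.fasta"))
  write_gff3(ga$reference, p("reference.gff3"), cds = ga$cds)
  write_gtf(ga$assembled, p("assembled.gtf"))
  write_fasta(ga$sequences, p("transcripts.fasta"))
  write_fasta(ga$libraries$housekeeping, p("housekeeping.fasta"))
  write_fasta(ga$libraries$mirna, p("mirna.fasta"))
  writeLines(paste0(">", names(ga$libraries$motifs), "\n",
                    ga$libraries$motifs), p("motifs.fasta"))
  write_fasta(ga$libraries$repeat_element, p("repeat_library.fasta"))
  cnt <- data.frame(feature_id = rownames(expr$counts), expr$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cnt, p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(expr$design), p("design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", sr$read_id, "\n", sr$sequence),
             p("smallrna_reads.fasta"))
  scores <- planted_coding_scores(ga$plan$lnc)
  utils::write.table(scores, p("cpc_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- build_manifest(cfg, ga$plan)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genome_ann = ga, expression = expr, smallrna = sr,
                 manifest = manifest,
                 paths = stats::setNames(
                   file.path(outdir,
                             c("genome.fasta", "reference.gff3",
                               "assembled.gtf", "transcripts.fasta",
                               "housekeeping.fasta", "mirna.fasta",
                               "motifs.fasta", "repeat_library.fasta",
                               "counts.tsv", "design.tsv",
                               "smallrna_reads.fasta", "cpc_scores.tsv",
                               "manifest.json")),
                   c("genome", "reference", "assembled", "transcripts",
                     "housekeeping", "mirna", "motifs", "repeat_library",
                     "counts", "design", "smallrna", "cpc_scores",
                     "manifest"))))
}

# External-mode coding scores consistent with the planted labels.
#' @noRd
planted_coding_scores <- function(lnc) {
  score <- rep(-2.5, nrow(lnc))
  score[lnc$role == "decoy_coding"] <- 2.0
  score[lnc$role == "ref_match"] <- 3.0
  data.frame(transcript_id = lnc$transcript_id, score = score,
             stringsAsFactors = FALSE)
}

#' @noRd
build_manifest <- function(cfg, plan) {
  lnc <- plan$lnc
  pc <- plan$pc
  cis <- lapply(seq_len(cfg$n_cis), function(ci) {
    list(lncrna_id = lnc$locus_id[!is.na(lnc$cis_index) &
                                    lnc$cis_index == ci],
         pc_gene_id = pc$gene_id[!is.na(pc$cis_index) &
                                   pc$cis_index == ci],
         target_r = cfg$cis_target_r[ci],
         detectable = abs(cfg$cis_target_r[ci]) > 0.5)
  })
  hubs <- lapply(seq_along(cfg$hub_targets), function(h) {
    list(lncrna_id = lnc$locus_id[!is.na(lnc$hub_index) &
                                    lnc$hub_index == h],
         target_r = cfg$hub_target_r,
         targets = pc$gene_id[!is.na(pc$hub_index) & pc$hub_index == h])
  })
  list(seed = cfg$seed,
       n_tissues = length(all_tissues(cfg)),
       features = lnc[, c("transcript_id", "locus_id", "chrom",
                          "class_code", "strand", "role", "length",
                          "survives", "removed_by", "repeat_class",
                          "smallrna_source", "generating", "expressed",
                          "exclusive_tissue", "hc")],
       pc_genes = pc[, c("gene_id", "chrom", "role", "length")],
       cis_pairs = cis, hubs = hubs)
}
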