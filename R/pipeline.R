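# End-to-end orchestration: cascade -> repeat / small-RNA / expression
# classification -> high-confidence call -> differential expression and
# correlation screens, with a funnel report mirroring the per-stage counts.

#' Default pipeline thresholds
#'
#' One auditable source of truth for every threshold: minimum length
#' 200 bp, coding-potential cutoff -1, similarity E-value 0.001, expressed
#' at > 2 FPKM in both replicates, repeat fraction 10 %, small-RNA
#' generating at > 10 mapped reads, DE at q < 0.01 and fold change > 2,
#' 10-kb neighbor window, cis |r| > 0.5, trans r < -0.7, hubs at > 10
#' targets.
#'
#' @return named list of defaults
#' @export
pipeline_defaults <- function() {
  list(length_min = 200L, cpc_cutoff = -1, evalue_cutoff = 0.001,
       orf_aa_max = 100L, orf_cov_max = 0.5,
       fpkm_min = 2, repeat_threshold = 0.10, repeat_min_score = 20,
       denovo_seed_l = 16L, denovo_min_count = 10L,
       smallrna_min_reads = 10L, smallrna_max_loci = 20L,
       de_q_max = 0.01, de_fc_min = 2,
       neighbor_gap = 10000L, cis_abs_r = 0.5, trans_r = -0.7,
       hub_min_targets = 10L, exclude_chroms = character(0),
       coding_mode = "heuristic")
}

#' High-confidence lncRNA classification
#'
#' A candidate is high-confidence (hc) when it is expressed (> 2 FPKM in
#' both replicates of at least one tissue), contains no repeats (masked
#' fraction < 10 %) and does not produce small RNAs (<= 10 mapped reads).
#'
#' @param records data.frame with logical column `expressed`, character
#'   column `repeat_class` and logical column `generating`
#' @return `records` with an added `hc` column, plus a `counts` attribute
#'   tabulating each criterion and the intersection
#' @export
classify_hc <- function(records) {
  records$hc <- records$expressed & records$repeat_class == "no_repeat" &
    !records$generating
  attr(records, "counts") <- c(
    expressed = sum(records$expressed),
    no_repeat = sum(records$repeat_class == "no_repeat"),
    non_generating = sum(!records$generating),
    hc = sum(records$hc))
  records
}

#' Run the full lncRNA identification and characterization pipeline
#'
#' Executes, in order: annotation reading and class-code assignment, the
#' non-coding filter cascade, de novo + library repeat masking and
#' classification, small-RNA mapping and association, FPKM / expressed /
#' Z-score / Jensen-Shannon specificity statistics, high-confidence
#' classification, successive-stage differential expression, and the
#' cis/trans correlation screens with hub detection. Writes records,
#' tables and the funnel report to `outdir`.
#'
#' @param inputs named list (or YAML file path) with paths: `reference`
#'   (GFF3), `assembled` (GTF), `transcripts` (FASTA), `housekeeping`,
#'   `mirna`, `repeat_library` (FASTA; optional), `motifs` (peptide FASTA;
#'   optional), `counts` (TSV), `design` (TSV), `smallrna` (FASTA;
#'   optional), `cpc_scores` (TSV; only with `coding_mode = "external"`)
#' @param outdir output directory
#' @param config threshold overrides of [pipeline_defaults()]
#' @return invisibly, a list with `records`, `funnel`, `de`, `cis`,
#'   `trans`, `hubs`, `trace` and output `paths`
#' @export
run_pipeline <- function(inputs, outdir, config = list()) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.character(inputs) && length(inputs) == 1L) {
    inputs <- yaml::read_yaml(inputs)
  }
  req <- c("reference", "assembled", "transcripts", "counts", "design")
  missing_in <- setdiff(req, names(inputs))
  if (length(missing_in)) {
    stop("missing inputs: ", paste(missing_in, collapse = ", "))
  }
  for (f in unlist(inputs[!vapply(inputs, is.null, logical(1))])) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  # no timestamps: identical runs must produce byte-identical outputs
  logmsg <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  logmsg("pipeline start; thresholds: ",
         paste(names(cfg), vapply(cfg, function(x)
           paste(x, collapse = ","), character(1)),
           sep = "=", collapse = " "))

  reference <- read_annotation(inputs$reference)
  assembled <- read_annotation(inputs$assembled)
  sequences <- read_fasta(inputs$transcripts)
  libraries <- list(
    housekeeping = if (!is.null(inputs$housekeeping))
      list(read_fasta(inputs$housekeeping)) else NULL,
    mirna = if (!is.null(inputs$mirna))
      unname(read_fasta(inputs$mirna)) else NULL,
    motifs = if (!is.null(inputs$motifs))
      read_plain_fasta(inputs$motifs) else NULL)
  scores <- NULL
  if (identical(cfg$coding_mode, "external")) {
    if (is.null(inputs$cpc_scores)) {
      stop("coding_mode 'external' requires a cpc_scores input")
    }
    tab <- utils::read.delim(inputs$cpc_scores, stringsAsFactors = FALSE)
    scores <- stats::setNames(tab$score, tab$transcript_id)
  }

  codes <- assign_class_codes(assembled, reference)
  write_class_codes(codes, assembled, file.path(outdir, "class_codes.tsv"))
  logmsg("class codes: ",
         paste(names(table(codes)), table(codes), sep = "=",
               collapse = " "))

  casc <- run_noncoding_cascade(assembled, codes, sequences, libraries,
                                external_scores = scores, config = cfg)
  cand <- casc$candidates
  logmsg("cascade survivors: ", length(cand))

  # repeat classification: union of de novo discovery and external library
  cand_seqs <- sequences[cand]
  denovo <- find_denovo_repeats(cand_seqs, l = cfg$denovo_seed_l,
                                min_count = cfg$denovo_min_count)
  external <- if (!is.null(inputs$repeat_library))
    read_fasta(inputs$repeat_library) else character(0)
  replib <- c(denovo, external)
  rep_frac <- vapply(cand, function(id)
    mask_fraction(sequences[[id]], replib,
                  min_score = cfg$repeat_min_score)$masked_fraction,
    numeric(1))
  rep_class <- vapply(rep_frac, classify_repeat_association, character(1),
                      threshold = cfg$repeat_threshold)

  # small-RNA association against the surviving lncRNA sequences,
  # counted at locus level
  tr <- assembled$transcripts
  locus_of <- stats::setNames(tr$gene_id, tr$transcript_id)
  cand_loci <- unname(locus_of[cand])
  sr_assoc <- data.frame(lncrna_id = cand_loci,
                         mapped_read_count = rep(0, length(cand_loci)),
                         generating = rep(FALSE, length(cand_loci)),
                         stringsAsFactors = FALSE)
  if (!is.null(inputs$smallrna)) {
    raw <- read_smallrna_fasta(inputs$smallrna)
    fr <- filter_reads(raw$sequences, raw$copy_counts)
    locus_seqs <- stats::setNames(cand_seqs, cand_loci)
    aln <- map_perfect(fr$reads, locus_seqs)
    aln <- multimap_filter(aln, max_loci = cfg$smallrna_max_loci)
    sr_assoc <- associate_smallrna(aln, cand_loci,
                                   min_reads = cfg$smallrna_min_reads)
    logmsg("small-RNA reads kept: ", nrow(fr$reads), "; rejects: ",
           paste(names(fr$rejects), fr$rejects, sep = "=", collapse = " "))
  }

  # expression statistics
  cnt_tab <- utils::read.delim(inputs$counts, check.names = FALSE,
                               stringsAsFactors = FALSE)
  counts <- as.matrix(cnt_tab[, -1L, drop = FALSE])
  rownames(counts) <- cnt_tab[[1L]]
  design <- sample_design(utils::read.delim(inputs$design,
                                            stringsAsFactors = FALSE))
  feat_len <- feature_lengths(assembled, reference)
  fk <- fpkm(counts, feat_len[rownames(counts)])
  expressed <- expressed_filter(fk, design, threshold = cfg$fpkm_min)
  tm <- tissue_mean(fk, design)
  zs <- tissue_zscore(fk, design)
  js <- js_specificity(tm)

  pc_sp <- gene_spans(reference)
  pc_sp <- pc_sp[pc_sp$coding & !pc_sp$chrom %in% cfg$exclude_chroms, ]
  js_lnc <- js[js$feature_id %in% cand_loci, ]
  js_pc <- js[js$feature_id %in% pc_sp$gene_id, ]
  ks <- if (nrow(js_lnc) > 1L && nrow(js_pc) > 1L)
    ks_two_sample(js_lnc$js_score[!is.na(js_lnc$js_score)],
                  js_pc$js_score[!is.na(js_pc$js_score)])
    else list(D = NA_real_, p = NA_real_)

  max_fpkm <- apply(tm, 1L, max)
  records <- data.frame(
    transcript_id = cand, locus_id = cand_loci,
    class_code = unname(codes[cand]),
    exon_count = tr$n_exons[match(cand, tr$transcript_id)],
    length_bp = tr$exonic_length[match(cand, tr$transcript_id)],
    max_tissue_fpkm = unname(max_fpkm[cand_loci]),
    expressed = unname(expressed[cand_loci]),
    repeat_fraction = unname(rep_frac),
    repeat_class = unname(rep_class),
    smallrna_count = sr_assoc$mapped_read_count[
      match(cand_loci, sr_assoc$lncrna_id)],
    generating = sr_assoc$generating[match(cand_loci, sr_assoc$lncrna_id)],
    js_score = js$js_score[match(cand_loci, js$feature_id)],
    js_tissue = js$js_tissue[match(cand_loci, js$feature_id)],
    stringsAsFactors = FALSE)
  records <- classify_hc(records)
  hc_counts <- attr(records, "counts")
  logmsg("hc classification: ",
         paste(names(hc_counts), hc_counts, sep = "=", collapse = " "))

  # differential expression between successive stages
  comparisons <- successive_stage_comparisons(design)
  de <- if (nrow(comparisons))
    pairwise_de(fk, design, comparisons, q_max = cfg$de_q_max,
                fc_min = cfg$de_fc_min)
    else data.frame()

  # correlation screens over tissue-averaged FPKM at locus level
  lnc_loci_df <- lnc_locus_spans(assembled, cand, cfg$exclude_chroms)
  pc_df <- data.frame(gene_id = pc_sp$gene_id, chrom = pc_sp$chrom,
                      start = pc_sp$start, end = pc_sp$end,
                      stringsAsFactors = FALSE)
  nb <- find_neighbors(lnc_loci_df, pc_df, max_gap = cfg$neighbor_gap)
  lnc_prof <- tm[rownames(tm) %in% lnc_loci_df$locus_id, , drop = FALSE]
  pc_prof <- tm[rownames(tm) %in% pc_df$gene_id, , drop = FALSE]
  cis <- cis_screen(lnc_prof, pc_prof, nb, abs_r_cutoff = cfg$cis_abs_r)
  trans <- trans_screen(lnc_prof, pc_prof, nb, r_cutoff = cfg$trans_r)
  hubs <- find_hubs(trans, min_targets = cfg$hub_min_targets)
  logmsg("neighbors: ", nrow(nb), "; cis pairs: ", nrow(cis),
         "; trans pairs: ", nrow(trans), "; hubs: ", nrow(hubs))

  funnel <- list(
    class_code_counts = as.list(table(codes)),
    cascade = as.list(casc$funnel),
    n_candidates = length(cand),
    expressed = unname(hc_counts[["expressed"]]),
    no_repeat = unname(hc_counts[["no_repeat"]]),
    non_generating = unname(hc_counts[["non_generating"]]),
    hc = unname(hc_counts[["hc"]]),
    n_neighbor_pairs = nrow(nb), n_cis_pairs = nrow(cis),
    n_trans_pairs = nrow(trans), n_hubs = nrow(hubs),
    js_ks = ks)

  paths <- write_pipeline_outputs(outdir, records, assembled, cand, codes,
                                  casc$trace, de, cis, trans, hubs, zs,
                                  funnel, log_lines)
  invisible(list(records = records, funnel = funnel, de = de, cis = cis,
                 trans = trans, hubs = hubs, trace = casc$trace,
                 neighbors = nb, paths = paths))
}

#' @noRd
write_pipeline_outputs <- function(outdir, records, assembled, cand,
                                   codes, trace, de, cis, trans, hubs,
                                   zs, funnel, log_lines) {
  p <- function(f) file.path(outdir, f)
  wr <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p(f)
  }
  wr(records, "lncrna_records.tsv")
  write_gtf(subset_transcripts(assembled, cand), p("lncrna.gtf"),
            class_codes = codes)
  wr(trace, "filter_trace.tsv")
  if (nrow(de)) wr(de, "de_calls.tsv") else
    writeLines("feature_id\tcomparison\tlog2fc\tt\tp\tq\tis_de",
               p("de_calls.tsv"))
  wr(cis, "cis_pairs.tsv")
  wr(trans, "trans_pairs.tsv")
  wr(hubs, "hubs.tsv")
  wr(data.frame(feature_id = rownames(zs), zs, check.names = FALSE),
     "zscores.tsv")
  jsonlite::write_json(funnel, p("funnel.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, p("run.log"))
  stats::setNames(
    p(c("lncrna_records.tsv", "lncrna.gtf", "filter_trace.tsv",
        "de_calls.tsv", "cis_pairs.tsv", "trans_pairs.tsv", "hubs.tsv",
        "zscores.tsv", "funnel.json", "run.log")),
    c("records", "gtf", "trace", "de", "cis", "trans", "hubs", "zscores",
      "funnel", "log"))
}

# exonic lengths for every feature id appearing in the count matrix:
# assembled loci (max transcript length per locus) and reference genes
#' @noRd
feature_lengths <- function(assembled, reference) {
  out <- numeric(0)
  for (ts in list(assembled, reference)) {
    tr <- ts$transcripts
    len <- tapply(tr$exonic_length, tr$gene_id, max)
    out <- c(out, stats::setNames(as.numeric(len), names(len)))
  }
  out
}

#' @noRd
lnc_locus_spans <- function(assembled, cand, exclude_chroms) {
  tr <- assembled$transcripts
  sub <- tr[tr$transcript_id %in% cand &
              !tr$chrom %in% exclude_chroms, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  sp <- do.call(rbind, lapply(split(sub, sub$gene_id), function(g) {
    data.frame(locus_id = g$gene_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

# Minimal FASTA reader for non-nucleotide records (peptide motifs).
#' @noRd
read_plain_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(unname(seqs), ids)
}
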