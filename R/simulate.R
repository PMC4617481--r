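# Deterministic synthetic-data generator. Builds a toy two-chromosome
# genome with planted protein-coding genes, lncRNA loci of every class
# code, filter decoys, repeat elements, small-RNA source loci and a
# tissue x replicate expression design with planted tissue-exclusive,
# cis-correlated and trans-hub structure — together with a ground-truth
# manifest recording every planted label. The seed fully determines every
# output byte.

#' Default generator configuration
#'
#' Returns the generator configuration: planted feature counts per class
#' code, decoy counts, the 37-tissue / 2-replicate design, negative
#' binomial dispersion, library-size range, correlation and hub plants.
#' Any element can be overridden.
#'
#' @param seed integer seed controlling every random choice
#' @param ... named overrides of defaults
#' @return configuration list
#' @export
simulate_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    tissue_types = c("anther", "carpel", "cortex", "pith", "embryo",
                     "wall", "style"),
    n_stages = 5L,
    extra_tissues = c("seedling", "leaf"),
    replicates = 2L,
    slot_gap = 14000L,
    n_pc_background = 9L,
    n_eq = 3L, n_j = 3L,
    n_lnc = c(u = 16L, o = 10L, x = 10L, i = 6L),
    n_decoys = c(short = 3L, coding = 3L, housekeeping = 3L, mirna = 3L),
    # lncRNA role split (must be consistent with n_lnc)
    n_exclusive = 4L, n_low = 2L, n_source_u = 3L, n_source_x = 2L,
    n_cis = 4L, cis_target_r = c(0.9, 0.8, -0.85, 0.3),
    hub_targets = c(20L, 15L, 12L), hub_target_r = -0.85,
    repeat_element_len = 150L,
    nb_dispersion = 0.005,
    library_size_range = c(1.2e6, 1.8e6),
    pc_base_fpkm = 8000, lnc_base_fpkm = 25, corr_lnc_base_fpkm = 200,
    # hub targets sit at a moderate level so that the ~50 co-regulated
    # genes do not dominate the library mass (FPKM normalisation would
    # otherwise partially cancel their shared planted signal)
    hub_target_fpkm = 500,
    exclusive_hot_fpkm = 80, low_fpkm = 0.15,
    tissue_noise_sd = 0.25, corr_cv = 0.35,
    reads_per_source = 25L)
  utils::modifyList(cfg, list(...))
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @noRd
random_peptide <- function(n) {
  aa <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# A CDS encoding `n_aa` amino acids: ATG + random non-stop codons + TAA.
#' @noRd
random_cds <- function(n_aa) {
  codons <- names(Biostrings::GENETIC_CODE)
  codons <- codons[!Biostrings::GENETIC_CODE %in% "*" & codons != "ATG"]
  paste0("ATG", paste(sample(codons, n_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' @noRd
canonical_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  w <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  rc <- revcomp(w)
  unique(ifelse(w <= rc, w, rc))
}

#' Latent tissue profiles with exact sample correlation
#'
#' Draws a standardized latent profile and one or more partner profiles
#' whose sample Pearson correlation with the anchor is exactly the target
#' (by orthogonalized construction, not rejection): partner =
#' `r * z + sqrt(1 - r^2) * e_perp` with `e_perp` standardized and exactly
#' orthogonal to the anchor.
#'
#' @param n_tissues profile length (>= 3)
#' @param target_r correlation target(s), one per partner
#' @return list with `anchor` (standardized vector) and `partners` (matrix,
#'   one row per target)
#' @export
latent_correlated_profiles <- function(n_tissues, target_r) {
  std <- function(v) (v - mean(v)) / stats::sd(v)
  z <- std(stats::rnorm(n_tissues))
  partners <- matrix(NA_real_, length(target_r), n_tissues)
  for (k in seq_along(target_r)) {
    e <- stats::rnorm(n_tissues)
    e <- e - mean(e)
    e <- e - (sum(e * z) / sum(z * z)) * z
    e <- std(e)
    partners[k, ] <- target_r[k] * z + sqrt(1 - target_r[k]^2) * e
  }
  list(anchor = z, partners = partners)
}

# ---------------------------------------------------------------------------
# Unit geometries. Each planted feature lives in its own "slot" along a
# chromosome; slots are spaced so that boundary gaps between adjacent units
# exceed the 10-kb neighbor window, making the planted cis pair the only
# neighbor relation.

#' @noRd
build_plan <- function(cfg) {
  units <- list()
  add <- function(kind, ...) {
    units[[length(units) + 1L]] <<- c(list(kind = kind), list(...))
  }
  for (k in seq_len(cfg$n_pc_background)) add("pc", pc_role = "background")
  for (k in seq_len(cfg$n_eq)) add("eq")
  for (k in seq_len(cfg$n_j)) add("jj")
  # lncRNA roles per class
  o_roles <- c(rep("repeat", cfg$n_lnc[["o"]] - 2L), rep("plain", 2L))
  x_roles <- c(rep("repeat", cfg$n_lnc[["x"]] - cfg$n_source_x),
               rep("source", cfg$n_source_x))
  i_roles <- rep("repeat", cfg$n_lnc[["i"]])
  u_roles <- c(rep("cis", cfg$n_cis), rep("hub", length(cfg$hub_targets)),
               rep("exclusive", cfg$n_exclusive), rep("low", cfg$n_low),
               rep("source", cfg$n_source_u))
  stopifnot(length(u_roles) == cfg$n_lnc[["u"]])
  for (r in o_roles) add("host_o", lnc_role = r)
  for (r in x_roles) add("host_x", lnc_role = r)
  for (r in i_roles) add("host_i", lnc_role = r)
  ci <- 0L
  for (r in u_roles) {
    if (r == "cis") {
      ci <- ci + 1L
      add("cis", lnc_role = "cis", cis_index = ci)
    } else if (r == "hub") {
      add("lnc_u", lnc_role = r,
          hub_index = sum(vapply(units, function(u)
            identical(u$lnc_role, "hub"), logical(1))) + 1L)
    } else {
      add("lnc_u", lnc_role = r)
    }
  }
  for (h in seq_along(cfg$hub_targets)) {
    for (k in seq_len(cfg$hub_targets[h])) {
      add("pc", pc_role = "hub_target", hub_index = h)
    }
  }
  for (nm in names(cfg$n_decoys)) {
    for (k in seq_len(cfg$n_decoys[[nm]])) add(paste0("decoy_", nm))
  }
  # alternate chromosomes, sequential slots per chromosome
  chrom <- rep(c("chr1", "chr2"), length.out = length(units))
  slot <- integer(length(units))
  cnt <- c(chr1 = 0L, chr2 = 0L)
  for (i in seq_along(units)) {
    slot[i] <- cnt[[chrom[i]]]
    cnt[[chrom[i]]] <- cnt[[chrom[i]]] + 1L
    units[[i]]$chrom <- chrom[i]
    units[[i]]$offset <- 3000L + slot[i] * cfg$slot_gap
  }
  chrom_len <- 3000L + max(cnt) * cfg$slot_gap + 3000L
  list(units = units, chrom_len = c(chr1 = chrom_len, chr2 = chrom_len))
}

# Exon layouts (offsets within a unit, 0-based half-open) per unit kind.
# All protein-coding transcripts carry a 112-codon CDS starting at +10 of
# their first exon.
#' @noRd
unit_geometry <- function(kind, lnc_len = NULL) {
  switch(kind,
    pc = list(gene_exons = rbind(c(0L, 700L), c(1100L, 1800L)),
              cds = c(10L, 346L)),
    eq = list(gene_exons = rbind(c(0L, 800L), c(1200L, 2000L)),
              cds = c(10L, 346L),
              lnc_exons = rbind(c(0L, 800L), c(1200L, 2000L))),
    jj = list(gene_exons = rbind(c(0L, 600L), c(900L, 1500L),
                                 c(1800L, 2400L)),
              cds = c(10L, 346L),
              lnc_exons = rbind(c(100L, 600L), c(900L, 1300L))),
    host_o = ,
    host_x = list(gene_exons = rbind(c(0L, 1200L), c(1600L, 2000L)),
                  cds = c(10L, 346L),
                  lnc_exons = rbind(c(700L, 1500L))),
    host_i = list(gene_exons = rbind(c(0L, 600L), c(3000L, 3600L)),
                  cds = c(10L, 346L),
                  lnc_exons = rbind(c(1000L, 1600L))),
    cis = list(gene_exons = rbind(c(0L, 700L), c(1100L, 1800L)),
               cds = c(10L, 346L),
               lnc_exons = rbind(c(2500L, 2500L + lnc_len))),
    lnc_u = ,
    decoy_short = ,
    decoy_coding = ,
    decoy_housekeeping = ,
    decoy_mirna = list(lnc_exons = rbind(c(0L, lnc_len))),
    stop("unknown unit kind: ", kind))
}

#' @noRd
lnc_length_for <- function(kind, role) {
  if (kind == "decoy_short") return(150L)
  if (kind == "decoy_coding") return(800L)
  if (kind == "decoy_housekeeping") return(500L)
  if (kind == "decoy_mirna") return(400L)
  if (identical(role, "repeat")) return(1000L)
  if (identical(role, "source")) return(800L)
  if (identical(role, "exclusive")) return(600L)
  700L
}

#' Generate the toy genome, annotation and sequence libraries
#'
#' Builds the genome, the reference annotation (protein-coding genes, each
#' with a >= 100-aa CDS), the assembled transcript models (planted lncRNAs
#' of classes u/o/x/i, reference-matching `=`/`j` transcripts and one decoy
#' per filter), plus the housekeeping-RNA, mature-miRNA, peptide-motif and
#' repeat libraries. Planted lncRNA survivors are rejection-sampled until
#' they unambiguously pass every cascade filter in both orientations;
#' decoys violate exactly the filter they are planted for. Class-code
#' geometry is verified internally against [assign_class_codes()] before
#' returning.
#'
#' @param cfg a [simulate_config()]
#' @return list with `reference` and `assembled` ([transcript_set()]s),
#'   `genome` (named character), `sequences` (assembled transcript
#'   sequences, sense orientation), `libraries`, `cds` (for the GFF3
#'   writer), and `plan` (per-feature role tables `lnc` and `pc`)
#' @export
generate_genome_and_annotation <- function(cfg = simulate_config()) {
  set.seed(cfg$seed)
  libraries <- list(
    housekeeping = stats::setNames(
      vapply(c(600L, 800L, 1000L, 1200L), random_dna, character(1)),
      c("rRNA_SSU", "rRNA_LSU", "tRNA_pool", "snRNA_pool")),
    mirna = stats::setNames(
      vapply(rep(21L, 12L), random_dna, character(1)),
      sprintf("miR%03d", seq_len(12L))),
    motifs = stats::setNames(
      vapply(rep(12L, 5L), random_peptide, character(1)),
      sprintf("motif_%d", seq_len(5L))),
    repeat_element = stats::setNames(random_dna(cfg$repeat_element_len),
                                     "repelem_1"))
  element_kmers <- canonical_kmers(libraries$repeat_element[[1L]], 16L)

  pt <- plan_tables(cfg)
  genome <- lapply(pt$chrom_len, random_dna)
  # write every protein-coding CDS into the genome (strand-aware)
  for (tid in names(pt$cds)) {
    iv <- pt$cds[[tid]]
    cds_seq <- random_cds(112L)
    ins <- if (iv$strand == "+") cds_seq else revcomp(cds_seq)
    substr(genome[[iv$chrom]], iv$start + 1L, iv$end) <- ins
  }

  # rejection-sample planted transcript sequences so that every survivor
  # unambiguously passes the cascade and every decoy fails exactly its
  # intended filter
  genome <- plant_sequences(genome, pt$lnc, pt$asm_exons, libraries,
                            element_kmers, cfg)

  reference <- transcript_set(do.call(rbind, pt$ref_exons),
                              coding_genes = pt$pc$gene_id)
  assembled <- transcript_set(do.call(rbind, pt$asm_exons))
  sequences <- extract_transcript_seqs(assembled, genome)

  codes <- assign_class_codes(assembled, reference)
  planned <- stats::setNames(pt$lnc$class_code, pt$lnc$transcript_id)
  if (!identical(unname(codes[names(planned)]), unname(planned))) {
    stop("internal error: planted class codes do not verify")
  }
  cds_list <- lapply(pt$cds, function(iv) cbind(start = iv$start,
                                                end = iv$end))
  list(reference = reference, assembled = assembled, genome = genome,
       sequences = sequences, libraries = libraries, cds = cds_list,
       plan = finalize_plan(pt$lnc, pt$pc, cfg))
}

#' Generator feature/role tables without sequence generation
#'
#' Builds the planted feature tables (lncRNA roles, protein-coding roles,
#' ground-truth labels) of the synthetic design without generating any
#' genome sequence — sufficient input for [generate_expression()], and
#' cheap enough to call in simulation loops.
#'
#' @param cfg a [simulate_config()]
#' @return list with `lnc` and `pc` role tables (as in the `plan` element
#'   of [generate_genome_and_annotation()])
#' @export
generator_plan <- function(cfg = simulate_config()) {
  pt <- plan_tables(cfg)
  finalize_plan(pt$lnc, pt$pc, cfg)
}

# Deterministic (RNG-free) construction of every planted feature: exon
# tables, CDS intervals, role tables.
#' @noRd
plan_tables <- function(cfg) {
  plan <- build_plan(cfg)

  ref_exons <- list()
  asm_exons <- list()
  cds_list <- list()
  lnc_rows <- list()
  pc_rows <- list()
  gene_n <- 0L
  lnc_n <- 0L
  pc_strands <- c("+", "-")

  for (u in plan$units) {
    geo <- unit_geometry(u$kind,
                         lnc_len = lnc_length_for(u$kind, u$lnc_role))
    if (!is.null(geo$gene_exons)) {
      gene_n <- gene_n + 1L
      gid <- sprintf("gene%03d", gene_n)
      tid <- paste0(gid, ".1")
      strand <- pc_strands[gene_n %% 2L + 1L]
      ex <- geo$gene_exons + u$offset
      ref_exons[[tid]] <- data.frame(
        chrom = u$chrom, start = ex[, 1L], end = ex[, 2L], strand = strand,
        transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
      cds_iv <- geo$cds + u$offset
      cds_list[[tid]] <- list(chrom = u$chrom, strand = strand,
                              start = cds_iv[1L], end = cds_iv[2L])
      pc_rows[[length(pc_rows) + 1L]] <- data.frame(
        gene_id = gid, chrom = u$chrom,
        role = if (!is.null(u$pc_role)) u$pc_role else
          if (u$kind == "cis") "cis_partner" else
          if (u$kind %in% c("eq", "jj")) "match_host" else "host",
        cis_index = if (!is.null(u$cis_index)) u$cis_index else NA_integer_,
        hub_index = if (!is.null(u$hub_index) &&
                        identical(u$pc_role, "hub_target")) u$hub_index
                    else NA_integer_,
        length = sum(ex[, 2L] - ex[, 1L]), gene_strand = strand,
        stringsAsFactors = FALSE)
      host_strand <- strand
    } else {
      host_strand <- NA_character_
    }
    if (!is.null(geo$lnc_exons)) {
      lnc_n <- lnc_n + 1L
      tid <- sprintf("TCONS_%05d", lnc_n)
      lid <- sprintf("XLOC_%05d", lnc_n)
      ex <- geo$lnc_exons + u$offset
      class_code <- switch(u$kind,
        eq = "=", jj = "j", host_o = "o", host_x = "x", host_i = "i", "u")
      strand <- switch(u$kind,
        eq = , jj = host_strand,
        host_o = host_strand,
        host_x = if (host_strand == "+") "-" else "+",
        host_i = host_strand,
        "+")
      role <- if (!is.null(u$lnc_role)) u$lnc_role else
        sub("^decoy_", "decoy_", u$kind)
      if (u$kind %in% c("eq", "jj")) role <- "ref_match"
      if (startsWith(u$kind, "decoy")) role <- u$kind
      # a couple of unknown-strand intergenic plants exercise the
      # both-orientation coding rule
      if (identical(role, "exclusive") && lnc_n %% 2L == 0L) strand <- "*"
      lnc_rows[[length(lnc_rows) + 1L]] <- data.frame(
        transcript_id = tid, locus_id = lid, chrom = u$chrom,
        class_code = class_code, strand = strand, role = role,
        cis_index = if (!is.null(u$cis_index)) u$cis_index else NA_integer_,
        hub_index = if (!is.null(u$hub_index)) u$hub_index else NA_integer_,
        start = ex[1L, 1L], end = ex[nrow(ex), 2L],
        length = sum(ex[, 2L] - ex[, 1L]), stringsAsFactors = FALSE)
      asm_exons[[tid]] <- data.frame(
        chrom = u$chrom, start = ex[, 1L], end = ex[, 2L], strand = strand,
        transcript_id = tid, gene_id = lid, stringsAsFactors = FALSE)
    }
  }
  list(lnc = do.call(rbind, lnc_rows), pc = do.call(rbind, pc_rows),
       ref_exons = ref_exons, asm_exons = asm_exons, cds = cds_list,
       chrom_len = plan$chrom_len)
}

# Per-transcript rejection sampling of genome content under the planted
# constraints. Redraws only the transcript's own exonic regions (protein
# CDS regions are never touched; unit geometry keeps them disjoint from
# lncRNA exons).
#' @noRd
plant_sequences <- function(genome, lnc, asm_exons, libraries,
                            element_kmers, cfg) {
  hk <- libraries$housekeeping
  mir <- libraries$mirna
  element <- libraries$repeat_element[[1L]]
  for (i in seq_len(nrow(lnc))) {
    row <- lnc[i, ]
    if (row$role == "ref_match") next     # '='/'j' share the host gene
    ex <- asm_exons[[row$transcript_id]]
    chrom <- row$chrom
    for (try in seq_len(60L)) {
      # redraw the exonic regions
      for (e in seq_len(nrow(ex))) {
        w <- ex$end[e] - ex$start[e]
        substr(genome[[chrom]], ex$start[e] + 1L, ex$end[e]) <-
          random_dna(w)
      }
      seq_plus <- paste(substring(genome[[chrom]], ex$start + 1L, ex$end),
                        collapse = "")
      sense <- if (row$strand == "-") revcomp(seq_plus) else seq_plus
      # role-specific implants
      if (row$role == "decoy_coding") {
        orf <- random_cds(131L)
        substr(genome[[chrom]], ex$start[1L] + 101L,
               ex$start[1L] + 100L + nchar(orf)) <- orf
        break
      }
      if (row$role == "decoy_housekeeping") {
        frag <- substr(hk[[1L]], 101L, 220L)
        substr(genome[[chrom]], ex$start[1L] + 201L,
               ex$start[1L] + 200L + nchar(frag)) <- frag
      }
      if (row$role == "decoy_mirna") {
        substr(genome[[chrom]], ex$start[1L] + 151L,
               ex$start[1L] + 150L + nchar(mir[[1L]])) <- mir[[1L]]
      }
      if (row$role == "repeat") {
        w1 <- ex$end[1L] - ex$start[1L]
        at <- ex$start[1L] + (w1 - nchar(element)) %/% 2L
        substr(genome[[chrom]], at + 1L, at + nchar(element)) <- element
      }
      if (row$role == "decoy_short") break  # dies at the length gate
      seq_plus <- paste(substring(genome[[chrom]], ex$start + 1L, ex$end),
                        collapse = "")
      sense <- if (row$strand == "-") revcomp(seq_plus) else seq_plus
      ok <- coding_call(row$transcript_id, sense, "*")$label == "noncoding"
      if (ok && row$role != "decoy_housekeeping") {
        ok <- !length(housekeeping_filter(
          stats::setNames(sense, row$transcript_id), list(hk)))
      }
      if (ok && row$role != "decoy_mirna") {
        ok <- !length(mirna_filter(stats::setNames(sense,
                                                   row$transcript_id), mir))
      }
      if (ok && !(row$role %in% c("repeat", "decoy_short", "decoy_coding",
                                  "decoy_housekeeping", "decoy_mirna"))) {
        # non-repeat survivors must not share seeds with the repeat element
        ok <- !any(canonical_kmers(sense, 16L) %in% element_kmers)
      }
      if (ok) break
      if (try == 60L) {
        stop("could not satisfy planted constraints for ",
             row$transcript_id)
      }
    }
  }
  genome
}

#' @noRd
extract_transcript_seqs <- function(ts, genome) {
  tr <- ts$transcripts
  out <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    ex <- ts$exons[[tr$transcript_id[i]]]
    s <- paste(substring(genome[[tr$chrom[i]]], ex[, 1L] + 1L, ex[, 2L]),
               collapse = "")
    out[i] <- if (tr$strand[i] == "-") revcomp(s) else s
  }
  stats::setNames(out, tr$transcript_id)
}

# Derive the downstream truth labels (cascade survival, repeat class,
# small-RNA, expression, hc) from the planted roles.
#' @noRd
finalize_plan <- function(lnc, pc, cfg) {
  surv_roles <- c("repeat", "source", "exclusive", "low", "cis", "hub",
                  "plain")
  lnc$survives <- lnc$role %in% surv_roles
  lnc$removed_by <- NA_character_
  lnc$removed_by[lnc$role == "ref_match"] <- "class_code"
  lnc$removed_by[lnc$role == "decoy_short"] <- "length"
  lnc$removed_by[lnc$role == "decoy_coding"] <- "coding_potential"
  lnc$removed_by[lnc$role == "decoy_housekeeping"] <- "housekeeping_rna"
  lnc$removed_by[lnc$role == "decoy_mirna"] <- "mirna_match"
  lnc$repeat_class <- ifelse(lnc$role == "repeat", "repeat_associated",
                             "no_repeat")
  lnc$smallrna_source <- lnc$role == "source"
  lnc$generating <- lnc$smallrna_source
  lnc$expressed <- lnc$survives & lnc$role != "low"
  tissues <- all_tissues(cfg)
  hot <- tissues[c(3L, 12L, 20L, 33L)]
  lnc$exclusive_tissue <- NA_character_
  lnc$exclusive_tissue[lnc$role == "exclusive"] <-
    hot[seq_len(sum(lnc$role == "exclusive"))]
  lnc$hc <- lnc$survives & lnc$expressed &
    lnc$repeat_class == "no_repeat" & !lnc$generating
  list(lnc = lnc, pc = pc)
}

#' @noRd
all_tissues <- function(cfg) {
  c(as.vector(t(outer(cfg$tissue_types, seq_len(cfg$n_stages),
                      paste, sep = "_"))), cfg$extra_tissues)
}
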