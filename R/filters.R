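# The non-coding filter cascade: class-code gate -> length -> coding
# potential -> protein domains -> housekeeping RNAs -> mature miRNAs.
# Survivors are lncRNA candidates; every transcript carries a filter trace
# recording where it stopped.

#' Remove transcripts whose ORFs encode known peptide motifs
#'
#' Built-in mode translates every ORF of each transcript and flags the
#' transcript when any library peptide occurs as an exact substring of a
#' translated ORF. Following the strand rule for unstranded libraries:
#' multi-exonic transcripts with a known strand are scanned on the sense
#' strand only, single-exon transcripts (and unknown-strand transcripts) on
#' either strand. Table mode removes transcripts listed in a precomputed
#' domain-hit table instead.
#'
#' @param info data.frame with columns `transcript_id`, `n_exons`, `strand`
#' @param sequences named character vector of transcript sequences
#' @param motifs character vector of library peptides (length >= 8 aa), or
#'   NULL
#' @param hit_table optional character vector of transcript ids with
#'   precomputed domain hits (table mode)
#' @param min_orf_aa only ORFs at least this long are translated
#' @return character vector of removed transcript ids
#' @export
domain_filter <- function(info, sequences, motifs = NULL, hit_table = NULL,
                          min_orf_aa = 8L) {
  if (!is.null(hit_table)) {
    return(intersect(info$transcript_id, hit_table))
  }
  if (is.null(motifs) || !length(motifs)) return(character(0))
  if (any(nchar(motifs) < 8L)) {
    stop("domain library peptides must be at least 8 aa long")
  }
  removed <- character(0)
  for (i in seq_len(nrow(info))) {
    id <- info$transcript_id[i]
    both <- info$n_exons[i] == 1L || info$strand[i] == "*"
    orfs <- scan_orfs(sequences[[id]], if (both) "both" else "sense")
    orfs <- orfs[orfs$aa_len >= min_orf_aa, , drop = FALSE]
    if (!nrow(orfs)) next
    hit <- FALSE
    for (k in seq_len(nrow(orfs))) {
      s <- if (orfs$strand[k] == "+") sequences[[id]]
           else revcomp(sequences[[id]])
      pep <- translate_nt(substr(s, orfs$start[k] + 1L, orfs$end[k] - 3L))
      if (any(vapply(motifs, grepl, logical(1), x = pep, fixed = TRUE))) {
        hit <- TRUE
        break
      }
    }
    if (hit) removed <- c(removed, id)
  }
  removed
}

#' Remove transcripts similar to housekeeping RNA libraries
#'
#' Runs the shared [similarity_search()] engine against each library
#' (rRNA / tRNA / structured-RNA collections); any hit with
#' `e_value < e_cutoff` removes the transcript.
#'
#' @param sequences named character vector of transcript sequences
#' @param rna_libraries list of named character vectors (one per library)
#' @param e_cutoff E-value threshold
#' @return character vector of removed transcript ids
#' @export
housekeeping_filter <- function(sequences, rna_libraries,
                                e_cutoff = 0.001) {
  removed <- character(0)
  for (lib in rna_libraries) {
    if (!length(lib)) next
    hits <- similarity_search(sequences, lib, e_cutoff = e_cutoff)
    removed <- union(removed, hits$query_id)
  }
  removed
}

#' Remove transcripts perfectly matching mature miRNAs
#'
#' A transcript is removed when any mature miRNA occurs as an exact
#' substring of the transcript or of its reverse complement (perfect-match
#' semantics: a single mismatch keeps the transcript).
#'
#' @param sequences named character vector of transcript sequences
#' @param mature_mirnas character vector of mature miRNA sequences
#'   (18-26 nt)
#' @return character vector of removed transcript ids
#' @export
mirna_filter <- function(sequences, mature_mirnas) {
  if (!length(mature_mirnas)) return(character(0))
  patterns <- unique(c(mature_mirnas, revcomp(mature_mirnas)))
  removed <- vapply(sequences, function(s) {
    any(vapply(patterns, grepl, logical(1), x = s, fixed = TRUE))
  }, logical(1))
  names(sequences)[removed]
}

#' Run the non-coding filter cascade
#'
#' Applies, in order: the class-code gate (only `u`/`o`/`x`/`i` enter;
#' `=`/`j` represent annotated protein-coding structure and are excluded),
#' the minimum-length filter (> 200 bp), the coding-potential call, the
#' protein-domain filter, the housekeeping-RNA filter and the mature-miRNA
#' filter. Survivors are lncRNA candidates. A transcript removed at stage k
#' has no trace entries for later stages.
#'
#' @param ts [transcript_set()] of assembled transcripts
#' @param class_codes named character vector from [assign_class_codes()]
#' @param sequences named character vector of transcript sequences (sense
#'   orientation where the strand is known); every transcript entering the
#'   cascade must have one
#' @param libraries list with elements `housekeeping` (list of named
#'   character vectors), `mirna` (character vector) and `motifs` (peptide
#'   character vector); any element may be absent
#' @param external_scores optional named coding-score vector (external
#'   coding-potential mode)
#' @param config list of thresholds; recognised keys (with defaults):
#'   `length_min = 200`, `cpc_cutoff = -1`, `evalue_cutoff = 0.001`,
#'   `orf_aa_max = 100`, `orf_cov_max = 0.5`
#' @return list with `candidates` (surviving transcript ids), `trace`
#'   (data.frame transcript_id/filter/passed/evidence) and `funnel` (named
#'   integer vector of survivor counts after each stage)
#' @export
run_noncoding_cascade <- function(ts, class_codes, sequences,
                                  libraries = list(),
                                  external_scores = NULL, config = list()) {
  cfg <- utils::modifyList(list(length_min = 200L, cpc_cutoff = -1,
                                evalue_cutoff = 0.001, orf_aa_max = 100L,
                                orf_cov_max = 0.5), config)
  tr <- ts$transcripts
  ids <- tr$transcript_id
  trace <- list()
  note <- function(id, filter, passed, evidence) {
    trace[[length(trace) + 1L]] <<- data.frame(
      transcript_id = id, filter = filter, passed = passed,
      evidence = evidence, stringsAsFactors = FALSE)
  }

  codes <- class_codes[ids]
  gate_ok <- codes %in% c("u", "o", "x", "i")
  for (k in seq_along(ids)) {
    note(ids[k], "class_code", gate_ok[k], unname(codes[k]))
  }
  alive <- ids[gate_ok]
  funnel <- c(class_code = length(alive))

  missing_seq <- alive[!alive %in% names(sequences)]
  if (length(missing_seq)) {
    stop("transcripts lack sequences: ",
         paste(missing_seq, collapse = ", "))
  }

  len <- stats::setNames(tr$exonic_length, ids)[alive]
  len_ok <- len > cfg$length_min
  for (k in seq_along(alive)) {
    note(alive[k], "length", len_ok[k], paste0(len[k], " bp"))
  }
  alive <- alive[len_ok]
  funnel <- c(funnel, length = length(alive))

  strand <- stats::setNames(tr$strand, ids)
  keep <- logical(length(alive))
  for (k in seq_along(alive)) {
    id <- alive[k]
    cc <- coding_call(id, sequences[[id]], strand[[id]],
                      external_scores = external_scores,
                      cutoff = cfg$cpc_cutoff, orf_aa_max = cfg$orf_aa_max,
                      orf_cov_max = cfg$orf_cov_max)
    keep[k] <- cc$label == "noncoding"
    ev <- if (cc$mode == "external") paste0("score=", cc$score)
          else sprintf("aa=%d cov=%.2f", cc$aa_len, cc$orf_coverage)
    note(id, "coding_potential", keep[k], ev)
  }
  alive <- alive[keep]
  funnel <- c(funnel, coding_potential = length(alive))

  info <- tr[match(alive, ids), c("transcript_id", "n_exons", "strand")]
  dom_rm <- domain_filter(info, sequences, motifs = libraries$motifs)
  for (id in alive) {
    note(id, "protein_domain", !(id %in% dom_rm),
         if (id %in% dom_rm) "motif hit" else "none")
  }
  alive <- setdiff(alive, dom_rm)
  funnel <- c(funnel, protein_domain = length(alive))

  hk_libs <- libraries$housekeeping
  hk_rm <- if (is.null(hk_libs)) character(0) else
    housekeeping_filter(sequences[alive], hk_libs,
                        e_cutoff = cfg$evalue_cutoff)
  for (id in alive) {
    note(id, "housekeeping_rna", !(id %in% hk_rm),
         if (id %in% hk_rm) "library hit" else "none")
  }
  alive <- setdiff(alive, hk_rm)
  funnel <- c(funnel, housekeeping_rna = length(alive))

  mir_rm <- if (is.null(libraries$mirna)) character(0) else
    mirna_filter(sequences[alive], libraries$mirna)
  for (id in alive) {
    note(id, "mirna_match", !(id %in% mir_rm),
         if (id %in% mir_rm) "perfect match" else "none")
  }
  alive <- setdiff(alive, mir_rm)
  funnel <- c(funnel, mirna_match = length(alive))

  trace_df <- do.call(rbind, trace)
  rownames(trace_df) <- NULL
  list(candidates = alive, trace = trace_df, funnel = funnel)
}
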