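#' Build a class-code reference index
#'
#' Precomputes, per chromosome, the reference transcript exon/intron
#' structures, splice-junction keys and gene spans needed by
#' [assign_class_code()]. Build it once and reuse it for many queries.
#'
#' @param reference a [transcript_set()] of reference (annotated) models
#' @return an opaque index object of class `classcode_index`
#' @export
classcode_index <- function(reference) {
  tr <- reference$transcripts
  sp <- gene_spans(reference)
  chroms <- unique(tr$chrom)
  idx <- vector("list", length(chroms))
  names(idx) <- chroms
  for (ch in chroms) {
    sub <- tr[tr$chrom == ch, , drop = FALSE]
    entries <- lapply(seq_len(nrow(sub)), function(i) {
      id <- sub$transcript_id[i]
      ex <- reference$exons[[id]]
      introns <- intron_matrix(ex)
      list(id = id, strand = sub$strand[i], exons = ex, introns = introns,
           span = c(sub$start[i], sub$end[i]),
           junctions = if (nrow(introns)) paste(introns[, 1L], introns[, 2L])
                       else character(0))
    })
    g <- sp[sp$chrom == ch, , drop = FALSE]
    idx[[ch]] <- list(transcripts = entries,
                      gene_spans = cbind(start = g$start, end = g$end))
  }
  structure(list(by_chrom = idx), class = "classcode_index")
}

# The deterministic priority ladder for relating an assembled transcript to
# the reference annotation (first match wins):
#   "=" identical intron chain (single-exon: identical exon boundaries),
#       strand-compatible;
#   "j" shares >= 1 identical splice junction with a same-strand reference;
#   "o" >= 1 bp exonic overlap, strands compatible (either unknown, or equal);
#   "x" >= 1 bp exonic overlap, both strands known and opposite;
#   "i" whole query lies strictly within a single reference intron, with no
#       exonic overlap anywhere;
#   "u" none of the above (intergenic / no reference relation).
# Queries that overlap a gene span without triggering o/x/i (e.g. a query
# intron spanning a whole reference gene) fall through to "u".

#' Assign a class code to one assembled transcript
#'
#' Relates a query transcript model to the reference annotation and returns
#' one of the codes `"="`, `"j"`, `"o"`, `"x"`, `"i"`, `"u"` following a
#' fixed priority ladder (identity, shared junction, sense exonic overlap,
#' antisense exonic overlap, intronic, intergenic). Unknown-strand queries
#' can receive `"o"` but never `"x"`: an antisense call requires both
#' strands to be known and opposite.
#'
#' @param query a single-transcript [transcript_set()] or a list with
#'   elements `chrom`, `strand`, `exons` (two-column 0-based half-open
#'   matrix, sorted)
#' @param index a [classcode_index()]
#' @return a single character class code
#' @export
assign_class_code <- function(query, index) {
  q <- as_query(query)
  chrom_idx <- index$by_chrom[[q$chrom]]
  if (is.null(chrom_idx)) {
    warning("query chromosome '", q$chrom,
            "' absent from reference index; coded 'u'")
    return("u")
  }
  qex <- q$exons
  qs <- qex[1L, 1L]
  qe <- qex[nrow(qex), 2L]
  qintr <- intron_matrix(qex)
  qjunc <- if (nrow(qintr)) paste(qintr[, 1L], qintr[, 2L]) else character(0)
  qstrand <- q$strand

  cand <- Filter(function(e) overlaps1(qs, qe, e$span[1L], e$span[2L]),
                 chrom_idx$transcripts)

  # "=": identical intron chain / identical single-exon boundaries
  for (e in cand) {
    if (!strand_compatible(qstrand, e$strand)) next
    if (nrow(qex) == 1L) {
      if (nrow(e$exons) == 1L && e$exons[1L, 1L] == qs &&
          e$exons[1L, 2L] == qe) return("=")
    } else if (length(e$junctions) == length(qjunc) &&
               all(e$junctions == qjunc)) {
      return("=")
    }
  }
  # "j": shared splice junction, both strands known and equal
  if (length(qjunc) && qstrand != "*") {
    for (e in cand) {
      if (e$strand == qstrand && any(qjunc %in% e$junctions)) return("j")
    }
  }
  # exonic overlap split into "o" (strand-compatible) and "x" (antisense)
  any_sense <- FALSE
  any_anti <- FALSE
  for (e in cand) {
    if (overlap_width(qex, e$exons) > 0L) {
      if (qstrand != "*" && e$strand != "*" && qstrand != e$strand) {
        any_anti <- TRUE
      } else {
        any_sense <- TRUE
      }
    }
  }
  if (any_sense) return("o")
  if (any_anti) return("x")
  # "i": wholly inside a single reference intron (no exonic overlap exists
  # at this point in the ladder)
  for (e in cand) {
    if (nrow(e$introns) &&
        any(e$introns[, 1L] <= qs & qe <= e$introns[, 2L])) return("i")
  }
  "u"
}

#' Assign class codes to every transcript of a set
#'
#' @param queries a [transcript_set()] of assembled transcripts
#' @param reference a [transcript_set()] or prebuilt [classcode_index()]
#' @return named character vector of class codes
#' @export
assign_class_codes <- function(queries, reference) {
  index <- if (inherits(reference, "classcode_index")) reference
           else classcode_index(reference)
  ids <- queries$transcripts$transcript_id
  out <- character(length(ids))
  for (k in seq_along(ids)) {
    tr <- queries$transcripts[k, ]
    out[k] <- assign_class_code(
      list(chrom = tr$chrom, strand = tr$strand,
           exons = queries$exons[[tr$transcript_id]]), index)
  }
  stats::setNames(out, ids)
}

#' @noRd
strand_compatible <- function(a, b) {
  a == "*" || b == "*" || a == b
}

#' @noRd
as_query <- function(query) {
  if (inherits(query, "transcript_set")) {
    stopifnot(nrow(query$transcripts) == 1L)
    tr <- query$transcripts[1L, ]
    return(list(chrom = tr$chrom, strand = tr$strand,
                exons = query$exons[[tr$transcript_id]]))
  }
  stopifnot(is.list(query), !is.null(query$exons))
  query
}

#' Find protein-coding neighbors of lncRNA loci
#'
#' For each lncRNA locus, returns the nearest non-overlapping protein-coding
#' gene on each side whose boundary gap is at most `max_gap` (10 kb by
#' default). Protein-coding genes overlapping the lncRNA locus are never
#' returned, and do not block the search for the nearest non-overlapping
#' gene. Gaps are measured between the nearest feature boundaries.
#'
#' @param lncrna_loci data.frame with columns `locus_id`, `chrom`, `start`,
#'   `end` (0-based half-open)
#' @param pc_genes data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`
#' @param max_gap maximum boundary-to-boundary distance in bp
#' @return data.frame: `lncrna_locus_id`, `pc_gene_id`, `side`
#'   (`"upstream"` = lower coordinates / `"downstream"` = higher), `gap_bp`
#' @export
find_neighbors <- function(lncrna_loci, pc_genes, max_gap = 10000L) {
  empty <- data.frame(lncrna_locus_id = character(0),
                      pc_gene_id = character(0), side = character(0),
                      gap_bp = integer(0), stringsAsFactors = FALSE)
  if (nrow(pc_genes) == 0L || nrow(lncrna_loci) == 0L) return(empty)
  res <- list()
  for (i in seq_len(nrow(lncrna_loci))) {
    l <- lncrna_loci[i, ]
    pc <- pc_genes[pc_genes$chrom == l$chrom, , drop = FALSE]
    if (nrow(pc) == 0L) next
    up <- pc[pc$end <= l$start, , drop = FALSE]
    if (nrow(up)) {
      gap <- l$start - up$end
      j <- which.min(gap)
      if (gap[j] <= max_gap) {
        res[[length(res) + 1L]] <- data.frame(
          lncrna_locus_id = l$locus_id, pc_gene_id = up$gene_id[j],
          side = "upstream", gap_bp = as.integer(gap[j]),
          stringsAsFactors = FALSE)
      }
    }
    dn <- pc[pc$start >= l$end, , drop = FALSE]
    if (nrow(dn)) {
      gap <- dn$start - l$end
      j <- which.min(gap)
      if (gap[j] <= max_gap) {
        res[[length(res) + 1L]] <- data.frame(
          lncrna_locus_id = l$locus_id, pc_gene_id = dn$gene_id[j],
          side = "downstream", gap_bp = as.integer(gap[j]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
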