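# Domain, housekeeping and miRNA filters, and the cascade as a whole.

test_that("domain filter follows the multi-exon sense-strand rule", {
  # motif peptide and a transcript encoding it in the sense orientation
  pep <- "MKLVNQWERTYH"
  nt <- paste(vapply(strsplit(pep, "")[[1]], function(a) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
  }, character(1)), collapse = "")
  orf <- paste0("ATG", nt, "TAA")
  set.seed(31)
  sense_seq <- paste0(rand_dna(60), orf, rand_dna(60))
  anti_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sense_seq)))
  seqs <- c(multi_sense = sense_seq, multi_anti = anti_seq,
            single_anti = anti_seq)
  info <- data.frame(
    transcript_id = c("multi_sense", "multi_anti", "single_anti"),
    n_exons = c(2L, 2L, 1L), strand = "+", stringsAsFactors = FALSE)
  removed <- domain_filter(info, seqs, motifs = paste0("M", pep))
  # multi-exon: only the sense-strand hit is removed; the single-exon
  # transcript is scanned on either strand and removed
  expect_true("multi_sense" %in% removed)
  expect_false("multi_anti" %in% removed)
  expect_true("single_anti" %in% removed)
  # empty motif library removes nothing
  expect_equal(domain_filter(info, seqs, motifs = character(0)),
               character(0))
  # precomputed hit-table mode
  expect_equal(domain_filter(info, seqs, hit_table = c("multi_anti", "zz")),
               "multi_anti")
})

test_that("housekeeping filter removes verbatim library carriers", {
  set.seed(32)
  lib <- c(rrna = rand_dna(300))
  hit <- paste0(rand_dna(100), substr(lib[[1]], 50, 129), rand_dna(100))
  miss <- rand_dna(280)
  removed <- housekeeping_filter(c(a = hit, b = miss), list(lib))
  expect_equal(removed, "a")
})

test_that("miRNA filter uses perfect-match semantics on both strands", {
  set.seed(33)
  mir <- rand_dna(21)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mir)))
  embed <- paste0(rand_dna(90), mir, rand_dna(90))
  embed_rc <- paste0(rand_dna(90), rc, rand_dna(90))
  mismatch <- mir
  substr(mismatch, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                      substr(mir, 11, 11))[1]
  embed_mm <- paste0(rand_dna(90), mismatch, rand_dna(90))
  seqs <- c(fw = embed, rv = embed_rc, mm = embed_mm)
  expect_setequal(mirna_filter(seqs, mir), c("fw", "rv"))
})

test_that("the cascade removes each decoy at its intended stage", {
  fx <- get_fixture()
  mf <- fx$sim$manifest$features
  trace <- fx$res$trace
  removed_at <- vapply(split(trace, trace$transcript_id), function(tt) {
    f <- tt$filter[!tt$passed]
    if (length(f)) f[1] else NA_character_
  }, character(1))
  for (i in seq_len(nrow(mf))) {
    if (mf$survives[i]) {
      expect_true(all(trace$passed[trace$transcript_id ==
                                     mf$transcript_id[i]]))
    } else {
      expect_equal(unname(removed_at[mf$transcript_id[i]]),
                   mf$removed_by[i], info = mf$transcript_id[i])
    }
  }
})

test_that("a transcript stopped at stage k has no later trace entries", {
  fx <- get_fixture()
  trace <- fx$res$trace
  stage_order <- c("class_code", "length", "coding_potential",
                   "protein_domain", "housekeeping_rna", "mirna_match")
  for (tt in split(trace, trace$transcript_id)) {
    idx <- match(tt$filter, stage_order)
    expect_true(all(diff(sort(idx)) == 1))
    failed <- which(!tt$passed)
    if (length(failed)) {
      expect_equal(max(idx), idx[failed[1]])
    }
  }
})

test_that("funnel counts equal the per-stage trace tallies", {
  fx <- get_fixture()
  trace <- fx$res$trace
  funnel <- unlist(fx$res$funnel$cascade)
  for (st in names(funnel)) {
    sub <- trace[trace$filter == st, ]
    expect_equal(unname(funnel[[st]]), sum(sub$passed), info = st)
  }
})

test_that("external coding-score mode reproduces the survivor set", {
  fx <- get_fixture()
  cfg_ext <- list(coding_mode = "external")
  inputs <- fx$inputs
  inputs$cpc_scores <- file.path(fx$dir_sim, "cpc_scores.tsv")
  out <- file.path(tempdir(), "lncsieve_pipeout_ext")
  res <- run_pipeline(inputs, out, config = cfg_ext)
  expect_setequal(res$records$transcript_id, fx$res$records$transcript_id)
})

test_that("missing sequences for cascade entrants raise an error", {
  ref <- make_ts(list(r1 = cbind(0L, 500L)), coding = "g1")
  qts <- make_ts(list(q1 = cbind(5000L, 5400L)))
  codes <- assign_class_codes(qts, ref)
  expect_error(run_noncoding_cascade(qts, codes, c(other = "ACGT")),
               "lack sequences")
})
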