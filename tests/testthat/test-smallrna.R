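# Small-RNA read filtering, perfect-match mapping and association.

test_that("read filtering applies length, composition and complexity", {
  set.seed(51)
  reads <- c(rand_dna(17),               # too short
             rand_dna(31),               # too long
             strrep("A", 21),            # mononucleotide run
             strrep("AT", 11),           # dinucleotide tandem
             paste0(rand_dna(10), "N", rand_dna(10)),  # non-ACGT
             rand_dna(21),
             rand_dna(24))
  fr <- filter_reads(reads)
  expect_equal(nrow(fr$reads), 2L)
  expect_equal(unname(fr$rejects["length"]), 2L)
  expect_equal(unname(fr$rejects["simple_repeat"]), 2L)
  expect_equal(unname(fr$rejects["non_acgt"]), 1L)
  # identical reads collapse with summed copies
  fr2 <- filter_reads(c("ACGTACGTACGTACGTACAAG", "ACGTACGTACGTACGTACAAG"),
                      copy_counts = c(2L, 3L))
  expect_equal(fr2$reads$copy_count, 5L)
})

test_that("a tandem motif covering less than 80 % is kept", {
  # 12 nt of AT tandem inside a 21-nt read = 57 % coverage
  r <- paste0(strrep("AT", 6), "GCCGTAGCC")
  expect_equal(nrow(filter_reads(r)$reads), 1L)
})

test_that("perfect-match mapping equals a naive all-pairs oracle", {
  set.seed(52)
  lncs <- stats::setNames(replicate(50, rand_dna(300)), paste0("L", 1:50))
  reads <- character(200)
  for (k in 1:200) {
    if (k %% 2 == 0) {
      src <- sample(50, 1)
      at <- sample(280, 1)
      reads[k] <- substr(lncs[[src]], at, at + 20)
      if (k %% 4 == 0) {
        reads[k] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(reads[k])))
      }
    } else {
      reads[k] <- rand_dna(21)
    }
  }
  fr <- filter_reads(reads)
  aln <- map_perfect(fr$reads, lncs)
  for (i in seq_len(nrow(fr$reads))) {
    rd <- fr$reads$sequence[i]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rd)))
    want <- names(lncs)[vapply(lncs, function(s) {
      grepl(rd, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE)
    }, logical(1))]
    expect_setequal(aln$loci[[i]], want)
  }
})

test_that("multimapper removal is a strict > 20 rule", {
  aln <- list(reads = data.frame(sequence = c(strrep("ACGTA", 4),
                                              strrep("CGTAC", 4),
                                              strrep("GTACG", 4)),
                                 copy_count = c(1L, 1L, 1L)),
              loci = list(paste0("L", 1:21), paste0("L", 1:20), "L1"))
  kept <- multimap_filter(aln, max_loci = 20)
  expect_equal(nrow(kept$reads), 2L)
  expect_equal(lengths(kept$loci), c(20L, 1L))
})

test_that("association counts are weighted and use a strict > 10 call", {
  mk <- function(n_copies) {
    reads <- data.frame(sequence = vapply(seq_along(n_copies), function(i)
      rand_dna(21), character(1)), copy_count = n_copies)
    list(reads = reads, loci = rep(list("L1"), length(n_copies)))
  }
  set.seed(53)
  a11 <- associate_smallrna(mk(c(5L, 6L)), "L1")
  expect_equal(a11$mapped_read_count, 11)
  expect_true(a11$generating)
  a10 <- associate_smallrna(mk(c(5L, 5L)), "L1")
  expect_equal(a10$mapped_read_count, 10)
  expect_false(a10$generating)
  # unweighted mode counts distinct reads
  u <- associate_smallrna(mk(c(5L, 6L)), "L1", weighted = FALSE)
  expect_equal(u$mapped_read_count, 2)
  # histogram sums to the mapped count
  expect_equal(sum(a11[, paste0("len", 18:30)]), 11)
})

test_that("counts are invariant to read order and monotone in removal", {
  set.seed(54)
  lncs <- stats::setNames(replicate(5, rand_dna(200)), paste0("L", 1:5))
  reads <- vapply(1:30, function(i) {
    src <- sample(5, 1)
    at <- sample(178, 1)
    substr(lncs[[src]], at, at + 21)
  }, character(1))
  fr <- filter_reads(reads)
  a1 <- associate_smallrna(map_perfect(fr$reads, lncs), names(lncs))
  perm <- sample(nrow(fr$reads))
  a2 <- associate_smallrna(map_perfect(fr$reads[perm, ], lncs),
                           names(lncs))
  expect_equal(a1$mapped_read_count, a2$mapped_read_count)
  # dropping one read never increases any count
  a3 <- associate_smallrna(map_perfect(fr$reads[-1, ], lncs), names(lncs))
  expect_true(all(a3$mapped_read_count <= a1$mapped_read_count))
})

test_that("the fixture's source loci are the exact generating set", {
  fx <- get_fixture()
  mf <- fx$sim$manifest$features
  rec <- fx$res$records
  expect_setequal(rec$locus_id[rec$generating],
                  mf$locus_id[mf$smallrna_source])
  # pooled mapped-read length mode is 21 nt
  raw <- read_smallrna_fasta(fx$inputs$smallrna)
  fr <- filter_reads(raw$sequences, raw$copy_counts)
  surv <- rec$transcript_id
  seqs <- read_annotation(fx$inputs$assembled)
  tx_seqs <- Biostrings::readDNAStringSet(fx$inputs$transcripts)
  locus_seqs <- stats::setNames(as.character(tx_seqs[surv]),
                                rec$locus_id)
  aln <- multimap_filter(map_perfect(fr$reads, locus_seqs))
  assoc <- associate_smallrna(aln, rec$locus_id)
  hist <- colSums(assoc[, paste0("len", 18:30)])
  expect_equal(names(which.max(hist)), "len21")
})
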