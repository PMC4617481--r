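# Annotation I/O, class-code assignment and neighbor finding.

test_that("GTF coordinates convert to 0-based half-open models", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tx\texon\t101\t200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\tx\texon\t301\t400\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";')), gtf)
  ts <- read_annotation(gtf)
  expect_equal(unname(ts$exons[["t1"]]),
               unname(cbind(c(100L, 300L), c(200L, 400L))))
  expect_equal(ts$transcripts$exonic_length, 200L)
})

test_that("GFF3 and GTF encodings of the same gene give identical models", {
  gtf <- tempfile(fileext = ".gtf")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    paste0("chr2\tx\texon\t51\t150\t.\t-\t.\t",
           'gene_id "gA"; transcript_id "tA";'),
    paste0("chr2\tx\texon\t201\t260\t.\t-\t.\t",
           'gene_id "gA"; transcript_id "tA";')), gtf)
  writeLines(c("##gff-version 3",
               "chr2\tx\tgene\t51\t260\t.\t-\t.\tID=gA",
               "chr2\tx\tmRNA\t51\t260\t.\t-\t.\tID=tA;Parent=gA",
               "chr2\tx\texon\t51\t150\t.\t-\t.\tID=e1;Parent=tA",
               "chr2\tx\texon\t201\t260\t.\t-\t.\tID=e2;Parent=tA"), gff)
  a <- read_annotation(gtf)
  b <- read_annotation(gff)
  expect_equal(a$exons[["tA"]], b$exons[["tA"]])
  expect_equal(a$transcripts[, c("chrom", "strand", "n_exons", "start",
                                 "end", "exonic_length")],
               b$transcripts[, c("chrom", "strand", "n_exons", "start",
                                 "end", "exonic_length")])
})

test_that("write-then-read round-trips a random multi-gene annotation", {
  set.seed(71)
  exon_list <- lapply(1:50, function(i) {
    rand_exons(i * 2000L, i * 2000L + 1500L)
  })
  names(exon_list) <- sprintf("t%02d", 1:50)
  ts <- make_ts(exon_list, strand = sample(c("+", "-"), 50, TRUE))
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(ts, gtf)
  back <- read_annotation(gtf)
  ord <- match(ts$transcripts$transcript_id, back$transcripts$transcript_id)
  expect_equal(back$transcripts[ord, ]$exonic_length,
               ts$transcripts$exonic_length)
  for (id in names(exon_list)) {
    expect_equal(unname(back$exons[[id]]), unname(ts$exons[[id]]))
  }
  # GFF3 writer round-trips too
  gff <- tempfile(fileext = ".gff3")
  write_gff3(ts, gff)
  back2 <- read_annotation(gff)
  for (id in names(exon_list)) {
    expect_equal(unname(back2$exons[[id]]), unname(ts$exons[[id]]))
  }
})

test_that("transcripts with zero exons are dropped with a warning", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t1\t500\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tx\texon\t1\t500\t.\t+\t.\tID=e1;Parent=t1",
               "chr1\tx\tmRNA\t1\t400\t.\t+\t.\tID=t_empty;Parent=g1"),
             gff)
  expect_warning(ts <- read_annotation(gff), "zero exons")
  expect_equal(ts$transcripts$transcript_id, "t1")
})

test_that("class-code ladder handles the canonical cases", {
  ref <- make_ts(list(r1 = cbind(c(100L, 300L), c(200L, 500L))),
                 strand = "+")
  idx <- classcode_index(ref)
  q <- function(exons, strand = "+") list(chrom = "chr1", strand = strand,
                                          exons = exons)
  # identical structure
  expect_equal(assign_class_code(
    q(cbind(c(100L, 300L), c(200L, 500L))), idx), "=")
  # shared junction, different chain end
  expect_equal(assign_class_code(
    q(cbind(c(150L, 300L, 600L), c(200L, 550L, 700L))), idx), "j")
  # intronic: single exon strictly inside the [200,300) intron
  ref2 <- make_ts(list(r1 = cbind(c(0L, 300L), c(200L, 500L))))
  expect_equal(assign_class_code(q(cbind(210L, 290L)),
                                 classcode_index(ref2)), "i")
  # antisense exonic overlap
  expect_equal(assign_class_code(q(cbind(150L, 250L), strand = "-"),
                                 idx), "x")
  # sense exonic overlap (not sharing a junction)
  expect_equal(assign_class_code(q(cbind(150L, 250L)), idx), "o")
  # unknown-strand overlap can be "o" but never "x"
  expect_equal(assign_class_code(q(cbind(150L, 250L), strand = "*"),
                                 idx), "o")
  # intergenic
  expect_equal(assign_class_code(q(cbind(5000L, 5600L)), idx), "u")
  # chromosome absent from the index
  expect_warning(
    code <- assign_class_code(list(chrom = "chrZ", strand = "+",
                                   exons = cbind(0L, 100L)), idx),
    "absent")
  expect_equal(code, "u")
})

test_that("class codes match the brute-force oracle on fuzzed cases", {
  set.seed(101)
  for (k in 1:500) {
    case <- rand_classcode_case()
    expect_equal(package_class_code(case),
                 oracle_class_code(case$query, case$refs),
                 info = paste("case", k))
  }
})

test_that("class codes are strand-symmetric", {
  set.seed(202)
  flip <- function(s) c("+" = "-", "-" = "+", "*" = "*")[[s]]
  for (k in 1:200) {
    case <- rand_classcode_case()
    flipped <- case
    flipped$query$strand <- flip(case$query$strand)
    for (i in seq_along(flipped$refs)) {
      flipped$refs[[i]]$strand <- flip(case$refs[[i]]$strand)
    }
    expect_equal(package_class_code(case), package_class_code(flipped))
  }
})

test_that("find_neighbors respects the gap window and overlap exclusion", {
  lnc <- data.frame(locus_id = "L1", chrom = "chr1", start = 5000L,
                    end = 6000L)
  nb <- function(pc_start, pc_end) {
    find_neighbors(lnc, data.frame(gene_id = "G1", chrom = "chr1",
                                   start = pc_start, end = pc_end))
  }
  got <- nb(6500L, 8000L)
  expect_equal(got$side, "downstream")
  expect_equal(got$gap_bp, 500L)
  # beyond 10 kb
  expect_equal(nrow(nb(17000L, 18000L)), 0L)
  # exactly 10 kb is allowed (gap <= max_gap)
  expect_equal(nb(16000L, 17000L)$gap_bp, 10000L)
  # overlapping gene excluded
  expect_equal(nrow(nb(5500L, 7000L)), 0L)
  # empty gene set
  expect_equal(nrow(find_neighbors(lnc, data.frame(gene_id = character(0),
                                                   chrom = character(0),
                                                   start = integer(0),
                                                   end = integer(0)))), 0L)
})

test_that("neighbor gaps are translation-invariant and bounded", {
  set.seed(9)
  for (k in 1:25) {
    lnc <- data.frame(locus_id = "L", chrom = "c", start = 20000L,
                      end = 21000L)
    pcs <- data.frame(gene_id = paste0("g", 1:6), chrom = "c",
                      start = sample(1000:40000, 6))
    pcs$end <- pcs$start + sample(500:3000, 6)
    a <- find_neighbors(lnc, pcs)
    shift <- 12345L
    b <- find_neighbors(transform(lnc, start = start + shift,
                                  end = end + shift),
                        transform(pcs, start = start + shift,
                                  end = end + shift))
    expect_equal(a, b)
    expect_true(all(a$gap_bp <= 10000L) && all(a$gap_bp >= 0L))
  }
})
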