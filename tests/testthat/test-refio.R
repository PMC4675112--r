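test_that("read_fasta normalizes case, folds lines and maps U to T", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ac", "gt", ">y desc", "ACGU"), f)
  out <- read_fasta(f)
  expect_identical(out, c(x = "ACGT", y = "ACGT"))
})

test_that("read_fasta rejects bad alphabets and empty records by name", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">bad", "ACQT"), f)
  expect_error(read_fasta(f), "bad")
  writeLines(c(">empty", "", ">ok", "ACGT"), f)
  expect_error(read_fasta(f), "empty")
})

test_that("fasta round-trips random sequences exactly", {
  set.seed(31)
  x <- setNames(vapply(1:8, function(i) rand_genome(sample(50:300, 1)),
                       character(1)),
                paste0("s", 1:8))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(x, f)
  expect_identical(read_fasta(f), x)
})

test_that("reference_genome validates intervals and gene ids", {
  g <- data.frame(gene_id = c("a", "b"), start = c(0L, 10L), end = c(6L, 15L),
                  strand = c("+", "-"), product = "")
  rg <- reference_genome("g1", "ACGTACGTACGTACGTACGT", genes = g)
  expect_s3_class(rg, "reference_genome")
  expect_error(reference_genome("g1", "ACGT",
                                genes = data.frame(gene_id = "a", start = 0L,
                                                   end = 10L, strand = "+",
                                                   product = "")),
               "outside")
  g2 <- g; g2$gene_id <- c("a", "a")
  expect_error(reference_genome("g1", "ACGTACGTACGTACGTACGT", genes = g2),
               "duplicate")
})

test_that("GFF and BED coordinates convert to the 0-based half-open convention", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  write_fasta(c(chr = strrep("ACGT", 25)), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
               "chr\t.\tgene\t1\t3\t.\t+\t.\tID=gA",
               "chr\t.\tgene\t11\t40\t.\t-\t.\tID=gB"), gff)
  bed <- file.path(dir, "m.bed")
  writeLines("chr\t10\t20", bed)
  rg <- read_annotations(fa, gff, bed)
  expect_equal(rg$genes$start, c(0L, 10L))
  expect_equal(rg$genes$end, c(3L, 40L))
  expect_equal(rg$genes$strand, c("+", "-"))
  expect_equal(rg$mobile_regions$start, 10L)
  expect_equal(rg$mobile_regions$end, 20L)

  # round trip through the writers restores the intervals
  gff2 <- file.path(dir, "out.gff3"); bed2 <- file.path(dir, "out.bed")
  write_annotations(rg, gff2, bed2)
  rg2 <- read_annotations(fa, gff2, bed2)
  expect_equal(rg2$genes[, c("start", "end", "strand")],
               rg$genes[, c("start", "end", "strand")])
  expect_equal(rg2$mobile_regions, rg$mobile_regions)
})

test_that("features beyond the sequence bounds are rejected", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fasta")
  write_fasta(c(chr = "ACGTACGT"), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3", "chr\t.\tgene\t1\t50\t.\t+\t.\tID=gA"), gff)
  expect_error(read_annotations(fa, gff), "outside")
})

test_that("homolog tables require a header and existing genes", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "h.tsv")
  writeLines(c("gene_a\tgene_b", "a\tb"), f)
  gA <- reference_genome("A", strrep("ACGT", 10),
                         genes = data.frame(gene_id = "a", start = 0L, end = 6L,
                                            strand = "+", product = ""))
  gB <- reference_genome("B", strrep("ACGT", 10),
                         genes = data.frame(gene_id = "b", start = 0L, end = 6L,
                                            strand = "+", product = ""))
  expect_equal(nrow(read_homologs(f, gA, gB)), 1L)
  writeLines(c("gene_a\tgene_b", "a\tmissing"), f)
  expect_error(read_homologs(f, gA, gB), "unknown")
})

test_that("write_sam emits 1-based POS, CIGAR, and unmapped flags", {
  set.seed(5)
  g <- rand_genome(300)
  read20 <- substr(g, 5, 24)                         # 0-based start 4
  p <- mapping_params("standard")
  aln <- map_reads(c(r1 = read20), g, p)
  expect_equal(aln$ref_start, 4)
  junk <- map_reads(c(r2 = strrep("AC", 10)), g, p)  # unmapped
  both <- rbind(aln, junk)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(both, c(genome = g), f, reads = c(r1 = read20,
                                              r2 = strrep("AC", 10)))
  lines <- readLines(f)
  expect_true(any(grepl("^@SQ\tSN:genome\tLN:300$", lines)))
  rec <- strsplit(grep("^r1\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(rec[2]), 0L)
  expect_equal(as.integer(rec[4]), 5L)   # POS is 1-based
  expect_equal(rec[6], "20M")
  rec2 <- strsplit(grep("^r2\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(rec2[2]), 4L)

  # a deletion is visible in the CIGAR
  del_read <- paste0(substr(g, 101, 115), substr(g, 117, 131))
  aln_d <- map_reads(c(rd = del_read), g, p)
  expect_match(aln_d$cigar, "1D")

  # empty alignment set gives a header-only SAM
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(both[0, ], c(genome = g), f2)
  expect_true(all(grepl("^@", readLines(f2))))
})

test_that("fastq writer and reader round-trip reads", {
  dir <- withr::local_tempdir()
  r1 <- c(a_1 = "ACGT", b_1 = "GGGG")
  r2 <- c(a_2 = "TTTT", b_2 = "CCCC")
  write_fastq(r1, r2, file.path(dir, "r1.fq"), file.path(dir, "r2.fq"))
  expect_identical(read_fastq(file.path(dir, "r1.fq")), r1)
  expect_identical(read_fastq(file.path(dir, "r2.fq")), r2)
})
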