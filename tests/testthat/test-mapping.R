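test_that("exact substring maps with full score and identity", {
  set.seed(101)
  g <- rand_genome(1000)
  r <- substr(g, 101, 150)                 # 0-based start 100, 50 bp
  a <- map_read(r, g, mapping_params("strict"))
  expect_true(a$mapped)
  expect_equal(a$ref_start, 100)
  expect_equal(a$n_match, 50L)
  expect_equal(a$score, 50)
  expect_equal(a$similarity, 1.0)
  expect_equal(a$cigar, "50M")
})

test_that("a single mismatch costs match+mismatch and stays accepted at 90/90", {
  set.seed(102)
  g <- rand_genome(1000)
  r <- substr(g, 201, 250)
  substr(r, 25, 25) <- setdiff(c("A", "C", "G", "T"), substr(r, 25, 25))[1]
  a <- map_read(r, g, mapping_params("strict"))
  b <- oracle_map(r, g, mapping_params("strict"))
  expect_true(a$mapped)
  expect_equal(a$score, 49 * 1 - 1 * 2)    # 47
  expect_equal(a$similarity, 49 / 50)
  expect_equal(a$ref_start, 200)
  expect_equal(a[, c("ref_start", "score", "cigar", "strand")],
               b[, c("ref_start", "score", "cigar", "strand")])
})

test_that("eight scattered mismatches fail 90/90 but pass 80/80", {
  set.seed(103)
  g <- rand_genome(1000)
  r <- substr(g, 301, 350)
  # scattered interior mismatches: a clean leading 19-mer keeps the seed
  # alive and no prefix/suffix clipping is score-beneficial, so the full
  # 50-column alignment (similarity 0.84) is optimal
  for (p in c(20, 23, 26, 29, 32, 35, 38, 41))
    substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
  strict <- map_read(r, g, mapping_params("strict"))
  std <- map_read(r, g, mapping_params("standard"))
  expect_false(strict$mapped)
  expect_true(std$mapped)
  expect_equal(std$similarity, 0.84)
  expect_equal(oracle_map(r, g, mapping_params("strict"))$mapped, FALSE)
  expect_equal(oracle_map(r, g, mapping_params("standard"))$similarity, 0.84)
})

test_that("unrelated reads stay unmapped and the oracle refuses big genomes", {
  set.seed(104)
  g <- rand_genome(2000)
  r <- rand_genome(100)
  expect_false(oracle_map(r, g, mapping_params("strict"))$mapped)
  expect_false(map_read(r, g, mapping_params("strict"))$mapped)
  expect_error(oracle_map(r, rand_genome(20000), mapping_params("strict")),
               "10 kb")
  expect_error(map_read(substr(r, 1, 10), g, mapping_params("strict")),
               "seed_kmer")
})

test_that("a reverse-complement palindrome resolves to the plus strand", {
  set.seed(105)
  half <- rand_genome(12)
  pal <- paste0(half, rc_seq(half))        # 24 bp, rc(pal) == pal
  g <- paste0(rand_genome(400), pal, rand_genome(400))
  a <- map_read(pal, g, mapping_params("strict"))
  b <- oracle_map(pal, g, mapping_params("strict"))
  expect_true(a$mapped)
  expect_equal(a$strand, "+")
  expect_equal(b$strand, "+")
  expect_equal(a$ref_start, b$ref_start)
})

test_that("seeded mapper and exhaustive oracle agree on random instances", {
  set.seed(106)
  for (preset in c("standard", "strict")) {
    p <- mapping_params(preset)
    for (i in 1:25) {
      g <- rand_genome(1500)
      kind <- i %% 3
      if (kind == 0) r <- rand_genome(100)
      else {
        st <- sample(1:1400, 1)
        r <- mutate_seq(substr(g, st, st + 99), if (kind == 1) 0.02 else 0.08)
        if (i %% 2 == 0) r <- rc_seq(r)
        if (i %% 5 == 0) r <- indel_seq(r, 1)
      }
      a <- map_read(r, g, p)
      b <- oracle_map(r, g, p)
      expect_equal(a$mapped, b$mapped)
      if (isTRUE(a$mapped)) {
        expect_equal(a$score, b$score)
        expect_equal(a$ref_start, b$ref_start)
        expect_equal(a$strand, b$strand)
        expect_equal(a$cigar, b$cigar)
      }
    }
  }
})

test_that("the mapper agrees with an independent pairwise aligner on gapless reads", {
  # cross-check scores against Biostrings local alignment under the same
  # substitution/gap costs for reads with a known unique placement
  set.seed(107)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (i in 1:10) {
    g <- rand_genome(800)
    st <- sample(1:700, 1)
    r <- mutate_seq(substr(g, st, st + 79), 0.03)
    a <- map_read(r, g, mapping_params("standard"))
    pw <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(r), Biostrings::DNAString(g), type = "local",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 3)
    expect_true(a$mapped)
    expect_equal(a$score, Biostrings::score(pw))
  }
})

test_that("lowering thresholds never unmaps a read", {
  set.seed(108)
  for (i in 1:30) {
    g <- rand_genome(1200)
    st <- sample(1:1100, 1)
    r <- mutate_seq(substr(g, st, st + 99), sample(c(0.02, 0.08, 0.15), 1))
    strict <- map_read(r, g, mapping_params("strict"))$mapped
    std <- map_read(r, g, mapping_params("standard"))$mapped
    relaxed <- map_read(r, g, mapping_params("relaxed"))$mapped
    low <- map_read(r, g, mapping_params("screen_low"))$mapped
    if (strict) expect_true(std)
    if (std) expect_true(low)
    if (relaxed) expect_true(low)
  }
})

test_that("covered_bases matches the brute-force position union", {
  mk <- function(starts, ends)
    data.frame(mapped = rep(TRUE, length(starts)), ref_start = starts,
               ref_end = ends)
  expect_equal(covered_bases(mk(integer(0), integer(0))), 0L)
  expect_equal(covered_bases(mk(7, 100)), 93L)
  expect_equal(covered_bases(mk(c(0, 40), c(50, 90))), 90L)
  set.seed(109)
  for (i in 1:20) {
    n <- sample(1:15, 1)
    s <- sample(0:500, n, replace = TRUE)
    e <- s + sample(1:80, n, replace = TRUE)
    df <- mk(s, e)
    expect_equal(covered_bases(df), bf_covered_bases(df))
    # monotone under adding alignments
    expect_gte(covered_bases(rbind(df, mk(100, 150))), covered_bases(df))
  }
})

test_that("error-free reads fully inside zero-divergence inserts all map at 90/90", {
  cfg <- tiny_config(seed = 3, insert_divergence = 0, error_rate = 0,
                     indel_rate_donors = 0)
  sim <- simulate_dataset(cfg)
  rt <- sim$truth$read_table
  it <- sim$truth$insert_table
  inside <- vapply(seq_len(nrow(rt)), function(i) {
    any(rt$host_start[i] >= it$host_start & rt$host_end[i] <= it$host_end &
        it$donor == rt$donor[i])
  }, logical(1))
  sel <- rt[inside & rt$donor == "A", ]
  sel <- sel[seq_len(min(nrow(sel), 150)), ]
  reads <- c(sim$reads1, sim$reads2)[sel$read_id]
  aln <- map_reads(reads, sim$donors$A, mapping_params("strict"))
  expect_true(all(aln$mapped))
  expect_true(all(aln$similarity == 1))
})
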