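test_that("reads matching a single genome are assigned to it", {
  set.seed(201)
  gA <- rand_genome(2000); gB <- rand_genome(2000)
  genomes <- c(A = gA, B = gB)
  r <- c(x1 = substr(gA, 101, 200), x2 = rc_seq(substr(gB, 501, 600)),
         junk = rand_genome(100))
  res <- competitive_map(r, genomes, mapping_params("strict"))
  asg <- setNames(res$assignments$assigned, res$assignments$read_id)
  expect_equal(asg[["x1"]], "A")
  expect_equal(asg[["x2"]], "B")
  expect_equal(asg[["junk"]], "unmapped")
  # partition invariant
  expect_true(all(res$assignments$assigned %in% c("A", "B", "unmapped",
                                                  "ambiguous")))
})

test_that("reads from regions identical in both genomes tie and are discarded", {
  set.seed(202)
  shared <- rand_genome(500)
  gA <- paste0(rand_genome(700), shared, rand_genome(700))
  gB <- paste0(rand_genome(400), shared, rand_genome(1000))
  r <- c(t1 = substr(shared, 101, 200), t2 = substr(shared, 301, 400))
  res_d <- competitive_map(r, c(A = gA, B = gB),
                           mapping_params("strict", ambiguous_policy = "discard"))
  expect_true(all(res_d$assignments$assigned == "ambiguous"))
  res_r <- competitive_map(r, c(A = gA, B = gB),
                           mapping_params("strict", ambiguous_policy = "random",
                                          rng_seed = 5))
  expect_true(all(res_r$assignments$assigned %in% c("A", "B")))
  # same seed -> identical resolution
  res_r2 <- competitive_map(r, c(A = gA, B = gB),
                            mapping_params("strict", ambiguous_policy = "random",
                                           rng_seed = 5))
  expect_identical(res_r$assignments, res_r2$assignments)
})

test_that("reciprocal specificity agrees with the exhaustive oracle per read", {
  set.seed(203)
  gA <- rand_genome(2000)
  gB <- mutate_seq(gA, 0.12)               # diverged sibling
  genomes <- c(A = gA, B = gB)
  p <- mapping_params("strict")
  reads <- character(0)
  for (i in 1:10) {
    st <- sample(1:1900, 1)
    div <- sample(c(0, 0.02, 0.05), 1)
    reads <- c(reads, mutate_seq(substr(gA, st, st + 99), div))
  }
  names(reads) <- sprintf("r%02d", 1:10)
  res <- competitive_map(reads, genomes, p)
  res <- reciprocal_specificity(res, reads, genomes, p)
  sp <- setNames(res$specific$specific, res$specific$read_id)
  for (rid in res$specific$read_id[res$specific$assigned == "A"]) {
    accepted_on_B <- oracle_map(reads[[rid]], gB, p)$mapped
    expect_equal(sp[[rid]], !accepted_on_B)
  }
  # swapping genome order changes no read's status
  res_sw <- competitive_map(reads, c(B = gB, A = gA), p)
  res_sw <- reciprocal_specificity(res_sw, reads, c(B = gB, A = gA), p)
  m <- merge(res$specific, res_sw$specific, by = "read_id")
  expect_true(all(m$specific.x == m$specific.y))
  expect_error(reciprocal_specificity(res, reads, c(A = gA), p), "2 genomes")
})

test_that("insert size estimation recovers a perfectly tiled insert exactly", {
  set.seed(204)
  gA <- rand_genome(6000)
  gB <- rand_genome(6000)                   # unrelated: everything specific
  insert <- substr(gA, 501, 5500)           # 0-based [500, 5500)
  starts <- seq(1, 4901, by = 20)           # 5x tiling, covers every base
  reads <- setNames(substring(insert, starts, starts + 99),
                    sprintf("t%04d", seq_along(starts)))
  p <- mapping_params("strict")
  res <- competitive_map(reads, c(A = gA, B = gB), p)
  res <- reciprocal_specificity(res, reads, c(A = gA, B = gB), p)
  est <- insert_size_estimate(res, reads, c(A = gA, B = gB), p)
  expect_equal(est$A$covered_bp_specific, 5000L)
  expect_equal(est$B$covered_bp_specific, 0L)
})

test_that("three identical genomes leave every mapped read discarded", {
  set.seed(205)
  g <- rand_genome(1500)
  reads <- setNames(substring(g, c(1, 301, 601), c(100, 400, 700)),
                    c("a", "b", "c"))
  scr <- multi_genome_screen(reads, c(g1 = g, g2 = g, g3 = g),
                             list(strict = mapping_params("strict")))
  expect_true(all(scr$reads_assigned == 0L))
})

test_that("screen attributes donor reads to the donor subset and relaxation is monotone", {
  cfg <- tiny_config(seed = 21)
  sim <- simulate_dataset(cfg)
  rt <- sim$truth$read_table
  reads <- c(sim$reads1, sim$reads2)
  sel <- rt$read_id[rt$donor != "host"]
  reads <- reads[sel[seq_len(min(400, length(sel)))]]
  gC <- reference_genome("decoy", rand_genome(20000))
  genomes <- list(sim$donors$A, sim$donors$B, gC)
  scr <- multi_genome_screen(reads, genomes,
                             list(strict = mapping_params("strict"),
                                  low = mapping_params("screen_low")))
  expect_gt(scr$focal_fraction[scr$params == "strict"][1], 0.95)
  # relaxing the thresholds never decreases a genome's mapped-read count
  for (g in c("donorA", "donorB", "decoy")) {
    n_strict <- scr$reads_assigned[scr$params == "strict" & scr$genome_id == g]
    n_low <- scr$reads_assigned[scr$params == "low" & scr$genome_id == g]
    expect_gte(n_low, n_strict)
  }
})

test_that("attribution results are deterministic given the seed", {
  cfg <- tiny_config(seed = 22)
  sim <- simulate_dataset(cfg)
  reads <- c(sim$reads1, sim$reads2)
  reads <- reads[seq_len(300)]
  genomes <- list(sim$donors$A, sim$donors$B)
  p <- mapping_params("strict", ambiguous_policy = "random", rng_seed = 9)
  r1 <- competitive_map(reads, genomes, p)
  r2 <- competitive_map(reads, genomes, p)
  expect_identical(r1$assignments, r2$assignments)
})
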