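test_that("zero divergence yields identical donors and paired homologs", {
  cfg <- tiny_config(seed = 11, divergence_donors = 0, indel_rate_donors = 0)
  d <- simulate_donors(cfg)
  expect_identical(d$A$sequence, d$B$sequence)
  expect_identical(d$A$genes, d$B$genes)
  expect_equal(nrow(d$homologs), cfg$n_genes)
  expect_true(all(d$homologs$gene_a %in% d$A$genes$gene_id))
})

test_that("observed donor divergence matches the two-lineage expectation", {
  cfg <- sim_config(seed = 12, ancestor_length = 100000L,
                    divergence_donors = 0.10, indel_rate_donors = 0,
                    inserts_per_donor = 0L, host_length = 1000L)
  d <- simulate_donors(cfg)
  a <- strsplit(d$A$sequence, "")[[1]]
  b <- strsplit(d$B$sequence, "")[[1]]
  mism <- sum(a != b)
  # each lineage substitutes at d/2 to a random distinct base
  r <- 0.05
  p <- 2 * r * (1 - r) + r * r * (2 / 3)
  expect_lt(abs(mism - 100000 * p), 3 * sqrt(100000 * p * (1 - p)))
})

test_that("mean donor identity decreases monotonically with divergence", {
  mism_frac <- vapply(c(0.02, 0.08, 0.20), function(dv) {
    m <- vapply(1:2, function(s) {
      cfg <- sim_config(seed = s, ancestor_length = 20000L, n_genes = 8L,
                        gene_length = 600L, divergence_donors = dv,
                        indel_rate_donors = 0, inserts_per_donor = 0L,
                        host_length = 1000L)
      d <- simulate_donors(cfg)
      mean(strsplit(d$A$sequence, "")[[1]] != strsplit(d$B$sequence, "")[[1]])
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(mism_frac) > 0))
})

test_that("exchanged mobile regions are byte-identical between donors", {
  cfg <- tiny_config(seed = 13, mobile_exchange = TRUE)
  d <- simulate_donors(cfg)
  expect_gte(nrow(d$A$mobile_regions), 1L)
  for (i in seq_len(nrow(d$A$mobile_regions))) {
    sa <- substr(d$A$sequence, d$A$mobile_regions$start[i] + 1L,
                 d$A$mobile_regions$end[i])
    sb <- substr(d$B$sequence, d$B$mobile_regions$start[i] + 1L,
                 d$B$mobile_regions$end[i])
    expect_identical(sa, sb)
  }
})

test_that("a world without inserts has an insert-free host and empty truth", {
  cfg <- tiny_config(seed = 14, inserts_per_donor = 0L)
  d <- simulate_donors(cfg)
  hh <- build_host(cfg, d)
  expect_equal(nrow(hh$truth$insert_table), 0L)
  expect_equal(nrow(hh$truth$shared_genes), 0L)
})

test_that("zero insert divergence copies exact donor substrings", {
  cfg <- tiny_config(seed = 15, insert_divergence = 0, nonsense_rate = 0)
  d <- simulate_donors(cfg)
  hh <- build_host(cfg, d)
  it <- hh$truth$insert_table
  expect_gt(nrow(it), 0L)
  for (i in seq_len(nrow(it))) {
    hostpiece <- substr(hh$host$sequence, it$host_start[i] + 1L, it$host_end[i])
    donorpiece <- substr(d[[it$donor[i]]]$sequence, it$src_start[i] + 1L,
                         it$src_end[i])
    expect_identical(hostpiece, donorpiece)
  }
})

test_that("nonsense mutations create in-frame stops absent from the donor", {
  # dense genes so every insert overlaps one; nonsense_rate 1 forces the edit
  cfg <- sim_config(seed = 16, ancestor_length = 12000L, n_genes = 10L,
                    gene_length = 900L, n_mobile = 1L, mobile_length = 1000L,
                    host_length = 30000L, inserts_per_donor = 2L,
                    insert_length = 4000L, insert_divergence = 0,
                    nonsense_rate = 1, indel_rate_donors = 0)
  d <- simulate_donors(cfg)
  hh <- build_host(cfg, d)
  it <- hh$truth$insert_table
  expect_true(any(it$nonsense))
  for (i in which(it$nonsense)) {
    dn <- d[[it$donor[i]]]
    created <- FALSE
    for (j in seq_len(nrow(dn$genes))) {
      gs <- dn$genes$start[j]; ge <- dn$genes$end[j]
      strand <- dn$genes$strand[j]
      n_codon <- (ge - gs) %/% 3L
      if (n_codon == 0L) next
      fwd_starts <- if (strand == "+") gs + 3L * (seq_len(n_codon) - 1L)
                    else ge - 3L * seq_len(n_codon)
      for (fs in fwd_starts) {
        if (fs < it$src_start[i] || fs + 3L > it$src_end[i]) next
        dc <- substr(dn$sequence, fs + 1L, fs + 3L)
        hc <- substr(hh$host$sequence,
                     it$host_start[i] + (fs - it$src_start[i]) + 1L,
                     it$host_start[i] + (fs - it$src_start[i]) + 3L)
        if (strand == "-") { dc <- rc_seq(dc); hc <- rc_seq(hc) }
        stops <- c("TAA", "TAG", "TGA")
        if (hc %in% stops && !(dc %in% stops)) created <- TRUE
      }
    }
    expect_true(created)
  }
})

test_that("read counts, labels and determinism follow the sampling design", {
  cfg <- tiny_config(seed = 17)
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  # determinism: identical config -> byte-identical reads and truth
  expect_identical(sim1$reads1, sim2$reads1)
  expect_identical(sim1$reads2, sim2$reads2)
  expect_identical(sim1$truth$read_table, sim2$truth$read_table)

  # expected pair count: depth * length / (2 * read_length) for both classes
  ins_len <- sum(sim1$truth$insert_table$host_end -
                 sim1$truth$insert_table$host_start)
  expected <- round(cfg$background_coverage_depth * cfg$host_length /
                    (2 * cfg$read_length)) +
              round((cfg$insert_coverage_depth - cfg$background_coverage_depth) *
                    ins_len / (2 * cfg$read_length))
  expect_equal(length(sim1$reads1), expected)
  expect_equal(length(sim1$reads2), expected)

  # every read id labeled exactly once
  rt <- sim1$truth$read_table
  expect_setequal(rt$read_id, c(names(sim1$reads1), names(sim1$reads2)))
  expect_equal(anyDuplicated(rt$read_id), 0L)

  # truth consistency: donor-labeled reads have midpoints inside an insert
  # interval of that donor
  it <- sim1$truth$insert_table
  don <- rt[rt$donor != "host", ]
  mid <- (don$host_start + don$host_end) %/% 2L
  ok <- vapply(seq_len(nrow(don)), function(i)
    any(mid[i] >= it$host_start & mid[i] < it$host_end &
        it$donor == don$donor[i]), logical(1))
  expect_true(all(ok))
})

test_that("error-free reads in zero-divergence inserts are donor substrings", {
  cfg <- tiny_config(seed = 18, insert_divergence = 0, error_rate = 0,
                     nonsense_rate = 0)
  sim <- simulate_dataset(cfg)
  rt <- sim$truth$read_table
  it <- sim$truth$insert_table
  reads <- c(sim$reads1, sim$reads2)
  sel <- rt[rt$donor == "A", ]
  inside <- vapply(seq_len(nrow(sel)), function(i)
    any(sel$host_start[i] >= it$host_start & sel$host_end[i] <= it$host_end),
    logical(1))
  sel <- head(sel[inside, ], 40)
  for (i in seq_len(nrow(sel))) {
    r <- reads[[sel$read_id[i]]]
    hit <- grepl(r, sim$donors$A$sequence, fixed = TRUE) ||
           grepl(rc_seq(r), sim$donors$A$sequence, fixed = TRUE)
    expect_true(hit)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(gc = 1.4), "0, 1")
  expect_error(sim_config(inserts_per_donor = 100L, insert_length = 5000L,
                          host_length = 100000L), "fit")
  cfg <- tiny_config(seed = 1, insert_coverage_depth = 0,
                     background_coverage_depth = 0)
  d <- simulate_donors(cfg)
  hh <- build_host(cfg, d)
  expect_error(simulate_reads(cfg, hh$host, hh$truth), "depth")
  expect_error(sim_config(n_genes = 100L, gene_length = 900L,
                          ancestor_length = 20000L) |> simulate_donors(),
               "overlap")
})
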