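# Independent brute-force oracles and small generators used across tests.

rand_genome <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_seq <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(ch)) < rate)
  for (k in idx) ch[k] <- sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1L)
  paste(ch, collapse = "")
}

indel_seq <- function(s, n_events) {
  for (k in seq_len(n_events)) {
    L <- nchar(s)
    p <- sample(2:(L - 4), 1)
    if (runif(1) < 0.5) {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                          replace = TRUE), collapse = "")
      s <- paste0(substr(s, 1, p), ins, substr(s, p + 1, L))
    } else {
      s <- paste0(substr(s, 1, p), substr(s, p + 1 + sample(1:3, 1), L))
    }
  }
  s
}

rc_seq <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# position-set union of covered reference bases
bf_covered_bases <- function(alignments) {
  a <- alignments[which(alignments$mapped), , drop = FALSE]
  if (!nrow(a)) return(0L)
  pos <- unlist(lapply(seq_len(nrow(a)), function(i)
    seq(a$ref_start[i], a$ref_end[i] - 1L)))
  length(unique(pos))
}

# exhaustive N50: check every candidate length
bf_n50 <- function(lengths) {
  total <- sum(lengths)
  best <- NA_integer_
  for (L in sort(unique(lengths))) {
    if (sum(lengths[lengths >= L]) >= total / 2) best <- L
  }
  best
}

# single-linkage clusters via hclust, returned as a canonical partition
bf_single_linkage <- function(idmat, cutoff) {
  if (nrow(idmat) == 1L) return(list(sort(rownames(idmat))))
  d <- stats::as.dist(100 - idmat)
  cl <- stats::cutree(stats::hclust(d, method = "single"),
                      h = 100 - 100 * cutoff)
  unname(lapply(split(names(cl), cl), sort))
}

canonical_partition <- function(clusters) {
  p <- unname(lapply(clusters, sort))
  p[order(vapply(p, `[`, character(1), 1L))]
}

# gap-free percent identity oracle on explicit character vectors
bf_identity <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  round(100 * sum(av == bv & ok) / sum(ok), 1)
}

fixture_path <- function(name)
  system.file("extdata", name, package = "nuwtscan", mustWork = TRUE)

# small-but-realistic simulation config used by several tests
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, ancestor_length = 20000L, n_genes = 12L,
                   gene_length = 600L, n_mobile = 1L, mobile_length = 1500L,
                   host_length = 40000L, inserts_per_donor = 2L,
                   insert_length = 2500L, insert_coverage_depth = 8,
                   background_coverage_depth = 0.5)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# in-frame stop codons of a (possibly strand-reversed) gene subsequence
stops_in_frame <- function(seq, strand = "+") {
  if (strand == "-") seq <- rc_seq(seq)
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(integer(0))
  starts <- 3L * (seq_len(n) - 1L) + 1L
  which(substring(seq, starts, starts + 2L) %in% c("TAA", "TAG", "TGA"))
}
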