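#' Mapping parameters
#'
#' Acceptance thresholds and alignment costs for the read mapper.  The four
#' named presets correspond to the threshold combinations used throughout
#' the pipeline: `standard` (80% similarity over 80% read length), `strict`
#' (90/90), `relaxed` (70/90) and `screen_low` (65/80).  Costs default to
#' mismatch 2, insertion 3, deletion 3 with a match reward of 1, which makes
#' the stated costs a complete linear-gap scoring scheme.
#'
#' An alignment is acceptable iff
#' `n_match / columns >= similarity_fraction` (columns include gap columns)
#' and `(n_match + n_mismatch + n_ins) / read_length >= length_fraction`.
#'
#' @param preset one of `"standard"`, `"strict"`, `"relaxed"`,
#'   `"screen_low"`, or `NULL` to set thresholds explicitly.
#' @param similarity_fraction minimum identity over alignment columns.
#' @param length_fraction minimum fraction of the read that must be aligned.
#' @param mismatch_cost,insertion_cost,deletion_cost,match_reward positive
#'   alignment costs/reward.
#' @param seed_kmer exact-match seed length for the seed-and-extend mapper.
#' @param ambiguous_policy how equal-score placements are resolved:
#'   `"discard"` (deterministic smallest `(ref_start, strand)`) or
#'   `"random"` (seeded RNG).
#' @param rng_seed integer seed driving all random tie-breaking.
#' @return A list of class `mapping_params`.
#' @export
mapping_params <- function(preset = NULL,
                           similarity_fraction = 0.8,
                           length_fraction = 0.8,
                           mismatch_cost = 2, insertion_cost = 3,
                           deletion_cost = 3, match_reward = 1,
                           seed_kmer = 15L,
                           ambiguous_policy = c("discard", "random"),
                           rng_seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("standard", "strict", "relaxed", "screen_low"))
    th <- switch(preset,
                 standard   = c(0.80, 0.80),
                 strict     = c(0.90, 0.90),
                 relaxed    = c(0.70, 0.90),
                 screen_low = c(0.65, 0.80))
    similarity_fraction <- th[1]
    length_fraction <- th[2]
  }
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(similarity_fraction >= 0, similarity_fraction <= 1,
            length_fraction >= 0, length_fraction <= 1,
            mismatch_cost > 0, insertion_cost > 0, deletion_cost > 0,
            match_reward > 0, seed_kmer >= 4)
  structure(list(similarity_fraction = similarity_fraction,
                 length_fraction = length_fraction,
                 mismatch_cost = mismatch_cost,
                 insertion_cost = insertion_cost,
                 deletion_cost = deletion_cost,
                 match_reward = match_reward,
                 seed_kmer = as.integer(seed_kmer),
                 ambiguous_policy = ambiguous_policy,
                 rng_seed = as.integer(rng_seed),
                 preset = if (is.null(preset)) NA_character_ else preset),
            class = "mapping_params")
}

#' @export
print.mapping_params <- function(x, ...) {
  cat(sprintf(
    "<mapping_params> %s: similarity >= %.2f over >= %.2f of read; costs mm=%g ins=%g del=%g (match +%g); seed k=%d; ties=%s\n",
    ifelse(is.na(x$preset), "custom", x$preset),
    x$similarity_fraction, x$length_fraction, x$mismatch_cost,
    x$insertion_cost, x$deletion_cost, x$match_reward, x$seed_kmer,
    x$ambiguous_policy))
  invisible(x)
}

as_read_vector <- function(reads) {
  if (is(reads, "DNAStringSet") || is(reads, "BStringSet")) {
    reads <- setNames(as.character(reads), names(reads))
  }
  stopifnot(is.character(reads))
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  reads
}

#' Map reads to a reference genome (seed-and-extend)
#'
#' Candidate placements are found by exact k-mer seeding on both strands
#' (with layered re-seeding at shorter k for sensitivity) and extended by
#' windowed local alignment with free read ends under the linear-gap
#' scoring of `params`.  The acceptable placement with maximal score is
#' returned per read; score ties within the genome are broken by seeded RNG
#' when `ambiguous_policy = "random"`, otherwise deterministically by
#' smallest `(ref_start, strand)`.  Reads with no acceptable placement are
#' reported unmapped.
#'
#' @param reads named character vector (or `DNAStringSet`) of read
#'   sequences.
#' @param genome a [reference_genome()] or a single DNA string.
#' @param params a [mapping_params()] object.
#' @return `data.frame` with one row per read: `read_id`, `genome_id`,
#'   `mapped`, `strand`, `ref_start`/`ref_end` (0-based half-open),
#'   `read_start`/`read_end`, edit counts, `score`, `similarity`,
#'   `aligned_read_fraction`, `cigar` and `n_best` (number of equal-best
#'   acceptable placements).
#' @export
map_reads <- function(reads, genome, params = mapping_params()) {
  stopifnot(is(params, "mapping_params"))
  reads <- as_read_vector(reads)
  seqs <- vapply(reads, normalize_dna, character(1))
  df <- cpp_map_reads(unname(seqs), names(reads), genome_sequence(genome),
                      unclass(params))
  df$genome_id <- genome_id(genome)
  df
}

#' Map a single read (convenience wrapper)
#'
#' @inheritParams map_reads
#' @param read_sequence a single read sequence.
#' @return One-row alignment `data.frame`; see [map_reads()].
#' @export
map_read <- function(read_sequence, genome, params = mapping_params()) {
  map_reads(c(read = read_sequence), genome, params)
}

#' Exhaustive dynamic-programming mapping oracle
#'
#' Scores every start position on both strands of the genome under exactly
#' the scoring and acceptance rules of [map_reads()], with identical tie
#' breaking.  Intended as an independent test oracle; refuses genomes
#' longer than 10 kb.
#'
#' @inheritParams map_reads
#' @param read_sequence a single read sequence (or named vector of reads).
#' @return Alignment `data.frame` as for [map_reads()].
#' @export
oracle_map <- function(read_sequence, genome, params = mapping_params()) {
  stopifnot(is(params, "mapping_params"))
  reads <- as_read_vector(read_sequence)
  seqs <- vapply(reads, normalize_dna, character(1))
  df <- cpp_oracle_map(unname(seqs), names(reads), genome_sequence(genome),
                       unclass(params))
  df$genome_id <- genome_id(genome)
  df
}

#' Count reference bases covered by accepted alignments
#'
#' Size of the union of reference positions consumed by match/mismatch/
#' deletion columns of the given alignments.  Each accepted alignment
#' covers the contiguous interval `[ref_start, ref_end)`.
#'
#' @param alignments alignment `data.frame` (rows with `mapped = FALSE`
#'   are ignored).
#' @param genome_id optional genome id filter.
#' @return Integer number of covered reference bases.
#' @export
covered_bases <- function(alignments, genome_id = NULL) {
  if (is.null(alignments) || nrow(alignments) == 0L) return(0L)
  a <- alignments[which(alignments$mapped), , drop = FALSE]
  if (!is.null(genome_id)) a <- a[a$genome_id == genome_id, , drop = FALSE]
  if (nrow(a) == 0L) return(0L)
  ir <- IRanges::IRanges(start = a$ref_start + 1L, end = a$ref_end)
  sum(IRanges::width(IRanges::reduce(ir)))
}
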