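#' Competitive (mutually exclusive) multi-genome read assignment
#'
#' Each read is mapped independently against every genome under the same
#' parameters and assigned to the genome holding the strictly best accepted
#' score.  Reads whose best accepted score is tied across genomes are
#' `ambiguous`; with `ambiguous_policy = "random"` the tie is resolved by a
#' seeded RNG (as in a two-genome competitive mapping with random placement
#' of non-specific reads), with `"discard"` they stay ambiguous (as in a
#' multi-supergroup screen).  Reads with no accepted alignment anywhere are
#' `unmapped`.
#'
#' @param reads named character vector of read sequences.
#' @param genomes list of [reference_genome()] objects (or named character
#'   vector of sequences); at least one, with unique ids.
#' @param params a [mapping_params()].
#' @return Object of class `attribution_result`: list with `assignments`
#'   (`data.frame`: `read_id`, `assigned`, `score`, `tied`), `alignments`
#'   (per-genome alignment `data.frame`s covering all reads), `specific`
#'   (filled by [reciprocal_specificity()]), and `params`.
#' @export
competitive_map <- function(reads, genomes, params = mapping_params()) {
  reads <- as_read_vector(reads)
  genomes <- as_genome_list(genomes)
  ids <- names(genomes)
  if (anyDuplicated(ids)) stop("duplicate genome ids")

  alns <- lapply(genomes, function(g) map_reads(reads, g, params))
  score_mat <- vapply(alns, function(a) ifelse(a$mapped, a$score, -Inf),
                      numeric(length(reads)))
  score_mat <- matrix(score_mat, nrow = length(reads), ncol = length(genomes),
                      dimnames = list(names(reads), ids))
  best <- apply(score_mat, 1L, max)
  n_best <- rowSums(score_mat == best & is.finite(score_mat))

  assigned <- rep("unmapped", length(reads))
  assigned[is.finite(best) & n_best == 1L] <-
    ids[apply(score_mat[is.finite(best) & n_best == 1L, , drop = FALSE],
              1L, which.max)]
  tie <- which(is.finite(best) & n_best > 1L)
  tied <- is.finite(best) & n_best > 1L
  if (length(tie)) {
    if (params$ambiguous_policy == "random") {
      assigned[tie] <- local_seed(params$rng_seed + 7L, {
        vapply(tie, function(i) {
          cand <- ids[score_mat[i, ] == best[i]]
          cand[sample.int(length(cand), 1L)]
        }, character(1))
      })
    } else {
      assigned[tie] <- "ambiguous"
    }
  }
  structure(list(
    assignments = data.frame(read_id = names(reads), assigned = assigned,
                             score = ifelse(is.finite(best), best, NA_real_),
                             tied = tied, stringsAsFactors = FALSE,
                             row.names = NULL),
    alignments = alns,
    specific = NULL,
    params = params), class = "attribution_result")
}

as_genome_list <- function(genomes) {
  if (is(genomes, "reference_genome")) genomes <- list(genomes)
  if (is.character(genomes)) {
    if (is.null(names(genomes))) stop("character genomes must be named")
    genomes <- lapply(seq_along(genomes), function(i)
      reference_genome(names(genomes)[i], genomes[[i]]))
  }
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  nm <- vapply(genomes, function(g) genome_id(g), character(1))
  setNames(genomes, nm)
}

#' @export
print.attribution_result <- function(x, ...) {
  tab <- table(x$assignments$assigned)
  cat("<attribution_result> ", nrow(x$assignments), " reads: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$specific))
    cat("  specific reads: ", sum(x$specific$specific), " of ",
        nrow(x$specific), " assigned\n", sep = "")
  invisible(x)
}

#' Reciprocal-mapping specificity classification
#'
#' Every read assigned to genome X is remapped alone against the other
#' genome Y under the same parameters; a read that accepts any placement on
#' Y is non-specific, otherwise specific.  Requires exactly two genomes.
#'
#' @param result an `attribution_result` from [competitive_map()].
#' @param reads the read vector used for the competitive mapping.
#' @param genomes the two genomes used for the competitive mapping.
#' @param params a [mapping_params()] (typically the same as used before).
#' @return `result` with `specific` filled: `data.frame` of `read_id`,
#'   `assigned`, `specific`.
#' @export
reciprocal_specificity <- function(result, reads, genomes,
                                   params = result$params) {
  stopifnot(is(result, "attribution_result"))
  genomes <- as_genome_list(genomes)
  if (length(genomes) != 2L)
    stop("reciprocal specificity is defined for exactly 2 genomes")
  reads <- as_read_vector(reads)
  ids <- names(genomes)
  rows <- list()
  for (gi in 1:2) {
    own <- ids[gi]; other <- ids[3L - gi]
    rid <- result$assignments$read_id[result$assignments$assigned == own]
    if (!length(rid)) next
    remap <- map_reads(reads[rid], genomes[[other]], params)
    rows[[own]] <- data.frame(read_id = rid, assigned = own,
                              specific = !remap$mapped,
                              stringsAsFactors = FALSE)
  }
  result$specific <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
                     else data.frame(read_id = character(),
                                     assigned = character(),
                                     specific = logical(),
                                     stringsAsFactors = FALSE)
  result
}

#' Insert-size estimate from specific reads
#'
#' The specific reads of each genome are remapped to that genome alone and
#' the union of covered reference bases is reported as the per-genome
#' insert-size estimate.
#'
#' @inheritParams reciprocal_specificity
#' @return Named list per genome: `covered_bp_specific` (the estimate) and
#'   the remapped `alignments`.
#' @export
insert_size_estimate <- function(result, reads, genomes,
                                 params = result$params) {
  stopifnot(is(result, "attribution_result"))
  if (is.null(result$specific))
    stop("run reciprocal_specificity() first")
  genomes <- as_genome_list(genomes)
  reads <- as_read_vector(reads)
  out <- list()
  for (own in names(genomes)) {
    rid <- result$specific$read_id[result$specific$assigned == own &
                                   result$specific$specific]
    if (!length(rid)) {
      out[[own]] <- list(covered_bp_specific = 0L, alignments = NULL)
      next
    }
    remap <- map_reads(reads[rid], genomes[[own]], params)
    out[[own]] <- list(covered_bp_specific = covered_bases(remap),
                       alignments = remap)
  }
  out
}

#' Multi-genome screen across parameter sets
#'
#' Runs [competitive_map()] with `ambiguous_policy = "discard"` for each
#' parameter set over three or more genomes and tabulates reads assigned
#' and reference bases covered per genome, plus the fraction of all
#' assigned reads captured by a designated genome subset.
#'
#' @param reads named character vector of read sequences.
#' @param genomes list of at least three genomes.
#' @param params_list named list of [mapping_params()] objects.
#' @param focal_genomes character vector of genome ids making up the
#'   designated subset (default: the first two genomes).
#' @return `data.frame` with one row per (parameter set, genome):
#'   `params`, `genome_id`, `reads_assigned`, `covered_bp`, plus the
#'   per-parameter-set `focal_fraction` repeated on each row.
#' @export
multi_genome_screen <- function(reads, genomes, params_list,
                                focal_genomes = NULL) {
  genomes <- as_genome_list(genomes)
  if (length(genomes) < 3L) stop("the screen expects at least 3 genomes")
  if (is.null(focal_genomes)) focal_genomes <- names(genomes)[1:2]
  if (is.null(names(params_list)))
    names(params_list) <- paste0("params", seq_along(params_list))
  rows <- list()
  for (pn in names(params_list)) {
    p <- params_list[[pn]]
    if (p$ambiguous_policy != "random") p$ambiguous_policy <- "discard"
    else stop("the multi-genome screen discards ambiguous reads; ",
              "use ambiguous_policy = 'discard'")
    res <- competitive_map(reads, genomes, p)
    asg <- res$assignments
    n_assigned_total <- sum(asg$assigned %in% names(genomes))
    focal <- sum(asg$assigned %in% focal_genomes)
    for (g in names(genomes)) {
      rid <- asg$read_id[asg$assigned == g]
      aln <- res$alignments[[g]]
      aln <- aln[aln$read_id %in% rid, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        params = pn, genome_id = g,
        reads_assigned = length(rid),
        covered_bp = covered_bases(aln),
        focal_fraction = if (n_assigned_total > 0)
          focal / n_assigned_total else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-genome attribution summary
#'
#' @param result an `attribution_result` (specificity optional).
#' @return `data.frame`: per genome, reads assigned, reads specific,
#'   covered bp over all assigned reads and over specific reads.
#' @export
attribution_summary <- function(result) {
  stopifnot(is(result, "attribution_result"))
  ids <- names(result$alignments)
  rows <- lapply(ids, function(g) {
    rid <- result$assignments$read_id[result$assignments$assigned == g]
    aln <- result$alignments[[g]]
    aln <- aln[aln$read_id %in% rid, , drop = FALSE]
    spec_n <- NA_integer_; spec_bp <- NA_integer_
    if (!is.null(result$specific)) {
      srid <- result$specific$read_id[result$specific$assigned == g &
                                      result$specific$specific]
      spec_n <- length(srid)
      spec_bp <- covered_bases(aln[aln$read_id %in% srid, , drop = FALSE])
    }
    data.frame(genome_id = g, reads_assigned = length(rid),
               reads_specific = spec_n,
               covered_bp = covered_bases(aln),
               covered_bp_specific = spec_bp, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
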