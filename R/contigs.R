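pileup_of <- function(alignments, genome, reads) {
  a <- alignments[which(alignments$mapped), , drop = FALSE]
  gseq <- genome_sequence(genome)
  if (nrow(a) == 0L)
    return(list(depth = integer(nchar(gseq)),
                base_counts = matrix(0L, 4, nchar(gseq))))
  reads <- as_read_vector(reads)
  miss <- setdiff(a$read_id, names(reads))
  if (length(miss)) stop("read sequences missing for: ",
                         paste(head(miss, 3), collapse = ", "))
  oriented <- unname(reads[a$read_id])
  neg <- a$strand == "-"
  if (any(neg)) oriented[neg] <- revcomp(oriented[neg])
  cpp_pileup(nchar(gseq), a$ref_start, a$cigar, oriented)
}

#' Build consensus contigs from mapped reads
#'
#' Contigs are the maximal reference intervals with read depth >= 1;
#' within a contig the consensus base at each reference column is the
#' plurality over aligned read bases, with ties broken toward the
#' reference base (columns covered only by read deletions also fall back
#' to the reference base).  Read insertions are excluded: the consensus is
#' reported in the reference frame.
#'
#' @param alignments accepted alignments on one genome (see [map_reads()]).
#' @param genome the [reference_genome()] the reads were mapped to.
#' @param reads named character vector of the read sequences.
#' @return `data.frame` of contigs: `genome_id`, `start`, `end` (0-based
#'   half-open), `length`, `consensus`, `mean_depth` and `region_label`
#'   (`"phage"` if >= 50% of the interval overlaps the genome's mobile
#'   regions, else `"non-phage"`).
#' @export
contigs_from_alignments <- function(alignments, genome, reads) {
  gseq <- genome_sequence(genome)
  pl <- pileup_of(alignments, genome, reads)
  depth <- pl$depth
  covered <- depth > 0L
  if (!any(covered)) {
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      consensus = character(), mean_depth = numeric(),
                      region_label = character(), stringsAsFactors = FALSE))
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)

  counts <- pl$base_counts
  bases <- c("A", "C", "G", "T")
  ref_chars <- strsplit(gseq, "", fixed = TRUE)[[1]]
  consensus_at <- function(lo, hi) {    # 1-based inclusive
    cols <- counts[, lo:hi, drop = FALSE]
    mx <- apply(cols, 2L, max)
    out <- character(hi - lo + 1L)
    for (j in seq_along(out)) {
      if (mx[j] == 0L) { out[j] <- ref_chars[lo + j - 1L]; next }
      top <- bases[cols[, j] == mx[j]]
      out[j] <- if (length(top) == 1L) top
                else if (ref_chars[lo + j - 1L] %in% top) ref_chars[lo + j - 1L]
                else top[1L]
    }
    paste(out, collapse = "")
  }

  mob <- if (is(genome, "reference_genome")) genome$mobile_regions else NULL
  rows <- lapply(runs, function(k) {
    lo <- starts[k]; hi <- ends[k]
    data.frame(genome_id = genome_id(genome), start = lo - 1L, end = hi,
               length = hi - lo + 1L,
               consensus = consensus_at(lo, hi),
               mean_depth = mean(depth[lo:hi]),
               stringsAsFactors = FALSE)
  })
  contigs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  contigs$region_label <- label_regions(contigs, mob)
  contigs
}

# "phage" when >= 50% of the contig interval overlaps mobile regions
label_regions <- function(contigs, mobile_regions) {
  if (is.null(mobile_regions) || nrow(mobile_regions) == 0L ||
      nrow(contigs) == 0L)
    return(rep("non-phage", nrow(contigs)))
  vapply(seq_len(nrow(contigs)), function(i) {
    ov <- pmin(contigs$end[i], mobile_regions$end) -
          pmax(contigs$start[i], mobile_regions$start)
    frac <- sum(pmax(ov, 0L)) / (contigs$end[i] - contigs$start[i])
    if (frac >= 0.5) "phage" else "non-phage"
  }, character(1))
}

#' Contig length statistics stratified by mobile regions
#'
#' N50 is the largest length L such that contigs of length >= L sum to at
#' least half the class's total contig length.
#'
#' @param contigs contig `data.frame` from [contigs_from_alignments()].
#' @param mobile_regions optional `data.frame` (`start`, `end`, 0-based
#'   half-open) used to (re)label contigs; if `NULL`, existing
#'   `region_label`s are used.
#' @return `data.frame` with one row per region class: `region_label`,
#'   `n`, `mean_length`, `n50`.
#' @export
contig_stats <- function(contigs, mobile_regions = NULL) {
  if (is.null(contigs) || nrow(contigs) == 0L)
    return(data.frame(region_label = character(), n = integer(),
                      mean_length = numeric(), n50 = integer(),
                      stringsAsFactors = FALSE))
  if (!is.null(mobile_regions))
    contigs$region_label <- label_regions(contigs, mobile_regions)
  if (is.null(contigs$region_label)) contigs$region_label <- "non-phage"
  rows <- lapply(split(contigs$length, contigs$region_label), function(l) {
    data.frame(n = length(l), mean_length = mean(l), n50 = n50(l))
  })
  out <- do.call(rbind, rows)
  out <- data.frame(region_label = rownames(out), out,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$region_label), , drop = FALSE]
}

#' N50 of a set of lengths
#'
#' @param lengths integer vector of contig lengths.
#' @return Largest L such that lengths >= L sum to >= half the total.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) return(NA_integer_)
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  min(lengths)
}

#' Per-position coverage track
#'
#' Raw depths are retained; a display column caps depth at
#' `max_depth_cap` (for plotting, mirroring a capped circular coverage
#' ring rendered as a linear track).
#'
#' @param alignments accepted alignments on one genome.
#' @param genome the reference genome.
#' @param reads named character vector of read sequences.
#' @param max_depth_cap display cap (default 30).
#' @param tsv optional path: write `pos`, `depth`, `display_depth` TSV.
#' @param plot_file optional path: write a PNG of the capped track.
#' @return `data.frame` with `pos` (0-based), `depth`, `display_depth`.
#' @export
coverage_track <- function(alignments, genome, reads, max_depth_cap = 30L,
                           tsv = NULL, plot_file = NULL) {
  pl <- pileup_of(alignments, genome, reads)
  df <- data.frame(pos = seq_along(pl$depth) - 1L, depth = pl$depth,
                   display_depth = pmin(pl$depth, max_depth_cap))
  if (!is.null(tsv))
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 1200, height = 300)
    graphics::plot(df$pos, df$display_depth, type = "s", xlab = "position",
                   ylab = sprintf("depth (capped at %d)", max_depth_cap),
                   main = genome_id(genome))
    grDevices::dev.off()
  }
  df
}
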