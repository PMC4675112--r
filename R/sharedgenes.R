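#' Parameters for dual-origin (shared) gene detection
#'
#' @param similarity_fraction,length_fraction relaxed thresholds used when
#'   mapping each donor's specific reads to the reciprocal genome
#'   (defaults 70% similarity over 90% of read length).
#' @param min_gene_read_bp minimum summed aligned read-bp on a gene; all
#'   four support values (own and reciprocal, both read classes) must
#'   exceed this (default 80 bp).
#' @return List of class `shared_gene_params`.
#' @export
shared_gene_params <- function(similarity_fraction = 0.70,
                               length_fraction = 0.90,
                               min_gene_read_bp = 80L) {
  stopifnot(min_gene_read_bp > 0)
  structure(list(similarity_fraction = similarity_fraction,
                 length_fraction = length_fraction,
                 min_gene_read_bp = as.integer(min_gene_read_bp)),
            class = "shared_gene_params")
}

# summed overlap of accepted alignment reference spans with a gene interval
gene_support_bp <- function(alignments, gs, ge) {
  a <- alignments[which(alignments$mapped), , drop = FALSE]
  if (!nrow(a)) return(0L)
  ov <- pmin(a$ref_end, ge) - pmax(a$ref_start, gs)
  as.integer(sum(pmax(ov, 0)))
}

# percent identity of the pileup consensus to the reference over the
# covered columns of [gs, ge); NA when no column is covered by a read base
consensus_identity <- function(pileup, gseq, gs, ge) {
  cols <- (gs + 1L):ge
  counts <- pileup$base_counts[, cols, drop = FALSE]
  has_base <- colSums(counts) > 0L
  if (!any(has_base)) return(NA_real_)
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(substr(gseq, gs + 1L, ge), "", fixed = TRUE)[[1]]
  idx <- which(has_base)
  match <- 0L
  for (j in idx) {
    mx <- max(counts[, j])
    top <- bases[counts[, j] == mx]
    cons <- if (length(top) == 1L) top
            else if (ref[j] %in% top) ref[j] else top[1L]
    if (cons == ref[j]) match <- match + 1L
  }
  100 * match / length(idx)
}

#' Detect genes represented in both donors' inserts
#'
#' For each homolog pair, per-gene read support is computed as the summed
#' reference-bp overlap of accepted alignments with the gene interval:
#' stringent mapping of each read class on its own genome, relaxed mapping
#' on the reciprocal genome.  Pairs whose four supports all exceed
#' `min_gene_read_bp` are verified by consensus identity: the pileup
#' consensus of each read class must be closer to its own genome's gene
#' than to the reciprocal homolog.  A full record with the rejection
#' reason is emitted for every homolog pair.
#'
#' @param a_reads,b_reads named character vectors: the donor-A-specific
#'   and donor-B-specific reads (see [reciprocal_specificity()]).
#' @param genome_a,genome_b the two donor [reference_genome()]s.
#' @param homologs `data.frame` with columns `gene_a`, `gene_b`.
#' @param stringent_params [mapping_params()] for own-genome mapping.
#' @param params a [shared_gene_params()].
#' @return `data.frame` with one row per homolog pair: supports
#'   (`a_on_a`, `a_on_b`, `b_on_b`, `b_on_a`), consensus identities
#'   (`id_a_own`, `id_a_cross`, `id_b_own`, `id_b_cross`), `shared`
#'   (logical) and `reason`.
#' @export
shared_gene_detection <- function(a_reads, b_reads, genome_a, genome_b,
                                  homologs,
                                  stringent_params = mapping_params("strict"),
                                  params = shared_gene_params()) {
  stopifnot(is(genome_a, "reference_genome"), is(genome_b, "reference_genome"))
  validate_homologs(homologs, genome_a, genome_b)
  relaxed <- stringent_params
  relaxed$similarity_fraction <- params$similarity_fraction
  relaxed$length_fraction <- params$length_fraction

  a_reads <- as_read_vector(a_reads)
  b_reads <- as_read_vector(b_reads)
  map_or_null <- function(reads, genome, p)
    if (length(reads)) map_reads(reads, genome, p) else NULL
  aln_aa <- map_or_null(a_reads, genome_a, stringent_params)
  aln_ab <- map_or_null(a_reads, genome_b, relaxed)
  aln_bb <- map_or_null(b_reads, genome_b, stringent_params)
  aln_ba <- map_or_null(b_reads, genome_a, relaxed)

  pil <- function(aln, genome, reads)
    if (is.null(aln)) NULL else pileup_of(aln, genome, reads)
  pl_aa <- pil(aln_aa, genome_a, a_reads)
  pl_ab <- pil(aln_ab, genome_b, a_reads)
  pl_bb <- pil(aln_bb, genome_b, b_reads)
  pl_ba <- pil(aln_ba, genome_a, b_reads)

  sup <- function(aln, gs, ge) if (is.null(aln)) 0L else gene_support_bp(aln, gs, ge)
  idy <- function(pl, gseq, gs, ge)
    if (is.null(pl)) NA_real_ else consensus_identity(pl, gseq, gs, ge)

  ga_tab <- genome_a$genes; gb_tab <- genome_b$genes
  rows <- lapply(seq_len(nrow(homologs)), function(i) {
    ga <- ga_tab[ga_tab$gene_id == homologs$gene_a[i], ]
    gb <- gb_tab[gb_tab$gene_id == homologs$gene_b[i], ]
    a_on_a <- sup(aln_aa, ga$start, ga$end)
    a_on_b <- sup(aln_ab, gb$start, gb$end)
    b_on_b <- sup(aln_bb, gb$start, gb$end)
    b_on_a <- sup(aln_ba, ga$start, ga$end)
    supports <- c(a_on_a, a_on_b, b_on_b, b_on_a)
    rec <- data.frame(gene_a = homologs$gene_a[i], gene_b = homologs$gene_b[i],
                      a_on_a = a_on_a, a_on_b = a_on_b,
                      b_on_b = b_on_b, b_on_a = b_on_a,
                      id_a_own = NA_real_, id_a_cross = NA_real_,
                      id_b_own = NA_real_, id_b_cross = NA_real_,
                      shared = FALSE, reason = "", stringsAsFactors = FALSE)
    if (all(supports == 0L)) { rec$reason <- "no support"; return(rec) }
    if (!all(supports > params$min_gene_read_bp)) {
      rec$reason <- "insufficient reciprocal support"; return(rec)
    }
    rec$id_a_own   <- idy(pl_aa, genome_a$sequence, ga$start, ga$end)
    rec$id_a_cross <- idy(pl_ab, genome_b$sequence, gb$start, gb$end)
    rec$id_b_own   <- idy(pl_bb, genome_b$sequence, gb$start, gb$end)
    rec$id_b_cross <- idy(pl_ba, genome_a$sequence, ga$start, ga$end)
    ok <- !anyNA(c(rec$id_a_own, rec$id_a_cross, rec$id_b_own, rec$id_b_cross)) &&
      rec$id_a_own > rec$id_a_cross && rec$id_b_own > rec$id_b_cross
    if (ok) { rec$shared <- TRUE; rec$reason <- "shared" }
    else rec$reason <- "identity order violated"
    rec
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Summary of dual-origin gene detection
#'
#' @param records output of [shared_gene_detection()].
#' @return List: `n_shared`, and per read class the mean and sd of the
#'   own-genome consensus identity over shared genes (omitted when no gene
#'   is shared).
#' @export
dual_origin_summary <- function(records) {
  sh <- records[records$shared, , drop = FALSE]
  out <- list(n_shared = nrow(sh))
  if (nrow(sh)) {
    out$mean_identity_a <- mean(sh$id_a_own)
    out$sd_identity_a <- sd(sh$id_a_own)
    out$mean_identity_b <- mean(sh$id_b_own)
    out$sd_identity_b <- sd(sh$id_b_own)
  }
  out
}
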