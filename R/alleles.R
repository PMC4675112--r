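#' Aligned allele set
#'
#' Holds equal-length aligned sequences over `{A,C,G,T,N,-}` (terminal N
#' padding marks shorter sequences; `-` marks alignment gaps), with
#' optional per-allele labels such as individual id and infection status.
#'
#' @param seqs named character vector of aligned sequences.
#' @param labels optional `data.frame` with one row per allele.
#' @return Object of class `allele_set`.
#' @export
allele_set <- function(seqs, labels = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("aligned sequences must all have the same length")
  bad <- gsub("[ACGTN-]", "", paste(seqs, collapse = ""))
  if (nzchar(bad))
    stop("aligned sequences may only contain A,C,G,T,N,-: found ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  structure(list(seqs = seqs, labels = labels, width = widths[1L]),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("<allele_set> ", length(x$seqs), " aligned sequences of ",
      x$width, " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA into an allele set
#'
#' @param path aligned FASTA (equal-length records over A,C,G,T,N,-).
#' @return An [allele_set()].
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  allele_set(setNames(as.character(set), ids))
}

#' Percent identity between two aligned sequences
#'
#' A column is comparable iff neither sequence has a gap (`-`) or `N` in
#' it; identity is matching comparable columns over comparable columns,
#' reported as a percentage to one decimal place.
#'
#' @param seq_a,seq_b aligned sequences of equal length.
#' @return Percent identity (one decimal).
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) == nchar(seq_b))
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  dna <- c("A", "C", "G", "T")
  comparable <- a %in% dna & b %in% dna
  if (!any(comparable))
    stop("identity undefined: no comparable columns")
  round(100 * sum(a == b & comparable) / sum(comparable), 1)
}

#' Pairwise identity matrix of an allele set
#'
#' @param x an [allele_set()].
#' @return Symmetric matrix of percent identities.
#' @export
identity_matrix <- function(x) {
  stopifnot(is(x, "allele_set"))
  n <- length(x$seqs)
  m <- matrix(100, n, n, dimnames = list(names(x$seqs), names(x$seqs)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- pairwise_identity(x$seqs[[i]], x$seqs[[j]])
  }
  m
}

#' Cluster alleles into haplotypes at an identity cutoff
#'
#' Single-linkage clusters over the graph whose edges join allele pairs
#' with identity >= cutoff, i.e. the connected components.  Cluster names
#' (`H1`, `H2`, ...) are assigned by decreasing size, then first-seen
#' order, so the result is invariant under input order.
#'
#' @param x an [allele_set()].
#' @param cutoff identity cutoff as a fraction (default 0.96).
#' @return List of class `haplotype_clustering`: `cutoff`, `membership`
#'   (named vector allele -> cluster name), `clusters` (list of member
#'   vectors).
#' @export
cluster_alleles <- function(x, cutoff = 0.96) {
  stopifnot(is(x, "allele_set"), cutoff >= 0, cutoff <= 1)
  m <- identity_matrix(x)
  n <- nrow(m)
  adj <- m >= 100 * cutoff
  # connected components by BFS
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp)
  first_seen <- vapply(seq_len(max(comp)), function(k) min(which(comp == k)),
                       integer(1))
  ord <- order(-sizes, first_seen)
  rank <- match(seq_along(ord), ord)
  names_out <- paste0("H", rank[comp])
  membership <- setNames(names_out, rownames(m))
  clusters <- split(names(membership), membership)
  clusters <- clusters[order(names(clusters))]
  structure(list(cutoff = cutoff, membership = membership,
                 clusters = clusters),
            class = "haplotype_clustering")
}

#' @export
print.haplotype_clustering <- function(x, ...) {
  cat("<haplotype_clustering> cutoff ", 100 * x$cutoff, "%: ",
      length(x$clusters), " clusters\n", sep = "")
  for (nm in names(x$clusters))
    cat("  ", nm, ": ", paste(x$clusters[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

STOPS <- c("TAA", "TAG", "TGA")

#' Infer the reading frame of an aligned allele set
#'
#' Chooses the frame offset (0, 1 or 2 columns from the alignment start)
#' minimizing the total number of in-frame stop codons across all alleles;
#' ties go to the smallest offset.  Codons containing gaps or N are not
#' counted.
#'
#' @param x an [allele_set()].
#' @return List: `frame` (0/1/2) and `stop_counts` (per-frame totals).
#' @export
infer_frame <- function(x) {
  stopifnot(is(x, "allele_set"), length(x$seqs) >= 1L)
  counts <- vapply(0:2, function(f) {
    total <- 0L
    for (s in x$seqs) {
      if (nchar(s) < f + 3L) next
      starts <- seq(f + 1L, nchar(s) - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      total <- total + sum(codons %in% STOPS)
    }
    total
  }, integer(1))
  list(frame = which.min(counts) - 1L, stop_counts = setNames(counts, 0:2))
}

allele_consensus <- function(x) {
  mat <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  dna <- c("A", "C", "G", "T")
  apply(mat, 2L, function(col) {
    col <- col[col %in% dna]
    if (!length(col)) return("N")
    tab <- table(factor(col, levels = dna))
    dna[which.max(tab)]   # ties resolve to the alphabetically first base
  })
}

#' Find premature stop codons created by substitution
#'
#' Scans each allele's in-frame codons before the final complete codon and
#' reports codons in `{TAA, TAG, TGA}` whose stop status was created by a
#' substitution relative to the column-majority consensus (the consensus
#' stands in for the ancestral state).  The position reported is the
#' 1-based alignment column of the (first) substituted base.
#'
#' @param x an [allele_set()].
#' @param frame_offset reading frame (0/1/2) from [infer_frame()].
#' @return `data.frame`: `allele`, `position` (1-based), `ref_base`,
#'   `alt_base`, `codon`.
#' @export
find_premature_stops <- function(x, frame_offset = 0L) {
  stopifnot(is(x, "allele_set"), frame_offset %in% 0:2)
  cons <- allele_consensus(x)
  W <- x$width
  starts <- if (W >= frame_offset + 3L) seq(frame_offset + 1L, W - 2L, by = 3L)
            else integer(0)
  if (length(starts) > 1L) starts <- starts[-length(starts)]  # before final codon
  else starts <- integer(0)
  rows <- list()
  for (nm in names(x$seqs)) {
    ch <- strsplit(x$seqs[[nm]], "", fixed = TRUE)[[1]]
    for (s in starts) {
      codon <- paste(ch[s:(s + 2L)], collapse = "")
      if (!codon %in% STOPS) next
      cons_codon <- paste(cons[s:(s + 2L)], collapse = "")
      if (cons_codon %in% STOPS || cons_codon == codon) next
      diff <- which(ch[s:(s + 2L)] != cons[s:(s + 2L)])[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        allele = nm, position = s + diff - 1L,
        ref_base = cons[s + diff - 1L], alt_base = ch[s + diff - 1L],
        codon = codon, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(allele = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      codon = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
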