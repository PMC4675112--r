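#' Reference genome with annotations
#'
#' Container for a donor or host reference sequence together with its gene
#' annotations and mobile-element (prophage) intervals.  All intervals are
#' stored 0-based half-open; 1-based inclusive coordinates appear only at
#' the GFF3/SAM boundaries.
#'
#' @param id single character genome identifier.
#' @param sequence DNA string over A, C, G, T, N.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`) and `product`; may be
#'   `NULL` for none.
#' @param mobile_regions `data.frame` with columns `start`, `end`
#'   (0-based half-open) flagging mobile/prophage intervals; may be `NULL`.
#' @return An object of class `reference_genome`.
#' @export
reference_genome <- function(id, sequence, genes = NULL, mobile_regions = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_dna(sequence, id)
  len <- nchar(sequence)
  if (len == 0L) stop("reference genome '", id, "' has an empty sequence")
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        product = character(), stringsAsFactors = FALSE)
  }
  if (is.null(mobile_regions)) {
    mobile_regions <- data.frame(start = integer(), end = integer(),
                                 stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  mobile_regions <- as.data.frame(mobile_regions, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene ids in genome '", id, "'")
    if (any(genes$end <= genes$start))
      stop("gene intervals must satisfy end > start in genome '", id, "'")
    if (any(genes$start < 0L) || any(genes$end > len))
      stop("gene interval outside [0, ", len, ") in genome '", id, "'")
    if (!all(genes$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-' in genome '", id, "'")
    if (is.null(genes$product)) genes$product <- ""
  }
  if (nrow(mobile_regions)) {
    if (any(mobile_regions$end <= mobile_regions$start))
      stop("mobile intervals must satisfy end > start in genome '", id, "'")
    if (any(mobile_regions$start < 0L) || any(mobile_regions$end > len))
      stop("mobile interval outside [0, ", len, ") in genome '", id, "'")
  }
  structure(list(id = id, sequence = sequence, genes = genes,
                 mobile_regions = mobile_regions),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", x$id, ": ", nchar(x$sequence), " bp, ",
      nrow(x$genes), " genes, ", nrow(x$mobile_regions),
      " mobile regions\n", sep = "")
  invisible(x)
}

genome_sequence <- function(genome) {
  if (is(genome, "reference_genome")) genome$sequence
  else if (is.character(genome) && length(genome) == 1L) genome
  else stop("expected a reference_genome or a single DNA string")
}

genome_id <- function(genome, default = "genome") {
  if (is(genome, "reference_genome")) genome$id else default
}

# uppercase, U -> T, validate alphabet
normalize_dna <- function(x, record = "<sequence>") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    stop("record '", record, "' contains non-DNA characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  x
}

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and U is mapped to T; characters outside
#' A, C, G, T, N are rejected with an error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("malformed FASTA header (empty id) in ", path)
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path)
  seqs <- as.character(set)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("record '", ids[i], "' in ", path, " is empty")
    seqs[i] <- normalize_dna(seqs[i], ids[i])
  }
  setNames(seqs, ids)
}

#' Write DNA sequences to a FASTA file
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(is.character(x), !is.null(names(x)))
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Assemble a reference genome from FASTA + GFF3 + BED files
#'
#' GFF3 gene features (1-based inclusive) and BED mobile-element intervals
#' (0-based half-open) are converted to the internal 0-based half-open
#' convention.  Features outside the sequence bounds raise an error.
#'
#' @param fasta_path FASTA with a single sequence record.
#' @param gff_path GFF3 with `gene` features, or `NULL` for none.
#' @param bed_path BED of mobile/prophage intervals, or `NULL` for none.
#' @return A [reference_genome()].
#' @export
read_annotations <- function(fasta_path, gff_path = NULL, bed_path = NULL) {
  seqs <- read_fasta(fasta_path)
  if (length(seqs) != 1L)
    stop("expected exactly one sequence record in ", fasta_path)
  id <- names(seqs)
  genes <- NULL
  if (!is.null(gff_path)) {
    gr <- rtracklayer::import(gff_path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "gene"]
    if (length(gr)) {
      gene_id <- as.character(gr$ID)
      if (all(is.na(gene_id)) && !is.null(gr$Name))
        gene_id <- as.character(gr$Name)
      product <- if (!is.null(gr$product)) as.character(gr$product) else ""
      product[is.na(product)] <- ""
      genes <- data.frame(
        gene_id = gene_id,
        start = GenomicRanges::start(gr) - 1L,  # 1-based -> 0-based
        end = GenomicRanges::end(gr),           # inclusive -> half-open
        strand = as.character(GenomicRanges::strand(gr)),
        product = product, stringsAsFactors = FALSE)
      genes$strand[!genes$strand %in% c("+", "-")] <- "+"
    }
  }
  mobile <- NULL
  if (!is.null(bed_path)) {
    gr <- rtracklayer::import(bed_path, format = "bed")
    if (length(gr)) {
      mobile <- data.frame(start = GenomicRanges::start(gr) - 1L,
                           end = GenomicRanges::end(gr),
                           stringsAsFactors = FALSE)
    }
  }
  reference_genome(id, seqs[[1L]], genes = genes, mobile_regions = mobile)
}

#' Write a reference genome's annotations to GFF3 and BED
#'
#' @param genome a [reference_genome()].
#' @param gff_path output GFF3 path for genes, or `NULL` to skip.
#' @param bed_path output BED path for mobile regions, or `NULL` to skip.
#' @return `genome`, invisibly.
#' @export
write_annotations <- function(genome, gff_path = NULL, bed_path = NULL) {
  stopifnot(is(genome, "reference_genome"))
  if (!is.null(gff_path) && nrow(genome$genes)) {
    g <- genome$genes
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand)
    gr$type <- "gene"
    gr$ID <- g$gene_id
    gr$product <- g$product
    rtracklayer::export(gr, gff_path, format = "gff3")
  }
  if (!is.null(bed_path) && nrow(genome$mobile_regions)) {
    m <- genome$mobile_regions
    gr <- GenomicRanges::GRanges(
      seqnames = genome$id,
      ranges = IRanges::IRanges(start = m$start + 1L, end = m$end))
    rtracklayer::export(gr, bed_path, format = "bed")
  }
  invisible(genome)
}

#' Read a two-column homolog table
#'
#' Tab-separated file pairing gene ids of genome A with gene ids of
#' genome B; a header line with columns `gene_a` and `gene_b` is required.
#'
#' @param path TSV path.
#' @param genome_a,genome_b optional [reference_genome()] objects used to
#'   validate that every referenced gene exists.
#' @return `data.frame` with columns `gene_a`, `gene_b`.
#' @export
read_homologs <- function(path, genome_a = NULL, genome_b = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab)))
    stop("homolog table must have columns 'gene_a' and 'gene_b'")
  tab <- tab[, c("gene_a", "gene_b")]
  validate_homologs(tab, genome_a, genome_b)
  tab
}

validate_homologs <- function(homologs, genome_a = NULL, genome_b = NULL) {
  if (anyDuplicated(homologs)) stop("duplicate pairs in homolog table")
  if (!is.null(genome_a)) {
    miss <- setdiff(homologs$gene_a, genome_a$genes$gene_id)
    if (length(miss))
      stop("homolog table references unknown genes in '", genome_a$id,
           "': ", paste(head(miss, 3), collapse = ", "))
  }
  if (!is.null(genome_b)) {
    miss <- setdiff(homologs$gene_b, genome_b$genes$gene_id)
    if (length(miss))
      stop("homolog table references unknown genes in '", genome_b$id,
           "': ", paste(head(miss, 3), collapse = ", "))
  }
  invisible(homologs)
}

#' Write alignments to a SAM file
#'
#' Emits a valid SAM with `@SQ` header lines, 1-based `POS` and the CIGAR
#' recorded by the mapper; unmapped reads are written with flag 4.
#'
#' @param alignments alignment `data.frame` as returned by [map_reads()]
#'   (one genome; must carry a `genome_id` column naming a reference).
#' @param references named character vector of reference sequences (or list
#'   of [reference_genome()]).
#' @param path output SAM path.
#' @param reads named character vector of read sequences (plus orientation);
#'   if `NULL`, SEQ is written as `*`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, references, path, reads = NULL) {
  if (is.list(references) && all(vapply(references, is, TRUE, "reference_genome"))) {
    refs <- vapply(references, function(g) g$sequence, character(1))
    names(refs) <- vapply(references, function(g) g$id, character(1))
  } else refs <- references
  stopifnot(is.character(refs), !is.null(names(refs)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(refs))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(refs[[nm]])), con)
  if (is.null(alignments) || nrow(alignments) == 0L) return(invisible(path))
  if (is.null(alignments$genome_id))
    stop("alignments must carry a 'genome_id' column")
  unknown <- setdiff(unique(alignments$genome_id[alignments$mapped]), names(refs))
  if (length(unknown))
    stop("alignments refer to unknown references: ",
         paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    seq_field <- "*"
    if (!is.null(reads) && a$read_id %in% names(reads)) {
      s <- reads[[a$read_id]]
      if (isTRUE(a$mapped) && identical(a$strand, "-"))
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      seq_field <- s
    }
    if (isTRUE(a$mapped)) {
      if (seq_field != "*" && cigar_read_span(a$cigar) != nchar(seq_field))
        stop("CIGAR '", a$cigar, "' inconsistent with sequence length for read '",
             a$read_id, "'")
      flag <- if (identical(a$strand, "-")) 16L else 0L
      writeLines(paste(a$read_id, flag, a$genome_id, a$ref_start + 1L, 60L,
                       a$cigar, "*", 0L, 0L, seq_field, "*", sep = "\t"), con)
    } else {
      writeLines(paste(a$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       seq_field, "*", sep = "\t"), con)
    }
  }
  invisible(path)
}

cigar_read_span <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  list(len = len, op = op)
}

#' Write paired reads to FASTQ files
#'
#' @param reads1,reads2 named character vectors of read sequences (mate 1
#'   and mate 2).
#' @param path1,path2 output FASTQ paths.
#' @param qual_char quality character used for every base.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq <- function(reads1, reads2, path1, path2, qual_char = "I") {
  wr <- function(reads, path) {
    lines <- character(4L * length(reads))
    lines[seq(1, by = 4, length.out = length(reads))] <- paste0("@", names(reads))
    lines[seq(2, by = 4, length.out = length(reads))] <- unname(reads)
    lines[seq(3, by = 4, length.out = length(reads))] <- "+"
    lines[seq(4, by = 4, length.out = length(reads))] <-
      vapply(nchar(reads), function(n) strrep(qual_char, n), character(1))
    writeLines(lines, path)
  }
  wr(reads1, path1)
  wr(reads2, path2)
  invisible(c(path1, path2))
}

#' Read single-end or paired FASTQ
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), by = 4)]))
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  setNames(seqs, ids)
}
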