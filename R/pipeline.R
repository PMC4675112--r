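#' Pipeline run configuration
#'
#' Bundles the simulation parameters, mapping presets, shared-gene
#' parameters and haplotype cutoff for an end-to-end run.  All randomness
#' flows from the single seed.
#'
#' @param seed global integer seed (propagated into the simulator and all
#'   random tie-breaking).
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param attribution_preset [mapping_params()] preset for the competitive
#'   two-donor mapping (default `"strict"`, i.e. 90/90).
#' @param ambiguous_policy tie policy for the two-donor mapping
#'   (default `"random"`).
#' @param shared a [shared_gene_params()].
#' @param cluster_cutoff haplotype identity cutoff (fraction).
#' @param allele_fasta optional aligned FASTA for the allele-level stage;
#'   `NULL` skips that stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = sim_config(),
                       attribution_preset = "strict",
                       ambiguous_policy = "random",
                       shared = shared_gene_params(),
                       cluster_cutoff = 0.96,
                       allele_fasta = NULL) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim,
                 attribution_preset = attribution_preset,
                 ambiguous_policy = ambiguous_policy,
                 shared = shared, cluster_cutoff = cluster_cutoff,
                 allele_fasta = allele_fasta),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on simulated data
#'
#' Simulate -> competitive two-donor mapping -> reciprocal specificity ->
#' insert-size estimation -> consensus contigs with region-stratified
#' stats -> shared-gene detection -> (optional) allele-level haplotype
#' analysis.  Identical config and seed produce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: per-stage TSV tables are written
#'   there deterministically.
#' @return A report list with per-stage summaries and the full
#'   intermediate objects under `$objects`.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL) {
  stopifnot(is(config, "run_config"))
  sim <- run_stage("simulate", simulate_dataset(config$sim))
  reads <- c(sim$reads1, sim$reads2)
  genomes <- list(sim$donors$A, sim$donors$B)
  params <- mapping_params(config$attribution_preset,
                           ambiguous_policy = config$ambiguous_policy,
                           rng_seed = config$seed)

  res <- run_stage("attribute", {
    r <- competitive_map(reads, genomes, params)
    reciprocal_specificity(r, reads, genomes, params)
  })
  est <- run_stage("insert-size",
                   insert_size_estimate(res, reads, genomes, params))

  contig_tabs <- run_stage("contigs", {
    lapply(setNames(names(res$alignments), names(res$alignments)),
           function(g) {
      rid <- res$assignments$read_id[res$assignments$assigned == g]
      aln <- res$alignments[[g]]
      aln <- aln[aln$read_id %in% rid, , drop = FALSE]
      gobj <- genomes[[which(vapply(genomes, genome_id, character(1)) == g)]]
      ctg <- contigs_from_alignments(aln, gobj, reads)
      list(contigs = ctg, stats = contig_stats(ctg))
    })
  })

  shared_records <- run_stage("shared-genes", {
    sp <- res$specific
    a_ids <- sp$read_id[sp$assigned == genome_id(genomes[[1]]) & sp$specific]
    b_ids <- sp$read_id[sp$assigned == genome_id(genomes[[2]]) & sp$specific]
    shared_gene_detection(reads[a_ids], reads[b_ids],
                          genomes[[1]], genomes[[2]], sim$homologs,
                          stringent_params = params, params = config$shared)
  })

  allele_report <- NULL
  if (!is.null(config$allele_fasta)) {
    allele_report <- run_stage("alleles", {
      aset <- read_aligned_fasta(config$allele_fasta)
      cl <- cluster_alleles(aset, config$cluster_cutoff)
      fr <- infer_frame(aset)
      list(n_alleles = length(aset$seqs),
           clustering = cl,
           frame = fr$frame,
           premature_stops = find_premature_stops(aset, fr$frame))
    })
  }

  report <- list(
    config = config,
    assignment_counts = table(res$assignments$assigned),
    attribution = attribution_summary(res),
    truth_evaluation = evaluate_attribution(res, sim$truth),
    insert_size = vapply(est, function(e) e$covered_bp_specific, numeric(1)),
    true_insert_bp = vapply(c(A = "A", B = "B"), function(d) {
      it <- sim$truth$insert_table
      sum(it$host_end[it$donor == d] - it$host_start[it$donor == d])
    }, numeric(1)),
    contig_stats = lapply(contig_tabs, `[[`, "stats"),
    shared_genes = shared_records,
    n_shared = sum(shared_records$shared),
    shared_truth = sim$truth$shared_genes,
    alleles = allele_report,
    objects = list(sim = sim, attribution = res, insert_size = est,
                   contigs = contig_tabs)
  )
  if (!is.null(out_dir)) write_report_tables(report, res, out_dir)
  report
}

write_report_tables <- function(report, res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(res$assignments, "assignments.tsv")
  if (!is.null(res$specific)) wt(res$specific, "specific.tsv")
  wt(report$attribution, "attribution_summary.tsv")
  wt(report$shared_genes, "shared_genes.tsv")
  for (g in names(report$contig_stats))
    wt(report$contig_stats[[g]], paste0("contig_stats_", g, ".tsv"))
  est <- data.frame(genome_id = names(report$insert_size),
                    covered_bp_specific = as.integer(report$insert_size))
  wt(est, "insert_size.tsv")
  if (!is.null(report$alleles)) {
    wt(data.frame(allele = names(report$alleles$clustering$membership),
                  cluster = unname(report$alleles$clustering$membership)),
       "haplotype_clusters.tsv")
    wt(report$alleles$premature_stops, "premature_stops.tsv")
  }
  invisible(out_dir)
}

#' Evaluate donor attribution against simulation truth
#'
#' @param result an `attribution_result`.
#' @param truth a `sim_truth` carrying the per-read donor labels.
#' @param genome_of_donor named map from truth donor labels to genome ids.
#' @return List: number of donor-derived reads, fractions assigned to the
#'   correct and to the wrong donor, and the fraction of host-background
#'   reads left unmapped.
#' @export
evaluate_attribution <- function(result, truth,
                                 genome_of_donor = c(A = "donorA",
                                                     B = "donorB")) {
  stopifnot(is(result, "attribution_result"), is(truth, "sim_truth"))
  rt <- truth$read_table
  asg <- result$assignments
  m <- merge(asg, rt, by = "read_id")
  donor_reads <- m[m$donor %in% names(genome_of_donor), , drop = FALSE]
  host_reads <- m[m$donor == "host", , drop = FALSE]
  expected <- genome_of_donor[donor_reads$donor]
  n <- nrow(donor_reads)
  list(
    n_donor_reads = n,
    frac_correct = if (n) mean(donor_reads$assigned == expected) else NA_real_,
    frac_wrong = if (n) mean(donor_reads$assigned %in% genome_of_donor &
                             donor_reads$assigned != expected) else NA_real_,
    frac_host_unmapped = if (nrow(host_reads))
      mean(host_reads$assigned == "unmapped") else NA_real_)
}
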