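#' Simulation configuration
#'
#' Parameters of the synthetic study system: two donor genomes diverged
#' from a common ancestor (emulating divergent endosymbiont supergroups,
#' optionally with mobile/prophage regions exchanged between them), a large
#' host genome carrying inserts copied from each donor with post-transfer
#' divergence and occasional nonsense mutations, and error-bearing
#' paired-end short reads.
#'
#' Defaults describe the conditions the pipeline is calibrated for:
#' 100 kb donors at 8% pairwise divergence, inserts at 2% post-transfer
#' divergence, 100 bp paired-end reads with 0.5% substitution error, 10x
#' coverage over inserts and 1x host background.
#'
#' @param seed integer seed; all outputs are pure functions of the config.
#' @param ancestor_length,gc donor ancestor length (bp) and GC fraction.
#' @param n_genes,gene_length number and length of protein-coding genes.
#' @param n_mobile,mobile_length number and length of mobile (prophage)
#'   regions.  Genes and mobile regions are placed jointly non-overlapping.
#' @param divergence_donors expected substitution fraction between the two
#'   donors (each lineage mutates at half this rate).
#' @param indel_rate_donors per-bp indel rate per lineage (lengths 1-3);
#'   the default corresponds to an indel:substitution ratio of about 1:10,
#'   typical of alignable regions between moderately diverged bacterial
#'   genomes.
#' @param mobile_exchange if `TRUE`, donor A's mobile regions overwrite
#'   donor B's after divergence (emulating phage transfer between donors).
#' @param host_length host genome length (bp).
#' @param inserts_per_donor,insert_length number and length of nuclear
#'   inserts copied from each donor.
#' @param insert_divergence substitution fraction applied to each insert
#'   after transfer.
#' @param nonsense_rate per-insert probability of overwriting one codon of
#'   a covered gene with a premature stop codon (single-substitution).
#' @param read_length read length (bp).
#' @param insert_coverage_depth,background_coverage_depth target fold
#'   coverage over insert regions and host background.
#' @param error_rate per-base sequencing substitution error rate.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ancestor_length = 100000L, gc = 0.35,
                       n_genes = 60L, gene_length = 900L,
                       n_mobile = 2L, mobile_length = 4000L,
                       divergence_donors = 0.08, indel_rate_donors = 4e-3,
                       mobile_exchange = FALSE,
                       host_length = 500000L,
                       inserts_per_donor = 5L, insert_length = 5000L,
                       insert_divergence = 0.02, nonsense_rate = 0.15,
                       read_length = 100L,
                       insert_coverage_depth = 10,
                       background_coverage_depth = 1,
                       error_rate = 0.005) {
  cfg <- list(seed = as.integer(seed),
              ancestor_length = as.integer(ancestor_length), gc = gc,
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              n_mobile = as.integer(n_mobile),
              mobile_length = as.integer(mobile_length),
              divergence_donors = divergence_donors,
              indel_rate_donors = indel_rate_donors,
              mobile_exchange = isTRUE(mobile_exchange),
              host_length = as.integer(host_length),
              inserts_per_donor = as.integer(inserts_per_donor),
              insert_length = as.integer(insert_length),
              insert_divergence = insert_divergence,
              nonsense_rate = nonsense_rate,
              read_length = as.integer(read_length),
              insert_coverage_depth = insert_coverage_depth,
              background_coverage_depth = background_coverage_depth,
              error_rate = error_rate)
  fracs <- c(cfg$gc, cfg$divergence_donors, cfg$insert_divergence,
             cfg$nonsense_rate, cfg$error_rate, cfg$indel_rate_donors)
  if (any(fracs < 0) || any(fracs > 1))
    stop("all rates and fractions must lie in [0, 1]")
  if (cfg$ancestor_length <= 0 || cfg$host_length <= 0 ||
      cfg$read_length <= 0 || cfg$gene_length <= 0 || cfg$mobile_length <= 0)
    stop("lengths must be positive")
  if (cfg$inserts_per_donor < 0) stop("inserts_per_donor must be >= 0")
  if (2L * cfg$inserts_per_donor * cfg$insert_length > cfg$host_length)
    stop("inserts do not fit inside host_length without overlapping")
  if (cfg$insert_length > cfg$ancestor_length)
    stop("insert_length exceeds donor length")
  structure(cfg, class = "sim_config")
}

# ---- internal helpers ------------------------------------------------------

rand_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

substitute_bases <- function(seq_chars, idx) {
  # random distinct base at each idx
  for (i in idx) {
    alt <- setdiff(c("A", "C", "G", "T"), seq_chars[i])
    seq_chars[i] <- alt[sample.int(3L, 1L)]
  }
  seq_chars
}

# apply substitutions + indels to a sequence; returns the mutated string and
# the indel event list (ancestor coordinate, signed length) for lifting
mutate_lineage <- function(seq, sub_rate, indel_rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  sub_idx <- which(runif(L) < sub_rate)
  ch <- substitute_bases(ch, sub_idx)
  ind_idx <- which(runif(L) < indel_rate)
  events <- data.frame(pos = integer(), delta = integer())
  if (length(ind_idx)) {
    lens <- sample(1:3, length(ind_idx), replace = TRUE)
    is_ins <- runif(length(ind_idx)) < 0.5
    # drop deletions that would run off the end
    keep <- is_ins | (ind_idx + lens - 1L <= L)
    ind_idx <- ind_idx[keep]; lens <- lens[keep]; is_ins <- is_ins[keep]
    # drop overlapping deletion events (rare at realistic rates)
    if (length(ind_idx) > 1L) {
      ord <- order(ind_idx)
      ind_idx <- ind_idx[ord]; lens <- lens[ord]; is_ins <- is_ins[ord]
      keep <- rep(TRUE, length(ind_idx))
      last_end <- -1L
      for (i in seq_along(ind_idx)) {
        if (ind_idx[i] <= last_end) { keep[i] <- FALSE; next }
        if (!is_ins[i]) last_end <- ind_idx[i] + lens[i] - 1L
      }
      ind_idx <- ind_idx[keep]; lens <- lens[keep]; is_ins <- is_ins[keep]
    }
    if (length(ind_idx)) {
      pieces <- character(0)
      prev <- 1L
      for (i in seq_along(ind_idx)) {
        p <- ind_idx[i]
        if (is_ins[i]) {
          pieces <- c(pieces, paste(ch[prev:(p - 1L)], collapse = ""),
                      paste(sample(c("A", "C", "G", "T"), lens[i],
                                   replace = TRUE), collapse = ""))
          prev <- p
        } else {
          if (p > prev) pieces <- c(pieces, paste(ch[prev:(p - 1L)], collapse = ""))
          prev <- p + lens[i]
        }
      }
      pieces <- c(pieces, if (prev <= L) paste(ch[prev:L], collapse = "") else "")
      events <- data.frame(pos = ind_idx - 1L,              # 0-based
                           delta = ifelse(is_ins, lens, -lens))
      return(list(seq = paste(pieces, collapse = ""), events = events))
    }
  }
  list(seq = paste(ch, collapse = ""), events = events)
}

# lift a 0-based ancestor coordinate through indel events
lift_point <- function(p, events) {
  off <- 0L
  if (nrow(events)) for (i in seq_len(nrow(events))) {
    e_pos <- events$pos[i]; d <- events$delta[i]
    if (d > 0) { if (e_pos < p) off <- off + d } # insertion before p shifts p
    else {
      dl <- -d
      if (e_pos + dl <= p) off <- off - dl       # deletion fully before p
      else if (e_pos < p) off <- off - (p - e_pos)  # p inside deletion
    }
  }
  p + off
}

lift_intervals <- function(df, events) {
  if (!nrow(df)) return(df)
  df$start <- vapply(df$start, lift_point, integer(1) * 1L, events = events)
  df$end <- vapply(df$end, lift_point, integer(1) * 1L, events = events)
  df
}

#' Simulate the two donor genomes
#'
#' Draws an i.i.d. ancestor at the configured GC, places genes and mobile
#' regions jointly non-overlapping, then derives donors A and B by
#' independent substitutions at half the configured donor divergence plus
#' short indels per lineage.  If `mobile_exchange` is set, donor A's mobile
#' regions overwrite donor B's after divergence (so the exchanged regions
#' are byte-identical between donors).  The homolog table pairs genes by
#' ancestral identity.  Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return List with elements `A` and `B` ([reference_genome()]s) and
#'   `homologs` (`data.frame` of `gene_a`, `gene_b`).
#' @export
simulate_donors <- function(config) {
  stopifnot(is(config, "sim_config"))
  local_seed(config$seed + 101L, {
    L <- config$ancestor_length
    ancestor <- rand_dna(L, config$gc)

    n_blk <- config$n_genes + config$n_mobile
    types <- sample(c(rep("gene", config$n_genes),
                      rep("mobile", config$n_mobile)))
    blk_len <- ifelse(types == "gene", config$gene_length, config$mobile_length)
    slack <- L - sum(blk_len)
    if (slack < 0)
      stop("cannot place genes and mobile regions without overlap: ",
           "total feature length exceeds ancestor_length")
    cuts <- sort(sample.int(slack + 1L, n_blk, replace = TRUE) - 1L)
    starts <- cuts + c(0L, cumsum(blk_len))[seq_len(n_blk)]
    feat <- data.frame(type = types, start = starts,
                       end = starts + blk_len, stringsAsFactors = FALSE)
    genes0 <- feat[feat$type == "gene", c("start", "end")]
    genes0$gene_id <- sprintf("g%03d", seq_len(nrow(genes0)))
    genes0$strand <- sample(c("+", "-"), nrow(genes0), replace = TRUE)
    genes0$product <- "hypothetical protein"
    genes0 <- genes0[, c("gene_id", "start", "end", "strand", "product")]
    mobile0 <- feat[feat$type == "mobile", c("start", "end")]

    make_donor <- function(id) {
      mut <- mutate_lineage(ancestor, config$divergence_donors / 2,
                            config$indel_rate_donors)
      genes <- lift_intervals(genes0, mut$events)
      mobile <- lift_intervals(mobile0, mut$events)
      reference_genome(id, mut$seq, genes = genes, mobile_regions = mobile)
    }
    A <- make_donor("donorA")
    B <- make_donor("donorB")

    if (config$mobile_exchange && nrow(A$mobile_regions)) {
      # descending order so earlier intervals stay valid while splicing
      ord <- order(B$mobile_regions$start, decreasing = TRUE)
      seqB <- B$sequence
      genesB <- B$genes
      mobB <- B$mobile_regions
      for (i in ord) {
        a_s <- A$mobile_regions$start[i]; a_e <- A$mobile_regions$end[i]
        b_s <- mobB$start[i]; b_e <- mobB$end[i]
        piece <- substr(A$sequence, a_s + 1L, a_e)
        seqB <- paste0(substr(seqB, 1L, b_s), piece,
                       substr(seqB, b_e + 1L, nchar(seqB)))
        delta <- nchar(piece) - (b_e - b_s)
        shift <- function(x) ifelse(x >= b_e, x + delta, x)
        genesB$start <- shift(genesB$start); genesB$end <- shift(genesB$end)
        mobB$start <- shift(mobB$start); mobB$end <- shift(mobB$end)
        mobB$end[i] <- mobB$start[i] + nchar(piece)
      }
      B <- reference_genome("donorB", seqB, genes = genesB,
                            mobile_regions = mobB)
    }

    homologs <- data.frame(gene_a = genes0$gene_id, gene_b = genes0$gene_id,
                           stringsAsFactors = FALSE)
    list(A = A, B = B, homologs = homologs)
  })
}

stop_codons <- c("TAA", "TAG", "TGA")

# codons (donor forward coordinates + strand-aware sequence) of a gene
gene_codons <- function(donor_seq, gs, ge, strand) {
  len <- ge - gs
  n_codon <- len %/% 3L
  if (n_codon == 0L) return(NULL)
  idx <- seq_len(n_codon) - 1L
  if (strand == "+") {
    starts <- gs + 3L * idx
    list(fwd_start = starts, n = n_codon)
  } else {
    starts <- ge - 3L * (idx + 1L)
    list(fwd_start = starts, n = n_codon)
  }
}

codon_seq <- function(seq, fwd_start, strand) {
  s <- substr(seq, fwd_start + 1L, fwd_start + 3L)
  if (strand == "-") revcomp(s) else s
}

#' Build the host genome with donor-derived inserts
#'
#' The host background is i.i.d. random sequence; inserts are copied from
#' random donor coordinates into non-overlapping host slots, mutated at the
#' configured post-transfer divergence, and, with probability
#' `nonsense_rate` per insert, one complete codon of a covered gene is
#' overwritten with a premature stop codon reachable by a single
#' substitution from the donor codon.  Ground truth (insert intervals,
#' donor source intervals, genes truly represented in both donors'
#' inserts) is recorded.
#'
#' @param config a [sim_config()].
#' @param donors output of [simulate_donors()].
#' @return List with `host` ([reference_genome()]) and `truth` (class
#'   `sim_truth`: `insert_table`, `shared_genes`).
#' @export
build_host <- function(config, donors) {
  stopifnot(is(config, "sim_config"))
  local_seed(config$seed + 202L, {
    host <- rand_dna(config$host_length, config$gc)
    k <- config$inserts_per_donor
    n_ins <- 2L * k
    insert_table <- data.frame(
      insert_id = character(), donor = character(), host_start = integer(),
      host_end = integer(), src_start = integer(), src_end = integer(),
      nonsense = logical(), stringsAsFactors = FALSE)

    if (n_ins > 0L) {
      donor_of <- sample(rep(c("A", "B"), each = k))
      il <- config$insert_length
      slack <- config$host_length - n_ins * il
      cuts <- sort(sample.int(slack + 1L, n_ins, replace = TRUE) - 1L)
      host_starts <- cuts + (seq_len(n_ins) - 1L) * il
      for (i in seq_len(n_ins)) {
        dn <- donors[[donor_of[i]]]
        src_max <- nchar(dn$sequence) - il
        ss <- sample.int(src_max + 1L, 1L) - 1L
        copy <- substr(dn$sequence, ss + 1L, ss + il)
        ch <- strsplit(copy, "", fixed = TRUE)[[1]]
        ch <- substitute_bases(ch, which(runif(il) < config$insert_divergence))
        copy <- paste(ch, collapse = "")

        nonsense <- FALSE
        if (runif(1) < config$nonsense_rate) {
          g <- dn$genes
          ov <- g[pmin(g$end, ss + il) - pmax(g$start, ss) >= 3L, , drop = FALSE]
          if (nrow(ov)) {
            gi <- ov[sample.int(nrow(ov), 1L), ]
            cd <- gene_codons(dn$sequence, gi$start, gi$end, gi$strand)
            if (!is.null(cd)) {
              # complete codons inside the insert, excluding the gene's final codon
              inside <- cd$fwd_start >= ss & cd$fwd_start + 3L <= ss + il
              inside[cd$n] <- FALSE
              cand <- which(inside)
              # find a codon turnable into a stop by one substitution
              for (ci in cand[sample.int(length(cand))]) {
                fs <- cd$fwd_start[ci]
                codon <- codon_seq(dn$sequence, fs, gi$strand)
                if (codon %in% stop_codons) next
                hits <- stop_codons[vapply(stop_codons, function(s)
                  sum(strsplit(codon, "")[[1]] != strsplit(s, "")[[1]]) == 1L,
                  logical(1))]
                if (!length(hits)) next
                new_codon <- hits[sample.int(length(hits), 1L)]
                fwd <- if (gi$strand == "-") revcomp(new_codon) else new_codon
                off <- fs - ss  # position of codon within the insert copy
                substr(copy, off + 1L, off + 3L) <- fwd
                nonsense <- TRUE
                break
              }
            }
          }
        }
        hs <- host_starts[i]
        substr(host, hs + 1L, hs + il) <- copy
        insert_table <- rbind(insert_table, data.frame(
          insert_id = sprintf("ins%02d", i), donor = donor_of[i],
          host_start = hs, host_end = hs + il,
          src_start = ss, src_end = ss + il,
          nonsense = nonsense, stringsAsFactors = FALSE))
      }
    }

    shared <- shared_genes_from_truth(donors, insert_table, min_overlap = 80L)
    truth <- structure(list(insert_table = insert_table,
                            shared_genes = shared),
                       class = "sim_truth")
    list(host = reference_genome("host", host), truth = truth)
  })
}

# genes with >= min_overlap bp covered by inserts of both donors
shared_genes_from_truth <- function(donors, insert_table, min_overlap = 80L) {
  rep_genes <- function(which_donor) {
    dn <- donors[[which_donor]]
    src <- insert_table[insert_table$donor == which_donor, , drop = FALSE]
    if (!nrow(src) || !nrow(dn$genes)) return(character(0))
    g <- dn$genes
    covered <- vapply(seq_len(nrow(g)), function(i) {
      ov <- pmin(g$end[i], src$src_end) - pmax(g$start[i], src$src_start)
      sum(pmax(ov, 0L))
    }, numeric(1))
    g$gene_id[covered >= min_overlap]
  }
  both <- intersect(rep_genes("A"), rep_genes("B"))
  data.frame(gene_a = both, gene_b = both, stringsAsFactors = FALSE)
}

#' Simulate paired-end reads from the host genome
#'
#' Fragments are placed uniformly (background) and uniformly-by-midpoint
#' inside inserts (to raise inserts to the configured depth); fragment
#' length is Normal(3 x read_length, 0.3 x read_length) truncated at the
#' read length.  Each read carries per-base substitution errors at
#' `error_rate` and is labeled with the donor of the midpoint of its source
#' interval.  Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param host host [reference_genome()] from [build_host()].
#' @param truth `sim_truth` from [build_host()]; returned updated with the
#'   per-read donor labels.
#' @return List with `reads1`, `reads2` (named character vectors) and
#'   `truth` (with added `read_table`: `read_id`, `donor`).
#' @export
simulate_reads <- function(config, host, truth) {
  stopifnot(is(config, "sim_config"), is(truth, "sim_truth"))
  if (config$insert_coverage_depth <= 0 && config$background_coverage_depth <= 0)
    stop("at least one of insert/background coverage depth must be positive")
  local_seed(config$seed + 303L, {
    rl <- config$read_length
    H <- nchar(host$sequence)
    it <- truth$insert_table
    ins_total <- sum(it$host_end - it$host_start)

    n_bg <- round(config$background_coverage_depth * H / (2 * rl))
    extra_depth <- max(0, config$insert_coverage_depth -
                          config$background_coverage_depth)
    n_it <- if (ins_total > 0) round(extra_depth * ins_total / (2 * rl)) else 0L

    frag_len <- function(n) {
      fl <- round(rnorm(n, 3 * rl, 0.3 * rl))
      pmax(fl, rl)
    }
    starts <- integer(0); flens <- integer(0)
    if (n_bg > 0) {
      fl <- frag_len(n_bg)
      fl <- pmin(fl, H)
      st <- floor(runif(n_bg) * (H - fl + 1))
      starts <- c(starts, st); flens <- c(flens, fl)
    }
    if (n_it > 0) {
      fl <- frag_len(n_it)
      fl <- pmin(fl, H)
      which_ins <- sample.int(nrow(it), n_it, replace = TRUE,
                              prob = it$host_end - it$host_start)
      mid <- it$host_start[which_ins] +
        floor(runif(n_it) * (it$host_end[which_ins] - it$host_start[which_ins]))
      st <- pmin(pmax(mid - fl %/% 2L, 0L), H - fl)
      starts <- c(starts, st); flens <- c(flens, fl)
    }
    n <- length(starts)
    if (n == 0L) stop("configuration produced zero read pairs")
    ids <- sprintf("f%06d", seq_len(n))

    r1 <- substring(host$sequence, starts + 1, starts + rl)
    r2_fwd <- substring(host$sequence, starts + flens - rl + 1, starts + flens)
    r2 <- revcomp(r2_fwd)

    donor_at <- function(pos) {
      lab <- rep("host", length(pos))
      if (nrow(it)) for (i in seq_len(nrow(it))) {
        inside <- pos >= it$host_start[i] & pos < it$host_end[i]
        lab[inside] <- it$donor[i]
      }
      lab
    }
    lab1 <- donor_at(starts + rl %/% 2L)
    lab2 <- donor_at(starts + flens - rl + rl %/% 2L)

    add_errors <- function(reads) {
      total <- length(reads) * rl
      err <- which(runif(total) < config$error_rate)
      if (length(err)) {
        ri <- (err - 1L) %/% rl + 1L
        pp <- (err - 1L) %% rl + 1L
        for (j in seq_along(err)) {
          cur <- substr(reads[ri[j]], pp[j], pp[j])
          alt <- setdiff(c("A", "C", "G", "T"), cur)
          substr(reads[ri[j]], pp[j], pp[j]) <- alt[sample.int(3L, 1L)]
        }
      }
      reads
    }
    r1 <- add_errors(r1)
    r2 <- add_errors(r2)

    names(r1) <- paste0(ids, "_1")
    names(r2) <- paste0(ids, "_2")
    truth$read_table <- data.frame(
      read_id = c(names(r1), names(r2)),
      donor = c(lab1, lab2),
      host_start = as.integer(c(starts, starts + flens - rl)),
      host_end = as.integer(c(starts + rl, starts + flens)),
      stringsAsFactors = FALSE)
    list(reads1 = r1, reads2 = r2, truth = truth)
  })
}

#' Run the full simulator
#'
#' Convenience wrapper: donors, host and reads in one call.
#'
#' @param config a [sim_config()].
#' @return List with `donors`, `host`, `truth`, `reads1`, `reads2`,
#'   `homologs` and the `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  donors <- simulate_donors(config)
  hh <- build_host(config, donors)
  rr <- simulate_reads(config, hh$host, hh$truth)
  list(donors = donors, host = hh$host, truth = rr$truth,
       reads1 = rr$reads1, reads2 = rr$reads2,
       homologs = donors$homologs, config = config)
}
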