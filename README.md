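# nuwtscan

Detection and donor attribution of nuclear endosymbiont insertions (NUWTs
— nuclear *Wolbachia* transfers) from short sequencing reads.

## The problem

Endosymbionts such as *Wolbachia* repeatedly copy fragments of their DNA
into the nuclear genomes of their arthropod hosts.  When a host lineage
has been exposed to **two divergent donor supergroups**, each insertion
raises the question: which donor did it come from?  Given short reads from
the host and a reference genome for each donor, `nuwtscan` answers this by
**competitive (mutually exclusive) read mapping**: every read is aligned
against both references under explicit acceptance thresholds and assigned
to the reference with the strictly best accepted score.

An alignment of a read is *accepted* iff

```
similarity            = n_match / columns                  >= s   (columns include gaps)
aligned_read_fraction = (n_match + n_mismatch + n_ins) / L >= f
```

under local alignment with free read ends and linear gap costs (match +1,
mismatch −2, insertion −3, deletion −3).  Four named presets cover the
pipeline's stages: `standard` 80/80, `strict` 90/90, `relaxed` 70/90,
`screen_low` 65/80.  Downstream of attribution the pipeline provides:

- **reciprocal specificity** — reads attributed to one donor are remapped
  against the other; reads accepting on both are "non-specific";
- **insert-size estimates** — union of reference bases covered by each
  donor's specific reads;
- **consensus contigs** with mean length and N50 stratified by
  prophage/mobile regions;
- **dual-origin gene detection** — homologous gene pairs supported by both
  donors' reads on both references (relaxed reciprocal mapping, >80 bp
  per-gene support, consensus-identity verification);
- **allele-level analysis** — percent identity (gap/N-excluded),
  single-linkage haplotype clustering at an identity cutoff, reading-frame
  inference, and premature stop-codon detection;
- a **synthetic-data generator** (two donors diverged from a common
  ancestor, host genome with inserts, error-bearing paired reads) with
  complete ground truth, so every stage is verifiable without access to
  the original sequencing data.

## Worked example

Allele-level analysis of the packaged marker-gene alignment (a *synthetic*
stand-in for a phage minor-capsid allele set; see
`vignettes/nuwtscan-methods.Rmd`):

```r
library(nuwtscan)
aln <- read_aligned_fasta(system.file("extdata",
        "synthetic_orf7_alignment.fasta", package = "nuwtscan"))
pairwise_identity(aln$seqs[["allele3"]], aln$seqs[["allele4"]])
#> [1] 97.7
cluster_alleles(allele_set(aln$seqs[paste0("allele", 2:8)]), 0.96)
#> <haplotype_clustering> cutoff 96%: 3 clusters
#>   H1: allele6, allele7, allele8
#>   H2: allele2, allele5
#>   H3: allele3, allele4
fr <- infer_frame(aln)
find_premature_stops(aln, fr$frame)
#>    allele position ref_base alt_base codon
#> 1 allele7       31        C        T   TAA
```

97.7% identity between alleles 3 and 4 places them in one haplotype at the
96% cutoff; allele 7 carries a C→T substitution at alignment position 31
that creates a premature TAA stop — a pseudogenizing change relative to
the column-majority consensus.

End-to-end on simulated data (100 kb donors at 8% divergence, 500 kb host
with five 5 kb inserts per donor, 10× insert coverage):

```r
rep <- run_end_to_end(run_config(seed = 1))
rep$assignment_counts
#>   donorA   donorB unmapped
#>     2412     2459     4629
rep$truth_evaluation$frac_correct     # donor reads assigned to the right donor
#> [1] 0.9917
rep$insert_size                       # covered bp of specific reads, per donor
#>  donorA  donorB
#>   20545   21003
rep$n_shared                          # genes detected in both donors' inserts
#> [1] 2
```

Host background reads stay unmapped (no host reference is consulted);
99.2% of donor-derived reads land on the correct donor, and the
specific-read covered bases estimate each donor's total insert length
(ground truth here: 25,000 bp per donor; recovery ≈ 82–84% at these
divergence settings — see the vignette for why the strict threshold sits
at the donors' divergence boundary).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "nuwtscan", package = "nuwtscan"))')" \
    run-all --seed 1 --out-dir run1/
```

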