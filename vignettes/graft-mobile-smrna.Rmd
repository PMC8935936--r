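---
title: "Detecting graft-mobile small RNAs with SNP-discriminative mapping"
author: "graftmobile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting graft-mobile small RNAs with SNP-discriminative mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftmobile)
```

## The problem

Grafting joins a shoot segment (the scion) to a root segment (the
rootstock). In a heterograft the two partners carry different genotypes,
and small RNAs (smRNAs) — 20–24-nt regulators produced from miRNA
hairpins and from siRNA-generating loci — can cross the graft junction
through the reconnected vasculature. A smRNA sequenced in one
compartment but explainable only by the *other* genotype's genome is
direct evidence of transport. `graftmobile` implements this inference
end-to-end: read cleaning, exact-occurrence mapping, coverage-based
cluster calling with dicer-call scoring, two-step SNP-discriminative
mobility classification, genomic annotation and cross-set comparison,
Fisher-exact term enrichment, and coverage-weighted identity scoring of
candidate target regions in the receiving genome.

Because real heterograft libraries require tens of millions of reads and
two full reference genomes, the package ships a synthetic heterograft
generator with complete ground truth, so that every stage of the
pipeline is testable at desk scale.

## The core procedure

### Two-step SNP-discriminative classification

Let $G_R$ be the genome of the compartment a library was sequenced from
(the *receptor*) and $G_D$ the graft partner's genome (the *donor*).
The two genomes differ at single-nucleotide polymorphisms (SNPs). Each
cleaned read $r$ is classified by two successive exact (0-mismatch)
alignments, both strands:

1. **Step 1 (native)** — if $r$ occurs exactly in $G_R$, it is native.
2. **Step 2 (mobile)** — otherwise, if $r$ occurs exactly in $G_D$, it
   is mobile: its sequence is only explainable by the donor genotype.
3. Otherwise it is unassigned (sequencing error, contaminant residue,
   or divergence from both references).

Step-1 precedence is strict. A read from a genomic region identical in
both genotypes maps to both genomes and is therefore called native:
only reads spanning at least one diagnostic SNP can ever be called
mobile. The classification consequently *underestimates* true exchange;
the package surfaces this through
`snp_spanning_detectable_fraction()`, which reports (when simulation
truth is available) the fraction of truly mobile reads that span a SNP
— the ceiling of what the procedure can detect.

Reported fractions follow the report conventions: counts are never
rounded; percentages are rounded half-up to one decimal place, and
`pct_native + pct_unmapped = 100` by construction.

### Cluster calling

Reads placed on a genome are grouped into clusters in the style of
coverage-based smRNA cluster callers:

* an **island** is a maximal run of positions with raw read depth
  $\ge$ `mincov` (default 5 reads);
* islands separated by $\le$ `pad` nucleotides (default 100, boundary
  inclusive) are merged transitively;
* every placement overlapping a merged interval is assigned to that
  cluster, and the cluster extent is widened to the span of its reads
  (merged intervals are $>$ `pad` apart and reads are $\le$ 50 nt, so
  the assignment is unique);
* a cluster is **dicer-derived** when at least 80% of its reads are
  20–24 nt long (the comparison is done in integer arithmetic so the
  80% boundary is exact), and its **size class** is the modal read
  length within 20–24 nt, ties resolved toward the larger length (the
  24-nt heterochromatic class dominates plant siRNA populations, which
  makes the larger length the conservative tie-break);
* clusters whose most abundant read matches a known hairpin as an
  ungapped substring with $\le 2$ mismatches are annotated as known
  miRNAs. This deliberately replaces structural hairpin annotation
  (secondary-structure and duplex criteria) with database matching;
  statistics that depend on *de novo* miRNA discovery are out of scope.

### Target scanning

Mobile 24-nt siRNA clusters guide RNA-directed DNA methylation at
homologous loci of the receiving genome. Candidate target regions are
found by ungapped seed-and-extend local alignment of the cluster
consensus (its genomic substring on the source genome) against the
receptor genome: exact 7-mers seed diagonals, each diagonal is scored
with +1 per match and −2 per mismatch, and the best segment per
diagonal is kept when it scores at least `min_score` (default 14,
roughly a 14-nt perfect seed — a raw-score stand-in for a short-query
e-value threshold, which we do not re-derive). Hits overlapping
repeat-annotated intervals are excluded, and the survivors are ranked
by the coverage-weighted identity

$$\mathrm{pident} = \frac{\ell - m}{\ell} \times 100,\qquad
  \mathrm{pident\_final} = \mathrm{pident}\times\frac{\ell}{L},$$

where $\ell$ is the aligned length, $m$ the mismatch count and $L$ the
cluster length. `pident_final` penalises partial alignments: a perfect
hit covering half the cluster scores 50, and a 37/38-nt perfect hit
scores 97.37. Gapped alignment is intentionally not supported: at these
query lengths substitution-only alignment is what exact-match read
classification implies, and an indel would make the hit unreliable as a
methylation target anyway.

### Annotation, comparison, enrichment

Clusters are annotated by 1-bp any-overlap (bedtools-intersect default
semantics) against gene bodies, 2-kb promoters (the 2 kb upstream of
each gene's 5′ end, strand-aware, clipped at chromosome edges, omitted
when empty) and repeats; multiple labels are allowed and label-free
clusters are intergenic. Two cluster sets are compared by the same
1-bp co-localization rule, each side reporting its own common/specific
split. Replicate reproducibility uses presence counts and the
coefficient of variation (sample standard deviation with $n-1$
denominator over per-replicate counts, divided by the mean, times 100;
the CV is undefined and reported as missing when the mean is 0 — the
$n-1$ convention is a package choice, since either is defensible).
Term enrichment is a per-term one-sided Fisher exact test at
$\alpha = 0.05$ with **no multiple-testing correction**, faithful to
the stated procedure it mirrors; users who need FDR control should
adjust the returned p-values themselves.

## The synthetic heterograft generator

`simulate_genome_pair()` creates a donor/receptor genome pair identical
except at i.i.d. per-position SNPs (rate `snp_rate`); the receptor
allele is uniform over the three non-donor bases. SNP placement is
intentionally unclustered — the simplest model that exposes the
SNP-spanning detection limit. One numerical design choice deserves
note: the allele-shift variates are pre-drawn for every position, so
the generator consumes the same RNG stream regardless of `snp_rate`.
For a fixed seed, SNP sets are therefore *nested* across rates (a
common-random-numbers design), which makes "detection rises with
divergence" a structural property rather than a statement about
average behaviour.

`plant_annotations()` lays out non-overlapping stranded genes and
uniformly placed repeats; `plant_loci()` plants smRNA loci in the
compartments where their classes live in real plants: 21-nt siRNA loci
in gene bodies, 24-nt siRNA loci in 2-kb promoters and repeats (the
RdDM-associated space), and miRNA hairpins in intergenic gaps. Loci on
a chromosome are kept $\ge 200$ nt apart — beyond `pad` + the longest
read — so cluster calling can recover them one-to-one.

`simulate_reads()` draws reads per locus with expression-weighted
sampling: class length (21 or 24 nt) with ±1-nt jitter at probability
0.1 (so dicer-call mixtures are exercised), uniform start within the
locus for siRNA loci, a fixed mature-arm offset and locus strand for
miRNA loci (siRNA loci are double-stranded sources, so their reads take
random strands). Mobile reads are drawn from the *other* genome at the
same locus coordinates — homologous loci expressed in both partners.
Errors are substitutions only (an indel would merely make a read
unmappable under exact matching, indistinguishable from any other
unmapped read). Each insert is 3′-extended with the sequencing adapter
and random fill to the 50-nt machine read length. Contaminant reads
(rRNA/tRNA/chloroplast stand-ins; synthetic random references) are
exact substrings of the contaminant set. Every read's provenance —
source genome, locus, interval, strand, SNP-spanning flag, error count
— is recorded in the truth table.

What the generator does **not** model: base-quality profiles, PCR
duplication, isomiR biogenesis, clustered SNPs, structural variation
between genotypes, and expression divergence between compartments.
Passing tests therefore demonstrate the pipeline's logic is correct
under its own assumptions, not that real libraries are free of the
artefacts these phenomena cause — most importantly, a deletion in the
receptor genotype relative to the donor could make a *native* read
look mobile, which the simulation excludes by construction.

## Preprocessing conventions

Stage order is fixed: adapter trim → length filter → complexity filter
→ decontamination; the read count is non-increasing across stages.

* **Adapter trimming** removes the earliest 3′-anchored adapter-prefix
  match of $\ge 3$ nt (or a full internal adapter occurrence) and
  everything after it. The 3-nt minimum overlap is the common trimmer
  default; it costs a small probability (1/64 per clean read) of
  clipping a genuine genomic 3′ base triplet, which downstream exact
  mapping tolerates because the read remains a genomic substring.
* **Length filter** keeps reads of $\ge 17$ nt. The inclusive boundary
  is one of two defensible readings of the tool chain this mirrors; we
  adopt "minimal read size of 17" (a 17-nt read passes).
* **Complexity filter** removes reads whose mononucleotide Shannon
  entropy is below 0.5 bits (kept at $\ge$ threshold). The 0.5-bit
  default discards homopolymer-like reads while keeping dinucleotide
  repeats (1.0 bit) — the named low-complexity tool it stands in for
  does not publish a canonical threshold.
* **Decontamination** removes reads occurring exactly — either strand —
  within the contaminant references, mirroring 0-mismatch filtering
  against rRNA/tRNA and chloroplast sequences.

## Mapping conventions

All genome mapping is exact-match, both strands, via a short-read
dictionary matcher. Multimapping reads are resolved by policy:
`random_one` (default; one occurrence drawn uniformly with a seeded
generator, `n_occurrences` recording the total), `all`, or
`unique_only`. Exactness everywhere (not only in the mobility steps) is
a deliberate simplification: mismatch-tolerant primary mapping would
change mapped fractions but not the mobility logic, which is defined by
exact occurrence; published mapped-fraction figures from
mismatch-tolerant mappers are therefore not comparison targets.
Coordinates are 0-based half-open package-wide; GFF3 (1-based
inclusive) converts at the boundary, BED passes through verbatim.

## Problem sizes and determinism

The reference study condition generated by `make_fixture(scale =
"medium")` is two 2 × 100-kb genomes (200 kb each) at SNP rate 0.005,
3 replicates × 50,000 50-nt reads per compartment, mobile fraction
0.05, sequencing error 0, and 40% contaminant admixture — the
contaminant share matching what rRNA/tRNA removal typically discards
from plant smRNA libraries. The `"small"` scale (2 × 20 kb, 6,000
reads per compartment) runs the full pipeline in seconds and is what
most examples and tests use. Every stochastic step takes an explicit
seed, and fixed seeds reproduce FASTQ files, placements, clusters and
reports byte-identically.

Under the medium condition the package's acceptance checks verify:
mobile-call precision 100%; the labeled-mobile set exactly equal to
the truth-mobile ∩ SNP-spanning set; one-to-one recovery of planted
loci as clusters; and detected mobile fraction strictly increasing
over SNP rates {0.001, 0.005, 0.02}.

## Degenerate inputs and tie-breaks

* Zero-denominator percentages report 0 with an `empty_input` flag.
* Empty placement sets yield empty cluster sets; clusters below
  `mincov` are never created, even when mobile reads exist.
* Size-class ties go to the larger length; miRNA database ties go to
  database order; target hits are ranked by `pident_final`, then
  score, then coordinates — all deterministic.
* `unique_only` mapping drops multimapping reads entirely; `random_one`
  is bit-reproducible for a fixed `rng_seed`.

## Known limitations

* Mobility detection is limited to SNP-spanning reads; reported
  exchange rates are lower bounds, and the diagnostic detectable
  fraction should accompany any quantitative claim.
* miRNA identification is database matching, not structural
  annotation; novel-miRNA statistics are out of scope.
* The target scanner's `min_score` is a raw-score surrogate for an
  e-value; hits near the threshold should be treated as candidates
  for experimental follow-up, not calls.
* A sequencing error in a native read can, in principle, create a
  false-positive mobile call if the mutated sequence coincidentally
  occurs in the donor genome; no heuristic correction is applied, and
  the simulator can quantify this rate under non-zero `error_rate`.
* rpm normalisation uses reads mapped in the same sample as the
  denominator; cross-study rpm comparisons need identical conventions.

## A worked example

```{r example, eval = FALSE}
fxdir <- file.path(tempdir(), "fx")
make_fixture(fxdir, scale = "small", seed = 1)
report <- run_pipeline(fxdir, seed = 1)

# per-compartment cluster summary
report$compartments$receptor$summary

# mobility, scion to rootstock
report$mobility$scion_to_rootstock$summary[
  c("n_total", "n_native", "n_mobile", "pct_native",
    "pct_mobile_of_unmapped")]
```

The README shows this example with the numbers it prints.
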