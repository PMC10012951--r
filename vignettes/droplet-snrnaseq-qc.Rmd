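---
title: "Droplet snRNA-seq preprocessing and barnyard QC: models and methods"
author: "droncqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet snRNA-seq preprocessing and barnyard QC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droncqc)
```

# Scope

`droncqc` implements the computational half of a DroNc-seq style
single-nucleus RNA-seq workflow: validating the droplet read structure,
selecting and repairing cell barcodes, collapsing UMIs into molecule
counts, estimating the doublet rate from a two-species ("barnyard")
mixing experiment, and summarizing read-region and concordance QC. A
synthetic droplet-encapsulation generator drives all of it, so every
stage can be exercised — and its statistical behavior verified — without
access to sequencing data.

# The loading model

Nuclei are diluted to Poisson-limiting concentrations so that only a
small fraction of droplets contain any nucleus. We parameterize the
generator by that *occupancy* rather than by the Poisson mean directly,
because occupancy is what protocols state ("nuclei in 5% of droplets"):

$$\lambda = -\ln(1 - \text{occupancy}),$$

so that $P(\text{droplet occupied}) = 1 - e^{-\lambda}$ equals the
requested occupancy exactly. Two quantities follow in closed form and are
exposed as pure functions:

```{r loading}
lam <- occupancy_to_lambda(0.05)
lam
doublet_fraction_among_occupied(lam)
```

At 5% occupancy about 2.5% of *occupied* droplets hold two or more
nuclei. The simulator draws per-droplet nucleus counts from
$\mathrm{Poisson}(\lambda)$ and each nucleus's species independently from
the mix proportions, which makes the cross-species fraction among
doublets $2pq$ — the identity the doublet correction below relies on.

# Read structure

Read 1 carries a 12 nt bead barcode, an 8 nt UMI, one anchor base that
must be A, C or G (the "V" base preceding the oligo-dT), and poly-T out
to the 26th cycle. `parse_read1()` is total: every sequence yields either
a valid parse or exactly one reject reason (`TOO_SHORT`,
`AMBIGUOUS_BASE`, `BAD_ANCHOR`, `BAD_POLYT`, checked in that order of
precedence). The poly-T contract is our own decision: protocols say
"then the poly-T" without a length, so we require at least 4 T among the
5 bases after the anchor, tolerating one sequencing error in the
observable stretch of a 26-cycle read; both the window and the minimum
are configurable. Any `N` in the barcode or UMI invalidates the read,
because Hamming repair downstream assumes an unambiguous 12-mer.

# Whitelisting and H2 repair

Barcodes expressing at least 150 genes are candidates; they are ranked
(by genes expressed or by total reads — ties broken by the other key,
then lexicographically, so ranking is deterministic) and the top
`n_expected` become the whitelist. Observed barcodes are then repaired to
the whitelist at Hamming distance ≤ 2 ("H2"; distances 0 and 1 are
selectable variants). Two choices here were genuinely open:

* **Ties are discarded.** A barcode equidistant from two whitelist
  entries at the minimal qualifying distance is left unassigned rather
  than resolved arbitrarily: assigning it would fabricate molecules in
  whichever entry happened to win. Tie counts are reported.
* **Nearest entry wins**, not first-found: the result is independent of
  input order.
* Candidate selection happens **before** repair, matching the stated
  order of the preprocessing steps; a flag could reverse this but the
  candidate floor is recomputed from raw tallies either way.

The implementation enumerates the Hamming ball of radius ≤ 2 around each
whitelist entry (631 neighbors per 12-mer) and hashes it, which is exact
and fast; the test suite checks it against a brute-force all-pairs scan
on hundreds of random instances, including tie cases.

# Quantification

Molecule counts are distinct UMI sequences per (gene, assigned barcode);
raw read support is kept alongside. There is no UMI error correction:
none is described for this workflow, and with 8 nt UMIs two molecules of
the same gene and barcode collide with probability $1/4^8 \approx
1.5\times10^{-5}$ per pair — a documented slight undercount we accept
rather than risk merging real molecules. Gene rows are kept even when
all-zero so matrices from different compartments stay alignable.

The per-barcode filters mirror the barnyard figure's cutoffs: a gene is
"expressed" in a barcode if its support reaches `min_reads_per_gene`
(default 1), and barcodes with fewer than 200 expressed genes are
removed. The support unit is read support by default (the figure says
"min. 1 read per gene") with a transcript-count mode, because the main
text counts transcripts; at the default threshold of 1 the two are
identical.

# The barnyard doublet estimate

A barcode is called human (murine) iff **strictly more than** 95% of its
transcripts map to that genome; everything else — including exactly
95% — is mixed. Same-species doublets are invisible in this design: with
mix proportions $(p, q)$ only $2pq$ of doublets are cross-species, so

$$\widehat{\text{doublet rate}} = \frac{M}{2pq\,N},$$

with $M$ mixed barcodes among $N$ classified (after the expression
filters). At $p=q=1/2$ the correction factor is exactly 2. The published
worked example is reproduced exactly:

```{r worked}
calls <- data.frame(label = rep(c("murine", "human", "mixed"),
                                c(204, 179, 8)))
estimate_doublet_rate(calls, c(0.5, 0.5))
```

The $1/(2pq)$ form is our inference: the reported rate equals exactly
twice the mixed fraction at a 1:1 mix, and $1/(2pq)$ is the unique
independence-model generalization that reduces to that doubling. The
denominator is all classified barcodes, which matches the printed counts
($204+179+8=391$). The fraction unit defaults to transcripts (UMI
counts), with a read-support mode available because figure and text
differ on the wording.

# The synthetic generator

The generator emulates: Poisson encapsulation at a stated occupancy; a
two-species nucleus mix with disjoint gene panels; per-nucleus molecule
counts; per-molecule UMIs and read multiplicities; per-base barcode
substitution errors; and a categorical region label per read. Its
defaults are the study conditions where the protocol states them
(occupancy 0.05, 1:1 mix, 12 + 8 + 1 + poly-T read structure at 26
cycles) and, where it does not, fixed realistic choices:

* **Molecules per nucleus**: log-normal, location 400, sigma 0.35,
  rounded up to ≥ 1. No per-nucleus distribution is stated anywhere; the
  log-normal shape reflects the right-skewed depth per cell typical of
  droplet data, and the location is set so nuclei comfortably clear the
  150-gene and 200-gene thresholds at a 1000-gene panel (expected
  distinct genes $\approx 1000(1-e^{-0.4}) \approx 330$).
* **Reads per molecule**: Poisson with mean 1, minimum one read emitted
  (a molecule that is never sequenced is not a molecule in the truth
  table).
* **Barcode error rate**: 0.001 per base, an Illumina-scale substitution
  rate; at 12 positions ~1.2% of reads carry at least one substitution.
* **Region probabilities**: (exonic 0.34, intronic 0.37, intergenic
  0.28, mitochondrial 0.01), shaped on the nuclei profile in which
  intronic reads rival exonic ones; these are simulation inputs, not
  measurements.

What it deliberately does **not** simulate: ambient RNA, bead-quality
effects, sequence-level cDNA and alignment errors in read 2 (read 2
carries the gene identifier as a pre-aligned payload), UMI biases, and
bead-barcode collisions (every droplet gets a unique barcode). Passing
tests therefore demonstrate the pipeline's correctness and statistical
calibration under the encapsulation model, not robustness to ambient
contamination or alignment artifacts in real libraries.

Determinism: a single seed governs a run; droplet-level and read-level
stages derive fixed offsets from it, so identical configuration and seed
reproduce byte-identical FASTQ and reports.

# Concordance QC

`mean_log_expression()` averages $\ln(\text{count}+1)$ per gene over
barcodes (zeros included). Natural log is our choice — the log base
cancels in Pearson correlation. Profiles are paired on the union of gene
sets with absent genes as zero (consistent with keeping all-zero gene
rows); intersection pairing is a flag, since the published analyses do
not state which was used. The p-value uses the exact t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom and is reported
as "< 2.2e-16" below that floor, matching the field's reporting style.
`deviating_genes()` is a declared stand-in for per-gene differential
expression (the original analysis used an external package): it ranks
genes by absolute difference of mean log expression, nothing more.

# Problem sizes and verification

The test suite verifies the statistical properties at sizes chosen to
make Monte-Carlo error small relative to the effects checked:
encapsulation calibration at $10^5$–$10^6$ droplets (binomial 99% CI /
3 SE), barcode-error rates at ≥ $10^5$ reads against the closed form
$1-0.99^{12}$, parameter recovery of the doublet rate from a
$2\times10^5$-droplet 1:1 barnyard, and repair-oracle equivalence on 100
random whitelist/readout instances. The no-noise identity check runs a
3000-droplet experiment deep enough (500 molecules/nucleus over a
300-gene panel) that every occupied barcode is whitelisted and verifies
the quantified matrix equals the truth molecule table cell for cell.

# Known limitations

* Doublet correction assumes independent species assignment per nucleus
  and exactly two species; triplets contribute a small upward bias that
  is negligible at 5% occupancy.
* With thousands of whitelist barcodes drawn uniformly from $4^{12}$
  sequences, chance near-neighbor pairs (Hamming ≤ 2) exist; repaired
  reads near such pairs are tie-discarded, slightly lowering recovery.
  Real bead libraries have the same property.
* The empirical correlations and region-fraction percentages published
  for real bladder-tumor and cell-line libraries depend on non-public
  sequencing data and are out of reach of the simulator by design; the
  package verifies the machinery, not those numbers.
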