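---
title: "Methods: segment maps, QTL scans and gene-allele triage in CSSL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment maps, QTL scans and gene-allele triage in CSSL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(csslqtl)
```

## The design this package analyses

A chromosome segment substitution line (CSSL) population is a panel of
near-isogenic lines, each carrying one or a few donor genomic segments in
an otherwise recurrent-parent genome, produced by repeated backcrossing to
the recurrent parent, selfing to homozygosity and marker-assisted
selection. Because each line differs from the recurrent parent by only a
handful of segments, a phenotypic difference can be attributed to the
donor segments that line carries, and a qualitative gene or QTL can be
mapped by comparing groups of lines rather than by linkage analysis in a
segregating family.

The package implements the analysis chain for such a panel genotyped by
low-coverage (~3x) resequencing, together with a simulator that generates
panels with known truth. This vignette records the models, the tunable
parameters and their defaults, the numerical choices, and what the
simulator does and does not emulate.

## Genotype model and QC

Genotypes are coded per line and SNP site as 0 (recurrent-homozygous),
1 (heterozygous), 2 (donor-homozygous) or missing. `qc_filter_snps`
retains sites with `QUAL >= 30`, missing-call fraction `<= 0.2` and mean
depth `>= 1.5` — the standard VCFtools-style thresholds for low-coverage
panels; all three are arguments.

## Breakpoint inference and segment calling

The procedure in `infer_line_segments` is, per line and chromosome:

1. **Smoothing.** Majority vote over a centred sliding window of
   `window = 15` non-missing sites. At ~3x depth with a ~1% symmetric
   mis-call rate, isolated flips are overwhelmingly errors; 15 sites is
   wide enough that a run of 8+ concordant sites always wins, narrow
   enough not to erase real short segments. A tie leaves the site's own
   call unchanged, which avoids oscillation between equally supported
   states. `window = 1` disables smoothing.
2. **Short-run absorption.** Runs supported by fewer than `min_sites = 5`
   sites are absorbed into the flanking run with more supporting sites
   (tie goes left, leftmost short run first). Five sites at ~3x depth is
   the point where a run is more likely real than a coincidence of
   errors; both parameters are exposed because the right values scale
   with depth and SNP density.
3. **Breakpoint placement.** The boundary between two runs is placed at
   the floor-rounded midpoint of the two flanking sites; the first and
   last segments extend to the chromosome ends, so the flanking parts of
   a chromosome are attributed to the nearest observed state.

**Coordinate convention.** Coordinates are 1-based inclusive; adjacent
segments and markers *share* their boundary coordinate and the physical
length of an interval is `end - start`. Under this convention per-
chromosome marker lengths telescope to the chromosome length (minus one
bp) and the published style of interval arithmetic (e.g. a block from
45,288,662 to 45,566,206 bp reported as 277.5 kb) is reproduced exactly.
Per-line composition percentages are denominated by the marker-covered
span so that recovery + donor + heterozygous + no-call = 100 exactly.

## SNPLDB markers

`build_snpldb_map` takes the union of all lines' breakpoints, which
partitions each chromosome into blocks within which *no* line recombines;
adjacent blocks whose per-line code vectors are identical across the
whole panel are merged. Each merged block is one SNP
linkage-disequilibrium block (SNPLDB) marker, named `<chrom>_LDB_<k>`
in 1-based positional order. This is the within-population definition of
a co-segregation block: an external germplasm-panel block structure, if
available, can be emulated by supplying pre-computed segment boundaries,
but none is required. Non-adjacent blocks can still carry identical code
vectors (collinear twins); they are deliberately kept as separate markers
because they are distinct genomic regions, and downstream analyses treat
them as statistically indistinguishable.

## Qualitative-trait mapping

`find_cosegregating_markers` contrasts each phenotype category pairwise
against the reference (recurrent-parent-like) category, excluding lines
of all other categories. The pairwise design matters under epistasis: with
a black-over-green two-locus seed-coat model, black lines may carry the
donor allele at the green locus without being green; excluding them from
the yellow-vs-green contrast prevents the green locus from being masked.
Markers are scored by the consistency C = n_pg/n_g x 100%, where n_g
counts donor-carrier lines in the contrast and n_pg the carriers with the
expected phenotype; heterozygous carriers count as non-carriers (the
panel is essentially homozygous) and a marker co-segregates when C = 100
and every line of the class carries it. C is reported exactly and rounded
to whole percent for display.

## Quantitative-trait mapping

`env_means` averages replicates within environment first, then
environments, so unbalanced replication does not reweight environments.
`heritability` estimates variance components from the two-way ANOVA
expected mean squares (line, environment, line x environment, residual):
sigma2_e = MS_err, sigma2_GE = (MS_GE - MS_err)/r,
sigma2_G = (MS_G - MS_GE)/(e r), and reports the entry-mean broad-sense
heritability h2 = sigma2_G / (sigma2_G + sigma2_GE/e + sigma2_e/(e r)).
Negative component estimates are truncated at zero. With one environment
the interaction is inseparable and h2 is flagged as entry-mean without it.

The additive scan is a stepwise-regression likelihood-ratio procedure on
the marker codes x in {-1, 0, +1} (donor = +1):

* `rstep_cofactors` runs forward-backward stepwise least squares with
  entry/exit thresholds `p_in = 0.001`, `p_out = 0.002` and a cofactor
  cap of n/5. The strict entry default follows the convention of
  stepwise QTL software for line populations. The choice is consequential:
  at near-perfect heritability a liberal threshold (say 0.05) admits
  dozens of cofactors whose carrier sets partially overlap true QTL
  carriers, which visibly biases small additive-effect estimates; with
  0.001 the selected set is essentially the true QTL blocks. Both
  thresholds are arguments.
* `lrt_scan` tests each marker m against the background B = cofactors
  minus those collinear with m (identical code columns — a marker is
  never masked by itself or its twins): LRT = n ln(RSS0/RSS1),
  LOD = LRT/(2 ln 10), ADD = the coefficient of m (half the carrier vs
  non-carrier contrast under +/-1 coding), PVE = 100 (RSS0 - RSS1)/TSS
  with TSS the cofactor-free total sum of squares, which makes PVE the
  share of raw phenotypic variance attributable to the individual QTL.
  LOD >= 2.5 declares a QTL; numerically perfect fits are capped at
  LOD 1e6; adjacent declared markers with identical codes merge to the
  peak-LOD representative. No multiple-testing correction is applied
  beyond the LOD threshold.
* `lines_vs_recurrent` uses a two-sided pooled-variance Student's t-test
  per line against the recurrent parent at alpha = 0.05 (Welch optional),
  and `explain_significant_lines` attributes each deviating line to
  declared QTL whose effect sign matches its direction.

## Candidate-gene triage

`expression_filter` removes a gene only when FPKM < 2 in *all* tissues
for *both* parents (a gene expressed anywhere may still act), and counts
differential tissues as those where the parental ratio exceeds 2, with an
epsilon floor of 0.01 on the denominator so that zero-expression tissues
count as differential rather than undefined. No replicate-based testing
is attempted — the filter is a fold-change rule on parental profiles.

`classify_variant_effect` assigns one primary class per variant and gene
with the precedence splice (2 bp at either intron end, donor at the
transcription-5' end) > coding change (stop gain / stop loss / missense /
synonymous by codon translation in CDS frame on the coding strand, with
strand-aware complementation) > UTR > intron > promoter > intergenic. The
promoter window defaults to 2000 bp upstream of the transcription start
site — a conventional choice for plant promoters — and is an argument.
Gene models are single-transcript. `rank_candidates` orders genes by
(impactful variant, differential-tissue count, maximum FPKM),
lexicographically descending, ties broken by gene id; "impactful" means
any protein-changing or splice variant, or at least `min_promoter_snps`
(default 3) promoter variants.

## Haplotype demonstration

`assign_haplotypes` labels a unit wild or cultivated at a gene only when
*all* diagnostic SNPs match the corresponding parent; any missing call
gives `missing` and any mixture `other` — a conservative rule that keeps
recombinants and third haplotypes out of the contrasts.
`background_matched_contrast` compares units wild at the focal gene and
cultivated at every other trait gene against the shared all-cultivated
background group, with a pooled-variance Student's t-test; groups smaller
than two are reported without a p-value. Under +/-1 coding the expected
contrast at an isolated QTL is twice its additive effect.

## The simulator: what it emulates and what it does not

`simulate_cssl_population` simulates explicit meioses: crossover counts
are Poisson per chromosome (default 1.25 Morgans, about one twentieth of
a ~2500 cM map over 20 chromosomes) with positions uniform on physical
length — no interference and no genetic-vs-physical map distortion.
Marker-assisted selection is approximated by keeping, at each backcross,
the gamete with fewer donor sites among two candidates. The
study-condition preset (`simulate_soja_population`) uses a 20-chromosome
~950 Mb genome with 200 evenly spaced SNP sites per chromosome (a
desk-scale stand-in for millions of SNPs; the block structure, not the
site count, drives the analysis), 177 lines drawn from BC3/BC4/BC5
schemes in proportions 103:46:28 with 7 selfing generations, and redraws
a line that carries no donor site (a substitution line carries at least
one segment by construction). Under these conditions the panels average
~97% recurrent-genome recovery and ~5 donor segments per line, inside
the intended 90-99% and 1-30 bands.

`observe_genotypes` draws per-site read depth Poisson(3.04 by default),
makes depth-zero calls missing, mis-calls symmetric with probability
0.01 and drops a further 2% of calls. Real low-coverage callers are
biased toward the reference allele rather than symmetric; the QC depth
filter makes this distinction immaterial at the pipeline level, and no
reference bias is simulated.

`simulate_phenotypes` plants a black-over-green epistatic seed-coat trait
and an additive days-to-flowering trait y = mu + sum(a_j x_j) + E_env +
eps over 3 environments x 3 replicates, with the six additive effects
(-0.58, 3.68, 2.63, -1.00, -0.72, 2.07 days) and a recurrent-parent mean
of 52.8 days. The residual scale is solved by bisection so that the
*realized* ANOVA-estimator heritability on the simulated table equals the
target (0.956 by default) — a closed-form solution would match the
population h2 but not the estimator on a finite draw. No genotype x
environment interaction, dominance or epistasis for the quantitative
trait is simulated.

`simulate_gene_models` builds toy single-transcript genes (2-3 exons,
canonical GT..AG introns, clean reading frames, short UTRs) and
`simulate_expression_and_variants` plants one variant of each requested
class per causal gene plus synonymous/intronic decoys, and parental
8-tissue FPKM profiles with >= 2-fold differences at causal genes and
sub-fold or sub-floor profiles at decoys.

Passing tests on these simulations therefore demonstrate that the
pipeline recovers the structure it assumes — mosaic segments, additive
QTL, fold-change expression signals, single-SNP effects — not that it is
robust to reference bias, structural variation, multi-isoform genes,
segregation distortion or population structure, none of which are
simulated.

## Numerical choices and degenerate inputs

* Bisection for the residual scale runs 60 iterations on [1e-6, 1e4] and
  fails loudly if the genetic variance is degenerate.
* A zero-variance phenotype yields all-zero LOD; a perfect fit caps LOD
  at 1e6; collinear markers give rank-deficient fits whose ADD is NA and
  LOD 0 at the masked marker (the twin carries the signal).
* An all-missing chromosome becomes a `no_call` segment, not an error;
  a marker with no donor carrier is omitted from a co-segregation
  contrast (C undefined at n_g = 0 is an explicit error in `cpg`).
* Majority-vote ties keep the observed call; absorption ties go left.
* Breakpoint midpoints are floor-rounded.

## Problem sizes used by the test suite

The suite simulates panels of 15-250 lines on genomes of 2-20
chromosomes with 25-200 sites each; the parameter-recovery study runs
100 seeded replicates of the full 177-line preset; the classifier oracle
covers 1000 random toy genes; the breeding-expectation check uses 500
unselected BC3 lines. The acceptance script runs the full pipeline once
at the preset scale.

## Known limitations

* Segment calling has no hidden-Markov model; at depths well below 3x or
  with strong reference bias the majority window will miscall short
  heterozygous residues.
* The scan is single-marker-with-cofactors; there is no interval mapping
  between markers, no dominance or epistasis terms, and no permutation
  threshold — the LOD 2.5 convention is used as-is.
* Small-effect QTL (well under 1 day here) carried by only a few lines
  are at the edge of detectability in a 177-line panel at ~97% recovery;
  the parameter-recovery tests quantify exactly this.
* Variant classification handles biallelic SNPs against single-transcript
  models only; indels, MNVs and isoform-level effects are out of scope.
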