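---
title: "Models and methods behind uselectr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind uselectr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uselectr)
```

`uselectr` analyses metagenomic libraries that were physically partitioned,
during single-stranded library preparation, into a uracil-enriched and a
uracil-depleted fraction. This vignette explains the models the package
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices a maintainer
should know about.

## The deamination model

Post-mortem cytosine deamination produces uracils, read as thymines, at a
rate that is elevated in the single-stranded overhangs at molecule ends. The
package models the per-site deamination probability at distance $i$ (bases)
from a molecule end as an exponential decay

$$p(i) = p_\mathrm{base} + (p_\mathrm{term} - p_\mathrm{base})\,e^{-i/\lambda}$$

with three interpretable parameters:

* `p_term` — probability at the terminal base (dimensionless, in $[0,1]$).
  Heavily degraded material sits around 0.3–0.5; herbarium-age material an
  order of magnitude lower. The package default is 0.3; the simulated study
  conditions use 0.4 for the heavily damaged taxon and 0.05 for the
  low-damage scenario.
* `p_base` — the interior plateau, the background C→T level far from ends
  (default 0.01).
* `decay_len` ($\lambda$) — the decay scale in bases (default 3), matching
  the few-base overhang lengths that dominate empirical damage curves.

No mechanistic form for the positional decay is implied by the chemistry;
the exponential was chosen because it matches the universally observed
end-elevated shape with the fewest parameters, and because it makes the
model self-consistent: `fit_decay_model()` can recover all three parameters
from a simulated library, which the tests exploit.

Two end conventions are supported. The default (`symmetric_ends = TRUE`)
applies C→T at both ends with the *smaller* of the two end distances driving
$p(i)$ — the single-stranded library chemistry that U-selection uses reads
both strands, so deamination appears as C→T at either end. A
`double_stranded` flag switches to the conventional double-stranded pattern
(C→T at 5′, G→A at 3′) for comparison with ordinary libraries.

## Fractionation and the conditional-damage oracle

The partition rule is mechanical: a molecule with at least one uracil is
released into the enriched fraction with probability `release_efficiency`,
a uracil-free molecule stays on the beads (depleted fraction) with
probability `retention_efficiency`. Both default to 1 — the idealised
protocol — and every molecule lands in exactly one fraction.

Conditioning on membership is what makes the enriched fraction a magnifying
glass. For a molecule whose C-bearing sites $\{i_j\}$ have probabilities
$p(i_j)$,

$$P_U = 1 - \prod_j \bigl(1 - p(i_j)\bigr)$$

and the expected C→T frequency at position $i$ among enriched molecules is
$p(i)/P_U$, aggregated over molecules weighted by their membership
probability (`expected_conditional_damage()`). The unselected library shows
$p(i)$, so the amplification fold at the terminal base is approximately
$1/\bar P_U$: *largest when damage is rare*, which is exactly the regime in
which damage-based authentication otherwise fails. The fold is therefore
monotonically decreasing in `p_term`, and undefined for a fully undamaged
model (the package returns `NA` with a warning rather than a number).

The oracle supports two input forms: an exact molecule set (using the actual
cytosine placements of the simulated fragments) for Monte-Carlo comparison,
and a fragment-length distribution with i.i.d. base composition for purely
analytic work. Both derivations were validated in the tests against a third
route — explicit enumeration over all $2^m$ deamination outcomes per
molecule — which is exact but only feasible for small molecules.

## What the generator emulates, and what it does not

`simulate_library()` composes fragment sampling (lognormal lengths, default
`meanlog = log(45)`, `sdlog = 0.35`, truncated at `min_length = 30` bp — the
usual mapping cutoff for short ancient reads), per-taxon deamination,
fractionation, and uniform sequencing error (default 0.003 per base where a
study condition, 0.001 otherwise). Deamination is applied before sequencing
error, and error can itself produce C→T — deliberately, so the depleted
fraction of a perfect partition shows the small error floor
(`error_rate`/3 per opportunity) seen in real data rather than an exact
zero frequency.

Deliberately **not** modelled: PCR duplicates, index hopping, adapters,
paired-end reads (the package lives in a merged-read world), fragmentation
bias, depurination, GC-dependent recovery, and mapping error (truth
alignments are exact). Passing tests therefore demonstrate the statistical
machinery — partition arithmetic, conditional frequencies, estimator
consistency, label logic — under a clean generative model; they do not
demonstrate robustness to mapper artefacts or library-preparation biases in
real data, where an external aligner's output should be supplied via
`read_alignments_sam()` or the alignment TSV interface.

Coordinates are 0-based half-open throughout; sequences are emitted 5′→3′ as
sequenced; truth labels ride in read headers after a reserved `|` delimiter
and in a TSV truth table. One master seed drives every stage through
deterministically derived child seeds, so identical `(config, seed)` produce
byte-identical outputs.

## Substitution profiles and decay fitting

`accumulate_profile()` counts all 16 ordered reference/read base pairs at
each of the first `n_positions` (default 25) positions from the 5′ and the
3′ end, in read orientation (reverse-strand alignments are flipped before
counting; the 3′ profile uses distance-from-3′-end on the same orientation,
matching the symmetric single-stranded model). `N` bases are excluded from
counts *and* opportunities, and positions with zero C opportunities are
reported as `NA`, never 0 — silent zeros would poison downstream decay fits.
Profiles are additive, so deep simulations can be accumulated in chunks.

`fit_decay_model()` performs bounded weighted least squares
(Levenberg–Marquardt via minpack.lm), weights proportional to opportunity
counts, parameterised as `p_term = p_base + delta` with `delta ≥ 0` so the
domain constraint is structural rather than clamped. Constant input is
detected up front and returned as a flagged degenerate fit
(`p_term = p_base`, `decay_len = NA`) instead of letting the optimiser wander
an unidentifiable ridge. Optional bootstrap standard errors resample
per-position counts binomially.

One subtlety: under the symmetric end model, 5′-profile positions near the
read centre mix in 3′-end damage from short molecules. Fits are therefore
run on the first 10 positions, where `min_length = 30` guarantees the 5′
distance is the smaller one for every molecule.

## Taxonomic binning

The classifier replaces an alignment-based search with canonical k-mer
counting: genome scores are numbers of shared k-mers (`k = 21`, odd, within
[11, 31]); candidates are genomes scoring at least `max_score × (1 − margin)`
(default `margin = 0.1`) and at least `min_score = 5`; the read is assigned
to the lowest common ancestor of the candidates' taxa. Ties always widen the
candidate set — conservative LCA semantics — and reads shorter than `k` are
unclassified, mirroring how very short single-stranded reads resist
taxonomic assignment in practice. The minimum-support and percentage knobs
of interactive metagenomics browsers are not reproduced; the three
parameters above are declared in the function signatures and the CLI.

`lca()` walks node pairs upward by depth; the test suite checks it against
an independent ancestor-set-intersection implementation on a thousand random
trees, and checks the per-node cumulative counts
(`cumulative(n) = direct(n) + Σ cumulative(children)`) against brute-force
descendant summation.

## Enrichment-based authentication

Per-taxon read counts in each fraction are normalised by the fraction's
total assigned reads (fractions are sequenced to unequal depth, so raw
counts are not comparable; a `raw_counts` flag retains the unnormalised
behaviour for figure parity). The statistic is the log2 ratio of
proportions. Uncertainty comes from Jeffreys posterior draws,
$\mathrm{Beta}(x + \tfrac12,\, n - x + \tfrac12)$ per proportion, propagated
through the ratio by simulation (1000 draws) — a choice that stays
well-behaved at the small counts typical of minor taxa, where Wald-type
intervals fail. Zero cells receive a pseudocount of 0.5 (and 1 on the
totals) for the point estimate only, so non-zero ratios remain exact
arithmetic; the pseudocount intentionally sacrifices exact scale invariance
for zero-count taxa.

Labels require the whole interval to clear a threshold: `ancient-like` when
the CI lower bound exceeds +0.5 log2 units, `recent-like` below −0.5,
`ambiguous` otherwise (threshold and `alpha = 0.05` both config-exposed).
Requiring the CI rather than the point estimate keeps the false
`ancient-like` rate under a one-multinomial null far below `alpha`, which
the tests verify over 500 replicates.

## Strain comparison

Historical-sample genotyping is majority-rule haploid consensus
(`min_depth = 3`, `majority_fraction = 0.7`, exact ties missing) — the
analysis needs a consensus allele at ascertained sites, not a likelihood
caller. By convention, genotyping of historical samples should use the
U-depleted fraction's alignments only, keeping deamination-induced C→T out
of the variant calls; this is a documented convention, not code magic, since
the functions cannot know where a pileup came from.

SNP ascertainment operates on modern samples only, with the
missing-to-reference merge policy (uncalled modern genotypes are taken as
reference calls), and keeps sites that segregate with strictly two alleles
counting the reference. The full-information filter then drops any site
missing in any historical sample, so retained sites are segregating in
modern material *and* covered in all historical samples. SNP identity is
plain Hamming agreement over those sites. PCA encodes alleles 0/1
(ref/alt), centers columns, and does not scale — standard practice for
biallelic haploid data; variance percentages are eigenvalue shares.

## Contig disambiguation

Contigs are length-filtered at 2 kb (inclusive: thresholds here are "at
least"), aligned to both candidate references, and called `unique_A` /
`unique_B` when their qualifying aligned span reaches 10 kb on one reference
with **zero** qualifying blocks (≥ 1 kb) on the other. Sub-1 kb incidental
matches on the other reference do not break uniqueness — the qualifying-block
rule makes that explicit. Whether the 10 kb rule sums blocks or requires a
single block is ambiguous in common usage; summed span is the default, with
`mode = "single"` as the strict alternative. Contigs aligned to one
reference only but below the span rule are reported distinctly as
`sub_threshold` rather than silently dropped.

The internal aligner is k-mer anchor seeding (`k = 15`) with
diagonal-banded grouping (`band = 30`) and gap-limited chaining
(`max_gap = 200` bases), stitching each chain into one ungapped block whose
identity is measured base-by-base. This is adequate for substitution-only
divergence up to ~10% and for the package's synthetic contigs; it does not
handle indels or rearrangements, so for real assemblies an external
aligner's coordinate table should be supplied in the `alignment_blocks`
layout. Reference coverage is the union length of merged reference
intervals over the reference length (IRanges), checked in the tests against
a per-base marking oracle.

The synthetic contig generator cuts contigs directly from two references
built around an identical shared segment, assigns k-mer coverage from two
lognormal modes (two organisms co-assembled at different abundances show
exactly this bimodality), and labels each contig with the classification it
should receive. Unique-class contigs are drawn at 10.5–12.5 kb — comfortably
above the 10 kb span rule, because ~1% divergence trims a few bases from
the chained block ends — while the `sub_threshold` class exercises the
region below the rule and a `filtered` class sits below the 2 kb length
filter.

## Problem sizes and tolerances

The test suite and the acceptance script use: 5×10⁴ molecules for partition
conservation/purity and oracle agreement (3 binomial SE); 10⁵ molecules for
the fold-amplification comparison (analytic vs Monte-Carlo within 20%);
9×5×10⁴ pooled molecules giving ≥10⁵ C opportunities per position for decay
recovery (`p_term` within ±0.05, `decay_len` within ±30%); 1000 random trees
for LCA; a 1500-read three-taxon mixture at 5% pairwise divergence for
binning accuracy (≥95% assigned to the true taxon or an ancestor); 100
authentication replicates plus a 500-replicate null; 20 strain-panel
replicates; and a 200-contig fixture. These sizes were chosen as the
smallest at which the binomial tolerances above are meaningful.

## Known limitations

* The deamination decay form is a modelling choice; real damage curves can
  deviate (e.g. nick-driven composite decays), and `fit_decay_model` will
  then return the best exponential approximation.
* Fraction-assignment efficiencies of the wet-lab protocol are unknown;
  `release_efficiency`/`retention_efficiency` are free parameters, not
  claims about the chemistry.
* The k-mer classifier is a minimal stand-in: no spaced seeds, no
  protein-mode search, no weighting by alignment quality.
* `read_alignments_sam` projects out indels; damage at positions adjacent
  to indels is attributed to the flanking match columns.
* The enrichment module performs no compositional transforms and no
  multiple-testing control across taxa; with many taxa, interpret
  `ancient-like` counts accordingly.
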