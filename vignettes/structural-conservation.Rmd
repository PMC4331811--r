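---
title: "Detecting DNA structural conservation in transcription factor binding sites"
author: "structcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DNA structural conservation in transcription factor binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structcons)
```

## The question

Binding sites of a transcription factor (TF) are conserved in primary
sequence — that is what a position weight matrix (PWM) captures. They may
*also* be conserved in DNA structure: different sequences can adopt similar
local geometry or thermodynamic behavior, and a TF may select its sites for
structure over and above what its sequence preference implies. `structcons`
asks, for a cohort of TFs with experimentally mapped binding sites, which
TF–structure pairs show structural conservation that is *not* explained by
sequence conservation, and where along the site the conservation
concentrates.

## Structural profiles and the conservation rate

DNA structure is represented by the nearest-neighbor model: each di- or
trinucleotide step carries a parametric value for one structural property
(roll angle in degrees, stacking energy in kcal/mol, ...). Sliding the
lookup along a sequence and anchoring each window's value at its first
nucleotide turns a length-$L$ sequence into a numerical profile of length
$L-1$ (dinucleotide), $L-2$ (trinucleotide), or $L$ for the hydroxyl-radical
cleavage table, whose per-trinucleotide intensity *triples* are averaged
over the windows covering each nucleotide. The mean of a profile is the
sequence's structural *level*; all tables are reverse-complement symmetric,
so levels are strand-invariant.

The shipped compendium holds 35 such tables (32 dinucleotide, 3
trinucleotide; conformational and thermodynamic). The thermodynamic tables
carry standard nearest-neighbor parameter sets; the remaining tables carry
representative values within published ranges, and the data file is named
`structural_properties_synthetic.tsv` to make that provenance explicit.
Every analysis accepts a user-supplied table file in the same dialect, so
a laboratory's preferred parameterization can be swapped in.

For a TF with $n$ aligned sites, the **conservation rate** under one
property is the mean, over all $n(n-1)/2$ site pairs, of the mean absolute
difference of their profiles; the per-position rate averages $|p_A(i) -
p_B(i)|$ over pairs at each position $i$. Low rates mean high structural
conservation. Normalization is per *profile* position rather than per
nucleotide, which makes rates comparable across word lengths and makes the
global rate exactly the mean of the per-position rates on clean sites
(both identities are tested). Windows containing non-ACGT characters are
treated as missing: levels average informative entries, and a site pair
contributes only at positions informative in both profiles.

## The three filters

Structural conservation is confounded with sequence conservation, with the
arbitrariness of any fixed value assignment, and with regional base
composition. Each confounder gets its own permutation filter; a TF–property
pair must survive all three.

1. **PWM-resampled null.** Random site sets are drawn from the real set's
   own PWM (each position independently from its base frequencies), holding
   expected sequence conservation fixed while destroying inter-column
   structure. The empirical p-value is the lower-tail rank of the real rate
   among `nPerm` null rates, with the add-one convention
   $p = (r+1)/(N+1)$ — ties count toward the extreme tail and $p$ is never
   zero. Bonferroni correction uses the number of properties as the family
   (per TF): with a genome-wide family the minimum attainable p at
   $N = 10{,}000$ permutations could never reach significance, so per-TF
   correction is the only workable reading.
2. **Shuffled-table null.** The same sites are re-scored under tables whose
   values were permuted among reverse-complement k-mer *classes* (10
   dinucleotide, 32 trinucleotide), preserving physical RC symmetry. A pair
   passes only if conservation depends on the true value assignment, not
   merely on sequence similarity (which any shuffled table reproduces).
   Shuffling over classes rather than raw k-mers is a deliberate choice:
   shuffling raw k-mers would produce physically impossible asymmetric
   tables. The positional hydroxyl-radical table has no meaningful value
   shuffle in this scheme; pairs reaching filter 2 under it are flagged
   `shuffleSkipped` and conservatively not passed. The family is the number
   of filter-1 survivors.
3. **Flank comparison.** Sites could appear "structurally conserved" merely
   because the surrounding region is. For each site the absolute structural
   level of the site is compared with that of its flanking sequence (30 bp
   on each side, site excluded, truncated at chromosome ends; the two
   segments are pooled into one flank observation per site, weighted by
   informative positions). A one-sided Mann–Whitney U test (exact for small
   tie-free samples via `stats::wilcox.test`) asks whether sites run higher
   in absolute level than flanks; the family is the number of filter-2
   survivors. Absolute values are used because many properties are signed;
   testing signed levels would conflate direction with magnitude.

Pairs surviving all three filters are localized per position: the real
per-position rate is ranked against the same position's rates in
PWM-resampled sets, Bonferroni-corrected by the profile length, and
reported 1-based.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nPerm` | 10000 | permutations per null (200 in the packaged benchmarks, which trades resolution for runtime; the smallest attainable p is $1/(N+1)$) |
| `alpha` | 0.05 | significance level after Bonferroni correction |
| `flankBp` | 30 | flank length per side in the filter-3 comparison |
| `minSites` | 15 | strict lower bound on sites per TF (`> minSites`) |
| `topN` | 500 | affinity-rank cutoff in the 8-mer correlation, controlling for nonspecific binding |

## Correlating structure with binding affinity

For protein-binding-microarray data, every 8-mer ($4^8 = 65{,}536$) gets a
structural level per property; within the `topN` highest-affinity 8-mers
(ties broken lexicographically) the Pearson correlation between affinity
and level is computed with a two-sided t-test on $n-2$ degrees of freedom.
A pair is flagged when $|r| > 0.1$ and $p < 0.05$; with $n = 500$ the
$|r|$ screen is the binding constraint, and under an independent-affinity
null the joint flag fires at the exact Pearson-null rate (≈2.5%), which the
acceptance suite verifies.

## What the synthetic generator emulates — and what it does not

`genFixtureGenome()` builds a toy genome with embedded, strand-randomized
binding sites, a matching site table, and promoter-forming gene
annotations. Constrained site sets are produced by oversampling a candidate
pool from the PWM (pool size $n(1 + 50\,s)$ for strength $s$) and greedily
selecting the $n$ candidates minimizing total pairwise conservation-rate
contribution, seeded at the densest $n$-neighborhood with ties broken by
candidate index. Strength 0 reduces exactly to PWM sampling; the mean rate
is non-increasing in strength (tested).

The packaged benchmark cohort was designed around how the three filters can
fail, and its choices are worth recording:

- **Structural synonymy drives the planted signal.** A planted property
  assigns one extreme value (±6) to *four* reverse-complement classes and
  distinct, well-separated values (spacing ≥ 2) to the rest. Sites can then
  be structurally near-identical while sequence-diverse. Fewer coincident
  classes are provably fragile: with two classes a value shuffle reproduces
  the coincidence with probability 1/45, and filter 2 loses its power.
- **A breaker class sits inside the dominant letter pair** (e.g. TA among
  the A/T classes, with the A/T classes AA, AT high): PWM resampling of a
  conserved set then produces windows that exit the coincident-value set,
  which is what makes filter 1 reject. Without a breaker,
  column-independent resampling reproduces the conservation and the signal
  is (correctly) attributed to sequence composition.
- **Permissive motifs.** Cohort PWMs carry ~0.1 bit/position. At high
  information content the candidate pool collapses onto consensus
  duplicates; a set of near-duplicates is conserved under *every* table and
  its own PWM, so all filters correctly reject it — there is no detectable
  structure-specific signal to plant. Constrained TFs use letter-composition
  bias (A/T-rich vs C/G-rich) rather than a consensus, which anchors the
  selected cluster on high-|value| windows (required by filter 3) while
  keeping columns diverse.
- **Study sizes.** 5 TFs × 30 sites × 10 bp, two planted constraints at
  strength 0.8, 200 permutations, flanks ±30 bp on an 80 kb genome. These
  sizes keep a full landscape run to a few seconds while leaving all three
  filters well-powered; site counts of ~30 are typical of TFs passing a
  more-than-15-sites cohort cut.

The generator emulates the *statistical* structure the method assumes —
PWM-distributed sites, tunable structural constraint, neutral flanks. It
does not model promoter base composition, nucleosome context, overlapping
sites, or inter-site spacing biases of real genomes; passing these
benchmarks shows the machinery is calibrated and powered under its own
assumptions, not that any particular biological cohort will yield signals.

## Numerical choices and degenerate inputs

- Empirical p-values use $(r+1)/(N+1)$ with ties counted as extreme;
  corrected significance is a strict inequality (`p·m < alpha`).
- Identical sites give rate 0 and, against a degenerate PWM null, p = 1 —
  degenerate cohorts are uninformative rather than significant.
- Mixed-length site lists keep the modal length; ambiguous-base sites are
  dropped at load time (both logged). Site/coordinate mismatches are hard
  errors naming the offending row.
- Coordinates are 0-based half-open everywhere at the file level
  (`--one-based` converts); minus-strand sites are reverse-complemented at
  extraction so profiles align positionally.
- Promoters are 600 bp upstream of the strand-aware gene start, truncated
  at neighboring gene bodies; a site between divergent genes goes to the
  gene whose start is nearest the site midpoint, ties to the
  lower-coordinate gene.
- Ends of chromosomes truncate flanks; a site whose flanks contain no
  informative window is dropped from filter 3.

## Known limitations

- The filter-1 statistic is conservative: the PWM is estimated from the
  tested set itself, so unconstrained cohorts yield fewer than α nominal
  rejections (the calibration test asserts the one-sided bound). This
  protects the landscape against false positives at some cost in power.
- The hydroxyl-radical cleavage property cannot pass filter 2 (no
  physically meaningful value shuffle exists for positional triples), so it
  can never appear in the final landscape under the default three-filter
  policy.
- Conservation rates are never compared *across* properties — each property
  is tested only against its own nulls; the per-position normalization
  makes rates dimensionally comparable but the landscape draws no such
  comparisons.

## A worked miniature

```{r example, eval = FALSE}
library(structcons)
set.seed(7)

comp <- structuralProperties()
roll <- comp[["roll"]]
pwm <- genPWM(10, 1)      # permissive motif: 1 bit over 10 positions
sites <- genConstrainedSiteSet(pwm, 30, roll, strength = 0.8, tfName = "toyTF")
conservationRate(sites, roll)
pwmNullTest(sites, roll, nPerm = 1000)$pValue
shuffledTableNullTest(sites, roll, nPerm = 1000)$pValue
```

The full pipeline is `buildLandscape()` (or the `structcons landscape`
command-line front end in `inst/exec/`), which emits the landscape table,
the TF × property pass matrix, the positional results and a run log.
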