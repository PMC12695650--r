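---
title: "strandkaryo: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strandkaryo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in `strandkaryo`, the
assumptions they rest on, the tunable parameters and why their defaults are
what they are, and the design choices made where more than one reasonable
option existed. Nothing here is a measured result; the quantitative behavior
of every component is established by the test suite, which builds all of its
inputs from the bundled synthetic generator.

## 1. The data model

Strand-directional single-cell sequencing reads the template strands a cell
inherited at its last division. `strandkaryo` works entirely at bin
resolution: the observation is a table of Watson and Crick read counts per
(cell, chromosome, 200-kb bin, haplotype tag). Three conventions hold
throughout:

* coordinates are 0-based, half-open (BED convention); bins tile each
  chromosome, the last bin may be short;
* haplotype information is carried as a per-read tag (`H1`, `H2`, `H3` or
  `untagged`): a configurable fraction of reads (default `tag_frac = 0.15`)
  is tagged with its true haplotype. Real pipelines phase reads at
  heterozygous SNPs; a bin-level tagged fraction carries the same
  information without modelling SNP positions;
* the default genome model is a reduced five-chromosome synthetic genome
  (50–150 Mb chromosomes). Nothing downstream depends on real coordinates,
  and an hg38-like size table is available for full-scale runs.

Cells with fewer than `qc_min_fragments = 50,000` mapped fragments are
flagged as QC failures. Published Strand-seq studies clearly apply per-cell
QC but rarely state thresholds; this value is a decision, not a
reproduction, and is configurable.

## 2. The synthetic population generator

The generator is the package's test bed and defines the conditions under
which every downstream claim is verified.

* **Depth.** Fragments per cell default to 285,000, the median reported for
  the motivating experimental setting. Expected totals are always exactly
  the depth parameter: sequencing depth is a property of the library, not
  of the genome's copy content.
* **Counts.** Per (bin, haplotype), expected counts are proportional to
  local copy number × bin width, drawn negative-binomially with
  `dispersion = 2` (variance = 2 × mean). No published quantitative noise
  model exists for these libraries; a doubling of the Poisson variance is a
  conservative, configurable stand-in.
* **Strand.** Each fragment maps to the strand of its source copy; a
  background `bg_flip = 0.02` fraction maps to the wrong strand so that
  strand states must be inferred rather than read off.
* **Templates and SCEs.** Each homologue gets a uniform random start
  template; SCE counts per cell are Poisson with mean `sce_mean = 6`
  genome-wide, positions uniform on interior bin boundaries. The rate only
  needs to make sister pairing informative; it is a free knob.
* **Sister pairs.** Daughters receive exactly complementary templates, and
  every parental SCE appears in both at the same boundary with mirrored
  orientation — the biological invariant the pairing module exploits.
* **Events.** Eleven injectable classes cover the CA taxonomy: whole
  chromosome gains/losses, terminal and interstitial gains/losses, terminal
  inverted duplications (gain on the strand opposite the host template),
  whole-arm events, amplifications (delta ≥ +2), isoacentric gains (even
  delta split 1:1 between Watson and Crick), telomere-anchored multi-step
  runs, and chromothripsis (alternating retained/lost fragments of one
  haplotype). Placement is uniform over allowed positions, sizes log-uniform
  between 1 Mb and the arm length with a 2-bin minimum, and the default
  class mix follows the observed spontaneous-micronucleation spectrum
  (terminal events most common, chromosome losses far exceeding gains,
  interstitial events rare).

What the generator does **not** emulate: read-level artifacts (GC and
mappability bias, duplicates), replication-timing structure, BrdU chemistry,
segmental sub-bin breakpoints, and doublets. Passing tests therefore show
correctness of the inference given the stated noise model, not robustness to
every artifact of real libraries; the blacklist and QC hooks are where such
artifacts would be absorbed.

## 3. Segmentation and state assignment

Per cell, two per-bin signals are stacked for change-point detection: the
normalized total copy signal and the overall Watson fraction. Both are
variance-stabilized (square root for counts, arcsine-square-root for the
fraction) so that one robust noise scale — estimated from median absolute
successive differences within chromosomes — holds across WC, WW and CC
chromosomes. The change-point engine is exact penalized least-squares
partitioning (PELT, compiled) with penalty `penalty × d × log(n)` per
change-point (`penalty = 1.5`, `d = 2` dimensions, `n` bins per chromosome).
Breakpoint count is provably non-increasing in the penalty, which the tests
exercise.

The sparse per-haplotype tag counts are deliberately excluded from the
change-point cost: their per-bin counts are small and heteroscedastic, and
pooled-scale costs on them generate spurious single-bin segments. They enter
instead in the per-segment state likelihood, which assigns each segment the
maximum-likelihood state over all per-haplotype copy numbers (cap
`cn_cap = 6` total, states at the cap flagged) and Watson/Crick copy
placements: negative-binomial depth × binomial overall strand × multinomial
haplotype-tag split × per-haplotype binomial tag strand. Ties break toward
the consensus state (minimal-change principle) through an infinitesimal
penalty on copy-number distance.

Two refinements follow:

* **Single-bin scan.** Bin-sized events sit below the two-change-point
  penalty, so each bin is tested by likelihood ratio against copy-number-
  changing neighbor states, using only the high-count depth and strand
  components (well approximated by a χ² reference). The threshold is set
  for a genome-wide false-positive budget `single_bin_alpha = 0.05`. A
  copy-changing alternative must also beat every same-total strand
  rearrangement, so a stray bin at a mislocalized SCE boundary — perfectly
  explained by a strand flip at unchanged copy number — is never called.
  Detection at this scale is intentionally marginal: it is the resolution
  limit, and single-bin calls should be treated as candidates (the examples
  filter at 2 bins for high-confidence sets).
* **State merging.** Adjacent segments assigned identical states are merged
  and re-assigned on pooled reads, which removes spurious change-points
  without biasing real ones.

Bins whose population-median coverage falls below `blacklist_frac = 0.25` of
the genome median are masked before segmentation — a proxy for unmappable
regions when no mappability track is in scope.

The consensus karyotype is the per-bin modal integer copy number across
cells (total and per haplotype), smoothed within chromosomes to the modal
value, since the population baseline is a whole-chromosome property; a
trisomic chromosome thus gets consensus 3 and de novo calls are deviations
from it. At least `consensus_min_cells = 3` cells are required.

## 4. Classification

Per (chromosome, haplotype), deviating runs against the consensus are
formed; adjacent runs of the same sign collapse into one event (an isolated
gain whose interior carries a further amplified step is still one isolated
gain, labelled by its dominant delta). The decision tree is then applied in
order:

1. one run covering the whole chromosome → chromosome gain/loss;
2. ≥ `chromothripsis_k = 5` oscillating switches between exactly two
   copy-number states (minor third states tolerated up to 5% of the span)
   → chromothripsis. `K = 5` separates chromothripsis from terminal
   multi-step events, which typically produce 2–4 switches; it is
   configurable;
3. ≥ 2 deviating runs forming one contiguous telomere-anchored block on a
   single arm → terminal multi-step. Arm contiguity is the separator
   between "localized oscillations alongside terminal events" (kept in
   multi-step) and scattered complex rearrangement; it is the exposed,
   documented rule for an ambiguity the source taxonomy leaves open;
4. more than two breakpoints not resolved above → complex;
5. a single telomere-anchored run → terminal gain/loss; a single interior
   run → interstitial gain/loss.

Annotations: `whole_arm` when an isolated call covers > 90% of an arm
(`whole_arm_frac = 0.9`); `amplification` when delta ≥ +2;
`inverted_duplication` when a terminal gain's extra copy sits on the strand
opposite the host homologue's template (the host template is read from the
nearest single-copy segment of the same haplotype); `on_breakpoint` when a
call edge lies within one bin of a user-supplied locus (targeted-DSB
experiments); `isoacentric_signature` for even-delta gains whose Watson and
Crick copy increments are equal.

The isoacentric read-level tolerance check deserves a note. The flag is
decided primarily at the integer-state level (equal W/C increments in the
assigned state). A per-event two-sided binomial check of the observed
Watson reads against the balanced state's expectation is applied on top
when raw counts are available — but a plain binomial at α = 0.05 would
wrongly strip the flag from ~5% of genuinely balanced events (and more,
because per-copy totals are negative-binomial, leaving the W/C split
overdispersed by about the dispersion factor). The check therefore uses
dispersion-scaled counts (a quasi-binomial correction) at a small default
`iso_alpha = 0.005`: it is a guard against grossly unbalanced states that
slipped through assignment, not a gatekeeper for clean ones.

Calls narrower than `min_size = 200,000` bp are filtered (chromothripsis is
judged by its whole affected span), reflecting the method's resolution
limit.

## 5. Sister-cell pairing

Template strands are inferred per homologue from single-copy segments;
within-homologue strand switches at constant copy number are SCEs with
orientation. Pair scoring: reciprocity is the fraction of homologue-bins
informative in both cells with opposite template; an SCE is mirrored when
both cells switch within `sce_tol_bins = 1` of the same boundary in opposite
orientations. The verdict is `sisters` when reciprocity ≥
`reciprocity_min = 0.95` and either ≥ 1 mirrored SCE or perfect reciprocity
over ≥ 90% of the genome; pairs with under 20% informative coverage are
`ambiguous` and excluded (the doublet/degenerate path). A cell against
itself scores reciprocity 0 — identical is not reciprocal. Under the null,
per-homologue reciprocity is Bernoulli(0.5), so with dozens of informative
homologue-bins per chromosome the false-sister rate at these thresholds is
vanishing; the tests verify both the null mean (≈ 0.5) and the absence of
false verdicts, and population matching is greedy by descending reciprocity
with deterministic id tie-breaks.

## 6. The agent-based rate model

States: normal interphase, micronucleated interphase; mitosis types normal /
laggard (lagging chromosome) / bridge (chromatin bridge); arrest. When a
cell's fixed-duration clock (the measured median cycle length; the duration
only sets the time scale) expires, it transitions to a mitosis type or
arrest with probabilities conditioned on its interphase state; a division
replaces the parent with two daughters, yields one micronucleated daughter
with probability `q_mn`(type), and acquires a heritable de novo CA with
probability `R`(type), assigned to one daughter uniformly — matching the
per-division phrasing of the rates. Runs start at 50 cells and stop exactly
at 50,000 (tests use 5,000 for speed).

Because all cells share the cycle duration, generations never interleave:
each generation is processed as one vectorized batch in clock-offset order,
reproducing the event-queue dynamics exactly while keeping a 50,000-cell run
in milliseconds. Population frequencies are sampled at ~30 geometric
population-size checkpoints; under wild-type imaging parameters (6.2%
laggard, 5.1% bridge mitoses; 32.3% / 17.2% daughter micronucleation;
micronucleated parents 9.5× as likely to produce a micronucleated daughter,
capped at 0.95, and more arrest-prone) the micronucleus frequency reaches a
stable plateau, which the tests check via the coefficient of variation of
the final ten checkpoints. The normal-mitosis daughter-micronucleation
probability (0.04) and the arrest probabilities (0 from normal, 0.25 from
micronucleated interphase) are not printed quantities; they are approximate
defaults chosen so the simulated interphase micronucleus frequency sits near
the observed ~5%, and simulated frequencies are treated as properties, not
reproductions.

**Rate estimation and identifiability.** Rates are estimated by multi-start
Nelder–Mead minimization of the SSE between simulated and target CA
frequencies, with a fixed set of replicate seeds per evaluation (common
random numbers) so each start's objective is deterministic, a simplex
restart from the first-round optimum (collapsed simplexes are common on
noisy piecewise-constant objectives), box constraints via clamping plus a
quadratic out-of-bounds penalty, and a residual-error-weighted average
across starts. The default target compartments are the CA frequencies of
micronucleated and normal cells — the two observable compartments — but two
observations cannot identify three rates: the laggard and bridge rates trade
off along a ridge, which is visible as scatter in per-start estimates. The
simulation therefore also reports *de novo* acquisition frequencies by
parent mitosis type (the fraction of live daughters of each mitosis type
whose CA arose at their own birth, ≈ R/2, observable in principle when
imaging genealogy is coupled to sequencing). The parameter-recovery tests
fit against these plus the two observable compartments, making the problem
well-posed; users fitting real data with only two compartments should read
the per-start spread as the honest uncertainty.

The basal rate is the dot product of the per-type rates with the
mitosis-type frequencies — a pure arithmetic reduction, validated against a
direct oracle.

## 7. Exact statistics

Fisher's 2×2 test and the two-sided exact binomial test delegate to R's
exact implementations (`fisher.test`, `binom.test`; point-probability
method); the test suite verifies both against independent brute-force
enumeration oracles for every configuration up to n = 12. Per-chromosome
enrichment tests each chromosome's call count against the total with a
one-sided exact binomial under the null that every homologue is equally
likely to acquire a CA (so a trisomy contributes three homologues; the
homologue weighting is overridable), with Benjamini–Hochberg adjustment by
default (`bonferroni` selectable) and flagging at adjusted p < 0.05. The
loss/gain bias test flips each event's direction with probability 0.5
(optionally within strata) and reports the fraction of permutations whose
absolute imbalance reaches the observed one, plus its Monte-Carlo standard
error; unstratified, it converges to the exact two-sided binomial tail,
which the tests use as its oracle. The published stratified construction
lives in supplementary material and is not reproduced; the sign-flip
construction is documented as this package's interpretation.

## 8. Numerical choices and degenerate inputs

* Watson fractions carry a pseudocount of 1 per strand; empty bins are
  well-defined.
* Zero-coverage cells raise a typed QC error; chromosomes at copy number 0
  are skipped in strand-state inference with a warning.
* All-arrest ABM parameterizations terminate with an extinction report
  rather than hanging; optimizer non-convergence is recorded per start, not
  fatal.
* Every malformed input (wrong columns, negative counts, off-grid
  coordinates, unknown chromosomes, bad probabilities) raises a classed
  condition; no partially-loaded objects escape.
* All stochastic entry points take a seed and restore the caller's RNG
  state; fixed seeds reproduce byte-identical outputs.

## 9. Problem sizes in the test suite

Unit tests run on a three-chromosome 90-Mb genome with depth scaled to
preserve per-bin coverage. The end-to-end property tests use the default
five-chromosome genome at full depth: 500 cells for per-class recovery, 20
seeded 30-cell populations for sister-pair precision/recall, 40 replicates
per size for the detection-limit sweep, and a stop population of 5,000 with
5 optimizer starts for ABM rate recovery. These sizes are the package's
choice of a thorough-but-routine regression suite; scaling any of them up
only narrows Monte-Carlo error.

## 10. Known limitations

* Breakpoints are reported at bin boundaries; no sub-bin refinement and no
  junction (read-pair) evidence.
* Precision at the single-bin scale is intentionally modest; 200-kb calls
  are candidates, not confident calls.
* The segmentation is a penalized least-squares engine with an enumerated
  state space, not a reimplementation of any published Bayesian caller;
  equivalence is claimed to the stated inputs (depth, strand, haplotype)
  and the 200-kb resolution, not to another tool's internals.
* The ABM has no explicit chromosome identity, no fitness differences and
  no spatial structure; arrest simply removes cells.
* Sister-pair matching is greedy; an optimal matching would matter only in
  pathological near-tie configurations.
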