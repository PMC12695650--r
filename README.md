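# strandkaryo

De novo chromosomal abnormality (CA) calling, classification and mutation-rate
modelling from binned, strand-resolved single-cell sequencing counts.

## The problem

Strand-seq sequences the BrdU-labelled template strands of a single cell, so
every read maps to the Watson (+) or Crick (−) strand according to the template
its homologue inherited at the last division. At intermediate coverage
(~285,000 mapped fragments per cell) this preserves haplotype identity along
whole homologues and makes three things visible at once:

* **copy number** — read depth per 200-kb bin;
* **strand state** — the Watson/Crick composition of each chromosome
  (WC, WW, CC, and derived states such as WWC after a gain);
* **lineage records** — sister cells inherit *complementary* template strands
  on every homologue, and each parental sister-chromatid exchange (SCE)
  appears in both daughters at the same breakpoint with mirrored orientation.

`strandkaryo` uses these signals to call de novo CAs in single cells against a
population consensus, classify them into the standard taxonomy (chromosome
gain/loss, terminal and interstitial gains/losses, terminal multi-step,
complex, chromothripsis) with strand-informative annotations (inverted
duplication, whole-arm, amplification, isoacentric signature, on-breakpoint),
identify sister-cell pairs directly from the sequencing data, and estimate
per-mitosis-type CA mutation rates with an agent-based model (ABM) of a
growing cell population. It targets researchers studying chromosomal
instability in near-diploid cell models, and ships a synthetic Strand-seq
population generator with a complete ground-truth ledger so every claim is
testable.

## Models in brief

**Calling.** For cell *i* and bin *b*, the tool forms the normalized copy
signal *y<sub>ib</sub>* (depth scaled so the consensus baseline maps to its
integer copy number) and the Watson fraction
*w<sub>ib</sub>/(w<sub>ib</sub>+c<sub>ib</sub>)*. Change-points are found by
penalized least-squares (PELT) on the variance-stabilized pair of signals;
each segment is then assigned the maximum-likelihood integer state over all
per-haplotype copy numbers and Watson/Crick copy assignments (negative
binomial depth × binomial strand × multinomial haplotype-tag likelihood),
with ties broken toward the consensus. A likelihood-ratio scan recovers
single-bin (200-kb) events that sit below the two-change-point penalty.

**Sister pairing.** Per-homologue template strands are read off single-copy
segments. Reciprocity of a cell pair is the fraction of informative
homologue-bins with opposite template state; under the null it is
Bernoulli(0.5) per homologue, so the genome-wide false-sister rate at the 0.95
reciprocity threshold is negligible, while true sisters score ≈ 1 with
mirrored SCEs.

**Rates.** Cell agents cycle through interphase → {normal, laggard, bridge}
mitosis or arrest with empirical transition probabilities; a division
produces a micronucleated daughter with a mitosis-type-specific probability
and a heritable de novo CA with probability *R*(type). Rates are estimated by
multi-start bound-constrained Nelder–Mead minimization of the sum of squared
errors between simulated and target CA frequencies (common random numbers per
start), and the basal CA rate is the mitosis-frequency-weighted average
Σ *R<sub>t</sub> f<sub>t</sub>*.

## Worked example

```r
library(strandkaryo)

genome <- synthetic_genome()
grid <- build_bin_grid(genome, bin_size = 200000)

sim <- simulate_population(genome, grid, n_cells = 40, depth = 285000,
                           event_rate = 1, events_per_cell = "fixed",
                           sister_fraction = 0.2, seed = 7)

consensus <- build_consensus(sim$counts, grid)
track <- segment_population(sim$counts, grid, consensus)
calls <- classify_population(track, consensus, grid, counts = sim$counts)

# single-bin (200-kb) calls sit at the detection limit; keep >= 2 bins
confident <- filter_min_size(calls, min_size = 400000)
class_breakdown(confident)$classes
#>                 class     n   pct
#> 1:      terminal_gain     8  24.2
#> 2: terminal_multistep     4  12.1
#> 3:    chromosome_loss     7  21.2
#> 4:     chromothripsis     2   6.1
#> 5:  interstitial_gain     6  18.2
#> 6:            complex     2   6.1
#> 7:      terminal_loss     2   6.1
#> 8:    chromosome_gain     1   3.0
#> 9:  interstitial_loss     1   3.0

recovery <- match_calls_to_truth(confident, sim$truth$events)
sum(recovery$recovered)  # 30 of the 32 injected events

states <- strand_state_population(track, grid)
find_sister_pairs(states, grid)[, .(cell_a, cell_b, reciprocity, mirrored_sces, verdict)]
#>     cell_a  cell_b reciprocity mirrored_sces verdict
#> 1: cell001 cell002           1             4 sisters
#> 2: cell003 cell004           1             5 sisters
#> 3: cell005 cell006           1             5 sisters
#> 4: cell007 cell008           1             7 sisters

basal_rate(c(3.7, 92.5, 84.4), c(0.887, 0.062, 0.051))
#> [1] 13.32127   # percent of divisions; 13.3% to one decimal
```

The breakdown table lists per-class counts and percentages of all calls; the
pair table shows that every planted sister pair was found with full-genome
template reciprocity and mirrored SCEs; the final number is the basal CA rate
per division obtained by weighting the mitosis-type-specific rates (normal
3.7%, laggard 92.5%, bridge 84.4%) by the observed mitosis-type frequencies.

A command-line interface mirroring the pipeline
(`strandkaryo simulate | segment | classify | pair | rates | stats`) is
installed under the package's `exec/` directory.

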