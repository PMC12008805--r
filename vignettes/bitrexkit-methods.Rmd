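---
title: "Models and methods behind bitrexkit"
author: "bitrexkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bitrexkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitrexkit)
```

`bitrexkit` studies the population dynamics of tandem gene arrays —
consecutive, same-orientation copies of a gene-sized repeat unit (the
canonical example is the budding-yeast *CUP1* array of ~2.0-kb units; the
human D4Z4 macrosatellite with its 3.3-kb unit is the same geometry). Two
opposing forces shape array copy number:

* **expansion** through break-induced replication (BIR): when a replication
  fork collapses at a nick placed just outside the array, the single-ended
  break inside the terminal repeat unit can only re-invade in register or
  further upstream — there is no downstream unit — so the array either
  stays the same or grows, never shrinks, through this route;
* **contraction** through homologous recombination between any two unit
  copies, a pairwise reaction whose rate grows with the square of the copy
  number.

The package provides (i) a per-lineage stochastic simulator of these
dynamics, (ii) the deterministic second-order contraction model and its
statistics, (iii) long-read genotyping of array length by spanning-read
dot-plot counting, (iv) read-depth copy-number estimation with duplicate
masking, and (v) a split-read screen for rearrangements involving the
array locus. Everything runs on synthetic data with complete truth tables,
so every estimator can be validated against known ground truth.

## The contraction model

Let $X$ be the repeat-unit copy number and $k$ the rate constant of
inter-unit recombination. Treating contraction as a pairwise event gives
the second-order rate law

$$\frac{dX}{dt} = -kX^2, \qquad X(t) = \frac{X_0}{1 + kX_0t},$$

a rectangular hyperbola in time. The observable used throughout is the
**copy-number alteration per generation**,
$\mathrm{CNA/G} = (X_T - X_0)/G$ for an exposure window of duration $T$
spanning $G$ divisions; under the model

$$\mathrm{CNA/G} = -\frac{1}{G}\,\frac{X_0^2}{X_0 + 1/(kT)},$$

which is algebraically identical to
`(closed_form_x(X0, k, T) - X0) / G` (the package asserts this identity to
$10^{-12}$). As $X_0 \to \infty$ the curve approaches the straight line
$-(X_0 - 1/(kT))/G$; the residual $c^2/((X_0+c)G)$ with $c = 1/(kT)$
vanishes, which is why measured CNA/G against initial copy number looks
linear for long arrays.

Two empirical companions: `cna_g_empirical()` is the measured statistic
$(\mathrm{copy}_T - \mathrm{copy}_0)/\mathrm{divisions}$, and
`divisions_from_od()` counts divisions as $\log_2$ of the optical-density
fold change of the culture over the window — the standard batch-growth
doubling count.

One modelling wart is intentional: at $X = 1$ the $kX^2$ rate is nonzero,
although a single-copy array has no recombination partner. We implement
the $X^2$ form as the primary model because it is the form the field uses,
and expose `pairwise = TRUE` to switch to $kX(X-1)$, which vanishes at a
single copy. The stochastic simulator does not share the wart: its
contraction magnitude is drawn from $\{1, \dots, X-1\}$, which is empty at
$X = 1$, so a single-copy lineage can never contract regardless of the
hazard.

### Fitting the rate constant

`fit_k()` fits the closed form to a measured trajectory by bounded
nonlinear least squares (Levenberg–Marquardt, $k \ge 0$), co-estimating
$X_0$ by default (`estimate_x0 = FALSE` pins it to the day-0 value).
Uncertainty comes from a case-resampling bootstrap over time points
(default 1000 draws, percentile interval, seeded). A series with no net
decrease carries no information about $k$ under the constraint, so the fit
short-circuits to $k = 0$ with a `no_contraction` flag rather than
reporting a spurious boundary estimate. Times are in days throughout; the
`G_per_day` argument only records how to convert fitted time into
generations.

`predict_fragment_size()` is the small accounting used to check expanded
arrays on pulsed-field gels: a restriction enzyme with no site in the unit
releases the whole array on one fragment of
$(n \cdot u + \mathrm{extra})/1000$ Mb, reported rounded
half-away-from-zero to one decimal — the reading precision of a gel. For
2.0-kb units this gives 0.5 Mb at 252 copies and 0.8 Mb at 377 copies.

## The stochastic population simulator

`simulate_population()` evolves a population of lineages, each an integer
copy number, through synchronous generations:

1. **Division with asymmetric inheritance.** Every cell divides; with
   probability $p_\mathrm{eff}$ (and only when $X \ge 2$ — a single copy
   offers no out-of-register donor) an expansion event occurs. One
   daughter always inherits the donor chromatid with the original $X$; the
   other receives $X + s$, with $s$ geometric on $\{1, 2, \dots\}$ of mean
   `step_mean` (default 1.5 — jump sizes are variable in practice but no
   distribution is established; geometric is the maximum-entropy choice on
   positive integers with a fixed mean).
2. **Contraction.** Independently, each daughter contracts with hazard
   $1 - e^{-kX^2}$, the exact per-generation probability implied by the
   continuous second-order rate; the magnitude is uniform on
   $\{1, \dots, X-1\}$ (no magnitude law is established; uniform is the
   least-informative choice, and it makes $X = 1$ absorbing).
3. **Dilution.** The population is resampled with replacement back to
   `population_cap` (multinomial dilution, the serial-transfer analogue).
   An infinite cap keeps the full lineage tree, which is what the
   enumeration oracle in the test suite checks against.

The **origin geometry** enters through $p_\mathrm{eff}$. With a
replication origin inside the repeat unit (`origin_mode = "internal"`),
the fork orientation the mechanism needs is always available:
$p_\mathrm{eff} = p_\mathrm{exp}$. With only external origins, the
nick-proximal fork races a fork arriving from beyond the array; for two
constant-speed forks the near fork wins with probability

$$p_\mathrm{eff} = p_\mathrm{exp}\,
  \frac{d_\mathrm{int}}{d_\mathrm{int} + d_\mathrm{ext} + X \cdot u},$$

with $d_\mathrm{int}$ the nick-side origin distance, $d_\mathrm{ext}$ the
far-side distance and $u$ the unit length in bp. Only monotone decline of
expansion with array length is established empirically; the race of two
constant-speed forks is the simplest mechanism producing it, and it yields
the observed plateau: expansion stalls as $X \cdot u$ dominates the
denominator.

Defaults (`p_exp = 0.05`, `step_mean = 1.5`, `k = 0`) are placeholders in
the sense that no empirical estimates of the per-division expansion
probability or step-size law exist; every quantitative test in the package
therefore either sets these explicitly or checks distribution-free
properties.

`simulate_qpcr_series()` turns replicate trajectories into measurement
series by adding i.i.d. Gaussian noise to the population mean — the error
structure of a calibrated qPCR population-average assay.

## Synthetic genomes and reads

`build_array_genome()` embeds `n_units` copies of a randomly drawn unit
(optionally separated by an intervening segment — the interrupted-array
configuration produced by plasmid integration) into a random background
chromosome, flanked by unique ~1-kb anchors. Anchor uniqueness is verified
on both strands after construction and the background is re-drawn (up to
10 times) if violated. The background is drawn before the per-copy
divergence substitutions, so genomes differing only in `n_units` share
unit and flank sequences — this is what lets a one-copy genome serve as
the masked mapping reference for a many-copy sample. All truth intervals
are 0-based half-open.

`simulate_reads()` emulates ligation-based long-read sequencing: lognormal
(heavy-tailed) or fixed read lengths, uniform starts over the
$C - L + 1$ admissible positions of each linear chromosome (reads longer
than the chromosome are truncated to it), both strands, and independent
substitution errors. There are no indels by design: the matcher stack
exploits the fact that substitution-only errors leave dot-plot diagonals
intact, and real nanopore indel noise is out of scope. Reverse-strand
reads are stored reverse-complemented, as a sequencer emits them. The
truth table records each read's source interval and whether it fully
covers array plus both anchors.

`inject_rearrangement()` engineers the three events the screen must
detect — reciprocal translocation at the array 3' edge, integration of an
excised multi-unit circle at an ectopic site, and whole-chromosome gain —
recording exact breakpoints.

## Spanning reads and automated dot-plot counting

Per-molecule genotyping selects reads that span the entire array
(both 1-kb flank anchors present, consistent strand, correct order:
`select_spanning_reads()`), then counts repeat units as the number of
diagonal lines in the read-versus-unit dot plot (`count_units()`). The
matcher is a seed-and-chain design: exact 15-mer seeds, grouped by
dot-plot diagonal (tolerance 16 bp), split at positional gaps larger than
10% of the unit length, each maximal diagonal segment being one candidate
unit copy. A segment counts as a unit iff it covers at least 60% of the
unit (`min_unit_fraction`) — partial terminal diagonals below that are
not counted, a convention the hit-count estimator documents explicitly
since a read covering 2.5 units reports 2 or 3 depending on this
threshold. Anchor location adds a full-anchor extension along the
diagonal and accepts hits at $\ge 0.8$ identity; spanning additionally
requires complete anchor coverage, which under a substitution-only error
model is exactly the "fully spans" condition. Seed length 15, identity
floor 0.8 and the 10% gap tolerance are tuned for substitution rates up to
~10% (at 5% errors, 46% of 15-mers survive, leaving dozens of seeds per
unit); all are configurable.

**Ascertainment.** A read spans only if it covers $S = A + 2a$ bp (array
plus both anchors), so long arrays are seen less often:
$P(\mathrm{span} \mid A, L) = \max(L - S + 1, 0)/(C - L + 1)$, capped at
1, averaged over the read-length law (`ascertainment_model()`). The
spanning-read copy-number histogram is therefore biased low in
length-heterogeneous populations; `bias_corrected_mean()` reweights each
read by $1/P(\mathrm{span} \mid A(n))$ — a Horvitz–Thompson estimate —
with a bootstrap interval. Reads whose spanning probability is zero under
the model cannot be reweighted and are excluded with a warning.

## Depth-based copy number with duplicate masking

Population-average copy number comes from sequencing depth: reads are
placed on a reference in which every duplicate copy of the unit beyond one
retained copy is masked (masked intervals are simply dropped from the
placer's seed index — the in-silico equivalent of `N`-masking a reference
before mapping). All unit-derived reads then pile onto the retained copy,
and after dividing by the mean depth of declared single-copy background
(`normalize_depth()`; background = genome minus an exclusion list, masked
bins never used), the retained copy's normalized depth reads out the copy
number directly. Bins are 100 bp by default; bin value is covered bases
per bin divided by bin size, so binned counts conserve total placed bases.
Normalization is idempotent by construction (the background mean after
normalization is 1).

The internal placer is seed-chain-extend with a unique-best rule: a
second candidate at a different locus within 5% of the best score makes
the read ambiguous, and ambiguous placements are discarded (counted in
`placer_stats`) — multi-mapping reads are never evidence. Reads that
cross unit junctions match the reference discontinuously; the placer
falls back to the seed-chain segment when the full-read projection fails
the identity floor, and unplaced read ends of at least 50 bp get one
re-placement pass, so junction reads contribute both pieces. With these
two rules, simulated 30x short-read data recovers copy numbers 2–50
within a few percent.

`region_copy_number()`, `region_ratio()` (e.g. macrosatellite versus
single-copy flank) and `chromosome_ploidy()` summarize the normalized
profile. Ploidy calls use strict thresholds (gain > 1.25, loss < 0.75 —
between a disomy's 1.0 and a trisomy's 1.5 on a diploid, and forgiving of
normalization drift); a mean exactly at a threshold stays euploid. The
array locus must be excluded from per-chromosome means since its depth
reflects repeat copy number, not ploidy.

## Split-read rearrangement screen

Reads containing the unit are split at their unit matches: sequence
before the first accepted unit segment is the 5' flank, after the last
the 3' flank; the repetitive core is discarded and flanks shorter than
200 bp are dropped (too short to place uniquely next to a repeat). Each
flank is reduced to its breakpoint — the reference position of the flank
end that abuts the array, strand-corrected — and compared with the
expected array edges within a ±2-kb window. Both breakpoints at the
edges: `in_situ`. A uniquely placed breakpoint elsewhere:
`translocation` (one-sided evidence suffices, as a read may cover only
one side of a junction). Both flanks off-site but within 20 kb of each
other at a common locus: `ectopic_integration`, the signature of an
integrated excision circle. Multi-mapped flanks are `ambiguous` and never
evidence — next to a repeat array this is the main false-positive
channel, and discarding it is what keeps clean simulations at zero false
calls. The screen reports per-class counts and rates rather than a binary
verdict; "no detectable events" is a statement about counts at a given
read depth, not a threshold crossing.

## Orchestration, reproducibility and file formats

`run_end_to_end()` chains genome → population/qPCR → long reads →
spanning genotyping → short-read depth → rearrangement screen → kinetics
summary from a single validated config (JSON or YAML; R has no
widely-installed TOML reader and YAML is the ecosystem norm). A single
master seed derives one child seed per stage through a fixed
multiplicative mixer (`derive_seed()`), so sibling stages have
independent streams and the whole run is bit-reproducible; the test suite
checks byte-identical outputs across repeated runs. Intermediate files
use standard formats only: FASTA and 4-line FASTQ (written directly —
C-level FASTQ writers cap line length below nanopore read lengths), BED
and bedGraph via `rtracklayer`, TSV series, JSON reports. Every estimate
in the report is paired with the truth value the generator recorded.

## Problem sizes and what the tests do (and do not) show

The validation suite runs at deliberately modest scale: arrays of 1–50
units, chromosomes of tens of kilobases, 30x short-read depth, dozens to
thousands of long reads, 50 bootstrap-calibration series, 20-replicate
screens. At these sizes the full suite completes in minutes while still
exercising every code path at the study conditions (2-kb units, 1-kb
anchors, 5% substitution error where errors are tested).

Synthetic data is i.i.d.-random background with exact repeats and
substitution-only errors. Passing tests therefore demonstrate
correctness of the algorithms and estimators under the stated model —
they do not demonstrate robustness to indel-rich nanopore error profiles,
genomic low-complexity or Ty-like dispersed repeats, GC-dependent
coverage bias, or mappability structure of real genomes. Those belong to
the tools the package's design mirrors (general-purpose aligners,
coverage normalizers with bias tracks) and are out of scope here.

Other known limitations: unit copies more diverged than the identity
floor (default 0.8) stop being counted rather than being genotyped
per-copy; free (unintegrated) excision circles are invisible to the
split-read screen; the depth reference must share unit/flank sequence
with the sample (guaranteed for generator-built pairs with matching
seeds); and the ascertainment model assumes a single chromosome length,
so mixtures should be simulated on equal-length chromosomes or the model
evaluated per stratum.
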