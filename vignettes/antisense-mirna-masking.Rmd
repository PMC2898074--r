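---
title: "Methods: miRNA binding-site depletion in sense-antisense overlap regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA binding-site depletion in sense-antisense overlap regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmirmask)
options(asmirmask.log_level = "quiet")
```

## The question and the statistic

Natural antisense transcripts (NATs) overlap a sense transcript on the
opposite strand and can form an RNA duplex with it across the overlapping
("pairing") region.  A duplex over a miRNA binding site can *mask* it — the
miRNA machinery and the antisense compete for the same nucleotides, as in the
BACE1 / BACE1-AS / miR-485-5p example.  If masking matters in evolution,
predicted miRNA sites should be depleted in pairing regions relative to the
non-pairing remainder of the same transcripts.

The pipeline turns that into one comparison.  For each conserved
sense-antisense pair the pairing and non-pairing regions are mapped, miRNA
binding sites are predicted in both, counts are normalized to region length,
and the per-pair densities

$$d_{i,\mathrm{pairing}} = \frac{n_{i,\mathrm{pairing}}}{L_{i,\mathrm{pairing}}},
\qquad
d_{i,\mathrm{nonpairing}} = \frac{n_{i,\mathrm{nonpairing}}}{L_{i,\mathrm{nonpairing}}}$$

are compared with a two-sided Wilcoxon rank-sum test, plus a Monte Carlo
randomization null with $P = x/N$ over $N$ randomizations, where $x$ counts
randomizations whose statistic is strictly smaller than the real data's.

## Pipeline stages and parameters that matter

### Overlap mapping (`find_overlap`)

The overlap is defined as the best local alignment between the sense sequence
and the reverse complement of the antisense sequence, with BLASTN-like scores
(match $+2$, mismatch $-3$, gap of length $k$ costing $5 + 2k$); a pair whose
best alignment scores below `min_score` (default 40, i.e. 20 net matches) has
no overlap.  `overlap_len` is the aligned span on the sense transcript, and
pairs with `overlap_len >= 25` nt pass the inclusion filter — the boundary is
inclusive.  Gaps inside the overlap are tolerated; one best alignment defines
the overlap (no HSP chaining).  The original analysis used BLAST with
unreported settings, so these scores are this package's explicit, exposed
choices; the region-class comparison is insensitive to them because both
classes are mapped under one setting.

### Site prediction (`scan_params`, `align_mirna`, `duplex_energy`)

A miRanda-style two-phase scheme.  Phase 1 aligns the reversed miRNA against
the target scoring complementarity — A:U and G:C as match ($+5$), G:U wobble
($+1$, symmetric in the two strands), mismatch $-3$, affine gaps
($-8 - 2k$) — with per-position pairing scores multiplied by 4 at miRNA seed
positions 2–8.  A perfect 22-mer complement therefore scores
$7 \times 5 \times 4 + 15 \times 5 = 215$; the default acceptance threshold
is $S \ge 90$, which an exact seed match alone (140) already clears.  All
local optima above threshold are reported greedily best-first with previously
used target spans masked, so one miRNA's sites never overlap; different
miRNAs' sites may, and all count.

Phase 2 filters candidates by nearest-neighbor RNA:RNA duplex free energy at
37&nbsp;°C: Watson-Crick stacks from the Turner-group table (Xia et al. 1998),
G:U wobble stacks following Mathews et al. (1999) — the wobble entries should
be read as approximate — duplex initiation $+4.09$ kcal/mol, $+0.45$ per
terminal A:U or G:U pair, a fixed $+3.0$ per interior helix interruption, and
dangling ends ignored.  Default cutoff $\Delta G \le -17$ kcal/mol, which in
practice demands roughly ten contiguous base pairs; a perfect 22-mer duplex
sits far below it.  The numeric agreement with Microinspector / RNA22 /
miRacle energies is *not* a goal; the energy model is internally consistent
and reproducible, nothing more.

All scores and thresholds are config-exposed.  The headline statistic
compares region classes under one fixed setting, which is what makes it
robust to these choices.

### Strand convention

Whether the original study scanned one or both transcripts is not stated.
The pairing region is one physical duplex, so this package scans it once, on
the sense transcript's aligned span; scanning the antisense core as well
would double-count the same nucleotides in complement space (a site planted
in the sense core appears in the antisense core as the miRNA sequence itself,
not as a target).  With the default `strands = "both"` the non-pairing pool
is the flanks of *both* transcripts; `strands = "sense"` restricts everything
to the sense transcript.  Region lengths used for densities always follow
the same convention as the scan.

### Statistics (`compare_regions`, `wilcoxon_rank_sum`)

The Wilcoxon observation unit is one pair in one region class.  Quartiles of
per-pair densities use linear interpolation between order statistics
(quantile type 7); the aggregate "mean per 100 nt" is the totals ratio
$100\sum n / \sum L$, the only definition under which printed means equal
printed totals.  The rank-sum test enumerates the exact null when
$\min(n, m) \le 10$ and there are no ties, and otherwise uses the normal
approximation with tie-corrected variance and continuity correction (the two
paths agree to within $|\Delta p| \le 0.01$ at $n = m = 10$); an
all-identical pooled sample gives $p = 1$ by convention.

### Randomization null (`randomization_test`)

Two interpretations of "shuffled sequences … randomly selected to create two
data sets" are implemented, and neither is claimed as the original:

* `label` (default): reassign the cached per-observation (count, length)
  records to simulated classes of the real sizes, uniformly at random — fast
  and exact; no record's count or length ever changes, only its class.
* `shuffle`: shuffle each region sequence's nucleotides (mono- or
  dinucleotide-preserving Euler-path shuffle), reassign, and re-run the
  scanner before computing densities — the literal reading, at re-scanning
  cost.

"Smaller than" is strict; ties count toward not-smaller, which is
conservative.  $P = x/N$ exactly, with $N = 1000$ by default and the
significance cut-off at 0.05.

## The synthetic world

`generate_pair_set` builds each pair as `left flank + core + right flank` on
the sense strand and the reverse-complemented core with its own flanks on
the antisense strand, so the pairing region has known coordinates.  Defaults
state the study-scale world: 391 pairs, overlap lengths uniform on
400–1400 nt, four non-pairing flanks uniform on 500–1500 nt each (2000–6000
nt of non-pairing sequence per pair), i.i.d. background at GC 0.5, a
20-miRNA panel of 22-mers, and planted per-nucleotide site rates 0.0521
(pairing) / 0.0708 (non-pairing) — the observed aggregate densities at those
region totals.

Two design points deserve emphasis:

* **Counts versus placements.**  A density of 0.0708 sites per nt exceeds
  the packing limit of disjoint 22-mers (1/22 ≈ 0.045) — real predicted
  sites overlap heavily across miRNAs, planted exact complements cannot.
  The generator therefore draws each region's site *count* from the exact
  Poisson(rate × length) law (recorded in the ground truth and used for all
  density statistics) and physically inserts as many of those sites as fit
  without overlap, flagging each event `placed`.  At packable rates every
  event is placed and the two notions coincide; recovery guarantees apply
  to placed sites.
* **Boundary insulators.**  Local alignment will extend a planted core into
  random flanks whenever the boundary score walk goes positive (roughly a
  30% chance per end), so the generator writes 12 deliberate mismatch
  positions on each side of the core (sense flank reads `A`, the aligned
  antisense positions read as `C`), making any cross-boundary column a
  mismatch under any gap shift.  This is what makes "the mapper recovers the
  planted core exactly" a testable statement rather than a probabilistic
  one.  Flank sites are planted outside the insulator margin.

Planted sites are perfect complements by default, decoupling generator
correctness from scanner tuning; a `mismatch_rate` knob exists for harder
tests.  What the generator does *not* emulate: splicing and UTR structure,
conservation, empirical k-mer composition, and overlapping site geometry.  A
green recovery test therefore establishes that the pipeline finds what was
planted and classifies it correctly — not that the scanner reproduces any
particular published site list.

## Worked example

```{r example}
cfg <- synthetic_config(n_pairs = 40, overlap_len_range = c(150, 300),
                        flank_len_range = c(150, 300),
                        rate_pairing = 0.008, rate_nonpairing = 0.02,
                        mirna_panel_size = 6, seed = 7)
ps <- generate_pair_set(cfg)
res <- nat_enrichment(ps$records, ps$pairs, ps$mirnas, n_reps = 200, seed = 7)
res
```

```{r figure, fig.width = 5, fig.height = 4}
plot(res)
```

## Numerical choices and degenerate inputs

* Internal alphabet is DNA; RNA input is mapped U→T on read, and `N` never
  pairs (always a mismatch, never a wobble).  Internal coordinates are
  0-based half-open; all written tables are 1-based inclusive.
* Scanner ties are broken by score, then leftmost target span; the overlap
  aligner's tie-break among equal-scoring local alignments is the
  deterministic traceback of the underlying alignment engine.
* miRNAs shorter than 7 nt are an error (no seed); shorter than 16 nt a
  warning.  Segments shorter than 7 nt are skipped with a log entry.
  Alignments with no paired position have energy 0 by convention, with a
  warning.
* Every random draw is scoped: generators and tests take explicit seeds and
  restore the caller's RNG state, so a (config, seed) pair is reproducible
  and composable.

## Known limitations

* The scanner approximates the published miRanda scheme but is not miRanda;
  absolute site counts depend on thresholds and should only be compared
  across region classes under a fixed setting.
* Wobble stack energies are approximate literature values; energies are
  reproducible, not server-comparable.
* One best local alignment defines the overlap; pairs with several widely
  separated overlap blocks are represented by the strongest block only.
* The real-data medians and IQRs of the original study depend on the
  FANTOM-3 and miRBase inputs and are not reproduced here; the package
  reproduces the arithmetic, the filter accounting, and the behavior of the
  statistics on synthetic data of stated geometry.
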