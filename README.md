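# asmirmask

Do predicted microRNA binding sites avoid the regions where sense and
antisense transcripts can pair?

Natural antisense transcripts (NATs) are RNAs transcribed from the strand
opposite a sense gene; over their overlapping region the two transcripts can
form an RNA duplex.  A duplex formed across a miRNA binding site can *mask*
it — antisense pairing and miRNA binding compete for the same nucleotides
(the BACE1 / BACE1-AS / miR-485-5p case).  If that competition matters over
evolutionary time, predicted miRNA sites should be depleted in the
sense-antisense pairing (overlap) regions relative to the non-pairing
remainder of the same transcripts.

`asmirmask` implements that genome-scale test as a reusable pipeline for
people working on NATs, miRNA targeting and ceRNA-style regulation:

1. **Overlap mapping** — the pairing region of each sense-antisense pair is
   the best local alignment of the sense sequence against the reverse
   complement of the antisense (BLASTN-like scores, match +2 / mismatch −3 /
   gap 5+2k); pairs with an overlap ≥ 25 nt enter the analysis.
2. **Site prediction** — a miRanda-style two-phase scanner: seed-weighted
   complementarity Smith–Waterman (A:U, G:C match +5; G:U wobble +1;
   mismatch −3; affine gaps −8−2k; miRNA positions 2–8 scaled ×4; S ≥ 90),
   then a nearest-neighbor RNA:RNA duplex free-energy filter at 37 °C
   (ΔG ≤ −17 kcal/mol).
3. **Enrichment statistics** — per-pair site densities *n/L*, medians and
   IQRs per region class, aggregate means 100·Σn/ΣL per 100 nt, and a
   two-sided Wilcoxon rank-sum test of pairing vs non-pairing densities.
4. **Randomization null** — the Monte Carlo test *P = x/1,000*: region
   observations are reassigned (or nucleotide-shuffled and re-scanned) into
   simulated pairing/non-pairing sets of the real sizes 1,000 times; *x*
   counts randomizations whose Wilcoxon statistic is smaller than the real
   one.
5. **Synthetic data** — a generator of sense-antisense pair sets with exact
   reverse-complement overlaps and planted miRNA complements at controlled
   per-nucleotide rates, plus mono- and dinucleotide-preserving (Euler-path)
   shufflers, so everything above is testable with no external data.

## Worked example

```r
library(asmirmask)

cfg <- synthetic_config(n_pairs = 40, overlap_len_range = c(150, 300),
                        flank_len_range = c(150, 300),
                        rate_pairing = 0.008, rate_nonpairing = 0.02,
                        mirna_panel_size = 6, seed = 7)
ps  <- generate_pair_set(cfg)
res <- nat_enrichment(ps$records, ps$pairs, ps$mirnas, n_reps = 200, seed = 7)
res
#> Sense-antisense miRNA binding-site depletion analysis
#>   pairs: 40 input, 40 usable (0 unresolved), 40 retained with overlap >= 25 nt (100.0%)
#>   predicted sites: 774 (strands = both)
#> miRNA site density by region class
#>   pairing     n=  40  median 0.00857 /nt (IQR 0.00526-0.01287)  mean 0.92 /100nt
#>   nonpairing  n=  40  median 0.01911 /nt (IQR 0.01656-0.02142)  mean 1.88 /100nt
#>   Wilcoxon rank-sum (two-sided): W = 931.5, p = 3.55e-11
#>   direction: nonpairing > pairing
#> Monte Carlo randomization test (label mode)
#>   x = 0 of 200 randomizations with simulated p < real (3.551e-11)
#>   P(randomization) = x/200 = 0
```

Reading the output: 40 synthetic pairs were built with sites planted at
0.008/nt in the overlap and 0.02/nt in the flanks.  The pipeline re-detects
those sites, the per-pair density medians (0.00857 vs 0.01911 per nt) sit
near the planted rates, the Wilcoxon test calls the depletion of the overlap
at p ≈ 4·10⁻¹¹, and none of 200 random reassignments of region labels
reproduces a separation that strong (P = 0/200).  `plot(res)` draws the
per-100-nt density boxplot by region class; `summary(res)` adds the
aggregate site/nucleotide totals.

Real data enter the same way: `read_fasta()` for transcripts and mature
miRNAs (miRBase-style, U→T normalized), `read_pair_table()` for the
sense-antisense pair list.  A thin command-line wrapper with
`simulate | partition | scan | enrich | randomize | run-all` subcommands is
installed at `system.file("scripts", "asmirmask.R", package = "asmirmask")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the two headline
quantities on the study-scale synthetic world (391 pairs; overlap lengths
uniform 400–1400 nt; 2000–6000 nt of non-pairing sequence per pair; planted
rates 0.0521/nt pairing vs 0.0708/nt non-pairing): the two-sided Wilcoxon
rank-sum p-value for per-pair density depletion (`t5`) and the 1,000-rep
label-permutation randomization p-value `x/1000` (`t6`), writing both to the
JSON file given by `--out`.

## Further reading

The methods vignette (`vignettes/antisense-mirna-masking.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, the synthetic world's design (including why site counts and
physical placements are distinct at saturating densities), numerical
conventions, and known limitations.
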