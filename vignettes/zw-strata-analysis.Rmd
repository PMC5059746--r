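---
title: "Inferring sex-linked scaffolds and evolutionary strata in ZW genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-linked scaffolds and evolutionary strata in ZW genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In snakes and many other ZW systems the female is the heterogametic sex:
she carries one Z and one W, the male two Zs.  Once recombination between
Z and W stops in some chromosomal region, the W copy of that region decays
-- it accumulates substitutions against its Z partner, loses genes to
nonsense and frameshift mutations, and is invaded by transposable
elements.  Because suppression typically happens in a few discrete events,
the Z carries *evolutionary strata*: adjacent regions with distinct,
shared levels of Z--W divergence, each dating one suppression event.

zwstrata implements the full evidence chain a resequencing study uses to
reconstruct that history from one male and one female genome:

1. genome size from a k-mer depth spectrum;
2. classification of assembly scaffolds as Z-linked, W-linked or autosomal
   from two-sex read depth;
3. sex-contrasted heterozygosity through standard variant filters;
4. windowed evidence tracks along the Z and their changepoint
   segmentation into strata;
5. W gametolog degeneration: ORF-disruption scans, Z--W divergence and
   tree-topology dating across species.

A deterministic synthetic generator (`sim_config()`, `simulate_bundle()`)
produces every input with known ground truth, so each estimator in the
chain is validated end-to-end.

# Coverage-based sex linkage

For each scaffold we compute mean depth and covered fraction per sex
(`summarize_coverage()`) and the **scaled M:F ratio**

$$ r = \frac{\bar d_M / N_M}{\bar d_F / N_F}, $$

where $N_M, N_F$ are per-sex autosomal reference depths.  After
normalization an autosome expects $r = 1$, a fully differentiated Z-linked
scaffold $r = 2$ (two male copies, one female copy), and a W scaffold has
essentially no male coverage.  The rule set (defaults in
`sex_thresholds()`):

* W rule first: female coverage $> 80\%$ of the length and male coverage
  $< 20\%$.  It precedes the eligibility filter because a genuine W
  scaffold *fails* male coverage by construction.
* eligibility: length $\ge 500$ bp and coverage $\ge 80\%$ in the
  better-covered sex;
* Z window $1.6 \le r \le 2.4$ (within 20% of 2, boundaries inclusive);
* autosome window $0.8 \le r \le 1.2$ (the mirrored tolerance around 1 --
  no standard autosome rule exists, so the Z tolerance is reused);
* otherwise UNASSIGNED, with the failed rule recorded as evidence.

## Two-pass normalization

$N_M$ and $N_F$ are not known a priori.  A plain median over all
scaffolds works only while autosomes dominate the assembly; when
sex-linked bp rivals autosomal bp the female median falls between the
autosomal and Z depth modes and the absolute windows capture nothing.
`classify_all()` therefore finds the autosomal set structurally first:
library-size-normalized log2 ratios (W-rule scaffolds excluded) are split
by an exact one-dimensional two-means partition, and the lower cluster is
taken as provisionally autosomal -- autosomes always sit below Z-linked
scaffolds on this axis, whatever the mixture proportions.  When the two
cluster centres are within 0.5 log2 units there is no Z-linked cluster
and everything is provisional-autosomal, so a genome without sex
chromosomes degrades gracefully.  Pass 2 normalizes by the provisional
cluster's length-weighted median depth, applies the absolute windows, and
re-derives the final norms from the resulting AUTO calls.  The split is
exact and deterministic, so classification is invariant to input order
and to rescaling either library.

# Genome size from the k-mer spectrum

With $K_{num}$ k-mer instances in the genomic (non-error) part of the
spectrum and a per-copy depth $D$, the genome size is $G = K_{num}/D$.
Two numerical choices matter:

* **Error cutoff.**  Sequencing errors produce a spike of near-unique
  k-mers at depth 1--3.  `find_peak()` smooths counts with a 3-bin moving
  average and takes the first local minimum scanning from depth 1 as the
  cutoff; $K_{num}$ sums $d \cdot c_d$ strictly above it.  A spectrum that
  only decreases has no main peak and is an error.
* **Peak depth: mean, not mode.**  `estimate_genome_size()` uses the
  *expected value* of the k-mer depth above the cutoff
  ($\sum d c_d / \sum c_d$, rounded to integer) rather than the modal
  depth.  The mode is quantized to whole depths, so a true per-copy depth
  of, say, 29.9 yields mode 29 and a $\sim 3\%$ error in $G$; the mean is
  unbiased to well under 1%.  The modal depth is still reported for
  diagnostics (`modal_depth`), with ties broken toward the lower depth.

The simulated spectrum is a multinomial draw of $G$ genomic k-mers over
Poisson depth bins (so instances are conserved) plus an error spike
holding $\approx G \cdot D \cdot (1-(1-e)^k)$ erroneous instances.
Heterozygosity and repeat structure of real spectra (e.g. the additional
minor peak a female Z/W produces) are *not* modelled, and no operation
interprets secondary peaks.

# Heterozygosity contrasts

Variants are kept when depth lies in $[10, 120]$ (inclusive -- the
bounds' inclusivity is configurable) and quality $\ge 100$.  The rate
denominator is **callable sites**: bp whose depth lies in the same
bounds, not scaffold length; this makes rates comparable between regions
of different coverage and is configurable.  A hemizygous female Z cannot
be truly heterozygous, so its residual rate measures the error floor.
Sexes are compared by a two-sided Wilcoxon signed-rank test over paired
1-Mb windows (`compare_het()`): zero differences are excluded
(Wilcoxon's rule; an all-zero comparison returns p = 1 with a warning),
the exact null is used up to 25 informative pairs and the
continuity-corrected normal approximation beyond.

# Tracks and strata segmentation

Five windowed tracks can be laid along the Z (1-Mb windows by default,
100 kb for repeats): female:autosome depth ratio (1 in recombining
regions, 0.5 where the female is hemizygous), length-weighted Z--W
p-distance of alignment fragments anchored on the Z, W-fragment density
(merged coverage per window; highest where suppression is recent),
cross-species alignment score (older strata have diverged further from
the outgroup Z because of male-biased mutation), and repeat-family
density.  Windows without evidence are NaN.

`segment_strata()` makes the usual by-eye demarcation explicit:
tracks are z-scored (equal weight, configurable via pre-scaling),
NaN windows are imputed from the nearest observed window *for the fit
only*, and the best piecewise-constant model is found by binary
segmentation followed by cyclic single-breakpoint refinement -- the
refinement repairs the occasional greedy misplacement on staircase
signals and makes the result agree with the exact dynamic program
(`method = "dp"`), which is kept as an oracle for moderate sizes.  The
breakpoint count is fixed (`k = 2` for a three-stratum model) or chosen
by a BIC-style penalty `3 * log(n) * sum(sigma2)` whose per-track noise
variance comes from the median absolute first difference -- a robust
estimate that does not see the segment structure itself.

`label_strata()` then names segments: a segment whose mean depth ratio
lies in $[0.85, 1.15]$ is a recombining PAR; the rest are ranked by mean
Z--W divergence, descending, as S1 (oldest), S2, ...; segments with no
divergence evidence are UNRANKED.  Note that the oldest stratum need not
sit at a chromosome end.

# Gametolog degeneration and dating

Alignment columns containing any gap or ambiguity are removed (a strict
stand-in for block-based cleaning), and only cleaned alignments longer
than 300 bp enter divergence or tree estimation.  Divergence is the
p-distance by default; the Kimura two-parameter correction is optional
and flagged when saturated.  `scan_orf()` walks a W sequence against its
intact Z partner in the Z reading frame: an in-frame stop before the
terminal codon is a premature stop; an indel run whose length is not a
multiple of three is a frameshift, with run-based accounting so paired
indels that restore the frame do not flag downstream codons.  Both
disruption types count toward pseudogene status.

For dating, per-gene neighbor-joining trees (ape) over all species' Z and
W copies are classified by edge-separability on the unrooted topology:
if the Z tips form one side of a single edge the gene clusters *by
chromosome* -- recombination suppression predates the species splits and
the stratum is shared -- while per-species {Z, W} pairs indicate
lineage-specific suppression; anything else is unresolved.  NJ replaces
maximum-likelihood inference because the decided quantity is this
monophyly classification, which NJ resolves reliably at the divergence
scales involved (verified on additive and simulated matrices).

# The synthetic generator

The generator's defaults are the study conditions of a viper-like ZW
system and are not tuned per analysis:

| quantity | default | rationale |
|---|---|---|
| Z length | 77 Mb | assembled Z-linked extent |
| strata boundaries | 42, 56 Mb | three strata: S2 (0--42), S1 (42--56), S3 (56--77) |
| Z--W p-distance (S2, S1, S3) | 0.15, 0.25, 0.05 | oldest stratum most diverged |
| W retention (S2, S1, S3) | 0.15, 0.08, 0.75 | ~23 Mb identifiable W, densest where young |
| W fragment size | 50 kb | matches the fragmented W assembly scale |
| depth | 80x per sex | deep resequencing, equal effort |
| autosomal heterozygosity | 0.1% | both sexes |
| male-Z heterozygosity | 0.08% | slightly below autosomes |
| sequencing error | 1e-4/bp | drives error k-mers and spurious calls |
| k | 17 | k-mer spectrum length |
| species | 2, split at JC 0.02 | younger than every stratum (shared strata) |

Depth is simulated at 1-kb granularity as Poisson with mean
$c/2 \cdot \lambda$ ($c$ = copy number) -- all consumers use windowed
statistics, so per-base simulation would only cost time.  Sequence
evolution is Jukes--Cantor with exact expected-distance calibration
($p = \tfrac34(1 - e^{-4d/3})$ per branch), codon-aware so that no stop
codon ever arises by chance: the only ORF disruptions are the ones
deliberately inserted (single-base deletions or stop substitutions at
non-adjacent interior codons, Poisson in number with mean
`w_disruption_rate` x stratum divergence), which is what makes the
disruption ground truth *exactly* recoverable and `scan_orf()` testable
to the event.  Quality scores are 4x depth with Gaussian spread for
genuine variants and exponential (mean 15) for error calls, so the
standard quality filter separates the two populations cleanly; the
generator exposes `seq_error` but does not claim to reproduce any
particular residual female-Z heterozygosity, which in real data conflates
error and the recombining fraction.

What the generator does **not** emulate -- mapping bias, reference bias,
GC-dependent coverage, collapsed repeats, indel-rich alignment error --
bounds what green tests mean: they validate the estimators against their
own generative assumptions, not against the full messiness of real
libraries.

# Problem sizes and determinism

Validation runs at desk scale, chosen so the whole suite completes in
minutes: the full preset (5 x 20 Mb autosomes + 77 Mb Z, 1-Mb scaffold
tiling) for strata recovery across 20 seeds; 100 + 100 1-Mb scaffolds
for the ratio contract; 10 Mb of autosome for heterozygosity recovery;
40--60 gametolog genes of 0.9--1.8 kb.  Every generator draws from an
isolated RNG stream derived from the config seed, so a fixed
configuration yields byte-identical output bundles regardless of caller
RNG state, and the command-line pipeline (`zwstrata all`) writes
identical summaries on repeated runs.

# Known limitations

* Coverage classification assumes autosomes form a recognizable
  lower-ratio cluster; an assembly containing *only* sex-linked sequence
  cannot be normalized and will mislabel.
* The divergence track needs alignable W fragments: in very old strata
  the track thins, and segments may be ranked on few windows.
* The exact dynamic program is quadratic in window count; use binary
  segmentation (the default) beyond a few hundred windows.
* K2P saturates near p = 0.75; saturated pairs are flagged, not guessed.
* Whether the 80% alignment-coverage eligibility filter should also gate
  W detection is genuinely ambiguous; here it does not, because the W
  rule's male-coverage criterion is itself the signal.
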