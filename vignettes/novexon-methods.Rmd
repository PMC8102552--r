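---
title: "Models and methods behind novexon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind novexon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novexon)
```

## The problem

During male germ-cell differentiation, alternative splicing reshapes the
transcriptome most actively around the entry into meiosis, and the gain
of previously unannotated exons is a prominent mode of change.  A gained
exon can carry a premature termination codon (PTC).  In most cells such
transcripts are removed by nonsense-mediated decay (NMD), but meiotic
spermatocytes and round spermatids have an unusually inefficient
PTC-dependent NMD background, so PTC-bearing isoforms can accumulate
exactly there — with real regulatory consequences when the truncated
protein acts as a dominant negative (the motivating case is an
*Mga* splice variant whose novel 145-nt exon inserts five codons and a
stop, removing the C-terminal bHLHZ domain while sparing the T-box).

`novexon` implements the computational route through this biology as a
reusable, fully testable pipeline: score-track screening for novel
intron-internal exons, junction-count PSI estimation with Bayes-factor
differential-splicing calls across an ordered stage series, reading
frame/PTC consequence annotation with domain-loss and NMD prediction,
NMD-efficiency estimation from translation-inhibitor assays, and a
seeded synthetic-data generator that stands in for staged germ-cell
RNA-seq so every claim in the package is checkable against planted
ground truth.

## Coordinate conventions and core containers

All coordinates are 1-based and closed on both ends, matching the GFF3
standard and the Bioconductor containers the package builds on
(`Biostrings`, `GenomicRanges`, `rtracklayer`); GFF3 I/O therefore needs
no conversion, and only the BED writer converts (to BED's 0-based
half-open convention) at the boundary.  A `transcript_model` stores
exons in genomic order; transcription order is derived from the strand
where needed, so every operation is strand symmetric by construction (a
property test mirrors whole genes and checks invariance).  Genomes
permit `N` bases; any codon containing `N` translates to `X` and never
counts as a stop.

## Screening score tracks for hidden exons

The screen consumes a per-position splice acceptor/donor probability
track (as produced by sequence-based splice-site predictors; the package
never computes these scores).  For every annotated intron, every
acceptor/donor position pair with both scores at least `min_score`
(default 0.1), the acceptor upstream of the donor in transcription
order, and an implied exon length within `[min_len, max_len]` (defaults
25 and 500 nt; the motivating exon is 145 nt) becomes one candidate.
All qualifying pairs are reported — no greedy selection — because real
screens report every putative region and validate downstream.

A candidate's score band uses the *minimum* of its two scores: an exon
requires both a working acceptor and a working donor, so the weaker site
limits it.  At least 0.9 is called `constitutive`, 0.1 up to 0.9
`alternative` (an exon under substantial splicing regulation), below 0.1
`reject`.  Whether candidate exons should additionally be required to
show GT/AG dinucleotides or preserve reading frame is deliberately left
out of the screen: the consequence module decides frame questions, and
dinucleotide checking would couple the screen to the genome sequence in
a way the score track already summarizes.

## PSI and the Bayes factor

Percent spliced in is estimated from junction reads only (exon-body
reads are not modelled).  Because the inclusion isoform exposes more
junctions than the skipping isoform, raw counts are first
length-normalized: with inclusion counts over $J_i$ junctions and
skipping counts over $J_s$ junctions,

$$ i = \frac{\sum_j k_j}{J_i}, \qquad s = \frac{\sum_j m_j}{J_s},
   \qquad \hat\Psi = \frac{i}{i+s}. $$

Uncertainty is carried by a conjugate beta-binomial on effective counts
$k_\mathrm{eff} = \mathrm{round}(i)$, $s_\mathrm{eff} =
\mathrm{round}(s)$: the posterior is $\mathrm{Beta}(\alpha_0 +
k_\mathrm{eff},\ \beta_0 + s_\mathrm{eff})$ with a uniform prior by
default, and the 95% interval is the central posterior interval.  This
replaces a full MCMC over read assignments with a closed form that has
the same decision semantics and is exactly testable.  With no
informative reads the estimate is flagged undefined and the posterior
equals the prior.

Differential splicing between two samples is a Bayes factor comparing an
independent-$\Psi$ model against a shared-$\Psi$ model, both with
uniform priors.  The binomial coefficients cancel, leaving

$$ \mathrm{BF} = \frac{B(k_A{+}1,\ n_A{-}k_A{+}1)\,
                        B(k_B{+}1,\ n_B{-}k_B{+}1)}
                      {B(k_A{+}k_B{+}1,\ n_A{+}n_B{-}k_A{-}k_B{+}1)}, $$

evaluated in log space via `lbeta`.  An event is called differentially
spliced at $\mathrm{BF} \ge 10$, the conventional strong-evidence
threshold used throughout.  With no data on either side the ratio is
exactly 1 — no data cannot discriminate the models.  The closed form is
verified against direct numerical integration of both marginal
likelihoods over all effective counts up to $n = 30$ (relative error
below $10^{-6}$; observed $\sim 10^{-14}$).

Two statistical facts about these choices are worth stating plainly.
First, with $n$ informative reads $\hat\Psi$ is a binomial proportion
with standard error $\sqrt{\Psi(1-\Psi)/n}$; at $n = 200$ and mid-range
$\Psi$ that is $\approx 0.035$, so an absolute error of 0.05 is only
$\approx 1.4$ standard errors and is achieved in roughly 85% of
replicates — guaranteed sub-0.05 recovery in 95% of replicates needs
roughly 400 informative reads, which is why the convergence property
test samples at depth 800.  Second, the *null* call rate of a
consistent Bayes-factor test is not monotone in depth (it falls as
evidence accumulates for the shared model), so power monotonicity is
asserted in effect size at every depth and in depth for non-null
effects only.

## Event typing, direction, persistence

Alternative-splicing events are enumerated from transcript pairs of one
gene by exon-chain comparison: a skipped exon (SE) is an internal exon
bridged by a direct junction in the partner; a retained intron (RI) is
a split exon with identical outer boundaries; alternative 5′/3′ splice
sites are intron pairs sharing exactly one boundary with the flanking
exon otherwise identical, with donor/acceptor assignment decided by
strand; mutually exclusive exons (MXE) are non-overlapping internal
exons between shared flanks, each absent from the other transcript.
The implementation is checked for exact agreement against an
independent pattern-matching oracle on *all* two-transcript models with
up to four exons drawn from a fixed boundary grid, on both strands.

Direction is defined transition-wise: a significant positive
$\Delta\Psi$ (later stage minus earlier stage) across a stage
transition is a *gain* of the variable exon, a negative one a *loss*.
This deliberately does not consult the reference annotation — the same
event can be a gain in one comparison and a loss in another, and the
staged design makes the transition the natural unit.  Only SE events
receive a direction.

A change called at a transition *persists* when every later stage keeps
the post-transition side of the pre-transition baseline by at least a
maintenance margin (default 0.05 PSI, with an every-later-stage
quantifier).  The margin absorbs estimation noise at realistic depths;
an undefined PSI at any later stage counts against persistence because
absence of evidence is not maintenance.

## Coding consequence, PTC and NMD

To annotate a candidate exon's consequence, the exon is inserted
between its flanking exons, the canonical start codon is mapped into
the variant's spliced sequence, and translation is scanned for the
first stop (translation itself goes through `Biostrings`):

* first stop overlapping the novel exon in the incoming frame →
  `ptc_in_novel_exon`; the added-codon count includes every codon
  before the stop whose third base lies within the exon, so
  junction-spanning codons are attributed to the exon that completes
  them;
* exon length divisible by three and stop-free → `in_frame_addition`
  (the protein gains a contiguous peptide; prefix and suffix are
  unchanged when the insertion falls on a codon boundary);
* frame-breaking exon with its first novel stop downstream →
  `frameshift_ptc`;
* insertion into an untranslated-region intron → `no_change`.

A frameshifted frame that runs off the transcript without any stop is
reported as `frameshift_ptc` with an absent stop position; nonstop
decay is outside scope.  NMD sensitivity follows the classical 50-nt
rule: a PTC more than 50 nt upstream of the final exon–exon junction
(strict inequality at the boundary) is predicted NMD-sensitive, and a
stop in the last exon never is.  Domain loss is reported exactly when a
domain's last residue exceeds the truncated protein length; this
single rule also yields the correct empty result for in-frame and
unchanged proteins.  The whole classifier is validated against a
brute-force splice–translate–scan oracle on 1000 random genes with
random insertions (100% category agreement required, and observed).

NMD efficiency per stage is estimated from paired ±translation-
inhibitor measurements as $1 - \bar{u}/\bar{t}$, clipped to $[0, 1)$ —
a steady-state ratio, not a kinetic model, because inhibitor endpoint
comparisons are what such assays measure.  Stages below an efficiency
of 0.2 are flagged low-NMD.

## What the synthetic generator emulates — and what it does not

The generator is first-class, tested code; its defaults *are* the study
conditions.

* **Stage design.** Five ordered stages (undifferentiated and
  differentiated spermatogonia, preleptotene and pachytene
  spermatocytes, round spermatids), with the splicing change planted at
  the spermatogonia → preleptotene transition, where staged germ-cell
  data show alternative splicing to be most active.
* **Counts.** An informative read supports inclusion with probability
  $J_i a / (J_i a + J_s b)$, where $a$ and $b$ are isoform abundances —
  the exact sampling counterpart of the junction-count normalization,
  so the estimator is consistent for the planted PSI.  Totals are
  binomial at the configured depth (default 300 per event and stage;
  the Mga-like fixture uses 1000) and are spread multinomially over
  junctions.  No overdispersion is added by default.
* **NMD.** Acts multiplicatively on the PTC-bearing isoform's
  abundance, with stage efficiencies high (0.8) in spermatogonia and
  near zero (0.05) in spermatocytes/spermatids — the qualitative
  germ-cell profile.  Non-maintained PTC events collapse back to
  baseline on the *observed* (NMD-suppressed) scale; collapsing the
  production PSI instead would leave them visibly above baseline in
  low-NMD stages and silently bias persistence estimates.
* **Composition.** Event-type mixture (default 55% SE, 15% RI, 10%
  each A5SS/A3SS/MXE), a 2:1 gain:loss ratio among SE events, 75% of
  gains PTC-bearing, and 80% maintenance are planted *exactly* via
  largest-remainder allocation with a seeded shuffle.  Recovery error
  then measures the estimation chain rather than generator sampling
  noise, which is the property the recovery tests are about.
* **Inhibitor assay.** Replicates are paired aliquots — one cell
  preparation split into ± inhibitor — so the replicate-level 10%
  log-normal factor is shared within each pair and a 3% technical
  factor is independent per measurement.  This is how split-sample
  inhibitor experiments actually behave; with fully independent 10%
  noise on six measurements, an efficiency-zero stage could not be
  pinned down to ±0.07 with three replicates at all.
* **The Mga-like fixture.** A condensed three-exon analog of the locus:
  a 1500-nt CDS across the exons, a hidden 145-nt exon in the second
  intron carrying five sense codons then TAA in the incoming frame,
  acceptor/donor scores 0.695/0.761 at its boundaries (the alternative
  band) versus >0.9 at annotated boundaries, a T-box-like domain
  upstream and a bHLHZ-like domain downstream of the insertion point.
  Everything is deterministic given the seed.

What the generator does **not** emulate: overdispersed or
length-biased read sampling, multi-isoform genes beyond pairs, exon
body reads, partially coupled events within a gene, mapping artefacts,
or kinetic NMD dynamics.  Passing recovery tests therefore demonstrate
correctness of the estimation chain under the stated model, not
robustness to real-library noise.

## Numerical and degenerate-input choices

Bayes factors are computed in log space (`lbeta`) and are symmetric in
sample order; effective counts use base R `round`.  Zero-data events
give an undefined PSI with prior posterior, a Bayes factor of exactly
1, and can never be significant.  Transitions with zero significant
events are flagged and their type fractions left `NA` rather than
0/0.  The intron-internal candidate scan excludes annotated exon
boundaries by construction (only positions strictly inside introns are
paired).  Variant construction refuses exons that touch or overlap
annotated exon boundaries and refuses an exon filling its intron
completely (that is intron retention, a different event class).

## Problem sizes used by the checks

The packaged checks run at: all effective-count pairs up to $n = 30$
for the Bayes-factor integration oracle; 500 replicates per PSI value
at depth 200 (and depth 800 for the convergence property); a
$3\times3$ seeded power grid at 150 replicates per cell; all
two-transcript chains from an 8-boundary grid on both strands (16,256
pairs) for event typing; 1000 random genes for the ORF oracle; a
2000-event cohort for composition recovery; and 3 paired replicates
per stage for NMD-efficiency recovery.  These sizes were chosen so the
binomial/beta arithmetic above makes each tolerance meaningful.

## Known limitations

* PSI uses junction reads only; genes with strong exon-body coverage
  information are estimated less efficiently than a full read model
  would allow.
* The Bayes-factor model is shared-vs-independent beta-binomial; it is
  a stated, testable stand-in for MCMC-based isoform quantifiers, not
  a reimplementation of any of them.
* The 50-nt rule is the only NMD branch modelled; long-3′UTR NMD and
  UPF-pathway regulation are out of scope.
* The screen trusts the score track; it neither recomputes splice-site
  scores nor checks splice-site dinucleotides.
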