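---
title: "Estimating transcription error rates from rolling-circle consensus sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating transcription error rates from rolling-circle consensus sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txerror)
```

## The measurement problem

RNA polymerase misincorporates bases at rates orders of magnitude above the
DNA mutation rate, but far below the error rate of any sequencing platform:
a transcription error occurs once in roughly $10^4$–$10^5$ transcribed
bases, while Illumina-class miscalls arrive at $10^{-2}$–$10^{-3}$ per base.
Direct RNA-seq therefore cannot see transcription errors at all — every
apparent mismatch is overwhelmingly a library or sequencing artifact.

Rolling-circle (circularized-cDNA) library chemistry solves this by
physical redundancy. Short mRNA fragments (80–100 nt) are circularized and
reverse-transcribed by rolling circle, so a single 300-base read carries
three or more tandem copies of the *same* original molecule. An error made
by the polymerase during transcription is part of the molecule and appears
in **every** repeat copy; an error made later — during reverse
transcription, amplification or sequencing — appears in **one** copy only.
Requiring unanimous agreement among copies drives the artifact rate down to
roughly $(e/3)^k$ for per-copy miscall rate $e$ and $k$ independent copies:
with $e = 10^{-2}$ and $k = 3$ that is about $10^{-7}$ per base, below the
signal of interest.

`txerror` implements this measurement end to end: a synthetic-data
generator that emulates the library chemistry with known injected errors, a
tandem-repeat consensus caller, rate estimation with composition
normalization, RNA:DNA-hybrid sequence-context analysis, and the
small-sample statistics used to compare a factorial knockout design of the
three candidate fidelity factors GreA, GreB and DksA.

## The simulator and what it emulates

`generate_transcriptome()` draws a reference of independent random
transcripts with expression weights; `simulate_molecules()` transcribes
molecules from it, injecting substitutions from a 12-entry per-base rate
matrix, single-base insertions and deletions, and an optional multiplier on
substitution rates conditioned on the preceding (5') base — the handle used
to emulate sequence-context effects in the RNA:DNA hybrid.
`build_library()` then shears molecules to 80–100 nt fragments,
circularizes each at a uniformly random rotation (random-hexamer priming
gives the circle no preferred origin), rolls it into a concatemer, cuts to
300–450 bp and reads the first 300 bases. Sequencing and
reverse-transcription miscalls are modeled jointly at a single per-copy
rate, because both occur once per repeat copy and are indistinguishable to
the consensus logic. Every injected transcription error is recorded in a
truth ledger, so downstream estimates can be checked against ground truth.

Default study conditions (chosen once, as plausible desk-scale versions of
a bacterial experiment): 50 transcripts of 0.8–1.2 kb at GC 0.5 with
log-normal expression weights; substitution rates spanning
$2\times10^{-5}$–$2\times10^{-4}$ per base with transitions above
transversions; indel rates $2\times10^{-5}$; per-copy miscall rate 0.01.
These rates sit above the real biological scale so that desk-scale runs
yield hundreds of events per sample; the scale is a documented knob, not a
claim about *E. coli*.

Qualities deserve a note: correct calls draw Phred scores uniformly from
30–40, erroneous calls from 10–35. The overlap is deliberate — a
substantial fraction of artifacts *pass* the Q20 cutoff and must be removed
by repeat concordance, not by quality filtering, which is exactly the
situation the consensus logic exists for.

What the simulator does **not** model: rRNA depletion efficiency, PCR
duplicates, paired-end reads, adapter read-through, strand effects (all
simulation and calling is in sense orientation), and any correlation
structure along real transcripts. Passing tests therefore demonstrate the
pipeline's correctness and power under idealized library chemistry, not
performance on real sequencing runs.

## Consensus calling

`detect_period()` finds the repeat period $p \in [80, 100]$ maximizing mean
base identity between positions $i$ and $i+p$, rejecting reads below 0.85
identity. `build_consensus()` partitions the read into copies of length
$p$; per position, only copies with quality $\ge$ 20 count, and a position
is called only when at least `min_repeats = 3` qualifying copies exist and
**all** of them agree. Everything else is masked and excluded from both
the error counts and the denominator — masking is how every ambiguity in
this pipeline is resolved, because removing a base from numerator and
denominator together never biases a rate.

Three full copies is not a value the chemistry dictates; it follows from
the read geometry (300 bases over 80–100 nt fragments gives exactly three
full copies plus a partial) and makes a concordant artifact cubically
unlikely. Unanimity rather than quality-weighted majority is the direct
encoding of "present in every repeat" and is conservative; a majority mode
is available (`mode = "majority"`) but unanimity is the tested default.
Partial terminal copies contribute wherever they cover, which raises usable
depth without changing the concordance logic.

## Mapping rotated fragments

Because the circle has no origin, a consensus is a *rotation* of its
reference window: as a linear string it aligns as two blocks that are
adjacent in the reference, meeting at a junction. `map_and_call()` anchors
the consensus with an exact 31-mer seed slid over the doubled consensus
(the circular sequence has a single reference discontinuity, so every
junction-avoiding clean window is a true reference k-mer), then finds the
junction in $O(p)$ by a cumulative-sum scan over the two branch
alignments. A 17-mer rescue tier is consulted when no clean 31-mer window
hits the index; without it, fragments carrying a genuine error lose seed
windows more often than clean fragments and rates would be biased low by
about 10%.

Numerical resolution rules, all chosen to be conservative:

* **Ambiguous loci.** Fragments whose best placement ties across two or
  more reference loci are discarded and counted.
* **Junction ties.** When several junction placements score equally, a
  mismatch whose reference coordinate differs among the optima cannot be
  localized; it is masked out of events and denominator. This absorbs both
  the one-off tie at the fragment's first/last base and rarer longer-range
  coincidences.
* **Indels.** Accepted alignments must not contain three mismatches within
  any ten-base window — independent transcription errors essentially never
  cluster, so a dense run means an indel shift or a misplaced junction.
  Such fragments are retried with a single-base gap over every candidate
  junction; the gapped fit must beat the ungapped one by at least three
  matches, or the fragment is discarded and counted. Multi-base indels are
  not called.

The denominators produced alongside the events record the total called
bases $N$, per-identity counts $N_b$, sequenced dinucleotide counts, and
per-position coverage — everything the rate and context modules need. The
seed index, period detection and per-fragment alignment loops are
implemented in compiled code (Rcpp), with k-mers packed two bits per base,
so whole studies run in seconds.

## Rates and normalization

The overall rate is total errors over total bases sequenced, and each of
the twelve substitution types is reported on the same denominator, so the
per-type rates plus the indel rates sum to the overall rate *exactly* (an
integer-count identity the tests assert). For comparisons across types the
rates are additionally composition-normalized: $R^{norm}_{X \to Y} =
E_{X \to Y} / N_X$, the count divided by the number of sequenced bases of
the from-identity. A generic stratification operator computes the same
tables within transcript-level strata (expression classes, location
classes) from stratum-specific denominators.

## Hybrid context and the Monte Carlo background

During elongation roughly the nine most recently transcribed bases remain
hybridized to the template inside the polymerase. The context module
reconstructs these bases from the reference at positions $-1..-9$ upstream
of each error. Observed composition is compared between strain groups with
Fisher's exact test per (position, base) cell, Benjamini–Hochberg corrected
over the full $9 \times 4$ grid, and normalized against a Monte Carlo
background: positions of the sequenced transcriptome are drawn $10^6$ times
per focal base, weighted by realized sequencing depth, and the upstream
composition of the draws is tallied. Normalized proportions divide the
observed proportions by this background (mixed over the group's focal-base
spectrum) and rescale to sum to one per position, so a uniform background
leaves proportions unchanged. The full nine-base window is used throughout;
it is a superset of the shorter windows one might normalize over and loses
nothing. Truncated contexts near transcript starts contribute to the
positions they have.

Preceding-nucleotide rate analysis divides, per sample, the count of
$X \to Y$ errors whose $-1$ reference base is $b$ by the sequenced count of
$(b, X)$ dinucleotides, and compares gene-intact against gene-deleted
sample groups per (preceding base, type) cell with the exact Mann–Whitney
test, BH-corrected across the $4 \times 12$ grid.

## Statistics for the factorial design

The design crosses presence/absence of greA, greB and dksA ($2^3$
genotypes, two replicates each), so grouping by any one gene yields eight
values per side. At these sizes only exact tests are defensible:

* `mann_whitney_exact()` enumerates all $\binom{n_x+n_y}{n_x}$ label
  assignments (ties included) for $n_x + n_y \le 20$ and doubles the
  smaller tail; the normal approximation with tie correction covers larger
  inputs. The complete-separation two-sided p at $8$ vs $8$ is
  $2/12870 \approx 1.55\times10^{-4}$.
* `t_test_unpaired()` is Student's pooled test by default (Welch by flag),
  with explicit resolution of zero-variance degeneracies.
* `fisher_exact_2x2()` and `benjamini_hochberg()` delegate to the standard
  `stats` implementations, whose two-sided rule and step-up rule coincide
  with the definitions used here; the test suite verifies both against
  independent enumeration oracles.

BH families mirror the comparison they serve: the twelve types within a
grouping, the 36-cell composition grid, the 48-cell context-rate grid.
Significance for the end-to-end design property is taken at $p < 0.01$,
the scale of the grouped comparisons this package is designed to
reproduce; the grouped power assertions are made on the
composition-normalized G>A rate, which is the channel the injected
contrast actually occupies.

## Problem sizes and what the tests show

The test suite runs the full pipeline at desk scale: about $10^5$–$10^6$
called bases per sample, 13k-read artifact runs, five-seed recovery runs at
12k reads, context runs at 6k reads per sample across 16 samples, and
twenty seeded 16-sample power runs at 1.5k reads per sample (which yields
$\ge 10^5$ denominator bases per sample). At these sizes the suite
demonstrates: called artifact rates below $10^{-6}$ with no injected
errors; recovery of all twelve injected rates within binomial confidence
intervals (pooled over seeds); detection and correct sizing of a 5-fold
preceding-C multiplier on G>A confined to greA-deleted samples, with null
false-positive control; and a greA grouping significant in $\ge 90\%$ of
seeded runs with no greB or dksA grouping — the qualitative structure of a
single-factor fidelity effect.

## Known limitations

* Events at the first or last base of a fragment, and rarer junction-tie
  coincidences, are masked as coordinate-ambiguous; sensitivity for any
  single fragment is therefore slightly below one even without noise
  (unbiased, since the masked base leaves the denominator too).
* Indel calling near the fragment junction is weaker than substitution
  calling, and an insertion adjacent to an identical base is inherently
  position-ambiguous; indel rates are reported but less precise.
* The Monte Carlo background and the per-type context rates assume the
  reference base at $-1..-9$ equals the transcribed base — true here by
  construction, approximate on real data if the template itself varies.
* Mapping assumes unspliced, sense-orientation, unique-ish references;
  repetitive transcriptomes will discard more fragments as ambiguous.
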