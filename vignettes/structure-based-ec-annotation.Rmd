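---
title: "Structure-based enzyme annotation with structEC"
author: "structEC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based enzyme annotation with structEC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structEC)
```

## The problem

Predicted structural models (AlphaFold-class) now cover whole proteomes of
organisms with no experimental structures at all. For such organisms the
most informative route to functional hypotheses is often structural: align
each confident model against a library of experimentally determined chains
that carry curated annotations, and transfer what the well-aligned chains
agree on. `structEC` implements the annotation layer of that workflow for
enzymatic function: it decides whether a model looks like an enzyme, assigns
a consensus Enzyme Commission (EC) label at the most specific defensible
depth, and maps residue-level active-site/binding-site evidence from the
hits onto the model's own residues.

The package deliberately does **not** run structure prediction or
large-scale structural alignment. Models arrive as coordinate files with
per-residue pLDDT in the B-factor column plus a JSON scores file with pTM;
alignments arrive as US-align-style text output or as the package's
canonical hits TSV. A small sequential superposition/TM-score engine is
included for toy-scale verification and fixture generation only — it is not
a substitute for a production aligner, and it does not implement
non-sequential alignment.

## The three-step pipeline

1. **Quality gate.** A model proceeds if pTM > 0.7 **or** mean pLDDT > 70,
   both strict. The disjunction matters: mean pLDDT punishes long flexible
   termini on otherwise well-modeled domains, while pTM can under-rate
   small proteins; either score clearing its bar is evidence enough to
   attempt annotation. Values exactly at a threshold fail.
2. **Hit retention.** Each model's structural alignments are ranked by the
   *average TM-score* — the arithmetic mean of the TM-scores normalized by
   each structure's length — and hits below 0.7 are discarded (the boundary
   value is retained). Averaging the two normalizations penalizes
   partial-coverage matches in either direction; 0.7 sits well above the
   ~0.5 same-fold threshold, so retained hits share global topology with
   the model rather than a mere domain fragment.
3. **Annotation.** The EC labels of the retained hits' chains form a sample
   whose distribution \(P\) is compared against the library background
   \(Q\) through the relative entropy, and residue features are transferred
   through the alignment correspondences.

## The statistic

For the sample distribution \(P\) over EC labels and library background
\(Q\),

\[
D_{KL}(P \,\|\, Q) \;=\; \sum_{x} P(x)\, \log_2 \frac{P(x)}{Q(x)}
\quad \text{(bits)}.
\]

\(D_{KL}\) is the information gained by observing the hit-set labels over
what the library base rates already predict. A hit set that merely mirrors
the library (abundant folds, abundant ECs) gains nothing; a hit set
concentrated on a label rare in the library gains a lot. The per-label
summands — the *components* — are retained because the consensus rule acts
on them, and they always sum to the total.

**Smoothing.** \(D_{KL}\) is undefined where \(Q(x) = 0\). A sampled label
absent from the background receives the floor probability
\(1/(2\,N_Q)\), where \(N_Q\) is the total EC label-occurrence count behind
\(Q\), and \(Q\) is renormalized for that evaluation. The floor is half the
weight of a single pseudo-observation: small enough not to distort
components of observed labels, large enough that a novel label yields a
large-but-finite component instead of a crash.

**Significance.** The null asks: how large does \(D_{KL}\) get when a
sample of the same size is drawn i.i.d. from \(Q\) itself? The package
draws `nDraws` (default 10,000) multinomial samples from \(Q\), computes
the null statistic for each, and standardizes the observed value into a
z-score; the p-value is the one-sided upper tail of the standard normal at
z. This Monte-Carlo construction is the package's own choice of null; with
small samples the null \(D_{KL}\) distribution is discrete and
right-skewed, so the normal tail is an approximation. Its operating
behaviour is checked empirically in the test suite: with samples genuinely
drawn from \(Q\) (1000 simulated models against the standard synthetic
library), the type-I rate at \(\alpha = 0.05\) lands within 0.05 ± 0.02,
and degenerate rare-label samples give z far above 5. Everything is
deterministic given the seed, which is echoed into every report.

**Verdicts.** A model with no retained hits is `NO_HITS`; with hits but an
empty EC sample, or \(p > \alpha\) (default 0.05), `NOT_ENZYME`; otherwise
`ENZYME`. No multiple-testing correction is applied across a proteome by
default — each model is a separate hypothesis with its own evidence, and
downstream users can apply `p.adjust` to the proteome table if they prefer
family-wise control.

## The consensus rule

Given the components and the total, the rule looks for a label holding at
least `majorityFraction` (default 0.5) of the total relative entropy:

- **Depth 4 first**: if a unique full label's component reaches the
  majority, it is the annotation.
- Otherwise components aggregate by prefix at depth 3, then 2, then 1; the
  first depth with a unique qualifying prefix wins. Searching most-specific
  first matters: when a depth-3 prefix dominates, its depth-2 and depth-1
  parents dominate trivially too, and the informative answer is the
  deepest one.
- If two labels qualify at the same depth (an exact tie at the threshold),
  or no depth qualifies, the answer is `NO_CONSENSUS`. Ties abort
  immediately rather than retrying shallower depths: a tie between
  `1.1.1.1` and `1.1.1.2` *would* aggregate to a dominant `1.1.1.*`, but
  the rule's mandate is a *single* majority-holding label, and a tie means
  the sample does not discriminate — the conservative answer is preferred.
- Labels that are themselves prefixes (provisional `"-"` fields in source
  records, stored as depth-reduced labels) participate only at depths they
  reach.
- A sample "below background" everywhere (all aggregates non-positive,
  possible since components of over-represented-in-\(Q\) labels are
  negative) returns `NO_CONSENSUS` with a diagnostic attribute.

## Residue-level evidence

For every aligned residue pair of every retained hit, each ACT_SITE or
BINDING feature element on the target residue increments the model
residue's **feature count**; the **conservation count** additionally
requires the model and target residue types to be identical. The two
categories are tallied into one feature count but kept separate in
per-category columns, and BINDING ligand labels are tallied verbatim. A
target residue carrying both an ACT_SITE and a BINDING record contributes
two elements — counting is per feature element, not per featured residue.
Counts are additive over hits and invariant to hit order, and conservation
never exceeds the feature count; these invariants are enforced by validity
checks and property tests.

The contrast between the two counts is the point: a residue with a high
feature count but low conservation sits in a position where homologs bind
things with varied chemistry; a residue with both counts high is a
candidate catalytic or cofactor-binding residue. The package surfaces the
evidence (`topFeatureResidues`, the per-residue TSV, a B-factor-colored
PDB) and leaves interpretation — including possible pseudoenzyme calls when
a catalytic position is substituted — to the user.

## The library

`buildLibrary` assembles one record per chain from: a chain list, per-chain
coordinate files, a chain-to-UniProt mapping TSV, and UniProtKB flat files.
Only `DE EC=` clauses and `FT ACT_SITE`/`FT BINDING` blocks (with `/ligand`
qualifiers) are ingested. Because PDB chain numbering and UniProt numbering
routinely disagree, feature positions are reconciled by global sequence
alignment (BLOSUM62, gap open 10, extend 0.5) of the UniProt canonical
sequence against the chain sequence read from the coordinates; features
landing on gaps or residue-type mismatches are dropped and counted. The
mapping table is an explicit input rather than a live lookup so runs are
reproducible and offline; SIFTS-style mappings convert to it trivially.

The background \(Q\) is the frequency of each EC label over all label
occurrences in the library — a chain carrying two EC labels contributes two
counts, and chains without labels contribute nothing to numerator or
denominator. Counting occurrences rather than chains keeps \(Q\) a
distribution over the label space the statistic sums over.

## Synthetic fixtures: what they emulate and what they don't

The fixture generator (`makeLibraryFixture`, `makeHitSet`,
`makeProteomeFixture`) emits exactly the file formats the pipeline
consumes, deterministically per seed. Chains are ideal CA helices in seeded
random orientations (CA–CA 3.8 Å, self-avoiding by construction) with
uniform-random sequences; EC labels are dealt per an explicit profile
(default: 12 chains, label counts 6/3/1 over three labels, so the rarest
label has background probability 0.1); features are seeded positions with
residue types consistent with the sequences. Hit sets are identity
correspondences with seeded average TM-scores.

These fixtures exercise the statistics, parsers and bookkeeping, not
structural realism: there are no realistic folds, no alignment errors, no
correlated EC co-occurrence, no biased amino-acid composition. Passing
tests therefore demonstrate the correctness of the annotation layer's
computation, not the accuracy of annotation transfer on real proteomes —
that depends on the upstream aligner and the library coverage. The planted
proteome recovery test (enzyme / non-enzyme / no-hit classes recovered
exactly) shows the decision plumbing is faithful under conditions where
the truth is unambiguous by construction.

## Numerical choices and problem sizes

- Test-suite and acceptance-script simulations use a 12-chain library,
  samples of 20 labels, 10,000 null draws, and 1000 simulated models for
  calibration; the whole suite runs in well under a minute. These sizes
  were chosen so that Monte-Carlo error on the calibrated type-I rate
  (binomial SE ≈ 0.007 at 1000 models) is well inside the ±0.02 band.
- Threshold comparisons in the consensus rule use a 10⁻¹² tolerance so that
  exact ties computed in floating point are recognized as ties.
- The toy TM-score engine seeds from contiguous fragments (full, half,
  quarter length), iterates close-pair re-superposition, and finishes with
  an iteratively-reweighted Kabsch polish; on small perturbed helices it
  matches (or slightly exceeds) a restarted 6-dof Nelder–Mead oracle within
  0.01.
- Kabsch superposition rejects fewer than 3 pairs and collinear geometry;
  the reflection case is handled by the usual determinant correction.
- Degenerate nulls (single-label backgrounds give zero null SD) are
  reported as errors rather than silently yielding infinite z.

## Known limitations

- The Monte-Carlo z/p construction is a stand-in for whatever analytic test
  one might derive for multinomial relative entropy; its normal-tail
  p-values are approximate in the extreme tail, where only the magnitude
  ordering is meaningful.
- The built-in aligner searches sequential correspondences only; hits from
  non-sequential alignment modes are consumed as parsed text but cannot be
  regenerated internally.
- Only single-chain records are supported; complexes must be split
  upstream.
- Partial EC labels in source records are folded into their prefix bucket;
  if a source corpus meant `1.2.3.-` as a label distinct from its prefix,
  that distinction is lost.
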