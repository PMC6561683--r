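---
title: "Identifying and analysing KFERQ-like motifs with kferqscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and analysing KFERQ-like motifs with kferqscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kferqscan)
library(dplyr)
```

## The biological question

Chaperone-mediated autophagy (CMA) degrades individual cytosolic proteins
through the lysosome. Selectivity comes from the chaperone HSC70, which
recognises a five-residue targeting signal — the KFERQ-like motif, named
after the pentapeptide of ribonuclease A — and hands substrates to the
lysosomal receptor LAMP-2A. The related pathway of endosomal microautophagy
uses the same signal. Knowing which proteins carry such motifs, where they
sit, how exposed they are, and how they are conserved across species is the
starting point for any systematic study of CMA substrates. `kferqscan`
implements the motif grammar and the full set of downstream proteome-scale
analyses as composable, tibble-returning functions.

## The motif grammar

A KFERQ-like motif is a pentapeptide read in either direction: a *flanking*
residue at the first or the last position, plus four *variable* residues.
The variable region must contain

* one or two basic residues (K, R),
* one or two hydrophobic residues (F, I, L, V), and
* exactly one acidic residue,

so that basic + hydrophobic + acidic counts sum to exactly four. The flank
and the identity of the acidic residue define the motif class:

| class | flank | acidic position filled by |
|---|---|---|
| canonical | Q | D or E |
| phosphorylation-generated | Q | exactly one S, T or Y (no D/E) |
| acetylation-generated | K (acetylatable) | D or E |
| `n_canonical` / `n_phospho` | N (advanced mode) | as above |

Two choices deserve comment, because the verbal description of the rules
leaves them open and we fixed them once:

* **Single-substitution classes only.** A window that would need two
  modifications at once (a K flank *and* a phospho-acceptor standing in for
  the acidic residue) is not a motif. Likewise a window mixing D/E with
  S/T/Y satisfies neither the canonical rule (two acidics once
  phosphorylated) nor the phospho rule (a D/E where none is allowed).
* **Both orientations are counted.** A window such as `KKFEK`, with lysines
  at both ends, satisfies the acetyl rule read in either direction and is
  reported twice, once per orientation. `scan_motifs()` therefore counts
  oriented matches. Exhaustive enumeration over all $20^5$ pentapeptides
  yields 2,304 oriented canonical, 3,456 phospho-generated and 2,304
  acetyl-generated windows, matching the closed-form multinomial counts —
  the test suite performs this enumeration.

The `n_acetyl` class label exists in the result schema for completeness but
is unreachable: N substitutes only the flanking Q, and the acetyl class is
defined by a K flank.

Ambiguity codes (X, B, Z, J, U, O) belong to no residue set; windows
containing them simply never match, and the scanner warns once per protein.

## Per-protein summaries

`summarize_motifs()` ranks classes canonical > phosphorylation-generated >
acetylation-generated; a protein's *hierarchy group* is the highest-ranking
class it carries (else `none`). The *fractional content* divides a
protein's motif counts over those classes into percentages summing to 100 —
a protein with two canonical, one phospho- and one acetyl-generated motif is
50/25/25. An alternative hierarchy (e.g. the N-variant classes only) can be
passed when the asparagine variants are the object of study.

## Positional analyses

Motif position is the motif's central residue (an option uses the start
instead), normalised by protein length to a 0–1 scale. The N-terminal
depletion statistic compares motif *densities* (motifs per unit of relative
length) in the first 2.5% of the chain against the rest:
$100\,(1 - d_{head}/d_{tail})$. Densities, not raw counts, keep the
2.5%/97.5% split scale-fair. Note that because a motif centre cannot sit on
the first two residues, even uniformly placed motifs show a small positive
depletion on short proteins; the statistic is meaningful on proteomes, not
single short chains. Excluding the initiator methionine shifts both the
position and the length scale by one.

## Amino-acid preferences against a scrambled baseline

For composition analyses all motifs of a class are aligned on a downstream
flank (motifs that start with the flank are mirrored) so the variable
positions are −4…−1, with −1 adjacent to the flank. The null model is the
same proteome with every sequence independently shuffled
(`scramble_proteome()`), which exactly preserves per-protein composition.
`baseline_comparison()` draws 40 subsamples of 10% of the proteins from the
observed and the scrambled proteome, computes per-cell (amino acid ×
position) frequencies as percent of total counts, and reports the
observed/scrambled ratio with mean, sd, and a two-sided Welch *t*-test per
cell, Bonferroni-corrected with a default factor of 32 (the 8 canonical
motif residues × 4 positions). The subsampling unit is the protein. One
scrambled replicate is used per analysis; the scramble seed makes it
reproducible.

## Protein length model

`fit_length_model()` regresses $\log_2(\text{motif count})$ on protein
length by OLS over proteins with at least one motif of the class
(zero-count proteins have no defined response). Outliers are removed in a
*single* pass — fit, drop all points with Cook's distance > 1, refit once —
mirroring the one-shot removal of a few extremely long proteins that
otherwise dominate the fit. `tidy()`, `glance()` and `autoplot()` expose
the result; `glance()` reports the final $R^2$ and the removal count. A
degenerate design (all lengths equal, or an essentially exact fit, where
leverage diagnostics are meaningless) is handled explicitly.

## Solvent exposure

Exposure analyses consume per-residue relative solvent accessibility (RSA)
tracks produced by any predictor or structure pipeline, as a plain TSV. A
residue with RSA < 0.25 is buried (RSA = 0.25 is exposed — the boundary is
part of the contract and tested). Because the predictor this contract was
designed around caps input at 800 residues, `filter_max_length()` removes
longer proteins rather than truncating. `exposure_profile()` aligns ±30
residue windows on motif centres and reports percent exposed per offset;
offsets outside a protein shrink the denominator rather than being padded,
and every motif contributes its own window even when windows overlap. The
baseline is the exposed percentage over *all* residues of all proteins in
the track set (not only motif-bearing proteins — the more conservative and
stable choice).

## Cross-species conservation

CMA capability of a species is proxied by the presence of a LAMP-2A-type
C-terminal tail: 3–4 consecutive basic residues (K/R/H), 1–3 arbitrary
residues, then `GYEQF` at the absolute terminus, searched within the last
100 residues (`is_lamp2a_tail()`; the pattern is `[KRH]{3,4}.{1,3}GYEQF$`).

For a human protein with a single canonical motif and an aligned ortholog
family, the five alignment columns holding the human motif are located
through the gapped reference row (`motif_alignment_columns()`); each
species' residues at those columns are classified: **conserved** if they
form a motif of the same class (either orientation), **partial** if only a
motif of a different class, **absent** otherwise (any gap inside the
pentapeptide is absent), and **no ortholog** if the species is missing from
the family. N-variant motifs do not count towards *partial* by default (a
flag includes them). The score per species group is

$$\mathrm{score} = \frac{n_{conserved} + 0.5\,n_{partial} -
n_{noOrtholog}}{n_{species}} \in [-1, 1],$$

with absent-motif species contributing zero to the numerator but counting
in the denominator. A motif is *selectively conserved* when its score is
> 0 among CMA-able species and ≤ 0 among CMA-unable ones.

## Enrichment

`enrich_terms()` combines, per (protein group, annotation term):

* a one-sided Fisher exact p-value on the 2×2 table over the background
  (one-sided because the question is enrichment; a two-sided flag exists);
* a resampling z-score: the term's annotation set is reassigned to a
  uniformly random subset of the background of the same size, 40 times, and
  the observed overlap is standardised by the replicate mean and sd. A
  zero replicate sd leaves z undefined (`NA`), and such terms are excluded
  from ranking with a message, rather than reported as ±∞;
* the combined score $-\ln(p) \cdot z$ used for ranking (ties broken by
  smaller p, then term id).

No multiple-testing correction is applied across terms: ranking uses the
combined score, and the p-values are one ingredient of it — consumers
should treat the ranked list as descriptive, not as a family of calibrated
hypothesis tests.

Because the z denominator is estimated from 40 replicates, the null
distribution of z has slightly heavier tails than normal (t with ~39 df,
plus discreteness of the overlap count): the two-sided |z| > 1.96 rate under
the null is ≈ 0.065 rather than 0.05, while the one-sided rate relevant to
enrichment (z > 1.96) is well below 0.05. This is inherent to the
40-resample design, which we kept as the study condition.

`compartment_chisq()` tests a compartment's hierarchy-group composition
against whole-proteome proportions (goodness of fit). `ternary_binning()`
bins motif-bearing proteins on the (canonical%, phospho%, acetyl%) simplex
at 5% per dimension — lower-edge binning with the 100% apexes folded into
the top bin, so every protein lands in exactly one bin — and scores each
occupied bin for a term of interest against the background of all
motif-bearing proteins. `term_similarity()` exports pairwise Jaccard
indices of annotation sets for network visualisation.

## Synthetic data generators

Every analysis has a seeded generator so the whole pipeline is testable
without downloads:

* `simulate_proteome()` draws i.i.d. sequences from a background
  composition (uniform over the 20 residues by default; an empirical table
  can be supplied) and plants valid motif pentapeptides at non-overlapping
  positions (start distance ≥ 5). It re-scans its own output and asserts
  every planted motif is found; chance motifs are recorded separately, so
  tests assert supersets where appropriate.
* `simulate_ortholog_families()` plants one canonical motif per family and
  degrades it per species: retained intact (conserved, probability 0.9 for
  CMA-able and 0.1 for CMA-unable species by default), flank swapped Q→K
  (partial, a different class), or acidic residue replaced by glycine
  (absent). Orthologs are missing entirely with probability 0.1 (able) or
  0.5 (unable) — missing orthologs dominate among CMA-unable species, which
  is what drives their scores negative. Alignments are gapless by
  construction.
* `simulate_annotations()` plants enriched terms by oversampling a target
  group at a given relative risk.
* `simulate_rsa_tracks()` exposes residues at a baseline rate (default 0.4)
  and boosts configured offsets from motif centres (default ±2 at rate
  0.9), emulating elevated exposure at motif flanks.

What the generators deliberately do **not** emulate: real proteome length
and composition distributions, domain structure, phylogenetic correlation
between species, annotation term hierarchies, or realistic indel processes.
Passing tests therefore demonstrate correctness of the computations and
power/calibration under controlled conditions, not performance on real
proteomes.

## Numerical choices and problem sizes

Fisher p-values agree with an exact hypergeometric-tail oracle to < 1e-10
over every feasible 2×2 table with N ≤ 12. Conservation-score recovery is
checked over 200 simulated families against the analytic per-species
expectation; enrichment power over 100 seeded annotation tables of 15 terms
on a 300-protein proteome; null calibration over 400 replicates per test.
These sizes give Monte-Carlo standard errors comfortably below the asserted
tolerances while the entire suite remains quick to run.

## A worked example

```{r example}
proteome <- simulate_proteome(
  60, 150, 400,
  planted = tibble::tibble(motif_class = c("canonical",
                                           "phospho_generated"),
                           count = 1L, prob = c(0.8, 0.5)),
  seed = 42)
matches <- scan_motifs(proteome)
summaries <- summarize_motifs(proteome, matches)
group_percentages(summaries)
fit <- fit_length_model(summaries)
glance(fit)
```

## Known limitations

* Motif detection is purely sequence-based; no PTM evidence, structural
  burial of the full motif, or HSC70 affinity is modelled.
* The conservation scorer consumes pre-aligned families; ortholog retrieval
  and alignment are upstream of this package.
* The LAMP-2A tail rule is a proxy for CMA capability; unusual C-termini
  (e.g. the fish variants with a trailing residue after GYEQF) are
  deliberately not matched.
* The enrichment ranking is descriptive (no across-term error control).
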