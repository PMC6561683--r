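# kferqscan

Proteome-wide identification and analysis of KFERQ-like motifs, the
pentapeptide targeting signals of chaperone-mediated autophagy (CMA) and
endosomal microautophagy.

## What it does, and for whom

HSC70 selects substrates for lysosomal degradation by recognising a
five-residue KFERQ-like motif (named after the ribonuclease A pentapeptide).
For anyone studying CMA substrates — cell biologists triaging candidate
substrates, or computational groups profiling whole proteomes — this package
provides:

* **Motif detection** (`scan_motifs()`): every pentapeptide window is read
  in both orientations against the motif grammar. A motif is a flanking
  residue at the first or last position plus four variable residues with
  1–2 basic (K/R), 1–2 hydrophobic (F/I/L/V) and exactly one acidic
  residue. The flank defines the class: Q with D/E → **canonical**; Q with
  exactly one phospho-acceptor S/T/Y (no D/E) → **phosphorylation-
  generated**; an acetylatable K flank with D/E → **acetylation-
  generated**; N-for-Q variants are reported in advanced mode. A
  lysine-containing motif can optionally be flagged as
  ubiquitylation-sensitive.
* **Per-protein summaries** (`summarize_motifs()`): class counts, hierarchy
  grouping (canonical > phospho > acetyl > none), combination signatures,
  and fractional motif composition (a protein with 2 canonical, 1 phospho-
  and 1 acetyl-generated motif is 50/25/25).
* **Proteome statistics**: group and combination percentages, motifs-per-
  protein histograms, positional distributions with N-terminal depletion,
  OLS of log2(motif count) on protein length with single-pass Cook's
  distance (> 1) outlier removal, amino-acid position preferences against a
  scrambled-proteome baseline (40 × 10% subsampling, Welch t-tests,
  Bonferroni n = 32).
* **Solvent exposure** (`exposure_profile()`): ±30-residue percent-exposed
  profiles around motif centres from per-residue RSA tracks (RSA < 0.25 =
  buried; proteins > 800 residues filtered).
* **Cross-species conservation** (`score_conservation()`): LAMP-2A tail
  detection (`[KRH]{3,4}.{1,3}GYEQF$`), classification of ortholog
  pentapeptides at the human motif position, and the conservation score
  (n_conserved + 0.5 n_partial − n_noOrtholog) / n_species per CMA-able /
  CMA-unable species group, with selective-conservation calls.
* **Enrichment** (`enrich_terms()`): one-sided Fisher exact tests,
  40-replicate resampling z-scores, the combined score −ln(p)·z, top-term
  ranking, compartment chi-squared tests, 5% ternary binning of motif
  composition, and Jaccard term-similarity export.
* **Seeded synthetic-data generators** for proteomes, ortholog families,
  annotation tables and RSA tracks, with recorded ground truth.

All user-facing functions take a data frame first and return tibbles, so
analyses chain with the pipe; fitted objects have `tidy()`/`glance()`
methods and result types have `autoplot()`/`plot_*()` functions.

## A worked example

```r
library(kferqscan)

proteome <- simulate_proteome(
  60, 150, 400,
  planted = tibble::tibble(motif_class = c("canonical",
                                           "phospho_generated"),
                           count = 1L, prob = c(0.8, 0.5)),
  seed = 42)
matches <- scan_motifs(proteome)
matches
#> # A tibble: 128 × 8
#>   accession start   end center pentapeptide motif_class       orientation
#>   <chr>     <int> <int>  <int> <chr>        <fct>             <fct>
#> 1 SYN0001     148   152    150 QLKDV        canonical         Q_left
#> 2 SYN0002      90    94     92 KVYLQ        phospho_generated Q_right
#> 3 SYN0002      94    98     96 QLKVD        canonical         Q_left
#> # ℹ 125 more rows

summaries <- summarize_motifs(proteome, matches)
group_percentages(summaries)
#> # A tibble: 4 × 3
#>   hierarchy_group   n_proteins percent
#>   <fct>                  <int>   <dbl>
#> 1 canonical                 46   76.7
#> 2 phospho_generated          9   15
#> 3 acetyl_generated           2    3.33
#> 4 none                       3    5
```

128 oriented motif matches are found: the 48 + 30 planted canonical and
phospho motifs plus chance motifs from the uniform background (recorded
separately in `attr(proteome, "incidental")`). 76.7% of proteins fall in
the canonical hierarchy group — every protein with ≥ 1 canonical motif,
regardless of other classes — and 5% carry no motif at all. The length
model on this small uniform simulation explains essentially nothing
(`glance(fit_length_model(summaries))$r.squared` ≈ 0.012), as it should
when motif counts are planted independently of length. The conservation
score of a motif conserved in 4 of 10 species, partially conserved in 2 and
lacking orthologs in 1 is `conservation_score(4, 2, 1, 10)` = 0.4.

A command-line interface wrapping these functions (subcommands `scan`,
`stats`, `exposure`, `conserve`, `enrich`, `simulate`) ships as
`system.file("cli", "kferqscan.R", package = "kferqscan")`.

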