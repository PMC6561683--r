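#' Fisher exact enrichment of an annotation term in a protein group
#'
#' Builds the 2x2 table (annotated/unannotated x in-group/out-of-group) over
#' the background and computes the Fisher exact p-value, one-sided for
#' enrichment by default.
#'
#' @param group Character vector of protein ids (must lie in `background`;
#'   ids outside it are dropped with a message).
#' @param term_proteins Character vector of proteins annotated with the term.
#' @param background Character vector of all proteins in scope.
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @return A one-row tibble with `k` (annotated in group), `K` (group size),
#'   `n` (annotated in background), `N` (background size) and `p`.
#' @export
fisher_enrichment <- function(group, term_proteins, background,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(group) == 0L || length(background) == 0L) {
    abort("`group` and `background` must be non-empty.",
          class = "kferq_invalid_input")
  }
  background <- unique(background)
  outside <- setdiff(group, background)
  if (length(outside)) {
    inform(paste0(length(outside),
                  " group protein(s) outside the background were dropped."))
  }
  group <- intersect(unique(group), background)
  term_proteins <- intersect(unique(term_proteins), background)
  k <- length(intersect(group, term_proteins))
  K <- length(group)
  n <- length(term_proteins)
  N <- length(background)
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2L)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  tibble(k = k, K = K, n = n, N = N, p = p)
}

#' Resampling z-score for a term's overlap with a group
#'
#' Repeatedly (default 40 times) reassigns the term's annotation set to a
#' uniformly random protein subset of the same size drawn from the
#' background, recomputes the overlap with the group, and standardises the
#' observed overlap: `z = (k_obs - mean(k_rep)) / sd(k_rep)`. When the
#' replicate overlaps have zero spread the z-score is undefined (`NA`).
#'
#' @inheritParams fisher_enrichment
#' @param n_reps Number of resampling replicates (>= 2).
#' @param seed Optional seed; results are reproducible given it.
#' @return A one-row tibble with `k`, `rep_mean`, `rep_sd` and `z`.
#' @export
resampled_z <- function(group, term_proteins, background, n_reps = 40,
                        seed = NULL) {
  if (n_reps < 2L) {
    abort("`n_reps` must be at least 2.", class = "kferq_invalid_input")
  }
  background <- unique(background)
  group <- intersect(unique(group), background)
  term_proteins <- intersect(unique(term_proteins), background)
  in_group <- background %in% group
  n_term <- length(term_proteins)
  k_obs <- length(intersect(group, term_proteins))
  run <- function() {
    vapply(seq_len(n_reps), function(i) {
      sum(in_group[sample.int(length(background), n_term)])
    }, numeric(1))
  }
  k_rep <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  m <- mean(k_rep); s <- stats::sd(k_rep)
  tibble(k = k_obs, rep_mean = m, rep_sd = s,
         z = if (s == 0) NA_real_ else (k_obs - m) / s)
}

#' Combined enrichment score
#'
#' `-ln(p) * z`: the term-ranking statistic combining the Fisher exact
#' p-value with the resampling z-score. Zero when p = 1; negative for
#' depleted terms (z < 0); `NA` when z is undefined.
#'
#' @param p Fisher p-values in (0, 1].
#' @param z Resampling z-scores.
#' @return Numeric vector of combined scores.
#' @export
#' @examples
#' combined_score(exp(-2), 3)  # 6
combined_score <- function(p, z) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    abort("`p` must lie in (0, 1].", class = "kferq_invalid_input")
  }
  -log(p) * z
}

#' Term enrichment of protein groups
#'
#' Runs [fisher_enrichment()] and [resampled_z()] for every (group, term)
#' pair and attaches the combined score. Annotation proteins that do not
#' resolve against the background are dropped (with a message).
#'
#' @param groups Named list of protein-id vectors, or a tibble with
#'   `accession` and `group` columns.
#' @param annotations Tibble with `term` and `accession` columns (see
#'   [read_annotations()]).
#' @param background Character vector of all proteins in scope.
#' @param n_reps Resampling replicates per term.
#' @param seed Optional seed for the resampling.
#' @inheritParams fisher_enrichment
#' @return A tibble with `group`, `term`, `k`, `K`, `n`, `N`, `p`,
#'   `rep_mean`, `rep_sd`, `z` and `combined`.
#' @export
enrich_terms <- function(groups, annotations, background, n_reps = 40,
                         seed = NULL, alternative = "greater") {
  if (is.data.frame(groups)) {
    groups <- split(groups$accession, groups$group)
  }
  background <- unique(background)
  unresolved <- setdiff(unique(annotations$accession), background)
  if (length(unresolved)) {
    inform(paste0(length(unresolved), " annotated protein id(s) not in the ",
                  "background were dropped."))
    annotations <- annotations |> filter(.data$accession %in% background)
  }
  term_sets <- split(annotations$accession, annotations$term)
  n_undef <- 0L
  run <- function() {
    res <- purrr::map_dfr(names(groups), function(g) {
      purrr::map_dfr(names(term_sets), function(tm) {
        fe <- fisher_enrichment(groups[[g]], term_sets[[tm]], background,
                                alternative = alternative)
        rz <- resampled_z(groups[[g]], term_sets[[tm]], background,
                          n_reps = n_reps)
        tibble(group = g, term = tm, k = fe$k, K = fe$K, n = fe$n, N = fe$N,
               p = fe$p, rep_mean = rz$rep_mean, rep_sd = rz$rep_sd,
               z = rz$z, combined = combined_score(fe$p, rz$z))
      })
    })
    res
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (any(is.na(out$z))) {
    inform(paste0(sum(is.na(out$z)), " term(s) had zero resampling spread; ",
                  "their z and combined scores are undefined."))
  }
  out
}

#' Top enriched terms per group
#'
#' Ranks terms by combined score (descending), breaking ties by smaller p
#' then term id, and keeps the top `per_group` per group. Terms with an
#' undefined combined score are excluded. A `pct_annotated` label
#' (100 * k / n, the share of the term's proteins falling in the group) is
#' attached.
#'
#' @param results Output of [enrich_terms()].
#' @param per_group Terms kept per group.
#' @return The ranked subset with an added `pct_annotated` column.
#' @export
top_terms <- function(results, per_group = 5) {
  results |>
    filter(!is.na(.data$combined)) |>
    arrange(.data$group, desc(.data$combined), .data$p, .data$term) |>
    group_by(.data$group) |>
    slice_head(n = per_group) |>
    ungroup() |>
    mutate(pct_annotated = 100 * .data$k / .data$n)
}

#' Chi-squared test of motif-class composition per compartment
#'
#' For each compartment, tests whether its distribution of proteins over the
#' hierarchy groups differs from the whole-proteome proportions
#' (goodness-of-fit chi-squared).
#'
#' @param summaries Result of [summarize_motifs()] for the whole proteome.
#' @param compartments Tibble with `accession` and `compartment`.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with `compartment`, `statistic`, `df`, `p` and
#'   `significant`.
#' @export
compartment_chisq <- function(summaries, compartments, alpha = 0.05) {
  props <- summaries |>
    count(.data$hierarchy_group, .drop = FALSE) |>
    mutate(prop = .data$n / sum(.data$n))
  keep <- props$prop > 0
  if (!all(keep)) {
    props <- props[keep, ]
    props$prop <- props$prop / sum(props$prop)
  }
  grp_of <- summaries$hierarchy_group[match(compartments$accession,
                                            summaries$accession)]
  if (anyNA(grp_of)) {
    abort("Some compartment proteins are absent from `summaries`.",
          class = "kferq_data_error")
  }
  purrr::map_dfr(split(grp_of, compartments$compartment), function(g) {
    cnt <- table(factor(g, levels = props$hierarchy_group))
    expected <- sum(cnt) * props$prop
    if (any(expected == 0)) {
      abort("Zero expected count in a motif-class cell; merge categories.",
            class = "kferq_data_error")
    }
    ht <- suppressWarnings(stats::chisq.test(as.numeric(cnt),
                                             p = props$prop))
    tibble(statistic = unname(ht$statistic),
           df = unname(ht$parameter), p = ht$p.value)
  }, .id = "compartment") |>
    mutate(significant = .data$p < alpha)
}

#' Bin proteins on the motif-composition simplex and score a term per bin
#'
#' Each motif-bearing protein has a fractional composition
#' (canonical%, phospho%, acetyl%) summing to 100. Proteins are assigned to
#' ternary bins of `bin_size` percent per dimension (lower-edge binning, the
#' 100% apexes folded into the top bin), and the proteins of each occupied
#' bin are scored for enrichment of `term_proteins` (Fisher p, resampling z,
#' combined score) against the background of all motif-bearing proteins.
#'
#' @param summaries Result of [summarize_motifs()].
#' @param term_proteins Proteins annotated with the term of interest.
#' @param bin_size Bin width in percent (default 5).
#' @param n_reps,seed Passed to [resampled_z()].
#' @return A tibble with the bin lower edges (`bin_canonical`,
#'   `bin_phospho`, `bin_acetyl`), `n_proteins`, `k`, `p`, `z` and
#'   `combined`.
#' @export
ternary_binning <- function(summaries, term_proteins, bin_size = 5,
                            n_reps = 40, seed = NULL) {
  stopifnot(bin_size > 0, 100 %% bin_size == 0)
  withmotif <- summaries |> filter(.data$hierarchy_group != "none")
  if (nrow(withmotif) == 0L) {
    abort("No motif-bearing proteins.", class = "kferq_data_error")
  }
  edge <- function(x) pmin(floor(x / bin_size), 100 / bin_size - 1) * bin_size
  withmotif <- withmotif |>
    mutate(bin_canonical = edge(.data$frac_canonical),
           bin_phospho = edge(.data$frac_phospho_generated),
           bin_acetyl = edge(.data$frac_acetyl_generated))
  background <- withmotif$accession
  run <- function() {
    withmotif |>
      group_by(.data$bin_canonical, .data$bin_phospho, .data$bin_acetyl) |>
      group_modify(function(d, key) {
        fe <- fisher_enrichment(d$accession, term_proteins, background)
        rz <- resampled_z(d$accession, term_proteins, background,
                          n_reps = n_reps)
        tibble(n_proteins = nrow(d), k = fe$k, p = fe$p, z = rz$z,
               combined = combined_score(fe$p, rz$z))
      }) |>
      ungroup()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pairwise Jaccard similarity of annotation terms
#'
#' Jaccard index (intersection over union) of the annotated protein sets of
#' every term pair, for export to network-visualisation tools.
#'
#' @param annotations Tibble with `term` and `accession`.
#' @param min_jaccard Keep pairs with similarity >= this threshold.
#' @return A tibble with `term_a`, `term_b` and `jaccard`
#'   (`term_a < term_b`).
#' @export
term_similarity <- function(annotations, min_jaccard = 0) {
  sets <- lapply(split(annotations$accession, annotations$term), unique)
  terms <- sort(names(sets))
  if (length(terms) < 2L) {
    return(tibble(term_a = character(), term_b = character(),
                  jaccard = numeric()))
  }
  pairs <- utils::combn(terms, 2L)
  jac <- vapply(seq_len(ncol(pairs)), function(i) {
    a <- sets[[pairs[1L, i]]]; b <- sets[[pairs[2L, i]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  tibble(term_a = pairs[1L, ], term_b = pairs[2L, ], jaccard = jac) |>
    filter(.data$jaccard >= min_jaccard)
}
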