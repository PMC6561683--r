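#' Percentage of proteins per hierarchy group
#'
#' @param summaries Result of [summarize_motifs()].
#' @return A tibble with `hierarchy_group`, `n_proteins` and `percent`
#'   (of all proteins; the percentages sum to 100).
#' @export
group_percentages <- function(summaries) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    abort("`summaries` must be a non-empty summary tibble.",
          class = "kferq_invalid_input")
  }
  summaries |>
    count(.data$hierarchy_group, name = "n_proteins", .drop = FALSE) |>
    mutate(percent = 100 * .data$n_proteins / sum(.data$n_proteins))
}

#' Percentage of proteins per motif-class combination
#'
#' Splits the hierarchy groups into every possible combination of motif
#' classes actually co-occurring in a protein (the `2^k` subsets of the
#' ranked classes, including `none`).
#'
#' @inheritParams group_percentages
#' @param hierarchy Ranked classes defining the signature space.
#' @return A tibble with `combination`, `n_proteins` and `percent` of all
#'   proteins; includes zero-count combinations so percentages sum to 100.
#' @export
combination_breakdown <- function(summaries, hierarchy = MAIN_CLASSES) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    abort("`summaries` must be a non-empty summary tibble.",
          class = "kferq_invalid_input")
  }
  lev <- combination_levels(hierarchy)
  summaries |>
    mutate(combination = factor(.data$combination, levels = lev)) |>
    count(.data$combination, name = "n_proteins", .drop = FALSE) |>
    mutate(percent = 100 * .data$n_proteins / sum(.data$n_proteins))
}

#' Histogram of motif counts per protein
#'
#' For each motif-bearing protein, counts the motifs of its group-defining
#' class (the class that placed it in its hierarchy group), and tabulates how
#' many proteins carry 1, 2, ... such motifs.
#'
#' @inheritParams group_percentages
#' @return A tibble with `hierarchy_group`, `n_motifs` and `n_proteins`.
#' @export
motif_count_histogram <- function(summaries) {
  grp <- as.character(summaries$hierarchy_group)
  keep <- grp != "none"
  if (!any(keep)) {
    return(tibble(
      hierarchy_group = factor(character(),
                               levels = levels(summaries$hierarchy_group)),
      n_motifs = integer(), n_proteins = integer()))
  }
  class_cols <- intersect(names(summaries), MOTIF_CLASSES)
  cnt <- as.matrix(summaries[class_cols])
  n_def <- cnt[cbind(which(keep), match(grp[keep], class_cols))]
  tibble(hierarchy_group = summaries$hierarchy_group[keep],
         n_motifs = as.integer(n_def)) |>
    count(.data$hierarchy_group, .data$n_motifs, name = "n_proteins")
}

#' Regress motif count on protein length
#'
#' Ordinary least squares of log2(motif count) on protein length, restricted
#' to proteins carrying at least one motif of `motif_class` (log2 of zero is
#' undefined). After an initial fit, all points with Cook's distance > 1 are
#' removed in a single pass and the model is refit once.
#'
#' @inheritParams group_percentages
#' @param motif_class Class whose counts are modelled (default canonical).
#' @param cooks_threshold Cook's distance above which a point is an outlier.
#' @return An object of class `kferq_length_fit`; see [tidy()], [glance()]
#'   and [ggplot2::autoplot()] methods.
#' @export
fit_length_model <- function(summaries, motif_class = "canonical",
                             cooks_threshold = 1) {
  motif_class <- match.arg(motif_class, MOTIF_CLASSES)
  if (is.null(summaries[[motif_class]])) {
    abort(paste0("`summaries` has no count column for ", motif_class, "."),
          class = "kferq_invalid_input")
  }
  dat <- summaries |>
    filter(.data[[motif_class]] >= 1L) |>
    transmute(accession = .data$accession, length = .data$length,
              log2_count = log2(.data[[motif_class]]))
  if (nrow(dat) < 3L) {
    abort("Need at least 3 proteins with >= 1 motif of the class.",
          class = "kferq_data_error")
  }
  if (stats::sd(dat$length) == 0) {
    abort("All proteins have the same length; model is degenerate.",
          class = "kferq_data_error")
  }
  fit0 <- stats::lm(log2_count ~ length, data = dat)
  cooks <- stats::cooks.distance(fit0)
  # an (essentially) exact fit has no meaningful leverage diagnostics
  if (stats::sigma(fit0) < 1e-8) cooks[] <- 0
  out_idx <- which(is.finite(cooks) & cooks > cooks_threshold)
  removed <- dat$accession[out_idx]
  dat_final <- if (length(out_idx)) dat[-out_idx, ] else dat
  if (nrow(dat_final) < 3L || stats::sd(dat_final$length) == 0) {
    abort("Too few points remain after outlier removal.",
          class = "kferq_data_error")
  }
  fit <- stats::lm(log2_count ~ length, data = dat_final)
  structure(
    list(fit = fit, data = as_tibble(dat_final),
         motif_class = motif_class,
         n_removed = length(out_idx), removed_accessions = removed,
         cooks_threshold = cooks_threshold),
    class = "kferq_length_fit")
}

#' @export
print.kferq_length_fit <- function(x, ...) {
  s <- summary(x$fit)
  cat("Length model: log2(n ", x$motif_class, ") ~ protein length\n", sep = "")
  cat(sprintf("  n = %d proteins (%d outlier(s) removed, Cook's D > %g)\n",
              nrow(x$data), x$n_removed, x$cooks_threshold))
  cat(sprintf("  slope = %.3g, intercept = %.3g, R^2 = %.3f\n",
              stats::coef(x$fit)[["length"]],
              stats::coef(x$fit)[["(Intercept)"]], s$r.squared))
  invisible(x)
}

#' Relative motif positions along the protein
#'
#' @param matches Result of [scan_motifs()].
#' @param proteins Protein tibble providing `length` per accession.
#' @param position Which residue marks the motif: its central residue
#'   (default) or its start.
#' @param exclude_initiator_met Drop the initiator methionine from the length
#'   scale (position and length both shifted by one).
#' @return A numeric vector in (0, 1], one entry per match.
#' @export
relative_motif_positions <- function(matches, proteins,
                                     position = c("center", "start"),
                                     exclude_initiator_met = FALSE) {
  position <- match.arg(position)
  lens <- proteins$length[match(matches$accession, proteins$accession)]
  if (anyNA(lens)) {
    abort("Some matches reference proteins absent from `proteins`.",
          class = "kferq_data_error")
  }
  pos <- if (position == "center") matches$center else matches$start
  if (exclude_initiator_met) {
    (pos - 1) / (lens - 1)
  } else {
    pos / lens
  }
}

#' Positional distribution of motifs along the normalised protein length
#'
#' Motif positions are normalised to a 0 (N-terminus) to 1 (C-terminus)
#' scale, using the central residue of the motif by default, and binned.
#'
#' @inheritParams relative_motif_positions
#' @param bin_size Width of the position bins (0.02 for the coarse view,
#'   0.001 for the N-terminal zoom).
#' @return A tibble of class `kferq_position_histogram` with `bin_start`,
#'   `bin_end` and `count`; bin counts sum to the number of matches.
#' @export
positional_distribution <- function(matches, proteins, bin_size = 0.02,
                                    position = c("center", "start"),
                                    exclude_initiator_met = FALSE) {
  stopifnot(bin_size > 0, bin_size <= 1)
  rel <- relative_motif_positions(matches, proteins, position,
                                  exclude_initiator_met)
  breaks <- seq(0, 1, by = bin_size)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- findInterval(rel, breaks, rightmost.closed = TRUE, left.open = FALSE)
  cnt <- tabulate(bin, nbins = length(breaks) - 1L)
  out <- tibble(bin_start = breaks[-length(breaks)],
                bin_end = breaks[-1],
                count = cnt)
  class(out) <- c("kferq_position_histogram", class(out))
  attr(out, "bin_size") <- bin_size
  attr(out, "exclude_initiator_met") <- exclude_initiator_met
  out
}

#' N-terminal motif depletion
#'
#' Compares motif density (motifs per unit of relative protein length) in the
#' first `head_fraction` of the protein against the remainder, and reports
#' how much lower the head density is, in percent:
#' `100 * (1 - head_density / tail_density)`.
#'
#' @inheritParams relative_motif_positions
#' @param head_fraction N-terminal fraction of the length scale (default the
#'   first 2.5%).
#' @return A one-row tibble with `head_fraction`, `head_density`,
#'   `tail_density` and `pct_depletion` (positive when the N-terminus is
#'   depleted; `NA` with a warning when the tail holds no motifs).
#' @export
terminal_depletion <- function(matches, proteins, head_fraction = 0.025,
                               position = c("center", "start"),
                               exclude_initiator_met = FALSE) {
  if (nrow(matches) == 0L) {
    abort("No matches supplied.", class = "kferq_data_error")
  }
  rel <- relative_motif_positions(matches, proteins, position,
                                  exclude_initiator_met)
  head_n <- sum(rel < head_fraction)
  tail_n <- sum(rel >= head_fraction)
  head_density <- head_n / head_fraction
  tail_density <- tail_n / (1 - head_fraction)
  pct <- if (tail_density == 0) {
    warn("Tail density is zero; depletion undefined.")
    NA_real_
  } else {
    100 * (1 - head_density / tail_density)
  }
  tibble(head_fraction = head_fraction, head_density = head_density,
         tail_density = tail_density, pct_depletion = pct)
}

## Variable residues of each match, mirrored so the flank sits downstream:
## returns an n x 4 matrix whose columns are positions -4..-1 relative to the
## flanking residue (-1 closest).
variable_residue_matrix <- function(matches) {
  chars <- pentapeptide_matrix(matches$pentapeptide)
  ql <- as.character(matches$orientation) == "Q_left"
  out <- chars[, 1:4, drop = FALSE]
  # motifs starting with the flank are mirrored onto the downstream-Q frame
  out[ql, ] <- chars[ql, 5:2, drop = FALSE]
  colnames(out) <- c("-4", "-3", "-2", "-1")
  out
}

#' Amino-acid frequencies at the four variable motif positions
#'
#' All motifs of one class are aligned on a downstream flanking residue
#' (motifs with the flank first are mirrored), and occurrences of each amino
#' acid are counted at positions -4 to -1 relative to the flank (-1 closest).
#' Counts per amino acid are normalised as a percentage of that amino acid's
#' total across the four positions.
#'
#' @param matches Result of [scan_motifs()], typically filtered to one class.
#' @param motif_class Class to tabulate.
#' @return A tibble with `amino_acid`, `position` (-4..-1), `count` and
#'   `percent` (each amino-acid's percentages sum to 100 when it occurs).
#' @export
aa_position_frequencies <- function(matches, motif_class = "canonical") {
  motif_class <- match.arg(motif_class, MOTIF_CLASSES)
  m <- matches |> filter(.data$motif_class == !!motif_class)
  alphabet <- if (motif_class %in% c("phospho_generated", "n_phospho")) {
    c(RES_BASIC, RES_HYDROPHOBIC, RES_PHOSPHO)
  } else {
    c(RES_BASIC, RES_HYDROPHOBIC, RES_ACIDIC)
  }
  alphabet <- sort(alphabet)
  grid <- tidyr::expand_grid(amino_acid = alphabet, position = -4:-1)
  if (nrow(m) == 0L) {
    return(grid |> mutate(count = 0L, percent = NA_real_))
  }
  vm <- variable_residue_matrix(m)
  long <- tibble(amino_acid = as.vector(vm),
                 position = rep(-4:-1, each = nrow(vm)))
  grid |>
    left_join(count(long, .data$amino_acid, .data$position, name = "count"),
              by = c("amino_acid", "position")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    group_by(.data$amino_acid) |>
    mutate(percent = if (sum(.data$count) > 0)
      100 * .data$count / sum(.data$count) else NA_real_) |>
    ungroup()
}

#' Residue-property frequencies at the four variable motif positions
#'
#' As [aa_position_frequencies()], but residues are grouped by biochemical
#' property (basic, hydrophobic, acidic). For the phosphorylation classes the
#' phospho-acceptors S/T/Y count as acidic, since they act as the acidic
#' residue once phosphorylated.
#'
#' @inheritParams aa_position_frequencies
#' @return A tibble with `property`, `position`, `count` and `percent`.
#' @export
property_position_frequencies <- function(matches,
                                          motif_class = "canonical") {
  motif_class <- match.arg(motif_class, MOTIF_CLASSES)
  m <- matches |> filter(.data$motif_class == !!motif_class)
  acidic_set <- if (motif_class %in% c("phospho_generated", "n_phospho")) {
    RES_PHOSPHO
  } else {
    RES_ACIDIC
  }
  grid <- tidyr::expand_grid(
    property = c("basic", "hydrophobic", "acidic"), position = -4:-1)
  if (nrow(m) == 0L) return(grid |> mutate(count = 0L, percent = NA_real_))
  vm <- variable_residue_matrix(m)
  prop <- matrix(NA_character_, nrow(vm), 4L)
  prop[vm %in% RES_BASIC] <- "basic"
  prop[vm %in% RES_HYDROPHOBIC] <- "hydrophobic"
  prop[vm %in% acidic_set] <- "acidic"
  long <- tibble(property = as.vector(prop),
                 position = rep(-4:-1, each = nrow(vm))) |>
    filter(!is.na(.data$property))
  grid |>
    left_join(count(long, .data$property, .data$position, name = "count"),
              by = c("property", "position")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    group_by(.data$property) |>
    mutate(percent = if (sum(.data$count) > 0)
      100 * .data$count / sum(.data$count) else NA_real_) |>
    ungroup()
}

#' Scramble every protein sequence
#'
#' Independently permutes the residues of each sequence with a uniform
#' shuffle, exactly preserving each protein's amino-acid composition. Used to
#' build the null proteome for [baseline_comparison()].
#'
#' @param proteins Protein tibble (or named character vector).
#' @param seed Optional integer seed (scrambling is deterministic given it).
#' @return The protein tibble with scrambled sequences.
#' @export
scramble_proteome <- function(proteins, seed = NULL) {
  proteins <- as_protein_tbl(proteins)
  do_scramble <- function() {
    proteins$sequence <- vapply(
      strsplit(proteins$sequence, "", fixed = TRUE),
      function(x) paste(sample(x), collapse = ""), character(1))
    proteins
  }
  if (is.null(seed)) do_scramble() else withr::with_seed(seed, do_scramble())
}

## Percent-of-total frequency vector over (amino acid x position) cells for
## the motifs of `motif_class` found in the proteins listed in `accessions`.
cell_frequencies <- function(matches, accessions, motif_class, alphabet) {
  m <- matches |>
    filter(.data$motif_class == !!motif_class,
           .data$accession %in% accessions)
  cells <- as.vector(outer(alphabet, -4:-1, paste, sep = "@"))
  if (nrow(m) == 0L) {
    return(stats::setNames(rep(NA_real_, length(cells)), cells))
  }
  vm <- variable_residue_matrix(m)
  key <- paste(as.vector(vm), rep(-4:-1, each = nrow(vm)), sep = "@")
  cnt <- table(factor(key, levels = cells))
  stats::setNames(100 * as.numeric(cnt) / sum(cnt), cells)
}

#' Observed vs scrambled-proteome amino-acid position preferences
#'
#' Compares the per-cell (amino acid x variable position) motif frequencies
#' of the observed proteome with those of a scrambled version of the same
#' proteome. Frequencies are expressed as percent of total counts. Means and
#' standard deviations of the observed/scrambled ratio come from repeatedly
#' (default 40 times) sampling 10% of the proteins of each proteome; per-cell
#' two-sided Welch t-tests compare the observed and scrambled frequencies
#' across the subsamples, with a Bonferroni correction (default n = 32, the
#' number of cells for canonical-class motifs).
#'
#' @param proteins Protein tibble.
#' @param motif_class Motif class analysed.
#' @param n_subsamples Number of subsample replicates.
#' @param subsample_fraction Fraction of proteins drawn per replicate.
#' @param bonferroni_n Multiplier applied to the t-test p-values (capped at
#'   1).
#' @param advanced_n Scan with N-for-Q variants enabled.
#' @param seed Optional seed controlling scrambling and subsampling.
#' @return A tibble with `amino_acid`, `position`, `ratio_mean`, `ratio_sd`,
#'   `t`, `p` and `p_corrected`, one row per cell.
#' @export
baseline_comparison <- function(proteins, motif_class = "canonical",
                                n_subsamples = 40,
                                subsample_fraction = 0.10,
                                bonferroni_n = 32,
                                advanced_n = FALSE, seed = NULL) {
  proteins <- as_protein_tbl(proteins)
  motif_class <- match.arg(motif_class, MOTIF_CLASSES)
  run <- function() {
    scrambled <- scramble_proteome(proteins)
    obs <- scan_motifs(proteins, advanced_n = advanced_n,
                       flag_ubiquitylation = FALSE)
    prm <- suppressWarnings(scan_motifs(scrambled, advanced_n = advanced_n,
                                        flag_ubiquitylation = FALSE))
    alphabet <- sort(if (motif_class %in% c("phospho_generated", "n_phospho"))
      c(RES_BASIC, RES_HYDROPHOBIC, RES_PHOSPHO)
      else c(RES_BASIC, RES_HYDROPHOBIC, RES_ACIDIC))
    n_take <- max(1L, round(subsample_fraction * nrow(proteins)))
    reps_obs <- list(); reps_prm <- list(); dropped <- 0L
    for (r in seq_len(n_subsamples)) {
      acc_o <- sample(proteins$accession, n_take)
      acc_p <- sample(proteins$accession, n_take)
      fo <- cell_frequencies(obs, acc_o, motif_class, alphabet)
      fp <- cell_frequencies(prm, acc_p, motif_class, alphabet)
      if (anyNA(fo) || anyNA(fp)) { dropped <- dropped + 1L; next }
      reps_obs[[length(reps_obs) + 1L]] <- fo
      reps_prm[[length(reps_prm) + 1L]] <- fp
    }
    if (dropped > 0L) {
      warn(paste0(dropped, " subsample replicate(s) had zero motifs and ",
                  "were dropped."))
    }
    if (length(reps_obs) < 2L) {
      abort("Fewer than 2 usable subsample replicates.",
            class = "kferq_data_error")
    }
    mo <- do.call(rbind, reps_obs)
    mp <- do.call(rbind, reps_prm)
    ratio <- mo / mp
    cell_test <- function(j) {
      o <- mo[, j]; p_ <- mp[, j]
      if (stats::sd(o) == 0 && stats::sd(p_) == 0) {
        return(c(t = NA_real_, p = NA_real_))
      }
      ht <- stats::t.test(o, p_, var.equal = FALSE)
      c(t = unname(ht$statistic), p = ht$p.value)
    }
    tests <- vapply(seq_len(ncol(mo)), cell_test, numeric(2))
    cells <- colnames(mo)
    parts <- stringr::str_split_fixed(cells, "@", 2)
    tibble(amino_acid = parts[, 1], position = as.integer(parts[, 2]),
           ratio_mean = colMeans(ratio),
           ratio_sd = apply(ratio, 2, stats::sd),
           t = tests["t", ], p = tests["p", ],
           p_corrected = pmin(tests["p", ] * bonferroni_n, 1)) |>
      arrange(.data$amino_acid, .data$position)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Amino-acid composition of motif-bearing vs motif-free proteins
#'
#' @param proteins Protein tibble.
#' @param summaries Optional [summarize_motifs()] result (computed when
#'   omitted).
#' @return A tibble with `pool` ("with_motif"/"without_motif"), `amino_acid`
#'   and `percent`; each pool's percentages sum to 100.
#' @export
composition_comparison <- function(proteins, summaries = NULL) {
  proteins <- as_protein_tbl(proteins)
  if (is.null(summaries)) summaries <- summarize_motifs(proteins)
  has <- summaries$accession[summaries$hierarchy_group != "none"]
  pool_of <- ifelse(proteins$accession %in% has, "with_motif",
                    "without_motif")
  purrr::map_dfr(c("with_motif", "without_motif"), function(pl) {
    seqs <- proteins$sequence[pool_of == pl]
    if (length(seqs) == 0L) {
      return(tibble(pool = pl, amino_acid = AA_STANDARD,
                    percent = NA_real_))
    }
    cnt <- table(factor(unlist(strsplit(seqs, "", fixed = TRUE),
                               use.names = FALSE), levels = AA_STANDARD))
    tibble(pool = pl, amino_acid = AA_STANDARD,
           percent = 100 * as.numeric(cnt) / sum(cnt))
  })
}
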