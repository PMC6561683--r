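#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

## Residue vocabulary of the KFERQ grammar. The pentapeptide holds a flanking
## residue (Q for canonical/phospho, K-acetyl for acetyl-generated, N in
## advanced mode) at its first or last position plus four variable residues:
## 1-2 basic, 1-2 hydrophobic and exactly one acidic (or one phospho-acceptor
## standing in for the acidic one).
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
RES_BASIC <- c("K", "R")
RES_HYDROPHOBIC <- c("F", "I", "L", "V")
RES_ACIDIC <- c("D", "E")
RES_PHOSPHO <- c("S", "T", "Y")

MOTIF_CLASSES <- c("canonical", "phospho_generated", "acetyl_generated",
                   "n_canonical", "n_phospho", "n_acetyl")
MAIN_CLASSES <- MOTIF_CLASSES[1:3]
ORIENTATIONS <- c("Q_left", "Q_right")

#' Residues that can take part in a KFERQ-like motif
#'
#' Returns the residue vocabulary of the motif grammar as a named list:
#' `basic` (K, R), `hydrophobic` (F, I, L, V), `acidic` (D, E), `phospho`
#' (S, T, Y; acidic once phosphorylated), and the flank residues
#' `flank_canonical` (Q), `flank_acetyl` (K) and `flank_advanced` (N).
#'
#' @return A named list of character vectors.
#' @export
#' @examples
#' motif_residue_sets()$basic
motif_residue_sets <- function() {
  list(basic = RES_BASIC, hydrophobic = RES_HYDROPHOBIC,
       acidic = RES_ACIDIC, phospho = RES_PHOSPHO,
       flank_canonical = "Q", flank_acetyl = "K", flank_advanced = "N")
}

## Vectorised classifier over an n x 5 character matrix. Returns a data frame
## (window = row index, motif_class, orientation). Non-standard letters
## (X, B, Z, J, U, O, gaps) belong to no residue set, so windows containing
## them silently fail every rule.
classify_window_matrix <- function(chars, advanced_n = FALSE) {
  n <- nrow(chars)
  if (n == 0L) {
    return(data.frame(window = integer(), motif_class = character(),
                      orientation = character()))
  }
  count_in <- function(cols, set) {
    m <- chars[, cols, drop = FALSE]
    rowSums(matrix(m %in% set, nrow = n))
  }
  out <- vector("list", 2L)
  for (i in seq_along(ORIENTATIONS)) {
    ori <- ORIENTATIONS[[i]]
    flank <- if (ori == "Q_left") chars[, 1L] else chars[, 5L]
    var_cols <- if (ori == "Q_left") 2:5 else 1:4
    nb <- count_in(var_cols, RES_BASIC)
    nh <- count_in(var_cols, RES_HYDROPHOBIC)
    na_ <- count_in(var_cols, RES_ACIDIC)
    np <- count_in(var_cols, RES_PHOSPHO)
    in_range <- nb >= 1L & nb <= 2L & nh >= 1L & nh <= 2L
    # canonical-style variable region: the acidic residue is D/E, no S/T/Y
    var_canonical <- in_range & na_ == 1L & (nb + nh + na_ == 4L)
    # phospho-style: one S/T/Y acts as the acidic residue, no D/E allowed
    var_phospho <- in_range & np == 1L & na_ == 0L & (nb + nh + np == 4L)
    hits <- list(
      canonical = flank == "Q" & var_canonical,
      phospho_generated = flank == "Q" & var_phospho,
      acetyl_generated = flank == "K" & var_canonical
    )
    if (advanced_n) {
      hits$n_canonical <- flank == "N" & var_canonical
      hits$n_phospho <- flank == "N" & var_phospho
    }
    idx <- lapply(hits, which)
    win <- unlist(idx, use.names = FALSE)
    out[[i]] <- data.frame(
      window = if (is.null(win)) integer() else win,
      motif_class = rep(names(idx), lengths(idx)),
      orientation = rep(ori, length(win))
    )
  }
  res <- rbind(out[[1L]], out[[2L]])
  res[order(res$window, match(res$motif_class, MOTIF_CLASSES),
            res$orientation), , drop = FALSE]
}

check_pentapeptides <- function(pentapeptide) {
  if (!is.character(pentapeptide) || length(pentapeptide) == 0L) {
    abort("`pentapeptide` must be a non-empty character vector.",
          class = "kferq_invalid_input")
  }
  bad_len <- nchar(pentapeptide) != 5L
  if (any(bad_len)) {
    abort(paste0("Pentapeptides must be exactly 5 residues long; offending: ",
                 paste(utils::head(pentapeptide[bad_len], 5), collapse = ", ")),
          class = "kferq_invalid_input")
  }
  if (any(pentapeptide != toupper(pentapeptide))) {
    abort("Pentapeptides must be uppercase.", class = "kferq_invalid_input")
  }
  invisible(pentapeptide)
}

pentapeptide_matrix <- function(x) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = 5L, byrow = TRUE)
}

#' Classify a pentapeptide window against the KFERQ-like motif grammar
#'
#' Tests each 5-residue window against the motif building rules in both
#' orientations (flanking residue first, `Q_left`, or last, `Q_right`). The
#' flank residue selects the candidate classes: Q for canonical and
#' phosphorylation-generated motifs, K (acetylatable) for
#' acetylation-generated motifs and, when `advanced_n = TRUE`, N for the
#' asparagine variants `n_canonical`/`n_phospho`. The four variable residues
#' must contain 1-2 basic (K/R), 1-2 hydrophobic (F/I/L/V) and exactly one
#' acidic residue -- D/E for the canonical-style classes, or exactly one
#' phospho-acceptor (S/T/Y, and then no D/E) for the phospho classes.
#'
#' @param pentapeptide Character vector of uppercase 5-residue windows.
#' @param advanced_n Also report motifs in which N substitutes the flanking Q.
#' @return A tibble with columns `pentapeptide`, `motif_class` and
#'   `orientation`; zero rows for windows matching no class.
#' @export
#' @examples
#' classify_window("KFERQ")
#' classify_window(c("KSLVQ", "KFERK", "AAAAQ"))
#' classify_window("KFERN", advanced_n = TRUE)
classify_window <- function(pentapeptide, advanced_n = FALSE) {
  check_pentapeptides(pentapeptide)
  chars <- pentapeptide_matrix(pentapeptide)
  res <- classify_window_matrix(chars, advanced_n = advanced_n)
  tibble(pentapeptide = pentapeptide[res$window],
         motif_class = factor(res$motif_class, levels = MOTIF_CLASSES),
         orientation = factor(res$orientation, levels = ORIENTATIONS))
}

#' Flag motifs that ubiquitylation could inactivate
#'
#' A motif containing at least one lysine (as a basic variable residue or as
#' the acetyl-class flank) can be lost when that lysine is ubiquitylated.
#' This is an annotation only; it never changes classification.
#'
#' @param pentapeptide Character vector of pentapeptides.
#' @return Logical vector: `TRUE` when the window contains a lysine.
#' @export
#' @examples
#' flag_ubiquitylation_sensitive(c("KFERQ", "RFEIQ"))
flag_ubiquitylation_sensitive <- function(pentapeptide) {
  stringr::str_detect(pentapeptide, stringr::fixed("K"))
}

#' Scan protein sequences for KFERQ-like motifs
#'
#' Slides a 5-residue window over every sequence and reports each
#' (window, class, orientation) hit as one row. Overlapping windows are all
#' reported, and a window that satisfies the acetyl rule in both orientations
#' (lysines at both ends) yields two rows.
#'
#' @param proteins A data frame with at least `accession` and `sequence`
#'   columns (as returned by [read_proteome()] or [simulate_proteome()]), or
#'   a named character vector of sequences.
#' @param advanced_n Also report N-for-Q motif variants.
#' @param flag_ubiquitylation Add the `ubiquitylation_sensitive` column.
#' @return A tibble with columns `accession`, `start`, `end`, `center`,
#'   `pentapeptide`, `motif_class`, `orientation` and (optionally)
#'   `ubiquitylation_sensitive`, sorted by accession (input order) and start.
#'   Positions are 1-based inclusive; `center = start + 2` is the residue the
#'   positional analyses use.
#' @export
#' @examples
#' scan_motifs(c(P1 = "MKFERQL"))
scan_motifs <- function(proteins, advanced_n = FALSE,
                        flag_ubiquitylation = TRUE) {
  proteins <- as_protein_tbl(proteins)
  seqs <- proteins$sequence
  if (any(seqs != toupper(seqs))) {
    abort("Sequences must be uppercase; see read_proteome().",
          class = "kferq_invalid_input")
  }
  illegal <- !stringr::str_detect(
    seqs, paste0("^[", paste(AA_STANDARD, collapse = ""), "]*$"))
  if (any(illegal)) {
    warn(paste0("Non-standard residues in: ",
                paste(utils::head(proteins$accession[illegal], 10),
                      collapse = ", "),
                "; windows containing them never match."))
  }
  lens <- nchar(seqs)
  short <- lens < 5L
  if (any(short)) {
    inform(paste0(sum(short), " sequence(s) shorter than 5 residues were ",
                  "skipped."))
  }
  n_win <- pmax(lens - 4L, 0L)
  if (sum(n_win) == 0L) return(empty_match_tbl(flag_ubiquitylation))
  prot_idx <- rep(seq_along(seqs), n_win)
  start <- sequence(n_win)
  windows <- substring(seqs[prot_idx], start, start + 4L)
  res <- classify_window_matrix(pentapeptide_matrix(windows),
                                advanced_n = advanced_n)
  if (nrow(res) == 0L) return(empty_match_tbl(flag_ubiquitylation))
  hit_start <- start[res$window]
  out <- tibble(
    accession = proteins$accession[prot_idx[res$window]],
    start = hit_start,
    end = hit_start + 4L,
    center = hit_start + 2L,
    pentapeptide = windows[res$window],
    motif_class = factor(res$motif_class, levels = MOTIF_CLASSES),
    orientation = factor(res$orientation, levels = ORIENTATIONS)
  )
  out <- out[order(match(out$accession, proteins$accession), out$start,
                   as.integer(out$motif_class)), ]
  if (flag_ubiquitylation) {
    out$ubiquitylation_sensitive <- flag_ubiquitylation_sensitive(
      out$pentapeptide)
  }
  out
}

empty_match_tbl <- function(flag_ubiquitylation = TRUE) {
  out <- tibble(accession = character(), start = integer(), end = integer(),
                center = integer(), pentapeptide = character(),
                motif_class = factor(character(), levels = MOTIF_CLASSES),
                orientation = factor(character(), levels = ORIENTATIONS))
  if (flag_ubiquitylation) out$ubiquitylation_sensitive <- logical()
  out
}

## Accepts a protein tibble or a named character vector of sequences.
as_protein_tbl <- function(proteins) {
  if (is.character(proteins)) {
    acc <- names(proteins) %||% paste0("seq", seq_along(proteins))
    proteins <- tibble(accession = acc, sequence = unname(proteins),
                       length = nchar(proteins))
  }
  if (!is.data.frame(proteins) ||
      !all(c("accession", "sequence") %in% names(proteins))) {
    abort("`proteins` must be a data frame with accession and sequence.",
          class = "kferq_invalid_input")
  }
  if (anyDuplicated(proteins$accession)) {
    abort("Duplicate accessions in `proteins`.", class = "kferq_data_error")
  }
  proteins <- as_tibble(proteins)
  if (!"length" %in% names(proteins)) {
    proteins$length <- nchar(proteins$sequence)
  }
  proteins
}

#' Summarise motif content per protein
#'
#' Counts motifs of each class per protein, assigns the hierarchy group
#' (highest-ranking class present, default rank canonical >
#' phosphorylation-generated > acetylation-generated, else `none`), the
#' combination signature (which ranked classes occur at all) and the
#' fractional motif composition (percentages of the ranked classes, summing
#' to 100 for any motif-bearing protein).
#'
#' @param proteins Protein tibble (or named character vector of sequences).
#' @param matches Optional result of [scan_motifs()]; scanned internally when
#'   omitted.
#' @param hierarchy Character vector of motif classes, highest rank first.
#'   Use `c("n_canonical", "n_phospho")` for an N-variant-only analysis.
#' @param advanced_n Passed to [scan_motifs()] when `matches` is omitted.
#' @return A tibble with one row per protein: `accession`, `length`, one
#'   count column per class in `hierarchy`, `n_motifs`, `hierarchy_group`,
#'   `combination`, and `frac_<class>` percentage columns (`NA` for proteins
#'   without motifs).
#' @export
#' @examples
#' p <- c(A = "MKFERQLLKSLVQMKDLLKM")
#' summarize_motifs(p)
summarize_motifs <- function(proteins, matches = NULL,
                             hierarchy = MAIN_CLASSES,
                             advanced_n = FALSE) {
  proteins <- as_protein_tbl(proteins)
  if (is.null(matches)) {
    matches <- scan_motifs(proteins, advanced_n = advanced_n)
  }
  stopifnot(all(c("accession", "motif_class") %in% names(matches)))
  hierarchy <- match.arg(hierarchy, MOTIF_CLASSES, several.ok = TRUE)
  counts <- matches |>
    filter(.data$motif_class %in% hierarchy) |>
    count(.data$accession, .data$motif_class) |>
    tidyr::pivot_wider(names_from = "motif_class", values_from = "n",
                       values_fill = 0L)
  for (cl in hierarchy) if (is.null(counts[[cl]])) counts[[cl]] <- 0L
  out <- proteins |>
    select("accession", "length") |>
    left_join(counts, by = "accession") |>
    mutate(across(all_of(hierarchy), ~ tidyr::replace_na(.x, 0L)))
  cnt <- as.matrix(out[hierarchy])
  total <- rowSums(cnt)
  first_present <- apply(cnt > 0L, 1L, function(x) {
    i <- which(x)[1]
    if (is.na(i)) "none" else hierarchy[[i]]
  })
  combo <- apply(cnt > 0L, 1L, function(x) {
    if (!any(x)) "none" else paste(hierarchy[x], collapse = "+")
  })
  out$n_motifs <- as.integer(total)
  out$hierarchy_group <- factor(first_present, levels = c(hierarchy, "none"))
  out$combination <- combo
  frac <- 100 * cnt / ifelse(total > 0, total, NA_real_)
  colnames(frac) <- paste0("frac_", hierarchy)
  bind_cols(out, as_tibble(frac))
}

#' All combination signatures over a motif-class hierarchy
#'
#' @param hierarchy Ranked motif classes.
#' @return Character vector of the `2^k` signatures ("none" plus every
#'   non-empty subset joined by "+", in rank order).
#' @export
combination_levels <- function(hierarchy = MAIN_CLASSES) {
  k <- length(hierarchy)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  sig <- apply(subsets, 1L, function(x) {
    if (!any(x)) "none" else paste(hierarchy[x], collapse = "+")
  })
  unique(c("none", sig))
}
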