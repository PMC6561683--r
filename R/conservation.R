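#' Does a sequence end in a LAMP-2A-type cytosolic tail?
#'
#' The splice variant of LAMP2 that licenses chaperone-mediated autophagy
#' (LAMP-2A) carries a distinctive C-terminus: three to four consecutive
#' basic residues (K/R/H), one to three arbitrary residues, then GYEQF at the
#' absolute end of the protein. The classifier examines the last 100 residues
#' and applies the pattern `[KRH]{3,4}.{1,3}GYEQF$`.
#'
#' @param sequence Character vector of protein sequences.
#' @return Logical vector; sequences shorter than 9 residues are `FALSE`.
#' @export
#' @examples
#' is_lamp2a_tail("MSSPTTKHHAGYEQF")
is_lamp2a_tail <- function(sequence) {
  len <- nchar(sequence)
  tail100 <- substr(sequence, pmax(1L, len - 99L), len)
  len >= 9L & stringr::str_detect(tail100, "[KRH]{3,4}.{1,3}GYEQF$")
}

#' Read an aligned ortholog family from FASTA
#'
#' @param path Aligned FASTA (all rows equal length, gaps as `-` or `.`).
#' @return A tibble with `species` (first header token) and `aligned_seq`
#'   (uppercased, `.` gaps normalised to `-`).
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) == 0L) {
    abort(paste0("Empty alignment file: ", path), class = "kferq_data_error")
  }
  seqs <- chartr(".", "-", toupper(as.character(aln)))
  if (length(unique(nchar(seqs))) != 1L) {
    abort(paste0("Rows of ", path, " differ in length; not an alignment."),
          class = "kferq_data_error")
  }
  tibble(species = stringr::str_split_i(names(aln), "\\s+", 1),
         aligned_seq = unname(seqs))
}

#' Map a human motif onto alignment columns
#'
#' Finds the five alignment columns that hold the residues of a motif whose
#' coordinates refer to the ungapped reference sequence. Gap columns in the
#' reference row are skipped, so the returned columns need not be contiguous.
#'
#' @param aligned_seq The gapped reference (human) row of the alignment.
#' @param start 1-based start of the motif on the ungapped sequence.
#' @return Integer vector of 5 alignment column indices.
#' @export
motif_alignment_columns <- function(aligned_seq, start) {
  chars <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  residue_cols <- which(chars != "-")
  if (start < 1L || start + 4L > length(residue_cols)) {
    abort("Motif coordinates fall outside the ungapped reference sequence.",
          class = "kferq_data_error")
  }
  residue_cols[start:(start + 4L)]
}

#' Classify one species' pentapeptide at the human motif position
#'
#' Extracts the species' residues at the five alignment columns of the human
#' motif and classifies them: `conserved` when the pentapeptide yields a
#' motif of the same class as the human motif (either orientation),
#' `partial` when it yields only motifs of a different class, and
#' `absent_motif` otherwise (including any gap inside the pentapeptide).
#'
#' @param aligned_seq The species' gapped row (or `NA` for a missing
#'   ortholog).
#' @param columns Alignment columns from [motif_alignment_columns()].
#' @param human_class Class of the human motif.
#' @param include_n Count N-for-Q variants as motifs when classifying.
#' @return One of `"conserved"`, `"partial"`, `"absent_motif"`,
#'   `"no_ortholog"`.
#' @export
classify_species_motif <- function(aligned_seq, columns, human_class,
                                   include_n = FALSE) {
  if (length(aligned_seq) != 1L || is.na(aligned_seq)) return("no_ortholog")
  chars <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  if (max(columns) > length(chars)) return("absent_motif")
  pent <- chars[columns]
  if (any(pent == "-")) return("absent_motif")
  hits <- classify_window_matrix(matrix(pent, nrow = 1L),
                                 advanced_n = include_n)
  classes <- unique(hits$motif_class)
  if (!include_n) classes <- intersect(classes, MAIN_CLASSES)
  if (length(classes) == 0L) return("absent_motif")
  if (human_class %in% classes) "conserved" else "partial"
}

#' Conservation score of a motif over a species group
#'
#' `(n_conserved + 0.5 * n_partial - n_no_ortholog) / n_species`. Species
#' whose ortholog lacks any motif at the position (`absent_motif`) contribute
#' zero to the numerator but count in `n_species`. The score lies in
#' \[-1, 1\]; a score > 0 means an ortholog with a motif at the human
#' position is more likely than not.
#'
#' @param n_conserved,n_partial,n_no_ortholog,n_species Integer tallies
#'   (vectorised).
#' @return Numeric score vector.
#' @export
#' @examples
#' conservation_score(4, 2, 1, 10)  # (4 + 1 - 1) / 10 = 0.4
conservation_score <- function(n_conserved, n_partial, n_no_ortholog,
                               n_species) {
  if (any(n_species <= 0)) {
    abort("`n_species` must be positive.", class = "kferq_invalid_input")
  }
  if (any(n_conserved + n_partial + n_no_ortholog > n_species)) {
    abort("Tallies exceed `n_species`.", class = "kferq_invalid_input")
  }
  (n_conserved + 0.5 * n_partial - n_no_ortholog) / n_species
}

#' Score motif conservation across species groups
#'
#' For every ortholog family, classifies each species' pentapeptide at the
#' human motif position and computes the conservation score separately for
#' CMA-able and CMA-unable species. A motif is *selectively conserved* when
#' its score is > 0 in the CMA-able group and <= 0 in the CMA-unable group.
#'
#' @param families Tibble with `accession` (human protein id), `species` and
#'   `aligned_seq` -- one row per aligned ortholog, including the reference
#'   row.
#' @param motifs Tibble with one human motif per accession: `accession`,
#'   `start` (on the ungapped reference) and `motif_class`.
#' @param species_table Tibble with `species` and logical `cma_able`; species
#'   listed here but missing from a family count as `no_ortholog`.
#' @param reference Species name of the reference (human) row.
#' @param include_n Count N-for-Q variants when classifying orthologs.
#' @return A tibble, one row per accession: per-group tallies
#'   (`conserved_able`, `partial_able`, `absent_able`, `no_ortholog_able` and
#'   the `_unable` counterparts), `n_able`, `n_unable`, `score_able`,
#'   `score_unable` and `selective`.
#' @export
score_conservation <- function(families, motifs, species_table,
                               reference = "human", include_n = FALSE) {
  if (anyDuplicated(species_table$species)) {
    abort("Species names must be unique.", class = "kferq_data_error")
  }
  species_table <- species_table |> filter(.data$species != reference)
  if (!any(species_table$cma_able) || !any(!species_table$cma_able)) {
    abort("Both CMA-able and CMA-unable species are required.",
          class = "kferq_data_error")
  }
  fam_split <- split(families, families$accession)
  rows <- purrr::map(names(fam_split), function(acc) {
    fam <- fam_split[[acc]]
    mot <- motifs |> filter(.data$accession == acc)
    if (nrow(mot) != 1L) {
      abort(paste0("Expected exactly one human motif for ", acc, "."),
            class = "kferq_data_error")
    }
    ref_row <- fam$aligned_seq[fam$species == reference]
    if (length(ref_row) != 1L) {
      abort(paste0("Missing reference row '", reference, "' for ", acc, "."),
            class = "kferq_data_error")
    }
    cols <- motif_alignment_columns(ref_row, mot$start)
    cls <- vapply(species_table$species, function(sp) {
      row <- fam$aligned_seq[fam$species == sp]
      classify_species_motif(if (length(row)) row[[1]] else NA_character_,
                             cols, as.character(mot$motif_class),
                             include_n = include_n)
    }, character(1))
    tally <- function(able) {
      sel <- species_table$cma_able == able
      c(conserved = sum(cls[sel] == "conserved"),
        partial = sum(cls[sel] == "partial"),
        absent = sum(cls[sel] == "absent_motif"),
        no_ortholog = sum(cls[sel] == "no_ortholog"),
        n = sum(sel))
    }
    a <- tally(TRUE); u <- tally(FALSE)
    tibble(accession = acc,
           conserved_able = a[["conserved"]], partial_able = a[["partial"]],
           absent_able = a[["absent"]],
           no_ortholog_able = a[["no_ortholog"]], n_able = a[["n"]],
           conserved_unable = u[["conserved"]],
           partial_unable = u[["partial"]], absent_unable = u[["absent"]],
           no_ortholog_unable = u[["no_ortholog"]], n_unable = u[["n"]])
  })
  out <- bind_rows(rows)
  out |>
    mutate(
      score_able = conservation_score(.data$conserved_able,
                                      .data$partial_able,
                                      .data$no_ortholog_able, .data$n_able),
      score_unable = conservation_score(.data$conserved_unable,
                                        .data$partial_unable,
                                        .data$no_ortholog_unable,
                                        .data$n_unable),
      selective = .data$score_able > 0 & .data$score_unable <= 0)
}
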