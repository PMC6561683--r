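#' Read per-residue relative solvent accessibility tracks
#'
#' Reads a TSV with columns `accession` (or `protein_id`), `position`
#' (1-based) and either `rsa` (relative solvent accessibility in \[0, 1\]) or
#' `exposed` (0/1). Numeric RSA is binarised with the burial rule
#' "RSA < 0.25 means buried" (so RSA = 0.25 is exposed).
#'
#' @param path TSV file.
#' @param proteins Optional protein tibble; when given, each track must cover
#'   every residue of its protein exactly once, or an error names the
#'   offending protein.
#' @return A tibble with `accession`, `position`, `rsa` (may be `NA` when
#'   only a binary track was supplied) and `exposed` (logical).
#' @export
read_rsa_tracks <- function(path, proteins = NULL) {
  tr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tr)[names(tr) == "protein_id"] <- "accession"
  if (!all(c("accession", "position") %in% names(tr)) ||
      !any(c("rsa", "exposed") %in% names(tr))) {
    abort("RSA track needs accession/protein_id, position and rsa or exposed.",
          class = "kferq_data_error")
  }
  rsa_tracks(tr, proteins)
}

#' Validate and binarise an RSA track tibble
#'
#' @param tracks Tibble with `accession`, `position` and `rsa` and/or
#'   `exposed` columns.
#' @inheritParams read_rsa_tracks
#' @param buried_below RSA threshold: residues with RSA strictly below it are
#'   buried.
#' @return The validated track with an `exposed` logical column.
#' @export
rsa_tracks <- function(tracks, proteins = NULL, buried_below = 0.25) {
  tracks <- as_tibble(tracks)
  if ("rsa" %in% names(tracks)) {
    if (any(tracks$rsa < 0 | tracks$rsa > 1, na.rm = TRUE)) {
      abort("RSA values must lie in [0, 1].", class = "kferq_data_error")
    }
    if (!"exposed" %in% names(tracks)) {
      tracks$exposed <- tracks$rsa >= buried_below
    }
  } else {
    tracks$rsa <- NA_real_
  }
  tracks$exposed <- as.logical(tracks$exposed)
  if (!is.null(proteins)) {
    lens <- tracks |>
      group_by(.data$accession) |>
      summarise(n = dplyr::n(), maxpos = max(.data$position))
    ref <- proteins$length[match(lens$accession, proteins$accession)]
    bad <- which(is.na(ref) | lens$n != ref | lens$maxpos != ref)
    if (length(bad)) {
      abort(paste0("RSA track length mismatch for: ",
                   paste(utils::head(lens$accession[bad], 10),
                         collapse = ", ")),
            class = "kferq_data_error")
    }
  }
  tracks[c("accession", "position", "rsa", "exposed")]
}

#' Drop proteins longer than a length limit
#'
#' Secondary-structure predictors often cap input length (800 residues for
#' the predictor whose tracks this package consumes); the exposure analysis
#' therefore removes longer proteins rather than truncating them.
#'
#' @param proteins Protein tibble.
#' @param max_length Maximum length kept (inclusive).
#' @return The filtered protein tibble; a message reports how many proteins
#'   were dropped.
#' @export
filter_max_length <- function(proteins, max_length = 800) {
  proteins <- as_protein_tbl(proteins)
  drop <- proteins$length > max_length
  if (any(drop)) {
    inform(paste0("Dropped ", sum(drop), " protein(s) longer than ",
                  max_length, " residues."))
  }
  proteins[!drop, ]
}

#' Solvent-exposure profile around motif centres
#'
#' For each offset in `-window .. +window` relative to the central residue of
#' every motif, computes the percentage of contributing residues classified
#' as exposed. Offsets that fall outside a protein contribute nothing (the
#' denominator shrinks; no padding). The baseline is the percentage of
#' exposed residues over all residues of all proteins in the track set.
#'
#' @param matches Result of [scan_motifs()]; every match's protein must have
#'   a track.
#' @param tracks RSA track tibble (see [rsa_tracks()]).
#' @param window Half-width of the profile in residues.
#' @return A tibble of class `kferq_exposure_profile` with `offset`,
#'   `pct_exposed`, `n` (contributing residues) and `baseline`.
#' @export
exposure_profile <- function(matches, tracks, window = 30) {
  if (nrow(matches) == 0L) {
    abort("No matches supplied.", class = "kferq_data_error")
  }
  tracks <- rsa_tracks(tracks)
  missing <- setdiff(unique(matches$accession), unique(tracks$accession))
  if (length(missing)) {
    abort(paste0("No RSA track for: ",
                 paste(utils::head(missing, 10), collapse = ", ")),
          class = "kferq_data_error")
  }
  offsets <- -window:window
  grid <- tibble(
    accession = rep(matches$accession, each = length(offsets)),
    position = rep(matches$center, each = length(offsets)) +
      rep(offsets, times = nrow(matches)),
    offset = rep(offsets, times = nrow(matches)))
  joined <- grid |>
    inner_join(tracks[c("accession", "position", "exposed")],
               by = c("accession", "position"))
  prof <- joined |>
    group_by(.data$offset) |>
    summarise(pct_exposed = 100 * mean(.data$exposed), n = dplyr::n()) |>
    tidyr::complete(offset = offsets,
                    fill = list(pct_exposed = NA_real_, n = 0L))
  prof$baseline <- 100 * mean(tracks$exposed)
  class(prof) <- c("kferq_exposure_profile", class(prof))
  attr(prof, "window") <- window
  prof
}
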