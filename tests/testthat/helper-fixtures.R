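# Shared tiny fixtures, built in code.

tiny_proteins <- function() {
  tibble::tibble(
    accession = c("P1", "P2", "P3", "P4"),
    sequence = c(
      "MKFERQAAAKSLVQAAAKFERKAAA",  # canonical + phospho + 2x acetyl
      "MKFERQLLLAAAGGG",            # canonical only
      "MAAAGGGPPPWWWCCHH",          # no motif
      "MKFERKAAAGGGPPP"             # acetyl only
    ),
    length = nchar(c(
      "MKFERQAAAKSLVQAAAKFERKAAA", "MKFERQLLLAAAGGG",
      "MAAAGGGPPPWWWCCHH", "MKFERKAAAGGGPPP"))
  )
}

# Independent rule oracle for a single pentapeptide: literal transcription of
# the motif building rules, deliberately un-vectorised and separate from the
# scanner's implementation.
oracle_classify <- function(pent, advanced_n = FALSE) {
  chars <- strsplit(pent, "")[[1]]
  stopifnot(length(chars) == 5)
  res <- list()
  for (ori in c("Q_left", "Q_right")) {
    flank <- if (ori == "Q_left") chars[1] else chars[5]
    var <- if (ori == "Q_left") chars[2:5] else chars[1:4]
    nb <- sum(var %in% c("K", "R"))
    nh <- sum(var %in% c("F", "I", "L", "V"))
    na_ <- sum(var %in% c("D", "E"))
    np <- sum(var %in% c("S", "T", "Y"))
    all_canon <- all(var %in% c("K", "R", "F", "I", "L", "V", "D", "E"))
    all_phos <- all(var %in% c("K", "R", "F", "I", "L", "V", "S", "T", "Y"))
    canon_ok <- all_canon && nb >= 1 && nb <= 2 && nh >= 1 && nh <= 2 &&
      na_ == 1
    phos_ok <- all_phos && nb >= 1 && nb <= 2 && nh >= 1 && nh <= 2 &&
      np == 1 && na_ == 0
    if (flank == "Q" && canon_ok) res[[length(res) + 1]] <- c("canonical", ori)
    if (flank == "Q" && phos_ok) {
      res[[length(res) + 1]] <- c("phospho_generated", ori)
    }
    if (flank == "K" && canon_ok) {
      res[[length(res) + 1]] <- c("acetyl_generated", ori)
    }
    if (advanced_n && flank == "N" && canon_ok) {
      res[[length(res) + 1]] <- c("n_canonical", ori)
    }
    if (advanced_n && flank == "N" && phos_ok) {
      res[[length(res) + 1]] <- c("n_phospho", ori)
    }
  }
  res
}

expect_no_rows <- function(x) testthat::expect_identical(nrow(x), 0L)
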