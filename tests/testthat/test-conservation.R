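# Brute-force oracle for the LAMP-2A tail: check every admissible suffix
# layout (3-4 basics, 1-3 spacers, terminal GYEQF) by direct character
# comparison.
oracle_lamp2a <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 9) return(FALSE)
  for (nb in 3:4) {
    for (ns in 1:3) {
      k <- nb + ns + 5
      if (k > L || k > 100) next
      suffix <- chars[(L - k + 1):L]
      ok <- all(suffix[1:nb] %in% c("K", "R", "H")) &&
        paste(suffix[(nb + ns + 1):k], collapse = "") == "GYEQF"
      if (ok) return(TRUE)
    }
  }
  FALSE
}

test_that("LAMP-2A tail classifier matches known positives and negatives", {
  expect_true(is_lamp2a_tail("MSSPTTKHHAGYEQF"))    # 3 basics, 1 spacer
  expect_false(is_lamp2a_tail("MSSPTTKHAGYEQF"))    # only 2 basics
  expect_false(is_lamp2a_tail("MSSPTTKHHAGYEQFX"))  # GYEQF not terminal
  expect_true(is_lamp2a_tail("MKRHRAAAGYEQF"))      # 4 basics, 3 spacers
  expect_false(is_lamp2a_tail("MKRHRAAAAGYEQF"))    # 4 spacers: too many
  expect_false(is_lamp2a_tail("GYEQF"))             # shorter than 9
})

test_that("LAMP-2A tail classifier agrees with a brute-force suffix oracle", {
  set.seed(61)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- character(10000)
  for (i in seq_len(10000)) {
    L <- sample(9:120, 1)
    chars <- sample(aa, L, replace = TRUE)
    if (i %% 3 == 0) {
      # force the terminal GYEQF and a basic-rich tail region so positives
      # are well represented
      chars[(L - 4):L] <- c("G", "Y", "E", "Q", "F")
      nb <- sample(2:5, 1); ns <- sample(1:4, 1)
      if (L >= nb + ns + 5) {
        chars[(L - 4 - ns - nb + 1):(L - 4 - ns)] <-
          sample(c("K", "R", "H"), nb, replace = TRUE)
      }
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  expect_identical(is_lamp2a_tail(seqs),
                   vapply(seqs, oracle_lamp2a, logical(1), USE.NAMES = FALSE))
})

test_that("motif columns are mapped through reference gaps", {
  # ungapped reference: columns are just start..start+4
  expect_identical(motif_alignment_columns("MKFERQLL", 2L), 2:6)
  # gap inside the motif region: non-contiguous columns
  expect_identical(motif_alignment_columns("MKF--ERQLL", 2L),
                   c(2L, 3L, 6L, 7L, 8L))
  # motif at the very end of the sequence
  expect_identical(motif_alignment_columns("AAAKFERQ", 4L), 4:8)
  expect_error(motif_alignment_columns("MKFERQ", 3L),
               class = "kferq_data_error")
})

test_that("species pentapeptides are classified against the human class", {
  cols <- 1:5
  expect_identical(classify_species_motif("KFERQAAA", cols, "canonical"),
                   "conserved")
  # same class, other orientation still counts as conserved
  expect_identical(classify_species_motif("QKFERAAA", cols, "canonical"),
                   "conserved")
  expect_identical(classify_species_motif("KFERKAAA", cols, "canonical"),
                   "partial")
  expect_identical(classify_species_motif("AAAAAAAA", cols, "canonical"),
                   "absent_motif")
  expect_identical(classify_species_motif("KF-RQAAA", cols, "canonical"),
                   "absent_motif")
  expect_identical(classify_species_motif(NA_character_, cols, "canonical"),
                   "no_ortholog")
  # N-variants only count when include_n is on
  expect_identical(classify_species_motif("KFERNAAA", cols, "canonical"),
                   "absent_motif")
  expect_identical(classify_species_motif("KFERNAAA", cols, "canonical",
                                          include_n = TRUE), "partial")
})

test_that("conservation score follows the published formula and bounds", {
  expect_equal(conservation_score(10, 0, 0, 10), 1)
  expect_equal(conservation_score(0, 0, 10, 10), -1)
  expect_equal(conservation_score(4, 2, 1, 10), 0.4)
  expect_equal(conservation_score(0, 0, 0, 10), 0)  # all absent_motif
  # single-species groups can only reach -1, 0, 0.5 or 1
  single <- c(conservation_score(1, 0, 0, 1), conservation_score(0, 1, 0, 1),
              conservation_score(0, 0, 0, 1), conservation_score(0, 0, 1, 1))
  expect_setequal(single, c(1, 0.5, 0, -1))
  expect_error(conservation_score(1, 0, 0, 0), class = "kferq_invalid_input")
  expect_error(conservation_score(5, 5, 5, 10),
               class = "kferq_invalid_input")
  # exhaustive small-tally check: scores stay within [-1, 1] and drop
  # monotonically as species degrade from conserved toward no_ortholog
  for (n in 1:5) {
    tallies <- expand.grid(c = 0:n, p = 0:n, no = 0:n)
    tallies <- tallies[rowSums(tallies) <= n, ]
    sc <- conservation_score(tallies$c, tallies$p, tallies$no, n)
    expect_true(all(sc >= -1 & sc <= 1))
  }
  expect_true(conservation_score(3, 0, 0, 5) > conservation_score(2, 1, 0, 5))
  expect_true(conservation_score(2, 1, 0, 5) > conservation_score(2, 0, 0, 5))
  expect_true(conservation_score(2, 0, 0, 5) > conservation_score(2, 0, 1, 5))
})

test_that("the reference row always classifies as conserved", {
  sim <- simulate_ortholog_families(n_families = 5, seed = 71)
  for (acc in unique(sim$families$accession)) {
    fam <- sim$families[sim$families$accession == acc, ]
    mot <- sim$motifs[sim$motifs$accession == acc, ]
    ref <- fam$aligned_seq[fam$species == "human"]
    cols <- motif_alignment_columns(ref, mot$start)
    expect_identical(classify_species_motif(ref, cols, "canonical"),
                     "conserved")
  }
})

test_that("group scoring recovers a planted retention gap", {
  sim <- simulate_ortholog_families(n_families = 120, seed = 73)
  sc <- score_conservation(sim$families, sim$motifs, sim$species)
  expect_identical(nrow(sc), 120L)
  expect_true(all(sc$n_able == 25 & sc$n_unable == 25))
  # classifications agree with the generator's ground truth
  truth_mean <- sim$truth |>
    dplyr::left_join(sim$species, by = "species") |>
    dplyr::filter(!is.na(cma_able))
  got_cons_able <- sum(sc$conserved_able)
  want_cons_able <- sum(truth_mean$classification == "conserved" &
                          truth_mean$cma_able)
  expect_identical(got_cons_able, want_cons_able)
  # analytic expectation of the per-species contribution:
  # E = P(cons) + 0.5 P(partial) - P(noOrth)
  exp_score <- function(r, p_no) {
    (1 - p_no) * r + 0.5 * (1 - p_no) * (1 - r) * 0.5 - p_no
  }
  se <- function(x) stats::sd(x) / sqrt(length(x))
  m_able <- mean(sc$score_able); m_unable <- mean(sc$score_unable)
  expect_lt(abs(m_able - exp_score(0.9, 0.1)), 4 * se(sc$score_able) + 0.02)
  expect_lt(abs(m_unable - exp_score(0.1, 0.5)),
            4 * se(sc$score_unable) + 0.02)
  expect_gt(m_able, 0)
  expect_lt(m_unable, 0)
  expect_gt(mean(sc$selective), 0.9)
})

test_that("identical groups give identical scores; full retention scores 1", {
  sim <- simulate_ortholog_families(n_families = 10,
                                    retention = c(able = 1, unable = 1),
                                    p_no_ortholog = 0, seed = 79)
  sc <- score_conservation(sim$families, sim$motifs, sim$species)
  expect_equal(sc$score_able, rep(1, 10))
  expect_equal(sc$score_unable, rep(1, 10))
  expect_false(any(sc$selective))
  # all-disrupting, ortholog-free extreme: score <= 0 everywhere
  sim0 <- simulate_ortholog_families(n_families = 10,
                                     retention = c(able = 0, unable = 0),
                                     p_no_ortholog = 0.5, seed = 83)
  sc0 <- score_conservation(sim0$families, sim0$motifs, sim0$species)
  expect_true(all(sc0$score_able <= 0.5))  # partials cap at 0.5
})

test_that("species missing from a family count as no_ortholog", {
  fam <- tibble::tibble(
    accession = "F1",
    species = c("human", "sp_a"),
    aligned_seq = c("KFERQAAA", "KFERQAAA"))
  motifs <- tibble::tibble(accession = "F1", start = 1L,
                           motif_class = "canonical")
  species <- tibble::tibble(species = c("sp_a", "sp_b", "sp_c"),
                            cma_able = c(TRUE, TRUE, FALSE))
  sc <- score_conservation(fam, motifs, species)
  expect_identical(sc$no_ortholog_able, 1L)
  expect_identical(sc$no_ortholog_unable, 1L)
  expect_equal(sc$score_able, (1 - 1) / 2)
  expect_equal(sc$score_unable, -1)
})

test_that("alignment round-trip through FASTA preserves rows", {
  sim <- simulate_ortholog_families(n_families = 2, n_able = 3, n_unable = 3,
                                    seed = 89)
  fam <- sim$families[sim$families$accession == "FAM0001", ]
  path <- withr::local_tempfile(fileext = ".fasta")
  set <- Biostrings::AAStringSet(fam$aligned_seq)
  names(set) <- fam$species
  Biostrings::writeXStringSet(set, path)
  got <- read_alignment(path)
  expect_identical(got$species, fam$species)
  expect_identical(got$aligned_seq, fam$aligned_seq)
})
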