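test_that("group percentages partition the proteome and recover planted groups", {
  pr <- tiny_proteins()
  gp <- group_percentages(summarize_motifs(pr))
  expect_equal(sum(gp$percent), 100)
  expect_equal(gp$percent[match(c("canonical", "acetyl_generated", "none"),
                                gp$hierarchy_group)], c(50, 25, 25))

  # a proteome without any motif is 100% none
  s_none <- summarize_motifs(c(A = "MAAAGGGPPP", B = "MWWWCCHHAA"))
  gp_none <- group_percentages(s_none)
  expect_equal(gp_none$percent[gp_none$hierarchy_group == "none"], 100)

  # planted fixture: groups recovered exactly for a motif-free background
  bg <- stats::setNames(rep(1, 20), names(motif_residue_sets()$basic))
  bg <- stats::setNames(rep(1, 17),
                        setdiff(c("A", "C", "D", "E", "F", "G", "H", "I",
                                  "K", "L", "M", "N", "P", "Q", "R", "S",
                                  "T", "V", "W", "Y"), c("Q", "K", "N")))
  mk <- function(class, n, prefix) {
    simulate_proteome(n, 100, 150, background_freqs = bg,
                      planted = tibble::tibble(motif_class = class,
                                               count = 1L),
                      seed = 5, prefix = prefix)
  }
  pr2 <- dplyr::bind_rows(
    mk("canonical", 6, "CAN"), mk("phospho_generated", 3, "PHO"),
    simulate_proteome(1, 100, 150, background_freqs = bg, seed = 6,
                      prefix = "NUL"))
  gp2 <- group_percentages(summarize_motifs(pr2))
  expect_equal(gp2$percent[match(c("canonical", "phospho_generated", "none"),
                                 gp2$hierarchy_group)], c(60, 30, 10))
  expect_error(group_percentages(summarize_motifs(pr2)[0, ]),
               class = "kferq_invalid_input")
})

test_that("combination breakdown splits groups into all subsets and sums to 100", {
  s <- summarize_motifs(tiny_proteins())
  cb <- combination_breakdown(s)
  expect_identical(nrow(cb), 8L)
  expect_equal(sum(cb$percent), 100)
  # consistency with the hierarchy grouping: signatures containing
  # "canonical" add up to the canonical group percentage
  gp <- group_percentages(s)
  with_can <- grepl("(^|\\+)canonical", cb$combination)
  expect_equal(sum(cb$percent[with_can]),
               gp$percent[gp$hierarchy_group == "canonical"])
})

test_that("motif count histogram tallies the group-defining class", {
  s <- summarize_motifs(tiny_proteins())
  h <- motif_count_histogram(s)
  # P1 and P2 are canonical-group with 1 canonical motif each
  expect_equal(h$n_proteins[h$hierarchy_group == "canonical" &
                              h$n_motifs == 1], 2)
  # P4's KFERK reads as acetyl in both orientations, so it carries 2
  expect_equal(h$n_proteins[h$hierarchy_group == "acetyl_generated" &
                              h$n_motifs == 2], 1)
  h0 <- motif_count_histogram(summarize_motifs(c(A = "MAAAGGG")))
  expect_identical(nrow(h0), 0L)
})

test_that("length model recovers exact log2-linear data with R^2 = 1", {
  lens <- seq(500L, 5000L, by = 500L)
  counts <- as.integer(2^(1 + lens / 500))  # integer exponents: exact data
  s <- tibble::tibble(accession = paste0("P", seq_along(lens)),
                      length = lens, canonical = counts)
  fit <- fit_length_model(s)
  g <- glance(fit)
  expect_equal(g$r.squared, 1)
  expect_identical(g$n_removed, 0L)
  expect_equal(g$slope, 1 / 500)

  # constant counts: slope 0, R^2 = 0
  s0 <- s |> dplyr::mutate(canonical = 4L)
  expect_equal(suppressWarnings(glance(fit_length_model(s0))$r.squared), 0)

  expect_error(fit_length_model(s[1:2, ]), class = "kferq_data_error")
  expect_error(
    fit_length_model(s |> dplyr::mutate(length = 300L)),
    class = "kferq_data_error")
})

test_that("length model removes Cook's distance outliers in a single pass", {
  set.seed(21)
  lens <- seq(100, 2000, length.out = 60)
  log2n <- 1 + lens / 1000 + stats::rnorm(60, sd = 0.3)
  s <- tibble::tibble(accession = paste0("P", 1:60), length = lens,
                      canonical = as.integer(pmax(1, round(2^log2n))))
  # one very long, very influential protein
  s <- dplyr::bind_rows(s, tibble::tibble(accession = "HUGE",
                                          length = 30000, canonical = 1L))
  fit <- fit_length_model(s)
  expect_identical(fit$removed_accessions, "HUGE")
  expect_identical(glance(fit)$n_removed, 1L)
  expect_false("HUGE" %in% fit$data$accession)
})

test_that("length model recovers generating slope from noisy simulated data", {
  set.seed(31)
  n <- 300
  lens <- round(stats::runif(n, 100, 2000))
  b <- 1 / 1500
  log2n <- 0.5 + b * lens + stats::rnorm(n, sd = 0.45)
  s <- tibble::tibble(accession = paste0("P", 1:n), length = lens,
                      canonical = as.integer(pmax(1, round(2^log2n))))
  fit <- fit_length_model(s)
  ci <- stats::confint(fit$fit)["length", ]
  expect_gt(b, ci[1])
  expect_lt(b, ci[2])
})

test_that("positional distribution normalises by length and conserves counts", {
  matches <- tibble::tibble(accession = "A", start = 48L, end = 52L,
                            center = 50L, pentapeptide = "KFERQ",
                            motif_class = factor("canonical"),
                            orientation = factor("Q_right"))
  pr <- tibble::tibble(accession = "A", sequence = strrep("A", 100),
                       length = 100L)
  expect_equal(relative_motif_positions(matches, pr), 0.5)
  # excluding the initiator methionine shifts both scales by one
  expect_equal(relative_motif_positions(matches, pr,
                                        exclude_initiator_met = TRUE),
               49 / 99)

  pr2 <- simulate_proteome(30, 100, 400,
                           planted = tibble::tibble(
                             motif_class = "canonical", count = 2L),
                           seed = 8)
  m <- scan_motifs(pr2)
  for (bs in c(0.02, 0.001, 0.13)) {
    h <- positional_distribution(m, pr2, bin_size = bs)
    expect_identical(sum(h$count), nrow(m))
  }

  # all motifs at the C-terminus land in the last bin
  prc <- tibble::tibble(accession = "C",
                        sequence = paste0(strrep("G", 95), "KFERQ"),
                        length = 100L)
  mc <- scan_motifs(prc)
  hc <- positional_distribution(mc, prc, bin_size = 0.02)
  expect_identical(hc$count[nrow(hc)], 1L)
  expect_identical(sum(hc$count), 1L)
})

test_that("uniformly planted motifs give a flat positional distribution", {
  pr <- simulate_proteome(150, 200, 400,
                          planted = tibble::tibble(motif_class = "canonical",
                                                   count = 2L),
                          seed = 13)
  m <- scan_motifs(pr)
  m <- m[m$motif_class == "canonical", ]
  h <- positional_distribution(m, pr, bin_size = 0.1)
  p <- suppressWarnings(stats::chisq.test(h$count)$p.value)
  expect_gt(p, 0.01)
})

test_that("terminal depletion compares head and tail densities", {
  pr1 <- tibble::tibble(accession = "A", sequence = strrep("A", 10000),
                        length = 10000L)
  mk <- function(rel) {
    tibble::tibble(accession = "A",
                   center = pmax(3L, pmin(9998L, round(rel * 10000))),
                   start = pmax(1L, pmin(9996L, round(rel * 10000)) - 2L))
  }
  # uniform relative positions: depletion ~ 0
  set.seed(19)
  d0 <- terminal_depletion(mk(stats::runif(20000)), pr1)
  expect_lt(abs(d0$pct_depletion), 10)

  # no motifs in the first 2.5%: exactly 100% depletion
  d100 <- terminal_depletion(mk(stats::runif(500, 0.025, 1)), pr1)
  expect_equal(d100$pct_depletion, 100)

  # planted head density at half the tail density: ~50% depletion
  rel_head <- stats::runif(300, 0, 0.025)      # density 12,000 per unit
  rel_tail <- stats::runif(23400, 0.025, 1)    # density 24,000 per unit
  d2 <- terminal_depletion(dplyr::bind_rows(mk(rel_head), mk(rel_tail)),
                           pr1)
  expect_equal(d2$pct_depletion, 50, tolerance = 0.12)

  expect_error(terminal_depletion(mk(numeric(0)), pr1),
               class = "kferq_data_error")
})

test_that("aa position frequencies align on a downstream flank and mirror Q_left", {
  mk_match <- function(pent, ori) {
    tibble::tibble(accession = "A", start = 1L, end = 5L, center = 3L,
                   pentapeptide = pent,
                   motif_class = factor("canonical",
                                        levels = levels(scan_motifs(
                                          c(x = "MKFERQ"))$motif_class)),
                   orientation = factor(ori, levels = c("Q_left", "Q_right")))
  }
  f <- aa_position_frequencies(mk_match("KFERQ", "Q_right"))
  expect_equal(f$percent[f$amino_acid == "K" & f$position == -4], 100)
  expect_equal(f$percent[f$amino_acid == "F" & f$position == -3], 100)
  expect_equal(f$percent[f$amino_acid == "E" & f$position == -2], 100)
  expect_equal(f$percent[f$amino_acid == "R" & f$position == -1], 100)

  # the mirrored Q_left motif gives the identical table
  f_mirror <- aa_position_frequencies(mk_match("QREFK", "Q_left"))
  expect_equal(f, f_mirror)

  # rows sum to 100 for occurring amino acids on simulated data
  pr <- simulate_proteome(50, 100, 200,
                          planted = tibble::tibble(motif_class = "canonical",
                                                   count = 2L),
                          seed = 23)
  fr <- aa_position_frequencies(scan_motifs(pr))
  sums <- fr |> dplyr::group_by(amino_acid) |>
    dplyr::summarise(s = sum(percent), n = sum(count))
  expect_equal(sums$s[sums$n > 0], rep(100, sum(sums$n > 0)))

  # property grouping: S/T/Y count as acidic for the phospho class
  prp <- c(A = "MKSLVQGG")  # K S L V Q: S (the acceptor) sits at -3
  fp <- property_position_frequencies(scan_motifs(prp),
                                      "phospho_generated")
  expect_equal(fp$count[fp$property == "acidic" & fp$position == -3], 1)
  expect_equal(fp$percent[fp$property == "acidic" & fp$position == -3], 100)
})

test_that("scramble_proteome preserves composition and is seed-deterministic", {
  pr <- tiny_proteins()
  sc1 <- scramble_proteome(pr, seed = 4)
  sc2 <- scramble_proteome(pr, seed = 4)
  expect_identical(sc1$sequence, sc2$sequence)
  comp <- function(x) sort(strsplit(x, "")[[1]])
  expect_true(all(mapply(function(a, b) identical(comp(a), comp(b)),
                         pr$sequence, sc1$sequence)))
  sc3 <- scramble_proteome(pr, seed = 5)
  expect_false(identical(sc1$sequence, sc3$sequence))
})

test_that("baseline comparison flags a planted composition bias", {
  # Proteome whose canonical motifs carry E at position -2 far more often
  # than scrambling would produce; the E@-2 cell must be enriched. The
  # background is uniform so the scrambled proteome still yields motifs.
  set.seed(3)
  n <- 150
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  seqs <- vapply(1:n, function(i) {
    bg <- sample(aa, 400, replace = TRUE)
    for (s0 in c(100L, 300L)) {  # planted [K/R][FILV]E[K/R]Q windows
      bg[s0:(s0 + 4)] <- c(sample(c("K", "R"), 1),
                           sample(c("F", "I", "L", "V"), 1), "E",
                           sample(c("K", "R"), 1), "Q")
    }
    paste(bg, collapse = "")
  }, character(1))
  pr <- tibble::tibble(accession = paste0("P", 1:n), sequence = seqs)
  bc <- suppressWarnings(baseline_comparison(pr, n_subsamples = 20,
                                             seed = 12))
  cell <- bc[bc$amino_acid == "E" & bc$position == -2, ]
  expect_gt(cell$ratio_mean, 1)
  expect_lt(cell$p_corrected, 0.05)
  expect_true(all(bc$p_corrected <= 1, na.rm = TRUE))
  expect_identical(nrow(bc), 32L)  # 8 motif residues x 4 positions
})

test_that("composition comparison reports per-pool percentages summing to 100", {
  pr <- tiny_proteins()
  cc <- composition_comparison(pr)
  sums <- cc |> dplyr::group_by(pool) |>
    dplyr::summarise(s = sum(percent))
  expect_equal(sums$s, c(100, 100))
  # identical pools give identical rows
  pr_same <- tibble::tibble(accession = c("A", "B"),
                            sequence = c("MKFERQAAA", "MAAAGGGPP"))
  cc2 <- composition_comparison(pr_same)
  expect_identical(nrow(cc2), 40L)
})
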