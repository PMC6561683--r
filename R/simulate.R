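## Draw one valid pentapeptide of the requested motif class. The variable
## region uses composition (basic, hydrophobic, acidic) of (2,1,1) or
## (1,2,1); the flank residue and orientation follow the class.
random_motif_pentapeptide <- function(motif_class) {
  acid_set <- if (motif_class %in% c("phospho_generated", "n_phospho")) {
    RES_PHOSPHO
  } else {
    RES_ACIDIC
  }
  flank <- switch(motif_class,
                  canonical = "Q", phospho_generated = "Q",
                  acetyl_generated = "K",
                  n_canonical = "N", n_phospho = "N",
                  abort(paste0("Cannot plant class ", motif_class, "."),
                        class = "kferq_invalid_input"))
  comp <- if (stats::runif(1) < 0.5) c(2L, 1L, 1L) else c(1L, 2L, 1L)
  res <- c(sample(RES_BASIC, comp[1], replace = TRUE),
           sample(RES_HYDROPHOBIC, comp[2], replace = TRUE),
           sample(acid_set, comp[3], replace = TRUE))
  res <- sample(res)
  pent <- if (stats::runif(1) < 0.5) paste0(flank, paste(res, collapse = ""))
          else paste0(paste(res, collapse = ""), flank)
  hit <- classify_window_matrix(pentapeptide_matrix(pent), advanced_n = TRUE)
  stopifnot(motif_class %in% hit$motif_class)
  pent
}

#' Simulate a proteome with planted KFERQ-like motifs
#'
#' Draws sequences i.i.d. from a background residue distribution (uniform
#' over the 20 standard amino acids by default, or an empirical composition)
#' and plants valid motif pentapeptides of requested classes at random,
#' non-overlapping positions (pairwise start distance >= 5), overwriting the
#' background residues. The generator re-scans its own output and asserts
#' that every planted motif is detected; chance motifs arising from the
#' background are not suppressed and are recorded separately.
#'
#' @param n_proteins Number of proteins.
#' @param min_length,max_length Uniform protein-length range.
#' @param background_freqs Optional named numeric vector of residue
#'   frequencies over (a subset of) the 20 standard amino acids; normalised
#'   to sum to 1. Set Q, K and N to zero to obtain a motif-free background.
#' @param planted Tibble with columns `motif_class` and `count` (motifs per
#'   protein) and optionally `prob` (fraction of proteins receiving them,
#'   default 1).
#' @param seed Optional seed; generation is deterministic given it.
#' @param prefix Accession prefix.
#' @return A protein tibble; `attr(, "planted")` holds the ground-truth
#'   tibble (`accession`, `start`, `motif_class`) -- see [planted_motifs()]
#'   -- and `attr(, "incidental")` the chance motifs found on re-scan.
#' @export
simulate_proteome <- function(n_proteins = 100, min_length = 150,
                              max_length = 600, background_freqs = NULL,
                              planted = NULL, seed = NULL,
                              prefix = "SYN") {
  run <- function() {
    if (is.null(background_freqs)) {
      background_freqs <- stats::setNames(rep(1, 20), AA_STANDARD)
    }
    if (!all(names(background_freqs) %in% AA_STANDARD)) {
      abort("background_freqs must be named by standard amino acids.",
            class = "kferq_invalid_input")
    }
    background_freqs <- background_freqs / sum(background_freqs)
    lens <- sample(min_length:max_length, n_proteins, replace = TRUE)
    if (min_length < 5L) {
      abort("Proteins must be at least 5 residues long.",
            class = "kferq_invalid_input")
    }
    acc <- sprintf("%s%04d", prefix, seq_len(n_proteins))
    seqs <- vapply(lens, function(L) {
      paste(sample(names(background_freqs), L, replace = TRUE,
                   prob = background_freqs), collapse = "")
    }, character(1))
    truth <- list()
    if (!is.null(planted) && nrow(planted) > 0L) {
      if (!"prob" %in% names(planted)) planted$prob <- 1
      for (i in seq_len(n_proteins)) {
        starts_taken <- integer(0)
        chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
        for (j in seq_len(nrow(planted))) {
          if (stats::runif(1) > planted$prob[[j]]) next
          for (rep_k in seq_len(planted$count[[j]])) {
            cand <- setdiff(seq_len(lens[[i]] - 4L), unlist(
              lapply(starts_taken, function(s) (s - 4L):(s + 4L))))
            if (length(cand) == 0L) {
              abort("Protein too short for the requested planted motifs.",
                    class = "kferq_invalid_input")
            }
            s <- if (length(cand) == 1L) cand else sample(cand, 1L)
            pent <- random_motif_pentapeptide(
              as.character(planted$motif_class[[j]]))
            chars[s:(s + 4L)] <- strsplit(pent, "", fixed = TRUE)[[1]]
            starts_taken <- c(starts_taken, s)
            truth[[length(truth) + 1L]] <- tibble(
              accession = acc[[i]], start = s,
              motif_class = as.character(planted$motif_class[[j]]))
          }
        }
        seqs[[i]] <- paste(chars, collapse = "")
      }
    }
    truth <- if (length(truth)) bind_rows(truth) else
      tibble(accession = character(), start = integer(),
             motif_class = character())
    out <- tibble(accession = acc, entry_name = acc, status = "Swiss-Prot",
                  protein_name = "synthetic protein",
                  gene_name = NA_character_, organism = "synthetic",
                  sequence = seqs, length = lens)
    # self-check: every planted motif must be recovered by the scanner
    advanced <- any(truth$motif_class %in% c("n_canonical", "n_phospho"))
    found <- scan_motifs(out, advanced_n = advanced,
                         flag_ubiquitylation = FALSE)
    if (nrow(truth)) {
      key_t <- paste(truth$accession, truth$start, truth$motif_class)
      key_f <- paste(found$accession, found$start, found$motif_class)
      stopifnot(all(key_t %in% key_f))
      incidental <- found[!paste(found$accession, found$start,
                                 found$motif_class) %in% key_t, ]
    } else {
      incidental <- found
    }
    attr(out, "planted") <- truth
    attr(out, "incidental") <- as_tibble(incidental)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Ground-truth planted motifs of a simulated proteome
#'
#' @param proteome Result of [simulate_proteome()].
#' @return Tibble with `accession`, `start`, `motif_class`.
#' @export
planted_motifs <- function(proteome) {
  attr(proteome, "planted") %||%
    abort("No planted ground truth attached.", class = "kferq_invalid_input")
}

#' Simulate aligned ortholog families with controlled motif retention
#'
#' Each family starts from a reference ("human") sequence carrying one
#' canonical motif. Every species in the species table independently: has no
#' ortholog with probability `p_no_ortholog`; otherwise retains the motif
#' intact (conserved) with its group's retention probability; otherwise the
#' motif is lost -- with probability `p_partial` the flanking Q is swapped to
#' K, turning the motif acetyl-generated (a different class, i.e. partial
#' conservation), and otherwise the acidic residue is replaced by glycine,
#' destroying the motif. Non-motif positions accumulate random substitutions
#' at rate `background_sub_rate`. Alignments are gapless by construction.
#'
#' @param n_families Number of families.
#' @param n_able,n_unable Number of CMA-able / CMA-unable species.
#' @param retention Named vector `c(able = , unable = )` of motif-retention
#'   probabilities.
#' @param p_no_ortholog Probability a species lacks an ortholog; a named
#'   vector `c(able = , unable = )` or a single value for both groups. The
#'   default makes missing orthologs much more common among CMA-unable
#'   species, which drives their scores negative.
#' @param p_partial Probability a lost motif degrades to a different class
#'   rather than to no motif.
#' @param seq_length Length of the simulated proteins.
#' @param background_sub_rate Per-residue substitution rate outside the
#'   motif.
#' @param seed Optional seed.
#' @return A list of tibbles: `families` (`accession`, `species`,
#'   `aligned_seq`, including the `"human"` reference rows), `motifs` (one
#'   canonical human motif per family), `species` (`species`, `cma_able`)
#'   and `truth` (the per-species classification actually generated).
#' @export
simulate_ortholog_families <- function(n_families = 100, n_able = 25,
                                       n_unable = 25,
                                       retention = c(able = 0.9,
                                                     unable = 0.1),
                                       p_no_ortholog = c(able = 0.1,
                                                         unable = 0.5),
                                       p_partial = 0.5,
                                       seq_length = 60,
                                       background_sub_rate = 0.05,
                                       seed = NULL) {
  if (length(p_no_ortholog) == 1L && is.null(names(p_no_ortholog))) {
    p_no_ortholog <- c(able = p_no_ortholog, unable = p_no_ortholog)
  }
  run <- function() {
    species_tbl <- tibble(
      species = c(sprintf("able%02d", seq_len(n_able)),
                  sprintf("unable%02d", seq_len(n_unable))),
      cma_able = rep(c(TRUE, FALSE), c(n_able, n_unable)))
    # background without Q/K/N/S/T/Y/D/E so classification at the motif
    # columns is fully controlled by the planted pentapeptide
    bg <- setdiff(AA_STANDARD,
                  c("Q", "K", "N", RES_PHOSPHO, RES_ACIDIC))
    fams <- list(); motifs <- list(); truth <- list()
    for (f in seq_len(n_families)) {
      acc <- sprintf("FAM%04d", f)
      start <- sample(seq(1L, seq_length - 4L), 1L)
      human <- sample(bg, seq_length, replace = TRUE)
      pent <- random_motif_pentapeptide("canonical")
      human[start:(start + 4L)] <- strsplit(pent, "", fixed = TRUE)[[1]]
      flank_first <- human[[start]] == "Q"
      flank_pos <- if (flank_first) start else start + 4L
      acid_pos <- start - 1L + which(human[start:(start + 4L)] %in%
                                       RES_ACIDIC)[1]
      rows <- list(tibble(accession = acc, species = "human",
                          aligned_seq = paste(human, collapse = "")))
      for (s in seq_len(nrow(species_tbl))) {
        sp <- species_tbl$species[[s]]
        grp <- if (species_tbl$cma_able[[s]]) "able" else "unable"
        u <- stats::runif(1)
        if (u < p_no_ortholog[[grp]]) {
          truth[[length(truth) + 1L]] <- tibble(
            accession = acc, species = sp, classification = "no_ortholog")
          next
        }
        sq <- human
        mut <- stats::runif(seq_length) < background_sub_rate
        mut[start:(start + 4L)] <- FALSE
        sq[mut] <- sample(bg, sum(mut), replace = TRUE)
        if (stats::runif(1) < retention[[grp]]) {
          cls <- "conserved"
        } else if (stats::runif(1) < p_partial) {
          sq[[flank_pos]] <- "K"   # Q -> K: acetyl-generated, other class
          cls <- "partial"
        } else {
          sq[[acid_pos]] <- "G"    # no acidic residue left: no motif
          cls <- "absent_motif"
        }
        rows[[length(rows) + 1L]] <- tibble(
          accession = acc, species = sp,
          aligned_seq = paste(sq, collapse = ""))
        truth[[length(truth) + 1L]] <- tibble(
          accession = acc, species = sp, classification = cls)
      }
      fams[[f]] <- bind_rows(rows)
      motifs[[f]] <- tibble(accession = acc, start = start,
                            motif_class = "canonical")
    }
    list(families = bind_rows(fams), motifs = bind_rows(motifs),
         species = species_tbl, truth = bind_rows(truth))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a term-to-protein annotation table with planted enrichment
#'
#' Background terms annotate uniform random protein subsets. Planted terms
#' oversample proteins of a target group: group members receive sampling
#' weight `relative_risk`, all others weight 1.
#'
#' @param groups Tibble with `accession` and `group` (e.g. the
#'   `hierarchy_group` column of [summarize_motifs()]).
#' @param n_terms Number of background terms.
#' @param term_size Proteins annotated per term.
#' @param planted Optional tibble with `group` and `relative_risk` (one
#'   planted term per row).
#' @param seed Optional seed.
#' @return Annotation tibble (`term`, `accession`); `attr(, "planted")`
#'   records the planted term ids, target groups and relative risks.
#' @export
simulate_annotations <- function(groups, n_terms = 30, term_size = 30,
                                 planted = NULL, seed = NULL) {
  if (term_size < 1L || term_size > nrow(groups)) {
    abort("`term_size` must be between 1 and the number of proteins.",
          class = "kferq_invalid_input")
  }
  run <- function() {
    acc <- groups$accession
    rows <- purrr::map(seq_len(n_terms), function(i) {
      tibble(term = sprintf("TERM%03d", i),
             accession = sample(acc, term_size))
    })
    truth <- tibble(term = character(), group = character(),
                    relative_risk = numeric())
    if (!is.null(planted) && nrow(planted) > 0L) {
      for (j in seq_len(nrow(planted))) {
        w <- ifelse(groups$group == planted$group[[j]],
                    planted$relative_risk[[j]], 1)
        id <- sprintf("PLANTED%02d", j)
        rows[[length(rows) + 1L]] <- tibble(
          term = id, accession = sample(acc, term_size, prob = w))
        truth <- bind_rows(truth, tibble(
          term = id, group = as.character(planted$group[[j]]),
          relative_risk = planted$relative_risk[[j]]))
      }
    }
    out <- bind_rows(rows)
    attr(out, "planted") <- truth
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate per-residue RSA tracks with boosted exposure at motif offsets
#'
#' Residues are exposed independently at `baseline_rate`, except residues
#' sitting at the configured offsets from a motif centre, which are exposed
#' at `boost_rate`. Numeric RSA values are drawn consistently with the
#' binary state (exposed: uniform on \[0.25, 1\]; buried: uniform on
#' \[0, 0.25)).
#'
#' @param proteins Protein tibble.
#' @param matches Motif matches whose offsets are boosted.
#' @param baseline_rate Background exposure probability.
#' @param boost_offsets Integer offsets (relative to motif centres) whose
#'   exposure probability is boosted.
#' @param boost_rate Exposure probability at boosted offsets.
#' @param seed Optional seed.
#' @return RSA track tibble (`accession`, `position`, `rsa`, `exposed`).
#' @export
simulate_rsa_tracks <- function(proteins, matches, baseline_rate = 0.4,
                                boost_offsets = c(-2L, 2L),
                                boost_rate = 0.9, seed = NULL) {
  proteins <- as_protein_tbl(proteins)
  run <- function() {
    tracks <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
      L <- proteins$length[[i]]
      acc <- proteins$accession[[i]]
      rate <- rep(baseline_rate, L)
      ctr <- matches$center[matches$accession == acc]
      if (length(ctr) && length(boost_offsets)) {
        pos <- as.vector(outer(ctr, boost_offsets, `+`))
        pos <- pos[pos >= 1L & pos <= L]
        rate[pos] <- boost_rate
      }
      exposed <- stats::runif(L) < rate
      rsa <- ifelse(exposed, stats::runif(L, 0.25, 1),
                    stats::runif(L, 0, 0.25 - 1e-9))
      tibble(accession = acc, position = seq_len(L), rsa = rsa,
             exposed = exposed)
    })
    tracks
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
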