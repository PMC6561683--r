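parse_uniprot_headers <- function(headers) {
  m <- stringr::str_match(headers, "^(sp|tr)\\|([^|]+)\\|(\\S+)\\s*(.*)$")
  uniprot <- !is.na(m[, 1])
  desc <- ifelse(uniprot, m[, 5], "")
  first_tok <- stringr::str_split_i(headers, "\\s+", 1)
  tibble(
    accession = ifelse(uniprot, m[, 3], first_tok),
    entry_name = ifelse(uniprot, m[, 4], first_tok),
    status = dplyr::case_when(m[, 2] == "sp" ~ "Swiss-Prot",
                              m[, 2] == "tr" ~ "TrEMBL",
                              .default = "unknown"),
    protein_name = dplyr::na_if(
      stringr::str_trim(stringr::str_remove(desc, "\\s+[A-Z]{2}=.*$")), ""),
    gene_name = stringr::str_match(desc, "GN=(\\S+)")[, 2],
    organism = stringr::str_match(desc, "OS=(.*?)(?: [A-Z]{2}=|$)")[, 2]
  )
}

#' Read a protein FASTA file
#'
#' Reads plain or UniProt-style FASTA (`sp|ACC|ENTRY Protein name OS=...
#' GN=...` headers). The database tag sets the review status (sp =
#' Swiss-Prot, tr = TrEMBL); plain headers use the first token as accession
#' and entry name with status "unknown". Lowercase sequence is uppercased
#' with a warning; non-standard residue letters (X, B, Z, J, U, O) are kept
#' but warned about -- motif windows containing them never match.
#'
#' @param path FASTA file.
#' @param reviewed_only Keep only Swiss-Prot (reviewed) entries.
#' @return A tibble with `accession`, `entry_name`, `status`,
#'   `protein_name`, `gene_name`, `organism`, `sequence` and `length`, in
#'   file order.
#' @export
read_proteome <- function(path, reviewed_only = FALSE) {
  # BStringSet preserves case so lowercase input can be reported
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("No sequences in ", path, "."), class = "kferq_data_error")
  }
  out <- parse_uniprot_headers(names(set))
  dup <- unique(out$accession[duplicated(out$accession)])
  if (length(dup)) {
    abort(paste0("Duplicate accessions in ", path, ": ",
                 paste(utils::head(dup, 10), collapse = ", ")),
          class = "kferq_data_error")
  }
  seqs <- as.character(set)
  lower <- seqs != toupper(seqs)
  if (any(lower)) {
    warn(paste0("Lowercase residues uppercased in: ",
                paste(utils::head(out$accession[lower], 10),
                      collapse = ", ")))
    seqs <- toupper(seqs)
  }
  nonstd <- !stringr::str_detect(
    seqs, paste0("^[", paste(AA_STANDARD, collapse = ""), "]*$"))
  if (any(nonstd)) {
    warn(paste0("Non-standard residue letters in: ",
                paste(utils::head(out$accession[nonstd], 10),
                      collapse = ", ")))
  }
  out$sequence <- unname(seqs)
  out$length <- nchar(out$sequence)
  if (reviewed_only) out <- out |> filter(.data$status == "Swiss-Prot")
  out
}

#' Write a protein tibble to FASTA
#'
#' Reconstructs UniProt-style headers for records with a known review
#' status, so that [read_proteome()] round-trips accessions, metadata and
#' sequences.
#'
#' @param proteins Protein tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteins, path) {
  proteins <- as_protein_tbl(proteins)
  db <- dplyr::case_when(proteins$status %in% "Swiss-Prot" ~ "sp",
                         proteins$status %in% "TrEMBL" ~ "tr",
                         .default = NA_character_)
  opt <- function(prefix, x) ifelse(is.na(x), "", paste0(" ", prefix, x))
  header <- ifelse(
    is.na(db), proteins$accession,
    paste0(db, "|", proteins$accession, "|",
           proteins$entry_name %||% proteins$accession,
           ifelse(is.na(proteins$protein_name %||% NA), "",
                  paste0(" ", proteins$protein_name)),
           opt("OS=", proteins$organism %||% rep(NA, nrow(proteins))),
           opt("GN=", proteins$gene_name %||% rep(NA, nrow(proteins)))))
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- header
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write the motif finder report
#'
#' One row per motif match with the eight report columns: entry name, review
#' status, protein names, gene name, protein length, motif composition (the
#' pentapeptide), motif position (1-based start residue) and motif type.
#' Rows are ordered by accession, start and class, so the output is
#' byte-identical across runs on the same input.
#'
#' @param matches Result of [scan_motifs()].
#' @param proteins Protein tibble covering every matched accession.
#' @param path Output TSV; when `NULL` the report tibble is returned
#'   unwritten.
#' @return The report tibble, invisibly when written.
#' @export
write_finder_report <- function(matches, proteins, path = NULL) {
  proteins <- as_protein_tbl(proteins)
  unknown <- setdiff(unique(matches$accession), proteins$accession)
  if (length(unknown)) {
    abort(paste0("Matches reference unknown protein(s): ",
                 paste(utils::head(unknown, 10), collapse = ", ")),
          class = "kferq_data_error")
  }
  fill_col <- function(col, default) {
    if (is.null(proteins[[col]])) rep(default, nrow(proteins))
    else proteins[[col]]
  }
  meta <- tibble(accession = proteins$accession,
                 entry_name = fill_col("entry_name", NA_character_),
                 status = fill_col("status", "unknown"),
                 protein_names = fill_col("protein_name", NA_character_),
                 gene_name = fill_col("gene_name", NA_character_),
                 length = proteins$length)
  report <- matches |>
    arrange(match(.data$accession, proteins$accession), .data$start,
            as.integer(.data$motif_class)) |>
    left_join(meta, by = "accession") |>
    transmute(entry_name = dplyr::coalesce(.data$entry_name,
                                           .data$accession),
              status = .data$status,
              protein_names = .data$protein_names,
              gene_name = .data$gene_name,
              length = .data$length,
              motif_composition = .data$pentapeptide,
              motif_position = .data$start,
              motif_type = as.character(.data$motif_class))
  if (!is.null(path)) {
    readr::write_tsv(report, path, na = "")
    return(invisible(report))
  }
  report
}

#' Read a term-to-protein annotation table
#'
#' Accepts either a two-column TSV (`term_id`, `protein_id`; a header row is
#' detected and skipped) or GAF 2.x (comment lines starting with `!`;
#' columns 2 and 5 used as protein id and term).
#'
#' @param path Annotation file.
#' @param background Optional protein-id vector; annotations for unresolved
#'   ids are dropped with a message.
#' @return A tibble with `term` and `accession` (distinct rows).
#' @export
read_annotations <- function(path, background = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort(paste0("Empty annotation file: ", path),
          class = "kferq_data_error")
  }
  body <- lines[!startsWith(lines, "!")]
  fields <- stringr::str_split(body, "\t")
  n_fields <- lengths(fields)
  gaf <- any(startsWith(lines, "!")) || all(n_fields >= 15L)
  if (gaf) {
    if (any(n_fields < 5L)) {
      abort("Malformed GAF line (need >= 5 columns).",
            class = "kferq_data_error")
    }
    out <- tibble(term = vapply(fields, `[[`, "", 5L),
                  accession = vapply(fields, `[[`, "", 2L))
  } else {
    if (any(n_fields < 2L)) {
      abort("Annotation TSV needs two columns (term, protein).",
            class = "kferq_data_error")
    }
    out <- tibble(term = vapply(fields, `[[`, "", 1L),
                  accession = vapply(fields, `[[`, "", 2L))
    if (out$term[[1]] %in% c("term", "term_id")) out <- out[-1L, ]
  }
  out <- distinct(out)
  if (!is.null(background)) {
    drop <- !out$accession %in% background
    if (any(drop)) {
      inform(paste0(sum(drop), " annotation row(s) with unresolved protein ",
                    "ids were dropped."))
      out <- out[!drop, ]
    }
  }
  out
}

#' Read a species table with CMA-ability flags
#'
#' @param path TSV with columns `species` and `cma_able` (logical or 0/1).
#' @return A tibble with `species` (unique) and logical `cma_able`.
#' @export
read_species_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species", "cma_able") %in% names(out))) {
    abort("Species table needs `species` and `cma_able` columns.",
          class = "kferq_data_error")
  }
  if (anyDuplicated(out$species)) {
    abort("Species names must be unique.", class = "kferq_data_error")
  }
  flag <- as.logical(out$cma_able)
  num <- suppressWarnings(as.numeric(out$cma_able))
  flag[is.na(flag) & !is.na(num)] <- num[is.na(flag) & !is.na(num)] != 0
  if (anyNA(flag)) {
    abort("`cma_able` must be logical or 0/1.", class = "kferq_data_error")
  }
  out$cma_able <- flag
  as_tibble(out[c("species", "cma_able")])
}
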