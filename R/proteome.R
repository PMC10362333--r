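#' Load a proteome from a FASTA file
#'
#' Reads protein sequences and splits UniProt-style headers
#' (`db|ACCESSION|ENTRY description`) into accession, entry name and
#' description; for any other header style the first whitespace-delimited
#' token becomes the accession. Sequences are upper-cased and validated
#' against the tolerated alphabet (the 20 standard residues plus X/U/B/Z).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `entry_name`, `description`
#'   and `sequence`, one row per proteome entry. Isoform entries are kept
#'   as independent records.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P0TEST|TEST_HUMAN demo", "MDEVDSK"), f)
#' load_proteome(f)
#' @export
load_proteome <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  parsed <- parse_fasta_headers(headers)
  sequence <- toupper(as.character(seqs))
  names(sequence) <- NULL
  if (any(nchar(sequence) == 0)) {
    stop("zero-length sequence for: ",
         paste(parsed$accession[nchar(sequence) == 0], collapse = ", "))
  }
  bad <- vapply(sequence, function(s) {
    offenders <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), aa_tolerated())
    paste(offenders, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop("sequence for ", parsed$accession[i],
         " contains characters outside the tolerated alphabet: ", bad[i])
  }
  dup <- parsed$accession[duplicated(parsed$accession)]
  if (length(dup) > 0) {
    stop("duplicate accession(s) in proteome: ",
         paste(unique(dup), collapse = ", "))
  }
  tibble(
    accession = parsed$accession,
    entry_name = parsed$entry_name,
    description = parsed$description,
    sequence = sequence
  )
}

parse_fasta_headers <- function(headers) {
  uniprot <- grepl("^[A-Za-z]{2,3}\\|[^|]+\\|\\S+", headers)
  accession <- entry_name <- description <- character(length(headers))
  if (any(uniprot)) {
    h <- headers[uniprot]
    accession[uniprot] <- sub("^[A-Za-z]{2,3}\\|([^|]+)\\|.*$", "\\1", h)
    entry_name[uniprot] <- sub("^[A-Za-z]{2,3}\\|[^|]+\\|(\\S+).*$", "\\1", h)
    description[uniprot] <- trimws(sub("^[A-Za-z]{2,3}\\|[^|]+\\|\\S+", "", h))
  }
  if (any(!uniprot)) {
    h <- headers[!uniprot]
    accession[!uniprot] <- sub("\\s.*$", "", h)
    entry_name[!uniprot] <- NA_character_
    description[!uniprot] <- trimws(sub("^\\S+", "", h))
  }
  description[!nzchar(description)] <- NA_character_
  list(accession = accession, entry_name = entry_name, description = description)
}

#' Write a proteome back to FASTA
#'
#' Headers are `>accession description` (description omitted when missing),
#' so reloading with [load_proteome()] round-trips the accession-to-sequence
#' map exactly.
#'
#' @param proteome A proteome tibble as returned by [load_proteome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  check_proteome(proteome)
  aa <- Biostrings::AAStringSet(proteome$sequence)
  desc <- proteome$description
  names(aa) <- ifelse(is.na(desc) | !nzchar(desc),
                      proteome$accession,
                      paste(proteome$accession, desc))
  Biostrings::writeXStringSet(aa, filepath = path, width = 60)
  invisible(path)
}

check_proteome <- function(proteome) {
  needed <- c("accession", "sequence")
  if (!is.data.frame(proteome) || !all(needed %in% names(proteome))) {
    stop("`proteome` must be a data frame with columns ",
         paste(needed, collapse = ", "))
  }
  if (anyDuplicated(proteome$accession)) stop("duplicate accessions in proteome")
  invisible(proteome)
}

protein_sequence <- function(proteome, accession) {
  i <- match(accession, proteome$accession)
  if (anyNA(i)) {
    stop("accession(s) not in proteome: ",
         paste(accession[is.na(i)], collapse = ", "))
  }
  proteome$sequence[i]
}

#' Load protein processing annotations
#'
#' Reads a tab-delimited table of per-protein maturation features derived
#' from UniProt-style annotation: initiator methionine, signal peptide,
#' transit peptide, propeptide and mature chain records. Coordinates are
#' 1-based inclusive residue indices.
#'
#' Rows that reference accessions absent from `proteome` are dropped (their
#' count is reported with a message); rows with out-of-range coordinates or
#' an unknown `feature_type` are rejected and returned in the `rejected`
#' attribute.
#'
#' @param path Path to a TSV file with columns `accession`, `feature_type`,
#'   `start`, `end`.
#' @param proteome A proteome tibble used to validate accessions and
#'   coordinate ranges.
#' @return A tibble of accepted annotations with attributes
#'   `rejected` (a tibble of rejected rows with a `reason` column) and
#'   `n_dropped_missing` (rows whose accession was not in the proteome).
#' @export
load_annotations <- function(path, proteome) {
  check_proteome(proteome)
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           accession = readr::col_character(),
                           feature_type = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer()
                         ))
  required <- c("accession", "feature_type", "start", "end")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  known_types <- c("init_met", "signal_peptide", "transit_peptide",
                   "propeptide", "chain")

  present <- ann$accession %in% proteome$accession
  n_dropped <- sum(!present)
  if (n_dropped > 0) {
    message(n_dropped, " annotation row(s) dropped: accession not in proteome")
  }
  ann <- ann[present, , drop = FALSE]

  plen <- nchar(protein_sequence(proteome, ann$accession))
  reason <- rep(NA_character_, nrow(ann))
  reason[!(ann$feature_type %in% known_types)] <- "unknown feature_type"
  bad_coord <- is.na(ann$start) | is.na(ann$end) |
    ann$start < 1 | ann$start > ann$end | ann$end > plen
  reason[is.na(reason) & bad_coord] <- "out-of-range coordinates"
  bad_init <- ann$feature_type == "init_met" & !(ann$start == 1 & ann$end == 1)
  reason[is.na(reason) & bad_init] <- "init_met must span residue 1 only"

  rejected <- ann[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " annotation row(s) rejected (see attr 'rejected')")
  }
  out <- as_tibble(ann[is.na(reason), , drop = FALSE])
  attr(out, "rejected") <- as_tibble(rejected)
  attr(out, "n_dropped_missing") <- n_dropped
  out
}

#' Load a table of known cleavage sites
#'
#' Reads a TSV export emulating degradomics databases (MEROPS, TopFind,
#' CASBAH, DegraBase): one row per reported cleavage with the protein
#' accession and the P1 residue position (the residue preceding the cleaved
#' bond).
#'
#' @param path Path to a TSV file with columns `accession`, `p1_position`
#'   and optionally `source`.
#' @param proteome Optional proteome tibble; when supplied, rows with
#'   accessions absent from the proteome or with `p1_position` outside
#'   `[1, length - 1]` are dropped with a message.
#' @return A tibble with columns `accession`, `p1_position`, `source`.
#' @export
load_known_sites <- function(path, proteome = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("accession", "p1_position")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("known-site table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"source" %in% names(x)) x$source <- basename(path)
  x$p1_position <- as.integer(x$p1_position)
  if (!is.null(proteome)) {
    check_proteome(proteome)
    keep <- x$accession %in% proteome$accession
    if (any(keep)) {
      plen <- nchar(protein_sequence(proteome, x$accession[keep]))
      ok <- x$p1_position[keep] >= 1 & x$p1_position[keep] < plen
      keep[keep] <- ok
    }
    if (any(!keep)) {
      message(sum(!keep), " known-site row(s) dropped (missing accession or ",
              "out-of-range position)")
    }
    x <- x[keep, , drop = FALSE]
  }
  as_tibble(x[, c("accession", "p1_position", "source")])
}
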