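#' Map a peptide to all matching proteome positions
#'
#' Exact substring matching of a peptide against every protein in the
#' proteome, optionally folding isoleucine and leucine together (the two
#' are isobaric and indistinguishable by standard fragmentation).
#'
#' @param peptide Peptide sequence string.
#' @param proteome Proteome tibble.
#' @param il_equivalent Fold I and L before matching?
#' @param min_length Minimum peptide length accepted for mapping
#'   (default 5); shorter queries are an error because they map
#'   promiscuously.
#' @return A tibble with columns `accession`, `start`, `end` (possibly
#'   zero rows).
#' @export
match_peptide <- function(peptide, proteome, il_equivalent = FALSE,
                          min_length = 5L) {
  check_proteome(proteome)
  stopifnot(is.character(peptide), length(peptide) == 1)
  if (nchar(peptide) < min_length) {
    stop("peptide shorter than the mapping floor of ", min_length, " residues")
  }
  query <- peptide
  subject <- proteome$sequence
  if (il_equivalent) {
    query <- gsub("I", "L", query, fixed = TRUE)
    subject <- gsub("I", "L", subject, fixed = TRUE)
  }
  hits <- gregexpr(query, subject, fixed = TRUE)
  rows <- lapply(seq_along(hits), function(i) {
    s <- hits[[i]]
    if (s[1] == -1) return(NULL)
    tibble(accession = proteome$accession[i],
           start = as.integer(s),
           end = as.integer(s) + nchar(peptide) - 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(accession = character(0), start = integer(0), end = integer(0))
  }
  out
}

nterm_state_of <- function(nterm_mod) {
  dplyr::case_when(
    nterm_mod %in% c("dimethyl_light", "dimethyl_heavy") ~ "free_labeled",
    nterm_mod == "acetyl" ~ "acetylated",
    TRUE ~ "free_unlabeled"
  )
}

# Category of one (peptide, single match) pair. Precedence:
#   start 1 -> ORF_start1; start 2 on a Met-initiated protein -> ORF_start2
#   (an ORF position is ORF regardless of label state);
#   otherwise internal when both termini are consistent with the stated
#   protease (NET = 2) AND the alpha-amine is free and unlabeled;
#   everything else is a neo N-terminus.
classify_one <- function(sequence, start, end, nterm_state, enzyme) {
  n <- nchar(sequence)
  if (start == 1L) return("ORF_start1")
  if (start == 2L) {
    return(if (substr(sequence, 1, 1) == "M") "ORF_start2" else "neo")
  }
  nt_enzymatic <- switch(enzyme,
    LysN = substr(sequence, start, start) == "K",
    trypsin_argc = substr(sequence, start - 1L, start - 1L) == "R",
    FALSE)
  ct_enzymatic <- switch(enzyme,
    LysN = end == n || substr(sequence, end + 1L, end + 1L) == "K",
    trypsin_argc = end == n || substr(sequence, end, end) == "R",
    FALSE)
  if (nt_enzymatic && ct_enzymatic && nterm_state == "free_unlabeled") {
    "internal"
  } else {
    "neo"
  }
}

#' Classify N-terminal observations against the proteome
#'
#' Maps every observation's peptide to the proteome and assigns one of the
#' exclusive categories `ORF_start1` (initiator Met retained),
#' `ORF_start2` (Met excised), `neo` (protease-generated N terminus),
#' `internal` (both termini enzymatic, free unlabeled alpha-amine) or
#' `unmatched`. Peptides matching multiple proteins are classified per
#' match; if all matches agree the category is kept (with the match count
#' recorded), otherwise the record is `ambiguous`.
#'
#' @param observations Observation tibble from [read_psm_tsv()] /
#'   [read_pepxml()] or the simulator.
#' @param proteome Proteome tibble.
#' @param il_equivalent Fold I/L during mapping?
#' @param min_length Mapping length floor passed to [match_peptide()].
#' @return A tibble: the observations plus `accession`, `start`, `end`,
#'   `category`, `nterm_state`, `met_excised`, `p1_residue`,
#'   `window_P4_P4p` and `n_matches`. For ambiguous or unmatched records
#'   the positional fields are `NA`.
#' @export
classify_observations <- function(observations, proteome,
                                  il_equivalent = FALSE, min_length = 5L) {
  check_proteome(proteome)
  stopifnot(nrow(observations) >= 1)
  states <- nterm_state_of(observations$nterm_mod)

  res <- vector("list", nrow(observations))
  for (i in seq_len(nrow(observations))) {
    pep <- observations$peptide[i]
    matches <- match_peptide(pep, proteome, il_equivalent = il_equivalent,
                             min_length = min_length)
    if (nrow(matches) == 0) {
      res[[i]] <- tibble(accession = NA_character_, start = NA_integer_,
                         end = NA_integer_, category = "unmatched",
                         n_matches = 0L)
      next
    }
    cats <- vapply(seq_len(nrow(matches)), function(j) {
      classify_one(protein_sequence(proteome, matches$accession[j]),
                   matches$start[j], matches$end[j], states[i],
                   observations$enzyme[i])
    }, character(1))
    if (length(unique(cats)) == 1L) {
      res[[i]] <- tibble(accession = matches$accession[1],
                         start = matches$start[1], end = matches$end[1],
                         category = cats[1], n_matches = nrow(matches))
    } else {
      res[[i]] <- tibble(accession = NA_character_, start = NA_integer_,
                         end = NA_integer_, category = "ambiguous",
                         n_matches = nrow(matches))
    }
  }
  pos <- dplyr::bind_rows(res)
  out <- dplyr::bind_cols(observations, pos)
  out$nterm_state <- states
  out$met_excised <- dplyr::case_when(
    out$category == "ORF_start1" ~ FALSE,
    out$category == "ORF_start2" ~ TRUE,
    TRUE ~ NA
  )
  out$p1_residue <- ifelse(
    !is.na(out$start) & out$start > 1,
    substr(protein_sequence(proteome,
                            ifelse(is.na(out$accession),
                                   proteome$accession[1], out$accession)),
           pmax(out$start - 1L, 1L), pmax(out$start - 1L, 1L)),
    NA_character_)
  out$p1_residue[is.na(out$accession)] <- NA_character_
  out$window_P4_P4p <- NA_character_
  has_site <- !is.na(out$start) & out$start > 1
  if (any(has_site)) {
    out$window_P4_P4p[has_site] <- vapply(which(has_site), function(i) {
      extract_window(protein_sequence(proteome, out$accession[i]),
                     out$start[i] - 1L)
    }, character(1))
  }
  out
}

#' Labeling efficiency of alpha- and epsilon-amines
#'
#' Computes, over PSMs, the fraction of N-terminal alpha-amines that were
#' isotopically dimethylated, the fraction naturally blocked by
#' acetylation, and the fraction of lysine side-chain epsilon-amines that
#' were (undesirably) dimethylated. In an efficient N-terminal-specific
#' labeling experiment the first two together exceed 0.95 while the third
#' stays below 0.05.
#'
#' @param observations Observation tibble.
#' @return A list with `alpha_labeled_fraction`,
#'   `alpha_acetylated_fraction` and `epsilon_labeled_fraction`.
#' @export
labeling_efficiency <- function(observations) {
  if (nrow(observations) == 0) stop("no observations")
  state <- nterm_state_of(observations$nterm_mod)
  n_k_total <- sum(stringr::str_count(observations$peptide, stringr::fixed("K")))
  n_k_labeled <- sum(vapply(observations$lysine_mods, function(m) {
    sum(m$mod %in% c("dimethyl_light", "dimethyl_heavy"))
  }, numeric(1)))
  list(
    alpha_labeled_fraction = mean(state == "free_labeled"),
    alpha_acetylated_fraction = mean(state == "acetylated"),
    epsilon_labeled_fraction = if (n_k_total == 0) NA_real_ else
      n_k_labeled / n_k_total
  )
}

#' Census of classified N-terminal peptides
#'
#' Counts classified records by category, N-terminal state and Met-excision
#' status, at PSM level and at peptide level (distinct
#' peptide/position/state combinations), and compares the proteins whose
#' free and acetylated N termini each enzyme identified.
#'
#' @param classified Output of [classify_observations()].
#' @return A list with `psm` and `peptide` count tables (each partitioning
#'   its input) and `protein_method` (per enzyme x N-terminal state protein
#'   counts with shared/unique breakdown).
#' @export
nterm_census <- function(classified) {
  stopifnot(nrow(classified) >= 1)
  key <- c("category", "nterm_state", "met_excised")
  psm <- classified %>%
    dplyr::count(dplyr::across(dplyr::all_of(key)), name = "n")
  pep <- classified %>%
    dplyr::distinct(.data$peptide, .data$accession, .data$start,
                    .data$category, .data$nterm_state, .data$met_excised) %>%
    dplyr::count(dplyr::across(dplyr::all_of(key)), name = "n")

  term <- classified %>%
    dplyr::filter(.data$category %in% c("ORF_start1", "ORF_start2", "neo"),
                  !is.na(.data$accession))
  protein_method <- NULL
  if (nrow(term) > 0) {
    sets <- term %>%
      dplyr::mutate(state_class = ifelse(.data$nterm_state == "acetylated",
                                         "acetylated", "free")) %>%
      dplyr::distinct(.data$enzyme, .data$state_class, .data$accession)
    protein_method <- sets %>%
      dplyr::group_by(.data$state_class, .data$accession) %>%
      dplyr::summarise(enzymes = paste(sort(unique(.data$enzyme)),
                                       collapse = "+"),
                       .groups = "drop") %>%
      dplyr::count(.data$state_class, .data$enzymes, name = "n_proteins")
  }
  list(psm = psm, peptide = pep, protein_method = protein_method)
}

#' Merge identifications from per-modification searches
#'
#' Database searches for acetylated, dimethylated and otherwise modified N
#' termini are run separately; this merges their observation tables into a
#' unified list. Records identical in (run, spectrum, peptide, N-terminal
#' modification) are deduplicated with provenance retained; the same
#' spectrum assigned differently by two searches is flagged as a conflict
#' and both records are kept with a warning.
#'
#' @param ... Observation tibbles, optionally named by search.
#' @return A tibble with added columns `search` (provenance, collapsed for
#'   duplicates) and `conflict`.
#' @export
merge_searches <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(inputs) <- paste0("search", seq_along(inputs))
  }
  all <- dplyr::bind_rows(inputs, .id = "search")
  key <- c("run_id", "spectrum_id", "peptide", "nterm_mod_mass")
  merged <- all %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
  provenance <- all %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) %>%
    dplyr::summarise(search = paste(sort(unique(.data$search)), collapse = "+"),
                     .groups = "drop")
  merged$search <- NULL
  merged <- dplyr::left_join(merged, provenance, by = key)
  spectra <- merged %>%
    dplyr::count(.data$run_id, .data$spectrum_id, name = "n_assignments")
  merged <- dplyr::left_join(merged, spectra, by = c("run_id", "spectrum_id"))
  merged$conflict <- merged$n_assignments > 1L
  merged$n_assignments <- NULL
  if (any(merged$conflict)) {
    warning(sum(merged$conflict), " record(s) from spectra with conflicting ",
            "assignments across searches were kept and flagged")
  }
  merged
}
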