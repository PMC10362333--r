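# Stage-count logging shared by the winnowing pipelines: every stage is a
# set-shrinking step, so n_out <= n_in always holds.
stage_log <- function(log, stage, n_in, n_out) {
  dplyr::bind_rows(log, tibble(stage = stage, n_in = n_in, n_out = n_out))
}

#' Winnow quantified neo-N termini to credible caspase cleavage sites
#'
#' Applies the caspase candidate-selection rule: keep neo-N-terminal
#' records that either meet the fold-change threshold or were identified
#' only in the treated samples, and whose P1 residue belongs to the
#' caspase specificity set (Asp, optionally extended with Glu). In
#' `"strict"` mode failing records are removed; in `"report-all"` mode
#' every record is returned with its filter flags set.
#'
#' @param records Quantified records (see [aggregate_nterm()] and
#'   [call_significant()]) restricted internally to category `neo`; must
#'   carry `p1_residue`.
#' @param p1_set Caspase P1 specificity set, default `c("D", "E")`.
#' @param mode `"strict"` or `"report-all"`.
#' @return A tibble of winnowed sites with `p1_position`, `neo_start` and
#'   the flags `caspase_p1`, `passes_ratio`, `treated_only`, `keep`; the
#'   per-stage input/output counts are attached as the `stages` attribute.
#' @export
caspase_winnow <- function(records, p1_set = c("D", "E"),
                           mode = c("strict", "report-all")) {
  mode <- match.arg(mode)
  if (!"significant" %in% names(records)) {
    records <- call_significant(records)
  }
  neo <- records %>% dplyr::filter(.data$category == "neo")
  sites <- neo %>%
    dplyr::mutate(
      p1_position = .data$start - 1L,
      neo_start = .data$start,
      caspase_p1 = .data$p1_residue %in% p1_set,
      passes_ratio = !is.na(.data$log2_ratio) & .data$significant,
      treated_only = .data$singleton_channel == "treated_only"
    )
  log <- stage_log(NULL, "neo records", nrow(records), nrow(sites))
  evidence <- sites$passes_ratio | sites$treated_only
  log <- stage_log(log, "ratio >= threshold or treated-only",
                   nrow(sites), sum(evidence))
  keep <- evidence & sites$caspase_p1
  log <- stage_log(log, paste0("P1 in {", paste(p1_set, collapse = ","), "}"),
                   sum(evidence), sum(keep))
  sites$keep <- keep
  out <- if (mode == "strict") sites[keep, , drop = FALSE] else sites
  attr(out, "stages") <- log
  out
}

#' Require a minimum amount of identification evidence
#'
#' Keeps records identified at least `k` times, where the evidence count
#' is the number of PSMs pooled across enrichment methods and runs.
#'
#' @param records Tibble with a `psm_count` (or `evidence_count`) column.
#' @param k Minimum evidence (default 2).
#' @return Filtered records, with a `stages` attribute recording the cut.
#' @export
min_evidence <- function(records, k = 2L) {
  stopifnot(k >= 1)
  count <- if ("evidence_count" %in% names(records)) {
    records$evidence_count
  } else {
    records$psm_count
  }
  out <- records[count >= k, , drop = FALSE]
  attr(out, "stages") <- stage_log(attr(records, "stages"),
                                   paste0("evidence >= ", k),
                                   nrow(records), nrow(out))
  out
}

#' Annotate sites against tables of previously reported cleavages
#'
#' Flags each site as `reported` when its exact (accession, p1_position)
#' pair occurs in any known-cleavage table, collecting the matching source
#' names; `novel_substrate` marks proteins absent from every table at any
#' position. A `tolerance_1` mode also accepts positions off by one
#' residue, documenting the P1 vs P1' indexing disagreement between
#' databases; it is off by default.
#'
#' @param sites Tibble with `accession` and `p1_position`.
#' @param known_tables A known-site tibble (see [load_known_sites()]) or a
#'   list of them.
#' @param tolerance_1 Accept +/-1 position matches?
#' @return `sites` with `reported`, `sources` and `novel_substrate`
#'   columns.
#' @export
annotate_reported <- function(sites, known_tables, tolerance_1 = FALSE) {
  if (is.data.frame(known_tables)) known_tables <- list(known_tables)
  known <- dplyr::bind_rows(known_tables)
  if (nrow(known) == 0) {
    sites$reported <- FALSE
    sites$sources <- ""
    sites$novel_substrate <- TRUE
    return(sites)
  }
  offsets <- if (tolerance_1) c(-1L, 0L, 1L) else 0L
  sources <- vapply(seq_len(nrow(sites)), function(i) {
    hit <- known$accession == sites$accession[i] &
      known$p1_position %in% (sites$p1_position[i] + offsets)
    paste(sort(unique(known$source[hit])), collapse = ",")
  }, character(1))
  sites$reported <- nzchar(sources)
  sites$sources <- sources
  sites$novel_substrate <- !(sites$accession %in% known$accession)
  sites
}

#' Match neo-N termini to annotated protein processing events
#'
#' A neo start position matches a known maturation event when it equals
#' the residue after the end of an annotated signal peptide, transit
#' peptide or propeptide, or the start of an annotated mature chain that
#' does not begin at residue 1.
#'
#' @param sites Tibble with `accession` and `neo_start`.
#' @param annotations Annotation tibble (see [load_annotations()]).
#' @return `sites` with `known_processing` (logical) and
#'   `processing_feature` (description of the matched feature or `NA`).
#' @export
annotate_processing <- function(sites, annotations) {
  removal <- annotations[annotations$feature_type %in%
                           c("signal_peptide", "transit_peptide", "propeptide"), ]
  chains <- annotations[annotations$feature_type == "chain" &
                          annotations$start > 1, ]
  feature <- vapply(seq_len(nrow(sites)), function(i) {
    acc <- sites$accession[i]
    ns <- sites$neo_start[i]
    r <- removal[removal$accession == acc & removal$end + 1L == ns, ]
    if (nrow(r) > 0) {
      return(paste0(r$feature_type[1], " 1-", r$end[1], " removal"))
    }
    ch <- chains[chains$accession == acc & chains$start == ns, ]
    if (nrow(ch) > 0) {
      return(paste0("chain ", ch$start[1], "-", ch$end[1]))
    }
    NA_character_
  }, character(1))
  sites$known_processing <- !is.na(feature)
  sites$processing_feature <- feature
  sites
}

#' Winnow acetylated neo-N-terminal peptides
#'
#' The staged workflow for discovering posttranslational neo-N-terminal
#' acetylation: (1) keep acetylated N termini; (2) drop ORF starts
#' (positions 1 and 2); (3) split off peptides explained by annotated
#' protein maturation (signal/transit peptide or propeptide removal,
#' chain starts) into a separate processing-derived output; (4) drop
#' positions reported as alternative translation-initiation sites;
#' (5) the remainder are candidate posttranslational neo-Nt-acetylation
#' events, optionally (6) flagged as caspase-linked when the site also
#' survives the caspase winnow.
#'
#' @param records Classified (and typically quantified) records with
#'   `accession`, `start`, `nterm_state`, `p1_residue`.
#' @param annotations Annotation tibble (see [load_annotations()]).
#' @param alt_init Optional tibble of alternative-initiation sites with
#'   columns `accession`, `position`.
#' @param caspase_sites Optional output of [caspase_winnow()] used to flag
#'   caspase-linked candidates.
#' @return A list with `candidates`, `processing_derived` and the
#'   per-stage count log `stages`.
#' @export
neo_acetylation_winnow <- function(records, annotations, alt_init = NULL,
                                   caspase_sites = NULL) {
  log <- NULL
  acet <- records %>% dplyr::filter(.data$nterm_state == "acetylated",
                                    !is.na(.data$start))
  log <- stage_log(log, "acetylated N termini", nrow(records), nrow(acet))

  neo <- acet %>% dplyr::filter(.data$start > 2)
  log <- stage_log(log, "drop ORF starts (positions 1-2)", nrow(acet), nrow(neo))

  neo$neo_start <- neo$start
  neo <- annotate_processing(neo, annotations)
  processing_derived <- neo[neo$known_processing, , drop = FALSE]
  rest <- neo[!neo$known_processing, , drop = FALSE]
  log <- stage_log(log, "split off known processing events",
                   nrow(neo), nrow(rest))

  if (!is.null(alt_init) && nrow(alt_init) > 0) {
    is_alt <- vapply(seq_len(nrow(rest)), function(i) {
      any(alt_init$accession == rest$accession[i] &
            alt_init$position == rest$start[i])
    }, logical(1))
  } else {
    is_alt <- rep(FALSE, nrow(rest))
  }
  candidates <- rest[!is_alt, , drop = FALSE]
  log <- stage_log(log, "drop alternative-initiation sites",
                   nrow(rest), nrow(candidates))

  if (!is.null(caspase_sites)) {
    candidates$caspase_linked <- vapply(seq_len(nrow(candidates)), function(i) {
      any(caspase_sites$accession == candidates$accession[i] &
            caspase_sites$neo_start == candidates$neo_start[i])
    }, logical(1))
  } else {
    candidates$caspase_linked <- candidates$p1_residue %in% c("D", "E")
  }
  list(candidates = candidates, processing_derived = processing_derived,
       stages = log)
}

#' Co-occurrence of acetylated and free forms per N terminus
#'
#' Counts, per (accession, start) key and optionally per sample, how many
#' PSMs were observed with an acetylated versus a free N terminus. This
#' supports readouts such as a cleavage product occurring almost
#' exclusively in its acetylated form, and time-course views of which form
#' appears when.
#'
#' @param classified Output of [classify_observations()].
#' @param per_sample Also break counts down by `sample_id`?
#' @return A tibble with `accession`, `start` (and `sample_id` when
#'   requested), `n_acetylated`, `n_free`.
#' @export
form_cooccurrence <- function(classified, per_sample = FALSE) {
  x <- classified %>% dplyr::filter(!is.na(.data$accession))
  keys <- c("accession", "start", if (per_sample) "sample_id")
  x %>%
    dplyr::mutate(state_class = ifelse(.data$nterm_state == "acetylated",
                                       "acetylated", "free")) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      n_acetylated = sum(.data$state_class == "acetylated"),
      n_free = sum(.data$state_class == "free"),
      .groups = "drop"
    )
}
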