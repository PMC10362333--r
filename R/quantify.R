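#' Median-centre the two-channel ratios of each run
#'
#' Per MS run, the median of the quantified PSMs' log2(heavy/light) ratios
#' is computed and removed by rescaling the heavy-channel areas, so that
#' the post-normalization median log2 ratio of the run is exactly zero.
#' This removes any global channel-mixing bias. Single-channel
#' (singleton) observations are left untouched. Runs with fewer than three
#' quantified observations are passed through unnormalized with a warning.
#'
#' @param observations Observation tibble with `run_id`, `light_area`,
#'   `heavy_area`.
#' @return The observations with adjusted `heavy_area` and recomputed
#'   `raw_ratio`; the per-run log2 normalization constants are attached as
#'   the `normalization` attribute.
#' @export
normalize_run <- function(observations) {
  stopifnot(all(c("run_id", "light_area", "heavy_area") %in%
                  names(observations)))
  out <- observations
  runs <- unique(out$run_id)
  log <- vector("list", length(runs))
  for (k in seq_along(runs)) {
    idx <- which(out$run_id == runs[k])
    q <- idx[out$light_area[idx] > 0 & out$heavy_area[idx] > 0]
    if (length(q) < 3) {
      warning("run ", runs[k], " has fewer than 3 quantified observations; ",
              "passed through unnormalized")
      log[[k]] <- tibble(run_id = runs[k], constant_log2 = NA_real_,
                         n_quantified = length(q))
      next
    }
    const <- stats::median(log2(out$heavy_area[q] / out$light_area[q]))
    out$heavy_area[q] <- out$heavy_area[q] * 2^(-const)
    log[[k]] <- tibble(run_id = runs[k], constant_log2 = const,
                       n_quantified = length(q))
  }
  if ("raw_ratio" %in% names(out)) {
    out$raw_ratio <- ifelse(out$light_area > 0 & out$heavy_area > 0,
                            out$heavy_area / out$light_area, NA_real_)
  }
  attr(out, "normalization") <- dplyr::bind_rows(log)
  out
}

#' Aggregate PSM-level quantification per N terminus
#'
#' Groups classified observations by (accession, start, N-terminal state)
#' and aggregates the two channels by summing peak areas across the
#' group's PSMs before forming the ratio. The reported `log2_ratio` is on
#' the treated/control scale according to the experiment's channel
#' orientation. A key observed in only one channel becomes a singleton
#' carrying a direction flag instead of a pseudo-ratio; keys with zero
#' area in both channels are dropped with a message.
#'
#' @param classified Classified observation tibble (see
#'   [classify_observations()]); rows without a proteome match are
#'   ignored.
#' @param orientation `"heavy_treated"` (default) or `"light_treated"`:
#'   which isotopic channel carries the treated sample.
#' @return A tibble of quantified N termini: `accession`, `start`,
#'   `nterm_state`, `category`, `peptide` (a representative, the longest),
#'   `p1_residue`, `log2_ratio`, `singleton_channel` (`none`,
#'   `treated_only`, `control_only`), `psm_count`, `runs`, `enzymes`.
#' @export
aggregate_nterm <- function(classified,
                            orientation = c("heavy_treated", "light_treated")) {
  orientation <- match.arg(orientation)
  x <- classified %>% dplyr::filter(!is.na(.data$accession))
  if (nrow(x) == 0) stop("no mapped observations to aggregate")
  agg <- x %>%
    dplyr::group_by(.data$accession, .data$start, .data$nterm_state) %>%
    dplyr::summarise(
      category = .data$category[1],
      peptide = .data$peptide[which.max(nchar(.data$peptide))],
      p1_residue = .data$p1_residue[1],
      sum_light = sum(.data$light_area),
      sum_heavy = sum(.data$heavy_area),
      psm_count = dplyr::n(),
      runs = paste(sort(unique(.data$run_id)), collapse = ","),
      enzymes = paste(sort(unique(.data$enzyme)), collapse = ","),
      .groups = "drop"
    )
  empty <- agg$sum_light == 0 & agg$sum_heavy == 0
  if (any(empty)) {
    message(sum(empty), " aggregated record(s) dropped: zero area in both channels")
    agg <- agg[!empty, , drop = FALSE]
  }
  treated <- if (orientation == "heavy_treated") agg$sum_heavy else agg$sum_light
  control <- if (orientation == "heavy_treated") agg$sum_light else agg$sum_heavy
  agg$log2_ratio <- ifelse(treated > 0 & control > 0,
                           log2(treated / control), NA_real_)
  agg$singleton_channel <- dplyr::case_when(
    treated > 0 & control > 0 ~ "none",
    treated > 0 ~ "treated_only",
    TRUE ~ "control_only"
  )
  agg$sum_light <- agg$sum_heavy <- NULL
  agg
}

#' Flag significant abundance changes
#'
#' A quantified N terminus is called significant when its treated/control
#' ratio meets a fixed fold-change threshold (inclusive by default:
#' log2 ratio >= log2(threshold)), or when it is a treated-only singleton
#' (identified exclusively in the treated sample). `strict = TRUE`
#' switches the ratio comparison to strictly greater.
#'
#' @param records Output of [aggregate_nterm()].
#' @param fold_threshold Fold-change threshold (> 1), default 2.
#' @param strict Use a strict (>) instead of inclusive (>=) comparison.
#' @return `records` with a logical `significant` column.
#' @export
call_significant <- function(records, fold_threshold = 2, strict = FALSE) {
  stopifnot(fold_threshold > 1)
  cut <- log2(fold_threshold)
  ratio_pass <- !is.na(records$log2_ratio) &
    (if (strict) records$log2_ratio > cut else records$log2_ratio >= cut)
  records$significant <- ratio_pass | records$singleton_channel == "treated_only"
  records
}

#' Pair acetylated and free forms of the same ORF N terminus
#'
#' For ORF N-terminal records, finds the (accession, start) keys that were
#' quantified both in the Nt-acetylated form and with a free (dimethylated
#' or unlabeled) N terminus, pairing the two ratios side by side.
#'
#' @param records Output of [aggregate_nterm()], restricted to ORF
#'   categories by the function.
#' @return A list with `pairs` (one row per key with `log2_acetylated` and
#'   `log2_free`) and `n_single_state` (keys seen in only one form).
#' @export
pair_forms <- function(records) {
  orf <- records %>%
    dplyr::filter(.data$category %in% c("ORF_start1", "ORF_start2")) %>%
    dplyr::mutate(state_class = ifelse(.data$nterm_state == "acetylated",
                                       "acetylated", "free"))
  per_key <- orf %>%
    dplyr::group_by(.data$accession, .data$start, .data$state_class) %>%
    dplyr::summarise(log2_ratio = .data$log2_ratio[1],
                     peptide = .data$peptide[1], .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "state_class",
                       values_from = c("log2_ratio", "peptide"))
  for (col in c("log2_ratio_acetylated", "log2_ratio_free")) {
    if (!col %in% names(per_key)) per_key[[col]] <- NA_real_
  }
  both <- !is.na(per_key$log2_ratio_acetylated) & !is.na(per_key$log2_ratio_free)
  pairs <- per_key[both, , drop = FALSE] %>%
    dplyr::rename(log2_acetylated = "log2_ratio_acetylated",
                  log2_free = "log2_ratio_free")
  list(pairs = pairs, n_single_state = sum(!both))
}

#' Cleavage susceptibility by N-terminal state and acidic-residue content
#'
#' Groups quantified ORF N-terminal peptides into four classes crossing
#' the N-terminal state (acetylated vs free) with the literal presence of
#' an Asp or Glu residue in the peptide sequence (a prerequisite for an
#' internal caspase recognition site), and summarises each class's
#' log2 treated/control ratios.
#'
#' @param records Output of [aggregate_nterm()] (ORF categories are
#'   selected internally); the representative `peptide` column provides
#'   the sequence.
#' @return A tibble with one row per group: `state_class`, `has_DE`, `n`,
#'   `median`, `q25`, `q75`.
#' @export
susceptibility_table <- function(records) {
  orf <- records %>%
    dplyr::filter(.data$category %in% c("ORF_start1", "ORF_start2"),
                  !is.na(.data$log2_ratio)) %>%
    dplyr::mutate(
      state_class = ifelse(.data$nterm_state == "acetylated",
                           "acetylated", "free"),
      has_DE = grepl("[DE]", .data$peptide)
    )
  grid <- tidyr::expand_grid(state_class = c("acetylated", "free"),
                             has_DE = c(TRUE, FALSE))
  summ <- orf %>%
    dplyr::group_by(.data$state_class, .data$has_DE) %>%
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$log2_ratio),
      q25 = stats::quantile(.data$log2_ratio, 0.25, names = FALSE),
      q75 = stats::quantile(.data$log2_ratio, 0.75, names = FALSE),
      .groups = "drop"
    )
  out <- dplyr::left_join(grid, summ, by = c("state_class", "has_DE"))
  out$n[is.na(out$n)] <- 0L
  out
}
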