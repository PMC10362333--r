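# Approximate amino-acid frequencies of the reviewed human proteome, used
# as the default composition for simulated protein sequences.
human_aa_frequencies <- function() {
  f <- c(A = 7.0, C = 2.3, D = 4.7, E = 7.1, F = 3.7, G = 6.6, H = 2.6,
         I = 4.3, K = 5.7, L = 10.0, M = 2.1, N = 3.6, P = 6.3, Q = 4.8,
         R = 5.6, S = 8.3, T = 5.4, V = 6.0, W = 1.2, Y = 2.7)
  f[aa_standard()] / sum(f)
}

#' Configuration for the synthetic N-terminomics experiment
#'
#' Defines the study conditions the simulator emulates: a proteome with
#' known Met-excision and ORF-acetylation states, spiked caspase cleavage
#' events with an assigned effect size, non-caspase background cleavages,
#' known-processing-derived and caspase-linked acetylated neo-N termini,
#' and two-channel PSM tables with multiplicative (log-normal) ratio
#' noise.
#'
#' Defaults reflect the biology the pipeline targets: 70% of proteins
#' undergo initiator-Met excision and 74% of ORF N termini are
#' Nt-acetylated (the fractions observed in deep human N-terminome
#' censuses); spiked caspase events carry a true log2 treated/control
#' ratio of 2 with sigma = 0.3 log-normal PSM noise and 4 PSMs per event,
#' the regime in which a fixed 2-fold threshold separates signal from the
#' null background.
#'
#' @param seed Mandatory integer seed; the whole simulation is
#'   deterministic given the configuration.
#' @param n_proteins Number of simulated proteins.
#' @param length_range Uniform protein-length range (min must be at least
#'   120 so planted sites fit).
#' @param aa_frequencies Named residue frequency vector (sums to 1).
#' @param p_met_excision,p_orf_acetylation Per-protein probabilities of
#'   initiator-Met excision and of ORF Nt-acetylation.
#' @param n_caspase_sites Number of spiked caspase cleavage events.
#' @param p1_set Residues planted at P1 of caspase events.
#' @param observable_classes Planting classes recycled over caspase
#'   events: `"both"`, `"late_only"`, `"hytane_only"` (terminating K/R
#'   residues are placed so each event is identifiable by exactly the
#'   stated method set).
#' @param effect_log2 True log2 treated/control ratio of caspase and
#'   caspase-linked events.
#' @param n_background_cleavages Number of spiked non-caspase (non-D/E P1)
#'   cleavage events.
#' @param background_log2 True log2 ratio of background events (0 = null).
#' @param n_processing_events Number of transit-peptide-removal events
#'   whose neo N terminus is acetylated (annotated in the feature table).
#' @param n_neo_acetylation Number of caspase-linked acetylated
#'   neo-N-terminal events (P1 = D, unannotated).
#' @param p_treated_only Probability that a caspase event appears only in
#'   the treated channel (singleton).
#' @param psm_per_event PSMs emitted per event and method.
#' @param ratio_noise_sigma Log2-scale standard deviation of PSM ratio
#'   noise.
#' @param global_mix_bias Global channel-mixing factor applied to every
#'   ratio (1 = none); removed exactly by median normalization.
#' @param n_internal_psms Internal (NET = 2, free unlabeled) background
#'   PSMs added per method.
#' @param p_lysine_label Probability that a lysine epsilon-amine is
#'   spuriously dimethylated in LysN runs.
#' @param window Identifiability length window used to compute
#'   observability.
#' @param sample_id Sample label written into the PSM table.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_proteins = 120L,
                       length_range = c(150L, 400L),
                       aa_frequencies = human_aa_frequencies(),
                       p_met_excision = 0.70,
                       p_orf_acetylation = 0.74,
                       n_caspase_sites = 30L,
                       p1_set = c("D", "E"),
                       observable_classes = c("both", "late_only",
                                              "hytane_only"),
                       effect_log2 = 2.0,
                       n_background_cleavages = 30L,
                       background_log2 = 0,
                       n_processing_events = 6L,
                       n_neo_acetylation = 6L,
                       p_treated_only = 0,
                       psm_per_event = 4L,
                       ratio_noise_sigma = 0.3,
                       global_mix_bias = 1,
                       n_internal_psms = 40L,
                       p_lysine_label = 0.03,
                       window = c(7L, 35L),
                       sample_id = "invitro") {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              aa_frequencies = aa_frequencies,
              p_met_excision = p_met_excision,
              p_orf_acetylation = p_orf_acetylation,
              n_caspase_sites = as.integer(n_caspase_sites),
              p1_set = p1_set, observable_classes = observable_classes,
              effect_log2 = effect_log2,
              n_background_cleavages = as.integer(n_background_cleavages),
              background_log2 = background_log2,
              n_processing_events = as.integer(n_processing_events),
              n_neo_acetylation = as.integer(n_neo_acetylation),
              p_treated_only = p_treated_only,
              psm_per_event = as.integer(psm_per_event),
              ratio_noise_sigma = ratio_noise_sigma,
              global_mix_bias = global_mix_bias,
              n_internal_psms = as.integer(n_internal_psms),
              p_lysine_label = p_lysine_label,
              window = as.integer(window), sample_id = sample_id)
  probs <- c(cfg$p_met_excision, cfg$p_orf_acetylation, cfg$p_treated_only,
             cfg$p_lysine_label)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$aa_frequencies) - 1) > 1e-9) {
    stop("aa_frequencies must sum to 1")
  }
  if (cfg$length_range[1] < 120) {
    stop("minimum protein length must be at least 120 to fit planted sites")
  }
  n_events <- cfg$n_caspase_sites + cfg$n_background_cleavages +
    cfg$n_processing_events + cfg$n_neo_acetylation
  if (cfg$n_proteins < n_events) {
    stop("n_proteins must be at least the total number of planted events (",
         n_events, ")")
  }
  if (cfg$global_mix_bias <= 0) stop("global_mix_bias must be positive")
  if (!all(cfg$p1_set %in% c("D", "E"))) {
    stop("caspase p1_set must be a subset of {D, E}")
  }
  structure(cfg, class = "sim_config")
}

# Planted-site geometry (offsets from the cleaved bond). The downstream
# region is first cleared of K/R, then terminating residues are placed so
# the LATE peptide is 12 residues and/or the HYTANE peptide 10 residues,
# both inside the default identifiability window.
PLANT_P1 <- 60L
PLANT_CLEAR <- 45L
PLANT_LATE_LEN <- 12L
PLANT_HYTANE_LEN <- 10L

plant_site <- function(chars, p1, class, p1_residue, motif_p4_p2 = c("D", "E", "V")) {
  if (p1 + PLANT_CLEAR + 5L > length(chars)) {
    stop("protein too short to plant a site at position ", p1)
  }
  chars[(p1 - 3L):(p1 - 1L)] <- motif_p4_p2
  chars[p1] <- p1_residue
  region <- (p1 + 1L):(p1 + PLANT_CLEAR)
  kr <- region[chars[region] %in% c("K", "R")]
  if (length(kr) > 0) {
    chars[kr] <- sample(c("A", "S", "G", "T", "N", "Q", "V", "L"),
                        length(kr), replace = TRUE)
  }
  start <- p1 + 1L
  if (class %in% c("both", "late_only")) {
    chars[start + PLANT_LATE_LEN] <- "K"
  }
  if (class %in% c("both", "hytane_only")) {
    chars[start + PLANT_HYTANE_LEN - 1L] <- "R"
  }
  chars
}

observability <- function(sequence, start, window) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  late <- terminal_peptide_bounds(chars, start, "LATE")
  hyt <- terminal_peptide_bounds(chars, start, "HYTANE")
  late_len <- late$end - late$start + 1L
  hyt_len <- hyt$end - hyt$start + 1L
  list(late_len = late_len, hytane_len = hyt_len,
       late = is_identifiable(late_len, window),
       hytane = is_identifiable(hyt_len, window))
}

#' Generate a synthetic proteome with ground truth
#'
#' Draws random protein sequences (always Met-initiated), assigns
#' Met-excision and ORF-acetylation states, and plants caspase cleavage
#' motifs, background cleavages, transit-peptide processing events and
#' caspase-linked neo-acetylation events at engineered offsets from
#' downstream K/R residues so that LATE-only, HYTANE-only and
#' both-identifiable classes exist in known numbers. Per-method
#' observability in the truth table is always recomputed through the
#' digestion engine, never asserted.
#'
#' @param config A [sim_config()].
#' @return A list of class `nterm_sim` with `proteome`, `truth` (one row
#'   per event with its true state and recomputed observability),
#'   `annotations` (transit-peptide features for processing events) and
#'   `alt_init` (empty placeholder table).
#' @export
make_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_proteins
    accession <- sprintf("SIM%04d", seq_len(n))
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    seqs <- lapply(lens, function(L) {
      ch <- sample(names(config$aa_frequencies), L, replace = TRUE,
                   prob = config$aa_frequencies)
      ch[1] <- "M"
      ch
    })

    roles <- rep("plain", n)
    idx <- 0L
    take <- function(k) {
      out <- idx + seq_len(k)
      idx <<- idx + k
      out
    }
    i_casp <- take(config$n_caspase_sites)
    i_bg <- take(config$n_background_cleavages)
    i_proc <- take(config$n_processing_events)
    i_neo <- take(config$n_neo_acetylation)

    truth <- list()
    annotations <- list()
    ev <- 0L
    add_event <- function(row) {
      ev <<- ev + 1L
      row$event_id <- sprintf("ev%04d", ev)
      truth[[ev]] <<- row
    }

    classes <- rep(config$observable_classes,
                   length.out = config$n_caspase_sites)
    for (k in seq_along(i_casp)) {
      i <- i_casp[k]
      p1_res <- config$p1_set[1L + (k - 1L) %% length(config$p1_set)]
      seqs[[i]] <- plant_site(seqs[[i]], PLANT_P1, classes[k], p1_res)
      add_event(tibble(
        accession = accession[i], event_type = "caspase",
        p1_position = PLANT_P1, start = PLANT_P1 + 1L, p1_residue = p1_res,
        nterm_state = "free_labeled", true_log2 = config$effect_log2,
        planted_class = classes[k],
        treated_only = stats::runif(1) < config$p_treated_only
      ))
    }

    bg_p1 <- c("G", "S", "A", "L", "N", "T", "Q", "V")
    for (k in seq_along(i_bg)) {
      i <- i_bg[k]
      p1_res <- bg_p1[1L + (k - 1L) %% length(bg_p1)]
      seqs[[i]] <- plant_site(seqs[[i]], PLANT_P1, "both", p1_res,
                              motif_p4_p2 = sample(bg_p1, 3, replace = TRUE))
      add_event(tibble(
        accession = accession[i], event_type = "background",
        p1_position = PLANT_P1, start = PLANT_P1 + 1L, p1_residue = p1_res,
        nterm_state = "free_labeled", true_log2 = config$background_log2,
        planted_class = "both", treated_only = FALSE
      ))
    }

    transit_end <- 34L
    for (i in i_proc) {
      seqs[[i]] <- plant_site(seqs[[i]], transit_end, "both", "G",
                              motif_p4_p2 = c("A", "S", "A"))
      add_event(tibble(
        accession = accession[i], event_type = "processing",
        p1_position = transit_end, start = transit_end + 1L, p1_residue = "G",
        nterm_state = "acetylated", true_log2 = 0,
        planted_class = "both", treated_only = FALSE
      ))
      annotations[[length(annotations) + 1L]] <- tibble(
        accession = accession[i], feature_type = "transit_peptide",
        start = 1L, end = transit_end
      )
    }

    for (i in i_neo) {
      seqs[[i]] <- plant_site(seqs[[i]], PLANT_P1, "both", "D")
      add_event(tibble(
        accession = accession[i], event_type = "neo_acetylation",
        p1_position = PLANT_P1, start = PLANT_P1 + 1L, p1_residue = "D",
        nterm_state = "acetylated", true_log2 = config$effect_log2,
        planted_class = "both", treated_only = FALSE
      ))
    }

    # ORF truth for every protein.
    met_excised <- stats::runif(n) < config$p_met_excision
    acetylated <- stats::runif(n) < config$p_orf_acetylation
    for (i in seq_len(n)) {
      add_event(tibble(
        accession = accession[i], event_type = "orf",
        p1_position = NA_integer_, start = if (met_excised[i]) 2L else 1L,
        p1_residue = if (met_excised[i]) "M" else NA_character_,
        nterm_state = if (acetylated[i]) "acetylated" else "free_labeled",
        true_log2 = 0, planted_class = NA_character_, treated_only = FALSE
      ))
    }

    sequence <- vapply(seqs, paste, character(1), collapse = "")
    proteome <- tibble(accession = accession, entry_name = NA_character_,
                       description = "synthetic protein",
                       sequence = sequence)

    truth <- dplyr::bind_rows(truth)
    obs <- lapply(seq_len(nrow(truth)), function(r) {
      observability(protein_sequence(proteome, truth$accession[r]),
                    truth$start[r], config$window)
    })
    truth$late_length <- vapply(obs, `[[`, integer(1), "late_len")
    truth$hytane_length <- vapply(obs, `[[`, integer(1), "hytane_len")
    truth$observable_late <- vapply(obs, `[[`, logical(1), "late")
    truth$observable_hytane <- vapply(obs, `[[`, logical(1), "hytane")

    structure(list(
      proteome = proteome,
      truth = truth,
      annotations = if (length(annotations) > 0) {
        dplyr::bind_rows(annotations)
      } else {
        tibble(accession = character(0), feature_type = character(0),
               start = integer(0), end = integer(0))
      },
      alt_init = tibble(accession = character(0), position = integer(0)),
      config = config
    ), class = "nterm_sim")
  })
}

#' Simulate two-channel PSM tables from the planted truth
#'
#' Every truth event emits `psm_per_event` PSMs for each enrichment method
#' that can observe it (per the recomputed observability). Peptide
#' sequences are the method's terminal peptides; light-channel areas are
#' log-normal, and the heavy channel is the light channel times
#' `2^(true_log2 + log2(global_mix_bias) + noise)` with normal log2-scale
#' noise, so the expected log2 ratio equals the truth plus the global
#' bias. Treated-only events have an empty control channel. Internal
#' full-digest peptides with free unlabeled N termini are added as
#' enrichment background.
#'
#' @param sim A `nterm_sim` from [make_proteome()].
#' @param config Optional [sim_config()]; defaults to the one embedded in
#'   `sim`.
#' @return An observation tibble (the same contract as [read_psm_tsv()])
#'   with additional provenance columns `event_id` and `method`.
#' @export
simulate_experiment <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "nterm_sim"))
  masses <- modification_masses()
  bias_log2 <- log2(config$global_mix_bias)
  withr::with_seed(config$seed + 1L, {
    rows <- list()
    counter <- new.env()
    for (method in c("LATE", "HYTANE")) {
      run_id <- paste0(method, "_run1")
      enzyme <- if (method == "LATE") "LysN" else "trypsin_argc"
      counter[[run_id]] <- 0L
      obs_col <- if (method == "LATE") "observable_late" else "observable_hytane"
      for (r in seq_len(nrow(sim$truth))) {
        if (!sim$truth[[obs_col]][r]) next
        seqs <- protein_sequence(sim$proteome, sim$truth$accession[r])
        chars <- strsplit(seqs, "", fixed = TRUE)[[1]]
        b <- terminal_peptide_bounds(chars, sim$truth$start[r], method)
        peptide <- substr(seqs, b$start, b$end)
        nterm_mass <- if (sim$truth$nterm_state[r] == "acetylated") {
          masses[["acetyl"]]
        } else {
          masses[["dimethyl_light"]]
        }
        for (p in seq_len(config$psm_per_event)) {
          counter[[run_id]] <- counter[[run_id]] + 1L
          light <- round(stats::rlnorm(1, log(2e4), 0.5), 4)
          eps <- stats::rnorm(1, 0, config$ratio_noise_sigma)
          heavy <- round(light *
                           2^(sim$truth$true_log2[r] + bias_log2 + eps), 4)
          if (sim$truth$treated_only[r]) light <- 0
          kmods <- simulate_lysine_mods(peptide, enzyme,
                                        config$p_lysine_label, masses)
          rows[[length(rows) + 1L]] <- tibble(
            spectrum_id = sprintf("%s.%05d", run_id, counter[[run_id]]),
            run_id = run_id, sample_id = config$sample_id,
            peptide = peptide, nterm_mod_mass = nterm_mass,
            lysine_mod_masses = kmods, enzyme = enzyme,
            probability = 0.99, light_area = light, heavy_area = heavy,
            event_id = sim$truth$event_id[r], method = method
          )
        }
      }
      # Internal-peptide background (NET = 2, free unlabeled alpha-amine).
      protease <- if (method == "LATE") protease_lysn() else protease_argc()
      added <- 0L
      guard <- 0L
      while (added < config$n_internal_psms && guard < 20L * config$n_internal_psms) {
        guard <- guard + 1L
        i <- sample.int(nrow(sim$proteome), 1)
        frags <- digest(sim$proteome$sequence[i], protease, 0L)
        frags <- frags[frags$start > 2 &
                         is_identifiable(pmax(nchar(frags$sequence), 1),
                                         config$window), , drop = FALSE]
        if (nrow(frags) == 0) next
        f <- frags[sample.int(nrow(frags), 1), ]
        counter[[run_id]] <- counter[[run_id]] + 1L
        light <- round(stats::rlnorm(1, log(2e4), 0.5), 4)
        eps <- stats::rnorm(1, 0, config$ratio_noise_sigma)
        heavy <- round(light * 2^(bias_log2 + eps), 4)
        rows[[length(rows) + 1L]] <- tibble(
          spectrum_id = sprintf("%s.%05d", run_id, counter[[run_id]]),
          run_id = run_id, sample_id = config$sample_id,
          peptide = f$sequence, nterm_mod_mass = 0,
          lysine_mod_masses = "", enzyme = enzyme,
          probability = 0.99, light_area = light, heavy_area = heavy,
          event_id = NA_character_, method = method
        )
        added <- added + 1L
      }
    }
    obs <- dplyr::bind_rows(rows)
    extras <- obs[, c("event_id", "method")]
    obs$event_id <- obs$method <- NULL
    obs <- finalize_observations(obs, probability_floor = 0)
    dplyr::bind_cols(obs, extras)
  })
}

simulate_lysine_mods <- function(peptide, enzyme, p_label, masses) {
  kpos <- which(strsplit(peptide, "", fixed = TRUE)[[1]] == "K")
  if (length(kpos) == 0) return("")
  if (enzyme == "trypsin_argc") {
    # whole-protein dimethylation blocks every lysine by design
    labeled <- kpos
  } else {
    labeled <- kpos[stats::runif(length(kpos)) < p_label]
  }
  if (length(labeled) == 0) return("")
  paste(sprintf("%d:%.4f", labeled, masses[["dimethyl_light"]]),
        collapse = ";")
}

#' Score pipeline outputs against the simulator truth
#'
#' Exact set arithmetic between predicted and true event keys: true
#' positives, false positives, false negatives, precision and recall.
#'
#' @param predicted Tibble of predicted records.
#' @param truth Tibble of true events (a subset of the simulator truth).
#' @param keys Key columns present in both tables (default
#'   `c("accession", "start")`).
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
score_recovery <- function(predicted, truth, keys = c("accession", "start")) {
  if (!all(keys %in% names(predicted)) || !all(keys %in% names(truth))) {
    stop("key column(s) missing from predicted or truth table: ",
         paste(keys, collapse = ", "))
  }
  pk <- unique(do.call(paste, c(predicted[keys], sep = "\r")))
  tk <- unique(do.call(paste, c(truth[keys], sep = "\r")))
  tp <- length(intersect(pk, tk))
  fp <- length(setdiff(pk, tk))
  fn <- length(setdiff(tk, pk))
  tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  )
}

#' Write a simulation to disk
#'
#' Writes the proteome FASTA, the truth and annotation TSVs and the PSM
#' table (reference dialect) with fixed numeric formatting, so repeated
#' writes of the same simulation are byte-identical.
#'
#' @param sim A `nterm_sim`.
#' @param observations Observation tibble from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, observations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    proteome = file.path(dir, "proteome.fasta"),
    truth = file.path(dir, "truth.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    psms = file.path(dir, "psms.tsv")
  )
  write_proteome(sim$proteome, paths[["proteome"]])
  truth <- sim$truth
  truth$true_log2 <- sprintf("%.4f", truth$true_log2)
  readr::write_tsv(truth, paths[["truth"]])
  readr::write_tsv(sim$annotations, paths[["annotations"]])
  write_psm_tsv(observations, paths[["psms"]])
  invisible(paths)
}
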