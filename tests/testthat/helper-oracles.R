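# Independent brute-force oracles. These scan every bond / position with
# plain loops and stay deliberately separate from the package internals.

# Brute-force digestion: test each bond individually, then assemble
# fragments, then enumerate contiguous unions of <= m+1 fragments.
oracle_digest <- function(sequence, protease, missed = 0L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cut <- logical(max(n - 1L, 0L))
  for (b in seq_len(max(n - 1L, 0L))) {
    if (protease$side == "C_side") {
      hit <- chars[b] %in% protease$residues
      if (hit && length(protease$blocked_next) > 0 &&
          chars[b + 1] %in% protease$blocked_next) {
        hit <- FALSE
      }
    } else {
      hit <- chars[b + 1] %in% protease$residues
    }
    cut[b] <- hit
  }
  starts <- c(1L, which(cut) + 1L)
  ends <- c(which(cut), n)
  out <- list()
  for (i in seq_along(starts)) {
    for (m in 0:missed) {
      j <- i + m
      if (j > length(ends)) break
      out[[length(out) + 1L]] <- data.frame(
        start = starts[i], end = ends[j],
        sequence = substr(sequence, starts[i], ends[j]),
        missed = m, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Brute-force motif scan: test every candidate P1 position.
oracle_scan <- function(sequence, motif_sets) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  L <- length(motif_sets)
  p1 <- integer(0)
  for (pos in seq_len(n - 1L)) {
    if (pos < L) next
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!(chars[pos - L + k] %in% motif_sets[[k]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) p1 <- c(p1, pos)
  }
  p1
}

# Brute-force substring search for peptide mapping.
oracle_match <- function(peptide, sequences) {
  hits <- list()
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    for (start in seq_len(nchar(s) - nchar(peptide) + 1L)) {
      if (substr(s, start, start + nchar(peptide) - 1L) == peptide) {
        hits[[length(hits) + 1L]] <- c(i = i, start = start)
      }
    }
  }
  hits
}

random_protein <- function(len, first_met = FALSE) {
  ch <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE)
  if (first_met) ch[1] <- "M"
  paste(ch, collapse = "")
}

toy_proteome <- function(...) {
  seqs <- c(...)
  tibble::tibble(
    accession = names(seqs),
    entry_name = NA_character_,
    description = NA_character_,
    sequence = unname(seqs)
  )
}

# A minimal PSM observation tibble in the post-ingestion contract.
make_obs <- function(peptide, nterm_mod = "dimethyl_light",
                     light = 100, heavy = 100, enzyme = "LysN",
                     run_id = "run1", sample_id = "s1",
                     spectrum_id = NULL, probability = 0.99,
                     k_labeled = integer(0)) {
  n <- max(length(peptide), length(light), length(heavy),
           length(nterm_mod), length(enzyme), length(run_id))
  peptide <- rep_len(peptide, n)
  nterm_mod <- rep_len(nterm_mod, n)
  light <- rep_len(light, n)
  heavy <- rep_len(heavy, n)
  enzyme <- rep_len(enzyme, n)
  run_id <- rep_len(run_id, n)
  masses <- nterminomics::modification_masses()
  if (is.null(spectrum_id)) spectrum_id <- sprintf("sp%04d", seq_len(n))
  tibble::tibble(
    spectrum_id = spectrum_id, run_id = run_id,
    sample_id = rep_len(sample_id, n), peptide = peptide,
    nterm_mod_mass = unname(masses[nterm_mod]),
    lysine_mod_masses = "",
    enzyme = enzyme, probability = rep_len(probability, n),
    light_area = light, heavy_area = heavy,
    nterm_mod = nterm_mod,
    lysine_mods = lapply(seq_len(n), function(i) {
      k <- if (is.list(k_labeled)) k_labeled[[i]] else k_labeled
      tibble::tibble(position = as.integer(k),
                     mass = rep(unname(masses["dimethyl_light"]), length(k)),
                     mod = rep("dimethyl_light", length(k)))
    }),
    raw_ratio = ifelse(light > 0 & heavy > 0, heavy / light, NA_real_),
    channel = dplyr::case_when(light > 0 & heavy > 0 ~ "both",
                               light > 0 ~ "light_only",
                               heavy > 0 ~ "heavy_only",
                               TRUE ~ "none")
  )
}
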