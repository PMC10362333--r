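#' Protease specificity definitions
#'
#' A protease is described by the side of the recognized residue at which
#' the peptide bond is hydrolysed (`"C_side"`: bond C-terminal to the
#' residue, as for trypsin/ArgC; `"N_side"`: bond N-terminal to the
#' residue, as for LysN), the set of recognized residues, and an optional
#' set of P1' residues that suppress cleavage (e.g. proline for trypsin).
#'
#' @param name Protease label.
#' @param side `"C_side"` or `"N_side"`.
#' @param residues Non-empty character vector of recognized residues.
#' @param blocked_next Optional character vector of P1' residues that block
#'   cleavage (C-side proteases only in practice).
#' @return An object of class `protease_spec`.
#' @export
protease_spec <- function(name, side = c("C_side", "N_side"), residues,
                          blocked_next = character()) {
  side <- match.arg(side)
  stopifnot(length(residues) >= 1)
  if (!all(residues %in% aa_standard()) || !all(blocked_next %in% aa_standard())) {
    stop("protease residues must belong to the 20-residue alphabet")
  }
  structure(
    list(name = name, side = side, residues = unique(residues),
         blocked_next = unique(blocked_next)),
    class = "protease_spec"
  )
}

#' @export
print.protease_spec <- function(x, ...) {
  cat("<protease_spec> ", x$name, ": ", x$side, " of {",
      paste(x$residues, collapse = ","), "}",
      if (length(x$blocked_next) > 0)
        paste0(", blocked by P1' {", paste(x$blocked_next, collapse = ","), "}"),
      "\n", sep = "")
  invisible(x)
}

#' Built-in proteases
#'
#' `protease_lysn()` cleaves N-terminally to lysine (the enzyme used for
#' LysN-based N-terminal enrichment); `protease_argc()` is trypsin acting
#' with ArgC-like specificity (lysines chemically blocked, cleavage
#' C-terminal to arginine only), the effective enzyme in
#' hydrophobic-tagging-based enrichment; `protease_trypsin()` cleaves after
#' K or R, optionally blocked by proline at P1'.
#'
#' @param block_proline Should P1' proline suppress tryptic cleavage?
#' @return A `protease_spec`.
#' @export
protease_lysn <- function() protease_spec("LysN", "N_side", "K")

#' @rdname protease_lysn
#' @export
protease_argc <- function() protease_spec("ArgC-like", "C_side", "R")

#' @rdname protease_lysn
#' @export
protease_trypsin <- function(block_proline = FALSE) {
  protease_spec("trypsin", "C_side", c("K", "R"),
                blocked_next = if (block_proline) "P" else character())
}

protease_for_method <- function(method) {
  switch(method,
         LATE = protease_lysn(),
         HYTANE = protease_argc(),
         stop("unknown enrichment method: ", method))
}

# Bond indices cleaved by a protease: bond b is between residues b and b+1.
cleavage_bonds <- function(chars, protease) {
  n <- length(chars)
  if (n < 2) return(integer(0))
  hits <- which(chars %in% protease$residues)
  if (protease$side == "C_side") {
    b <- hits[hits < n]
    if (length(protease$blocked_next) > 0) {
      b <- b[!(chars[b + 1] %in% protease$blocked_next)]
    }
  } else {
    b <- hits[hits >= 2] - 1L
  }
  sort(unique(b))
}

#' Digest a protein sequence in silico
#'
#' Splits a sequence at every bond matching the protease specificity. At
#' `missed_cleavages = 0` the peptides tile the sequence exactly; with
#' missed cleavages allowed, every contiguous union of up to
#' `missed_cleavages + 1` adjacent fragments is also emitted.
#'
#' @param sequence A protein sequence string (or a single-row proteome
#'   tibble).
#' @param protease A [protease_spec()].
#' @param missed_cleavages Maximum number of internal uncleaved sites per
#'   peptide (0-5).
#' @return A tibble with columns `start`, `end`, `sequence`, `missed`,
#'   ordered by start then end.
#' @examples
#' digest("MKAAKTR", protease_lysn())
#' digest("MARVKDR", protease_argc())
#' @export
digest <- function(sequence, protease, missed_cleavages = 0L) {
  sequence <- as_sequence(sequence)
  stopifnot(inherits(protease, "protease_spec"))
  missed_cleavages <- as.integer(missed_cleavages)
  if (missed_cleavages < 0 || missed_cleavages > 5) {
    stop("missed_cleavages must be between 0 and 5")
  }
  n <- nchar(sequence)
  if (n == 0) stop("cannot digest a zero-length sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bounds <- c(0L, cleavage_bonds(chars, protease), n)
  k <- length(bounds) - 1L
  out <- vector("list", missed_cleavages + 1L)
  for (m in 0:missed_cleavages) {
    i <- seq_len(k - m)
    if (length(i) == 0) break
    out[[m + 1L]] <- tibble(
      start = bounds[i] + 1L,
      end = bounds[i + 1L + m],
      missed = m
    )
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  res$sequence <- substring(sequence, res$start, res$end)
  res[, c("start", "end", "sequence", "missed")]
}

as_sequence <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, "sequence" %in% names(x))
    x <- x$sequence
  }
  stopifnot(is.character(x), length(x) == 1)
  x
}

#' Parse a cleavage motif specification
#'
#' A motif is a position-specific residue-set pattern of one to four
#' positions ending at P1 (the residue N-terminal to the cleaved bond).
#' It can be given as a plain string (`"DEVD"`), as a string with bracketed
#' residue sets (`"DEV[DE]"`), or as a list of character vectors. The
#' ambiguity codes X/U/B/Z never match.
#'
#' @param motif Motif specification.
#' @return A list of residue-set character vectors, ordered towards P1.
#' @export
parse_motif <- function(motif) {
  if (is.list(motif)) {
    sets <- lapply(motif, function(s) unique(as.character(s)))
  } else {
    stopifnot(is.character(motif), length(motif) == 1)
    if (!nzchar(motif)) stop("empty motif")
    toks <- regmatches(motif, gregexpr("\\[[A-Z]+\\]|[A-Z]", motif))[[1]]
    if (sum(nchar(toks)) != nchar(motif)) stop("unparseable motif: ", motif)
    sets <- lapply(toks, function(t) {
      strsplit(gsub("\\[|\\]", "", t), "", fixed = FALSE)[[1]]
    })
  }
  if (length(sets) < 1 || length(sets) > 4) {
    stop("motif must span 1-4 positions ending at P1")
  }
  ok <- vapply(sets, function(s) length(s) >= 1 && all(s %in% aa_standard()),
               logical(1))
  if (!all(ok)) stop("motif positions must be non-empty sets of standard residues")
  sets
}

#' Scan a protein for motif-defined cleavage sites
#'
#' Finds every position where the motif (anchored with its last position at
#' P1) matches. The reported site is the bond after the P1 residue; a match
#' whose P1 is the final residue is excluded because it generates no
#' downstream peptide. Overlapping matches are all reported.
#'
#' @inheritParams digest
#' @param motif Motif specification, see [parse_motif()].
#' @param accession Optional accession carried into the output.
#' @return A tibble with columns `accession`, `p1_position`, `p1_residue`.
#' @examples
#' scan_motif("AADEVDGK", "DEVD")
#' @export
scan_motif <- function(sequence, motif, accession = NA_character_) {
  sequence <- as_sequence(sequence)
  sets <- parse_motif(motif)
  L <- length(sets)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  p1 <- integer(0)
  if (n >= L + 1) {
    # candidate P1 positions: L .. n-1 (need a downstream residue)
    cand <- L:(n - 1L)
    ok <- rep(TRUE, length(cand))
    for (k in seq_len(L)) {
      ok <- ok & (chars[cand - L + k] %in% sets[[k]])
    }
    p1 <- cand[ok]
  }
  tibble(
    accession = rep(accession, length(p1)),
    p1_position = as.integer(p1),
    p1_residue = chars[p1]
  )
}

#' Scan a whole proteome for motif sites
#'
#' @param proteome Proteome tibble.
#' @param motif Motif specification, see [parse_motif()].
#' @return A tibble of sites across all proteins.
#' @export
scan_proteome <- function(proteome, motif) {
  check_proteome(proteome)
  dplyr::bind_rows(lapply(seq_len(nrow(proteome)), function(i) {
    scan_motif(proteome$sequence[i], motif, accession = proteome$accession[i])
  }))
}

# Terminal peptide observed for a given start position under an enrichment
# method. LATE (LysN digestion): the peptide runs from `start` to the
# residue before the first K strictly after `start`. HYTANE (ArgC-like
# digestion of lysine-blocked protein): the peptide runs from `start`
# through the first R at or after `start`, inclusive.
terminal_peptide_bounds <- function(chars, start, method) {
  n <- length(chars)
  if (method == "LATE") {
    ks <- which(chars == "K")
    ks <- ks[ks > start]
    if (length(ks) == 0) {
      list(start = start, end = n, runs_to_end = TRUE)
    } else {
      list(start = start, end = ks[1] - 1L, runs_to_end = FALSE)
    }
  } else if (method == "HYTANE") {
    rs <- which(chars == "R")
    rs <- rs[rs >= start]
    if (length(rs) == 0) {
      list(start = start, end = n, runs_to_end = TRUE)
    } else {
      list(start = start, end = rs[1], runs_to_end = FALSE)
    }
  } else {
    stop("unknown enrichment method: ", method)
  }
}

#' Neo-N-terminal peptide generated by a cleavage under a given method
#'
#' Returns the enrichment-observable peptide that starts at the residue
#' after the cleaved bond (P1'). Under LATE (LysN) the peptide ends before
#' the first downstream lysine; under HYTANE (ArgC-like) it ends at the
#' first arginine at or after the start, inclusive. When no terminating
#' residue exists, the peptide runs to the protein C terminus and is
#' flagged `runs_to_end`.
#'
#' @inheritParams digest
#' @param p1_position 1-based index of the P1 residue (the cleaved bond
#'   follows it); must be strictly less than the protein length.
#' @param method `"LATE"` or `"HYTANE"`.
#' @return A one-row tibble with `start`, `end`, `length`, `sequence`,
#'   `runs_to_end`.
#' @examples
#' neo_peptide("AADGSAAKLL", 3, "LATE")   # GSAA
#' neo_peptide("AADGSARLL", 3, "HYTANE")  # GSAR
#' @export
neo_peptide <- function(sequence, p1_position, method = c("LATE", "HYTANE")) {
  sequence <- as_sequence(sequence)
  method <- match.arg(method)
  n <- nchar(sequence)
  p1_position <- as.integer(p1_position)
  if (p1_position < 1 || p1_position >= n) {
    stop("p1_position must lie in [1, length - 1]")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  b <- terminal_peptide_bounds(chars, p1_position + 1L, method)
  tibble(
    start = b$start, end = b$end, length = b$end - b$start + 1L,
    sequence = substr(sequence, b$start, b$end),
    runs_to_end = b$runs_to_end
  )
}

#' Length-window identifiability rule
#'
#' A peptide is considered identifiable by mass spectrometry when its
#' length falls inside an inclusive window, by default 7-35 residues.
#'
#' @param peptide_length Integer vector of peptide lengths (>= 1).
#' @param window Length-2 inclusive window `c(min_len, max_len)`.
#' @return Logical vector.
#' @export
is_identifiable <- function(peptide_length, window = c(7L, 35L)) {
  stopifnot(length(window) == 2)
  if (window[1] > window[2]) stop("window minimum exceeds maximum")
  if (any(peptide_length < 1)) stop("peptide_length must be >= 1")
  peptide_length >= window[1] & peptide_length <= window[2]
}

#' Distance to the nearest residue of a set
#'
#' Smallest `d >= 1` such that the residue at `start + d - 1` belongs to
#' `residue_set`; the start residue itself counts as distance 1. Returns
#' `NA` when no such residue exists through the C terminus.
#'
#' @inheritParams digest
#' @param start 1-based start position of the segment.
#' @param residue_set Character vector of residues.
#' @return Integer distance or `NA_integer_`.
#' @export
nearest_residue_distance <- function(sequence, start, residue_set = "R") {
  sequence <- as_sequence(sequence)
  n <- nchar(sequence)
  stopifnot(start >= 1, start <= n)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- which(chars[start:n] %in% residue_set)
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1])
}

site_identifiability <- function(sequence, start, methods, window) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  rows <- lapply(methods, function(m) {
    b <- terminal_peptide_bounds(chars, start, m)
    len <- b$end - b$start + 1L
    tibble(method = m, peptide_start = b$start, peptide_end = b$end,
           peptide_length = len, runs_to_end = b$runs_to_end,
           identifiable = is_identifiable(len, window))
  })
  dplyr::bind_rows(rows)
}

#' Per-method identifiability of motif sites and ORF N termini
#'
#' For every motif match in the proteome, computes the neo-N-terminal
#' peptide that each enrichment method would observe and whether its length
#' lies in the identifiability window; summarises the sites into the four
#' exclusive categories LATE-only / HYTANE-only / both / neither. ORF
#' N-terminus identifiability is evaluated the same way for both the
#' Met-retained (start 1) and Met-excised (start 2) forms and reported
#' separately.
#'
#' @param proteome Proteome tibble.
#' @param motif Motif specification, see [parse_motif()]; default the
#'   canonical caspase-3 recognition sequence DEVD.
#' @param methods Enrichment methods to evaluate.
#' @param window Identifiability length window, inclusive.
#' @return A list with elements `sites` (per site x method table),
#'   `site_summary` (category counts for motif sites), `orf` (per protein x
#'   start x method table) and `orf_summary` (category counts per ORF
#'   form).
#' @export
coverage_report <- function(proteome, motif = "DEVD",
                            methods = c("LATE", "HYTANE"),
                            window = c(7L, 35L)) {
  check_proteome(proteome)
  if (nrow(proteome) == 0) stop("empty proteome")
  stopifnot(all(methods %in% c("LATE", "HYTANE")))

  sites <- scan_proteome(proteome, motif)
  site_rows <- lapply(seq_len(nrow(sites)), function(i) {
    seqs <- protein_sequence(proteome, sites$accession[i])
    res <- site_identifiability(seqs, sites$p1_position[i] + 1L, methods, window)
    res$accession <- sites$accession[i]
    res$p1_position <- sites$p1_position[i]
    res$p1_residue <- sites$p1_residue[i]
    res
  })
  site_tbl <- dplyr::bind_rows(site_rows)

  orf_rows <- lapply(seq_len(nrow(proteome)), function(i) {
    out <- lapply(c(1L, 2L), function(s) {
      if (nchar(proteome$sequence[i]) < s + 1L) return(NULL)
      res <- site_identifiability(proteome$sequence[i], s, methods, window)
      res$accession <- proteome$accession[i]
      res$orf_start <- s
      res
    })
    dplyr::bind_rows(out)
  })
  orf_tbl <- dplyr::bind_rows(orf_rows)

  list(
    sites = site_tbl,
    site_summary = identifiability_categories(site_tbl,
                                              c("accession", "p1_position")),
    orf = orf_tbl,
    orf_summary = dplyr::bind_rows(lapply(split(orf_tbl, orf_tbl$orf_start),
      function(d) {
        s <- identifiability_categories(d, "accession")
        s$orf_start <- d$orf_start[1]
        s
      }))
  )
}

identifiability_categories <- function(tbl, key) {
  if (nrow(tbl) == 0) {
    return(tibble(category = c("LATE_only", "HYTANE_only", "both", "neither"),
                  n = 0L))
  }
  wide <- tbl %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "method")))) %>%
    dplyr::summarise(identifiable = any(.data$identifiable), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "method", values_from = "identifiable",
                       values_fill = FALSE)
  late <- if ("LATE" %in% names(wide)) wide$LATE else rep(FALSE, nrow(wide))
  hyt <- if ("HYTANE" %in% names(wide)) wide$HYTANE else rep(FALSE, nrow(wide))
  category <- dplyr::case_when(
    late & hyt ~ "both",
    late & !hyt ~ "LATE_only",
    !late & hyt ~ "HYTANE_only",
    TRUE ~ "neither"
  )
  counts <- table(factor(category,
                         levels = c("LATE_only", "HYTANE_only", "both", "neither")))
  tibble(category = names(counts), n = as.integer(counts))
}
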