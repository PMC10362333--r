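#' Extract the P4-P4' window around a cleavage site
#'
#' Returns the eight residues flanking the cleaved bond in
#' Schechter-Berger numbering: positions P4..P1 are residues
#' `p1_position - 3 .. p1_position`, positions P1'..P4' are
#' `p1_position + 1 .. p1_position + 4`. Slots outside the protein are
#' padded with `'-'`.
#'
#' @inheritParams digest
#' @param p1_position 1-based index of the P1 residue.
#' @param flank Number of positions on each side of the bond (default 4).
#' @return A `2 * flank` character string.
#' @examples
#' extract_window("AADEVDGSKL", 6)  # "DEVDGSKL"
#' @export
extract_window <- function(sequence, p1_position, flank = 4L) {
  sequence <- as_sequence(sequence)
  n <- nchar(sequence)
  stopifnot(p1_position >= 1, p1_position <= n)
  pos <- (p1_position - flank + 1L):(p1_position + flank)
  chars <- rep("-", length(pos))
  inside <- pos >= 1 & pos <= n
  chars[inside] <- substring(sequence, pos[inside], pos[inside])
  paste(chars, collapse = "")
}

position_labels <- function(flank = 4L) {
  c(paste0("P", flank:1), paste0("P", 1:flank, "p"))
}

#' Background amino-acid frequencies of a proteome
#'
#' Frequencies of the 20 standard residues over all sequences (ambiguity
#' codes are excluded from numerator and denominator); sums to 1.
#'
#' @param proteome Proteome tibble (or character vector of sequences).
#' @return Named numeric vector over the 20 standard residues.
#' @export
aa_frequencies <- function(proteome) {
  seqs <- if (is.data.frame(proteome)) proteome$sequence else proteome
  chars <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE))
  chars <- chars[chars %in% aa_standard()]
  counts <- table(factor(chars, levels = aa_standard()))
  stats::setNames(as.numeric(counts) / sum(counts), aa_standard())
}

#' Differential amino-acid-usage logo matrix
#'
#' For each window position, computes the foreground frequency of each of
#' the 20 residues over the non-padded windows and subtracts the
#' background frequency, scaled to percent. Padded slots are excluded from
#' both the numerator and the denominator of their column, which keeps
#' every column of the difference matrix summing to zero.
#'
#' @param windows Character vector of equal-length windows (see
#'   [extract_window()]), `'-'` marking padding.
#' @param background Either a proteome tibble / sequence vector (passed to
#'   [aa_frequencies()]) or a named frequency vector over the 20 standard
#'   residues summing to 1. The same vector is applied to every position.
#' @return An object of class `logo_matrix`: a list with `values`
#'   (20 x positions percent-difference matrix), `foreground` (frequency
#'   matrix), `positions`, `n_sites` and `background`.
#' @export
dag_logo <- function(windows, background) {
  if (length(windows) == 0) stop("no windows supplied")
  width <- unique(nchar(windows))
  if (length(width) != 1) stop("windows must have equal length")
  if (width %% 2 != 0) stop("window width must be even (P-side = P'-side)")
  bg <- if (is.numeric(background)) background else aa_frequencies(background)
  if (!setequal(names(bg), aa_standard()) ||
      abs(sum(bg) - 1) > 1e-9) {
    stop("background must be a frequency vector over the 20 standard ",
         "residues summing to 1")
  }
  bg <- bg[aa_standard()]
  mat <- matrix(0, nrow = 20, ncol = width,
                dimnames = list(aa_standard(), position_labels(width / 2)))
  fg <- mat
  chars <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  for (j in seq_len(width)) {
    col <- chars[, j]
    col <- col[col %in% aa_standard()]
    if (length(col) == 0) next
    f <- as.numeric(table(factor(col, levels = aa_standard()))) / length(col)
    fg[, j] <- f
    mat[, j] <- (f - bg) * 100
  }
  structure(list(values = mat, foreground = fg,
                 positions = colnames(mat), n_sites = length(windows),
                 background = bg),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("<logo_matrix> ", x$n_sites, " sites, positions ",
      paste(x$positions, collapse = " "), "\n", sep = "")
  print(round(x$values, 1))
  invisible(x)
}

#' Write a logo matrix as TSV
#'
#' Rows are amino acids, columns the window positions, values the percent
#' difference against the background.
#'
#' @param logo A `logo_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- as.data.frame(logo$values)
  df <- cbind(amino_acid = rownames(df), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Nearest-basic-residue distance distribution of cleavage sites
#'
#' For each site, measures the distance from the neo-N-terminal start
#' (P1') to the nearest residue of `residue_set` downstream (the start
#' residue counting as distance 1); sites with no such residue through the
#' C terminus are binned as censored beyond `max_d`. Because the
#' enrichment peptide ends at (HYTANE, arginine) or before (LATE, lysine)
#' that residue, the fraction of distances outside the identifiability
#' window measures how many sites the corresponding method cannot see.
#'
#' @param sites Tibble with `accession` and `neo_start` columns.
#' @param proteome Proteome tibble.
#' @param residue_set Residues to search for, default `"R"`.
#' @param window Identifiability length window.
#' @param max_d Censoring bound for the histogram (default 50).
#' @return A list with `distances` (per-site tibble; `NA` = censored),
#'   `histogram` (distance counts with a `">max_d"` bin),
#'   `fraction_outside_window` and `n_sites`.
#' @export
distance_histogram <- function(sites, proteome, residue_set = "R",
                               window = c(7L, 35L), max_d = 50L) {
  check_proteome(proteome)
  d <- vapply(seq_len(nrow(sites)), function(i) {
    nearest_residue_distance(protein_sequence(proteome, sites$accession[i]),
                             sites$neo_start[i], residue_set)
  }, integer(1))
  binned <- ifelse(is.na(d) | d > max_d, paste0(">", max_d), as.character(d))
  lev <- c(as.character(seq_len(max_d)), paste0(">", max_d))
  counts <- table(factor(binned, levels = lev))
  counts <- counts[counts > 0]
  outside <- is.na(d) | d < window[1] | d > window[2]
  list(
    distances = tibble(accession = sites$accession,
                       neo_start = sites$neo_start, distance = d),
    histogram = tibble(distance = names(counts), n = as.integer(counts)),
    fraction_outside_window = if (nrow(sites) == 0) NA_real_ else mean(outside),
    n_sites = nrow(sites)
  )
}

parse_context_table <- function(context) {
  stopifnot(all(c("accession", "ss", "rsa") %in% names(context)))
  context$rsa_values <- lapply(strsplit(context$rsa, ",", fixed = TRUE),
                               as.numeric)
  context
}

site_context <- function(sites, context) {
  context <- parse_context_table(context)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    j <- match(sites$accession[i], context$accession)
    if (is.na(j)) return(NULL)
    p1 <- sites$p1_position[i]
    rsa <- context$rsa_values[[j]]
    n <- length(rsa)
    if (p1 < 1 || p1 + 1 > n) return(NULL)
    tibble(
      accession = sites$accession[i], p1_position = p1,
      ss_p1 = substr(context$ss[j], p1, p1),
      ss_p1p = substr(context$ss[j], p1 + 1, p1 + 1),
      rsa_p1 = rsa[p1], rsa_p1p = rsa[p1 + 1]
    )
  })
  dplyr::bind_rows(rows)
}

#' Structural context of cleavage sites
#'
#' Summarises externally supplied secondary-structure codes and relative
#' solvent accessibility (RSA) at the P1 and P1' residues of a set of
#' sites, and optionally contrasts two site groups with a label-permutation
#' test on the difference of median P1 RSA.
#'
#' The context table has one row per protein: `accession`, `ss` (a string
#' of one secondary-structure code per residue, e.g. H/E/C) and `rsa`
#' (comma-separated per-residue RSA values in [0, 1]). Sites whose
#' accession is missing from the table are skipped and counted.
#'
#' @param sites Tibble with `accession`, `p1_position` and, when
#'   contrasting, a `group` column with exactly two levels.
#' @param context Context table as described above.
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Seed for the permutation draw (applied locally).
#' @return A list with `per_site` values, `ss_distribution` (P1 codes,
#'   summing to 1), `rsa_summary` (median and quartiles at P1 and P1'),
#'   `n_skipped`, and when a `group` column is present a `contrast` list
#'   with the observed median difference and permutation p value.
#' @export
context_summary <- function(sites, context, n_permutations = 10000L,
                            seed = NULL) {
  per_site <- site_context(sites, context)
  n_skipped <- nrow(sites) - nrow(per_site)
  if (n_skipped > 0) {
    message(n_skipped, " site(s) skipped: accession missing from context table")
  }
  if (nrow(per_site) == 0) stop("no sites with structural context")
  ss_tab <- table(per_site$ss_p1)
  ss_distribution <- tibble(ss = names(ss_tab),
                            fraction = as.numeric(ss_tab) / sum(ss_tab))
  qs <- function(x) {
    stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, na.rm = TRUE)
  }
  rsa_summary <- tibble(
    position = c("P1", "P1p"),
    q25 = c(qs(per_site$rsa_p1)[1], qs(per_site$rsa_p1p)[1]),
    median = c(qs(per_site$rsa_p1)[2], qs(per_site$rsa_p1p)[2]),
    q75 = c(qs(per_site$rsa_p1)[3], qs(per_site$rsa_p1p)[3])
  )
  out <- list(per_site = per_site, ss_distribution = ss_distribution,
              rsa_summary = rsa_summary, n_skipped = n_skipped)

  if ("group" %in% names(sites)) {
    matched <- dplyr::inner_join(
      sites[, c("accession", "p1_position", "group")],
      per_site, by = c("accession", "p1_position"))
    groups <- unique(matched$group)
    if (length(groups) != 2) stop("`group` must have exactly two levels")
    x <- matched$rsa_p1
    g <- matched$group == groups[1]
    obs <- stats::median(x[g]) - stats::median(x[!g])
    perm_diff <- function() {
      gp <- sample(g)
      stats::median(x[gp]) - stats::median(x[!gp])
    }
    perms <- if (is.null(seed)) {
      replicate(n_permutations, perm_diff())
    } else {
      withr::with_seed(seed, replicate(n_permutations, perm_diff()))
    }
    p <- (1 + sum(abs(perms) >= abs(obs))) / (n_permutations + 1)
    out$contrast <- list(groups = groups, median_difference = obs,
                         p_value = p, n_permutations = n_permutations)
  }
  out
}
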