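# Monoisotopic atomic masses (Da) used to derive modification deltas.
.ATOM <- c(H = 1.00782503207, C = 12.0, C13 = 13.0033548378,
           D = 2.0141017778, O = 15.9949146196)

#' Named N-terminal / lysine modification masses
#'
#' Monoisotopic mass shifts of the modifications handled by the pipeline,
#' derived from standard atomic masses: light dimethyl (2 x CH2), heavy
#' dimethyl (2 x 13C-D2, from 13CD2-formaldehyde labeling) and acetyl
#' (C2H2O). The two dimethyl isotopologues are spaced 6.0318 Da apart.
#'
#' @return Named numeric vector (Da).
#' @export
modification_masses <- function() {
  c(
    free = 0,
    dimethyl_light = 2 * (.ATOM[["C"]] + 2 * .ATOM[["H"]]),
    dimethyl_heavy = 2 * (.ATOM[["C13"]] + 2 * .ATOM[["D"]]),
    acetyl = 2 * .ATOM[["C"]] + 2 * .ATOM[["H"]] + .ATOM[["O"]]
  )
}

#' Name a modification from its observed mass shift
#'
#' Maps delta masses to the nearest named modification within a tolerance.
#' Masses matching nothing are reported as `"unknown"` (the raw value is
#' retained by the callers that need it).
#'
#' @param delta_mass Numeric vector of observed mass shifts (Da).
#' @param tolerance Matching tolerance in Da (default 0.01, well below the
#'   6.03 Da spacing of the dimethyl isotopologues).
#' @return Character vector of modification names.
#' @export
assign_mod_names <- function(delta_mass, tolerance = 0.01) {
  stopifnot(tolerance > 0)
  masses <- modification_masses()
  vapply(delta_mass, function(m) {
    if (is.na(m)) return("free")
    d <- abs(masses - m)
    hit <- which(d <= tolerance)
    if (length(hit) > 1) {
      stop("ambiguous modification mass ", m, ": matches ",
           paste(names(masses)[hit], collapse = ", "),
           " within tolerance ", tolerance)
    }
    if (length(hit) == 0) "unknown" else names(masses)[hit]
  }, character(1))
}

# Columns of the reference PSM TSV dialect.
psm_tsv_columns <- function() {
  c("spectrum_id", "run_id", "sample_id", "peptide", "nterm_mod_mass",
    "lysine_mod_masses", "enzyme", "probability", "light_area", "heavy_area")
}

# Parse "pos:mass;pos:mass" lysine modification strings into a list of
# tibbles(position, mass, mod).
parse_lysine_mods <- function(x, tolerance = 0.01) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble(position = integer(0), mass = numeric(0),
                    mod = character(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    position <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    mass <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    tibble(position = position, mass = mass,
           mod = assign_mod_names(mass, tolerance))
  })
}

format_lysine_mods <- function(mods) {
  vapply(mods, function(m) {
    if (nrow(m) == 0) return("")
    paste(sprintf("%d:%.4f", m$position, m$mass), collapse = ";")
  }, character(1))
}

finalize_observations <- function(x, probability_floor, tolerance = 0.01,
                                  source = "input") {
  n_in <- nrow(x)
  bad_area <- is.na(x$light_area) | is.na(x$heavy_area) |
    x$light_area < 0 | x$heavy_area < 0
  if (any(bad_area)) {
    message(sum(bad_area), " row(s) rejected from ", source,
            ": missing or negative peak area")
    x <- x[!bad_area, , drop = FALSE]
  }
  low <- !is.na(x$probability) & x$probability < probability_floor
  if (any(low)) {
    message(sum(low), " row(s) dropped from ", source,
            ": probability below ", probability_floor)
    x <- x[!low, , drop = FALSE]
  }
  x$nterm_mod <- assign_mod_names(x$nterm_mod_mass, tolerance)
  x$lysine_mods <- parse_lysine_mods(x$lysine_mod_masses, tolerance)
  x$raw_ratio <- ifelse(x$light_area > 0 & x$heavy_area > 0,
                        x$heavy_area / x$light_area, NA_real_)
  # Rows empty in both channels are retained as unquantified observations;
  # they are only discarded at the aggregation stage.
  x$channel <- dplyr::case_when(
    x$light_area > 0 & x$heavy_area > 0 ~ "both",
    x$light_area > 0 ~ "light_only",
    x$heavy_area > 0 ~ "heavy_only",
    TRUE ~ "none"
  )
  attr(x, "n_input") <- n_in
  attr(x, "n_kept") <- nrow(x)
  as_tibble(x)
}

#' Read PSM observations from the reference TSV dialect
#'
#' The dialect has one row per peptide-spectrum match with columns
#' `spectrum_id`, `run_id`, `sample_id`, `peptide`, `nterm_mod_mass`,
#' `lysine_mod_masses` (semicolon-separated `position:mass` pairs, empty
#' when unmodified), `enzyme` (`LysN` or `trypsin_argc`), `probability`,
#' `light_area`, `heavy_area`. Rows below the probability floor, rows with
#' unparseable areas and rows empty in both channels are dropped with
#' reported counts, so that input rows = kept + reported-dropped.
#'
#' @param path Path to the TSV file.
#' @param schema Optional named character vector remapping file column
#'   names, `c(canonical = "file_column")`.
#' @param probability_floor Identification probability gate (default 0.95);
#'   rows below it are dropped with a message.
#' @param tolerance Modification mass matching tolerance (Da).
#' @return A tibble of observations with derived columns `nterm_mod`,
#'   `lysine_mods` (list column), `raw_ratio` (heavy/light, `NA` for
#'   single-channel rows) and `channel`.
#' @export
read_psm_tsv <- function(path, schema = NULL, probability_floor = 0.95,
                         tolerance = 0.01) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(x)) {
        stop("schema maps `", canon, "` to missing column `", schema[[canon]], "`")
      }
      names(x)[names(x) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(psm_tsv_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("PSM table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- x[, psm_tsv_columns()]
  suppressWarnings({
    x$nterm_mod_mass <- as.numeric(x$nterm_mod_mass)
    x$probability <- as.numeric(x$probability)
    x$light_area <- as.numeric(x$light_area)
    x$heavy_area <- as.numeric(x$heavy_area)
  })
  finalize_observations(as_tibble(x), probability_floor, tolerance,
                        source = basename(path))
}

#' Write observations in the reference TSV dialect
#'
#' Numeric fields are written with fixed precision (4 decimals) so that
#' repeated writes of the same records are byte-identical.
#'
#' @param observations Observation tibble (from a reader or the simulator).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_tsv <- function(observations, path) {
  out <- tibble(
    spectrum_id = observations$spectrum_id,
    run_id = observations$run_id,
    sample_id = observations$sample_id,
    peptide = observations$peptide,
    nterm_mod_mass = sprintf("%.4f", observations$nterm_mod_mass),
    lysine_mod_masses = if ("lysine_mods" %in% names(observations)) {
      format_lysine_mods(observations$lysine_mods)
    } else {
      ifelse(is.na(observations$lysine_mod_masses), "",
             observations$lysine_mod_masses)
    },
    enzyme = observations$enzyme,
    probability = sprintf("%.4f", observations$probability),
    light_area = sprintf("%.4f", observations$light_area),
    heavy_area = sprintf("%.4f", observations$heavy_area)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read PSM observations from a pepXML file
#'
#' A reader for Trans-Proteomic-Pipeline-style pepXML: for each
#' `spectrum_query` the top `search_hit` is taken, with the identification
#' probability from the PeptideProphet `analysis_result`, the two-channel
#' peak areas from the XPRESS `xpressratio_result`, and modifications from
#' `modification_info` (`mod_nterm_mass` is the total N-terminal mass, so
#' the hydrogen mass is subtracted to recover the delta; per-residue
#' `mod_aminoacid_mass` entries on lysine are converted to deltas against
#' the lysine residue mass). Hits lacking quantification become
#' single-channel records. The record contract is identical to
#' [read_psm_tsv()].
#'
#' @param path Path to a pepXML file.
#' @inheritParams read_psm_tsv
#' @return A tibble of observations, as for [read_psm_tsv()].
#' @export
read_pepxml <- function(path, probability_floor = 0.95, tolerance = 0.01) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  lysine_residue_mass <- 128.09496301519  # C6H12N2O monoisotopic

  runs <- xml2::xml_find_all(doc, ".//msms_run_summary")
  rows <- list()
  for (run in runs) {
    run_id <- basename(xml2::xml_attr(run, "base_name"))
    enzyme_raw <- xml2::xml_attr(xml2::xml_find_first(run, ".//sample_enzyme"),
                                 "name")
    enzyme <- if (!is.na(enzyme_raw) && grepl("lysn", enzyme_raw,
                                              ignore.case = TRUE)) {
      "LysN"
    } else {
      "trypsin_argc"
    }
    queries <- xml2::xml_find_all(run, ".//spectrum_query")
    for (q in queries) {
      hit <- xml2::xml_find_first(q, ".//search_hit")
      if (inherits(hit, "xml_missing")) next
      peptide <- xml2::xml_attr(hit, "peptide")
      chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
      minfo <- xml2::xml_find_first(hit, ".//modification_info")
      nterm_mass <- 0
      kmods <- tibble(position = integer(0), mass = numeric(0))
      if (!inherits(minfo, "xml_missing")) {
        tot <- as.numeric(xml2::xml_attr(minfo, "mod_nterm_mass"))
        if (!is.na(tot)) nterm_mass <- tot - .ATOM[["H"]]
        aam <- xml2::xml_find_all(minfo, ".//mod_aminoacid_mass")
        if (length(aam) > 0) {
          pos <- as.integer(xml2::xml_attr(aam, "position"))
          mass <- as.numeric(xml2::xml_attr(aam, "mass"))
          is_k <- chars[pos] == "K"
          kmods <- tibble(position = pos[is_k],
                          mass = mass[is_k] - lysine_residue_mass)
        }
      }
      prob <- as.numeric(xml2::xml_attr(
        xml2::xml_find_first(q, ".//peptideprophet_result"), "probability"))
      xq <- xml2::xml_find_first(q, ".//xpressratio_result")
      light <- heavy <- 0
      if (!inherits(xq, "xml_missing")) {
        light <- as.numeric(xml2::xml_attr(xq, "light_area"))
        heavy <- as.numeric(xml2::xml_attr(xq, "heavy_area"))
      }
      rows[[length(rows) + 1L]] <- tibble(
        spectrum_id = xml2::xml_attr(q, "spectrum"),
        run_id = run_id,
        sample_id = run_id,
        peptide = peptide,
        nterm_mod_mass = nterm_mass,
        lysine_mod_masses = if (nrow(kmods) == 0) "" else
          paste(sprintf("%d:%.4f", kmods$position, kmods$mass), collapse = ";"),
        enzyme = enzyme,
        probability = ifelse(is.na(prob), 1, prob),
        light_area = ifelse(is.na(light), 0, light),
        heavy_area = ifelse(is.na(heavy), 0, heavy)
      )
    }
  }
  if (length(rows) == 0) {
    stop("no spectrum_query records found in ", path)
  }
  finalize_observations(dplyr::bind_rows(rows), probability_floor, tolerance,
                        source = basename(path))
}
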