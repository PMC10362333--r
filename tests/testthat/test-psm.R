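# Expected modification deltas recomputed from standard monoisotopic
# atomic masses, independently of the package's lookup table.
independent_mod_masses <- function() {
  H <- 1.00782503207; C <- 12; C13 <- 13.0033548378
  D <- 2.0141017778; O <- 15.9949146196
  c(dimethyl_light = 2 * (C + 2 * H),      # two CH2 additions
    dimethyl_heavy = 2 * (C13 + 2 * D),    # two 13CD2 additions
    acetyl = C * 2 + H * 2 + O)            # C2H2O
}

test_that("modification masses match first-principles atomic-mass sums", {
  want <- independent_mod_masses()
  got <- modification_masses()
  expect_equal(got[["dimethyl_light"]], want[["dimethyl_light"]], tolerance = 1e-9)
  expect_equal(got[["dimethyl_heavy"]], want[["dimethyl_heavy"]], tolerance = 1e-9)
  expect_equal(got[["acetyl"]], want[["acetyl"]], tolerance = 1e-9)
  # the printed-precision values used in interchange files
  expect_equal(round(got[["dimethyl_light"]], 4), 28.0313)
  expect_equal(round(got[["dimethyl_heavy"]], 4), 34.0631)
  expect_equal(round(got[["acetyl"]], 4), 42.0106)
})

test_that("mass-to-name assignment respects the tolerance", {
  expect_equal(assign_mod_names(c(28.0313, 34.0631, 42.0106, 0)),
               c("dimethyl_light", "dimethyl_heavy", "acetyl", "free"))
  expect_equal(assign_mod_names(27.90), "unknown")
  expect_equal(assign_mod_names(28.0313, tolerance = 0.0001), "dimethyl_light")
  # a tolerance wide enough to cover two names is an ambiguity error
  expect_error(assign_mod_names(31, tolerance = 4), "ambiguous")
})

write_psm_fixture <- function(path) {
  writeLines(c(
    paste("spectrum_id", "run_id", "sample_id", "peptide", "nterm_mod_mass",
          "lysine_mod_masses", "enzyme", "probability", "light_area",
          "heavy_area", sep = "\t"),
    "r1.1\trun1\ts1\tGSAADF\t28.0313\t\tLysN\t0.99\t100\t400",
    "r1.2\trun1\ts1\tGSAADF\t28.0313\t\tLysN\t0.50\t100\t100",
    "r1.3\trun1\ts1\tKAADLF\t42.0106\t\tLysN\t0.99\t120\t0",
    "r1.4\trun1\ts1\tKAADKF\t0\t5:28.0313\tLysN\t0.99\t50\t60",
    "r1.5\trun1\ts1\tKAADRF\t28.0313\t\tLysN\t0.99\tnot_a_number\t10"
  ), path)
}

test_that("TSV ingestion keeps, drops and reports rows per the contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psm_fixture(f)
  expect_message(expect_message(obs <- read_psm_tsv(f),
                                "rejected.*area"),
                 "dropped.*probability")
  # 5 input rows = 3 kept + 1 below floor + 1 bad area
  expect_equal(attr(obs, "n_input"), 5)
  expect_equal(nrow(obs), 3)
  expect_equal(obs$raw_ratio[obs$spectrum_id == "r1.1"], 4.0)
  # single-channel observation carries a flag, not a pseudo-ratio
  singleton <- obs[obs$spectrum_id == "r1.3", ]
  expect_equal(singleton$channel, "light_only")
  expect_true(is.na(singleton$raw_ratio))
  expect_equal(singleton$nterm_mod, "acetyl")
  # lysine modification parsing
  km <- obs$lysine_mods[obs$spectrum_id == "r1.4"][[1]]
  expect_equal(km$position, 5L)
  expect_equal(km$mod, "dimethyl_light")
})

test_that("column remapping works and missing columns are hard errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("spec", "run_id", "sample_id", "peptide", "nterm_mod_mass",
          "lysine_mod_masses", "enzyme", "probability", "light_area",
          "heavy_area", sep = "\t"),
    "r1.1\trun1\ts1\tGSAADF\t28.0313\t\tLysN\t0.99\t100\t400"
  ), f)
  expect_error(read_psm_tsv(f), "missing column")
  obs <- read_psm_tsv(f, schema = c(spectrum_id = "spec"))
  expect_equal(obs$spectrum_id, "r1.1")
})

pepxml_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<msms_pipeline_analysis xmlns="http://regis-web.systemsbiology.net/pepXML">',
    '<msms_run_summary base_name="/data/LATE_run1">',
    '<sample_enzyme name="lysn"/>',
    '<spectrum_query spectrum="LATE_run1.00001.2">',
    '<search_result>',
    '<search_hit hit_rank="1" peptide="GSAADF" protein="P1">',
    '<modification_info mod_nterm_mass="29.0391"/>',
    '<analysis_result analysis="peptideprophet">',
    '<peptideprophet_result probability="0.9900"/>',
    '</analysis_result>',
    '<analysis_result analysis="xpress">',
    '<xpressratio_result light_area="100.0000" heavy_area="400.0000"/>',
    '</analysis_result>',
    '</search_hit>',
    '</search_result>',
    '</spectrum_query>',
    '<spectrum_query spectrum="LATE_run1.00002.2">',
    '<search_result>',
    '<search_hit hit_rank="1" peptide="KAADKF" protein="P2">',
    '<modification_info>',
    '<mod_aminoacid_mass position="5" mass="156.1263"/>',
    '</modification_info>',
    '<analysis_result analysis="peptideprophet">',
    '<peptideprophet_result probability="0.9800"/>',
    '</analysis_result>',
    '</search_hit>',
    '</search_result>',
    '</spectrum_query>',
    '<spectrum_query spectrum="LATE_run1.00003.2">',
    '<search_result>',
    '<search_hit hit_rank="1" peptide="SAADLF" protein="P3">',
    '<analysis_result analysis="peptideprophet">',
    '<peptideprophet_result probability="0.9990"/>',
    '</analysis_result>',
    '<analysis_result analysis="xpress">',
    '<xpressratio_result light_area="80.0000" heavy_area="0.0000"/>',
    '</analysis_result>',
    '</search_hit>',
    '</search_result>',
    '</spectrum_query>',
    '</msms_run_summary>',
    '</msms_pipeline_analysis>'
  ), path)
}

test_that("pepXML ingestion meets the same record contract as the TSV reader", {
  f <- withr::local_tempfile(fileext = ".pep.xml")
  pepxml_fixture(f)
  obs <- read_pepxml(f)
  expect_equal(nrow(obs), 3)
  expect_equal(obs$enzyme, rep("LysN", 3))
  # N-terminal total mass minus hydrogen recovers the dimethyl delta
  expect_equal(obs$nterm_mod[1], "dimethyl_light")
  expect_equal(obs$raw_ratio[1], 4.0)
  # per-residue lysine mass minus the K residue mass recovers the delta
  km <- obs$lysine_mods[[2]]
  expect_equal(km$position, 5L)
  expect_equal(km$mod, "dimethyl_light")
  # hit without a quantification element is an unquantified observation
  expect_equal(obs$channel[2], "none")
  # hit with one empty channel is a singleton
  expect_equal(obs$channel[3], "light_only")

  expect_error(read_pepxml(withr::local_tempfile(fileext = ".xml")))
})

test_that("pepXML records round-trip through the TSV dialect", {
  f <- withr::local_tempfile(fileext = ".pep.xml")
  pepxml_fixture(f)
  obs <- read_pepxml(f)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_psm_tsv(obs, tsv)
  back <- read_psm_tsv(tsv)
  shared <- c("spectrum_id", "run_id", "sample_id", "peptide", "enzyme",
              "probability", "light_area", "heavy_area", "nterm_mod",
              "channel")
  expect_equal(as.data.frame(back[shared]), as.data.frame(obs[shared]))
  expect_equal(back$lysine_mods[[2]]$position, obs$lysine_mods[[2]]$position)
  # writing the re-read table reproduces the file byte for byte
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_psm_tsv(back, tsv2)
  expect_identical(readLines(tsv2), readLines(tsv))
})
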