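test_that("peptide mapping finds all exact matches, with optional I/L folding", {
  p <- toy_proteome(
    P1 = "MAAAADEVDGSAAK",
    P2 = "MKKKDEVDGNIDEV"
  )
  m <- match_peptide("DEVDG", p)
  expect_equal(m$accession, c("P1", "P2"))
  expect_equal(m$start, c(6L, 5L))
  expect_equal(m$end, c(10L, 9L))

  # I/L equivalence folds isobaric residues before matching
  expect_equal(nrow(match_peptide("NLDEV", p)), 0)
  mi <- match_peptide("NLDEV", p, il_equivalent = TRUE)
  expect_equal(mi$accession, "P2")
  expect_equal(mi$start, 10L)

  expect_equal(nrow(match_peptide("WWWWW", p)), 0)
  expect_error(match_peptide("DEV", p), "floor")
})

test_that("peptide mapping agrees with a brute-force scanner", {
  set.seed(404)
  seqs <- vapply(1:15, function(i) random_protein(150), character(1))
  p <- tibble::tibble(accession = sprintf("B%02d", 1:15),
                      entry_name = NA, description = NA, sequence = seqs)
  for (rep in 1:50) {
    i <- sample(15, 1)
    start <- sample(1:(150 - 8), 1)
    pep <- substr(seqs[i], start, start + 7)
    got <- match_peptide(pep, p)
    want <- oracle_match(pep, seqs)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      expect_equal(got$accession[k], p$accession[want[[k]]["i"]])
      expect_equal(got$start[k], unname(as.integer(want[[k]]["start"])))
    }
  }
})

test_that("categories follow the ORF / neo / internal precedence rules", {
  set.seed(505)
  ch <- strsplit(random_protein(130, first_met = TRUE), "")[[1]]
  ch[ch %in% c("K", "R")] <- "G"       # control boundaries explicitly
  ch[92] <- "D"                        # cleaved bond after 92, neo start 93
  ch[102] <- "K"                       # LysN boundary
  ch[113] <- "K"                       # closes the internal peptide 102..112
  seqs <- paste(ch, collapse = "")
  p <- toy_proteome(P1 = seqs)

  obs <- make_obs(
    peptide = c(
      substr(seqs, 1, 12),    # ORF start 1, acetylated
      substr(seqs, 2, 12),    # ORF start 2 of Met protein, dimethylated
      substr(seqs, 93, 101),  # neo start 93, P1 = D, labeled
      substr(seqs, 102, 112)  # full LysN peptide (K..K-1), free -> internal
    ),
    nterm_mod = c("acetyl", "dimethyl_light", "dimethyl_heavy", "free"),
    enzyme = "LysN"
  )
  cl <- classify_observations(obs, p)
  expect_equal(cl$category,
               c("ORF_start1", "ORF_start2", "neo", "internal"))
  expect_equal(cl$met_excised, c(FALSE, TRUE, NA, NA))
  expect_equal(cl$p1_residue[3], "D")
  expect_equal(cl$start[3], 93L)
  expect_equal(cl$nterm_state,
               c("acetylated", "free_labeled", "free_labeled", "free_unlabeled"))
  # P4-P4' window around the cleaved bond of the neo record
  expect_equal(cl$window_P4_P4p[3],
               paste0(substr(seqs, 89, 92), substr(seqs, 93, 96)))
})

test_that("enzymatic-boundary internal calls require a free unlabeled amine", {
  seqs <- paste0("M", strrep("A", 50), "K", strrep("G", 10), "K", strrep("A", 30))
  p <- toy_proteome(P1 = seqs)
  kpos <- 52L
  pep <- substr(seqs, kpos, kpos + 10)  # K...K-1 region, full LysN peptide
  free <- classify_observations(make_obs(pep, nterm_mod = "free"), p)
  labeled <- classify_observations(make_obs(pep, nterm_mod = "dimethyl_light"), p)
  expect_equal(free$category, "internal")
  expect_equal(labeled$category, "neo")
  # a start-2 peptide of a non-Met protein is neo, not ORF
  p2 <- toy_proteome(P2 = paste0("G", strrep("A", 30), "K", strrep("G", 30)))
  st2 <- classify_observations(
    make_obs(substr(p2$sequence, 2, 12), nterm_mod = "dimethyl_light"), p2)
  expect_equal(st2$category, "neo")
})

test_that("multi-protein peptides agreeing on category keep it, else ambiguous", {
  p <- toy_proteome(
    A = paste0("M", strrep("G", 40), "DSAAELGWT", strrep("A", 40)),
    B = paste0("M", strrep("C", 30), "DSAAELGWT", strrep("C", 40)),
    C = paste0("GSAAELGWT", strrep("W", 40))
  )
  # matches A and B as neo (starts 43/33), and C at start 2 of non-Met -> neo
  pep <- "SAAELGWT"
  cl <- classify_observations(make_obs(pep, nterm_mod = "dimethyl_light"), p)
  expect_equal(cl$category, "neo")
  expect_equal(cl$n_matches, 3L)

  # C now Met-initiated: start-2 match becomes ORF_start2, so categories clash
  p$sequence[3] <- sub("^G", "M", p$sequence[3])
  cl2 <- classify_observations(make_obs(pep, nterm_mod = "dimethyl_light"), p)
  expect_equal(cl2$category, "ambiguous")

  # unmatched peptides are reported, never silently dropped
  cl3 <- classify_observations(make_obs("WHWHWHWH", nterm_mod = "free"), p)
  expect_equal(cl3$category, "unmatched")
})

test_that("labeling-efficiency arithmetic is exact on constructed inputs", {
  obs <- make_obs(
    peptide = rep("AAAAAA", 100),
    nterm_mod = c(rep("dimethyl_light", 96), rep("free", 4))
  )
  eff <- labeling_efficiency(obs)
  expect_equal(eff$alpha_labeled_fraction, 0.96)
  expect_equal(eff$alpha_acetylated_fraction, 0)

  # 200 lysines of which 8 labeled
  obs2 <- make_obs(
    peptide = rep("AKAKAA", 100),  # 2 K each
    nterm_mod = "dimethyl_light",
    k_labeled = c(rep(list(c(2L, 4L)), 4), rep(list(integer(0)), 96))
  )
  expect_equal(labeling_efficiency(obs2)$epsilon_labeled_fraction, 8 / 200)

  obs3 <- make_obs(rep("AAAA", 5), nterm_mod = "acetyl")
  eff3 <- labeling_efficiency(obs3)
  expect_equal(eff3$alpha_labeled_fraction, 0)
  expect_equal(eff3$alpha_acetylated_fraction, 1)

  expect_error(labeling_efficiency(obs[0, ]), "no observations")
})

test_that("census counts partition PSMs and deduplicate peptides", {
  seqs <- paste0("M", strrep("A", 40), "DSSGGEETAAAGK", strrep("G", 20))
  p <- toy_proteome(P1 = seqs)
  obs <- make_obs(
    peptide = c(substr(seqs, 1, 10), substr(seqs, 1, 10),
                substr(seqs, 43, 52)),
    nterm_mod = c("acetyl", "acetyl", "dimethyl_light"),
    enzyme = c("LysN", "trypsin_argc", "LysN")
  )
  cl <- classify_observations(obs, p)
  cen <- nterm_census(cl)
  expect_equal(sum(cen$psm$n), nrow(cl))
  # the duplicated peptide counts once at peptide level, twice at PSM level
  expect_equal(sum(cen$peptide$n), 2)
  expect_equal(cen$psm$n[cen$psm$category == "ORF_start1"], 2)
  # protein-method table sees P1 acetylated shared by both enzymes
  pm <- cen$protein_method
  expect_equal(pm$enzymes[pm$state_class == "acetylated"], "LysN+trypsin_argc")
})

test_that("search merging deduplicates and flags conflicting assignments", {
  a <- make_obs(c("AAAADEVD", "CCCCDEVD"), spectrum_id = c("s1", "s2"))
  b <- make_obs(c("AAAADEVD", "GGGGDEVD"), spectrum_id = c("s1", "s3"))
  # identical s1 rows deduplicate; s2/s3 concatenate
  m <- merge_searches(dimethyl = a, acetyl = b)
  expect_equal(nrow(m), 3)
  expect_equal(m$search[m$spectrum_id == "s1"], "acetyl+dimethyl")
  expect_false(any(m$conflict))

  # the same spectrum assigned different peptides by two searches: both kept
  b2 <- make_obs(c("TTTTDEVD"), spectrum_id = "s1")
  expect_warning(m2 <- merge_searches(dimethyl = a, acetyl = b2),
                 "conflicting")
  expect_equal(nrow(m2), 3)
  expect_equal(sum(m2$conflict), 2)
})

test_that("internal-peptide depletion reproduces the configured enrichment", {
  # same seed -> identical events; only the internal background differs
  pre_cfg <- sim_config(seed = 17, n_proteins = 60, n_caspase_sites = 10,
                        n_background_cleavages = 5, n_processing_events = 2,
                        n_neo_acetylation = 2, psm_per_event = 2,
                        n_internal_psms = 400)
  post_cfg <- sim_config(seed = 17, n_proteins = 60, n_caspase_sites = 10,
                         n_background_cleavages = 5, n_processing_events = 2,
                         n_neo_acetylation = 2, psm_per_event = 2,
                         n_internal_psms = 40)
  sim <- make_proteome(pre_cfg)
  pre <- classify_observations(simulate_experiment(sim, pre_cfg),
                               sim$proteome)
  post <- classify_observations(simulate_experiment(sim, post_cfg),
                                sim$proteome)
  term_frac <- function(cl) {
    mean(cl$category %in% c("ORF_start1", "ORF_start2", "neo"))
  }
  observed <- term_frac(post) / term_frac(pre)

  # configured enrichment from the truth table's observability counts
  n_term <- sum(sim$truth$observable_late) + sum(sim$truth$observable_hytane)
  n_term <- n_term * pre_cfg$psm_per_event
  configured <- (n_term / (n_term + 2 * post_cfg$n_internal_psms)) /
    (n_term / (n_term + 2 * pre_cfg$n_internal_psms))
  expect_lt(abs(observed - configured) / configured, 0.10)
  expect_gt(observed, 1)
})
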