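test_that("N-side and C-side digestion follow the specificity rules", {
  lysn <- digest("MKAAKTR", protease_lysn())
  expect_equal(lysn$sequence, c("M", "KAA", "KTR"))
  expect_equal(lysn$start, c(1L, 2L, 5L))
  expect_equal(lysn$end, c(1L, 4L, 7L))

  argc <- digest("MARVKDR", protease_argc())
  expect_equal(argc$sequence, c("MAR", "VKDR"))

  # peptides tile the protein at zero missed cleavages
  expect_equal(paste(lysn$sequence, collapse = ""), "MKAAKTR")
  expect_equal(paste(argc$sequence, collapse = ""), "MARVKDR")

  # trypsin with proline block skips K.P bonds
  tryp <- digest("AKPAKA", protease_trypsin(block_proline = TRUE))
  expect_equal(tryp$sequence, c("AKPAK", "A"))

  expect_error(digest("", protease_lysn()), "zero-length")
})

test_that("missed cleavages emit all contiguous unions of adjacent fragments", {
  d <- digest("MKAAKTR", protease_lysn(), missed_cleavages = 1)
  expect_true(all(c("MKAA", "KAAKTR") %in% d$sequence))
  d2 <- digest("MKAAKTR", protease_lysn(), missed_cleavages = 2)
  expect_true("MKAAKTR" %in% d2$sequence)
  # fragment count: k tiles, k-1 single-missed, k-2 double-missed
  expect_equal(nrow(d2), 3 + 2 + 1)
})

test_that("digestion agrees with the per-bond brute-force oracle", {
  set.seed(101)
  proteases <- list(protease_lysn(), protease_argc(),
                    protease_trypsin(block_proline = TRUE))
  for (rep in 1:40) {
    s <- random_protein(sample(50:300, 1))
    prot <- proteases[[1 + rep %% 3]]
    m <- rep %% 3
    got <- as.data.frame(digest(s, prot, m))
    want <- oracle_digest(s, prot, m)
    expect_equal(got, want)
  }
})

test_that("motif scanning is anchored at P1 and excludes terminal matches", {
  s1 <- scan_motif("AADEVDGK", "DEVD")
  expect_equal(s1$p1_position, 6L)
  expect_equal(s1$p1_residue, "D")

  # protein ending exactly at P1: no downstream residue, no site
  expect_equal(nrow(scan_motif("DEVD", "DEVD")), 0)

  # relaxed single-position motif; last residue never a site
  s2 <- scan_motif("MDAD", "D")
  expect_equal(s2$p1_position, 2L)

  # residue sets and overlapping matches
  s3 <- scan_motif("ADDDG", "[DE]")
  expect_equal(s3$p1_position, c(2L, 3L, 4L))

  expect_error(scan_motif("MDAD", ""), "empty motif")
  expect_error(parse_motif("DEVDX"))  # X not a standard residue
  expect_error(parse_motif("DEVDG"))  # longer than P4..P1
})

test_that("motif scanning agrees with the brute-force position scanner", {
  set.seed(202)
  motifs <- list("DEVD", "[DE]", "D", "DxVD" = list("D", c("E", "A"), "V", "D"))
  for (rep in 1:40) {
    s <- random_protein(sample(50:300, 1))
    m <- motifs[[1 + rep %% 4]]
    got <- scan_motif(s, m)$p1_position
    want <- oracle_scan(s, parse_motif(m))
    expect_equal(got, want)
  }
})

test_that("neo peptides terminate at the method's basic residue", {
  # LATE: ends before the first K strictly after the start
  late <- neo_peptide("AADGSAAKLL", 3, "LATE")
  expect_equal(late$sequence, "GSAA")
  expect_false(late$runs_to_end)

  # HYTANE: ends at the first R at or after the start, inclusive
  hyt <- neo_peptide("AADGSARLL", 3, "HYTANE")
  expect_equal(hyt$sequence, "GSAR")

  # a start residue that is itself R terminates a HYTANE peptide at length 1
  expect_equal(neo_peptide("AADRGG", 3, "HYTANE")$sequence, "R")
  # ... but a start K does not terminate a LATE peptide
  expect_equal(neo_peptide("AADKGGKAA", 3, "LATE")$sequence, "KGG")

  # no terminating residue: peptide runs to the C terminus, flagged
  run <- neo_peptide("AADGGGG", 3, "LATE")
  expect_equal(run$sequence, "GGGG")
  expect_true(run$runs_to_end)

  expect_error(neo_peptide("AADG", 4, "LATE"), "p1_position")
})

test_that("the identifiability window is inclusive on both edges", {
  expect_true(is_identifiable(7))
  expect_true(is_identifiable(35))
  expect_false(is_identifiable(6))
  expect_false(is_identifiable(36))
  expect_error(is_identifiable(10, c(9, 7)), "window")
  expect_error(is_identifiable(0))
})

test_that("nearest-residue distance counts the start residue as 1", {
  expect_equal(nearest_residue_distance("GSAAR", 1, "R"), 5L)
  expect_equal(nearest_residue_distance("RSAAR", 1, "R"), 1L)
  expect_true(is.na(nearest_residue_distance("GSAAG", 1, "R")))
  # distance equals the HYTANE peptide length from the same start
  set.seed(33)
  for (rep in 1:20) {
    s <- random_protein(60)
    start <- sample(3:40, 1)
    d <- nearest_residue_distance(s, start, "R")
    hyt <- neo_peptide(s, start - 1, "HYTANE")
    if (is.na(d)) {
      expect_true(hyt$runs_to_end)
    } else {
      expect_equal(hyt$length, d)
    }
  }
})

test_that("coverage report recovers engineered method-exclusive sites", {
  # each protein carries one DEVD site with K/R terminators at controlled
  # offsets from the neo start
  mk <- function(dk = NA, dr = NA) {
    ch <- rep("G", 80)
    ch[1] <- "M"
    ch[7:10] <- c("D", "E", "V", "D")
    start <- 11
    if (!is.na(dk)) ch[start + dk] <- "K"       # LATE length dk
    if (!is.na(dr)) ch[start + dr - 1] <- "R"   # HYTANE length dr
    paste(ch, collapse = "")
  }
  p <- toy_proteome(
    HONLY = mk(dk = 40, dr = 10),
    LONLY = mk(dk = 10, dr = 40),
    BOTH = mk(dk = 12, dr = 9)
  )
  rep <- coverage_report(p, motif = "DEVD")
  counts <- setNames(rep$site_summary$n, rep$site_summary$category)
  expect_equal(counts[["LATE_only"]], 1L)
  expect_equal(counts[["HYTANE_only"]], 1L)
  expect_equal(counts[["both"]], 1L)
  expect_equal(counts[["neither"]], 0L)

  # zero-match proteome: all-zero summary
  p0 <- toy_proteome(A = "MGGGGGGGGG")
  rep0 <- coverage_report(p0, motif = "DEVD")
  expect_equal(sum(rep0$site_summary$n), 0L)
  expect_equal(nrow(rep0$sites), 0L)
})

test_that("coverage categories partition the scanned sites", {
  set.seed(77)
  p <- toy_proteome()
  seqs <- vapply(1:60, function(i) random_protein(sample(80:400, 1)),
                 character(1))
  p <- tibble::tibble(accession = sprintf("R%03d", 1:60),
                      entry_name = NA, description = NA, sequence = seqs)
  rep <- coverage_report(p, motif = "[DE]")
  n_sites <- nrow(dplyr::distinct(rep$sites, accession, p1_position))
  expect_equal(sum(rep$site_summary$n), n_sites)
  # ORF categories partition the proteins (every protein long enough)
  for (s in unique(rep$orf_summary$orf_start)) {
    expect_equal(sum(rep$orf_summary$n[rep$orf_summary$orf_start == s]),
                 nrow(p))
  }
})

test_that("widening the identifiability window never decreases coverage", {
  set.seed(88)
  seqs <- vapply(1:30, function(i) random_protein(200), character(1))
  p <- tibble::tibble(accession = sprintf("W%03d", 1:30),
                      entry_name = NA, description = NA, sequence = seqs)
  narrow <- coverage_report(p, motif = "[DE]", window = c(7, 35))
  wide <- coverage_report(p, motif = "[DE]", window = c(5, 45))
  n_ident <- function(rep) {
    x <- setNames(rep$site_summary$n, rep$site_summary$category)
    x[["LATE_only"]] + x[["HYTANE_only"]] + x[["both"]]
  }
  expect_gte(n_ident(wide), n_ident(narrow))
})
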