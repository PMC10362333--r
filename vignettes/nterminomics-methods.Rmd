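---
title: "Models and methods behind nterminomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nterminomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nterminomics)
```

## The scientific problem

Proteases such as caspase-3, the executioner protease of apoptosis, cleave
substrates at specific peptide bonds and thereby create new protein N
termini ("neo-N termini"). Negative-selection N-terminomics methods isolate
these N-terminal peptides: the sample is digested, alpha-amines are
isotopically dimethylated (or found naturally blocked by Nt-acetylation),
and internal peptides are depleted through their free lysine epsilon-amines.
Two complementary chemistries are modelled here:

* **LATE** — LysN digestion with N-terminal-specific dimethylation. LysN
  cleaves N-terminally to lysine, so the observable N-terminal peptide runs
  from the (neo-)N terminus to the residue *before* the first downstream
  lysine.
* **HYTANE** — whole-protein dimethylation (blocking every lysine) followed
  by trypsin digestion, which then behaves like ArgC: the observable peptide
  runs from the N terminus *through* the first downstream arginine.

Because the two methods terminate peptides on different basic residues, each
can see cleavage sites the other cannot. The package quantifies that
complementarity, classifies observed peptides, aggregates two-channel
isotopic ratios, winnows candidate caspase-3 cleavage sites, and searches
for posttranslational Nt-acetylation on protease-generated neo-N termini.

## Coordinate conventions

All residue indices are 1-based and inclusive. A cleavage site is the bond
**after** the P1 residue: a site with `p1_position = 93` cleaves between
residues 93 and 94, and the neo-N-terminal peptide starts at 94. The
Schechter–Berger window P4–P4' around a site is the eight residues
`p1 - 3 .. p1 + 4`, padded with `-` at protein termini. Ambiguity codes
(X/U/B/Z) are tolerated in sequences but never match a protease specificity
residue or a motif position — a deliberately conservative rule that can
miss, but never fabricate, a cleavage.

## Identifiability model

A peptide is "identifiable" when its length falls in an inclusive window,
by default 7–35 residues — the usual size range for confident MS
identification of dimethylated peptides. No charge, hydrophobicity or
detectability model is layered on top: the window is the sole criterion,
and it is configurable for sensitivity analysis (`coverage_report(...,
window = )`). Widening the window can only add identifiable sites (a tested
monotonicity property). A neo peptide with no terminating basic residue runs
to the protein C terminus; it is flagged `runs_to_end` and judged by the
same length rule.

For a cleavage site, the HYTANE peptide length equals the distance from the
neo start to the nearest downstream arginine (start residue counted as 1),
and the LATE length is one less than the distance to the first lysine
strictly after the start. `distance_histogram()` exploits this equivalence,
and a cross-module test enforces it.

## Ingestion and classification

The reference interchange format is a documented PSM TSV dialect
(`read_psm_tsv()`); pepXML from a TPP-style search is supported as a reader
(`read_pepxml()`) with the same record contract. Rows are only ever dropped
with a reported count (probability below the 0.95 floor standing in for an
upstream 1% peptide FDR filter, unparseable areas), so input rows always
equal kept plus reported-dropped. Modification deltas are named by nearest
match within 0.01 Da — far below the 6.03 Da spacing of the light/heavy
dimethyl isotopologues.

Classification maps each peptide to the proteome by exact substring search
(optionally folding isobaric I/L) and assigns exactly one category:

* `ORF_start1` / `ORF_start2` — peptide begins at ORF position 1, or at
  position 2 of a Met-initiated protein (initiator-Met excision). ORF
  positions take precedence regardless of label state.
* `internal` — both termini are consistent with the stated enzyme (NET = 2)
  **and** the alpha-amine is free and unlabeled. We require both termini,
  not only the N-terminal one, because a labeled N terminus at an enzymatic
  boundary is evidence the peptide existed before digestion.
* `neo` — everything else mapped, including a start-2 peptide of a
  non-Met-initiated record. A free unlabeled peptide at a non-enzymatic
  boundary is also called neo: its N terminus cannot have been produced by
  the sample-preparation protease, and discarding it would silently lose
  real unlabeled neo termini.
* multi-protein peptides are classified per match; agreeing matches keep
  the category (with multiplicity recorded), disagreeing ones are
  `ambiguous`. No "primary protein" is elected.

## Quantification model

Two-channel areas are median-centred per MS run: the median of
log2(heavy/light) over quantified PSMs is removed by rescaling the heavy
areas, making the post-normalization median exactly zero and cancelling any
global channel-mixing bias. Normalization happens at PSM level, *before*
aggregation — with summed-area aggregation the alternative order is not
equivalent, and centring first keeps the per-run constant interpretable.
Runs with fewer than three quantified PSMs pass through unnormalized with a
warning. Singletons (one empty channel) are never given pseudo-ratios; they
carry a direction flag (`treated_only` / `control_only`) resolved through
the experiment's channel-orientation setting, because the treated sample
may be labeled heavy in one experiment and light in another.

Aggregation groups PSMs by (accession, start, N-terminal state) and sums
areas per channel before forming the ratio, weighting each PSM by its
signal. Significance is a fixed fold-change rule, inclusive by default
(log2 ratio >= 1 at the default 2-fold threshold), with treated-only
singletons always significant; a strict (>) mode is available because the
source literature states the threshold both ways.

## Winnowing

Candidate caspase-3 sites are neo records that (pass the ratio threshold OR
are treated-only) AND have P1 in {D} or {D, E} — Asp is the canonical
caspase P1 and Glu a documented minor specificity. Every stage logs
input/output counts and is monotone (output ⊆ input). `min_evidence()`
implements "identified at least twice" counting PSMs pooled across methods
and runs — the least restrictive reading; per-run distinctness is reported
but not required.

The acetylated-neo-N-terminus workflow routes records through fixed stages:
keep acetylated termini; drop ORF starts; split off peptides explained by
annotated maturation (signal/transit peptide or propeptide removal, mature
chains not starting at residue 1) into a separate processing-derived
output; drop user-supplied alternative-initiation positions; the remainder
are candidate posttranslational neo-Nt-acetylation events, flagged
caspase-linked when they also survive the caspase winnow. The
known-processing split is placed before the alternative-initiation filter
so that a position matching both is reported as a processing product — the
better-evidenced explanation. Reported/novel annotation against
known-cleavage tables is exact-position by default; a ±1 tolerance mode
exists only to document the P1 vs P1' indexing disagreement between public
databases.

## Sequence-context statistics

`dag_logo()` builds differential amino-acid-usage matrices: per window
position, foreground frequency minus background frequency, times 100. The
background is a single frequency vector (typically the whole proteome)
applied to all positions. Padded slots are excluded from both numerator and
denominator rather than treated as a 21st symbol, which preserves the
column-sum-zero property to machine precision. Structural context
(externally computed secondary structure and relative solvent
accessibility) is summarised at P1/P1', and two site groups are contrasted
by a label-permutation test on the difference of median P1 RSA (10,000
permutations by default, seeded) — a deliberately assumption-light stand-in
for an unspecified comparison of RSA distributions.

## The synthetic-data generator

`sim_config()` / `make_proteome()` / `simulate_experiment()` define the
study conditions under which the pipeline is validated:

* random Met-initiated proteins (120 by default, 150–400 residues, human-like
  residue composition); 70% undergo Met excision and 74% carry ORF
  Nt-acetylation — the fractions reported by deep human N-terminome censuses;
* spiked caspase cleavage events (DEVD/DEVE motifs planted at position 60)
  with true log2 treated/control effect of 2.0; terminating K/R residues
  are placed at controlled offsets (LATE peptide 12 residues, HYTANE 10)
  after clearing the downstream region, so LATE-only, HYTANE-only and
  both-identifiable classes exist in known numbers. Observability recorded
  in the truth table is always *recomputed* through the digestion engine,
  never asserted;
* non-caspase background cleavages (null ratio by default), annotated
  transit-peptide processing events with acetylated neo termini,
  caspase-linked neo-acetylation events, and internal full-digest peptides
  with free unlabeled N termini;
* two-channel areas: light ~ log-normal, heavy = light ×
  2^(true_log2 + log2(bias) + N(0, sigma)) with sigma = 0.3 — multiplicative
  ratio noise matching two-channel MS intensity behaviour — at 4 PSMs per
  event and method by default;
* full determinism under the mandatory seed, with fixed-precision TSV/FASTA
  output, so two runs are byte-identical.

What the simulator does **not** emulate: spectrum-level detail (no m/z
peaks), search-engine scoring and FDR behaviour, retention time, missed
cleavages in observed peptides, chimeric spectra, or shared-peptide
ambiguity beyond what random sequences produce. Passing tests therefore
demonstrate the correctness of the computational pipeline under its stated
statistical model, not the behaviour of upstream identification software on
real spectra.

## Numerical choices and validation scale

Tolerances: modification matching 0.01 Da; median-centring asserted to
1e-9; logo column sums to 1e-6; permutation p-values use the
add-one estimator (1 + #extreme)/(n + 1). Ties in peptide-representative
selection take the longest peptide; aggregation is permutation-invariant in
PSM order (tested). The validation suite uses problem sizes chosen to make
every property decisive yet quick: 1,000 random proteins for the
digestion/motif oracle equivalence, 500 spiked + 200 null keys for ratio
recovery (recovered mean within ±0.15, null false-positive rate ≤ 2%), and
the packaged default configuration for end-to-end byte determinism.

## Known limitations

* Exact substring mapping treats isoforms as independent records; peptide
  evidence shared across isoforms becomes `ambiguous` rather than being
  apportioned.
* The identifiability rule is purely length-based; real detectability also
  depends on charge, hydrophobicity and ionisation.
* Database winnowing consumes user-supplied tables (known cleavages,
  alternative initiation); no databases ship with the package.
* Secondary structure and solvent accessibility must be precomputed
  externally; the package only summarises them.
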