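test_that("mature-peptide grammar handles the canonical processing variants", {
  # nonapeptide with GKR signal
  cands <- find_mature_peptides("MKAVLACLITNCPRGGKRSADD")
  expect_equal(cands$residues[1], "CLITNCPRG")
  expect_equal(cands$amidation_signal[1], "GKR")
  expect_true(cands$amidated[1])
  expect_equal(cands$length_class[1], "nonapeptide")

  # unprocessed precursor: ring but no donor/dibasic downstream
  cands <- find_mature_peptides("MSFAVCFILDCPLMIRNDD")
  expect_equal(cands$residues[1], "CFILDCPLM")
  expect_false(cands$amidated[1])
  expect_match(cands$flags[1], "no_processing_site")

  # decapeptide: 4-residue tail before the processing site
  cands <- find_mature_peptides("MAVLCFITNCPVGGGKRDD")
  expect_equal(cands$residues[1], "CFITNCPVGG")
  expect_true(cands$amidated[1])
  expect_equal(cands$length_class[1], "decapeptide")
  expect_match(cands$flags[1], "decapeptide")

  # terminal alanine variant: amidated but non-canonical terminal residue
  cands <- find_mature_peptides("MAVLCFITNCPRAGKRDD")
  expect_equal(cands$residues[1], "CFITNCPRA")
  expect_true(cands$amidated[1])
  expect_match(cands$flags[1], "non_canonical_terminal")

  # no C-X4-C ring at all
  expect_equal(nrow(find_mature_peptides("MAAAAAQQQ")), 0L)
})

test_that("neurophysin framework extraction recovers the template and degrades on truncation", {
  p <- generate_precursor(generator_config(mutation_rate = 0), seed = 31)
  after_mature <- p$truth$mature_interval[2] + 3L  # skip ring + signal
  np <- find_neurophysin(p$record$residues, downstream_of = after_mature)
  expect_equal(np$n_cysteines, 14L)
  expect_length(np$segment_lengths, 13L)
  expect_true(np$complete)
  expect_equal(np$cysteine_positions, p$truth$cysteine_positions)

  trunc <- substr(p$record$residues, 1,
                  floor(0.6 * nchar(p$record$residues)))
  np_t <- find_neurophysin(trunc, downstream_of = after_mature)
  expect_lt(np_t$n_cysteines, 14L)
  expect_false(np_t$complete)

  none <- find_neurophysin("MAAAAAQQQLLLVVV")
  expect_equal(none$n_cysteines, 0L)
  expect_false(none$complete)
})

test_that("annotation recovers generator ground truth exactly at mu = 0", {
  cfg <- generator_config(mutation_rate = 0)
  for (sd in c(1, 12, 33)) {
    p <- generate_precursor(cfg, seed = sd)
    a <- annotate_precursor(p$record)
    expect_equal(a$completeness, "complete")
    expect_equal(c(a$mature$start, a$mature$end), p$truth$mature_interval)
    expect_equal(a$mature$residues, p$truth$peptide)
    expect_equal(a$neurophysin$cysteine_positions,
                 p$truth$cysteine_positions)
    expect_equal(a$signal_region, c(1L, p$truth$mature_interval[1] - 1L))
    # re-annotation of the same residues is identical (deterministic)
    expect_identical(annotate_precursor(p$record), a)
  }
  frag <- generate_precursor(cfg, fragment = TRUE, seed = 44)
  expect_equal(annotate_precursor(frag$record)$completeness,
               "partial_neurophysin_only")
  junk <- sequence_records("j", "MKLAVAVAQQEDDSGHWTYR")
  expect_equal(annotate_precursor(junk)$completeness, "rejected")
})

test_that("batch annotation reports survey statistics and multiplicity", {
  sv <- generate_survey_precursors(generator_config(seed = 9))
  ba <- batch_annotate(sv$records, sv$manifest)
  expect_equal(ba$summary$n_complete, 110L)
  expect_equal(ba$summary$n_amidated_terminal_glycine, 103L)
  expect_equal(ba$summary$n_dibasic_motif, 109L)
  # ordering invariant: amidated-G <= dibasic <= complete
  expect_lte(ba$summary$n_amidated_terminal_glycine,
             ba$summary$n_dibasic_motif)
  expect_lte(ba$summary$n_dibasic_motif, ba$summary$n_complete)

  # two distinct precursors in one species -> multiplicity 2
  cfg <- generator_config(mutation_rate = 0)
  p1 <- generate_precursor(cfg, id = "a1", species = "spA",
                           peptide = "CLITNCPKG", seed = 3)
  p2 <- generate_precursor(cfg, id = "a2", species = "spA",
                           peptide = "CLITNCPIG", seed = 4)
  man <- data.frame(species = "spA", order = "Coleoptera",
                    subphylum = "Hexapoda", dataset = "d",
                    group_label = "Coleoptera")
  ba2 <- batch_annotate(rbind(p1$record, p2$record), man)
  expect_equal(unname(ba2$multiplicity[["spA"]]), 2L)

  expect_error(batch_annotate(p1$record,
                              within(man, species <- "other")),
               "missing from manifest")
  empty <- batch_annotate(p1$record[0, ], man)
  expect_equal(empty$summary$n_complete, 0L)
  expect_equal(empty$summary$n_dibasic_motif, 0L)
})

test_that("complete annotations have internally consistent intervals", {
  cfg <- generator_config(mutation_rate = 0.05)
  set.seed(60)
  for (k in 1:10) {
    p <- generate_precursor(cfg, id = paste0("p", k))
    a <- annotate_precursor(p$record)
    if (a$completeness != "complete") next
    expect_equal(a$signal_region[2] + 1L, a$mature$start)
    sig_len <- if (a$mature$amidated) 3L else 0L
    expect_lte(a$mature$end + sig_len, a$neurophysin$interval[1])
  }
})
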