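sch <- scoring_scheme()

test_that("Smith-Waterman reproduces hand-computed and degenerate cases", {
  # BLOSUM62 diagonal: C9 L4 I4 T5 N6 C9 P7 R5 G6 = 55
  expect_equal(smith_waterman("CLITNCPRG", "CLITNCPRG", sch)$raw_score, 55L)
  al <- smith_waterman("AAAA", "CCCC", sch)  # no positive-scoring pair
  expect_equal(al$raw_score, 0L)
  expect_equal(al$aligned_query, "")
  expect_error(smith_waterman("", "ACD", sch), "empty")
})

test_that("Smith-Waterman equals the exhaustive matching oracle", {
  set.seed(200)
  for (rep in 1:200) {
    a <- random_protein(sample(3:6, 1))
    b <- random_protein(sample(3:6, 1))
    expect_equal(smith_waterman(a, b, sch)$raw_score,
                 bf_local_score(a, b, sch),
                 label = paste(a, "vs", b))
  }
})

test_that("Smith-Waterman agrees with an independent implementation on 15-mers", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(201)
  for (rep in 1:200) {
    a <- random_protein(sample(8:15, 1))
    b <- random_protein(sample(8:15, 1))
    mine <- smith_waterman(a, b, sch)$raw_score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = e$BLOSUM62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    if (mine > 0) expect_equal(mine, as.integer(ref),
                               label = paste(a, "vs", b))
  }
})

test_that("alignment score is symmetric and self-consistent", {
  set.seed(202)
  for (rep in 1:25) {
    a <- random_protein(sample(8:20, 1))
    b <- random_protein(sample(8:20, 1))
    al_ab <- smith_waterman(a, b, sch)
    expect_equal(al_ab$raw_score, smith_waterman(b, a, sch)$raw_score)
    if (al_ab$raw_score > 0) {
      expect_equal(rescore_alignment(al_ab$aligned_query,
                                     al_ab$aligned_subject, sch),
                   al_ab$raw_score)
      # reported intervals really delimit the aligned residues
      expect_equal(gsub("-", "", al_ab$aligned_query),
                   substr(a, al_ab$q_start, al_ab$q_end))
      expect_equal(gsub("-", "", al_ab$aligned_subject),
                   substr(b, al_ab$s_start, al_ab$s_end))
    }
  }
})

test_that("E-values follow the closed form and are monotone in score", {
  # S chosen so lambda*S = ln(K*m*n) gives E = 1
  m <- 120; n <- 5e5
  s_unit <- log(sch$K * m * n) / sch$lambda
  expect_equal(evalue(s_unit, m, n, sch), 1, tolerance = 1e-12)
  expect_equal(evalue(55, 9, 9, sch),
               0.041 * 9 * 9 * exp(-0.267 * 55), tolerance = 1e-12)
  ev <- evalue(40:80, 100, 1e4, sch)
  expect_true(all(diff(ev) < 0))
  expect_error(evalue(50, 0, 10, sch), "positive")
})

test_that("dataset search finds a mutated copy among shuffled decoys", {
  q <- reference_queries()[1, , drop = FALSE]  # the precursor query
  cfg <- generator_config(seed = 77, mutation_rate = 0.05)
  set.seed(cfg$seed)
  copy <- generate_precursor(cfg, id = "copy", species = "spX")$record
  decoys <- do.call(rbind, lapply(1:50, function(i) {
    sequence_records(paste0("d", i),
                     paste(sample(strsplit(copy$residues, "")[[1]]),
                           collapse = ""), species = "spX")
  }))
  hits <- search_dataset(q, rbind(copy, decoys), sch, e_cutoff = 1e-4)
  expect_equal(hits$subject_id, "copy")
  expect_true(hits$e_value < 1e-4)
  # E is strictly positive, so a zero cutoff yields nothing
  expect_equal(nrow(search_dataset(q, rbind(copy, decoys), sch,
                                   e_cutoff = 0)), 0L)
  expect_error(search_dataset(q[0, ], copy), "empty query")
  expect_equal(nrow(search_dataset(q, copy[0, ])), 0L)
})

test_that("nucleotide subjects are found in the right frame with protein coordinates", {
  q <- sequence_records("q", "CLITNCPRGMKWLVNEHG")
  dna <- reverse_translate(q$residues)
  # one leading base on the reverse strand puts the ORF in frame -2
  subject <- sequence_records("nt1", revcomp(paste0("G", dna)),
                              molecule_type = "nucleotide")
  hits <- search_dataset(q, subject, sch, e_cutoff = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$frame, -2L)
  tr <- six_frame_translate(subject)
  frame_prot <- tr$residues[tr$id == "nt1_frame-2"]
  expect_equal(substr(frame_prot, hits$s_start, hits$s_end), q$residues)
})

test_that("perfect-identity search recalls every embedded family member", {
  ds <- generate_dataset(generator_config(seed = 5, n_species = 10,
                                          decoy_count = 20))
  q <- reference_queries()
  prec_hits <- search_dataset(q[1, , drop = FALSE], ds$records, sch)
  rec_hits <- search_dataset(q[2, , drop = FALSE], ds$records, sch)
  want_prec <- ds$truth$record_id[ds$truth$class_label == "precursor"]
  want_rec <- ds$truth$record_id[grepl("^receptor", ds$truth$class_label)]
  expect_true(all(want_prec %in% prec_hits$subject_id))
  expect_true(all(want_rec %in% rec_hits$subject_id))
  # results sorted by significance
  expect_true(!is.unsorted(prec_hits$e_value))
})
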