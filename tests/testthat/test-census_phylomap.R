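test_that("census counts peptides per precursor with deterministic ordering", {
  cen <- build_census(c("P", "P", "Q"))
  expect_equal(unname(cen$counts), c(2L, 1L))
  expect_equal(names(cen$counts), c("P", "Q"))
  expect_equal(cen$total, 3L)
  expect_equal(cen$unique_count, 2L)

  empty <- build_census(character(0))
  expect_equal(empty$total, 0L)
  expect_equal(empty$unique_count, 0L)

  # census conservation: total always equals contributing annotations
  sv <- generate_survey_precursors(generator_config(seed = 2))
  ba <- batch_annotate(sv$records, sv$manifest)
  cen <- build_census(ba)
  expect_equal(cen$total, ba$summary$n_complete)
  expect_setequal(unlist(cen$species_of[["CLITNCPRG"]]),
                  ba$table$species[ba$table$mature == "CLITNCPRG"])
})

test_that("position frequency matrices are proper column distributions", {
  pfm <- build_pfm("CLITNCPRG")
  expect_true(all(apply(pfm$frequencies, 2, max) == 1))
  two <- build_pfm(c("CLITNCPRG", "CLITNCPKG"))
  expect_equal(sort(two$frequencies[, 8][two$frequencies[, 8] > 0]),
               c(0.5, 0.5), ignore_attr = TRUE)
  expect_error(build_pfm(c("CLITNCPRG", "CYIINCIDND")), "length")

  set.seed(10)
  peps <- vapply(1:30, function(i) random_protein(9), character(1))
  pfm <- build_pfm(peps)
  expect_equal(colSums(pfm$frequencies), rep(1, 9), ignore_attr = TRUE,
               tolerance = 1e-12)
  # leave-one-out recomputation equals down-weighting
  res <- rownames(pfm$frequencies)
  expand <- function(p) {
    m <- matrix(0, length(res), 9, dimnames = list(res, 1:9))
    m[rownames(p$frequencies), ] <- p$frequencies
    m
  }
  loo <- expand(build_pfm(peps[-1]))
  manual <- (pfm$frequencies * 30 - expand(build_pfm(peps[1]))) / 29
  expect_equal(loo, manual, tolerance = 1e-12)
})

test_that("consensus derivation marks invariant, majority and variable positions", {
  one <- derive_consensus(build_pfm("CLITNCPRG"))
  expect_equal(one$pattern, "CLITNCPRG")
  expect_equal(one$invariant_positions, 1:9)

  # no residue above the majority threshold -> all X
  set.seed(30)
  peps <- c("AC", "CD", "DA", "GG")
  expect_equal(derive_consensus(build_pfm(peps))$pattern, "XX")

  mix <- derive_consensus(build_pfm(c("CLITNCPRG", "CLITNCPKG",
                                      "CLITNCPKG")))
  expect_equal(substr(mix$pattern, 8, 8), "k")  # majority, not invariant
  expect_false(8 %in% mix$invariant_positions)
})

test_that("neurophysin segment statistics summarise complete frameworks", {
  cfg <- generator_config(mutation_rate = 0)
  set.seed(50)
  fw <- lapply(1:40, function(i) {
    p <- generate_precursor(cfg, id = paste0("p", i))
    find_neurophysin(p$record$residues,
                     downstream_of = p$truth$mature_interval[2] + 3L)
  })
  st <- neurophysin_stats(fw)
  expect_equal(st$n_complete, 40L)
  expect_equal(nrow(st$segments), 13L)
  # jitter is +-1 around the template, so means land within it
  expect_true(all(abs(st$segments$mean - neurophysin_template()) <= 1))
  expect_true(all(st$segments$sd >= 0 & st$segments$sd <= 1))

  same <- fw[c(1, 1, 1)]
  st3 <- neurophysin_stats(same)
  expect_equal(st3$segments$sd, rep(0, 13))
  st1 <- neurophysin_stats(fw[1])
  expect_equal(st1$segments$sd, rep(0, 13))
  expect_equal(st1$segments$flag, rep("single_framework", 13))
  expect_error(neurophysin_stats(list()), "no frameworks")
})

test_that("presence tables and INT/T summaries respect partial evidence", {
  man <- data.frame(species = paste0("sp", 1:4),
                    order = "Coleoptera", subphylum = "Hexapoda",
                    dataset = "d", group_label = "Coleoptera")
  ptab <- data.frame(record_id = c("a", "b"), species = c("sp1", "sp2"),
                     completeness = c("complete",
                                      "partial_neurophysin_only"),
                     mature = c("CLITNCPRG", ""), stringsAsFactors = FALSE)
  calls <- data.frame(record_id = "r1", species = "sp2",
                      label = "inotocin_like", partial = FALSE,
                      stringsAsFactors = FALSE)
  pt <- build_presence_table(ptab, calls, man)
  expect_equal(pt$taxon_summary$INT, 2L)
  expect_equal(pt$taxon_summary$T, 4L)
  # partial precursor plus receptor still counts toward INT
  expect_equal(pt$presence$precursor_status,
               c("present", "partial", "absent", "absent"))
  expect_equal(pt$presence$receptor_status[2], "present")

  none <- build_presence_table(ptab[0, ], calls[0, ], man)
  expect_equal(none$taxon_summary$INT, 0L)

  # INT is monotone as hits are added
  pt2 <- build_presence_table(ptab, rbind(calls, data.frame(
    record_id = "r2", species = "sp3", label = "inotocin_like",
    partial = TRUE)), man)
  expect_gte(pt2$taxon_summary$INT, pt$taxon_summary$INT)

  expect_error(build_presence_table(
    data.frame(record_id = "z", species = "unknown_sp",
               completeness = "complete", mature = "CLITNCPRG"),
    NULL, man), "missing from manifest")
})

test_that("Dollo inference is minimal against exhaustive search", {
  # all leaves present -> no losses
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  pres <- setNames(rep(TRUE, 4), c("A", "B", "C", "D"))
  expect_equal(dollo_losses(tr, pres)$n_losses, 0L)
  # no leaves present -> empty result
  expect_equal(dollo_losses(tr, !pres)$n_losses, 0L)

  set.seed(70)
  for (n in 4:6) {
    tree <- ape::rtree(n)
    combs <- expand.grid(rep(list(c(TRUE, FALSE)), n))
    for (k in seq_len(nrow(combs))) {
      pres <- setNames(unlist(combs[k, ]), tree$tip.label)
      if (!any(pres)) next
      got <- dollo_losses(tree, pres)
      expect_equal(got$n_losses, bf_dollo_losses(tree, pres),
                   label = paste("n =", n, "pattern", k))
      # every present leaf is inside the gain clade, outside loss clades
      lost <- unlist(got$loss_clades)
      expect_true(all(names(pres)[pres] %in% got$gain_clade_tips))
      expect_false(any(names(pres)[pres] %in% lost))
      expect_true(all(!pres[lost]))
    }
  }
  for (n in 7:8) {
    tree <- ape::rtree(n)
    for (k in 1:25) {
      pres <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                       tree$tip.label)
      if (!any(pres)) next
      expect_equal(dollo_losses(tree, pres)$n_losses,
                   bf_dollo_losses(tree, pres))
    }
  }
})

test_that("the ordinal loss of the terminal insect clade is recovered", {
  tr <- load_order_tree()
  absent <- c("Trichoptera", "Lepidoptera", "Siphonaptera", "Mecoptera",
              "Diptera")
  pres <- setNames(!(tr$tip.label %in% absent), tr$tip.label)
  d <- dollo_losses(tr, pres)
  expect_equal(d$n_losses, 1L)
  expect_setequal(d$loss_clades[[1]], absent)
})

test_that("contamination flagging needs both loneliness and peptide sharing", {
  man <- data.frame(
    species = c("fly1", "fly2", "fly3", "fly4", "cope1"),
    order = c(rep("Diptera", 4), "Copepoda"),
    subphylum = c(rep("Hexapoda", 4), "Crustacea"),
    dataset = "d",
    group_label = c(rep("Diptera", 4), "Crustacea"))
  ptab <- data.frame(record_id = c("x", "y"),
                     species = c("fly1", "cope1"),
                     completeness = "complete",
                     mature = "CFITNCPSG", stringsAsFactors = FALSE)
  pt <- build_presence_table(ptab, NULL, man)
  cen <- build_census(ptab)
  expect_equal(flag_contamination(pt, cen, man), "fly1")

  # unique peptide -> condition (b) fails
  ptab2 <- within(ptab, mature <- c("CYITNCPWG", "CFITNCPSG"))
  expect_equal(length(flag_contamination(pt, build_census(ptab2), man)), 0L)

  # whole order present -> no flags
  ptab3 <- data.frame(record_id = letters[1:4],
                      species = paste0("fly", 1:4),
                      completeness = "complete", mature = "CFITNCPSG")
  pt3 <- build_presence_table(ptab3, NULL, man)
  expect_equal(length(flag_contamination(pt3, build_census(ptab3), man)),
               0L)
})
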