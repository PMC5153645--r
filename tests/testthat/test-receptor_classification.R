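test_that("motif scanning applies the anchor rules of both families", {
  # TM2/ECL1 window with all four anchors
  s <- paste0(strrep("G", 10), "LPQLKWDARGTF", strrep("G", 30))
  h <- scan_motif(s, "TM2_ECL1")
  expect_equal(h$matched_window, "LPQLKWDARGTF")
  expect_equal(h$anchor_matches, 4L)
  expect_equal(h$family_vote, "inotocin")
  expect_equal(h$end - h$start + 1L, 12L)

  # TM7 motif in the C-terminal quarter
  s <- paste0(strrep("G", 80), "CYNPW", strrep("G", 3))
  h <- scan_motif(s, "TM7")
  expect_equal(h$matched_window, "CYNPW")
  expect_equal(h$anchor_matches, 2L)
  expect_equal(h$family_vote, "inotocin")

  s <- paste0(strrep("G", 80), "ASNPV", strrep("G", 3))
  h <- scan_motif(s, "TM7")
  expect_equal(h$family_vote, "ccap")

  # the same window outside the C-terminal quarter is not reported
  s <- paste0(strrep("G", 5), "CYNPW", strrep("G", 80))
  expect_equal(nrow(scan_motif(s, "TM7")), 0L)

  # anchor counts recomputable from the matched window
  s <- paste0(strrep("G", 10), "LPQLKWDARGTF", strrep("G", 20),
              "APQLKWDARGTL", strrep("G", 10))
  h <- scan_motif(s, "TM2_ECL1")
  for (k in seq_len(nrow(h))) {
    w <- strsplit(h$matched_window[k], "")[[1]]
    n_ino <- sum(w[2] == "P", w[3] == "Q", w[6] == "W",
                 w[length(w)] == "F")
    if (h$family_vote[k] == "inotocin")
      expect_equal(h$anchor_matches[k], n_ino)
  }
})

test_that("generated receptors classify to their own family, truncations via TM7", {
  cfg <- generator_config(mutation_rate = 0)
  for (sd in c(2, 13, 27)) {
    ino <- generate_receptor(cfg, "inotocin", seed = sd)
    expect_equal(classify_receptor(ino$record)$label, "inotocin_like")
    cc <- generate_receptor(cfg, "ccap", seed = sd + 100)
    expect_equal(classify_receptor(cc$record)$label, "ccap_like")
  }
  tr <- generate_receptor(cfg, "inotocin", truncate_nterm = TRUE, seed = 5)
  call <- classify_receptor(tr$record, partial = TRUE)
  expect_equal(call$label, "inotocin_like")
  expect_true(call$partial)
  expect_true(all(call$hits$motif_id == "TM7"))
})

test_that("classification is deterministic and order-invariant", {
  cfg <- generator_config(mutation_rate = 0)
  set.seed(88)
  recs <- do.call(rbind, lapply(1:6, function(i)
    generate_receptor(cfg, if (i %% 2) "inotocin" else "ccap",
                      id = paste0("r", i))$record))
  a <- classify_receptors(recs)
  b <- classify_receptors(recs[rev(seq_len(nrow(recs))), ])
  b <- b[match(a$record_id, b$record_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("a family's motifs never yield the opposite label, even under heavy mutation", {
  # anchor sparing off at mu = 0.3: calls may degrade to unclassified but
  # never flip family while >= 3 TM2 inotocin anchors are intact
  set.seed(300)
  flips <- 0L
  for (k in 1:100) {
    cfg <- generator_config(mutation_rate = 0.3)
    ino <- generate_receptor(cfg, "inotocin", anchor_sparing = FALSE)
    ch <- strsplit(ino$record$residues, "")[[1]]
    tm2_anchors <- ino$truth$anchor_positions[1:4]
    intact <- sum(ch[tm2_anchors] == c("P", "Q", "W", "F"))
    lab <- classify_receptor(ino$record)$label
    if (intact >= 3 && lab == "ccap_like") flips <- flips + 1L
    cc <- generate_receptor(cfg, "ccap", anchor_sparing = FALSE)
    if (classify_receptor(cc$record)$label == "inotocin_like") {
      # an inotocin call needs a strictly stronger inotocin margin, which
      # mutation cannot manufacture while the CCAP evidence stands
      ch2 <- strsplit(cc$record$residues, "")[[1]]
      tm7 <- cc$truth$anchor_positions[3:6]
      if (all(ch2[tm7[1:3]] == c("A", "N", "P")) &&
          ch2[tm7[4]] %in% c("V", "L", "F"))
        flips <- flips + 1L
    }
  }
  expect_equal(flips, 0L)
})

test_that("neighbour-joining over alignment identity groups families", {
  cfg <- generator_config(mutation_rate = 0)
  set.seed(41)
  same <- sequence_records(c("a", "b", "c"),
                           rep(random_protein(60), 3))
  tr <- pairwise_identity_tree(same)
  expect_s3_class(tr, "phylo")
  expect_equal(sum(tr$edge.length), 0)

  # additive four-taxon distances: ((A,B),(C,D)) recovered
  base <- random_protein(100)
  mut <- function(s, idx) {
    ch <- strsplit(s, "")[[1]]
    ch[idx] <- ifelse(ch[idx] == "A", "S", "A")
    paste(ch, collapse = "")
  }
  quart <- sequence_records(c("A", "B", "C", "D"),
                            c(mut(base, 1:5), mut(base, 6:10),
                              mut(base, 41:55), mut(base, 56:70)))
  tr <- pairwise_identity_tree(quart)
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))

  cfg2 <- generator_config(mutation_rate = 0.05)
  set.seed(42)
  recs <- do.call(rbind, c(
    lapply(1:8, function(i) generate_receptor(
      cfg2, "inotocin", id = paste0("ino", i))$record),
    lapply(1:8, function(i) generate_receptor(
      cfg2, "ccap", id = paste0("ccap", i))$record)))
  tr <- pairwise_identity_tree(recs)
  expect_true(ape::is.monophyletic(tr, paste0("ino", 1:8)))
  expect_true(ape::is.monophyletic(tr, paste0("ccap", 1:8)))

  expect_error(pairwise_identity_tree(same[1:2, ]), "at least 3")
})
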