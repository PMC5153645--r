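# Average proteome amino-acid composition (Swiss-Prot-style frequencies),
# selectable as scaffold/decoy background instead of the uniform default.
.PROTEOME_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9,
                    E = 6.7, G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8,
                    M = 2.4, F = 3.9, P = 4.7, S = 6.6, T = 5.3, W = 1.1,
                    Y = 2.9, V = 6.9)
.HYDROPHOBIC <- c("A", "V", "L", "I", "F", "M", "W")

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.sample_res <- function(n, background = "uniform", exclude = "C") {
  w <- if (background == "proteome") .PROTEOME_FREQ
    else setNames(rep(1, 20), names(.PROTEOME_FREQ))
  w <- w[setdiff(names(w), exclude)]
  sample(names(w), n, replace = TRUE, prob = w)
}

#' Inter-cysteine segment lengths of the packaged neurophysin template
#'
#' Thirteen fixed segment lengths (residues between consecutive
#' framework cysteines) used to assemble synthetic neurophysin domains.
#' They are package configuration chosen within the short ranges typical
#' of real neurophysins, not claims about any particular species;
#' length 4 is deliberately avoided so no C-X4-C ring motif can occur
#' inside the framework.
#'
#' @return integer vector of length 13.
#' @export
neurophysin_template <- function() {
  c(6L, 2L, 9L, 3L, 5L, 1L, 0L, 7L, 3L, 2L, 6L, 10L, 2L)
}

#' Configuration for the synthetic-data generator
#'
#' @param seed integer RNG seed; identical config and seed reproduce
#'   every emitted sequence byte-identically.
#' @param n_species number of species in a generated dataset.
#' @param peptide_pool data.frame with columns `sequence` and `weight`;
#'   defaults to the packaged arthropod peptides weighted by their
#'   observed precursor frequencies.
#' @param mutation_rate per-residue substitution probability (< 0.5).
#' @param truncation_prob probability that a species' precursor is
#'   emitted as a neurophysin-only fragment (truncated transcript).
#' @param decoy_count number of shuffled decoy sequences in a dataset.
#' @param receptor_family_mix named proportions over
#'   `c(inotocin, ccap)` for receptors carried by sampled species.
#' @param amidation_signal_weights named proportions over the dibasic
#'   signals `GKR`, `GRK`, `GKK` (GKR highest, as observed).
#' @param background scaffold/decoy residue composition: `"uniform"`
#'   over the 20 residues or `"proteome"` (average composition).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_species = 20L,
                             peptide_pool = NULL, mutation_rate = 0,
                             truncation_prob = 0, decoy_count = 50L,
                             receptor_family_mix = c(inotocin = 0.7,
                                                     ccap = 0.3),
                             amidation_signal_weights = c(GKR = 0.8,
                                                          GRK = 0.12,
                                                          GKK = 0.08),
                             background = c("uniform", "proteome")) {
  background <- match.arg(background)
  if (is.null(peptide_pool)) {
    fx <- load_table1_fixture()
    fx <- fx[fx$frequency > 0, ]
    peptide_pool <- data.frame(sequence = fx$sequence,
                               weight = fx$frequency,
                               amidated = fx$amidated,
                               stringsAsFactors = FALSE)
  }
  if (!nrow(peptide_pool)) stop("empty peptide pool")
  if (is.null(peptide_pool$amidated)) peptide_pool$amidated <- TRUE
  if (mutation_rate < 0 || mutation_rate >= 0.5)
    stop("mutation_rate must be in [0, 0.5)")
  if (abs(sum(receptor_family_mix) - 1) > 1e-9 ||
      abs(sum(amidation_signal_weights) - 1) > 1e-9)
    stop("proportions must sum to 1")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 peptide_pool = peptide_pool,
                 mutation_rate = mutation_rate,
                 truncation_prob = truncation_prob,
                 decoy_count = as.integer(decoy_count),
                 receptor_family_mix = receptor_family_mix,
                 amidation_signal_weights = amidation_signal_weights,
                 background = background),
            class = "generator_config")
}

# Fixed base scaffolds shared by all generated family members, so that
# synthetic homologues are actually homologous (recoverable by local
# alignment). Built once per session from a private RNG stream and
# sanitised against accidental diagnostic-motif windows.
.base_scaffolds <- function() {
  if (!is.null(.inoto_env$scaffolds)) return(.inoto_env$scaffolds)
  sc <- .with_seed(7041776L, {
    signal <- paste0("M", paste(sample(.HYDROPHOBIC, 21, replace = TRUE),
                                collapse = ""))
    linker <- paste(.sample_res(6), collapse = "")
    np_fillers <- lapply(neurophysin_template(),
                         function(L) .sample_res(L))
    tail <- paste(.sample_res(5), collapse = "")
    # receptor scaffold: background residues with 7 hydrophobic stretches
    L <- 385L
    res <- .sample_res(L)
    tm_starts <- round(seq(0.05, 0.87, length.out = 7) * L)
    for (s in tm_starts) {
      idx <- s:min(L, s + 20L)
      res[idx] <- sample(.HYDROPHOBIC, length(idx), replace = TRUE)
    }
    list(signal = signal, linker = linker, np_fillers = np_fillers,
         tail = tail, receptor = res,
         tm2_at = round(0.22 * L), tm7_at = round(0.88 * L))
  })
  sc$receptor <- .sanitize_receptor_scaffold(sc$receptor, sc$tm2_at,
                                             sc$tm7_at)
  .inoto_env$scaffolds <- sc
  sc
}

# remove chance motif windows from a scaffold (positions that will be
# overwritten by the embedded motifs are exempt)
.sanitize_receptor_scaffold <- function(res, tm2_at, tm7_at) {
  embedded <- c(tm2_at:(tm2_at + 12L), tm7_at:(tm7_at + 4L))
  for (iter in 1:50) {
    s <- paste(res, collapse = "")
    hits <- rbind(scan_motif(s, "TM2_ECL1"), scan_motif(s, "TM7"))
    if (nrow(hits))
      hits <- hits[!(hits$start %in% embedded | hits$end %in% embedded), ,
                   drop = FALSE]
    if (!nrow(hits)) break
    h <- hits[1, ]
    # break the window's first matched anchor
    pos <- if (h$motif_id == "TM2_ECL1") {
      cand <- c(h$start + 1L, h$start + 2L, h$start + 5L, h$end)
      ok <- strsplit(h$matched_window, "")[[1]][cand - h$start + 1L] %in%
        c("P", "Q", "W", "F", "D")
      if (!any(ok)) cand[1] else cand[ok][1]
    } else h$start
    res[pos] <- if (res[pos] == "T") "S" else "T"
  }
  res
}

.mutate <- function(ch, mu, protected = integer(0)) {
  if (mu <= 0) return(ch)
  idx <- setdiff(which(runif(length(ch)) < mu), protected)
  for (i in idx) {
    # substitutions only; never create or destroy a cysteine outside the
    # protected set, so framework/ring labels stay true
    repl <- setdiff(names(.PROTEOME_FREQ), c(ch[i], "C"))
    ch[i] <- sample(repl, 1)
  }
  ch
}

#' Generate one synthetic inotocin precursor
#'
#' Assembles signal region (hydrophobic, 22 residues) + mature peptide
#' (drawn from the pool) + amidation signal (drawn by weight) +
#' linker + 14-cysteine neurophysin built from the packaged template
#' with inter-cysteine lengths jittered by one residue + tail. Point
#' mutations at the configured rate are applied outside the two ring
#' cysteines and the 14 framework cysteines, and never introduce new
#' cysteines, so ground-truth domain labels remain valid.
#'
#' @param config a [generator_config()]; its RNG seed is NOT set here —
#'   callers seed once (see [generate_dataset()]) or pass `seed`.
#' @param id,species record metadata.
#' @param peptide mature peptide override (default: drawn from pool).
#' @param amidated override for the amidation signal's presence
#'   (default: the pool row's flag).
#' @param fragment emit only the neurophysin-containing C-terminal
#'   fragment (truncated transcript; expected annotation
#'   `partial_neurophysin_only`).
#' @param seed optional integer; when given, generation is seeded and
#'   reproducible in isolation.
#' @return list: `record` (1-row sequence-record data.frame), `truth`
#'   (class label, domain intervals, peptide, amidation signal).
#' @export
generate_precursor <- function(config = generator_config(), id = "prec1",
                               species = "sp1", peptide = NULL,
                               amidated = NULL, fragment = FALSE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- .base_scaffolds()
  pool <- config$peptide_pool
  if (is.null(peptide)) {
    k <- sample(nrow(pool), 1, prob = pool$weight)
    peptide <- pool$sequence[k]
    if (is.null(amidated)) amidated <- pool$amidated[k]
  }
  if (is.null(amidated)) {
    row <- match(peptide, pool$sequence)
    amidated <- if (!is.na(row)) pool$amidated[row] else TRUE
  }
  sig <- if (amidated) {
    nm <- sample(names(config$amidation_signal_weights), 1,
                 prob = config$amidation_signal_weights)
    paste0("G", substr(nm, 2, 3))
  } else ""
  tmpl <- neurophysin_template()
  repeat {
    np <- character(0)
    seg_lens <- integer(0)
    for (k in seq_along(tmpl)) {
      L <- tmpl[k]
      allowed <- setdiff(max(0L, L - 1L):(L + 1L), 4L)
      jl <- if (length(allowed) > 1L) sample(allowed, 1) else allowed
      seg_lens <- c(seg_lens, jl)
      # jitter the shared filler so family members stay homologous
      filler <- sc$np_fillers[[k]]
      filler <- if (jl < L) filler[seq_len(jl)]
        else if (jl > L) c(filler, .sample_res(jl - L, config$background))
        else filler
      np <- c(np, "C", filler)
    }
    np <- c(np, "C")
    # adjacent short segments may combine into an accidental C-X4-C
    # ring; redraw the jitter so the framework stays ring-free
    cpos <- which(np == "C")
    if (!any(outer(cpos, cpos, "-") == 5L)) break
  }
  parts <- c(strsplit(sc$signal, "")[[1]], strsplit(peptide, "")[[1]],
             strsplit(sig, "")[[1]], strsplit(sc$linker, "")[[1]], np,
             strsplit(sc$tail, "")[[1]])
  sig_len <- nchar(sc$signal)
  mat_start <- sig_len + 1L
  mat_end <- sig_len + nchar(peptide)
  np_start <- mat_end + nchar(sig) + nchar(sc$linker) + 1L
  cys <- np_start + cumsum(c(0L, seg_lens + 1L))
  protected <- c(mat_start, mat_start + 5L, cys)
  parts <- .mutate(parts, config$mutation_rate, protected)
  truth <- list(record_id = id, class_label = "precursor",
                species = species, peptide = peptide, amidated = amidated,
                amidation_signal = sig,
                signal_interval = c(1L, sig_len),
                mature_interval = c(mat_start, mat_end),
                neurophysin_interval = c(cys[1], cys[length(cys)]),
                cysteine_positions = cys, segment_lengths = seg_lens,
                fragment = fragment)
  if (fragment) {
    from <- mat_end + nchar(sig) + 1L  # drop signal + mature + amidation
    parts <- parts[from:length(parts)]
    truth$class_label <- "precursor_fragment"
    shift <- function(x) x - from + 1L
    truth$signal_interval <- truth$mature_interval <- NULL
    truth$neurophysin_interval <- shift(truth$neurophysin_interval)
    truth$cysteine_positions <- shift(truth$cysteine_positions)
  }
  list(record = sequence_records(id, paste(parts, collapse = ""),
                                 species = species,
                                 source_dataset = "synthetic"),
       truth = truth)
}

#' Generate one synthetic receptor
#'
#' Emits a ~385-residue 7-transmembrane-like scaffold (shared across
#' all generated receptors, so family members are recoverable by local
#' alignment) with the family's TM2/ECL1 variant embedded in the
#' N-terminal region and its TM7 variant in the C-terminal region.
#' Inotocin family: `X-P-Q-X-X-W-X{5,6}-F` and `C-X-N-P-W`; CCAP:
#' `X-X-D-X{8}-W` and `A-X-N-P-[V/L/F]`. Mutations at the configured
#' rate spare the anchor residues unless `anchor_sparing = FALSE`.
#'
#' @param config a [generator_config()].
#' @param family `"inotocin"` or `"ccap"`.
#' @param id,species record metadata.
#' @param anchor_sparing protect embedded anchor residues from
#'   mutation (default TRUE).
#' @param truncate_nterm drop the N-terminal half (partial receptor
#'   retaining only the TM7 evidence).
#' @param seed optional integer for isolated reproducible generation.
#' @return list: `record`, `truth` (family, motif intervals, anchors).
#' @export
generate_receptor <- function(config = generator_config(),
                              family = c("inotocin", "ccap"),
                              id = "rec1", species = "sp1",
                              anchor_sparing = TRUE,
                              truncate_nterm = FALSE, seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  sc <- .base_scaffolds()
  res <- sc$receptor
  bg <- config$background
  if (family == "inotocin") {
    spacer <- sample(5:6, 1)
    tm2 <- c(.sample_res(1, bg), "P", "Q", .sample_res(2, bg), "W",
             .sample_res(spacer, bg), "F")
    tm7 <- c("C", .sample_res(1, bg), "N", "P", "W")
  } else {
    tm2 <- c(.sample_res(2, bg), "D", .sample_res(8, bg), "W")
    tm7 <- c("A", .sample_res(1, bg), "N", "P", sample(c("V", "L", "F"), 1))
  }
  pre <- res[1:(sc$tm2_at - 1L)]
  mid <- res[(sc$tm2_at + 13L):(sc$tm7_at - 1L)]
  post <- res[(sc$tm7_at + 5L):length(res)]
  ch <- c(pre, tm2, mid, tm7, post)
  tm2_start <- length(pre) + 1L
  tm7_start <- length(pre) + length(tm2) + length(mid) + 1L
  anchors <- if (family == "inotocin")
    c(tm2_start + 1L, tm2_start + 2L, tm2_start + 5L,
      tm2_start + length(tm2) - 1L, tm7_start, tm7_start + 2L,
      tm7_start + 3L, tm7_start + 4L)
  else
    c(tm2_start + 2L, tm2_start + 11L, tm7_start, tm7_start + 2L,
      tm7_start + 3L, tm7_start + 4L)
  ch <- .mutate(ch, config$mutation_rate,
                protected = if (anchor_sparing) anchors else integer(0))
  truth <- list(record_id = id,
                class_label = paste0("receptor_", family),
                species = species,
                tm2_interval = c(tm2_start, tm2_start + length(tm2) - 1L),
                tm7_interval = c(tm7_start, tm7_start + 4L),
                anchor_positions = anchors, truncated = truncate_nterm)
  if (truncate_nterm) {
    from <- floor(length(ch) / 2) + 1L
    ch <- ch[from:length(ch)]
    truth$tm2_interval <- NULL
    truth$tm7_interval <- truth$tm7_interval - from + 1L
    truth$anchor_positions <- truth$anchor_positions -
      from + 1L
    truth$anchor_positions <-
      truth$anchor_positions[truth$anchor_positions > 0]
  }
  list(record = sequence_records(id, paste(ch, collapse = ""),
                                 species = species,
                                 source_dataset = "synthetic"),
       truth = truth)
}

#' Generate a shuffled decoy sequence
#'
#' Decoys are composition-preserving shuffles of a source sequence (or
#' random background draws), subsequently sanitised so that no window
#' votes for either receptor family — they are guaranteed negatives.
#'
#' @param config a [generator_config()].
#' @param source residues to shuffle; when NULL a random background
#'   sequence of `length` residues is drawn.
#' @param length length of a random decoy.
#' @param id,species record metadata.
#' @return list: `record`, `truth`.
#' @export
generate_decoy <- function(config = generator_config(), source = NULL,
                           length = 200L, id = "decoy1", species = "sp1") {
  ch <- if (!is.null(source)) sample(strsplit(toupper(source), "")[[1]])
    else .sample_res(length, config$background, exclude = character(0))
  n <- base::length(ch)
  ch <- .sanitize_receptor_scaffold(ch, tm2_at = n + 10L, tm7_at = n + 10L)
  list(record = sequence_records(id, paste(ch, collapse = ""),
                                 species = species,
                                 source_dataset = "synthetic"),
       truth = list(record_id = id, class_label = "decoy",
                    species = species))
}

#' Generate the precursor survey set used for amidation statistics
#'
#' Composes a synthetic survey of 110 complete precursors mirroring the
#' canonical proportions of a mined arthropod collection: 103 carrying
#' an amidated C-terminal glycine, 6 amidated peptides with a
#' non-glycine terminal residue (terminal A/S nonapeptides and the
#' terminal-D/S decapeptides), and 1 unprocessed precursor with no
#' amidation signal. All 110 carry a complete neurophysin framework, so
#' 109 have the dibasic amidation motif.
#'
#' @param config a [generator_config()]; `seed` is applied.
#' @return list: `records` (110 protein records), `manifest`, `truth`
#'   (per-record peptide and amidation), `expected` counts.
#' @export
generate_survey_precursors <- function(config = generator_config()) {
  set.seed(config$seed)
  fx <- load_table1_fixture()
  arth <- fx[fx$frequency > 0, ]
  gly <- arth[arth$amidated &
                substr(arth$sequence, nchar(arth$sequence),
                       nchar(arth$sequence)) == "G", ]
  nong <- c("CFITNCPRA", "CFITNCPPA", "CFISNCPVS", "CFISNCPVS",
            "CYIINCIDND", "CFITNCPVGS")
  peps <- c(sample(gly$sequence, 103, replace = TRUE, prob = gly$frequency),
            nong, "CFILDCPLM")
  amid <- c(rep(TRUE, 109), FALSE)
  orders <- c("Coleoptera", "Hymenoptera", "Hemiptera", "Orthoptera",
              "Chelicerata", "Crustacea")
  subp <- c(rep("Hexapoda", 4), "Chelicerata", "Crustacea")
  grp <- rep_len(seq_along(orders), 110)
  manifest <- data.frame(
    species = sprintf("survey_sp_%03d", 1:110),
    order = orders[grp], subphylum = subp[grp],
    dataset = "synthetic_survey", stringsAsFactors = FALSE)
  manifest$group_label <- ifelse(manifest$subphylum == "Hexapoda",
                                 manifest$order, manifest$subphylum)
  out <- lapply(1:110, function(i)
    generate_precursor(config, id = sprintf("survey_prec_%03d", i),
                       species = manifest$species[i], peptide = peps[i],
                       amidated = amid[i]))
  list(records = do.call(rbind, lapply(out, `[[`, "record")),
       manifest = manifest,
       truth = data.frame(record_id = vapply(out, function(x)
         x$truth$record_id, character(1)), peptide = peps, amidated = amid,
         stringsAsFactors = FALSE),
       expected = list(n = 110L, n_amidated_terminal_glycine = 103L,
                       n_dibasic_motif = 109L))
}

#' Generate a complete labelled dataset
#'
#' A runnable input set for the whole pipeline: per-species precursor
#' and receptor sequences over a taxonomy, shuffled decoys, a species
#' manifest, ground-truth labels and the pruned taxonomy tree. Species
#' assigned to `absent_groups` receive no inotocin system (ground-truth
#' absences for loss inference); every species may carry a CCAP
#' receptor according to the configured family mix. A fraction of
#' precursors (`truncation_prob`) is emitted as neurophysin-only
#' fragments.
#'
#' @param config a [generator_config()]; `seed` is applied, and the
#'   same config reproduces every sequence byte-identically.
#' @param groups taxon groups (tips of [load_order_tree()]) to sample.
#' @param absent_groups groups whose species lack the system.
#' @return list: `records`, `manifest`, `truth`, `tree` (pruned
#'   `phylo`), `config`.
#' @export
generate_dataset <- function(config = generator_config(),
                             groups = c("Chelicerata", "Crustacea",
                                        "Orthoptera", "Hymenoptera",
                                        "Coleoptera", "Trichoptera",
                                        "Lepidoptera", "Diptera"),
                             absent_groups = c("Trichoptera",
                                               "Lepidoptera", "Diptera")) {
  set.seed(config$seed)
  tree <- load_order_tree()
  if (!all(groups %in% tree$tip.label))
    stop("unknown groups: ",
         paste(setdiff(groups, tree$tip.label), collapse = ", "))
  grp <- rep_len(groups, config$n_species)
  subph <- ifelse(grp %in% c("Chelicerata", "Myriapoda", "Crustacea"),
                  grp, "Hexapoda")
  manifest <- data.frame(
    species = sprintf("sp_%s_%02d", tolower(grp), seq_len(config$n_species)),
    order = grp, subphylum = subph, dataset = "synthetic",
    stringsAsFactors = FALSE)
  manifest$group_label <- ifelse(manifest$subphylum == "Hexapoda",
                                 manifest$order, manifest$subphylum)
  recs <- list(); truths <- list()
  add <- function(x) {
    recs[[length(recs) + 1L]] <<- x$record
    truths[[length(truths) + 1L]] <<- x$truth
  }
  for (i in seq_len(config$n_species)) {
    sp <- manifest$species[i]
    if (grp[i] %in% absent_groups) {
      # no inotocin system; a CCAP receptor may still be present
      if (runif(1) < config$receptor_family_mix[["ccap"]])
        add(generate_receptor(config, "ccap",
                              id = sprintf("%s_ccapr", sp), species = sp))
      next
    }
    frag <- runif(1) < config$truncation_prob
    add(generate_precursor(config, id = sprintf("%s_prec", sp),
                           species = sp, fragment = frag))
    add(generate_receptor(config, "inotocin",
                          id = sprintf("%s_inor", sp), species = sp))
    if (runif(1) < config$receptor_family_mix[["ccap"]])
      add(generate_receptor(config, "ccap",
                            id = sprintf("%s_ccapr", sp), species = sp))
  }
  records <- do.call(rbind, recs)
  if (config$decoy_count > 0) {
    srcs <- records$residues[1 + (seq_len(config$decoy_count) - 1L) %%
                               nrow(records)]
    for (d in seq_len(config$decoy_count)) {
      sp <- manifest$species[1 + (d - 1L) %% config$n_species]
      add(generate_decoy(config, source = srcs[d],
                         id = sprintf("decoy_%03d", d), species = sp))
    }
    records <- do.call(rbind, recs)
  }
  truth <- do.call(rbind, lapply(truths, function(t)
    data.frame(record_id = t$record_id, class_label = t$class_label,
               species = t$species, stringsAsFactors = FALSE)))
  list(records = records, manifest = manifest, truth = truth,
       truth_details = truths,
       tree = ape::keep.tip(tree, unique(grp)), config = config)
}

#' Write a generated dataset to disk
#'
#' Emits `sequences.faa`, `manifest.tsv`, `truth.tsv`, `taxonomy.nwk`
#' and `config.json` into a directory; regenerating from the same
#' config reproduces the files byte-identically.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$records, file.path(dir, "sequences.faa"))
  write.table(dataset$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, file.path(dir, "taxonomy.nwk"))
  cfg <- dataset$config
  cfg$peptide_pool <- NULL  # recoverable from the packaged fixture
  writeLines(.config_json(cfg), file.path(dir, "config.json"))
  invisible(dir)
}

.config_json <- function(cfg) {
  num <- function(x) paste0("[", paste(unname(x), collapse = ","), "]")
  paste0('{"seed":', cfg$seed, ',"n_species":', cfg$n_species,
         ',"mutation_rate":', cfg$mutation_rate,
         ',"truncation_prob":', cfg$truncation_prob,
         ',"decoy_count":', cfg$decoy_count,
         ',"receptor_family_mix":', num(cfg$receptor_family_mix),
         ',"amidation_signal_weights":', num(cfg$amidation_signal_weights),
         ',"background":"', cfg$background, '"}')
}

#' Deterministic reference query sequences
#'
#' A mutation-free canonical precursor (mature peptide CLITNCPRG, GKR
#' signal) and inotocin-family receptor, generated from fixed internal
#' seeds, for use as homology-search queries.
#'
#' @return sequence-record data.frame with records `ref_precursor` and
#'   `ref_receptor`.
#' @export
reference_queries <- function() {
  cfg <- generator_config(mutation_rate = 0)
  p <- .with_seed(1609L, generate_precursor(
    cfg, id = "ref_precursor", species = "reference",
    peptide = "CLITNCPRG", amidated = TRUE))
  r <- .with_seed(1905L, generate_receptor(
    cfg, "inotocin", id = "ref_receptor", species = "reference"))
  rbind(p$record, r$record)
}
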