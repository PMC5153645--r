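# Kyte-Doolittle hydropathy, used only for the advisory signal-peptide flag
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.DIBASIC <- c("KR", "RK", "KK")

#' Scan a precursor for candidate mature peptides
#'
#' The mature oxytocin/vasopressin-family peptide is recognised by its
#' disulfide ring grammar: a cysteine at positions 1 and 6 (C-X4-C)
#' followed by a 3-residue tail (nonapeptide) or 4-residue tail
#' (decapeptide) and an amidation signal — a glycine amide donor
#' immediately after the terminal residue, then a dibasic convertase
#' pair (KR, RK or KK; RR is accepted but flagged `unusual_dibasic`).
#' For each ring the nonapeptide reading is tried first, then the
#' decapeptide; rings with neither valid signal are still reported as
#' unamidated nonapeptide candidates (flag `no_processing_site`) so that
#' unprocessed precursors remain representable.
#'
#' @param precursor protein sequence string.
#' @return data.frame of candidates in sequence order: `start`, `end`
#'   (1-based inclusive, mature domain), `residues`, `ring`, `tail`,
#'   `terminal_residue`, `amidated`, `amidation_signal` (`""` if
#'   absent), `length_class`, `flags` (`;`-separated).
#' @export
find_mature_peptides <- function(precursor) {
  s <- toupper(precursor)
  if (!nzchar(s)) stop("empty precursor sequence")
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  ring_starts <- which(ch == "C" & c(ch[-(1:5)], rep("", 5)) == "C")
  ring_starts <- ring_starts[ring_starts + 5 <= n]
  out <- list()
  for (i in ring_starts) {
    cand <- NULL
    for (tail_len in c(3L, 4L)) {
      end <- i + 5L + tail_len
      if (end > n) next
      sig <- substr(s, end + 1L, end + 3L)
      if (nchar(sig) == 3L && substr(sig, 1, 1) == "G" &&
          substr(sig, 2, 3) %in% c(.DIBASIC, "RR")) {
        flags <- character(0)
        if (substr(sig, 2, 3) == "RR") flags <- "unusual_dibasic"
        term <- substr(s, end, end)
        if (term != "G") flags <- c(flags, "non_canonical_terminal")
        if (tail_len == 4L) flags <- c(flags, "decapeptide")
        cand <- data.frame(
          start = i, end = end, residues = substr(s, i, end),
          ring = substr(s, i, i + 5L), tail = substr(s, i + 6L, end),
          terminal_residue = term, amidated = TRUE, amidation_signal = sig,
          length_class = if (tail_len == 3L) "nonapeptide" else "decapeptide",
          flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(cand) && i + 8L <= n) {
      end <- i + 8L
      cand <- data.frame(
        start = i, end = end, residues = substr(s, i, end),
        ring = substr(s, i, i + 5L), tail = substr(s, i + 6L, end),
        terminal_residue = substr(s, end, end), amidated = FALSE,
        amidation_signal = "", length_class = "nonapeptide",
        flags = "no_processing_site", stringsAsFactors = FALSE)
    }
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      residues = character(), ring = character(),
                      tail = character(), terminal_residue = character(),
                      amidated = logical(), amidation_signal = character(),
                      length_class = character(), flags = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Locate the cysteine-rich neurophysin framework
#'
#' Finds the densest cysteine chain downstream of a position: the
#' maximal run of cysteines in which consecutive cysteines are at most
#' `max_gap` residues apart. At least `min_cysteines` are required to
#' call a framework at all; the canonical framework carries 14
#' conserved cysteines, so `complete` is TRUE iff exactly 14 are found.
#'
#' @param precursor protein sequence string.
#' @param downstream_of only cysteines strictly after this 1-based
#'   position are considered (0 = whole sequence).
#' @param max_gap maximum number of residues between consecutive
#'   framework cysteines (default 30).
#' @param min_cysteines minimum cysteines to call a framework (default 6).
#' @return list: `interval` (first/last cysteine, 1-based inclusive, or
#'   NULL), `cysteine_positions`, `segment_lengths` (residues strictly
#'   between consecutive cysteines), `n_cysteines`, `complete`.
#' @export
find_neurophysin <- function(precursor, downstream_of = 0L,
                             max_gap = 30L, min_cysteines = 6L) {
  s <- toupper(precursor)
  if (downstream_of < 0L || downstream_of > nchar(s))
    stop("downstream_of out of bounds")
  cys <- which(strsplit(s, "")[[1]] == "C")
  cys <- cys[cys > downstream_of]
  none <- list(interval = NULL, cysteine_positions = integer(0),
               segment_lengths = integer(0), n_cysteines = 0L,
               complete = FALSE)
  if (!length(cys)) return(none)
  # split into chains broken where the inter-cysteine gap exceeds max_gap
  brk <- c(0L, which(diff(cys) > max_gap + 1L), length(cys))
  chains <- lapply(seq_len(length(brk) - 1L),
                   function(k) cys[(brk[k] + 1L):brk[k + 1L]])
  sizes <- vapply(chains, length, integer(1))
  best <- chains[[which.max(sizes)]]  # most cysteines, ties -> first
  if (length(best) < min_cysteines) return(none)
  list(interval = c(best[1], best[length(best)]),
       cysteine_positions = best,
       segment_lengths = if (length(best) > 1L) diff(best) - 1L else integer(0),
       n_cysteines = length(best),
       complete = length(best) == 14L)
}

#' Annotate one candidate precursor
#'
#' Parses a protein record into the canonical precursor architecture:
#' signal region, mature peptide, amidation signal, neurophysin
#' framework. The best mature candidate is the first ring with a valid
#' amidation signal; failing that, the first ring followed within
#' `neurophysin_window` residues by a neurophysin framework.
#' Completeness: `complete` (mature + framework), `partial_neurophysin_only`
#' (framework only; truncated transcripts lacking the mature domain),
#' `rejected` (neither).
#'
#' @param record single-row protein sequence record.
#' @param max_gap,min_cysteines passed to [find_neurophysin()].
#' @param neurophysin_window maximum distance (residues) between mature
#'   domain end and framework start for the fallback selection.
#' @return list of class `precursor_annotation`: `record_id`, `species`,
#'   `signal_region` (c(start,end) or NULL), `mature` (one-row candidate
#'   data.frame or NULL), `neurophysin`, `completeness`, `flags`.
#' @export
annotate_precursor <- function(record, max_gap = 30L, min_cysteines = 6L,
                               neurophysin_window = 150L) {
  if (nrow(record) != 1L) stop("annotate_precursor takes a single record")
  s <- toupper(record$residues)
  cands <- find_mature_peptides(s)
  flags <- character(0)
  mature <- NULL
  if (nrow(cands)) {
    with_sig <- which(cands$amidated)
    if (length(with_sig)) {
      mature <- cands[with_sig[1], ]
      if (length(with_sig) > 1L) flags <- c(flags, "multiple_mature_candidates")
    } else {
      # fall back to the first ring followed closely by a framework
      for (k in seq_len(nrow(cands))) {
        np <- find_neurophysin(s, downstream_of = cands$end[k],
                               max_gap = max_gap,
                               min_cysteines = min_cysteines)
        if (np$n_cysteines >= min_cysteines &&
            np$interval[1] - cands$end[k] <= neurophysin_window) {
          mature <- cands[k, ]
          break
        }
      }
    }
  }
  sig_len <- if (!is.null(mature) && mature$amidated) 3L else 0L
  np <- if (!is.null(mature)) {
    find_neurophysin(s, downstream_of = mature$end + sig_len,
                     max_gap = max_gap, min_cysteines = min_cysteines)
  } else {
    find_neurophysin(s, downstream_of = 0L, max_gap = max_gap,
                     min_cysteines = min_cysteines)
  }
  has_np <- np$n_cysteines >= min_cysteines
  completeness <- if (!is.null(mature) && has_np) "complete"
    else if (is.null(mature) && has_np) "partial_neurophysin_only"
    else "rejected"
  signal_region <- if (!is.null(mature) && mature$start > 1L)
    c(1L, mature$start - 1L) else NULL
  if (!is.null(mature)) {
    flags <- c(flags, strsplit(mature$flags, ";")[[1]])
    if (!is.null(signal_region) && !.has_hydrophobic_core(s, signal_region[2]))
      flags <- c(flags, "weak_signal_like")
  }
  structure(list(record_id = record$id, species = record$species,
                 signal_region = signal_region, mature = mature,
                 neurophysin = np, completeness = completeness,
                 flags = unique(flags[nzchar(flags)])),
            class = "precursor_annotation")
}

# advisory: does the prefix carry an 8-residue window of Kyte-Doolittle
# mean hydropathy > 1.5 within its first 30 residues?
.has_hydrophobic_core <- function(s, prefix_end, window = 8L, cut = 1.5) {
  pre <- substr(s, 1L, min(30L, prefix_end))
  v <- .KD[strsplit(pre, "")[[1]]]
  v[is.na(v)] <- 0
  if (length(v) < window) return(FALSE)
  mx <- max(vapply(seq_len(length(v) - window + 1L),
                   function(i) mean(v[i:(i + window - 1L)]), numeric(1)))
  mx > cut
}

#' Annotate a set of precursor candidates and summarise
#'
#' Runs [annotate_precursor()] over every record, checks each species
#' against the manifest, and reports the headline counts: complete and
#' partial precursors, precursors whose amidated terminal residue is the
#' conserved glycine, precursors carrying the dibasic amidation motif,
#' and per-species multiplicity of complete precursors.
#'
#' @param records protein sequence records.
#' @param manifest species manifest (see [read_species_manifest()]).
#' @param ... passed to [annotate_precursor()].
#' @return list: `annotations` (one list of `precursor_annotation`),
#'   `table` (one row per record: record_id, species, completeness,
#'   mature peptide, amidation signal, terminal residue, cysteine count,
#'   flags), `summary` (named counts), `multiplicity` (complete
#'   precursors per species).
#' @export
batch_annotate <- function(records, manifest, ...) {
  unknown <- setdiff(unique(records$species), manifest$species)
  if (length(unknown))
    stop("species missing from manifest: ", paste(unknown, collapse = ", "))
  anns <- lapply(seq_len(nrow(records)),
                 function(i) annotate_precursor(records[i, ], ...))
  tab <- do.call(rbind, lapply(anns, function(a) {
    data.frame(record_id = a$record_id, species = a$species,
               completeness = a$completeness,
               mature = if (is.null(a$mature)) "" else a$mature$residues,
               amidated = if (is.null(a$mature)) FALSE else a$mature$amidated,
               amidation_signal = if (is.null(a$mature)) ""
                 else a$mature$amidation_signal,
               terminal_residue = if (is.null(a$mature)) ""
                 else a$mature$terminal_residue,
               n_cysteines = a$neurophysin$n_cysteines,
               neurophysin_complete = a$neurophysin$complete,
               flags = paste(a$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) tab <- data.frame()
  cmpl <- tab$completeness == "complete"
  summ <- list(
    n_records = nrow(records),
    n_complete = sum(cmpl),
    n_partial = sum(tab$completeness == "partial_neurophysin_only"),
    n_rejected = sum(tab$completeness == "rejected"),
    n_amidated_terminal_glycine =
      sum(cmpl & tab$amidated & tab$terminal_residue == "G"),
    n_dibasic_motif = sum(cmpl & tab$amidated))
  mult <- if (any(cmpl)) table(tab$species[cmpl]) else table(character(0))
  list(annotations = anns, table = tab, summary = summ, multiplicity = mult)
}
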