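#' Motif definitions for receptor classification
#'
#' Two diagnostic regions separate oxytocin/vasopressin-family
#' (inotocin) receptors from their closest paralogues, the CCAP
#' (crustacean cardioactive peptide) receptors:
#'
#' * `TM2_ECL1` — end of transmembrane helix 2 / start of extracellular
#'   loop 1: consensus `X-P-Q-X-X-W-X{5,6}-F` (12 residues with the
#'   5-spacer, 13 with the 6-spacer), anchors P2, Q3, W6 and the final
#'   F; at least 3 of the 4 anchors must be identical for an inotocin
#'   vote. The CCAP variant is `X-X-D-X{8}-W` (both anchors required).
#' * `TM7` — transmembrane helix 7 around the NP motif common to both
#'   families: `C-X-N-P-W` with anchors C1 and W5 (at least 1 required)
#'   versus the CCAP variant `A-X-N-P-[V/L/F]`.
#'
#' @format list keyed by motif id with pattern spans, anchor positions
#'   and minimum anchor counts.
#' @export
MOTIF_DEFINITIONS <- list(
  TM2_ECL1 = list(spans = c(12L, 13L), min_anchor_matches = 3L,
                  ccap_min_anchor_matches = 2L, region_frac = c(0, 0.60)),
  TM7 = list(spans = 5L, min_anchor_matches = 1L,
             ccap_min_anchor_matches = 1L, region_frac = c(0.75, 1)))

.anchor_counts <- function(w, motif_id) {
  ch <- strsplit(w, "")[[1]]
  L <- length(ch)
  if (motif_id == "TM2_ECL1") {
    ino <- sum(ch[2] == "P", ch[3] == "Q", ch[6] == "W", ch[L] == "F")
    ccap <- if (L == 12L) sum(ch[3] == "D", ch[12] == "W") else 0L
  } else { # TM7: NP scaffold at positions 3-4 is common to both families
    if (!(ch[3] == "N" && ch[4] == "P")) return(c(ino = 0L, ccap = 0L))
    ino <- sum(ch[1] == "C", ch[5] == "W")
    ccap <- sum(ch[1] == "A", ch[5] %in% c("V", "L", "F"))
  }
  c(ino = as.integer(ino), ccap = as.integer(ccap))
}

#' Scan a protein for one diagnostic receptor motif
#'
#' Slides every spacer variant of the motif over its positional window
#' (TM2/ECL1 over the N-terminal 60% of the sequence, TM7 over the
#' C-terminal 25%, as deterministic proxies for helix position), scores
#' each window by anchor identity against both the inotocin-family
#' pattern and the CCAP variant, and votes for the family whose
#' mandatory anchors are satisfied (equal-strength votes cancel to
#' `none`). Overlapping hits are pruned to the best per locus (more
#' anchors, then leftmost).
#'
#' @param seq protein sequence string.
#' @param motif_id `"TM2_ECL1"` or `"TM7"`.
#' @param region_frac length-2 fraction of the sequence to scan;
#'   defaults from [MOTIF_DEFINITIONS].
#' @return data.frame of hits: `motif_id`, `start`, `end` (1-based
#'   inclusive), `matched_window`, `anchor_matches` (winning family),
#'   `ccap_anchor_matches`, `family_vote`.
#' @export
scan_motif <- function(seq, motif_id = c("TM2_ECL1", "TM7"),
                       region_frac = NULL) {
  motif_id <- match.arg(motif_id)
  s <- toupper(seq)
  if (!nzchar(s)) stop("empty sequence")
  def <- MOTIF_DEFINITIONS[[motif_id]]
  if (is.null(region_frac)) region_frac <- def$region_frac
  n <- nchar(s)
  lo <- max(1L, floor(region_frac[1] * n) + 1L)
  hi <- ceiling(region_frac[2] * n)
  rows <- list()
  for (span in def$spans) {
    if (hi - lo + 1L < span) next
    for (i in lo:(hi - span + 1L)) {
      w <- substr(s, i, i + span - 1L)
      ac <- .anchor_counts(w, motif_id)
      ino_ok <- ac[["ino"]] >= def$min_anchor_matches
      ccap_ok <- ac[["ccap"]] >= def$ccap_min_anchor_matches
      vote <- if (ino_ok && (!ccap_ok || ac[["ino"]] > ac[["ccap"]])) "inotocin"
        else if (ccap_ok && (!ino_ok || ac[["ccap"]] > ac[["ino"]])) "ccap"
        else "none"
      if (vote == "none") next
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = motif_id, start = i, end = i + span - 1L,
        matched_window = w,
        anchor_matches = if (vote == "inotocin") ac[["ino"]] else ac[["ccap"]],
        ccap_anchor_matches = ac[["ccap"]], family_vote = vote,
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(motif_id = character(), start = integer(),
                      end = integer(), matched_window = character(),
                      anchor_matches = integer(),
                      ccap_anchor_matches = integer(),
                      family_vote = character(), stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  h <- do.call(rbind, rows)
  # prune overlaps: most anchors, then leftmost
  h <- h[order(-h$anchor_matches, h$start), , drop = FALSE]
  keep <- logical(nrow(h))
  taken <- integer(0)
  for (k in seq_len(nrow(h))) {
    span_k <- h$start[k]:h$end[k]
    if (!any(span_k %in% taken)) {
      keep[k] <- TRUE
      taken <- c(taken, span_k)
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Classify a candidate GPCR as inotocin-like or CCAP-like
#'
#' Full-length sequences are classified from both motifs (an inotocin
#' vote from either suffices); partial sequences lacking the N-terminal
#' domain use only the TM7 motif. When both families receive votes, the
#' vote margins are compared (margin = anchors matched minus the
#' family's minimum for that motif, maximised over hits):
#' `inotocin_like` requires the inotocin margin to strictly exceed the
#' CCAP margin, otherwise the call is `unclassified` with flag
#' `conflicting_evidence`. `ccap_like` additionally requires that no
#' window voted inotocin at all, so a sequence retaining three or more
#' inotocin TM2/ECL1 anchors can never be called CCAP-like.
#'
#' @param record single-row protein sequence record.
#' @param partial TRUE when the N-terminal domain is missing.
#' @return list of class `receptor_call`: `record_id`, `species`,
#'   `label` (`inotocin_like` / `ccap_like` / `unclassified`), `hits`,
#'   `partial`, `flags`.
#' @export
classify_receptor <- function(record, partial = FALSE) {
  if (nrow(record) != 1L) stop("classify_receptor takes a single record")
  s <- record$residues
  hits <- if (partial) scan_motif(s, "TM7")
    else rbind(scan_motif(s, "TM2_ECL1"), scan_motif(s, "TM7"))
  flags <- character(0)
  margin <- function(fam) {
    h <- hits[hits$family_vote == fam, , drop = FALSE]
    if (!nrow(h)) return(-Inf)
    mins <- vapply(h$motif_id, function(m) {
      d <- MOTIF_DEFINITIONS[[m]]
      if (fam == "inotocin") d$min_anchor_matches else d$ccap_min_anchor_matches
    }, integer(1))
    max(h$anchor_matches - mins)
  }
  ino_m <- margin("inotocin")
  ccap_m <- margin("ccap")
  ino <- is.finite(ino_m)
  ccap <- is.finite(ccap_m)
  label <- if (ino && (!ccap || ino_m > ccap_m)) "inotocin_like"
    else if (ccap && !ino) "ccap_like"
    else "unclassified"
  if (ino && ccap) flags <- "conflicting_evidence"
  structure(list(record_id = record$id, species = record$species,
                 label = label, hits = hits, partial = partial,
                 flags = flags),
            class = "receptor_call")
}

#' Classify a set of receptors into a calls table
#'
#' @param records protein sequence records.
#' @param partial logical, recycled over records.
#' @return data.frame: `record_id`, `species`, `label`, `partial`,
#'   `tm2_anchor_matches`, `tm7_anchor_matches`, `tm2_window`,
#'   `tm7_window`, `flags`.
#' @export
classify_receptors <- function(records, partial = FALSE) {
  partial <- rep_len(partial, nrow(records))
  do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    cl <- classify_receptor(records[i, ], partial = partial[i])
    pick <- function(id) {
      h <- cl$hits[cl$hits$motif_id == id & cl$hits$family_vote != "none", ]
      if (!nrow(h)) return(list(a = 0L, w = ""))
      h <- h[order(-h$anchor_matches, h$start), ]
      list(a = h$anchor_matches[1], w = h$matched_window[1])
    }
    t2 <- pick("TM2_ECL1"); t7 <- pick("TM7")
    data.frame(record_id = cl$record_id, species = cl$species,
               label = cl$label, partial = cl$partial,
               tm2_anchor_matches = t2$a, tm7_anchor_matches = t7$a,
               tm2_window = t2$w, tm7_window = t7$w,
               flags = paste(cl$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Neighbour-joining tree over pairwise alignment identities
#'
#' A quick grouping check for receptor families: pairwise global
#' alignments with free end gaps (same substitution matrix and gap
#' costs as the search scheme), distance 1 - identities/alignment
#' length, then neighbour joining.
#'
#' @param records >= 3 protein sequence records.
#' @param scheme a [scoring_scheme()].
#' @return unrooted `phylo` tree (tips = record ids).
#' @export
pairwise_identity_tree <- function(records, scheme = scoring_scheme()) {
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 records")
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  aas <- Biostrings::AAStringSet(setNames(records$residues, records$id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    al <- Biostrings::pairwiseAlignment(
      aas[[i]], aas[[j]], type = "overlap",
      substitutionMatrix = scheme$substitution_scores,
      gapOpening = scheme$gap_open_penalty,
      gapExtension = scheme$gap_extend_penalty)
    pid <- Biostrings::nmatch(al) / Biostrings::nchar(al)
    d[i, j] <- d[j, i] <- 1 - pid
  }
  ape::nj(stats::as.dist(d))
}
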