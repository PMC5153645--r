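#' Census of mature peptides
#'
#' Deduplicated counts of mature peptides over complete precursor
#' annotations. Counting is per precursor, not per species: a species
#' with two precursors encoding different peptides contributes two.
#'
#' @param annotations output of [batch_annotate()], its `table`
#'   component, or a plain character vector of mature peptides.
#' @param species optional species per peptide when `annotations` is a
#'   character vector.
#' @return list of class `peptide_census`: `counts` (named integer,
#'   descending count then lexicographic), `species_of` (peptide ->
#'   character vector of species), `total`, `unique_count`.
#' @export
build_census <- function(annotations, species = NULL) {
  if (is.list(annotations) && !is.data.frame(annotations) &&
      !is.null(annotations$table))
    annotations <- annotations$table
  if (is.data.frame(annotations)) {
    keep <- annotations$completeness == "complete"
    peptides <- annotations$mature[keep]
    species <- annotations$species[keep]
  } else {
    peptides <- as.character(annotations)
    if (is.null(species)) species <- rep("", length(peptides))
  }
  if (!length(peptides)) {
    return(structure(list(counts = integer(0),
                          species_of = list(), total = 0L,
                          unique_count = 0L), class = "peptide_census"))
  }
  tab <- table(peptides)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[order(-counts, names(counts))]
  species_of <- lapply(names(counts),
                       function(p) sort(unique(species[peptides == p])))
  names(species_of) <- names(counts)
  structure(list(counts = counts, species_of = species_of,
                 total = length(peptides),
                 unique_count = length(counts)),
            class = "peptide_census")
}

#' Position frequency matrix over equal-length peptides
#'
#' Column-wise residue frequencies (logo data), weighted one count per
#' precursor occurrence, not per unique peptide.
#'
#' @param peptides character vector of equal-length peptides.
#' @return list of class `position_frequency_matrix`: `length`,
#'   `frequencies` (residues x positions, columns sum to 1), `support`
#'   (peptides contributing per position).
#' @export
build_pfm <- function(peptides) {
  if (!length(peptides)) stop("no peptides given")
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1L)
    stop("peptides differ in length: ",
         paste(unique(peptides[lens != lens[1]]), collapse = ", "))
  L <- lens[1]
  mat <- do.call(rbind, strsplit(toupper(peptides), ""))
  residues <- sort(unique(as.vector(mat)))
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = residues))
    as.numeric(tab) / nrow(mat)
  }, numeric(length(residues)))
  freq <- matrix(freq, nrow = length(residues),
                 dimnames = list(residues, seq_len(L)))
  structure(list(length = L, frequencies = freq,
                 support = rep(nrow(mat), L)),
            class = "position_frequency_matrix")
}

#' Derive a consensus pattern from a position frequency matrix
#'
#' Positions whose top residue frequency is 1 are invariant and printed
#' upper-case; positions whose top frequency exceeds the majority
#' threshold (but is below 1) are printed lower-case; all others are X.
#'
#' @param pfm a [build_pfm()] result.
#' @param majority_threshold frequency above which a non-invariant
#'   residue is reported in lower case (default 0.5).
#' @return list of class `consensus_result`: `pattern`,
#'   `invariant_positions` (1-based).
#' @export
derive_consensus <- function(pfm, majority_threshold = 0.5) {
  tol <- 1e-9
  top_i <- apply(pfm$frequencies, 2, which.max)
  top_f <- pfm$frequencies[cbind(top_i, seq_len(pfm$length))]
  top_r <- rownames(pfm$frequencies)[top_i]
  pattern <- ifelse(top_f >= 1 - tol, top_r,
                    ifelse(top_f > majority_threshold, tolower(top_r), "X"))
  structure(list(pattern = paste(pattern, collapse = ""),
                 invariant_positions = which(top_f >= 1 - tol)),
            class = "consensus_result")
}

#' Inter-cysteine segment statistics of neurophysin frameworks
#'
#' Means and standard deviations (n-1 denominator) of the 13 aligned
#' inter-cysteine segment lengths over complete (14-cysteine)
#' frameworks; partial frameworks contribute to bookkeeping only.
#'
#' @param frameworks list of [find_neurophysin()] results.
#' @return list: `segments` data.frame (`segment`, `mean`, `sd`, `n`,
#'   `flag`), `n_complete`, `n_partial`.
#' @export
neurophysin_stats <- function(frameworks) {
  if (!length(frameworks)) stop("no frameworks given")
  complete <- Filter(function(f) isTRUE(f$complete), frameworks)
  n_partial <- length(frameworks) - length(complete)
  if (!length(complete))
    return(list(segments = data.frame(), n_complete = 0L,
                n_partial = n_partial))
  segs <- do.call(rbind, lapply(complete, function(f) f$segment_lengths))
  n <- nrow(segs)
  sds <- if (n > 1L) apply(segs, 2, sd) else rep(0, ncol(segs))
  list(segments = data.frame(
         segment = seq_len(ncol(segs)),
         mean = colMeans(segs), sd = sds, n = n,
         flag = if (n == 1L) "single_framework" else ""),
       n_complete = n, n_partial = n_partial)
}

#' Per-species presence table and per-taxon summaries
#'
#' Species status for precursor and receptor, each `present`, `partial`
#' or `absent`, plus per-group INT/T summaries: INT counts species with
#' receptor and/or precursor present or partial, T the species sampled.
#'
#' @param precursor_annotations a [batch_annotate()] result (or its
#'   `table`); may be NULL.
#' @param receptor_calls a [classify_receptors()] table; may be NULL.
#' @param manifest species manifest covering every species involved.
#' @return list: `presence` data.frame (`species`, `group_label`,
#'   `precursor_status`, `receptor_status`, `system_present`),
#'   `taxon_summary` data.frame (`group_label`, `INT`, `T`).
#' @export
build_presence_table <- function(precursor_annotations = NULL,
                                 receptor_calls = NULL, manifest) {
  ptab <- if (is.list(precursor_annotations) &&
              !is.data.frame(precursor_annotations))
    precursor_annotations$table else precursor_annotations
  seen <- c(if (!is.null(ptab)) ptab$species,
            if (!is.null(receptor_calls)) receptor_calls$species)
  unknown <- setdiff(unique(seen), manifest$species)
  if (length(unknown))
    stop("species missing from manifest: ", paste(unknown, collapse = ", "))
  status_of <- function(sp) {
    prec <- "absent"
    if (!is.null(ptab) && nrow(ptab)) {
      cc <- ptab$completeness[ptab$species == sp]
      if (any(cc == "complete")) prec <- "present"
      else if (any(cc == "partial_neurophysin_only")) prec <- "partial"
    }
    rec <- "absent"
    if (!is.null(receptor_calls) && nrow(receptor_calls)) {
      rr <- receptor_calls[receptor_calls$species == sp &
                             receptor_calls$label == "inotocin_like", ]
      if (nrow(rr)) rec <- if (any(!rr$partial)) "present" else "partial"
    }
    c(prec, rec)
  }
  st <- vapply(manifest$species, status_of, character(2))
  presence <- data.frame(species = manifest$species,
                         group_label = manifest$group_label,
                         precursor_status = st[1, ],
                         receptor_status = st[2, ],
                         stringsAsFactors = FALSE)
  presence$system_present <- presence$precursor_status != "absent" |
    presence$receptor_status != "absent"
  ts <- do.call(rbind, lapply(split(presence, presence$group_label),
                              function(g) data.frame(
                                group_label = g$group_label[1],
                                INT = sum(g$system_present),
                                T = nrow(g), stringsAsFactors = FALSE)))
  rownames(ts) <- NULL
  list(presence = presence, taxon_summary = ts[order(ts$group_label), ])
}

#' Dollo parsimony loss inference on a rooted tree
#'
#' Single-gain Dollo parsimony: the character is gained once, at the
#' most recent common ancestor of all leaves where it is present, and
#' lost on the minimal set of edges below that node that explains every
#' absent leaf. The minimal loss set is the set of maximal all-absent
#' subtrees inside the gain clade, which is unique, hence deterministic.
#'
#' @param tree rooted `phylo` tree.
#' @param presence named logical vector over all tip labels.
#' @return list of class `dollo_result`: `gain_node` (node number, NA
#'   if no present leaf), `gain_clade_tips`, `loss_nodes` (node
#'   numbers), `loss_clades` (list of tip-label vectors, one per loss),
#'   `n_losses`.
#' @export
dollo_losses <- function(tree, presence) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  tips <- tree$tip.label
  if (!all(tips %in% names(presence)))
    stop("presence value missing for: ",
         paste(setdiff(tips, names(presence)), collapse = ", "))
  presence <- presence[tips]
  n_tip <- length(tips)
  present_tips <- which(presence)
  if (!length(present_tips))
    return(structure(list(gain_node = NA_integer_,
                          gain_clade_tips = character(0),
                          loss_nodes = integer(0), loss_clades = list(),
                          n_losses = 0L), class = "dollo_result"))
  gain <- if (length(present_tips) == 1L) present_tips
    else ape::getMRCA(tree, present_tips)

  kids <- split(tree$edge[, 2], tree$edge[, 1])
  # tips under each node, and whether all of them are absent
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  losses <- integer(0)
  walk <- function(node) {
    for (child in if (node <= n_tip) integer(0)
         else kids[[as.character(node)]]) {
      under <- tips_under(child)
      if (!any(presence[under])) {
        losses <<- c(losses, child)  # maximal all-absent subtree
      } else {
        walk(child)
      }
    }
  }
  walk(gain)
  structure(list(gain_node = gain,
                 gain_clade_tips = tips[tips_under(gain)],
                 loss_nodes = losses,
                 loss_clades = lapply(losses,
                                      function(nd) tips[tips_under(nd)]),
                 n_losses = length(losses)),
            class = "dollo_result")
}

#' Flag candidate dataset contaminations
#'
#' A species is flagged when (a) it is the only sampled member of its
#' order with the signalling system present while at least
#' `min_other_absent` other sampled members of the order lack it, and
#' (b) it shares a byte-identical mature peptide with a species from a
#' different subphylum.
#'
#' @param presence a [build_presence_table()] result (or its `presence`
#'   data.frame).
#' @param census a [build_census()] result with species tracking.
#' @param manifest species manifest.
#' @param min_other_absent minimum number of other sampled, absent
#'   members of the order (default 3).
#' @return character vector of flagged species.
#' @export
flag_contamination <- function(presence, census, manifest,
                               min_other_absent = 3L) {
  pres <- if (is.data.frame(presence)) presence else presence$presence
  flagged <- character(0)
  for (sp in pres$species[pres$system_present]) {
    ord <- manifest$order[manifest$species == sp]
    subp <- manifest$subphylum[manifest$species == sp]
    mates <- pres[pres$species != sp &
                    pres$species %in% manifest$species[manifest$order == ord], ]
    lone <- nrow(mates) >= min_other_absent && !any(mates$system_present)
    if (!lone) next
    shared <- vapply(names(census$counts), function(p) {
      owners <- census$species_of[[p]]
      if (!sp %in% owners) return(FALSE)
      other_subp <- manifest$subphylum[manifest$species %in% setdiff(owners, sp)]
      any(other_subp != subp)
    }, logical(1))
    if (any(shared)) flagged <- c(flagged, sp)
  }
  flagged
}
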