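# Independent oracles used across the suite. They never call the code
# paths they check.

# Exhaustive local-alignment score: enumerate every monotone matching of
# aligned column pairs; residues skipped between consecutive pairs are
# charged as affine gap runs (open + extend * length per sequence).
bf_local_score <- function(a, b, scheme) {
  sm <- scheme$substitution_scores
  go <- scheme$gap_open_penalty
  ge <- scheme$gap_extend_penalty
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  best <- 0L
  rec <- function(li, lj, score) {
    if (score > best) best <<- score
    if (li >= m || lj >= n) return()
    for (i in (li + 1L):m) for (j in (lj + 1L):n) {
      gap <- 0L
      if (li > 0L) {
        gx <- i - li - 1L; gy <- j - lj - 1L
        if (gx > 0L) gap <- gap + go + ge * gx
        if (gy > 0L) gap <- gap + go + ge * gy
      }
      rec(i, j, score + sm[av[i], bv[j]] - gap)
    }
  }
  rec(0L, 0L, 0L)
  best
}

# Exhaustive single-gain Dollo minimisation: gain at the MRCA of present
# leaves, then try every subset of edges below it as the loss set.
bf_dollo_losses <- function(tree, presence) {
  tips <- tree$tip.label
  presence <- presence[tips]
  pres_idx <- which(presence)
  if (!length(pres_idx)) return(0L)
  gain <- if (length(pres_idx) == 1L) pres_idx
    else ape::getMRCA(tree, pres_idx)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= length(tips)) return(node)
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  edges_below <- function(node) {
    if (node <= length(tips)) return(NULL)
    ch <- kids[[as.character(node)]]
    rbind(cbind(node, ch), do.call(rbind, lapply(ch, edges_below)))
  }
  ed <- edges_below(gain)
  if (is.null(ed)) return(0L)  # gain at a single present leaf
  clade_tips <- tips_under(gain)
  ne <- nrow(ed)
  best <- Inf
  for (mask in 0:(2^ne - 1L)) {
    cut <- which(bitwAnd(mask, 2^(seq_len(ne) - 1L)) > 0)
    if (length(cut) >= best) next
    lost <- unique(unlist(lapply(ed[cut, 2], tips_under)))
    state <- setNames(rep(TRUE, length(clade_tips)), clade_tips)
    state[as.character(lost[lost <= length(tips)])] <- FALSE
    ok <- all(state == presence[clade_tips])
    if (ok) best <- length(cut)
  }
  as.integer(best)
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# reverse-translate a peptide with one fixed codon per residue
reverse_translate <- function(prot) {
  codon <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
             Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
             L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
             S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
  paste(codon[strsplit(prot, "")[[1]]], collapse = "")
}

revcomp <- function(dna) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", dna), "")[[1]]), collapse = "")
}
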