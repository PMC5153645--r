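#' Scoring scheme for local alignment search
#'
#' Bundles a substitution matrix with affine gap penalties and the
#' Karlin-Altschul parameters used for E-values. Defaults follow common
#' protein-search practice: BLOSUM62 with gap open 11 / extend 1 and the
#' published gapped Karlin-Altschul constants for that combination
#' (lambda = 0.267, K = 0.041).
#'
#' @param matrix_name name of a substitution matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`), ignored when `substitution_scores`
#'   is given.
#' @param substitution_scores integer matrix with residue dimnames;
#'   must be symmetric.
#' @param gap_open_penalty,gap_extend_penalty positive integers; a gap
#'   of length g costs `gap_open_penalty + gap_extend_penalty * g`.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62",
                           substitution_scores = NULL,
                           gap_open_penalty = 11L, gap_extend_penalty = 1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(substitution_scores)) {
    if (matrix_name == "BLOSUM62" && !is.null(.inoto_env$BLOSUM62)) {
      substitution_scores <- .inoto_env$BLOSUM62
    } else {
      e <- new.env()
      utils::data(list = matrix_name, package = "Biostrings", envir = e)
      substitution_scores <- get(matrix_name, envir = e)
    }
  }
  substitution_scores <- as.matrix(substitution_scores)
  storage.mode(substitution_scores) <- "integer"
  if (!isTRUE(all.equal(substitution_scores, t(substitution_scores))))
    stop("substitution matrix must be symmetric")
  if (gap_open_penalty <= 0 || gap_extend_penalty <= 0)
    stop("gap penalties must be positive")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be strictly positive")
  structure(list(matrix_name = matrix_name,
                 substitution_scores = substitution_scores,
                 gap_open_penalty = as.integer(gap_open_penalty),
                 gap_extend_penalty = as.integer(gap_extend_penalty),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman dynamic programming with affine gaps (gap of
#' length g costs open + extend * g). Traceback ties are broken
#' deterministically: diagonal, then up, then left. Residues absent
#' from the matrix (including `*`) score via its X column.
#'
#' @param query,subject protein sequence strings.
#' @param scheme a [scoring_scheme()].
#' @return list of class `local_alignment`: `raw_score`, 1-based
#'   inclusive `q_start`/`q_end`/`s_start`/`s_end` (NA for an empty
#'   alignment), `aligned_query`, `aligned_subject`, `frame` (0 for a
#'   protein subject), `e_value` (NA until set by [search_dataset()]).
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  r <- .sw_align_cpp(toupper(query), toupper(subject),
                     scheme$substitution_scores,
                     scheme$gap_open_penalty, scheme$gap_extend_penalty)
  structure(list(query_id = NA_character_, subject_id = NA_character_,
                 raw_score = r$score, q_start = r$q_start, q_end = r$q_end,
                 s_start = r$s_start, s_end = r$s_end,
                 aligned_query = r$aligned_query,
                 aligned_subject = r$aligned_subject,
                 frame = 0L, e_value = NA_real_),
            class = "local_alignment")
}

#' Rescore a gapped alignment from its aligned strings
#'
#' Self-consistency helper: recomputes the raw score of an alignment
#' from the two gapped strings under a scheme, charging
#' open + extend * g per gap run.
#'
#' @param aligned_query,aligned_subject equal-length gapped strings.
#' @param scheme a [scoring_scheme()].
#' @return integer score.
#' @export
rescore_alignment <- function(aligned_query, aligned_subject,
                              scheme = scoring_scheme()) {
  a <- strsplit(aligned_query, "")[[1]]
  b <- strsplit(aligned_subject, "")[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  sm <- scheme$substitution_scores
  res <- rownames(sm)
  score <- 0L
  in_gap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      score <- score - scheme$gap_extend_penalty -
        (if (!in_gap) scheme$gap_open_penalty else 0L)
      in_gap <- TRUE
    } else {
      ra <- if (a[k] %in% res) a[k] else "X"
      rb <- if (b[k] %in% res) b[k] else "X"
      score <- score + sm[ra, rb]
      in_gap <- FALSE
    }
  }
  score
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `raw_score`
#' in a search of a query of length m against a database of n residues:
#' E = K * m * n * exp(-lambda * S).
#'
#' @param raw_score alignment score S.
#' @param query_len,db_len positive lengths m and n (residues).
#' @param scheme a [scoring_scheme()] supplying lambda and K.
#' @return non-negative E-value.
#' @export
evalue <- function(raw_score, query_len, db_len, scheme = scoring_scheme()) {
  if (any(query_len <= 0) || any(db_len <= 0))
    stop("sequence and database lengths must be positive")
  scheme$K * query_len * db_len * exp(-scheme$lambda * raw_score)
}

#' Search a sequence dataset with protein queries
#'
#' Aligns every query against every dataset entry (nucleotide entries
#' are searched in all six reading frames) and keeps hits at or below
#' the E-value cutoff. Each subject is reported at most once per query,
#' at its best frame. The database length for E-values is the total
#' residue count of the searched dataset (translated length for
#' nucleotide entries).
#'
#' @param queries protein sequence records.
#' @param dataset protein or nucleotide sequence records.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff maximum E-value (default 1e-4).
#' @return data.frame of hits sorted by ascending `e_value` then
#'   descending `score`: `query_id`, `subject_id`, `frame`, `score`,
#'   `e_value`, `q_start`, `q_end`, `s_start`, `s_end` (1-based
#'   inclusive, protein-space for translated subjects), `aligned_query`,
#'   `aligned_subject`.
#' @export
search_dataset <- function(queries, dataset, scheme = scoring_scheme(),
                           e_cutoff = 1e-4) {
  if (nrow(queries) == 0) stop("empty query set")
  empty <- data.frame(query_id = character(), subject_id = character(),
                      frame = integer(), score = integer(),
                      e_value = numeric(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), aligned_query = character(),
                      aligned_subject = character(),
                      stringsAsFactors = FALSE)
  if (nrow(dataset) == 0) return(empty)
  if (any(queries$molecule_type != "protein"))
    stop("queries must be protein records")

  # expand nucleotide subjects into translated frames
  targets <- do.call(rbind, lapply(seq_len(nrow(dataset)), function(i) {
    rec <- dataset[i, ]
    if (rec$molecule_type == "protein") {
      data.frame(subject_id = rec$id, frame = 0L, residues = rec$residues,
                 stringsAsFactors = FALSE)
    } else {
      tr <- six_frame_translate(rec)
      fr <- as.integer(sub(".*_frame([+-]\\d)$", "\\1", tr$id))
      data.frame(subject_id = rec$id, frame = fr, residues = tr$residues,
                 stringsAsFactors = FALSE)
    }
  }))
  db_len <- sum(nchar(targets$residues))

  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    q <- queries[qi, ]
    best <- list()
    for (ti in seq_len(nrow(targets))) {
      tg <- targets[ti, ]
      al <- smith_waterman(q$residues, tg$residues, scheme)
      if (al$raw_score <= 0) next
      ev <- evalue(al$raw_score, nchar(q$residues), db_len, scheme)
      if (ev > e_cutoff) next
      prev <- best[[tg$subject_id]]
      if (is.null(prev) || al$raw_score > prev$score) {
        best[[tg$subject_id]] <- data.frame(
          query_id = q$id, subject_id = tg$subject_id, frame = tg$frame,
          score = al$raw_score, e_value = ev, q_start = al$q_start,
          q_end = al$q_end, s_start = al$s_start, s_end = al$s_end,
          aligned_query = al$aligned_query,
          aligned_subject = al$aligned_subject, stringsAsFactors = FALSE)
      }
    }
    rows <- c(rows, best)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$e_value, -out$score, out$query_id, out$subject_id), ,
      drop = FALSE]
}
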