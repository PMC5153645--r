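#' Mine a sequence collection for the inotocin signalling system
#'
#' The full discovery pipeline: similarity search for precursor and
#' receptor candidates (Smith-Waterman against reference queries, hits
#' kept at the E-value cutoff), rule-based precursor annotation of the
#' precursor candidates, motif-anchor classification of the receptor
#' candidates (sequences shorter than `partial_length` are treated as
#' N-terminally truncated and classified on TM7 evidence only), then
#' census and presence mapping.
#'
#' @param records protein (or nucleotide) sequence records to mine.
#' @param manifest species manifest covering all record species.
#' @param queries protein query records; ids containing `"prec"` are
#'   used for precursor discovery, the rest for receptor discovery.
#'   Defaults to [reference_queries()].
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff E-value cutoff (default 1e-4).
#' @param partial_length below this length a receptor candidate is
#'   classified as partial (default 250).
#' @return list: `precursor_hits`, `receptor_hits` (search tables),
#'   `annotations` ([batch_annotate()] result), `receptor_calls`
#'   ([classify_receptors()] table), `census`, `presence`.
#' @export
mine_dataset <- function(records, manifest, queries = reference_queries(),
                         scheme = scoring_scheme(), e_cutoff = 1e-4,
                         partial_length = 250L) {
  is_prec <- grepl("prec", queries$id)
  prec_hits <- search_dataset(queries[is_prec, , drop = FALSE], records,
                              scheme, e_cutoff)
  rec_hits <- search_dataset(queries[!is_prec, , drop = FALSE], records,
                             scheme, e_cutoff)
  prec_ids <- unique(prec_hits$subject_id)
  rec_ids <- setdiff(unique(rec_hits$subject_id), prec_ids)
  annotations <- batch_annotate(records[records$id %in% prec_ids, ,
                                        drop = FALSE], manifest)
  rec_cand <- records[records$id %in% rec_ids, , drop = FALSE]
  receptor_calls <- if (nrow(rec_cand))
    classify_receptors(rec_cand,
                       partial = nchar(rec_cand$residues) < partial_length)
  else NULL
  list(precursor_hits = prec_hits, receptor_hits = rec_hits,
       annotations = annotations, receptor_calls = receptor_calls,
       census = build_census(annotations),
       presence = build_presence_table(annotations, receptor_calls,
                                       manifest))
}
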