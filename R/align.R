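# Exact local alignment against a transposable-element consensus
# library.  BLAST's role in the original screen is replaced by exact
# Smith-Waterman with affine gaps and iterative query masking, which is
# oracle-testable at desk scale.

#' Alignment scoring scheme
#'
#' Gap cost convention: a gap of length L costs
#' `gap_open + L * gap_extend`.  Defaults are conventional
#' nucleotide-search values.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0); `N` against anything scores
#'   as a mismatch.
#' @param gap_open Gap opening penalty (>= gap_extend, positive).
#' @param gap_extend Gap extension penalty (> 0).
#' @param min_score Minimum raw score for a reportable hit.
#' @param min_length Minimum query-span length of a reportable hit.
#' @param min_identity Minimum identity (matches / aligned columns).
#' @return An object of class `selnc_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L, min_score = 40,
                           min_length = 50L, min_identity = 0.65) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (!(gap_open >= gap_extend && gap_extend > 0))
    stop("need gap_open >= gap_extend > 0")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = min_score, min_length = as.integer(min_length),
                 min_identity = min_identity),
            class = "selnc_scheme")
}

#' Local alignment with iterative masking
#'
#' The first hit is the optimal Smith-Waterman local alignment of
#' `query` against `target` under `scheme`.  The aligned query interval
#' is then masked (replaced by `N`, which scores as mismatch) and the
#' alignment re-run, producing non-overlapping secondary hits, until
#' the optimal score drops below `scheme$min_score`.  Hits shorter than
#' `min_length` on the query or below `min_identity` are discarded but
#' still mask their interval.
#'
#' @param query,target Sequences over `{A,C,G,T,N}`.
#' @param scheme A [scoring_scheme()].
#' @param query_id,target_id Identifiers stored in the hits.
#' @return data.frame with one row per hit: `query_id`, `target_id`,
#'   `q_start`, `q_end`, `t_start`, `t_end` (0-based half-open),
#'   `score`, `identity`.  Zero rows when nothing qualifies.
#' @export
local_align <- function(query, target, scheme = scoring_scheme(),
                        query_id = "query", target_id = "target") {
  if (nchar(query) < 1L || nchar(target) < 1L) stop("empty sequence")
  rows <- list()
  q <- query
  for (iter in seq_len(100L)) {
    al <- cpp_sw_align(q, target, scheme$match, scheme$mismatch,
                       scheme$gap_open, scheme$gap_extend)
    if (al$score < scheme$min_score) break
    len <- al$q_end - al$q_start
    identity <- al$matches / al$columns
    if (len >= scheme$min_length && identity >= scheme$min_identity) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = query_id, target_id = target_id,
        q_start = al$q_start, q_end = al$q_end,
        t_start = al$t_start, t_end = al$t_end,
        score = al$score, identity = identity,
        stringsAsFactors = FALSE)
    }
    substr(q, al$q_start + 1L, al$q_end) <-
      strrep("N", al$q_end - al$q_start)
  }
  if (length(rows) == 0L)
    return(data.frame(query_id = character(0), target_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      score = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
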