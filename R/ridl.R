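# Repeat-insertion-domain (RIDL) detection: combine local alignment
# against a TE consensus library with k-mer community profiling, then
# triage transcripts into valid-RIDL / polyA-only / no-RIDL.

#' Detect low-complexity (homopolymer-rich) intervals
#'
#' Slides a window of length `min_run`; windows in which one base's
#' frequency reaches `min_purity` are candidate low-complexity windows.
#' Overlapping or adjacent candidate windows of the same dominant base
#' are merged into maximal intervals.
#'
#' @param seq Sequence over `{A,C,G,T,N}`.
#' @param min_run Minimum run/window length (>= 5), default 15.
#' @param min_purity Dominant-base frequency threshold in `(0.5, 1]`,
#'   default 0.9.
#' @return data.frame with columns `start`, `end` (0-based half-open)
#'   and `base`.
#' @export
detect_low_complexity <- function(seq, min_run = 15L, min_purity = 0.9) {
  min_run <- as.integer(min_run)
  if (min_run < 5L) stop("min_run must be >= 5")
  if (min_purity <= 0.5 || min_purity > 1) stop("min_purity must be in (0.5, 1]")
  L <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      base = character(0), stringsAsFactors = FALSE)
  if (L < min_run) return(empty)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    ind <- as.integer(chars == b)
    cs <- c(0L, cumsum(ind))
    # count of b in each window [i, i + min_run)
    wc <- cs[(min_run + 1L):(L + 1L)] - cs[1:(L - min_run + 1L)]
    hit <- which(wc / min_run >= min_purity)
    if (length(hit) == 0L) next
    # merge overlapping/adjacent windows (starts within min_run of each other)
    brk <- c(0L, which(diff(hit) > min_run), length(hit))
    for (j in seq_len(length(brk) - 1L)) {
      grp <- hit[(brk[j] + 1L):brk[j + 1L]]
      out[[length(out) + 1L]] <- data.frame(
        start = grp[1L] - 1L, end = grp[length(grp)] - 1L + min_run,
        base = b, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# Fraction of [start, end) covered by the low-complexity intervals.
.lc_coverage <- function(start, end, lc) {
  if (nrow(lc) == 0L) return(0)
  cov <- pmax(0L, pmin(end, lc$end) - pmax(start, lc$start))
  # intervals for different bases may overlap; count covered positions
  pos <- rep(FALSE, end - start)
  for (i in seq_len(nrow(lc))) {
    s <- max(start, lc$start[i]); e <- min(end, lc$end[i])
    if (s < e) pos[(s - start + 1L):(e - start)] <- TRUE
  }
  mean(pos)
}

# Dominant base of a subsequence.
.dominant_base <- function(seq, start, end) {
  frag <- substr(seq, start + 1L, end)
  tab <- table(strsplit(frag, "", fixed = TRUE)[[1L]])
  names(tab)[which.max(tab)]
}

#' Call repeat insertion domains on one transcript
#'
#' Pipeline: (1) local alignment of the transcript against every
#' consensus in the TE library; (2) hits whose query intervals overlap
#' by more than 50% (of the shorter) are merged into one fragment,
#' keeping the best-scoring hit; (3) fragments at least 80% covered by
#' low-complexity intervals are reclassified `low_complexity` with
#' family `poly<base>`; (4) surviving fragments become `TE_repeat`
#' calls annotated with `kmer_delta`: the fragment profile's mean
#' similarity to the functional reference members minus the mean of the
#' same quantity over dinucleotide-preserving shuffles of the fragment;
#' (5) a transcript with no fragments yields one `none` call.
#'
#' @param transcript Transcript sequence.
#' @param te_library Named character vector of TE consensus sequences.
#' @param kmer_reference A `selnc_kmer_ref` built from a functional
#'   lncRNA set.
#' @param scheme A [scoring_scheme()].
#' @param seq_id Transcript identifier.
#' @param n_shuffles Shuffles for the k-mer null, default 20.
#' @param seed Seed for the shuffle null.
#' @param lc_min_run,lc_min_purity Low-complexity detector parameters.
#' @param lc_cover Coverage fraction above which a fragment is vetoed
#'   as low complexity, default 0.8.
#' @return data.frame of calls: `seq_id`, `klass` (`TE_repeat`,
#'   `low_complexity`, `none`), `family`, `start`, `end`, `score`,
#'   `identity`, `kmer_delta`.
#' @export
call_ridls <- function(transcript, te_library, kmer_reference,
                       scheme = scoring_scheme(), seq_id = "transcript",
                       n_shuffles = 20L, seed = 1L,
                       lc_min_run = 15L, lc_min_purity = 0.9,
                       lc_cover = 0.8) {
  if (length(te_library) == 0L) stop("TE library is empty")
  hits <- do.call(rbind, lapply(names(te_library), function(tid)
    local_align(transcript, te_library[[tid]], scheme,
                query_id = seq_id, target_id = tid)))
  none_call <- data.frame(seq_id = seq_id, klass = "none", family = NA_character_,
                          start = NA_integer_, end = NA_integer_,
                          score = NA_real_, identity = NA_real_,
                          kmer_delta = NA_real_, stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(none_call)
  # merge query intervals overlapping > 50% of the shorter hit
  hits <- hits[order(-hits$score), , drop = FALSE]
  taken <- rep(FALSE, nrow(hits))
  frags <- list()
  for (i in seq_len(nrow(hits))) {
    if (taken[i]) next
    taken[i] <- TRUE
    for (j in seq_len(nrow(hits))) {
      if (taken[j]) next
      ov <- min(hits$q_end[i], hits$q_end[j]) -
        max(hits$q_start[i], hits$q_start[j])
      shorter <- min(hits$q_end[i] - hits$q_start[i],
                     hits$q_end[j] - hits$q_start[j])
      if (ov > 0.5 * shorter) taken[j] <- TRUE
    }
    frags[[length(frags) + 1L]] <- hits[i, , drop = FALSE]
  }
  lc <- detect_low_complexity(transcript, lc_min_run, lc_min_purity)
  calls <- list()
  for (f in frags) {
    s <- f$q_start; e <- f$q_end
    if (.lc_coverage(s, e, lc) >= lc_cover) {
      calls[[length(calls) + 1L]] <- data.frame(
        seq_id = seq_id, klass = "low_complexity",
        family = paste0("poly", .dominant_base(transcript, s, e)),
        start = s, end = e, score = f$score, identity = f$identity,
        kmer_delta = NA_real_, stringsAsFactors = FALSE)
      next
    }
    frag_seq <- substr(transcript, s + 1L, e)
    kd <- NA_real_
    if (nchar(frag_seq) >= kmer_reference$k) {
      z <- kmer_profile(frag_seq, kmer_reference)
      obs <- .ref_similarity(z, kmer_reference)
      shuf <- dinuc_shuffle(frag_seq, n = n_shuffles, seed = seed)
      null <- vapply(shuf, function(sq)
        .ref_similarity(kmer_profile(sq, kmer_reference), kmer_reference),
        numeric(1))
      kd <- obs - mean(null)
    }
    calls[[length(calls) + 1L]] <- data.frame(
      seq_id = seq_id, klass = "TE_repeat", family = f$target_id,
      start = s, end = e, score = f$score, identity = f$identity,
      kmer_delta = kd, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) return(none_call)
  do.call(rbind, calls)
}

#' Triage a transcript from its RIDL calls
#'
#' @param calls data.frame of calls for one transcript from
#'   [call_ridls()].
#' @return `"valid_RIDL"` if any call is `TE_repeat`, else
#'   `"polyA_only"` if any is `low_complexity`, else `"no_RIDL"`.
#' @export
classify_se_lncrna <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stop("empty call list")
  if (any(calls$klass == "TE_repeat")) "valid_RIDL"
  else if (any(calls$klass == "low_complexity")) "polyA_only"
  else "no_RIDL"
}

#' Run the RIDL detector over a transcript set
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param te_library Named character vector of TE consensi.
#' @param kmer_reference A `selnc_kmer_ref`.
#' @param scheme A [scoring_scheme()].
#' @param seed Seed for the shuffle nulls.
#' @param ... Passed to [call_ridls()].
#' @return List with `calls` (row-bound calls for all transcripts) and
#'   `status` (named vector of per-transcript triage labels).
#' @export
ridl_screen <- function(transcripts, te_library, kmer_reference,
                        scheme = scoring_scheme(), seed = 1L, ...) {
  all_calls <- list()
  status <- character(length(transcripts))
  names(status) <- names(transcripts)
  for (id in names(transcripts)) {
    cl <- call_ridls(transcripts[[id]], te_library, kmer_reference,
                     scheme, seq_id = id, seed = seed, ...)
    all_calls[[id]] <- cl
    status[[id]] <- classify_se_lncrna(cl)
  }
  list(calls = do.call(rbind, c(all_calls, list(make.row.names = FALSE))),
       status = status)
}
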