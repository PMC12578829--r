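# SEEKR-style k-mer community profiling: length-normalised, log2
# transformed k-mer spectra standardised against a reference sequence
# set and compared by Pearson correlation.

.kmer_order <- function(k) {
  mkAllStrings <- Biostrings::mkAllStrings
  mkAllStrings(c("A", "C", "G", "T"), k)
}

#' Count k-mers in a sequence
#'
#' The window slides by one position; any window containing `N`
#' contributes to no k-mer, so the total of the returned counts equals
#' `nchar(seq) - k + 1` minus the number of N-touching windows.
#'
#' @param seq A DNA string over `{A,C,G,T,N}`.
#' @param k Word length (>= 1); `nchar(seq) >= k` required.
#' @return Named integer vector of length `4^k` in lexicographic order.
#' @export
count_kmers <- function(seq, k) {
  k <- as.integer(k)
  if (nchar(seq) < k) stop("sequence shorter than k")
  Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
}

# log2 length-normalised spectrum: counts per kilobase of counted
# windows, plus a pseudocount added after normalisation (so that exact
# sequence duplication leaves the spectrum unchanged).
.kmer_lognorm <- function(seq, k, pseudocount) {
  cnt <- count_kmers(seq, k)
  w <- sum(cnt)
  if (w == 0L) stop("no countable windows (all contain N)")
  log2(cnt * 1000 / w + pseudocount)
}

#' Build a k-mer reference from a functional sequence set
#'
#' Each reference sequence is converted to a log2 length-normalised
#' k-mer spectrum; per-k-mer mean and population standard deviation
#' across the reference members define the standardisation used by
#' [kmer_profile()].  Standard deviations are floored at `1e-8`.
#'
#' @param ref_seqs Named character vector of >= 2 sequences, each of
#'   length >= k.
#' @param k Word length (>= 2), default 4.
#' @param pseudocount Positive pseudocount (per-kilobase units) added
#'   after length normalisation, default 1.
#' @return An object of class `selnc_kmer_ref` with fields `k`,
#'   `kmer_order`, `mean`, `sd`, `pseudocount` and the member z-profiles
#'   (`member_z`).
#' @export
build_kmer_reference <- function(ref_seqs, k = 4L, pseudocount = 1) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (length(ref_seqs) < 2L)
    stop("need >= 2 reference sequences (sd undefined otherwise)")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  L <- t(vapply(ref_seqs, .kmer_lognorm, numeric(4L^k),
                k = k, pseudocount = pseudocount))
  mu <- colMeans(L)
  n <- nrow(L)
  sdv <- sqrt(colMeans(sweep(L, 2L, mu)^2))   # population sd
  sdv <- pmax(sdv, 1e-8)
  ref <- structure(list(k = k, kmer_order = .kmer_order(k), mean = mu,
                        sd = sdv, pseudocount = pseudocount),
                   class = "selnc_kmer_ref")
  ref$member_z <- t(apply(L, 1L, function(x) (x - mu) / sdv))
  rownames(ref$member_z) <- names(ref_seqs)
  ref
}

#' Standardised k-mer profile of a sequence
#'
#' @param seq A DNA string of length >= `reference$k`.
#' @param reference A `selnc_kmer_ref` from [build_kmer_reference()].
#' @return Numeric z-vector of length `4^k`.
#' @export
kmer_profile <- function(seq, reference) {
  x <- .kmer_lognorm(seq, reference$k, reference$pseudocount)
  (x - reference$mean) / reference$sd
}

#' Pearson similarity of two k-mer profiles
#'
#' @param p,q Profiles from [kmer_profile()] sharing a reference.
#' @return Pearson correlation in `[-1, 1]`, or `NA` with a warning
#'   when either profile has zero variance.
#' @export
kmer_similarity <- function(p, q) {
  if (length(p) != length(q)) stop("profiles have different lengths")
  if (sd(p) == 0 || sd(q) == 0) {
    warning("zero-variance profile; similarity undefined")
    return(NA_real_)
  }
  cor(p, q)
}

# Mean similarity of a profile to the reference members.
.ref_similarity <- function(z, reference) {
  mean(apply(reference$member_z, 1L, function(m) kmer_similarity(z, m)))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-walk shuffle: the shuffled sequence has exactly the
#' same dinucleotide (and hence mononucleotide) composition as the
#' input.  Implemented by permuting each vertex's outgoing edge list
#' and rejecting permutations that strand the walk before all edges are
#' used, which draws uniformly from the valid orderings.
#'
#' @param seq Input sequence (length >= 2).
#' @param n Number of shuffles.
#' @param seed Integer seed; the global RNG state is not disturbed.
#' @return Character vector of `n` shuffled sequences.
#' @export
dinuc_shuffle <- function(seq, n = 1L, seed = 1L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 2L) stop("sequence too short to shuffle")
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(i) .dinuc_shuffle_once(chars), character(1))
  })
}

.dinuc_shuffle_once <- function(chars) {
  L <- length(chars)
  from <- chars[-L]
  to <- chars[-1L]
  verts <- unique(chars)
  out <- split(to, factor(from, levels = verts))
  for (attempt in seq_len(1000L)) {
    perm <- lapply(out, function(e) if (length(e) > 1L) sample(e) else e)
    ptr <- setNames(rep(1L, length(verts)), verts)
    res <- character(L)
    res[1L] <- chars[1L]
    v <- chars[1L]
    ok <- TRUE
    for (i in 2:L) {
      edges <- perm[[v]]
      p <- ptr[[v]]
      if (is.null(edges) || p > length(edges)) { ok <- FALSE; break }
      ptr[[v]] <- p + 1L
      v <- edges[[p]]
      res[i] <- v
    }
    if (ok) return(paste(res, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian ordering")
}
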