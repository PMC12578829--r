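# Independent oracles and fixture builders shared across tests.  The
# oracles deliberately use naive algorithms (double loops, full DP
# recursions) so they share no code path with the implementation.

# Brute-force O(n*m) interval overlap: indices of `ivs` overlapping
# [start, end) on chrom (half-open, "chr" prefix ignored).
bf_query <- function(ivs, chrom, start, end) {
  nc <- sub("^chr", "", chrom)
  which(vapply(ivs, function(iv)
    sub("^chr", "", iv$chrom) == nc && iv$start < end && start < iv$end,
    logical(1)))
}

# Brute-force SE x gene catalogue: data.frame(gene_id, se_name,
# overlap_bp) by double loop.
bf_catalog <- function(se, genes) {
  rows <- list()
  for (g in genes) {
    for (s in se) {
      if (sub("^chr", "", g$chrom) != sub("^chr", "", s$chrom)) next
      ov <- min(g$span$end, s$end) - max(g$span$start, s$start)
      if (ov >= 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, se_name = s$name, overlap_bp = ov,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), se_name = character(0),
                      overlap_bp = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$se_name), , drop = FALSE]
}

# Score-only affine-gap local alignment DP (Gotoh), written
# independently of the package's traceback implementation.  Gap of
# length L costs open + L * ext.
bf_sw_score <- function(q, t, match = 2, mismatch = -3, open = 5, ext = 2) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F_ <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
      F_[i, j] <- max(H[i, j - 1] - open - ext, F_[i, j - 1] - ext)
      s <- if (qc[i - 1] == tc[j - 1] && qc[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Literal Benjamini-Hochberg definition: q_(i) = min_{j >= i} p_(j)*m/j.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q[order(o)]
}

# Random DNA string.
rand_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Random interval fixture on a toy genome.
rand_intervals <- function(n, chroms = c("chr1", "chr2"), len_max = 200L,
                           genome = 10000L, prefix = "iv") {
  lapply(seq_len(n), function(i) {
    len <- sample.int(len_max, 1L)
    s <- sample.int(genome - len, 1L) - 1L
    genomic_interval(sample(chroms, 1L), s, s + len,
                     paste0(prefix, i))
  })
}

rand_genes <- function(n, chroms = c("chr1", "chr2"), len_max = 300L,
                       genome = 10000L) {
  lapply(seq_len(n), function(i) {
    len <- sample.int(len_max, 1L) + 1L
    s <- sample.int(genome - len, 1L) - 1L
    gene_model(sprintf("G%03d", i), sample(chroms, 1L),
               sample(c("+", "-"), 1L), s, s + len)
  })
}

# Dinucleotide count table of a sequence.
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}
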