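# Synthetic-data generators with planted ground truth.  Every
# generator is a pure function of (config, seed): reruns are
# bitwise-reproducible.  Defaults emulate the statistical structure of
# the real inputs (super-enhancer intervals, lncRNA transcripts with
# embedded transposable-element fragments, subtype-shifted expression,
# hazard driven by a sparse linear predictor).

#' Simulation configuration
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_chroms,chrom_len Genome shape (default 3 chromosomes of
#'   2 Mb).
#' @param n_se Number of super-enhancers (default 50); lengths drawn
#'   uniformly from `se_len_range` (default 5-20 kb).
#' @param n_genes Number of lncRNA genes (default 100); lengths from
#'   `gene_len_range` (default 1-10 kb).
#' @param overlap_fraction Fraction `f` of genes planted to overlap an
#'   SE (default 0.3).
#' @param n_transcripts Transcript count (default 200); lengths from
#'   `tx_len_range` (default 800-1500 nt).
#' @param class_fractions Named fractions of TE-inserted, polyA-only
#'   and background transcripts (default 0.3/0.3/0.4).
#' @param te_len_range Planted TE fragment length (default 150-300 nt).
#' @param divergence Substitution rate applied to planted fragments
#'   (default 0.05); small indels are applied at `divergence / 10`.
#' @param polya_len Length of planted poly(A) runs (default 30).
#' @param subtypes Subtype labels (PAM50-style vocabulary).
#' @param n_per_subtype Samples per subtype (default 40).
#' @param baseline_mean,baseline_sd Per-feature baseline log2 mean
#'   distribution (default 3, 1).
#' @param shift Subtype shift added to planted DE features (default 2).
#' @param noise_sd Residual log2 noise (default 0.5).
#' @param n_de_per_subtype Planted DE features per subtype (default 10).
#' @param n_prognostic Features with nonzero hazard coefficients
#'   (default 5).
#' @param beta_effect Absolute value of the nonzero coefficients
#'   (default 1).
#' @param baseline_hazard Exponential baseline hazard per year
#'   (default 0.1).
#' @param censoring_fraction Target censoring fraction (default 0.3).
#' @return List of class `selnc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L, chrom_len = 2e6, n_se = 50L,
                       se_len_range = c(5000L, 20000L),
                       n_genes = 100L, gene_len_range = c(1000L, 10000L),
                       overlap_fraction = 0.3,
                       n_transcripts = 200L, tx_len_range = c(800L, 1500L),
                       class_fractions = c(te = 0.3, polya = 0.3,
                                           background = 0.4),
                       te_len_range = c(150L, 300L), divergence = 0.05,
                       polya_len = 30L,
                       subtypes = c("Basal", "Her2", "LumA", "LumB",
                                    "Normal"),
                       n_per_subtype = 40L, baseline_mean = 3,
                       baseline_sd = 1, shift = 2, noise_sd = 0.5,
                       n_de_per_subtype = 10L, n_prognostic = 5L,
                       beta_effect = 1, baseline_hazard = 0.1,
                       censoring_fraction = 0.3) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (divergence < 0 || divergence > 0.3)
    stop("divergence must be in [0, 0.3]")
  if (censoring_fraction < 0 || censoring_fraction > 0.9)
    stop("censoring_fraction must be in [0, 0.9]")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  cfg <- as.list(environment())
  class(cfg) <- "selnc_sim_config"
  cfg
}

.random_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

#' Simulate super-enhancer intervals and gene models
#'
#' Exactly `round(f * n_genes)` genes are planted to overlap an SE by
#' at least 1 bp; the remaining genes are placed by rejection sampling
#' to overlap no SE.
#'
#' @param config A [sim_config()].
#' @return List with `se` (intervals), `genes` (gene models) and
#'   `truth` (list with `se_lncrna_ids` and the per-gene overlap
#'   table).
#' @export
simulate_annotation <- function(config) {
  withr::with_seed(config$seed + 101L, {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    se <- vector("list", config$n_se)
    for (i in seq_len(config$n_se)) {
      len <- sample(config$se_len_range[1L]:config$se_len_range[2L], 1L)
      ch <- sample(chroms, 1L)
      if (config$chrom_len <= len) stop("chromosome too short for SE")
      s <- sample.int(config$chrom_len - len, 1L) - 1L
      se[[i]] <- genomic_interval(ch, s, s + len, paste0("SE", i))
    }
    se_by_chrom <- split(se, vapply(se, `[[`, character(1), "chrom"))
    n_plant <- round(config$overlap_fraction * config$n_genes)
    genes <- vector("list", config$n_genes)
    planted <- character(0)
    for (i in seq_len(config$n_genes)) {
      gid <- sprintf("LNC%03d", i)
      len <- sample(config$gene_len_range[1L]:config$gene_len_range[2L], 1L)
      strand <- sample(c("+", "-"), 1L)
      if (i <= n_plant) {
        anchor <- se[[sample.int(config$n_se, 1L)]]
        # place the gene to overlap the anchor SE by >= 1 bp
        lo <- max(0L, anchor$start - len + 1L)
        hi <- min(config$chrom_len - len, anchor$end - 1L)
        s <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
        ch <- anchor$chrom
        planted <- c(planted, gid)
      } else {
        ok <- FALSE
        for (try in seq_len(2000L)) {
          ch <- sample(chroms, 1L)
          s <- sample.int(config$chrom_len - len, 1L) - 1L
          hits <- vapply(se_by_chrom[[ch]], function(iv)
            s < iv$end && iv$start < s + len, logical(1))
          if (!any(hits)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place a non-overlapping gene; ",
                      "chromosomes too crowded")
      }
      n_ex <- sample.int(3L, 1L)
      bounds <- sort(sample.int(len - 1L, 2L * (n_ex - 1L)))
      edges <- c(0L, bounds, len)
      exons <- lapply(seq_len(n_ex), function(j)
        genomic_interval(ch, s + edges[2L * j - 1L], s + edges[2L * j],
                         name = paste0(gid, ".e", j), strand = strand))
      genes[[i]] <- gene_model(gid, ch, strand, s, s + len,
                               biotype = "lncRNA", exons = exons)
    }
    truth <- list(se_lncrna_ids = planted)
    list(se = se, genes = genes, truth = truth)
  })
}

# Apply substitutions (rate = divergence) and short indels (rate =
# divergence / 10) to a sequence; returns the mutated sequence.
.mutate_seq <- function(seq, divergence) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  n <- length(chars)
  sub_pos <- which(runif(n) < divergence)
  for (i in sub_pos)
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  indel_pos <- which(runif(n) < divergence / 10)
  if (length(indel_pos) > 0L) {
    out <- character(0)
    last <- 0L
    for (i in indel_pos) {
      out <- c(out, chars[(last + 1L):i])
      if (runif(1) < 0.5) out <- out[-length(out)]     # deletion
      else out <- c(out, sample(bases, 1L))            # insertion
      last <- i
    }
    if (last < n) out <- c(out, chars[(last + 1L):n])
    chars <- out
  }
  paste(chars, collapse = "")
}

#' Simulate transcript sequences with planted RIDLs
#'
#' Three transcript classes in the configured proportions: TE-inserted
#' (a mutated copy of a consensus at recorded coordinates), polyA-only
#' (a planted poly(A) run) and background.  The TE consensus library
#' (a fixed synthetic "L2-like" and "MIR-like" pair) and a functional
#' lncRNA reference set are generated alongside.
#'
#' @param config A [sim_config()].
#' @param transcript_ids Optional ids (default `LNC001..`, matching
#'   [simulate_annotation()] when counts agree).
#' @param te_library Named character vector of consensus sequences;
#'   defaults to the fixed synthetic two-member library shipped in
#'   `extdata/te_consensus_synthetic.fa` (no licensed repeat content).
#' @return List with `transcripts`, `te_library`, `functional_ref`
#'   (named character vectors) and `truth` (data.frame `seq_id`,
#'   `class`, `start`, `end`, `family`).
#' @export
simulate_sequences <- function(config, transcript_ids = NULL,
                               te_library = NULL) {
  n <- config$n_transcripts
  if (is.null(transcript_ids))
    transcript_ids <- sprintf("LNC%03d", seq_len(n))
  if (length(transcript_ids) != n) stop("transcript_ids length mismatch")
  if (is.null(te_library))
    te_library <- read_fasta(system.file("extdata",
                                         "te_consensus_synthetic.fa",
                                         package = "selnc"))
  withr::with_seed(config$seed + 202L, {
    functional_ref <- setNames(
      lapply(1:5, function(i) .random_seq(1500L,
        c(A = 0.25 + 0.02 * i, C = 0.25 - 0.02 * i,
          G = 0.25 - 0.01 * i, T = 0.25 + 0.01 * i) /
          (1 + 0.02 * i))),
      paste0("FUNC", 1:5))
    functional_ref <- vapply(functional_ref, identity, character(1))
    n_te <- round(config$class_fractions[["te"]] * n)
    n_pa <- round(config$class_fractions[["polya"]] * n)
    classes <- c(rep("te", n_te), rep("polya", n_pa),
                 rep("background", n - n_te - n_pa))
    rows <- vector("list", n)
    tx <- character(n)
    for (i in seq_len(n)) {
      L <- sample(config$tx_len_range[1L]:config$tx_len_range[2L], 1L)
      bg <- .random_seq(L)
      cls <- classes[i]
      if (cls == "te") {
        fam <- sample(names(te_library), 1L)
        cons <- te_library[[fam]]
        fmax <- min(config$te_len_range[2L], nchar(cons))
        if (config$te_len_range[1L] > fmax)
          stop("te_len_range exceeds consensus length")
        flen <- sample(config$te_len_range[1L]:fmax, 1L)
        t_start <- sample.int(nchar(cons) - flen + 1L, 1L) - 1L
        frag <- .mutate_seq(substr(cons, t_start + 1L, t_start + flen),
                            config$divergence)
        if (nchar(frag) > L) stop("insertion longer than transcript")
        ins <- sample.int(L - nchar(frag) + 1L, 1L) - 1L
        tx[i] <- paste0(substr(bg, 1L, ins), frag,
                        substr(bg, ins + 1L, L))
        rows[[i]] <- data.frame(seq_id = transcript_ids[i], class = "te",
                                start = ins, end = ins + nchar(frag),
                                family = fam, stringsAsFactors = FALSE)
      } else if (cls == "polya") {
        run <- strrep("A", config$polya_len)
        ins <- sample.int(L - config$polya_len + 1L, 1L) - 1L
        tx[i] <- paste0(substr(bg, 1L, ins), run,
                        substr(bg, ins + 1L, L))
        rows[[i]] <- data.frame(seq_id = transcript_ids[i],
                                class = "polya", start = ins,
                                end = ins + config$polya_len,
                                family = "polyA", stringsAsFactors = FALSE)
      } else {
        tx[i] <- bg
        rows[[i]] <- data.frame(seq_id = transcript_ids[i],
                                class = "background", start = NA_integer_,
                                end = NA_integer_, family = NA_character_,
                                stringsAsFactors = FALSE)
      }
    }
    list(transcripts = setNames(tx, transcript_ids),
         te_library = te_library, functional_ref = functional_ref,
         truth = do.call(rbind, rows))
  })
}

#' Simulate expression and survival with planted effects
#'
#' Log2 expression is baseline + subtype shift (planted DE features
#' only) + Gaussian noise.  Survival times are exponential with hazard
#' `h0 * exp(beta' x)` over the standardised planted prognostic
#' features; censoring is independent uniform with its upper bound
#' tuned so the expected censoring fraction matches the target.
#'
#' @param config A [sim_config()].
#' @param feature_ids Optional feature ids (default `LNC001..` over
#'   `n_genes`).
#' @param de_features Optional named list (subtype -> feature ids)
#'   overriding the random draw of planted DE features.
#' @param prognostic_features Optional feature ids overriding the
#'   random draw of planted prognostic features.
#' @return List with `expr` ([expression_matrix()]), `clinical`
#'   (clinical data.frame with `subtype`), and `truth` (list with
#'   `de_features` per subtype, `beta` named vector, `lp` true linear
#'   predictor per sample).
#' @export
simulate_expression_survival <- function(config, feature_ids = NULL,
                                         de_features = NULL,
                                         prognostic_features = NULL) {
  if (is.null(feature_ids))
    feature_ids <- sprintf("LNC%03d", seq_len(config$n_genes))
  p <- length(feature_ids)
  subtypes <- config$subtypes
  if (length(subtypes) < 1L || config$n_per_subtype < 1L)
    stop("empty subtype configuration")
  withr::with_seed(config$seed + 303L, {
    n <- length(subtypes) * config$n_per_subtype
    labels <- rep(subtypes, each = config$n_per_subtype)
    sample_ids <- sprintf("S%03d", seq_len(n))
    base <- rnorm(p, config$baseline_mean, config$baseline_sd)
    M <- base::matrix(rep(base, n), nrow = p)
    pool <- seq_len(p)
    if (is.null(de_features)) {
      de_features <- list()
      for (si in seq_along(subtypes)) {
        st <- subtypes[si]
        k <- min(config$n_de_per_subtype, length(pool))
        feats <- sort(sample(pool, k))
        pool <- setdiff(pool, feats)
        de_features[[st]] <- feature_ids[feats]
      }
    } else {
      pool <- setdiff(pool, match(unlist(de_features), feature_ids))
    }
    for (si in seq_along(subtypes)) {
      st <- subtypes[si]
      feats <- match(de_features[[st]], feature_ids)
      if (length(feats) == 0L) next
      sign_st <- if (si %% 2L == 0L) -1 else 1
      M[feats, labels == st] <- M[feats, labels == st] +
        sign_st * config$shift
    }
    M <- M + base::matrix(rnorm(p * n, 0, config$noise_sd), nrow = p)
    dimnames(M) <- list(feature_ids, sample_ids)
    if (is.null(prognostic_features)) {
      # drawn from the non-DE pool when possible
      prog_pool <- if (length(pool) >= config$n_prognostic) pool
                   else seq_len(p)
      prog <- sort(sample(prog_pool, config$n_prognostic))
    } else {
      prog <- match(prognostic_features, feature_ids)
      if (anyNA(prog)) stop("unknown prognostic feature id")
    }
    beta <- setNames(rep(0, p), feature_ids)
    beta[prog] <- config$beta_effect * rep(c(1, -1),
                                           length.out = length(prog))
    Z <- scale(t(M))                 # samples x features, standardised
    Z[!is.finite(Z)] <- 0            # zero-variance features carry no hazard
    lp <- drop(Z %*% beta)
    T_true <- rexp(n, rate = config$baseline_hazard * exp(lp))
    cf <- config$censoring_fraction
    if (cf > 0) {
      # choose cmax so that mean P(C < T) matches the target fraction
      f <- function(cmax) mean(pmin(T_true / cmax, 1)) - cf
      cmax <- uniroot(f, c(1e-6, 1e6))$root
      C <- runif(n, 0, cmax)
      time <- pmin(T_true, C)
      event <- as.integer(T_true <= C)
    } else {
      time <- T_true
      event <- rep(1L, n)
    }
    time <- pmax(time, 1e-4)
    clinical <- data.frame(sample = sample_ids, time = time,
                           event = event, subtype = labels,
                           stringsAsFactors = FALSE)
    class(clinical) <- c("selnc_clinical", "data.frame")
    list(expr = expression_matrix(M, scale = "log2"),
         clinical = clinical,
         truth = list(de_features = de_features,
                      beta = beta[beta != 0],
                      prognostic_features = feature_ids[prog],
                      lp = setNames(lp, sample_ids)))
  })
}

#' Generate a complete simulated input bundle
#'
#' Runs all three generators with consistent gene/transcript/feature
#' ids, writes every file a pipeline run needs under `out_dir`, and
#' returns the combined ground truth.
#'
#' @param config A [sim_config()] whose `n_transcripts` should equal
#'   `n_genes` for id consistency (enforced here).
#' @param out_dir Output directory (created if missing).
#' @return List of file paths plus `truth`.
#' @export
simulate_bundle <- function(config, out_dir) {
  if (config$n_transcripts != config$n_genes)
    stop("bundle generation requires n_transcripts == n_genes")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  seqs <- simulate_sequences(config)
  es <- simulate_expression_survival(config)
  paths <- list(
    se_bed = file.path(out_dir, "se.bed"),
    genes_gtf = file.path(out_dir, "genes.gtf"),
    transcripts_fa = file.path(out_dir, "transcripts.fa"),
    te_fa = file.path(out_dir, "te.fa"),
    functional_fa = file.path(out_dir, "functional_ref.fa"),
    expr_tsv = file.path(out_dir, "expr.tsv"),
    clinical_tsv = file.path(out_dir, "clinical.tsv"))
  write_bed(ann$se, paths$se_bed)
  write_gtf(ann$genes, paths$genes_gtf)
  write_fasta(seqs$transcripts, paths$transcripts_fa)
  write_fasta(seqs$te_library, paths$te_fa)
  write_fasta(seqs$functional_ref, paths$functional_fa)
  write_matrix(es$expr, paths$expr_tsv)
  write_clinical(es$clinical, paths$clinical_tsv)
  truth <- list(annotation = ann$truth, sequences = seqs$truth,
                expression = es$truth)
  tdir <- file.path(out_dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  writeLines(ann$truth$se_lncrna_ids, file.path(tdir, "se_lncrnas.txt"))
  write.table(seqs$truth, file.path(tdir, "ridl_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(names(es$truth$beta), file.path(tdir, "prognostic.txt"))
  c(paths, list(truth = truth))
}

#' Generate a bundle with exactly one fully planted candidate
#'
#' Builds a synthetic input bundle in which gene `LNC001` — and only
#' that gene — carries all four candidate properties at once: its
#' locus overlaps a super-enhancer, its transcript has a planted TE
#' fragment, it is differentially expressed in the target subtype, and
#' it has a nonzero hazard coefficient.  Other planted TE transcripts
#' coincide with the SE-overlap set but are excluded from the DE and
#' prognostic plants, so no second gene can satisfy the full funnel.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param n_genes Number of genes/transcripts (default 60).
#' @param target_subtype Subtype carrying the DE contrast (default
#'   `"Basal"`).
#' @return As [simulate_bundle()].
#' @export
simulate_hit_bundle <- function(seed, out_dir, n_genes = 60L,
                                target_subtype = "Basal") {
  cfg <- sim_config(seed = seed, n_genes = n_genes,
                    n_transcripts = n_genes,
                    overlap_fraction = 0.25,
                    class_fractions = c(te = 0.25, polya = 0.25,
                                        background = 0.5),
                    n_per_subtype = 50L,
                    subtypes = c("Basal", "LumA", "LumB"),
                    shift = 2, beta_effect = 1.2,
                    censoring_fraction = 0.25)
  ids <- sprintf("LNC%03d", seq_len(n_genes))
  # TE transcripts and SE-overlapping genes are both the first
  # quarter of ids; DE/prognostic plants take the hit plus genes
  # outside that block.
  de <- list()
  de[[target_subtype]] <- ids[c(1L, 20:23)]
  for (st in setdiff(cfg$subtypes, target_subtype))
    de[[st]] <- ids[24:26]
  prog <- ids[c(1L, 30:32)]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  seqs <- simulate_sequences(cfg)
  es <- simulate_expression_survival(cfg, de_features = de,
                                     prognostic_features = prog)
  paths <- list(
    se_bed = file.path(out_dir, "se.bed"),
    genes_gtf = file.path(out_dir, "genes.gtf"),
    transcripts_fa = file.path(out_dir, "transcripts.fa"),
    te_fa = file.path(out_dir, "te.fa"),
    functional_fa = file.path(out_dir, "functional_ref.fa"),
    expr_tsv = file.path(out_dir, "expr.tsv"),
    clinical_tsv = file.path(out_dir, "clinical.tsv"))
  write_bed(ann$se, paths$se_bed)
  write_gtf(ann$genes, paths$genes_gtf)
  write_fasta(seqs$transcripts, paths$transcripts_fa)
  write_fasta(seqs$te_library, paths$te_fa)
  write_fasta(seqs$functional_ref, paths$functional_fa)
  write_matrix(es$expr, paths$expr_tsv)
  write_clinical(es$clinical, paths$clinical_tsv)
  c(paths, list(truth = list(annotation = ann$truth,
                             sequences = seqs$truth,
                             expression = es$truth,
                             hit = ids[1L])))
}

#' Validate that emitted files and truth are mutually consistent
#'
#' Reloads a bundle from disk and checks the planted SE-overlap set,
#' the planted fragment coordinates and the expression/clinical
#' alignment against the returned truth.
#'
#' @param bundle Return value of [simulate_bundle()].
#' @return `TRUE` (invisibly) or an error describing the mismatch.
#' @export
validate_bundle <- function(bundle) {
  se <- read_bed(bundle$se_bed)
  genes <- read_gtf(bundle$genes_gtf, biotype_filter = "lncRNA")
  cat_ <- identify_se_lncrnas(se, genes, mode = "gene_overlap")
  want <- sort(bundle$truth$annotation$se_lncrna_ids)
  got <- sort(cat_$se_lncrna_ids)
  if (!identical(want, got))
    stop("SE-lncRNA truth mismatch: planted ", length(want),
         ", recovered ", length(got))
  tx <- read_fasta(bundle$transcripts_fa)
  tr <- bundle$truth$sequences
  if (!identical(sort(names(tx)), sort(tr$seq_id)))
    stop("transcript id mismatch")
  expr <- read_matrix(bundle$expr_tsv)
  clin <- read_clinical(bundle$clinical_tsv)
  if (!identical(colnames(expr$values), clin$sample))
    stop("expression/clinical sample mismatch")
  invisible(TRUE)
}
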