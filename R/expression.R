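# Subtype assignment, supervised LDA, empirical-Bayes moderated
# differential screening with BH control, and small qPCR computations.

#' Construct a subtype centroid table
#'
#' @param centroids Numeric matrix, genes in rows, subtypes in columns.
#' @param min_corr Correlation threshold below which a sample is
#'   labelled `"Unknown"`; default 0.1.
#' @return An object of class `selnc_centroids`.
#' @export
subtype_centroids <- function(centroids, min_corr = 0.1) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) < 2L) stop("need >= 2 subtypes")
  if (nrow(centroids) < 2L) stop("need >= 2 genes")
  if (min_corr < -1 || min_corr > 1) stop("min_corr must be in [-1, 1]")
  if (is.null(rownames(centroids)) || is.null(colnames(centroids)))
    stop("centroid matrix needs gene and subtype names")
  structure(list(values = centroids, min_corr = min_corr),
            class = "selnc_centroids")
}

#' Nearest-centroid subtype assignment
#'
#' Correlates the sample against every centroid over the shared genes
#' (Spearman by default, the common choice for PAM50-style
#' classification) and returns the best label, or `"Unknown"` when the
#' best correlation is below `min_corr`.  Exact ties go to the
#' lexicographically first label.
#'
#' @param sample_vector Named numeric vector of expression values.
#' @param centroids A [subtype_centroids()] object.
#' @param method Correlation method, `"spearman"` (default) or
#'   `"pearson"`.
#' @return The winning subtype label (character scalar) with the
#'   correlation in attribute `"corr"`.
#' @export
classify_subtype <- function(sample_vector, centroids,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  genes <- intersect(rownames(centroids$values), names(sample_vector))
  if (length(genes) < 2L) stop("fewer than 2 shared genes")
  if (length(genes) < 0.5 * nrow(centroids$values))
    stop("sample covers < 50% of centroid genes")
  r <- apply(centroids$values[genes, , drop = FALSE], 2L, function(cv)
    suppressWarnings(cor(sample_vector[genes], cv, method = method)))
  r[is.na(r)] <- -Inf
  labs <- sort(colnames(centroids$values))   # lexicographic tie-break
  r <- r[labs]
  best <- labs[which.max(r)]
  out <- if (max(r) < centroids$min_corr) "Unknown" else best
  attr(out, "corr") <- max(r)
  out
}

#' Fit a ridge-regularised linear discriminant model
#'
#' Axes maximise the generalised Rayleigh quotient of between-class to
#' (ridge-regularised) within-class scatter; classification is by
#' nearest class mean in the projected space.
#'
#' @param matrix Numeric matrix, samples in rows, features in columns.
#' @param labels Class label per sample; every class needs >= 2 samples.
#' @param ridge Non-negative ridge added to the within-class scatter
#'   diagonal; must be > 0 when features >= samples.
#' @return An object of class `selnc_lda` with fields `axes`
#'   (features x axes), `class_means` (projected), `grand_mean`,
#'   `eigvals`, `priors`.
#' @export
lda_fit <- function(matrix, labels, ridge = 0) {
  X <- as.matrix(matrix)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need >= 2 classes")
  nk <- table(labels)
  if (any(nk < 2L)) stop("every class needs >= 2 samples")
  n <- nrow(X); p <- ncol(X)
  if (p >= n && ridge <= 0) stop("ridge > 0 required when features >= samples")
  gm <- colMeans(X)
  Sw <- diag(ridge, p)
  Sb <- base::matrix(0, p, p)
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    Xc <- sweep(Xi, 2L, mu)
    Sw <- Sw + crossprod(Xc)
    d <- mu - gm
    Sb <- Sb + nrow(Xi) * tcrossprod(d)
  }
  if (ridge == 0 && rcond(Sw) < 1e-12)
    stop("within-class scatter is singular; increase ridge")
  ei <- eigen(solve(Sw, Sb))
  keep <- seq_len(min(length(classes) - 1L, p))
  axes <- Re(ei$vectors[, keep, drop = FALSE])
  eigvals <- Re(ei$values[keep])
  cm <- do.call(rbind, lapply(classes, function(cl)
    drop((colMeans(X[labels == cl, , drop = FALSE]) - gm) %*% axes)))
  cm <- base::matrix(cm, nrow = length(classes),
                     dimnames = list(classes, NULL))
  structure(list(axes = axes, class_means = cm, grand_mean = gm,
                 eigvals = eigvals,
                 priors = as.numeric(nk[classes]) / n, classes = classes),
            class = "selnc_lda")
}

#' Project samples onto LDA axes
#'
#' @param model A `selnc_lda` model.
#' @param matrix Samples x features matrix.
#' @return Samples x axes matrix of discriminant coordinates.
#' @export
lda_transform <- function(model, matrix) {
  sweep(as.matrix(matrix), 2L, model$grand_mean) %*% model$axes
}

#' Classify samples with a fitted LDA model
#'
#' @param model A `selnc_lda` model.
#' @param matrix Samples x features matrix.
#' @return Character vector of predicted class labels.
#' @export
lda_classify <- function(model, matrix) {
  Z <- lda_transform(model, matrix)
  pred <- apply(Z, 1L, function(z) {
    d2 <- rowSums(sweep(model$class_means, 2L, z)^2)
    model$classes[which.min(d2)]
  })
  unname(pred)
}

# Invert the trigamma function by Newton iteration (for the moment
# estimator of the prior degrees of freedom).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' Per feature, ordinary two-sample pooled-variance t components are
#' computed; with `moderation = TRUE` a scaled inverse-chi-square prior
#' `(d0, s0^2)` is fitted to the sample variances by moment matching on
#' the log variances (mean and variance of `log s^2` matched through
#' digamma/trigamma identities), and the posterior variance
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` replaces `s^2` in the t
#' statistic, which then has `d0 + d` degrees of freedom.  With
#' `moderation = FALSE` the ordinary pooled t is returned exactly.
#'
#' @param matrix Features x samples matrix on log2 scale.
#' @param group_mask Logical vector over samples; `TRUE` marks the
#'   target group.  Both groups need >= 2 samples.
#' @param moderation Logical, default `TRUE`.
#' @return data.frame: `feature_id`, `log2fc` (target minus rest),
#'   `t_mod`, `df`, `p`, `q` (BH-adjusted).
#' @export
moderated_ttest <- function(matrix, group_mask, moderation = TRUE) {
  X <- as.matrix(matrix)
  group_mask <- as.logical(group_mask)
  n1 <- sum(group_mask); n2 <- sum(!group_mask)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 samples")
  X1 <- X[, group_mask, drop = FALSE]
  X2 <- X[, !group_mask, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- apply(X1, 1L, var); v2 <- apply(X2, 1L, var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  se_factor <- sqrt(1 / n1 + 1 / n2)
  lfc <- m1 - m2
  if (moderation) {
    if (all(s2 == 0)) stop("zero variance in every feature")
    ok <- s2 > 0
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    n_ok <- length(z)
    evar <- var(e) * (n_ok - 1) / n_ok - trigamma(d / 2)
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
      s02 <- exp(mean(e))
    } else {
      d0 <- 2 * .trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
               else (d0 * s02 + d * s2) / (d0 + d)
    df_total <- d0 + d
    tstat <- lfc / (sqrt(s2_post) * se_factor)
  } else {
    df_total <- d
    tstat <- lfc / (sqrt(s2) * se_factor)
    tstat[s2 == 0 & lfc == 0] <- 0
  }
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[is.na(p)] <- 1
  data.frame(feature_id = rownames(X), log2fc = lfc, t_mod = tstat,
             df = rep(df_total, length(lfc)), p = p, q = bh_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure with monotone enforcement; the mapping back to the
#' input order is preserved.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  q[order(o)]
}

#' Per-subtype differential expression summary
#'
#' Runs [moderated_ttest()] for each subtype against the rest and
#' intersects the significant sets.  A feature is differentially
#' expressed when `q < alpha` and `|log2fc| >= lfc_min`.
#'
#' @param matrix Features x samples log2 matrix.
#' @param subtype_labels Subtype label per sample (>= 2 subtypes).
#' @param alpha FDR threshold, default 0.05.
#' @param lfc_min Minimum absolute log2 fold change, default 1.
#' @param moderation Passed to [moderated_ttest()].
#' @return List with `tables` (per-subtype result data.frames),
#'   `de_sets` (per-subtype DE feature id vectors), `pairwise`
#'   (named intersection sizes) and `common` (features DE in every
#'   subtype).
#' @export
subtype_de_summary <- function(matrix, subtype_labels, alpha = 0.05,
                               lfc_min = 1, moderation = TRUE) {
  labels <- as.character(subtype_labels)
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2L) stop("need >= 2 subtypes")
  tables <- list(); de_sets <- list()
  for (st in subtypes) {
    res <- moderated_ttest(matrix, labels == st, moderation = moderation)
    res$de_flag <- res$q < alpha & abs(res$log2fc) >= lfc_min
    tables[[st]] <- res
    de_sets[[st]] <- res$feature_id[res$de_flag]
  }
  pairs <- utils::combn(subtypes, 2L)
  pairwise <- apply(pairs, 2L, function(pr)
    length(intersect(de_sets[[pr[1L]]], de_sets[[pr[2L]]])))
  names(pairwise) <- apply(pairs, 2L, paste, collapse = "&")
  common <- Reduce(intersect, de_sets)
  list(tables = tables, de_sets = de_sets, pairwise = pairwise,
       common = common)
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_trt,ct_ref_trt Target/reference gene Ct in the
#'   treated condition.
#' @param ct_target_ctl,ct_ref_ctl Target/reference gene Ct in the
#'   control condition.
#' @return `2^-((ct_target_trt - ct_ref_trt) - (ct_target_ctl - ct_ref_ctl))`.
#' @export
ddct <- function(ct_target_trt, ct_ref_trt, ct_target_ctl, ct_ref_ctl) {
  cts <- c(ct_target_trt, ct_ref_trt, ct_target_ctl, ct_ref_ctl)
  if (any(!is.finite(cts))) stop("all Ct values must be finite")
  2^-((ct_target_trt - ct_ref_trt) - (ct_target_ctl - ct_ref_ctl))
}

#' RNA half-life from a transcription-blocked decay series
#'
#' Fits `ln(expression)` against time by least squares (first-order
#' decay, as after actinomycin D treatment) and returns
#' `t_half = ln(2) / |slope|`.  A non-negative slope (no decay) returns
#' `Inf` with a warning.
#'
#' @param times_h Time points in hours (>= 3).
#' @param rel_expression Positive relative expression at each time.
#' @return Half-life in hours.
#' @export
estimate_half_life <- function(times_h, rel_expression) {
  if (length(times_h) < 3L) stop("need >= 3 timepoints")
  if (length(times_h) != length(rel_expression)) stop("length mismatch")
  if (any(rel_expression <= 0)) stop("expression must be > 0")
  fit <- stats::lm.fit(cbind(1, times_h), log(rel_expression))
  slope <- fit$coefficients[[2L]]
  if (slope >= 0) {
    warning("no decay observed; returning Inf")
    return(Inf)
  }
  log(2) / abs(slope)
}
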