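test_that("nearest-centroid subtype calls follow the stated rules", {
  set.seed(51)
  genes <- paste0("g", 1:20)
  cen <- matrix(rnorm(40), 20, 2,
                dimnames = list(genes, c("Basal", "LumA")))
  ct <- subtype_centroids(cen, min_corr = 0.1)
  lab <- classify_subtype(setNames(cen[, "Basal"], genes), ct)
  expect_equal(as.character(lab), "Basal")
  expect_equal(attr(lab, "corr"), 1)
  # all below min_corr -> Unknown
  ct_hi <- subtype_centroids(cen, min_corr = 0.999)
  noise <- setNames(rnorm(20), genes)
  expect_equal(as.character(classify_subtype(noise, ct_hi)), "Unknown")
  # exact tie -> lexicographically first label
  cen_tie <- cbind(Zeta = cen[, 1], Alpha = cen[, 1])
  rownames(cen_tie) <- genes
  lab2 <- classify_subtype(setNames(cen[, 1], genes),
                           subtype_centroids(cen_tie))
  expect_equal(as.character(lab2), "Alpha")
  expect_error(classify_subtype(setNames(rnorm(1), "g1"), ct), "shared")
  expect_error(classify_subtype(setNames(rnorm(5), genes[1:5]), ct),
               "50%")
})

test_that("LDA separates separable classes and matches the grid oracle", {
  set.seed(52)
  x <- c(rnorm(20, -1, 0.1), rnorm(20, 1, 0.1))
  lab <- rep(c("a", "b"), each = 20)
  m <- lda_fit(cbind(v = x), lab)
  expect_equal(lda_classify(m, cbind(v = x)), lab)
  # identical class distributions: leading scatter ratio collapses
  m0 <- lda_fit(cbind(v = c(x[1:20], x[1:20])), lab, ridge = 1e-6)
  expect_lt(m0$eigvals[1] / m$eigvals[1], 1e-3)
  # 2-D grid oracle: Fisher ratio maximised over 3600 directions
  n <- 40
  X <- cbind(rnorm(2 * n), rnorm(2 * n, sd = 2))
  X[1:n, ] <- X[1:n, ] + matrix(rep(c(2, 1), each = n), ncol = 2)
  lab2 <- rep(c("p", "q"), each = n)
  fit <- lda_fit(X, lab2)
  ratio <- function(theta) {
    w <- c(cos(theta), sin(theta))
    z <- X %*% w
    mb <- tapply(z, lab2, mean)
    sw <- sum(tapply(z, lab2, function(v) sum((v - mean(v))^2)))
    sb <- sum(tapply(z, lab2, length) * (mb - mean(z))^2)
    sb / sw
  }
  grid <- seq(0, pi, length.out = 3600)
  best <- grid[which.max(vapply(grid, ratio, numeric(1)))]
  got <- atan2(fit$axes[2, 1], fit$axes[1, 1]) %% pi
  expect_lt(min(abs(got - best), pi - abs(got - best)),
            0.5 * pi / 180)
  expect_error(lda_fit(cbind(x), rep(c("a", "b", "c"), c(20, 19, 1))),
               ">= 2 samples")
})

test_that("moderation off reduces exactly to the pooled two-sample t", {
  # 4-sample hand toy: group1 = (1, 3), group2 = (2, 6)
  M <- matrix(c(1, 3, 2, 6), 1, 4,
              dimnames = list("f1", paste0("s", 1:4)))
  res <- moderated_ttest(rbind(M, M + 1), c(TRUE, TRUE, FALSE, FALSE),
                         moderation = FALSE)
  m1 <- 2; m2 <- 4
  s2 <- (var(c(1, 3)) + var(c(2, 6))) / 2
  t_hand <- (m1 - m2) / sqrt(s2 * (1 / 2 + 1 / 2))
  expect_equal(res$t_mod[1], t_hand)
  expect_equal(res$p[1], 2 * pt(-abs(t_hand), df = 2))
  # identical group means: t = 0, p = 1
  M0 <- matrix(c(1, 2, 2, 1, 5, 7, 7, 5), 2, 4, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("s", 1:4)))
  r0 <- moderated_ttest(M0, c(TRUE, FALSE, TRUE, FALSE),
                        moderation = FALSE)
  expect_equal(r0$t_mod, c(0, 0))
  expect_equal(r0$p, c(1, 1))
  # random matrix: equals the closed-form pooled t feature-wise
  set.seed(53)
  M2 <- matrix(rnorm(50 * 8), 50, 8,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  g <- rep(c(TRUE, FALSE), each = 4)
  r2 <- moderated_ttest(M2, g, moderation = FALSE)
  tt <- apply(M2, 1, function(v)
    t.test(v[g], v[!g], var.equal = TRUE)$statistic)
  expect_equal(r2$t_mod, unname(tt), tolerance = 1e-12)
})

test_that("moderated t agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(54)
  M <- matrix(rnorm(300 * 10, sd = rep(sqrt(1 / rgamma(300, 4, 4)), 10)),
              300, 10, dimnames = list(paste0("g", 1:300),
                                       paste0("s", 1:10)))
  M[1:10, 1:5] <- M[1:10, 1:5] + 3
  g <- rep(c(1, 0), each = 5)
  mine <- moderated_ttest(M, g == 1)
  fit <- limma::eBayes(limma::lmFit(M, cbind(1, g)))
  expect_equal(mine$log2fc, unname(fit$coefficients[, 2]),
               tolerance = 1e-10)
  # same moment-matching family; small numerical differences allowed
  expect_equal(mine$t_mod, unname(fit$t[, 2]), tolerance = 0.05)
  expect_gt(cor(mine$p, fit$p.value[, 2]), 0.999)
})

test_that("bh_fdr equals the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(55)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), bf_bh(p))
  }
})

test_that("subtype DE summary recovers planted sets exactly", {
  # one-vs-rest contrasts dilute a single-subtype shift by (K-1)/K
  # into the other subtypes; with 5 subtypes and lfc_min = 1 the
  # leak-through (3/4 = 0.75, 1.8/4 = 0.45+0.45) stays sub-threshold
  set.seed(56)
  p <- 60; n_per <- 10
  feats <- paste0("g", seq_len(p))
  subtypes <- c("A", "B", "C", "D", "E")
  labs <- rep(subtypes, each = n_per)
  M <- matrix(rnorm(p * 5 * n_per, 5, 0.2), p, 5 * n_per,
              dimnames = list(feats, paste0("s", 1:(5 * n_per))))
  planted_a <- feats[1:10]   # shifted only in A
  shared <- feats[11:13]     # shifted in both A and B
  M[planted_a, labs == "A"] <- M[planted_a, labs == "A"] + 3
  M[shared, labs %in% c("A", "B")] <-
    M[shared, labs %in% c("A", "B")] + 1.6
  sm <- subtype_de_summary(M, labs, alpha = 0.05, lfc_min = 1)
  expect_setequal(sm$de_sets$A, c(planted_a, shared))
  expect_setequal(sm$de_sets$B, shared)
  for (st in c("C", "D", "E")) expect_length(sm$de_sets[[st]], 0L)
  expect_equal(unname(sm$pairwise["A&B"]), 3L)
  # alpha = 0: every set empty
  sm0 <- subtype_de_summary(M, labs, alpha = 0)
  expect_true(all(lengths(sm0$de_sets) == 0))
})

test_that("ddct closed forms and shift invariance", {
  expect_equal(ddct(20, 20, 20, 20), 1.0)
  expect_equal(ddct(21, 20, 20, 20), 0.5)
  expect_equal(ddct(19, 20, 20, 20), 2.0)
  set.seed(57)
  for (i in 1:20) {
    ct <- runif(4, 15, 30)
    k <- runif(1, -5, 5)
    expect_equal(ddct(ct[1], ct[2], ct[3], ct[4]),
                 ddct(ct[1] + k, ct[2] + k, ct[3] + k, ct[4] + k))
  }
  expect_error(ddct(Inf, 20, 20, 20), "finite")
})

test_that("half-life estimation from first-order decay", {
  times <- c(0, 2, 4, 6, 8)
  expect_equal(estimate_half_life(times, 2^-(times / 2)), 2.0)
  expect_warning(hl <- estimate_half_life(times, rep(1, 5)), "no decay")
  expect_equal(hl, Inf)
  expect_error(estimate_half_life(times, c(1, 1, -1, 1, 1)), "> 0")
  expect_error(estimate_half_life(c(0, 1), c(1, 0.5)), ">= 3")
  set.seed(58)
  expr <- exp(-log(2) / 4 * times) * exp(rnorm(5, 0, 0.05))
  est <- estimate_half_life(times, expr)
  expect_gt(est, 3.5); expect_lt(est, 4.5)
})
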