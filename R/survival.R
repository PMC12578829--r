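# Prognostic cascade: Kaplan-Meier / log-rank, Cox partial-likelihood
# Newton fitting with Breslow ties, univariate screen with BH control,
# L1-penalised Cox selection, a random survival forest risk score,
# permutation importance and IPCW time-dependent AUC.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 event, 0 censored); >= 1 event
#'   required.
#' @return An object of class `selnc_km`: data.frame with `time`
#'   (distinct event times), `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) != length(event)) stop("length mismatch")
  if (sum(event) < 1) stop("need >= 1 event")
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) as.numeric(sum(time >= t)), numeric(1))
  n_event <- vapply(et, function(t) as.numeric(sum(time == t & event == 1)),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       surv = surv, row.names = NULL),
            class = c("selnc_km", "data.frame"))
}

# Evaluate a KM curve (left-continuous step: S(t) uses events <= t;
# strict = TRUE gives the left limit S(t-)).
.km_eval <- function(km, t, strict = FALSE) {
  idx <- if (strict) sum(km$time < t) else sum(km$time <= t)
  if (idx == 0L) 1 else km$surv[idx]
}

#' Two-group log-rank test
#'
#' Hypergeometric expectation and variance summed over distinct event
#' times; the statistic is referred to a chi-square distribution with
#' one degree of freedom.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Vector with exactly two distinct values.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- unique(group)
  if (length(g) != 2L) stop("need exactly 2 non-empty groups")
  in1 <- group == g[1L]
  et <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in et) {
    at <- time >= t
    nj <- sum(at); n1 <- sum(at & in1)
    dj <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in1)
    U <- U + d1 - dj * n1 / nj
    if (nj > 1)
      V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  chi2 <- if (V > 0) U^2 / V else 0
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Breslow partial log-likelihood, gradient and information for beta.
# Vectorised over events via reverse cumulative sums of the weighted
# moments S0, S1, S2 over the (tied-time shared) risk sets.
.cox_pll <- function(beta, X, time, event) {
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)             # numerical stabilisation
  w <- exp(eta)
  ord <- order(time)
  Xo <- X[ord, , drop = FALSE]; wo <- w[ord]
  to <- time[ord]; eo <- event[ord]
  n <- length(to); p <- ncol(X)
  etao <- eta[ord]
  revcs <- function(v) rev(cumsum(rev(v)))
  rs0 <- revcs(wo)
  rs1 <- base::matrix(
    apply(Xo * wo, 2L, revcs), nrow = n)
  pair_idx <- expand.grid(a = seq_len(p), b = seq_len(p))
  rs2 <- base::matrix(
    vapply(seq_len(p * p), function(k)
      revcs(Xo[, pair_idx$a[k]] * Xo[, pair_idx$b[k]] * wo),
      numeric(n)),
    nrow = n)
  first_ge <- match(to, to)          # first index of each tie group
  ev <- which(eo == 1)
  j <- first_ge[ev]
  s0 <- rs0[j]
  ll <- sum(etao[ev] - log(s0))
  M <- rs1[j, , drop = FALSE] / s0
  grad <- colSums(Xo[ev, , drop = FALSE]) - colSums(M)
  info <- base::matrix(colSums(rs2[j, , drop = FALSE] / s0), p, p) -
    crossprod(M)
  list(ll = ll, grad = grad, info = info)
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Newton-Raphson maximisation of the Breslow partial likelihood with a
#' small ridge `l2_eps` on the information matrix for numerical
#' stability, to a max-gradient tolerance of `1e-8` within 100
#' iterations.  Non-convergence and ill-conditioned information are
#' flagged, never silent.
#'
#' @param X Samples x features numeric matrix (no constant column).
#' @param time,event Survival outcome.
#' @param l2_eps Stabilising ridge, default `1e-9`.
#' @return An object of class `selnc_cox`: list with `beta`, `se`,
#'   `z`, `p`, `loglik`, `converged`, `stable`, `n_iter`.
#' @export
cox_fit <- function(X, time, event, l2_eps = 1e-9) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) stop("constant column in X: ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  if (sum(event) < 1) stop("need >= 1 event")
  p <- ncol(X)
  beta <- numeric(p)
  cur <- .cox_pll(beta, X, time, event)
  converged <- FALSE; it <- 0L
  for (it in seq_len(100L)) {
    if (max(abs(cur$grad)) < 1e-8) { converged <- TRUE; break }
    H <- cur$info + diag(l2_eps, p)
    step <- tryCatch(solve(H, cur$grad), error = function(e) NULL)
    if (is.null(step)) break
    # step halving
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + step / 2^h
      nxt <- .cox_pll(cand, X, time, event)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) {
        beta <- cand; cur <- nxt; ok <- TRUE; break
      }
    }
    if (!ok) break
  }
  if (max(abs(cur$grad)) < 1e-8) converged <- TRUE
  H <- cur$info + diag(l2_eps, p)
  stable <- is.finite(rcond(H)) && rcond(H) > 1e-10
  se <- rep(NA_real_, p)
  if (stable) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov) && all(diag(cov) > 0)) se <- sqrt(diag(cov))
    else stable <- FALSE
  }
  z <- beta / se
  structure(list(beta = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)), z = z,
                 p = 2 * pnorm(-abs(z)), loglik = cur$ll,
                 converged = converged && stable, stable = stable,
                 n_iter = it),
            class = "selnc_cox")
}

#' Univariate prognostic screen
#'
#' One single-feature Cox fit per feature (Wald p), BH correction
#' across features, plus a median-split log-rank p as a secondary
#' column.  Constant features are skipped with a warning and listed in
#' the `skipped` attribute.
#'
#' @param X Samples x features matrix.
#' @param time,event Survival outcome.
#' @param alpha FDR threshold for the significant set, default 0.05.
#' @return data.frame `feature`, `beta`, `se`, `p`, `q`, `logrank_p`,
#'   `significant`; skipped feature names in `attr(, "skipped")`.
#' @export
univariate_screen <- function(X, time, event, alpha = 0.05) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  feats <- colnames(X)
  skipped <- character(0)
  rows <- list()
  for (f in feats) {
    x <- X[, f]
    if (sd(x) == 0) {
      warning("skipping constant feature ", f)
      skipped <- c(skipped, f)
      next
    }
    fit <- cox_fit(cbind(x = x), time, event)
    med <- median(x)
    grp <- x > med
    lr_p <- if (length(unique(grp)) == 2L)
      logrank_test(time, event, grp)$p else NA_real_
    rows[[f]] <- data.frame(feature = f, beta = unname(fit$beta),
                            se = unname(fit$se), p = unname(fit$p),
                            logrank_p = lr_p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res) || nrow(res) == 0L) stop("no usable features")
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < alpha
  res <- res[, c("feature", "beta", "se", "p", "q", "logrank_p",
                 "significant")]
  attr(res, "skipped") <- skipped
  res
}

#' L1-penalised Cox regression path with cross-validated selection
#'
#' Backed by coordinate descent on the penalised partial likelihood
#' (glmnet); columns are standardised internally and coefficients
#' reported on the original scale.  The lambda grid is log-spaced and
#' descending from `lambda_max` (all coefficients zero); the selection
#' rule is k-fold cross-validated partial-likelihood deviance with
#' either the `min` or the `1se` rule.
#'
#' @param X Samples x features matrix.
#' @param time,event Survival outcome.
#' @param n_lambda Grid size, default 100.
#' @param cv_folds Folds, default 5; must not exceed the event count.
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed Seed for the fold assignment.
#' @param lambda_min_ratio Optional smallest-lambda ratio of the grid
#'   (glmnet default when `NULL`); drive towards 0 to approach the
#'   unpenalised fit.
#' @param thresh Coordinate-descent convergence threshold.
#' @return An object of class `selnc_lasso`: list with `lambda`
#'   (descending), `beta` (feature x lambda), `selected_lambda`,
#'   `selected_features`, `rule`, `cvm`, `lambda_min`, `lambda_1se`.
#' @export
lasso_cox_path <- function(X, time, event, n_lambda = 100L, cv_folds = 5L,
                           rule = c("1se", "min"), seed = 1L,
                           lambda_min_ratio = NULL, thresh = 1e-10) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (cv_folds > sum(event)) stop("cv_folds exceeds the number of events")
  y <- cbind(time = time, status = event)
  foldid <- withr::with_seed(as.integer(seed),
                             sample(rep(seq_len(cv_folds), length.out = nrow(X))))
  args <- list(x = X, y = y, family = "cox", foldid = foldid,
               nlambda = n_lambda, standardize = TRUE, thresh = thresh)
  if (!is.null(lambda_min_ratio)) {
    # explicit log-spaced grid from lambda_max down; an explicit
    # sequence also disables glmnet's early path stopping
    # inflate the top of the grid slightly so the first solution is
    # exactly the zero vector
    lmax <- 1.01 * glmnet::glmnet(X, y, family = "cox",
                                  nlambda = 3L)$lambda[1L]
    args$lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = n_lambda))
    args$nlambda <- NULL
  }
  cv <- do.call(glmnet::cv.glmnet, args)
  fit <- cv$glmnet.fit
  sel_lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.matrix(fit$beta)
  colnames(beta) <- NULL
  j <- which.min(abs(fit$lambda - sel_lambda))
  selected <- rownames(beta)[beta[, j] != 0]
  structure(list(lambda = fit$lambda, beta = beta,
                 selected_lambda = sel_lambda,
                 selected_features = selected, rule = rule,
                 cvm = cv$cvm, cv_lambda = cv$lambda,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se),
            class = "selnc_lasso")
}

# ---- random survival forest -------------------------------------------

.rsf_grow_node <- function(idx, X, time, event, grid, mtry,
                           min_node_events, depth, max_depth) {
  d_here <- sum(event[idx])
  make_leaf <- function() {
    # Nelson-Aalen cumulative hazard of the node sample on the grid
    t_i <- time[idx]; e_i <- event[idx]
    ts <- sort(unique(t_i[e_i == 1]))
    if (length(ts) == 0L) {
      chf <- numeric(length(grid))
    } else {
      srt <- sort(t_i)
      n_i <- length(t_i)
      # at risk at ts_j: samples with t_i >= ts_j
      n_risk <- n_i - findInterval(ts, srt, left.open = TRUE)
      d_j <- vapply(ts, function(tt)
        as.numeric(sum(t_i == tt & e_i == 1)), numeric(1))
      cumna <- cumsum(d_j / n_risk)
      pos <- findInterval(grid, ts)
      chf <- c(0, cumna)[pos + 1L]
    }
    list(leaf = TRUE, chf = chf, chf_sum = sum(chf),
         n = length(idx), d = d_here)
  }
  if (d_here < 2L * min_node_events || length(idx) < 4L ||
      depth >= max_depth)
    return(make_leaf())
  p <- ncol(X)
  feats <- sample.int(p, min(mtry, p))
  best <- NULL; best_stat <- -1
  for (f in feats) {
    x <- X[idx, f]
    if (length(unique(x)) < 2L) next
    sp <- cpp_logrank_best_split(x, time[idx], as.integer(event[idx]),
                                 as.integer(min_node_events))
    if (sp[3L] == 1 && sp[2L] > best_stat) {
      best_stat <- sp[2L]; best <- list(feature = f, value = sp[1L])
    }
  }
  if (is.null(best)) return(make_leaf())
  left <- idx[X[idx, best$feature] <= best$value]
  right <- idx[X[idx, best$feature] > best$value]
  if (length(left) == 0L || length(right) == 0L) return(make_leaf())
  list(leaf = FALSE, feature = best$feature, value = best$value,
       left = .rsf_grow_node(left, X, time, event, grid, mtry,
                             min_node_events, depth + 1L, max_depth),
       right = .rsf_grow_node(right, X, time, event, grid, mtry,
                              min_node_events, depth + 1L, max_depth))
}

#' Fit a random survival forest
#'
#' Bootstrap survival trees with log-rank split selection over `mtry`
#' randomly drawn features and Nelson-Aalen cumulative-hazard leaf
#' estimates on the shared grid of observed event times.  Fully
#' deterministic given `seed`.
#'
#' @param X Samples x features matrix (the selected feature set).
#' @param time,event Survival outcome.
#' @param n_trees Number of trees (>= 10), default 200.
#' @param mtry Features tried per split; default `ceiling(sqrt(p))`.
#' @param min_node_events Minimum events per child, default 3.
#' @param seed Integer seed.
#' @param max_depth Depth cap, default 20.
#' @return An object of class `selnc_rsf`.
#' @export
rsf_fit <- function(X, time, event, n_trees = 200L, mtry = NULL,
                    min_node_events = 3L, seed = 1L, max_depth = 20L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (n_trees < 10L) stop("n_trees must be >= 10")
  if (sum(event) < 1) stop("need >= 1 event")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  grid <- sort(unique(time[event == 1]))
  n <- nrow(X)
  trees <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_trees), function(b) {
      boot <- sample.int(n, n, replace = TRUE)
      # grow on the bootstrap sample (duplicates kept)
      Xb <- X[boot, , drop = FALSE]
      .rsf_grow_node(seq_len(n), Xb, time[boot], event[boot], grid,
                     mtry, min_node_events, 0L, max_depth)
    })
  })
  structure(list(trees = trees, features = colnames(X), grid = grid,
                 n_trees = n_trees, mtry = mtry,
                 min_node_events = min_node_events, seed = seed),
            class = "selnc_rsf")
}

# Drop all rows of X down one tree at once; returns per-sample summed
# leaf cumulative hazard (the tree's contribution to the mortality
# score).
.rsf_tree_scores <- function(node, X, idx, out) {
  if (node$leaf) {
    out[idx] <- node$chf_sum
    return(out)
  }
  go_left <- X[idx, node$feature] <= node$value
  if (any(go_left))
    out <- .rsf_tree_scores(node$left, X, idx[go_left], out)
  if (any(!go_left))
    out <- .rsf_tree_scores(node$right, X, idx[!go_left], out)
  out
}

#' Ensemble risk scores from a survival forest
#'
#' The per-sample ensemble cumulative hazard function (average over
#' trees) is summed over the event-time grid; higher scores mean worse
#' expected survival ("ensemble mortality").
#'
#' @param model A `selnc_rsf` from [rsf_fit()].
#' @param X Samples x features matrix with the model's features.
#' @return Numeric vector of risk scores.
#' @export
risk_score <- function(model, X) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  n <- nrow(X)
  acc <- numeric(n)
  for (tr in model$trees)
    acc <- acc + .rsf_tree_scores(tr, X, seq_len(n), numeric(n))
  setNames(acc / model$n_trees, rownames(X))
}

#' Harrell concordance index
#'
#' @param scores Risk scores (higher = worse).
#' @param time,event Survival outcome.
#' @return C-index in `[0, 1]`; tied scores count 1/2.
#' @export
c_index <- function(scores, time, event) {
  n <- length(scores)
  conc <- 0; comp <- 0
  for (i in which(event == 1)) {
    cmp <- time > time[i]
    comp <- comp + sum(cmp)
    conc <- conc + sum(scores[i] > scores[cmp]) +
      0.5 * sum(scores[i] == scores[cmp])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

#' Permutation feature importance for a survival forest
#'
#' Importance of a feature is the mean drop in Harrell C-index when
#' its column is permuted, over `n_perm` permutations.  Features are
#' returned in descending importance, ties broken by name.
#'
#' @param model A `selnc_rsf`.
#' @param X,time,event Evaluation data.
#' @param n_perm Permutations per feature (> 0), default 5.
#' @param seed Seed.
#' @return data.frame `feature`, `importance`, sorted.
#' @export
feature_importance <- function(model, X, time, event, n_perm = 5L,
                               seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  X <- as.matrix(X)[, model$features, drop = FALSE]
  base_c <- c_index(risk_score(model, X), time, event)
  imp <- withr::with_seed(as.integer(seed), {
    vapply(model$features, function(f) {
      drops <- vapply(seq_len(n_perm), function(r) {
        Xp <- X
        Xp[, f] <- sample(Xp[, f])
        base_c - c_index(risk_score(model, Xp), time, event)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  res <- data.frame(feature = model$features, importance = unname(imp),
                    stringsAsFactors = FALSE)
  res[order(-res$importance, res$feature), , drop = FALSE]
}

#' IPCW time-dependent (cumulative/dynamic) AUC
#'
#' Cases are samples with an observed event at or before `horizon`;
#' controls are samples still at risk beyond `horizon`.  Pairs are
#' weighted by inverse probability of censoring from the Kaplan-Meier
#' estimate of the censoring distribution (left limit at the case's
#' event time; value at `horizon` for controls).  Tied scores count
#' 1/2.
#'
#' @param scores Risk scores (higher = predicted worse).
#' @param time,event Survival outcome.
#' @param horizon Evaluation time.
#' @return AUC at `horizon`.
#' @export
time_dependent_auc <- function(scores, time, event, horizon) {
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (length(cases) == 0L) stop("no cases (events before horizon)")
  if (length(controls) == 0L) stop("no controls (at risk beyond horizon)")
  cens_km <- if (sum(event == 0) > 0)
    km_estimate(time, 1 - event) else NULL
  G <- function(t, strict = FALSE) {
    if (is.null(cens_km)) return(1)
    max(.km_eval(cens_km, t, strict = strict), 1e-8)
  }
  w_case <- vapply(time[cases], function(t) 1 / G(t, strict = TRUE),
                   numeric(1))
  w_ctrl <- rep(1 / G(horizon), length(controls))
  num <- 0
  sc <- scores[cases]; sk <- scores[controls]
  for (a in seq_along(cases)) {
    cmpgt <- sum(w_ctrl[sc[a] > sk])
    cmpeq <- sum(w_ctrl[sc[a] == sk])
    num <- num + w_case[a] * (cmpgt + 0.5 * cmpeq)
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' Risk-group analysis
#'
#' Median split of the risk scores into high/low groups, Kaplan-Meier
#' curves per group, log-rank test, and the Spearman correlation of
#' score with observed survival time among events (expected negative
#' for a prognostic score).
#'
#' @param scores Risk scores.
#' @param time,event Survival outcome (n >= 4).
#' @return List with `km_high`, `km_low`, `logrank` (`chi2`, `p`),
#'   `score_time_cor`, `group` (character vector "high"/"low").
#' @export
risk_group_analysis <- function(scores, time, event) {
  if (length(scores) < 4L) stop("need >= 4 samples")
  if (length(unique(scores)) == 1L) stop("all scores identical; no split")
  med <- median(scores)
  grp <- ifelse(scores > med, "high", "low")
  if (length(unique(grp)) < 2L)
    grp <- ifelse(scores >= med, "high", "low")
  if (length(unique(grp)) < 2L) stop("degenerate score split")
  lr <- logrank_test(time, event, grp)
  ev <- event == 1
  stc <- if (sum(ev) >= 3)
    suppressWarnings(cor(scores[ev], time[ev], method = "spearman"))
  else NA_real_
  list(km_high = km_estimate(time[grp == "high"], event[grp == "high"]),
       km_low = km_estimate(time[grp == "low"], event[grp == "low"]),
       logrank = lr, score_time_cor = stc, group = grp)
}
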