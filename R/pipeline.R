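# End-to-end orchestration: catalogue -> RIDL -> differential
# expression -> prognosis, with a machine-readable manifest and a final
# candidate report reproducing the discovery funnel (SE-lncRNA AND
# differentially expressed in the target subtype AND prognostic AND
# carrying a valid RIDL).

#' Assemble a pipeline run configuration
#'
#' @param se_bed,genes_gtf,transcripts_fa,te_fa,functional_fa,expr_tsv,clinical_tsv
#'   Input paths (all must exist at launch).
#' @param out_dir Output directory.
#' @param seed Master seed for all stochastic stages.
#' @param target_subtype Subtype whose differential features feed the
#'   funnel (default `"Basal"`).
#' @param mode,window_bp Catalogue matching parameters.
#' @param de_alpha,lfc_min Differential-expression thresholds.
#' @param screen_alpha Univariate prognostic screen FDR threshold.
#' @param lasso_rule `"1se"` or `"min"`.
#' @param cv_folds Cross-validation folds for the penalised Cox.
#' @param n_trees,min_node_events Survival forest parameters.
#' @param auc_horizons Evaluation times for the time-dependent AUC.
#' @return List of class `selnc_run_config`.
#' @export
run_config <- function(se_bed, genes_gtf, transcripts_fa, te_fa,
                       functional_fa, expr_tsv, clinical_tsv, out_dir,
                       seed = 1L, target_subtype = "Basal",
                       mode = "gene_overlap", window_bp = 2000L,
                       de_alpha = 0.05, lfc_min = 1,
                       screen_alpha = 0.05, lasso_rule = "1se",
                       cv_folds = 5L, n_trees = 200L,
                       min_node_events = 3L,
                       auc_horizons = c(1, 3, 5)) {
  cfg <- as.list(environment())
  files <- c(se_bed, genes_gtf, transcripts_fa, te_fa, functional_fa,
             expr_tsv, clinical_tsv)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L)
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  class(cfg) <- "selnc_run_config"
  cfg
}

.stage <- function(name, expr, log_env) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log_env$stages[[name]] <- list(
    seconds = round(proc.time()[["elapsed"]] - t0, 3))
  res
}

#' Run the full discovery pipeline
#'
#' Stages in order: catalogue (SE x gene matching and chromosome
#' density), RIDL screen on the SE-lncRNA transcripts, per-subtype
#' differential expression, prognostic cascade (univariate screen,
#' L1-penalised Cox on the screen/DE intersection, survival forest
#' risk score, risk-group analysis, time-dependent AUC, permutation
#' importance), and the final candidate report.  All intermediate
#' tables are written under `config$out_dir` together with a JSON
#' manifest recording parameters, seeds and md5 checksums; a rerun
#' with the same config reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @return List with `report` (the candidate data.frame), `stages`
#'   (intermediate objects) and `manifest`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logs <- new.env()
  logs$stages <- list()

  inputs <- .stage("load_inputs", {
    list(se = read_bed(config$se_bed),
         genes = read_gtf(config$genes_gtf, biotype_filter = "lncRNA"),
         tx = read_fasta(config$transcripts_fa),
         te = read_fasta(config$te_fa),
         func = read_fasta(config$functional_fa),
         expr = read_matrix(config$expr_tsv),
         clin = read_clinical(config$clinical_tsv))
  }, logs)

  catalog <- .stage("catalog", {
    ct <- identify_se_lncrnas(inputs$se, inputs$genes,
                              mode = config$mode,
                              window_bp = config$window_bp)
    write_catalog(ct, file.path(out, "catalog.tsv"))
    dens <- chromosome_density(ct, inputs$genes, inputs$se)
    write.table(dens, file.path(out, "density.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ct
  }, logs)
  se_ids <- catalog$se_lncrna_ids

  ridl <- .stage("ridl", {
    tx <- inputs$tx[names(inputs$tx) %in% se_ids]
    if (length(tx) == 0L) {
      list(calls = NULL, status = character(0))
    } else {
      ref <- build_kmer_reference(inputs$func)
      rs <- ridl_screen(tx, inputs$te, ref, seed = config$seed)
      write.table(rs$calls, file.path(out, "ridl_calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      rs
    }
  }, logs)

  de <- .stage("differential", {
    expr <- inputs$expr
    clin <- inputs$clin
    if (!"subtype" %in% colnames(clin))
      stop("clinical table lacks a subtype column")
    common <- intersect(colnames(expr$values), clin$sample)
    M <- expr$values[rownames(expr$values) %in% se_ids, common,
                     drop = FALSE]
    labels <- clin$subtype[match(common, clin$sample)]
    if (nrow(M) == 0L) {
      # empty catalogue: nothing to screen, funnel is empty downstream
      list(tables = list(), de_sets = list(),
           pairwise = integer(0), common = character(0))
    } else {
      sm <- subtype_de_summary(M, labels, alpha = config$de_alpha,
                               lfc_min = config$lfc_min)
      tab <- do.call(rbind, lapply(names(sm$tables), function(st) {
        x <- sm$tables[[st]]; x$subtype <- st; x
      }))
      write.table(tab, file.path(out, "de.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      sm
    }
  }, logs)
  de_target <- de$de_sets[[config$target_subtype]]
  if (is.null(de_target)) de_target <- character(0)

  prog <- .stage("prognosis", {
    expr <- inputs$expr
    clin <- inputs$clin
    common <- intersect(colnames(expr$values), clin$sample)
    clin <- clin[match(common, clin$sample), ]
    X_all <- t(expr$values[rownames(expr$values) %in% se_ids, common,
                           drop = FALSE])
    if (ncol(X_all) == 0L) {
      screen <- data.frame(feature = character(0), beta = numeric(0),
                           se = numeric(0), p = numeric(0),
                           q = numeric(0), logrank_p = numeric(0),
                           significant = logical(0))
    } else {
      screen <- univariate_screen(X_all, clin$time, clin$event,
                                  alpha = config$screen_alpha)
    }
    write.table(screen, file.path(out, "screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sig <- screen$feature[screen$significant]
    candidates <- intersect(sig, de_target)
    res <- list(screen = screen, significant = sig,
                candidates = candidates, selected = character(0),
                model = NULL, scores = NULL, auc = NULL,
                groups = NULL, importance = NULL)
    if (length(candidates) >= 2L &&
        config$cv_folds <= sum(clin$event)) {
      Xc <- X_all[, candidates, drop = FALSE]
      path <- lasso_cox_path(Xc, clin$time, clin$event,
                             cv_folds = config$cv_folds,
                             rule = config$lasso_rule,
                             seed = config$seed)
      res$selected <- path$selected_features
      res$lasso <- path
      writeLines(res$selected, file.path(out, "selected.txt"))
    } else {
      res$selected <- candidates
    }
    model_feats <- if (length(res$selected) >= 1L) res$selected
                   else candidates
    if (length(model_feats) >= 1L) {
      Xm <- X_all[, model_feats, drop = FALSE]
      model <- rsf_fit(Xm, clin$time, clin$event,
                       n_trees = config$n_trees,
                       min_node_events = config$min_node_events,
                       seed = config$seed)
      sc <- risk_score(model, Xm)
      res$model <- model
      res$scores <- sc
      write.table(data.frame(sample = common, score = unname(sc)),
                  file.path(out, "risk_scores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      aucs <- vapply(config$auc_horizons, function(h)
        tryCatch(time_dependent_auc(sc, clin$time, clin$event, h),
                 error = function(e) NA_real_), numeric(1))
      res$auc <- data.frame(horizon = config$auc_horizons, auc = aucs)
      write.table(res$auc, file.path(out, "auc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res$groups <- tryCatch(
        risk_group_analysis(sc, clin$time, clin$event),
        error = function(e) NULL)
      if (!is.null(res$groups))
        jsonlite::write_json(
          list(chi2 = res$groups$logrank$chi2, p = res$groups$logrank$p,
               score_time_cor = res$groups$score_time_cor),
          file.path(out, "km_logrank.json"), auto_unbox = TRUE,
          digits = NA)
      if (ncol(Xm) >= 1L) {
        res$importance <- feature_importance(model, Xm, clin$time,
                                             clin$event,
                                             seed = config$seed)
        write.table(res$importance, file.path(out, "importance.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    res
  }, logs)

  report <- .stage("report", {
    status <- ridl$status
    rep <- data.frame(
      gene_id = se_ids,
      de_target = se_ids %in% de_target,
      prognostic = se_ids %in% prog$significant,
      in_risk_model = se_ids %in% prog$selected,
      ridl_status = ifelse(se_ids %in% names(status),
                           status[se_ids], NA_character_),
      stringsAsFactors = FALSE)
    rep$final_flag <- rep$de_target & rep$prognostic &
      !is.na(rep$ridl_status) & rep$ridl_status == "valid_RIDL"
    write.table(rep, file.path(out, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rep
  }, logs)

  input_files <- c(se_bed = config$se_bed, genes_gtf = config$genes_gtf,
                   transcripts_fa = config$transcripts_fa,
                   te_fa = config$te_fa,
                   functional_fa = config$functional_fa,
                   expr_tsv = config$expr_tsv,
                   clinical_tsv = config$clinical_tsv)
  out_files <- list.files(out, pattern = "\\.(tsv|txt|json)$",
                          full.names = TRUE)
  out_files <- setdiff(out_files, file.path(out, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("selnc")),
    seed = config$seed,
    parameters = {
      p <- unclass(config); p$out_dir <- NULL; p
    },
    input_checksums = as.list(tools::md5sum(input_files)),
    output_checksums = as.list(tools::md5sum(sort(out_files))),
    record_counts = list(
      se = length(inputs$se), genes = length(inputs$genes),
      se_lncrnas = length(se_ids),
      de_target = length(de_target),
      prognostic = length(prog$significant),
      selected = length(prog$selected),
      final = sum(report$final_flag)),
    stages = logs$stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(report = report,
       stages = list(catalog = catalog, ridl = ridl, de = de,
                     prognosis = prog),
       manifest = manifest)
}
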