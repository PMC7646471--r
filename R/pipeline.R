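#' Pipeline configuration
#'
#' Collects stage toggles, paths, thresholds and the master seed.  All
#' randomness in a run flows from `seed` through fixed per-stage offsets,
#' so any stage can be re-run in isolation and two runs with the same
#' config are identical.
#'
#' @param out_dir output directory (created if needed).
#' @param snv_path optional SNV TSV; when NULL a cohort is simulated from
#'   `sim` (the built-in demonstration mode).
#' @param sim simulation config from [sim_config()].
#' @param expr optional expression matrix (genes x samples); simulated
#'   when NULL and needed.
#' @param signatures signature reference matrix.
#' @param alpha significance level used by the association test and the
#'   classifier.
#' @param window folding window length (odd, 13-31).
#' @param run_strand,run_regulon stage toggles.
#' @param seed master seed.
#' @return config list.
#' @export
pipeline_config <- function(out_dir, snv_path = NULL, sim = sim_config(),
                            expr = NULL,
                            signatures = synthetic_signature_reference(),
                            alpha = 0.05, window = 25,
                            run_strand = TRUE, run_regulon = FALSE,
                            seed = 17) {
  stopifnot(window %% 2 == 1, window >= 13, window <= 31)
  sim$seed <- seed
  list(out_dir = out_dir, snv_path = snv_path, sim = sim, expr = expr,
       signatures = signatures, alpha = alpha, window = window,
       run_strand = run_strand, run_regulon = run_regulon, seed = seed)
}

stage_error <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the hotspot discovery and classification pipeline
#'
#' Stages, in order: ingest (or simulate) -> hotspot calling ->
#' signature refitting and APOBEC association -> replication-strand
#' profiling (optional) -> hairpin folding and loop stability ->
#' expression ranking -> driver/passenger classification with permutation
#' FDR -> regulon analysis (optional).  Each stage writes its table under
#' `out_dir`; `log.json` records parameters, seeds and per-stage row
#' counts.  A stage failure halts the run with an error naming the stage.
#'
#' @param config from [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, alpha = config$alpha,
              window = config$window, stages = list())
  truth <- NULL

  cohort <- tryCatch({
    if (is.null(config$snv_path)) {
      sim <- simulate_cohort(config$sim)
      truth <- sim$truth
      write_snv_table(sim$cohort, file.path(config$out_dir, "cohort.tsv"))
      sim$cohort
    } else {
      read_snv_table(config$snv_path)
    }
  }, error = function(e) stage_error("ingest", e))
  log$stages$ingest <- list(n_records = nrow(cohort$records),
                            n_samples = cohort$n_samples)

  panel <- tryCatch(call_hotspots(cohort),
                    error = function(e) stage_error("hotspots", e))
  log$stages$hotspots <- list(threshold = attr(panel, "threshold"),
                              n_hotspots = nrow(panel))

  assoc <- tryCatch({
    catalog <- build_96_catalog(cohort)
    exposures <- fit_signature_exposures(catalog, config$signatures)
    scores <- apobec_score(exposures)
    panel <- hotspot_association_test(panel, scores, alpha = config$alpha)
    list(exposures = exposures, scores = scores, panel = panel)
  }, error = function(e) stage_error("signatures", e))
  panel <- assoc$panel
  write_panel_tsv(panel, file.path(config$out_dir, "panel.tsv"))
  write_expression_matrix(assoc$exposures,
                          file.path(config$out_dir, "exposures.tsv"),
                          id_col = "sample")
  log$stages$signatures <- list(
    n_apobec = sum(panel$apobec_associated, na.rm = TRUE))

  lagging <- NULL
  if (isTRUE(config$run_strand)) {
    lagging <- tryCatch({
      tracks <- simulate_rfd(config$sim)
      lp <- vapply(seq_len(nrow(panel)), function(i) {
        pos <- (panel$pos[i] %% (config$sim$rfd_chrom_length - 2)) + 1
        lagging_probability(panel$ref[i], "chr1", pos,
                            tracks)$lagging_probability
      }, numeric(1))
      lp
    }, error = function(e) stage_error("strand", e))
    log$stages$strand <- list(n_profiled = sum(!is.na(lagging)))
  }

  folds <- tryCatch({
    half <- (config$window - 1) %/% 2
    lapply(seq_len(nrow(panel)), function(i) {
      ctx <- panel$context25[i]
      if (is.na(ctx)) return(NULL)
      mid <- (nchar(ctx) + 1) %/% 2
      fold_mfe(substr(ctx, mid - half, mid + half))
    })
  }, error = function(e) stage_error("fold", e))
  dg <- vapply(folds, function(f) if (is.null(f)) 0 else f$delta_g,
               numeric(1))
  in_loop <- vapply(folds, function(f) !is.null(f) && f$centre_in_loop,
                    logical(1))
  panel$delta_g <- dg
  panel$in_loop <- in_loop
  panel$loop_score <- normalised_loop_stability(dg, in_loop)
  log$stages$fold <- list(n_in_loop = sum(in_loop))

  expr <- config$expr
  if (is.null(expr)) expr <- simulate_expression(config$sim)
  ranks <- tryCatch(gapdh_percentile_rank(expr),
                    error = function(e) stage_error("rank", e))
  panel$expr_rank <- ranks$percentile[match(panel$gene, ranks$gene)]
  panel$expr_rank[is.na(panel$expr_rank)] <- 0
  write_panel_tsv(panel, file.path(config$out_dir, "features.tsv"))
  log$stages$rank <- list(n_ranked = sum(panel$gene %in% ranks$gene))

  result <- tryCatch({
    seed_label <- rep("unknown", nrow(panel))
    if (!is.null(truth)) {
      m <- match(panel$key, truth$sites$key)
      seed_label[!is.na(m)] <- truth$sites$seed_label[m[!is.na(m)]]
    }
    apo_idx <- which(panel$apobec_associated %in% TRUE |
                       seed_label != "unknown")
    pts <- feature_points(panel$key[apo_idx], panel$loop_score[apo_idx],
                          panel$expr_rank[apo_idx], seed_label[apo_idx])
    if (sum(pts$seed_label == "known_driver") >= 2 &&
        sum(pts$seed_label == "known_passenger") >= 2) {
      res <- iterative_similarity_classify(pts, alpha = config$alpha)
      res <- permutation_fdr(res, pts, seed = config$seed + 7L)
      write.table(res[, c("key", "predicted_label", "iteration_assigned",
                          "mdod", "perm_p", "fdr")],
                  file.path(config$out_dir, "predictions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res
    } else {
      NULL
    }
  }, error = function(e) stage_error("classify", e))
  if (!is.null(result)) {
    log$stages$classify <- list(
      n_driver = sum(result$predicted_label == "driver"),
      n_passenger = sum(result$predicted_label == "passenger"),
      n_undetermined = sum(result$predicted_label == "undetermined"))
  }

  regulon <- NULL
  if (isTRUE(config$run_regulon)) {
    regulon <- tryCatch({
      model <- select_regulon_candidates(expr, "AHR", "CYP1A1")
      kd <- simulate_knockdown(config$sim)
      de <- nb_differential_expression(kd, attr(kd, "group"))
      model <- finalise_regulon(model, de)
      jsonlite::write_json(
        list(anchors = as.list(model$anchors),
             rho_threshold = model$rho_threshold,
             candidates = model$candidates,
             validated_set = model$validated_set),
        file.path(config$out_dir, "regulon.json"), auto_unbox = TRUE)
      model
    }, error = function(e) stage_error("regulon", e))
    log$stages$regulon <- list(
      n_candidates = length(regulon$candidates),
      n_validated = length(regulon$validated_set))
  }

  jsonlite::write_json(log, file.path(config$out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, panel = panel, exposures = assoc$exposures,
                 scores = assoc$scores, lagging = lagging,
                 result = result, regulon = regulon, truth = truth,
                 log = log))
}

write_panel_tsv <- function(panel, path) {
  out <- panel
  out$carriers <- vapply(panel$carriers, paste, character(1),
                         collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
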