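# Orchestration of the analysis stages: genotyping -> immune profiling ->
# target screening -> outcome statistics -> survival, with per-stage
# exclusion accounting and deterministic, seedable outputs. Each stage is
# also exported on its own; run_pipeline() wires them into the full graph.

#' Pipeline configuration
#'
#' Inputs may be file paths (read with the cohort readers) or in-memory
#' objects built by this package; synthetic and real cohorts are therefore
#' interchangeable.
#'
#' @param expr expression matrix or TSV path.
#' @param cnv copy-call table or TSV path (required for `basis = "genomic"`).
#' @param clinical clinical table or TSV path.
#' @param markers,pathways,targets gene-set collections or GMT paths;
#'   defaults are the collections shipped with the package.
#' @param basis `"genomic"` (copy calls) or `"surrogate"` (hi_hi/lo_lo
#'   expression medians).
#' @param endpoint survival endpoint: `"os"`, `"pfs"` or `"dss"`.
#' @param contrast length-2 label pair compared throughout; defaults to
#'   `c("LOSS", "WT")` for the genomic basis and `c("lo_lo", "hi_hi")` for
#'   the surrogate basis.
#' @param fc_threshold,q_threshold DEG screen thresholds.
#' @param seed integer seed recorded in output metadata.
#' @param out_dir output directory (created if needed).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expr, clinical, cnv = NULL,
                            markers = NULL, pathways = NULL, targets = NULL,
                            basis = c("surrogate", "genomic"),
                            endpoint = c("os", "pfs", "dss"),
                            contrast = NULL,
                            fc_threshold = 1.2, q_threshold = 0.05,
                            seed = 1L, out_dir = tempfile("icbstrat_run_")) {
  basis <- match.arg(basis)
  endpoint <- match.arg(endpoint)
  if (basis == "genomic" && is.null(cnv)) {
    abort_icb("basis = 'genomic' requires a copy-call table", "icb_config_error")
  }
  if (is.null(contrast)) {
    contrast <- if (basis == "genomic") c("LOSS", "WT") else c("lo_lo", "hi_hi")
  }
  ext <- function(f) system.file("extdata", f, package = "icbstrat", mustWork = TRUE)
  structure(list(
    expr = expr, clinical = clinical, cnv = cnv,
    markers = if (is.null(markers)) ext("markers.gmt") else markers,
    pathways = if (is.null(pathways)) ext("immune_pathways.gmt") else pathways,
    targets = if (is.null(targets)) ext("druggable_targets.gmt") else targets,
    basis = basis, endpoint = endpoint, contrast = contrast,
    fc_threshold = fc_threshold, q_threshold = q_threshold,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

.load_input <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

#' Run the full stratification pipeline
#'
#' Stages: load/validate -> 9p21 labels (genomic or surrogate basis) ->
#' immune abundance + ssGSEA pathway scores with differential abundance ->
#' DEG and Spearman target screens -> response-rate stratification (and the
#' composite response score when TMB and PD-L1 are available) -> survival
#' (Kaplan-Meier, log-rank, Cox). Result tables are written as TSV with
#' JSON sidecars plus a run manifest holding per-stage sample-exclusion
#' counts. Any stage error aborts the run and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with every stage's result tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0L)
  manifest <- list(seed = config$seed, basis = config$basis,
                   endpoint = config$endpoint, contrast = config$contrast,
                   stages = list())
  emit <- function(tbl, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_results(tbl, path, seed = config$seed,
                  config = config[c("basis", "endpoint", "contrast",
                                    "fc_threshold", "q_threshold")])
    written <<- c(written, path, paste0(path, ".json"))
    path
  }
  on_fail <- function(stage, e) {
    unlink(written)
    abort_icb(sprintf("pipeline stage '%s' failed: %s", stage,
                      conditionMessage(e)), "icb_pipeline_error")
  }
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) on_fail(name, e))
  }

  # -- load -----------------------------------------------------------------
  inputs <- stage("load", function() {
    list(
      expr = .load_input(config$expr, read_expression),
      clinical = .load_input(config$clinical, read_clinical),
      cnv = if (!is.null(config$cnv)) .load_input(config$cnv, read_copy_calls),
      markers = .load_input(config$markers, read_gene_sets),
      pathways = .load_input(config$pathways, read_gene_sets),
      targets = .load_input(config$targets, read_gene_sets)
    )
  })
  n_input <- ncol(inputs$expr)

  # -- genotype -------------------------------------------------------------
  labels_df <- stage("genotype", function() {
    if (config$basis == "genomic") {
      g <- genotype_9p21(inputs$cnv)
      data.frame(sample_id = g$sample_id, label = g$group, basis = g$basis,
                 stringsAsFactors = FALSE)
    } else {
      s <- surrogate_from_expression(inputs$expr)
      data.frame(sample_id = s$sample_id, label = s$label, basis = s$basis,
                 stringsAsFactors = FALSE)
    }
  })
  emit(labels_df, "labels")
  labels <- stats::setNames(labels_df$label, labels_df$sample_id)
  in_contrast <- sum(labels %in% config$contrast)
  manifest$stages$genotype <- list(
    n_in = n_input, n_labelled = nrow(labels_df),
    n_in_contrast = in_contrast,
    n_excluded_from_contrast = nrow(labels_df) - in_contrast
  )

  # -- profile --------------------------------------------------------------
  profile <- stage("profile", function() {
    scores <- marker_abundance_scores(inputs$expr, inputs$markers)
    pscores <- ssgsea_scores(inputs$expr, inputs$pathways)
    list(
      abundance = scores, pathway = pscores,
      diff_abundance = differential_abundance(scores, labels, config$contrast),
      diff_pathway = differential_abundance(pscores, labels, config$contrast)
    )
  })
  emit(data.frame(feature = rownames(profile$abundance), profile$abundance,
                  check.names = FALSE), "abundance_scores")
  emit(data.frame(feature = rownames(profile$pathway), profile$pathway,
                  check.names = FALSE), "pathway_scores")
  emit(profile$diff_abundance, "differential_abundance")
  emit(profile$diff_pathway, "differential_pathways")
  manifest$stages$profile <- list(
    n_features = nrow(profile$abundance), n_pathways = nrow(profile$pathway)
  )

  # -- screen ---------------------------------------------------------------
  screen <- stage("screen", function() {
    list(
      deg = deg_screen(inputs$expr, labels, inputs$targets, config$contrast,
                       fc_threshold = config$fc_threshold,
                       q_threshold = config$q_threshold),
      spearman = spearman_target_screen(inputs$expr, c("CDKN2A", "MTAP"),
                                        inputs$targets)
    )
  })
  emit(screen$deg, "deg_screen")
  emit(screen$spearman, "spearman_screen")
  manifest$stages$screen <- list(
    n_tested = nrow(screen$deg), n_passing = sum(screen$deg$passes)
  )

  # -- stratify -------------------------------------------------------------
  clin <- inputs$clinical
  strat <- stage("stratify", function() {
    responder <- stats::setNames(clin$response %in% c("CR", "PR"), clin$sample_id)
    responder[is.na(clin$response)] <- NA
    rc <- response_rates_compare(responder, labels, config$contrast)
    row <- data.frame(
      stratum = rc$stratum, n = rc$total, responders = rc$responders,
      rate = rc$rate, p = rc$test$p, stringsAsFactors = FALSE
    )
    score <- NULL
    if (all(c("tmb", "pdl1_ic") %in% names(clin)) && config$basis == "surrogate") {
      med <- stats::median(clin$tmb, na.rm = TRUE)
      score <- compute_response_score(clin$tmb, med,
                                      unname(labels[clin$sample_id]),
                                      clin$pdl1_ic, clin$sample_id)
    }
    list(rates = row, rc = rc, score = score, responder = responder)
  })
  emit(strat$rates, "response_rates")
  manifest$stages$stratify <- list(
    n_compared = sum(strat$rates$n), n_dropped_na_outcome = strat$rc$n_dropped
  )
  if (!is.null(strat$score)) {
    emit(strat$score, "response_score")
    tiers <- strat$score$tier
    ok <- !is.na(tiers) & !is.na(strat$responder[strat$score$sample_id])
    tier_tab <- build_contingency(
      stats::setNames(tiers, strat$score$sample_id)[ok],
      strat$responder[strat$score$sample_id][ok]
    )
    manifest$stages$score <- list(
      n_scored = sum(!is.na(tiers)), n_excluded = sum(is.na(tiers)),
      tier_test_p = if (all(dim(tier_tab) >= 2L)) fisher_exact_rxc(tier_tab)$p else NA
    )
  }

  # -- survival -------------------------------------------------------------
  tcol <- paste0(config$endpoint, "_time")
  ecol <- paste0(config$endpoint, "_event")
  surv <- stage("survival", function() {
    if (!all(c(tcol, ecol) %in% names(clin))) {
      abort_icb(sprintf("clinical table lacks %s/%s", tcol, ecol),
                "icb_config_error")
    }
    idx <- match(names(labels), clin$sample_id)
    keep <- !is.na(idx) & labels %in% config$contrast
    tt <- clin[[tcol]][idx[keep]]
    ee <- clin[[ecol]][idx[keep]]
    gg <- labels[keep]
    usable <- !is.na(tt) & !is.na(ee)
    km <- lapply(split(seq_along(tt)[usable], gg[usable]), function(i) {
      km_estimate(tt[i], ee[i])
    })
    lr <- logrank_test(tt[usable], ee[usable], gg[usable])
    cx <- cox_fit(tt[usable], ee[usable],
                  data.frame(group = as.numeric(gg[usable] == config$contrast[1L])))
    list(km = km, logrank = lr, cox = cx, n_usable = sum(usable),
         n_missing = sum(!usable))
  })
  km_rows <- do.call(rbind, lapply(names(surv$km), function(g) {
    k <- surv$km[[g]]
    data.frame(stratum = g, time = k$time, survival = k$surv,
               at_risk = k$n_risk, events = k$n_event, stringsAsFactors = FALSE)
  }))
  emit(km_rows, "km_curves")
  emit(surv$cox, "cox_fit")
  manifest$stages$survival <- list(
    n_usable = surv$n_usable, n_missing_survival = surv$n_missing,
    logrank_p = surv$logrank$p,
    median = lapply(surv$km, function(k) k$median)
  )

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(labels = labels_df, profile = profile, screen = screen,
                 stratify = strat, survival = surv, manifest = manifest,
                 out_dir = config$out_dir))
}
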