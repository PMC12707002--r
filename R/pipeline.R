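#' Build a pipeline configuration
#'
#' Assembles (and validates) the configuration for [run_pipeline()].
#' Either a CSV `input` path (with an optional `columns` mapping from the
#' canonical names to the file's column names) or `synthetic = TRUE` with
#' generator settings.
#'
#' @param input Path to a microdata CSV, or `NULL` with
#'   `synthetic = TRUE`.
#' @param synthetic Generate the input with [simulate_survey()].
#' @param sim Optional [sim_config()] used when `synthetic = TRUE`.
#' @param columns Named character vector mapping canonical column names to
#'   the input file's names (e.g. `c(community_id = "stratum")`).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed (propagated to the generator and recorded in
#'   the summary).
#' @param k_range Candidate cluster counts.
#' @param outcomes Binary outcomes for the inequality stage.
#' @param ml_outcome Outcome for the multilevel ladder.
#' @param use_weights Weighted aggregation of prevalences.
#' @param quad_points Adaptive quadrature nodes for the multilevel stage.
#' @param no_dv_subsample Treat every row as violence-eligible (for inputs
#'   without the half-sample design): sets `dv_flag = TRUE` and
#'   `dv_weight = survey_weight` everywhere.
#' @param run_multilevel Include the multilevel stage (the slowest one).
#' @return A list of class `"gcci_pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, synthetic = is.null(input),
                            sim = NULL, columns = NULL,
                            out_dir = tempfile("gcci_run_"),
                            seed = 20210L, k_range = 3:5,
                            outcomes = "multiparity",
                            ml_outcome = "multiparity",
                            use_weights = TRUE, quad_points = 12L,
                            no_dv_subsample = FALSE,
                            run_multilevel = TRUE) {
  if (!synthetic && (is.null(input) || !file.exists(input))) {
    stop("input CSV not found: ", input, call. = FALSE)
  }
  if (synthetic && is.null(sim)) sim <- sim_config(seed = as.integer(seed))
  structure(list(input = input, synthetic = synthetic, sim = sim,
                 columns = columns, out_dir = out_dir,
                 seed = as.integer(seed), k_range = k_range,
                 outcomes = outcomes, ml_outcome = ml_outcome,
                 use_weights = use_weights,
                 quad_points = as.integer(quad_points),
                 no_dv_subsample = no_dv_subsample,
                 run_multilevel = run_multilevel),
            class = "gcci_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the [pipeline_config()] arguments; generator
#' settings go under a `sim:` block whose keys are [sim_config()]
#' arguments.
#'
#' @param path Path to a YAML file.
#' @return A `"gcci_pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    if (!is.null(sim_args$outcome_covariate_effects)) {
      sim_args$outcome_covariate_effects <-
        unlist(sim_args$outcome_covariate_effects)
    }
    sim <- do.call(sim_config, sim_args)
  }
  args <- raw[setdiff(names(raw), "sim")]
  if (!is.null(args$columns)) args$columns <- unlist(args$columns)
  do.call(pipeline_config, c(args, list(sim = sim)))
}

#' Run the full index-construction and validation pipeline
#'
#' Executes, in order: data acquisition (CSV or synthetic), indicator
#' coding, community prevalence aggregation, the alpha item analysis, the
#' one-factor index fit with scores, ordinal categorisation with
#' Calinski-Harabasz diagnostics, the risk-gradient/concentration-index
#' table, and (optionally) the three-model random-intercept ladder.  Every
#' stage writes a plain CSV/JSON artifact into `config$out_dir` so each
#' step is independently auditable, and a `summary.json` collects the
#' headline statistics.  A stage failure halts the run with the stage name
#' and leaves a `FAILED` marker alongside whatever artifacts completed.
#'
#' @param config A [pipeline_config()] or [read_pipeline_config()] object.
#' @return (Invisibly) a list with the fitted objects and the summary
#'   list; side effect: the report bundle in `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "gcci_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fail_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  stage <- function(name, expr) {
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      writeLines(c(name, conditionMessage(e)), fail_marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  data <- stage("data", {
    if (config$synthetic) {
      simulate_survey(config$sim)
    } else {
      d <- utils::read.csv(config$input, stringsAsFactors = FALSE)
      if (!is.null(config$columns)) {
        for (canonical in names(config$columns)) {
          src <- config$columns[[canonical]]
          if (!src %in% names(d)) {
            stop(sprintf("mapped column '%s' (for '%s') not in input", src,
                         canonical))
          }
          names(d)[names(d) == src] <- canonical
        }
      }
      d
    }
  })
  if (config$no_dv_subsample) {
    data$dv_flag <- TRUE
    data$dv_weight <- data$survey_weight
  }

  data <- stage("indicators", code_indicators(data))

  fit <- stage("index", gcci(data, k_range = config$k_range,
                             use_weights = config$use_weights))

  stage("artifacts_index", {
    prev <- data.frame(community_id = fit$prevalence$community_id,
                       fit$prevalence$prevalence,
                       n = fit$prevalence$n, n_dv = fit$prevalence$n_dv)
    utils::write.csv(prev, file.path(config$out_dir, "prevalence.csv"),
                     row.names = FALSE)
    al <- fit$alpha
    utils::write.csv(
      rbind(al$items,
            data.frame(item = "test scale", sign = "",
                       item_test_r = NA, item_rest_r = NA,
                       avg_interitem_cov = al$avg_interitem_cov,
                       alpha_if_deleted = al$alpha, raises_alpha = NA)),
      file.path(config$out_dir, "alpha.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(loadings = fit$model$loadings,
           uniqueness = fit$model$uniqueness,
           scoring = fit$model$scoring,
           eigenvalues = fit$model$eigenvalues,
           proportion_of_variance = fit$model$proportion_of_variance),
      file.path(config$out_dir, "factor_model.json"),
      digits = NA, auto_unbox = TRUE)
    utils::write.csv(fit$gccs$ch_table,
                     file.path(config$out_dir, "ch_diagnostics.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$gccs$assignment,
                     file.path(config$out_dir, "gccs.csv"), row.names = FALSE)
  })

  gradient <- stage("inequality", {
    g <- risk_gradient_table(data, fit$gccs, config$outcomes)
    utils::write.csv(g, file.path(config$out_dir, "risk_gradient.csv"),
                     row.names = FALSE)
    g
  })

  ladder <- NULL
  if (config$run_multilevel) {
    ladder <- stage("multilevel", {
      l <- model_ladder(data, fit$gccs, outcome = config$ml_outcome,
                        quad_points = config$quad_points)
      tab <- data.frame(
        model = names(l$fits),
        sigma2_u = vapply(l$fits, function(f) f$sigma2_u, numeric(1)),
        sigma2_u_se = vapply(l$fits, function(f) f$sigma2_u_se, numeric(1)),
        icc = unname(l$icc),
        minus2LL = vapply(l$fits, function(f) -2 * f$logLik, numeric(1)))
      utils::write.csv(tab, file.path(config$out_dir, "model_ladder.csv"),
                       row.names = FALSE)
      or3 <- l$fits$individual_gccs$or
      utils::write.csv(cbind(term = rownames(or3), or3),
                       file.path(config$out_dir, "model3_odds_ratios.csv"),
                       row.names = FALSE)
      l
    })
  }

  summary <- stage("summary", {
    s <- list(
      seed = config$seed,
      n = nrow(data),
      n_communities = nrow(fit$scores),
      alpha = fit$alpha$alpha,
      proportion_of_variance = fit$model$proportion_of_variance,
      loadings = as.list(fit$model$loadings),
      score_sd = stats::sd(fit$scores$score),
      score_range = range(fit$scores$score),
      k_selected = fit$gccs$k,
      ch_values = stats::setNames(as.list(fit$gccs$ch_table$pseudo_F),
                                  paste0("k", fit$gccs$ch_table$k)),
      concentration_index = stats::setNames(
        as.list(gradient$wagstaff_ci), gradient$outcome)
    )
    if (!is.null(ladder)) {
      s$icc <- as.list(ladder$icc)
      s$pcv <- as.list(ladder$pcv)
      s$lr_test <- ladder$lr_23
    }
    jsonlite::write_json(s, file.path(config$out_dir, "summary.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    s
  })

  invisible(list(data = data, fit = fit, gradient = gradient,
                 ladder = ladder, summary = summary,
                 out_dir = config$out_dir))
}
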