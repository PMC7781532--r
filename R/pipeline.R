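#' Run the four-stage model revision pipeline
#'
#' Orchestrates the full revision workflow on one model + data compendium:
#' (1) `estimate` the four default parameters from all-context qualitative
#' data; (2) `validate` and break the agreement down by class and context;
#' (3) `deletion` scan and `morris` screening of per-reaction EC50 in the
#' focal context, then `sobol` variance decomposition on the Morris-selected
#' subset; (4) `calibrate` the EC50 of the top-ranked reactions against
#' qualitative + semi-quantitative data, and screen `crosstalk` candidates
#' on the revised parameters. Any stage subset can be run; stages consume
#' the outputs of earlier stages and error explicitly when a dependency
#' (e.g. the Morris subset for Sobol) is missing. All stage outputs are
#' written under `out_dir` together with a JSON run manifest (config
#' snapshot, input file hashes, derived per-stage seeds, output paths,
#' per-stage objective values).
#'
#' @param config named list or path to a YAML file. Keys: `model` (directory
#'   of species/reactions sheets, or a `network_model`), `data` (experiment
#'   table path or `experiment_records`), optional `semiquant_data`,
#'   `context` (focal context; default: first in the data), `stages`
#'   (default all), `seed`, `out_dir`, and per-stage option lists
#'   `estimate`, `morris`, `sobol`, `calibrate`, `crosstalk`.
#' @return the run manifest (list of class `run_manifest`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages_all <- c("estimate", "validate", "deletion", "morris", "sobol",
                  "calibrate", "crosstalk")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% "hillnet_run"
  engine <- do.call(hillnet_config, config$engine %||% list())

  hashes <- list()
  if (inherits(config$model, "network_model")) {
    model <- config$model
  } else {
    if (!dir.exists(config$model)) {
      stop("model path does not exist: ", config$model, call. = FALSE)
    }
    model <- read_network(config$model)
    hashes$model <- unname(tools::md5sum(list.files(config$model,
                                                    full.names = TRUE)))
  }
  if (inherits(config$data, "experiment_records")) {
    records <- config$data
  } else {
    if (!file.exists(config$data)) {
      stop("data path does not exist: ", config$data, call. = FALSE)
    }
    records <- read_experiments(config$data)
    hashes$data <- unname(tools::md5sum(config$data))
  }
  semiquant <- NULL
  if (!is.null(config$semiquant_data)) {
    semiquant <- if (inherits(config$semiquant_data, "experiment_records")) {
      config$semiquant_data
    } else {
      if (!file.exists(config$semiquant_data)) {
        stop("semiquant_data path does not exist: ", config$semiquant_data,
             call. = FALSE)
      }
      hashes$semiquant_data <- unname(tools::md5sum(config$semiquant_data))
      read_experiments(config$semiquant_data)
    }
  }
  check_records(records, model)
  context <- config$context %||% records$context[1]
  ctx_records <- records[records$context == context, , drop = FALSE]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  params <- do.call(param_set, config$defaults %||% list())
  stage_seed <- function(i) seed + 1000L * i
  outputs <- list()
  objectives <- list()
  morris_subset <- config$morris_subset %||% NULL

  if ("estimate" %in% stages) {
    opts <- config$estimate %||% list()
    est <- estimate_defaults(model, records,
                             n_starts = opts$n_starts %||% 100,
                             n_refine = opts$n_refine %||% 5L,
                             refine_control = opts$refine_control %||% list(),
                             seed = stage_seed(1L), base_params = params,
                             config = engine)
    params <- est$best_params
    f <- file.path(out_dir, "estimate.json")
    jsonlite::write_json(list(best_values = as.list(est$best_values),
                              best_objective = est$best_objective,
                              trace = est$trace),
                         f, auto_unbox = TRUE, digits = NA)
    outputs$estimate <- f
    objectives$estimate <- est$best_objective
  }

  if ("validate" %in% stages) {
    rep <- validate_model(model, params, records, engine)
    f <- file.path(out_dir, "validation.csv")
    write_validation_report(rep, f, file.path(out_dir, "validation.json"))
    outputs$validate <- f
    objectives$validate <- rep$validation_percent
  }

  if ("deletion" %in% stages) {
    ds <- deletion_scan(model, params, records, config = engine)
    f <- file.path(out_dir, "deletion_scan.csv")
    utils::write.csv(data.frame(reaction = rownames(ds$delta), ds$delta,
                                category = ds$category, check.names = FALSE),
                     f, row.names = FALSE)
    outputs$deletion <- f
    objectives$deletion <- sum(ds$category != "non_sensitive")
  }

  if ("morris" %in% stages) {
    opts <- config$morris %||% list()
    ospec <- objective_spec(model, params, ctx_records,
                            factors = opts$factors %||% intermediate_reactions(model),
                            bounds = opts$bounds %||% c(0.2, 0.6),
                            objective = opts$objective %||% "validation",
                            output_nodes = opts$output_nodes,
                            config = engine)
    mres <- morris_screen(ospec,
                          levels = opts$levels %||% 8,
                          trajectories = opts$trajectories %||% 16,
                          oversample = opts$oversample %||% 300,
                          threshold = opts$threshold %||% 1.5,
                          seed = stage_seed(4L))
    morris_subset <- select_important(mres)
    f <- file.path(out_dir, "morris.csv")
    utils::write.csv(mres$factors, f, row.names = FALSE)
    outputs$morris <- f
    objectives$morris <- length(morris_subset)
  }

  if ("sobol" %in% stages) {
    if (is.null(morris_subset) || !length(morris_subset)) {
      stop("sobol stage needs the Morris-selected subset; run the morris ",
           "stage first or supply `morris_subset` in the config", call. = FALSE)
    }
    opts <- config$sobol %||% list()
    ospec <- objective_spec(model, params, ctx_records, factors = morris_subset,
                            bounds = opts$bounds %||% c(0.2, 0.6),
                            objective = opts$objective %||% "validation",
                            output_nodes = opts$output_nodes,
                            config = engine)
    sres <- sobol_analysis(ospec, N = opts$N %||% 1024,
                           bootstrap_reps = opts$bootstrap_reps %||% 2000,
                           seed = stage_seed(5L))
    f <- file.path(out_dir, "sobol.csv")
    utils::write.csv(sres$first_order, f, row.names = FALSE)
    utils::write.csv(sres$second_order, file.path(out_dir, "sobol_pairs.csv"),
                     row.names = FALSE)
    outputs$sobol <- f
    objectives$sobol <- max(sres$first_order$T)
  }

  if ("calibrate" %in% stages) {
    opts <- config$calibrate %||% list()
    subset <- opts$reactions %||% morris_subset
    if (is.null(subset)) {
      stop("calibrate stage needs a reaction subset; run the morris stage ",
           "first or supply `calibrate$reactions` in the config", call. = FALSE)
    }
    subset <- utils::head(subset, opts$n_reactions %||% 12L)
    cal_records <- if (is.null(semiquant)) ctx_records else {
      rbind(ctx_records, semiquant[semiquant$context == context, , drop = FALSE])
    }
    cal <- calibrate_ec50(model, params, subset, cal_records,
                          n_starts = opts$n_starts %||% 20,
                          refine_control = opts$refine_control %||% list(),
                          seed = stage_seed(6L), config = engine)
    params <- cal$best_params
    f <- file.path(out_dir, "calibrate.json")
    jsonlite::write_json(list(reactions = subset,
                              best_values = as.list(cal$best_values),
                              best_objective = cal$best_objective),
                         f, auto_unbox = TRUE, digits = NA)
    outputs$calibrate <- f
    objectives$calibrate <- cal$best_objective
  }

  if ("crosstalk" %in% stages) {
    opts <- config$crosstalk %||% list()
    gate <- opts$gate %||% "both"
    cands <- switch(gate,
                    or = enumerate_or_candidates(model),
                    and = enumerate_and_candidates(model),
                    both = rbind(enumerate_or_candidates(model),
                                 enumerate_and_candidates(model)))
    if (!is.null(opts$max_candidates)) {
      cands <- utils::head(cands, opts$max_candidates)
    }
    scr <- screen_crosstalks(model, params, ctx_records, cands, engine)
    f <- file.path(out_dir, "crosstalk.csv")
    utils::write.csv(scr$candidates, f, row.names = FALSE)
    utils::write.csv(scr$summary, file.path(out_dir, "crosstalk_summary.csv"),
                     row.names = FALSE)
    outputs$crosstalk <- f
    objectives$crosstalk <- scr$baseline_percent + max(0, scr$candidates$delta[1])
  }

  manifest <- structure(list(
    version = as.character(utils::packageVersion("hillnet")),
    seed = seed,
    stage_seeds = stats::setNames(as.list(stage_seed(seq_along(stages_all))),
                                  stages_all),
    context = context,
    stages = stages,
    input_hashes = hashes,
    outputs = outputs,
    objectives = objectives,
    final_defaults = params$defaults,
    n_overrides = nrow(params$overrides)
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> stages: %s\n", paste(x$stages, collapse = ", ")))
  for (nm in names(x$objectives)) {
    cat(sprintf("  %-10s %s\n", nm, format(x$objectives[[nm]])))
  }
  invisible(x)
}
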