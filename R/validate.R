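#' Percent change of a treated activity versus its control
#'
#' Relative change `100 * (treated - control) / control`, except when the
#' control activity is effectively zero (`control < eps_c * Ymax`), where the
#' absolute change expressed in percent of `Ymax` is used instead so that
#' near-zero baselines do not produce unbounded changes.
#'
#' @param treated,control activities (>= 0).
#' @param Ymax maximum activity of the measured node.
#' @param eps_c near-zero guard as a fraction of `Ymax`.
#' @return percent change (vectorized).
#' @export
percent_change <- function(treated, control, Ymax = 1, eps_c = 1e-4) {
  ifelse(control >= eps_c * Ymax,
         100 * (treated - control) / control,
         100 * (treated - control) / pmax(Ymax, .Machine$double.eps))
}

#' Classify a simulated change as increase / decrease / nochange
#'
#' A change is an increase when the percent change from control exceeds
#' `threshold` (1\% by default), a decrease when it falls below
#' `-threshold`, and no change otherwise.
#'
#' @inheritParams percent_change
#' @param threshold in-silico threshold, in percent.
#' @return direction string (vectorized).
#' @examples
#' classify_change(0.52, 0.50)   # increase (+4%)
#' classify_change(0.498, 0.50)  # nochange (-0.4%)
#' @export
classify_change <- function(treated, control, threshold = 1, Ymax = 1,
                            eps_c = 1e-4) {
  pc <- percent_change(treated, control, Ymax, eps_c)
  ifelse(pc > threshold, "increase", ifelse(pc < -threshold, "decrease", "nochange"))
}

#' Classify a fold change into a semi-quantitative category
#'
#' Six categories partition fold space: increases `LH` (1.01–2 fold),
#' `MH` (2–5 fold), `HH` (> 5 fold) and decreases `LL` (0.5–0.99 fold),
#' `ML` (0.2–0.5 fold), `HL` (< 0.2 fold). Folds in (0.99, 1.01\] map to a
#' seventh `NC` (no change) code.
#'
#' @param fold positive fold change treated/control (already guarded).
#' @return category string (vectorized).
#' @examples
#' classify_fold_change(c(1.5, 7, 0.3))  # LH HH ML
#' @export
classify_fold_change <- function(fold) {
  if (any(!is.finite(fold) | fold <= 0)) {
    stop("fold change must be positive and finite (after guarding)", call. = FALSE)
  }
  ifelse(fold > 5, "HH",
  ifelse(fold > 2, "MH",
  ifelse(fold > 1.01, "LH",
  ifelse(fold > 0.99, "NC",
  ifelse(fold >= 0.5, "LL",
  ifelse(fold >= 0.2, "ML", "HL"))))))
}

condition_key <- function(perts) {
  if (!length(perts)) return("<rest>")
  toks <- vapply(perts, function(p) paste(p$kind, p$target, format(p$value),
                                          sep = ":"), character(1))
  paste(sort(toks), collapse = "|")
}

cached_steady_state <- function(model, params, perts, config, cache) {
  key <- condition_key(perts)
  if (!is.null(cache[[key]])) return(cache[[key]])
  res <- simulate_network(model, params, perts, mode = "steady_state",
                          config = config)
  cache[[key]] <- res
  res
}

condition_pair <- function(record_class, perts) {
  stims <- Filter(function(p) p$kind == "stimulus", perts)
  switch(record_class,
         InputOutput = ,
         InputIntermediate = list(control = list(), treatment = perts),
         IntermediateInhibition = list(control = stims, treatment = perts),
         IntermediateOverexpression = list(control = list(), treatment = perts),
         stop("unknown data class: ", record_class, call. = FALSE))
}

#' Simulate one experimental record against its control
#'
#' The control and treatment conditions are defined by the record's data
#' class: for `InputOutput`/`InputIntermediate` the control is the resting
#' state (all inputs at `W_i`) and the treatment applies the record's
#' perturbations (the context stimulus at `W_e`); for
#' `IntermediateInhibition` the control is the stimulus alone and the
#' treatment adds the node knockdown; for `IntermediateOverexpression` the
#' control is the resting state and the treatment is the overexpression plus
#' any stimulus the record specifies. The measured node is compared between
#' the two steady states.
#'
#' @param model a [network_model()].
#' @param params a [param_set()].
#' @param record one row of an `experiment_records` frame (data.frame or list).
#' @param config a [hillnet_config()].
#' @param cache optional environment memoizing steady states across records.
#' @return one-row data.frame (a prediction outcome): ids, activities,
#'   percent change, predicted vs observed, `match`, `resolved`.
#' @export
run_condition <- function(model, params, record, config = hillnet_config(),
                          cache = new.env(parent = emptyenv())) {
  if (is.data.frame(record)) {
    perts <- record$perturbations[[1]]
    record <- as.list(record[1, setdiff(names(record), "perturbations")])
    record$perturbations <- perts
  }
  if (!record$measured_node %in% model$nodes$id) {
    stop(sprintf("record '%s': measured node '%s' not in model",
                 record$record_id, record$measured_node), call. = FALSE)
  }
  cp <- condition_pair(record$data_class, record$perturbations)
  ctl <- cached_steady_state(model, params, cp$control, config, cache)
  trt <- cached_steady_state(model, params, cp$treatment, config, cache)
  i <- record$measured_node
  ymax_i <- param_lookup(params, i, "Ymax", model$nodes$Ymax[model$nodes$id == i])
  c_act <- ctl$steady_state[[i]]
  t_act <- trt$steady_state[[i]]
  resolved <- isTRUE(ctl$converged) && isTRUE(trt$converged)
  pc <- percent_change(t_act, c_act, ymax_i, config$eps_c)
  if (identical(record$type, "semiquant")) {
    fold <- (t_act + config$eps_f) / (c_act + config$eps_f)
    predicted <- classify_fold_change(fold)
  } else {
    fold <- NA_real_
    predicted <- classify_change(t_act, c_act, config$threshold, ymax_i,
                                 config$eps_c)
  }
  data.frame(record_id = record$record_id, context = record$context,
             data_class = record$data_class, measured_node = i,
             control_activity = c_act, treated_activity = t_act,
             percent_change = pc, fold = fold,
             predicted = predicted, observed = record$observed,
             match = identical(predicted, record$observed) ||
               semiquant_lenient_match(predicted, record$observed,
                                       record$type, config),
             resolved = resolved, stringsAsFactors = FALSE)
}

semiquant_lenient_match <- function(predicted, observed, type, config) {
  if (!identical(type, "semiquant") || !identical(config$semiquant_mode, "lenient")) {
    return(FALSE)
  }
  up <- c("LH", "MH", "HH"); down <- c("LL", "ML", "HL")
  same_dir <- (predicted %in% up && observed %in% up) ||
    (predicted %in% down && observed %in% down)
  if (!same_dir) return(FALSE)
  lv <- function(x) if (x %in% up) match(x, up) else match(x, down)
  abs(lv(predicted) - lv(observed)) <= 1
}

breakdown <- function(outcomes, by) {
  if (!nrow(outcomes)) {
    return(data.frame(group = character(), n = integer(), matches = integer(),
                      percent = numeric()))
  }
  groups <- interaction(outcomes[, by, drop = FALSE], drop = TRUE, sep = " / ")
  agg <- lapply(split(outcomes, groups), function(d) {
    data.frame(n = nrow(d), matches = sum(d$match),
               percent = 100 * sum(d$match) / nrow(d))
  })
  out <- do.call(rbind, agg)
  out <- cbind(data.frame(group = names(agg), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

validate_internal <- function(model, params, records, config, want_type) {
  records <- records[records$type == want_type, , drop = FALSE]
  if (!nrow(records)) stop("no ", want_type, " records to validate", call. = FALSE)
  check_records(records, model)
  cache <- new.env(parent = emptyenv())
  outcomes <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    run_condition(model, params, records[i, , drop = FALSE], config, cache)
  }))
  scored <- outcomes[outcomes$resolved, , drop = FALSE]
  vp <- if (nrow(scored)) 100 * sum(scored$match) / nrow(scored) else NA_real_
  structure(list(
    outcomes = outcomes,
    validation_percent = vp,
    n_records = nrow(outcomes),
    n_unresolved = sum(!outcomes$resolved),
    by_class = breakdown(scored, "data_class"),
    by_context = breakdown(scored, "context"),
    by_class_context = breakdown(scored, c("data_class", "context")),
    mode = if (want_type == "semiquant") config$semiquant_mode else "qualitative"
  ), class = "validation_report")
}

#' Validate a model against qualitative records
#'
#' Simulates every record's condition pair, classifies the predicted
#' direction of the measured node with the in-silico threshold, and reports
#' the validation percent (share of records whose direction the model
#' reproduces) overall and broken down by data class and context. Records
#' whose simulation fails to converge are excluded from the percent and
#' counted in `n_unresolved`.
#'
#' @inheritParams run_condition
#' @param records `experiment_records` (qualitative rows are scored).
#' @return object of class `validation_report`.
#' @export
validate_model <- function(model, params, records, config = hillnet_config()) {
  validate_internal(model, params, records, config, "qualitative")
}

#' Validate a model against semi-quantitative fold-category records
#'
#' The simulated fold change (with additive guard `eps_f` on numerator and
#' denominator) is classified into the six fold categories and compared to
#' the observed category: strict mode requires identity, lenient mode
#' (`config$semiquant_mode = "lenient"`) accepts the same direction within
#' one level.
#'
#' @inheritParams validate_model
#' @return object of class `validation_report`.
#' @export
validate_semiquant <- function(model, params, records,
                               config = hillnet_config()) {
  validate_internal(model, params, records, config, "semiquant")
}

#' Combined qualitative + semi-quantitative validation percent
#'
#' Equal weight per record: `100 * (matches_qual + matches_semi) /
#' (N_qual + N_semi)`, the objective used for EC50 calibration.
#'
#' @inheritParams validate_model
#' @return list with `percent`, `qualitative` and `semiquant` reports.
#' @export
validate_combined <- function(model, params, records,
                              config = hillnet_config()) {
  has_q <- any(records$type == "qualitative")
  has_s <- any(records$type == "semiquant")
  rq <- if (has_q) validate_model(model, params, records, config) else NULL
  rs <- if (has_s) validate_semiquant(model, params, records, config) else NULL
  m <- sum(c(if (has_q) sum(rq$outcomes$match[rq$outcomes$resolved]),
             if (has_s) sum(rs$outcomes$match[rs$outcomes$resolved])))
  n <- sum(c(if (has_q) sum(rq$outcomes$resolved),
             if (has_s) sum(rs$outcomes$resolved)))
  list(percent = 100 * m / n, qualitative = rq, semiquant = rs)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %.1f%% (%d/%d records", x$validation_percent,
              sum(x$outcomes$match[x$outcomes$resolved]),
              x$n_records - x$n_unresolved))
  if (x$n_unresolved) cat(sprintf(", %d unresolved", x$n_unresolved))
  cat(")\n")
  if (nrow(x$by_class) > 1) {
    cat("by class:\n")
    print(x$by_class, row.names = FALSE)
  }
  invisible(x)
}

#' Export a validation report
#'
#' Writes the per-record outcomes as CSV and the summary (overall percent,
#' breakdowns, unresolved count) as JSON next to it.
#'
#' @param report a `validation_report`.
#' @param csv path for the per-record table.
#' @param json optional path for the JSON summary.
#' @return `csv`, invisibly.
#' @export
write_validation_report <- function(report, csv, json = NULL) {
  utils::write.csv(report$outcomes, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(list(
      validation_percent = report$validation_percent,
      n_records = report$n_records, n_unresolved = report$n_unresolved,
      by_class = report$by_class, by_context = report$by_context,
      mode = report$mode
    ), json, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv)
}
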