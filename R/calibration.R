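# Deterministic coordinate pattern search for a piecewise-constant objective.
# The validation percent takes finitely many values, so gradient-based local
# refinement is vacuous; a shrinking coordinate search is used instead.
pattern_search <- function(fn, x0, lower, upper, step_frac = 1/8,
                           min_step_frac = 1/256, max_iter = 200) {
  stopifnot(length(x0) == length(lower), length(lower) == length(upper))
  width <- upper - lower
  step <- width * step_frac
  x <- pmin(pmax(x0, lower), upper)
  fx <- fn(x)
  iter <- 0L
  while (any(step > width * min_step_frac) && iter < max_iter) {
    iter <- iter + 1L
    improved <- FALSE
    for (j in seq_along(x)) {
      for (s in c(1, -1)) {
        cand <- x
        cand[j] <- min(max(x[j] + s * step[j], lower[j]), upper[j])
        if (cand[j] == x[j]) next
        fc <- fn(cand)
        if (fc > fx) {
          x <- cand; fx <- fc; improved <- TRUE
        }
      }
    }
    if (!improved) step <- step / 2
  }
  list(par = x, value = fx, iterations = iter)
}

multistart_maximize <- function(fn, lower, upper, n_starts, seed,
                                n_refine = min(5L, n_starts), ref_point = NULL,
                                refine_control = list(), incumbent = NULL) {
  k <- length(lower)
  starts <- matrix(NA_real_, n_starts, k)
  for (i in seq_len(n_starts)) {
    # nested per-start seeds: the first m rows are identical for any n >= m
    starts[i, ] <- with_seed(seed + i, lower + stats::runif(k) * (upper - lower))
  }
  f_start <- apply(starts, 1, fn)
  ord <- order(-f_start)
  refine_idx <- ord[seq_len(min(n_refine, n_starts))]
  refine_pts <- lapply(refine_idx, function(i) starts[i, ])
  if (!is.null(incumbent)) {
    # the current parameter set is always a candidate and always refined,
    # so estimation never returns something worse than its starting point
    incumbent <- pmin(pmax(incumbent, lower), upper)
    refine_pts <- c(refine_pts, list(incumbent))
  }
  refined <- lapply(refine_pts, function(x0) {
    do.call(pattern_search,
            c(list(fn = fn, x0 = x0, lower = lower, upper = upper),
              refine_control))
  })
  trace <- data.frame(start = seq_len(n_starts), start_objective = f_start)
  for (j in seq_len(k)) trace[[paste0("start_x", j)]] <- starts[, j]
  trace$refined_objective <- NA_real_
  for (m in seq_along(refine_idx)) {
    trace$refined_objective[refine_idx[m]] <- refined[[m]]$value
  }
  cand_par <- c(lapply(seq_len(n_starts), function(i) starts[i, ]),
                lapply(refined, `[[`, "par"))
  cand_val <- c(f_start, vapply(refined, `[[`, numeric(1), "value"))
  if (!is.null(incumbent)) {
    cand_par <- c(cand_par, list(incumbent))
    cand_val <- c(cand_val, fn(incumbent))
  }
  best_val <- max(cand_val)
  tied <- which(cand_val >= best_val - 1e-12)
  if (length(tied) > 1 && !is.null(ref_point)) {
    width <- pmax(upper - lower, 1e-12)  # degenerate (pinned) bounds allowed
    d <- vapply(tied, function(i) {
      sqrt(sum(((cand_par[[i]] - ref_point) / width)^2))
    }, numeric(1))
    best_i <- tied[which.min(d)]
  } else {
    best_i <- tied[1]
  }
  list(par = cand_par[[best_i]], value = cand_val[best_i], trace = trace)
}

#' Estimate the four default parameters from qualitative data
#'
#' Stage-1 revision: maximizes the overall validation percent over the four
#' shared default parameters — Hill coefficient `n`, reaction weight `W_R`,
#' resting input weight `W_i` and stimulated input weight `W_e` — by
#' multi-start search (random scatter of starts, each promising start
#' refined by a deterministic shrinking coordinate search; the objective is
#' piecewise constant, so derivative-free refinement is used throughout).
#' Ties between parameter sets with equal objective are broken by the
#' smallest bound-normalized distance from the original defaults, favoring
#' minimal revision.
#'
#' @param model a [network_model()].
#' @param records qualitative `experiment_records` (all contexts).
#' @param bounds named list of length-2 ranges for `n`, `W_R`, `W_i`, `W_e`.
#' @param n_starts number of random initial sets.
#' @param seed RNG seed; starts are drawn from nested per-start seeds so the
#'   first m starts coincide for any `n_starts >= m`.
#' @param base_params baseline [param_set()] supplying the non-estimated
#'   defaults.
#' @param n_refine how many top-ranked starts get local refinement.
#' @param refine_control named list tuning the coordinate search
#'   (`step_frac`, `min_step_frac`, `max_iter`).
#' @param config a [hillnet_config()].
#' @return object of class `estimation_result`: `best_params` (a
#'   `param_set`), `best_objective` (validation percent), `trace`, `seed`.
#' @export
estimate_defaults <- function(model, records,
                              bounds = list(n = c(1, 10), W_R = c(0, 1),
                                            W_i = c(0, 0.5), W_e = c(0.5, 1)),
                              n_starts = 100, seed = 1,
                              base_params = param_set(),
                              n_refine = min(5L, n_starts),
                              refine_control = list(),
                              config = hillnet_config()) {
  stopifnot(nrow(records) > 0, n_starts >= 1)
  nm <- c("n", "W_R", "W_i", "W_e")
  if (!setequal(names(bounds), nm)) {
    stop("bounds must name exactly n, W_R, W_i, W_e", call. = FALSE)
  }
  lower <- vapply(nm, function(p) bounds[[p]][1], numeric(1))
  upper <- vapply(nm, function(p) bounds[[p]][2], numeric(1))
  mk <- function(v) {
    p <- base_params
    p$defaults[nm] <- as.list(v)
    p
  }
  fn <- function(v) {
    p <- tryCatch(check_param_set(mk(v)), error = function(e) NULL)
    if (is.null(p)) return(-Inf)  # e.g. EC50^n at the singular point
    validate_model(model, p, records, config)$validation_percent
  }
  ref <- unlist(param_set()$defaults[nm])
  opt <- multistart_maximize(fn, lower, upper, n_starts, seed,
                             n_refine = n_refine, ref_point = ref,
                             refine_control = refine_control,
                             incumbent = unlist(base_params$defaults[nm]))
  names(opt$par) <- nm
  structure(list(best_params = mk(opt$par), best_values = opt$par,
                 best_objective = opt$value, trace = opt$trace, seed = seed),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> best objective %.2f%% over %d start(s)\n",
              x$best_objective, nrow(x$trace)))
  print(round(x$best_values, 4))
  invisible(x)
}

#' Validation-percent landscape over a parameter pair
#'
#' Grid evaluation of the overall validation percent while one pair of
#' default parameters varies and the others stay at the supplied optimum;
#' used for heat-map style uncertainty inspection around the estimate.
#' Grid cells whose parameters violate the transfer-function validity
#' (`EC50^n = 0.5`) are flagged `NaN` rather than silently skipped.
#'
#' @inheritParams estimate_defaults
#' @param pair character pair, `c("W_R", "n")` or `c("W_e", "W_i")` (any two
#'   of the four defaults are accepted).
#' @param grid named list with one numeric vector of values per pair member.
#' @param at the [param_set()] holding the non-varied optimum.
#' @return matrix of validation percents (rows = first pair member).
#' @export
objective_landscape <- function(model, records, pair, grid, at = param_set(),
                                config = hillnet_config()) {
  stopifnot(length(pair) == 2, all(pair %in% names(grid)))
  v1 <- grid[[pair[1]]]; v2 <- grid[[pair[2]]]
  out <- matrix(NA_real_, length(v1), length(v2),
                dimnames = list(format(v1), format(v2)))
  for (i in seq_along(v1)) {
    for (j in seq_along(v2)) {
      p <- at
      p$defaults[[pair[1]]] <- v1[i]
      p$defaults[[pair[2]]] <- v2[j]
      ok <- tryCatch({ check_param_set(p); TRUE }, error = function(e) FALSE)
      out[i, j] <- if (ok) {
        validate_model(model, p, records, config)$validation_percent
      } else NaN
    }
  }
  out
}

#' Calibrate per-reaction EC50 against qualitative + semi-quantitative data
#'
#' Stage-3 refinement: only the EC50 values of the selected reaction subset
#' (typically the top-ranked reactions from the global sensitivity analysis)
#' vary; the objective is the combined validation percent with equal weight
#' per record, `100 * (matches_qual + matches_semi) / (N_qual + N_semi)`.
#'
#' @inheritParams estimate_defaults
#' @param params baseline [param_set()] (e.g. the stage-1 estimate).
#' @param reaction_subset reaction ids whose EC50 is calibrated; an empty
#'   subset returns `params` unchanged.
#' @param records `experiment_records` mixing qualitative and
#'   semi-quantitative rows.
#' @param bounds length-2 EC50 range, excluding the singular point.
#' @return object of class `estimation_result` with per-reaction EC50
#'   overrides in `best_params`.
#' @export
calibrate_ec50 <- function(model, params, reaction_subset, records,
                           bounds = c(0.2, 0.6), n_starts = 20, seed = 1,
                           n_refine = min(3L, n_starts),
                           refine_control = list(),
                           config = hillnet_config()) {
  if (length(reaction_subset) == 0L) {
    obj <- validate_combined(model, params, records, config)$percent
    return(structure(list(best_params = params, best_values = numeric(0),
                          best_objective = obj,
                          trace = data.frame(), seed = seed),
                     class = "estimation_result"))
  }
  bad <- setdiff(reaction_subset, model$reactions$id)
  if (length(bad)) stop("subset reaction(s) not in model: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  k <- length(reaction_subset)
  mk <- function(v) {
    p <- params
    for (i in seq_len(k)) p <- set_override(p, reaction_subset[i], "EC50", v[i])
    p
  }
  fn <- function(v) validate_combined(model, mk(v), records, config)$percent
  inc <- vapply(reaction_subset, function(r) {
    param_lookup(params, r, "EC50")
  }, numeric(1))
  opt <- multistart_maximize(fn, rep(bounds[1], k), rep(bounds[2], k),
                             n_starts, seed, n_refine = n_refine,
                             ref_point = rep(params$defaults$EC50, k),
                             refine_control = refine_control,
                             incumbent = inc)
  names(opt$par) <- reaction_subset
  structure(list(best_params = mk(opt$par), best_values = opt$par,
                 best_objective = opt$value, trace = opt$trace, seed = seed),
            class = "estimation_result")
}
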