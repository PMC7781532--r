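#' Single-reaction deletion scan
#'
#' Re-validates the model after deleting each intermediate reaction in turn
#' (weight `W_R = 0`), per context. The per-reaction score is the change in
#' validation percent (after minus before); reactions are categorized as
#' `non_sensitive` (no context affected), `direct` (exactly one context
#' affected) or `shared` (two or more contexts affected).
#'
#' @param model a [network_model()].
#' @param params a [param_set()].
#' @param records `experiment_records` spanning one or more contexts.
#' @param reactions reaction ids to scan (default: all intermediate).
#' @param config a [hillnet_config()].
#' @return object of class `deletion_scan_result`: `delta` (reaction x
#'   context matrix of percent-point changes), `baseline` (named vector),
#'   `category` (named factor-like character vector).
#' @export
deletion_scan <- function(model, params, records,
                          reactions = intermediate_reactions(model),
                          config = hillnet_config()) {
  contexts <- unique(records$context)
  val_by_ctx <- function(p) {
    vapply(contexts, function(cx) {
      validate_model(model, p, records[records$context == cx, , drop = FALSE],
                     config)$validation_percent
    }, numeric(1))
  }
  baseline <- val_by_ctx(params)
  delta <- matrix(NA_real_, length(reactions), length(contexts),
                  dimnames = list(reactions, contexts))
  for (r in reactions) {
    delta[r, ] <- val_by_ctx(set_override(params, r, "W_R", 0)) - baseline
  }
  affected <- rowSums(abs(delta) > 1e-9)
  category <- ifelse(affected == 0, "non_sensitive",
                     ifelse(affected == 1, "direct", "shared"))
  structure(list(delta = delta, baseline = baseline,
                 category = stats::setNames(category, reactions)),
            class = "deletion_scan_result")
}

#' @export
print.deletion_scan_result <- function(x, ...) {
  cat(sprintf("<deletion_scan_result> %d reactions x %d contexts; %d sensitive\n",
              nrow(x$delta), ncol(x$delta), sum(x$category != "non_sensitive")))
  invisible(x)
}

# ---- objective wrapping -----------------------------------------------------

#' Sensitivity-analysis objective over per-reaction parameters
#'
#' Describes the function the global sensitivity methods probe: one context's
#' validation percent (or, alternatively, the mean activity of designated
#' output nodes at the stimulated steady state) as a function of one varied
#' parameter (EC50 by default) of a set of reactions, each scaled to \[0, 1\]
#' over its bounds. Non-listed reactions keep their default parameter.
#'
#' @param model a [network_model()].
#' @param params baseline [param_set()].
#' @param records `experiment_records` of one context (validation objective).
#' @param factors reaction ids to vary (default all intermediate reactions).
#' @param param varied parameter name, default `"EC50"`.
#' @param bounds length-2 numeric, shared bounds for all factors (default
#'   `c(0.2, 0.6)`, excluding the transfer-function singularity).
#' @param objective `"validation"` or `"output_mean"`.
#' @param stimulus input node stimulated for the `output_mean` objective
#'   (defaults to the records' context).
#' @param output_nodes nodes averaged by the `output_mean` objective
#'   (defaults to role `output`).
#' @param config a [hillnet_config()].
#' @return object of class `objective_spec`.
#' @export
objective_spec <- function(model, params, records = NULL,
                           factors = intermediate_reactions(model),
                           param = "EC50", bounds = c(0.2, 0.6),
                           objective = c("validation", "output_mean"),
                           stimulus = NULL, output_nodes = NULL,
                           config = hillnet_config()) {
  objective <- match.arg(objective)
  stopifnot(length(factors) >= 1, length(bounds) == 2, bounds[1] < bounds[2])
  bad <- setdiff(factors, intermediate_reactions(model))
  if (length(bad)) stop("factor(s) not intermediate reactions: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (objective == "validation" && is.null(records)) {
    stop("validation objective needs records", call. = FALSE)
  }
  if (param == "EC50") {
    n_def <- params$defaults$n
    sing <- 0.5^(1 / n_def)
    if (bounds[1] <= sing && sing <= bounds[2]) {
      stop(sprintf("EC50 bounds [%g, %g] straddle the singular EC50 = %.4g for n = %g",
                   bounds[1], bounds[2], sing, n_def), call. = FALSE)
    }
  }
  structure(list(model = model, params = params, records = records,
                 factors = factors, param = param, bounds = bounds,
                 objective = objective, stimulus = stimulus,
                 output_nodes = output_nodes, config = config),
            class = "objective_spec")
}

#' Build the numeric objective function from an [objective_spec()]
#'
#' @param spec an `objective_spec`.
#' @return function mapping a numeric vector in `[0,1]^k` (scaled factors)
#'   to the objective value.
#' @export
make_objective <- function(spec) {
  stopifnot(inherits(spec, "objective_spec"))
  lo <- spec$bounds[1]; hi <- spec$bounds[2]
  outs <- spec$output_nodes
  if (is.null(outs)) outs <- spec$model$nodes$id[spec$model$nodes$role == "output"]
  stim <- spec$stimulus
  if (is.null(stim) && !is.null(spec$records)) stim <- spec$records$context[1]
  function(x) {
    stopifnot(length(x) == length(spec$factors))
    p <- spec$params
    vals <- lo + x * (hi - lo)
    for (i in seq_along(spec$factors)) {
      p <- set_override(p, spec$factors[i], spec$param, vals[i])
    }
    if (spec$objective == "validation") {
      validate_model(spec$model, p, spec$records, spec$config)$validation_percent
    } else {
      ss <- simulate_network(spec$model, p,
                             list(perturbation("stimulus", stim)),
                             config = spec$config)$steady_state
      mean(ss[outs])
    }
  }
}

eval_rows <- function(f, X) {
  vapply(seq_len(nrow(X)), function(i) f(X[i, ]), numeric(1))
}

# ---- Morris elementary effects ----------------------------------------------

morris_trajectory <- function(k, levels, delta) {
  grid <- seq(0, 1, length.out = levels)
  start_pool <- grid[grid <= 1 - delta + 1e-12]
  x0 <- sample(start_pool, k, replace = TRUE)
  signs <- sample(c(-1, 1), k, replace = TRUE)
  x0 <- ifelse(signs < 0, x0 + delta, x0)  # keep both endpoints in [0, 1]
  perm <- sample.int(k)
  X <- matrix(NA_real_, k + 1L, k)
  X[1, ] <- x0
  x <- x0
  for (s in seq_len(k)) {
    j <- perm[s]
    x[j] <- x[j] + signs[j] * delta
    X[s + 1L, ] <- x
  }
  list(X = X, perm = perm, signs = signs)
}

trajectory_distance <- function(Xa, Xb) {
  # aggregate spread: sum of pairwise point distances between trajectories
  cross <- outer(seq_len(nrow(Xa)), seq_len(nrow(Xb)),
                 Vectorize(function(i, j) sqrt(sum((Xa[i, ] - Xb[j, ])^2))))
  sum(cross)
}

select_spread <- function(trajs, r) {
  n <- length(trajs)
  if (r >= n) return(seq_len(n))
  D <- matrix(0, n, n)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      D[a, b] <- D[b, a] <- trajectory_distance(trajs[[a]]$X, trajs[[b]]$X)
    }
  }
  sel <- as.integer(arrayInd(which.max(D), dim(D)))
  while (length(sel) < r) {
    rest <- setdiff(seq_len(n), sel)
    mind <- vapply(rest, function(i) min(D[i, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)])
  }
  sort(sel)
}

#' Morris elementary-effects screening
#'
#' Screens the factors of an objective by Morris's method: factors scaled to
#' \[0, 1\] are placed on a grid of `levels` points with step
#' `delta = levels / (2 * (levels - 1))`; `oversample` random one-at-a-time
#' trajectories of `k + 1` points are generated and `trajectories` of them
#' are retained by greedy max–min spread maximization (the sampling-for-
#' uniformity stand-in; `strategy = "first"` keeps the first ones instead).
#' The elementary effect of factor j on a trajectory is the signed finite
#' difference of the objective across that factor's step, divided by
#' `delta`. Reported per factor: `mu_star` (mean absolute EE), `mu` (mean
#' EE), `sigma` (sd of EEs), a monotonicity flag (`|mu|/mu_star >= 0.99`)
#' and an importance flag (`mu_star > threshold`). The objective is
#' evaluated exactly `trajectories * (k + 1)` times.
#'
#' @param objective an [objective_spec()] or a plain function on `[0,1]^k`.
#' @param k number of factors (required for a plain function).
#' @param levels number of grid levels (even).
#' @param trajectories trajectories retained.
#' @param oversample trajectories generated before selection.
#' @param threshold importance cutoff on `mu_star`.
#' @param seed RNG seed.
#' @param strategy `"maxmin"` spread selection or `"first"`.
#' @return object of class `morris_result`: data.frame `factors` with the
#'   statistics, plus `n_evals`, `levels`, `delta`, `seed`.
#' @examples
#' f <- function(x) 3 * x[1]          # linear: mu_star = 3, sigma = 0
#' morris_screen(f, k = 3, trajectories = 4, oversample = 8, seed = 1)
#' @export
morris_screen <- function(objective, k = NULL, levels = 8, trajectories = 16,
                          oversample = 300, threshold = 1.5, seed = 1,
                          strategy = c("maxmin", "first")) {
  strategy <- match.arg(strategy)
  if (inherits(objective, "objective_spec")) {
    f <- make_objective(objective)
    k <- length(objective$factors)
    factor_ids <- objective$factors
  } else {
    f <- objective
    if (is.null(k)) stop("k is required for a plain objective function", call. = FALSE)
    factor_ids <- sprintf("x%d", seq_len(k))
  }
  if (levels %% 2 != 0) stop("levels must be even", call. = FALSE)
  if (trajectories > oversample) stop("trajectories > oversample", call. = FALSE)
  delta <- levels / (2 * (levels - 1))

  with_seed(seed, {
    pool <- replicate(oversample, morris_trajectory(k, levels, delta),
                      simplify = FALSE)
    keep <- if (strategy == "maxmin") select_spread(pool, trajectories)
            else seq_len(trajectories)
    trajs <- pool[keep]
  })

  EE <- matrix(NA_real_, length(trajs), k)
  n_evals <- 0L
  for (t in seq_along(trajs)) {
    tr <- trajs[[t]]
    fx <- eval_rows(f, tr$X)
    n_evals <- n_evals + nrow(tr$X)
    for (s in seq_len(k)) {
      j <- tr$perm[s]
      EE[t, j] <- (fx[s + 1L] - fx[s]) / (tr$signs[j] * delta)
    }
  }
  mu <- colMeans(EE)
  mu_star <- colMeans(abs(EE))
  sigma <- apply(EE, 2, stats::sd)
  res <- data.frame(factor = factor_ids, mu_star = mu_star, mu = mu,
                    sigma = sigma,
                    monotonic = mu_star > 0 & abs(mu) / pmax(mu_star, 1e-300) >= 0.99,
                    important = mu_star > threshold,
                    stringsAsFactors = FALSE)
  structure(list(factors = res, ee = EE, n_evals = n_evals, levels = levels,
                 delta = delta, threshold = threshold, seed = seed),
            class = "morris_result")
}

#' @export
print.morris_result <- function(x, ...) {
  cat(sprintf("<morris_result> %d factors, %d evaluations; %d important (mu* > %g)\n",
              nrow(x$factors), x$n_evals, sum(x$factors$important), x$threshold))
  print(utils::head(x$factors[order(-x$factors$mu_star), ], 10), row.names = FALSE)
  invisible(x)
}

#' Select the important factors of a Morris screen
#'
#' Factors with `mu_star > threshold`, ranked by `mu_star` descending, ties
#' broken lexicographically by factor id.
#'
#' @param morris a `morris_result`.
#' @param threshold non-negative cutoff (0 keeps every factor with any effect).
#' @return character vector of factor ids.
#' @export
select_important <- function(morris, threshold = morris$threshold) {
  stopifnot(inherits(morris, "morris_result"), threshold >= 0)
  d <- morris$factors[morris$factors$mu_star > threshold, ]
  d$factor[order(-d$mu_star, d$factor)]
}

# ---- Sobol (Jansen estimators) ----------------------------------------------

#' Sobol variance decomposition with Jansen estimators
#'
#' Monte-Carlo estimation of main (`S_i`), total (`T_i`) and second-order
#' (`S_ij`) Sobol indices of an objective on `[0,1]^k`. Two base matrices A
#' and B (`N x k`, seeded uniform) are drawn; for each factor the hybrid
#' matrix `A_B^(i)` swaps column i of A with B's, and for each pair the
#' matrix `A_B^(i,j)` swaps both columns. With `V` the sample variance over
#' all A and B evaluations, the Jansen estimators are
#' \deqn{T_i = \frac{1}{2NV}\sum_r (f(A)_r - f(A_B^{(i)})_r)^2, \quad
#'       S_i = 1 - \frac{1}{2NV}\sum_r (f(B)_r - f(A_B^{(i)})_r)^2}
#' and the closed pair index from `A_B^(i,j)` analogously, with
#' `S_ij = S^c_ij - S_i - S_j`. Percentile bootstrap confidence intervals
#' resample the N rows. The pair synergy is
#' `S_ij / ((T_i - S_i) + (T_j - S_j))`, reported as 0 when the summed
#' higher-order effects fall below `synergy_eps` (the ratio of two
#' Monte-Carlo zeros carries no information).
#'
#' @inheritParams morris_screen
#' @param N base sample size (`>= 64`).
#' @param bootstrap_reps bootstrap replicates for the 95\% CIs.
#' @param pairs estimate second-order indices for all factor pairs.
#' @param synergy_eps higher-order-effect floor below which synergy is 0.
#' @return object of class `sobol_result`: `first_order` data.frame
#'   (`factor`, `S`, `S_lo`, `S_hi`, `T`, `T_lo`, `T_hi`), `second_order`
#'   data.frame (`factor_i`, `factor_j`, `S_ij`, CI, `synergy`), plus
#'   `variance`, `N`, `n_evals`, `seed`.
#' @export
sobol_analysis <- function(objective, k = NULL, N = 1024, seed = 1,
                           bootstrap_reps = 2000, pairs = TRUE,
                           synergy_eps = 0.05) {
  if (inherits(objective, "objective_spec")) {
    f <- make_objective(objective)
    k <- length(objective$factors)
    factor_ids <- objective$factors
  } else {
    f <- objective
    if (is.null(k)) stop("k is required for a plain objective function", call. = FALSE)
    factor_ids <- sprintf("x%d", seq_len(k))
  }
  if (N < 64) stop("N must be >= 64", call. = FALSE)
  pair_idx <- if (pairs && k >= 2) utils::combn(k, 2) else matrix(integer(), 2, 0)

  with_seed(seed, {
    A <- matrix(stats::runif(N * k), N, k)
    B <- matrix(stats::runif(N * k), N, k)
  })
  fA <- eval_rows(f, A)
  fB <- eval_rows(f, B)
  fABi <- matrix(NA_real_, N, k)
  for (i in seq_len(k)) {
    M <- A; M[, i] <- B[, i]
    fABi[, i] <- eval_rows(f, M)
  }
  fABij <- matrix(NA_real_, N, ncol(pair_idx))
  for (p in seq_len(ncol(pair_idx))) {
    M <- A; M[, pair_idx[, p]] <- B[, pair_idx[, p]]
    fABij[, p] <- eval_rows(f, M)
  }
  n_evals <- N * (2L + k + ncol(pair_idx))

  V <- stats::var(c(fA, fB))
  if (!is.finite(V) || V <= 0) {
    stop("objective has zero variance over the sample; Sobol indices undefined",
         call. = FALSE)
  }
  dT <- (fA - fABi)^2            # N x k
  dS <- (fB - fABi)^2
  dC <- (fB - fABij)^2           # N x n_pairs

  est <- function(idx) {
    Vb <- stats::var(c(fA[idx], fB[idx]))
    Tb <- colMeans(dT[idx, , drop = FALSE]) / (2 * Vb)
    Sb <- 1 - colMeans(dS[idx, , drop = FALSE]) / (2 * Vb)
    Cb <- if (ncol(dC)) 1 - colMeans(dC[idx, , drop = FALSE]) / (2 * Vb) else numeric(0)
    Pb <- if (length(Cb)) Cb - Sb[pair_idx[1, ]] - Sb[pair_idx[2, ]] else numeric(0)
    c(Sb, Tb, Pb)
  }
  point <- est(seq_len(N))
  boots <- matrix(NA_real_, bootstrap_reps, length(point))
  with_seed(seed + 1L, {
    for (r in seq_len(bootstrap_reps)) {
      boots[r, ] <- est(sample.int(N, N, replace = TRUE))
    }
  })
  ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)

  iS <- seq_len(k); iT <- k + seq_len(k); iP <- 2L * k + seq_len(ncol(pair_idx))
  first <- data.frame(factor = factor_ids,
                      S = point[iS], S_lo = ci[1, iS], S_hi = ci[2, iS],
                      T = point[iT], T_lo = ci[1, iT], T_hi = ci[2, iT],
                      stringsAsFactors = FALSE)
  second <- if (length(iP)) {
    Sij <- point[iP]
    hoi <- (point[iT] - point[iS])[pair_idx[1, ]] +
           (point[iT] - point[iS])[pair_idx[2, ]]
    data.frame(factor_i = factor_ids[pair_idx[1, ]],
               factor_j = factor_ids[pair_idx[2, ]],
               S_ij = Sij, S_ij_lo = ci[1, iP], S_ij_hi = ci[2, iP],
               synergy = ifelse(hoi < synergy_eps, 0, Sij / hoi),
               stringsAsFactors = FALSE)
  } else {
    data.frame(factor_i = character(), factor_j = character(), S_ij = numeric(),
               S_ij_lo = numeric(), S_ij_hi = numeric(), synergy = numeric())
  }
  structure(list(first_order = first, second_order = second, variance = V,
                 N = N, n_evals = n_evals, seed = seed,
                 bootstrap_reps = bootstrap_reps,
                 pair_construction = "closed-pair Jansen differences"),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("<sobol_result> N=%d, %d factors, %d evaluations, V=%.4g\n",
              x$N, nrow(x$first_order), x$n_evals, x$variance))
  print(x$first_order, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sobol sample-size convergence check
#'
#' Recomputes the first-order and total indices across an increasing grid of
#' sample sizes and reports the maximum index drift between successive
#' sizes; convergence is flagged when the final drift falls below `tol`.
#'
#' @inheritParams sobol_analysis
#' @param N_grid increasing integer vector of sample sizes.
#' @param tol drift tolerance.
#' @return data.frame (`N`, per-factor `S_*`/`T_*` columns, `max_drift`)
#'   with attribute `converged`.
#' @export
convergence_check <- function(objective, k = NULL, N_grid = c(256, 1024, 4096),
                              seed = 1, tol = 0.05) {
  stopifnot(all(diff(N_grid) > 0))
  rows <- lapply(seq_along(N_grid), function(g) {
    res <- sobol_analysis(objective, k = k, N = N_grid[g], seed = seed + g,
                          bootstrap_reps = 100, pairs = FALSE)
    stats::setNames(c(res$first_order$S, res$first_order$T),
                    c(paste0("S_", res$first_order$factor),
                      paste0("T_", res$first_order$factor)))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(N = N_grid, tab)
  drift <- c(NA, vapply(seq_len(nrow(tab) - 1), function(i) {
    max(abs(unlist(tab[i + 1, -1]) - unlist(tab[i, -1])))
  }, numeric(1)))
  tab$max_drift <- drift
  attr(tab, "converged") <- utils::tail(drift, 1) < tol
  tab
}
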