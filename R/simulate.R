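#' Engine configuration
#'
#' Collects the numerical knobs of the simulator and validator with their
#' defaults: `tol_ss` (steady-state criterion on `max |dy/dt| / max(Ymax, 1e-6)`),
#' `t_max` (`NULL` means `40 * max(tau)`), `overexpression` (`"clamp"` pins
#' the node at `Ymax` exactly; `"literal"` uses `Y0 = Ymax`, `tau = 1e9`),
#' solver tolerances `rtol`/`atol`, the in-silico direction threshold
#' `threshold` (percent change from control), the near-zero control guard
#' `eps_c` (fraction of `Ymax`) and the fold-change guard `eps_f`.
#'
#' @param ... named replacements for any of the defaults.
#' @return named list.
#' @export
hillnet_config <- function(...) {
  cfg <- list(tol_ss = 1e-6, t_max = NULL, overexpression = "clamp",
              rtol = 1e-8, atol = 1e-10, threshold = 1,
              eps_c = 1e-4, eps_f = 1e-3, semiquant_mode = "strict")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  cfg
}

# Resolve model + parameter set + perturbations into flat numeric structures
# the RHS closure can evaluate cheaply.
compile_model <- function(model, params, perturbations = list(),
                          config = hillnet_config()) {
  stopifnot(inherits(model, "network_model"), inherits(params, "param_set"))
  nodes <- model$nodes
  rxn <- model$reactions
  nn <- nrow(nodes)
  nr <- nrow(rxn)
  node_idx <- stats::setNames(seq_len(nn), nodes$id)
  rxn_idx <- stats::setNames(seq_len(nr), rxn$id)

  num <- function(i, col, param) {
    v <- nodes[[col]][i]
    param_lookup(params, nodes$id[i], param, v)
  }
  Ymax <- vapply(seq_len(nn), num, numeric(1), col = "Ymax", param = "Ymax")
  Y0 <- vapply(seq_len(nn), num, numeric(1), col = "Y0", param = "Y0")
  tau <- vapply(seq_len(nn), num, numeric(1), col = "tau", param = "tau")
  Y0 <- pmin(Y0, Ymax)

  W <- vapply(seq_len(nr), function(i) {
    param_lookup(params, rxn$id[i], "W_R", rxn$W_R[i])
  }, numeric(1))
  nH <- vapply(seq_len(nr), function(i) {
    param_lookup(params, rxn$id[i], "n", rxn$n[i])
  }, numeric(1))
  EC50 <- vapply(seq_len(nr), function(i) {
    param_lookup(params, rxn$id[i], "EC50", rxn$EC50[i])
  }, numeric(1))

  is_input <- rxn$is_input
  input_w <- ifelse(is_input,
                    vapply(seq_len(nr), function(i) {
                      param_lookup(params, rxn$id[i], "W_i")
                    }, numeric(1)),
                    NA_real_)
  clamped <- logical(nn)

  for (p in perturbations) {
    switch(p$kind,
      stimulus = {
        j <- which(is_input & (rxn$id == p$target | rxn$target == p$target))
        if (!length(j)) {
          stop(sprintf("stimulus target '%s' is not a receptor input", p$target),
               call. = FALSE)
        }
        input_w[j] <- if (is.na(p$value)) {
          vapply(j, function(i) param_lookup(params, rxn$id[i], "W_e"), numeric(1))
        } else p$value
      },
      knockdown = {
        i <- node_idx[p$target]
        if (is.na(i)) stop(sprintf("knockdown target '%s' not in model", p$target),
                           call. = FALSE)
        Ymax[i] <- 0
        Y0[i] <- 0
      },
      overexpression = {
        i <- node_idx[p$target]
        if (is.na(i)) stop(sprintf("overexpression target '%s' not in model",
                                   p$target), call. = FALSE)
        Y0[i] <- Ymax[i]
        if (identical(config$overexpression, "literal")) {
          tau[i] <- 1e9
        } else {
          clamped[i] <- TRUE
        }
      },
      reaction_deletion = {
        j <- rxn_idx[p$target]
        if (is.na(j)) stop(sprintf("deletion target '%s' not a reaction",
                                   p$target), call. = FALSE)
        W[j] <- 0
      },
      reaction_weight = {
        j <- rxn_idx[p$target]
        if (is.na(j)) stop(sprintf("weight target '%s' not a reaction",
                                   p$target), call. = FALSE)
        W[j] <- p$value
      }
    )
  }

  # flat reactant-instance vectors; Hill constants precomputed per reaction
  hc <- hill_constants(nH[!is_input], EC50[!is_input])
  Bv <- Kn <- rep(NA_real_, nr)
  Bv[!is_input] <- hc$B
  Kn[!is_input] <- hc$K^nH[!is_input]

  inst_node <- integer(0); inst_rxn <- integer(0); inst_inhib <- logical(0)
  for (j in seq_len(nr)) {
    re <- rxn$reactants[[j]]
    if (nrow(re)) {
      inst_node <- c(inst_node, unname(node_idx[re$node]))
      inst_rxn <- c(inst_rxn, rep(j, nrow(re)))
      inst_inhib <- c(inst_inhib, re$sign == "inhibiting")
    }
  }
  inst_B <- Bv[inst_rxn]; inst_Kn <- Kn[inst_rxn]
  inst_n <- nH[inst_rxn]; inst_W <- W[inst_rxn]
  n_inst_per_rxn <- tabulate(inst_rxn, nbins = nr)
  multi_rxn <- which(!is_input & n_inst_per_rxn > 1L)
  single_map <- integer(nr)  # instance index for single-reactant reactions
  single_rxn <- which(!is_input & n_inst_per_rxn == 1L)
  single_map[single_rxn] <- match(single_rxn, inst_rxn)
  inst_by_rxn <- split(seq_along(inst_rxn), inst_rxn)  # names = rxn index

  tgt <- unname(node_idx[rxn$target])
  rxn_by_node <- split(seq_len(nr), tgt)  # names = node index as character

  list(nn = nn, nr = nr, node_ids = nodes$id, rxn_ids = rxn$id,
       Ymax = Ymax, Y0 = Y0, tau = tau, clamped = clamped,
       W = W, is_input = is_input, input_w = input_w,
       inst_node = inst_node, inst_rxn = inst_rxn, inst_inhib = inst_inhib,
       inst_B = inst_B, inst_Kn = inst_Kn, inst_n = inst_n, inst_W = inst_W,
       multi_rxn = multi_rxn, single_map = single_map,
       inst_by_rxn = inst_by_rxn, rxn_by_node = rxn_by_node,
       config = config)
}

rhs_from_compiled <- function(cm) {
  force(cm)
  function(t, y, parms = NULL) {
    x <- pmin(pmax(y, 0), pmax(cm$Ymax, 0))
    # transfer functions are defined on [0, 1]; clamp against overshoot
    xi <- pmin(x[cm$inst_node], 1)
    f <- cm$inst_B * xi^cm$inst_n / (cm$inst_Kn + xi^cm$inst_n)
    term_inst <- ifelse(cm$inst_inhib, 1 - cm$inst_W * f, cm$inst_W * f)
    term_rxn <- numeric(cm$nr)
    term_rxn[cm$is_input] <- cm$input_w[cm$is_input]
    sm <- cm$single_map
    term_rxn[sm > 0L] <- term_inst[sm[sm > 0L]]
    for (j in cm$multi_rxn) {
      term_rxn[j] <- and_gate(term_inst[cm$inst_by_rxn[[as.character(j)]]])
    }
    Fnode <- numeric(cm$nn)
    for (k in seq_along(cm$rxn_by_node)) {
      i <- as.integer(names(cm$rxn_by_node)[k])
      Fnode[i] <- or_gate(term_rxn[cm$rxn_by_node[[k]]])
    }
    dy <- (cm$Ymax * Fnode - x) / cm$tau
    dy[cm$clamped] <- 0
    list(dy)
  }
}

#' Build the LDE right-hand side
#'
#' For each node i, `dy_i/dt = (Ymax_i * F_i(y) - y_i) / tau_i`, where `F_i`
#' is the OR combination of all reactions targeting i. A signaling reaction
#' contributes the AND of its reactant terms ([activator_term()] for
#' activating, [inhibitor_term()] for inhibiting reactants, evaluated on
#' Ymax-normalized activities); a receptor input reaction contributes its
#' input weight (`W_i` at rest, `W_e` under stimulus). Perturbations are
#' folded in before the closure is built.
#'
#' @param model a [network_model()].
#' @param params a [param_set()].
#' @param perturbations list of [perturbation()]s.
#' @param config a [hillnet_config()].
#' @return function `(t, y, parms)` returning `list(dy/dt)`, as deSolve
#'   expects; the compiled structures are attached as attribute `"compiled"`.
#' @export
build_rhs <- function(model, params = param_set(), perturbations = list(),
                      config = hillnet_config()) {
  cm <- compile_model(model, params, perturbations, config)
  f <- rhs_from_compiled(cm)
  attr(f, "compiled") <- cm
  f
}

#' Simulate the network to steady state or a time point
#'
#' Integrates the LDE system with an adaptive stiff-capable solver
#' (`deSolve::lsodar`). In `steady_state` mode integration stops at the root
#' of `max_i |dy_i/dt| / max(Ymax_i, 1e-6) - tol_ss`, or at `t_max`
#' (`40 * max(tau)` by default) with `converged = FALSE`.
#'
#' @inheritParams build_rhs
#' @param mode `"steady_state"` or `"timepoint"`.
#' @param t_end end time for `timepoint` mode.
#' @return list of class `simulation_result`: `steady_state` (named activity
#'   vector), `converged`, `t_end`.
#' @examples
#' m <- make_toy_network(toy_spec("cascade", n_nodes = 4))
#' simulate_network(m, param_set(W_i = 0.1))$steady_state
#' @export
simulate_network <- function(model, params = param_set(), perturbations = list(),
                             mode = c("steady_state", "timepoint"), t_end = NULL,
                             config = hillnet_config()) {
  mode <- match.arg(mode)
  cm <- compile_model(model, params, perturbations, config)
  f <- rhs_from_compiled(cm)
  y0 <- cm$Y0
  names(y0) <- cm$node_ids
  scale <- pmax(cm$Ymax, 1e-6)
  crit <- function(y) max(abs(f(0, y)[[1]]) / scale)

  if (mode == "timepoint") {
    if (is.null(t_end) || !is.finite(t_end)) stop("timepoint mode needs finite t_end",
                                                  call. = FALSE)
    if (t_end == 0) {
      return(structure(list(steady_state = y0, converged = NA, t_end = 0),
                       class = "simulation_result"))
    }
    out <- deSolve::lsoda(y0, c(0, t_end), f, rtol = config$rtol,
                          atol = config$atol)
    y <- pmin(pmax(out[nrow(out), -1], 0), cm$Ymax + 1e-9)
    return(structure(list(steady_state = stats::setNames(unname(y), cm$node_ids),
                          converged = NA, t_end = t_end),
                     class = "simulation_result"))
  }

  t_max <- config$t_max
  if (is.null(t_max)) t_max <- 40 * max(cm$tau[!cm$clamped], 1)
  if (crit(y0) < config$tol_ss) {
    return(structure(list(steady_state = y0, converged = TRUE, t_end = 0),
                     class = "simulation_result"))
  }
  root <- function(t, y, parms) crit(y) - config$tol_ss
  out <- deSolve::lsodar(y0, c(0, t_max), f, rootfunc = root,
                         rtol = config$rtol, atol = config$atol)
  y <- out[nrow(out), -1]
  t_reached <- out[nrow(out), 1]
  y <- pmin(pmax(y, 0), cm$Ymax + 1e-9)
  structure(list(steady_state = stats::setNames(unname(y), cm$node_ids),
                 converged = crit(y) < config$tol_ss * 1.01,
                 t_end = unname(t_reached)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> t_end=%.3g converged=%s\n", x$t_end,
              format(x$converged)))
  print(round(x$steady_state, 4))
  invisible(x)
}
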