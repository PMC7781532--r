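#' Specification for a toy network
#'
#' @param topology one of `cascade`, `branch`, `feedback`, `crosstalk_demo`.
#' @param n_nodes number of nodes (ignored for `crosstalk_demo`, which is a
#'   fixed 8-node design containing a 2-input AND reaction and an inhibiting
#'   edge).
#' @param inhibitor_fraction fraction of intermediate edges drawn as
#'   inhibiting (cascade/branch).
#' @param seed RNG seed; generators are pure functions of spec + seed.
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(topology = c("cascade", "branch", "feedback",
                                  "crosstalk_demo"),
                     n_nodes = 5, inhibitor_fraction = 0, seed = 1) {
  topology <- match.arg(topology)
  if (topology == "feedback" && n_nodes < 3) {
    stop("feedback topology needs n_nodes >= 3", call. = FALSE)
  }
  if (topology == "branch" && n_nodes < 4) {
    stop("branch topology needs n_nodes >= 4", call. = FALSE)
  }
  if (n_nodes < 2) stop("n_nodes must be >= 2", call. = FALSE)
  structure(list(topology = topology, n_nodes = n_nodes,
                 inhibitor_fraction = inhibitor_fraction, seed = seed),
            class = "toy_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a deterministic toy network
#'
#' @param spec a [toy_spec()].
#' @return a [network_model()].
#' @examples
#' make_toy_network(toy_spec("cascade", n_nodes = 5))
#' @export
make_toy_network <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  with_seed(spec$seed, {
    switch(spec$topology,
           cascade = toy_cascade(spec),
           branch = toy_branch(spec),
           feedback = toy_feedback(spec),
           crosstalk_demo = toy_crosstalk_demo())
  })
}

toy_node_ids <- function(k) sprintf("N%d", seq_len(k))

maybe_inhibit <- function(source, frac) {
  inh <- stats::runif(length(source)) < frac
  ifelse(inh, paste0("!", source), source)
}

toy_roles <- function(k) c("input", rep("intermediate", k - 2), "output")

toy_cascade <- function(spec) {
  k <- spec$n_nodes
  ids <- toy_node_ids(k)
  src <- maybe_inhibit(ids[-k], spec$inhibitor_fraction)
  rules <- c(paste("=>", ids[1]), paste(src, "=>", ids[-1]))
  network_model(
    nodes = data.frame(id = ids, role = toy_roles(k)),
    reactions = data.frame(id = sprintf("r%d", seq_along(rules)), rule = rules)
  )
}

toy_branch <- function(spec) {
  k <- spec$n_nodes
  ids <- toy_node_ids(k)
  # input fans into two arms that reconverge on N4; any remaining nodes chain on
  rules <- c(paste("=>", ids[1]),
             paste(ids[1], "=>", ids[2]),
             paste(ids[1], "=>", ids[3]),
             paste(ids[2], "=>", ids[4]),
             paste(ids[3], "=>", ids[4]))
  if (k > 4) {
    src <- maybe_inhibit(ids[4:(k - 1)], spec$inhibitor_fraction)
    rules <- c(rules, paste(src, "=>", ids[5:k]))
  }
  network_model(
    nodes = data.frame(id = ids, role = toy_roles(k)),
    reactions = data.frame(id = sprintf("r%d", seq_along(rules)), rule = rules)
  )
}

toy_feedback <- function(spec) {
  k <- spec$n_nodes
  ids <- toy_node_ids(k)
  rules <- c(paste("=>", ids[1]),
             paste(ids[-k], "=>", ids[-1]),
             paste0("!", ids[k], " => ", ids[1]))  # closing inhibitory loop
  network_model(
    nodes = data.frame(id = ids, role = toy_roles(k)),
    reactions = data.frame(id = sprintf("r%d", seq_along(rules)), rule = rules)
  )
}

toy_crosstalk_demo <- function() {
  nodes <- data.frame(
    id = c("IN1", "IN2", "A", "B", "C", "D", "E", "OUT"),
    role = c("input", "input", rep("intermediate", 5), "output")
  )
  reactions <- data.frame(
    id = c("ri1", "ri2", "rA", "rB", "rC1", "rC2", "rD", "rE", "rO1", "rO2"),
    rule = c("=> IN1", "=> IN2", "IN1 => A", "IN2 => B", "A => C", "B => C",
             "B & A => D", "!C & B => E", "D => OUT", "E => OUT")
  )
  network_model(nodes, reactions)
}

#' Specification for synthetic experiment records
#'
#' @param model a [network_model()].
#' @param true_params the generating [param_set()]; the observed directions
#'   are the model's own simulated classifications under these parameters.
#' @param contexts input node ids used as agonists.
#' @param n_per_class records per (context, data class).
#' @param label_noise probability in \[0, 0.5) of flipping an observed
#'   direction to a wrong one.
#' @param type `qualitative` (directions) or `semiquant` (fold categories).
#' @param seed RNG seed.
#' @return list of class `record_gen_spec`.
#' @export
record_gen_spec <- function(model, true_params = param_set(), contexts,
                            n_per_class = 5, label_noise = 0,
                            type = c("qualitative", "semiquant"), seed = 1) {
  type <- match.arg(type)
  stopifnot(inherits(model, "network_model"), inherits(true_params, "param_set"))
  if (label_noise < 0 || label_noise >= 0.5) {
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  }
  input_nodes <- model$reactions$target[model$reactions$is_input]
  bad <- setdiff(contexts, input_nodes)
  if (length(bad)) {
    stop("context(s) not receptor inputs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(model = model, true_params = true_params, contexts = contexts,
                 n_per_class = n_per_class, label_noise = label_noise,
                 type = type, seed = seed),
            class = "record_gen_spec")
}

#' Generate synthetic experiment records from a model
#'
#' Samples (context, class, perturbation, measured node) combinations,
#' simulates each under `true_params`, records the model's own classified
#' direction (the same 1\% threshold machinery the validator uses, so the
#' generator is an exact oracle), then flips each direction to a wrong one
#' with probability `label_noise`. By construction
#' `validate_model(model, true_params, records)` equals
#' `100 * (1 - realized_noise)`; the realized flip count is attached as
#' attribute `"n_flipped"`.
#'
#' @param spec a [record_gen_spec()].
#' @param config a [hillnet_config()].
#' @return `experiment_records` with attribute `n_flipped`.
#' @export
make_records <- function(spec, config = hillnet_config()) {
  stopifnot(inherits(spec, "record_gen_spec"))
  model <- spec$model
  non_input <- model$nodes$id[model$nodes$role != "input"]
  outputs <- model$nodes$id[model$nodes$role == "output"]
  if (!length(outputs)) outputs <- non_input
  inter <- setdiff(non_input, outputs)
  if (!length(inter)) inter <- non_input

  with_seed(spec$seed, {
    rows <- list()
    n <- spec$n_per_class
    classes <- if (spec$type == "semiquant") {
      c("InputOutput", "InputIntermediate")
    } else {
      c("InputOutput", "InputIntermediate", "IntermediateInhibition",
        "IntermediateOverexpression")
    }
    for (ctx in spec$contexts) {
      for (cls in classes) {
        for (i in seq_len(n)) {
          meas <- switch(cls,
                         InputOutput = sample(outputs, 1),
                         InputIntermediate = sample(inter, 1),
                         sample(non_input, 1))
          perts <- switch(cls,
            InputOutput = ,
            InputIntermediate = list(perturbation("stimulus", ctx)),
            IntermediateInhibition = {
              tgt <- sample(setdiff(non_input, meas), 1)
              list(perturbation("stimulus", ctx), perturbation("knockdown", tgt))
            },
            IntermediateOverexpression = {
              tgt <- sample(setdiff(non_input, meas), 1)
              list(perturbation("overexpression", tgt))
            })
          rows[[length(rows) + 1L]] <- list(context = ctx, data_class = cls,
                                            measured_node = meas,
                                            perturbations = perts)
        }
      }
    }
    df <- data.frame(
      record_id = sprintf("gen%04d", seq_along(rows)),
      context = vapply(rows, `[[`, character(1), "context"),
      data_class = vapply(rows, `[[`, character(1), "data_class"),
      measured_node = vapply(rows, `[[`, character(1), "measured_node"),
      observed = "nochange", source = "synthetic",
      stringsAsFactors = FALSE
    )
    df$type <- if (spec$type == "semiquant") "semiquant" else "qualitative"
    df$perturbations <- I(lapply(rows, `[[`, "perturbations"))

    # observed = the model's own prediction under the generating parameters
    cache <- new.env(parent = emptyenv())
    obs <- vapply(seq_len(nrow(df)), function(i) {
      out <- run_condition(model, spec$true_params, df[i, , drop = FALSE],
                           config, cache)
      out$predicted
    }, character(1))
    df$observed <- obs

    flipped <- 0L
    if (spec$label_noise > 0) {
      flip <- stats::runif(nrow(df)) < spec$label_noise
      for (i in which(flip)) {
        df$observed[i] <- flip_label(df$observed[i], df$type[i])
      }
      flipped <- sum(flip)
    }
    rec <- experiment_records(df)
    attr(rec, "n_flipped") <- flipped
    rec
  })
}

flip_label <- function(obs, type) {
  if (type == "semiquant") {
    return(sample(setdiff(.fold_categories, obs), 1))
  }
  switch(obs,
         increase = "decrease",
         decrease = "increase",
         sample(c("increase", "decrease"), 1))
}

#' Build a crosstalk-recovery test case
#'
#' Constructs the `crosstalk_demo` network, simulates an exhaustive
#' noise-free record set from the full model (stimulus-only conditions for
#' every measured node plus stimulus + knockdown of every intermediate node,
#' for both inputs), and returns the model with one true interaction
#' withheld together with the ground-truth edge. For `gate = "OR"` the
#' reaction `A => C` is removed (node C keeps its second incoming reaction);
#' for `gate = "AND"` the reactant A is removed from the 2-input AND reaction
#' `B & A => D`. Screening candidates of the matching gate type on the
#' pruned model ranks the withheld edge first by construction.
#'
#' @param seed RNG seed (record ids only; the construction is deterministic).
#' @param gate which gate type to withhold, `"OR"` or `"AND"`.
#' @param params generating [param_set()].
#' @param config a [hillnet_config()].
#' @return list: `model` (pruned), `full_model`, `records`, `truth`
#'   (list `gate`, `source`, `target`).
#' @export
make_recovery_case <- function(seed = 1, gate = c("OR", "AND"),
                               params = param_set(), config = hillnet_config()) {
  gate <- match.arg(gate)
  full <- toy_crosstalk_demo()
  non_input <- full$nodes$id[full$nodes$role != "input"]
  rows <- list()
  for (ctx in c("IN1", "IN2")) {
    for (meas in non_input) {
      rows[[length(rows) + 1L]] <- list(
        context = ctx,
        data_class = if (meas == "OUT") "InputOutput" else "InputIntermediate",
        measured_node = meas, perturbations = list(perturbation("stimulus", ctx)))
    }
    for (kd in non_input) {
      for (meas in setdiff(non_input, kd)) {
        rows[[length(rows) + 1L]] <- list(
          context = ctx, data_class = "IntermediateInhibition",
          measured_node = meas,
          perturbations = list(perturbation("stimulus", ctx),
                               perturbation("knockdown", kd)))
      }
    }
  }
  df <- data.frame(
    record_id = sprintf("rec%04d", seq_along(rows)),
    context = vapply(rows, `[[`, character(1), "context"),
    data_class = vapply(rows, `[[`, character(1), "data_class"),
    measured_node = vapply(rows, `[[`, character(1), "measured_node"),
    observed = "nochange", source = "synthetic", type = "qualitative",
    stringsAsFactors = FALSE
  )
  df$perturbations <- I(lapply(rows, `[[`, "perturbations"))
  cache <- new.env(parent = emptyenv())
  df$observed <- vapply(seq_len(nrow(df)), function(i) {
    run_condition(full, params, df[i, , drop = FALSE], config, cache)$predicted
  }, character(1))
  records <- experiment_records(df)

  if (gate == "OR") {
    pruned_rxn <- full$reactions[full$reactions$id != "rC1",
                                 c("id", "rule", "W_R", "n", "EC50")]
    truth <- list(gate = "OR", source = "A", target = "C")
  } else {
    rx <- full$reactions[, c("id", "rule", "W_R", "n", "EC50")]
    rx$rule[rx$id == "rD"] <- "B => D"
    pruned_rxn <- rx
    truth <- list(gate = "AND", source = "A", target = "rD")
  }
  pruned <- network_model(full$nodes[, c("id", "name", "role", "Ymax", "Y0", "tau")],
                          pruned_rxn)
  list(model = pruned, full_model = full, records = records, truth = truth)
}
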