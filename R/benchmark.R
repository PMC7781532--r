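#' Synthetic network at the cardiac-hypertrophy network's dimensions
#'
#' Generates a random signed interaction graph with the same dimensions as
#' the published prior-knowledge cardiac hypertrophy network: 106 nodes, 191
#' reactions, 17 receptor inputs (hence 174 intermediate reactions) and 7
#' output nodes. This is a synthetic stand-in used for structural and
#' enumeration checks, not a curated biological network: topology is random
#' (each non-input node gets one incoming edge from an earlier node to keep
#' every node reachable, then extra edges are sprinkled uniformly).
#'
#' @param n_nodes,n_reactions,n_inputs,n_outputs dimensions; defaults are the
#'   published network's.
#' @param inhibitor_fraction fraction of intermediate edges drawn inhibiting.
#' @param seed RNG seed.
#' @return a [network_model()].
#' @export
make_benchmark_network <- function(n_nodes = 106, n_reactions = 191,
                                   n_inputs = 17, n_outputs = 7,
                                   inhibitor_fraction = 0.2, seed = 1) {
  n_inter_nodes <- n_nodes - n_inputs
  n_inter_rxn <- n_reactions - n_inputs
  if (n_inter_nodes < 1 || n_inter_rxn < n_inter_nodes) {
    stop("infeasible dimensions: need one incoming reaction per non-input node",
         call. = FALSE)
  }
  with_seed(seed, {
    inputs <- sprintf("I%02d", seq_len(n_inputs))
    others <- sprintf("N%03d", seq_len(n_inter_nodes))
    ids <- c(inputs, others)
    roles <- c(rep("input", n_inputs),
               rep("intermediate", n_inter_nodes - n_outputs),
               rep("output", n_outputs))
    rules <- paste("=>", inputs)
    # backbone: node k draws its source among nodes 1..k-1 (reachability)
    for (k in seq_along(others)) {
      pool <- ids[seq_len(n_inputs + k - 1L)]
      src <- sample(pool, 1)
      if (stats::runif(1) < inhibitor_fraction) src <- paste0("!", src)
      rules <- c(rules, paste(src, "=>", others[k]))
    }
    extra <- n_inter_rxn - length(others)
    for (e in seq_len(extra)) {
      tgt <- sample(others, 1)
      src <- sample(setdiff(ids, tgt), sample(1:2, 1, prob = c(0.8, 0.2)))
      src <- vapply(src, function(s) {
        if (stats::runif(1) < inhibitor_fraction) paste0("!", s) else s
      }, character(1))
      rules <- c(rules, paste(paste(src, collapse = " & "), "=>", tgt))
    }
    network_model(
      nodes = data.frame(id = ids, role = roles),
      reactions = data.frame(id = sprintf("r%03d", seq_along(rules)),
                             rule = rules)
    )
  })
}

#' Synthetic experiment tables at the published compendium's dimensions
#'
#' Generates the structural shape of the curated data compendium: 450
#' qualitative records spread over six agonist contexts with 75 records per
#' context (the four studied contexts ISO, PE, AngII and Stretch among
#' them), and 100 semi-quantitative ISO-specific records. Observed labels
#' are sampled at random (this generator is a synthetic structural stand-in
#' for parsing/counting checks; use [make_records()] when observations must
#' be simulation-consistent).
#'
#' @param model a [network_model()] whose first six inputs serve as contexts.
#' @param n_per_context qualitative records per context.
#' @param n_semiquant semi-quantitative records (first context).
#' @param seed RNG seed.
#' @return list with `qualitative` and `semiquant` `experiment_records`.
#' @export
make_benchmark_records <- function(model, n_per_context = 75,
                                   n_semiquant = 100, seed = 1) {
  input_nodes <- model$reactions$target[model$reactions$is_input]
  if (length(input_nodes) < 6) stop("model needs >= 6 receptor inputs", call. = FALSE)
  contexts <- stats::setNames(input_nodes[1:6],
                              c("ISO", "PE", "AngII", "Stretch", "ET1", "IGF1"))
  non_input <- model$nodes$id[model$nodes$role != "input"]
  outputs <- model$nodes$id[model$nodes$role == "output"]
  inter <- setdiff(non_input, outputs)
  # per-context class frequencies echo the compendium's relative class sizes
  class_n <- c(InputOutput = 8, InputIntermediate = 30,
               IntermediateInhibition = 27, IntermediateOverexpression = 10)
  class_n <- round(class_n * n_per_context / sum(class_n))
  class_n[1] <- class_n[1] + (n_per_context - sum(class_n))

  with_seed(seed, {
    rows <- list()
    for (cx in names(contexts)) {
      stim <- contexts[[cx]]
      for (cls in names(class_n)) {
        for (i in seq_len(class_n[[cls]])) {
          meas <- switch(cls, InputOutput = sample(outputs, 1),
                         sample(inter, 1))
          pert <- switch(cls,
            InputOutput = ,
            InputIntermediate = sprintf("stim:%s", stim),
            IntermediateInhibition = sprintf("stim:%s;inhib:%s", stim,
                                             sample(setdiff(non_input, meas), 1)),
            IntermediateOverexpression = sprintf("oex:%s",
                                                 sample(setdiff(non_input, meas), 1)))
          rows[[length(rows) + 1L]] <- data.frame(
            context = cx, data_class = cls, perturbations = pert,
            measured_node = meas,
            observed = sample(c("increase", "decrease", "nochange"), 1,
                              prob = c(0.5, 0.3, 0.2)),
            stringsAsFactors = FALSE)
        }
      }
    }
    qual <- do.call(rbind, rows)
    qual <- cbind(record_id = sprintf("q%03d", seq_len(nrow(qual))), qual,
                  source = "synthetic")

    semi <- data.frame(
      record_id = sprintf("s%03d", seq_len(n_semiquant)),
      context = "ISO",
      data_class = sample(c("InputOutput", "InputIntermediate"), n_semiquant,
                          replace = TRUE, prob = c(0.3, 0.7)),
      perturbations = sprintf("stim:%s", contexts[["ISO"]]),
      measured_node = sample(non_input, n_semiquant, replace = TRUE),
      observed = sample(.fold_categories, n_semiquant, replace = TRUE),
      source = "synthetic", stringsAsFactors = FALSE)

    list(qualitative = experiment_records(qual),
         semiquant = experiment_records(semi))
  })
}
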