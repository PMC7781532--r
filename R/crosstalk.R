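#' Enumerate candidate OR-gate crosstalk edges
#'
#' One candidate per ordered node pair (source, target), self-pairs
#' included: a new single-reactant activating reaction `source => target`,
#' OR-combined with the target's existing reactions. The count is exactly
#' N^2 for N nodes (22,236 would be N^2 for a 106-node network: 11,236).
#' Inhibiting candidates (`!source => target`) can be added behind a flag,
#' doubling the candidate space.
#'
#' @param model a [network_model()].
#' @param include_inhibiting also enumerate inhibiting edges.
#' @return data.frame of candidates: `gate`, `source`, `target`, `sign`.
#' @export
enumerate_or_candidates <- function(model, include_inhibiting = FALSE) {
  ids <- model$nodes$id
  g <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(gate = "OR", source = g$source, target = g$target,
                    sign = "activating", stringsAsFactors = FALSE)
  if (include_inhibiting) {
    inh <- out
    inh$sign <- "inhibiting"
    out <- rbind(out, inh)
  }
  out
}

#' Enumerate candidate AND-gate crosstalk additions
#'
#' One candidate per (node, intermediate reaction) pair: the node joins that
#' reaction's AND as an extra activating reactant. The count is exactly
#' N * R_int (106 nodes x 174 intermediate reactions = 18,444).
#'
#' @inheritParams enumerate_or_candidates
#' @return data.frame of candidates: `gate`, `source`, `target` (reaction
#'   id), `sign`.
#' @export
enumerate_and_candidates <- function(model, include_inhibiting = FALSE) {
  ids <- model$nodes$id
  rxn <- intermediate_reactions(model)
  if (!length(rxn)) {
    return(data.frame(gate = character(), source = character(),
                      target = character(), sign = character()))
  }
  g <- expand.grid(source = ids, target = rxn, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(gate = "AND", source = g$source, target = g$target,
                    sign = "activating", stringsAsFactors = FALSE)
  if (include_inhibiting) {
    inh <- out
    inh$sign <- "inhibiting"
    out <- rbind(out, inh)
  }
  out
}

candidate_is_duplicate <- function(model, cand) {
  if (cand$gate == "OR") {
    any(vapply(seq_len(nrow(model$reactions)), function(i) {
      re <- model$reactions$reactants[[i]]
      model$reactions$target[i] == cand$target && nrow(re) == 1L &&
        re$node == cand$source &&
        re$sign == cand$sign
    }, logical(1)))
  } else {
    re <- model$reactions$reactants[[which(model$reactions$id == cand$target)]]
    cand$source %in% re$node
  }
}

#' Apply a crosstalk candidate to a model
#'
#' Returns a revised model with the edge permanently added: OR candidates
#' append a new single-reactant reaction (`source => target`); AND
#' candidates splice the source node into the target reaction's AND rule.
#' The rewritten rule strings round-trip through [write_network()] /
#' [read_network()]. New edges inherit default reaction parameters.
#'
#' @param model a [network_model()].
#' @param candidate one-row data.frame (or list) with `gate`, `source`,
#'   `target`, `sign`.
#' @param allow_duplicate insert even when an equivalent edge exists.
#' @return revised [network_model()].
#' @export
apply_candidate <- function(model, candidate, allow_duplicate = FALSE) {
  cand <- as.list(as.data.frame(candidate)[1, ])
  dup <- candidate_is_duplicate(model, cand)
  if (dup && !allow_duplicate) {
    stop(sprintf("candidate %s -> %s duplicates an existing edge", cand$source,
                 cand$target), call. = FALSE)
  }
  # a node cannot appear twice in one AND rule; re-adding it is a no-op
  if (dup && cand$gate == "AND") return(model)
  rx <- model$reactions[, c("id", "rule", "W_R", "n", "EC50")]
  mark <- if (identical(cand$sign, "inhibiting")) "!" else ""
  if (cand$gate == "OR") {
    if (!cand$target %in% model$nodes$id) {
      stop("OR candidate target must be a node: ", cand$target, call. = FALSE)
    }
    new_id <- make.unique(c(rx$id, paste0("xt_", cand$source, "_", cand$target)))
    new_id <- new_id[length(new_id)]
    rx <- rbind(rx, data.frame(id = new_id,
                               rule = paste0(mark, cand$source, " => ", cand$target),
                               W_R = NA_real_, n = NA_real_, EC50 = NA_real_))
  } else {
    j <- which(rx$id == cand$target)
    if (!length(j)) stop("AND candidate target must be a reaction: ",
                         cand$target, call. = FALSE)
    if (model$reactions$is_input[j]) {
      stop("AND candidates attach to intermediate reactions only", call. = FALSE)
    }
    parts <- strsplit(rx$rule[j], "=>", fixed = TRUE)[[1]]
    rx$rule[j] <- paste0(trimws(parts[1]), " & ", mark, cand$source, " => ",
                         trimws(parts[2]))
  }
  network_model(model$nodes[, c("id", "name", "role", "Ymax", "Y0", "tau")], rx)
}

#' Screen crosstalk candidates by re-validation
#'
#' For each candidate the model is cloned, the edge inserted (duplicates are
#' evaluated normally but flagged), and the records re-validated; the
#' candidate's score is the change in validation percent together with the
#' counts of records flipped wrong-to-right (`corrected`) and right-to-wrong
#' (`broken`). Candidates are ranked by `delta` descending, ties broken by
#' `corrected` descending then (source, target) lexicographically. The input
#' model is never modified.
#'
#' @param model a [network_model()].
#' @param params a [param_set()].
#' @param records `experiment_records` of the screened context.
#' @param candidates data.frame from the enumerators (default: both gates).
#' @param config a [hillnet_config()].
#' @return object of class `crosstalk_screen`: `candidates` (ranked, with
#'   `delta`, `corrected`, `broken`, `duplicate`), `summary` (per-gate
#'   fractions of candidates that decreased / increased / left unchanged the
#'   validation percent, and the fraction improving more than one record),
#'   `baseline_percent`.
#' @export
screen_crosstalks <- function(model, params, records,
                              candidates = rbind(enumerate_or_candidates(model),
                                                 enumerate_and_candidates(model)),
                              config = hillnet_config()) {
  base <- validate_model(model, params, records, config)
  base_match <- stats::setNames(base$outcomes$match, base$outcomes$record_id)
  n_rec <- sum(base$outcomes$resolved)

  res <- candidates
  res$delta <- NA_real_
  res$corrected <- NA_integer_
  res$broken <- NA_integer_
  res$duplicate <- FALSE
  for (i in seq_len(nrow(res))) {
    cand <- res[i, ]
    res$duplicate[i] <- candidate_is_duplicate(model, as.list(cand))
    revised <- apply_candidate(model, cand, allow_duplicate = TRUE)
    rep_i <- validate_model(revised, params, records, config)
    m <- stats::setNames(rep_i$outcomes$match, rep_i$outcomes$record_id)
    m <- m[names(base_match)]
    res$corrected[i] <- sum(!base_match & m)
    res$broken[i] <- sum(base_match & !m)
    res$delta[i] <- rep_i$validation_percent - base$validation_percent
  }
  res <- res[order(-res$delta, -res$corrected, res$source, res$target), ]
  rownames(res) <- NULL

  summ <- do.call(rbind, lapply(split(res, res$gate), function(d) {
    data.frame(gate = d$gate[1], n = nrow(d),
               frac_decreased = mean(d$delta < 0),
               frac_increased = mean(d$delta > 0),
               frac_unchanged = mean(d$delta == 0),
               frac_improving_gt1 = mean(d$corrected - d$broken > 1))
  }))
  rownames(summ) <- NULL
  structure(list(candidates = res, summary = summ,
                 baseline_percent = base$validation_percent, n_records = n_rec),
            class = "crosstalk_screen")
}

#' @export
print.crosstalk_screen <- function(x, ...) {
  cat(sprintf("<crosstalk_screen> %d candidates, baseline %.1f%%\n",
              nrow(x$candidates), x$baseline_percent))
  print(utils::head(x$candidates, 5), row.names = FALSE)
  invisible(x)
}
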