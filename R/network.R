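#' Construct a signaling network model
#'
#' A `network_model` bundles the species sheet and the reactions sheet of a
#' Netflux-style interaction graph. Reactants within one reaction combine by
#' AND; all reactions targeting one node combine by OR. Per-element parameter
#' columns may be `NA`, meaning "use the default from the active parameter
#' set".
#'
#' @param nodes data.frame with columns `id`, `name`, `role`
#'   (`input`/`intermediate`/`output`) and optional `Ymax`, `Y0`, `tau`.
#' @param reactions data.frame with columns `id`, `rule` and optional `W_R`,
#'   `n`, `EC50`. Rules are parsed with [parse_rule()].
#' @return object of class `network_model` with components `nodes` and
#'   `reactions` (the latter carrying parsed `target`, `is_input` and a
#'   `reactants` list column).
#' @examples
#' m <- network_model(
#'   nodes = data.frame(id = c("A", "B"), role = c("input", "output")),
#'   reactions = data.frame(id = c("r1", "r2"), rule = c("=> A", "A => B"))
#' )
#' summary(m)
#' @export
network_model <- function(nodes, reactions) {
  stopifnot(is.data.frame(nodes), is.data.frame(reactions))
  if (nrow(nodes) == 0L || nrow(reactions) == 0L) {
    stop("a network model needs at least one node and one reaction", call. = FALSE)
  }
  nodes$id <- trimws(as.character(nodes$id))
  if (is.null(nodes$name)) nodes$name <- nodes$id
  if (is.null(nodes$role)) nodes$role <- "intermediate"
  for (p in c("Ymax", "Y0", "tau")) {
    nodes[[p]] <- if (is.null(nodes[[p]])) NA_real_ else as.numeric(nodes[[p]])
  }
  nodes <- nodes[, c("id", "name", "role", "Ymax", "Y0", "tau")]

  reactions$id <- trimws(as.character(reactions$id))
  reactions$rule <- as.character(reactions$rule)
  for (p in c("W_R", "n", "EC50")) {
    reactions[[p]] <- if (is.null(reactions[[p]])) NA_real_ else as.numeric(reactions[[p]])
  }
  parsed <- lapply(seq_len(nrow(reactions)), function(i) {
    tryCatch(parse_rule(reactions$rule[i]),
             error = function(e) stop(sprintf("reaction '%s' (row %d): %s",
                                              reactions$id[i], i, conditionMessage(e)),
                                      call. = FALSE))
  })
  reactions$target <- vapply(parsed, `[[`, character(1), "target")
  reactions$is_input <- vapply(parsed, `[[`, logical(1), "is_input")
  reactions$rule <- vapply(seq_along(parsed), function(i) {
    format_rule(parsed[[i]]$reactants, parsed[[i]]$target)
  }, character(1))
  reactions <- reactions[, c("id", "rule", "target", "is_input", "W_R", "n", "EC50")]
  reactions$reactants <- I(lapply(parsed, `[[`, "reactants"))

  model <- structure(list(nodes = nodes, reactions = reactions),
                     class = "network_model")
  check_network_model(model)
  model
}

check_network_model <- function(model) {
  nodes <- model$nodes
  rxn <- model$reactions
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ", paste(unique(nodes$id[duplicated(nodes$id)]),
                                       collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(nodes$id))) stop("empty node id", call. = FALSE)
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction ids: ", paste(unique(rxn$id[duplicated(rxn$id)]),
                                           collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(rxn$target, nodes$id)
  if (length(bad)) {
    rows <- which(rxn$target %in% bad)
    stop(sprintf("rule targets undeclared node(s) %s (reaction row(s) %s)",
                 paste(bad, collapse = ", "), paste(rows, collapse = ", ")),
         call. = FALSE)
  }
  for (i in seq_len(nrow(rxn))) {
    miss <- setdiff(rxn$reactants[[i]]$node, nodes$id)
    if (length(miss)) {
      stop(sprintf("rule '%s' (row %d) references undeclared node(s): %s",
                   rxn$rule[i], i, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  ok <- is.na(nodes$Ymax) | nodes$Ymax >= 0
  if (any(!ok)) stop("Ymax must be >= 0", call. = FALSE)
  both <- !is.na(nodes$Y0) & !is.na(nodes$Ymax)
  if (any(nodes$Y0[both] < 0 | nodes$Y0[both] > nodes$Ymax[both])) {
    stop("Y0 must lie in [0, Ymax]", call. = FALSE)
  }
  if (any(!is.na(nodes$tau) & nodes$tau <= 0)) stop("tau must be > 0", call. = FALSE)
  orphan <- setdiff(nodes$id[nodes$role != "input"], rxn$target)
  if (length(orphan)) {
    stop("node(s) neither declared input nor targeted by any reaction: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d nodes, %d reactions (%d inputs, %d intermediate)\n",
              nrow(x$nodes), nrow(x$reactions), sum(x$reactions$is_input),
              sum(!x$reactions$is_input)))
  invisible(x)
}

#' @export
summary.network_model <- function(object, ...) {
  c(nodes = nrow(object$nodes),
    reactions = nrow(object$reactions),
    inputs = sum(object$reactions$is_input),
    intermediate = sum(!object$reactions$is_input))
}

#' Ids of the intermediate (non-input) reactions
#'
#' @param model a [network_model()].
#' @return character vector of reaction ids.
#' @export
intermediate_reactions <- function(model) {
  model$reactions$id[!model$reactions$is_input]
}

#' Ids of the receptor input reactions
#'
#' @param model a [network_model()].
#' @return character vector of reaction ids.
#' @export
input_reactions <- function(model) {
  model$reactions$id[model$reactions$is_input]
}
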