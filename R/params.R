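#' Default parameter set
#'
#' Eight default parameters regulate node activity: the reaction-specific
#' Hill parameters `EC50` and `n` and reaction weight `W_R`; the input
#' weights `W_i` (baseline activity of all receptor inputs at rest) and `W_e`
#' (elevated activity of a stimulated input); and the node parameters `Ymax`
#' (maximum activity), `Y0` (initial activity) and `tau` (time constant).
#' The shipped defaults (`W_R = 1`, `n = 1.4`, `EC50 = 0.5`, `W_i = 0`,
#' `W_e = 1`, `Ymax = 1`, `Y0 = 0`, `tau = 1`) are the published defaults of
#' the beta-adrenergic normalized-Hill signaling model from which this model
#' family descends. Any default can be overridden globally or per element.
#'
#' @param ... named default replacements, e.g. `n = 2, W_i = 0.1`.
#' @param overrides data.frame with columns `element`, `param`, `value` for
#'   sparse per-element overrides (element = node or reaction id).
#' @return object of class `param_set`.
#' @examples
#' p <- param_set(n = 2, W_i = 0.1)
#' p <- set_override(p, "r3", "EC50", 0.4)
#' @export
param_set <- function(..., overrides = NULL) {
  defaults <- list(EC50 = 0.5, n = 1.4, W_R = 1, W_i = 0, W_e = 1,
                   Ymax = 1, Y0 = 0, tau = 1)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(defaults))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    defaults[names(dots)] <- dots
  }
  if (is.null(overrides)) {
    overrides <- data.frame(element = character(), param = character(),
                            value = numeric(), stringsAsFactors = FALSE)
  }
  ps <- structure(list(defaults = defaults, overrides = overrides),
                  class = "param_set")
  check_param_set(ps)
  ps
}

check_param_set <- function(ps) {
  d <- ps$defaults
  if (d$W_R < 0 || d$W_R > 1 || d$W_i < 0 || d$W_i > 1 || d$W_e < 0 || d$W_e > 1) {
    stop("weights W_R, W_i, W_e must lie in [0, 1]", call. = FALSE)
  }
  if (d$n < 1) stop("Hill coefficient n must be >= 1", call. = FALSE)
  if (d$Ymax < 0) stop("Ymax must be >= 0", call. = FALSE)
  if (d$tau <= 0) stop("tau must be > 0", call. = FALSE)
  hill_constants(d$n, d$EC50)  # errors on invalid (n, EC50)
  invisible(ps)
}

#' Add or replace a per-element parameter override
#'
#' @param ps a [param_set()].
#' @param element node or reaction id.
#' @param param parameter name.
#' @param value numeric value.
#' @return updated `param_set`.
#' @export
set_override <- function(ps, element, param, value) {
  stopifnot(inherits(ps, "param_set"))
  ov <- ps$overrides
  hit <- ov$element == element & ov$param == param
  if (any(hit)) {
    ov$value[hit] <- value
  } else {
    ov <- rbind(ov, data.frame(element = element, param = param, value = value,
                               stringsAsFactors = FALSE))
  }
  ps$overrides <- ov
  ps
}

param_lookup <- function(ps, element, param, model_value = NA_real_) {
  ov <- ps$overrides
  hit <- which(ov$element == element & ov$param == param)
  if (length(hit)) return(ov$value[hit[1]])
  if (!is.na(model_value)) return(model_value)
  ps$defaults[[param]]
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set> defaults:",
      paste(sprintf("%s=%g", names(x$defaults), unlist(x$defaults)),
            collapse = ", "), "\n")
  if (nrow(x$overrides)) {
    cat(sprintf("  %d per-element override(s)\n", nrow(x$overrides)))
  }
  invisible(x)
}

#' Construct a perturbation
#'
#' Perturbation semantics mirror the wet-lab operations the experiment
#' records encode: `stimulus` raises one receptor input's weight from `W_i`
#' to `W_e` (or an explicit value); `knockdown` sets the node's `Ymax` to 0;
#' `overexpression` pins the node at `Ymax` (a clamp contractually equivalent
#' to setting `Y0 = Ymax` with a very large `tau`); `reaction_deletion` sets
#' a reaction's `W_R` to 0; `reaction_weight` sets it to `value`.
#'
#' @param kind one of `stimulus`, `knockdown`, `overexpression`,
#'   `reaction_deletion`, `reaction_weight`.
#' @param target node id (stimulus/knockdown/overexpression) or reaction id.
#' @param value optional numeric weight.
#' @return list of class `perturbation`.
#' @export
perturbation <- function(kind, target, value = NA_real_) {
  kind <- match.arg(kind, c("stimulus", "knockdown", "overexpression",
                            "reaction_deletion", "reaction_weight"))
  structure(list(kind = kind, target = target, value = as.numeric(value)),
            class = "perturbation")
}
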