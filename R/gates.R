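#' Normalized-Hill transfer function constants
#'
#' The normalized-Hill activation function is a standard Hill curve rescaled
#' so that `f(0) = 0`, `f(1) = 1` and `f(EC50) = 0.5` on the normalized
#' activity interval \[0, 1\]. The rescaling is achieved with two derived
#' constants:
#' \deqn{B = \frac{EC_{50}^n - 1}{2\,EC_{50}^n - 1}, \qquad K = (B - 1)^{1/n}}
#' which are finite and positive whenever `EC50^n != 0.5`.
#'
#' @param n Hill coefficient, `n >= 1`.
#' @param EC50 half-maximal activation, in (0, 1).
#' @param eps guard half-width around the singular point `EC50^n = 0.5`.
#' @return list with components `B` and `K`.
#' @examples
#' hc <- hill_constants(1.4, 0.5)
#' hill_activation(0.5, 1.4, 0.5)  # 0.5 by construction
#' @export
hill_constants <- function(n, EC50, eps = 1e-9) {
  stopifnot(is.numeric(n), is.numeric(EC50))
  if (any(n < 1)) stop("Hill coefficient n must be >= 1", call. = FALSE)
  if (any(EC50 <= 0 | EC50 >= 1)) {
    stop("EC50 must lie strictly inside (0, 1)", call. = FALSE)
  }
  en <- EC50^n
  if (any(abs(2 * en - 1) < 2 * eps)) {
    stop("invalid Hill parameters: EC50^n too close to 0.5 (singular gain B)",
         call. = FALSE)
  }
  B <- (en - 1) / (2 * en - 1)
  K <- (B - 1)^(1 / n)
  list(B = B, K = K)
}

#' Normalized-Hill activation
#'
#' `f_act(x) = B x^n / (K^n + x^n)` with `B`, `K` from [hill_constants()].
#' Monotone non-decreasing on \[0, 1\] with `f(0) = 0`, `f(1) = 1`,
#' `f(EC50) = 0.5`. Arguments outside \[0, 1\] are clamped before
#' evaluation so that solver overshoot cannot propagate out-of-range
#' activities.
#'
#' @param x activity in \[0, 1\] (vectorized).
#' @inheritParams hill_constants
#' @return activity in \[0, 1\].
#' @export
hill_activation <- function(x, n, EC50) {
  hc <- hill_constants(n, EC50)
  x <- pmin(pmax(x, 0), 1)
  hc$B * x^n / (hc$K^n + x^n)
}

#' Weighted activator term of a reaction
#'
#' Contribution of one activating reactant: `W_R * f_act(x)`. A reaction
#' weight of zero silences the reaction (deletion).
#'
#' @param x reactant activity in \[0, 1\].
#' @param W_R reaction weight in \[0, 1\].
#' @inheritParams hill_constants
#' @export
activator_term <- function(x, W_R, n, EC50) {
  W_R * hill_activation(x, n, EC50)
}

#' Weighted inhibitor term of a reaction
#'
#' Contribution of one inhibiting reactant, `1 - W_R * f_act(x)`. This form
#' guarantees two properties the original normalized-Hill inhibition lacked:
#' decreasing the weight of an inhibition reaction increases the activity of
#' its downstream effectors, and `W_R = 0` removes the inhibition entirely so
#' that a deleted inhibitory reaction returns its target to the un-inhibited
#' baseline.
#'
#' @inheritParams activator_term
#' @export
inhibitor_term <- function(x, W_R, n, EC50) {
  1 - W_R * hill_activation(x, n, EC50)
}

#' Mean-normalized AND gate
#'
#' Combines the reactant terms of one reaction. The plain product of m terms
#' shrinks with m, so the product is divided by the mean of the terms raised
#' to the power m - 1:
#' \deqn{AND(t_1,\dots,t_m) = \frac{\prod_i t_i}{\bar t^{\,m-1}}}
#' which equalizes the order of magnitude of output and inputs: the gate is
#' the identity for a single term and maps equal inputs to themselves,
#' `AND(x, ..., x) = x`. A zero mean (all terms zero) returns 0.
#'
#' @param terms numeric vector of activities in \[0, 1\], length >= 1.
#' @return single activity value.
#' @export
and_gate <- function(terms) {
  if (length(terms) == 0L) stop("AND gate needs at least one term", call. = FALSE)
  m <- length(terms)
  if (m == 1L) return(terms)
  mu <- mean(terms)
  if (mu == 0) return(0)
  prod(terms) / mu^(m - 1L)
}

#' Noisy-OR gate
#'
#' Combines the contributions of all reactions targeting one node:
#' `OR(t_1, ..., t_k) = 1 - prod(1 - t_i)`. Commutative, monotone in each
#' argument, identity for a single term, absorbing at 1; an empty term list
#' yields 0 (no production).
#'
#' @param terms numeric vector of activities in \[0, 1\] (possibly empty).
#' @return single activity value.
#' @export
or_gate <- function(terms) {
  if (length(terms) == 0L) return(0)
  1 - prod(1 - terms)
}
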