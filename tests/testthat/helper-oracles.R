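# Independent oracles, written from the defining formulas (not via the
# package's engine), used to cross-check simulation results.

# normalized-Hill activation, straight from the definition
oracle_fact <- function(x, n, ec50) {
  B <- (ec50^n - 1) / (2 * ec50^n - 1)
  K <- (B - 1)^(1 / n)
  B * x^n / (K^n + x^n)
}

# resolve one parameter for an element: override > model value > default
oracle_param <- function(params, element, name, model_value = NA_real_) {
  ov <- params$overrides
  hit <- which(ov$element == element & ov$param == name)
  if (length(hit)) return(ov$value[hit[1]])
  if (!is.na(model_value)) return(model_value)
  params$defaults[[name]]
}

# production term F_i(y) for every node, evaluated directly from the rules
oracle_F <- function(model, params, y, stimulated = character()) {
  d <- params$defaults
  vapply(model$nodes$id, function(nid) {
    rows <- which(model$reactions$target == nid)
    if (!length(rows)) return(0)
    terms <- vapply(rows, function(j) {
      rj <- model$reactions[j, ]
      if (rj$is_input) {
        return(if (nid %in% stimulated) oracle_param(params, rj$id, "W_e")
               else oracle_param(params, rj$id, "W_i"))
      }
      W <- oracle_param(params, rj$id, "W_R", rj$W_R)
      n <- oracle_param(params, rj$id, "n", rj$n)
      e <- oracle_param(params, rj$id, "EC50", rj$EC50)
      re <- model$reactions$reactants[[j]]
      tt <- vapply(seq_len(nrow(re)), function(q) {
        f <- oracle_fact(min(max(y[[re$node[q]]], 0), 1), n, e)
        if (re$sign[q] == "inhibiting") 1 - W * f else W * f
      }, numeric(1))
      if (length(tt) == 1L) tt else prod(tt) / mean(tt)^(length(tt) - 1L)
    }, numeric(1))
    1 - prod(1 - terms)
  }, numeric(1))
}

# damped fixed-point iteration y <- Ymax * F(y) (tau-free steady state)
oracle_fixed_point <- function(model, params, stimulated = character(),
                               damping = 0.5, tol = 1e-12, iters = 20000) {
  ymax <- vapply(model$nodes$id, function(nid) {
    oracle_param(params, nid, "Ymax",
                 model$nodes$Ymax[model$nodes$id == nid])
  }, numeric(1))
  y <- setNames(rep(0, nrow(model$nodes)), model$nodes$id)
  for (it in seq_len(iters)) {
    target <- ymax * oracle_F(model, params, y, stimulated)
    if (max(abs(target - y)) < tol) return(y)
    y <- (1 - damping) * y + damping * target
  }
  y
}

# topological-order evaluation for acyclic networks: exact steady state
oracle_topo_steady_state <- function(model, params, stimulated = character()) {
  ids <- model$nodes$id
  dep <- lapply(ids, function(nid) {
    rows <- which(model$reactions$target == nid & !model$reactions$is_input)
    unique(unlist(lapply(rows, function(j) model$reactions$reactants[[j]]$node)))
  })
  names(dep) <- ids
  ymax <- vapply(ids, function(nid) {
    oracle_param(params, nid, "Ymax", model$nodes$Ymax[model$nodes$id == nid])
  }, numeric(1))
  y <- setNames(rep(NA_real_, length(ids)), ids)
  done <- character()
  while (length(done) < length(ids)) {
    ready <- ids[!ids %in% done &
                   vapply(ids, function(n) all(dep[[n]] %in% done), logical(1))]
    if (!length(ready)) stop("network is not acyclic")
    for (nid in ready) {
      yy <- ifelse(is.na(y), 0, y)
      y[nid] <- ymax[nid] * oracle_F(model, params, as.list(yy), stimulated)[nid]
    }
    done <- c(done, ready)
  }
  y
}

# closed-form variance decomposition of the Ishigami function
ishigami <- function(X, a = 7, b = 0.1) {
  x <- -pi + 2 * pi * X  # scale [0,1]^3 onto [-pi,pi]^3
  sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1])
}

ishigami_indices <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- V1 + V2 + V13
  list(S1 = V1 / V, S2 = V2 / V, S3 = 0,
       T1 = (V1 + V13) / V, T2 = V2 / V, T3 = V13 / V, V = V)
}
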