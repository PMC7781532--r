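test_that("deletion scan matches hand-counted deltas on a cascade", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 4))
  p <- param_set(W_i = 0)
  # one stimulus record per downstream node, all observed increase
  df <- data.frame(record_id = paste0("r", 2:4), context = "N1",
                   data_class = "InputIntermediate",
                   perturbations = "stim:N1",
                   measured_node = c("N2", "N3", "N4"), observed = "increase")
  rec <- experiment_records(df)
  ds <- deletion_scan(m, p, rec)
  # deleting r2 (N1 => N2) silences every record; r3 spares N2; r4 spares N2, N3
  expect_equal(unname(ds$delta[, "N1"]),
               c(-100, -2 / 3 * 100, -1 / 3 * 100),
               tolerance = 1e-9)
  expect_true(all(ds$category == "direct"))
})

test_that("reactions with no path to measured nodes score zero", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  p <- param_set(W_i = 0.1)
  df <- data.frame(record_id = "d1", context = "IN1",
                   data_class = "InputIntermediate", perturbations = "stim:IN1",
                   measured_node = "D", observed = "nochange")
  ds <- deletion_scan(m, p, experiment_records(df))
  # the E-branch reactions cannot reach measured node D
  expect_equal(unname(ds$delta["rE", ]), 0)
  expect_equal(unname(ds$delta["rO2", ]), 0)
  expect_equal(unname(ds$category[["rE"]]), "non_sensitive")
})

test_that("deletion via weight zero equals physical removal in the scan", {
  rc <- make_recovery_case(gate = "OR")   # full model + rich record set
  m <- rc$full_model
  p <- param_set(W_i = 0.05)
  ds <- deletion_scan(m, p, rc$records, reactions = "rC1")
  m2 <- network_model(m$nodes, m$reactions[m$reactions$id != "rC1",
                                           c("id", "rule", "W_R", "n", "EC50")])
  for (cx in colnames(ds$delta)) {
    sub <- rc$records[rc$records$context == cx, , drop = FALSE]
    base <- validate_model(m, p, sub)$validation_percent
    removed <- validate_model(m2, p, sub)$validation_percent
    expect_equal(unname(ds$delta["rC1", cx]), removed - base, tolerance = 1e-9)
  }
})

test_that("shared versus direct categories follow per-context sensitivity", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  p <- param_set(W_i = 0)
  df <- data.frame(
    record_id = c("a", "b", "c"),
    context = c("IN1", "IN2", "IN2"),
    data_class = "InputIntermediate",
    perturbations = c("stim:IN1", "stim:IN2", "stim:IN2"),
    measured_node = c("C", "C", "B"),
    observed = "increase")
  ds <- deletion_scan(m, p, experiment_records(df))
  expect_equal(unname(ds$category[["rA"]]), "direct")   # IN1 arm only
  expect_equal(unname(ds$category[["rB"]]), "direct")   # IN2 arm only
  # rC2 (B => C) matters only under IN2 here; rC1 only under IN1
  expect_equal(unname(ds$category[["rC1"]]), "direct")
})

test_that("Morris statistics vanish for a constant objective", {
  res <- morris_screen(function(x) 42, k = 3, trajectories = 4, oversample = 8,
                       seed = 1)
  expect_equal(res$factors$mu_star, rep(0, 3))
  expect_equal(res$factors$sigma, rep(0, 3))
  expect_false(any(res$factors$important))
})

test_that("Morris recovers analytic elementary effects of a linear function", {
  f <- function(x) 3 * x[1] - 1.5 * x[2]
  res <- morris_screen(f, k = 4, levels = 8, trajectories = 6, oversample = 20,
                       seed = 2)
  expect_equal(res$factors$mu_star, c(3, 1.5, 0, 0), tolerance = 1e-9)
  expect_equal(res$factors$mu[1:2], c(3, -1.5), tolerance = 1e-9)
  expect_equal(res$factors$sigma[1:2], c(0, 0), tolerance = 1e-9)
  expect_true(all(res$factors$monotonic[1:2]))
  # cost accounting: exactly trajectories * (k + 1) objective calls
  expect_equal(res$n_evals, 6 * 5)
  # mu* always dominates |mu|
  expect_true(all(res$factors$mu_star >= abs(res$factors$mu) - 1e-12))
})

test_that("important-factor selection is ranked, tie-broken and nested", {
  f <- function(x) 3 * x[1] + 2 * x[2] + 0.5 * x[3]
  res <- morris_screen(f, k = 3, trajectories = 4, oversample = 10, seed = 3)
  expect_equal(select_important(res, 1.0), c("x1", "x2"))
  expect_equal(select_important(res, 0), c("x1", "x2", "x3"))
  expect_length(select_important(res, 10), 0)
  s15 <- select_important(res, 1.5)
  s12 <- select_important(res, 1.2)
  expect_true(all(s15 %in% s12))
  expect_error(morris_screen(f, k = 3, trajectories = 20, oversample = 10),
               "oversample")
})

test_that("Jansen estimators are exact-in-expectation for a single factor", {
  res <- sobol_analysis(function(x) x[1], k = 1, N = 2048, seed = 1,
                        bootstrap_reps = 200, pairs = FALSE)
  expect_equal(res$first_order$S, 1, tolerance = 0.05)
  expect_equal(res$first_order$T, 1, tolerance = 0.05)
  expect_equal(res$n_evals, 2048 * 3)
})

test_that("an additive function has no second-order effect or synergy", {
  res <- sobol_analysis(function(x) x[1] + x[2], k = 2, N = 2048, seed = 4,
                        bootstrap_reps = 500)
  so <- res$second_order
  expect_true(so$S_ij_lo <= 0.02 & so$S_ij_hi >= -0.02)  # CI covers ~0
  expect_lt(abs(so$S_ij), 0.05)
  # the synergy ratio divides two Monte-Carlo zeros here; it must not blow up
  expect_lt(abs(so$synergy), 0.5)
  expect_equal(res$first_order$S, c(0.5, 0.5), tolerance = 0.07)
  expect_true(all(res$first_order$T >= res$first_order$S - 0.05))
})

test_that("a zero-variance objective is an explicit error", {
  expect_error(sobol_analysis(function(x) 1, k = 2, N = 64, seed = 1,
                              bootstrap_reps = 10),
               "zero variance")
})

test_that("Sobol results are reproducible under a fixed seed", {
  f <- function(x) x[1]^2 + 0.3 * x[2]
  r1 <- sobol_analysis(f, k = 2, N = 256, seed = 5, bootstrap_reps = 50)
  r2 <- sobol_analysis(f, k = 2, N = 256, seed = 5, bootstrap_reps = 50)
  expect_identical(r1$first_order, r2$first_order)
})

test_that("convergence check flags a deterministic linear objective quickly", {
  tab <- convergence_check(function(x) 2 * x[1] + x[2], k = 2,
                           N_grid = c(256, 512, 1024), seed = 2)
  expect_equal(nrow(tab), 3)
  expect_true(attr(tab, "converged"))
  expect_true(all(diff(tab$N) > 0))
})

test_that("the EC50 that drives the output ranks first by mu* and total index", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  p <- param_set(W_i = 0, W_e = 0.6)
  # under IN2 stimulation node C is driven through rC2; rB saturates upstream
  ospec <- objective_spec(m, p, factors = c("rB", "rC2"),
                          objective = "output_mean", stimulus = "IN2",
                          output_nodes = "C")
  mres <- morris_screen(ospec, trajectories = 4, oversample = 12, seed = 6)
  ranked <- mres$factors[order(-mres$factors$mu_star), "factor"]
  expect_equal(ranked[1], "rC2")
  sres <- sobol_analysis(ospec, N = 128, seed = 6, bootstrap_reps = 100)
  expect_gt(sres$first_order$T[sres$first_order$factor == "rC2"],
            sres$first_order$T[sres$first_order$factor == "rB"])
})

test_that("objective bounds straddling the EC50 singularity are rejected", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  p <- param_set(n = 1.4)
  sing <- 0.5^(1 / 1.4)
  expect_error(objective_spec(m, p, factors = "rA",
                              bounds = c(sing - 0.05, sing + 0.05),
                              objective = "output_mean", stimulus = "IN1"),
               "singular")
})
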