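fast_refine <- list(min_step_frac = 1/32, max_iter = 40)

test_that("multi-start estimation recovers a generator-consistent optimum", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  truth <- param_set(n = 2, W_R = 0.8, W_i = 0.1, W_e = 0.9)
  rec <- make_records(record_gen_spec(m, truth, contexts = "IN1",
                                      n_per_class = 3, seed = 5))
  expect_equal(validate_model(m, truth, rec)$validation_percent, 100)
  est <- estimate_defaults(m, rec, n_starts = 4, n_refine = 2, seed = 3,
                           refine_control = fast_refine)
  expect_equal(est$best_objective, 100)
  # the reported optimum reproduces its objective through validate()
  expect_equal(validate_model(m, est$best_params, rec)$validation_percent,
               est$best_objective)
  expect_equal(nrow(est$trace), 4)
})

test_that("a single start reduces to one local search from that start", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 4))
  rec <- make_records(record_gen_spec(m, param_set(W_i = 0.1), contexts = "N1",
                                      n_per_class = 3, seed = 1))
  est <- estimate_defaults(m, rec, n_starts = 1, n_refine = 1, seed = 9,
                           refine_control = fast_refine)
  expect_equal(nrow(est$trace), 1)
  expect_gte(est$best_objective, est$trace$start_objective[1])
})

test_that("estimation is reproducible and monotone in the number of starts", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 4))
  rec <- make_records(record_gen_spec(m, param_set(n = 3, W_i = 0.2),
                                      contexts = "N1", n_per_class = 3,
                                      seed = 2))
  e1 <- estimate_defaults(m, rec, n_starts = 2, n_refine = 2, seed = 7,
                          refine_control = fast_refine)
  e2 <- estimate_defaults(m, rec, n_starts = 2, n_refine = 2, seed = 7,
                          refine_control = fast_refine)
  expect_identical(e1$trace, e2$trace)
  expect_identical(e1$best_values, e2$best_values)
  # nested per-start seeds: more starts can only improve the best objective
  e4 <- estimate_defaults(m, rec, n_starts = 4, n_refine = 4, seed = 7,
                          refine_control = fast_refine)
  expect_equal(e4$trace$start_objective[1:2], e1$trace$start_objective)
  expect_gte(e4$best_objective, e1$best_objective)
})

test_that("multi-start search matches exhaustive grid search on a 2-parameter toy", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  truth <- param_set(W_i = 0.15, W_e = 0.8)
  rec <- make_records(record_gen_spec(m, truth, contexts = "IN1",
                                      n_per_class = 3, seed = 11))
  # only (W_i, W_e) free; n and W_R pinned at their defaults
  bounds <- list(n = c(1.4, 1.4), W_R = c(1, 1), W_i = c(0, 0.5),
                 W_e = c(0.5, 1))
  est <- estimate_defaults(m, rec, bounds = bounds, n_starts = 5, n_refine = 2,
                           seed = 4, refine_control = fast_refine)
  grid_best <- max(objective_landscape(
    m, rec, pair = c("W_i", "W_e"),
    grid = list(W_i = seq(0, 0.5, length.out = 9),
                W_e = seq(0.5, 1, length.out = 9))))
  expect_gte(est$best_objective, grid_best)
})

test_that("objective landscape is consistent with direct validation", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 4))
  p <- param_set(W_i = 0.1)
  rec <- make_records(record_gen_spec(m, p, contexts = "N1", n_per_class = 3,
                                      seed = 3))
  l11 <- objective_landscape(m, rec, pair = c("W_R", "n"),
                             grid = list(W_R = 1, n = 1.4), at = p)
  expect_equal(dim(l11), c(1, 1))
  expect_equal(l11[1, 1], validate_model(m, p, rec)$validation_percent)
  # cells on the transfer-function singularity are flagged, not skipped
  l <- objective_landscape(m, rec, pair = c("W_R", "n"),
                           grid = list(W_R = c(0.5, 1), n = c(1, 2)), at = p)
  expect_true(is.nan(l["0.5", "1"]))  # EC50 = 0.5 with n = 1 is singular
  expect_false(anyNA(l[, "2"]))
})

test_that("EC50 calibration recovers a mis-set reaction against mixed data", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  truth <- set_override(param_set(W_i = 0.1, W_e = 0.6), "rC2", "EC50", 0.25)
  q <- make_records(record_gen_spec(m, truth, contexts = "IN2",
                                    n_per_class = 3, seed = 6))
  s <- make_records(record_gen_spec(m, truth, contexts = "IN2",
                                    n_per_class = 3, type = "semiquant",
                                    seed = 7))
  s$record_id <- paste0("sq_", s$record_id)
  both <- rbind(q, s); class(both) <- class(q)
  start <- param_set(W_i = 0.1, W_e = 0.6)  # EC50 back at default 0.5
  truth_pct <- validate_combined(m, truth, both)$percent
  cal <- calibrate_ec50(m, start, "rC2", both, n_starts = 6, n_refine = 2,
                        seed = 2, refine_control = fast_refine)
  expect_gte(cal$best_objective,
             validate_combined(m, start, both)$percent)
  expect_equal(cal$best_objective, truth_pct)
  expect_equal(validate_combined(m, cal$best_params, both)$percent,
               cal$best_objective)
})

test_that("an empty calibration subset returns the input parameters unchanged", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 4))
  p <- param_set(W_i = 0.1)
  rec <- make_records(record_gen_spec(m, p, contexts = "N1", n_per_class = 2,
                                      seed = 1))
  cal <- calibrate_ec50(m, p, character(0), rec)
  expect_identical(cal$best_params, p)
  expect_equal(cal$best_objective, 100)
  expect_error(calibrate_ec50(m, p, "nope", rec), "not in model")
})
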