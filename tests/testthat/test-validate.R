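test_that("direction classification uses the relative threshold with a near-zero guard", {
  expect_equal(classify_change(0.52, 0.50), "increase")    # +4%
  expect_equal(classify_change(0.498, 0.50), "nochange")   # -0.4%
  expect_equal(classify_change(0.40, 0.50), "decrease")    # -20%
  # near-zero control falls back to absolute change in % of Ymax
  expect_equal(classify_change(0.05, 0), "increase")
  expect_equal(classify_change(5e-5, 0), "nochange")
  # raising the threshold can only grow the set of nochange calls
  pc <- percent_change(c(0.52, 0.56, 0.49, 0.42), rep(0.5, 4))
  for (th in c(1, 5, 10, 20)) {
    n_nc <- sum(abs(pc) <= th)
    n_nc_higher <- sum(abs(pc) <= th * 2)
    expect_gte(n_nc_higher, n_nc)
  }
})

test_that("fold changes map onto the six categories plus NC", {
  expect_equal(classify_fold_change(1.5), "LH")
  expect_equal(classify_fold_change(7.0), "HH")
  expect_equal(classify_fold_change(0.3), "ML")
  expect_equal(classify_fold_change(c(3.1, 0.7, 0.1, 1.005)),
               c("MH", "LL", "HL", "NC"))
  expect_error(classify_fold_change(0), "positive")
})

test_that("records generated from the model's own directions validate at 100%", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  p <- param_set(W_i = 0.1)
  rec <- make_records(record_gen_spec(m, p, contexts = c("IN1", "IN2"),
                                      n_per_class = 4, seed = 3))
  rep <- validate_model(m, p, rec)
  expect_equal(rep$validation_percent, 100)
  expect_equal(rep$n_unresolved, 0)
})

test_that("flipping the directed observations of a consistent set zeroes them", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 5))
  p <- param_set(W_i = 0.1)
  rec <- make_records(record_gen_spec(m, p, contexts = "N1", n_per_class = 5,
                                      seed = 2))
  directed <- rec$observed != "nochange"
  rec$observed[directed] <- ifelse(rec$observed[directed] == "increase",
                                   "decrease", "increase")
  rep <- validate_model(m, p, rec[directed, , drop = FALSE])
  expect_equal(rep$validation_percent, 0)
})

test_that("overall percent is the record-weighted mean of class percents", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  p <- param_set(W_i = 0.15)
  rec <- make_records(record_gen_spec(m, p, contexts = c("IN1", "IN2"),
                                      n_per_class = 4, label_noise = 0.25,
                                      seed = 8))
  rep <- validate_model(m, p, rec)
  by_class <- rep$by_class
  expect_equal(sum(by_class$n), rep$n_records - rep$n_unresolved)
  expect_equal(stats::weighted.mean(by_class$percent, by_class$n),
               rep$validation_percent, tolerance = 1e-12)
})

test_that("validation is deterministic for identical inputs", {
  m <- make_toy_network(toy_spec("branch", n_nodes = 6, seed = 5))
  p <- param_set(W_i = 0.2)
  rec <- make_records(record_gen_spec(m, p, contexts = "N1", n_per_class = 3,
                                      seed = 5))
  r1 <- validate_model(m, p, rec)
  r2 <- validate_model(m, p, rec)
  expect_identical(r1$outcomes, r2$outcomes)
})

test_that("semi-quantitative scoring honors strict and lenient modes", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 4))
  p <- param_set(W_i = 0.1)
  rec <- make_records(record_gen_spec(m, p, contexts = "N1", n_per_class = 4,
                                      type = "semiquant", seed = 6))
  rep <- validate_semiquant(m, p, rec)
  expect_equal(rep$validation_percent, 100)  # self-consistent by construction
  expect_equal(rep$mode, "strict")

  # an off-by-one category fails strict but passes lenient
  one <- rec[rec$observed %in% c("LH", "MH", "HH"), , drop = FALSE][1, ]
  shift <- c(LH = "MH", MH = "HH", HH = "MH")
  one$observed <- unname(shift[one$observed])
  strict <- validate_semiquant(m, p, one)
  lenient <- validate_semiquant(m, p, one,
                                hillnet_config(semiquant_mode = "lenient"))
  expect_equal(strict$validation_percent, 0)
  expect_equal(lenient$validation_percent, 100)
})

test_that("all-zero controls produce finite guarded folds", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 3))
  p <- param_set(W_i = 0)  # resting state identically zero
  df <- data.frame(record_id = "s1", context = "N1", data_class = "InputOutput",
                   perturbations = "stim:N1", measured_node = "N3",
                   observed = "HH")
  out <- run_condition(m, p, experiment_records(df)[1, ])
  expect_true(is.finite(out$fold))
  expect_gt(out$fold, 1)
})

test_that("records measuring unknown nodes are rejected", {
  m <- make_toy_network(toy_spec("cascade", n_nodes = 3))
  df <- data.frame(record_id = "x", context = "N1", data_class = "InputOutput",
                   perturbations = "stim:N1", measured_node = "nope",
                   observed = "increase")
  expect_error(validate_model(m, param_set(), experiment_records(df)),
               "not in model")
})

test_that("combined objective weighs every record equally", {
  m <- make_toy_network(toy_spec("crosstalk_demo"))
  p <- param_set(W_i = 0.1)
  q <- make_records(record_gen_spec(m, p, contexts = "IN1", n_per_class = 3,
                                    seed = 2))
  s <- make_records(record_gen_spec(m, p, contexts = "IN1", n_per_class = 3,
                                    type = "semiquant", seed = 3))
  s$record_id <- paste0("sq_", s$record_id)
  both <- rbind(q, s)
  class(both) <- class(q)
  comb <- validate_combined(m, p, both)
  nq <- sum(comb$qualitative$outcomes$resolved)
  ns <- sum(comb$semiquant$outcomes$resolved)
  mq <- sum(comb$qualitative$outcomes$match[comb$qualitative$outcomes$resolved])
  ms <- sum(comb$semiquant$outcomes$match[comb$semiquant$outcomes$resolved])
  expect_equal(comb$percent, 100 * (mq + ms) / (nq + ns))
})
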