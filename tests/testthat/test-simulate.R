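test_that("population draws honor degenerate and moment structure", {
  hyper <- dplyr::mutate(default_hyper(),
                         sigma2_beta = ifelse(quantifier == "many",
                                              1e-18, sigma2_beta),
                         delta = ifelse(quantifier == "many", -0.1, delta))
  pop <- population_spec(hyper = hyper)
  params <- draw_population(pop, 20, seed = 3)
  expect_equal(params$beta[params$quantifier == "many"], rep(-0.1, 20),
               tolerance = 1e-8)
  # Beta(2, 20) response-error mean = 2/22
  big <- draw_population(population_spec(), 20000, seed = 4)
  g <- big$gamma[big$quantifier == "few"]
  expect_equal(mean(big$gamma), 2 / 22, tolerance = 0.003)
  expect_true(all(big$gamma > 0 & big$gamma < 0.5))
  expect_true(all(big$alpha > 0))
})

test_that("invalid population variances are rejected naming the quantifier", {
  hyper <- dplyr::mutate(default_hyper(),
                         sigma2_beta = ifelse(quantifier == "most", -1, sigma2_beta))
  expect_error(population_spec(hyper = hyper), "most")
})

test_that("planted cluster offsets produce the planted component means", {
  offsets <- matrix(c(-0.15, 0.15), 2, 1, dimnames = list(NULL, "many"))
  hyper <- dplyr::mutate(default_hyper(), delta = 0)
  pop <- population_spec(hyper = hyper,
                         clusters = list(weights = c(0.5, 0.5),
                                         beta_offsets = offsets))
  params <- draw_population(pop, 10000, seed = 11)
  many <- params[params$quantifier == "many", ]
  comp_means <- tapply(many$beta, many$cluster, mean)
  expect_equal(as.vector(comp_means), c(-0.15, 0.15), tolerance = 0.02)
  # zero offsets reproduce the unclustered draw on the same seed path
  pop0 <- population_spec(hyper = hyper,
                          clusters = list(weights = c(0.5, 0.5),
                                          beta_offsets = offsets * 0))
  plain <- dplyr::mutate(draw_population(population_spec(hyper = hyper),
                                         200, seed = 12), cluster = NULL)
  zeroed <- dplyr::mutate(draw_population(pop0, 200, seed = 12), cluster = NULL)
  expect_identical(plain, zeroed)
})

test_that("simulated percentages respect the balancing rule and trial count", {
  params <- draw_population(population_spec(), 4, seed = 21)
  trials <- simulate_trials(experiment_design(), params, seed = 22)
  expect_equal(nrow(trials), 4 * 5 * 50)
  counts <- trials |>
    dplyr::filter(quantifier %in% c("most", "more than half", "fewer than half")) |>
    dplyr::group_by(participant_id, quantifier) |>
    dplyr::summarise(below = sum(percent < 50), above = sum(percent > 50),
                     .groups = "drop")
  expect_true(all(counts$below == 25 & counts$above == 25))
  expect_false(any(trials$percent == 50))
  expect_true(all(trials$percent %in% 1:99))
})

test_that("a sharp zero-error responder produces step-function data", {
  params <- tidyr::expand_grid(participant_id = "p001",
                               quantifier = "more than half") |>
    dplyr::mutate(beta = 0, alpha = 1e-6, gamma = 0)
  design <- experiment_design(quantifiers = "more than half",
                              trials_per_quantifier = 500,
                              rt_fast_rate = 0, rt_slow_rate = 0)
  trials <- simulate_trials(design, params, seed = 30)
  expect_true(all(trials$response[trials$percent > 50] == 1))
  expect_true(all(trials$response[trials$percent < 50] == 0))
})

test_that("empirical response rates match the closed-form curve", {
  params <- tibble::tibble(participant_id = "p001", quantifier = "many",
                           beta = -0.061, alpha = 0.019, gamma = 0.048)
  design <- experiment_design(quantifiers = "many",
                              trials_per_quantifier = 100000,
                              rt_fast_rate = 0, rt_slow_rate = 0)
  trials <- simulate_trials(design, params, seed = 31)
  at44 <- trials$response[trials$percent == 44]
  p_true <- response_probability(center_percent(44), -0.061, 0.019, 0.048)
  se <- sqrt(p_true * (1 - p_true) / length(at44))
  expect_lt(abs(mean(at44) - p_true), 3 * se)
})

test_that("negative quantifiers are emitted on the raw decreasing scale", {
  params <- tibble::tibble(participant_id = "p001", quantifier = "few",
                           beta = -0.1, alpha = 0.01, gamma = 0)
  design <- experiment_design(quantifiers = "few", trials_per_quantifier = 2000,
                              rt_fast_rate = 0, rt_slow_rate = 0)
  trials <- simulate_trials(design, params, seed = 33)
  lo <- mean(trials$response[trials$percent < 30])
  hi <- mean(trials$response[trials$percent > 60])
  expect_gt(lo, 0.95)
  expect_lt(hi, 0.05)
})

test_that("simulation is byte-deterministic under a fixed seed", {
  pop <- population_spec()
  p1 <- draw_population(pop, 6, seed = 41)
  p2 <- draw_population(pop, 6, seed = 41)
  expect_identical(p1, p2)
  d <- experiment_design()
  expect_identical(simulate_trials(d, p1, seed = 42),
                   simulate_trials(d, p2, seed = 42))
})

test_that("empirical curves converge to the model curve as trials grow", {
  params <- tibble::tibble(participant_id = "p001", quantifier = "many",
                           beta = -0.05, alpha = 0.05, gamma = 0.05)
  kd <- vapply(c(400, 6400), function(n) {
    design <- experiment_design(quantifiers = "many", trials_per_quantifier = n,
                                rt_fast_rate = 0, rt_slow_rate = 0)
    trials <- simulate_trials(design, params, seed = 50)
    emp <- tapply(trials$response, trials$percent, mean)
    pct <- as.integer(names(emp))
    thr <- response_probability(center_percent(pct), -0.05, 0.05, 0.05)
    max(abs(emp - thr))
  }, numeric(1))
  expect_lt(kd[2], kd[1])
})

test_that("trial CSV round-trips and malformed rows are reported by line", {
  params <- draw_population(population_spec(), 3, seed = 61)
  trials <- simulate_trials(experiment_design(trials_per_quantifier = 4),
                            params, seed = 62)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back, trials)

  bad <- trials
  bad$quantifier[3] <- "loads"
  write_trials(bad, path)
  expect_error(read_trials(path), "line 4")
  bad <- trials
  bad$percent[5] <- 50L
  write_trials(bad, path)
  expect_error(read_trials(path), "line 6")
})

test_that("ground-truth sidecar serializes parameters and hyperparameters", {
  pop <- population_spec()
  params <- draw_population(pop, 3, seed = 71)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(params, pop, path)
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(truth$params$beta, params$beta, tolerance = 1e-12)
  expect_equal(truth$hyper$delta, pop$hyper$delta, tolerance = 1e-12)
})
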