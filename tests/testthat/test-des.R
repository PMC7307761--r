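test_that("no arrivals means an empty log and zero occupancy", {
  s <- single_node_scenario(10, 8,
                            interarrival = dist_spec("deterministic",
                                                     value = 1e7))
  r <- simulate_ecn(s, NULL, horizon = 2, warmup = 0, seed = 3)
  expect_equal(nrow(r$patients), 0)
  expect_equal(r$node_stats$occupancy, 0)
})

test_that("a lone deterministic patient waits exactly the pre-physician path", {
  stages <- list(triage = dist_spec("deterministic", value = 5),
                 admission = dist_spec("deterministic", value = 4),
                 bed_prep = dist_spec("deterministic", value = 6),
                 nursing = dist_spec("deterministic", value = 7),
                 physician = dist_spec("deterministic", value = 10),
                 treatment = dist_spec("deterministic", value = 20))
  pip <- flat_pipelines(dist_spec("deterministic", value = 1000))
  nd <- node_spec("N1", "poc", beds = 5, insurers = "S",
                  demand_mean = 10, demand_var = 1,
                  stage_servers = setNames(rep(1L, 6), names(stages)),
                  stage_service = stages, pipelines = pip)
  tt <- matrix(NA_real_, 1, 1, dimnames = list("N1", "N1"))
  s <- network_scenario(list(nd), list(P1 = tt, P2 = tt, P3 = tt),
                        data.frame(insurer = "S", affiliated = 1,
                                   unit_utility_M = 10),
                        payment = list(gamma = 0.19, theta = 0.46,
                                       floors = c(A = 3.92, B = 3.5, C = 4.5),
                                       arrangement = c(N1 = "A")),
                        triage_mix = c(0.05, 0.12, 0.18, 0.19, 0.46),
                        usl = 30,
                        population = list(special_regime = 0, uncovered = 0))
  r <- simulate_ecn(s, NULL, horizon = 1.2, warmup = 0, seed = 9)
  expect_equal(nrow(r$patients), 1)
  # no queueing: wait = triage + admission + bed prep + nursing
  expect_equal(r$patients$door_to_physician, 5 + 4 + 6 + 7)
  expect_equal(r$patients$departure, 1000 + 5 + 4 + 6 + 7 + 10 + 20)
  # stage timestamps are nondecreasing along the flow
  log <- r$stage_log[order(r$stage_log$start), ]
  expect_true(all(diff(log$start) >= 0))
  expect_true(all(log$end >= log$start))
})

test_that("identical seeds give bitwise-identical results", {
  s <- generate_scenario(77, n_hospitals = 1, n_pocs = 2)
  a <- simulate_ecn(s, transfer_policy("dynamic"), 2, 0.5, seed = 123)
  b <- simulate_ecn(s, transfer_policy("dynamic"), 2, 0.5, seed = 123)
  expect_identical(a$patients, b$patients)
  expect_identical(a$stage_log, b$stage_log)
  expect_identical(a$node_stats, b$node_stats)
  c2 <- simulate_ecn(s, transfer_policy("dynamic"), 2, 0.5, seed = 124)
  expect_false(identical(a$patients, c2$patients))
})

test_that("patients are conserved and timestamps are monotone", {
  s <- generate_scenario(55, n_hospitals = 1, n_pocs = 2)
  r <- simulate_ecn(s, transfer_policy("dynamic"), 2, 0, seed = 6)
  n_arrived <- nrow(r$patients)
  n_departed <- sum(!is.na(r$patients$departure))
  in_system <- sum(is.na(r$patients$departure))
  expect_equal(n_arrived, n_departed + in_system)
  # every transfer has exactly one origin and one destination
  expect_equal(sum(r$transfer_counts$n), sum(r$patients$transferred))
  # per-patient stage sequences are nondecreasing
  sl <- split(r$stage_log, r$stage_log$patient)
  ok <- vapply(sl, function(g) {
    g <- g[order(g$start), ]
    all(diff(g$start) >= 0) && all(g$end[!is.na(g$end)] >=
                                     g$start[!is.na(g$end)])
  }, logical(1))
  expect_true(all(ok))
  # waits are nonnegative
  w <- r$patients$door_to_physician
  expect_true(all(w[!is.na(w)] >= 0))
})

test_that("M/M/1 queueing wait matches the closed form", {
  # lambda = 1/10, mu = 1/8: Wq = 32 min
  s <- single_node_scenario(10, 8)
  sm <- run_replications(s, NULL, n_reps = 12, horizon = 16, warmup = 2,
                         base_seed = 2026, metric = mean_wait)
  wq <- erlang_c_wq(1 / 10, 1 / 8, 1)
  expect_equal(wq, 32)
  expect_lt(abs(sm$mean - wq), sm$half_width + 1e-12)
})

test_that("M/M/3 queueing wait matches Erlang C", {
  # lambda = 0.3, mu = 0.125, c = 3: rho = 0.8
  s <- single_node_scenario(1 / 0.3, 8, servers = 3)
  sm <- run_replications(s, NULL, n_reps = 12, horizon = 12, warmup = 2,
                         base_seed = 31, metric = mean_wait)
  wq <- erlang_c_wq(0.3, 0.125, 3)
  expect_lt(abs(sm$mean - wq), sm$half_width + 1e-12)
})

test_that("an arrival finding all beds busy is blocked but still queues", {
  stages <- list(triage = dist_spec("deterministic", value = 1),
                 admission = dist_spec("deterministic", value = 1),
                 bed_prep = dist_spec("deterministic", value = 1),
                 nursing = dist_spec("deterministic", value = 1),
                 physician = dist_spec("deterministic", value = 1),
                 treatment = dist_spec("deterministic", value = 500))
  pip <- flat_pipelines(dist_spec("deterministic", value = 10))
  nd <- node_spec("N1", "poc", beds = 1, insurers = "S",
                  demand_mean = 10, demand_var = 1,
                  stage_servers = setNames(rep(5L, 6), names(stages)),
                  stage_service = stages, pipelines = pip)
  tt <- matrix(NA_real_, 1, 1, dimnames = list("N1", "N1"))
  s <- network_scenario(list(nd), list(P1 = tt, P2 = tt, P3 = tt),
                        data.frame(insurer = "S", affiliated = 1,
                                   unit_utility_M = 10),
                        payment = list(gamma = 0.19, theta = 0.46,
                                       floors = c(A = 3.92, B = 3.5, C = 4.5),
                                       arrangement = c(N1 = "A")),
                        triage_mix = c(0.05, 0.12, 0.18, 0.19, 0.46),
                        usl = 30,
                        population = list(special_regime = 0, uncovered = 0))
  r <- simulate_ecn(s, NULL, horizon = 0.05, warmup = 0, seed = 2)
  expect_gte(nrow(r$patients), 3)
  expect_false(r$patients$blocked[1])     # first patient takes the bed
  expect_true(all(r$patients$blocked[-1]))  # later bed requests find it busy
  expect_gt(r$node_stats$blocking, 0)
  # blocked patients still receive care eventually (no balking): the
  # second patient is still in the system, not dropped
  expect_true(all(!is.na(r$patients$door_to_physician[1])))
})

test_that("replication summaries are reproducible and tighten with n", {
  s <- single_node_scenario(10, 6)
  a <- run_replications(s, NULL, n_reps = 4, horizon = 4, warmup = 1,
                        base_seed = 9, metric = mean_wait)
  b <- run_replications(s, NULL, n_reps = 4, horizon = 4, warmup = 1,
                        base_seed = 9, metric = mean_wait)
  expect_identical(a$values, b$values)
  expect_gte(a$half_width, 0)
  big <- run_replications(s, NULL, n_reps = 16, horizon = 4, warmup = 1,
                          base_seed = 9, metric = mean_wait)
  # half-width shrinks roughly as 1/sqrt(n); allow wide stochastic slack
  expect_lt(big$half_width, a$half_width)
})

test_that("replication sizing follows the normal-theory formula", {
  expect_equal(required_replications(10, 0.5, 0.95), 1537L)
  expect_equal(required_replications(10, 1e6, 0.95), 2L)
  # hand check: ceil((z * sd / h)^2)
  z <- qnorm(0.975)
  expect_equal(required_replications(3, 0.25, 0.95),
               as.integer(ceiling((z * 3 / 0.25)^2)))
  expect_error(required_replications(-1, 1), "presample_sd")
  expect_error(required_replications(1, 0), "half_width")
  expect_error(required_replications(1, 1, 1.5), "confidence")
})

test_that("warm-up detection finds the stabilization point", {
  expect_equal(detect_warmup(rep(0.02, 50), 0.001), 0L)
  # 100 decreasing then 100 constant values
  series <- c(seq(0.5, 0.02, length.out = 100), rep(0.02, 100))
  w <- detect_warmup(series, 1e-6)
  expect_lte(w, 100L)
  expect_gt(w, 0L)
  # brute-force scan oracle: no change after the detected index
  d <- abs(diff(series))
  expect_true(all(d[seq.int(w + 1, length(d))] <= 1e-6))
  # oscillation above tolerance never stabilizes
  osc <- rep(c(0.1, 0.4), 50)
  expect_equal(detect_warmup(osc, 0.05), 100L)
  expect_error(detect_warmup(0.5, 0.1), "length")
})

test_that("validation against an observed mean behaves across regimes", {
  # degenerate equal case
  v <- validate_against_observed(rep(58.9, 5), 58.9)
  expect_equal(v$p_value, 1)
  expect_true(v$degenerate)
  # degenerate unequal case is flagged with p = 0
  v0 <- validate_against_observed(rep(60, 5), 58.9)
  expect_equal(v0$p_value, 0)
  expect_true(v0$degenerate)
  # a 10-sd shift is decisively rejected
  set.seed(15)
  x <- rnorm(30, 58.9 + 10 * 2, 2)
  v1 <- validate_against_observed(x, 58.9)
  expect_lt(v1$p_value, 0.001)
  # a well-calibrated model is not rejected
  set.seed(16)
  x2 <- rnorm(30, 58.9, 2)
  v2 <- validate_against_observed(x2, 58.9)
  expect_gt(v2$p_value, 0.05)
  expect_true(v2$ci[1] <= 58.9 + 2 && v2$ci[2] >= 58.9 - 2)
})

test_that("scenario comparison recovers a constructed shift", {
  set.seed(21)
  cur <- rgamma(4000, shape = 4, rate = 0.08)
  prop <- cur - 8
  cmp <- compare_scenarios(cur, prop)
  expect_lt(cmp$p_value, 1e-10)
  expect_lt(cmp$ci[1], -8 + 0.5)
  expect_gt(cmp$ci[2], -8 - 0.5)
  # identical samples: the interval covers zero
  cmp0 <- compare_scenarios(cur, cur)
  expect_true(cmp0$ci[1] <= 0 && cmp0$ci[2] >= 0)
  expect_error(compare_scenarios(numeric(0), 1:3), "nonempty")
})
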