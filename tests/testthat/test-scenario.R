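test_that("reference case encodes the published network", {
  s <- reference_case_scenario()
  expect_length(s$nodes, 10)
  expect_equal(sum(vapply(s$nodes, function(n) n$node_class == "hospital",
                          logical(1))), 2)
  # afternoon transfer times, spot checks against the printed matrix
  expect_equal(s$transfer_times$P2["H1", "POC1"], 6)
  expect_equal(s$transfer_times$P2["H1", "H2"], 11)
  expect_equal(s$transfer_times$P2["H2", "H1"], 12)  # asymmetric
  expect_true(all(is.na(diag(s$transfer_times$P2))))
  # insurer utilities and payment parameters
  expect_equal(s$insurers$unit_utility_M[s$insurers$insurer == "S"], 10.34)
  expect_equal(s$insurers$unit_utility_M[s$insurers$insurer == "SV"], 9.97)
  expect_equal(s$payment$gamma, 0.19)
  expect_equal(s$payment$theta, 0.46)
  expect_equal(s$payment$floors, c(A = 3.92, B = 3.50, C = 4.50))
  expect_equal(unname(s$payment$arrangement[["H2"]]), "A")
  expect_equal(unname(s$payment$arrangement[["H1"]]), "C")
  expect_equal(unname(s$payment$arrangement[["POC3"]]), "B")
  expect_equal(s$usl, 30)
  # POC4's ED is disabled: no beds, accepts no arrivals
  expect_false(ed_enabled(s$nodes$POC4))
  expect_null(s$nodes$POC4$pipelines)
  # planning waits expose the post-improvement means
  expect_equal(unname(planning_waits(s)[["POC1"]]), 126.03)
  expect_equal(unname(planning_waits(s)[["H2"]]), 3.71)
})

test_that("coverage totals add up to the published population with access", {
  s <- reference_case_scenario()
  expect_identical(sum(s$insurers$affiliated), 1229996)
  expect_identical(population_with_access(s), 1315283)
})

test_that("serialization round-trips a scenario field for field", {
  s <- reference_case_scenario()
  for (fmt in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    serialize_scenario(s, path)
    s2 <- load_scenario(path)
    expect_equal(s2, s, tolerance = 1e-9)
    unlink(path)
  }
})

test_that("validation rejects malformed documents with named errors", {
  s <- reference_case_scenario()
  bad <- s
  bad$transfer_times$P2["H1", "H2"] <- -3
  expect_error(validate_scenario(bad), class = "ecn_validation_error")
  expect_error(validate_scenario(bad), "off-diagonal")

  bad2 <- s
  bad2$payment$gamma <- 0.8   # gamma + theta > 1
  expect_error(validate_scenario(bad2), class = "ecn_validation_error")

  bad3 <- s
  rownames(bad3$transfer_times$P1)[1] <- "NOPE"
  expect_error(validate_scenario(bad3), class = "ecn_reference_error")

  bad4 <- s
  bad4$nodes$POC1$insurers <- c("S", "UNKNOWN_INSURER")
  expect_error(validate_scenario(bad4), "not in global roster")
})

test_that("a node without beds accepts no arrivals until enabled", {
  s <- reference_case_scenario()
  r <- simulate_ecn(s, NULL, horizon = 1, warmup = 0, seed = 11)
  expect_false("POC4" %in% r$patients$node_arrival)
  expect_false("POC4" %in% r$node_stats$node)
})

test_that("generated scenarios are deterministic and structurally valid", {
  a <- generate_scenario(1, 2, 8, 1.0)
  b <- generate_scenario(1, 2, 8, 1.0)
  expect_equal(a, b)
  # every enabled node carries exactly 21 weekday-by-slot pipelines
  for (nd in a$nodes)
    if (ed_enabled(nd)) expect_length(nd$pipelines, 21)
  # doubling demand halves each pipeline's mean interarrival
  d2 <- generate_scenario(1, 2, 8, 2.0)
  m1 <- dist_mean(a$nodes[[1]]$pipelines[["Mon.P2"]])
  m2 <- dist_mean(d2$nodes[[1]]$pipelines[["Mon.P2"]])
  expect_equal(m2, m1 / 2, tolerance = 1e-9)
})

test_that("any generated scenario passes all invariants (100 seeds)", {
  for (seed in 1:100) {
    s <- generate_scenario(seed, n_hospitals = 1, n_pocs = 2)
    expect_silent(validate_scenario(s))
  }
})

test_that("pipelines spread semester demand consistently", {
  pip <- make_pipelines(18200)  # 100 patients/day
  expect_length(pip, 21)
  # total expected arrivals per average week ~ 700
  rates <- vapply(pip, function(d) 480 / dist_mean(d), numeric(1))
  expect_equal(sum(rates), 700, tolerance = 1e-9)
})

test_that("transfer matrices import from CSV with id headers", {
  s <- reference_case_scenario()
  path <- tempfile(fileext = ".csv")
  m <- s$transfer_times$P2
  utils::write.csv(as.data.frame(m), path)
  m2 <- read_transfer_matrix(path)
  expect_equal(m2, m)
  unlink(path)
})
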