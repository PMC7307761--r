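test_that("eligibility enforces triage, coverage and no-dumping rules", {
  s <- reference_case_scenario()
  # only triage 4 and 5 qualify
  for (lvl in 1:3)
    expect_length(eligible_destinations(lvl, "S", "POC1", s), 0)
  # triage 4, covered: all other enabled nodes (POC4 disabled)
  cand <- eligible_destinations(4, "S", "POC1", s)
  expect_setequal(cand, c("H1", "H2", "POC2", "POC3", "POC5",
                          "POC6", "POC7", "POC8"))
  expect_false("POC4" %in% cand)
  # uncovered patients are never transferred
  expect_length(eligible_destinations(5, "UNCOVERED", "POC1", s), 0)
  expect_error(eligible_destinations(4, "XX", "POC1", s),
               class = "ecn_configuration_error")
  # destination must hold the agreement
  s2 <- s
  s2$nodes$H2$insurers <- setdiff(s2$nodes$H2$insurers, "SV")
  cand2 <- eligible_destinations(4, "SV", "POC1", s2)
  expect_false("H2" %in% cand2)
  # and so must the origin
  s3 <- s
  s3$nodes$POC1$insurers <- setdiff(s3$nodes$POC1$insurers, "SV")
  expect_length(eligible_destinations(4, "SV", "POC1", s3), 0)
})

test_that("the load-based wait estimator follows its definition", {
  expect_equal(expected_wait(0, 10, 1), 0)
  expect_equal(expected_wait(4, 10, 2), 20)
  expect_equal(expected_wait(7, 6, 3), 14)
})

test_that("planning-mode decisions match the published desk reasoning", {
  s <- reference_case_scenario()
  waits <- planning_waits(s)
  tt <- s$transfer_times$P2
  # POC1: the best alternative is H2 at 3.71 + 19 = 22.71 < 126.03
  cand <- eligible_destinations(4, "S", "POC1", s)
  d <- select_destination("POC1", cand, waits, tt)
  expect_equal(d$verdict, "transfer")
  expect_equal(d$destination, "H2")
  expect_equal(unname(min(d$candidate_scores)), 22.71)
  expect_lt(min(d$candidate_scores), 126.03)
  # H2 itself: every candidate sum exceeds its own 3.71-minute wait
  cand2 <- eligible_destinations(4, "S", "H2", s)
  d2 <- select_destination("H2", cand2, waits, tt)
  expect_equal(d2$verdict, "stay")
  expect_true(is.na(d2$destination))
})

test_that("ties break to the lexicographically first node id", {
  est <- c(O = 100, B = 10, A = 10)
  tt <- matrix(5, 3, 3, dimnames = list(c("O", "A", "B"), c("O", "A", "B")))
  diag(tt) <- NA
  d <- select_destination("O", c("B", "A"), est, tt)
  expect_equal(d$verdict, "transfer")
  expect_equal(d$destination, "A")
})

test_that("no candidates or missing inputs are handled per contract", {
  est <- c(O = 40)
  tt <- matrix(NA_real_, 1, 1, dimnames = list("O", "O"))
  d <- select_destination("O", character(0), est, tt)
  expect_equal(d$verdict, "stay")
  expect_error(select_destination("O", "X", est, tt),
               class = "ecn_configuration_error")
  est2 <- c(O = 40, X = 10)
  expect_error(select_destination("O", "X", est2, tt),
               class = "ecn_configuration_error")
})

test_that("decisions equal exhaustive enumeration on random problems", {
  set.seed(2024)
  for (i in 1:1000) {
    k <- sample(1:8, 1)
    ids <- paste0("N", sample(99, k + 1))
    origin <- ids[1]; cand <- ids[-1]
    est <- setNames(runif(k + 1, 0, 150), ids)
    tt <- matrix(runif((k + 1)^2, 1, 40), k + 1, k + 1,
                 dimnames = list(ids, ids))
    diag(tt) <- NA
    d <- select_destination(origin, cand, est, tt)
    # brute-force oracle over every candidate sum
    sums <- vapply(cand, function(j) est[[j]] + tt[origin, j], numeric(1))
    best <- sort(cand[sums == min(sums)])[1]
    if (min(sums) < est[[origin]]) {
      expect_equal(d$verdict, "transfer")
      expect_equal(d$destination, best)
      # the policy never raises the ex-ante expected wait
      expect_lt(min(d$candidate_scores), d$origin_expected_wait)
    } else {
      expect_equal(d$verdict, "stay")
    }
    expect_equal(unname(d$candidate_scores[cand]), unname(sums))
  }
})

test_that("simulated transfers respect triage and insurer-coverage safety", {
  s <- generate_scenario(31, n_hospitals = 2, n_pocs = 3)
  r <- simulate_ecn(s, transfer_policy("dynamic"), horizon = 3, warmup = 0,
                    seed = 5)
  moved <- r$patients[r$patients$transferred, ]
  expect_gt(nrow(moved), 0)
  expect_true(all(moved$triage %in% 4:5))
  expect_false(any(moved$insurer == "UNCOVERED"))
  for (i in seq_len(nrow(moved)))
    expect_true(moved$insurer[i] %in%
                  s$nodes[[moved$destination[i]]]$insurers)
  # and no transfers at all without a policy
  r0 <- simulate_ecn(s, NULL, horizon = 3, warmup = 0, seed = 5)
  expect_equal(sum(r0$patients$transferred), 0)
})
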