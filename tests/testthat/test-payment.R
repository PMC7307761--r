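ref_rule <- function(...) scenario_rule(reference_case_scenario(), ...)

test_that("destination shares reproduce the worked per-patient values", {
  rule <- ref_rule()
  # S-insured under arrangement A: formula wins over the floor
  expect_equal(round(destination_share(10.34, 0.015, "A", rule), 2), 6.36)
  # low-utility insurers under A: the 3.92 floor binds
  expect_equal(destination_share(4.91, 0.054, "A", rule), 3.92)
  expect_equal(destination_share(4.91, 0.043, "A", rule), 3.92)
  # arrangement C, reverse direction
  expect_equal(round(destination_share(10.34, 0.13, "C", rule), 2), 7.08)
  expect_equal(round(destination_share(9.97, 0.035, "C", rule), 2), 6.25)
  # identity limit: no triage shares, no correlation, no floor
  free <- settlement_rule(0, 0, floors = c(A = 1e-9, B = 1e-9, C = 1e-9),
                          M = c(S = 7.77))
  expect_equal(destination_share(7.77, 0, "A", free), 7.77)
  expect_error(destination_share(10, 0.1, "Z", rule), "arrangement")
  expect_error(destination_share(10, -0.1, "A", rule), "r must be")
})

test_that("admission settlement splits M exactly and honors same-node rule", {
  rule <- ref_rule()
  sp <- settle_admission("S", "H2", "H1", 0.13, rule)
  expect_equal(sp$arrangement, "C")
  expect_equal(sp$origin_share + sp$destination_share, 10.34)
  expect_equal(round(sp$destination_share, 2), 7.08)
  # same node: the treating node receives M in full
  same <- settle_admission("SV", "POC3", "POC3", 0.5, rule)
  expect_equal(same$destination_share, 9.97)
  expect_equal(same$origin_share, 0)
  expect_error(settle_admission("NOPE", "H1", "H2", 0, rule),
               class = "ecn_settlement_error")
})

test_that("coalition statements reproduce the printed yearly ledgers", {
  rule <- ref_rule()
  h1h2 <- data.frame(
    insurer = c("S", "BU", "MS", "COM", "COO", "SV"),
    nap = c(1190, 788, 1833, 529, 1249, 463),
    r = c(0.015, 0.054, 0.043, 0.046, 0.016, 0.021))
  st <- settle_coalition(h1h2, "H1", "H2", rule)
  dest <- setNames(st$table$destination_usd, st$table$insurer)
  expect_equal(unname(dest[["S"]]), 7569)
  expect_equal(unname(dest[["BU"]]), 3089)
  expect_equal(unname(dest[["MS"]]), 7185)
  orig <- setNames(st$table$origin_usd, st$table$insurer)
  expect_equal(unname(orig[["S"]]), 4735)
  # row totals equal nap times the per-admission share before rounding
  expect_equal(st$table$destination_exact,
               st$table$nap * st$table$unit_destination)
  # grand totals are the row sums
  expect_equal(st$destination_total, sum(st$table$destination_exact))

  empty <- settle_coalition(h1h2[0, ], "H1", "H2", rule)
  expect_equal(empty$origin_total, 0)
  expect_equal(empty$destination_total, 0)
})

test_that("settlement conserves money and responds monotonically", {
  set.seed(99)
  for (i in 1:300) {
    g <- runif(1, 0, 0.5); th <- runif(1, 0, 0.5)
    fl <- c(A = runif(1, 0.5, 6), B = runif(1, 0.5, 6), C = runif(1, 0.5, 6))
    M <- runif(1, 1, 15); r <- runif(1, 0, 0.5)
    arr <- sample(c("A", "B", "C"), 1)
    rule <- settlement_rule(g, th, fl, arrangement = c(X = arr),
                            M = c(S = M))
    d <- destination_share(M, r, arr, rule)
    # conservation through the split
    sp <- settle_admission("S", "O", "X", r, rule)
    expect_equal(sp$origin_share + sp$destination_share, M)
    # floor dominance, equality iff formula value under floor
    expect_gte(d, fl[[arr]])
    formula_val <- M * (1 + r) / (1 + g + th)
    if (formula_val <= fl[[arr]]) expect_equal(d, fl[[arr]])
    # monotone: up in r and M, down in gamma/theta above the floor
    expect_gte(destination_share(M, r + 0.1, arr, rule), d)
    expect_gte(destination_share(M + 1, r, arr, rule), d)
    rule2 <- settlement_rule(min(g + 0.1, 0.5), th, fl,
                             arrangement = c(X = arr), M = c(S = M))
    expect_lte(destination_share(M, r, arr, rule2), d)
  }
})

test_that("the denominator is the sum form, with the product as an option", {
  rule <- ref_rule()
  expect_equal(destination_share(10.34, 0.015, "A", rule),
               10.34 * 1.015 / 1.65)
  prod_rule <- ref_rule(denominator = "product")
  expect_equal(destination_share(10.34, 0.015, "A", prod_rule),
               10.34 * 1.015 / (1 + 0.19 * 0.46))
})

test_that("r estimation is a clamped Pearson correlation", {
  # perfectly linear relation
  n <- 50; counts <- 1:n
  expect_equal(as.numeric(estimate_r(5 + 2 * counts, counts)), 1)
  # independent series stay near zero (clamped at 0 from below)
  set.seed(7)
  r <- estimate_r(rnorm(10000), rpois(10000, 5))
  expect_lt(as.numeric(r), 0.05)
  expect_gte(as.numeric(r), 0)
  # degenerate constant series
  expect_warning(r0 <- estimate_r(rep(3, 10), 1:10), "degenerate")
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "degenerate"))
  expect_error(estimate_r(1:5, 1:4), "equal length")
})

test_that("network profits aggregate same-node receipts and shares", {
  rule <- ref_rule()
  led <- data.frame(insurer = c("S", "SV"), nap = c(10, 5),
                    r = c(0.1, 0.2))
  ab <- settle_coalition(led, "H1", "H2", rule)
  ba <- settle_coalition(led, "H2", "H1", rule)
  expect_error(network_profits(list(ab, ab)), "duplicate")
  # no transfers: profit = same-node M receipts only
  same <- data.frame(node = c("H1", "H2"), insurer = c("S", "SV"),
                     n = c(3, 4))
  p0 <- network_profits(list(), same, rule)
  expect_equal(unname(p0[["H1"]]), 3 * 10.34)
  expect_equal(unname(p0[["H2"]]), 4 * 9.97)
  # symmetric opposite ledgers under equal arrangements give equal profits
  sym_rule <- settlement_rule(0.19, 0.46,
                              c(A = 3.92, B = 3.50, C = 4.50),
                              arrangement = c(H1 = "A", H2 = "A"),
                              M = c(S = 10.34, SV = 9.97))
  p <- network_profits(list(settle_coalition(led, "H1", "H2", sym_rule),
                            settle_coalition(led, "H2", "H1", sym_rule)))
  expect_equal(unname(p[["H1"]]), unname(p[["H2"]]))
  # total payout is conserved regardless of arrangement
  expect_equal(sum(p), 2 * sum(led$nap * c(10.34, 9.97)))
})
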