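# The collateral payment model: when a patient is transferred, the
# destination node receives max{floor(arrangement), M (1 + r) / (1 + gamma
# + theta)} of the insurer-agreed unit utility M, and the origin keeps the
# remainder; a node treating its own patient keeps M in full. r is the
# correlation between the destination's waiting time and the number of
# transferred admissions it receives, compensating nodes whose timeliness
# degrades from collaborating.

#' Construct a settlement rule
#'
#' @param gamma,theta population shares of triage-4 and triage-5 patients
#'   (0 <= gamma, theta, gamma + theta <= 1).
#' @param floors named numeric vector of per-admission floors (USD) for
#'   arrangements \code{A}, \code{B}, \code{C}.
#' @param arrangement named character vector mapping each destination node
#'   id to an arrangement letter.
#' @param M named numeric vector of unit utility values (USD) per insurer.
#' @param denominator \code{"sum"} (the default, denominator
#'   \code{1 + gamma + theta}) or \code{"product"}
#'   (\code{1 + gamma * theta}), the latter retained only for sensitivity
#'   analysis.
#' @return an object of class \code{ecn_rule}.
#' @export
settlement_rule <- function(gamma, theta,
                            floors = c(A = 3.92, B = 3.50, C = 4.50),
                            arrangement = character(), M = numeric(),
                            denominator = c("sum", "product")) {
  denominator <- match.arg(denominator)
  stopifnot(gamma >= 0, theta >= 0, gamma + theta <= 1,
            all(floors > 0), setequal(names(floors), c("A", "B", "C")),
            all(M > 0))
  structure(list(gamma = gamma, theta = theta,
                 floors = floors[c("A", "B", "C")],
                 arrangement = arrangement, M = M,
                 denominator = denominator),
            class = "ecn_rule")
}

#' Settlement rule of a scenario
#' @param s an \code{ecn_scenario}.
#' @param ... passed to [settlement_rule()] (e.g. \code{denominator}).
#' @return an \code{ecn_rule} built from the scenario's payment block and
#'   insurer table.
#' @export
scenario_rule <- function(s, ...) {
  settlement_rule(s$payment$gamma, s$payment$theta, s$payment$floors,
                  s$payment$arrangement,
                  stats::setNames(s$insurers$unit_utility_M,
                                  s$insurers$insurer), ...)
}

rule_denom <- function(rule) {
  if (rule$denominator == "sum") 1 + rule$gamma + rule$theta
  else 1 + rule$gamma * rule$theta
}

#' Destination node's per-admission share
#'
#' \code{max(floor(arrangement), M (1 + r) / (1 + gamma + theta))}. With the
#' reference parameters gamma = 0.19 and theta = 0.46 the denominator is
#' 1.65.
#'
#' @param M unit utility value (USD).
#' @param r waiting-time/admissions correlation (>= 0).
#' @param arrangement \code{"A"}, \code{"B"} or \code{"C"}.
#' @param rule an \code{ecn_rule}.
#' @return destination share in USD (unrounded).
#' @export
#' @examples
#' rule <- settlement_rule(0.19, 0.46, M = c(S = 10.34))
#' destination_share(10.34, 0.015, "A", rule)  # 6.36 to cents
destination_share <- function(M, r, arrangement, rule) {
  stopifnot(inherits(rule, "ecn_rule"))
  if (!is.numeric(r) || r < 0) stop("r must be >= 0", call. = FALSE)
  if (!arrangement %in% c("A", "B", "C"))
    stop("unknown arrangement: ", arrangement, call. = FALSE)
  max(rule$floors[[arrangement]], M * (1 + r) / rule_denom(rule))
}

#' Settle one admission between origin and destination
#'
#' Same-node admissions: the treating node receives M in full. Transfers:
#' the destination receives [destination_share()] under the arrangement its
#' node id maps to, and the origin keeps the remainder (which may be
#' negative when the floor exceeds M; the split always sums to M exactly).
#'
#' @param insurer insurer label; must have an agreed unit utility in the
#'   rule.
#' @param origin,destination node ids.
#' @param r correlation for this (direction, insurer).
#' @param rule an \code{ecn_rule}; \code{rule$arrangement} must resolve the
#'   destination.
#' @return an object of class \code{ecn_split}: insurer, M, r, arrangement,
#'   \code{origin_share}, \code{destination_share} (USD, unrounded).
#' @export
settle_admission <- function(insurer, origin, destination, r, rule) {
  stopifnot(inherits(rule, "ecn_rule"))
  if (!insurer %in% names(rule$M))
    ecn_error("ecn_settlement_error",
              paste0("no agreed unit utility for insurer ", insurer))
  M <- unname(rule$M[[insurer]])
  if (identical(origin, destination)) {
    return(structure(list(insurer = insurer, origin = origin,
                          destination = destination, M = M, r = r,
                          arrangement = NA_character_,
                          origin_share = 0, destination_share = M),
                     class = "ecn_split"))
  }
  if (!destination %in% names(rule$arrangement))
    ecn_error("ecn_settlement_error",
              paste0("no arrangement for destination ", destination))
  arr <- unname(rule$arrangement[[destination]])
  d <- destination_share(M, r, arr, rule)
  structure(list(insurer = insurer, origin = origin,
                 destination = destination, M = M, r = r,
                 arrangement = arr, origin_share = M - d,
                 destination_share = d),
            class = "ecn_split")
}

#' Estimate the waiting-time/admissions correlation r
#'
#' Pearson correlation between a destination node's per-period waiting
#' times and the per-period counts of transferred admissions it received.
#' Negative estimates are clamped to zero (the compensation term only ever
#' raises the destination share); degenerate zero-variance series return 0
#' with a \code{degenerate} attribute and a warning.
#'
#' @param destination_wait_by_period numeric waiting-time series (minutes).
#' @param transferred_admissions_by_period count series, same length
#'   (>= 3).
#' @return correlation in [0, 1] with attribute \code{degenerate}.
#' @export
estimate_r <- function(destination_wait_by_period,
                       transferred_admissions_by_period) {
  w <- destination_wait_by_period; a <- transferred_admissions_by_period
  if (length(w) != length(a))
    stop("series must have equal length", call. = FALSE)
  if (length(w) < 3) stop("need series of length >= 3", call. = FALSE)
  if (stats::sd(w) == 0 || stats::sd(a) == 0) {
    warning("degenerate (zero-variance) series; r set to 0")
    return(structure(0, degenerate = TRUE))
  }
  structure(max(0, stats::cor(w, a)), degenerate = FALSE)
}

#' Settle a full coalition direction
#'
#' Builds the per-insurer settlement statement for one transfer direction
#' (origin -> destination): per-admission shares times admission counts.
#' Monetary totals are kept exact internally and rounded half-away-from-zero
#' to the nearest dollar in the report columns.
#'
#' @param ledger data.frame with columns \code{insurer}, \code{nap}
#'   (admissions, >= 0) and \code{r} (correlation per insurer).
#' @param origin,destination node ids of the direction.
#' @param rule an \code{ecn_rule}.
#' @return an object of class \code{ecn_statement}: the per-insurer table
#'   (unit shares, exact and rounded totals) plus direction metadata and
#'   grand totals \code{origin_total}/\code{destination_total}.
#' @export
settle_coalition <- function(ledger, origin, destination, rule) {
  stopifnot(all(c("insurer", "nap", "r") %in% names(ledger)),
            all(ledger$nap >= 0))
  rows <- lapply(seq_len(nrow(ledger)), function(i) {
    sp <- settle_admission(ledger$insurer[i], origin, destination,
                           ledger$r[i], rule)
    data.frame(insurer = ledger$insurer[i], nap = ledger$nap[i],
               r = ledger$r[i], M = sp$M, arrangement = sp$arrangement,
               unit_destination = sp$destination_share,
               unit_origin = sp$origin_share,
               destination_exact = ledger$nap[i] * sp$destination_share,
               origin_exact = ledger$nap[i] * sp$origin_share,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(insurer = character(), nap = numeric(), r = numeric(),
               M = numeric(), arrangement = character(),
               unit_destination = numeric(), unit_origin = numeric(),
               destination_exact = numeric(), origin_exact = numeric(),
               stringsAsFactors = FALSE)
  tab$destination_usd <- round_half_up(tab$destination_exact, 0)
  tab$origin_usd <- round_half_up(tab$origin_exact, 0)
  structure(list(origin = origin, destination = destination, table = tab,
                 origin_total = sum(tab$origin_exact),
                 destination_total = sum(tab$destination_exact)),
            class = "ecn_statement")
}

# round half away from zero (commercial rounding used in monetary reports)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.ecn_statement <- function(x, ...) {
  cat("<ecn_statement> ", x$origin, " -> ", x$destination, "\n", sep = "")
  print(x$table[, c("insurer", "nap", "r", "arrangement",
                    "unit_destination", "origin_usd", "destination_usd")],
        ...)
  cat("totals: origin US$", round_half_up(x$origin_total),
      ", destination US$", round_half_up(x$destination_total), "\n", sep = "")
  invisible(x)
}

#' Aggregate node profits across coalition statements
#'
#' Each node's total = its same-node receipts (every self-treated admission
#' earns the full unit utility M) plus its origin shares over directions
#' where it is the origin plus its destination shares where it is the
#' destination.
#'
#' @param statements list of [settle_coalition()] statements with pairwise
#'   distinct directions.
#' @param same_node_admissions optional data.frame with columns \code{node},
#'   \code{insurer}, \code{n}: admissions treated where they arrived.
#' @param rule an \code{ecn_rule} (needed to price same-node admissions).
#' @return named numeric vector of per-node USD totals (exact; round for
#'   reporting).
#' @export
network_profits <- function(statements, same_node_admissions = NULL,
                            rule = NULL) {
  dirs <- vapply(statements, function(s)
    paste(s$origin, s$destination, sep = "->"), character(1))
  if (anyDuplicated(dirs))
    stop("duplicate direction(s): ",
         paste(unique(dirs[duplicated(dirs)]), collapse = ", "),
         call. = FALSE)
  totals <- numeric(0)
  add <- function(node, amt) {
    cur <- if (node %in% names(totals)) totals[[node]] else 0
    totals[[node]] <<- cur + amt
  }
  for (s in statements) {
    add(s$origin, s$origin_total)
    add(s$destination, s$destination_total)
  }
  if (!is.null(same_node_admissions) && nrow(same_node_admissions)) {
    stopifnot(!is.null(rule))
    for (i in seq_len(nrow(same_node_admissions))) {
      r <- same_node_admissions[i, ]
      if (!r$insurer %in% names(rule$M))
        ecn_error("ecn_settlement_error",
                  paste0("no agreed unit utility for insurer ", r$insurer))
      add(r$node, r$n * unname(rule$M[[r$insurer]]))
    }
  }
  totals
}

#' Settle every direction of a simulated replication
#'
#' Convenience bridge from simulator output to the settlement engine:
#' aggregates the replication's transfer counts per (origin, destination,
#' insurer), estimates r per direction from weekly waiting-time and
#' admission aggregates at the destination, and settles each direction.
#'
#' @param rep an \code{ecn_replication}.
#' @param scenario the scenario it was simulated from.
#' @param rule optional \code{ecn_rule}; default [scenario_rule()].
#' @param period_min aggregation window for r estimation, default one week.
#' @return list of \code{ecn_statement} objects (possibly empty).
#' @export
settle_replication <- function(rep, scenario, rule = scenario_rule(scenario),
                               period_min = 7 * 1440) {
  tc <- rep$transfer_counts
  if (!nrow(tc)) return(list())
  pats <- rep$patients
  dirs <- unique(tc[, c("origin", "destination")])
  out <- vector("list", nrow(dirs))
  for (i in seq_len(nrow(dirs))) {
    o <- dirs$origin[i]; d <- dirs$destination[i]
    sub <- tc[tc$origin == o & tc$destination == d, , drop = FALSE]
    # r from weekly aggregates at the destination
    dest <- pats[pats$node_treated == d & !is.na(pats$door_to_physician), ]
    per <- floor(dest$arrival / period_min)
    waits <- tapply(dest$door_to_physician, per, mean)
    trans <- tapply(dest$transferred, per, sum)
    r <- if (length(waits) >= 3)
      as.numeric(estimate_r(as.numeric(waits), as.numeric(trans))) else 0
    ledger <- data.frame(insurer = sub$insurer, nap = sub$n, r = r,
                         stringsAsFactors = FALSE)
    out[[i]] <- settle_coalition(ledger, o, d, rule)
  }
  out
}
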