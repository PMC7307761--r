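#' Run independent replications of the network simulation
#'
#' Executes \code{n_reps} independent replications (seeds derived from
#' \code{base_seed} through one draw of the seeded RNG, so results are fully
#' reproducible) and summarizes the across-replication distribution of the
#' mean door-to-physician time.
#'
#' @inheritParams simulate_ecn
#' @param n_reps number of replications (>= 2).
#' @param base_seed root seed from which per-replication seeds are derived.
#' @param confidence confidence level for the half-width (default 0.95).
#' @param metric function mapping an \code{ecn_replication} to one number;
#'   default is the network-wide mean door-to-physician time of post-warmup
#'   patients.
#' @return an object of class \code{ecn_summary}: replication count,
#'   per-replication values, their mean, standard deviation and Student-t
#'   confidence half-width, plus a node-by-replication matrix of mean waits.
#' @export
run_replications <- function(scenario, policy = NULL, n_reps, horizon,
                             warmup = 0, base_seed = 1L, confidence = 0.95,
                             metric = NULL) {
  stopifnot(n_reps >= 2)
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  if (is.null(metric))
    metric <- function(rep) {
      w <- rep$patients$door_to_physician
      ok <- rep$patients$arrival >= rep$meta$warmup * 1440 & !is.na(w)
      mean(w[ok])
    }
  vals <- numeric(n_reps)
  node_means <- NULL
  for (r in seq_len(n_reps)) {
    sim <- simulate_ecn(scenario, policy, horizon, warmup, seed = seeds[r],
                        collect_stage_log = FALSE)
    vals[r] <- metric(sim)
    nm <- stats::setNames(sim$node_stats$mean_wait, sim$node_stats$node)
    node_means <- if (is.null(node_means)) matrix(nm, ncol = 1,
                                                  dimnames = list(names(nm)))
      else cbind(node_means, nm)
  }
  s <- stats::sd(vals)
  hw <- stats::qt((1 + confidence) / 2, df = n_reps - 1) * s / sqrt(n_reps)
  structure(list(n_reps = n_reps, values = vals, mean = mean(vals),
                 sd = s, half_width = hw, confidence = confidence,
                 node_means = node_means, seeds = seeds),
            class = "ecn_summary")
}

#' @export
print.ecn_summary <- function(x, ...) {
  cat("<ecn_summary> ", x$n_reps, " replications: mean ",
      format(x$mean, digits = 5), " +/- ", format(x$half_width, digits = 4),
      " min (", x$confidence * 100, "% CI)\n", sep = "")
  invisible(x)
}

#' Replication sample size for a target confidence half-width
#'
#' Standard normal-theory sizing from a pre-sample: the number of
#' replications needed so that the half-width of the confidence interval for
#' the mean is at most \code{half_width}, given the pre-sample standard
#' deviation.
#'
#' @param presample_sd standard deviation estimated from the pre-sample
#'   (minutes), > 0.
#' @param half_width target confidence half-width (minutes), > 0.
#' @param confidence confidence level in (0, 1).
#' @return integer count, \code{ceiling((z * sd / h)^2)}, never below 2.
#' @export
#' @examples
#' required_replications(10, 0.5, 0.95)  # 1537
required_replications <- function(presample_sd, half_width,
                                  confidence = 0.95) {
  if (!is.numeric(presample_sd) || presample_sd <= 0)
    stop("presample_sd must be > 0", call. = FALSE)
  if (!is.numeric(half_width) || half_width <= 0)
    stop("half_width must be > 0", call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm((1 + confidence) / 2)
  max(2L, as.integer(ceiling((z * presample_sd / half_width)^2)))
}

#' Detect the warm-up period from a blocking-probability series
#'
#' Scans the per-period blocking-probability series for the point after
#' which its change stays within \code{tolerance}: the steady-state
#' criterion used to truncate initial-transient bias. The change series is
#' the absolute first difference, optionally smoothed by a moving average of
#' width \code{window}.
#'
#' @param blocking numeric series of per-period blocking probabilities
#'   (length >= 2).
#' @param tolerance maximum allowed change (fraction) after warm-up.
#' @param window moving-average width for the change series (default 1 =
#'   raw differences).
#' @return integer number of warm-up periods: 0 when the series is stable
#'   from the start, the series length when it never stabilizes.
#' @export
detect_warmup <- function(blocking, tolerance, window = 1L) {
  if (length(blocking) < 2)
    stop("detect_warmup: series must have length >= 2", call. = FALSE)
  stopifnot(tolerance >= 0, window >= 1)
  d <- abs(diff(blocking))
  if (window > 1) {
    d <- stats::filter(d, rep(1 / window, window), sides = 1)
    d[is.na(d)] <- d[!is.na(d)][1]
  }
  viol <- which(d > tolerance)
  if (!length(viol)) return(0L)
  last <- max(viol)
  if (last >= length(d)) return(length(blocking))
  as.integer(last)
}

#' Validate simulated means against an observed system mean
#'
#' One-sample location test (Student t) of the per-replication mean waits
#' against the observed real-system mean, with a confidence interval for the
#' simulated mean. The degenerate zero-variance case is reported rather than
#' erroring: p = 1 when all replications equal the observed mean, p = 0
#' (flagged) otherwise.
#'
#' @param per_replication_means numeric vector of replication means
#'   (length >= 2).
#' @param observed_mean observed mean waiting time (minutes).
#' @param confidence confidence level (default 0.95).
#' @return list with \code{statistic}, \code{p_value}, \code{ci},
#'   \code{mean}, \code{degenerate} flag.
#' @export
validate_against_observed <- function(per_replication_means, observed_mean,
                                      confidence = 0.95) {
  x <- per_replication_means
  if (length(x) < 2)
    stop("need >= 2 replication means", call. = FALSE)
  if (stats::sd(x) == 0) {
    eq <- isTRUE(all.equal(x[1], observed_mean))
    return(list(statistic = if (eq) 0 else Inf,
                p_value = if (eq) 1 else 0,
                ci = c(x[1], x[1]), mean = x[1], degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = observed_mean, conf.level = confidence)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       ci = unname(tt$conf.int), mean = mean(x), degenerate = FALSE)
}

#' Compare waiting times between two network configurations
#'
#' Two-sample rank test (Wilcoxon/Mann-Whitney) of the proposed
#' configuration's waits against the current ones, with a confidence
#' interval for the location difference. Direction convention: differences
#' are proposed minus current, so a negative interval means the proposed
#' network reduces waiting times.
#'
#' @param waits_current,waits_proposed nonempty numeric vectors of waiting
#'   times (minutes).
#' @param confidence confidence level (default 0.95).
#' @return list with \code{statistic} (W), \code{p_value}, \code{ci}
#'   (location difference, proposed - current), \code{estimate}.
#' @export
compare_scenarios <- function(waits_current, waits_proposed,
                              confidence = 0.95) {
  if (!length(waits_current) || !length(waits_proposed))
    stop("both samples must be nonempty", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(waits_proposed, waits_current, conf.int = TRUE,
                       conf.level = confidence, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       ci = unname(wt$conf.int), estimate = unname(wt$estimate))
}
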