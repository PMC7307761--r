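# Input modeling for the simulator: randomness (runs test), homogeneity
# (Kruskal-Wallis), chi-squared goodness of fit with equal-probability
# binning, and the weekday-by-slot partitioning of arrival streams into 21
# pipelines.

#' Runs test for randomness about the median
#'
#' Counts runs of the series above/below its median (observations equal to
#' the median are dropped) and applies the normal approximation for the run
#' count, with a two-sided p-value. Both the raw run count and the
#' standardized statistic are reported.
#'
#' @param series numeric vector, length >= 10, not all equal.
#' @param alpha significance level for the randomness verdict (default
#'   0.05).
#' @return an object of class \code{ecn_runs}: \code{runs} (raw count),
#'   \code{k} (standardized statistic), \code{expected_runs},
#'   \code{p_value}, \code{random} (logical at \code{alpha}), \code{n1},
#'   \code{n2}.
#' @export
runs_test <- function(series, alpha = 0.05) {
  if (length(series) < 10)
    stop("need at least 10 observations", call. = FALSE)
  med <- stats::median(series)
  x <- series[series != med]
  if (length(x) < 2 || length(unique(x)) < 2)
    ecn_error("ecn_degenerate_error",
              "series is (near-)constant; runs test undefined")
  above <- x > med
  n1 <- sum(above); n2 <- sum(!above)
  runs <- 1L + sum(above[-1] != above[-length(above)])
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(runs = runs, k = z, expected_runs = mu, p_value = p,
                 random = p >= alpha, n1 = n1, n2 = n2),
            class = "ecn_runs")
}

#' @export
print.ecn_runs <- function(x, ...) {
  cat("<ecn_runs> ", x$runs, " runs (expected ",
      format(x$expected_runs, digits = 5), "), z = ",
      format(x$k, digits = 4), ", p = ", format(x$p_value, digits = 4),
      " -> ", if (x$random) "random" else "non-random", "\n", sep = "")
  invisible(x)
}

#' Homogeneity test across groups
#'
#' Rank-based k-sample (Kruskal-Wallis) test of whether the groups share a
#' common distribution; the conclusion label mirrors the usual input-model
#' summary: "Homogeneous" when p >= 0.05, "Heterogeneous" otherwise.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @return list with \code{statistic}, \code{p_value}, \code{conclusion}.
#' @export
homogeneity_test <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       conclusion = if (kt$p.value >= alpha) "Homogeneous"
                    else "Heterogeneous")
}

# supported candidate families and their free-parameter counts for the
# chi-squared degrees of freedom
GOF_NPAR <- c(exponential = 1L, gamma = 2L, lognormal = 2L, normal = 2L,
              uniform = 2L, triangular = 2L)

fit_family <- function(series, family) {
  n <- length(series)
  switch(family,
    exponential = {
      fit <- list(rate = 1 / base::mean(series))
      list(par = fit, q = function(p) stats::qexp(p, fit$rate))
    },
    gamma = {
      fd <- fitdistrplus::fitdist(series, "gamma", method = "mle")
      par <- as.list(fd$estimate)
      list(par = par, q = function(p)
        stats::qgamma(p, shape = par$shape, rate = par$rate))
    },
    lognormal = {
      par <- list(meanlog = base::mean(log(series)),
                  sdlog = stats::sd(log(series)))
      list(par = par, q = function(p)
        stats::qlnorm(p, par$meanlog, par$sdlog))
    },
    normal = {
      par <- list(mean = base::mean(series), sd = stats::sd(series))
      list(par = par, q = function(p) stats::qnorm(p, par$mean, par$sd))
    },
    uniform = {
      par <- list(min = min(series), max = max(series))
      list(par = par, q = function(p) stats::qunif(p, par$min, par$max))
    },
    triangular = {
      # moment-matched symmetric triangle
      d <- dist_from_moments("triangular", base::mean(series),
                             stats::var(series))
      list(par = list(min = d$min, mode = d$mode, max = d$max),
           q = function(p) qtri(p, d$min, d$mode, d$max))
    },
    stop("unsupported family: ", family, call. = FALSE))
}

qtri <- function(p, a, c, b) {
  fc <- if (b > a) (c - a) / (b - a) else 0.5
  ifelse(p < fc,
         a + sqrt(p * (b - a) * (c - a)),
         b - sqrt((1 - p) * (b - a) * (b - c)))
}

#' Chi-squared goodness of fit over candidate families
#'
#' Estimates each candidate family's parameters from the series (maximum
#' likelihood where available, moment matching otherwise), bins the data
#' into equal-probability cells under the fitted distribution —
#' \code{max(5, floor(n/50))} bins, capped at 30 — and computes the
#' chi-squared statistic with \code{bins - 1 - n_parameters} degrees of
#' freedom. Results are ranked best-first by p-value.
#'
#' @param series numeric vector, length >= 30, non-degenerate.
#' @param candidates character vector of family names among
#'   \code{exponential}, \code{gamma}, \code{lognormal}, \code{normal},
#'   \code{uniform}, \code{triangular}.
#' @param alpha acceptance level (default 0.05).
#' @return data.frame, one row per candidate, best-first: \code{family},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{accepted}; fitted
#'   parameters attached as attribute \code{"fits"}.
#' @export
fit_distribution <- function(series, candidates, alpha = 0.05) {
  if (length(series) < 30)
    stop("need at least 30 observations", call. = FALSE)
  if (stats::sd(series) == 0)
    ecn_error("ecn_degenerate_error", "constant series cannot be fitted")
  if (!length(candidates)) stop("need at least one candidate", call. = FALSE)
  candidates <- match.arg(candidates, names(GOF_NPAR), several.ok = TRUE)
  n <- length(series)
  k <- min(30L, max(5L, floor(n / 50)))
  rows <- list(); fits <- list()
  for (fam in candidates) {
    f <- fit_family(series, fam)
    brk <- f$q(seq(0, 1, length.out = k + 1))
    brk[1] <- -Inf; brk[k + 1] <- Inf
    obs <- tabulate(findInterval(series, brk, rightmost.closed = TRUE),
                    nbins = k)
    expd <- rep(n / k, k)
    stat <- sum((obs - expd)^2 / expd)
    df <- max(1L, k - 1L - GOF_NPAR[[fam]])
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    rows[[fam]] <- data.frame(family = fam, statistic = stat, df = df,
                              p_value = p, accepted = p >= alpha,
                              stringsAsFactors = FALSE)
    fits[[fam]] <- f$par
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Partition arrival timestamps into the 21 weekday-by-slot pipelines
#'
#' Assigns each arrival to one of the 21 (weekday, slot) cells with
#' half-open slot boundaries P1 = [00:00, 08:00), P2 = [08:00, 16:00),
#' P3 = [16:00, 24:00), computes interarrival gaps within each cell (gaps
#' are taken between consecutive arrivals inside the same calendar-day
#' slot block, then pooled by cell across weeks), and runs an across-cell
#' test of whether partitioning is warranted. The across-cell test is
#' rank-based (Kruskal-Wallis) by default, interarrival gaps being skewed;
#' a classical one-way ANOVA F-test is available.
#'
#' @param timestamps sorted \code{POSIXct} arrival times.
#' @param test \code{"kruskal"} (default) or \code{"anova"}.
#' @param alpha significance level (default 0.05).
#' @return an object of class \code{ecn_pipelines}: \code{cells} (data
#'   frame with weekday, slot and count per cell — always 21 rows),
#'   \code{interarrivals} (named list of per-cell gap vectors, minutes),
#'   \code{assignment} (cell key per arrival), \code{p_value} and
#'   \code{heterogeneous} (the partition verdict).
#' @export
partition_arrivals <- function(timestamps, test = c("kruskal", "anova"),
                               alpha = 0.05) {
  test <- match.arg(test)
  if (is.unsorted(as.numeric(timestamps)))
    stop("timestamps must be sorted", call. = FALSE)
  lt <- as.POSIXlt(timestamps)
  wd <- ECN_WEEKDAYS[((lt$wday + 6L) %% 7L) + 1L]  # POSIXlt: 0 = Sunday
  slot <- ECN_SLOTS[lt$hour %/% 8L + 1L]
  key <- paste(wd, slot, sep = ".")
  day_block <- paste(format(timestamps, "%Y-%m-%d"), slot)
  gaps <- split(data.frame(t = as.numeric(timestamps), block = day_block,
                           key = key, stringsAsFactors = FALSE), key)
  all_keys <- paste(rep(ECN_WEEKDAYS, each = 3), ECN_SLOTS, sep = ".")
  inter <- stats::setNames(vector("list", 21L), all_keys)
  for (kk in all_keys) {
    g <- gaps[[kk]]
    inter[[kk]] <- if (is.null(g)) numeric(0) else
      unlist(lapply(split(g$t, g$block), function(tt)
        if (length(tt) > 1) diff(tt) / 60 else numeric(0)),
        use.names = FALSE)
  }
  cells <- data.frame(
    weekday = rep(ECN_WEEKDAYS, each = 3), slot = rep(ECN_SLOTS, 7),
    count = vapply(all_keys, function(kk) sum(key == kk), integer(1)),
    stringsAsFactors = FALSE)
  nonempty <- inter[lengths(inter) >= 2]
  pv <- if (length(nonempty) >= 2) {
    if (test == "kruskal") stats::kruskal.test(nonempty)$p.value
    else {
      vals <- unlist(nonempty, use.names = FALSE)
      grp <- factor(rep(names(nonempty), lengths(nonempty)))
      stats::anova(stats::lm(vals ~ grp))[["Pr(>F)"]][1]
    }
  } else NA_real_
  structure(list(cells = cells, interarrivals = inter, assignment = key,
                 p_value = pv,
                 heterogeneous = isTRUE(!is.na(pv) && pv < alpha)),
            class = "ecn_pipelines")
}

#' @export
print.ecn_pipelines <- function(x, ...) {
  cat("<ecn_pipelines> ", sum(x$cells$count), " arrivals over 21 cells; ",
      "across-cell p = ", format(x$p_value, digits = 4), " -> ",
      if (isTRUE(x$heterogeneous)) "slot partitioning warranted"
      else "no partition needed", "\n", sep = "")
  invisible(x)
}
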