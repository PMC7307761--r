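#' Distribution specifications for service and interarrival times
#'
#' Every stochastic duration in a network scenario (interarrival times per
#' weekday/slot pipeline, per-stage service times) is described by a small
#' distribution specification: a family name plus its parameters, in minutes.
#' The supported vocabulary is \code{exponential}, \code{gamma},
#' \code{lognormal}, \code{triangular}, \code{uniform} and
#' \code{deterministic}. Families parameterized by moments are constructed by
#' moment matching via [dist_from_moments()].
#'
#' @param family character; one of the supported family names.
#' @param ... numeric parameters. Expected fields per family:
#'   \code{exponential}: \code{mean};
#'   \code{gamma}: \code{shape}, \code{rate};
#'   \code{lognormal}: \code{meanlog}, \code{sdlog};
#'   \code{triangular}: \code{min}, \code{mode}, \code{max};
#'   \code{uniform}: \code{min}, \code{max};
#'   \code{deterministic}: \code{value}.
#' @return an object of class \code{ecn_dist}.
#' @export
#' @examples
#' d <- dist_spec("exponential", mean = 10)
#' dist_mean(d)
dist_spec <- function(family, ...) {
  family <- match.arg(family, c("exponential", "gamma", "lognormal",
                                "triangular", "uniform", "deterministic"))
  par <- list(...)
  needed <- switch(family,
    exponential   = "mean",
    gamma         = c("shape", "rate"),
    lognormal     = c("meanlog", "sdlog"),
    triangular    = c("min", "mode", "max"),
    uniform       = c("min", "max"),
    deterministic = "value")
  missing <- setdiff(needed, names(par))
  if (length(missing))
    stop("dist_spec('", family, "'): missing parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  par <- lapply(par[needed], as.numeric)
  if (any(!vapply(par, is.finite, logical(1))))
    stop("dist_spec: parameters must be finite", call. = FALSE)
  if (family == "triangular" &&
      !(par$min <= par$mode && par$mode <= par$max))
    stop("dist_spec('triangular'): need min <= mode <= max", call. = FALSE)
  if (family == "uniform" && par$min > par$max)
    stop("dist_spec('uniform'): need min <= max", call. = FALSE)
  structure(c(list(family = family), par), class = "ecn_dist")
}

#' Build a distribution specification by moment matching
#'
#' Converts a (mean, variance) pair into the parameters of the requested
#' family. For the triangular family a symmetric triangle around the mean is
#' used (variance of a symmetric triangular on \code{[a, b]} is
#' \code{(b - a)^2 / 24}).
#'
#' @param family family name (see [dist_spec()]).
#' @param mean target mean (minutes), > 0 for positive families.
#' @param var target variance (minutes squared); ignored where the family has
#'   a single parameter (\code{exponential}, \code{deterministic}).
#' @return an \code{ecn_dist} object whose mean (and, where the family has
#'   two free parameters, variance) matches the request.
#' @export
dist_from_moments <- function(family, mean, var = NULL) {
  family <- match.arg(family, c("exponential", "gamma", "lognormal",
                                "triangular", "uniform", "deterministic"))
  if (!is.numeric(mean) || !is.finite(mean))
    stop("dist_from_moments: 'mean' must be finite", call. = FALSE)
  if (family %in% c("exponential", "deterministic")) {
    return(switch(family,
      exponential   = dist_spec("exponential", mean = mean),
      deterministic = dist_spec("deterministic", value = mean)))
  }
  if (is.null(var) || !is.finite(var) || var <= 0)
    stop("dist_from_moments('", family, "'): positive 'var' required",
         call. = FALSE)
  switch(family,
    gamma = dist_spec("gamma", shape = mean^2 / var, rate = mean / var),
    lognormal = {
      s2 <- log(1 + var / mean^2)
      dist_spec("lognormal", meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    triangular = {
      h <- sqrt(6 * var)  # half-width of symmetric triangle
      dist_spec("triangular", min = mean - h, mode = mean, max = mean + h)
    },
    uniform = {
      h <- sqrt(3 * var)
      dist_spec("uniform", min = mean - h, max = mean + h)
    })
}

#' Theoretical mean of a distribution specification
#' @param d an \code{ecn_dist}.
#' @return numeric mean in minutes.
#' @export
dist_mean <- function(d) {
  stopifnot(inherits(d, "ecn_dist"))
  switch(d$family,
    exponential   = d$mean,
    gamma         = d$shape / d$rate,
    lognormal     = exp(d$meanlog + d$sdlog^2 / 2),
    triangular    = (d$min + d$mode + d$max) / 3,
    uniform       = (d$min + d$max) / 2,
    deterministic = d$value)
}

#' Theoretical variance of a distribution specification
#' @param d an \code{ecn_dist}.
#' @return numeric variance in minutes squared.
#' @export
dist_var <- function(d) {
  stopifnot(inherits(d, "ecn_dist"))
  switch(d$family,
    exponential   = d$mean^2,
    gamma         = d$shape / d$rate^2,
    lognormal     = (exp(d$sdlog^2) - 1) * exp(2 * d$meanlog + d$sdlog^2),
    triangular    = (d$min^2 + d$mode^2 + d$max^2 -
                     d$min * d$mode - d$min * d$max - d$mode * d$max) / 18,
    uniform       = (d$max - d$min)^2 / 12,
    deterministic = 0)
}

#' Draw random variates from a distribution specification
#'
#' Uses the session RNG stream, so results are reproducible under
#' \code{set.seed()}. Draws from location-shifted families
#' (triangular/uniform constructed by moment matching) are truncated at zero,
#' durations being nonnegative.
#'
#' @param d an \code{ecn_dist}.
#' @param n number of draws.
#' @return numeric vector of length \code{n}.
#' @export
draw_dist <- function(d, n = 1L) {
  stopifnot(inherits(d, "ecn_dist"))
  x <- switch(d$family,
    exponential   = stats::rexp(n, rate = 1 / d$mean),
    gamma         = stats::rgamma(n, shape = d$shape, rate = d$rate),
    lognormal     = stats::rlnorm(n, meanlog = d$meanlog, sdlog = d$sdlog),
    triangular    = rtri(n, d$min, d$mode, d$max),
    uniform       = stats::runif(n, d$min, d$max),
    deterministic = rep.int(d$value, n))
  pmax(x, 0)
}

# inverse-CDF sampler for the triangular distribution
rtri <- function(n, a, c, b) {
  u <- stats::runif(n)
  fc <- if (b > a) (c - a) / (b - a) else 0.5
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

# plain-list (de)serialization used by the scenario YAML/JSON round trip
dist_to_list <- function(d) unclass(d)

dist_from_list <- function(x) {
  do.call(dist_spec, c(list(family = x$family),
                       x[setdiff(names(x), "family")]))
}
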