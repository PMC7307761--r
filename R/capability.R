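# Six-sigma waiting-time diagnostics against an upper specification limit
# (USL). One-sided by construction: waiting time has no lower spec. Under a
# normal model, Zu = (USL - mean)/sd standardizes the distance to the
# limit; Cps = Zu/3; P(error) is the upper-tail probability beyond the USL;
# PPM scales it to defects per million; the short-term sigma level equals
# Zu and the long-term level applies the conventional 1.5-sigma shift.

#' Capability metrics for a waiting-time process
#'
#' @param mean process mean (minutes).
#' @param sd process standard deviation (minutes), > 0.
#' @param usl upper specification limit (minutes).
#' @return an object of class \code{ecn_capability}: \code{usl},
#'   \code{mean}, \code{sd}, \code{zu}, \code{cps}, \code{p_error},
#'   \code{ppm}, \code{efficiency}, \code{sigma_short}, \code{sigma_long}.
#' @export
#' @examples
#' r <- capability_metrics(201.6, 81.6, 30)
#' round(r$zu, 2)          # -2.10
#' round(r$sigma_long, 2)  # -3.60
capability_metrics <- function(mean, sd, usl) {
  if (!is.numeric(sd) || sd <= 0)
    stop("sd must be > 0", call. = FALSE)
  zu <- (usl - mean) / sd
  p_err <- stats::pnorm(zu, lower.tail = FALSE)
  structure(list(
    usl = usl, mean = mean, sd = sd,
    zu = zu, cps = zu / 3,
    p_error = p_err, ppm = 1e6 * p_err, efficiency = 1 - p_err,
    sigma_short = zu, sigma_long = zu - 1.5),
    class = "ecn_capability")
}

#' @export
print.ecn_capability <- function(x, ...) {
  cat("<ecn_capability> USL ", x$usl, " min | mean ", format(x$mean),
      ", sd ", format(x$sd, digits = 5), "\n",
      "  Zu = ", round(x$zu, 2), "  Cps = ", round(x$cps, 2),
      "  PPM = ", round(x$ppm, 1),
      "  efficiency = ", sprintf("%.2f%%", 100 * x$efficiency), "\n",
      "  sigma: short-term ", round(x$sigma_short, 2),
      ", long-term ", round(x$sigma_long, 2), "\n", sep = "")
  if (!is.null(x$normality_p))
    cat("  normality p-value: ", format(x$normality_p, digits = 3),
        if (isTRUE(x$normality_warning)) "  ** non-normal: report with care"
        , "\n", sep = "")
  invisible(x)
}

#' Capability report from a waiting-time series
#'
#' Estimates mean and standard deviation from the data, runs a
#' correlation-based normality check (Shapiro-Francia, of the Ryan-Joiner
#' family; applied to at most 5,000 points for longer series) and delegates
#' to [capability_metrics()]. The report carries the normality p-value; a
#' warning is raised when it is below 0.05, since the PPM/sigma figures
#' assume normal waits.
#'
#' @param waits numeric waiting-time series (minutes), length >= 3.
#' @param usl upper specification limit (minutes).
#' @return an \code{ecn_capability} with extra fields \code{n},
#'   \code{normality_p}, \code{normality_warning}.
#' @export
capability_from_series <- function(waits, usl) {
  if (length(waits) < 3)
    stop("need at least 3 observations", call. = FALSE)
  s <- stats::sd(waits)
  if (s == 0) stop("sd must be > 0 (constant series)", call. = FALSE)
  x <- if (length(waits) > 5000) waits[seq_len(5000)] else waits
  np <- if (length(x) >= 5) nortest::sf.test(x)$p.value else NA_real_
  rep <- capability_metrics(base::mean(waits), s, usl)
  rep$n <- length(waits)
  rep$normality_p <- np
  rep$normality_warning <- isTRUE(!is.na(np) && np < 0.05)
  if (rep$normality_warning)
    warning("waiting times look non-normal (p = ",
            format(np, digits = 3),
            "); capability indices assume normality")
  rep
}

#' Individuals / moving-range control chart
#'
#' X-mR chart for individual waiting-time observations: individuals limits
#' are the mean plus/minus 2.66 times the mean moving range; the
#' moving-range chart's upper limit is 3.267 times the mean moving range
#' (lower limit 0). Out-of-control points fall outside [LCL, UCL].
#'
#' @param series numeric vector, length >= 2.
#' @return an object of class \code{ecn_chart}: \code{center}, \code{ucl},
#'   \code{lcl}, \code{mr_center}, \code{mr_ucl}, \code{out_of_control}
#'   (indices), and the point data.
#' @export
#' @examples
#' individuals_chart(c(10, 12, 11))$ucl  # 14.99
individuals_chart <- function(series) {
  if (length(series) < 2)
    stop("need at least 2 observations", call. = FALSE)
  center <- base::mean(series)
  mr <- abs(diff(series))
  mr_bar <- base::mean(mr)
  ucl <- center + 2.66 * mr_bar
  lcl <- center - 2.66 * mr_bar
  ooc <- which(series > ucl | series < lcl)
  structure(list(center = center, ucl = ucl, lcl = lcl,
                 mr_center = mr_bar, mr_ucl = 3.267 * mr_bar, mr_lcl = 0,
                 out_of_control = ooc, series = series,
                 moving_range = mr),
            class = "ecn_chart")
}

#' @export
print.ecn_chart <- function(x, ...) {
  cat("<ecn_chart> individuals: center ", format(x$center, digits = 5),
      ", limits [", format(x$lcl, digits = 5), ", ",
      format(x$ucl, digits = 5), "]; MR-bar ",
      format(x$mr_center, digits = 5), "\n",
      "  out-of-control points: ",
      if (length(x$out_of_control))
        paste(x$out_of_control, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
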