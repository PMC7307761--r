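# FMEA prioritization of network operating risks: RPN = severity x
# frequency x detection, each scored 1-10. High-RPN risks (> 125) with
# significant severity (S >= 8) are flagged "double-star"; high-RPN risks
# with lower severity get "single-star". The published rule leaves S = 7
# unassigned between its two bands; it is mapped to single-star here (the
# severity test for the double flag is S >= 8).

#' Score and prioritize failure modes
#'
#' @param items data.frame with columns \code{failure} (label),
#'   \code{severity}, \code{frequency}, \code{detection} — all integer
#'   scores in 1-10.
#' @param rpn_threshold RPN above which a risk is prioritized (default
#'   125).
#' @param severity_cut minimum severity for the double-star flag (default
#'   8).
#' @return data.frame sorted by RPN descending (ties by severity then
#'   label): input columns plus \code{rpn} and \code{flag} in
#'   \code{c("double-star", "single-star", "none")}.
#' @export
#' @examples
#' score_risks(data.frame(failure = "delay to triage",
#'                        severity = 10, frequency = 9, detection = 5))
score_risks <- function(items, rpn_threshold = 125, severity_cut = 8) {
  stopifnot(all(c("failure", "severity", "frequency", "detection")
                %in% names(items)))
  sc <- as.matrix(items[, c("severity", "frequency", "detection")])
  if (any(sc < 1 | sc > 10 | sc != floor(sc)))
    stop("severity, frequency and detection must be integers in 1-10",
         call. = FALSE)
  out <- items
  out$rpn <- items$severity * items$frequency * items$detection
  out$flag <- ifelse(out$rpn > rpn_threshold,
                     ifelse(items$severity >= severity_cut,
                            "double-star", "single-star"),
                     "none")
  out <- out[order(-out$rpn, -out$severity, out$failure), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write risk registers as CSV
#'
#' @param path CSV with columns failure, severity, frequency, detection.
#' @param ... passed to [score_risks()].
#' @return scored register (see [score_risks()]).
#' @export
read_risk_register <- function(path, ...) {
  score_risks(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}
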