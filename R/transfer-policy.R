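#' Construct a patient-transfer policy
#'
#' The network's transfer rules: only triage-4/5 patients are transfer
#' candidates; both origin and destination must hold an agreement with the
#' patient's insurer (uncovered patients are never transferred — patient
#' dumping is prohibited); a patient is transferred only when the origin's
#' expected wait exceeds the best candidate's expected wait plus the
#' transfer time, choosing the candidate with the lowest sum.
#'
#' Two operating modes are provided. \code{"dynamic"} estimates destination
#' waits from the live simulation state at the decision epoch (the epoch is
#' immediately after triage completion); \code{"planning"} uses a static
#' table of per-node mean waits — the desk-planning view used when sizing a
#' network from published node summaries.
#'
#' @param mode \code{"dynamic"} or \code{"planning"}.
#' @param static_waits named numeric vector of per-node expected waits
#'   (minutes), required in planning mode. [planning_waits()] builds it from
#'   a scenario's post-improvement node moments.
#' @param allow_retransfer may a transferred patient be transferred again
#'   from the destination? Default \code{FALSE} (one transfer at most).
#' @return an object of class \code{ecn_policy}.
#' @export
transfer_policy <- function(mode = c("dynamic", "planning"),
                            static_waits = NULL, allow_retransfer = FALSE) {
  mode <- match.arg(mode)
  if (mode == "planning" &&
      (is.null(static_waits) || is.null(names(static_waits))))
    stop("planning mode needs a named static_waits vector", call. = FALSE)
  structure(list(mode = mode, static_waits = static_waits,
                 allow_retransfer = allow_retransfer),
            class = "ecn_policy")
}

#' Static per-node planning waits from a scenario
#'
#' Extracts each enabled node's post-improvement mean waiting time as the
#' static expected-wait table used by the planning-mode policy.
#'
#' @param scenario an \code{ecn_scenario}.
#' @return named numeric vector (minutes) over enabled nodes.
#' @export
planning_waits <- function(scenario) {
  en <- Filter(ed_enabled, scenario$nodes)
  stats::setNames(vapply(en, `[[`, numeric(1), "post_lss_wait_mean"),
                  vapply(en, `[[`, character(1), "id"))
}

#' Destinations a patient is eligible to be transferred to
#'
#' Applies the eligibility policies: only triage levels 4 and 5 qualify;
#' candidates are all ED-enabled nodes other than the origin holding an
#' agreement with the patient's insurer, provided the origin holds one too;
#' uncovered patients get no candidates and are treated at the origin.
#'
#' @param triage_level patient triage level (1-5).
#' @param insurer patient insurer label, or \code{"UNCOVERED"}.
#' @param origin origin node id.
#' @param scenario an \code{ecn_scenario}.
#' @return character vector of candidate node ids (sorted; possibly empty).
#' @export
eligible_destinations <- function(triage_level, insurer, origin, scenario) {
  stopifnot(origin %in% names(scenario$nodes))
  if (!(triage_level %in% 4:5)) return(character(0))
  if (identical(insurer, "UNCOVERED") || is.na(insurer))
    return(character(0))
  if (!insurer %in% scenario$insurers$insurer)
    ecn_error("ecn_configuration_error",
              paste0("unknown insurer: ", insurer))
  if (!insurer %in% scenario$nodes[[origin]]$insurers) return(character(0))
  cand <- Filter(function(nd) {
    nd$id != origin && ed_enabled(nd) && insurer %in% nd$insurers
  }, scenario$nodes)
  sort(unname(vapply(cand, `[[`, character(1), "id")))
}

#' Ex-ante expected door-to-physician wait
#'
#' The default load-based estimator: patients ahead of the arriving patient
#' (queued at or above the arriving priority, plus those currently in
#' pre-physician service) times the mean pre-physician service time, divided
#' by the effective number of servers.
#'
#' @param n_ahead patients ahead at the decision epoch.
#' @param mean_service mean pre-physician service time (minutes).
#' @param servers effective server count (>= 1).
#' @return expected wait in minutes (nonnegative).
#' @export
#' @examples
#' expected_wait(4, 10, 2)  # 20 minutes
expected_wait <- function(n_ahead, mean_service, servers = 1) {
  stopifnot(n_ahead >= 0, mean_service >= 0, servers >= 1)
  n_ahead * mean_service / servers
}

#' Decide whether and where to transfer a patient
#'
#' Scores every candidate destination as its expected wait plus the
#' slot-specific transfer time from the origin, and applies the transfer
#' inequality: transfer when the lowest score beats the origin's expected
#' wait, otherwise stay. Ties between candidates break deterministically to
#' the lexicographically first node id.
#'
#' @param origin origin node id.
#' @param candidates character vector of candidate node ids (may be empty).
#' @param estimates named numeric vector of expected waits (minutes),
#'   covering the origin and every candidate.
#' @param transfer_times square transfer-time matrix for the decision slot.
#' @param patient_id optional identifier echoed in the decision.
#' @return an object of class \code{ecn_decision}: list with
#'   \code{patient_id}, \code{origin}, \code{verdict} ("stay"/"transfer"),
#'   \code{destination} (or \code{NA}), \code{candidate_scores} and
#'   \code{origin_expected_wait}.
#' @export
select_destination <- function(origin, candidates, estimates, transfer_times,
                               patient_id = NA) {
  candidates <- unname(candidates)
  need <- c(origin, candidates)
  if (!all(need %in% names(estimates)))
    ecn_error("ecn_configuration_error",
              paste0("estimates missing for: ",
                     paste(setdiff(need, names(estimates)), collapse = ", ")))
  if (!origin %in% rownames(transfer_times) ||
      !all(candidates %in% colnames(transfer_times)))
    ecn_error("ecn_configuration_error",
              paste0("missing transfer time ", origin, " -> ",
                     paste(setdiff(candidates, colnames(transfer_times)),
                           collapse = ", ")))
  origin_wait <- unname(estimates[[origin]])
  if (!length(candidates)) {
    return(structure(list(patient_id = patient_id, origin = origin,
                          verdict = "stay", destination = NA_character_,
                          candidate_scores = numeric(0),
                          origin_expected_wait = origin_wait),
                     class = "ecn_decision"))
  }
  candidates <- sort(candidates)
  tt <- transfer_times[origin, candidates]
  if (any(is.na(tt)))
    ecn_error("ecn_configuration_error",
              paste0("missing transfer time ", origin, " -> ",
                     paste(candidates[is.na(tt)], collapse = ", ")))
  scores <- stats::setNames(unname(estimates[candidates]) + unname(tt),
                            candidates)
  b <- which.min(scores)  # first minimum = lexicographically lowest id
  transfer <- unname(scores[b]) < origin_wait
  structure(list(
    patient_id = patient_id, origin = origin,
    verdict = if (transfer) "transfer" else "stay",
    destination = if (transfer) candidates[b] else NA_character_,
    candidate_scores = scores,
    origin_expected_wait = origin_wait),
    class = "ecn_decision")
}

#' @export
print.ecn_decision <- function(x, ...) {
  cat("<ecn_decision> ", x$origin, ": ", x$verdict,
      if (x$verdict == "transfer")
        paste0(" -> ", x$destination, " (score ",
               format(min(x$candidate_scores), digits = 4), " < origin ",
               format(x$origin_expected_wait, digits = 4), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Plan transfers for every origin in a scenario (planning mode)
#'
#' Applies [eligible_destinations()] and [select_destination()] for a
#' triage-4/5 patient of the given insurer at every enabled origin node,
#' using static planning waits and the transfer matrix of the given slot.
#'
#' @param scenario an \code{ecn_scenario}.
#' @param insurer insurer label (default the first roster entry).
#' @param slot time-slot label, default \code{"P2"} (afternoon decisions use
#'   the afternoon matrix).
#' @param triage_level 4 or 5.
#' @param waits static wait table; default [planning_waits()].
#' @return data.frame with one row per origin: verdict, destination, best
#'   score, origin wait.
#' @export
transfer_plan <- function(scenario, insurer = scenario$insurers$insurer[1],
                          slot = "P2", triage_level = 4L,
                          waits = planning_waits(scenario)) {
  tt <- scenario$transfer_times[[slot]]
  origins <- names(waits)
  rows <- lapply(origins, function(o) {
    cand <- eligible_destinations(triage_level, insurer, o, scenario)
    d <- select_destination(o, cand, waits, tt)
    data.frame(origin = o, verdict = d$verdict,
               destination = d$destination,
               best_score = if (length(d$candidate_scores))
                 min(d$candidate_scores) else NA_real_,
               origin_wait = d$origin_expected_wait,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
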