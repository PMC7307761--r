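#' @keywords internal
"_PACKAGE"

# canonical calendar labels: the simulated week starts Monday 00:00 and each
# day is partitioned into three 8-hour slots, half-open: P1 = [00:00, 08:00),
# P2 = [08:00, 16:00), P3 = [16:00, 24:00)
ECN_WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
ECN_SLOTS <- c("P1", "P2", "P3")

ecn_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL, ...)))
}

#' Describe one emergency-care node
#'
#' A node is either a hospital or a point of care (POC). A node whose
#' \code{beds} field is \code{NA} has its emergency department disabled: it
#' accepts no arrivals and is never a transfer destination until enabled.
#'
#' @param id unique node label.
#' @param node_class \code{"hospital"} or \code{"poc"}.
#' @param complexity ordinal complexity level, 1-3.
#' @param beds installed capacity (number of ED beds), or \code{NA} for a
#'   node that does not currently provide emergency care.
#' @param insurers character vector of insurer labels the node holds an
#'   agreement with.
#' @param demand_mean,demand_var semester demand (patients per semester) mean
#'   and variance.
#' @param wait_mean,wait_var baseline door-to-physician waiting time
#'   (minutes) mean and variance.
#' @param stage_servers named integer vector: servers per service stage, in
#'   flow order. Defaults to one server per standard stage.
#' @param stage_service named list of [dist_spec()] objects, one per stage.
#' @param pipelines named list of 21 interarrival [dist_spec()] objects keyed
#'   \code{"<weekday>.<slot>"} (e.g. \code{"Mon.P2"}), or \code{NULL} for a
#'   disabled node.
#' @param post_lss_wait_mean,post_lss_wait_var waiting-time moments after
#'   per-node process improvement, used by the planning-mode transfer policy.
#' @return an object of class \code{ecn_node}.
#' @export
node_spec <- function(id, node_class = c("poc", "hospital"), complexity = 2,
                      beds = NA_real_, insurers = character(),
                      demand_mean = NA_real_, demand_var = NA_real_,
                      wait_mean = NA_real_, wait_var = NA_real_,
                      stage_servers = NULL, stage_service = NULL,
                      pipelines = NULL,
                      post_lss_wait_mean = NA_real_,
                      post_lss_wait_var = NA_real_) {
  node_class <- match.arg(node_class)
  structure(list(
    id = as.character(id), node_class = node_class,
    complexity = complexity, beds = as.numeric(beds),
    insurers = as.character(insurers),
    demand_mean = as.numeric(demand_mean), demand_var = as.numeric(demand_var),
    wait_mean = as.numeric(wait_mean), wait_var = as.numeric(wait_var),
    stage_servers = stage_servers, stage_service = stage_service,
    pipelines = pipelines,
    post_lss_wait_mean = as.numeric(post_lss_wait_mean),
    post_lss_wait_var = as.numeric(post_lss_wait_var)),
    class = "ecn_node")
}

#' Is a node's emergency department enabled?
#' @param node an \code{ecn_node}.
#' @return logical.
#' @export
ed_enabled <- function(node) {
  !is.na(node$beds) && node$beds >= 1
}

#' Assemble a network scenario
#'
#' The scenario is the full description of an emergency care network: its
#' nodes, the slot-specific transfer-time matrices, the insurer roster with
#' affiliation counts and agreed unit utility values, the payment parameters
#' of the collateral settlement model, the population triage mix, and the
#' waiting-time standard (upper specification limit).
#'
#' @param nodes list of [node_spec()] objects.
#' @param transfer_times named list (one entry per slot \code{P1}-\code{P3})
#'   of square numeric matrices in minutes, dimnames = node ids, diagonal
#'   \code{NA}.
#' @param insurers data.frame with columns \code{insurer}, \code{affiliated}
#'   (patient counts) and \code{unit_utility_M} (USD per admission).
#' @param payment list with \code{gamma}, \code{theta} (triage-4 and triage-5
#'   population shares), \code{floors} (named numeric, arrangements
#'   \code{A}/\code{B}/\code{C}, USD) and \code{arrangement} (named character
#'   mapping each destination node id to an arrangement).
#' @param triage_mix numeric probabilities over triage levels 1-5, summing
#'   to 1.
#' @param usl waiting-time upper specification limit in minutes.
#' @param population list with counts \code{special_regime} and
#'   \code{uncovered}: patients without an insurer agreement, who may never
#'   be transferred but must still be treated at the origin node.
#' @param metadata free-form list (policy flags, provenance).
#' @param validate run [validate_scenario()] before returning.
#' @return an object of class \code{ecn_scenario}.
#' @export
network_scenario <- function(nodes, transfer_times, insurers, payment,
                             triage_mix, usl = 30,
                             population = list(special_regime = 0,
                                               uncovered = 0),
                             metadata = list(), validate = TRUE) {
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  s <- structure(list(
    nodes = nodes, transfer_times = transfer_times, insurers = insurers,
    payment = payment, triage_mix = triage_mix, usl = as.numeric(usl),
    population = population, metadata = metadata),
    class = "ecn_scenario")
  if (validate) validate_scenario(s)
  s
}

#' Validate a network scenario against all structural invariants
#'
#' Checks node-id uniqueness, bed/demand nonnegativity, insurer-roster
#' containment, pipeline completeness (21 weekday-by-slot cells for every
#' enabled node), transfer-matrix coverage and positivity, payment-parameter
#' ranges, the triage-mix simplex constraint and a positive USL. All
#' violations are collected and reported together.
#'
#' @param s an \code{ecn_scenario}.
#' @return \code{s}, invisibly, if valid; otherwise signals a condition of
#'   class \code{ecn_validation_error} (or \code{ecn_reference_error} when a
#'   matrix references an unknown node) whose message lists every offending
#'   field.
#' @export
validate_scenario <- function(s) {
  stopifnot(inherits(s, "ecn_scenario"))
  bad <- character()
  ids <- vapply(s$nodes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) bad <- c(bad, "nodes: duplicate node ids")
  roster <- as.character(s$insurers$insurer)

  for (nd in s$nodes) {
    pre <- paste0("node ", nd$id, ": ")
    if (!is.na(nd$beds) && (nd$beds < 1 || nd$beds != floor(nd$beds)))
      bad <- c(bad, paste0(pre, "beds must be a positive integer or NA"))
    for (f in c("demand_mean", "demand_var", "wait_mean", "wait_var"))
      if (!is.na(nd[[f]]) && nd[[f]] < 0)
        bad <- c(bad, paste0(pre, f, " must be nonnegative"))
    if (length(setdiff(nd$insurers, roster)))
      bad <- c(bad, paste0(pre, "insurers not in global roster: ",
                           paste(setdiff(nd$insurers, roster), collapse = ", ")))
    if (ed_enabled(nd)) {
      want <- paste(rep(ECN_WEEKDAYS, each = 3), ECN_SLOTS, sep = ".")
      if (is.null(nd$pipelines) || !setequal(names(nd$pipelines), want) ||
          length(nd$pipelines) != 21L)
        bad <- c(bad, paste0(pre, "enabled node needs exactly 21 ",
                             "weekday.slot arrival pipelines"))
      if (is.null(nd$stage_service) || is.null(nd$stage_servers) ||
          !identical(names(nd$stage_service), names(nd$stage_servers)))
        bad <- c(bad, paste0(pre, "stage_service and stage_servers must ",
                             "name the same stages in flow order"))
    }
  }

  if (!setequal(names(s$transfer_times), ECN_SLOTS))
    bad <- c(bad, "transfer_times: need one matrix per slot P1, P2, P3")
  for (sl in names(s$transfer_times)) {
    m <- s$transfer_times[[sl]]
    if (!setequal(rownames(m), ids) || !setequal(colnames(m), ids)) {
      extra <- setdiff(union(rownames(m), colnames(m)), ids)
      if (length(extra))
        ecn_error("ecn_reference_error",
                  paste0("transfer matrix ", sl,
                         " references unknown node(s): ",
                         paste(extra, collapse = ", ")))
      bad <- c(bad, paste0("transfer_times[", sl, "]: must cover all nodes"))
      next
    }
    off <- m[row(m) != col(m)]
    if (any(!is.na(off) & off <= 0))
      bad <- c(bad, paste0("transfer_times[", sl,
                           "]: off-diagonal entries must be > 0"))
  }

  if (any(s$insurers$affiliated < 0) || any(s$insurers$unit_utility_M <= 0))
    bad <- c(bad, "insurers: counts must be >= 0 and unit utilities > 0")

  p <- s$payment
  if (p$gamma < 0 || p$theta < 0 || p$gamma + p$theta > 1)
    bad <- c(bad, "payment: need 0 <= gamma, theta and gamma + theta <= 1")
  if (!setequal(names(p$floors), c("A", "B", "C")) || any(p$floors <= 0))
    bad <- c(bad, "payment: floors must be positive and named A, B, C")
  if (!all(ids %in% names(p$arrangement)) ||
      !all(p$arrangement %in% c("A", "B", "C")))
    bad <- c(bad, "payment: every destination node needs an arrangement in A/B/C")

  if (abs(sum(s$triage_mix) - 1) > 1e-8 || length(s$triage_mix) != 5L ||
      any(s$triage_mix < 0))
    bad <- c(bad, "triage_mix: five nonnegative probabilities summing to 1")
  if (!is.finite(s$usl) || s$usl <= 0)
    bad <- c(bad, "usl: must be > 0")

  if (length(bad))
    ecn_error("ecn_validation_error",
              paste0("invalid scenario:\n  - ",
                     paste(bad, collapse = "\n  - ")),
              fields = bad)
  invisible(s)
}

#' @export
print.ecn_scenario <- function(x, ...) {
  enabled <- vapply(x$nodes, ed_enabled, logical(1))
  cat("<ecn_scenario> ", length(x$nodes), " nodes (",
      sum(vapply(x$nodes, function(n) n$node_class == "hospital", logical(1))),
      " hospitals), ", sum(enabled), " with ED enabled\n", sep = "")
  cat("  insurers: ", paste(x$insurers$insurer, collapse = ", "), "\n", sep = "")
  cat("  USL: ", x$usl, " min; gamma = ", x$payment$gamma,
      ", theta = ", x$payment$theta, "\n", sep = "")
  invisible(x)
}

# ---- serialization -------------------------------------------------------

scenario_to_list <- function(s) {
  node_to_list <- function(nd) {
    out <- unclass(nd)
    if (!is.null(out$stage_service))
      out$stage_service <- lapply(out$stage_service, dist_to_list)
    if (!is.null(out$stage_servers))
      out$stage_servers <- as.list(out$stage_servers)
    if (!is.null(out$pipelines))
      out$pipelines <- lapply(out$pipelines, dist_to_list)
    out
  }
  list(
    nodes = lapply(unname(s$nodes), node_to_list),
    transfer_times = lapply(s$transfer_times, function(m)
      c(list(ids = rownames(m)),
        list(minutes = lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))))),
    insurers = list(insurer = as.character(s$insurers$insurer),
                    affiliated = s$insurers$affiliated,
                    unit_utility_M = s$insurers$unit_utility_M),
    payment = list(gamma = s$payment$gamma, theta = s$payment$theta,
                   floors = as.list(s$payment$floors),
                   arrangement = as.list(s$payment$arrangement)),
    triage_mix = unname(s$triage_mix),
    usl = s$usl,
    population = s$population,
    metadata = s$metadata)
}

scenario_from_list <- function(x, validate = TRUE) {
  node_from_list <- function(nl) {
    svc <- if (!is.null(nl$stage_service))
      lapply(nl$stage_service, dist_from_list)
    srv <- if (!is.null(nl$stage_servers))
      unlist(nl$stage_servers)
    pip <- if (!is.null(nl$pipelines)) lapply(nl$pipelines, dist_from_list)
    node_spec(id = nl$id, node_class = nl$node_class,
              complexity = nl$complexity,
              beds = if (is.null(nl$beds)) NA_real_ else nl$beds,
              insurers = unlist(nl$insurers),
              demand_mean = nl$demand_mean %||% NA_real_,
              demand_var = nl$demand_var %||% NA_real_,
              wait_mean = nl$wait_mean %||% NA_real_,
              wait_var = nl$wait_var %||% NA_real_,
              stage_servers = srv, stage_service = svc, pipelines = pip,
              post_lss_wait_mean = nl$post_lss_wait_mean %||% NA_real_,
              post_lss_wait_var = nl$post_lss_wait_var %||% NA_real_)
  }
  nodes <- lapply(x$nodes, node_from_list)
  tt <- lapply(x$transfer_times, function(tl) {
    ids <- unlist(tl$ids)
    m <- do.call(rbind, lapply(tl$minutes, function(r)
      vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))))
    dimnames(m) <- list(ids, ids)
    m
  })
  ins <- data.frame(insurer = unlist(x$insurers$insurer),
                    affiliated = unlist(x$insurers$affiliated),
                    unit_utility_M = unlist(x$insurers$unit_utility_M),
                    stringsAsFactors = FALSE)
  payment <- list(gamma = x$payment$gamma, theta = x$payment$theta,
                  floors = unlist(x$payment$floors),
                  arrangement = unlist(x$payment$arrangement))
  network_scenario(nodes, tt, ins, payment,
                   triage_mix = unlist(x$triage_mix), usl = x$usl,
                   population = lapply(x$population, as.numeric),
                   metadata = x$metadata %||% list(),
                   validate = validate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario to a YAML or JSON document
#'
#' @param s an \code{ecn_scenario}.
#' @param path output file; the extension selects the format unless
#'   \code{format} is given.
#' @param format \code{"yaml"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @seealso [load_scenario()] for the inverse; the round trip reproduces the
#'   scenario field for field.
#' @export
serialize_scenario <- function(s, path, format = NULL) {
  stopifnot(inherits(s, "ecn_scenario"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  x <- scenario_to_list(s)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
  invisible(path)
}

#' Load and validate a scenario document
#'
#' Reads a scenario description from YAML or JSON (the schema produced by
#' [serialize_scenario()]) and validates every structural invariant before
#' returning.
#'
#' @param path file path, or \code{NULL} when \code{text} is given.
#' @param text document text (alternative to \code{path}).
#' @return a validated \code{ecn_scenario}.
#' @export
load_scenario <- function(path = NULL, text = NULL) {
  if (is.null(path) && is.null(text))
    stop("load_scenario: give 'path' or 'text'", call. = FALSE)
  raw <- if (!is.null(text)) text else
    paste(readLines(path, warn = FALSE), collapse = "\n")
  x <- if (grepl("^\\s*\\{", raw)) {
    jsonlite::fromJSON(raw, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(raw)
  }
  scenario_from_list(x, validate = TRUE)
}

#' Read a transfer-time matrix from CSV
#'
#' The CSV must carry node ids as both header row and first column; empty or
#' \code{NA} cells mark the (unused) diagonal.
#'
#' @param path CSV file.
#' @return square numeric matrix with node-id dimnames.
#' @export
read_transfer_matrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !setequal(rownames(m), colnames(m)))
    ecn_error("ecn_validation_error",
              "transfer matrix CSV must be square with matching ids")
  m[colnames(m), , drop = FALSE][, colnames(m), drop = FALSE]
  m
}

#' Total population with access to the network
#'
#' Sum of insurer-affiliated patients plus the special-regime and uncovered
#' populations, i.e. everyone the network must be prepared to admit (patient
#' dumping being prohibited).
#'
#' @param s an \code{ecn_scenario}.
#' @return integer-valued count.
#' @export
population_with_access <- function(s) {
  sum(s$insurers$affiliated) + s$population$special_regime +
    s$population$uncovered
}
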