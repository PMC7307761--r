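# Report writers and run manifests. CSV dialect everywhere: UTF-8,
# comma-separated, header row, "." decimal separator.

# 32-bit FNV-1a content hash, used to fingerprint the scenario a run used
fnv1a <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    # xor on the low byte only; keeps everything inside integer range
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply split into 16-bit halves to stay exact
    h <- ((h %% 65536) * 16777619 +
            (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint a scenario
#'
#' Stable content hash of the serialized scenario, recorded in run
#' manifests so every artifact can be traced to the exact configuration
#' that produced it.
#'
#' @param s an \code{ecn_scenario}.
#' @return 8-hex-digit character hash.
#' @export
scenario_hash <- function(s) {
  fnv1a(jsonlite::toJSON(scenario_to_list(s), auto_unbox = TRUE,
                         digits = 10))
}

#' Write a run manifest
#'
#' Every CLI artifact directory carries exactly one manifest describing the
#' command, scenario fingerprint, seed and parameters that produced its
#' files.
#'
#' @param dir output directory.
#' @param command subcommand name.
#' @param scenario scenario used (or \code{NULL}).
#' @param seed seed used (or \code{NULL}).
#' @param params named list echoed verbatim.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, scenario = NULL, seed = NULL,
                           params = list()) {
  m <- list(command = command,
            scenario_hash = if (!is.null(scenario)) scenario_hash(scenario),
            seed = seed, params = params,
            tool = "ecnsim",
            version = as.character(utils::packageVersion("ecnsim")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(m, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Export a replication to CSV files
#'
#' Writes the patient log, per-node summary, transfer counts and daily
#' blocking series of a replication into a directory.
#'
#' @param rep an \code{ecn_replication}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
export_replication <- function(rep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$node_stats, file.path(dir, "node_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$transfer_counts, file.path(dir, "transfers.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$blocking_by_day, file.path(dir, "blocking.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Export coalition statements
#'
#' @param statements list of \code{ecn_statement} objects.
#' @param path base path; \code{<path>.csv} (long per-insurer table) and
#'   \code{<path>.json} are written.
#' @return invisible character vector of the two paths.
#' @export
export_statements <- function(statements, path) {
  long <- do.call(rbind, lapply(statements, function(s) {
    cbind(data.frame(origin = s$origin, destination = s$destination,
                     stringsAsFactors = FALSE), s$table)
  }))
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(long, csv, row.names = FALSE)
  jsonlite::write_json(
    lapply(statements, function(s)
      list(origin = s$origin, destination = s$destination,
           table = s$table,
           origin_total = round_half_up(s$origin_total),
           destination_total = round_half_up(s$destination_total))),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv, js))
}

#' Read a transfer ledger CSV
#'
#' Columns: \code{origin}, \code{destination}, \code{insurer}, \code{nap}
#' (count), \code{r}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ledger <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("origin", "destination", "insurer", "nap", "r")
  if (!all(need %in% names(d)))
    ecn_error("ecn_validation_error",
              paste0("ledger must have columns: ",
                     paste(need, collapse = ", ")))
  d
}
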