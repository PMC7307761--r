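# Discrete-event simulation of patient flow through an emergency care
# network. The engine is event-driven with two event classes (arrival /
# stage completion) plus transfer arrivals; stage queues are priority queues
# ordered by triage level (1 = most urgent) with FIFO within level. Beds are
# seized at the bed-preparation stage and released at departure. All
# randomness flows through the session RNG, so a fixed seed yields a
# bitwise-identical patient log.

# calendar-time helpers: minute 0 is Monday 00:00
minute_weekday <- function(t) (floor(t / 1440) %% 7) + 1L
minute_slot <- function(t) floor((t %% 1440) / 480) + 1L

#' Simulate an emergency care network
#'
#' Runs one replication of the network discrete-event model. Patients arrive
#' at each ED-enabled node according to its 21 weekday-by-slot interarrival
#' pipelines, flow through the node's service stages in order (by default
#' triage, admission, bed preparation, nursing assistance, physician
#' assessment, treatment), and depart. When a transfer policy is supplied,
#' triage-4/5 covered patients are evaluated for transfer immediately after
#' triage completion; a transferred patient travels for the slot-specific
#' transfer time and re-enters the destination at its post-triage point
#' (triage is not repeated). An arrival finding all beds occupied at its
#' bed-request epoch is counted as blocked but still queues.
#'
#' @param scenario a validated \code{ecn_scenario}.
#' @param policy a [transfer_policy()] object, or \code{NULL} for no
#'   transfers.
#' @param horizon replication length in days.
#' @param warmup initial days excluded from all statistics.
#' @param seed integer RNG seed.
#' @param collect_stage_log keep the per-stage timestamp log (needed for
#'   flow audits; modest memory cost).
#' @return an object of class \code{ecn_replication}: a list with
#'   \describe{
#'     \item{patients}{data.frame, one row per arrival: ids, arrival epoch
#'       (minutes), triage level, insurer, treating node, transfer outcome,
#'       \code{door_to_physician} wait, departure epoch, blocked flag.}
#'     \item{node_stats}{per-node mean/variance of door-to-physician time,
#'       bed occupancy and blocking probability (post-warmup).}
#'     \item{transfer_counts}{counts by (origin, destination, insurer).}
#'     \item{blocking_by_day}{daily bed-request and blocked counts across
#'       the full horizon, for warm-up diagnostics.}
#'     \item{stage_log}{per-stage start/end timestamps (if collected).}
#'     \item{meta}{seed, horizon, warmup, policy mode.}
#'   }
#' @export
simulate_ecn <- function(scenario, policy = NULL, horizon = 30, warmup = 0,
                         seed = 1L, collect_stage_log = TRUE) {
  stopifnot(inherits(scenario, "ecn_scenario"), horizon > warmup, warmup >= 0)
  if (!is.null(policy) && !inherits(policy, "ecn_policy"))
    stop("policy must be NULL or a transfer_policy()", call. = FALSE)
  set.seed(as.integer(seed))

  ids <- names(scenario$nodes)
  n_nodes <- length(ids)
  enabled <- vapply(scenario$nodes, ed_enabled, logical(1))
  horizon_min <- horizon * 1440
  warm_min <- warmup * 1440

  # --- per-node static tables ---------------------------------------------
  max_k <- 0L
  stages <- vector("list", n_nodes); svc <- vector("list", n_nodes)
  servers <- vector("list", n_nodes); pipes <- vector("list", n_nodes)
  triage_ix <- post_triage_ix <- phys_ix <- bed_ix <- last_ix <-
    rep(NA_integer_, n_nodes)
  beds <- rep(NA_real_, n_nodes)
  est_mean <- est_srv <- rep(NA_real_, n_nodes)
  node_insurers <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    nd <- scenario$nodes[[i]]
    node_insurers[[i]] <- nd$insurers
    if (!enabled[i]) next
    st <- names(nd$stage_service)
    stages[[i]] <- st; k <- length(st); max_k <- max(max_k, k)
    svc[[i]] <- nd$stage_service
    servers[[i]] <- as.numeric(nd$stage_servers)
    beds[i] <- nd$beds
    triage_ix[i] <- match("triage", st)
    post_triage_ix[i] <- if (is.na(triage_ix[i])) 1L else triage_ix[i] + 1L
    if (post_triage_ix[i] > k) post_triage_ix[i] <- k
    phys_ix[i] <- if ("physician" %in% st) match("physician", st) else k
    bed_ix[i] <- match("bed_prep", st)
    last_ix[i] <- k
    # expected-wait estimator constants: the pre-physician segment a
    # post-triage entrant must traverse before physician assessment starts
    rng <- seq.int(post_triage_ix[i], phys_ix[i] - 1L)
    if (phys_ix[i] <= post_triage_ix[i]) rng <- phys_ix[i]
    est_mean[i] <- sum(vapply(svc[[i]][rng], dist_mean, numeric(1)))
    est_srv[i] <- min(servers[[i]][rng])
    # pipeline lookup matrix [weekday, slot]
    pm <- matrix(list(), 7, 3)
    for (w in 1:7) for (sl in 1:3)
      pm[[w, sl]] <- nd$pipelines[[paste(ECN_WEEKDAYS[w], ECN_SLOTS[sl],
                                         sep = ".")]]
    pipes[[i]] <- pm
  }
  tt_by_slot <- lapply(ECN_SLOTS, function(sl)
    scenario$transfer_times[[sl]][ids, ids, drop = FALSE])

  # insurer sampling: roster plus an uncovered/special-regime pseudo-class
  ins_labels <- as.character(scenario$insurers$insurer)
  ins_w <- c(scenario$insurers$affiliated,
             scenario$population$special_regime + scenario$population$uncovered)
  ins_w <- ins_w / sum(ins_w)
  n_ins <- length(ins_labels)
  # coverage[i, j]: does node j hold an agreement with insurer i
  coverage <- matrix(FALSE, n_ins, n_nodes)
  for (j in seq_len(n_nodes))
    coverage[match(node_insurers[[j]], ins_labels), j] <- TRUE

  planning <- !is.null(policy) && policy$mode == "planning"
  static_est <- if (planning) policy$static_waits[ids]

  # --- mutable state -------------------------------------------------------
  qn <- n_nodes * max_k
  q_pat <- vector("list", qn); q_key <- vector("list", qn)
  for (q in seq_len(qn)) { q_pat[[q]] <- integer(0); q_key[[q]] <- numeric(0) }
  busy <- matrix(0, n_nodes, max_k)
  beds_busy <- rep(0, n_nodes)
  occ_int <- rep(0, n_nodes); occ_last <- rep(warm_min, n_nodes)
  breq <- bblk <- rep(0, n_nodes)
  n_days <- as.integer(ceiling(horizon))
  breq_day <- bblk_day <- rep(0, n_days)
  qseq <- 0

  # patient store (grow by doubling)
  cap <- 1024L; np <- 0L
  P_arr <- P_tphys <- P_dep <- numeric(cap)
  P_node0 <- P_nodeT <- P_tri <- P_ins <- P_dest <- integer(cap)
  P_blocked <- P_hasbed <- logical(cap)
  grow_p <- function() {
    cap2 <- cap * 2L
    for (v in c("P_arr", "P_tphys", "P_dep"))
      assign(v, `length<-`(get(v), cap2), inherits = TRUE)
    for (v in c("P_node0", "P_nodeT", "P_tri", "P_ins", "P_dest"))
      assign(v, `length<-`(get(v), cap2), inherits = TRUE)
    for (v in c("P_blocked", "P_hasbed")) {
      x <- get(v); x <- `length<-`(x, cap2); x[is.na(x)] <- FALSE
      assign(v, x, inherits = TRUE)
    }
    cap <<- cap2
  }

  # stage log (grow by doubling)
  lcap <- 4096L; nl <- 0L
  L_pat <- L_node <- L_stage <- integer(lcap)
  L_start <- L_end <- numeric(lcap)
  open_row <- integer(cap)  # current open log row per patient (0 = none)
  log_start <- function(p, i, s, t) {
    if (!collect_stage_log) return(invisible())
    nl <<- nl + 1L
    if (nl > lcap) {
      lcap2 <- lcap * 2L
      L_pat <<- `length<-`(L_pat, lcap2); L_node <<- `length<-`(L_node, lcap2)
      L_stage <<- `length<-`(L_stage, lcap2)
      L_start <<- `length<-`(L_start, lcap2); L_end <<- `length<-`(L_end, lcap2)
      lcap <<- lcap2
    }
    L_pat[nl] <<- p; L_node[nl] <<- i; L_stage[nl] <<- s
    L_start[nl] <<- t; L_end[nl] <<- NA_real_
    if (p > length(open_row)) open_row <<- `length<-`(open_row, cap)
    open_row[p] <<- nl
  }
  log_end <- function(p, t) {
    if (!collect_stage_log) return(invisible())
    L_end[open_row[p]] <<- t
  }

  # transfer decision log
  tr_o <- tr_d <- tr_ins <- integer(0); tr_t <- numeric(0)

  # event calendar: parallel vectors, free-list reuse, pop = earliest time
  ecap <- 256L
  ev_t <- rep(Inf, ecap)
  ev_type <- ev_node <- ev_pat <- ev_stage <- integer(ecap)
  ev_free <- seq_len(ecap)
  schedule <- function(t, type, node = 0L, pat = 0L, stage = 0L) {
    if (!length(ev_free)) {
      ecap2 <- ecap * 2L
      ev_t <<- c(ev_t, rep(Inf, ecap)); ev_type <<- `length<-`(ev_type, ecap2)
      ev_node <<- `length<-`(ev_node, ecap2)
      ev_pat <<- `length<-`(ev_pat, ecap2)
      ev_stage <<- `length<-`(ev_stage, ecap2)
      ev_free <<- seq.int(ecap + 1L, ecap2); ecap <<- ecap2
    }
    idx <- ev_free[length(ev_free)]; ev_free <<- ev_free[-length(ev_free)]
    ev_t[idx] <<- t; ev_type[idx] <<- type; ev_node[idx] <<- node
    ev_pat[idx] <<- pat; ev_stage[idx] <<- stage
    invisible(idx)
  }

  occ_update <- function(i, t) {
    t2 <- min(t, horizon_min)
    if (t2 > occ_last[i]) {
      from <- max(occ_last[i], warm_min)
      if (t2 > from) occ_int[i] <<- occ_int[i] + beds_busy[i] * (t2 - from)
    }
    occ_last[i] <<- max(occ_last[i], t2)
  }

  qid <- function(i, s) (i - 1L) * max_k + s

  try_start <- function(i, s, t) {
    q <- qid(i, s)
    repeat {
      if (busy[i, s] >= servers[[i]][s]) break
      if (!length(q_pat[[q]])) break
      is_bed <- !is.na(bed_ix[i]) && s == bed_ix[i]
      if (is_bed && beds_busy[i] >= beds[i]) break
      j <- which.min(q_key[[q]])
      p <- q_pat[[q]][j]
      q_pat[[q]] <<- q_pat[[q]][-j]; q_key[[q]] <<- q_key[[q]][-j]
      if (is_bed) {
        occ_update(i, t); beds_busy[i] <<- beds_busy[i] + 1
        P_hasbed[p] <<- TRUE
      }
      busy[i, s] <<- busy[i, s] + 1
      if (s == phys_ix[i] && is.na(P_tphys[p])) P_tphys[p] <<- t
      log_start(p, i, s, t)
      schedule(t + draw_dist(svc[[i]][[s]], 1L), 2L, i, p, s)
    }
  }

  join_stage <- function(i, p, s, t) {
    if (!is.na(bed_ix[i]) && s == bed_ix[i]) {
      d <- min(n_days, floor(t / 1440) + 1L)
      breq_day[d] <<- breq_day[d] + 1
      if (t >= warm_min) breq[i] <<- breq[i] + 1
      if (beds_busy[i] >= beds[i]) {
        P_blocked[p] <<- TRUE
        bblk_day[d] <<- bblk_day[d] + 1
        if (t >= warm_min) bblk[i] <<- bblk[i] + 1
      }
    }
    q <- qid(i, s); qseq <<- qseq + 1
    q_pat[[q]] <<- c(q_pat[[q]], p)
    q_key[[q]] <<- c(q_key[[q]], P_tri[p] * 1e9 + qseq)
    try_start(i, s, t)
  }

  # dynamic ex-ante door-to-physician estimate for a triage-`pr` entrant at
  # node j: patients ahead (queued at or above priority in stages up to
  # physician start, plus those in pre-physician service) times mean
  # pre-physician service time over effective servers
  dyn_est <- function(j, pr) {
    ahead <- 0
    for (s in seq.int(post_triage_ix[j], phys_ix[j])) {
      kq <- q_key[[qid(j, s)]]
      if (length(kq)) ahead <- ahead + sum(kq < (pr + 1) * 1e9)
      if (s < phys_ix[j] || phys_ix[j] == post_triage_ix[j])
        ahead <- ahead + busy[j, s]
    }
    ahead * est_mean[j] / est_srv[j]
  }

  decide_transfer <- function(p, i, t) {
    ins <- P_ins[p]
    if (ins == 0L) return(invisible())      # uncovered: treat at origin
    if (!coverage[ins, i]) return(invisible())  # origin lacks agreement
    cand <- which(enabled & coverage[ins, ] & seq_len(n_nodes) != i)
    if (!length(cand)) return(invisible())
    cand <- cand[order(ids[cand])]          # deterministic tie-break
    sl <- minute_slot(t)
    ttrow <- tt_by_slot[[sl]][i, cand]
    if (planning) {
      est_o <- static_est[[i]]
      est_c <- static_est[cand]
    } else {
      pr <- P_tri[p]
      est_o <- dyn_est(i, pr)
      est_c <- vapply(cand, dyn_est, numeric(1), pr = pr)
    }
    scores <- est_c + ttrow
    b <- which.min(scores)
    if (scores[b] < est_o) {
      j <- cand[b]
      P_dest[p] <<- j
      tr_o <<- c(tr_o, i); tr_d <<- c(tr_d, j)
      tr_ins <<- c(tr_ins, ins); tr_t <<- c(tr_t, t)
      schedule(t + ttrow[b], 3L, j, p)
      return(TRUE)
    }
    invisible()
  }

  # --- prime arrivals ------------------------------------------------------
  next_arrival <- function(i, t) {
    dt <- draw_dist(pipes[[i]][[minute_weekday(t), minute_slot(t)]], 1L)
    tn <- t + dt
    if (tn <= horizon_min) schedule(tn, 1L, i)
  }
  for (i in which(enabled)) next_arrival(i, 0)

  # --- main loop -----------------------------------------------------------
  repeat {
    live <- which(is.finite(ev_t))
    if (!length(live)) break
    idx <- live[which.min(ev_t[live])]
    t <- ev_t[idx]; type <- ev_type[idx]; i <- ev_node[idx]
    p <- ev_pat[idx]; s <- ev_stage[idx]
    ev_t[idx] <- Inf; ev_free <- c(ev_free, idx)
    if (t > horizon_min) break

    if (type == 1L) {                       # arrival at node i
      next_arrival(i, t)
      np <- np + 1L
      if (np > cap) grow_p()
      P_arr[np] <- t; P_node0[np] <- i; P_nodeT[np] <- i
      P_tri[np] <- sample.int(5L, 1L, prob = scenario$triage_mix)
      ki <- sample.int(n_ins + 1L, 1L, prob = ins_w)
      P_ins[np] <- if (ki > n_ins) 0L else ki
      P_tphys[np] <- NA_real_; P_dep[np] <- NA_real_
      P_dest[np] <- NA_integer_
      P_blocked[np] <- FALSE; P_hasbed[np] <- FALSE
      join_stage(i, np, 1L, t)
    } else if (type == 2L) {                # stage s completed at node i
      busy[i, s] <- busy[i, s] - 1
      log_end(p, t)
      moved <- FALSE
      if (!is.null(policy) && !is.na(triage_ix[i]) && s == triage_ix[i] &&
          P_tri[p] >= 4L && is.na(P_dest[p])) {
        moved <- isTRUE(decide_transfer(p, i, t))
      }
      if (!moved) {
        if (s == last_ix[i]) {
          P_dep[p] <- t
          if (P_hasbed[p]) {
            occ_update(i, t); beds_busy[i] <- beds_busy[i] - 1
            P_hasbed[p] <- FALSE
            if (!is.na(bed_ix[i])) try_start(i, bed_ix[i], t)
          }
        } else {
          join_stage(i, p, s + 1L, t)
        }
      }
      try_start(i, s, t)
    } else {                                # transfer arrival at node i
      P_nodeT[p] <- i
      join_stage(i, p, post_triage_ix[i], t)
    }
  }
  for (i in which(enabled)) occ_update(i, horizon_min)

  # --- assemble results ----------------------------------------------------
  seq_p <- seq_len(np)
  ins_chr <- c(ins_labels, "UNCOVERED")[ifelse(P_ins[seq_p] == 0L,
                                               n_ins + 1L, P_ins[seq_p])]
  patients <- data.frame(
    id = seq_p,
    node_arrival = ids[P_node0[seq_p]],
    node_treated = ids[P_nodeT[seq_p]],
    arrival = P_arr[seq_p],
    triage = P_tri[seq_p],
    insurer = ins_chr,
    transferred = !is.na(P_dest[seq_p]),
    destination = ifelse(is.na(P_dest[seq_p]), NA_character_,
                         ids[ifelse(is.na(P_dest[seq_p]), 1L, P_dest[seq_p])]),
    door_to_physician = P_tphys[seq_p] - P_arr[seq_p],
    departure = P_dep[seq_p],
    blocked = P_blocked[seq_p],
    stringsAsFactors = FALSE)

  post <- patients$arrival >= warm_min & !is.na(patients$door_to_physician)
  node_stats <- do.call(rbind, lapply(which(enabled), function(i) {
    sel <- post & patients$node_treated == ids[i]
    w <- patients$door_to_physician[sel]
    data.frame(
      node = ids[i], n = length(w),
      mean_wait = if (length(w)) mean(w) else NA_real_,
      var_wait = if (length(w) > 1) stats::var(w) else NA_real_,
      occupancy = occ_int[i] / (beds[i] * max(horizon_min - warm_min, 1e-12)),
      blocking = if (breq[i] > 0) bblk[i] / breq[i] else 0,
      stringsAsFactors = FALSE)
  }))
  rownames(node_stats) <- NULL

  transfer_counts <- if (length(tr_o)) {
    tc <- stats::aggregate(
      list(n = rep(1L, length(tr_o))),
      by = list(origin = ids[tr_o], destination = ids[tr_d],
                insurer = ins_labels[tr_ins]), FUN = sum)
    tc[order(tc$origin, tc$destination, tc$insurer), , drop = FALSE]
  } else {
    data.frame(origin = character(), destination = character(),
               insurer = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(transfer_counts) <- NULL

  blocking_by_day <- data.frame(
    day = seq_len(n_days), requests = breq_day, blocked = bblk_day,
    fraction = ifelse(breq_day > 0, bblk_day / breq_day, 0))

  stage_log <- if (collect_stage_log && nl > 0) {
    sl <- seq_len(nl)
    data.frame(patient = L_pat[sl],
               node = ids[L_node[sl]],
               stage = vapply(sl, function(r)
                 stages[[L_node[r]]][L_stage[r]], character(1)),
               start = L_start[sl], end = L_end[sl],
               stringsAsFactors = FALSE)
  }

  structure(list(
    patients = patients, node_stats = node_stats,
    transfer_counts = transfer_counts, blocking_by_day = blocking_by_day,
    stage_log = stage_log,
    meta = list(seed = as.integer(seed), horizon = horizon, warmup = warmup,
                policy = if (is.null(policy)) "none" else policy$mode)),
    class = "ecn_replication")
}

#' @export
print.ecn_replication <- function(x, ...) {
  cat("<ecn_replication> ", nrow(x$patients), " arrivals, ",
      sum(x$patients$transferred), " transfers; seed ", x$meta$seed,
      ", horizon ", x$meta$horizon, " d (warm-up ", x$meta$warmup, " d)\n",
      sep = "")
  print(x$node_stats, ...)
  invisible(x)
}
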