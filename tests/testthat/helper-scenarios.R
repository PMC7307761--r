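# shared fixtures: single-node M/M/c scenarios and the Erlang-C oracle

# single node with one "service" stage: an M/M/c station when both
# distributions are exponential
single_node_scenario <- function(interarrival_mean, service_mean,
                                 servers = 1L, beds = 1000,
                                 interarrival = NULL, service = NULL) {
  pip <- lapply(stats::setNames(
    paste(rep(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"), each = 3),
          c("P1", "P2", "P3"), sep = "."),
    paste(rep(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"), each = 3),
          c("P1", "P2", "P3"), sep = ".")),
    function(k) interarrival %||%
      dist_spec("exponential", mean = interarrival_mean))
  nd <- node_spec("N1", "poc", beds = beds, insurers = "S",
                  demand_mean = 1000, demand_var = 1,
                  stage_servers = c(service = as.integer(servers)),
                  stage_service = list(
                    service = service %||%
                      dist_spec("exponential", mean = service_mean)),
                  pipelines = pip)
  tt <- matrix(NA_real_, 1, 1, dimnames = list("N1", "N1"))
  network_scenario(
    list(nd), list(P1 = tt, P2 = tt, P3 = tt),
    data.frame(insurer = "S", affiliated = 1000, unit_utility_M = 10,
               stringsAsFactors = FALSE),
    payment = list(gamma = 0.19, theta = 0.46,
                   floors = c(A = 3.92, B = 3.50, C = 4.50),
                   arrangement = c(N1 = "A")),
    triage_mix = c(0.05, 0.12, 0.18, 0.19, 0.46), usl = 30,
    population = list(special_regime = 0, uncovered = 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent closed-form oracle: Erlang-C mean queueing delay for M/M/c
erlang_c_wq <- function(lambda, mu, c) {
  a <- lambda / mu
  rho <- a / c
  stopifnot(rho < 1)
  inv_terms <- sum(a^(0:(c - 1)) / factorial(0:(c - 1)))
  pc <- (a^c / factorial(c)) / (1 - rho)
  p_wait <- pc / (inv_terms + pc)
  p_wait / (c * mu - lambda)
}

# mean post-warmup door-to-physician wait of a replication
mean_wait <- function(rep) {
  w <- rep$patients$door_to_physician
  ok <- rep$patients$arrival >= rep$meta$warmup * 1440 & !is.na(w)
  mean(w[ok])
}

# full 21-key pipeline list with one fixed spec (e.g. zero/slow arrivals)
flat_pipelines <- function(spec) {
  keys <- paste(rep(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"),
                    each = 3), c("P1", "P2", "P3"), sep = ".")
  stats::setNames(rep(list(spec), 21), keys)
}
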