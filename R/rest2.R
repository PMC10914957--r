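# REST2 temperature-ladder construction and exchange/mixing diagnostics.
# The ladder is geometric: T_i = T_min * exp(i * ln(T_max/T_min) / (N-1)),
# i = 0..N-1, so adjacent rungs share a constant ratio and the endpoints
# hit T_min and T_max exactly.

#' Build a REST2 effective-temperature ladder
#'
#' @param T_min,T_max Temperature range, K (`T_max >= T_min > 0`).
#' @param N_rep Number of replicas (>= 1). With `N_rep = 1` the range must
#'   be degenerate (`T_min == T_max`).
#' @return A `ladder_spec`: list with `T_min`, `T_max`, `N_rep`,
#'   `temperatures`.
#' @export
make_ladder <- function(T_min, T_max, N_rep) {
  if (T_min <= 0 || T_max < T_min) stop("need T_max >= T_min > 0")
  N_rep <- as.integer(N_rep)
  if (N_rep < 1) stop("N_rep must be >= 1")
  if (N_rep == 1) {
    if (T_min != T_max) stop("N_rep = 1 requires T_min == T_max")
    temps <- T_min
  } else {
    i <- 0:(N_rep - 1)
    temps <- T_min * exp(i * log(T_max / T_min) / (N_rep - 1))
    temps[1] <- T_min
    temps[N_rep] <- T_max
  }
  structure(list(T_min = T_min, T_max = T_max, N_rep = N_rep,
                 temperatures = temps),
            class = "ladder_spec")
}

#' @export
print.ladder_spec <- function(x, ...) {
  cat("<ladder_spec> ", x$N_rep, " replicas, ", x$T_min, " .. ", x$T_max,
      " K\n  ", paste(formatC(x$temperatures, format = "f", digits = 2),
                      collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Exchange-rate diagnostics of a replica-exchange log
#'
#' Per adjacent rung pair: accepted / attempted. Pairs with no attempts are
#' reported as `NA`. The mean is reported both over pairs (N-1 values) and,
#' for comparison with conventions that average per replica, over replicas
#' (each replica averaging the rates of its adjacent pairs).
#'
#' @param log An `exchange_log` from [read_exchange_log()] or
#'   [generate_exchange_log()].
#' @return List: `per_pair` data frame (`i`, `j`, `attempted`, `accepted`,
#'   `rate`), `mean_rate_pairs`, `mean_rate_replicas`.
#' @export
exchange_rates <- function(log) {
  n <- log$n_replicas
  att <- log$attempts
  pairs <- data.frame(i = 0:(max(n - 1, 1) - 1))
  pairs$j <- pairs$i + 1L
  pairs$attempted <- vapply(pairs$i, function(i) sum(att$i == i), integer(1))
  pairs$accepted <- vapply(pairs$i, function(i)
    sum(att$accepted[att$i == i]), integer(1))
  pairs$rate <- ifelse(pairs$attempted > 0,
                       pairs$accepted / pairs$attempted, NA_real_)
  # per-replica convention: replica r touches pairs (r-1, r) and (r, r+1)
  rep_rate <- vapply(seq_len(n), function(r) {
    touching <- pairs$rate[pairs$i %in% c(r - 2L, r - 1L)]
    mean(touching, na.rm = TRUE)
  }, numeric(1))
  list(per_pair = pairs,
       mean_rate_pairs = mean(pairs$rate, na.rm = TRUE),
       mean_rate_replicas = mean(rep_rate, na.rm = TRUE))
}

#' Mixing diagnostics of a replica-exchange log
#'
#' For each replica: the set of temperature rungs visited, whether all
#' rungs were visited, and the number of round trips (excursions from the
#' bottom rung to the top rung and back). Replicas that never visit every
#' rung are flagged.
#'
#' @param log An `exchange_log` with a replayed rung series.
#' @return List: `per_replica` data frame (`replica`, `n_rungs_visited`,
#'   `visited_all`, `round_trips`), `all_mixed` flag.
#' @export
mixing_diagnostics <- function(log) {
  n <- log$n_replicas
  series <- log$replica_rung_series
  if (is.null(series) || n == 0) stop("log carries no rung series")
  per <- lapply(seq_len(n), function(r) {
    s <- c(r - 1L, series[r, ])  # include the starting rung
    visited <- unique(s)
    # round trips: 0 -> top -> 0 excursions
    trips <- 0L
    phase <- if (s[1] == 0L) "up" else "seek0"
    for (v in s) {
      if (phase == "seek0") {
        if (v == 0L) phase <- "up"
      } else if (phase == "up") {
        if (v == n - 1L) phase <- "down"
      } else if (phase == "down") {
        if (v == 0L) { trips <- trips + 1L; phase <- "up" }
      }
    }
    data.frame(replica = r - 1L, n_rungs_visited = length(visited),
               visited_all = length(visited) == n, round_trips = trips)
  })
  per <- do.call(rbind, per)
  list(per_replica = per, all_mixed = all(per$visited_all))
}
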