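# Synthetic collective-variable samples and replica-exchange logs with
# analytic ground truth.

#' Sample a Gaussian-mixture collective variable
#'
#' Emulates a two-population peptide-bilayer distance distribution. The
#' analytic free-energy difference between two modes is
#' `-kT ln(w1 / w2)` (in kT), available for acceptance checks.
#'
#' @param means,sds,weights Equal-length mixture parameters; weights are
#'   normalised to sum to 1.
#' @param n Sample size.
#' @param seed RNG seed.
#' @return Numeric vector of samples, with attribute `components` (the
#'   drawn component per sample).
#' @export
sample_two_state_cv <- function(means, sds, weights, n, seed = 1) {
  k <- length(means)
  stopifnot(length(sds) == k, length(weights) == k, n >= 1)
  if (any(sds <= 0)) stop("mixture sds must be positive")
  if (any(weights < 0) || sum(weights) == 0) stop("invalid mixture weights")
  weights <- weights / sum(weights)
  set.seed(seed)
  comp <- sample.int(k, n, replace = TRUE, prob = weights)
  x <- stats::rnorm(n, mean = means[comp], sd = sds[comp])
  attr(x, "components") <- comp
  x
}

#' Generate a synthetic replica-exchange log
#'
#' Attempts alternate between even pairs (0,1), (2,3), ... and odd pairs
#' (1,2), (3,4), ... every `attempt_interval` ps, mirroring the usual
#' exchange cadence. Each attempt on pair `(i, i+1)` is accepted with the
#' prescribed probability `p_accept[i+1]` (Bernoulli thinning of a
#' Metropolis criterion with a matching mean acceptance).
#'
#' @param ladder A `ladder_spec`.
#' @param n_sweeps Number of attempt sweeps (each sweep attempts every
#'   pair of its parity).
#' @param p_accept Mean acceptance per adjacent pair; scalar or length
#'   `N_rep - 1`, values in (0, 1].
#' @param seed RNG seed.
#' @param attempt_interval Time between sweeps, ps.
#' @return An `exchange_log`.
#' @export
generate_exchange_log <- function(ladder, n_sweeps, p_accept = 0.2,
                                  seed = 1, attempt_interval = 2) {
  stopifnot(inherits(ladder, "ladder_spec"))
  n_rep <- ladder$N_rep
  if (n_rep < 2) stop("need at least 2 replicas for exchanges")
  p_accept <- rep(p_accept, length.out = n_rep - 1)
  if (any(p_accept <= 0 | p_accept > 1)) {
    stop("p_accept must lie in (0, 1]")
  }
  set.seed(seed)
  rows <- vector("list", n_sweeps)
  for (s in seq_len(n_sweeps)) {
    first <- if (s %% 2 == 1) 0L else 1L
    i <- seq(first, n_rep - 2L, by = 2L)
    if (!length(i)) next
    acc <- stats::runif(length(i)) < p_accept[i + 1L]
    rows[[s]] <- data.frame(time = s * attempt_interval, i = i, j = i + 1L,
                            accepted = acc)
  }
  att <- do.call(rbind, rows)
  new_exchange_log(att, n_rep)
}
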