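# Energy-gated stochastic spiking network and avalanche statistics.
#
# Each node i carries a binary activity q_i and an energy E_i.  Firing costs
#   cost_i = r1 * outdeg_i/<Nout> + r2 * (active in-neighbours)/<Nin>
# and is only possible while E_i > cost_i (strict gate, unlike the mean-field
# Heaviside which pays at equality).  All nodes update synchronously with
# costs evaluated on the pre-update activities.

#' Agent-network parameters
#'
#' @param n Node count (ignored when `adjacency` is given).
#' @param adjacency Optional 0/1 adjacency matrix (`a[i, j] = 1` for a link
#'   i -> j, zero diagonal).  `NULL` (default) means fully connected,
#'   `c_ij = 1 - delta_ij`.
#' @param p Maximal activation probability.
#' @param e_low,e_bar,w,eps Energy threshold, recovery value, sigmoid
#'   steepness and relaxation rate, as in [mf_params()].
#' @param r1 Output (spike generation) cost weight.
#' @param r2 Input (signal transmission) cost weight.
#' @param firing_rule `"corrected"` (default) fires with probability
#'   `1 - (1 - p*sigma(E))^(1+k)`, increasing in the number `k` of active
#'   inputs, matching the mean-field activation form; `"as_printed"` fires
#'   with the complementary probability `(1 - p*sigma(E))^(1+k)`, which
#'   decreases with `k`.  Both are provided; see the package vignette for why
#'   the corrected form is the default.
#' @return An `agent_params` object.
#' @examples
#' agent_params(n = 625)
#' @export
agent_params <- function(n = 625, adjacency = NULL, p = 0.01, e_low = 2,
                         e_bar = 4, w = 1.5, eps = 0.0025, r1 = 1.1,
                         r2 = 5.5, firing_rule = c("corrected", "as_printed")) {
  firing_rule <- match.arg(firing_rule)
  check_scalar(p, "p", 0, 1, strict_upper = TRUE)
  check_scalar(e_low, "e_low", 0, strict_lower = TRUE)
  check_scalar(e_bar, "e_bar", e_low, strict_lower = TRUE)
  check_scalar(w, "w", 0, strict_lower = TRUE)
  check_scalar(eps, "eps", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(r1, "r1", 0)
  check_scalar(r2, "r2", 0)
  if (is.null(adjacency)) {
    if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
      stop("`n` must be an integer >= 2", call. = FALSE)
    }
    n <- as.integer(n)
    fully_connected <- TRUE
    out_deg <- rep(n - 1, n)
    mean_deg <- n - 1
  } else {
    adjacency <- as.matrix(adjacency)
    n <- nrow(adjacency)
    if (ncol(adjacency) != n) stop("`adjacency` must be square", call. = FALSE)
    if (!all(adjacency %in% c(0, 1))) {
      stop("`adjacency` entries must be 0 or 1", call. = FALSE)
    }
    if (any(diag(adjacency) != 0)) {
      stop("`adjacency` must have a zero diagonal (no self-loops)",
           call. = FALSE)
    }
    if (sum(adjacency) == 0) {
      stop("`adjacency` must contain at least one link", call. = FALSE)
    }
    fully_connected <- FALSE
    out_deg <- rowSums(adjacency)
    mean_deg <- sum(adjacency) / n # <Nin> = <Nout>
  }
  structure(
    list(n = n, adjacency = adjacency, fully_connected = fully_connected,
         out_deg = out_deg, mean_in = mean_deg, mean_out = mean_deg,
         p = p, e_low = e_low, e_bar = e_bar, w = w, eps = eps,
         r1 = r1, r2 = r2, firing_rule = firing_rule),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> n = %d (%s), p = %g, eps = %g, r1 = %g, r2 = %g, rule = %s\n",
    x$n, if (x$fully_connected) "fully connected" else
      sprintf("<deg> = %.3g", x$mean_in),
    x$p, x$eps, x$r1, x$r2, x$firing_rule))
  invisible(x)
}

# active in-neighbour counts k_i = sum_j c_ji q_j
active_in_counts <- function(params, q) {
  if (params$fully_connected) {
    sum(q) - q
  } else {
    as.vector(crossprod(params$adjacency, q))
  }
}

#' Per-node firing cost
#'
#' `cost_i = r1 * outdeg_i / <Nout> + r2 * k_i / <Nin>`, where `k_i` is the
#' number of currently active in-neighbours of node i.  In a fully connected
#' network with no activity the cost is exactly `r1` for every node.
#'
#' @param params An [agent_params()] object.
#' @param q Current 0/1 activity vector of length `n`.
#' @return Numeric vector of per-node costs.
#' @export
fire_cost <- function(params, q) {
  stopifnot(inherits(params, "agent_params"), length(q) == params$n)
  k <- active_in_counts(params, q)
  params$r1 * params$out_deg / params$mean_out + params$r2 * k / params$mean_in
}

#' Per-node firing probability
#'
#' With `k_i` active in-neighbours and `s_i = p * sigma(E_i)`, the
#' `"corrected"` rule gives `1 - (1 - s_i)^(1 + k_i)` and the `"as_printed"`
#' rule gives `(1 - s_i)^(1 + k_i)`.  The energy gate (`E_i` must exceed the
#' firing cost) is applied separately, in [step_network()].
#'
#' @param params An [agent_params()] object.
#' @param q Current 0/1 activity vector.
#' @param e Current energy vector.
#' @return Numeric vector of per-node firing probabilities.
#' @export
fire_probability <- function(params, q, e) {
  stopifnot(inherits(params, "agent_params"),
            length(q) == params$n, length(e) == params$n)
  k <- active_in_counts(params, q)
  s <- params$p * sigma_energy(e, params$e_low, params$w)
  if (params$firing_rule == "corrected") {
    -expm1((1 + k) * log1p(-s))
  } else {
    (1 - s)^(1 + k)
  }
}

#' One synchronous network step (reference implementation)
#'
#' Pure-R step used for small studies and as the reference the compiled
#' simulator is checked against: both draw one uniform deviate per node per
#' step in node order, so seeded runs agree exactly.
#'
#' @param state List with 0/1 vector `q` and energy vector `E`.
#' @param params An [agent_params()] object.
#' @return The updated state, a list with `q` and `E`.
#' @export
step_network <- function(state, params) {
  stopifnot(inherits(params, "agent_params"))
  q <- state$q
  e <- state$E
  cost <- fire_cost(params, q)
  pf <- fire_probability(params, q, e)
  u <- runif(params$n)
  a <- as.integer(e > cost & u < pf) # strict energy gate
  e_new <- (1 - params$eps) * e + params$eps * params$e_bar - a * cost
  list(q = a, E = e_new)
}

#' Simulate the agent network
#'
#' Starts from the all-silent state `q_{i,0} = 0` with initial energies drawn
#' uniformly from `[0.5 * e_low, e_bar]`, and iterates for `steps` steps.
#' The population activity `sum_i q_{i,t}` is recorded at every step; the
#' full per-node history is kept only on request (memory grows as
#' `n * steps`).
#'
#' @param params An [agent_params()] object.
#' @param steps Number of steps, >= 1.
#' @param seed Optional integer seed (initial energies and firing draws).
#' @param full_history Keep per-node `q` and `E` matrices (refused when
#'   `n * steps > 5e6`).
#' @return An `agent_trace`: list with `activity` (integer vector, t =
#'   0..steps), `e_min`, `e_max` (energy extremes seen over the run),
#'   `params`, `steps`, `seed`, and optionally `q_history`, `e_history`.
#' @examples
#' tr <- simulate_network(agent_params(n = 50), steps = 500, seed = 1)
#' sum(tr$activity)
#' @export
simulate_network <- function(params, steps, seed = NULL,
                             full_history = FALSE) {
  stopifnot(inherits(params, "agent_params"))
  if (!is.numeric(steps) || length(steps) != 1 || steps < 1) {
    stop("`steps` must be >= 1", call. = FALSE)
  }
  steps <- as.integer(steps)
  if (full_history && as.numeric(params$n) * steps > 5e6) {
    stop("`full_history` refused for n * steps > 5e6; rerun shorter",
         call. = FALSE)
  }
  if (params$fully_connected) {
    adj_targets <- integer(0)
    adj_ptr <- integer(params$n + 1)
  } else {
    # CSR over out-edges, 0-based
    idx <- which(params$adjacency == 1, arr.ind = TRUE)
    ord <- order(idx[, 1], idx[, 2])
    adj_targets <- as.integer(idx[ord, 2] - 1L)
    adj_ptr <- as.integer(c(0, cumsum(tabulate(idx[, 1], params$n))))
  }
  res <- with_local_seed(seed, {
    e0 <- runif(params$n, 0.5 * params$e_low, params$e_bar)
    cpp_simulate_agents(params$n, steps, params$p, params$e_low,
                        params$e_bar, params$w, params$eps, params$r1,
                        params$r2, params$firing_rule == "corrected", e0,
                        params$fully_connected, adj_targets, adj_ptr,
                        as.numeric(params$out_deg), params$mean_in,
                        params$mean_out, full_history)
  })
  structure(
    c(res, list(params = params, steps = steps, seed = seed)),
    class = "agent_trace"
  )
}

#' @export
print.agent_trace <- function(x, ...) {
  act <- x$activity[-1]
  cat(sprintf(
    "<agent_trace> n = %d, %d steps; mean activity %.4g, active fraction of steps %.3g\n",
    x$params$n, x$steps, mean(act), mean(act > 0)))
  invisible(x)
}

#' Detect firing avalanches in an activity series
#'
#' An avalanche is a maximal run of consecutive steps with nonzero total
#' activity bounded by silent steps on both sides; its duration is the run
#' length and its size the summed activity over the run.  Runs touching
#' either end of the series lack a confirmed bounding zero and are discarded.
#'
#' @param activity Non-negative integer vector (population activity per
#'   step), e.g. the `activity` component of [simulate_network()].
#' @return A data.frame with columns `t_start`, `t_end` (1-based indices into
#'   `activity`), `duration`, `size`.
#' @examples
#' detect_avalanches(c(0, 1, 2, 0, 0, 3, 0)) # sizes 3 and 3
#' @export
detect_avalanches <- function(activity) {
  if (inherits(activity, "agent_trace")) activity <- activity$activity
  if (any(activity < 0 | !is.finite(activity))) {
    stop("`activity` must be non-negative and finite", call. = FALSE)
  }
  pos <- activity > 0
  if (!any(pos)) {
    return(data.frame(t_start = integer(0), t_end = integer(0),
                      duration = integer(0), size = numeric(0)))
  }
  rl <- rle(pos)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values & starts > 1L & ends < length(activity)
  starts <- starts[keep]
  ends <- ends[keep]
  size <- vapply(seq_along(starts),
                 function(i) sum(activity[starts[i]:ends[i]]), numeric(1))
  data.frame(t_start = starts, t_end = ends,
             duration = ends - starts + 1L, size = size)
}

#' Avalanche size/duration statistics and power-law exponents
#'
#' Builds logarithmically binned histograms of avalanche sizes and durations
#' and estimates the power-law exponent two ways: (default) the negative
#' slope of a least-squares line through `(log10 bin centre, log10 density)`
#' over the fit range, and a discrete maximum-likelihood estimate
#' `1 + n / sum(log(x / (xmin - 0.5)))` as a cross-check.  Fitting requires
#' at least `min_avalanches` events and at least three occupied bins;
#' otherwise the histograms are returned with the fits skipped (with a
#' warning).
#'
#' @param avalanches A [detect_avalanches()] data.frame.
#' @param n_bins Number of logarithmic bins.
#' @param fit_range Optional `c(lo, hi)` restricting the fitted values
#'   (applied to bin centres for the slope fit and as `xmin` for the MLE).
#' @param min_avalanches Minimum number of events for exponent fitting.
#' @return An `avalanche_stats` object: per-quantity (`size`, `duration`)
#'   histograms (`data.frame` of bin edges, centres, counts, densities) and
#'   fits (`exponent`, `se`, `r_squared`, `exponent_mle`, `fit_range`), plus
#'   `n_avalanches`.
#' @export
avalanche_statistics <- function(avalanches, n_bins = 20, fit_range = NULL,
                                 min_avalanches = 50) {
  stopifnot(is.data.frame(avalanches))
  n_av <- nrow(avalanches)
  out <- list(n_avalanches = n_av)
  for (what in c("size", "duration")) {
    x <- as.numeric(avalanches[[what]])
    out[[what]] <- fit_power_law(x, n_bins = n_bins, fit_range = fit_range,
                                 min_n = min_avalanches, label = what)
  }
  structure(out, class = "avalanche_stats")
}

# log-binned histogram + LS slope + discrete MLE for one positive sample
fit_power_law <- function(x, n_bins, fit_range, min_n, label) {
  x <- x[is.finite(x) & x > 0]
  n <- length(x)
  if (n == 0) {
    return(list(histogram = data.frame(), exponent = NA_real_, se = NA_real_,
                r_squared = NA_real_, exponent_mle = NA_real_,
                fit_range = fit_range, n = 0L))
  }
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    warning("all ", label, " values identical (", lo,
            "); exponent fit skipped", call. = FALSE)
    return(list(histogram = data.frame(lower = lo, upper = hi, centre = lo,
                                       count = n, density = NA_real_),
                exponent = NA_real_, se = NA_real_, r_squared = NA_real_,
                exponent_mle = NA_real_, fit_range = fit_range, n = n))
  }
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  edges[1] <- lo * (1 - 1e-9)
  edges[n_bins + 1] <- hi * (1 + 1e-9)
  counts <- as.vector(table(cut(x, breaks = edges, include.lowest = TRUE)))
  centre <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  width <- diff(edges)
  hist <- data.frame(lower = edges[-(n_bins + 1)], upper = edges[-1],
                     centre = centre, count = counts,
                     density = counts / width / n)
  fit <- list(exponent = NA_real_, se = NA_real_, r_squared = NA_real_,
              exponent_mle = NA_real_)
  keep <- counts > 0
  if (!is.null(fit_range)) {
    keep <- keep & centre >= fit_range[1] & centre <= fit_range[2]
  }
  if (n < min_n) {
    warning("only ", n, " avalanches (< ", min_n, "); ", label,
            " exponent fit skipped", call. = FALSE)
  } else if (sum(keep) < 3) {
    warning("fewer than 3 occupied ", label, " bins in range; fit skipped",
            call. = FALSE)
  } else {
    d <- hist[keep, ]
    m <- lm(log10(density) ~ log10(centre), data = d)
    sm <- summary(m)
    fit$exponent <- -unname(coef(m)[2])
    fit$se <- sm$coefficients[2, 2]
    fit$r_squared <- sm$r.squared
    xmin <- if (is.null(fit_range)) min(x) else max(min(x), fit_range[1])
    xf <- x[x >= xmin]
    # discrete power-law MLE (Clauset-style approximation)
    fit$exponent_mle <- 1 + length(xf) / sum(log(xf / (xmin - 0.5)))
  }
  c(list(histogram = hist), fit,
    list(fit_range = if (is.null(fit_range)) range(x) else fit_range, n = n))
}

#' @export
print.avalanche_stats <- function(x, ...) {
  cat(sprintf("<avalanche_stats> %d avalanches\n", x$n_avalanches))
  for (what in c("size", "duration")) {
    f <- x[[what]]
    cat(sprintf(
      "  %-8s exponent = %.3g (se %.2g, R^2 %.3g), MLE = %.3g\n",
      what, f$exponent, f$se, f$r_squared, f$exponent_mle))
  }
  invisible(x)
}
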