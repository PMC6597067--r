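# Array-wide spike detection rate (ASDR) and burstiness index (BI) of a
# population-activity series, plus the ensemble protocol that sweeps an
# in-silico "culture batch" over connectivity.

#' Array-wide spike detection rate of an activity series
#'
#' `ASDR_t = (q_t - theta) * [q_t > theta]` with the threshold
#' `theta = median(q) / 0.6745` (a robust scale estimate of the series)
#' unless given explicitly.
#'
#' @param q_series Numeric activity series (non-empty).
#' @param theta Optional explicit threshold; default `median(q)/0.6745`.
#' @return Numeric vector of the same length, with the threshold attached as
#'   attribute `"theta"`.
#' @examples
#' asdr(c(0, 0, 0, 1)) # theta = 0: series unchanged
#' @export
asdr <- function(q_series, theta = NULL) {
  if (length(q_series) == 0 || !is.numeric(q_series)) {
    stop("`q_series` must be a non-empty numeric vector", call. = FALSE)
  }
  if (is.null(theta)) theta <- median(q_series) / 0.6745
  out <- pmax(q_series - theta, 0)
  attr(out, "theta") <- theta
  out
}

#' Metrics configuration
#'
#' @param k Steps per bin for the burstiness index (default 30; roughly three
#'   model ASDR spike widths).
#' @param m Top-bin percentage (default 50).
#' @return A `metrics_config` list.
#' @export
metrics_config <- function(k = 30, m = 50) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  check_scalar(m, "m", 0, 100, strict_lower = TRUE, strict_upper = TRUE)
  structure(list(k = as.integer(k), m = m), class = "metrics_config")
}

#' Burstiness index of an ASDR series
#'
#' Partitions the series into adjacent non-overlapping bins of `k` steps
#' (trailing partial bin discarded), ranks bins by their summed activity and
#' computes `f_m`, the fraction of total activity carried by the top `m`% of
#' bins (`round(m/100 * n_bins)` bins; rank ties broken earlier-bin-first).
#' `BI = (f_m - m/100) / (1 - m/100)`: 0 for tonic (uniform) activity, 1 when
#' all activity falls in a single bin.
#'
#' @param asdr_series Non-negative series, e.g. from [asdr()].
#' @param config A [metrics_config()]; or pass `k`/`m` directly.
#' @param k,m Bin width and top percentage, used when `config` is missing.
#' @return The burstiness index in `[0, 1]`, or `NA` when the series carries
#'   no activity.
#' @examples
#' burstiness_index(rep(1, 300))                   # 0
#' burstiness_index(c(rep(0, 270), rep(5, 30)))    # 1
#' @export
burstiness_index <- function(asdr_series, config = metrics_config(k, m),
                             k = 30, m = 50) {
  stopifnot(inherits(config, "metrics_config"))
  k <- config$k
  m <- config$m
  if (length(asdr_series) < k) {
    stop("series shorter than one bin (k = ", k, ")", call. = FALSE)
  }
  n_bins <- length(asdr_series) %/% k
  x <- asdr_series[seq_len(n_bins * k)]
  sums <- colSums(matrix(x, nrow = k))
  total <- sum(sums)
  if (total == 0) return(NA_real_)
  n_top <- round(m / 100 * n_bins)
  if (n_top < 1) n_top <- 1
  f_m <- sum(sort(sums, decreasing = TRUE)[seq_len(n_top)]) / total
  (f_m - m / 100) / (1 - m / 100)
}

#' Ensemble specification for the connectivity sweep
#'
#' Describes a batch of in-silico cultures: `n_triples` random draws of
#' `(p, r, e_low)` emulating culture-to-culture variability, each swept over
#' `z_grid` connectivities emulating development.  Defaults follow the full
#' protocol (60 triples, 86 z values in `[10, 180]`, 2e5-step orbits with
#' 3e4-step analysis tails); a `preset = "reduced"` variant at roughly 1/10
#' scale is provided for quick runs.
#'
#' @param n_triples Number of `(p, r, e_low)` draws.
#' @param p_range,r_range,e_low_range Sampling intervals.  The p interval
#'   defaults to `[0.10, 0.11]`, bracketing the base value `p = 0.1`.
#' @param z_grid Increasing vector of connectivities.
#' @param steps,tail Orbit length and analysed tail length.
#' @param seed Optional integer seed.
#' @param preset `"full"` or `"reduced"`.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_triples = 60, p_range = c(0.10, 0.11),
                          r_range = c(1.5, 2), e_low_range = c(2, 2.5),
                          z_grid = seq(10, 180, length.out = 86),
                          steps = 2e5, tail = 3e4, seed = NULL,
                          preset = c("full", "reduced")) {
  preset <- match.arg(preset)
  if (preset == "reduced" && missing(n_triples)) {
    n_triples <- 6
    if (missing(z_grid)) z_grid <- seq(10, 180, length.out = 9)
    if (missing(steps)) steps <- 2e4
    if (missing(tail)) tail <- 3e3
  }
  stopifnot(n_triples >= 1, length(p_range) == 2, diff(p_range) > 0,
            length(r_range) == 2, diff(r_range) > 0,
            length(e_low_range) == 2, diff(e_low_range) > 0,
            !is.unsorted(z_grid, strictly = TRUE), tail < steps)
  structure(
    list(n_triples = as.integer(n_triples), p_range = p_range,
         r_range = r_range, e_low_range = e_low_range, z_grid = z_grid,
         steps = as.integer(steps), tail = as.integer(tail), seed = seed,
         preset = preset),
    class = "ensemble_spec"
  )
}

#' Run the ensemble connectivity sweep
#'
#' For every `(p, r, e_low)` triple and every connectivity `z`, simulates the
#' activity-energy map (from `q0 = 0.5`, `E0 = e_bar`), keeps the tail,
#' computes the ASDR and reports its summary together with the burstiness
#' index.  The default summary (`asdr_summary = "interval_median"`) is the
#' median of per-interval ASDR sums over adjacent non-overlapping intervals
#' of `k` steps; `"raw_median"` gives the median of the raw `ASDR_t` values.
#'
#' @param spec An [ensemble_spec()].
#' @param w,e_bar,eps Parameters held fixed across the ensemble.
#' @param config A [metrics_config()] (bin width `k` and top percentage `m`).
#' @param asdr_summary `"interval_median"` or `"raw_median"`.
#' @return A data.frame with one row per (triple, z): `triple_id`, `p`, `r`,
#'   `e_low`, `z`, `median_asdr`, `bi`.
#' @examples
#' \donttest{
#' tab <- run_ensemble(ensemble_spec(preset = "reduced", seed = 1))
#' aggregate(median_asdr ~ z, tab, mean)
#' }
#' @export
run_ensemble <- function(spec, w = 1.5, e_bar = 4, eps = 0.05,
                         config = metrics_config(),
                         asdr_summary = c("interval_median", "raw_median")) {
  stopifnot(inherits(spec, "ensemble_spec"))
  asdr_summary <- match.arg(asdr_summary)
  with_local_seed(spec$seed, {
    triples <- data.frame(
      triple_id = seq_len(spec$n_triples),
      p = runif(spec$n_triples, spec$p_range[1], spec$p_range[2]),
      r = runif(spec$n_triples, spec$r_range[1], spec$r_range[2]),
      e_low = runif(spec$n_triples, spec$e_low_range[1], spec$e_low_range[2])
    )
    rows <- vector("list", spec$n_triples * length(spec$z_grid))
    idx <- 1L
    for (i in seq_len(spec$n_triples)) {
      for (z in spec$z_grid) {
        pars <- mf_params(p = triples$p[i], z = z, w = w,
                          e_low = triples$e_low[i], e_bar = e_bar,
                          eps = eps, r = triples$r[i])
        orb <- simulate_meanfield(pars, q0 = 0.5, e0 = e_bar,
                                  steps = spec$steps)
        q_tail <- tail(orb$q, spec$tail)
        a <- asdr(q_tail)
        med <- if (asdr_summary == "interval_median") {
          nb <- length(a) %/% config$k
          median(colSums(matrix(a[seq_len(nb * config$k)], nrow = config$k)))
        } else {
          median(a)
        }
        rows[[idx]] <- data.frame(
          triple_id = i, p = triples$p[i], r = triples$r[i],
          e_low = triples$e_low[i], z = z, median_asdr = med,
          bi = burstiness_index(a, config)
        )
        idx <- idx + 1L
      }
    }
    do.call(rbind, rows)
  })
}
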