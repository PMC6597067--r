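# Experiment drivers: parametric regime portraits over (e_low, z), the
# hypoxia/reoxygenation protocol, and config/serialization utilities.

#' Parametric-portrait specification
#'
#' Grid study of the asymptotic regime of the activity-energy map over the
#' `(e_low, z)` plane at fixed `w, p, e_bar, eps` and a chosen cost `r`.
#' The full preset uses 21 threshold values in `[1, 3]` and a piecewise z
#' grid (step 0.1 on `(0, 50]` and `(200, 300]`, step 5 on `(50, 200]`) with
#' 3e5-step orbits; the reduced preset uses a coarse grid
#' (5 thresholds x 8 connectivities, 3e4-step orbits) suitable for quick
#' runs.
#'
#' @param r Energy cost of activation.
#' @param e_low_grid,z_grid Increasing grids.
#' @param n_init Random initial conditions per grid point (q uniform in
#'   (0, 1], E uniform in `[0, e_bar]`).
#' @param steps,tail Orbit length and analysed tail.
#' @param w,p,e_bar,eps Fixed map parameters.
#' @param seed Optional integer seed.
#' @param preset `"full"` or `"reduced"`.
#' @return A `portrait_spec` list.
#' @export
portrait_spec <- function(r = 1,
                          e_low_grid = seq(1, 3, length.out = 21),
                          z_grid = c(seq(0.1, 50, by = 0.1),
                                     seq(55, 200, by = 5),
                                     seq(200.1, 300, by = 0.1)),
                          n_init = 5, steps = 3e5, tail = 2e4,
                          w = 1.5, p = 0.1, e_bar = 4, eps = 0.05,
                          seed = NULL, preset = c("full", "reduced")) {
  preset <- match.arg(preset)
  if (preset == "reduced") {
    if (missing(e_low_grid)) e_low_grid <- seq(1, 3, length.out = 5)
    # concentrated near the bifurcation cascade (the full protocol likewise
    # refines its z steps to 0.1 near the transitions)
    if (missing(z_grid)) {
      z_grid <- c(5, 8, 10.5, 11.25, 11.75, 12.5, 13.5, 15, 17, 20)
    }
    if (missing(steps)) steps <- 3e4
  }
  stopifnot(!is.unsorted(e_low_grid, strictly = TRUE),
            !is.unsorted(z_grid, strictly = TRUE),
            length(e_low_grid) >= 1, length(z_grid) >= 1,
            n_init >= 2, tail < steps)
  structure(
    list(r = r, e_low_grid = e_low_grid, z_grid = z_grid,
         n_init = as.integer(n_init), steps = as.integer(steps),
         tail = as.integer(tail), w = w, p = p, e_bar = e_bar, eps = eps,
         seed = seed, preset = preset),
    class = "portrait_spec"
  )
}

#' Compute a regime map over the (e_low, z) plane
#'
#' For every grid point, simulates `n_init` orbits from random initial
#' conditions and labels the asymptotic regime with
#' [classify_asymptotic_regime()].
#'
#' @param spec A [portrait_spec()].
#' @param progress Print a line per threshold column.
#' @return A `regime_map`: data.frame with columns `e_low`, `z`, `label`
#'   (consensus regime, possibly `"multistable"`) and `stage` (the most
#'   advanced dynamical stage among the orbits, in the order silent <
#'   interior < periodic < complex — the stage that determines a cell's
#'   colour in a portrait even when a competing attractor coexists);
#'   attributes `spec` and `config_hash`.
#' @examples
#' \donttest{
#' spec <- portrait_spec(r = 10, preset = "reduced", seed = 1,
#'                       e_low_grid = c(1.5, 2.5), z_grid = c(5, 12, 20))
#' run_portrait(spec)
#' }
#' @export
run_portrait <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "portrait_spec"))
  grid <- expand.grid(e_low = spec$e_low_grid, z = spec$z_grid,
                      KEEP.OUT.ATTRS = FALSE)
  labels <- character(nrow(grid))
  stages <- character(nrow(grid))
  with_local_seed(spec$seed, {
    for (i in seq_len(nrow(grid))) {
      pars <- mf_params(p = spec$p, z = grid$z[i], w = spec$w,
                        e_low = grid$e_low[i], e_bar = spec$e_bar,
                        eps = spec$eps, r = spec$r)
      orbits <- lapply(seq_len(spec$n_init), function(k) {
        q0 <- 1 - runif(1) # uniform on (0, 1]; q = 0 is absorbing
        e0 <- runif(1, 0, spec$e_bar)
        simulate_meanfield(pars, q0 = q0, e0 = e0, steps = spec$steps)
      })
      cl <- classify_asymptotic_regime(orbits, tail = spec$tail)
      labels[i] <- cl$regime
      stages[i] <- regime_stage(cl)
      if (progress && i %% length(spec$e_low_grid) == 0) {
        message(sprintf("portrait: %d / %d grid points", i, nrow(grid)))
      }
    }
  })
  out <- data.frame(e_low = grid$e_low, z = grid$z, label = labels,
                    stage = stages)
  attr(out, "spec") <- spec
  attr(out, "config_hash") <- rlang::hash(unclass(spec))
  class(out) <- c("regime_map", "data.frame")
  out
}

# most advanced dynamical stage present among a classification's orbits
regime_stage <- function(cl) {
  per <- cl$per_orbit
  stage <- ifelse(per$label == "fixed-point",
                  ifelse(per$q_max < 1e-6, "silent", "interior"),
                  per$label)
  order_levels <- c("silent", "interior", "periodic", "complex")
  order_levels[max(match(stage, order_levels))]
}

#' Hypoxia/reoxygenation protocol
#'
#' Piecewise schedule for the recovery energy `e_bar(t)` and activation
#' probability `p(t)` emulating acute oxygen deprivation of a culture:
#' \describe{
#'   \item{a `[1, 1500]`}{normal functioning: `e_bar = 4`, `p = 0.1`.}
#'   \item{b `(1500, 2500]`}{acute hypoxia: `e_bar` drops to 0.4.}
#'   \item{c `(2500, 2700)`}{reoxygenation + glutamate surge: `e_bar`
#'     restored to 4, `p` raised to 0.15.}
#'   \item{d `[2700, 5000]`}{glutamate-induced suppression: `p = 0.07`.}
#'   \item{e `(5000, t_end]`}{degeneration: `p` decreases linearly to
#'     `p_end` at `t_end`.}
#' }
#' The map parameters default to r 1.5, z 170, eps 0.05, w 1.5, e_low 2.
#'
#' @param t_end Final step of the run (default 8000).
#' @param p_end Activation probability reached at `t_end` (default 0.01).
#' @param z,r,eps,w,e_low Map parameters.
#' @param e_bar_normal,e_bar_hypoxic Nominal and deprived recovery levels.
#' @param p_normal,p_surge,p_suppressed Schedule levels for `p`.
#' @return A `hypoxia_protocol`: list with per-step vectors `p_t`, `e_bar_t`
#'   (length `t_end`), a `zones` data.frame (`zone`, `t_start`, `t_end`) and
#'   the fixed parameters.
#' @export
hypoxia_protocol <- function(t_end = 8000, p_end = 0.01, z = 170, r = 1.5,
                             eps = 0.05, w = 1.5, e_low = 2,
                             e_bar_normal = 4, e_bar_hypoxic = 0.4,
                             p_normal = 0.1, p_surge = 0.15,
                             p_suppressed = 0.07) {
  if (t_end <= 5000) stop("`t_end` must exceed 5000", call. = FALSE)
  check_scalar(p_end, "p_end", 0, p_suppressed, strict_lower = TRUE)
  t <- seq_len(t_end)
  e_bar_t <- ifelse(t > 1500 & t <= 2500, e_bar_hypoxic, e_bar_normal)
  p_t <- rep(p_normal, t_end)
  p_t[t > 2500 & t < 2700] <- p_surge
  p_t[t >= 2700 & t <= 5000] <- p_suppressed
  ramp <- t > 5000
  p_t[ramp] <- p_suppressed +
    (p_end - p_suppressed) * (t[ramp] - 5000) / (t_end - 5000)
  zones <- data.frame(
    zone = c("a", "b", "c", "d", "e"),
    t_start = c(1, 1501, 2501, 2700, 5001),
    t_end = c(1500, 2500, 2699, 5000, t_end)
  )
  structure(
    list(p_t = p_t, e_bar_t = e_bar_t, zones = zones, t_end = t_end,
         z = z, r = r, eps = eps, w = w, e_low = e_low,
         e_bar_normal = e_bar_normal),
    class = "hypoxia_protocol"
  )
}

#' Run the hypoxia/reoxygenation protocol
#'
#' Iterates the activity-energy map with the time-varying `p(t)` and
#' `e_bar(t)` of the protocol.  Deterministic.
#'
#' @param protocol A [hypoxia_protocol()].
#' @param q0,e0 Initial state (default `q0 = 0.5`, `e0` at the nominal
#'   recovery level).
#' @return A `hypoxia_run`: list with `t` (0..t_end), `q`, `E`, the per-step
#'   schedule (`p_t`, `e_bar_t`) and the protocol's `zones`.
#' @examples
#' run <- run_hypoxia(hypoxia_protocol())
#' zone_means(run)
#' @export
run_hypoxia <- function(protocol, q0 = 0.5, e0 = protocol$e_bar_normal) {
  stopifnot(inherits(protocol, "hypoxia_protocol"))
  res <- cpp_simulate_meanfield_schedule(q0, e0, protocol$p_t,
                                         protocol$e_bar_t, protocol$z,
                                         protocol$w, protocol$e_low,
                                         protocol$eps, protocol$r)
  structure(
    list(t = 0:protocol$t_end, q = res$q, E = res$E, p_t = protocol$p_t,
         e_bar_t = protocol$e_bar_t, zones = protocol$zones,
         protocol = protocol),
    class = "hypoxia_run"
  )
}

#' @export
print.hypoxia_run <- function(x, ...) {
  zm <- zone_means(x)
  cat("<hypoxia_run> mean activity by zone:\n")
  print(round(zm, 4))
  invisible(x)
}

#' Mean activity per protocol zone
#'
#' @param run A [run_hypoxia()] result.
#' @return Named numeric vector of the mean `q` over each zone a-e.
#' @export
zone_means <- function(run) {
  stopifnot(inherits(run, "hypoxia_run"))
  q <- run$q[-1] # q[t], t = 1..t_end
  vapply(seq_len(nrow(run$zones)), function(i) {
    mean(q[run$zones$t_start[i]:run$zones$t_end[i]])
  }, numeric(1)) |> stats::setNames(run$zones$zone)
}

# ---- configuration round-trip --------------------------------------------

config_required_fields <- list(
  portrait_spec = c("r", "e_low_grid", "z_grid", "n_init", "steps", "tail",
                    "w", "p", "e_bar", "eps"),
  ensemble_spec = c("n_triples", "p_range", "r_range", "e_low_range",
                    "z_grid", "steps", "tail"),
  mf_params = c("p", "z", "w", "e_low", "e_bar", "eps", "r")
)

#' Save / load an experiment configuration
#'
#' Specs are written as YAML with a `type` field recording the class, and
#' validated on load (a missing required field is reported by name).
#' `config_load(config_save(x, path))` restores `x` exactly for
#' [portrait_spec()], [ensemble_spec()] and [mf_params()] objects.
#'
#' @param x A spec object.
#' @param path File path.
#' @return `config_save` returns `path` invisibly; `config_load` the restored
#'   object.
#' @export
config_save <- function(x, path) {
  type <- class(x)[1]
  if (!type %in% names(config_required_fields)) {
    stop("don't know how to serialise objects of class ", type,
         call. = FALSE)
  }
  payload <- c(list(type = type), unclass(x))
  payload <- payload[!vapply(payload, is.null, logical(1))]
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname config_save
#' @export
config_load <- function(path) {
  payload <- yaml::read_yaml(path)
  type <- payload$type
  if (is.null(type) || !type %in% names(config_required_fields)) {
    stop("config is missing a valid `type` field", call. = FALSE)
  }
  required <- config_required_fields[[type]]
  missing <- setdiff(required, names(payload))
  if (length(missing)) {
    stop("config of type ", type, " is missing required field(s): ",
         paste0("`", missing, "`", collapse = ", "), call. = FALSE)
  }
  payload$type <- NULL
  structure(payload, class = type)
}

#' Hash of a configuration object
#'
#' Stable content hash attached to output files for provenance.
#'
#' @param x Any spec object.
#' @return A character hash.
#' @export
config_hash <- function(x) rlang::hash(unclass(x))

# ---- writers --------------------------------------------------------------

#' Write an orbit, a regime map or a spanning curve to CSV
#'
#' Plain CSV with a leading `# config_hash:` comment line for provenance.
#'
#' @param x The object to write.
#' @param path Output file.
#' @param hash Hash recorded in the header (default: hash of the object's
#'   parameters/spec).
#' @return `path`, invisibly.
#' @export
write_orbit_csv <- function(x, path, hash = config_hash(x$params)) {
  stopifnot(inherits(x, c("mf_orbit", "hypoxia_run")))
  df <- data.frame(t = x$t, q = x$q, E = x$E)
  write_csv_hashed(df, path, hash)
}

#' @rdname write_orbit_csv
#' @export
write_regime_map_csv <- function(x, path,
                                 hash = attr(x, "config_hash")) {
  stopifnot(inherits(x, "regime_map"))
  write_csv_hashed(as.data.frame(x), path, hash)
}

write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash %||% "none"), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
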