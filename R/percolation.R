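# Continuum percolation of neurite-mediated connectivity in the unit square.
#
# Each cell is a soma with a dendrite ("tail") disk of radius R and a straight
# axon of length H whose tip carries a "head" disk, also of radius R.  Three
# coupling rules are supported:
#   circle - H ignored; undirected edge when tail disks overlap,
#   dipole - undirected edge when any of the four tail/head disk pairs of two
#            cells overlap,
#   vector - directed edge i -> j when the head disk of i overlaps the tail
#            disk of j.
# The control parameter is the mean disk occupancy B = pi R^2 n, with n the
# cell density (cells per unit area).

#' Sample a random field of cells
#'
#' Draws `n` cells with soma positions i.i.d. uniform on the unit square and
#' axon directions i.i.d. uniform on `[0, 2*pi)`.  The axon head of cell *i*
#' lies at `position_i + h * (cos(angle_i), sin(angle_i))`; heads (but not
#' somata) may fall outside the square and are kept unclipped.
#'
#' @param n Number of cells (>= 1).
#' @param r Dendrite-disk radius, in unit-square units (> 0).
#' @param h Axon length, same units (>= 0). `h = 0` makes heads coincide with
#'   tails.
#' @param seed Optional integer seed; the caller's RNG state is left
#'   untouched.
#' @return A `cell_field` object: list with `positions` (n x 2 matrix),
#'   `angles`, `heads` (n x 2 matrix), `r`, `h`, `n`.
#' @examples
#' f <- sample_field(100, r = 0.02, h = 0.04, seed = 1)
#' range(sqrt(rowSums((f$heads - f$positions)^2))) # == h
#' @export
sample_field <- function(n, r, h = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  check_scalar(r, "r", lower = 0, strict_lower = TRUE)
  check_scalar(h, "h", lower = 0)
  n <- as.integer(n)
  with_local_seed(seed, {
    positions <- cbind(x = runif(n), y = runif(n))
    angles <- runif(n, 0, 2 * pi)
    heads <- positions + h * cbind(cos(angles), sin(angles))
    colnames(heads) <- c("x", "y")
    structure(
      list(positions = positions, angles = angles, heads = heads,
           r = r, h = h, n = n),
      class = "cell_field"
    )
  })
}

#' Construct a cell field from explicit geometry
#'
#' Companion to [sample_field()] for deterministic arrangements: positions
#' (and either axon angles or `h = 0`) are given explicitly.
#'
#' @param positions n x 2 matrix of soma positions in the unit square.
#' @param r Dendrite-disk radius (> 0).
#' @param h Axon length (>= 0).
#' @param angles Axon angles in radians (recycled; default 0).
#' @return A `cell_field` object.
#' @examples
#' cell_field(rbind(c(0.2, 0.5), c(0.33, 0.5)), r = 0.02, h = 0.1)
#' @export
cell_field <- function(positions, r, h = 0, angles = 0) {
  positions <- matrix(as.numeric(positions), ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
  n <- nrow(positions)
  if (n < 1) stop("`positions` must contain at least one cell", call. = FALSE)
  if (any(positions < 0 | positions > 1)) {
    stop("soma positions must lie in the unit square", call. = FALSE)
  }
  check_scalar(r, "r", lower = 0, strict_lower = TRUE)
  check_scalar(h, "h", lower = 0)
  angles <- rep_len(angles, n) %% (2 * pi)
  heads <- positions + h * cbind(cos(angles), sin(angles))
  colnames(heads) <- c("x", "y")
  structure(
    list(positions = positions, angles = angles, heads = heads,
         r = r, h = h, n = n),
    class = "cell_field"
  )
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("<cell_field> n = %d cells, R = %g, H = %g (H/R = %g)\n",
              x$n, x$r, x$h, x$h / x$r))
  invisible(x)
}

#' Build the connectivity graph of a cell field
#'
#' Applies one of the three geometric coupling rules.  Two disks of radius R
#' overlap when their centres are within `2R` (closed inequality).
#'
#' @param field A [sample_field()] result.
#' @param case One of `"circle"` (tail-tail overlap, undirected; axons
#'   ignored), `"dipole"` (any tail/head pair overlap, undirected) or
#'   `"vector"` (head of i reaches tail of j, directed).
#' @return A `connectivity_graph`: list with `n`, `edges` (m x 2 integer
#'   matrix; ordered pairs for `"vector"`, i < j otherwise), `directed`,
#'   `case`.
#' @examples
#' f <- sample_field(50, r = 0.05, h = 0.1, seed = 1)
#' g <- build_connectivity(f, "vector")
#' @export
build_connectivity <- function(field, case = c("circle", "dipole", "vector")) {
  stopifnot(inherits(field, "cell_field"))
  case <- match.arg(case)
  cutoff <- 2 * field$r
  tx <- field$positions[, 1]; ty <- field$positions[, 2]
  hx <- field$heads[, 1];     hy <- field$heads[, 2]
  directed <- FALSE
  if (case == "circle") {
    edges <- cpp_close_pairs(tx, ty, cutoff)
  } else if (case == "dipole") {
    tt <- cpp_close_pairs(tx, ty, cutoff)
    hh <- cpp_close_pairs(hx, hy, cutoff)
    th <- cpp_cross_pairs(tx, ty, hx, hy, cutoff) # (tail_i, head_j)
    th <- th[th[, 1] != th[, 2], , drop = FALSE]
    th <- cbind(pmin(th[, 1], th[, 2]), pmax(th[, 1], th[, 2]))
    edges <- unique(rbind(tt, hh, th))
  } else { # vector: head of i within 2R of tail of j
    e <- cpp_cross_pairs(hx, hy, tx, ty, cutoff)
    edges <- e[e[, 1] != e[, 2], , drop = FALSE]
    directed <- TRUE
  }
  if (nrow(edges) == 0) edges <- matrix(integer(0), 0, 2)
  dimnames(edges) <- NULL
  structure(
    list(n = field$n, edges = edges, directed = directed, case = case),
    class = "connectivity_graph"
  )
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> case = %s, %d nodes, %d %s edges\n",
              x$case, x$n, nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Test for a left-right spanning cluster
#'
#' A cluster spans when some connected component (undirected connectivity;
#' directed edges of the `"vector"` case are symmetrised) contains both a cell
#' whose tail or head disk reaches the left edge (`x <= R`) and one reaching
#' the right edge (`x >= 1 - R`).  For the `"circle"` case only tail disks
#' count.
#'
#' @param graph A [build_connectivity()] result.
#' @param field The `cell_field` the graph was built from.
#' @return `TRUE` or `FALSE`.
#' @export
spanning_cluster_exists <- function(graph, field) {
  stopifnot(inherits(graph, "connectivity_graph"),
            inherits(field, "cell_field"))
  if (graph$n != field$n) {
    stop("graph and field have different cell counts", call. = FALSE)
  }
  n <- field$n
  if (n == 0) return(FALSE)
  r <- field$r
  tx <- field$positions[, 1]
  left <- tx <= r
  right <- tx >= 1 - r
  if (graph$case != "circle") {
    hx <- field$heads[, 1]
    left <- left | hx <= r
    right <- right | hx >= 1 - r
  }
  if (!any(left) || !any(right)) return(FALSE)
  g <- igraph::make_graph(t(graph$edges), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  length(intersect(unique(memb[left]), unique(memb[right]))) > 0
}

#' Estimate the percolation threshold B_c
#'
#' For each mean occupancy `B` in `b_grid`, generates `n_realizations`
#' independent fields of `n_cells` cells with dendrite radius
#' `R = sqrt(B / (pi * n_cells))` (so that `B = pi R^2 n`) and axon length
#' `H = h_over_r * R`, and records the fraction of realizations with a
#' left-right spanning cluster.  The threshold estimate `b_c_hat` is the point
#' where the isotonic (monotone non-decreasing) fit of the spanning curve
#' crosses 0.5, linearly interpolated between the bracketing grid points.
#'
#' @param case Coupling rule, see [build_connectivity()].
#' @param h_over_r Axon length over dendrite radius (0 for `"circle"`).
#' @param n_cells Cells per field.
#' @param n_realizations Independent fields per grid point.
#' @param b_grid Increasing positive grid of B values.
#' @param seed Optional integer seed.
#' @return A `percolation_estimate`: list with `case`, `h_over_r`, `b_c_hat`,
#'   `spanning_curve` (data.frame `B`, `spanning_prob`), `n_cells`,
#'   `n_realizations`, `seed`.
#' @examples
#' \donttest{
#' est <- estimate_bc("circle", n_cells = 500, n_realizations = 10,
#'                    b_grid = seq(0.6, 1.8, by = 0.2), seed = 1)
#' est$b_c_hat
#' }
#' @export
estimate_bc <- function(case = c("circle", "dipole", "vector"), h_over_r = 0,
                        n_cells = 3000, n_realizations = 20,
                        b_grid = seq(0.6, 1.6, by = 0.05), seed = NULL) {
  case <- match.arg(case)
  check_scalar(h_over_r, "h_over_r", lower = 0)
  if (!is.numeric(b_grid) || length(b_grid) < 1 || any(b_grid <= 0) ||
      is.unsorted(b_grid, strictly = TRUE)) {
    stop("`b_grid` must be a strictly increasing positive vector",
         call. = FALSE)
  }
  probs <- with_local_seed(seed, {
    vapply(b_grid, function(b) {
      r <- sqrt(b / (pi * n_cells))
      h <- h_over_r * r
      hits <- 0L
      for (k in seq_len(n_realizations)) {
        f <- sample_field(n_cells, r = r, h = h)
        g <- build_connectivity(f, case)
        if (spanning_cluster_exists(g, f)) hits <- hits + 1L
      }
      hits / n_realizations
    }, numeric(1))
  })
  curve <- data.frame(B = b_grid, spanning_prob = probs)
  iso <- if (length(b_grid) > 1) isoreg(b_grid, probs)$yf else probs
  i <- which(iso >= 0.5)[1]
  if (is.na(i)) {
    stop("spanning curve never reaches 0.5 within `b_grid` ",
         "(max spanning probability ", max(iso), "); ",
         "cannot bracket the crossing from above", call. = FALSE)
  }
  if (i == 1) {
    stop("spanning probability is already ", iso[1], " >= 0.5 at the first ",
         "grid point B = ", b_grid[1], "; cannot bracket the crossing from ",
         "below", call. = FALSE)
  }
  b_c <- b_grid[i - 1] +
    (0.5 - iso[i - 1]) * (b_grid[i] - b_grid[i - 1]) / (iso[i] - iso[i - 1])
  structure(
    list(case = case, h_over_r = h_over_r, b_c_hat = b_c,
         spanning_curve = curve, n_cells = n_cells,
         n_realizations = n_realizations, seed = seed),
    class = "percolation_estimate"
  )
}

#' @export
print.percolation_estimate <- function(x, ...) {
  cat(sprintf(
    "<percolation_estimate> case = %s, H/R = %g\n  B_c_hat = %.4g  (%d cells, %d realizations, %d grid points)\n",
    x$case, x$h_over_r, x$b_c_hat, x$n_cells, x$n_realizations,
    nrow(x$spanning_curve)
  ))
  invisible(x)
}

#' @export
plot.percolation_estimate <- function(x, ...) {
  plot(x$spanning_curve$B, x$spanning_curve$spanning_prob, type = "b",
       xlab = "B = pi R^2 n", ylab = "spanning probability",
       main = sprintf("%s percolation, H/R = %g", x$case, x$h_over_r), ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$b_c_hat, col = 2, lty = 2)
  invisible(x)
}
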