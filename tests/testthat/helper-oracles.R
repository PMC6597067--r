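# shared oracles and fixture builders (all fixtures are built in code)

# discrete power-law sampler P(s) = s^(-alpha) / zeta on {xmin, ..., xmax}:
# exact inverse-CDF draw from the enumerated pmf (independent of the
# package's estimator)
rpowerlaw_discrete <- function(n, alpha, xmin = 1, xmax = 1e4) {
  s <- xmin:xmax
  pmf <- s^(-alpha)
  cdf <- cumsum(pmf / sum(pmf))
  s[findInterval(runif(n), cdf) + 1L]
}

# brute-force O(n^2) edge lists for the three coupling rules; oracle for the
# cell-list neighbour search
brute_edges <- function(field, case) {
  n <- field$n
  cutoff <- 2 * field$r
  d <- function(a, b) sqrt(sum((a - b)^2))
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ti <- field$positions[i, ]; tj <- field$positions[j, ]
      hi <- field$heads[i, ];     hj <- field$heads[j, ]
      hit <- switch(case,
        circle = i < j && d(ti, tj) <= cutoff,
        dipole = i < j && (d(ti, tj) <= cutoff || d(hi, hj) <= cutoff ||
                           d(ti, hj) <= cutoff || d(hi, tj) <= cutoff),
        vector = d(hi, tj) <= cutoff
      )
      if (isTRUE(hit)) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# canonical form for edge-set comparison
edge_key <- function(edges, directed) {
  if (nrow(edges) == 0) return(character(0))
  if (!directed) edges <- cbind(pmin(edges[, 1], edges[, 2]),
                                pmax(edges[, 1], edges[, 2]))
  sort(paste(edges[, 1], edges[, 2]))
}

fig4_params <- function(z, r = 10) {
  mf_params(p = 0.1, z = z, w = 1.5, e_low = 2, e_bar = 4, eps = 0.05, r = r)
}
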