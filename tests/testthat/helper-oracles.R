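# Independent oracles and geometric constructions used across tests.

# Brute-force BFS over the pairwise-distance graph: the independent
# clustering oracle (no union-find, no shared code with cluster_records).
bfs_components <- function(x, y, threshold) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  adj <- (outer(x, x, "-")^2 + outer(y, y, "-")^2) < threshold^2
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# canonical form of a partition for equality checks
canon_partition <- function(assignment) {
  unname(split(seq_along(assignment), assignment)[
    order(vapply(split(seq_along(assignment), assignment), min, integer(1)))])
}

# respondents on a circle: their buffers form a ring with an interior hole
ring_respondents <- function(n = 12, R = 120) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  data.frame(x = R * cos(th), y = R * sin(th))
}

# respondents along three sides of an open channel; the mouth (open side)
# is a controllable share of the enclosed pocket's perimeter
u_respondents <- function(width = 300, depth = 160, spacing = 20) {
  data.frame(
    x = c(seq(0, width, spacing), rep(0, depth / spacing), rep(width, depth / spacing)),
    y = c(rep(0, width / spacing + 1), seq(spacing, depth, spacing),
          seq(spacing, depth, spacing))
  )
}

square_polyset <- function(side = 1000, x0 = 0, y0 = 0) {
  polyset(list(list(x = x0 + c(0, side, side, 0), y = y0 + c(0, 0, side, side))))
}
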