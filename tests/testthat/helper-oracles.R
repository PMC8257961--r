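# Shared fixtures and independent oracles used across the suite.

# segment from coordinate vectors, fixes every `by` seconds
make_seg <- function(x, y, by = 3, id = "seg") {
  flight_segment(id, data.frame(t = (seq_along(x) - 1) * by, x = x, y = y))
}

# straight due-north track: n fixes, `step` metres per fix
north_track <- function(n, step = 15, by = 3, id = "north") {
  make_seg(rep(0, n), (seq_len(n) - 1) * step, by = by, id = id)
}

# circular loop: radius r, speed v, sampled every `by` seconds
circle_track <- function(n, r = 15, v = 5, by = 3, id = "circle",
                         center = c(0, 0)) {
  th <- (seq_len(n) - 1) * by * v / r
  make_seg(center[1] + r * cos(th), center[2] + r * sin(th),
           by = by, id = id)
}

# brute-force connected components of the <= cutoff adjacency graph
# (breadth-first search; independent of hclust)
bf_components <- function(points, cutoff) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      nb <- which(d[j, ] <= cutoff & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# do two cluster assignments define the same partition?
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# moment-formula kurtosis written independently (sums, not means)
kurtosis_oracle <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m4 <- sum((v - m)^4) / n
  m4 / m2^2
}

# Monte-Carlo pixel masses of one bridge timeslice
mc_slice_masses <- function(mu, s, spec, ndraw = 1e5) {
  px <- stats::rnorm(ndraw, mu[1], s)
  py <- stats::rnorm(ndraw, mu[2], s)
  ix <- floor((px - spec$origin[1]) / spec$pixel_m) + 1
  iy <- floor((py - spec$origin[2]) / spec$pixel_m) + 1
  ok <- ix >= 1 & ix <= spec$nx & iy >= 1 & iy <= spec$ny
  m <- matrix(0, spec$nx, spec$ny)
  tab <- table(ix[ok] + (iy[ok] - 1) * spec$nx)
  m[as.integer(names(tab))] <- as.integer(tab) / ndraw
  m
}
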