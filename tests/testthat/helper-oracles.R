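# Independent oracles used across the suite. These deliberately avoid the
# package's own numeric paths: closed forms, brute-force scans, and simple
# fixpoint iterations.

# closed-form arc length of the cylinder+cone curve between t0 and t1.
# Cylinder: constant speed sqrt((2 pi r_max)^2 + P^2). Cone: speed
# sqrt((2 pi r(t))^2 + P^2) with r linear in t, integrable in closed form
# via F(v) = v/2 sqrt(v^2+P^2) + P^2/2 log(v + sqrt(v^2+P^2)).
oracle_arc_length <- function(spec, t0, t1) {
  P <- spec$pitch; rmax <- spec$r_max; tcyl <- spec$t_cyl
  tcap <- rmax / (P * sin(spec$alpha * pi / 180))
  Fv <- function(v) v / 2 * sqrt(v^2 + P^2) + P^2 / 2 * log(v + sqrt(v^2 + P^2))
  cone_part <- function(a, b) {       # a,b in [tcyl, tcyl+tcap]
    r_of <- function(t) rmax * (1 - (t - tcyl) / tcap)
    va <- 2 * pi * r_of(a); vb <- 2 * pi * r_of(b)
    tcap / (2 * pi * rmax) * (Fv(va) - Fv(vb))
  }
  cyl_speed <- sqrt((2 * pi * rmax)^2 + P^2)
  if (t1 <= tcyl) return((t1 - t0) * cyl_speed)
  if (t0 >= tcyl) return(cone_part(t0, t1))
  (tcyl - t0) * cyl_speed + cone_part(tcyl, t1)
}

# full pairwise distance matrix (brute force)
oracle_dist <- function(atoms) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  as.matrix(stats::dist(xyz))
}

# brute-force O(n^2) clash scan between different chains
oracle_clashes <- function(atoms, cutoff) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  n <- nrow(xyz)
  hits <- 0L
  for (i in seq_len(n - 1L)) {
    d2 <- colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2)
    hits <- hits + sum(d2 < cutoff^2 &
                         atoms$chain[(i + 1):n] != atoms$chain[i])
  }
  hits
}

# max-min bottleneck by Bellman-Ford-style relaxation over all grid paths
# (exhaustive fixpoint; independent of the package's threshold search)
oracle_maxmin <- function(clr, s, e) {
  d <- dim(clr)
  best <- array(-Inf, d)
  best[s[1], s[2], s[3]] <- clr[s[1], s[2], s[3]]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  repeat {
    changed <- FALSE
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (clr[i, j, k] <= 0) next
      for (oi in seq_len(nrow(offs))) {
        ii <- i + offs[oi, 1]; jj <- j + offs[oi, 2]; kk <- k + offs[oi, 3]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
          next
        cand <- min(best[ii, jj, kk], clr[i, j, k])
        if (cand > best[i, j, k]) { best[i, j, k] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  best[e[1], e[2], e[3]]
}

# grid-search RSS floor for the collapse sigmoid
oracle_grid_rss <- function(p, od, p0_range, k_range, n = 200) {
  p0s <- seq(p0_range[1], p0_range[2], length.out = n)
  ks <- seq(k_range[1], k_range[2], length.out = n)
  best <- Inf
  for (k in ks) {
    for (p0 in p0s) {
      r <- sum((od - 1 / (1 + exp(k * (p - p0))))^2)
      if (r < best) best <- r
    }
  }
  best
}

# default spec used across shell tests
default_spec <- function() vesicle_spec()
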