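# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force numerics, exhaustive scans, quadrature.

# Numeric Newton / Gauss-Newton solve of the two-point saturation system
# B_k = Bmax * S * I_k / (1 + S * I_k), with finite-difference Jacobian.
# Acts as a brute-force least-squares oracle (residual -> 0 at the optimum).
oracle_saturation_two_point <- function(I, B, iters = 60) {
  resid <- function(p) B - p[2] * p[1] * I / (1 + p[1] * I)
  p <- c(S = 1 / stats::median(I), Bmax = 2 * max(B))
  for (k in seq_len(iters)) {
    r <- resid(p)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- max(abs(p[j]), 1e-8) * 1e-7
      ph <- p; ph[j] <- ph[j] + h
      J[, j] <- (resid(ph) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) rep(0, 2))
    # damped update to stay positive
    lam <- 1
    while (any(p + lam * step <= 0) && lam > 1e-8) lam <- lam / 2
    p <- p + lam * step
    if (sum(r^2) < 1e-28) break
  }
  c(S_B = unname(p[1]), B_max = unname(p[2]))
}

# Exhaustive 26-neighbour check of 3D local maxima (no vectorized tricks).
oracle_local_maxima <- function(vol, threshold = 1) {
  d <- dim(vol)
  out <- NULL
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    v <- vol[z, y, x]
    if (v <= threshold) next
    ok <- TRUE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      zz <- z + dz; yy <- y + dy; xx <- x + dx
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3]) next
      if (vol[zz, yy, xx] >= v) { ok <- FALSE; break }
    }
    if (ok) out <- rbind(out, c(z, y, x))
  }
  out
}

# Brute-force horizontal extent of the above-threshold run through (y, x)
# of a 2D image, in pixels left/right of the centre.
oracle_run_extent <- function(img, y, x, threshold = 1) {
  left <- 0
  while (x - left - 1 >= 1 && img[y, x - left - 1] > threshold) left <- left + 1
  right <- 0
  while (x + right + 1 <= ncol(img) && img[y, x + right + 1] > threshold) right <- right + 1
  c(left = left, right = right)
}

# Two-sided t probability by adaptive quadrature of the t density.
oracle_t_two_sided <- function(t, v) {
  dens <- function(u) {
    exp(lgamma((v + 1) / 2) - lgamma(v / 2) - 0.5 * log(v * pi) -
          (v + 1) / 2 * log1p(u^2 / v))
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}

# Simulate one cohort of independent-noise lognormal pairs and return the
# plain and bias-corrected ratio estimates (vectorised over replicates).
oracle_ratio_mc <- function(reps, n, R, cv) {
  s <- sqrt(log(1 + cv^2))
  x <- matrix(stats::rlnorm(reps * n, -s^2 / 2, s), reps)
  y <- R * matrix(stats::rlnorm(reps * n, -s^2 / 2, s), reps)
  sx <- rowSums(x); sy <- rowSums(y)
  r <- sy / sx
  rc <- n * r - (n - 1) / n * rowSums((sy - y) / (sx - x))
  list(r = r, rc = rc)
}
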