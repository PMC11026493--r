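# shared fixtures and independent oracles

# reference Table-style parameters (bulk sensitive cell)
ref_params <- function() hill_params(e0 = 1, emax = 0.16,
                                     ec50 = 10^-7.72, hs = 2^-1.02)

# independent re-evaluation of the sigmoid in log space:
# (d/ec50)^hs is computed as exp(hs * (log d - log ec50))
sigmoid_oracle <- function(e0, emax, ec50, hs, d) {
  if (d == 0) return(e0)
  emax + (e0 - emax) / (1 + exp(hs * (log(d) - log(ec50))))
}

# bisection search for the smallest dose with response < threshold * e0,
# independent of the closed form in inhibition_dose
bisect_inhibition_dose <- function(p, threshold, lo = 1e-16, hi = 1e2,
                                   iters = 200) {
  target <- threshold * p$e0
  f <- function(d) hill_response(p, d) - target
  if (f(hi) >= 0) return(Inf)
  if (f(lo) <= 0) return(lo)
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# random in-bounds decreasing-response Hill parameters
random_hill <- function() {
  e0 <- runif(1, 0.5, 2)
  emax <- runif(1, 0, 0.9) * e0 * 0.5
  hill_params(e0 = e0, emax = emax, ec50 = 10^runif(1, -9, -5),
              hs = 2^runif(1, -2, 2))
}

# brute-force nearest-seed label expansion (per-pixel search)
brute_expand <- function(mask, radius) {
  lab <- mask$labels
  out <- lab
  seeds <- which(lab > 0, arr.ind = TRUE)
  seed_lab <- lab[lab > 0]
  bg <- which(lab == 0, arr.ind = TRUE)
  for (i in seq_len(nrow(bg))) {
    d2 <- (seeds[, 1] - bg[i, 1])^2 + (seeds[, 2] - bg[i, 2])^2
    m <- min(d2)
    if (m <= radius^2)
      out[bg[i, 1], bg[i, 2]] <- min(seed_lab[d2 == m])
  }
  labeled_mask(out)
}

# draw a filled disk of a given label into an integer matrix
draw_disk <- function(m, cy, cx, r, value) {
  for (dy in -r:r) for (dx in -r:r)
    if (dy^2 + dx^2 <= r^2) m[cy + dy, cx + dx] <- value
  m
}

# a small population spec with zero spread (every cell identical)
constant_spec <- function(n = 5, e0 = 1, emax = 0.16, lec50 = -7.72,
                          lhs = -1.02) {
  population_spec(list(list(
    count = n, label = "const",
    e0 = param_dist(e0, 0), emax = param_dist(emax, 0),
    ec50 = param_dist(lec50, 0, "log10"),
    hs = param_dist(lhs, 0, "log2"))), name = "constant")
}
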