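# Independent oracles used across the suite. Each is a brute-force or
# closed-form route kept deliberately separate from the package
# implementation it checks.

# Numerical convolution of the Tofts integrand on a fine trapezoid grid.
oracle_tofts_numeric <- function(t, ktrans, ve, aif = population_aif(),
                                 dt = 0.001) {
  if (t == 0 || ktrans == 0) return(0)
  tau <- seq(0, t, by = dt)
  kep <- ktrans / ve
  f <- aif_concentration(tau, aif) * exp(-kep * (t - tau))
  ktrans * (sum(f) - (f[1] + f[length(f)]) / 2) * dt
}

# Scalar queue-based flood fill over a logical 3D array.
oracle_flood_fill <- function(super, seed, connectivity = 26L) {
  d <- dim(super)
  offs <- expand.grid(-1:1, -1:1, -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  visited <- array(FALSE, d)
  if (!super[seed[1], seed[2], seed[3]]) return(visited)
  queue <- list(seed)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (k in seq_len(nrow(offs))) {
      nb <- v + as.integer(offs[k, ])
      if (any(nb < 1) || any(nb > d)) next
      if (visited[nb[1], nb[2], nb[3]] || !super[nb[1], nb[2], nb[3]]) next
      visited[nb[1], nb[2], nb[3]] <- TRUE
      queue <- c(queue, list(nb))
    }
  }
  visited
}

# AUC by exhaustive concordant/discordant pair counting.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "malignant"]
  neg <- scores[labels != "malignant"]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Percentile by explicit sort-and-interpolate between closest ranks.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Noise-free homogeneous lesion with known kinetics.
make_uniform_lesion <- function(ktrans = 0.25, ve = 0.35, alpha = 8,
                                semi_axes = c(4, 4, 4),
                                protocol = dce_protocol(), s0 = 100) {
  spec <- lesion_spec(semi_axes = semi_axes, ktrans_mean = ktrans,
                      ktrans_cv = 0, ve_mean = ve, ve_cv = 0)
  generate_lesion_volume(spec, protocol, s0 = s0, alpha = alpha,
                         noise_sd = 0)
}

# 4D series built directly from per-voxel Tofts curves on a slab grid;
# kt_map / ve_map are 3D arrays covering the whole grid.
make_phantom_series <- function(kt_map, ve_map, alpha = 8, s0 = 100,
                                protocol = dce_protocol()) {
  d <- dim(kt_map)
  tm <- frame_times(protocol, "minutes")
  ct <- breastdce:::tofts_concentration_matrix(tm, as.vector(kt_map),
                                               as.vector(ve_map))
  series <- array(0, c(d, protocol$n_timepoints))
  for (j in seq_len(protocol$n_timepoints))
    series[, , , j] <- array(s0 * (1 + alpha * ct[, j]), d)
  series
}
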