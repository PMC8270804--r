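#' Tofts tissue concentration (closed form)
#'
#' Two-compartment Tofts model: tissue concentration is the plasma curve
#' convolved with `ktrans * exp(-kep * t)`, where `kep = ktrans / ve`. For a
#' bi-exponential population AIF the convolution has the closed form
#' \deqn{C_t(t) = D\,k^{trans} \sum_i a_i
#'   \frac{e^{-m_i t} - e^{-k_{ep} t}}{k_{ep} - m_i}}
#' with the removable singularity at `kep == m_i` evaluated as
#' `a_i t exp(-m_i t)`.
#'
#' @param t time in minutes (vectorized), nonnegative.
#' @param ktrans transfer constant plasma -> EES, 1/min (>= 0).
#' @param ve extravascular extracellular volume fraction, in (0, 1].
#' @param aif a [population_aif()].
#' @return tissue concentration, same length as `t`; 0 at t = 0 and
#'   identically 0 when `ktrans = 0`.
#' @export
tofts_concentration <- function(t, ktrans, ve, aif = population_aif()) {
  if (any(t < 0)) stop("time must be nonnegative")
  if (ktrans < 0) stop("ktrans must be nonnegative")
  if (ve <= 0 || ve > 1) stop("ve must lie in (0, 1]")
  if (ktrans == 0) return(numeric(length(t)))
  kep <- ktrans / ve
  term <- function(a, m) {
    if (abs(kep - m) < 1e-10) a * t * exp(-m * t)
    else a * (exp(-m * t) - exp(-kep * t)) / (kep - m)
  }
  aif$dose * ktrans * (term(aif$a1, aif$m1) + term(aif$a2, aif$m2))
}

# Vectorized over voxels: ktrans, ve vectors (length n), t vector (length T).
# Returns n x T matrix. Internal workhorse for simulation and map fitting.
tofts_concentration_matrix <- function(t, ktrans, ve, aif = population_aif()) {
  n <- length(ktrans)
  kep <- ktrans / ve
  et <- function(rate) exp(-outer(rate, t))     # n x T
  ekep <- et(kep)
  term <- function(a, m) {
    d <- kep - m
    safe <- abs(d) >= 1e-10
    out <- matrix(0, n, length(t))
    if (any(safe))
      out[safe, ] <- a * (exp(-outer(rep(m, sum(safe)), t)) - ekep[safe, , drop = FALSE]) /
        d[safe]
    if (any(!safe))
      out[!safe, ] <- a * outer(rep(1, sum(!safe)), t) *
        exp(-outer(rep(m, sum(!safe)), t))
    out
  }
  aif$dose * ktrans * (term(aif$a1, aif$m1) + term(aif$a2, aif$m2))
}

#' Voxelwise Tofts fitting of relative-enhancement curves
#'
#' Bounded nonlinear least squares of the Tofts model against measured
#' relative-enhancement curves `rel(t) = alpha * C_t(t; ktrans, ve)`. Fitting
#' uses a damped Gauss-Newton (Levenberg-Marquardt) iteration run from a
#' 3 x 3 coarse grid of starting points spanning the parameter box
#' `ktrans` in [0, 5] /min, `ve` in (0.01, 1]; the best of the nine local
#' solutions is kept per voxel. All voxels are iterated simultaneously
#' (matrix arithmetic), so the cost per iteration is a handful of
#' closed-form model evaluations.
#'
#' @param curves numeric matrix, voxels x timepoints, relative enhancement
#'   (precontrast point 0 at t = 0).
#' @param times_min frame times in minutes.
#' @param aif a [population_aif()].
#' @param alpha enhancement gain linking concentration to relative signal
#'   enhancement.
#' @param lower,upper parameter bounds `c(ktrans, ve)`.
#' @param max_iter Gauss-Newton iteration cap per start.
#' @return data.frame with one row per voxel: `ktrans`, `ve`, `kep`,
#'   `rss`, `rmse`, `fit_ok`. Voxels whose curve is all-zero or contains
#'   non-finite values get `fit_ok = FALSE` and `NA` parameters.
#' @export
fit_tofts_map <- function(curves, times_min, aif = population_aif(),
                          alpha = 1,
                          lower = c(0, 0.01), upper = c(5, 1),
                          max_iter = 60L) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  n <- nrow(curves)
  stopifnot(ncol(curves) == length(times_min))
  bad <- !apply(is.finite(curves), 1, all) | apply(curves == 0, 1, all)
  bad[is.na(bad)] <- TRUE

  y <- curves
  y[bad, ] <- 0
  sse <- function(kt, ve) {
    m <- alpha * tofts_concentration_matrix(times_min, kt, ve, aif)
    rowSums((m - y)^2)
  }

  best_kt <- rep(NA_real_, n); best_ve <- rep(NA_real_, n)
  best_sse <- rep(Inf, n)
  starts <- expand.grid(kt = c(0.05, 0.6, 2.5), ve = c(0.1, 0.45, 0.9))

  for (s in seq_len(nrow(starts))) {
    kt <- rep(starts$kt[s], n); ve <- rep(starts$ve[s], n)
    f <- sse(kt, ve)
    lam <- rep(1e-3, n)
    for (it in seq_len(max_iter)) {
      hk <- pmax(kt, 0.05) * 1e-6
      hv <- pmax(ve, 0.05) * 1e-6
      m0 <- alpha * tofts_concentration_matrix(times_min, kt, ve, aif)
      r <- m0 - y
      ve2 <- ifelse(ve + hv > upper[2], ve - hv, ve + hv)
      j1 <- (alpha * tofts_concentration_matrix(times_min, kt + hk, ve, aif) - m0) / hk
      j2 <- (alpha * tofts_concentration_matrix(times_min, kt, ve2, aif) - m0) / (ve2 - ve)
      a11 <- rowSums(j1 * j1); a12 <- rowSums(j1 * j2); a22 <- rowSums(j2 * j2)
      g1 <- rowSums(j1 * r); g2 <- rowSums(j2 * r)
      d11 <- a11 * (1 + lam) + 1e-12; d22 <- a22 * (1 + lam) + 1e-12
      det <- d11 * d22 - a12 * a12
      det[abs(det) < 1e-300] <- 1e-300
      dk <- (-g1 * d22 + g2 * a12) / det
      dv <- (-g2 * d11 + g1 * a12) / det
      kt_new <- pmin(pmax(kt + dk, lower[1]), upper[1])
      ve_new <- pmin(pmax(ve + dv, lower[2] + 1e-9), upper[2])
      f_new <- sse(kt_new, ve_new)
      ok <- is.finite(f_new) & (f_new <= f)
      delta_rel <- numeric(n)
      delta_rel[ok] <- (f[ok] - f_new[ok]) / (f[ok] + 1e-30)
      kt[ok] <- kt_new[ok]; ve[ok] <- ve_new[ok]
      f[ok] <- f_new[ok]
      lam[ok] <- pmax(lam[ok] / 3, 1e-12)
      lam[!ok] <- pmin(lam[!ok] * 10, 1e12)
      if (it > 5 && all((ok & delta_rel < 1e-14) | lam >= 1e8)) break
    }
    take <- f < best_sse
    best_kt[take] <- kt[take]; best_ve[take] <- ve[take]
    best_sse[take] <- f[take]
  }

  fit_ok <- !bad & is.finite(best_sse)
  best_kt[!fit_ok] <- NA_real_; best_ve[!fit_ok] <- NA_real_
  best_sse[!fit_ok] <- NA_real_
  data.frame(
    ktrans = best_kt, ve = best_ve, kep = best_kt / best_ve,
    rss = best_sse,
    rmse = sqrt(best_sse / ncol(curves)),
    fit_ok = fit_ok)
}

#' Fit the Tofts model to a single enhancement curve
#'
#' Convenience scalar interface over [fit_tofts_map()].
#'
#' @inheritParams fit_tofts_map
#' @param curve relative-enhancement series (length = number of frames,
#'   precontrast at t = 0).
#' @return list with `ktrans`, `ve`, `kep`, `rmse`, `rss`, `fit_ok`.
#' @examples
#' p <- dce_protocol(); tm <- frame_times(p, "minutes")
#' y <- 8 * tofts_concentration(tm, 0.25, 0.35)
#' fit_tofts(y, tm, alpha = 8)$ktrans  # ~0.25
#' @export
fit_tofts <- function(curve, times_min, aif = population_aif(), alpha = 1,
                      lower = c(0, 0.01), upper = c(5, 1)) {
  res <- fit_tofts_map(matrix(curve, nrow = 1), times_min, aif, alpha,
                       lower, upper)
  as.list(res[1, ])
}

#' Initial area under the enhancement curve (iAUC)
#'
#' Trapezoidal area of the baseline-subtracted relative-enhancement curve
#' from contrast arrival (t = 0) over a fixed early window, with linear
#' interpolation at the window edge when it falls between frames. Computed
#' on the measured curve, not the fitted model.
#'
#' @param curve relative-enhancement values at `times_sec` (matrix voxels x
#'   timepoints, or a single vector).
#' @param times_sec frame times in seconds, starting at 0.
#' @param window integration window in seconds (default 90).
#' @return iAUC in relative-enhancement x seconds; vector with one value
#'   per voxel (scalar for a vector input).
#' @export
compute_iauc <- function(curve, times_sec, window = 90) {
  if (window <= 0) stop("window must be positive")
  if (window > max(times_sec)) stop("window exceeds the last frame time")
  w <- iauc_weights(times_sec, window)
  if (is.null(dim(curve))) sum(curve * w) else drop(curve %*% w)
}

# Trapezoid integration of the linear interpolant of (times, y - y[1]) over
# [0, window], expressed as a weight vector so matrices of curves integrate
# with one matrix product.
iauc_weights <- function(times_sec, window) {
  k <- length(times_sec)
  w <- numeric(k)
  for (i in seq_len(k - 1)) {
    t0 <- times_sec[i]; t1 <- times_sec[i + 1]
    if (t0 >= window) break
    if (t1 <= window) {          # full interval
      w[i] <- w[i] + (t1 - t0) / 2
      w[i + 1] <- w[i + 1] + (t1 - t0) / 2
    } else {                     # partial: interpolate at the window edge
      h <- window - t0
      th <- h / (t1 - t0)
      # area = h * (y0 + yW)/2 with yW = y0 + th*(y1 - y0)
      w[i] <- w[i] + h * (1 - th / 2)
      w[i + 1] <- w[i + 1] + h * th / 2
    }
  }
  # baseline subtraction folds into the first weight
  w[1] <- w[1] - sum(w)
  w
}
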