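#' Enhancement-curve typing rules
#'
#' Thresholds defining the 9 curve type combinations. Initial (wash-in,
#' P0 to P1) bands: slow 33-50%, medium >50-100%, fast >100%; voxels below
#' 33% are excluded from analysis. Delayed bands (P1 to P2, relative to
#' P1): persistent >+10%, plateau within +/-10% (inclusive), washout
#' <-10%. Boundary ties: wash-in exactly 0.50 is slow, exactly 1.00 is
#' medium; delayed exactly +/-10% is plateau.
#'
#' @param washin_threshold exclusion threshold (default 0.33, inclusive).
#' @param slow_upper,medium_upper upper bounds of the slow and medium bands
#'   (inclusive).
#' @param delayed_band plateau half-width on the delayed change (default
#'   0.10, inclusive).
#' @return list of thresholds, class `curve_type_rules`.
#' @export
curve_type_rules <- function(washin_threshold = 0.33, slow_upper = 0.50,
                             medium_upper = 1.00, delayed_band = 0.10) {
  stopifnot(washin_threshold < slow_upper, slow_upper < medium_upper,
            delayed_band > 0)
  structure(list(washin_threshold = washin_threshold,
                 slow_upper = slow_upper, medium_upper = medium_upper,
                 delayed_band = delayed_band),
            class = "curve_type_rules")
}

# Fixed cell ordering of the 9 curve types.
curve_type_levels <- function() {
  as.vector(outer(c("persistent", "plateau", "washout"),
                  c("slow", "medium", "fast"),
                  function(d, i) paste(i, d, sep = "_")))
}

#' Classify a voxel's enhancement curve
#'
#' Assigns the curve type from the three readout signal intensities:
#' precontrast P0, early P1 and delayed P2. Vectorized.
#'
#' @param si_pre,si_early,si_delayed signal intensities at P0, P1, P2;
#'   `si_pre` must be positive.
#' @param rules a [curve_type_rules()].
#' @return character vector: `"excluded"` (wash-in below threshold) or
#'   `"<initial>_<delayed>"` with initial in slow/medium/fast and delayed
#'   in persistent/plateau/washout.
#' @examples
#' classify_voxel_curve(100, 220, 200)  # "fast_plateau"
#' classify_voxel_curve(100, 140, 160)  # "slow_persistent"
#' @export
classify_voxel_curve <- function(si_pre, si_early, si_delayed,
                                 rules = curve_type_rules()) {
  if (any(!(si_pre > 0))) stop("invalid voxel: nonpositive precontrast signal")
  washin <- (si_early - si_pre) / si_pre
  delayed <- (si_delayed - si_early) / si_early
  initial <- ifelse(washin <= rules$slow_upper, "slow",
                    ifelse(washin <= rules$medium_upper, "medium", "fast"))
  late <- ifelse(delayed > rules$delayed_band, "persistent",
                 ifelse(delayed < -rules$delayed_band, "washout", "plateau"))
  out <- paste(initial, late, sep = "_")
  out[washin < rules$washin_threshold] <- "excluded"
  out
}

# SI matrix (voxels x timepoints) for a mask, plus the three readouts.
lesion_si_matrix <- function(series, mask, protocol = NULL) {
  x <- as_dce_array(series)
  if (is.null(protocol)) protocol <- attr(x, "protocol")
  nt <- dim(x)[4]
  nvox <- prod(dim(x)[1:3])
  lin <- mask$voxels[, 1] + (mask$voxels[, 2] - 1L) * mask$dim[1] +
    (mask$voxels[, 3] - 1L) * mask$dim[1] * mask$dim[2]
  si <- vapply(seq_len(nt), function(j) x[lin + (j - 1L) * nvox],
               numeric(length(lin)))
  if (is.null(dim(si))) si <- matrix(si, nrow = 1)
  list(si = si, protocol = protocol)
}

# Indices of the three readout columns within the SI matrix.
readout_cols <- function(protocol)
  c(pre = 1L, early = protocol$early_index + 1L,
    delayed = protocol$delayed_index + 1L)

#' Curve-type subvolume distribution
#'
#' Percentages of the lesion volume occupied by each of the 9 curve types,
#' over threshold-passing voxels, plus the 3 overall delayed-phase
#' percentages (washout / plateau / persistent, marginal over the initial
#' bands).
#'
#' @param series 4D signal array or [generate_lesion_volume()] result.
#' @param mask a `lesion_mask`.
#' @param protocol a [dce_protocol()]; inferred when possible.
#' @param rules a [curve_type_rules()].
#' @return list: `cells` (named 9-vector, percentages summing to 100),
#'   `overall` (named 3-vector: washout, plateau, persistent), `n_passing`,
#'   `n_excluded`.
#' @export
curve_type_distribution <- function(series, mask, protocol = NULL,
                                    rules = curve_type_rules()) {
  m <- lesion_si_matrix(series, mask, protocol)
  rc <- readout_cols(m$protocol)
  si <- m$si
  valid <- si[, rc["pre"]] > 0
  types <- rep("excluded", nrow(si))
  types[valid] <- classify_voxel_curve(si[valid, rc["pre"]],
                                       si[valid, rc["early"]],
                                       si[valid, rc["delayed"]], rules)
  passing <- types != "excluded"
  if (!any(passing)) stop("non-enhancing lesion: no voxel passes the wash-in threshold")
  lv <- curve_type_levels()
  counts <- table(factor(types[passing], levels = lv))
  cells <- 100 * as.numeric(counts) / sum(counts)
  names(cells) <- lv
  overall <- vapply(c("washout", "plateau", "persistent"),
                    function(d) sum(cells[grepl(paste0("_", d, "$"), lv)]),
                    numeric(1))
  list(cells = cells, overall = overall,
       n_passing = sum(passing), n_excluded = sum(!passing))
}

#' Lesion mean enhancement curve
#'
#' Arithmetic mean signal intensity per time point over threshold-passing
#' voxels (precontrast included).
#'
#' @inheritParams curve_type_distribution
#' @return numeric vector of length `n_timepoints`.
#' @export
mean_curve <- function(series, mask, protocol = NULL,
                       rules = curve_type_rules()) {
  m <- lesion_si_matrix(series, mask, protocol)
  rc <- readout_cols(m$protocol)
  si <- m$si
  washin <- (si[, rc["early"]] - si[, rc["pre"]]) / si[, rc["pre"]]
  passing <- si[, rc["pre"]] > 0 & washin >= rules$washin_threshold
  if (!any(passing)) stop("non-enhancing lesion: no voxel passes the wash-in threshold")
  colMeans(si[passing, , drop = FALSE])
}

#' Most-suspicious representative 3x3 voxel clusters
#'
#' Scans every in-plane (axial) 3x3 neighborhood fully contained in the
#' lesion mask and returns the mean curves of the neighborhoods maximizing
#' (a) wash-in (mean relative enhancement P0 to P1), (b) wash-out (mean
#' relative signal decrease P1 to P2) and (c) their unweighted sum. When
#' the mask admits no complete 3x3 neighborhood the single most extreme
#' voxel is used instead and `fallback` is set.
#'
#' @inheritParams curve_type_distribution
#' @return list with `max_washin` (8 absolute SIs), `max_washout` (7
#'   relative postcontrast values), `max_washin_washout` (7 relative
#'   values), the winning center voxels, and `fallback` flag.
#' @export
find_representative_clusters <- function(series, mask, protocol = NULL) {
  x <- as_dce_array(series)
  if (is.null(protocol)) protocol <- attr(x, "protocol")
  if (mask$n_voxels == 0) stop("empty mask")
  d <- mask$dim
  ma <- mask_array(mask)
  pre <- frame3d(x, 1L)
  early <- frame3d(x, protocol$early_index + 1L)
  delayed <- frame3d(x, protocol$delayed_index + 1L)
  washin <- (early - pre) / pmax(pre, 1e-9)
  washout <- (early - delayed) / pmax(early, 1e-9)
  dim(washin) <- d; dim(washout) <- d

  box3 <- function(m2) {   # 3x3 box sum, valid interior only
    n1 <- nrow(m2); n2 <- ncol(m2)
    out <- matrix(NA_real_, n1, n2)
    if (n1 < 3 || n2 < 3) return(out)
    s <- matrix(0, n1 - 2, n2 - 2)
    for (i in -1:1) for (j in -1:1)
      s <- s + m2[(2 + i):(n1 - 1 + i), (2 + j):(n2 - 1 + j)]
    out[2:(n1 - 1), 2:(n2 - 1)] <- s
    out
  }

  nb_wi <- array(NA_real_, d); nb_wo <- array(NA_real_, d)
  cnt <- array(0, d)
  slice2d <- function(a, z) matrix(a[, , z], d[1], d[2])
  for (z in seq_len(d[3])) {
    mz <- slice2d(ma, z) * 1
    cz <- box3(mz)
    nb_wi[, , z] <- box3(slice2d(washin, z) * mz) / 9
    nb_wo[, , z] <- box3(slice2d(washout, z) * mz) / 9
    cnt[, , z] <- ifelse(is.na(cz), 0, cz)
  }
  full <- cnt == 9
  fallback <- !any(full)

  curve_of <- function(vox_mat) {
    sub <- as_lesion_mask_at(vox_mat, d)
    si <- lesion_si_matrix(x, sub, protocol)$si
    colMeans(si)
  }
  pick <- function(score_nb, score_vox) {
    if (!fallback) {
      sc <- ifelse(full, score_nb, -Inf)
      c0 <- as.integer(arrayInd(which.max(sc), d))
      offs <- as.matrix(expand.grid(-1:1, -1:1))
      vox <- cbind(c0[1] + offs[, 1], c0[2] + offs[, 2], c0[3])
    } else {
      sv <- ifelse(ma, score_vox, -Inf)
      c0 <- as.integer(arrayInd(which.max(sv), d))
      vox <- matrix(c0, nrow = 1)
    }
    list(center = c0, curve = curve_of(vox))
  }

  wi <- pick(nb_wi, washin)
  wo <- pick(nb_wo, washout)
  wiwo <- pick(nb_wi + nb_wo, washin + washout)

  rel <- function(curve) (curve[-1] - curve[1]) / curve[1]
  list(max_washin = wi$curve,
       max_washout = rel(wo$curve),
       max_washin_washout = rel(wiwo$curve),
       centers = list(max_washin = wi$center, max_washout = wo$center,
                      max_washin_washout = wiwo$center),
       fallback = fallback)
}

as_lesion_mask_at <- function(vox_mat, d) {
  vox <- vox_mat
  colnames(vox) <- c("x", "y", "z")
  structure(list(voxels = vox, n_voxels = nrow(vox),
                 seed = as.integer(vox[1, ]), dim = d,
                 threshold = NA_real_, connectivity = NA_integer_),
            class = "lesion_mask")
}

#' Relative wash-out rates of the representative curves
#'
#' For each curve the rate is the relative SI at a reference postcontrast
#' time point minus the relative SI at the last time point
#' (`relSI_initial - relSI_delayed`); the first and second postcontrast
#' frames serve as reference points, giving two values per curve.
#'
#' @param curves named list of the four curves: `mean` and `max_washin` as
#'   absolute 8-point SI curves, `max_washout` and `max_washin_washout` as
#'   7-point relative curves.
#' @return named numeric vector of 8 rates (positive = net wash-out).
#' @examples
#' washout_rates(list(mean = c(100, 180, 190, rep(150, 5)),
#'                    max_washin = c(100, 200, 210, rep(160, 5)),
#'                    max_washout = c(0.8, 0.9, rep(0.5, 5)),
#'                    max_washin_washout = c(0.8, 0.9, rep(0.5, 5))))
#' @export
washout_rates <- function(curves) {
  stopifnot(all(c("mean", "max_washin", "max_washout",
                  "max_washin_washout") %in% names(curves)))
  to_rel <- function(x) if (length(x) == 8L) (x[-1] - x[1]) / x[1] else x
  out <- unlist(lapply(curves[c("mean", "max_washin", "max_washout",
                                "max_washin_washout")], function(cv) {
    r <- to_rel(cv)
    c(ref1 = r[1] - r[length(r)], ref2 = r[2] - r[length(r)])
  }))
  names(out) <- paste0("washrate_", names(out))
  out
}

#' Pharmacokinetic histogram features
#'
#' Voxelwise distribution summaries of iAUC, ktrans and ve over
#' successfully fitted voxels: percentiles 10-90 in steps of 10 plus the
#' quartiles P25/P75 (11 values per parameter, linear interpolation
#' between closest ranks) and the interquartile range per parameter.
#'
#' @param pk data.frame with columns `iauc`, `ktrans`, `ve`, `fit_ok`.
#' @return named numeric vector of 36 values (33 percentiles + 3 IQRs).
#' @export
pk_histogram_features <- function(pk) {
  ok <- pk$fit_ok
  if (!any(ok)) stop("no pharmacokinetic data: zero successfully fitted voxels")
  probs <- c(.10, .20, .25, .30, .40, .50, .60, .70, .75, .80, .90)
  pname <- paste0("p", round(100 * probs))
  out <- c()
  iqrs <- c()
  for (par in c("iauc", "ktrans", "ve")) {
    q <- stats::quantile(pk[[par]][ok], probs = probs, type = 7, names = FALSE)
    names(q) <- paste(par, pname, sep = "_")
    out <- c(out, q)
    iqr <- q[9] - q[3]
    names(iqr) <- paste0(par, "_iqr")
    iqrs <- c(iqrs, iqr)
  }
  c(out, iqrs)
}

#' Voxelwise pharmacokinetic maps for a lesion
#'
#' Fits the Tofts model to every mask voxel's relative-enhancement curve
#' and computes the iAUC on the measured curve.
#'
#' @inheritParams curve_type_distribution
#' @param aif a [population_aif()].
#' @param alpha enhancement gain of the signal model.
#' @param iauc_window iAUC window in seconds (default 90).
#' @return data.frame: voxel indices, `ktrans`, `ve`, `kep`, `iauc`,
#'   `rmse`, `fit_ok`.
#' @export
compute_pk_maps <- function(series, mask, protocol = NULL,
                            aif = population_aif(), alpha = 8,
                            iauc_window = 90) {
  m <- lesion_si_matrix(series, mask, protocol)
  si <- m$si
  pre <- si[, 1]
  rel <- (si - pre) / ifelse(pre > 0, pre, NA_real_)
  tmin <- frame_times(m$protocol, "minutes")
  fit <- fit_tofts_map(rel, tmin, aif, alpha)
  iauc <- compute_iauc(rel, frame_times(m$protocol, "seconds"), iauc_window)
  cbind(as.data.frame(mask$voxels), fit["ktrans"], fit["ve"], fit["kep"],
        iauc = iauc, rmse = fit$rmse, fit_ok = fit$fit_ok & is.finite(iauc))
}

#' Assemble the 86-parameter lesion feature vector
#'
#' Concatenates the seven feature groups in a fixed documented order:
#' mean curve SIs (8), max-wash-in cluster SIs (8), relative max-wash-out
#' curve (7), relative max-wash-in/wash-out curve (7), curve-type
#' subvolume percentages (9), pharmacokinetic percentiles (33), relative
#' wash-out rates (8), overall delayed-phase percentages (3) and
#' pharmacokinetic IQRs (3) - 86 parameters in total.
#'
#' @param mean_curve 8-point mean SI curve.
#' @param clusters result of [find_representative_clusters()].
#' @param distribution result of [curve_type_distribution()].
#' @param pk_features result of [pk_histogram_features()].
#' @param rates result of [washout_rates()].
#' @return named numeric vector of length 86.
#' @export
assemble_feature_vector <- function(mean_curve, clusters, distribution,
                                    pk_features, rates) {
  miss <- c(mean_curve = missing(mean_curve) || is.null(mean_curve),
            clusters = missing(clusters) || is.null(clusters),
            distribution = missing(distribution) || is.null(distribution),
            pk_features = missing(pk_features) || is.null(pk_features),
            rates = missing(rates) || is.null(rates))
  if (any(miss))
    stop("missing feature group(s): ", paste(names(miss)[miss], collapse = ", "))
  stopifnot(length(mean_curve) == 8L,
            length(clusters$max_washin) == 8L,
            length(clusters$max_washout) == 7L,
            length(clusters$max_washin_washout) == 7L,
            length(distribution$cells) == 9L,
            length(pk_features) == 36L,
            length(rates) == 8L,
            length(distribution$overall) == 3L)
  v <- c(
    stats::setNames(mean_curve, paste0("mean_si_t", 0:7)),
    stats::setNames(clusters$max_washin, paste0("maxwi_si_t", 0:7)),
    stats::setNames(clusters$max_washout, paste0("maxwo_rel_t", 1:7)),
    stats::setNames(clusters$max_washin_washout, paste0("maxwiwo_rel_t", 1:7)),
    stats::setNames(distribution$cells,
                    paste0("subvol_pct_", names(distribution$cells))),
    pk_features[1:33],
    rates,
    stats::setNames(distribution$overall,
                    paste0("overall_pct_", names(distribution$overall))),
    pk_features[34:36])
  stopifnot(length(v) == 86L)
  v
}

#' Extract the full feature vector of one lesion
#'
#' Runs curve typing, representative-cluster search, pharmacokinetic
#' mapping and assembly for a single segmented lesion.
#'
#' @inheritParams compute_pk_maps
#' @param rules a [curve_type_rules()].
#' @return list: `features` (length-86 named vector), `pk` (voxel table),
#'   `clusters`, `distribution`.
#' @export
extract_lesion_features <- function(series, mask, protocol = NULL,
                                    aif = population_aif(), alpha = 8,
                                    iauc_window = 90,
                                    rules = curve_type_rules()) {
  mc <- mean_curve(series, mask, protocol, rules)
  cl <- find_representative_clusters(series, mask, protocol)
  dist <- curve_type_distribution(series, mask, protocol, rules)
  pk <- compute_pk_maps(series, mask, protocol, aif, alpha, iauc_window)
  pkf <- pk_histogram_features(pk)
  rates <- washout_rates(list(mean = mc, max_washin = cl$max_washin,
                              max_washout = cl$max_washout,
                              max_washin_washout = cl$max_washin_washout))
  list(features = assemble_feature_vector(mc, cl, dist, pkf, rates),
       pk = pk, clusters = cl, distribution = dist)
}

#' Feature dictionary
#'
#' @return data.frame naming each of the 86 features, its group and unit.
#' @export
feature_dictionary <- function() {
  grp <- c(rep("mean curve", 8), rep("max wash-in cluster", 8),
           rep("max wash-out cluster", 7), rep("max wash-in/wash-out cluster", 7),
           rep("curve-type subvolume", 9), rep("pk percentiles", 33),
           rep("wash-out rates", 8), rep("overall delayed-phase", 3),
           rep("pk IQR", 3))
  unit <- c(rep("signal intensity", 16), rep("relative enhancement", 14),
            rep("percent", 9),
            rep(c("rel.enh.*s", "1/min", "fraction"), each = 11),
            rep("relative enhancement", 8), rep("percent", 3),
            c("rel.enh.*s", "1/min", "fraction"))
  nm <- names(example_feature_names())
  data.frame(feature = nm, group = grp, unit = unit)
}

# Canonical ordered names (via a tiny synthetic lesion kept in sync with
# assemble_feature_vector()).
example_feature_names <- function() {
  lv <- curve_type_levels()
  probs <- c(10, 20, 25, 30, 40, 50, 60, 70, 75, 80, 90)
  nm <- c(paste0("mean_si_t", 0:7), paste0("maxwi_si_t", 0:7),
          paste0("maxwo_rel_t", 1:7), paste0("maxwiwo_rel_t", 1:7),
          paste0("subvol_pct_", lv),
          unlist(lapply(c("iauc", "ktrans", "ve"),
                        function(p) paste0(p, "_p", probs))),
          paste0("washrate_", rep(c("mean", "max_washin", "max_washout",
                                    "max_washin_washout"), each = 2),
                 c(".ref1", ".ref2")),
          paste0("overall_pct_", c("washout", "plateau", "persistent")),
          paste0(c("iauc", "ktrans", "ve"), "_iqr"))
  stats::setNames(numeric(86), nm)
}
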