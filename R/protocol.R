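#' Dynamic acquisition protocol
#'
#' Describes the timing and geometry of a dynamic contrast-enhanced (DCE)
#' acquisition: one precontrast frame (P0) followed by equally spaced
#' postcontrast frames. The default mirrors a clinical breast protocol with
#' 8 dynamic T1-weighted measurements at 60 s temporal resolution, where the
#' early readout P1 is the 1-min frame and the delayed readout P2 the 7-min
#' frame.
#'
#' @param n_timepoints total number of dynamic frames (1 pre + rest post).
#' @param frame_interval seconds between consecutive frames.
#' @param early_index 0-based frame index of the early postcontrast readout
#'   P1 (default 1, i.e. t = 60 s).
#' @param delayed_index 0-based frame index of the delayed readout P2
#'   (default `n_timepoints - 1`, i.e. t = 420 s for 8 frames).
#' @param voxel_spacing voxel size in mm along (x, y, z).
#' @return an object of class `dce_protocol`.
#' @examples
#' p <- dce_protocol()
#' frame_times(p)  # 0, 60, ..., 420 seconds
#' @export
dce_protocol <- function(n_timepoints = 8L,
                         frame_interval = 60,
                         early_index = 1L,
                         delayed_index = n_timepoints - 1L,
                         voxel_spacing = c(1.1, 0.9, 3.0)) {
  n_timepoints <- as.integer(n_timepoints)
  early_index <- as.integer(early_index)
  delayed_index <- as.integer(delayed_index)
  if (n_timepoints < 3L)
    stop("protocol needs at least 3 frames (pre, early, delayed)")
  if (!(early_index > 0L && early_index < delayed_index &&
        delayed_index < n_timepoints))
    stop("frame indices must satisfy 0 < early < delayed < n_timepoints")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("voxel_spacing must be 3 positive values (mm)")
  structure(
    list(n_timepoints = n_timepoints,
         frame_interval = frame_interval,
         early_index = early_index,
         delayed_index = delayed_index,
         voxel_spacing = as.numeric(voxel_spacing)),
    class = "dce_protocol")
}

#' Frame acquisition times
#'
#' @param protocol a [dce_protocol()].
#' @param unit `"seconds"` or `"minutes"`.
#' @return numeric vector of length `n_timepoints`; the precontrast frame is
#'   at t = 0 (contrast arrival).
#' @export
frame_times <- function(protocol, unit = c("seconds", "minutes")) {
  unit <- match.arg(unit)
  t <- (seq_len(protocol$n_timepoints) - 1) * protocol$frame_interval
  if (unit == "minutes") t / 60 else t
}

#' @export
print.dce_protocol <- function(x, ...) {
  cat(sprintf(
    "DCE protocol: %d frames every %g s (P1 at %g s, P2 at %g s), voxels %s mm\n",
    x$n_timepoints, x$frame_interval,
    x$early_index * x$frame_interval, x$delayed_index * x$frame_interval,
    paste(signif(x$voxel_spacing, 3), collapse = " x ")))
  invisible(x)
}
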