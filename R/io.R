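#' Write a synthetic cohort to disk
#'
#' Volumes as 4D NIfTI-1 (time as the 4th dimension, voxel spacing in the
#' header), truth and seeds as a JSON sidecar, and a cohort manifest CSV
#' (lesion_id, label, seed voxel, file path). Voxel indices are written
#' 0-based, the convention of the NIfTI world; in-memory R structures are
#' 1-based.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- cohort$truth
  files <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    f <- file.path(dir, paste0(tr$lesion_id[i], ".nii.gz"))
    img <- RNifti::asNifti(cohort$lesions[[i]]$series,
                           pixdim = c(cohort$config$protocol$voxel_spacing,
                                      cohort$config$protocol$frame_interval))
    RNifti::writeNifti(img, f)
    files[i] <- f
  }
  manifest <- data.frame(lesion_id = tr$lesion_id, label = tr$label,
                         seed_x = tr$seed_x - 1L, seed_y = tr$seed_y - 1L,
                         seed_z = tr$seed_z - 1L, file = files,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed,
         truth = cohort$truth,
         config = list(n_lesions = cohort$config$n_lesions,
                       prevalence = cohort$config$prevalence,
                       alpha = cohort$config$alpha,
                       s0 = cohort$config$s0,
                       noise_sd = cohort$config$noise_sd)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
    pretty = TRUE)
  invisible(manifest)
}

#' Read a 4D DCE series from NIfTI
#'
#' @param path NIfTI file (3 spatial dimensions + time).
#' @param protocol a [dce_protocol()] describing the timing.
#' @return list with `series` (4D array) and `protocol`, as produced by
#'   the generator.
#' @export
read_dce_nifti <- function(path, protocol = dce_protocol()) {
  img <- RNifti::readNifti(path)
  x <- unclass(as.array(img))
  attributes(x) <- list(dim = dim(x))
  if (length(dim(x)) != 4L) stop("expected a 4D NIfTI volume")
  if (dim(x)[4] != protocol$n_timepoints)
    stop("time dimension does not match the protocol")
  list(series = x, protocol = protocol)
}

#' Write per-lesion pharmacokinetic maps as CSV
#'
#' Voxel indices are written 0-based.
#'
#' @param pk data.frame from [compute_pk_maps()].
#' @param path output CSV path.
#' @export
write_pk_csv <- function(pk, path) {
  out <- pk
  out$x <- out$x - 1L; out$y <- out$y - 1L; out$z <- out$z - 1L
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
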