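## File formats: NIfTI volumes with JSON sidecars, contour/segment/cohort
## CSV tables, JSON reports. Every writer has a reader that round-trips.

#' Write a multi-echo stack as NIfTI plus JSON sidecar
#'
#' The 4-D magnitude array (x, y, slice, echo) is written as NIfTI; echo
#' times (ms), RV-insertion angle (degrees) and the generation seed go to
#' a JSON sidecar next to it.
#'
#' @param stack 4-D array or `heart_phantom`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param echo_times,rv_insertion_angle,seed Sidecar fields (taken from
#'   the phantom when one is given).
#' @return `path`, invisibly.
#' @export
write_stack_nifti <- function(stack, path, echo_times = NULL,
                              rv_insertion_angle = NULL, seed = NULL) {
  if (inherits(stack, "heart_phantom")) {
    if (is.null(echo_times)) echo_times <- stack$echo_times
    if (is.null(rv_insertion_angle))
      rv_insertion_angle <- stack$rv_insertion_angle
    stack <- stack$stack
  }
  stopifnot(length(dim(stack)) == 4L, !is.null(echo_times))
  RNifti::writeNifti(stack, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(echo_times_ms = echo_times,
         rv_insertion_angle_deg = rv_insertion_angle, seed = seed),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-echo stack written by [write_stack_nifti()]
#'
#' @param path NIfTI path; the JSON sidecar must sit next to it.
#' @return List with `stack` (4-D array), `echo_times`,
#'   `rv_insertion_angle`, `seed`.
#' @export
read_stack_nifti <- function(path) {
  arr <- array(as.array(RNifti::readNifti(path)),
               dim = dim(RNifti::readNifti(path)))
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D stack in ", path)
  if (dim(arr)[4] != length(meta$echo_times_ms))
    stop("echo count mismatch between image and sidecar")
  list(stack = arr, echo_times = meta$echo_times_ms,
       rv_insertion_angle = meta$rv_insertion_angle_deg, seed = meta$seed)
}

#' Write / read a 3-D map (T2 map, mask, labels) as NIfTI
#'
#' @param map 3-D array (logical masks are stored as 0/1).
#' @param path Output NIfTI path.
#' @return `path` invisibly / the array.
#' @export
write_map_nifti <- function(map, path) {
  stopifnot(length(dim(map)) == 3L)
  RNifti::writeNifti(map * 1, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.array(v), dim = dim(v))
}

#' Write / read a segment table CSV
#'
#' Columns: segment_id, segment, level, mean_t2_ms, pixel_sd_ms,
#' n_pixels, flagged.
#'
#' @param table A `segment_table`.
#' @param path CSV path.
#' @return `path` invisibly / a `segment_table`.
#' @export
write_segments_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment_id", "level", "mean_t2_ms", "pixel_sd_ms", "n_pixels")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("segment CSV is missing column(s): ", paste(miss, collapse = ", "))
  class(x) <- c("segment_table", "data.frame")
  x
}

#' Write / read a cohort table CSV
#'
#' @param cohort A `cohort_table`.
#' @param path CSV path.
#' @return `path` invisibly / a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(x))
    stop("cohort CSV is missing the required 'group' column")
  bad <- setdiff(unique(x$group), c("control", "patient"))
  if (length(bad))
    stop("cohort CSV has invalid group label(s): ",
         paste(bad, collapse = ", "))
  x$group <- factor(x$group, levels = c("control", "patient"))
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Write a JSON report
#'
#' Scalars are written unboxed at full precision.
#'
#' @param x A list of report values.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
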