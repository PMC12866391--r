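#' Dynamic PET image container
#'
#' A `dynamic_image` bundles a 4D activity volume (x, y, z, frame) with its
#' grid geometry, frame schedule and dose/weight metadata.  Voxel indices
#' are 1-based; voxel centres sit at `(i - 0.5) * spacing` mm along each
#' axis so a grid of `n` voxels covers the physical extent
#' `[0, n * spacing]`.
#'
#' @param values 4D numeric array, dimensions x, y, z, frame.
#' @param spacing Voxel spacing in mm, length 3, positive.
#' @param schedule A [frame_schedule()]; its frame count must match the
#'   fourth array dimension.
#' @param injected_dose_MBq,body_weight_kg Dose and weight metadata used
#'   for SUV normalization; may be `NA` for images already in SUV.
#' @param units Either `"kBq/mL"` (activity concentration) or `"SUV"`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(values, spacing, schedule,
                          injected_dose_MBq = NA_real_,
                          body_weight_kg = NA_real_,
                          units = c("kBq/mL", "SUV")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 4) {
    abort("`values` must be a 4D array (x, y, z, frame).")
  }
  if (length(spacing) != 3 || any(spacing <= 0)) {
    abort("`spacing` must be three positive mm values.")
  }
  assert_frame_schedule(schedule)
  if (dim(values)[4] != nrow(schedule)) {
    abort(sprintf(
      "Image has %d frames but the schedule describes %d.",
      dim(values)[4], nrow(schedule)
    ))
  }
  structure(
    list(
      values = values, spacing = as.numeric(spacing), schedule = schedule,
      injected_dose_MBq = injected_dose_MBq,
      body_weight_kg = body_weight_kg, units = units
    ),
    class = "dynamic_image"
  )
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<dynamic_image> %d x %d x %d voxels, %d frames, %s\n",
    d[1], d[2], d[3], d[4], x$units
  ))
  cat(sprintf(
    "  spacing %g x %g x %g mm, %.0f s acquisition\n",
    x$spacing[1], x$spacing[2], x$spacing[3], sum(x$schedule$duration_s)
  ))
  if (!is.na(x$injected_dose_MBq)) {
    cat(sprintf(
      "  dose %.1f MBq, weight %.1f kg\n",
      x$injected_dose_MBq, x$body_weight_kg
    ))
  }
  invisible(x)
}

#' Write / read a dynamic image as NIfTI plus JSON sidecar
#'
#' The 4D volume is stored as NIfTI-1 (64-bit float, so round trips are
#' bit-exact) and the acquisition metadata (frame starts/durations in
#' seconds, injected dose, body weight, units) in a JSON sidecar next to
#' it.
#'
#' @param img A [dynamic_image()].
#' @param nifti_path Path of the `.nii`/`.nii.gz` file.
#' @param sidecar_path Path of the JSON sidecar; defaults to the NIfTI path
#'   with a `.json` extension.
#' @return `write_dynamic()` returns the paths invisibly; `read_dynamic()`
#'   returns a [dynamic_image()].
#' @export
write_dynamic <- function(img, nifti_path, sidecar_path = NULL) {
  stopifnot(inherits(img, "dynamic_image"))
  sidecar_path <- sidecar_path %||% sub("\\.nii(\\.gz)?$", ".json", nifti_path)
  nim <- RNifti::asNifti(img$values)
  RNifti::pixdim(nim) <- c(img$spacing, 1)
  RNifti::writeNifti(nim, nifti_path, datatype = "double")
  meta <- list(
    frame_starts_s = img$schedule$start_s,
    frame_durations_s = img$schedule$duration_s,
    injected_dose_MBq = img$injected_dose_MBq,
    body_weight_kg = img$body_weight_kg,
    units = img$units
  )
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(nifti = nifti_path, sidecar = sidecar_path))
}

#' @rdname write_dynamic
#' @export
read_dynamic <- function(nifti_path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||% sub("\\.nii(\\.gz)?$", ".json", nifti_path)
  if (!file.exists(nifti_path)) abort(sprintf("No such file: %s", nifti_path))
  if (!file.exists(sidecar_path)) abort(sprintf("No sidecar: %s", sidecar_path))
  nim <- RNifti::readNifti(nifti_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  values <- array(as.numeric(nim), dim = dim(nim))
  if (length(dim(values)) == 3) dim(values) <- c(dim(values), 1L)
  if (length(meta$frame_durations_s) != dim(values)[4]) {
    abort(sprintf(
      "Sidecar lists %d frame durations but the image has %d frames.",
      length(meta$frame_durations_s), dim(values)[4]
    ))
  }
  sched <- frame_schedule(meta$frame_durations_s)
  if (!isTRUE(all.equal(sched$start_s, meta$frame_starts_s))) {
    abort("Sidecar frame starts are inconsistent with the durations.")
  }
  dynamic_image(
    values,
    spacing = RNifti::pixdim(nim)[1:3],
    schedule = sched,
    injected_dose_MBq = meta$injected_dose_MBq %||% NA_real_,
    body_weight_kg = meta$body_weight_kg %||% NA_real_,
    units = meta$units %||% "kBq/mL"
  )
}

# linear interpolation of one axis onto a new cell-centred grid
.resample_axis <- function(arr, axis, new_spacing) {
  d <- dim(arr)
  old_n <- d[axis]
  extent <- attr(arr, "extent")[axis]
  old_sp <- extent / old_n
  new_n <- max(1L, as.integer(round(extent / new_spacing)))
  if (new_n == old_n && isTRUE(all.equal(old_sp, new_spacing))) return(arr)
  old_c <- (seq_len(old_n) - 0.5) * old_sp
  new_c <- (seq_len(new_n) - 0.5) * new_spacing
  # clamp to the edge voxels (constant extrapolation)
  pos <- findInterval(new_c, old_c, all.inside = TRUE)
  lo <- pmin(pos, old_n - 1L)
  hi <- lo + 1L
  w <- (old_c[hi] - new_c) / (old_c[hi] - old_c[lo])
  w <- pmin(pmax(w, 0), 1)
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(arr, perm), nrow = old_n)
  res <- m[lo, , drop = FALSE] * w + m[hi, , drop = FALSE] * (1 - w)
  out <- array(res, dim = c(new_n, d[-axis]))
  out <- aperm(out, order(perm))
  attr(out, "extent") <- attr(arr, "extent")
  out
}

#' Resample a dynamic image onto a target grid
#'
#' Each frame is interpolated trilinearly (separable per-axis linear
#' interpolation on cell-centred grids, edge values clamped) onto a grid
#' with the requested spacing covering the same physical extent.  The
#' default target, 1 x 1 x 4 mm, is the standard homogenization grid for
#' this workflow.  Images already on the target grid are returned
#' unchanged.
#'
#' @param img A [dynamic_image()].
#' @param target_spacing Target voxel spacing in mm, length 3.
#' @return A [dynamic_image()] on the target grid.
#' @export
resample_to_grid <- function(img, target_spacing = c(1, 1, 4)) {
  stopifnot(inherits(img, "dynamic_image"))
  if (length(target_spacing) != 3 || any(target_spacing <= 0)) {
    abort("`target_spacing` must be three positive mm values.")
  }
  if (isTRUE(all.equal(img$spacing, as.numeric(target_spacing)))) return(img)
  d <- dim(img$values)
  extent <- d[1:3] * img$spacing
  arr <- img$values
  attr(arr, "extent") <- c(extent, d[4])
  for (ax in 1:3) arr <- .resample_axis(arr, ax, target_spacing[ax])
  attr(arr, "extent") <- NULL
  dynamic_image(
    arr, spacing = target_spacing, schedule = img$schedule,
    injected_dose_MBq = img$injected_dose_MBq,
    body_weight_kg = img$body_weight_kg, units = img$units
  )
}

#' Convert an activity-concentration image to SUV
#'
#' The standardized uptake value divides the activity concentration by the
#' injected dose per body mass:
#' `SUV = conc [kBq/mL] / (dose [kBq] / weight [g])`, taking 1 g ~ 1 mL of
#' tissue.
#'
#' @param img A [dynamic_image()] in `kBq/mL` with dose and weight set.
#' @return A [dynamic_image()] in SUV.
#' @export
to_suv <- function(img) {
  stopifnot(inherits(img, "dynamic_image"))
  if (img$units == "SUV") abort("Image is already in SUV.")
  if (is.na(img$injected_dose_MBq) || is.na(img$body_weight_kg)) {
    abort("SUV conversion needs `injected_dose_MBq` and `body_weight_kg`.")
  }
  divisor <- (img$injected_dose_MBq * 1000) / (img$body_weight_kg * 1000)
  out <- img
  out$values <- img$values / divisor
  out$units <- "SUV"
  out
}
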