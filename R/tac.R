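#' Extract voxelwise time-activity curves
#'
#' Reads the raw (uninterpolated) SUV time course of every biopsy voxel,
#' producing a voxels-by-frames matrix in the biopsy's documented voxel
#' ordering (x fastest).
#'
#' @param img A [dynamic_image()] in SUV.
#' @param biopsy A [place_biopsy()] object, or a list of them (e.g. from
#'   [place_biopsies()]), in which case the matrices are stacked with
#'   [bind_tacs()].
#' @return A `tac_matrix`: list with `values` (voxels x frames matrix),
#'   `midpoints_min`, `voxels` (tibble `voi`, `voxel_id`, `x`, `y`, `z`)
#'   and `schedule`.
#' @export
extract_tacs <- function(img, biopsy) {
  stopifnot(inherits(img, "dynamic_image"))
  if (img$units != "SUV") abort("TAC extraction expects an image in SUV.")
  if (is.list(biopsy) && !inherits(biopsy, "digital_biopsy")) {
    return(bind_tacs(purrr::map(biopsy, function(b) extract_tacs(img, b))))
  }
  stopifnot(inherits(biopsy, "digital_biopsy"))
  d <- dim(img$values)
  v <- biopsy$voxels
  lin <- v$x + (v$y - 1L) * d[1] + (v$z - 1L) * d[1] * d[2]
  nvox_slice <- prod(d[1:3])
  values <- vapply(seq_len(d[4]), function(f) {
    img$values[lin + (f - 1L) * nvox_slice]
  }, numeric(nrow(v)))
  new_tac_matrix(
    values = matrix(values, nrow = nrow(v)),
    midpoints_min = img$schedule$midpoint_min,
    voxels = tibble(voi = biopsy$label, voxel_id = v$voxel_id,
                    x = v$x, y = v$y, z = v$z),
    schedule = img$schedule
  )
}

new_tac_matrix <- function(values, midpoints_min, voxels, schedule) {
  stopifnot(nrow(values) == nrow(voxels),
            ncol(values) == length(midpoints_min),
            !is.unsorted(midpoints_min, strictly = TRUE))
  structure(
    list(values = values, midpoints_min = midpoints_min,
         voxels = voxels, schedule = schedule),
    class = "tac_matrix"
  )
}

#' Stack TAC matrices from multiple VOIs or scans
#'
#' @param tac_list List of `tac_matrix` objects sharing a frame axis.
#' @param scan_ids Optional character vector; when given, each matrix's
#'   VOI labels are prefixed with its scan id so identically named VOIs
#'   from different scans stay distinct.
#' @return A `tac_matrix`.
#' @export
bind_tacs <- function(tac_list, scan_ids = NULL) {
  stopifnot(length(tac_list) >= 1)
  mids <- tac_list[[1]]$midpoints_min
  same <- vapply(tac_list, function(t) {
    length(t$midpoints_min) == length(mids) &&
      isTRUE(all.equal(t$midpoints_min, mids))
  }, logical(1))
  if (!all(same)) {
    abort("All TAC matrices must share the same frame schedule.")
  }
  if (!is.null(scan_ids)) {
    stopifnot(length(scan_ids) == length(tac_list))
    tac_list <- purrr::map2(tac_list, scan_ids, function(t, id) {
      t$voxels$voi <- paste(id, t$voxels$voi, sep = ":")
      t
    })
  }
  new_tac_matrix(
    values = do.call(rbind, purrr::map(tac_list, "values")),
    midpoints_min = mids,
    voxels = dplyr::bind_rows(purrr::map(tac_list, "voxels")),
    schedule = tac_list[[1]]$schedule
  )
}

#' @export
print.tac_matrix <- function(x, ...) {
  cat(sprintf(
    "<tac_matrix> %d voxels x %d frames, %d VOI(s)\n",
    nrow(x$values), ncol(x$values), dplyr::n_distinct(x$voxels$voi)
  ))
  invisible(x)
}

#' @export
as_tibble.tac_matrix <- function(x, ...) {
  wide <- as_tibble(x$values, .name_repair = function(nm) {
    sprintf("t%.3f", x$midpoints_min)
  })
  out <- dplyr::bind_cols(x$voxels, wide)
  tidyr::pivot_longer(out, dplyr::starts_with("t"),
                      names_to = "midpoint_min", values_to = "suv") |>
    mutate(midpoint_min = as.numeric(sub("^t", "", .data$midpoint_min)))
}

#' Static uptake parameters of a biopsy
#'
#' Summarises the late static window (40-60 min by default): every voxel
#' gets a duration-weighted mean SUV over the frames whose midpoints fall
#' inside the window (inclusive), then `suv_max` is the maximum and
#' `suv_mean` the mean over voxels.  The time to peak of the VOI-mean
#' curve is reported alongside.
#'
#' @param img A [dynamic_image()] in SUV.
#' @param biopsy A [place_biopsy()] object.
#' @param window Window in minutes post-injection; default `c(40, 60)`.
#' @return One-row tibble: `label`, `suv_max`, `suv_mean`, `ttp_min`,
#'   `window_lo`, `window_hi`.
#' @export
static_params <- function(img, biopsy, window = c(40, 60)) {
  tacs <- extract_tacs(img, biopsy)
  mids <- tacs$midpoints_min
  sel <- mids >= window[1] & mids <= window[2]
  if (!any(sel)) abort("No frame midpoint falls inside the static window.")
  w <- tacs$schedule$duration_s[sel]
  voxel_suv <- as.numeric(tacs$values[, sel, drop = FALSE] %*% w / sum(w))
  mean_curve <- colMeans(tacs$values)
  tibble(
    label = biopsy$label,
    suv_max = max(voxel_suv),
    suv_mean = mean(voxel_suv),
    ttp_min = time_to_peak(mean_curve, tacs$schedule),
    window_lo = window[1], window_hi = window[2]
  )
}

#' Time to peak of a time-activity curve
#'
#' Returns the midpoint time of the first frame attaining the curve
#' maximum (ties break to the earlier frame).
#'
#' @param tac Numeric vector, one value per frame.
#' @param schedule The matching [frame_schedule()].
#' @return Minutes post-injection.
#' @export
time_to_peak <- function(tac, schedule) {
  assert_frame_schedule(schedule)
  if (length(tac) != nrow(schedule)) {
    abort("`tac` length must equal the number of frames.")
  }
  schedule$midpoint_min[which.max(tac)]
}

#' VOI-mean time-activity curves
#'
#' @param tacs A `tac_matrix`.
#' @return Tibble `voi`, `midpoint_min`, `mean_suv`, `sd_suv` (population
#'   SD over voxels).
#' @export
voi_mean_tacs <- function(tacs) {
  as_tibble(tacs) |>
    group_by(.data$voi, .data$midpoint_min) |>
    summarise(
      mean_suv = mean(.data$suv),
      sd_suv = sd_pop(.data$suv),
      .groups = "drop"
    )
}

# population SD (divisor n); used for frame-wise TAC dispersion
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
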