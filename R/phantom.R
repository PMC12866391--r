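#' Specify a synthetic dynamic-PET phantom
#'
#' A phantom is a set of non-overlapping axis-aligned tissue blocks on a
#' regular grid, each block carrying one or more kinetic subpopulations
#' (see [lesion_subpopulations()]), plus a noise level and dose/weight
#' metadata.  Anatomical realism is deliberately out of scope: blocks are
#' placed so each can be sampled by one standardized digital biopsy.
#'
#' @param organs A tibble with one row per tissue block: columns `name`
#'   (unique VOI label), `x0`, `y0`, `z0` (1-based corner), `nx`, `ny`,
#'   `nz` (block extent in voxels) and `kinetics` (list column of
#'   `kinetic_params` tibbles with a `fraction` column summing to 1).
#' @param grid_dim Grid size in voxels, length 3.
#' @param spacing Voxel spacing in mm; default the 1 x 1 x 4 mm
#'   homogenization grid.
#' @param schedule A [frame_schedule()]; default the 28-frame clinical
#'   schedule.
#' @param noise_scale Unitless scale of the frame-duration-weighted
#'   Gaussian noise (see [add_noise()]); default 0.2.
#' @param injected_dose_MBq,body_weight_kg Dose and weight written into the
#'   image metadata; defaults 140 MBq / 70 kg (the 2 MBq/kg protocol).
#' @param seed Integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(organs, grid_dim = c(40, 40, 7),
                         spacing = c(1, 1, 4),
                         schedule = default_frame_schedule(),
                         noise_scale = 0.2,
                         injected_dose_MBq = 140, body_weight_kg = 70,
                         seed = 1L) {
  stopifnot(is.data.frame(organs))
  needed <- c("name", "x0", "y0", "z0", "nx", "ny", "nz", "kinetics")
  if (!all(needed %in% names(organs))) {
    abort(paste("`organs` needs columns:", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(organs$name)) abort("Organ names must be unique.")
  if (noise_scale < 0) abort("`noise_scale` must be non-negative.")
  assert_frame_schedule(schedule)
  # bounds and overlap checks
  occupied <- array(FALSE, dim = grid_dim)
  for (i in seq_len(nrow(organs))) {
    o <- organs[i, ]
    xs <- o$x0:(o$x0 + o$nx - 1)
    ys <- o$y0:(o$y0 + o$ny - 1)
    zs <- o$z0:(o$z0 + o$nz - 1)
    if (min(xs, ys, zs) < 1 || max(xs) > grid_dim[1] ||
        max(ys) > grid_dim[2] || max(zs) > grid_dim[3]) {
      abort(sprintf("Organ '%s' exceeds the grid.", o$name))
    }
    if (any(occupied[xs, ys, zs])) {
      abort(sprintf("Organ '%s' overlaps another organ.", o$name))
    }
    occupied[xs, ys, zs] <- TRUE
    k <- o$kinetics[[1]]
    fr <- k$fraction %||% rep(1 / nrow(k), nrow(k))
    if (abs(sum(fr) - 1) > 1e-8) {
      abort(sprintf("Subpopulation fractions of '%s' must sum to 1.", o$name))
    }
  }
  structure(
    list(
      organs = organs, grid_dim = as.integer(grid_dim),
      spacing = as.numeric(spacing), schedule = schedule,
      noise_scale = noise_scale, injected_dose_MBq = injected_dose_MBq,
      body_weight_kg = body_weight_kg, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

.organ_row <- function(name, class_name, slot_x, slot_y, kinetics = NULL) {
  k <- kinetics %||% dplyr::filter(tissue_kinetics(), .data$class_name == !!class_name)
  if (!"fraction" %in% names(k)) k$fraction <- rep(1 / nrow(k), nrow(k))
  tibble(
    name = name, x0 = slot_x, y0 = slot_y, z0 = 3L,
    nx = 10L, ny = 10L, nz = 3L, kinetics = list(k)
  )
}

#' Standard phantom layouts
#'
#' `default_phantom_spec()` builds the reference validation scan: one
#' slow-washout malignant lesion, one fast-washout inflammatory lesion and
#' the five control tissues (kidney, liver, blood, muscle, fat), each a
#' 10 x 10 x 3 voxel block on the 1 x 1 x 4 mm grid.
#' `two_kidney_phantom_spec()` replaces the lesions with left and right
#' kidney blocks sharing the same kinetic class, for coclustering studies.
#' `cohort_phantom_spec()` builds a lesion cohort on a larger grid:
#' `n_single` lesions with one kinetic subpopulation and `n_double` lesions
#' with two equally mixed subpopulations (the generator's default washout
#' contrast), plus the five controls.
#'
#' @param seed Integer seed.
#' @param noise_scale Noise level; default 0.2.
#' @param n_single,n_double Number of one- and two-subpopulation lesions.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 1L, noise_scale = 0.2) {
  slots <- expand.grid(x = c(3L, 17L, 31L), y = c(3L, 17L, 31L))
  organs <- dplyr::bind_rows(
    .organ_row("malignant", "malignant", slots$x[1], slots$y[1]),
    .organ_row("inflammatory", "inflammatory", slots$x[2], slots$y[2]),
    .organ_row("kidney", "kidney", slots$x[3], slots$y[3]),
    .organ_row("liver", "liver", slots$x[4], slots$y[4]),
    .organ_row("blood", "blood", slots$x[5], slots$y[5]),
    .organ_row("muscle", "muscle", slots$x[6], slots$y[6]),
    .organ_row("fat", "fat", slots$x[7], slots$y[7])
  )
  phantom_spec(organs, grid_dim = c(40L, 40L, 7L),
               noise_scale = noise_scale, seed = seed)
}

#' @rdname default_phantom_spec
#' @export
two_kidney_phantom_spec <- function(seed = 1L, noise_scale = 0.2) {
  slots <- expand.grid(x = c(3L, 17L, 31L), y = c(3L, 17L, 31L))
  kid <- dplyr::filter(tissue_kinetics(), .data$class_name == "kidney")
  organs <- dplyr::bind_rows(
    .organ_row("kidney_left", NULL, slots$x[1], slots$y[1], kid),
    .organ_row("kidney_right", NULL, slots$x[2], slots$y[2], kid),
    .organ_row("liver", "liver", slots$x[3], slots$y[3]),
    .organ_row("blood", "blood", slots$x[4], slots$y[4]),
    .organ_row("muscle", "muscle", slots$x[5], slots$y[5]),
    .organ_row("fat", "fat", slots$x[6], slots$y[6])
  )
  phantom_spec(organs, grid_dim = c(40L, 40L, 7L),
               noise_scale = noise_scale, seed = seed)
}

#' @rdname default_phantom_spec
#' @export
cohort_phantom_spec <- function(n_single = 4, n_double = 6,
                                seed = 1L, noise_scale = 0.2) {
  n_lesions <- n_single + n_double
  controls <- c("kidney", "liver", "blood", "muscle", "fat")
  n_blocks <- n_lesions + length(controls)
  per_side <- ceiling(sqrt(n_blocks))
  corners <- 3L + 14L * (seq_len(per_side) - 1L)
  slots <- expand.grid(x = corners, y = corners)
  gd <- c(max(corners) + 11L, max(corners) + 11L, 7L)
  lesions <- purrr::map(seq_len(n_lesions), function(i) {
    n_sub <- if (i <= n_single) 1L else 2L
    .organ_row(sprintf("lesion_%02d", i), NULL, slots$x[i], slots$y[i],
               lesion_subpopulations("malignant", n_sub))
  })
  ctrl <- purrr::map(seq_along(controls), function(j) {
    i <- n_lesions + j
    .organ_row(controls[j], controls[j], slots$x[i], slots$y[i])
  })
  phantom_spec(dplyr::bind_rows(c(lesions, ctrl)), grid_dim = gd,
               noise_scale = noise_scale, seed = seed)
}

#' Generate a synthetic dynamic PET scan
#'
#' Renders a [phantom_spec()] into a [dynamic_image()] plus voxelwise
#' ground truth.  The noise-free value of a voxel in frame f is the exact
#' duration-weighted mean of its subpopulation's kinetic model over the
#' frame interval; voxels outside any organ are zero.  Subpopulation
#' membership within a lesion is assigned voxelwise at the given mixing
#' fractions, and zero-mean Gaussian noise is added via [add_noise()].
#' All randomness is governed by `spec$seed`, so equal specs yield
#' identical scans.  The image is produced in activity-concentration units
#' (kBq/mL) consistent with the dose/weight metadata, so that [to_suv()]
#' recovers the model SUV scale.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (a [dynamic_image()]), `labels`
#'   (3D integer array of organ ids, 0 = background), `subpops` (3D
#'   integer array of subpopulation ids within each organ), `legend`
#'   (tibble mapping organ id/name/subpopulation to kinetic parameters)
#'   and `centers` (tibble of organ block centres usable as biopsy seeds).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gd <- spec$grid_dim
  n_frames <- nrow(spec$schedule)
  t0 <- spec$schedule$start_s / 60
  t1 <- (spec$schedule$start_s + spec$schedule$duration_s) / 60
  suv <- array(0, dim = c(gd, n_frames))
  labels <- array(0L, dim = gd)
  subpops <- array(0L, dim = gd)
  legend <- list()
  centers <- list()
  nvox_slice <- prod(gd)
  withr::with_seed(spec$seed, {
    for (i in seq_len(nrow(spec$organs))) {
      o <- spec$organs[i, ]
      xs <- o$x0:(o$x0 + o$nx - 1)
      ys <- o$y0:(o$y0 + o$ny - 1)
      zs <- o$z0:(o$z0 + o$nz - 1)
      vox <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
      lin <- vox[, 1] + (vox[, 2] - 1L) * gd[1] + (vox[, 3] - 1L) * gd[1] * gd[2]
      labels[lin] <- i
      k <- o$kinetics[[1]]
      fr <- k$fraction %||% rep(1 / nrow(k), nrow(k))
      sp <- if (nrow(k) == 1) rep(1L, nrow(vox)) else
        sample(seq_len(nrow(k)), nrow(vox), replace = TRUE, prob = fr)
      subpops[lin] <- sp
      for (s in seq_len(nrow(k))) {
        curve <- tac_frame_mean(k[s, ], t0, t1)
        sel <- lin[sp == s]
        for (f in seq_len(n_frames)) {
          suv[sel + (f - 1L) * nvox_slice] <- curve[f]
        }
      }
      legend[[i]] <- mutate(k, organ_id = i, organ = o$name,
                            subpop = dplyr::row_number())
      centers[[i]] <- tibble(
        label = o$name,
        cx = o$x0 + o$nx %/% 2L, cy = o$y0 + o$ny %/% 2L,
        cz = o$z0 + o$nz %/% 2L
      )
    }
    divisor <- (spec$injected_dose_MBq * 1000) / (spec$body_weight_kg * 1000)
    img <- dynamic_image(
      suv * divisor, spacing = spec$spacing, schedule = spec$schedule,
      injected_dose_MBq = spec$injected_dose_MBq,
      body_weight_kg = spec$body_weight_kg, units = "kBq/mL"
    )
    if (spec$noise_scale > 0) {
      img <- add_noise(img, spec$noise_scale,
                       seed = sample.int(.Machine$integer.max, 1))
    }
  })
  list(
    image = img, labels = labels, subpops = subpops,
    legend = dplyr::bind_rows(legend), centers = dplyr::bind_rows(centers)
  )
}

#' Add frame-duration-scaled Gaussian noise
#'
#' Emulates the count-statistics structure of reconstructed dynamic PET:
#' each voxel-frame value receives independent zero-mean Gaussian noise
#' with standard deviation
#' `noise_scale * sqrt(max(value, eps) / duration_min)`, so noise grows
#' with signal and shrinks with frame duration.  For images in kBq/mL the
#' value entering the formula is the SUV-scale value (concentration
#' normalized by dose per weight), keeping `noise_scale` comparable across
#' units.  Values are not clipped, so noisy values can be negative, as in
#' real reconstructions.
#'
#' @param img A [dynamic_image()].
#' @param noise_scale Non-negative noise scale; 0 returns the input
#'   unchanged.
#' @param seed Integer seed.
#' @param eps Variance floor on the value, in SUV; default 0.01.
#' @return A [dynamic_image()] with noise added.
#' @export
add_noise <- function(img, noise_scale, seed = 1L, eps = 0.01) {
  stopifnot(inherits(img, "dynamic_image"))
  if (noise_scale < 0) abort("`noise_scale` must be non-negative.")
  if (noise_scale == 0) return(img)
  d <- dim(img$values)
  dur_min <- img$schedule$duration_s / 60
  scale_to_suv <- if (img$units == "SUV" || is.na(img$injected_dose_MBq)) 1 else
    (img$injected_dose_MBq * 1000) / (img$body_weight_kg * 1000)
  out <- img
  withr::with_seed(seed, {
    for (f in seq_len(d[4])) {
      v_suv <- img$values[, , , f] / scale_to_suv
      sdv <- noise_scale * sqrt(pmax(v_suv, eps) / dur_min[f])
      out$values[, , , f] <- img$values[, , , f] +
        rnorm(length(v_suv), sd = sdv) * scale_to_suv
    }
  })
  out
}
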