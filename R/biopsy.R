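#' Place a standardized digital biopsy
#'
#' A digital biopsy is a fixed-size axis-aligned block of exactly 300
#' voxels sampled from the image as a surrogate tissue sample.  On the
#' 1 x 1 x 4 mm homogenization grid the default block is 10 x 10 x 3
#' voxels (10 x 10 x 12 mm), the only near-cubic integer block of 300
#' voxels at that anisotropy.  The block spans `(cx-5):(cx+4)` and
#' `(cy-5):(cy+4)` in-plane and `(cz-1):(cz+1)` axially (1-based); a block
#' that would exceed the image bounds is an error, never silently clipped.
#'
#' @param img A [dynamic_image()].
#' @param center Voxel index triple (x, y, z), 1-based.
#' @param label VOI label (tissue name) carried by the biopsy.
#' @param shape Block extent in voxels; must multiply to the biopsy size.
#' @return An object of class `digital_biopsy` with the label, center and
#'   a `voxels` tibble (`voxel_id`, `x`, `y`, `z`) in x-fastest order.
#' @examples
#' ph <- generate_phantom(default_phantom_spec(seed = 1, noise_scale = 0))
#' b <- place_biopsy(ph$image, center = c(8, 8, 4), label = "malignant")
#' nrow(b$voxels)  # 300
#' @export
place_biopsy <- function(img, center, label, shape = c(10, 10, 3)) {
  stopifnot(inherits(img, "dynamic_image"))
  if (length(center) != 3) abort("`center` must be a voxel index triple.")
  center <- as.integer(center)
  shape <- as.integer(shape)
  d <- dim(img$values)[1:3]
  rng <- lapply(1:3, function(a) {
    e <- shape[a]
    if (e %% 2L == 0L) (center[a] - e %/% 2L):(center[a] + e %/% 2L - 1L)
    else (center[a] - (e - 1L) %/% 2L):(center[a] + (e - 1L) %/% 2L)
  })
  for (a in 1:3) {
    if (min(rng[[a]]) < 1L || max(rng[[a]]) > d[a]) {
      abort(sprintf(
        "Biopsy '%s' at (%d, %d, %d) exceeds the image along axis %d.",
        label, center[1], center[2], center[3], a
      ))
    }
  }
  vox <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  structure(
    list(
      label = label, alias = NULL, center = center, shape = shape,
      voxels = tibble(voxel_id = seq_len(nrow(vox)),
                      x = vox$x, y = vox$y, z = vox$z)
    ),
    class = "digital_biopsy"
  )
}

#' @export
print.digital_biopsy <- function(x, ...) {
  cat(sprintf(
    "<digital_biopsy> '%s'%s: %d voxels (%dx%dx%d) centred at (%d, %d, %d)\n",
    x$label, if (!is.null(x$alias)) sprintf(" [alias %s]", x$alias) else "",
    nrow(x$voxels), x$shape[1], x$shape[2], x$shape[3],
    x$center[1], x$center[2], x$center[3]
  ))
  invisible(x)
}

#' Place biopsies from a manifest
#'
#' @param img A [dynamic_image()].
#' @param manifest Tibble with columns `label`, `cx`, `cy`, `cz` (such as
#'   the `centers` element returned by [generate_phantom()]).
#' @param shape Passed to [place_biopsy()].
#' @return A named list of [place_biopsy()] results.
#' @export
place_biopsies <- function(img, manifest, shape = c(10, 10, 3)) {
  stopifnot(all(c("label", "cx", "cy", "cz") %in% names(manifest)))
  if (anyDuplicated(manifest$label)) abort("Biopsy labels must be unique.")
  out <- purrr::pmap(manifest, function(label, cx, cy, cz, ...) {
    place_biopsy(img, c(cx, cy, cz), label, shape = shape)
  })
  setNames(out, manifest$label)
}

#' Tumor-to-background positivity gate
#'
#' Computes the tumor-to-background ratio of a lesion biopsy against the
#' aortic blood pool in the final dynamic frame, TBR = mean lesion SUV /
#' mean blood-pool SUV, and flags the lesion FAPI-positive when TBR is at
#' least the threshold (1.5 by default; the boundary is inclusive).
#'
#' @param lesion,blood_pool [place_biopsy()] objects.
#' @param img A [dynamic_image()] in SUV.
#' @param threshold Positivity threshold; default 1.5.
#' @param statistic `"mean"` (conventional) or `"max"` for the lesion
#'   summary; the blood pool always uses the mean.
#' @return A one-row tibble: `label`, `tbr`, `positive`.
#' @export
tbr_positive <- function(lesion, blood_pool, img, threshold = 1.5,
                         statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(img, "dynamic_image"))
  if (img$units != "SUV") abort("TBR needs an image in SUV; run to_suv() first.")
  last_f <- nrow(img$schedule)
  vals <- function(b) {
    v <- b$voxels
    img$values[cbind(v$x, v$y, v$z, last_f)]
  }
  lesion_stat <- if (statistic == "mean") mean(vals(lesion)) else max(vals(lesion))
  blood_mean <- mean(vals(blood_pool))
  if (blood_mean <= 0) {
    abort("Blood-pool mean SUV is not positive; TBR is undefined.")
  }
  tbr <- lesion_stat / blood_mean
  tibble(label = lesion$label, tbr = tbr, positive = tbr >= threshold)
}

#' Mask and unmask VOI labels
#'
#' Before network analysis, biopsy labels can be replaced by opaque
#' aliases so that clustering is blind to tissue identity; the masking
#' table is kept aside and used to restore the true labels on any
#' downstream table once interpretation starts.  Aliases are random
#' `#`-prefixed digit tokens that share no substring with any label.
#'
#' @param biopsies A list of [place_biopsy()] objects with unique labels.
#' @param seed Integer seed for alias assignment.
#' @return `mask_labels()`: a list with `biopsies` (aliases set, labels
#'   blanked) and `table` (a `masking_table` tibble `label` / `alias`).
#' @export
mask_labels <- function(biopsies, seed = 1L) {
  labels <- vapply(biopsies, function(b) b$label, character(1))
  if (anyDuplicated(labels)) abort("Biopsy labels must be unique to mask.")
  aliases <- withr::with_seed(seed, {
    sprintf("#%06d", sample.int(999999L, length(labels)))
  })
  table <- tibble(label = labels, alias = aliases)
  class(table) <- c("masking_table", class(table))
  attr(table, "seed") <- seed
  masked <- purrr::map2(biopsies, aliases, function(b, a) {
    b$alias <- a
    b$label <- a   # downstream modules only ever see the alias
    b
  })
  list(biopsies = setNames(masked, aliases), table = table)
}

#' @rdname mask_labels
#' @param x A tibble with a `voi` column, an `mcl_clustering`, or a
#'   `cluster_report` whose aliases should be replaced by true labels.
#' @param table The `masking_table` returned by [mask_labels()].
#' @return `unmask()`: `x` with aliases replaced by true labels; numbers
#'   are untouched.
#' @export
unmask <- function(x, table) {
  stopifnot(inherits(table, "masking_table"))
  swap <- function(v) {
    if (is.null(v) || !is.character(v)) return(v)
    hit <- v %in% table$alias
    unknown <- setdiff(v[grepl("^#", v)], table$alias)
    if (length(unknown) > 0) {
      abort(sprintf("Alias %s not present in the masking table.", unknown[1]))
    }
    v[hit] <- table$label[match(v[hit], table$alias)]
    v
  }
  recurse <- function(obj) {
    if (is.data.frame(obj)) {
      for (col in intersect(c("voi", "voi_a", "voi_b", "majority_voi", "label"),
                            names(obj))) {
        obj[[col]] <- swap(obj[[col]])
      }
      obj
    } else if (is.list(obj)) {
      cls <- class(obj)
      obj <- lapply(obj, recurse)
      class(obj) <- cls
      obj
    } else {
      obj
    }
  }
  recurse(x)
}
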