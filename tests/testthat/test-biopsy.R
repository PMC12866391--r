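test_that("a standardized biopsy is a 300-voxel near-cubic block", {
  img <- make_test_image(c(1, 2))
  b <- place_biopsy(img, c(6, 6, 3), "lesion")
  expect_equal(nrow(b$voxels), 300)
  expect_equal(range(b$voxels$x), c(1, 10))
  expect_equal(range(b$voxels$y), c(1, 10))
  expect_equal(range(b$voxels$z), c(2, 4))
  expect_equal(nrow(dplyr::distinct(b$voxels[, c("x", "y", "z")])), 300)
})

test_that("out-of-bounds biopsies error rather than clip", {
  img <- make_test_image(c(1, 2))
  expect_error(place_biopsy(img, c(1, 1, 1), "corner"), "exceeds")
  expect_error(place_biopsy(img, c(6, 6, 1), "edge-z"), "axis 3")
  expect_error(place_biopsy(img, c(12, 6, 3), "edge-x"), "exceeds")
})

test_that("biopsies offset by a block width are disjoint", {
  ph <- generate_phantom(default_phantom_spec(seed = 1))
  img <- to_suv(ph$image)
  a <- place_biopsy(img, c(10, 10, 4), "a")
  b <- place_biopsy(img, c(20, 10, 4), "b")
  key <- function(x) paste(x$voxels$x, x$voxels$y, x$voxels$z)
  expect_length(intersect(key(a), key(b)), 0)
})

test_that("TBR gating compares lesion to blood pool in the last frame", {
  mk <- function(lesion_val, blood_val) {
    im <- make_test_image(c(1, 1), dim3 = c(24, 12, 5))
    im$values[1:10, , , 2] <- lesion_val
    im$values[13:22, , , 2] <- blood_val
    list(im = im,
         lesion = place_biopsy(im, c(6, 6, 3), "lesion"),
         blood = place_biopsy(im, c(18, 6, 3), "blood"))
  }
  x <- mk(3.0, 2.0)
  res <- tbr_positive(x$lesion, x$blood, x$im)
  expect_equal(res$tbr, 1.5)
  expect_true(res$positive)
  x <- mk(2.9, 2.0)
  res <- tbr_positive(x$lesion, x$blood, x$im)
  expect_equal(res$tbr, 1.45)
  expect_false(res$positive)
  # a region against itself is trivially TBR 1 and negative
  res <- tbr_positive(x$blood, x$blood, x$im)
  expect_equal(res$tbr, 1)
  expect_false(res$positive)
  x <- mk(1.0, 0)
  expect_error(tbr_positive(x$lesion, x$blood, x$im), "not positive")
  raw <- make_test_image(c(1, 2), units = "kBq/mL")
  expect_error(
    tbr_positive(place_biopsy(raw, c(6, 6, 3), "a"),
                 place_biopsy(raw, c(6, 6, 3), "b"), raw),
    "SUV"
  )
})

test_that("masking is a bijective round trip with opaque aliases", {
  img <- make_test_image(c(1, 2))
  biopsies <- list(
    place_biopsy(img, c(6, 6, 3), "malignant_head"),
    place_biopsy(img, c(7, 6, 3), "blood_pool")
  )
  m <- mask_labels(biopsies, seed = 42)
  expect_setequal(m$table$label, c("malignant_head", "blood_pool"))
  expect_false(any(m$table$label %in% m$table$alias))
  tab <- tibble::tibble(voi = m$table$alias, value = c(1, 2))
  restored <- unmask(tab, m$table)
  expect_setequal(restored$voi, m$table$label)
  expect_identical(restored$value, tab$value)
  # unknown aliases are a table error
  expect_error(unmask(tibble::tibble(voi = "#000000"), m$table),
               "not present")
  # different seeds give different aliases
  m2 <- mask_labels(biopsies, seed = 43)
  expect_false(identical(m$table$alias, m2$table$alias))
})

test_that("aliases share no substring with any true label", {
  img <- make_test_image(c(1, 2), dim3 = c(24, 12, 5))
  labels <- c("malignant", "inflammatory", "kidney_left", "blood")
  biopsies <- lapply(seq_along(labels), function(i) {
    place_biopsy(img, c(5 + i, 6, 3), labels[i])
  })
  for (seed in 1:10) {
    m <- mask_labels(biopsies, seed = seed)
    for (al in m$table$alias) {
      for (lb in m$table$label) {
        expect_false(grepl(lb, al, fixed = TRUE))
        expect_false(grepl(al, lb, fixed = TRUE))
      }
    }
  }
})

test_that("the clustering pipeline is invariant under masking", {
  ph <- generate_phantom(default_phantom_spec(seed = 9))
  img <- to_suv(ph$image)
  biopsies <- place_biopsies(img, ph$centers[1:3, ])  # lesions + kidney
  plain <- extract_tacs(img, biopsies)
  cl_plain <- quiet(cluster_voxels(plain))
  m <- mask_labels(biopsies, seed = 7)
  masked <- extract_tacs(img, m$biopsies)
  cl_masked <- quiet(cluster_voxels(masked))
  restored <- unmask(cl_masked, m$table)
  # identical partitions up to alias renaming
  expect_identical(
    partition_sets(seq_len(nrow(cl_plain$assignment)),
                   cl_plain$assignment$cluster),
    partition_sets(seq_len(nrow(restored$assignment)),
                   restored$assignment$cluster)
  )
  expect_setequal(unique(restored$assignment$voi),
                  unique(cl_plain$assignment$voi))
})
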