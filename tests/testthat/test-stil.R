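test_that("sTIL follows the definitional ratio on constructed maps", {
  # tumor region with 100 original stroma px; one 25 px lymphocyte on it
  m <- blank_map(40, 40, "other")
  m$labels[11:20, 11:20] <- 3L                 # 100 stroma px
  tumor <- matrix(FALSE, 40, 40); tumor[11:20, 11:20] <- TRUE
  lymph_px <- as.vector(outer((13:17), (13:17 - 1) * 40, "+"))
  m$labels[lymph_px] <- 1L                     # lymphocyte displaces stroma
  ly <- fake_lymphocyte(lymph_px, centroid = c(14, 14))
  res <- compute_stil(list(ly), m, tumor)
  expect_equal(res$stil_percent, 25)
  expect_equal(res$stroma_area, 100)

  # no lymphocytes: zero percent
  expect_equal(compute_stil(list(), m, tumor)$stil_percent, 0)

  # no stroma inside the region: flagged like a low-quality slide
  bare <- blank_map(40, 40, "other")
  expect_error(compute_stil(list(), bare, tumor), "stroma")
  expect_error(compute_stil(list(), m, matrix(FALSE, 40, 40)), "tumor")
})

test_that("adding an in-mask stromal lymphocyte never decreases the
           percentage", {
  m <- blank_map(40, 40, "stroma")
  tumor <- matrix(TRUE, 40, 40)
  px1 <- as.vector(outer(5:8, (5:8 - 1) * 40, "+"))
  m1 <- m; m1$labels[px1] <- 1L
  one <- compute_stil(list(fake_lymphocyte(px1, c(5, 5))), m1, tumor)
  px2 <- as.vector(outer(25:28, (25:28 - 1) * 40, "+"))
  m2 <- m1; m2$labels[px2] <- 1L
  two <- compute_stil(list(fake_lymphocyte(px1, c(5, 5)),
                           fake_lymphocyte(px2, c(25, 25))), m2, tumor)
  expect_gte(two$stil_percent, one$stil_percent)
})

test_that("patient aggregation pools by area and stays within tile
           range", {
  r1 <- structure(list(stromal_til_area = 25, stroma_area = 100,
                       stil_percent = 25), class = "stil_result")
  r2 <- structure(list(stromal_til_area = 75, stroma_area = 100,
                       stil_percent = 75), class = "stil_result")
  expect_equal(aggregate_patient_stil(list(r1)), 25)
  expect_equal(aggregate_patient_stil(list(r1, r2)), 50)
  set.seed(8)
  rs <- lapply(1:5, function(i) {
    n <- sample(50:400, 1)
    structure(list(stromal_til_area = sample(0:n, 1), stroma_area = n,
                   stil_percent = NA), class = "stil_result")
  })
  pooled <- aggregate_patient_stil(rs)
  pcts <- vapply(rs, function(r) 100 * r$stromal_til_area / r$stroma_area,
                 numeric(1))
  expect_gte(pooled, min(pcts)); expect_lte(pooled, max(pcts))
  expect_error(aggregate_patient_stil(list()), "valid tiles")
})

test_that("tumor-region identification respects provenance and the
           density heuristic covers nucleus clusters", {
  ext <- matrix(c(TRUE, FALSE), 32, 32)
  got <- identify_tumor_regions(NULL, provided_mask = ext)
  expect_identical(unname(got == TRUE), unname(ext))
  expect_identical(attr(got, "source"), "provided")

  # a single dense cluster of non-lymphocyte nuclei -> one connected
  # region containing the cluster
  m <- blank_map(96, 96, "stroma")
  centers <- list(c(40, 40), c(40, 55), c(55, 40), c(55, 55), c(47, 47))
  for (ct in centers) m <- paint_disc(m, ct[1], ct[2], 4, "nucleus")
  nuc <- classify_lymphocytes(
    attribute_cell(extract_nuclei(m, min_area = 10L), m),
    lymphocyte_thresholds(relative_size_max = 0))   # force all "other"
  mask <- identify_tumor_regions(nuc, r_density = 15, r_close = 8)
  expect_identical(attr(mask, "source"), "derived")
  for (ct in centers) expect_true(mask[ct[1], ct[2]])
  comp <- stilquant:::label_components(unclass(mask), 8L)
  expect_identical(max(comp), 1L)

  # zero non-lymphocyte nuclei -> empty mask with a warning
  empty_set <- classify_lymphocytes(
    attribute_cell(extract_nuclei(m, min_area = 10L), m),
    lymphocyte_thresholds(relative_size_max = Inf, roundness_min = 0,
                          eccentricity_max = 1, ncr_min = 0,
                          staining_sd_max = Inf))
  expect_warning(em <- identify_tumor_regions(empty_set), "empty")
  expect_false(any(em))
})

test_that("the sTIL estimate is invariant under rotation and
           mirroring", {
  r <- small_sim(seed = 71, target = 30)
  run <- function(px_arr, tmask) {
    tile <- rgb_tile(px_arr)
    quantify_tile(tile, seed = 73, K_range = 2:5,
                  tumor_mask = tmask)$result$stil_percent
  }
  base <- run(r$tile$pixels, r$truth$tumor_mask)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  px90 <- array(0L, c(256, 256, 3))
  for (ch in 1:3) px90[, , ch] <- rot90(r$tile$pixels[, , ch])
  expect_lt(abs(run(px90, rot90(r$truth$tumor_mask)) - base), 1)
  pxm <- r$tile$pixels[, 256:1, , drop = FALSE]
  expect_lt(abs(run(pxm, r$truth$tumor_mask[, 256:1]) - base), 1)
})
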