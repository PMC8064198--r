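square_map <- function(h, w, squares, class_name = "nucleus") {
  m <- blank_map(h, w, "stroma")
  code <- as.integer(names(semantic_legend)[semantic_legend == class_name])
  for (s in squares) m$labels[s$rows, s$cols] <- code
  m
}

test_that("connected-component extraction honors the connectivity
           contract", {
  m <- square_map(32, 32, list(list(rows = 3:7, cols = 3:7),
                               list(rows = 20:24, cols = 20:24)))
  nuc <- extract_nuclei(m, min_area = 4L)
  expect_length(nuc$pixels, 2L)
  expect_equal(nuc$features$area, c(25L, 25L))

  # two squares touching only at a corner
  diag_m <- square_map(32, 32, list(list(rows = 3:6, cols = 3:6),
                                    list(rows = 7:10, cols = 7:10)))
  expect_length(extract_nuclei(diag_m, min_area = 4L,
                               connectivity = 8L)$pixels, 1L)
  expect_length(extract_nuclei(diag_m, min_area = 4L,
                               connectivity = 4L)$pixels, 2L)

  # no nucleus pixels: empty result, not an error
  expect_length(extract_nuclei(blank_map(32, 32), min_area = 4L)$pixels, 0L)
  # undersized components are discarded and counted
  tiny <- square_map(32, 32, list(list(rows = 3:4, cols = 3:4),
                                  list(rows = 20:26, cols = 20:26)))
  nt <- extract_nuclei(tiny, min_area = 30L)
  expect_length(nt$pixels, 1L)
  expect_identical(nt$n_discarded_small, 1L)
})

test_that("shape features match closed-form values on rasterized
           fixtures", {
  d <- disc_mask(64, 64, 32, 32, 15)
  f <- compute_shape_features(d)
  expect_gt(f$roundness, 0.9); expect_lt(f$roundness, 1.05)
  expect_lte(f$eccentricity, 0.2)

  # axis-aligned ellipse, semi-axes 20 and 10 -> ecc sqrt(1 - 0.25)
  g <- expand.grid(r = 1:90, c = 1:90)
  e <- matrix(((g$r - 45) / 20)^2 + ((g$c - 45) / 10)^2 <= 1, 90, 90)
  fe <- compute_shape_features(e)
  expect_lt(abs(fe$eccentricity - sqrt(1 - 0.25)), 0.05)

  # constant color: zero staining variation
  tile <- rgb_tile(array(100L, c(64, 64, 3)))
  expect_equal(compute_shape_features(d, tile)$staining_sd, 0)
  expect_error(compute_shape_features(matrix(FALSE, 8, 8)), "degenerate")
})

test_that("cell attribution grows through cytoplasm only and partitions
           shared cytoplasm", {
  # nucleus disc r=5 inside cytoplasm disc r=7: ratio ~ 25/49
  m <- blank_map(40, 40, "stroma")
  m <- paint_disc(m, 20, 20, 7, "cytoplasm")
  m <- paint_disc(m, 20, 20, 5, "nucleus")
  nuc <- extract_nuclei(m, min_area = 10L)
  nuc <- attribute_cell(nuc, m, max_dilation = 3L)
  expect_lt(abs(nuc$features$nucleus_to_cell_ratio - 25 / 49), 0.08)

  # nucleus with no adjacent cytoplasm: ratio exactly 1
  iso <- square_map(32, 32, list(list(rows = 10:14, cols = 10:14)))
  niso <- attribute_cell(extract_nuclei(iso, min_area = 4L), iso)
  expect_identical(niso$features$nucleus_to_cell_ratio, 1)

  # two nuclei sharing one cytoplasm band: claims disjoint, inside band
  m2 <- blank_map(40, 60, "stroma")
  m2$labels[15:25, 10:50] <- 2L          # cytoplasm band
  m2$labels[18:22, 15:19] <- 1L          # nucleus A
  m2$labels[18:22, 40:44] <- 1L          # nucleus B
  n2 <- attribute_cell(extract_nuclei(m2, min_area = 10L), m2,
                       max_dilation = 10L)
  cells <- n2$cell_labels
  claimed <- which(cells > 0L)
  nucleus_px <- unlist(n2$pixels)
  cyto_px <- which(m2$labels == 2L)
  expect_true(all(setdiff(claimed, nucleus_px) %in% cyto_px))
  expect_identical(sum(cells == 1L) + sum(cells == 2L), length(claimed))
})

test_that("lymphocyte classification follows the conjunctive threshold
           rule and is monotone", {
  m <- blank_map(40, 40, "stroma")
  m <- paint_disc(m, 20, 20, 6, "nucleus")
  nuc <- classify_lymphocytes(attribute_cell(extract_nuclei(
    m, min_area = 10L), m))
  # a single nucleus has relative size 1 > 0.8: classified other
  expect_false(nuc$features$is_lymphocyte)
  vac <- classify_lymphocytes(attribute_cell(extract_nuclei(
    m, min_area = 10L), m),
    lymphocyte_thresholds(relative_size_max = Inf, roundness_min = 0,
                          eccentricity_max = 1, ncr_min = 0,
                          staining_sd_max = Inf))
  expect_true(all(vac$features$is_lymphocyte))

  # monotone: relaxing any threshold never removes a lymphocyte
  r <- small_sim(seed = 3, target = 20)
  q <- quantify_tile(r$tile, seed = 51, K_range = 2:5,
                     tumor_mask = r$truth$tumor_mask)
  base <- q$nuclei
  strict <- lymphocyte_thresholds()
  for (nm in names(strict)) {
    relaxed <- strict
    relaxed[[nm]] <- if (grepl("min$", nm)) strict[[nm]] - 0.15
                     else strict[[nm]] + 0.15
    a <- classify_lymphocytes(base, strict)$features$is_lymphocyte
    b <- classify_lymphocytes(base, do.call(lymphocyte_thresholds,
                                            relaxed))$features$is_lymphocyte
    expect_true(all(b[a]), info = nm)
  }
})

test_that("on synthetic tiles nucleus counts reconcile with the ground
           truth and classification separates the populations", {
  r <- small_sim(seed = 29, target = 25)
  sel <- select_num_classes(r$tile, K_range = 2:6, seed = 5)
  map <- annotate_segments(quantize(r$tile, sel$scheme), sel$scheme)
  nuc <- extract_nuclei(map, r$tile, min_area = 30L)
  truth_n <- r$truth$n_tumor_nuclei + r$truth$n_lymphocytes_in_tumor +
    r$truth$n_lymphocytes_outside
  expect_identical(length(nuc$pixels) + nuc$n_discarded_small,
                   as.integer(truth_n))
  nuc <- classify_lymphocytes(attribute_cell(nuc, map))
  at <- round(nuc$features$centroid_col) * 256 +
    round(nuc$features$centroid_row) + 1
  is_lymph_truth <- r$truth$lymph_nucleus_mask[at]
  sens <- mean(nuc$features$is_lymphocyte[is_lymph_truth])
  spec <- mean(!nuc$features$is_lymphocyte[!is_lymph_truth])
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("assembled lymphocytes conserve pixels and keep sets disjoint", {
  r <- small_sim(seed = 59, target = 15)
  q <- quantify_tile(r$tile, seed = 61, K_range = 2:5,
                     tumor_mask = r$truth$tumor_mask)
  for (ly in q$lymphocytes) {
    expect_length(intersect(ly$nucleus_pixels, ly$cytoplasm_pixels), 0L)
    expect_setequal(ly$total_pixels,
                    c(ly$nucleus_pixels, ly$cytoplasm_pixels))
  }
  # attributed cytoplasm confined to cytoplasm class, claims disjoint
  all_cyto <- unlist(lapply(q$lymphocytes, function(l) l$cytoplasm_pixels))
  expect_identical(anyDuplicated(all_cyto), 0L)
  cyto_code <- as.integer(names(q$map$legend)[q$map$legend == "cytoplasm"])
  expect_true(all(q$map$labels[all_cyto] == cyto_code))
  # nucleus with no adjacent cytoplasm: empty cytoplasm set
  m <- square_map(32, 32, list(list(rows = 10:14, cols = 10:14)))
  n1 <- classify_lymphocytes(
    attribute_cell(extract_nuclei(m, min_area = 4L), m),
    lymphocyte_thresholds(relative_size_max = Inf))
  ly <- assemble_lymphocytes(n1)
  expect_length(ly[[1]]$cytoplasm_pixels, 0L)
})
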