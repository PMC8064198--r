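# Connected-component labeling by iterative minimum-label propagation.
# Converges in O(geodesic diameter) sweeps; nuclei are small compact
# objects so this stays cheap even on full tiles.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- which(mask)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- shift_matrix(lab, s[1], s[2])
      upd <- mask & sh > 0L & (new == 0L | sh < new)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

# Shift a matrix by (dr, dc), padding with 0.
shift_matrix <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Chaikin corner-cutting of a closed polygon.
chaikin <- function(x, y, iterations = 2L) {
  closed <- abs(x[1] - x[length(x)]) < 1e-9 && abs(y[1] - y[length(y)]) < 1e-9
  if (closed) { x <- x[-length(x)]; y <- y[-length(y)] }
  for (i in seq_len(iterations)) {
    nx <- c(rbind(0.75 * x + 0.25 * c(x[-1], x[1]),
                  0.25 * x + 0.75 * c(x[-1], x[1])))
    ny <- c(rbind(0.75 * y + 0.25 * c(y[-1], y[1]),
                  0.25 * y + 0.75 * c(y[-1], y[1])))
    x <- nx; y <- ny
  }
  list(x = c(x, x[1]), y = c(y, y[1]))
}

contour_length <- function(co) sum(sqrt(diff(co$x)^2 + diff(co$y)^2))

#' Morphometric and stain features of one nucleus
#'
#' Computes the five lymphocyte-identification features for a single
#' connected nuclear region: area; perimeter as the length of the
#' marching-squares boundary contour of the binary mask; roundness
#' (circularity) 4*pi*A / P^2; eccentricity sqrt(1 - l2/l1) from the
#' eigenvalues l1 >= l2 of the central second-moment matrix; and staining
#' variation as the standard deviation of luminance
#' (0.299 R + 0.587 G + 0.114 B) over the nucleus pixels. Relative size
#' and the nucleus-to-cell ratio are populated at the tile level by
#' [extract_nuclei()] and [attribute_cell()].
#'
#' @param mask logical matrix marking the nucleus pixels.
#' @param tile optional [rgb_tile()] sharing the mask frame (needed for
#'   staining sd).
#' @return named list of features.
#' @export
compute_shape_features <- function(mask, tile = NULL) {
  lum <- if (is.null(tile)) NULL else
    luminance(tile$pixels[, , 1], tile$pixels[, , 2], tile$pixels[, , 3])
  shape_features_idx(which(mask), nrow(mask), lum)
}

shape_features_idx <- function(idx, H, lum = NULL) {
  area <- length(idx)
  if (area < 2L) stop("degenerate nucleus (area < 2): min-size filter violated")
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  # marching-squares outer contour on the padded mask
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  sub <- matrix(0, r1 - r0 + 3L, c1 - c0 + 3L)
  sub[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- 1
  cl <- grDevices::contourLines(x = seq_len(nrow(sub)),
                                y = seq_len(ncol(sub)), z = sub, levels = 0.5)
  # marching squares yields a 0/45/90-degree staircase whose length
  # overestimates smooth boundaries; two rounds of Chaikin corner-cutting
  # before measuring removes most of the staircase bias
  per <- max(vapply(cl, function(co)
    contour_length(chaikin(co$x, co$y, 2L)), numeric(1)))
  # central second moments (0-based pixel coordinates)
  mr <- mean(rows); mc <- mean(cols)
  mu20 <- mean((rows - mr)^2); mu02 <- mean((cols - mc)^2)
  mu11 <- mean((rows - mr) * (cols - mc))
  tr <- mu20 + mu02
  det_part <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det_part) / 2; l2 <- (tr - det_part) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  stain_sd <- if (is.null(lum)) NA_real_ else stats::sd(lum[idx])
  list(area = area, perimeter = per,
       roundness = 4 * pi * area / per^2,
       eccentricity = ecc,
       centroid_row = mr - 1, centroid_col = mc - 1,
       staining_sd = stain_sd)
}

#' Extract nucleus segments from a semantic map
#'
#' Connected components (default 8-connectivity) of the nucleus class.
#' Components smaller than `min_area` are discarded and counted. Each
#' retained nucleus gets its shape and stain features; `relative_size` is
#' area over the median nuclear area on the tile.
#'
#' @param map a `semantic_map` from [annotate_segments()] (or any
#'   [label_mask()] whose legend contains "nucleus").
#' @param tile the companion [rgb_tile()] (for staining sd).
#' @param min_area minimum component area in px.
#' @param connectivity 4 or 8.
#' @return a `nucleus_set`: `labels` (H x W, 0 = none), `pixels` (list of
#'   linear index vectors), `features` data frame, `n_discarded_small`.
#' @export
extract_nuclei <- function(map, tile = NULL, min_area = 30L,
                           connectivity = 8L) {
  stopifnot(inherits(map, "label_mask"))
  nuc_code <- as.integer(names(map$legend)[map$legend == "nucleus"])
  if (!length(nuc_code)) stop("map has no nucleus class")
  mask <- map$labels == nuc_code
  if (!any(mask))
    return(structure(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                          pixels = list(), features = empty_features(),
                          n_discarded_small = 0L, dim = dim(mask)),
                     class = "nucleus_set"))
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  n_discarded <- sum(sizes < min_area)
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0L] <- match(lab[lab > 0L], keep)
  pixels <- split(which(lab > 0L), lab[lab > 0L])
  lum <- if (is.null(tile)) NULL else
    luminance(tile$pixels[, , 1], tile$pixels[, , 2], tile$pixels[, , 3])
  feats <- lapply(pixels, function(idx)
    shape_features_idx(idx, nrow(mask), lum))
  fd <- do.call(rbind, lapply(feats, as.data.frame))
  fd <- cbind(id = seq_along(pixels), fd)
  # size relative to the other detected nuclei: normalized by the 90th
  # percentile of nuclear areas, a tumor-scale reference that stays put
  # on lymphocyte-rich tiles (where the median itself is a lymphocyte)
  fd$relative_size <- fd$area / stats::quantile(fd$area, 0.9, names = FALSE)
  fd$cell_area <- NA_real_
  fd$nucleus_to_cell_ratio <- NA_real_
  rownames(fd) <- NULL
  structure(list(labels = lab, pixels = unname(pixels), features = fd,
                 n_discarded_small = n_discarded, dim = dim(mask)),
            class = "nucleus_set")
}

empty_features <- function() {
  data.frame(id = integer(), area = integer(), perimeter = numeric(),
             roundness = numeric(), eccentricity = numeric(),
             centroid_row = numeric(), centroid_col = numeric(),
             staining_sd = numeric(), relative_size = numeric(),
             cell_area = numeric(), nucleus_to_cell_ratio = numeric())
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei (%d discarded below min size)\n",
              length(x$pixels), x$n_discarded_small))
  invisible(x)
}

#' Attribute cytoplasm to nuclei and compute nucleus-to-cell ratios
#'
#' Each nucleus is grown by iterative unit (8-neighbor) dilation through
#' cytoplasm-class pixels only, stopping at other classes, at pixels
#' already claimed by another cell, or after `max_dilation` rounds.
#' Conflicting simultaneous claims resolve by nucleus priority order
#' (nuclei sorted by centroid row, then column). The cell is the nucleus
#' plus its claimed cytoplasm; `nucleus_to_cell_ratio` = nucleus area /
#' cell area.
#'
#' @param nuclei a `nucleus_set`.
#' @param map the `semantic_map`.
#' @param max_dilation maximum dilation rounds (>= 0).
#' @return the `nucleus_set` with `cell_labels` matrix and filled
#'   `cell_area` / `nucleus_to_cell_ratio`.
#' @export
attribute_cell <- function(nuclei, map, max_dilation = 3L) {
  stopifnot(inherits(nuclei, "nucleus_set"), max_dilation >= 0L)
  n <- length(nuclei$pixels)
  cyto_code <- as.integer(names(map$legend)[map$legend == "cytoplasm"])
  cyto <- map$labels == cyto_code
  H <- nuclei$dim[1]; W <- nuclei$dim[2]
  # priority = centroid order; claims by smaller priority win
  ord <- order(nuclei$features$centroid_row, nuclei$features$centroid_col)
  prio <- integer(n); prio[ord] <- seq_len(n)
  lab <- matrix(0L, H, W)
  for (j in seq_len(n)) lab[nuclei$pixels[[j]]] <- prio[j]
  INF <- n + 1L
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  if (n > 0L && max_dilation > 0L) for (round in seq_len(max_dilation)) {
    best <- matrix(INF, H, W)
    for (s in shifts) {
      sh <- shift_matrix(lab, s[1], s[2])
      upd <- sh > 0L & sh < best
      best[upd] <- sh[upd]
    }
    claim <- cyto & lab == 0L & best < INF
    if (!any(claim)) break
    lab[claim] <- best[claim]
  }
  cell_area <- tabulate(lab[lab > 0L], n)
  # map priorities back to nucleus ids
  feats <- nuclei$features
  feats$cell_area <- cell_area[prio]
  feats$nucleus_to_cell_ratio <- feats$area / feats$cell_area
  nuclei$features <- feats
  inv <- integer(n); inv[prio] <- seq_len(n)
  relab <- lab
  relab[lab > 0L] <- inv[lab[lab > 0L]]
  nuclei$cell_labels <- relab
  nuclei
}

#' Default lymphocyte classification thresholds
#'
#' Cut-offs for the five nuclear features; a nucleus is a lymphocyte only
#' if it passes all five (conjunctive rule). The feature list is fixed;
#' the cut-offs are configuration.
#'
#' @param relative_size_max max area relative to the tile's median
#'   nuclear area (lymphocyte nuclei are small).
#' @param roundness_min minimum circularity (lymphocyte nuclei are round).
#' @param eccentricity_max maximum eccentricity.
#' @param ncr_min minimum nucleus-to-cell ratio (lymphocytes have a high
#'   nucleus-to-cell ratio).
#' @param staining_sd_max maximum luminance sd (lymphocyte nuclei stain
#'   darkly and evenly).
#' @export
lymphocyte_thresholds <- function(relative_size_max = 0.8,
                                  roundness_min = 0.80,
                                  eccentricity_max = 0.80,
                                  ncr_min = 0.60,
                                  staining_sd_max = 20.0) {
  list(relative_size_max = relative_size_max, roundness_min = roundness_min,
       eccentricity_max = eccentricity_max, ncr_min = ncr_min,
       staining_sd_max = staining_sd_max)
}

#' Classify nuclei into lymphocyte vs other
#'
#' Conjunctive rule over the five features; see
#' [lymphocyte_thresholds()]. Monotone in every threshold: relaxing any
#' cut-off never removes a lymphocyte.
#'
#' @param nuclei a `nucleus_set` with cell attribution done.
#' @param thresholds a [lymphocyte_thresholds()] list.
#' @return the `nucleus_set` with logical `features$is_lymphocyte`.
#' @export
classify_lymphocytes <- function(nuclei, thresholds = lymphocyte_thresholds()) {
  f <- nuclei$features
  if (!nrow(f)) stop("no nuclei to classify")
  ncr <- ifelse(is.na(f$nucleus_to_cell_ratio), 1, f$nucleus_to_cell_ratio)
  stain <- ifelse(is.na(f$staining_sd), 0, f$staining_sd)
  f$is_lymphocyte <- f$relative_size <= thresholds$relative_size_max &
    f$roundness >= thresholds$roundness_min &
    f$eccentricity <= thresholds$eccentricity_max &
    ncr >= thresholds$ncr_min &
    stain <= thresholds$staining_sd_max
  nuclei$features <- f
  nuclei
}

#' Assemble lymphocyte objects from nuclei and attributed cytoplasm
#'
#' One lymphocyte per lymphocyte-classified nucleus: its nucleus pixels
#' plus the cytoplasm pixels claimed by its cell. Nucleus and cytoplasm
#' sets are disjoint; the total is their union.
#'
#' @param nuclei a classified `nucleus_set` (after [attribute_cell()] and
#'   [classify_lymphocytes()]).
#' @return list of `lymphocyte` objects: `nucleus_id`, `nucleus_pixels`,
#'   `cytoplasm_pixels`, `total_pixels`, `centroid`.
#' @export
assemble_lymphocytes <- function(nuclei) {
  stopifnot(!is.null(nuclei$cell_labels), !is.null(nuclei$features$is_lymphocyte))
  ids <- which(nuclei$features$is_lymphocyte)
  lapply(ids, function(j) {
    nuc <- nuclei$pixels[[j]]
    cell <- which(nuclei$cell_labels == j)
    structure(list(nucleus_id = j, nucleus_pixels = nuc,
                   cytoplasm_pixels = setdiff(cell, nuc),
                   total_pixels = cell,
                   centroid = c(nuclei$features$centroid_row[j],
                                nuclei$features$centroid_col[j])),
              class = "lymphocyte")
  })
}
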