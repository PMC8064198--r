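#' Identify tumor regions on a tile
#'
#' When an external or ground-truth mask is supplied it is returned
#' unchanged and recorded as the source. Otherwise the region is derived
#' from the tissue architecture: the union of discs (radius `r_density`)
#' centered at the centroids of non-lymphocyte nuclei, morphologically
#' closed with a disc of radius `r_close` and hole-filled — tumor nuclei
#' are dense inside tumor nests, so their dilated union traces the nests
#' plus a stromal margin.
#'
#' @param nuclei a classified `nucleus_set`.
#' @param provided_mask optional logical matrix (external annotation or
#'   ground truth); takes precedence.
#' @param r_density disc radius around non-lymphocyte nuclei (px).
#' @param r_close closing radius (px).
#' @param source label recorded when `provided_mask` is given
#'   ("provided" or "ground_truth").
#' @return logical tumor-region matrix with attribute `source`.
#' @export
identify_tumor_regions <- function(nuclei, provided_mask = NULL,
                                   r_density = 24, r_close = 12,
                                   source = "provided") {
  if (!is.null(provided_mask)) {
    stopifnot(is.logical(provided_mask))
    attr(provided_mask, "source") <- source
    return(provided_mask)
  }
  H <- nuclei$dim[1]; W <- nuclei$dim[2]
  mask <- matrix(FALSE, H, W)
  f <- nuclei$features
  idx <- which(!f$is_lymphocyte)
  if (length(idx)) {
    off <- disc_offsets(r_density)
    for (j in idx) {
      rr <- round(f$centroid_row[j]) + 1L + off$dr
      cc <- round(f$centroid_col[j]) + 1L + off$dc
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      mask[(cc[ok] - 1L) * H + rr[ok]] <- TRUE
    }
    if (r_close > 0) {
      kern <- EBImage::makeBrush(2L * ceiling(r_close) + 1L, "disc")
      mask <- EBImage::closing(mask, kern) > 0
    }
    mask <- EBImage::fillHull(mask * 1) > 0
  } else {
    warning("no non-lymphocyte nuclei: derived tumor region is empty")
  }
  attr(mask, "source") <- "derived"
  mask
}

#' Compute the stromal-TIL percentage of one tile
#'
#' A lymphocyte is stromal when its nucleus centroid lies on a
#' stroma-class pixel inside the tumor region. The numerator is the
#' total pixel area (nucleus + cytoplasm) of stromal lymphocytes clipped
#' to the tumor region; the denominator is the stroma area inside the
#' tumor region with lymphocyte-occupied stroma counted as stroma (the
#' inclusive convention: lymphocyte pixels over stroma count in both the
#' numerator and the denominator, bounding the percentage by 100).
#'
#' @param lymphocytes list from [assemble_lymphocytes()].
#' @param map the `semantic_map`.
#' @param tumor_mask logical tumor-region matrix.
#' @param tile_id identifier carried into the result.
#' @return a `stil_result`: `stromal_til_area`, `stroma_area`,
#'   `stil_percent`, `tumor_region_source`, `n_stromal_lymphocytes`.
#' @export
compute_stil <- function(lymphocytes, map, tumor_mask, tile_id = "tile") {
  if (!any(tumor_mask)) stop("empty tumor region: tile flagged low quality")
  stroma_code <- as.integer(names(map$legend)[map$legend == "stroma"])
  stroma <- map$labels == stroma_code
  H <- nrow(stroma)
  stromal_px <- 0L
  n_stromal <- 0L
  for (ly in lymphocytes) {
    r <- round(ly$centroid[1]) + 1L
    c <- round(ly$centroid[2]) + 1L
    at <- (c - 1L) * H + r
    # centroid must sit on in-mask stroma; the centroid pixel itself is
    # nucleus-class, so test stroma on the nearest surrounding ring
    if (!tumor_mask[at]) next
    if (!centroid_on_stroma(stroma, r, c, lymph_extent(ly, H))) next
    n_stromal <- n_stromal + 1L
    stromal_px <- stromal_px + sum(tumor_mask[ly$total_pixels])
  }
  denom <- sum(stroma & tumor_mask) + stromal_px
  if (denom == 0)
    stop("no stroma inside the tumor region: tile flagged low quality")
  structure(list(tile_id = tile_id,
                 stromal_til_area = stromal_px,
                 stroma_area = denom,
                 stil_percent = 100 * stromal_px / denom,
                 tumor_region_source = attr(tumor_mask, "source") %||%
                   "provided",
                 n_stromal_lymphocytes = n_stromal),
            class = "stil_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A lymphocyte sits *in* the stroma, so its own footprint has displaced
# the stroma class locally; test stroma membership on the ring just
# outside its footprint.
lymph_extent <- function(ly, H) {
  rows <- (ly$total_pixels - 1L) %% H + 1L
  cols <- (ly$total_pixels - 1L) %/% H + 1L
  max(sqrt((rows - mean(rows))^2 + (cols - mean(cols))^2))
}

centroid_on_stroma <- function(stroma, r, c, radius) {
  H <- nrow(stroma); W <- ncol(stroma)
  if (stroma[(c - 1L) * H + r]) return(TRUE)
  ring <- disc_offsets(radius + 2)
  ring <- ring[ring$dr^2 + ring$dc^2 > radius^2, , drop = FALSE]
  rr <- r + ring$dr; cc <- c + ring$dc
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  if (!any(ok)) return(FALSE)
  mean(stroma[(cc[ok] - 1L) * H + rr[ok]]) > 0.5
}

#' @export
print.stil_result <- function(x, ...) {
  cat(sprintf(
    "<stil_result> %s: sTIL %.2f%% (%d / %d px; tumor region: %s)\n",
    x$tile_id, x$stil_percent, x$stromal_til_area, x$stroma_area,
    x$tumor_region_source))
  invisible(x)
}

#' Pool per-tile sTIL results into one patient-level percentage
#'
#' Area-weighted pooled ratio: 100 * sum(numerators) / sum(denominators).
#' Lies within the range of the tile-level percentages.
#'
#' @param results list of `stil_result` objects (>= 1 valid tile).
#' @export
aggregate_patient_stil <- function(results) {
  results <- Filter(function(r) inherits(r, "stil_result"), results)
  if (!length(results)) stop("no valid tiles for this patient")
  num <- sum(vapply(results, function(r) r$stromal_til_area, numeric(1)))
  den <- sum(vapply(results, function(r) r$stroma_area, numeric(1)))
  100 * num / den
}

#' Quantify sTIL on a tile end to end
#'
#' Runs the full three-step algorithm: (1) per-channel GMM decomposition,
#' Dunn-criterion class-count selection, k-means threshold derivation and
#' multi-class quantization with semantic annotation; (2) nucleus
#' extraction, five-feature morphometry and lymphocyte classification
#' with cell attribution; (3) tumor-region identification, stromal
#' restriction and sTIL ratio.
#'
#' @param tile an [rgb_tile()].
#' @param seed run seed (subsampling and GMM fitting).
#' @param K_range candidate quantization class counts.
#' @param tumor_mask optional externally provided tumor-region mask.
#' @param thresholds lymphocyte classification cut-offs.
#' @param prototypes semantic color prototypes.
#' @param min_area minimum nucleus area (px).
#' @param max_dilation cytoplasm attribution rounds.
#' @param tile_id identifier.
#' @param ... passed to [identify_tumor_regions()] (`r_density`,
#'   `r_close`).
#' @return a `stil_quantification`: the `stil_result` plus the
#'   intermediate `scheme`, `map`, `nuclei`, selected `K`.
#' @export
quantify_tile <- function(tile, seed = 1L, K_range = 3:8, tumor_mask = NULL,
                          thresholds = lymphocyte_thresholds(),
                          prototypes = default_semantic_prototypes(),
                          min_area = 30L, max_dilation = 3L,
                          tile_id = "tile", ...) {
  sel <- select_num_classes(tile, K_range = K_range, seed = seed)
  labels <- quantize(tile, sel$scheme)
  map <- annotate_segments(labels, sel$scheme, prototypes)
  nuclei <- extract_nuclei(map, tile, min_area = min_area)
  if (!length(nuclei$pixels))
    stop("no nuclei detected: tile flagged low quality")
  nuclei <- attribute_cell(nuclei, map, max_dilation = max_dilation)
  nuclei <- classify_lymphocytes(nuclei, thresholds)
  lymphs <- assemble_lymphocytes(nuclei)
  tmask <- identify_tumor_regions(
    nuclei, provided_mask = tumor_mask,
    source = if (!is.null(tumor_mask)) "provided" else "derived", ...)
  res <- compute_stil(lymphs, map, tmask, tile_id = tile_id)
  structure(list(result = res, K = sel$K, dunn = sel$dunn,
                 scheme = sel$scheme, map = map, nuclei = nuclei,
                 lymphocytes = lymphs, tumor_mask = tmask),
            class = "stil_quantification")
}

#' @export
print.stil_quantification <- function(x, ...) {
  cat(sprintf("<stil_quantification> K = %d classes; %d nuclei, %d lymphocytes\n",
              x$K, length(x$nuclei$pixels), length(x$lymphocytes)))
  print(x$result)
  invisible(x)
}
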