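#' RGB tissue tile
#'
#' Constructs an 8-bit RGB tile, the unit of image analysis. Pixels are
#' stored as an integer H x W x 3 array with intensities in [0, 255],
#' row-major, 0-based pixel coordinates (row, col) in all reported
#' centroids. Companion masks share the tile's frame.
#'
#' @param pixels integer or numeric H x W x 3 array, intensities in [0, 255].
#' @param pixel_size_um optional micrometers-per-pixel scalar.
#' @return an object of class `rgb_tile`.
#' @export
rgb_tile <- function(pixels, pixel_size_um = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 32L || d[2] < 32L)
    stop("tile must be at least 32 x 32 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  pixels <- array(as.integer(round(as.numeric(pixels))), d)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "rgb_tile")
}

#' @export
print.rgb_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_tile> %d x %d, 8-bit RGB", d[1], d[2]))
  if (!is.null(x$pixel_size_um))
    cat(sprintf(", %.3f um/px", x$pixel_size_um))
  cat("\n")
  invisible(x)
}

#' @export
dim.rgb_tile <- function(x) dim(x$pixels)

#' Label mask with class legend
#'
#' @param labels integer H x W matrix of class codes.
#' @param legend named character vector mapping code (name) to class name.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, legend) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  codes <- sort(unique(as.integer(labels)))
  known <- as.integer(names(legend))
  if (!all(codes %in% known))
    stop("labels contain codes absent from the legend: ",
         paste(setdiff(codes, known), collapse = ", "))
  structure(list(labels = labels, legend = legend), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d; classes: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(x$legend, collapse = ", ")))
  invisible(x)
}

#' Read an 8-bit RGB tile from PNG or TIFF
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return an [rgb_tile()].
#' @export
read_tile <- function(path) {
  if (!file.exists(path)) stop("cannot read tile: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L)
      stop("unsupported bit depth ", info$bit.depth, " (8-bit required): ", path)
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (!is.null(bits) && any(bits != 8L))
      stop("unsupported bit depth ", bits[1], " (8-bit required): ", path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(raw)) == 3L && dim(raw)[3] == 4L) raw <- raw[, , 1:3]
  if (length(dim(raw)) != 3L || dim(raw)[3] != 3L)
    stop("not an RGB image (", paste(dim(raw), collapse = "x"), "): ", path)
  rgb_tile(round(raw * 255))
}

#' Write an 8-bit RGB tile to PNG or TIFF
#'
#' Round-trips losslessly with [read_tile()] for PNG.
#'
#' @param tile an [rgb_tile()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_tile <- function(tile, path) {
  stopifnot(inherits(tile, "rgb_tile"))
  arr <- tile$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(arr, path, bits.per.sample = 8L, compression = "none")
  else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read / write a label mask (single-channel PNG + JSON legend sidecar)
#'
#' Class codes are stored as gray levels; the legend travels in
#' `<path>.json`.
#'
#' @param path mask PNG path.
#' @return a [label_mask()].
#' @export
read_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  legend_path <- paste0(path, ".json")
  if (!file.exists(legend_path)) stop("missing legend sidecar: ", legend_path)
  legend <- unlist(jsonlite::read_json(legend_path))
  label_mask(round(raw * 255), legend)
}

#' @rdname read_mask
#' @param mask a [label_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  png::writePNG(mask$labels / 255, path)
  jsonlite::write_json(as.list(mask$legend), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

# Declared cohort schema: column name -> type tag. Genotype columns are
# declared via `snps`, a named list SNP -> c(allele_A, allele_B).
#' Cohort schema declaration
#'
#' @param columns named character vector, column name -> one of
#'   "id", "numeric", "integer", "factor", "genotype".
#' @param snps named list mapping each genotype column to its two declared
#'   alleles, e.g. `list(rs1800682 = c("T", "C"))`.
#' @param required character vector of mandatory columns.
#' @export
cohort_schema <- function(columns, snps = list(), required = names(columns)) {
  structure(list(columns = columns, snps = snps, required = required),
            class = "cohort_schema")
}

#' Default cohort schema used by the simulator and the analysis stages
#'
#' @param snp_names character vector of genotype column names.
#' @export
default_cohort_schema <- function(snp_names = character()) {
  cols <- c(id = "id", age = "numeric", sex = "factor", bmi = "factor",
            treatment = "factor", grade = "factor", tea = "factor",
            stil = "numeric", dfs_time = "numeric", dfs_event = "integer")
  cols <- c(cols, stats::setNames(rep("genotype", length(snp_names)), snp_names))
  # allele pairs unknown until read; validated only when declared
  cohort_schema(cols, snps = stats::setNames(
    rep(list(NULL), length(snp_names)), snp_names))
}

#' Read and validate a cohort table
#'
#' Delimited text in, typed data frame out. Rows whose mandatory fields do
#' not parse or fail validation (negative follow-up time, non-binary event
#' indicator, genotype alleles outside the SNP's declared pair) are
#' rejected and reported with their row numbers; nothing is imputed.
#' Missing values are the empty string or "NA".
#'
#' @param path CSV/TSV path (delimiter sniffed from the header line).
#' @param schema a [cohort_schema()].
#' @return a data frame of class `cohort_table` with attribute `rejected`,
#'   a data frame of (row, reason).
#' @export
read_cohort <- function(path, schema) {
  stopifnot(inherits(schema, "cohort_schema"))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = c("", "NA"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(schema$required, names(df))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- list()
  flag <- function(rows, reason) {
    if (length(rows)) bad[[length(bad) + 1L]] <<- data.frame(row = rows,
                                                            reason = reason)
  }
  out <- df
  for (col in intersect(names(schema$columns), names(df))) {
    type <- schema$columns[[col]]
    v <- df[[col]]
    if (type %in% c("numeric", "integer")) {
      parsed <- suppressWarnings(as.numeric(v))
      flag(which(!is.na(v) & is.na(parsed)), paste0("unparseable ", col))
      out[[col]] <- parsed
    } else if (type == "factor") {
      out[[col]] <- factor(v)
    } else if (type == "genotype") {
      ok <- is.na(v) | grepl("^[A-Za-z]+/[A-Za-z]+$", v)
      flag(which(!ok), paste0("malformed genotype in ", col))
      alleles <- schema$snps[[col]]
      if (!is.null(alleles)) {
        parts <- strsplit(ifelse(is.na(v), "NA/NA", v), "/", fixed = TRUE)
        valid <- vapply(parts, function(p) all(p %in% c(alleles, "NA")),
                        logical(1))
        flag(which(ok & !is.na(v) & !valid),
             paste0("allele outside declared pair in ", col))
      }
    }
  }
  if ("dfs_time" %in% names(out))
    flag(which(!is.na(out$dfs_time) & out$dfs_time < 0), "negative dfs_time")
  if ("dfs_event" %in% names(out))
    flag(which(!is.na(out$dfs_event) & !out$dfs_event %in% c(0, 1)),
         "dfs_event not in {0,1}")
  if ("stil" %in% names(out))
    flag(which(!is.na(out$stil) & (out$stil < 0 | out$stil > 100)),
         "sTIL outside [0,100]")
  rejected <- if (length(bad)) do.call(rbind, bad)
              else data.frame(row = integer(), reason = character())
  keep <- setdiff(seq_len(nrow(out)), unique(rejected$row))
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cohort_table", "data.frame")
  attr(res, "rejected") <- rejected
  res
}

#' Write a cohort table to CSV
#'
#' @param cohort a cohort data frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Patient-accounting exclusion ledger
#'
#' Applies the study's exclusion accounting: from `n_genotyped` eligible
#' genotyped cases, remove those lost to follow-up and those whose
#' H&E slide images were of too low quality to score; a patient carrying
#' both flags is removed once. Percentages are reported relative to the
#' genotyped total, rounded to one decimal.
#'
#' @param n_genotyped total genotyped eligible cases.
#' @param lost_to_followup count (or logical vector) of patients lost to
#'   follow-up.
#' @param low_image_quality count (or logical vector) of patients with
#'   unusable slide images.
#' @param both count of patients carrying both flags (0 when counts are
#'   given as disjoint totals).
#' @return list with `retained`, per-exclusion counts and percentages.
#' @export
apply_exclusions <- function(n_genotyped, lost_to_followup = 0,
                             low_image_quality = 0, both = 0) {
  if (is.logical(lost_to_followup) || is.logical(low_image_quality)) {
    lf <- as.logical(lost_to_followup)
    lq <- as.logical(low_image_quality)
    stopifnot(length(lf) == n_genotyped, length(lq) == n_genotyped)
    both <- sum(lf & lq)
    lost_to_followup <- sum(lf)
    low_image_quality <- sum(lq)
  }
  counts <- c(n_genotyped, lost_to_followup, low_image_quality, both)
  if (any(counts < 0)) stop("negative counts")
  excluded <- lost_to_followup + low_image_quality - both
  if (excluded > n_genotyped) stop("exclusions exceed cohort size")
  list(
    n_genotyped = n_genotyped,
    lost_to_followup = lost_to_followup,
    lost_to_followup_pct = round(100 * lost_to_followup / n_genotyped, 1),
    low_image_quality = low_image_quality,
    low_image_quality_pct = round(100 * low_image_quality / n_genotyped, 1),
    excluded = excluded,
    retained = n_genotyped - excluded
  )
}

#' Percentage of a count within a total, one-decimal convention
#'
#' Formatting convention used throughout the cohort accounting tables.
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @export
category_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, 1)
}
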