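#' Configuration for the synthetic H&E tile generator
#'
#' The generator emulates the qualitative contrasts the sTIL algorithm
#' relies on: tumor nests of cytoplasm-stained tissue carrying large,
#' elongated, variably stained tumor nuclei; pink stroma between and
#' around the nests; small, round, darkly and evenly stained lymphocyte
#' nuclei with a thin cytoplasm rim, lying in the stroma; and near-white
#' background. Each class renders as an RGB prototype plus independent
#' Gaussian channel noise clipped to [0, 255], so every class has a
#' mixture-recoverable unimodal channel signature.
#'
#' @param height,width tile size in pixels.
#' @param tumor_nest_count number of tumor nests (discs).
#' @param nest_radius length-2 range of nest radii (px).
#' @param nest_fill `"cytoplasm"` (tumor tissue) or `"stroma"`
#'   (stroma-only tumor interior, for controlled-coverage experiments).
#' @param tumor_nucleus_density tumor nuclei per 1e4 px of nest area.
#' @param lymphocyte_density lymphocytes per 1e4 px of stroma area
#'   (applied both inside and outside tumor regions).
#' @param lymph_radius length-2 range of lymphocyte nucleus radii (px).
#' @param lymph_rim_width cytoplasm rim width around a lymphocyte nucleus (px).
#' @param tumor_nucleus_axis length-2 range of tumor-nucleus semi-major
#'   axes (px).
#' @param tumor_nucleus_axis_ratio length-2 range of major/minor axis ratios.
#' @param colors named list of RGB prototype means for `nucleus`,
#'   `cytoplasm`, `stroma`, `background`.
#' @param noise_sd per-channel Gaussian noise sd (intensity units).
#' @param tumor_stain_sd extra per-pixel stain noise inside tumor nuclei,
#'   giving them the higher staining variation the classifier uses.
#' @param nest_dilation dilation radius (px) defining the true tumor
#'   region as the dilated union of nests.
#' @param background_blob_count,background_blob_radius near-white slide
#'   regions outside the tissue.
#' @param seed RNG seed for [render_tile()].
#' @return a `tile_sim_config` list.
#' @export
tile_sim_config <- function(height = 512L, width = 512L,
                            tumor_nest_count = 4L,
                            nest_radius = c(55, 85),
                            nest_fill = c("cytoplasm", "stroma"),
                            tumor_nucleus_density = 14,
                            lymphocyte_density = 12,
                            lymph_radius = c(4, 6),
                            lymph_rim_width = 1,
                            tumor_nucleus_axis = c(9, 14),
                            tumor_nucleus_axis_ratio = c(1.7, 2.6),
                            colors = list(
                              nucleus    = c(70, 50, 120),
                              cytoplasm  = c(150, 100, 200),
                              stroma     = c(228, 140, 160),
                              background = c(245, 242, 245)),
                            noise_sd = 6,
                            tumor_stain_sd = 14,
                            nest_dilation = 18,
                            background_blob_count = 2L,
                            background_blob_radius = c(35, 60),
                            seed = 1L) {
  nest_fill <- match.arg(nest_fill)
  stopifnot(height >= 64, width >= 64,
            tumor_nucleus_density >= 0, lymphocyte_density >= 0,
            all(nest_radius > 0), all(lymph_radius > 0),
            all(tumor_nucleus_axis > 0),
            max(lymph_radius) < min(tumor_nucleus_axis))
  proto <- do.call(rbind, colors)
  for (i in seq_len(nrow(proto) - 1L)) for (j in seq(i + 1L, nrow(proto))) {
    if (max(abs(proto[i, ] - proto[j, ])) < 20)
      stop("color prototypes '", rownames(proto)[i], "' and '",
           rownames(proto)[j],
           "' differ by < 20 intensity units in every channel")
  }
  structure(as.list(environment()), class = "tile_sim_config")
}

# Sample non-overlapping centers for footprints given by `offsets` within
# the eligible mask; each placement claims its own pixels in `occupied`.
place_objects <- function(eligible, occupied, n_target, offsets_fun,
                          max_tries = 40L) {
  nr <- nrow(eligible)
  placed <- list()
  free <- which(eligible & !occupied)
  tries <- 0L
  while (length(placed) < n_target && tries < max_tries * n_target) {
    tries <- tries + 1L
    if (!length(free)) break
    center <- free[sample.int(length(free), 1L)]
    row <- (center - 1L) %% nr + 1L
    col <- (center - 1L) %/% nr + 1L
    obj <- offsets_fun()
    rr <- row + obj$dr; cc <- col + obj$dc
    if (min(rr) < 2L || min(cc) < 2L || max(rr) > nr - 1L ||
        max(cc) > ncol(eligible) - 1L) next
    idx <- (cc - 1L) * nr + rr
    # require a 1-px clearance so nuclei never touch, even diagonally
    pad <- unique(c(outer(idx, c(-1L, 0L, 1L), "+")))
    pad <- unique(c(outer(pad, nr * c(-1L, 0L, 1L), "+")))
    if (!all(eligible[pad]) || any(occupied[pad])) next
    occupied[idx] <- TRUE
    placed[[length(placed) + 1L]] <- list(row = row, col = col, idx = idx)
  }
  list(placed = placed, occupied = occupied)
}

# Integer offsets of a filled, rotated ellipse (semi-axes a >= b, angle th).
ellipse_offsets <- function(a, b, theta) {
  m <- ceiling(a)
  s <- seq(-m, m)
  g <- expand.grid(dr = s, dc = s)
  u <- g$dc * cos(theta) + g$dr * sin(theta)
  v <- -g$dc * sin(theta) + g$dr * cos(theta)
  g[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
}

#' Render a synthetic H&E tile with ground truth
#'
#' Deterministic given the config seed. Nuclei never overlap. Lymphocytes
#' (nucleus plus rim) are placed entirely on stroma; when
#' `target_stil_percent` is given, lymphocytes are added to the stroma
#' inside the tumor region until the covered fraction of that stroma
#' reaches the target, while stroma outside tumor regions receives
#' lymphocytes at the configured density (so the tumor-region restriction
#' is genuinely exercised).
#'
#' @param config a [tile_sim_config()].
#' @param target_stil_percent optional target true sTIL percentage in
#'   (0, 100); overrides density-driven placement inside tumor regions.
#' @return list with `tile` ([rgb_tile()]) and `truth`, a ground-truth
#'   list: `semantic` ([label_mask()] over tumor-nucleus /
#'   lymphocyte-nucleus / cytoplasm / stroma / background), `tumor_mask`,
#'   `lymph_mask`, `stroma_base` (stroma before lymphocyte placement),
#'   `true_stil_percent` and placement counts.
#' @export
render_tile <- function(config, target_stil_percent = NULL) {
  stopifnot(inherits(config, "tile_sim_config"))
  with_seed(config$seed, render_tile_impl(config, target_stil_percent))
}

render_tile_impl <- function(cfg, target) {
  H <- cfg$height; W <- cfg$width
  # class codes in the semantic ground truth
  TUMOR_NUC <- 1L; LYMPH_NUC <- 2L; CYTO <- 3L; STROMA <- 4L; BACKGROUND <- 5L
  sem <- matrix(STROMA, H, W)

  # background blobs (slide regions without tissue)
  for (i in seq_len(cfg$background_blob_count)) {
    r <- stats::runif(1, cfg$background_blob_radius[1],
                      cfg$background_blob_radius[2])
    row <- sample.int(H, 1L); col <- sample.int(W, 1L)
    off <- disc_offsets(r)
    rr <- row + off$dr; cc <- col + off$dc
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    sem[(cc[ok] - 1L) * H + rr[ok]] <- BACKGROUND
  }

  # tumor nests: non-overlapping discs inside the tile
  nests <- matrix(FALSE, H, W)
  margin <- max(cfg$nest_radius)
  n_placed <- 0L; tries <- 0L
  centers <- NULL
  while (n_placed < cfg$tumor_nest_count && tries < 400L) {
    tries <- tries + 1L
    r <- stats::runif(1, cfg$nest_radius[1], cfg$nest_radius[2])
    row <- sample(seq(ceiling(r) + 1L, H - ceiling(r)), 1L)
    col <- sample(seq(ceiling(r) + 1L, W - ceiling(r)), 1L)
    if (!is.null(centers) &&
        any((centers[, 1] - row)^2 + (centers[, 2] - col)^2 <
            (centers[, 3] + r + 6)^2)) next
    off <- disc_offsets(r)
    idx <- (col + off$dc - 1L) * H + (row + off$dr)
    nests[idx] <- TRUE
    centers <- rbind(centers, c(row, col, r))
    n_placed <- n_placed + 1L
  }
  if (n_placed < cfg$tumor_nest_count)
    stop("could not place ", cfg$tumor_nest_count, " tumor nests; achieved ",
         n_placed)
  sem[nests] <- if (cfg$nest_fill == "cytoplasm") CYTO else STROMA

  # true tumor region: dilated union of nests
  kern <- EBImage::makeBrush(2L * ceiling(cfg$nest_dilation) + 1L, "disc")
  tumor_mask <- EBImage::dilate(nests, kern) > 0

  occupied <- matrix(FALSE, H, W)

  # tumor nuclei: ellipses inside the nests
  tumor_centers <- NULL
  if (cfg$nest_fill == "cytoplasm" && cfg$tumor_nucleus_density > 0) {
    n_tn <- round(cfg$tumor_nucleus_density * sum(nests) / 1e4)
    gen <- function() {
      a <- stats::runif(1, cfg$tumor_nucleus_axis[1], cfg$tumor_nucleus_axis[2])
      ratio <- stats::runif(1, cfg$tumor_nucleus_axis_ratio[1],
                            cfg$tumor_nucleus_axis_ratio[2])
      ellipse_offsets(a, a / ratio, stats::runif(1, 0, pi))
    }
    res <- place_objects(nests, occupied, n_tn, gen)
    occupied <- res$occupied
    for (p in res$placed) sem[p$idx] <- TUMOR_NUC
    tumor_centers <- do.call(rbind, lapply(res$placed,
                                           function(p) c(p$row, p$col)))
    if (length(res$placed) < 0.6 * n_tn)
      stop("tumor nucleus placement failed; achieved density ",
           round(length(res$placed) / sum(nests) * 1e4, 2), " per 1e4 px")
  }

  stroma_base <- sem == STROMA
  lymph_mask <- matrix(FALSE, H, W)
  lymph_nuc_mask <- matrix(FALSE, H, W)
  lymph_centers <- NULL

  commit_lymph <- function(row, col, obj, count_mask) {
    idx <- (col + obj$all[, 2] - 1L) * H + (row + obj$all[, 1])
    nidx <- (col + obj$nuc[, 2] - 1L) * H + (row + obj$nuc[, 1])
    occupied[idx] <<- TRUE
    lymph_mask[idx] <<- TRUE
    lymph_nuc_mask[nidx] <<- TRUE
    sem[idx] <<- CYTO
    sem[nidx] <<- LYMPH_NUC
    lymph_centers <<- rbind(lymph_centers, c(row, col))
    sum(count_mask[idx])
  }

  # the footprint must lie on free stroma; the placement region
  # (inside/outside the tumor mask) constrains only the center, matching
  # the centroid rule used for stromal membership in scoring
  lymph_fits <- function(row, col, obj, eligible) {
    if (row < 1L || col < 1L || row > H || col > W ||
        !eligible[(col - 1L) * H + row]) return(FALSE)
    rr <- row + obj$all[, 1]; cc <- col + obj$all[, 2]
    if (min(rr) < 1L || min(cc) < 1L || max(rr) > H || max(cc) > W)
      return(FALSE)
    idx <- (cc - 1L) * H + rr
    if (!all(stroma_base[idx]) || any(occupied[idx])) return(FALSE)
    # 1-px clearance: no nucleus-class pixel may touch the footprint,
    # so nuclei never become 8-connected across cells
    rr2 <- row + obj$ring[, 1]; cc2 <- col + obj$ring[, 2]
    ok <- rr2 >= 1L & rr2 <= H & cc2 >= 1L & cc2 <= W
    !any(sem[(cc2[ok] - 1L) * H + rr2[ok]] %in% c(1L, 2L))
  }

  # shape cache over a quantized radius grid (offsets as matrices)
  disc_m <- function(r) {
    s <- seq(-ceiling(r), ceiling(r))
    g <- as.matrix(expand.grid(dr = s, dc = s))
    g[g[, 1]^2 + g[, 2]^2 <= r^2, , drop = FALSE]
  }
  lymph_radii <- seq(cfg$lymph_radius[1], cfg$lymph_radius[2], by = 0.25)
  lymph_shapes <- lapply(lymph_radii, function(r) {
    all <- disc_m(r + cfg$lymph_rim_width)
    halo <- disc_m(r + cfg$lymph_rim_width + 1.5)
    keep <- !(paste(halo[, 1], halo[, 2]) %in% paste(all[, 1], all[, 2]))
    list(nuc = disc_m(r), all = all, ring = halo[keep, , drop = FALSE])
  })
  lymph_shape <- function(r) {
    lymph_shapes[[which.min(abs(lymph_radii - r))]]
  }

  place_lymphs <- function(eligible, n_target, stop_px = Inf,
                           count_mask = eligible) {
    # lymphocyte = nucleus disc + thin cytoplasm rim, fully on stroma.
    # Random sequential placement jams near ~45% coverage, so dense
    # targets start from a jittered hexagonal lattice of candidate
    # centers and fall back to random top-up placement.
    placed_px <- 0L; count <- 0L
    dense <- is.finite(stop_px) &&
      stop_px > 0.3 * sum(eligible & stroma_base & !occupied)
    if (dense) {
      s <- 2 * (cfg$lymph_radius[1] + cfg$lymph_rim_width) + 1
      rows <- seq(1, H, by = ceiling(s * 0.87))
      cand <- do.call(rbind, lapply(seq_along(rows), function(i) {
        cols <- seq(1 + (i %% 2) * s / 2, W, by = s)
        cbind(rows[i], round(cols))
      }))
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        if (count >= n_target || placed_px >= stop_px) break
        row <- cand[i, 1] + sample(-1:1, 1)
        col <- cand[i, 2] + sample(-1:1, 1)
        obj <- lymph_shape(stats::runif(1, cfg$lymph_radius[1],
                                        cfg$lymph_radius[2]))
        if (!lymph_fits(row, col, obj, eligible))
          obj <- lymph_shape(cfg$lymph_radius[1])
        if (!lymph_fits(row, col, obj, eligible)) next
        placed_px <- placed_px + commit_lymph(row, col, obj, count_mask)
        count <- count + 1L
      }
    }
    tries <- 0L
    free_ok <- eligible & stroma_base & !occupied
    while (count < n_target && placed_px < stop_px && tries < 4000L) {
      tries <- tries + 1L
      free <- which(free_ok)
      if (!length(free)) break
      center <- free[sample.int(length(free), 1L)]
      row <- (center - 1L) %% H + 1L
      col <- (center - 1L) %/% H + 1L
      obj <- lymph_shape(stats::runif(1, cfg$lymph_radius[1],
                                      cfg$lymph_radius[2]))
      if (!lymph_fits(row, col, obj, eligible)) { free_ok[center] <- FALSE; next }
      placed_px <- placed_px + commit_lymph(row, col, obj, count_mask)
      free_ok[occupied] <- FALSE
      count <- count + 1L
    }
    count
  }

  stroma_in_tumor <- sum(stroma_base & tumor_mask)
  n_in <- 0L
  if (!is.null(target)) {
    stopifnot(target > 0, target < 100)
    need_px <- target / 100 * stroma_in_tumor
    n_in <- place_lymphs(tumor_mask, n_target = Inf, stop_px = need_px,
                         count_mask = tumor_mask & stroma_base)
  } else if (cfg$lymphocyte_density > 0) {
    n_in <- place_lymphs(tumor_mask,
                         round(cfg$lymphocyte_density * stroma_in_tumor / 1e4))
  }
  n_out <- if (cfg$lymphocyte_density > 0) {
    place_lymphs(!tumor_mask,
                 round(cfg$lymphocyte_density *
                       sum(stroma_base & !tumor_mask) / 1e4))
  } else 0L

  denom <- sum(stroma_base & tumor_mask)
  numer <- sum(lymph_mask & stroma_base & tumor_mask)
  true_stil <- if (denom > 0) 100 * numer / denom else NA_real_

  # render: prototype + iid Gaussian channel noise, clipped
  proto <- rbind(cfg$colors$nucleus, cfg$colors$nucleus, cfg$colors$cytoplasm,
                 cfg$colors$stroma, cfg$colors$background)
  px <- array(0, c(H, W, 3))
  extra_sd <- ifelse(sem == TUMOR_NUC, cfg$tumor_stain_sd, 0)
  for (ch in 1:3) {
    base <- proto[sem, ch]
    noise <- stats::rnorm(H * W, 0, cfg$noise_sd) +
      stats::rnorm(H * W, 0, 1) * extra_sd
    px[, , ch] <- pmin(255, pmax(0, round(base + noise)))
  }

  legend <- c(`1` = "tumor_nucleus", `2` = "lymphocyte_nucleus",
              `3` = "cytoplasm", `4` = "stroma", `5` = "background")
  truth <- list(
    semantic = label_mask(sem, legend),
    tumor_mask = tumor_mask,
    lymph_mask = lymph_mask,
    lymph_nucleus_mask = lymph_nuc_mask,
    stroma_base = stroma_base,
    nest_mask = nests,
    true_stil_percent = true_stil,
    stromal_til_area = numer,
    stroma_area = denom,
    n_lymphocytes_in_tumor = n_in,
    n_lymphocytes_outside = n_out,
    n_tumor_nuclei = if (is.null(tumor_centers)) 0L else nrow(tumor_centers),
    tumor_nucleus_centers = tumor_centers,
    lymphocyte_centers = lymph_centers)
  list(tile = rgb_tile(px), truth = truth)
}

#' Write a simulated tile, its ground-truth masks and truth JSON
#'
#' Emits `<prefix>.png` (tile), `<prefix>_semantic.png` (+ `.json`
#' legend sidecar), `<prefix>_tumor.png` (tumor-region mask) and
#' `<prefix>_truth.json` (true sTIL, counts).
#'
#' @param sim a list from [render_tile()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return the tile path, invisibly.
#' @export
save_tile_bundle <- function(sim, dir, prefix = "tile") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, ".png"))
  write_tile(sim$tile, p)
  write_mask(sim$truth$semantic, file.path(dir, paste0(prefix,
                                                       "_semantic.png")))
  tm <- label_mask(matrix(as.integer(sim$truth$tumor_mask),
                          nrow(sim$truth$tumor_mask)),
                   c(`0` = "outside", `1` = "tumor_region"))
  write_mask(tm, file.path(dir, paste0(prefix, "_tumor.png")))
  jsonlite::write_json(
    list(true_stil_percent = sim$truth$true_stil_percent,
         stromal_til_area = sim$truth$stromal_til_area,
         stroma_area = sim$truth$stroma_area,
         n_lymphocytes_in_tumor = sim$truth$n_lymphocytes_in_tumor,
         n_lymphocytes_outside = sim$truth$n_lymphocytes_outside,
         n_tumor_nuclei = sim$truth$n_tumor_nuclei),
    file.path(dir, paste0(prefix, "_truth.json")), auto_unbox = TRUE,
    digits = NA)
  invisible(p)
}

#' Recompute the true sTIL percentage from emitted ground-truth masks
#'
#' Identical counting to the generator's: lymphocyte pixels lying on
#' pre-placement stroma inside the tumor region over all pre-placement
#' stroma inside the tumor region.
#'
#' @param truth a ground-truth list from [render_tile()].
#' @export
true_stil_from_masks <- function(truth) {
  denom <- sum(truth$stroma_base & truth$tumor_mask)
  100 * sum(truth$lymph_mask & truth$stroma_base & truth$tumor_mask) / denom
}
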