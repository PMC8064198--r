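# Shared fixtures built in code.

semantic_legend <- c(`1` = "nucleus", `2` = "cytoplasm", `3` = "stroma",
                     `4` = "other")

# A semantic map filled with one class.
blank_map <- function(h = 64, w = 64, fill = "stroma") {
  code <- as.integer(names(semantic_legend)[semantic_legend == fill])
  m <- label_mask(matrix(code, h, w), semantic_legend)
  class(m) <- c("semantic_map", class(m))
  m
}

# Paint a filled disc of a semantic class onto a map.
paint_disc <- function(map, row, col, r, class_name) {
  code <- as.integer(names(semantic_legend)[semantic_legend == class_name])
  H <- nrow(map$labels)
  off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  rr <- row + off$dr; cc <- col + off$dc
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= ncol(map$labels)
  map$labels[(cc[ok] - 1L) * H + rr[ok]] <- code
  map
}

# A minimal lymphocyte object for compute_stil.
fake_lymphocyte <- function(pixel_idx, centroid) {
  structure(list(nucleus_id = 1L, nucleus_pixels = pixel_idx,
                 cytoplasm_pixels = integer(0), total_pixels = pixel_idx,
                 centroid = centroid),
            class = "lymphocyte")
}

# Binary disc mask.
disc_mask <- function(h, w, row, col, r) {
  m <- matrix(FALSE, h, w)
  off <- expand.grid(dr = -ceiling(r):ceiling(r), dc = -ceiling(r):ceiling(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  m[(col + off$dc - 1L) * h + (row + off$dr)] <- TRUE
  m
}

# Exponential two-group survival data.
sim_surv_groups <- function(n_per, rate1, rate2, cens = Inf) {
  t1 <- stats::rexp(n_per, rate1); t2 <- stats::rexp(n_per, rate2)
  cnt <- if (is.finite(cens)) stats::runif(2 * n_per, 0, cens) else
    rep(Inf, 2 * n_per)
  tt <- c(t1, t2)
  data.frame(dfs_time = pmin(tt, cnt), dfs_event = as.integer(tt <= cnt),
             group = rep(c(0, 1), each = n_per))
}

# A quick small-tile simulation shared across image tests.
small_sim <- function(seed = 5, target = 25, noise_sd = 6) {
  cfg <- tile_sim_config(height = 256L, width = 256L, tumor_nest_count = 2L,
                         nest_radius = c(40, 55), noise_sd = noise_sd,
                         background_blob_count = 1L,
                         background_blob_radius = c(25, 35), seed = seed)
  render_tile(cfg, target_stil_percent = target)
}
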