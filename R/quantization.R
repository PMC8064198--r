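#' Fit a univariate Gaussian mixture to one color channel by EM
#'
#' Decomposes the intensity distribution of a single RGB channel into
#' `n_components` Gaussian components. EM runs until the log-likelihood
#' gain drops below `tol` or `max_iter` is reached; the log-likelihood is
#' non-decreasing across iterations. Component variances are clamped at a
#' floor (default 1e-2 intensity^2) to prevent singularities. If the fit
#' collapses (components with coincident means at the variance floor),
#' the fit is restarted from a perturbed initialization up to
#' `max_restarts` times before erroring.
#'
#' @param values numeric intensity sample (at least `10 * n_components`).
#' @param n_components number of Gaussian components (>= 1).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed RNG seed (used only for restart perturbations).
#' @param var_floor variance floor in intensity^2.
#' @param max_restarts bounded restart count on degeneracy.
#' @return a `channel_gmm`: components data frame (weight, mean, variance,
#'   sorted by mean), `log_likelihood`, `n_iterations`, `ll_trace`.
#' @export
fit_channel_gmm <- function(values, n_components = 4L, tol = 1e-6,
                            max_iter = 200L, seed = 1L, var_floor = 1e-2,
                            max_restarts = 5L) {
  stopifnot(n_components >= 1L, length(values) >= 10L * n_components)
  values <- as.numeric(values)
  with_seed(seed, {
    for (attempt in 0:max_restarts) {
      fit <- em_gmm_1d(values, n_components, tol, max_iter, var_floor,
                       jitter = attempt > 0)
      if (!fit$degenerate) {
        fit$restarts <- attempt
        class(fit) <- "channel_gmm"
        return(fit)
      }
    }
    stop("GMM fit degenerate after ", max_restarts,
         " restarts (coincident components at the variance floor)")
  })
}

em_gmm_1d <- function(x, k, tol, max_iter, var_floor, jitter = FALSE) {
  n <- length(x)
  # quantile initialization; restarts perturb it
  mu <- stats::quantile(x, (seq_len(k) - 0.5) / k, names = FALSE)
  if (jitter) mu <- mu + stats::rnorm(k, 0, max(stats::sd(x) / 4, 1))
  sig2 <- rep(max(stats::var(x) / max(k, 1)^2, var_floor), k)
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step in log space
    logd <- vapply(seq_len(k), function(j)
      stats::dnorm(x, mu[j], sqrt(sig2[j]), log = TRUE) + log(w[j]),
      numeric(n))
    m <- logd[, 1L]
    if (k > 1L) for (j in 2:k) m <- pmax(m, logd[, j])
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logd - lse)
    if (ll - ll_old < tol || iter >= max_iter) break
    ll_old <- ll
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sig2 <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, var_floor)
  }
  ord <- order(mu)
  degenerate <- k > 1L &&
    any(diff(sort(mu)) < 1e-6 & sig2[ord][-1] <= var_floor + 1e-12)
  list(components = data.frame(weight = w[ord], mean = mu[ord],
                               variance = sig2[ord]),
       log_likelihood = ll_trace[length(ll_trace)],
       n_iterations = iter, ll_trace = ll_trace, degenerate = degenerate)
}

#' @export
print.channel_gmm <- function(x, ...) {
  cat(sprintf("<channel_gmm> %d components, logLik %.2f (%d iterations)\n",
              nrow(x$components), x$log_likelihood, x$n_iterations))
  print(round(x$components, 3))
  invisible(x)
}

# Exact 1-D k-means by dynamic programming over the sorted points
# (globally optimal within-cluster sum of squares; deterministic).
kmeans_1d <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1L, k <= length(unique(x)))
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  sse <- function(i, j) { # within-SS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in seq_len(n)) D[1, j] <- sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      v <- D[m - 1, i - 1] + sse(i, j)
      if (v < D[m, j]) { D[m, j] <- v; B[m, j] <- i }
    }
  }
  # backtrack
  cl_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else B[m, j]
    cl_sorted[i:j] <- m
    j <- i - 1L
  }
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  centers <- vapply(seq_len(k), function(m) mean(x[cluster == m]), numeric(1))
  list(cluster = cluster, centers = centers, tot_withinss = D[k, n])
}

#' Derive a multi-class quantization scheme from per-channel GMMs
#'
#' The means of all Gaussian components across the three channels are
#' pooled as channel-tagged scalars and clustered into `K` groups by
#' exact one-dimensional k-means (dynamic programming over the sorted
#' means, globally optimal within-cluster sum of squares). Per-channel
#' thresholds are the midpoints between consecutive distinct cluster
#' centers projected onto that channel. Class centroids in RGB space are
#' initialized from the clustered component means and, when a pixel
#' sample is supplied, refined by Lloyd k-means iterations on it; pixels
#' are quantized by nearest RGB centroid.
#'
#' @param gmms list of three `channel_gmm` fits, in R, G, B order.
#' @param K number of quantization classes.
#' @param pixels optional n x 3 RGB pixel sample used to refine class
#'   centroids and estimate class pixel fractions.
#' @param seed RNG seed (the derivation itself is deterministic; kept for
#'   interface symmetry and provenance).
#' @return a `quantization_scheme`: `K`, `thresholds` (per channel),
#'   `centroids` (K x 3), `pixel_fraction`, `component_cluster` map.
#' @export
derive_thresholds <- function(gmms, K, pixels = NULL, seed = 1L) {
  stopifnot(length(gmms) == 3L)
  means <- unlist(lapply(gmms, function(g) g$components$mean))
  channel <- rep(c("R", "G", "B"), vapply(gmms, function(g)
    nrow(g$components), integer(1)))
  if (K > length(unique(means)))
    stop("K = ", K, " exceeds the ", length(unique(means)),
         " distinct component means")
  km <- kmeans_1d(means, K)
  ord <- order(km$centers)
  relabel <- match(seq_len(K), ord)  # clusters ordered by center
  cluster <- relabel[km$cluster]
  centers <- km$centers[ord]

  thresholds <- list()
  for (ci in 1:3) {
    ch <- c("R", "G", "B")[ci]
    proj <- vapply(seq_len(K), function(m) {
      sel <- cluster == m & channel == ch
      if (any(sel)) mean(means[sel]) else NA_real_
    }, numeric(1))
    pc <- sort(unique(proj[!is.na(proj)]))
    thresholds[[ch]] <- if (length(pc) > 1) (pc[-1] + pc[-length(pc)]) / 2
                        else numeric(0)
  }

  centroids <- t(vapply(seq_len(K), function(m) {
    vapply(c("R", "G", "B"), function(ch) {
      sel <- cluster == m & channel == ch
      if (any(sel)) mean(means[sel]) else centers[m]
    }, numeric(1))
  }, numeric(3)))
  colnames(centroids) <- c("R", "G", "B")

  frac <- rep(NA_real_, K)
  if (!is.null(pixels)) {
    pixels <- as.matrix(pixels)
    # Lloyd refinement from the component-mean initialization, guarded
    # against local optima by a few seeded restarts from random pixels;
    # the lowest within-cluster sum of squares wins (deterministic).
    best <- lloyd_kmeans(pixels, centroids)
    with_seed(child_seed(seed, 97L), {
      for (rs in 1:5) {
        cand <- lloyd_kmeans(pixels, kmeanspp_init(pixels, K))
        if (cand$wss < best$wss - 1e-9) best <- cand
      }
    })
    centroids <- best$centers
    # keep classes ordered by luminance so labels are stable
    ord2 <- order(luminance(centroids[, 1], centroids[, 2], centroids[, 3]))
    centroids <- centroids[ord2, , drop = FALSE]
    colnames(centroids) <- c("R", "G", "B")
    assign <- nearest_centroid(pixels, centroids)
    frac <- tabulate(assign, K) / nrow(pixels)
  }
  structure(list(K = K, thresholds = thresholds, centroids = centroids,
                 pixel_fraction = frac, cluster_centers = centers,
                 component_cluster = data.frame(channel = channel,
                                                mean = means,
                                                cluster = cluster),
                 seed = seed),
            class = "quantization_scheme")
}

#' @export
print.quantization_scheme <- function(x, ...) {
  cat(sprintf("<quantization_scheme> K = %d classes\n", x$K))
  cat("class centroids (RGB):\n")
  print(round(x$centroids, 1))
  invisible(x)
}

# k-means++ seeding: spread initial centers, covering separated blobs
# with high probability even when one blob is small.
kmeanspp_init <- function(pixels, K) {
  n <- nrow(pixels)
  centers <- pixels[sample.int(n, 1L), , drop = FALSE]
  d2 <- rowSums((pixels - centers[rep(1L, n), , drop = FALSE])^2)
  while (nrow(centers) < K) {
    pick <- sample.int(n, 1L, prob = pmax(d2, 1e-12))
    centers <- rbind(centers, pixels[pick, , drop = FALSE])
    nd <- rowSums((pixels - pixels[rep(pick, n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

lloyd_kmeans <- function(pixels, centers, max_iter = 30L) {
  K <- nrow(centers)
  for (it in seq_len(max_iter)) {
    assign <- nearest_centroid(pixels, centers)
    newc <- centers
    for (m in seq_len(K)) {
      sel <- assign == m
      if (any(sel)) newc[m, ] <- colMeans(pixels[sel, , drop = FALSE])
    }
    if (max(abs(newc - centers)) < 1e-8) { centers <- newc; break }
    centers <- newc
  }
  assign <- nearest_centroid(pixels, centers)
  wss <- sum((pixels - centers[assign, , drop = FALSE])^2)
  list(centers = centers, wss = wss)
}

nearest_centroid <- function(pixels, centroids) {
  d <- matrix(0, nrow(pixels), nrow(centroids))
  for (m in seq_len(nrow(centroids)))
    d[, m] <- (pixels[, 1] - centroids[m, 1])^2 +
      (pixels[, 2] - centroids[m, 2])^2 +
      (pixels[, 3] - centroids[m, 3])^2
  max.col(-d, ties.method = "first")
}

#' Quantize a tile into K classes by nearest class centroid
#'
#' Idempotent: re-quantizing an image repainted with its class centroid
#' colors reproduces the same labels.
#'
#' @param tile an [rgb_tile()].
#' @param scheme a `quantization_scheme` from [derive_thresholds()].
#' @return integer H x W class-label matrix (1..K).
#' @export
quantize <- function(tile, scheme) {
  stopifnot(inherits(tile, "rgb_tile"), inherits(scheme, "quantization_scheme"))
  d <- dim(tile$pixels)
  px <- matrix(as.numeric(tile$pixels), d[1] * d[2], 3)
  matrix(nearest_centroid(px, scheme$centroids), d[1], d[2])
}

#' Dunn cluster-validity index
#'
#' Ratio of the minimum inter-cluster point-to-point distance to the
#' maximum intra-cluster diameter (Euclidean). Larger is better. When
#' every cluster is a singleton the diameter is zero and `Inf` is
#' returned as the degenerate sentinel.
#'
#' @param points n x d numeric matrix (or vector, treated as 1-D).
#' @param labels integer cluster labels, at least 2 non-empty clusters.
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  dunn_from_dm(as.matrix(stats::dist(points)), labels)
}

dunn_from_dm <- function(dm, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("dunn_index requires at least 2 clusters")
  max_diam <- 0
  for (m in seq_len(k)) {
    sel <- labels == m
    if (sum(sel) > 1) max_diam <- max(max_diam, max(dm[sel, sel]))
  }
  min_sep <- Inf
  for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
    sa <- labels == a; sb <- labels == b
    min_sep <- min(min_sep, min(dm[sa, sb]))
  }
  if (max_diam == 0) return(Inf)
  min_sep / max_diam
}

#' Default semantic color prototypes
#'
#' Reference RGB colors of the four H&E semantic classes used by
#' [annotate_segments()]: hematoxylin-dark nuclei, intermediate purple
#' cytoplasm, eosin-pink stroma, and near-white background ("other").
#' These are configuration, not a hard rule; override to match a stain
#' protocol.
#'
#' @export
default_semantic_prototypes <- function() {
  rbind(nucleus = c(70, 50, 120),
        cytoplasm = c(150, 100, 200),
        stroma = c(228, 140, 160),
        other = c(245, 242, 245))
}

#' Annotate quantization classes into semantic tissue classes
#'
#' Each quantization class is mapped to the semantic class whose color
#' prototype is nearest (Euclidean, RGB) to the class centroid. The
#' class-to-semantic mapping is returned as provenance.
#'
#' @param class_labels integer label matrix from [quantize()].
#' @param scheme the `quantization_scheme` used.
#' @param prototypes 4 x 3 semantic prototype matrix with rownames
#'   nucleus, cytoplasm, stroma, other.
#' @return a `semantic_map`: [label_mask()] over codes 1 nucleus /
#'   2 cytoplasm / 3 stroma / 4 other, with attribute `provenance`.
#' @export
annotate_segments <- function(class_labels, scheme,
                              prototypes = default_semantic_prototypes()) {
  sem_names <- rownames(prototypes)
  mapping <- nearest_centroid(scheme$centroids, prototypes)
  labels <- matrix(mapping[class_labels], nrow(class_labels),
                   ncol(class_labels))
  mm <- label_mask(labels, stats::setNames(sem_names, seq_along(sem_names)))
  attr(mm, "provenance") <- data.frame(
    quant_class = seq_len(scheme$K),
    semantic = sem_names[mapping],
    centroid_R = scheme$centroids[, 1],
    centroid_G = scheme$centroids[, 2],
    centroid_B = scheme$centroids[, 3])
  class(mm) <- c("semantic_map", class(mm))
  mm
}

#' Select the number of quantization classes by the Dunn criterion
#'
#' For each K in `K_range` a scheme is derived from the per-channel GMMs,
#' a uniform pixel subsample is quantized, and the Dunn index of the
#' resulting RGB clusters is computed; the K with the largest Dunn index
#' wins, ties broken toward the smallest K (parsimony).
#'
#' @param tile an [rgb_tile()].
#' @param K_range candidate class counts (within 2..10).
#' @param subsample_size pixels used for Dunn scoring (>= 1000; the full
#'   image would be quadratic in n).
#' @param seed run seed (subsampling and GMM fitting).
#' @param n_components GMM components per channel.
#' @param gmm_sample intensity sample size per channel for EM.
#' @return list: `K` (selected), `scheme` (for the selected K),
#'   `dunn` (named vector over K_range), `gmms`.
#' @export
select_num_classes <- function(tile, K_range = 3:8, subsample_size = 2000L,
                               seed = 1L, n_components = 4L,
                               gmm_sample = 6000L) {
  stopifnot(all(K_range >= 2L), all(K_range <= 10L), subsample_size >= 1000L)
  d <- dim(tile$pixels)
  n_px <- d[1] * d[2]
  px <- matrix(as.numeric(tile$pixels), n_px, 3)
  with_seed(seed, {
    gmm_idx <- sample.int(n_px, min(gmm_sample, n_px))
    gmms <- lapply(1:3, function(ch)
      fit_channel_gmm(px[gmm_idx, ch], n_components, tol = 1e-4,
                      max_iter = 80L, seed = child_seed(seed, ch)))
    sub_idx <- sample.int(n_px, min(subsample_size, n_px))
    sub <- px[sub_idx, , drop = FALSE]
    dm <- as.matrix(stats::dist(sub))   # shared across candidate K
    dunn <- stats::setNames(rep(NA_real_, length(K_range)), K_range)
    schemes <- vector("list", length(K_range))
    for (i in seq_along(K_range)) {
      K <- K_range[i]
      sc <- tryCatch(derive_thresholds(gmms, K, pixels = sub, seed = seed),
                     error = function(e) NULL)
      if (is.null(sc)) next
      lab <- nearest_centroid(sub, sc$centroids)
      if (length(unique(lab)) < 2L) next
      dunn[i] <- dunn_from_dm(dm, lab)
      schemes[[i]] <- sc
    }
    if (all(is.na(dunn))) stop("no candidate K produced >= 2 clusters")
    best <- which(dunn == max(dunn, na.rm = TRUE))[1L]  # ties -> smallest K
    list(K = K_range[best], scheme = schemes[[best]], dunn = dunn,
         gmms = gmms)
  })
}
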