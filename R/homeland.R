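#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted samples containing
#' `ceiling(level * n)` points; ties resolved toward the earliest window.
#'
#' @param samples numeric vector (>= 2 values).
#' @param level mass fraction in (0, 1).
#' @return named numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")
  x <- sort(samples)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  m <- ceiling(level * n)
  if (m >= n) return(c(low = x[1], high = x[n]))
  widths <- x[seq.int(m, n)] - x[seq.int(1, n - m + 1)]
  i <- which.min(widths)  # which.min takes the first (earliest) minimum
  c(low = x[i], high = x[i + m - 1])
}

#' Maximum clade credibility tree
#'
#' Scores every post-burn-in sampled tree by the sum over its internal
#' clades of log posterior clade frequencies and returns the best one,
#' re-annotated with per-clade summaries: posterior support, median height
#' (node heights are replaced by the posterior medians, clamped to keep
#' parents older than children), 95% height HPD, and the median sampled
#' location of the clade's ancestor.
#'
#' @param trace a `lexigeo_trace`.
#' @return list of class `mcc_summary`: `tree` (annotated [time_tree()]),
#'   `support` (per-node posterior clade probability), `height_hpd`
#'   (2-column matrix), `log_clade_score` of the winning topology, and a
#'   per-internal-node tibble.
#' @export
mcc_tree <- function(trace) {
  keep <- trace_keep(trace)
  trees <- trace$trees[keep]
  if (!length(trees)) stop("no post-burn-in trees in trace")
  n <- trees[[1]]$n_tips
  nn <- 2L * n - 1L
  # clade frequencies over the sample (bitmask keys)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  heights <- new.env(hash = TRUE, parent = emptyenv())
  lats <- new.env(hash = TRUE, parent = emptyenv())
  lons <- new.env(hash = TRUE, parent = emptyenv())
  clade_keys <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tt <- trees[[i]]
    keys <- sprintf("%.0f", tt_clades(tt)[(n + 1):nn])
    clade_keys[[i]] <- keys
    for (j in seq_along(keys)) {
      k <- keys[j]
      v <- n + j
      counts[[k]] <- (counts[[k]] %||% 0) + 1
      heights[[k]] <- c(heights[[k]], tt$height[v])
      if (is.finite(tt$location[v, 1])) {
        lats[[k]] <- c(lats[[k]], tt$location[v, 1])
        lons[[k]] <- c(lons[[k]], tt$location[v, 2])
      }
    }
  }
  nt <- length(trees)
  score <- vapply(clade_keys, function(keys) {
    sum(log(vapply(keys, function(k) counts[[k]], 1) / nt))
  }, 1)
  best <- which.max(score)
  tt <- trees[[best]]
  keys <- clade_keys[[best]]
  support <- rep(1, nn)
  hpd <- matrix(NA_real_, nn, 2, dimnames = list(NULL, c("low", "high")))
  for (j in seq_along(keys)) {
    v <- n + j
    k <- keys[j]
    support[v] <- counts[[k]] / nt
    hs <- heights[[k]]
    tt$height[v] <- stats::median(hs)
    if (length(hs) >= 2) hpd[v, ] <- hpd_interval(hs, 0.95)
    if (!is.null(lats[[k]])) {
      tt$location[v, ] <- c(stats::median(lats[[k]]), stats::median(lons[[k]]))
    }
  }
  # clamp so parents stay older than children (medians can cross)
  for (v in order(tt$height[(n + 1):nn]) + n) {
    kids <- which(!is.na(tt$parent) & tt$parent == v)
    mx <- max(tt$height[kids])
    if (tt$height[v] <= mx) tt$height[v] <- mx + 1e-9
  }
  internal <- (n + 1):nn
  structure(list(
    tree = tt, support = support, height_hpd = hpd,
    log_clade_score = score[best],
    nodes = tibble::tibble(
      node = internal, support = support[internal],
      height_median = tt$height[internal],
      height_hpd_low = hpd[internal, 1], height_hpd_high = hpd[internal, 2],
      lat = tt$location[internal, 1], lon = tt$location[internal, 2])),
    class = "mcc_summary")
}

#' @export
print.mcc_summary <- function(x, ...) {
  root <- tt_root(x$tree)
  cat(sprintf("<mcc_summary> %d tips; root %.0f BP (95%% HPD %.0f-%.0f), support %.2f\n",
              x$tree$n_tips, x$tree$height[root],
              x$height_hpd[root, 1], x$height_hpd[root, 2], x$support[root]))
  invisible(x)
}

# root (or clade-MRCA) location samples from a trace
trace_node_locations <- function(trace, node_selector = NULL) {
  keep <- trace_keep(trace)
  out <- t(vapply(trace$trees[keep], function(tt) {
    v <- if (is.null(node_selector)) tt_root(tt) else tt_mrca(tt, node_selector)
    tt$location[v, ]
  }, numeric(2)))
  colnames(out) <- c("lat", "lon")
  out[is.finite(out[, 1]) & is.finite(out[, 2]), , drop = FALSE]
}

#' Highest-posterior-density location polygon
#'
#' Kernel density estimate of an ancestral node's sampled locations on a
#' regular grid (plug-in bandwidth unless given), restricted to the land
#' mask; the polygon is the highest-density region holding `level` of the
#' (land-restricted) posterior mass, extracted as contour rings.
#'
#' @param trace a `lexigeo_trace`.
#' @param node_selector `NULL` for the root, or a character vector of taxa
#'   whose MRCA is summarized (found per sampled tree).
#' @param level mass fraction (default 0.80).
#' @param grid_resolution grid cell size in degrees (default 0.02).
#' @param mask optional [land_mask()] to intersect with.
#' @param bandwidth optional 2-vector of KDE bandwidths (lat, lon).
#' @return object of class `hpd_polygon`: `level`, `rings` (list of (lon,
#'   lat) matrices), `node`, `samples`, plus the grid threshold.
#' @export
location_hpd_polygon <- function(trace, node_selector = NULL, level = 0.80,
                                 grid_resolution = 0.02, mask = NULL,
                                 bandwidth = NULL) {
  pts <- trace_node_locations(trace, node_selector)
  hpd_polygon_from_points(pts, level = level,
                          grid_resolution = grid_resolution,
                          mask = mask, bandwidth = bandwidth,
                          node = if (is.null(node_selector)) "root"
                                 else paste(node_selector, collapse = "+"))
}

# shared by location_hpd_polygon and the randomization pooling
hpd_polygon_from_points <- function(pts, level = 0.80, grid_resolution = 0.02,
                                    mask = NULL, bandwidth = NULL,
                                    node = "root") {
  if (nrow(pts) < 10) stop("need at least 10 location samples")
  lat <- pts[, 1]; lon <- pts[, 2]
  bw <- bandwidth %||% c(stats::bw.nrd0(lat), stats::bw.nrd0(lon))
  bw[bw <= 0] <- grid_resolution
  pad <- 4 * max(bw)
  rlat <- range(lat) + c(-pad, pad)
  rlon <- range(lon) + c(-pad, pad)
  nlat <- max(20, min(400, ceiling(diff(rlat) / grid_resolution)))
  nlon <- max(20, min(400, ceiling(diff(rlon) / grid_resolution)))
  kd <- MASS::kde2d(lon, lat, h = c(bw[2], bw[1]) * 4, n = c(nlon, nlat),
                    lims = c(rlon, rlat))
  z <- kd$z
  if (!is.null(mask)) {
    on_land <- outer(seq_along(kd$x), seq_along(kd$y), Vectorize(function(i, j) {
      point_in_rings(kd$x[i], kd$y[j], mask$rings)
    }))
    z <- z * on_land
  }
  if (sum(z) == 0) stop("no posterior mass on land at this grid resolution")
  p <- z / sum(z)
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  thr_idx <- which(cum >= level)[1]
  thr <- p[ord][thr_idx] * sum(z)  # back to density scale
  cl <- grDevices::contourLines(kd$x, kd$y, z, levels = max(thr, 1e-300))
  rings <- lapply(cl, function(c_) cbind(lon = c_$x, lat = c_$y))
  if (!length(rings)) {
    # degenerate (all samples nearly identical): tiny box around the mode
    i <- which(z == max(z), arr.ind = TRUE)[1, ]
    cx <- kd$x[i[1]]; cy <- kd$y[i[2]]
    e <- grid_resolution
    rings <- list(cbind(lon = cx + c(-e, e, e, -e), lat = cy + c(-e, -e, e, e)))
  }
  structure(list(level = level, rings = rings, node = node,
                 samples = pts, threshold = thr, bandwidth = bw),
            class = "hpd_polygon")
}

#' @export
print.hpd_polygon <- function(x, ...) {
  cat(sprintf("<hpd_polygon> %.0f%% HPD for %s: %d ring(s), area %.3f deg^2\n",
              100 * x$level, x$node, length(x$rings), hpd_polygon_area(x)))
  invisible(x)
}

#' Area of an HPD polygon (square degrees, even-odd rule)
#' @param poly an `hpd_polygon`.
#' @export
hpd_polygon_area <- function(poly) {
  sum(vapply(poly$rings, function(r) abs(ring_area_centroid(r)$area), 1))
}

#' Is a point inside an HPD polygon?
#' @param poly an `hpd_polygon`.
#' @param p point `c(lat, lon)`.
#' @export
point_in_hpd <- function(poly, p) point_in_rings(p[2], p[1], poly$rings)

#' Write HPD polygons as a GeoJSON FeatureCollection
#' @param polys an `hpd_polygon` or list of them.
#' @param path output path.
#' @param ages optional vector of `median_age_BP` properties.
#' @export
write_hpd_geojson <- function(polys, path, ages = NULL) {
  if (inherits(polys, "hpd_polygon")) polys <- list(polys)
  feats <- lapply(seq_along(polys), function(i) {
    poly <- polys[[i]]
    coords <- lapply(poly$rings, function(r) {
      rr <- rbind(r, r[1, ])
      lapply(seq_len(nrow(rr)), function(k) c(rr[k, 1], rr[k, 2]))
    })
    props <- list(level = poly$level, node = poly$node)
    if (!is.null(ages)) props$median_age_BP <- ages[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' North/south region split
#'
#' @param boundary_lat latitude of the east-west boundary; conventionally
#'   the area centroid of the focal landmass polygon (see
#'   [region_split_from_mask()]).
#' @export
region_split <- function(boundary_lat) {
  structure(list(boundary_lat = boundary_lat), class = "region_split")
}

#' @rdname region_split
#' @param mask a [land_mask()].
#' @param ring index of the polygon whose centroid defines the boundary
#'   (default 1, the first/primary landmass).
#' @export
region_split_from_mask <- function(mask, ring = 1) {
  ac <- ring_area_centroid(mask$rings[[ring]])
  region_split(boundary_lat = ac$centroid[2])
}

#' Bayes factor for a northern vs southern homeland
#'
#' Posterior-to-prior odds ratio of the root location falling north of the
#' boundary: `BF = [P(north|data)/P(south|data)] / [P(north)/P(south)]`,
#' with probabilities estimated as sample fractions from a posterior and a
#' prior-only trace. A Monte-Carlo standard error for log BF comes from the
#' binomial approximation `1/a + 1/b + 1/c + 1/d`. If the posterior puts no
#' samples in one region, a one-sided bound at one pseudo-count is returned
#' and flagged.
#'
#' @param trace posterior `lexigeo_trace`.
#' @param prior_trace prior-only trace (same mask; e.g. [mcmc_run()] with
#'   `beta = 0`).
#' @param split a [region_split()].
#' @param within optional polygon ring (matrix of (lon, lat)) restricting
#'   the comparison to root samples inside it -- e.g. the focal landmass
#'   when the north/south division concerns that island only; samples
#'   elsewhere belong to neither region and are dropped from both traces.
#' @return list: `bf`, `log_bf_se`, counts, `bound` (TRUE when one-sided).
#' @export
homeland_region_bf <- function(trace, prior_trace, split, within = NULL) {
  post <- trace_node_locations(trace)
  prior <- trace_node_locations(prior_trace)
  if (!is.null(within)) {
    keep_in <- function(m) {
      m[apply(m, 1, function(p) point_in_rings(p[2], p[1], list(within))), ,
        drop = FALSE]
    }
    post <- keep_in(post)
    prior <- keep_in(prior)
  }
  a <- sum(post[, 1] > split$boundary_lat); b <- nrow(post) - a
  c_ <- sum(prior[, 1] > split$boundary_lat); d <- nrow(prior) - c_
  if (c_ == 0 || d == 0) stop("prior trace has an empty region; cannot form odds")
  bound <- FALSE
  if (a == 0 || b == 0) {
    a <- max(a, 1); b <- max(b, 1)
    bound <- TRUE
  }
  bf <- (a / b) / (c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(bf = bf, log_bf_se = se,
       posterior_north = a, posterior_south = b,
       prior_north = c_, prior_south = d, bound = bound)
}

#' Tip-location randomization control
#'
#' Re-runs the geographic inference after randomly permuting the assignment
#' of coordinates to varieties, `n_reps` times, with the arbitrary root
#' calibration N(1500 BP, sd 400) replacing the data-driven one -- the
#' control for "does the diffusion model just return the center of mass".
#' Root-location samples are collected per replicate and pooled (equal
#' weight per replicate) into a 90% HPD polygon.
#'
#' @inheritParams mcmc_run
#' @param n_reps number of random reassignments (>= 1; 50 in the standard
#'   design).
#' @param seed seed for the permutation sequence (replicate chains use
#'   `seed + replicate`).
#' @param level pooled HPD level (default 0.90).
#' @param root_calibration calibration applied to the root in every
#'   replicate.
#' @return list: `replicates` (list of per-replicate root-sample matrices),
#'   `permutations`, `pooled_hpd` (an `hpd_polygon`), `n_failed`.
#' @export
randomization_control <- function(m, geo, mask, config, n_reps = 50,
                                  seed = 1, level = 0.90,
                                  root_calibration = calibration_prior(
                                    m$taxa, mean = 1500, sd = 400)) {
  stopifnot(n_reps >= 1)
  perms <- withr_seed(seed, {
    lapply(seq_len(n_reps), function(i) sample.int(nrow(geo)))
  })
  reps <- vector("list", n_reps)
  failed <- 0L
  for (i in seq_len(n_reps)) {
    g2 <- geo
    g2$lat <- geo$lat[perms[[i]]]
    g2$lon <- geo$lon[perms[[i]]]
    cfg <- config
    cfg$calibration <- root_calibration
    cfg$seed <- seed + i
    res <- tryCatch(mcmc_run(m, g2, mask, cfg), error = function(e) {
      message("replicate ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { failed <- failed + 1L; next }
    reps[[i]] <- trace_node_locations(res)
  }
  ok <- !vapply(reps, is.null, TRUE)
  if (!any(ok)) stop("all randomization replicates failed")
  # equal weight per replicate: subsample each to the smallest count
  nmin <- min(vapply(reps[ok], nrow, 1L))
  pooled <- do.call(rbind, lapply(reps[ok], function(r) r[seq_len(nmin), , drop = FALSE]))
  pooled_hpd <- hpd_polygon_from_points(pooled, level = level, mask = mask,
                                        node = "root (randomized tips)")
  list(replicates = reps, permutations = perms, pooled_hpd = pooled_hpd,
       n_failed = failed)
}
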