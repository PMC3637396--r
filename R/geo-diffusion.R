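#' Land masks
#'
#' A `land_mask` is a set of polygon rings in (lon, lat) decimal degrees.
#' Rings use the even-odd rule, so a ring nested inside another is a hole
#' (a lake); a point is on land when it falls inside an odd number of rings.
#' Boundary points count as land.
#'
#' @param rings list of numeric matrices, each with columns (lon, lat);
#'   rings need not repeat the first vertex.
#' @return An object of class `land_mask`.
#' @export
land_mask <- function(rings) {
  stopifnot(is.list(rings), length(rings) >= 1)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    # drop a duplicated closing vertex; point_in_rings closes implicitly
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    colnames(r) <- c("lon", "lat")
    r
  })
  structure(list(rings = rings), class = "land_mask")
}

#' @export
print.land_mask <- function(x, ...) {
  bb <- mask_bbox(x)
  cat(sprintf("<land_mask> %d ring(s), bbox lon [%.2f, %.2f] lat [%.2f, %.2f]\n",
              length(x$rings), bb[1], bb[2], bb[3], bb[4]))
  invisible(x)
}

mask_bbox <- function(mask) {
  lon <- unlist(lapply(mask$rings, function(r) r[, 1]))
  lat <- unlist(lapply(mask$rings, function(r) r[, 2]))
  c(min(lon), max(lon), min(lat), max(lat))
}

#' Is a point on land?
#'
#' @param mask a [land_mask()].
#' @param p point as `c(lat, lon)` (the tip-coordinate convention).
#' @return `TRUE` iff the point is inside the mask (boundary included).
#' @export
point_on_land <- function(mask, p) {
  point_in_rings(p[2], p[1], mask$rings)
}

# area centroid of the mask (even-odd: holes subtract); returns c(lat, lon)
mask_centroid <- function(mask) {
  tot_a <- 0; cx <- 0; cy <- 0
  for (ring in mask$rings) {
    ac <- ring_area_centroid(ring)
    a <- abs(ac$area)
    # crude hole handling: a ring nested in another subtracts
    inside <- any(vapply(mask$rings, function(other) {
      !identical(other, ring) && point_in_rings(ring[1, 1], ring[1, 2], list(other))
    }, TRUE))
    sgn <- if (inside) -1 else 1
    tot_a <- tot_a + sgn * a
    cx <- cx + sgn * a * ac$centroid[1]
    cy <- cy + sgn * a * ac$centroid[2]
  }
  c(lat = cy / tot_a, lon = cx / tot_a)
}

#' Read / write a land mask as GeoJSON
#'
#' Accepts Polygon and MultiPolygon geometries (bare geometry, Feature, or
#' FeatureCollection). All rings are pooled; interior rings act as holes via
#' the even-odd rule.
#'
#' @param path GeoJSON file path.
#' @return A [land_mask()].
#' @export
read_land_mask <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  rings <- list()
  add_poly <- function(coords) {
    for (ring in coords) {
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      rings[[length(rings) + 1L]] <<- m
    }
  }
  walk <- function(obj) {
    type <- obj$type
    if (is.null(type)) return()
    switch(type,
      FeatureCollection = lapply(obj$features, walk),
      Feature = walk(obj$geometry),
      Polygon = add_poly(obj$coordinates),
      MultiPolygon = lapply(obj$coordinates, add_poly))
    invisible()
  }
  walk(g)
  if (!length(rings)) stop("no Polygon/MultiPolygon geometry in ", path)
  land_mask(rings)
}

#' @rdname read_land_mask
#' @param mask a [land_mask()].
#' @export
write_land_mask <- function(mask, path) {
  close_ring <- function(r) rbind(r, r[1, ])
  coords <- lapply(mask$rings, function(r) {
    lapply(seq_len(nrow(r) + 1), function(i) {
      rr <- close_ring(r)
      c(rr[i, 1], rr[i, 2])
    })
  })
  obj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "land"),
    geometry = list(type = "Polygon", coordinates = coords))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Diffusion models for the relaxed random walk
#'
#' Branch displacements are bivariate normal with covariance
#' \eqn{\Sigma \, t_b \, \phi_b}: base covariance `sigma` (degrees^2 per
#' year), branch duration, and a branch-specific scalar \eqn{\phi_b} drawn
#' i.i.d. from the chosen law. `"homogeneous"` fixes all scalars at 1
#' (plain Brownian motion); `"gamma"` and `"lognormal"` use mean-1 laws with
#' one free shape parameter; `"cauchy"` draws \eqn{\phi_b = 1/\gamma_b} with
#' \eqn{\gamma_b \sim} Gamma(1/2, rate 1/2), the inverse-gamma scale mixture
#' that makes marginal displacements bivariate-Cauchy-tailed.
#'
#' @param kind one of `"cauchy"`, `"gamma"`, `"lognormal"`, `"homogeneous"`.
#' @param sigma 2x2 symmetric positive-definite base covariance
#'   (degrees^2/year); a scalar is expanded to `diag(scalar, 2)`.
#' @param shape gamma shape, or lognormal log-sd, as applicable.
#' @return An object of class `diffusion_model`.
#' @export
diffusion_model <- function(kind = c("cauchy", "gamma", "lognormal", "homogeneous"),
                            sigma = diag(1e-5, 2), shape = 1) {
  kind <- match.arg(kind)
  if (length(sigma) == 1) sigma <- diag(as.numeric(sigma), 2)
  sigma <- as.matrix(sigma)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("sigma must be positive-definite")
  if (kind %in% c("gamma", "lognormal") && shape <= 0) stop("shape must be > 0")
  structure(list(kind = kind, sigma = sigma, shape = shape),
            class = "diffusion_model")
}

#' Draw branch diffusion scalars
#'
#' @param model a [diffusion_model()].
#' @param n_branches number of branches.
#' @param seed RNG seed.
#' @return numeric vector of scalars, mean 1 for gamma/lognormal, all 1 for
#'   homogeneous, heavy-tailed (undefined variance) for cauchy.
#' @export
draw_branch_scalars <- function(model, n_branches, seed = 1) {
  stopifnot(n_branches >= 1)
  withr_seed(seed, switch(model$kind,
    homogeneous = rep(1, n_branches),
    gamma = stats::rgamma(n_branches, shape = model$shape, rate = model$shape),
    lognormal = stats::rlnorm(n_branches, meanlog = -model$shape^2 / 2,
                              sdlog = model$shape),
    cauchy = 1 / stats::rgamma(n_branches, shape = 0.5, rate = 0.5)))
}

# log-density of the scalar law (for the MCMC prior); homogeneous/cauchy
# handled separately (point mass / gamma on 1/phi with Jacobian)
scalar_log_density <- function(model, phi) {
  switch(model$kind,
    homogeneous = 0,
    gamma = sum(stats::dgamma(phi, shape = model$shape, rate = model$shape,
                              log = TRUE)),
    lognormal = sum(stats::dlnorm(phi, meanlog = -model$shape^2 / 2,
                                  sdlog = model$shape, log = TRUE)),
    cauchy = {
      g <- 1 / phi
      sum(stats::dgamma(g, shape = 0.5, rate = 0.5, log = TRUE) - 2 * log(phi))
    })
}

#' Relaxed-random-walk log-likelihood of node locations
#'
#' Sum over branches of the bivariate normal log-density of the child-minus-
#' parent displacement (lat, lon) with covariance
#' \eqn{\Sigma \, t_b \, \phi_b}. Every node (tips and internal, except the
#' root, whose location is the starting point) must carry a location.
#' Coordinates are treated as planar degrees; at sub-10-degree spatial
#' scales the curvature correction is negligible.
#'
#' @param tt a [time_tree()] with `location` filled in and `diff_scalar`
#'   holding the branch scalars.
#' @param model a [diffusion_model()] (its `sigma` is used; scalars come
#'   from the tree).
#' @return log-density (scalar); `-Inf` if a branch has nonpositive duration
#'   but nonzero displacement.
#' @export
rrw_loglik <- function(tt, model) {
  p <- rrw_loglik_parts(tt, model)
  p[["tip"]] + p[["internal"]]
}

# split into the tip-branch part (the data term: observed coordinates) and
# the internal-branch part (latent ancestral locations); their sum is
# rrw_loglik. The MCMC powers only the tip part in power-posterior runs.
# Vectorized over branches: cov_b = sigma * c_b factorizes, so
# logdet_b = logdet(sigma) + 2 log c_b and q_b = d' sigma^{-1} d / c_b.
rrw_loglik_parts <- function(tt, model) {
  if (any(!is.finite(tt$location))) stop("every node needs a location")
  root <- tt_root(tt)
  n <- tt$n_tips
  child <- which(!is.na(tt$parent))
  d1 <- tt$location[child, 1] - tt$location[tt$parent[child], 1]
  d2 <- tt$location[child, 2] - tt$location[tt$parent[child], 2]
  cb <- (tt$height[tt$parent[child]] - tt$height[child]) *
    tt$diff_scalar[child]
  bad <- cb <= 0
  if (any(bad)) {
    if (any(d1[bad] != 0 | d2[bad] != 0)) {
      return(c(tip = -Inf, internal = -Inf))
    }
    d1 <- d1[!bad]; d2 <- d2[!bad]; child <- child[!bad]; cb <- cb[!bad]
  }
  s <- model$sigma
  det_s <- s[1, 1] * s[2, 2] - s[1, 2] * s[2, 1]
  i11 <- s[2, 2] / det_s; i22 <- s[1, 1] / det_s; i12 <- -s[1, 2] / det_s
  q <- d1^2 * i11 + 2 * d1 * d2 * i12 + d2^2 * i22
  ll <- -log(2 * pi) - 0.5 * (log(det_s) + 2 * log(cb)) - 0.5 * q / cb
  is_tip <- child <= n
  c(tip = sum(ll[is_tip]), internal = sum(ll[!is_tip]))
}
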