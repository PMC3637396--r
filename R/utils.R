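# Internal numerical helpers shared across modules.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Log-density of a bivariate normal with mean 0 and covariance `sigma` (2x2).
ldbvnorm <- function(d, sigma) {
  det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  if (!is.finite(det_s) || det_s <= 0) return(-Inf)
  inv11 <- sigma[2, 2] / det_s
  inv22 <- sigma[1, 1] / det_s
  inv12 <- -sigma[1, 2] / det_s
  q <- d[1]^2 * inv11 + 2 * d[1] * d[2] * inv12 + d[2]^2 * inv22
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

# Even-odd (crossing number) point-in-polygon over a list of rings.
# Rings are matrices with columns (lon, lat); a point inside an odd number of
# rings is "inside" overall, so holes fall out naturally. Boundary points are
# treated as inside by a small half-open convention plus an explicit edge test.
point_in_rings <- function(lon, lat, rings) {
  crossings <- 0L
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    nr <- length(x)
    j <- nr
    for (i in seq_len(nr)) {
      # exact boundary: vertex or on-segment
      if (on_segment(lon, lat, x[j], y[j], x[i], y[i])) return(TRUE)
      if ((y[i] > lat) != (y[j] > lat)) {
        xint <- x[j] + (lat - y[j]) * (x[i] - x[j]) / (y[i] - y[j])
        if (lon < xint) crossings <- crossings + 1L
      }
      j <- i
    }
  }
  (crossings %% 2L) == 1L
}

on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-12) {
  len2 <- (bx - ax)^2 + (by - ay)^2
  if (len2 <= eps) {  # degenerate edge (e.g. a duplicated closing vertex)
    return(abs(px - ax) <= eps && abs(py - ay) <= eps)
  }
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  if (abs(cross) > eps * max(1, abs(bx - ax), abs(by - ay))) return(FALSE)
  dot <- (px - ax) * (bx - ax) + (py - ay) * (by - ay)
  dot >= -eps && dot <= len2 + eps
}

# Shoelace area and centroid of a single ring (lon, lat), sign-aware.
ring_area_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    return(list(area = 0, centroid = c(mean(x), mean(y))))
  }
  cx <- sum((x[j] + x) * cr) / (6 * a)
  cy <- sum((y[j] + y) * cr) / (6 * a)
  list(area = a, centroid = c(cx, cy))
}

# Effective sample size by the initial positive sequence estimator
# (Geyer 1992), used for trace summaries only.
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[, 1, 1]
  s <- ac[1]
  k <- 2
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + 2 * pair
    k <- k + 2
  }
  max(1, n / max(s, 1))
}
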