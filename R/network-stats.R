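#' Quartet delta score
#'
#' Measures how tree-like a distance matrix is. For each quartet
#' \eqn{\{i,j,k,l\}} the three pairwise sums
#' \eqn{d_{ij}+d_{kl},\; d_{ik}+d_{jl},\; d_{il}+d_{jk}}
#' are ordered \eqn{m_1 \ge m_2 \ge m_3}; the quartet's score is
#' \eqn{\delta = (m_1-m_2)/(m_1-m_3)}, with \eqn{\delta = 0} when
#' \eqn{m_1 = m_3} (a perfectly unresolved but consistent quartet, the
#' additive-limit convention). On any additive (tree) metric the four-point
#' condition forces \eqn{m_1 = m_2}, so the score is 0; values near 0 indicate
#' tree-like evolution, values toward 1 heavy conflict.
#'
#' All \eqn{\binom{n}{4}} quartets are enumerated exhaustively up to
#' `max_exhaustive` taxa; beyond that a seeded random subsample of quartets
#' is scored.
#'
#' @param d symmetric distance matrix (or a `lexical_distance`, whose
#'   `$distance` is used), finite, nonnegative, zero diagonal.
#' @param max_exhaustive largest n for exhaustive enumeration (default 25).
#' @param n_sample number of quartets sampled when n exceeds `max_exhaustive`.
#' @param seed RNG seed for the subsampled regime.
#' @return A list of class `treelikeness_score`: `mean` (the average delta),
#'   `per_taxon` (named vector of per-taxon averages over quartets containing
#'   the taxon), `n_quartets`.
#' @export
delta_score <- function(d, max_exhaustive = 25, n_sample = 20000, seed = 1) {
  d <- as_dist_matrix(d)
  qs <- quartet_stats(d, max_exhaustive, n_sample, seed)
  m1 <- qs$m[, 1]; m2 <- qs$m[, 2]; m3 <- qs$m[, 3]
  delta <- ifelse(m1 - m3 <= 0, 0, (m1 - m2) / (m1 - m3))
  per_taxon <- per_taxon_mean(delta, qs$quartets, rownames(d))
  structure(list(mean = mean(delta), per_taxon = per_taxon,
                 n_quartets = length(delta), statistic = "delta"),
            class = "treelikeness_score")
}

#' Quartet Q-residual score
#'
#' Companion statistic to [delta_score()]: the matrix is first normalized by
#' its mean off-diagonal distance (making the score scale-free), then each
#' quartet contributes \eqn{(m_1-m_2)^2}; the score is the mean over
#' quartets. 0 on any additive metric.
#'
#' @inheritParams delta_score
#' @return A `treelikeness_score` (statistic = "qres").
#' @export
q_residual <- function(d, max_exhaustive = 25, n_sample = 20000, seed = 1) {
  d <- as_dist_matrix(d)
  off <- d[upper.tri(d)]
  if (all(off == 0)) stop("all distances zero: Q-residual normalization undefined")
  d <- d / mean(off)
  qs <- quartet_stats(d, max_exhaustive, n_sample, seed)
  qres <- (qs$m[, 1] - qs$m[, 2])^2
  per_taxon <- per_taxon_mean(qres, qs$quartets, rownames(d))
  structure(list(mean = mean(qres), per_taxon = per_taxon,
                 n_quartets = length(qres), statistic = "qres"),
            class = "treelikeness_score")
}

#' @export
print.treelikeness_score <- function(x, ...) {
  cat(sprintf("<treelikeness_score> average %s = %.4g over %d quartets\n",
              if (x$statistic == "delta") "delta score" else "Q-residual",
              x$mean, x$n_quartets))
  invisible(x)
}

as_dist_matrix <- function(d) {
  if (inherits(d, "lexical_distance")) d <- d$distance
  d <- as.matrix(d)
  if (nrow(d) < 4) stop("need at least 4 taxa")
  if (any(!is.finite(d))) stop("distances must be finite (undefined pairs?)")
  if (any(d < 0)) stop("negative distance")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  d
}

# The three quartet sums for each enumerated/sampled quartet, sorted
# descending per row.
quartet_stats <- function(d, max_exhaustive, n_sample, seed) {
  n <- nrow(d)
  if (n <= max_exhaustive) {
    q <- utils::combn(n, 4)
  } else {
    q <- withr_seed(seed, {
      replicate(n_sample, sort(sample.int(n, 4)))
    })
  }
  i <- q[1, ]; j <- q[2, ]; k <- q[3, ]; l <- q[4, ]
  s1 <- d[cbind(i, j)] + d[cbind(k, l)]
  s2 <- d[cbind(i, k)] + d[cbind(j, l)]
  s3 <- d[cbind(i, l)] + d[cbind(j, k)]
  m <- t(apply(cbind(s1, s2, s3), 1, sort, decreasing = TRUE))
  list(m = m, quartets = t(q))
}

per_taxon_mean <- function(score, quartets, taxa) {
  n <- length(taxa)
  tot <- numeric(n); cnt <- numeric(n)
  for (c in 1:4) {
    tot <- tot + as.vector(tapply(score, factor(quartets[, c], levels = 1:n), sum, default = 0))
    cnt <- cnt + as.vector(table(factor(quartets[, c], levels = 1:n)))
  }
  out <- ifelse(cnt > 0, tot / cnt, NA_real_)
  names(out) <- taxa
  out
}

# run expr under a local RNG seed without touching the global stream state;
# `seed` is forced first so computing it (e.g. from the global stream) is
# not undone by the restore
withr_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Swadesh-criterion mutual intelligibility estimate
#'
#' Treats two varieties as mutually intelligible when they share at least
#' `threshold` (default 90%) of their basic vocabulary. For each variety the
#' fraction of other varieties above threshold is computed; the headline
#' number is the mean of those fractions -- "with how much of the speech
#' community can a speaker communicate at a time".
#'
#' @param s symmetric similarity matrix in `[0,1]` (or a `lexical_distance`,
#'   whose `$similarity` is used).
#' @param threshold sharing fraction above which a pair counts as
#'   intelligible (default 0.90).
#' @return List with `mean` (overall fraction) and `per_taxon` tibble.
#' @export
intelligibility_estimate <- function(s, threshold = 0.90) {
  if (inherits(s, "lexical_distance")) s <- s$similarity
  s <- as.matrix(s)
  n <- nrow(s)
  if (n < 2) stop("need at least 2 taxa")
  if (any(s < 0 | s > 1, na.rm = TRUE)) stop("similarities must lie in [0,1]")
  diag(s) <- NA
  per <- rowMeans(s >= threshold, na.rm = TRUE)
  taxa <- rownames(s) %||% paste0("t", seq_len(n))
  list(mean = mean(per),
       per_taxon = tibble::tibble(taxon = taxa, fraction_intelligible = unname(per)))
}
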