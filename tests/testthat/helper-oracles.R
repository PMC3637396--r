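# Independent oracle implementations used to validate the package's fast
# likelihood code. These deliberately share no code with R/: integrals are
# done on a numerical grid and tree recursions are written from the model
# definition directly.

# -- small hand-built trees ---------------------------------------------------

two_tip_tree <- function(T_root = 700, labels = c("A", "B")) {
  time_tree(labels, parent = c(3L, 3L, NA), height = c(0, 0, T_root))
}

three_tip_tree <- function() {
  # ((A:400,B:400):600,C:1000)
  time_tree(c("A", "B", "C"), parent = c(4L, 4L, 5L, 5L, NA),
            height = c(0, 0, 0, 400, 1000))
}

four_tip_tree <- function() {
  # ((A:300,B:300):500,(C:450,D:450):350)
  time_tree(c("A", "B", "C", "D"),
            parent = c(5L, 5L, 6L, 6L, 7L, 7L, NA),
            height = c(0, 0, 0, 0, 300, 450, 800))
}

# -- stochastic Dollo oracle --------------------------------------------------

# P(tip pattern | cognate alive at node v), by explicit recursion over the
# two-state death chain written from the model definition
oracle_subtree_alive <- function(tt, mu, pattern, v) {
  n <- tt$n_tips
  if (v <= n) {
    x <- pattern[v]
    if (is.na(x)) return(1)
    return(as.numeric(x == 1))
  }
  kids <- which(!is.na(tt$parent) & tt$parent == v)
  out <- 1
  for (k in kids) {
    tb <- (tt$height[v] - tt$height[k]) * tt$clock_rate[k]
    ps <- exp(-mu * tb)
    dead_ok <- oracle_all_absent(tt, pattern, k)
    out <- out * (ps * oracle_subtree_alive(tt, mu, pattern, k) +
                    (1 - ps) * dead_ok)
  }
  out
}

oracle_all_absent <- function(tt, pattern, v) {
  n <- tt$n_tips
  tips <- if (v <= n) v else {
    below <- c()
    stack <- v
    while (length(stack)) {
      w <- stack[1]; stack <- stack[-1]
      if (w <= n) below <- c(below, w)
      else stack <- c(stack, which(!is.na(tt$parent) & tt$parent == w))
    }
    below
  }
  as.numeric(all(is.na(pattern[tips]) | pattern[tips] == 0))
}

# birth-placement integral by fine-grid Simpson quadrature on every branch
# (and the stem); the independent counterpart of dollo_integral
oracle_dollo_integral <- function(tt, mu, pattern, stem_factor = 1,
                                  n_grid = 2000) {
  n <- tt$n_tips
  nn <- 2L * n - 1L
  root <- which(is.na(tt$parent))
  simpson <- function(f, a, b, m) {
    if (m %% 2 == 1) m <- m + 1
    x <- seq(a, b, length.out = m + 1)
    w <- c(1, rep(c(4, 2), length.out = m - 1), 1)
    sum(w * vapply(x, f, 1)) * (b - a) / (3 * m)
  }
  total <- 0
  for (v in seq_len(nn)) {
    if (v == root) next
    Tb <- tt$height[tt$parent[v]] - tt$height[v]
    r <- mu * tt$clock_rate[v]
    outside_tips <- setdiff(seq_len(n), {
      below <- c(); stack <- v
      while (length(stack)) {
        w <- stack[1]; stack <- stack[-1]
        if (w <= n) below <- c(below, w)
        else stack <- c(stack, which(!is.na(tt$parent) & tt$parent == w))
      }
      below
    })
    if (!all(is.na(pattern[outside_tips]) | pattern[outside_tips] == 0)) next
    Sa <- oracle_subtree_alive(tt, mu, pattern, v)
    Sd <- oracle_all_absent(tt, pattern, v)
    f <- function(u) exp(-r * u) * Sa + (1 - exp(-r * u)) * Sd
    total <- total + simpson(f, 0, Tb, n_grid)
  }
  stem <- tt$height[root] * stem_factor
  if (stem > 0) {
    Sa <- oracle_subtree_alive(tt, mu, pattern, root)
    Sd <- oracle_all_absent(tt, pattern, root)
    f <- function(u) exp(-mu * u) * Sa + (1 - exp(-mu * u)) * Sd
    total <- total + simpson(f, 0, stem, n_grid)
  }
  total
}

oracle_dollo_matrix_loglik <- function(tt, mu, states, stem_factor = 1,
                                       n_grid = 2000) {
  n <- tt$n_tips
  root <- which(is.na(tt$parent))
  dur <- tt$height[tt$parent] - tt$height
  L_tot <- sum(dur[-root], na.rm = TRUE) + tt$height[root] * stem_factor
  I0 <- oracle_dollo_integral(tt, mu, rep(0L, n), stem_factor, n_grid)
  ll <- 0
  for (k in seq_len(ncol(states))) {
    ll <- ll + log(oracle_dollo_integral(tt, mu, states[, k], stem_factor,
                                         n_grid))
  }
  ll - ncol(states) * log(L_tot - I0)
}

# -- dense multivariate-normal RRW oracle -------------------------------------

# joint density of all non-root node locations as one big MVN built from
# shared root-path variances
oracle_rrw_loglik <- function(tt, sigma) {
  nn <- length(tt$parent)
  root <- which(is.na(tt$parent))
  nonroot <- setdiff(seq_len(nn), root)
  path <- function(v) {
    out <- c()
    while (!is.na(tt$parent[v])) { out <- c(out, v); v <- tt$parent[v] }
    out
  }
  bvar <- (tt$height[tt$parent] - tt$height) * tt$diff_scalar
  V <- matrix(0, length(nonroot), length(nonroot))
  for (i in seq_along(nonroot)) for (j in seq_along(nonroot)) {
    shared <- intersect(path(nonroot[i]), path(nonroot[j]))
    V[i, j] <- sum(bvar[shared])
  }
  C <- kronecker(V, sigma)  # per node the 2x2 block (lat, lon)
  x <- as.vector(t(sweep(tt$location[nonroot, , drop = FALSE], 2,
                         tt$location[root, ])))
  ch <- chol(C)
  -length(x) / 2 * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, x, transpose = TRUE)^2)
}

# -- quartet statistics by direct enumeration ---------------------------------

oracle_quartet_scores <- function(d) {
  n <- nrow(d)
  deltas <- c(); qres <- c()
  for (i in 1:(n - 3)) for (j in (i + 1):(n - 2)) {
    for (k in (j + 1):(n - 1)) for (l in (k + 1):n) {
      s <- sort(c(d[i, j] + d[k, l], d[i, k] + d[j, l], d[i, l] + d[j, k]),
                decreasing = TRUE)
      deltas <- c(deltas, if (s[1] - s[3] <= 0) 0 else (s[1] - s[2]) / (s[1] - s[3]))
      qres <- c(qres, (s[1] - s[2])^2)
    }
  }
  list(delta = deltas, qres = qres)
}

# additive (tree-metric) distance matrix from a time tree
tree_metric <- function(tt) {
  phy <- as_phylo(tt)
  as.matrix(stats::cophenetic(phy))[tt$labels, tt$labels]
}
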