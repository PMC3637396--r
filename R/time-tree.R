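#' Time-calibrated trees with geographic annotations
#'
#' A `time_tree` is a rooted binary tree whose nodes carry heights in years
#' BP, per-branch clock-rate multipliers, per-branch diffusion-rate scalars,
#' and per-node (lat, lon) locations. Internally nodes are indexed
#' `1..n` for tips and `n+1..2n-1` for internal nodes, with a parent vector
#' (`NA` at the root); this representation makes the MCMC topology moves and
#' pruning recursions straightforward, and [as_phylo()] / [as_time_tree()]
#' convert to and from `ape::phylo` for everything else.
#'
#' @param labels character tip labels (length n >= 2).
#' @param parent integer parent index per node, `NA` for the root.
#' @param height numeric node heights (years BP), tips usually 0; every
#'   parent strictly older than its children.
#' @param clock_rate,diff_scalar per-node multipliers for the branch above
#'   each node (ignored at the root); default 1.
#' @param location optional (2n-1) x 2 matrix of (lat, lon).
#' @return An object of class `time_tree`.
#' @export
time_tree <- function(labels, parent, height, clock_rate = NULL,
                      diff_scalar = NULL, location = NULL) {
  n <- length(labels)
  nn <- 2L * n - 1L
  stopifnot(n >= 2, length(parent) == nn, length(height) == nn)
  parent <- as.integer(parent)
  root <- which(is.na(parent))
  if (length(root) != 1) stop("exactly one root required")
  ch <- tabulate(parent[!is.na(parent)], nbins = nn)
  if (any(ch[1:n] != 0)) stop("tips cannot have children")
  if (any(ch[(n + 1):nn] != 2)) stop("tree must be binary")
  ok <- !is.na(parent)
  if (any(height[parent[ok]] <= height[ok])) {
    stop("every parent must be strictly older than its children")
  }
  if (height[root] <= 0) stop("root height must be positive")
  tt <- structure(list(
    n_tips = n, labels = labels, parent = parent, height = as.numeric(height),
    clock_rate = clock_rate %||% rep(1, nn),
    diff_scalar = diff_scalar %||% rep(1, nn),
    location = location %||% matrix(NA_real_, nn, 2,
                                    dimnames = list(NULL, c("lat", "lon")))),
    class = "time_tree")
  tt
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("<time_tree> %d tips, root height %.1f BP", x$n_tips,
              x$height[tt_root(x)]))
  if (any(is.finite(x$location))) cat(", geo-annotated")
  cat("\n")
  invisible(x)
}

tt_root <- function(tt) which(is.na(tt$parent))

# children list indexed by node
tt_children <- function(tt) {
  nn <- length(tt$parent)
  kids <- vector("list", nn)
  for (v in seq_len(nn)) {
    p <- tt$parent[v]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], v)
  }
  kids
}

# internal nodes in postorder (children before parents)
tt_postorder <- function(tt) {
  n <- tt$n_tips
  ord <- order(tt$height[(n + 1):(2 * n - 1)])
  (n + 1):(2 * n - 1)
  ((n + 1):(2 * n - 1))[ord]
}

# branch durations (years) for every non-root node (branch above the node)
tt_durations <- function(tt) {
  d <- tt$height[tt$parent] - tt$height
  d[is.na(tt$parent)] <- NA_real_
  d
}

# bitmask (numeric, sum of 2^(tip-1)) of the tip set below each node
tt_clades <- function(tt) {
  n <- tt$n_tips
  nn <- 2L * n - 1L
  mask <- numeric(nn)
  mask[1:n] <- 2^(0:(n - 1))
  kids <- tt_children(tt)
  for (v in tt_postorder(tt)) mask[v] <- sum(mask[kids[[v]]])
  mask
}

# logical matrix (nn x n): does tip j descend from node i
tt_clade_matrix <- function(tt) {
  n <- tt$n_tips
  nn <- 2L * n - 1L
  m <- matrix(FALSE, nn, n)
  m[cbind(1:n, 1:n)] <- TRUE
  kids <- tt_children(tt)
  for (v in tt_postorder(tt)) {
    m[v, ] <- m[kids[[v]][1], ] | m[kids[[v]][2], ]
  }
  m
}

#' Most recent common ancestor of a set of tips
#' @param tt a [time_tree()].
#' @param taxa character vector of tip labels.
#' @return internal node index.
#' @export
tt_mrca <- function(tt, taxa) {
  idx <- match(taxa, tt$labels)
  if (anyNA(idx)) stop("unknown taxon: ", paste(taxa[is.na(idx)], collapse = ", "))
  if (length(idx) == 1) return(idx)
  anc <- function(v) {
    out <- v
    while (!is.na(tt$parent[v])) { v <- tt$parent[v]; out <- c(out, v) }
    out
  }
  common <- Reduce(intersect, lapply(idx, anc))
  common[which.min(tt$height[common])]
}

#' Convert a time_tree to ape::phylo
#' @param tt a [time_tree()].
#' @return An `ape::phylo` object with branch lengths in years.
#' @export
as_phylo <- function(tt) {
  n <- tt$n_tips
  nn <- 2L * n - 1L
  root <- tt_root(tt)
  # ape wants the root to be node n+1; remap internal ids
  internal <- c(root, setdiff((n + 1):nn, root))
  map <- integer(nn)
  map[1:n] <- 1:n
  map[internal] <- n + seq_along(internal)
  child <- which(!is.na(tt$parent))
  edge <- cbind(map[tt$parent[child]], map[child])
  len <- tt$height[tt$parent[child]] - tt$height[child]
  ord <- order(edge[, 1], edge[, 2])
  phy <- structure(list(edge = edge[ord, , drop = FALSE],
                        edge.length = len[ord],
                        tip.label = tt$labels, Nnode = n - 1L),
                   class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert an ape::phylo (rooted, binary, with branch lengths) to time_tree
#' @param phy an `ape::phylo`; branch lengths are durations in years.
#' @param tip_height heights of the tips (default all 0).
#' @return A [time_tree()].
#' @export
as_time_tree <- function(phy, tip_height = 0) {
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    stop("tree must be rooted and binary")
  }
  n <- length(phy$tip.label)
  nn <- 2L * n - 1L
  depth <- ape::node.depth.edgelength(phy)  # distance from root
  h <- max(depth) - depth
  # ape node ids already follow the tips 1..n convention
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  th <- rep_len(tip_height, n)
  # shift so tips sit at their stated heights (ultrametric assumed if scalar)
  if (length(unique(round(h[1:n], 9))) == 1) h <- h - h[1] + th[1]
  time_tree(phy$tip.label, parent, h)
}

# ---- annotated newick / NEXUS trees I/O (BEAST-style [&...] comments) ----

#' Write time trees as an annotated NEXUS TREES block
#'
#' Node comments follow the BEAST annotation dialect:
#' `[&height=..,rate=..,scalar=..,location={lat,lon}]`, which keeps the
#' files readable by standard tree viewers.
#'
#' @param trees a `time_tree` or list of them.
#' @param path output path.
#' @param names optional tree names.
#' @return `path`, invisibly.
#' @export
write_trees_nexus <- function(trees, path, names = NULL) {
  if (inherits(trees, "time_tree")) trees <- list(trees)
  labels <- trees[[1]]$labels
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN TREES;", "  TRANSLATE"), con)
  writeLines(paste0("    ", seq_along(labels), " ", labels,
                    c(rep(",", length(labels) - 1), "")), con)
  writeLines("  ;", con)
  nm <- names %||% paste0("STATE_", seq_along(trees))
  for (i in seq_along(trees)) {
    writeLines(sprintf("  TREE %s = %s;", nm[i],
                       tt_newick(trees[[i]], translate = TRUE)), con)
  }
  writeLines("END;", con)
  invisible(path)
}

tt_newick <- function(tt, translate = FALSE, digits = 8) {
  kids <- tt_children(tt)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  ann <- function(v) {
    parts <- c(sprintf("height=%s", fmt(tt$height[v])))
    if (!is.na(tt$parent[v])) {
      parts <- c(parts, sprintf("rate=%s", fmt(tt$clock_rate[v])),
                 sprintf("scalar=%s", fmt(tt$diff_scalar[v])))
    }
    if (all(is.finite(tt$location[v, ]))) {
      parts <- c(parts, sprintf("location={%s,%s}", fmt(tt$location[v, 1]),
                                fmt(tt$location[v, 2])))
    }
    paste0("[&", paste(parts, collapse = ","), "]")
  }
  rec <- function(v) {
    lab <- if (v <= tt$n_tips) {
      if (translate) as.character(v) else tt$labels[v]
    } else ""
    body <- if (v > tt$n_tips) {
      paste0("(", paste(vapply(kids[[v]], rec, ""), collapse = ","), ")")
    } else ""
    blen <- if (is.na(tt$parent[v])) 0 else tt$height[tt$parent[v]] - tt$height[v]
    paste0(body, lab, ann(v), ":", fmt(blen))
  }
  rec(tt_root(tt))
}

#' Read annotated trees from a NEXUS TREES block
#' @param path file written by [write_trees_nexus()] (or BEAST-style).
#' @return list of [time_tree()] objects.
#' @export
read_trees_nexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  up <- toupper(lines)
  # translate table
  tr_start <- grep("^\\s*TRANSLATE", up)
  labels <- NULL
  if (length(tr_start)) {
    i <- tr_start[1] + 1
    labels <- character()
    while (i <= length(lines) && !grepl("^\\s*;", lines[i])) {
      m <- regmatches(lines[i], regexec("^\\s*([0-9]+)\\s+([^,;\\s]+)", lines[i]))[[1]]
      if (length(m) == 3) labels[as.integer(m[2])] <- m[3]
      i <- i + 1
    }
  }
  tl <- grep("^\\s*TREE\\s", up, value = FALSE)
  lapply(tl, function(i) {
    s <- sub("^[^=]*=\\s*", "", lines[i])
    s <- sub(";\\s*$", "", s)
    parse_annotated_newick(s, labels)
  })
}

parse_annotated_newick <- function(s, labels = NULL) {
  pos <- 1L
  nchar_s <- nchar(s)
  peek <- function() if (pos <= nchar_s) substr(s, pos, pos) else ""
  nodes <- list()  # each: list(children=idx, label, ann, blen)
  new_node <- function(label, ann, blen, children) {
    nodes[[length(nodes) + 1L]] <<- list(label = label, ann = ann,
                                         blen = blen, children = children)
    length(nodes)
  }
  read_until <- function(stopchars) {
    start <- pos
    while (pos <= nchar_s && !(substr(s, pos, pos) %in% stopchars)) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  read_ann <- function() {
    if (peek() != "[") return("")
    start <- pos
    while (pos <= nchar_s && substr(s, pos, pos) != "]") pos <<- pos + 1L
    pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  parse_clade <- function() {
    children <- integer()
    label <- ""
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children <- c(children, parse_clade())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("newick parse error near position ", pos)
      }
      label <- read_until(c("[", ":", ",", ")", ";"))
    } else {
      label <- read_until(c("[", ":", ",", ")", ";"))
    }
    ann <- read_ann()
    blen <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      blen <- as.numeric(read_until(c(",", ")", ";", "[")))
    }
    new_node(label, ann, blen, children)
  }
  root_id <- parse_clade()
  # assemble into time_tree index space
  is_tip <- vapply(nodes, function(n) length(n$children) == 0, TRUE)
  tip_ids <- which(is_tip)
  tip_labels <- vapply(nodes[tip_ids], function(n) n$label, "")
  if (!is.null(labels)) {
    num <- suppressWarnings(as.integer(tip_labels))
    if (!anyNA(num)) tip_labels <- labels[num]
  }
  n <- length(tip_ids)
  remap <- integer(length(nodes))
  remap[tip_ids] <- seq_len(n)
  remap[!is_tip] <- n + seq_len(sum(!is_tip))
  parent <- rep(NA_integer_, 2L * n - 1L)
  blen <- rep(NA_real_, 2L * n - 1L)
  ann <- character(2L * n - 1L)
  for (i in seq_along(nodes)) {
    for (c in nodes[[i]]$children) parent[remap[c]] <- remap[i]
    blen[remap[i]] <- nodes[[i]]$blen
    ann[remap[i]] <- nodes[[i]]$ann
  }
  # heights from annotations if present, else from branch lengths
  get_num <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, "=([-0-9.eE+]+)"), a))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else NA_real_
  }
  h <- vapply(ann, get_num, 0, key = "height", USE.NAMES = FALSE)
  if (anyNA(h)) {  # derive from branch lengths, tips at 0
    h <- rep(NA_real_, length(parent))
    depth <- function(v) {
      if (is.na(parent[v])) return(0)
      depth(parent[v]) + blen[v]
    }
    dp <- vapply(seq_along(parent), depth, 0)
    h <- max(dp) - dp
  }
  rate <- vapply(ann, get_num, 0, key = "rate", USE.NAMES = FALSE)
  scal <- vapply(ann, get_num, 0, key = "scalar", USE.NAMES = FALSE)
  loc <- t(vapply(ann, function(a) {
    m <- regmatches(a, regexec("location=\\{([-0-9.eE+]+),([-0-9.eE+]+)\\}", a))[[1]]
    if (length(m) == 3) as.numeric(m[2:3]) else c(NA_real_, NA_real_)
  }, numeric(2), USE.NAMES = FALSE))
  colnames(loc) <- c("lat", "lon")
  rate[is.na(rate)] <- 1; scal[is.na(scal)] <- 1
  time_tree(tip_labels, parent, h, clock_rate = rate, diff_scalar = scal,
            location = loc)
}
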