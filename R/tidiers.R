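#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a posterior trace
#'
#' One row per retained post-burn-in sample and monitored scalar, in long
#' format -- convenient for dplyr/ggplot2 summaries.
#'
#' @param x a `lexigeo_trace`.
#' @param ... unused.
#' @return tibble with columns `state`, `parameter`, `value`.
#' @export
tidy.lexigeo_trace <- function(x, ...) {
  keep <- trace_keep(x)
  s <- x$samples[keep, ]
  params <- setdiff(names(s), "state")
  out <- do.call(rbind, lapply(params, function(p) {
    tibble::tibble(state = s$state, parameter = p, value = s[[p]])
  }))
  tibble::as_tibble(out)
}

#' One-row summary of a posterior trace
#'
#' @param x a `lexigeo_trace`.
#' @param ... unused.
#' @return tibble with posterior medians, 95% HPDs and effective sample
#'   sizes of the headline parameters.
#' @export
glance.lexigeo_trace <- function(x, ...) {
  keep <- trace_keep(x)
  s <- x$samples[keep, ]
  rh <- s$root_height
  hpd <- hpd_interval(rh, 0.95)
  tibble::tibble(
    n_samples = nrow(s),
    log_post_mean = mean(s$log_post),
    root_height_median = stats::median(rh),
    root_height_mean = mean(rh),
    root_height_hpd_low = hpd[["low"]],
    root_height_hpd_high = hpd[["high"]],
    mu_median = stats::median(s$mu),
    ess_root_height = ess(rh),
    ess_log_post = ess(s$log_post))
}

#' Trace plots of the monitored parameters
#'
#' @param object a `lexigeo_trace`.
#' @param parameters which columns to show (default the headline four).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lexigeo_trace <- function(object,
                                   parameters = c("log_post", "root_height",
                                                  "mu", "root_lat"),
                                   ...) {
  td <- tidy(object)
  td <- td[td$parameter %in% parameters, ]
  ggplot2::ggplot(td, ggplot2::aes(x = state, y = value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "MCMC state", y = NULL)
}

#' Map of an HPD location polygon
#'
#' @param object an `hpd_polygon`.
#' @param mask optional [land_mask()] drawn underneath.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hpd_polygon <- function(object, mask = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(mask)) {
    md <- do.call(rbind, lapply(seq_along(mask$rings), function(i) {
      data.frame(lon = mask$rings[[i]][, 1], lat = mask$rings[[i]][, 2],
                 ring = paste0("land", i))
    }))
    p <- p + ggplot2::geom_polygon(
      data = md, ggplot2::aes(lon, lat, group = ring),
      fill = "grey85", colour = "grey60")
  }
  rd <- do.call(rbind, lapply(seq_along(object$rings), function(i) {
    data.frame(lon = object$rings[[i]][, 1], lat = object$rings[[i]][, 2],
               ring = paste0("hpd", i))
  }))
  sd_ <- data.frame(lat = object$samples[, 1], lon = object$samples[, 2])
  p +
    ggplot2::geom_point(data = sd_, ggplot2::aes(lon, lat),
                        size = 0.3, alpha = 0.3) +
    ggplot2::geom_polygon(
      data = rd, ggplot2::aes(lon, lat, group = ring),
      fill = NA, colour = "firebrick") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  title = sprintf("%.0f%% HPD, %s", 100 * object$level,
                                  object$node))
}

#' Plot an MCC tree with support values
#'
#' Thin wrapper over `ape::plot.phylo` showing posterior clade support.
#'
#' @param mcc an `mcc_summary` from [mcc_tree()].
#' @param ... passed to `ape::plot.phylo`.
#' @export
plot_mcc <- function(mcc, ...) {
  phy <- as_phylo(mcc$tree)
  ape::plot.phylo(phy, ...)
  n <- mcc$tree$n_tips
  sup <- sprintf("%.2f", mcc$support[(n + 1):(2 * n - 1)])
  ape::nodelabels(text = sup, frame = "none", cex = 0.7, adj = c(1.1, -0.3))
  invisible(phy)
}
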