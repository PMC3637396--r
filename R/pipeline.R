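#' Read a pipeline run configuration
#'
#' YAML schema (all chain/model keys optional, shown with defaults):
#' ```yaml
#' data:
#'   matrix: cognates.nex      # NEXUS binary matrix
#'   coords: coords.tsv        # taxon \t lat \t lon
#'   mask:   land.geojson      # Polygon/MultiPolygon land mask
#' output: out/                # artifact directory
#' model:
#'   clock: strict             # strict | relaxed-lognormal
#'   diffusion: gamma          # cauchy | gamma | lognormal | homogeneous
#'   skyline_groups: 5
#'   stem_factor: 1.0
#' chain:
#'   length: 20000
#'   thin: 20
#'   burnin: 0.1
#'   seed: 1
#' calibration:
#'   taxa: [sak01, sak02]
#'   mean: 500
#'   sd: 102.04
#' summaries:
#'   hpd_level: 0.80
#' ```
#'
#' @param path YAML file.
#' @return nested list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

config_to_mcmc <- function(cfg, overrides = list()) {
  ch <- cfg$chain %||% list()
  md <- cfg$model %||% list()
  cal <- NULL
  if (!is.null(cfg$calibration)) {
    cal <- calibration_prior(unlist(cfg$calibration$taxa),
                             mean = cfg$calibration$mean,
                             sd = cfg$calibration$sd %||% (200 / stats::qnorm(0.975)))
  }
  args <- list(chain_length = ch$length %||% 20000, thin = ch$thin %||% 20,
               burnin = ch$burnin %||% 0.1, seed = ch$seed %||% 1,
               clock = md$clock %||% "strict",
               diffusion = md$diffusion %||% "gamma",
               skyline_groups = md$skyline_groups %||% 5,
               stem_factor = md$stem_factor %||% 1,
               calibration = cal)
  args[names(overrides)] <- overrides
  do.call(mcmc_config, args)
}

#' Run the full pipeline: validate, infer, summarize, write artifacts
#'
#' Reads the data named in the config, runs [mcmc_run()], then writes the
#' trace log (+ annotated trees), the MCC tree, the root-age HPD, the root
#' location HPD polygon (GeoJSON), a node summary table, and a JSON
#' manifest with the config hash, seed and file list. On failure the output
#' directory keeps partial files plus a `.partial` marker.
#'
#' @param config a `run_config` (see [read_run_config()]) or a path to one.
#' @param overrides named list of [mcmc_config()] arguments overriding the
#'   file (e.g. `list(seed = 7, chain_length = 1000)`).
#' @return list with `status` (0 on success) and `manifest`, invisibly.
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config)) config <- read_run_config(config)
  for (field in c("matrix", "coords", "mask")) {
    p <- config$data[[field]]
    if (is.null(p)) stop("config error: data.", field, " is missing")
    if (!file.exists(p)) stop("config error: data.", field,
                              " does not exist: ", p)
  }
  outdir <- config$output %||% "lexigeo_out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(outdir, ".partial")
  file.create(marker)
  status <- 1L
  manifest <- NULL
  on.exit({
    if (status == 0L) unlink(marker)
  })
  m <- read_nexus_binary(config$data$matrix)
  geo <- read_taxon_geo(config$data$coords)
  mask <- read_land_mask(config$data$mask)
  mc <- config_to_mcmc(config, overrides)
  trace <- mcmc_run(m, geo, mask, mc)
  files <- character()
  add <- function(p) { files <<- c(files, p); p }
  write_trace(trace, add(file.path(outdir, "trace.log")))
  add(file.path(outdir, "trace.log.trees"))
  mcc <- mcc_tree(trace)
  write_trees_nexus(mcc$tree, add(file.path(outdir, "mcc.trees")),
                    names = "MCC")
  keep <- trace_keep(trace)
  root_h <- trace$samples$root_height[keep]
  level <- config$summaries$hpd_level %||% 0.80
  poly <- location_hpd_polygon(trace, level = level, mask = mask)
  write_hpd_geojson(poly, add(file.path(outdir, "root_hpd.geojson")),
                    ages = stats::median(root_h))
  utils::write.table(mcc$nodes, add(file.path(outdir, "node_summary.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hh <- hpd_interval(root_h, 0.95)
  utils::write.table(
    data.frame(quantity = c("root_age_median", "root_age_mean",
                            "root_age_hpd95_low", "root_age_hpd95_high"),
               value = c(stats::median(root_h), mean(root_h), hh[1], hh[2])),
    add(file.path(outdir, "root_age.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_file <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  files <- c(files, cfg_file)
  hashes <- tools::md5sum(files)
  manifest <- list(seed = mc$seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   package_version = as.character(utils::packageVersion("lexigeo")),
                   files = as.list(setNames(unname(hashes), basename(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  status <- 0L
  invisible(list(status = status, manifest = manifest))
}
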