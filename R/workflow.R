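STOCHASTIC_STAGES <- c("stochastic-dist", "network-xstar", "synth-study")

#' Run one analysis stage from a configuration
#'
#' Dispatches a named stage with its parameters, writes the resulting
#' data tables as CSV into the output directory together with a JSON
#' manifest (configuration echo plus package version) sufficient to
#' re-run the stage bit-identically. Stochastic stages refuse to run
#' without an explicit seed.
#'
#' Supported stages and their main parameters:
#' \describe{
#'   \item{`analytic-curve`}{`s` (vector), `t_points`: minimal crosstalk
#'     and optimal concentration along a `t` grid.}
#'   \item{`design-grid`}{`s`, `grid`: busy/idle comparison over (p, q).}
#'   \item{`stochastic-dist`}{`m`, `gamma`, `s`, `n`, `seed`: sampled and
#'     exact minimal-crosstalk distribution.}
#'   \item{`motif-energies`}{`pcm_dir` (or `pcm_paths`), `min_counts`,
#'     `pseudocount`: energy matrices, consensus table, pairwise binding
#'     energies, per-gene similarities (needs `regulon` TSV for a
#'     non-trivial gene map).}
#'   \item{`network-xstar`}{`pcm_dir`/`pcm_paths` + `regulon`, or
#'     `n_tf` for a synthetic network; `t_points`, `draws`, `seed`:
#'     concentration-optimized crosstalk curve plus fitted s_effective.}
#'   \item{`fit-seff`}{`curve` (CSV path with columns t, mean_xstar).}
#'   \item{`synth-study`}{`n_tf`, `sizes`, `networks`, `seed`: subnetwork
#'     s_effective study.}
#' }
#'
#' @param config either a YAML file path or a named list with at least
#'   `stage` and `out_dir`; stage parameters as further entries.
#' @param overrides named list merged over the config (e.g. flag-style
#'   overrides).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_stage <- function(config, overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML path")
  config[names(overrides)] <- overrides
  stage <- config$stage
  if (is.null(stage)) stop("config must name a 'stage'")
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an 'out_dir'")
  if (stage %in% STOCHASTIC_STAGES && is.null(config$seed))
    stop("stage '", stage, "' is stochastic and requires a 'seed' ",
         "in the config")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  tables <- switch(stage,
    "analytic-curve" = stage_analytic_curve(config),
    "design-grid" = stage_design_grid(config),
    "stochastic-dist" = stage_stochastic_dist(config),
    "motif-energies" = stage_motif_energies(config),
    "network-xstar" = stage_network_xstar(config),
    "fit-seff" = stage_fit_seff(config),
    "synth-study" = stage_synth_study(config),
    stop("unknown stage: ", stage))

  files <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE)
    files <- c(files, path)
  }
  manifest <- list(
    stage = stage,
    config = config[setdiff(names(config), "out_dir")],
    package = "xtalknet",
    version = as.character(utils::packageVersion("xtalknet")),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

cfg <- function(config, name, default) {
  if (!is.null(config[[name]])) config[[name]] else default
}

stage_analytic_curve <- function(config) {
  s <- cfg(config, "s", 0.01)
  t_points <- cfg(config, "t_points", 101L)
  list(analytic_curve = xstar_curve(s, t_points = t_points))
}

stage_design_grid <- function(config) {
  n <- cfg(config, "grid", 101L)
  g <- design_comparison_grid(seq(0, 1, length.out = n),
                              seq(0, 1, length.out = n),
                              s = cfg(config, "s", 0.01))
  list(design_grid = as.data.frame(g))
}

stage_stochastic_dist <- function(config) {
  m <- gene_activity_model(cfg(config, "m", 3000L),
                           gamma = cfg(config, "gamma", 0.12))
  s <- cfg(config, "s", 0.01)
  n <- cfg(config, "n", 1e5)
  x <- xstar_samples(m, s, n_realizations = n, seed = config$seed)
  h <- graphics::hist(x, breaks = 50, plot = FALSE)
  dist <- xstar_distribution(m, s, method = "exact")
  list(
    histogram = data.frame(mid = h$mids, density = h$density,
                           count = h$counts),
    analytic = data.frame(x_star = dist$support, pmf = dist$pmf,
                          cdf = cumsum(dist$pmf)))
}

stage_load_network <- function(config) {
  if (!is.null(config$pcm_dir) || !is.null(config$pcm_paths)) {
    paths <- if (!is.null(config$pcm_paths)) config$pcm_paths
             else list.files(config$pcm_dir,
                             pattern = "\\.(pfm|jaspar|txt)$",
                             full.names = TRUE)
    if (length(paths) == 0L) stop("no motif files found")
    pcms <- load_and_filter_pcms(paths,
                                 cfg(config, "min_counts", 5))
    if (length(pcms) == 0L) stop("no motifs survived filtering")
    tfs <- lapply(pcms, energy_matrix_from_pcm,
                  delta = cfg(config, "pseudocount", 0.1))
    regulon <- NULL
    if (!is.null(config$regulon)) {
      regulon <- utils::read.delim(config$regulon, header = TRUE,
                                   stringsAsFactors = FALSE)
      names(regulon)[1:2] <- c("tf_id", "gene_id")
    }
    conc <- NULL
    if (!is.null(config$concentrations)) {
      ct <- utils::read.delim(config$concentrations, header = TRUE,
                              stringsAsFactors = FALSE)
      conc <- stats::setNames(ct[[2]], ct[[1]])
    }
    tf_network(tfs, regulon = regulon, concentrations = conc)
  } else {
    if (is.null(config$seed))
      stop("a synthetic network needs a 'seed' (or supply 'pcm_dir')")
    generate_network(n_tf = cfg(config, "n_tf", 60L),
                     seed = config$seed)
  }
}

stage_motif_energies <- function(config) {
  net <- stage_load_network(config)
  eps <- do.call(rbind, lapply(net$tfs, function(e) {
    data.frame(tf_id = e$tf_id, position = seq_len(e$L),
               A = e$epsilon[1, ], C = e$epsilon[2, ],
               G = e$epsilon[3, ], T = e$epsilon[4, ])
  }))
  sim <- network_similarities(net)
  Ekl <- as.data.frame(as.table(net$energy_table))
  names(Ekl) <- c("site", "tf", "energy")
  list(energy_matrices = eps,
       consensus = data.frame(tf_id = net$tf_ids,
                              consensus = net$consensus),
       binding_energies = Ekl,
       similarities = sim)
}

stage_network_xstar <- function(config) {
  net <- stage_load_network(config)
  tg <- seq(1 / length(net$tf_ids), 1,
            length.out = cfg(config, "t_points", 20L))
  cur <- min_crosstalk_curve(net, t_grid = tg,
                             n_draws = cfg(config, "draws", 100L),
                             seed = config$seed)
  fit <- fit_s_effective(cur)
  list(crosstalk_curve = as.data.frame(cur),
       s_effective = data.frame(s_effective = fit$s_effective,
                                ssr = fit$ssr))
}

stage_fit_seff <- function(config) {
  if (is.null(config$curve)) stop("'fit-seff' needs a 'curve' CSV path")
  cur <- utils::read.csv(config$curve)
  fit <- fit_s_effective(cur)
  list(s_effective = data.frame(s_effective = fit$s_effective,
                                ssr = fit$ssr))
}

stage_synth_study <- function(config) {
  st <- seffective_study(
    sizes = cfg(config, "sizes", c(10L, 23L, 50L)),
    n_networks = cfg(config, "networks", 20L),
    n_tf = cfg(config, "n_tf", 60L),
    t_grid = seq(0.1, 1, length.out = cfg(config, "t_points", 10L)),
    n_draws = cfg(config, "draws", 30L),
    seed = config$seed)
  list(s_effective_study = as.data.frame(st),
       length_correlation = data.frame(
         network = seq_along(attr(st, "consensus_length_cor")),
         cor_s_consensus_length = attr(st, "consensus_length_cor")))
}

#' Regenerate the data tables behind the headline figures
#'
#' Convenience wrapper over [run_stage()] that emits, at the study's
#' stated parameters, the data behind each figure-style analysis:
#' \describe{
#'   \item{`fig2`}{minimal crosstalk and optimal concentration versus `t`
#'     for several similarities (default `s = 10^-3, 10^-2, 10^-1`).}
#'   \item{`fig3`}{busy/idle comparison grids at `s = 10^-2` and the
#'     anomalous-regime map at `s = 1`.}
#'   \item{`fig3f`}{stochastic minimal-crosstalk distributions at
#'     `M = 3000`, `p = 1/3`, `gamma = 0.12` and `0.92` (reduced
#'     realization count by default; pass `n` for full scale).}
#'   \item{`fig4b-like`}{synthetic-network crosstalk curve plus
#'     s_effective fit (motif data may be supplied via `pcm_dir` +
#'     `regulon`).}
#'   \item{`fig4c-like`}{reduced-scale subnetwork sampling study.}
#' }
#'
#' @param figure one of `"fig2"`, `"fig3"`, `"fig3f"`, `"fig4b-like"`,
#'   `"fig4c-like"`.
#' @param out_dir output directory.
#' @param seed seed for the stochastic figures.
#' @param ... stage parameter overrides (e.g. `n`, `draws`, `n_tf`).
#' @return Invisibly, the manifest (list of manifests for `fig3`).
#' @export
regenerate_figure_data <- function(figure = c("fig2", "fig3", "fig3f",
                                              "fig4b-like", "fig4c-like"),
                                   out_dir, seed = 1L, ...) {
  figure <- match.arg(figure)
  dots <- list(...)
  base <- function(stage, defaults, sub = NULL) {
    config <- c(list(stage = stage,
                     out_dir = if (is.null(sub)) out_dir
                               else file.path(out_dir, sub)),
                defaults)
    config[names(dots)] <- dots
    run_stage(config)
  }
  switch(figure,
    fig2 = base("analytic-curve",
                list(s = c(1e-3, 1e-2, 1e-1), t_points = 101L)),
    fig3 = {
      m1 <- base("design-grid", list(s = 1e-2, grid = 101L),
                 sub = "s_0.01")
      m2 <- base("design-grid", list(s = 1, grid = 101L), sub = "s_1")
      invisible(list(m1, m2))
    },
    fig3f = {
      m1 <- base("stochastic-dist",
                 list(m = 3000L, gamma = 0.12, s = 1e-2, n = 1e5,
                      seed = seed), sub = "idle_gamma_0.12")
      m2 <- base("stochastic-dist",
                 list(m = 3000L, gamma = 0.92, s = 1e-2, n = 1e5,
                      seed = seed + 1L), sub = "busy_gamma_0.92")
      invisible(list(m1, m2))
    },
    "fig4b-like" = base("network-xstar",
                        list(n_tf = 60L, t_points = 20L, draws = 100L,
                             seed = seed)),
    "fig4c-like" = base("synth-study",
                        list(n_tf = 60L, sizes = c(5L, 15L, 30L, 60L),
                             networks = 20L, seed = seed)))
}
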