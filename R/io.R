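#' Experiment configuration with defaults
#'
#' Builds the fully expanded configuration of one experiment: network sizes,
#' biophysical parameters, training settings, stimulus protocol, variant
#' descriptor and seed. Unknown fields in `overrides` are rejected with an
#' error naming the field; everything else is filled with the defaults
#' (`N_E = 400`, `N_I = 50`, `dt = 1` ms, 100 ms pulses at 2.5 Hz from
#' \{100, 200, 300, 400\} pA, 8-trial batches of 600 ms).
#'
#' @param overrides nested named list of replacements.
#' @return list of class `ci_experiment_config`.
#' @export
experiment_config <- function(overrides = list()) {
  cfg <- list(
    network = list(N_E = 400, N_I = 50, output_mode = "shared",
                   preassign = FALSE, knockout = character(0),
                   init = list(w_ei_scale = 5, w_ii_scale = 1,
                               w_out_scale = 0.5, u_halfwidth = 0.2)),
    params = default_params(),
    training = list(n_updates = 400, batch_size = 8,
                    lr = list(w_ei = 1e-3, u = 4e-3, w_ii = 1e-3, w_out = 1e-3),
                    alpha_base = 1, clip = 1, freeze_stp = FALSE,
                    patience = 100, lr_decay = 0.3, lr_decay_at = 0.6),
    stimulus = list(pulse_ms = 100, rate_hz = 2.5,
                    amplitudes = c(100, 200, 300, 400), trial_ms = 600,
                    correlation = 0),
    variant = "self-organized",
    seed = 1,
    out = "runs"
  )
  cfg <- modify_list_strict(cfg, overrides, "config")
  # YAML represents empty/character vectors as lists; normalize
  cfg$network$knockout <- as.character(unlist(cfg$network$knockout))
  cfg$stimulus$amplitudes <- as.numeric(unlist(cfg$stimulus$amplitudes))
  validate_params(cfg$params)
  structure(cfg, class = "ci_experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Reads a YAML file, validates it against the configuration schema
#' (unknown keys are rejected with an error naming the field) and fills all
#' missing fields with defaults.
#'
#' @param path YAML file path.
#' @return a [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  experiment_config(yaml::read_yaml(path))
}

#' Save an experiment configuration to YAML
#'
#' @param cfg a [experiment_config()].
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

# Materialize the pieces of a configuration.
config_network <- function(cfg) {
  network_config(cfg$network$N_E, cfg$network$N_I, cfg$network$output_mode,
                 preassign = cfg$network$preassign,
                 knockout = if (length(cfg$network$knockout)) cfg$network$knockout,
                 init = cfg$network$init)
}
config_protocol <- function(cfg) {
  stimulus_protocol(cfg$stimulus$pulse_ms, cfg$stimulus$rate_hz,
                    cfg$stimulus$amplitudes, cfg$stimulus$trial_ms,
                    cfg$stimulus$correlation)
}
config_train <- function(cfg) {
  train_config(cfg$training$n_updates, cfg$training$batch_size,
               config_protocol(cfg), cfg$training$lr,
               cfg$training$alpha_base, cfg$training$clip,
               cfg$training$freeze_stp, cfg$training$patience,
               cfg$training$lr_decay, cfg$training$lr_decay_at)
}

#' Persist a run record
#'
#' Saves results (trained network, records, histories, tables) as an RDS
#' file together with a YAML sidecar carrying the full configuration echo,
#' seed and package version, so that a persisted run can be re-executed
#' exactly.
#'
#' @param results named list of result objects.
#' @param cfg the [experiment_config()] used.
#' @param path output path (`.rds`; the sidecar gets `.yaml`).
#' @export
save_run <- function(results, cfg, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  meta <- list(config = unclass(cfg), seed = cfg$seed,
               package_version = as.character(utils::packageVersion("compinhib")))
  saveRDS(list(meta = meta, results = results), path)
  save_config(cfg, sub("\\.rds$", ".yaml", path))
  invisible(path)
}

#' Load a persisted run record
#'
#' @param path path written by [save_run()].
#' @return list with `meta` (config echo, seed, version) and `results`.
#' @export
load_run <- function(path) {
  if (!file.exists(path)) {
    stop("run record not found: ", path,
         " (train or evaluate first, or check the path)")
  }
  readRDS(path)
}

#' Reproduce one figure-level experiment
#'
#' End-to-end drivers for the standard experiments, at the scale given in
#' `cfg`: `fig1` trains self-organized networks and writes per-IN
#' connectivity/PPR features with mixture labels and the E/I correlations;
#' `fig2` adds the pre-assigned control; `fig3` probes input-output curves
#' with current pulses; `fig4` sweeps input correlations; `fig5` summarizes
#' IN -> IN connectivity by class and runs the knockout family; `s1`/`s2`
#' sweep the minimum-rate baseline; `s3` trains without short-term
#' plasticity; `s4` uses heterogeneous output weights. Summary tables are
#' written as CSV files under `cfg$out`.
#'
#' @param figure_id one of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`,
#'   `"s1"`, `"s2"`, `"s3"`, `"s4"`.
#' @param cfg a [experiment_config()]; `cfg$network`, `cfg$training` and
#'   `cfg$seed` set the scale and reproducibility.
#' @param n_networks networks trained (pooled) where the analysis pools
#'   several networks.
#' @return invisibly, a named list of the summary tables (also written to
#'   CSV).
#' @export
run_figure <- function(figure_id = c("fig1", "fig2", "fig3", "fig4", "fig5",
                                     "s1", "s2", "s3", "s4"),
                       cfg = experiment_config(), n_networks = 5) {
  figure_id <- match.arg(figure_id)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  params <- cfg$params
  tc <- config_train(cfg)
  tables <- list()

  train_family <- function(preassign, n) {
    lapply(seq_len(n), function(k) {
      nc <- config_network(cfg)
      nc <- network_config(nc$N_E, nc$N_I, nc$output_mode,
                           preassign = preassign, init = nc$init)
      net <- build_network(nc, params, seed = derive_seed(cfg$seed, paste0("net", k)))
      train_network(net, tc, seed = derive_seed(cfg$seed, paste0("tr", k)))
    })
  }
  pooled_features <- function(trainings) {
    do.call(rbind, lapply(trainings, function(tr) {
      ev <- evaluate_network(tr$net, "pulses300", seed = derive_seed(cfg$seed, "ev"))
      cbind(in_features(tr$net, ev$record),
            r_soma = ev$r[["soma"]], r_dend = ev$r[["dend"]])
    }))
  }

  # weight filter expressed on this implementation's weight scale (weights
  # are of order 0.25/N_I; the cutoff drops only disconnected interneurons)
  min_w <- 0.1 / cfg$network$N_I

  if (figure_id %in% c("fig1", "fig2")) {
    trs <- train_family(preassign = (figure_id == "fig2"), n_networks)
    feats <- pooled_features(trs)
    cl <- cluster_interneurons(feats, 2, min_weight = min_w)
    feats$label <- NA
    feats$label[cl$keep] <- as.character(cl$labels)
    tables$features <- feats
    tables$cluster_means <- as.data.frame(cl$means)
    tables$ei <- unique(feats[, c("network", "r_soma", "r_dend")])
  } else if (figure_id == "fig3") {
    tr <- train_family(FALSE, 1)[[1]]
    ev <- evaluate_network(tr$net, "pulses300", seed = derive_seed(cfg$seed, "ev"))
    cl <- cluster_interneurons(in_features(tr$net, ev$record), 2,
                               min_weight = min_w)
    labels <- rep(NA, cfg$network$N_I)
    labels[cl$keep] <- as.character(cl$labels)
    tables$probe_soma <- pulse_probe(tr$net, "soma", labels = labels,
                                     seed = cfg$seed)
    tables$probe_dend <- pulse_probe(tr$net, "dend", labels = labels,
                                     seed = cfg$seed)
  } else if (figure_id == "fig4") {
    grid <- run_experiment_grid("input-correlation", config_network(cfg), tc,
                                params, seed = cfg$seed)
    tables$specialization <- data.frame(
      correlation = vapply(grid, function(g) as.numeric(g$level), 1),
      specialization = vapply(grid, function(g) g$specialization, 1),
      r_soma = vapply(grid, function(g) g$r[["soma"]], 1),
      r_dend = vapply(grid, function(g) g$r[["dend"]], 1))
  } else if (figure_id == "fig5") {
    trs <- train_family(FALSE, n_networks)
    feats <- pooled_features(trs)
    cl <- cluster_interneurons(feats, 2, min_weight = min_w)
    conn <- lapply(seq_along(trs), function(k) {
      rows <- which(feats$network == trs[[k]]$net$seed)
      labs <- rep(NA, length(rows))
      labs[cl$keep[rows]] <- as.character(cl$labels[cl$keep[rows] &
                                                      feats$network[cl$keep] == trs[[k]]$net$seed])
      labs <- factor(ifelse(is.na(labs), "PV", labs), levels = c("PV", "SST"))
      cluster_connectivity(labs, trs[[k]]$net$W_ii)
    })
    tables$connectivity <- cbind(network = seq_along(conn),
                                 as.data.frame(do.call(rbind, conn)))
    grid <- run_experiment_grid("knockout", config_network(cfg), tc, params,
                                seed = cfg$seed)
    tables$knockout <- data.frame(
      knockout = vapply(grid, function(g) as.character(g$level), ""),
      r_soma = vapply(grid, function(g) g$r[["soma"]], 1),
      r_dend = vapply(grid, function(g) g$r[["dend"]], 1))
  } else if (figure_id %in% c("s1", "s2")) {
    grid <- run_experiment_grid("min-rate", config_network(cfg), tc, params,
                                seed = cfg$seed)
    tables$min_rate <- data.frame(
      alpha_base = vapply(grid, function(g) as.numeric(g$level), 1),
      min_pv_rate = vapply(grid, function(g) {
        stats::quantile(g$features$rate, 0.1)
      }, 1),
      specialization = vapply(grid, function(g) g$specialization, 1),
      r_soma = vapply(grid, function(g) g$r[["soma"]], 1),
      r_dend = vapply(grid, function(g) g$r[["dend"]], 1))
  } else if (figure_id == "s3") {
    grid <- run_experiment_grid("no-stp", config_network(cfg), tc, params,
                                seed = cfg$seed)
    tables$no_stp <- data.frame(
      r_soma = vapply(grid, function(g) g$r[["soma"]], 1),
      r_dend = vapply(grid, function(g) g$r[["dend"]], 1))
  } else if (figure_id == "s4") {
    grid <- run_experiment_grid("heterogeneous", config_network(cfg), tc,
                                params, seed = cfg$seed)
    feats <- grid[[1]]$features
    cl <- cluster_interneurons(feats, 4, use_ppr = FALSE, min_weight = min_w)
    tables$clusters <- as.data.frame(cl$means)
    tables$proportions <- data.frame(label = rownames(cl$means),
                                     proportion = cl$proportions)
  }

  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]],
                     file.path(cfg$out, paste0(figure_id, "_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(tables)
}
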