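#' Evaluate a network on a standard stimulus
#'
#' Simulates the network on either the standard evaluation stimulus (fixed
#' 300 pA, 100 ms pulses at 2.5 Hz, onsets drawn independently for soma and
#' dendrite so the two input streams are uncorrelated) or on random-amplitude
#' batches (amplitudes from \{100, 200, 300, 400\} pA), and computes the
#' excitation-inhibition correlation of each compartment per batch.
#'
#' @param net a `ci_network`.
#' @param stimulus `"pulses300"` (fixed amplitude) or `"random"`.
#' @param n_batches,batch_size evaluation size (default 5 batches of 8
#'   trials).
#' @param seed integer seed.
#' @return list with the pooled `record`, per-batch correlations
#'   `r_batches`, and their mean `r` (named soma/dend).
#' @export
evaluate_network <- function(net, stimulus = c("pulses300", "random"),
                             n_batches = 5, batch_size = 8, seed = 1) {
  stimulus <- match.arg(stimulus)
  proto <- stimulus_protocol(
    fixed_amplitude = if (stimulus == "pulses300") 300 else NULL,
    correlation = 0)
  stim <- make_stimulus(proto, n_batches * batch_size,
                        seed = derive_seed(seed, "eval-stim"))
  rec <- simulate_network(net, stim, seed = derive_seed(seed, "eval-noise"))
  r_batches <- t(vapply(seq_len(n_batches), function(k) {
    ei_correlation(subset_record(rec, ((k - 1) * batch_size + 1):(k * batch_size)))
  }, numeric(2)))
  colnames(r_batches) <- c("soma", "dend")
  list(record = rec, r_batches = r_batches, r = colMeans(r_batches))
}

# Restrict a record to a subset of trials.
subset_record <- function(record, trials) {
  out <- record
  out$spikes_E <- record$spikes_E[, trials, , drop = FALSE]
  out$spikes_I <- record$spikes_I[, trials, , drop = FALSE]
  out$E_s <- record$E_s[, trials, , drop = FALSE]
  out$E_d <- record$E_d[, trials, , drop = FALSE]
  if (record$shared) {
    out$I_s <- record$I_s[trials, , drop = FALSE]
    out$I_d <- record$I_d[trials, , drop = FALSE]
  } else {
    out$I_s <- record$I_s[, trials, , drop = FALSE]
    out$I_d <- record$I_d[, trials, , drop = FALSE]
  }
  out$n_trials <- length(trials)
  out
}

#' Input-output curves under current-pulse probes
#'
#' Injects 100 ms current pulses of varying amplitude into one PC
#' compartment (all PCs) while the other compartment receives a constant
#' current, and measures during the pulse window: population event rate,
#' burst rate, burst probability, mean inhibitory current of each
#' compartment, and (when `labels` are given) PV and SST firing rates.
#' Means and standard deviations are over `n_repeats` stimulus repetitions.
#'
#' @param net a `ci_network`.
#' @param compartment `"soma"` or `"dend"`: the pulsed compartment.
#' @param amplitudes pulse amplitudes (pA).
#' @param background_other constant current to the other compartment (pA).
#' @param n_repeats repetitions per amplitude.
#' @param labels optional factor of IN class labels (PV/SST) for per-class
#'   rates.
#' @param seed integer seed.
#' @param window event-grouping window (ms).
#' @return data frame, one row per amplitude, with `<metric>_mean` and
#'   `<metric>_sd` columns.
#' @export
pulse_probe <- function(net, compartment = c("soma", "dend"),
                        amplitudes = c(100, 200, 300, 400),
                        background_other = 0, n_repeats = 10,
                        labels = NULL, seed = 1, window = 16) {
  compartment <- match.arg(compartment)
  trial_ms <- 600; on <- 200; off <- 300
  T_ <- trial_ms
  rows <- lapply(seq_along(amplitudes), function(ai) {
    amp <- amplitudes[ai]
    pulse <- matrix(0, T_, n_repeats)
    pulse[(on + 1):off, ] <- amp
    const <- matrix(background_other, T_, n_repeats)
    stim <- list(soma = if (compartment == "soma") pulse else const,
                 dend = if (compartment == "dend") pulse else const,
                 dt = 1)
    rec <- simulate_network(net, stim,
                            seed = derive_seed(seed, paste0("probe", compartment, ai)))
    win <- (on + 1):off
    per_rep <- vapply(seq_len(n_repeats), function(b) {
      N_E <- dim(rec$spikes_E)[1]
      ev <- unlist(lapply(seq_len(N_E), function(i) {
        tt <- which(rec$spikes_E[i, b, ] > 0)
        de <- detect_events(tt, window)
        c(sum(de$event_times > on & de$event_times <= off),
          sum(de$is_burst & de$event_times > on & de$event_times <= off))
      }))
      ev <- matrix(ev, nrow = 2)
      n_event <- sum(ev[1, ]); n_burst <- sum(ev[2, ])
      dur_s <- length(win) / 1000
      i_s <- if (rec$shared) mean(rec$I_s[b, win]) else mean(rec$I_s[, b, win])
      i_d <- if (rec$shared) mean(rec$I_d[b, win]) else mean(rec$I_d[, b, win])
      out <- c(event_rate = n_event / dur_s / N_E,
               burst_rate = n_burst / dur_s / N_E,
               burst_prob = burst_probability(n_burst, max(n_event, n_burst)),
               inh_soma = i_s, inh_dend = i_d)
      if (!is.null(labels)) {
        rate_in <- function(lab) {
          j <- which(labels == lab)
          if (!length(j)) return(NA_real_)
          mean(rec$spikes_I[j, b, win]) * 1000
        }
        out <- c(out, pv_rate = rate_in("PV"), sst_rate = rate_in("SST"))
      }
      out
    }, numeric(if (is.null(labels)) 5 else 7))
    stats_ <- cbind(amplitude = amp,
                    as.data.frame(t(rowMeans(per_rep))),
                    setNames(as.data.frame(t(apply(per_rep, 1, stats::sd))),
                             paste0(rownames(per_rep), "_sd")))
    stats_
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("^(event_rate|burst_rate|burst_prob|inh_soma|inh_dend|pv_rate|sst_rate)$",
                    "\\1_mean", names(out))
  out
}

#' Train families of networks for the standard experiment variants
#'
#' Drives the training of one network per level of a variant:
#' `"input-correlation"` sweeps the soma-dendrite input correlation,
#' `"min-rate"` sweeps the baseline-subtraction fraction `alpha_base`
#' (lower values force a higher minimum interneuron rate), `"knockout"`
#' trains pre-assigned networks that each lack one IN -> IN connection
#' class, `"no-stp"` freezes the release probabilities (training runs 4x
#' longer so a convergence deficit cannot explain failures), and
#' `"heterogeneous"` uses per-PC output weights.
#'
#' @param variant experiment family.
#' @param config a [network_config()] for the base network.
#' @param train_cfg a [train_config()] base configuration.
#' @param params biophysical parameters.
#' @param levels variant levels; defaults per variant: correlations
#'   `c(0, 0.5, 1)`, `alpha_base` `c(1, 0.9, 0.8)`, knockouts
#'   `c("none", "pv_pv", "pv_sst", "sst_pv", "sst_sst")`.
#' @param seed integer master seed.
#' @param eval_batches batches for the post-training evaluation.
#' @return list with one element per level: the trained result, the level,
#'   and evaluation metrics (E/I correlations, specialization, per-IN PPR).
#' @export
run_experiment_grid <- function(variant = c("input-correlation", "min-rate",
                                            "knockout", "no-stp",
                                            "heterogeneous"),
                                config = network_config(),
                                train_cfg = train_config(),
                                params = default_params(),
                                levels = NULL, seed = 1, eval_batches = 5) {
  variant <- match.arg(variant)
  levels <- switch(variant,
    "input-correlation" = levels %||% c(0, 0.5, 1),
    "min-rate" = levels %||% c(1, 0.9, 0.8),
    "knockout" = levels %||% c("none", "pv_pv", "pv_sst", "sst_pv", "sst_sst"),
    "no-stp" = levels %||% "frozen-stp",
    "heterogeneous" = levels %||% "heterogeneous")
  lapply(seq_along(levels), function(li) {
    lv <- levels[[li]]
    cfg <- config; tc <- train_cfg
    if (variant == "input-correlation") {
      tc$protocol$correlation <- as.numeric(lv)
    } else if (variant == "min-rate") {
      tc$alpha_base <- as.numeric(lv)
      cfg <- network_config(cfg$N_E, cfg$N_I, cfg$output_mode,
                            preassign = TRUE, init = cfg$init)
    } else if (variant == "knockout") {
      cfg <- network_config(cfg$N_E, cfg$N_I, cfg$output_mode,
                            preassign = TRUE,
                            knockout = if (identical(lv, "none")) NULL else lv,
                            init = cfg$init)
    } else if (variant == "no-stp") {
      tc$freeze_stp <- TRUE
      tc$n_updates <- 4 * tc$n_updates
    } else if (variant == "heterogeneous") {
      cfg <- network_config(cfg$N_E, cfg$N_I, "heterogeneous",
                            preassign = cfg$preassign, init = cfg$init)
    }
    net <- build_network(cfg, params, seed = derive_seed(seed, paste0("net", li)))
    tr <- train_network(net, tc, seed = derive_seed(seed, paste0("train", li)))
    ev <- evaluate_network(tr$net, "random", n_batches = eval_batches,
                           seed = derive_seed(seed, paste0("eval", li)))
    feats <- in_features(tr$net, ev$record)
    list(level = lv, training = tr, r = ev$r, r_batches = ev$r_batches,
         specialization = specialization(feats$w_soma, feats$w_dend),
         features = feats)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
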