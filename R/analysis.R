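#' Paired-pulse ratio of a Tsodyks-Markram synapse
#'
#' Simulates the release scale `mu = u * R` for two presynaptic spikes
#' `isi` ms apart, starting from rest (`u = U`, `R = 1`), with facilitation
#' applied before depletion at each spike and exact exponential relaxation
#' between the spikes. The paired-pulse ratio is `mu2 / mu1`: > 1 indicates
#' short-term facilitation, < 1 short-term depression. Because the
#' postsynaptic compartments are linear in their input, the ratio of release
#' scales equals the ratio of EPSP amplitudes in a passive postsynaptic
#' probe.
#'
#' For `U = 0` the first pulse releases nothing; the ratio is then computed
#' with an `eps`-regularized denominator and flagged as
#' facilitation-dominated.
#'
#' @param U initial release probability in \[0, 1\] (vectorized).
#' @param F facilitation fraction in \[0, 1\].
#' @param tau_u,tau_R facilitation and recovery time constants (ms).
#' @param isi inter-spike interval (ms); 10 ms is a typical interval within
#'   a burst.
#' @param eps denominator regularization.
#' @return list with `ppr`, the release scales `mu1`, `mu2`, and
#'   `facilitation_dominated` (`TRUE` where `mu1 < eps`).
#' @export
measure_ppr <- function(U, F, tau_u, tau_R, isi = 10, eps = 1e-9) {
  if (any(U < 0 | U > 1)) stop("invalid parameter: U must lie in [0, 1]")
  if (F < 0 || F > 1) stop("invalid parameter: F must lie in [0, 1]")
  if (tau_u <= 0 || tau_R <= 0 || isi <= 0) {
    stop("invalid parameter: time constants and isi must be > 0")
  }
  u1 <- U + (1 - U) * F          # facilitated utilization at spike 1
  mu1 <- u1                      # R = 1 at the first spike
  R2 <- 1 - u1 * exp(-isi / tau_R)
  u2m <- U + (u1 - U) * exp(-isi / tau_u)
  u2 <- u2m + (1 - u2m) * F
  mu2 <- u2 * R2
  list(ppr = mu2 / pmax(mu1, eps), mu1 = mu1, mu2 = mu2,
       facilitation_dominated = mu1 < eps)
}

#' Per-interneuron paired-pulse ratio of a network
#'
#' The PPR of one interneuron is the mean PPR over all its excitatory
#' afferents (one PC -> IN synapse each, with its own release probability).
#'
#' @param net a `ci_network`.
#' @param isi inter-spike interval (ms).
#' @return numeric vector of length `N_I`.
#' @export
network_ppr <- function(net, isi = 10) {
  s <- net$params$stp
  ppr <- measure_ppr(net$U, s$F, s$tau_u, s$tau_R, isi = isi)$ppr
  colMeans(matrix(ppr, nrow(net$U), ncol(net$U)))
}

#' Decompose a spike train into events and bursts
#'
#' Greedy left-to-right grouping: a spike within `window` ms of the previous
#' spike joins the current group; each group is one event, timestamped at
#' its first spike; groups of two or more spikes are bursts. Every spike
#' belongs to exactly one event.
#'
#' @param spike_times sorted numeric vector of spike times (ms).
#' @param window grouping window (ms).
#' @return list with `event_times`, logical `is_burst`, and `n_spikes` per
#'   event.
#' @export
detect_events <- function(spike_times, window = 16) {
  if (length(spike_times) == 0) {
    return(list(event_times = numeric(0), is_burst = logical(0),
                n_spikes = integer(0)))
  }
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  grp <- cumsum(c(1L, as.integer(diff(spike_times) > window)))
  n_spikes <- as.integer(table(grp))
  first <- which(!duplicated(grp))
  list(event_times = spike_times[first], is_burst = n_spikes >= 2,
       n_spikes = n_spikes)
}

#' Burst probability
#'
#' `100 * burst_rate / event_rate` (percent); defined as 0 where the event
#' rate is 0.
#'
#' @param burst_rate,event_rate non-negative rates with
#'   `burst_rate <= event_rate` elementwise.
#' @return percentage in \[0, 100\].
#' @export
burst_probability <- function(burst_rate, event_rate) {
  if (any(burst_rate < 0) || any(event_rate < burst_rate)) {
    stop("need event_rate >= burst_rate >= 0")
  }
  ifelse(event_rate > 0, 100 * burst_rate / event_rate, 0)
}

#' Smoothed population rate trace
#'
#' Counts occurrences (spikes, events or bursts) in `bin`-ms bins across a
#' population and smooths with a Gaussian kernel (standard deviation
#' `smooth_sd` ms, normalized to unit mass so that total counts are
#' conserved away from the edges).
#'
#' @param times occurrence times pooled over the population (ms).
#' @param t_max trace duration (ms).
#' @param bin bin width (ms).
#' @param smooth_sd Gaussian kernel standard deviation (ms).
#' @param n_neurons population size used to express the result per neuron.
#' @return data frame with `time` (bin centers, ms) and `rate`
#'   (occurrences per second per neuron).
#' @export
population_rates <- function(times, t_max, bin = 1, smooth_sd = 2,
                             n_neurons = 1) {
  breaks <- seq(0, t_max, by = bin)
  counts <- if (length(times)) {
    as.vector(table(cut(times, breaks, right = FALSE,
                        include.lowest = FALSE)))
  } else rep(0, length(breaks) - 1)
  half <- ceiling(4 * smooth_sd / bin)
  kern <- stats::dnorm(seq(-half, half) * bin, 0, smooth_sd)
  kern <- kern / sum(kern)
  padded <- c(rep(0, half), counts, rep(0, half))
  sm <- stats::filter(padded, kern, sides = 2)
  sm <- as.vector(sm)[(half + 1):(half + length(counts))]
  data.frame(time = breaks[-length(breaks)] + bin / 2,
             rate = sm * 1000 / (bin * n_neurons))
}

#' Excitation-inhibition correlation per compartment
#'
#' Pearson correlation between the population-mean excitatory current and
#' the (sign-flipped) population-mean inhibitory current of each PC
#' compartment, over the concatenated trials of a record. A positive value
#' means inhibition tracks excitation in time.
#'
#' @param record a `ci_record`.
#' @return named vector `c(soma = r_s, dend = r_d)`; `NA` where a trace has
#'   zero variance.
#' @export
ei_correlation <- function(record) {
  pop_e_s <- apply(record$E_s, c(2, 3), mean)   # (B, T)
  pop_e_d <- apply(record$E_d, c(2, 3), mean)
  if (record$shared) {
    pop_i_s <- record$I_s; pop_i_d <- record$I_d
  } else {
    pop_i_s <- apply(record$I_s, c(2, 3), mean)
    pop_i_d <- apply(record$I_d, c(2, 3), mean)
  }
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  c(soma = safe_cor(as.vector(pop_e_s), -as.vector(pop_i_s)),
    dend = safe_cor(as.vector(pop_e_d), -as.vector(pop_i_d)))
}

#' Specialization index of the interneuron output weights
#'
#' `1 - cos(x, y)` where `x` and `y` are the vectors of somatic and
#' dendritic output weights across interneurons. 1 means every IN targets a
#' single compartment (disjoint support); 0 means the two weight vectors are
#' proportional (no compartment specialization).
#'
#' @param x,y non-negative weight vectors of equal length.
#' @return scalar in \[0, 1\]; `NA` if either vector is all zero.
#' @export
specialization <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("weights must be non-negative")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  1 - sum(x * y) / (nx * ny)
}

# Mclust() builds a call to mclustBIC() and evaluates it in the caller's
# frame, so the symbol must be visible in this namespace.
mclustBIC <- mclust::mclustBIC

#' Per-interneuron feature table for clustering
#'
#' Collects, for every interneuron of a network, the somatic and dendritic
#' output weight (absolute value; mean over PCs in heterogeneous mode), the
#' mean paired-pulse ratio of its excitatory afferents, and its firing rate
#' on an evaluation record.
#'
#' @param net a `ci_network`.
#' @param record a `ci_record` of the evaluation stimulus (for the rates).
#' @return data frame with one row per IN: `w_soma`, `w_dend`, `ppr`,
#'   `rate`, `network` (the network seed, for pooling).
#' @export
in_features <- function(net, record) {
  if (net$config$output_mode == "shared") {
    w_s <- abs(net$w_soma) * net$masks$soma
    w_d <- abs(net$w_dend) * net$masks$dend
  } else {
    w_s <- rowMeans(abs(net$w_soma) * net$masks$soma)
    w_d <- rowMeans(abs(net$w_dend) * net$masks$dend)
  }
  data.frame(w_soma = as.vector(w_s), w_dend = as.vector(w_d),
             ppr = network_ppr(net), rate = record$rate_I,
             network = net$seed)
}

#' Cluster interneurons by connectivity and short-term plasticity
#'
#' Fits a Gaussian mixture model to the per-IN features (somatic weight,
#' dendritic weight, paired-pulse ratio; or the 2-D weight space when
#' `use_ppr = FALSE`), after discarding inactive INs (rate <= `min_rate`
#' spk/s) and INs without a medium-to-strong projection to either
#' compartment (max weight <= `min_weight`). Hard labels are assigned by
#' maximum responsibility. With two components the higher-PPR component is
#' named SST (facilitating, dendrite-targeting) and the lower-PPR component
#' PV (depressing, soma-targeting); without PPR the naming uses the
#' soma-vs-dendrite weight contrast.
#'
#' @param features feature table, typically [in_features()] pooled over
#'   several networks.
#' @param n_components number of mixture components (1, 2 or 4).
#' @param min_rate activity filter (spk/s).
#' @param min_weight projection-strength filter.
#' @param use_ppr include the PPR as a clustering feature.
#' @return list with the fitted `model` (a `mclust::Mclust` object), `keep`
#'   (logical filter over input rows), `labels` (factor per kept IN),
#'   `means` (feature means per component) and `proportions`.
#' @export
cluster_interneurons <- function(features, n_components = 2, min_rate = 1,
                                 min_weight = 0.01, use_ppr = TRUE) {
  keep <- features$rate > min_rate &
    pmax(features$w_soma, features$w_dend) > min_weight
  X <- features[keep, c("w_soma", "w_dend", if (use_ppr) "ppr"), drop = FALSE]
  if (nrow(X) < n_components) stop("fewer data points than mixture components")
  fit <- mclust::Mclust(as.matrix(X), G = n_components, verbose = FALSE)
  if (is.null(fit)) stop("mixture model failed to fit")
  means <- t(fit$parameters$mean)
  cls <- fit$classification
  comp_names <- paste0("C", seq_len(n_components))
  if (n_components == 2) {
    score <- if (use_ppr) means[, "ppr"] else means[, "w_dend"] - means[, "w_soma"]
    comp_names[order(score)] <- c("PV", "SST")
  } else if (n_components == 4) {
    spec_score <- (means[, "w_dend"] - means[, "w_soma"]) /
      pmax(means[, "w_dend"] + means[, "w_soma"], 1e-12)
    comp_names[which.min(spec_score)] <- "PV"
    comp_names[which.max(spec_score)] <- "SST"
    rest <- setdiff(seq_len(4), c(which.min(spec_score), which.max(spec_score)))
    comp_names[rest] <- paste0("NS", seq_along(rest))
  }
  rownames(means) <- comp_names
  labels <- factor(comp_names[cls], levels = comp_names)
  list(model = fit, keep = keep, labels = labels, means = means,
       proportions = as.vector(table(labels)) / length(labels))
}

#' Mean connection strength between interneuron classes
#'
#' Averages the absolute IN -> IN weights within and between the PV and SST
#' classes (autapses excluded). Naming is pre_post: `pv_sst` is the mean
#' strength of PV -> SST connections.
#'
#' @param labels factor of class labels (`"PV"`/`"SST"`) per IN, aligned
#'   with the rows/columns of `W_ii`.
#' @param W_ii IN -> IN weight matrix (rows = postsynaptic).
#' @return named vector `c(pv_pv, pv_sst, sst_pv, sst_sst)`.
#' @export
cluster_connectivity <- function(labels, W_ii) {
  stopifnot(length(labels) == nrow(W_ii), nrow(W_ii) == ncol(W_ii))
  W <- abs(W_ii)
  off <- !diag(TRUE, nrow(W))
  blk <- function(pre, post) {
    sel <- outer(labels == post, labels == pre) & off   # rows post, cols pre
    if (!any(sel)) return(NA_real_)
    mean(W[sel])
  }
  c(pv_pv = blk("PV", "PV"), pv_sst = blk("PV", "SST"),
    sst_pv = blk("SST", "PV"), sst_sst = blk("SST", "SST"))
}
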