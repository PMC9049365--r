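#' Parameters of the linear PV/SST/PC rate model
#'
#' A reduced circuit in which PC activity is summarized by an event rate `e`
#' (driven by somatic input) and a burst rate `b` (driven by dendritic
#' input, assumed independent of the somatic input), and the interneuron
#' populations by rates `p` (PV) and `s` (SST). Short-term plasticity of
#' each PC -> IN pathway is a single static transmission parameter: the PC
#' drive onto population Y is `W * (lambda * e + (1 - lambda) * b)`, where
#' `lambda = 1` transmits events but not bursts ("perfectly depressing") and
#' `lambda = 0` transmits only bursts ("perfectly facilitating"); `alpha` is
#' the parameter of the PC -> PV pathway and `beta` of the PC -> SST
#' pathway. Inhibition between interneurons is subtractive with
#' non-negative weights `W_<post>_<pre>`.
#'
#' @param W_p_pc,W_s_pc PC drive weights onto PV and SST.
#' @param W_p_s SST -> PV weight; `W_s_p` PV -> SST; `W_p_p`, `W_s_s`
#'   self-inhibition within each class.
#' @param alpha,beta event-transmission parameters in \[0, 1\] of the
#'   PC -> PV and PC -> SST synapses.
#' @return list of class `ci_rate_params`.
#' @export
rate_params <- function(W_p_pc = 1, W_s_pc = 1, W_p_s = 0, W_s_p = 0,
                        W_p_p = 0, W_s_s = 0, alpha = 1, beta = 0) {
  prm <- list(W_p_pc = W_p_pc, W_s_pc = W_s_pc, W_p_s = W_p_s, W_s_p = W_s_p,
              W_p_p = W_p_p, W_s_s = W_s_s, alpha = alpha, beta = beta)
  if (any(unlist(prm[1:6]) < 0)) stop("rate-model weights must be non-negative")
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop("transmission parameters must lie in [0, 1]")
  }
  structure(prm, class = "ci_rate_params")
}

rate_drives <- function(prm, e, b) {
  c(p = prm$W_p_pc * (prm$alpha * e + (1 - prm$alpha) * b),
    s = prm$W_s_pc * (prm$beta * e + (1 - prm$beta) * b))
}

#' Steady state of the rate model
#'
#' Solves the rectified linear fixed point
#' `p = [d_p - W_p_s s - W_p_p p]_+`, `s = [d_s - W_s_p p - W_s_s s]_+`
#' where `d_p`, `d_s` are the PC drives. The interior 2x2 system is solved
#' first; if a rate comes out negative it is clamped to zero and the other
#' population re-solved (one-sided rectification).
#'
#' @param prm a [rate_params()].
#' @param e,b non-negative event and burst rates.
#' @return named vector `c(p, s)` and attribute `"interior"` (`TRUE` when
#'   neither rate is rectified).
#' @export
rate_steady_state <- function(prm, e, b) {
  stopifnot(e >= 0, b >= 0)
  d <- rate_drives(prm, e, b)
  M <- matrix(c(1 + prm$W_p_p, prm$W_p_s,
                prm$W_s_p, 1 + prm$W_s_s), 2, 2, byrow = TRUE)
  det_ <- det(M)
  if (det_ <= 0) {
    stop(sprintf("rate circuit has no stable fixed point (determinant %.3g <= 0)",
                 det_))
  }
  x <- solve(M, d)
  interior <- all(x >= 0)
  if (!interior) {
    if (x[1] < 0 && x[2] < 0) x <- c(0, 0)
    else if (x[1] < 0) x <- c(0, max(0, d[2] / (1 + prm$W_s_s)))
    else x <- c(max(0, d[1] / (1 + prm$W_p_p)), 0)
  }
  out <- c(p = unname(x[1]), s = unname(x[2]))
  attr(out, "interior") <- interior
  out
}

#' Sensitivities of the interneuron rates to events and bursts
#'
#' At an interior fixed point the steady state is linear in `(e, b)`:
#' `s = A e + B b` and `p = A_p e + B_p b`. The factors are computed exactly
#' from the solved linear system. `A = 0` is the condition for the SST rate
#' (and hence dendritic inhibition, if SST targets only dendrites) to be
#' independent of somatic input; `B_p = 0` is the somatic mirror condition.
#'
#' @param prm a [rate_params()].
#' @param e,b operating point (only relevant through rectification; the
#'   interior sensitivities are constant).
#' @return named vector `c(A = ds/de, B = ds/db, A_p = dp/de, B_p = dp/db)`.
#' @export
rate_sensitivities <- function(prm, e = 1, b = 1) {
  ss <- rate_steady_state(prm, e, b)
  if (!attr(ss, "interior")) {
    warning("rectified fixed point: sensitivities are one-sided")
  }
  M <- matrix(c(1 + prm$W_p_p, prm$W_p_s,
                prm$W_s_p, 1 + prm$W_s_s), 2, 2, byrow = TRUE)
  Minv <- solve(M)
  de <- c(prm$W_p_pc * prm$alpha, prm$W_s_pc * prm$beta)
  db <- c(prm$W_p_pc * (1 - prm$alpha), prm$W_s_pc * (1 - prm$beta))
  se <- Minv %*% de; sb <- Minv %*% db
  c(A = se[2], B = sb[2], A_p = se[1], B_p = sb[1])
}

#' Residual of the dendritic-specificity condition
#'
#' `beta * W_SST<-PC - alpha * W_SST<-PV * W_PV<-PC`: the monosynaptic
#' event drive onto SST minus the event drive relayed through the disynaptic
#' PC -> PV -> SST pathway. Without interneuron self-connections this
#' residual is proportional to the sensitivity `A = ds/de`, so residual 0
#' means the SST rate ignores somatic input; unless PC -> SST synapses are
#' perfectly facilitating (`beta = 0`), PV -> SST connections are needed to
#' cancel the monosynaptic term.
#'
#' @param prm a [rate_params()].
#' @return scalar residual.
#' @export
dendritic_specificity_residual <- function(prm) {
  prm$beta * prm$W_s_pc - prm$alpha * prm$W_s_p * prm$W_p_pc
}

#' Residual of the somatic-specificity condition
#'
#' The mirror condition obtained by exchanging the roles of PV and SST and
#' of events and bursts: `(1 - alpha) * W_PV<-PC - (1 - beta) * W_PV<-SST *
#' W_SST<-PC`. Without self-connections it is proportional to
#' `B_p = dp/db`; residual 0 means the PV rate (somatic inhibition) ignores
#' dendritic input, which requires disynaptic PC -> SST -> PV inhibition
#' unless PC -> PV synapses are perfectly depressing (`alpha = 1`).
#'
#' @param prm a [rate_params()].
#' @return scalar residual.
#' @export
somatic_specificity_residual <- function(prm) {
  (1 - prm$alpha) * prm$W_p_pc - (1 - prm$beta) * prm$W_p_s * prm$W_s_pc
}
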