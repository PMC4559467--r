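stdp_amp_plus <- function(w, params) {
  switch(params$mode,
         additive = params$a_plus_eff,
         partly_multiplicative = params$a_plus_eff,
         fully_multiplicative = params$a_plus_eff * (1 - w / params$w_max))
}

stdp_amp_minus <- function(w, params) {
  switch(params$mode,
         additive = params$a_minus_eff,
         partly_multiplicative = params$a_minus_eff * (w / params$w_max),
         fully_multiplicative = params$a_minus_eff * (w / params$w_max))
}

#' Weight change of a single spike pairing
#'
#' Exponential STDP kernel with all-to-all pairing semantics: a pairing
#' with `delta_t = t_post - t_pre > 0` potentiates by
#' `A_plus(w) exp(-delta_t / tau_plus)`, a pairing with `delta_t <= 0`
#' depresses by `A_minus(w) exp(delta_t / tau_minus)` (zero lag belongs to
#' the depression branch).
#'
#' @param delta_t `t_post - t_pre` (ms).
#' @param w current weight (only used by the weight-dependent rules).
#' @param params an [stdp_params()] record.
#' @return The signed weight change.
#' @export
#' @examples
#' pair_delta_w(10, 1, stdp_params())   # potentiation
#' pair_delta_w(-10, 1, stdp_params())  # depression
pair_delta_w <- function(delta_t, w = 1, params = stdp_params()) {
  ifelse(delta_t > 0,
         stdp_amp_plus(w, params) * exp(-delta_t / params$tau_plus),
         -stdp_amp_minus(w, params) * exp(delta_t / params$tau_minus))
}

#' Online STDP updates at a pre- or postsynaptic spike
#'
#' Standard online realization of the all-to-all pair rule with
#' exponential eligibility traces.  `traces` is a list with `x_pre` and
#' `x_post`, the presynaptic and postsynaptic trace values of the synapse
#' *already decayed to the current spike time*.  `stdp_on_pre` is called
#' when the presynaptic cell fires: the weight is depressed by
#' `A_minus(w) * x_post` and the presynaptic trace increments by one.
#' `stdp_on_post` mirrors this with potentiation and `x_pre`.  Weights are
#' clipped to `[0, w_max]`.
#'
#' @param w current synaptic weight.
#' @param traces list with numeric `x_pre`, `x_post`.
#' @param params an [stdp_params()] record.
#' @return A list with the updated `w` and `traces`.
#' @export
stdp_on_pre <- function(w, traces, params = stdp_params()) {
  w <- max(0, w - stdp_amp_minus(w, params) * traces$x_post)
  traces$x_pre <- traces$x_pre + 1
  list(w = min(w, params$w_max), traces = traces)
}

#' @rdname stdp_on_pre
#' @export
stdp_on_post <- function(w, traces, params = stdp_params()) {
  w <- min(params$w_max, w + stdp_amp_plus(w, params) * traces$x_pre)
  traces$x_post <- traces$x_post + 1
  list(w = max(0, w), traces = traces)
}

#' Accumulated STDP change over a pair of spike trains
#'
#' Processes two spike trains through the online trace realization and
#' returns the accumulated weight change of the synapse.  With
#' `clip = FALSE` (and the additive rule) this is exactly equivalent to
#' summing the kernel over all spike pairs, which is the brute-force
#' oracle used in the tests.  Simultaneous pre/post spikes follow the
#' engine's ordering: the zero-lag pairing takes the depression branch.
#'
#' @param pre_times,post_times spike times (ms).
#' @param params an [stdp_params()] record.
#' @param w0 initial weight.
#' @param clip clip to `[0, w_max]` after each event (as the engine does).
#' @return Final weight `w0 + sum(dw)`.
#' @export
stdp_accumulate_train <- function(pre_times, post_times,
                                  params = stdp_params(), w0 = 0,
                                  clip = FALSE) {
  ev <- rbind(data.frame(t = pre_times, pre = TRUE),
              data.frame(t = post_times, pre = FALSE))
  # at equal times the post event is processed first so that the zero-lag
  # pairing is seen by the depression branch
  ev <- ev[order(ev$t, ev$pre), , drop = FALSE]
  w <- w0
  x_pre <- 0; x_post <- 0
  t_pre <- -Inf; t_post <- -Inf
  for (k in seq_len(nrow(ev))) {
    t <- ev$t[k]
    if (ev$pre[k]) {
      x_post <- x_post * exp(-(t - t_post) / params$tau_minus); t_post <- t
      w <- w - stdp_amp_minus(w, params) * x_post
      if (clip) w <- max(0, w)
      x_pre <- x_pre * exp(-(t - t_pre) / params$tau_plus) + 1; t_pre <- t
    } else {
      x_pre <- x_pre * exp(-(t - t_pre) / params$tau_plus); t_pre <- t
      w <- w + stdp_amp_plus(w, params) * x_pre
      if (clip) w <- min(params$w_max, w)
      x_post <- x_post * exp(-(t - t_post) / params$tau_minus) + 1; t_post <- t
    }
  }
  w
}

#' Normalize the incoming weight vector of one cell
#'
#' Multiplicative weight normalization at the postsynaptic site: the
#' vector of incoming E-E weights is rescaled to
#' `w * in_degree * target_mean / sum(w)`, so the post-normalization sum
#' equals `in_degree * target_mean` exactly while relative proportions are
#' preserved.  An all-zero vector is returned unchanged with a warning.
#'
#' @param weights_in numeric vector of incoming weights.
#' @param in_degree its length (checked).
#' @param target_mean target per-synapse mean (default 1).
#' @return The rescaled weight vector.
#' @export
#' @examples
#' normalize_incoming(c(3, 1), 2) # c(1.5, 0.5)
normalize_incoming <- function(weights_in, in_degree = length(weights_in),
                               target_mean = 1) {
  stopifnot(length(weights_in) == in_degree, in_degree > 0)
  s <- sum(weights_in)
  if (s <= 0) {
    warning("all-zero incoming weight vector: normalization skipped")
    return(weights_in)
  }
  weights_in * (in_degree * target_mean / s)
}

#' One synaptic scaling step
#'
#' Slow homeostatic scaling `dw/dt = -gamma (nu - nu_0) w^2`, integrated
#' over one step of length `dt_step` and clipped to `[0, w_max]`.
#'
#' @param w weight (scalar or vector).
#' @param nu measured firing rate (Hz).
#' @param gamma learning rate, `nu_0` target rate (Hz).
#' @param nu_0 target rate (Hz).
#' @param dt_step step length (s).
#' @param w_max clipping bound.
#' @return The updated weight.
#' @export
#' @examples
#' scaling_step(1, nu = 5, dt_step = 0.05) # 1 - 2.5e-7
scaling_step <- function(w, nu, gamma = 1e-6, nu_0 = 0, dt_step = 0.05,
                         w_max = 20) {
  stopifnot(all(nu >= 0), gamma >= 0, dt_step > 0)
  pmin(pmax(w - gamma * (nu - nu_0) * w^2 * dt_step, 0), w_max)
}

#' Integral of an STDP kernel
#'
#' `A_plus tau_plus - A_minus tau_minus` with the effective amplitudes:
#' negative for the depression-dominated E-E rule (factor 1.05), positive
#' for the potentiation-dominated I-E rule (ratio 4).
#'
#' @param params an [stdp_params()] record.
#' @return The signed kernel integral.
#' @export
stdp_kernel_integral <- function(params) {
  params$a_plus_eff * params$tau_plus - params$a_minus_eff * params$tau_minus
}
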