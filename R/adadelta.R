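#' One Adadelta update step
#'
#' Adadelta scales each parameter's update by the ratio of the running RMS
#' of past updates to the running RMS of current gradients, removing the
#' need for a global learning rate:
#' \deqn{E[g^2]_t = \gamma E[g^2]_{t-1} + (1-\gamma) g_t^2}
#' \deqn{\Delta\theta_t = -\frac{RMS[\Delta\theta]_{t-1}}{RMS[g]_t} g_t,
#'       \quad RMS[v]_t = \sqrt{E[v^2]_t + \epsilon}}
#' \deqn{E[\Delta\theta^2]_t = \gamma E[\Delta\theta^2]_{t-1}
#'       + (1-\gamma)\Delta\theta_t^2, \qquad
#'       \theta_{t+1} = \theta_t + \Delta\theta_t}
#' with decay `gamma = 0.95` and smoothing `epsilon = 1e-7` by default.
#' All operations are element-wise.
#'
#' @param state an [AdadeltaState-class] (see [adadeltaInit()]).
#' @param gradient gradient vector, same length as `state@theta`.
#' @return The updated [AdadeltaState-class].
#' @export
adadeltaStep <- function(state, gradient) {
  stopifnot(is(state, "AdadeltaState"))
  g <- as.numeric(gradient)
  if (length(g) != length(state@theta))
    stop("adadeltaStep: gradient length mismatch")
  if (any(!is.finite(g)))
    stop("adadeltaStep: non-finite gradient")
  upd <- adadeltaCore(state@theta, g, state@accumGradSq, state@accumUpdateSq,
                      state@gamma, state@epsilon)
  state@theta <- upd$theta
  state@accumGradSq <- upd$Eg
  state@accumUpdateSq <- upd$Ed
  state@t <- state@t + 1L
  state
}

# shared element-wise kernel; also used internally on weight arrays
adadeltaCore <- function(theta, g, Eg, Ed, gamma, epsilon) {
  Eg <- gamma * Eg + (1 - gamma) * g * g
  delta <- -(sqrt(Ed + epsilon) / sqrt(Eg + epsilon)) * g
  Ed <- gamma * Ed + (1 - gamma) * delta * delta
  list(theta = theta + delta, Eg = Eg, Ed = Ed)
}
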