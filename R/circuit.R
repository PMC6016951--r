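# Closed-form algebra of the passive isopotential equivalent circuit.
#
# All conductances are dimensionless, expressed relative to the leak
# conductance; all voltages are in mV relative to the leak reversal
# potential (E_leak = 0 by convention). The exc--inh configuration
# additionally reports responses relative to the resting potential
# V_rest = E_inh / 2 that obtains when the tonic inhibitory conductance
# equals the leak.

#' Parameters of the passive membrane equivalent circuit
#'
#' Bundles the battery (reversal) potentials and the leak conductance of a
#' passive isopotential membrane patch. Conductances elsewhere in the
#' package are expressed relative to \code{g_leak}, and voltages relative
#' to \code{E_leak}.
#'
#' @param E_exc Excitatory reversal potential (mV, relative to leak).
#' @param E_inh Inhibitory reversal potential (mV, relative to leak).
#' @param E_leak Leak reversal potential (mV); kept at 0 by convention.
#' @param g_leak Leak conductance (dimensionless reference, must be > 0).
#'
#' @return An object of class \code{"circuit_params"}.
#' @export
#' @examples
#' circuit_params(E_exc = 50, E_inh = -10)
circuit_params <- function(E_exc = 50, E_inh = -20, E_leak = 0, g_leak = 1) {
  if (!is.numeric(g_leak) || g_leak <= 0) {
    stop("`g_leak` must be a positive number", call. = FALSE)
  }
  structure(
    list(E_exc = E_exc, E_inh = E_inh, E_leak = E_leak, g_leak = g_leak),
    class = "circuit_params"
  )
}

#' Steady-state membrane voltage of the passive patch
#'
#' Solves the equivalent circuit at steady state (capacitive current
#' neglected): \deqn{V_m = (E_{exc} g_{exc} + E_{inh} g_{inh}) /
#' (g_{exc} + g_{inh} + g_{leak})} with voltages relative to the leak
#' reversal. Vectorised over the conductance arguments.
#'
#' @param g_exc Excitatory conductance(s), relative to leak, >= 0.
#' @param g_inh Inhibitory conductance(s), relative to leak, >= 0.
#' @param params A \code{\link{circuit_params}} object.
#'
#' @return Membrane voltage(s) in mV relative to \code{E_leak}.
#' @export
#' @examples
#' steady_state_voltage(1, 1, circuit_params(E_exc = 50, E_inh = -20)) # 10 mV
steady_state_voltage <- function(g_exc, g_inh, params = circuit_params()) {
  if (any(g_exc < 0) || any(g_inh < 0)) {
    stop("conductances must be non-negative", call. = FALSE)
  }
  (params$E_exc * g_exc + params$E_inh * g_inh) /
    (g_exc + g_inh + params$g_leak)
}

#' Response of the circuit to two excitatory inputs (sublinear regime)
#'
#' Drives two excitatory conductances with equal inputs \code{x} and
#' compares the response to both inputs with the linear expectation
#' (sum of the responses to each input alone). For a passive membrane the
#' nonlinear component \code{R_nonlin = R12 - (R1 + R2)} is always
#' negative: the circuit is sublinear.
#'
#' @param x Dimensionless input drive(s), >= 0; each drive sets one
#'   excitatory conductance directly.
#' @param params A \code{\link{circuit_params}} object (only \code{E_exc}
#'   and \code{g_leak} are used).
#'
#' @return A data frame with columns \code{x, R1, R2, R12,
#'   linear_expectation, R_nonlin, V_rest} (all voltages mV, relative to
#'   rest; here \code{V_rest = 0}).
#' @export
#' @examples
#' response_exc_exc(1, circuit_params(E_exc = 50))  # R_nonlin = -50/3
response_exc_exc <- function(x, params = circuit_params()) {
  if (any(x < 0)) stop("input drive must be non-negative", call. = FALSE)
  E <- params$E_exc
  R1 <- E * x / (x + 1)
  R12 <- E * 2 * x / (2 * x + 1)
  data.frame(
    x = x,
    R1 = R1,
    R2 = R1,
    R12 = R12,
    linear_expectation = 2 * R1,
    R_nonlin = E * (-2 * x^2) / (2 * x^2 + 3 * x + 1),
    V_rest = 0
  )
}

#' Response to an excitatory input paired with release from inhibition
#'
#' The excitatory conductance follows the drive \code{x} while the
#' inhibitory conductance follows \code{1 - y} (with \code{x = y} here):
#' the second input does not excite, it withdraws tonic inhibition. At
#' rest (\code{x = y = 0}) the inhibitory conductance equals the leak, so
#' \code{V_rest = E_inh / 2}; all responses are reported relative to this
#' resting potential. When \code{abs(E_exc) > abs(E_inh)} the nonlinear
#' component is positive for all \code{0 < x <= 1}: disinhibition raises
#' the input resistance and amplifies concurrent excitation even in a
#' purely passive membrane.
#'
#' @param x Dimensionless drive(s) in [0, 1] applied to both inputs.
#' @param params A \code{\link{circuit_params}} object.
#'
#' @return A data frame as in \code{\link{response_exc_exc}}, with
#'   \code{V_rest = E_inh / 2} and responses relative to it.
#' @export
#' @examples
#' response_exc_inh(1, circuit_params(E_exc = 50, E_inh = -10))
response_exc_inh <- function(x, params = circuit_params()) {
  if (any(x < 0) || any(x > 1)) {
    stop("input drive must lie in [0, 1] for the exc-inh configuration",
         call. = FALSE)
  }
  E <- params$E_exc
  Ei <- params$E_inh
  data.frame(
    x = x,
    R1 = (2 * E - Ei) * x / (2 * (x + 2)),
    R2 = (-Ei) * x / (2 * (2 - x)),
    R12 = (E - Ei) * x / 2,
    linear_expectation = (E * (2 - x) - 2 * Ei) * x / (4 - x^2),
    R_nonlin = x^2 * (E * (2 - x) + Ei * x) / (2 * (4 - x^2)),
    V_rest = Ei / 2
  )
}

#' Sweep the circuit nonlinearity over a grid of input drives
#'
#' Tabulates \code{R1, R2, R12}, the linear expectation and the nonlinear
#' response component over a drive grid, for either the two-excitatory
#' configuration (sublinear) or the excitatory/release-from-inhibition
#' configuration (supralinear).
#'
#' @param x_grid Numeric vector of drives (within the mode's domain).
#' @param params A \code{\link{circuit_params}} object.
#' @param mode \code{"exc_exc"} or \code{"exc_inh"}.
#'
#' @return A data frame, one row per grid point, ready for plotting or
#'   CSV export.
#' @export
nonlinearity_sweep <- function(x_grid, params = circuit_params(),
                               mode = c("exc_exc", "exc_inh")) {
  mode <- match.arg(mode)
  switch(mode,
    exc_exc = response_exc_exc(x_grid, params),
    exc_inh = response_exc_inh(x_grid, params)
  )
}
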