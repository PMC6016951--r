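# The motion-detector array: maps pathway signals onto conductances of
# the passive membrane for a (n-2) x n grid of rightward-preferring
# units (38 x 40 at the default geometry), solves the steady-state
# membrane voltage per frame, and pools the population after
# rectification -- the lobula-plate-tangential-cell-like readout.

#' Parameters of the detector membrane
#'
#' The passive-membrane constants used by the detector array:
#' \code{E_exc = +50} mV, \code{E_inh = -20} mV, \code{g_leak = 1}
#' (relative), and a rectification threshold of 0 mV for the population
#' readout.
#'
#' @inheritParams circuit_params
#' @param threshold Rectification threshold for the population readout,
#'   mV (default 0).
#'
#' @return An object of classes \code{"detector_params"} and
#'   \code{"circuit_params"}.
#' @export
detector_params <- function(E_exc = 50, E_inh = -20, g_leak = 1,
                            threshold = 0) {
  p <- circuit_params(E_exc = E_exc, E_inh = E_inh, g_leak = g_leak)
  p$threshold <- threshold
  class(p) <- c("detector_params", class(p))
  p
}

#' Detector variants
#'
#' \code{"full"}: both inhibitory arms present. \code{"nds_only"}: the
#' left (preferred-side, Mi9-like) arm is blocked, leaving only null
#' direction suppression by the trailing Mi4-like input.
#' \code{"pde_only"}: the right (null-side, Mi4-like) arm is blocked,
#' leaving only preferred direction enhancement by release from the
#' Mi9-like inhibition.
#'
#' @format Character vector of the three variant names.
#' @export
detector_variants <- c("full", "nds_only", "pde_only")

#' Map pathway signals onto detector conductances
#'
#' Each detector at column \code{i} (1 .. n-2), row \code{j} samples
#' three horizontally adjacent receptors: its excitatory conductance is
#' the central ON high-pass signal at column \code{i+1}; its inhibitory
#' conductance is the sum of the leading OFF low-pass signal at column
#' \code{i} (Mi9-like) and the trailing ON low-pass signal at column
#' \code{i+2} (Mi4-like). Blocking a variant's arm zeroes that
#' conductance term.
#'
#' @param pathways A \code{"pathway_signals"} object.
#' @param variant One of \code{\link{detector_variants}}.
#'
#' @return List with arrays \code{g_exc} and \code{g_inh} of dimension
#'   (n-2, n, nt).
#' @export
conductances <- function(pathways, variant = c("full", "nds_only",
                                               "pde_only")) {
  variant <- match.arg(variant)
  n <- dim(pathways$ON_hp)[1]
  if (n < 3L) stop("need at least 3 receptor columns", call. = FALSE)
  cols <- seq_len(n - 2L)
  g_exc <- pathways$ON_hp[cols + 1L, , , drop = FALSE]
  g_left <- pathways$OFF_lp[cols, , , drop = FALSE]       # Mi9-like, PD side
  g_right <- pathways$ON_lp[cols + 2L, , , drop = FALSE]  # Mi4-like, ND side
  g_inh <- switch(variant,
    full = g_left + g_right,
    nds_only = g_right,
    pde_only = g_left
  )
  list(g_exc = g_exc, g_inh = g_inh)
}

#' Membrane voltage of every detector
#'
#' Steady-state voltage of the passive patch per grid point and frame
#' (capacitive current neglected); same algebra as
#' \code{\link{steady_state_voltage}}. Unlike the circuit-level
#' operation this does not reject negative drives: under strong
#' luminance noise the OFF low-pass signal (low-pass of 1 minus
#' luminance) can transiently dip below zero, and the detector evaluates
#' the membrane equation on the filtered drives exactly as wired.
#'
#' @param g_exc,g_inh Conductance arrays from \code{\link{conductances}}.
#' @param params A \code{\link{detector_params}} object.
#'
#' @return Voltage array, mV relative to the leak reversal.
#' @export
membrane_voltage <- function(g_exc, g_inh, params = detector_params()) {
  (params$E_exc * g_exc + params$E_inh * g_inh) /
    (g_exc + g_inh + params$g_leak)
}

#' Rectified population average of the detector array
#'
#' The tangential-cell-like readout: at each frame, the mean over all
#' detectors of the membrane voltage rectified at \code{threshold}.
#'
#' @param Vm Voltage array (nc, nr, nt).
#' @param threshold Rectification threshold, mV.
#'
#' @return Numeric vector of length nt (>= 0 for threshold 0).
#' @export
population_output <- function(Vm, threshold = 0) {
  d <- dim(Vm)
  colMeans(matrix(pmax(Vm - threshold, 0), ncol = d[3]))
}

#' Run the full detector pipeline on a stimulus movie
#'
#' Composition: down-sample to the receptor grid, compute the pathway
#' signals, wire them onto the detector conductances for the requested
#' variant, solve the membrane voltage, and pool the rectified
#' population. Deterministic given its inputs.
#'
#' @param movie A \code{\link{stimulus_movie}}.
#' @param variant One of \code{\link{detector_variants}}.
#' @param params A \code{\link{detector_params}} object.
#' @param n_receptors Receptors per axis for the down-sampling step.
#' @param tau_lp,tau_hp,dc_fraction Filter parameters, see
#'   \code{\link{pathway_signals}}.
#'
#' @return An object of class \code{"detector_output"}: list with
#'   \code{Vm} (array (n-2) x n x nt, mV relative to leak reversal),
#'   \code{population} (rectified mean time series), \code{t},
#'   \code{variant} and \code{params}.
#' @export
#' @examples
#' g <- make_grating(1, dims = c(50, 50, 200))
#' out <- run_detector(g, n_receptors = 10)
#' max(out$population)
run_detector <- function(movie, variant = "full", params = detector_params(),
                         n_receptors = 40L, tau_lp = 0.05, tau_hp = 0.25,
                         dc_fraction = 0.1) {
  pw <- pathway_signals(downsample(movie, n_receptors),
                        tau_lp = tau_lp, tau_hp = tau_hp,
                        dc_fraction = dc_fraction)
  run_detector_from_pathways(pw, variant = variant, params = params)
}

#' Run the detector stage on precomputed pathway signals
#'
#' Useful when several variants are evaluated on the same stimulus: the
#' peripheral filtering is shared and only the wiring differs.
#'
#' @param pathways A \code{"pathway_signals"} object.
#' @inheritParams run_detector
#' @return A \code{"detector_output"}, as \code{\link{run_detector}}.
#' @export
run_detector_from_pathways <- function(pathways, variant = "full",
                                       params = detector_params()) {
  g <- conductances(pathways, variant)
  Vm <- membrane_voltage(g$g_exc, g$g_inh, params)
  structure(
    list(
      Vm = Vm,
      population = population_output(Vm, params$threshold),
      t = pathways$t,
      variant = variant,
      params = params
    ),
    class = "detector_output"
  )
}

#' Scalar response of a detector run
#'
#' Time-mean of the rectified population output after the onset
#' transient (default: from 1 s to the end of the movie). This is the
#' scalar entering the tuning curves.
#'
#' @param output A \code{"detector_output"}.
#' @param t_min Start of the averaging window, seconds.
#'
#' @return A single number (mV).
#' @export
mean_response <- function(output, t_min = 1) {
  mean(output$population[output$t >= t_min])
}
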