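# Peripheral processing: photoreceptor down-sampling and the temporal
# filter / rectification stages producing the interneuron-like pathway
# signals (Mi9-like OFF low-pass, Mi1-like ON high-pass, Mi4-like ON
# low-pass) on the receptor grid.

#' Down-sample a movie onto the photoreceptor grid
#'
#' Each photoreceptor averages a non-overlapping square block of pixels,
#' per frame (with the default geometry: 200 px / 40 receptors = 5 x 5
#' pixel blocks of 4.5 x 4.5 deg).
#'
#' @param movie A \code{\link{stimulus_movie}} whose spatial dimensions
#'   are divisible by \code{n}.
#' @param n Number of receptors per axis (default 40).
#'
#' @return An object of class \code{"photoreceptor_signals"}: a list with
#'   \code{signal} (array n x n x nt), \code{spacing} (deg between
#'   receptors), \code{dt} and \code{t}.
#' @export
downsample <- function(movie, n = 40L) {
  l <- movie$luminance
  d <- dim(l)
  if (d[1] %% n != 0L || d[2] %% n != 0L) {
    stop("movie spatial dimensions must be divisible by `n`", call. = FALSE)
  }
  bx <- d[1] %/% n; by <- d[2] %/% n; nt <- d[3]
  # sum within x-blocks, then within y-blocks, via reshapes
  sx <- colSums(array(l, c(bx, n, d[2] * nt)), dims = 1L)
  sxy <- colSums(aperm(array(sx, c(n, by, n, nt)), c(2L, 1L, 3L, 4L)),
                 dims = 1L)
  structure(
    list(signal = sxy / (bx * by), spacing = movie$pitch * bx,
         dt = movie$dt, t = movie$t),
    class = "photoreceptor_signals"
  )
}

#' First-order low-pass filter
#'
#' Discrete first-order low-pass with the exact exponential update
#' coefficient: \code{y[t] = y[t-1] + (1 - exp(-dt/tau)) * (x[t] -
#' y[t-1])}, applied along the last (time) dimension. The state is
#' initialised to the first sample, which suppresses spurious onset
#' transients; for a step from that initial state the discrete response
#' matches \code{1 - exp(-k dt / tau)} exactly.
#'
#' @param x Numeric vector, or array with time as the last dimension.
#' @param tau Time constant, seconds (> 0).
#' @param dt Sample interval, seconds.
#'
#' @return Filtered signal, same shape as \code{x}.
#' @export
lowpass <- function(x, tau, dt) {
  if (tau <= 0 || dt <= 0) stop("`tau` and `dt` must be positive",
                                call. = FALSE)
  d <- dim(x)
  nt <- if (is.null(d)) length(x) else d[length(d)]
  m <- matrix(x, ncol = nt)
  a <- 1 - exp(-dt / tau)
  y <- m
  if (nt > 1L) {
    for (k in 2:nt) y[, k] <- y[, k - 1L] + a * (m[, k] - y[, k - 1L])
  }
  if (is.null(d)) as.vector(y) else array(y, d)
}

#' First-order high-pass filter
#'
#' Complement of the low-pass: \code{x - lowpass(x, tau, dt)}. A constant
#' input yields zero everywhere (state initialised to the first sample).
#'
#' @inheritParams lowpass
#' @return Filtered signal, same shape as \code{x}.
#' @export
highpass <- function(x, tau, dt) {
  x - lowpass(x, tau, dt)
}

#' Compute the interneuron-like pathway signals
#'
#' From the photoreceptor signal \code{I} (per receptor, over time):
#' \itemize{
#'   \item \code{ON_hp}: high-pass (tau 250 ms) plus a 10\% DC fraction of
#'     \code{I}, rectified at 0 — the fast, transient central input
#'     (Mi1/Tm3 role);
#'   \item \code{ON_lp}: low-pass (tau 50 ms) of \code{I} — the slow,
#'     sustained null-side input (Mi4 role);
#'   \item \code{OFF_lp}: low-pass of \code{1 - I} — the OFF-centre,
#'     slow preferred-side input (Mi9 role);
#'   \item \code{OFF_hp}: sign-inverted high-pass, rectified — the OFF
#'     pathway's transient signal, computed for completeness but not used
#'     by the rightward ON-pathway detector.
#' }
#'
#' @param receptors A \code{"photoreceptor_signals"} object from
#'   \code{\link{downsample}}.
#' @param tau_lp Low-pass time constant, seconds (default 0.05).
#' @param tau_hp High-pass time constant, seconds (default 0.25).
#' @param dc_fraction Fraction of the raw receptor signal added to the
#'   high-pass output before rectification (default 0.1).
#'
#' @return An object of class \code{"pathway_signals"}: list with arrays
#'   \code{ON_hp}, \code{ON_lp}, \code{OFF_lp}, \code{OFF_hp} on the
#'   receptor grid, plus \code{spacing}, \code{dt}, \code{t}.
#' @export
pathway_signals <- function(receptors, tau_lp = 0.05, tau_hp = 0.25,
                            dc_fraction = 0.1) {
  I <- receptors$signal
  dt <- receptors$dt
  h <- highpass(I, tau_hp, dt) + dc_fraction * I
  structure(
    list(
      ON_hp = pmax(h, 0),
      OFF_hp = pmax(-h, 0),
      ON_lp = lowpass(I, tau_lp, dt),
      OFF_lp = lowpass(1 - I, tau_lp, dt),
      spacing = receptors$spacing, dt = dt, t = receptors$t
    ),
    class = "pathway_signals"
  )
}
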