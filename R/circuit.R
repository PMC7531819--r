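#' Parameters of the reduced two-population working-memory circuit
#'
#' Constructs the parameter set of the mean-field reduction of a
#' two-population spiking circuit for working memory. Each selective
#' excitatory population is described by its average NMDA synaptic gating
#' variable \eqn{S_i}; populations excite themselves with effective strength
#' \eqn{J_+} (`J11`, `J22`) and inhibit each other, through a linearized
#' interneuron pool, with strength \eqn{J_-} (`J12`, `J21`).
#'
#' The gating dynamics are
#' \deqn{dS_i/dt = -S_i/\tau_S + (1 - S_i)\,\gamma\, f(I_{i,tot})}
#' with the transfer function \eqn{f} given by [fi_curve()] and total
#' currents \eqn{I_{1,tot} = J_{11} S_1 - J_{12} S_2 + I_0 + I_{ext,1}}
#' (symmetrically for population 2).
#'
#' The kinetic coefficient `gamma` multiplies a rate in Hz, so it is stored
#' as a dimensionless number; the default 0.60 reproduces the canonical
#' attractor structure of the circuit (three attractors at the baseline
#' couplings, with the intermediate both-active state emerging near
#' \eqn{J_+ = 0.35} nA at \eqn{J_- = 0.05} nA).
#'
#' @param a f-I curve gain (Hz/nA).
#' @param b f-I curve threshold (Hz).
#' @param d f-I curve curvature (s).
#' @param gamma dimensionless kinetic coefficient of NMDA channel opening.
#' @param tau_S NMDA gating decay time constant (s).
#' @param J_plus self-excitation \eqn{J_+} (nA); sets both `J11` and `J22`.
#' @param J_minus mutual inhibition \eqn{J_-} (nA); sets both `J12` and `J21`.
#' @param I0 background synaptic current (nA).
#' @param I_ext1,I_ext2 selective external currents to populations 1 and 2 (nA).
#' @param J11,J22,J12,J21 individual couplings (nA); override `J_plus` /
#'   `J_minus` when supplied. Asymmetric values are accepted but flagged.
#'
#' @return An object of class `circuit_params`.
#' @examples
#' p <- circuit_params()
#' fi_curve(0.5, p)
#' @export
circuit_params <- function(a = 270, b = 108, d = 0.154,
                           gamma = 0.60, tau_S = 0.1,
                           J_plus = 0.30, J_minus = 0.05,
                           I0 = 0.31, I_ext1 = 0, I_ext2 = 0,
                           J11 = J_plus, J22 = J_plus,
                           J12 = J_minus, J21 = J_minus) {
  vals <- c(a = a, b = b, d = d, gamma = gamma, tau_S = tau_S,
            J11 = J11, J22 = J22, J12 = J12, J21 = J21,
            I0 = I0, I_ext1 = I_ext1, I_ext2 = I_ext2)
  if (!all(is.finite(vals)))
    stop("all circuit parameters must be finite")
  if (tau_S <= 0 || a <= 0 || d <= 0)
    stop("tau_S, a and d must be positive")
  p <- as.list(vals)
  p$symmetric <- isTRUE(all.equal(J11, J22)) && isTRUE(all.equal(J12, J21))
  if (!p$symmetric)
    warning("asymmetric couplings (J11 != J22 or J12 != J21); ",
            "the r/m1/m2/m3 taxonomy assumes population symmetry")
  class(p) <- "circuit_params"
  p
}

#' @exportS3Method base::print
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  cat(sprintf("  f-I curve: a = %g Hz/nA, b = %g Hz, d = %g s\n", x$a, x$b, x$d))
  cat(sprintf("  gating:    gamma = %g, tau_S = %g s\n", x$gamma, x$tau_S))
  cat(sprintf("  couplings: J+ = (%g, %g) nA, J- = (%g, %g) nA\n",
              x$J11, x$J22, x$J12, x$J21))
  cat(sprintf("  currents:  I0 = %g nA, I_ext = (%g, %g) nA\n",
              x$I0, x$I_ext1, x$I_ext2))
  invisible(x)
}

#' Replace the external stimulus currents of a parameter set
#'
#' @param params a [circuit_params()] object.
#' @param I_ext1,I_ext2 selective external currents (nA).
#' @return A modified `circuit_params` object.
#' @export
set_stimulus <- function(params, I_ext1 = 0, I_ext2 = 0) {
  stopifnot(inherits(params, "circuit_params"))
  params$I_ext1 <- I_ext1
  params$I_ext2 <- I_ext2
  params
}

#' Affine map between gating and current coordinates
#'
#' The total currents are an affine image of the gating state,
#' \eqn{I = M S + c} with \eqn{M = [[J_{11}, -J_{12}], [-J_{21}, J_{22}]]}
#' and \eqn{c = (I_0 + I_{ext,1}, I_0 + I_{ext,2})}. The map is invertible
#' whenever \eqn{J_{11} J_{22} > J_{12} J_{21}}, which holds for all
#' physiological coupling ranges considered here.
#'
#' @param params a [circuit_params()] object.
#' @return A list with the matrix `M`, offset `c`, inverse `Minv`, and
#'   determinant `detM`.
#' @export
coupling_map <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  M <- matrix(c(params$J11, -params$J21, -params$J12, params$J22), 2, 2)
  detM <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (abs(detM) < 1e-12)
    stop("singular coupling map: J11*J22 must differ from J12*J21")
  list(M = M,
       c = c(params$I0 + params$I_ext1, params$I0 + params$I_ext2),
       Minv = solve(M),
       detM = detM)
}

#' Population transfer function (f-I curve)
#'
#' First-passage-corrected transfer function of an integrate-and-fire
#' population, \eqn{f(I) = (aI - b) / (1 - e^{-d(aI - b)})}. The removable
#' singularity at \eqn{aI = b} is evaluated by series expansion, so the
#' returned rate is continuous and strictly increasing, with
#' \eqn{f(b/a) = 1/d}.
#'
#' @param I_tot total synaptic input current (nA); vectorized.
#' @param params a [circuit_params()] object.
#' @return Firing rate in Hz, same length as `I_tot`.
#' @export
fi_curve <- function(I_tot, params = circuit_params()) {
  if (!all(is.finite(I_tot))) stop("non-finite input current")
  x <- params$a * I_tot - params$b
  z <- params$d * x
  r <- ifelse(abs(z) < 1e-8,
              1 / params$d + x / 2 + params$d * x^2 / 12,
              x / (1 - exp(-z)))
  pmax(r, 0)
}

# derivative of the f-I curve with respect to current (Hz/nA)
fi_curve_deriv <- function(I_tot, params) {
  x <- params$a * I_tot - params$b
  z <- params$d * x
  e <- exp(-z)
  g <- ifelse(abs(z) < 1e-6,
              0.5 + z / 6 - z^3 / 180,
              (1 - e - x * params$d * e) / (1 - e)^2)
  params$a * g
}

#' Total synaptic currents from a gating state, and the inverse map
#'
#' @param S gating state: a length-2 vector or an n-by-2 matrix of
#'   \eqn{(S_1, S_2)} values.
#' @param params a [circuit_params()] object.
#' @return `currents_from_gating` returns the total currents \eqn{(I_{1,tot},
#'   I_{2,tot})} in nA, in the same shape as the input;
#'   `gating_from_currents` inverts the affine map.
#' @export
currents_from_gating <- function(S, params) {
  cm <- coupling_map(params)
  S <- rbind2cols(S)
  I <- S %*% t(cm$M)
  I[, 1] <- I[, 1] + cm$c[1]
  I[, 2] <- I[, 2] + cm$c[2]
  drop_shape(I, S)
}

#' @rdname currents_from_gating
#' @param I total currents: a length-2 vector or an n-by-2 matrix.
#' @export
gating_from_currents <- function(I, params) {
  cm <- coupling_map(params)
  I <- rbind2cols(I)
  Ic <- sweep(I, 2, cm$c)
  drop_shape(Ic %*% t(cm$Minv), I)
}

rbind2cols <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 2) else as.matrix(x)
}
drop_shape <- function(out, inp) {
  if (nrow(inp) == 1L && nrow(out) == 1L) drop(out) else out
}

#' Deterministic drift of the gating variables
#'
#' Evaluates \eqn{dS_i/dt = -S_i/\tau_S + (1 - S_i)\gamma f(I_{i,tot})}
#' at one state or at many states simultaneously.
#'
#' @param S a length-2 vector or n-by-2 matrix of gating states.
#' @param params a [circuit_params()] object.
#' @return Drift in gating units per second, same shape as `S`.
#' @export
drift_gating <- function(S, params) {
  Sm <- rbind2cols(S)
  I <- rbind2cols(currents_from_gating(Sm, params))
  f <- cbind(fi_curve(I[, 1], params), fi_curve(I[, 2], params))
  out <- -Sm / params$tau_S + (1 - Sm) * params$gamma * f
  drop_shape(out, Sm)
}

#' Deterministic drift in current coordinates
#'
#' The conjugated drift \eqn{F_I(I) = M F_S(M^{-1}(I - c))}, used when the
#' Fokker-Planck or Langevin problem is posed in the current plane where
#' the injected noise is isotropic.
#'
#' @param I a length-2 vector or n-by-2 matrix of total currents (nA).
#' @param params a [circuit_params()] object.
#' @return Drift in nA per second, same shape as `I`.
#' @export
drift_current <- function(I, params) {
  cm <- coupling_map(params)
  Im <- rbind2cols(I)
  S <- rbind2cols(gating_from_currents(Im, params))
  FS <- rbind2cols(drift_gating(S, params))
  drop_shape(FS %*% t(cm$M), Im)
}

#' Jacobian of the gating drift at a state
#'
#' @param S a length-2 gating state.
#' @param params a [circuit_params()] object.
#' @return The 2-by-2 Jacobian matrix \eqn{\partial F_i / \partial S_j}
#'   (units 1/s).
#' @export
drift_jacobian <- function(S, params) {
  cm <- coupling_map(params)
  I <- currents_from_gating(S, params)
  f <- fi_curve(I, params)
  fp <- fi_curve_deriv(I, params)
  J <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    J[i, j] <- -(i == j) / params$tau_S -
      (i == j) * params$gamma * f[i] +
      (1 - S[i]) * params$gamma * fp[i] * cm$M[i, j]
  }
  J
}

#' Dopamine D1 modulation factor for the synaptic couplings
#'
#' D1 receptor activation scales the NMDA-mediated effective couplings.
#' Both \eqn{J_+} and \eqn{J_-} are multiplied by the sigmoid
#' \deqn{Ce\,(1 + 0.2 / (1 + e^{(0.8 - D_1)/0.25}))}
#' where \eqn{D_1} is the relative receptor-activation level and the
#' normalization \eqn{Ce} is calibrated so that the factor equals 1 at
#' \eqn{D_1 = 1}. The factor is strictly increasing in \eqn{D_1} and
#' bounded in \eqn{(Ce, 1.2\,Ce)}.
#'
#' @param D1 relative D1 receptor activation level(s), non-negative;
#'   vectorized.
#' @return The multiplicative factor(s) on the couplings.
#' @examples
#' d1_factor(1)   # exactly 1 by calibration
#' d1_factor(0)   # hypodopaminergic weakening, ~0.886
#' @export
d1_factor <- function(D1) {
  if (!all(is.finite(D1)) || any(D1 < 0))
    stop("D1 must be finite and non-negative")
  Ce <- 1 / (1 + 0.2 / (1 + exp((0.8 - 1) / 0.25)))
  Ce * (1 + 0.2 / (1 + exp((0.8 - D1) / 0.25)))
}

#' Apply D1 modulation to a circuit parameter set
#'
#' @param params a [circuit_params()] object.
#' @param D1 relative D1 receptor-activation level (scalar, >= 0).
#' @return A `circuit_params` object with all four couplings multiplied by
#'   [d1_factor()] of `D1`.
#' @export
modulate_params <- function(params, D1) {
  stopifnot(inherits(params, "circuit_params"), length(D1) == 1L)
  fac <- d1_factor(D1)
  for (nm in c("J11", "J22", "J12", "J21")) params[[nm]] <- params[[nm]] * fac
  params
}

#' Stimulus protocols for working-memory trials
#'
#' A protocol is an ordered sequence of phases, each holding the selective
#' external currents fixed for a given duration. The named presets follow
#' the standard delayed-response structure: `"resting"` (no input),
#' `"loading"` (0.02 nA target current to population 1), and `"distractor"`
#' (0.02 nA to population 2 during maintenance).
#'
#' @param phases a data.frame with columns `duration` (s), `I_ext1`,
#'   `I_ext2` (nA), one row per phase.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(phases) {
  phases <- as.data.frame(phases)
  stopifnot(all(c("duration", "I_ext1", "I_ext2") %in% names(phases)))
  if (any(phases$duration <= 0)) stop("phase durations must be positive")
  if (any(phases$I_ext1 < 0 | phases$I_ext2 < 0))
    stop("stimulus amplitudes must be non-negative")
  structure(phases[c("duration", "I_ext1", "I_ext2")],
            class = c("stimulus_protocol", "data.frame"))
}

#' @rdname stimulus_protocol
#' @param name preset name: `"resting"`, `"loading"`, `"distractor"`, or
#'   `"trial"` (resting 0.5 s, loading 1 s, maintenance 2 s).
#' @param amplitude stimulus amplitude in nA (default 0.02).
#' @param duration phase duration in seconds for single-phase presets.
#' @export
protocol_preset <- function(name = c("resting", "loading", "distractor",
                                     "trial"),
                            amplitude = 0.02, duration = 2) {
  name <- match.arg(name)
  ph <- switch(name,
    resting    = data.frame(duration = duration, I_ext1 = 0, I_ext2 = 0),
    loading    = data.frame(duration = duration, I_ext1 = amplitude, I_ext2 = 0),
    distractor = data.frame(duration = duration, I_ext1 = 0, I_ext2 = amplitude),
    trial      = data.frame(duration = c(0.5, 1, 2),
                            I_ext1 = c(0, amplitude, 0),
                            I_ext2 = c(0, 0, 0)))
  stimulus_protocol(ph)
}
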