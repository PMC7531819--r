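# Mean first passage time: backward boundary-value problem
#   F . grad(tau) + D : grad grad(tau) = -1
# with tau = 0 on the absorbing destination set and zero normal derivative
# on the outer boundary. The backward operator is the transpose of the
# conservative forward finite-volume operator, so both solvers share the
# same exponential-fitting discretization and convergence behavior.

#' Destination region for first-passage problems
#'
#' @param center length-2 coordinates of the region center (grid frame).
#' @param radius disk radius in grid-frame units (default 0.02, shared
#'   with the Monte-Carlo passage sampler for comparability).
#' @return A list of class `destination`.
#' @export
destination_disk <- function(center, radius = 0.02) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(type = "disk", center = center, radius = radius),
            class = "destination")
}

destination_mask <- function(grid, destination) {
  if (is.matrix(destination) || is.logical(destination)) {
    m <- matrix(as.logical(destination), grid$nx, grid$ny)
    return(m)
  }
  stopifnot(inherits(destination, "destination"))
  pts <- grid_points(grid)
  d2 <- (pts[, 1] - destination$center[1])^2 +
    (pts[, 2] - destination$center[2])^2
  matrix(d2 <= destination$radius^2, grid$nx, grid$ny)
}

#' Mean first passage time field for an arbitrary drift
#'
#' @param grid a [grid2d()] object.
#' @param drift_fn vectorized drift function (see [fpe_operator()]).
#' @param Dt constant 2-by-2 diffusion tensor.
#' @param destination a [destination_disk()] or a logical matrix marking
#'   absorbing cells.
#' @return An object of class `mfpt_field`: list with `tau` (matrix, s),
#'   `grid`, `destination`, and the absorbing-cell count.
#' @export
mfpt_solve <- function(grid, drift_fn, Dt, destination) {
  mask <- destination_mask(grid, destination)
  if (!any(mask)) stop("destination region contains no grid cells")
  if (all(mask)) stop("destination region covers the whole domain")
  A <- fpe_operator(grid, drift_fn, Dt)
  N <- grid$nx * grid$ny
  B <- Matrix::t(A)
  dest <- which(as.logical(mask))
  # absorbing rows: tau = 0
  diagfix <- Matrix::sparseMatrix(i = dest, j = dest, x = 1, dims = c(N, N))
  keepmask <- Matrix::Diagonal(N, x = as.numeric(!(seq_len(N) %in% dest)))
  Bmod <- keepmask %*% B + diagfix
  rhs <- rep(-1, N); rhs[dest] <- 0
  tau <- as.numeric(Matrix::solve(Bmod, rhs))
  if (min(tau) < -1e-8 * max(abs(tau)))
    warning(sprintf("MFPT solution has negative values (min %.3e); discretization may be under-resolved", min(tau)))
  tau <- pmax(tau, 0)
  structure(list(tau = matrix(tau, grid$nx, grid$ny), grid = grid,
                 destination = destination, n_absorbing = length(dest)),
            class = "mfpt_field")
}

#' @exportS3Method base::print
print.mfpt_field <- function(x, ...) {
  cat(sprintf("<mfpt_field> %d x %d grid, %d absorbing cells, tau in [%.3g, %.3g] s\n",
              x$grid$nx, x$grid$ny, x$n_absorbing, min(x$tau), max(x$tau)))
  invisible(x)
}

#' Evaluate an MFPT field at a point
#'
#' @param field an `mfpt_field`.
#' @param point length-2 coordinates (or n-by-2 matrix).
#' @return Interpolated mean first passage time(s) in seconds.
#' @export
mfpt_at <- function(field, point) {
  interp_field(field$grid, field$tau, point)
}

#' Mean first passage time for the working-memory circuit
#'
#' Solves the backward problem for the circuit drift in the requested
#' frame, with the destination expressed in the same frame.
#'
#' @param params a [circuit_params()] object (stimulus currents included).
#' @param D scalar current-space diffusion coefficient.
#' @param grid a [grid2d()]; its frame selects the solve frame.
#' @param destination a [destination_disk()] (or logical matrix) in grid
#'   frame coordinates; for the gating frame, typically a 0.02-radius disk
#'   around the destination attractor.
#' @param start optional length-2 start point; when given, the scalar
#'   `tau_start` is included in the result.
#' @return An `mfpt_field`, with `tau_start` when `start` was supplied.
#' @export
solve_mfpt <- function(params, D = 1.4e-2, grid = grid2d(200),
                       destination, start = NULL) {
  stopifnot(inherits(params, "circuit_params"))
  Dt <- diffusion_tensor(params, D, grid$frame)
  drift_fn <- circuit_drift_fn(params, grid$frame)
  out <- mfpt_solve(grid, drift_fn, Dt, destination)
  if (!is.null(start)) {
    if (inherits(destination, "destination") &&
        sqrt(sum((start - destination$center)^2)) <= destination$radius)
      stop("start point lies inside the absorbing destination region")
    out$tau_start <- mfpt_at(out, start)
    out$start <- start
  }
  out$params <- params
  out
}

#' Robustness and flexibility of a memory state
#'
#' Computes the pair \eqn{(\tau, \tau')}: the mean first passage time out
#' of the target memory attractor `m1` without any stimulus (robustness
#' against random fluctuations) and under a 0.02 nA distractor stimulus to
#' population 2 (flexibility to a new stimulus). The destination follows
#' the convention used throughout: transitions proceed to the resting
#' state `r` while no intermediate state exists and to `m3` once it does;
#' for \eqn{\tau'} with no `m3`, the destination is the dominant
#' distractor attractor `m2`.
#'
#' @param params a [circuit_params()] (any stimulus currents are replaced
#'   by the scenario definitions).
#' @param D scalar diffusion coefficient.
#' @param grid a gating-frame [grid2d()].
#' @param dest_radius absorbing-disk radius in gating units.
#' @param amplitude distractor amplitude (nA).
#' @return A list with `tau`, `tau_prime`, the destination labels used,
#'   and the underlying `mfpt_field`s.
#' @export
robustness_flexibility_pair <- function(params, D = 1.4e-2,
                                        grid = grid2d(100),
                                        dest_radius = 0.02,
                                        amplitude = 0.02) {
  stopifnot(grid$frame == "gating")
  p0 <- set_stimulus(params, 0, 0)
  fps0 <- classify_attractors(find_fixed_points(p0))
  start0 <- attractor_location(fps0, "m1")
  dest0_label <- if ("m3" %in% fps0$label) "m3" else "r"
  f0 <- solve_mfpt(p0, D, grid,
                   destination_disk(attractor_location(fps0, dest0_label),
                                    dest_radius),
                   start = start0)
  pd <- set_stimulus(params, 0, amplitude)
  fpsd <- classify_attractors(find_fixed_points(pd))
  startd <- attractor_location(fpsd, "m1")
  destd_label <- if ("m3" %in% fpsd$label) "m3" else "m2"
  fd <- solve_mfpt(pd, D, grid,
                   destination_disk(attractor_location(fpsd, destd_label),
                                    dest_radius),
                   start = startd)
  list(tau = f0$tau_start, tau_prime = fd$tau_start,
       tau_destination = dest0_label, tau_prime_destination = destd_label,
       field_tau = f0, field_tau_prime = fd)
}
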