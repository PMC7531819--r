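# Finite-volume discretization of the Fokker-Planck equation
#   dP/dt = -div J,   J = F P - D grad P
# on a rectangular cell-centered grid with zero-flux (reflecting)
# boundaries. Advective-diffusive face fluxes use exponential fitting
# (Scharfetter-Gummel weights), which stays positive and sharp in the
# strongly advection-dominated regime of the circuit's small noise.
# Off-diagonal tensor entries (from the current-to-gating coordinate
# change) enter as centered tangential-gradient corrections on each face.

# Bernoulli weight B(z) = z / (e^z - 1), the exponential-fitting kernel
bernoulli_w <- function(z) {
  out <- numeric(length(z))
  small <- abs(z) < 1e-10
  out[small] <- 1 - z[small] / 2
  zb <- z[!small]
  e <- expm1(zb)
  w <- zb / e
  w[!is.finite(w) & zb > 0] <- 0        # e^z overflow: pure upwind limit
  out[!small] <- w
  out
}

#' Discrete Fokker-Planck operator on a grid
#'
#' Assembles the sparse generator `A` of the semi-discrete conservation law
#' \eqn{dp/dt = A p} for cell-center densities `p`, using
#' exponentially-fitted finite-volume face fluxes and zero-flux outer
#' boundaries. Columns of `A` sum to zero, so total probability is
#' conserved exactly.
#'
#' @param grid a [grid2d()] object.
#' @param drift_fn vectorized drift: maps an n-by-2 matrix of coordinates
#'   to an n-by-2 matrix of drift components (frame units per second).
#' @param Dt constant symmetric 2-by-2 diffusion tensor in grid-frame units.
#' @param active optional logical `nx`-by-`ny` matrix marking the cells
#'   inside the domain of interest; faces touching inactive cells carry no
#'   flux, so the active region gets its own reflecting (staircase)
#'   boundary. Used for the current-frame parallelogram interior.
#' @return A `dgCMatrix` of dimension `nx*ny`.
#' @export
fpe_operator <- function(grid, drift_fn, Dt, active = NULL) {
  nx <- grid$nx; ny <- grid$ny
  hx <- grid$hx; hy <- grid$hy
  Dxx <- Dt[1, 1]; Dyy <- Dt[2, 2]; Dxy <- Dt[1, 2]
  if (Dxx <= 0 || Dyy <= 0)
    stop("diffusion tensor must have positive diagonal (deterministic dynamics have no stationary density)")
  N <- nx * ny
  act <- if (is.null(active)) rep(TRUE, N) else as.logical(active)
  ii <- jj <- xx <- list()
  kslot <- 0L
  add <- function(i, j, x) {
    kslot <<- kslot + 1L
    ii[[kslot]] <<- i; jj[[kslot]] <<- j; xx[[kslot]] <<- x
  }

  ## vertical faces between (i,j) and (i+1,j), i = 1..nx-1
  fi <- rep(seq_len(nx - 1L), times = ny)
  fj <- rep(seq_len(ny), each = nx - 1L)
  L <- fi + (fj - 1L) * nx
  R <- L + 1L
  fon <- act[L] & act[R]                # faces fully inside the domain
  fx <- grid$xlim[1] + fi * hx          # face x-coordinate
  fy <- grid$yc[fj]
  v <- drift_fn(cbind(fx, fy))[, 1]
  w <- v * hx / Dxx
  Bm <- bernoulli_w(-w) * fon; Bp <- bernoulli_w(w) * fon
  cf <- Dxx / hx^2
  # SG part: F = (Dxx/hx) (Bm pL - Bp pR); dpL/dt -= F/hx ; dpR/dt += F/hx
  add(L, L, -cf * Bm); add(L, R,  cf * Bp)
  add(R, L,  cf * Bm); add(R, R, -cf * Bp)
  if (abs(Dxy) > 0) {
    # cross flux -Dxy dP/dy on the face, centered tangential gradient
    up  <- pmin(fj + 1L, ny); dn <- pmax(fj - 1L, 1L)
    wgt <- 1 / ((up - dn) * 2 * hy)     # 1/(4hy) interior, 1/(2hy) edges
    ccr <- Dxy / hx
    for (st in list(list(o = up, s = +1), list(o = dn, s = -1))) {
      for (side in c(0L, 1L)) {         # neighbors above L and above R
        m <- (fi + side) + (st$o - 1L) * nx
        add(L, m,  ccr * st$s * wgt * fon * act[m])
        add(R, m, -ccr * st$s * wgt * fon * act[m])
      }
    }
  }

  ## horizontal faces between (i,j) and (i,j+1), j = 1..ny-1
  fi <- rep(seq_len(nx), times = ny - 1L)
  fj <- rep(seq_len(ny - 1L), each = nx)
  B_ <- fi + (fj - 1L) * nx
  Tp <- B_ + nx
  fon <- act[B_] & act[Tp]
  fx <- grid$xc[fi]
  fy <- grid$ylim[1] + fj * hy
  v <- drift_fn(cbind(fx, fy))[, 2]
  w <- v * hy / Dyy
  Bm <- bernoulli_w(-w) * fon; Bp <- bernoulli_w(w) * fon
  cf <- Dyy / hy^2
  add(B_, B_, -cf * Bm); add(B_, Tp,  cf * Bp)
  add(Tp, B_,  cf * Bm); add(Tp, Tp, -cf * Bp)
  if (abs(Dxy) > 0) {
    rt <- pmin(fi + 1L, nx); lf <- pmax(fi - 1L, 1L)
    wgt <- 1 / ((rt - lf) * 2 * hx)
    ccr <- Dxy / hy
    for (st in list(list(o = rt, s = +1), list(o = lf, s = -1))) {
      for (side in c(0L, 1L)) {
        m <- st$o + (fj + side - 1L) * nx
        add(B_, m,  ccr * st$s * wgt * fon * act[m])
        add(Tp, m, -ccr * st$s * wgt * fon * act[m])
      }
    }
  }

  Matrix::sparseMatrix(i = unlist(ii[seq_len(kslot)]),
                       j = unlist(jj[seq_len(kslot)]),
                       x = unlist(xx[seq_len(kslot)]),
                       dims = c(N, N))
}

# drift function and diffusion tensor for a circuit in a given frame
circuit_drift_fn <- function(params, frame) {
  if (frame == "gating") function(x) rbind2cols(drift_gating(x, params))
  else function(x) rbind2cols(drift_current(x, params))
}

#' Stationary solution of the Fokker-Planck equation
#'
#' Solves \eqn{\nabla\cdot(F P_{ss}) - \nabla\cdot\nabla\cdot(D P_{ss}) = 0}
#' with reflecting boundaries for an arbitrary drift field and constant
#' diffusion tensor. A short implicit time-march from the uniform density
#' conditions the problem, after which the one-dimensional null space of
#' the discrete operator is obtained by a direct sparse solve anchored at
#' the current density maximum; if the direct solve fails or degrades the
#' residual, implicit marching continues to tolerance.
#'
#' @param grid a [grid2d()] object.
#' @param drift_fn vectorized drift function (see [fpe_operator()]).
#' @param Dt constant 2-by-2 diffusion tensor.
#' @param tol convergence tolerance on the stationary residual
#'   \eqn{\|A p\|_1 \times} cell area (probability mass per unit time).
#' @param max_march maximum implicit-march steps in the fallback phase.
#' @param floor_rel relative density floor used when taking the potential
#'   \eqn{U = -\ln P_{ss}}: cells below `floor_rel * max(Pss)` are masked.
#' @param active optional logical domain mask (see [fpe_operator()]).
#' @return An object of class `landscape` with elements `P` (cell
#'   probability density, integrates to 1), `U` (potential from cell masses,
#'   `NA` on floored cells), `Jx`, `Jy` (cell-centered flux), `div_J`
#'   (divergence residual), `residual`, `iterations`, `neg_clamped`,
#'   `floor`, `grid`, `Dt`.
#' @export
fpe_steady_state <- function(grid, drift_fn, Dt, tol = 1e-9,
                             max_march = 200L, floor_rel = 1e-12,
                             active = NULL) {
  A <- fpe_operator(grid, drift_fn, Dt, active = active)
  N <- grid$nx * grid$ny
  area <- grid$hx * grid$hy
  act <- if (is.null(active)) rep(TRUE, N) else as.logical(active)
  resid <- function(p) sum(abs(A %*% p)) * area
  p <- as.numeric(act) / (sum(act) * area)
  res_hist <- resid(p)
  neg <- 0
  for (dt in c(0.05, 0.5, 5)) {
    p <- as.numeric(Matrix::solve(Matrix::Diagonal(N) / dt - A, p / dt))
    neg <- max(neg, -min(p, 0) / max(p))
    p <- pmax(p, 0); p <- p / (sum(p) * area)
    res_hist <- c(res_hist, resid(p))
  }
  # direct null-space solve anchored where the density is largest;
  # inactive cells get trivial identity rows so the system stays regular
  r0 <- which.max(p)
  Amod <- A
  if (!all(act))
    Amod <- Amod + Matrix::Diagonal(N, x = as.numeric(!act))
  Amod[r0, ] <- 0
  Amod[r0, r0] <- 1
  b <- numeric(N); b[r0] <- 1
  pd <- tryCatch(as.numeric(Matrix::solve(Amod, b)), error = function(e) NULL)
  used_direct <- FALSE
  if (!is.null(pd) && all(is.finite(pd))) {
    negd <- -min(pd, 0) / max(pd)
    pd <- pmax(pd, 0)
    pd <- pd / (sum(pd) * area)
    if (resid(pd) < res_hist[length(res_hist)] && negd < 1e-6) {
      p <- pd; neg <- max(neg, negd); used_direct <- TRUE
      res_hist <- c(res_hist, resid(p))
    }
  }
  it <- 0L
  if (res_hist[length(res_hist)] > tol) {
    dt <- 50
    Msys <- Matrix::Diagonal(N) / dt - A
    f <- Matrix::lu(Msys)
    while (res_hist[length(res_hist)] > tol && it < max_march) {
      p <- as.numeric(Matrix::solve(f, p / dt))
      neg <- max(neg, -min(p, 0) / max(p))
      p <- pmax(p, 0); p <- p / (sum(p) * area)
      res_hist <- c(res_hist, resid(p))
      it <- it + 1L
    }
  }
  res <- res_hist[length(res_hist)]
  if (res > tol * 100)
    stop(sprintf("Fokker-Planck solve did not converge (residual %.3e); history: %s",
                 res, paste(signif(utils::tail(res_hist, 5), 3), collapse = " ")))
  P <- matrix(p, grid$nx, grid$ny)
  out <- structure(list(P = P, grid = grid, Dt = Dt,
                        residual = res, residual_history = res_hist,
                        iterations = it, used_direct = used_direct,
                        neg_clamped = neg, floor = floor_rel,
                        active = if (is.null(active)) NULL else
                          matrix(act, grid$nx, grid$ny),
                        frame = grid$frame),
                   class = "landscape")
  out$U <- potential_from_density(P * area, floor_rel)
  fl <- flux_field_core(p, grid, drift_fn, Dt, active = active)
  out$Jx <- fl$Jx; out$Jy <- fl$Jy; out$div_J <- fl$div
  out$drift_fn <- drift_fn
  out
}

#' Steady-state landscape of the working-memory circuit
#'
#' Convenience wrapper: builds the drift and diffusion tensor of a circuit
#' in the requested frame (gating-square default) and calls
#' [fpe_steady_state()].
#'
#' @param params a [circuit_params()] object.
#' @param D scalar current-space diffusion coefficient (default 1.4e-2).
#' @param grid a [grid2d()]; default 200x200 over the gating square.
#'   Its `frame` tag selects the solve frame.
#' @param ... passed to [fpe_steady_state()].
#' @return A `landscape` object (see [fpe_steady_state()]).
#' @export
solve_steady_state <- function(params, D = 1.4e-2, grid = grid2d(200), ...) {
  stopifnot(inherits(params, "circuit_params"))
  if (D <= 0) stop("D must be positive: the deterministic limit has no density")
  Dt <- diffusion_tensor(params, D, grid$frame)
  drift_fn <- circuit_drift_fn(params, grid$frame)
  active <- NULL
  if (grid$frame == "current") {
    # reflecting boundary lives on the image of the gating square: mask
    # the bounding-box cells whose gating preimage falls outside [0,1]^2
    S <- rbind2cols(gating_from_currents(grid_points(grid), params))
    eps <- 1e-9
    active <- matrix(S[, 1] >= -eps & S[, 1] <= 1 + eps &
                     S[, 2] >= -eps & S[, 2] <= 1 + eps,
                     grid$nx, grid$ny)
  }
  out <- fpe_steady_state(grid, drift_fn, Dt, active = active, ...)
  out$params <- params
  out$D <- D
  out
}

#' @exportS3Method base::print
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d grid (%s frame)\n",
              x$grid$nx, x$grid$ny, x$frame))
  cat(sprintf("  residual %.3e after %d fallback steps (direct solve: %s)\n",
              x$residual, x$iterations, x$used_direct))
  cat(sprintf("  potential range %.2f .. %.2f (%d floored cells)\n",
              min(x$U, na.rm = TRUE), max(x$U, na.rm = TRUE), sum(is.na(x$U))))
  invisible(x)
}

#' Potential landscape from a normalized density
#'
#' \eqn{U = -\ln P_{ss}} evaluated on cell masses. Cells whose density
#' falls below `floor_rel * max(P)` are masked with `NA` and excluded from
#' attractor and barrier analysis.
#'
#' @param P matrix of cell probabilities (masses summing to 1, or densities
#'   up to a constant factor; a constant rescaling only shifts `U`).
#' @param floor_rel relative density floor.
#' @return Matrix of potential values, `NA` on floored cells.
#' @export
potential_from_density <- function(P, floor_rel = 1e-12) {
  mx <- max(P)
  if (!is.finite(mx) || mx <= 0) stop("density field is empty or degenerate")
  U <- -log(P)
  U[P < floor_rel * mx] <- NA_real_
  if (all(is.na(U))) stop("all cells fall below the density floor")
  U
}

# face fluxes and cell-centered flux/divergence for a density vector p
flux_field_core <- function(p, grid, drift_fn, Dt, active = NULL) {
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  Dxx <- Dt[1, 1]; Dyy <- Dt[2, 2]; Dxy <- Dt[1, 2]
  P <- matrix(p, nx, ny)
  act <- if (is.null(active)) matrix(TRUE, nx, ny) else
    matrix(as.logical(active), nx, ny)
  # vertical faces (nx-1) x ny
  fxc <- grid$xlim[1] + seq_len(nx - 1L) * hx
  ptsx <- cbind(rep(fxc, times = ny), rep(grid$yc, each = nx - 1L))
  vx <- matrix(drift_fn(ptsx)[, 1], nx - 1L, ny)
  w <- vx * hx / Dxx
  Fx <- (Dxx / hx) * (bernoulli_w(-w) * P[-nx, ] - bernoulli_w(w) * P[-1, ])
  Fx <- Fx * (act[-nx, ] & act[-1, ])
  if (abs(Dxy) > 0) {
    jup <- pmin(seq_len(ny) + 1L, ny); jdn <- pmax(seq_len(ny) - 1L, 1L)
    dPdy <- (P[-nx, jup] + P[-1, jup] - P[-nx, jdn] - P[-1, jdn]) /
      (2 * hy * rep(jup - jdn, each = nx - 1L))
    Fx <- Fx - Dxy * dPdy
  }
  # horizontal faces nx x (ny-1)
  fyc <- grid$ylim[1] + seq_len(ny - 1L) * hy
  ptsy <- cbind(rep(grid$xc, times = ny - 1L), rep(fyc, each = nx))
  vy <- matrix(drift_fn(ptsy)[, 2], nx, ny - 1L)
  w <- vy * hy / Dyy
  Fy <- (Dyy / hy) * (bernoulli_w(-w) * P[, -ny] - bernoulli_w(w) * P[, -1])
  Fy <- Fy * (act[, -ny] & act[, -1])
  if (abs(Dxy) > 0) {
    irt <- pmin(seq_len(nx) + 1L, nx); ilf <- pmax(seq_len(nx) - 1L, 1L)
    dPdx <- (P[irt, -ny] + P[irt, -1] - P[ilf, -ny] - P[ilf, -1]) /
      (2 * hx * (irt - ilf))
    Fy <- Fy - Dxy * dPdx
  }
  # pad with the zero boundary fluxes, average faces to centers
  Fx_full <- rbind(0, Fx, 0)            # (nx+1) x ny
  Fy_full <- cbind(0, Fy, 0)            # nx x (ny+1)
  Jx <- (Fx_full[-1, , drop = FALSE] + Fx_full[-(nx + 1L), , drop = FALSE]) / 2
  Jy <- (Fy_full[, -1, drop = FALSE] + Fy_full[, -(ny + 1L), drop = FALSE]) / 2
  div <- (Fx_full[-1, ] - Fx_full[-(nx + 1L), ]) / hx +
    (Fy_full[, -1] - Fy_full[, -(ny + 1L)]) / hy
  list(Fx = Fx, Fy = Fy, Jx = Jx, Jy = Jy, div = div)
}

#' Steady-state probability flux field
#'
#' Evaluates \eqn{J = F P - D \nabla P} at cell centers from a solved
#' density (boundary-normal components vanish by the reflecting boundary
#' construction), together with its discrete divergence.
#'
#' @param landscape a `landscape` object from [solve_steady_state()] or
#'   [fpe_steady_state()].
#' @return A list with matrices `Jx`, `Jy` and `div` (divergence residual).
#' @export
flux_field <- function(landscape) {
  stopifnot(inherits(landscape, "landscape"))
  flux_field_core(as.numeric(landscape$P), landscape$grid,
                  landscape$drift_fn, landscape$Dt,
                  active = landscape$active)
}

#' Transient evolution of a probability density
#'
#' Integrates the probability conservation law \eqn{\partial P/\partial t =
#' -\nabla\cdot J} by unconditionally stable implicit Euler steps using the
#' same conservative operator as the stationary solver; total mass is
#' conserved to round-off at every step.
#'
#' @param P0 initial density: matrix of cell densities (any positive
#'   normalization; renormalized to mass 1).
#' @param grid a [grid2d()] object.
#' @param drift_fn vectorized drift function.
#' @param Dt constant 2-by-2 diffusion tensor.
#' @param t total integration time (s).
#' @param dt implicit step size (s).
#' @param save_times optional vector of times at which to return snapshots.
#' @return If `save_times` is `NULL`, the final density matrix; otherwise a
#'   list with `times`, `densities` (list of matrices) and `mass` at each
#'   saved time.
#' @export
evolve_density <- function(P0, grid, drift_fn, Dt, t, dt = t / 50,
                           save_times = NULL) {
  N <- grid$nx * grid$ny
  area <- grid$hx * grid$hy
  p <- as.numeric(P0)
  if (any(p < 0) || sum(p) <= 0) stop("P0 must be a non-negative density")
  p <- p / (sum(p) * area)
  A <- fpe_operator(grid, drift_fn, Dt)
  nst <- max(1L, ceiling(t / dt))
  dt <- t / nst
  f <- Matrix::lu(Matrix::Diagonal(N) / dt - A)
  keep <- if (is.null(save_times)) integer(0) else
    pmin(pmax(round(save_times / dt), 1L), nst)
  snaps <- list(); times <- numeric(0); mass <- numeric(0)
  for (k in seq_len(nst)) {
    p <- as.numeric(Matrix::solve(f, p / dt))
    if (k %in% keep) {
      snaps[[length(snaps) + 1L]] <- matrix(p, grid$nx, grid$ny)
      times <- c(times, k * dt)
      mass <- c(mass, sum(p) * area)
    }
  }
  if (is.null(save_times)) return(matrix(p, grid$nx, grid$ny))
  list(times = times, densities = snaps, mass = mass)
}
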