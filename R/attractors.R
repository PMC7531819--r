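# Fixed-point location, attractor taxonomy (r / m1 / m2 / m3), and
# barrier heights by minimax paths on the potential landscape.

#' Locate the fixed points of the deterministic circuit
#'
#' Runs damped Newton refinement from a dense lattice of seeds over the
#' gating square, merges duplicates, and classifies stability from the
#' analytic Jacobian. All Newton iterations are advanced simultaneously in
#' vectorized form.
#'
#' @param params a [circuit_params()] object.
#' @param n_seed seeds per axis of the starting lattice (default 25).
#' @param tol residual tolerance on \eqn{|F(S)|} for accepting a root.
#' @param merge_radius roots closer than this are considered duplicates.
#' @return An object of class `attractor_set`: a data.frame with columns
#'   `S1`, `S2`, `stable`, `eig_max_re` (largest real part of the Jacobian
#'   eigenvalues) and `label` (filled by [classify_attractors()]).
#' @export
find_fixed_points <- function(params, n_seed = 25, tol = 1e-9,
                              merge_radius = 1e-4) {
  stopifnot(inherits(params, "circuit_params"))
  s <- seq(0.005, 0.995, length.out = n_seed)
  S <- as.matrix(expand.grid(S1 = s, S2 = s))
  cm <- coupling_map(params)
  for (it in seq_len(120L)) {
    F <- rbind2cols(drift_gating(S, params))
    I <- rbind2cols(currents_from_gating(S, params))
    f1 <- fi_curve(I[, 1], params); f2 <- fi_curve(I[, 2], params)
    g1 <- fi_curve_deriv(I[, 1], params); g2 <- fi_curve_deriv(I[, 2], params)
    J11 <- -1 / params$tau_S - params$gamma * f1 +
      (1 - S[, 1]) * params$gamma * g1 * cm$M[1, 1]
    J12 <- (1 - S[, 1]) * params$gamma * g1 * cm$M[1, 2]
    J21 <- (1 - S[, 2]) * params$gamma * g2 * cm$M[2, 1]
    J22 <- -1 / params$tau_S - params$gamma * f2 +
      (1 - S[, 2]) * params$gamma * g2 * cm$M[2, 2]
    det <- J11 * J22 - J12 * J21
    det[abs(det) < 1e-14] <- NA
    d1 <- (-F[, 1] * J22 + F[, 2] * J12) / det
    d2 <- (-F[, 2] * J11 + F[, 1] * J21) / det
    d1[is.na(d1)] <- 0; d2[is.na(d2)] <- 0
    d1 <- pmax(pmin(d1, 0.15), -0.15)
    d2 <- pmax(pmin(d2, 0.15), -0.15)
    S[, 1] <- S[, 1] + d1
    S[, 2] <- S[, 2] + d2
    if (max(abs(c(d1, d2))) < 1e-13) break
  }
  F <- rbind2cols(drift_gating(S, params))
  ok <- is.finite(S[, 1]) & is.finite(S[, 2]) &
    S[, 1] > -0.02 & S[, 1] < 1.02 & S[, 2] > -0.02 & S[, 2] < 1.02 &
    sqrt(F[, 1]^2 + F[, 2]^2) < tol
  S <- S[ok, , drop = FALSE]
  roots <- matrix(numeric(0), 0, 2)
  for (k in seq_len(nrow(S))) {
    if (nrow(roots) == 0 ||
        min(sqrt(rowSums(sweep(roots, 2, S[k, ])^2))) > merge_radius)
      roots <- rbind(roots, S[k, ])
  }
  n <- nrow(roots)
  stable <- logical(n); eig_max <- numeric(n)
  for (k in seq_len(n)) {
    ev <- eigen(drift_jacobian(roots[k, ], params), only.values = TRUE)$values
    eig_max[k] <- max(Re(ev))
    stable[k] <- eig_max[k] < 0
  }
  out <- data.frame(S1 = roots[, 1], S2 = roots[, 2],
                    stable = stable, eig_max_re = eig_max,
                    label = rep(NA_character_, n))
  out <- out[order(-out$stable, out$S1 + out$S2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("attractor_set", "data.frame"), params = params)
}

#' Assign the r / m1 / m2 / m3 taxonomy to stable fixed points
#'
#' Labels stable attractors by which populations are active: `r` both low
#' (resting), `m1` population 1 high (target memory), `m2` population 2
#' high (distractor memory), `m3` both high (intermediate state). "High"
#' means a gating value above the midpoint between the lowest and highest
#' gating coordinates found among the stable points, which adapts the
#' threshold to each parameter set; when all stable points cluster
#' together the fixed fallback threshold is used.
#'
#' @param fps an `attractor_set` from [find_fixed_points()].
#' @param threshold optional fixed gating threshold overriding the
#'   adaptive rule.
#' @param fallback threshold used when the stable points span a gating
#'   range too narrow to define a midpoint (default 0.35).
#' @return The `attractor_set` with the `label` column filled for stable
#'   points (`"unclassified"` for saddles/unstable points).
#' @export
classify_attractors <- function(fps, threshold = NULL, fallback = 0.35) {
  stopifnot(inherits(fps, "attractor_set"))
  st <- fps$stable
  if (!any(st)) {
    fps$label[!st] <- "unclassified"
    return(fps)
  }
  pool <- c(fps$S1[st], fps$S2[st])
  thr <- if (!is.null(threshold)) threshold
  else if (diff(range(pool)) < 0.15) fallback
  else mean(range(pool))
  hi1 <- fps$S1 >= thr; hi2 <- fps$S2 >= thr
  lab <- ifelse(hi1 & hi2, "m3",
         ifelse(hi1 & !hi2, "m1",
         ifelse(!hi1 & hi2, "m2", "r")))
  lab[!st] <- "unclassified"
  if (anyDuplicated(lab[st]))
    stop("two stable fixed points received the same label; ",
         "tighten the classification threshold")
  fps$label <- lab
  attr(fps, "threshold") <- thr
  fps
}

#' Locate and label the attractors of a circuit in one call
#'
#' @param params a [circuit_params()] object.
#' @param ... passed to [find_fixed_points()].
#' @return A labeled `attractor_set`.
#' @export
attractors <- function(params, ...) {
  classify_attractors(find_fixed_points(params, ...))
}

#' Coordinates of a labeled attractor
#'
#' @param fps a labeled `attractor_set`.
#' @param label one of `"r"`, `"m1"`, `"m2"`, `"m3"`.
#' @return Length-2 gating coordinates; errors if the label is absent.
#' @export
attractor_location <- function(fps, label) {
  k <- which(fps$label == label & fps$stable)
  if (length(k) != 1L)
    stop(sprintf("attractor '%s' not present for these parameters", label))
  c(fps$S1[k], fps$S2[k])
}

#' Barrier height between two attractors on a potential landscape
#'
#' The saddle between two basins is found as the minimax elevation over
#' grid paths (4-neighbor connectivity): cells are flooded in order of
#' increasing potential and the barrier top is the cell whose addition
#' first connects the two minima. The barrier height is
#' \eqn{U_{saddle} - U_{min}} of the source attractor.
#'
#' @param U potential matrix (from a `landscape`; `NA` marks floored cells).
#' @param grid the [grid2d()] the potential lives on.
#' @param attractors a labeled `attractor_set` (locations in grid frame).
#' @param source,target attractor labels, e.g. `"m1"`, `"r"`.
#' @return An object of class `barrier`: list with `source`, `target`,
#'   `U_min`, `U_saddle`, `height`, `saddle` (coordinates), `source_min`
#'   (coordinates of the source minimum cell).
#' @export
barrier_height <- function(U, grid, attractors, source, target) {
  src_pt <- attractor_location(attractors, source)
  tgt_pt <- attractor_location(attractors, target)
  src <- nearest_unfloored_cell(U, grid, src_pt)
  tgt <- nearest_unfloored_cell(U, grid, tgt_pt)
  # refine to the local minimum of U around each attractor
  src <- descend_to_minimum(U, grid, src)
  tgt <- descend_to_minimum(U, grid, tgt)
  mm <- minimax_flood(U, grid$nx, grid$ny, src, tgt)
  if (!mm$connected)
    stop("minimax path between attractors is blocked by floored cells; ",
         "lower the density floor or refine the grid")
  U_min <- U[src[1], src[2]]
  structure(list(source = source, target = target,
                 U_min = U_min, U_saddle = mm$value,
                 height = mm$value - U_min,
                 saddle = c(grid$xc[mm$cell[1]], grid$yc[mm$cell[2]]),
                 source_min = c(grid$xc[src[1]], grid$yc[src[2]])),
            class = "barrier")
}

#' @exportS3Method base::print
print.barrier <- function(x, ...) {
  cat(sprintf("<barrier> %s -> %s: height %.4f (U_min %.4f, U_saddle %.4f at [%.3f, %.3f])\n",
              x$source, x$target, x$height, x$U_min, x$U_saddle,
              x$saddle[1], x$saddle[2]))
  invisible(x)
}

nearest_unfloored_cell <- function(U, grid, pt) {
  i <- pmin(pmax(round((pt[1] - grid$xc[1]) / grid$hx) + 1L, 1L), grid$nx)
  j <- pmin(pmax(round((pt[2] - grid$yc[1]) / grid$hy) + 1L, 1L), grid$ny)
  if (!is.na(U[i, j])) return(c(i, j))
  ok <- which(!is.na(U), arr.ind = TRUE)
  if (nrow(ok) == 0) stop("potential field is fully floored")
  d2 <- (ok[, 1] - i)^2 + (ok[, 2] - j)^2
  as.integer(ok[which.min(d2), ])
}

descend_to_minimum <- function(U, grid, cell) {
  nx <- grid$nx; ny <- grid$ny
  repeat {
    i <- cell[1]; j <- cell[2]
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny, ,
             drop = FALSE]
    vals <- U[nb]
    if (all(is.na(vals)) || min(vals, na.rm = TRUE) >= U[i, j]) return(cell)
    cell <- nb[which.min(vals), ]
  }
}

# union-find flood: activate cells by increasing U until src and tgt join
minimax_flood <- function(U, nx, ny, src, tgt) {
  n <- nx * ny
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  active <- logical(n)
  ord <- order(U, na.last = NA)          # floored cells never activate
  ksrc <- src[1] + (src[2] - 1L) * nx
  ktgt <- tgt[1] + (tgt[2] - 1L) * nx
  if (ksrc == ktgt)
    return(list(connected = TRUE, value = U[src[1], src[2]], cell = src))
  for (k in ord) {
    active[k] <- TRUE
    i <- ((k - 1L) %% nx) + 1L
    j <- ((k - 1L) %/% nx) + 1L
    for (nb in list(if (i > 1L) k - 1L, if (i < nx) k + 1L,
                    if (j > 1L) k - nx, if (j < ny) k + nx)) {
      if (!is.null(nb) && active[nb]) {
        ra <- find(k); rb <- find(nb)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (active[ksrc] && active[ktgt] && find(ksrc) == find(ktgt))
      return(list(connected = TRUE, value = U[i, j], cell = c(i, j)))
  }
  list(connected = FALSE, value = NA_real_, cell = c(NA_integer_, NA_integer_))
}

#' Emergence threshold of the intermediate state
#'
#' Scans the self-excitation \eqn{J_+} at fixed mutual inhibition
#' \eqn{J_-} and reports the smallest value at which a stable
#' both-populations-active fixed point (`m3`) exists.
#'
#' @param params_base a [circuit_params()] giving all non-swept parameters
#'   (external stimuli are removed for the scan).
#' @param J_minus mutual inhibition (nA) held fixed during the scan.
#' @param J_plus_range scan range for \eqn{J_+} (nA).
#' @param step scan step (nA).
#' @return A list with `threshold` (smallest \eqn{J_+} with a stable `m3`,
#'   or `NA` if none in range), `found`, `step` (the +/- uncertainty), and
#'   the per-point `table` of attractor counts.
#' @export
intermediate_state_threshold <- function(params_base = circuit_params(),
                                         J_minus = 0.05,
                                         J_plus_range = c(0.30, 0.37),
                                         step = 0.005) {
  stopifnot(step > 0, diff(J_plus_range) >= 0)
  Jp <- seq(J_plus_range[1], J_plus_range[2], by = step)
  rows <- lapply(Jp, function(jp) {
    p <- circuit_params(a = params_base$a, b = params_base$b,
                        d = params_base$d, gamma = params_base$gamma,
                        tau_S = params_base$tau_S,
                        J_plus = jp, J_minus = J_minus,
                        I0 = params_base$I0)
    fps <- classify_attractors(find_fixed_points(p))
    data.frame(J_plus = jp, n_stable = sum(fps$stable),
               has_m3 = "m3" %in% fps$label)
  })
  tab <- do.call(rbind, rows)
  hit <- which(tab$has_m3)
  list(threshold = if (length(hit)) tab$J_plus[min(hit)] else NA_real_,
       found = length(hit) > 0, step = step, table = tab)
}
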