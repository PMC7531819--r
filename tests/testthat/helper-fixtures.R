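# shared fixtures: the baseline circuit and the default noise level
baseline_params <- function(...) circuit_params(...)
D_NOISE <- 1.4e-2

# brute-force minimax barrier oracle: binary search over potential
# thresholds with BFS connectivity on the sublevel set
brute_minimax <- function(U, src, tgt) {
  nx <- nrow(U); ny <- ncol(U)
  connected_below <- function(thr) {
    ok <- !is.na(U) & U <= thr
    if (!ok[src[1], src[2]] || !ok[tgt[1], tgt[2]]) return(FALSE)
    seen <- matrix(FALSE, nx, ny)
    queue <- list(src); seen[src[1], src[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (all(cur == tgt)) return(TRUE)
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nb <- cur + d
        if (nb[1] >= 1 && nb[1] <= nx && nb[2] >= 1 && nb[2] <= ny &&
            ok[nb[1], nb[2]] && !seen[nb[1], nb[2]]) {
          seen[nb[1], nb[2]] <- TRUE
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
    FALSE
  }
  vals <- sort(unique(as.numeric(U[!is.na(U)])))
  lo <- 1L; hi <- length(vals)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connected_below(vals[mid])) hi <- mid else lo <- mid + 1L
  }
  vals[lo]
}
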