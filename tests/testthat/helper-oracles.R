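# Brute-force absorption oracle for tiny chains: the first-step equations
#   h(k) = p_up h(k+1) + p_down h(k-1) + p_toE h(E)
# solved by exhaustive fixed-point iteration, independent of the package's
# sparse tridiagonal solve.  Returns h(k) for k = 0..N for one target.
oracle_absorption <- function(N, v, target = c("zero", "N", "E"),
                              tol = 1e-14, max_iter = 1e6) {
  target <- match.arg(target)
  bz <- as.numeric(target == "zero")
  bN <- as.numeric(target == "N")
  bE <- as.numeric(target == "E")
  h <- numeric(N + 1)
  h[1] <- bz
  h[N + 1] <- bN
  for (iter in seq_len(max_iter)) {
    h_new <- h
    for (k in seq_len(N - 1)) {
      rE <- k * v
      rUp <- k * (1 - v) * (N - k) / N
      rDown <- k * (N - k) / N
      tot <- rE + rUp + rDown
      h_new[k + 1] <- (rUp * h[k + 2] + rDown * h[k] + rE * bE) / tot
    }
    if (max(abs(h_new - h)) < tol) return(h_new)
    h <- h_new
  }
  stop("oracle fixed point did not converge")
}

# Central finite difference of a scalar function.
fd_derivative <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
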