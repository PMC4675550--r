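#' Parameters of the tumor growth and progression (TGP) process
#'
#' Bundles the three parameters of the Moran model with mutations: the
#' critical tumor size `N` (also the relevant cell number for competition),
#' the wild-type to type-I mutation probability `u`, and the type-I to
#' type-II mutation probability `v`.  The risk coefficient
#' `gamma = N^2 * v` is the single quantity that controls the asymptotic
#' absorption and regression behavior; exactly one of `v` and `gamma` is
#' supplied and the other is derived.
#'
#' @param N Positive integer `>= 2`; critical tumor size / relevant cell
#'   number of the Moran dynamics.
#' @param u Mutation probability per birth from wild-type to type-I, in
#'   `[0, 1)`.  Only the trajectory simulator uses `u`; all analytic
#'   operations work on the `u = 0` sub-process in which each type-I
#'   lineage is followed in isolation.
#' @param v Mutation probability per birth from type-I to type-II, in
#'   `[0, 1)`.  Mutually exclusive with `gamma`.
#' @param gamma Nonnegative risk coefficient; when supplied, `v` is derived
#'   as `gamma / N^2`, which must be below 1.
#'
#' @return An object of class `"tgp_params"`: a list with elements `N`,
#'   `u`, `v`, `gamma`.
#' @examples
#' tgp_params(N = 100, gamma = 0.152)
#' tgp_params(N = 50, v = 1e-4)
#' @export
tgp_params <- function(N, u = 0, v = NULL, gamma = NULL) {
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N))
    stop("`N` must be a single integer >= 2")
  N <- as.integer(N)
  if (length(u) != 1L || !is.finite(u) || u < 0 || u >= 1)
    stop("`u` must be a probability in [0, 1)")
  if (is.null(v) == is.null(gamma))
    stop("supply exactly one of `v` and `gamma`")
  if (is.null(v)) {
    if (length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
      stop("`gamma` must be a single nonnegative number")
    v <- gamma / N^2
    if (v >= 1)
      stop("`gamma`/N^2 = ", format(v), " is not a valid mutation probability; ",
           "increase N or decrease gamma")
  } else {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v >= 1)
      stop("`v` must be a probability in [0, 1)")
    gamma <- N^2 * v
  }
  structure(list(N = N, u = u, v = v, gamma = gamma), class = "tgp_params")
}

#' @export
print.tgp_params <- function(x, ...) {
  cat("TGP process parameters\n")
  cat(sprintf("  N     = %d (critical tumor size)\n", x$N))
  cat(sprintf("  u     = %g (type-I mutation probability)\n", x$u))
  cat(sprintf("  v     = %g (type-II mutation probability)\n", x$v))
  cat(sprintf("  gamma = %g (risk coefficient N^2 v)\n", x$gamma))
  invisible(x)
}

# The decomposition of the full process into independent type-I lineages
# requires type-I mutations to be rare on the timescale of a lineage:
# u*N < 1.  Analytic operations call this before trusting the u = 0
# sub-process.
check_decomposition_regime <- function(params) {
  if (params$u * params$N >= 1)
    stop("decomposition into single-mutant sub-processes requires u*N < 1 ",
         "(got u*N = ", format(params$u * params$N), ")")
  invisible(params)
}

as_tgp_params <- function(params) {
  if (!inherits(params, "tgp_params"))
    stop("`params` must be created by tgp_params()")
  params
}
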