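#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random stream set from `seed`, then restores
#' whatever stream was active before the call. Every stochastic operation in
#' the package funnels through this helper so that results are pure functions
#' of `(inputs, seed)`.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a stage tag
#'
#' Deterministic fan-out: `child_seed(master, "depth", 3)` always yields the
#' same value, and different tags give unrelated streams, so any single
#' pipeline stage can be re-run in isolation. Result is in `[1, 2^31 - 2]`.
#'
#' @param seed Master integer seed.
#' @param tag Character stage tag.
#' @param index Optional integer (e.g. frame or repetition number).
#' @return Integer child seed.
#' @export
child_seed <- function(seed, tag, index = 0L) {
  m <- 2147483629  # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + h * 69621 + as.numeric(index) * 16807 + 1) %% m
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_endonav <- function(msg, class) {
  stop(structure(class = c(class, "endonav_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

as_points_matrix <- function(points, what = "points") {
  if (is.null(dim(points))) {
    if (length(points) != 3L)
      stop(sprintf("%s must be an N x 3 matrix", what))
    points <- matrix(points, 1L, 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop(sprintf("%s must be an N x 3 matrix", what))
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop(sprintf("non-finite coordinates in %s", what))
  storage.mode(points) <- "double"
  points
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Levenberg-Marquardt least squares with numeric Jacobian
#'
#' Small damped Gauss-Newton solver used by the calibration refinements.
#' Jacobians are computed by forward differences; at the problem sizes in this
#' package (tens of parameters, hundreds of residuals) this is fast and
#' avoids hand-derived derivative bugs.
#'
#' @param par Numeric start vector.
#' @param fn Function returning the residual vector.
#' @param max_iter Iteration cap.
#' @param tol Relative cost-decrease tolerance.
#' @return List with `par`, `rss`, `iterations`, `converged`.
#' @keywords internal
lm_least_squares <- function(par, fn, max_iter = 100L, tol = 1e-10) {
  r <- fn(par)
  cost <- sum(r^2)
  lambda <- 1e-3
  np <- length(par)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # forward-difference Jacobian
    J <- matrix(0, length(r), np)
    h <- 1e-7 * pmax(abs(par), 1e-4)
    for (j in seq_len(np)) {
      pj <- par
      pj[j] <- pj[j] + h[j]
      J[, j] <- (fn(pj) - r) / h[j]
    }
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    improved <- FALSE
    for (k in 1:12) {
      A <- JtJ + lambda * diag(diag(JtJ) + 1e-12, np)
      step <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- par + as.numeric(step)
        rc <- fn(cand)
        cc <- sum(rc^2)
        if (is.finite(cc) && cc < cost) {
          if (cost - cc <= tol * (cost + 1e-300)) converged <- TRUE
          par <- cand; r <- rc; cost <- cc
          lambda <- max(lambda / 4, 1e-12)
          improved <- TRUE
          break
        }
      }
      lambda <- lambda * 8
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  list(par = par, rss = cost, iterations = iter, converged = converged)
}
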