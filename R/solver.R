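#' Jacobi (diagonal) preconditioner of the implicit RAD system
#'
#' The preconditioner is the diagonal part of `A = D + alpha * L`, i.e.
#' `1 + alpha * s` per pixel; applying it means elementwise division.
#' (At boundary pixels the assembled matrix folds the reflected neighbor
#' into the diagonal, so there the true diagonal is `1 + alpha * (s - c_b)`;
#' the difference only perturbs the preconditioner's constants, never the
#' solution.) Entries are always >= 1, so division is safe.
#'
#' @param coeffs a [coefficient_field()].
#' @param alpha_diff nonnegative diffusion weight.
#' @return a positive matrix, the approximate diagonal of `A`.
#' @export
jacobi_preconditioner <- function(coeffs, alpha_diff) {
  stopifnot(alpha_diff >= 0)
  1 + alpha_diff * coeffs$s
}

#' Preconditioned bi-conjugate gradient solver
#'
#' Solves `A x = b` for a general (possibly nonsymmetric) linear operator
#' given matrix-free, using the standard PBCG recurrence: paired residuals
#' `r, rbar`, preconditioned vectors `z = r / M`, `zbar = rbar / M` and
#' direction pairs `p, pbar`, with step `alpha_k = (rbar.z)/(pbar.Ap)` and
#' `beta_k = (rbar_{k+1}.z_{k+1})/(rbar_k.z_k)`. When `A` is symmetric
#' positive definite (as the RAD system is) and `rbar_0 = r_0`, the iterates
#' coincide with preconditioned CG.
#'
#' Iteration stops when the relative residual `|b - A x| / |b|` drops to
#' `tol` (an absolute floor of 1e-30 guards `b = 0`) or `maxiter` is
#' reached; the reported `final_residual` is recomputed from scratch, not
#' taken from the recurrence.
#'
#' @param apply_A function mapping a grid to `A` times that grid.
#' @param apply_At function applying the transpose of `A`; pass `apply_A`
#'   itself when `A` is symmetric.
#' @param rhs right-hand-side grid `b`.
#' @param precond strictly positive grid holding the diagonal preconditioner
#'   (see [jacobi_preconditioner()]); `NULL` for no preconditioning.
#' @param tol relative residual tolerance.
#' @param maxiter iteration cap.
#' @param x0 initial guess; defaults to `rhs`, which for `A = D + alpha*L`
#'   with small `alpha` already lies near the solution.
#' @param keep_iterates if `TRUE`, store each iterate (small systems only;
#'   used for algorithmic cross-checks).
#' @return an object of class `solver_result`: fields `solution`,
#'   `iterations`, `final_residual`, `converged`, `residual_history` and
#'   (optionally) `iterates`.
#' @export
pbcg_solve <- function(apply_A, apply_At = apply_A, rhs, precond = NULL,
                       tol = 1e-8, maxiter = 10L * length(rhs), x0 = rhs,
                       keep_iterates = FALSE) {
  stopifnot(is.function(apply_A), is.function(apply_At),
            tol > 0, maxiter >= 1L)
  if (is.null(precond)) precond <- array(1, dim(rhs))
  check_same_dim(rhs, precond, "rhs and preconditioner")
  if (min(precond) <= 0) stop("preconditioner must be strictly positive")
  nrm <- function(v) sqrt(sum(v * v))
  bnorm <- max(nrm(rhs), 1e-30)
  tiny <- 1e-300

  x <- x0
  r <- rhs - apply_A(x)
  rbar <- r
  hist <- nrm(r) / bnorm
  iterates <- if (keep_iterates) list(x) else NULL
  k <- 0L
  if (hist[1] > tol) {
    z <- r / precond; zbar <- rbar / precond
    p <- z; pbar <- zbar
    rz <- sum(rbar * z)
    repeat {
      k <- k + 1L
      Ap <- apply_A(p)
      denom <- sum(pbar * Ap)
      if (abs(denom) < tiny)
        stop(errorCondition(
          sprintf("PBCG breakdown at iteration %d: pbar . A p vanished", k),
          class = c("radusm_breakdown_error", "error"), iteration = k))
      ak <- rz / denom
      x <- x + ak * p
      r <- r - ak * Ap
      rbar <- rbar - ak * apply_At(pbar)
      hist <- c(hist, nrm(r) / bnorm)
      if (keep_iterates) iterates[[k + 1L]] <- x
      if (hist[k + 1L] <= tol || k >= maxiter) break
      z <- r / precond; zbar <- rbar / precond
      if (abs(rz) < tiny)
        stop(errorCondition(
          sprintf("PBCG breakdown at iteration %d: rbar . z vanished", k),
          class = c("radusm_breakdown_error", "error"), iteration = k))
      rz_new <- sum(rbar * z)
      bk <- rz_new / rz
      rz <- rz_new
      p <- z + bk * p
      pbar <- zbar + bk * pbar
    }
  }
  final <- nrm(rhs - apply_A(x)) / bnorm
  structure(list(solution = x, iterations = k, final_residual = final,
                 converged = final <= tol, residual_history = hist,
                 iterates = iterates),
            class = "solver_result")
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf("<solver_result> %s in %d iterations, relative residual %.3g\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_residual))
  invisible(x)
}
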