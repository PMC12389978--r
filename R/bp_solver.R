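# Equality-constrained L1 minimization (basis pursuit):
#
#     min ||s||_1   subject to   Theta s = y
#
# solved by a primal-dual interior-point method on the linear-program
# reformulation  min 1'u  s.t.  s - u <= 0, -s - u <= 0, Theta s = y.
# The Newton system is reduced to an m x m solve in the dual variable of the
# equality constraint; with a feasible start every iterate stays on the
# affine manifold Theta s = y.  Termination is on the surrogate duality gap
# eta = -(fu1' lam1 + fu2' lam2), which upper-bounds the suboptimality of the
# current objective.

#' Minimum-norm feasible starting point
#'
#' Returns `s0 = Theta' (Theta Theta')^{-1} y`, the least-L2-norm solution of
#' `Theta s = y`. The basis-pursuit solver needs a strictly feasible start;
#' the zero vector commonly passed as an initial guess is infeasible whenever
#' `y != 0` and is silently replaced by this point.
#'
#' @param Theta m x n matrix with full row rank.
#' @param y Measurement vector of length m.
#' @return Feasible vector of length n.
#' @export
feasible_init <- function(Theta, y) {
  if (nrow(Theta) != length(y)) {
    stop("nrow(Theta) must equal length(y)", call. = FALSE)
  }
  G <- tcrossprod(Theta)
  z <- tryCatch(solve(G, y), error = function(e) {
    stop("Theta appears rank deficient: ", conditionMessage(e), call. = FALSE)
  })
  drop(crossprod(Theta, z))
}

#' Solve basis pursuit by a primal-dual interior-point method
#'
#' Minimizes the L1 norm of `s` subject to `Theta s = y`. Defaults follow the
#' classical equality-constrained L1 solver contract: surrogate duality-gap
#' tolerance `1e-6`, at most 26 primal-dual iterations, barrier update
#' mu = 10, and backtracking line search with alpha = 0.01, beta = 0.5.
#' Hitting the iteration cap or the numerical floor of the line search
#' returns the best iterate with a status flag, not an error.
#'
#' @param Theta m x n matrix (m <= n) with full row rank.
#' @param y Measurement vector of length m.
#' @param s0 Optional starting point; replaced by [feasible_init()] when
#'   absent or infeasible.
#' @param tol Surrogate duality-gap target (> 0).
#' @param max_iter Maximum number of interior-point iterations (>= 1).
#' @param keep_trace Record the per-iteration objective/gap trace.
#' @return Object of class `bp_solution`: list with the coefficient vector
#'   `s`, `iterations`, `duality_gap`, `feasibility_residual`
#'   (`||Theta s - y||_2`), `objective` (`||s||_1`), a `status` string
#'   (`"converged"`, `"max_iter"`, or `"line_search"`), and optionally a
#'   `trace` tibble.
#' @examples
#' Theta <- matrix(rnorm(40), 4, 10)
#' s_true <- c(2, rep(0, 9))
#' fit <- solve_bp(Theta, drop(Theta %*% s_true))
#' glance(fit)
#' @export
solve_bp <- function(Theta, y, s0 = NULL, tol = 1e-6, max_iter = 26,
                     keep_trace = FALSE) {
  stopifnot(is.matrix(Theta), tol > 0, max_iter >= 1)
  m <- nrow(Theta); n <- ncol(Theta)
  if (m > n) stop("Theta must have m <= n", call. = FALSE)
  y <- as.numeric(y)
  if (length(y) != m) stop("length(y) must equal nrow(Theta)", call. = FALSE)
  alpha <- 0.01; beta <- 0.5; mu <- 10

  ynorm <- max(1, l2norm(y))
  x <- s0
  if (is.null(x) || l2norm(drop(Theta %*% x) - y) > 1e-8 * ynorm) {
    x <- feasible_init(Theta, y)
  }
  if (all(y == 0) && is.null(s0)) {
    # unique L1 minimizer of the homogeneous system restricted to the
    # feasible affine set through the origin
    return(new_bp_solution(numeric(n), 0L, 0, 0, "converged", keep_trace, NULL))
  }

  u <- 0.95 * abs(x) + 0.10 * max(abs(x))
  if (max(abs(x)) == 0) u <- rep(1e-2, n)
  fu1 <- x - u; fu2 <- -x - u
  lamu1 <- -1 / fu1; lamu2 <- -1 / fu2
  v <- drop(-Theta %*% (lamu1 - lamu2))
  Atv <- drop(crossprod(Theta, v))
  rpri <- drop(Theta %*% x) - y
  sdg <- -(sum(fu1 * lamu1) + sum(fu2 * lamu2))
  tau <- mu * 2 * n / sdg
  rdual <- c(lamu1 - lamu2 + Atv, 1 - lamu1 - lamu2)
  rcent <- c(-lamu1 * fu1, -lamu2 * fu2) - 1 / tau
  resnorm <- l2norm(c(rdual, rcent, rpri))

  trace <- if (keep_trace) list(step0 = c(iter = 0, objective = sum(abs(x)),
                                          duality_gap = sdg, step = NA)) else NULL
  tTheta <- t(Theta)
  iter <- 0L
  status <- "converged"
  while (sdg >= tol) {
    if (iter >= max_iter) { status <- "max_iter"; break }
    iter <- iter + 1L
    w1 <- -(1 / tau) * (-1 / fu1 + 1 / fu2) - Atv
    w2 <- -1 - (1 / tau) * (1 / fu1 + 1 / fu2)
    w3 <- -rpri
    sig1 <- -lamu1 / fu1 - lamu2 / fu2
    sig2 <- lamu1 / fu1 - lamu2 / fu2
    # sigx = sig1 - sig2^2/sig1, written in product form: the difference
    # cancels catastrophically near convergence, while 4ab/sig1 (with
    # a = lam1/f1, b = lam2/f2, both negative) is exact and strictly positive
    sigx <- 4 * (lamu1 / fu1) * (lamu2 / fu2) / sig1
    # H11p = Theta diag(1/sigx) Theta' via a symmetric rank-k update
    H11p <- crossprod(sqrt(1 / sigx) * tTheta)
    w1p <- drop(Theta %*% ((w1 - w2 * sig2 / sig1) / sigx)) - w3
    dv <- tryCatch({
      R <- chol(H11p)
      backsolve(R, forwardsolve(t(R), w1p))
    }, error = function(e) {
      tryCatch(solve(H11p, w1p), error = function(e2) NULL)
    })
    if (is.null(dv)) { status <- "line_search"; iter <- iter - 1L; break }
    Atdv <- drop(crossprod(Theta, dv))
    dx <- (w1 - w2 * sig2 / sig1 - Atdv) / sigx
    du <- (w2 - sig2 * dx) / sig1
    dlamu1 <- (lamu1 / fu1) * (-dx + du) - lamu1 - (1 / tau) / fu1
    dlamu2 <- (lamu2 / fu2) * (dx + du) - lamu2 - (1 / tau) / fu2
    if (!all(is.finite(c(dx, du, dv, dlamu1, dlamu2)))) {
      status <- "line_search"; iter <- iter - 1L; break
    }
    Adx <- drop(Theta %*% dx)

    # largest interior step, then 0.99 safety factor
    s_max <- 1
    ind <- dlamu1 < 0
    if (any(ind)) s_max <- min(s_max, min(-lamu1[ind] / dlamu1[ind]))
    ind <- dlamu2 < 0
    if (any(ind)) s_max <- min(s_max, min(-lamu2[ind] / dlamu2[ind]))
    dfu1 <- dx - du; dfu2 <- -dx - du
    ind <- dfu1 > 0
    if (any(ind)) s_max <- min(s_max, min(-fu1[ind] / dfu1[ind]))
    ind <- dfu2 > 0
    if (any(ind)) s_max <- min(s_max, min(-fu2[ind] / dfu2[ind]))
    step <- 0.99 * s_max

    suffdec <- FALSE; backiter <- 0L
    while (!suffdec && backiter <= 32L) {
      xp <- x + step * dx; up <- u + step * du
      vp <- v + step * dv; Atvp <- Atv + step * Atdv
      lamu1p <- lamu1 + step * dlamu1; lamu2p <- lamu2 + step * dlamu2
      fu1p <- xp - up; fu2p <- -xp - up
      rdp <- c(lamu1p - lamu2p + Atvp, 1 - lamu1p - lamu2p)
      rcp <- c(-lamu1p * fu1p, -lamu2p * fu2p) - 1 / tau
      rpp <- rpri + step * Adx
      suffdec <- l2norm(c(rdp, rcp, rpp)) <= (1 - alpha * step) * resnorm
      if (!suffdec) step <- beta * step
      backiter <- backiter + 1L
    }
    if (!suffdec) { status <- "line_search"; iter <- iter - 1L; break }

    x <- xp; u <- up; v <- vp; Atv <- Atvp
    lamu1 <- lamu1p; lamu2 <- lamu2p; fu1 <- fu1p; fu2 <- fu2p
    rpri <- rpp
    sdg <- -(sum(fu1 * lamu1) + sum(fu2 * lamu2))
    tau <- mu * 2 * n / sdg
    rdual <- c(lamu1 - lamu2 + Atv, 1 - lamu1 - lamu2)
    rcent <- c(-lamu1 * fu1, -lamu2 * fu2) - 1 / tau
    resnorm <- l2norm(c(rdual, rcent, rpri))
    if (keep_trace) {
      trace[[length(trace) + 1L]] <- c(iter = iter, objective = sum(abs(x)),
                                       duality_gap = sdg, step = step)
    }
  }
  if (status != "converged") {
    warning("basis pursuit stopped (", status, ") with duality gap ",
            format(sdg, digits = 3), " above tol ", tol, call. = FALSE)
  }
  feas <- l2norm(drop(Theta %*% x) - y)
  new_bp_solution(x, iter, sdg, feas, status, keep_trace, trace)
}

new_bp_solution <- function(s, iterations, duality_gap, feasibility_residual,
                            status, keep_trace, trace) {
  out <- list(
    s = s,
    iterations = as.integer(iterations),
    duality_gap = duality_gap,
    feasibility_residual = feasibility_residual,
    objective = sum(abs(s)),
    status = status
  )
  if (keep_trace) {
    out$trace <- if (is.null(trace)) {
      tibble::tibble(iter = integer(), objective = numeric(),
                     duality_gap = numeric(), step = numeric())
    } else {
      tibble::as_tibble(do.call(rbind, trace))
    }
  }
  structure(out, class = "bp_solution")
}

#' @export
print.bp_solution <- function(x, ...) {
  cat(sprintf(
    "<bp_solution> n=%d ||s||_1=%.6g gap=%.3g feas=%.3g iters=%d status=%s\n",
    length(x$s), x$objective, x$duality_gap, x$feasibility_residual,
    x$iterations, x$status))
  invisible(x)
}

#' @rdname solve_bp
#' @param x A `bp_solution` object.
#' @param ... Unused.
#' @method tidy bp_solution
#' @export
tidy.bp_solution <- function(x, ...) {
  tibble::tibble(index = seq_along(x$s), value = x$s)
}

#' @rdname solve_bp
#' @method glance bp_solution
#' @export
glance.bp_solution <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    duality_gap = x$duality_gap,
    feasibility_residual = x$feasibility_residual,
    iterations = x$iterations,
    status = x$status
  )
}

#' Exact basis-pursuit reference via linear programming
#'
#' Independent cross-check for [solve_bp()] on small instances: the L1
#' problem is rewritten with a nonnegative split `s = p - q`, `p, q >= 0`, as
#' the linear program `min 1'p + 1'q` subject to `Theta (p - q) = y`, and
#' handed to a generic simplex routine. Exponential in the worst case, so
#' restricted to `n <= 256`.
#'
#' @param Theta m x n matrix, `n <= 256`.
#' @param y Measurement vector of length m.
#' @return Basis-pursuit solution vector of length n.
#' @export
bp_lp_oracle <- function(Theta, y) {
  stopifnot(is.matrix(Theta))
  n <- ncol(Theta)
  if (n > 256) stop("LP oracle restricted to n <= 256", call. = FALSE)
  A3 <- cbind(Theta, -Theta)
  b3 <- as.numeric(y)
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, , drop = FALSE]
  b3[neg] <- -b3[neg]
  out <- boot::simplex(a = rep(1, 2 * n), A3 = A3, b3 = b3, maxi = FALSE,
                       n.iter = 500 * n, eps = 1e-10)
  if (out$solved != 1) {
    stop("LP oracle did not solve (status ", out$solved,
         "): Theta may be rank deficient", call. = FALSE)
  }
  unname(out$soln[seq_len(n)] - out$soln[n + seq_len(n)])
}
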