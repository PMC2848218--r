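#' Parameters of the frontostriatal circuit model
#'
#' The circuit couples three populations — prefrontal cortex (PFC), striatum,
#' and midbrain DA nuclei — with striatal DA release fed back onto two
#' presynaptic D2 receptor populations: heteroreceptors on the frontostriatal
#' glutamatergic terminals (coefficient `b`, depressing cortical input to the
#' striatum by a factor `1 - b*P`) and autoreceptors on the dopaminergic
#' terminals (coefficient `a`, suppressing release by `1 - a*P`), where
#' `P = Y/(1+Y)` is the D2 occupancy by DA.
#'
#' All analyses use normalized variables, in which the connectivity products
#' are absorbed into the state; the `w_*` coefficients therefore default to 1
#' and are only needed for un-normalized experiments.  `activation` selects
#' the population activation function: `"linear"` (`f(x) = x`, used for all
#' equilibrium analysis) or `"tanh"` (the saturating full model, available in
#' time-domain simulation).
#'
#' @param a autoreceptor suppression coefficient (>= 0).
#' @param b heteroreceptor depression coefficient (>= 0).
#' @param j_d normalized tonic drive to the DA nuclei (> 0, default 1).
#' @param tau_s,tau_d,tau_y time constants of the striatal population, the DA
#'   nuclei, and DA release (arbitrary time units, > 0).
#' @param w_ps,w_sd,w_dy connectivity / releasability coefficients (> 0,
#'   default 1 = normalized variables).
#' @param activation `"linear"` or `"tanh"`.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(a = 0, b = 0, j_d = 1,
                           tau_s = 1, tau_d = 1, tau_y = 1,
                           w_ps = 1, w_sd = 1, w_dy = 1,
                           activation = c("linear", "tanh")) {
  activation <- match.arg(activation)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    x
  }
  for (nm in c("a", "b", "j_d", "tau_s", "tau_d", "tau_y",
               "w_ps", "w_sd", "w_dy")) num1(get(nm), nm)
  if (a < 0 || b < 0) stop("'a' and 'b' must be non-negative", call. = FALSE)
  if (j_d <= 0) stop("'j_d' must be strictly positive", call. = FALSE)
  if (any(c(tau_s, tau_d, tau_y) <= 0))
    stop("time constants must be strictly positive", call. = FALSE)
  if (any(c(w_ps, w_sd, w_dy) <= 0))
    stop("connectivity coefficients must be strictly positive", call. = FALSE)
  structure(list(a = a, b = b, j_d = j_d,
                 tau_s = tau_s, tau_d = tau_d, tau_y = tau_y,
                 w_ps = w_ps, w_sd = w_sd, w_dy = w_dy,
                 activation = activation),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Frontostriatal circuit parameters\n")
  cat(sprintf("  D2 autoreceptor a = %.3g, heteroreceptor b = %.3g, J_d = %.3g\n",
              x$a, x$b, x$j_d))
  cat(sprintf("  tau (s, d, y) = (%.3g, %.3g, %.3g); W (ps, sd, dy) = (%.3g, %.3g, %.3g)\n",
              x$tau_s, x$tau_d, x$tau_y, x$w_ps, x$w_sd, x$w_dy))
  cat(sprintf("  activation: %s\n", x$activation))
  invisible(x)
}

# occupancy from possibly-transient (negative) y; clamped into [0, 1)
.occ <- function(y) {
  y <- pmax(y, 0)
  y / (1 + y)
}

# D2 modulation gains, clamped at zero so transmission never turns negative
.gains <- function(p, params) {
  list(hetero = max(0, 1 - params$b * p),
       auto   = max(0, 1 - params$a * p))
}

#' Time derivatives of the circuit state
#'
#' The right-hand side of the circuit dynamics.  The state is
#' `(x_p, x_s, x_d, y)`: PFC activity, striatal activity, DA-nucleus
#' activity, and striatal DA release.  With `f` the activation function and
#' `P` the D2 occupancy computed from the current `y`:
#' \deqn{\tau_s \dot x_s = -x_s + W_{ps} f(x_p)(1 - bP)}
#' \deqn{\tau_d \dot x_d = -x_d + J_d - W_{sd} f(x_s)}
#' \deqn{\tau_y \dot y   = -y + W_{dy} x_d (1 - aP)}
#' PFC activity relaxes to the external drive, `tau_s * x_p' = drive - x_p`.
#' The D2 gain factors are clamped at zero.
#'
#' @param state numeric vector `c(x_p, x_s, x_d, y)`.
#' @param params a [circuit_params()].
#' @param pfc_input external drive to the PFC.
#' @return Numeric vector of the four time derivatives.
#' @export
dynamics_rhs <- function(state, params, pfc_input = 0) {
  stopifnot(inherits(params, "circuit_params"),
            is.numeric(state), length(state) == 4L)
  f <- if (params$activation == "tanh") tanh else identity
  x_p <- state[[1L]]; x_s <- state[[2L]]; x_d <- state[[3L]]; y <- state[[4L]]
  p <- .occ(y)
  g <- .gains(p, params)
  c(x_p = (pfc_input - x_p) / params$tau_s,
    x_s = (-x_s + params$w_ps * f(x_p) * g$hetero) / params$tau_s,
    x_d = (-x_d + params$j_d - params$w_sd * f(x_s)) / params$tau_d,
    y   = (-y + params$w_dy * x_d * g$auto) / params$tau_y)
}

# scalar fixed-point map in Y: chains striatum -> DA nucleus -> release
.release_map <- function(y, params, x_p) {
  p <- .occ(y)
  g <- .gains(p, params)
  x_s <- params$w_ps * x_p * g$hetero
  x_d <- params$j_d - params$w_sd * x_s
  params$w_dy * x_d * g$auto
}

#' Equilibrium of the linearized circuit
#'
#' Solves the self-consistent fixed point of the linearized circuit at a
#' given PFC activity:
#' \deqn{X_s = X_p (1 - bP), \quad X_d = J_d - X_s, \quad
#'       Y = X_d (1 - aP), \quad P = Y/(1+Y),}
#' (with the `w_*` coefficients inserted when they differ from 1).  The
#' scalar residual in `Y` is solved by damped fixed-point iteration
#' (damping 0.5, tolerance 1e-10) with a bracketed root scan as fallback; on
#' the physical branch the positive solution is unique when it exists.
#' Solutions violating the positivity constraints (all of `x_s`, `x_d`, `y`
#' must be positive) are rejected as infeasible.
#'
#' @param params a [circuit_params()]; equilibrium analysis requires
#'   `activation = "linear"`.
#' @param x_p normalized PFC activity (> 0).
#' @param tol convergence tolerance on the fixed-point residual.
#' @return An object of class `equilibrium_state`: a list with elements
#'   `x_p`, `x_s`, `x_d`, `y`, `p` (D2 occupancy) and `residual`.
#' @examples
#' solve_equilibrium(circuit_params(a = 0, b = 1), x_p = 0.7)$y  # ~0.548
#' @export
solve_equilibrium <- function(params, x_p, tol = 1e-10) {
  stopifnot(inherits(params, "circuit_params"))
  if (params$activation != "linear")
    stop("equilibrium analysis uses the linear activation; ",
         "set activation = \"linear\"", call. = FALSE)
  if (!is.numeric(x_p) || length(x_p) != 1L || !is.finite(x_p) || x_p <= 0)
    stop("'x_p' must be a single positive number", call. = FALSE)

  g <- function(y) .release_map(y, params, x_p)
  y_max <- params$w_dy * params$j_d  # Y = W_dy * X_d * (1-aP) <= W_dy * J_d

  # damped iteration
  y <- max(g(0), tol)
  converged <- FALSE
  for (i in seq_len(10000L)) {
    y_new <- 0.5 * y + 0.5 * max(g(y), 0)
    if (abs(y_new - y) < tol) { y <- y_new; converged <- TRUE; break }
    y <- y_new
  }
  if (!converged || abs(y - g(y)) > 1e3 * tol) {
    # bracketing root-scan fallback on h(y) = y - g(y)
    h <- function(y) y - g(y)
    grid <- seq(0, y_max, length.out = 2048L)
    hv <- vapply(grid, h, numeric(1))
    sgn <- which(hv[-1L] * hv[-length(hv)] <= 0)
    if (!length(sgn))
      stop("no positive equilibrium exists for these parameters ",
           "(positivity constraints violated)", call. = FALSE)
    y <- stats::uniroot(h, c(grid[sgn[1L]], grid[sgn[1L] + 1L]),
                        tol = tol / 10)$root
  }

  # Newton polish to push the fixed-point residual to machine precision
  for (i in 1:5) {
    hy <- y - g(y)
    if (abs(hy) < 1e-14) break
    dl <- max(1e-7 * max(y, 1), 1e-9)
    dh <- ((y + dl - g(y + dl)) - (y - dl - g(y - dl))) / (2 * dl)
    if (!is.finite(dh) || abs(dh) < 1e-8) break
    step <- hy / dh
    if (y - step < 0) break
    y <- y - step
  }

  p <- .occ(y)
  gg <- .gains(p, params)
  x_s <- params$w_ps * x_p * gg$hetero
  x_d <- params$j_d - params$w_sd * x_s
  if (!(x_s > 0 && x_d > 0 && y > 0))
    stop("no positive equilibrium exists for these parameters ",
         "(positivity constraints violated)", call. = FALSE)
  structure(list(x_p = x_p, x_s = x_s, x_d = x_d, y = y, p = p,
                 residual = abs(y - g(y)), params = params),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Circuit equilibrium (linearized)\n")
  cat(sprintf("  X_p = %.4f  X_s = %.4f  X_d = %.4f\n", x$x_p, x$x_s, x$x_d))
  cat(sprintf("  DA release Y = %.4f   D2 occupancy P = %.1f%%\n",
              x$y, 100 * x$p))
  cat(sprintf("  fixed-point residual: %.2e\n", x$residual))
  invisible(x)
}

#' Equilibrium sweep over PFC activity and D2 coefficients
#'
#' Solves the circuit equilibrium over a grid of PFC activities for each
#' combination of the D2 coefficients, producing the striatal-activity and
#' DA-release curves as functions of PFC activity.  Grid points with no
#' positive equilibrium are flagged (`feasible = FALSE`) rather than dropped.
#'
#' @param x_p numeric vector of PFC activities (> 0).
#' @param a,b numeric vectors of D2 auto-/heteroreceptor coefficients.
#' @param j_d tonic drive to the DA nuclei.
#' @return A data frame with columns `x_p`, `a`, `b`, `j_d`, `x_s`, `x_d`,
#'   `y`, `p`, `feasible` (one row per grid point; state columns are `NA`
#'   where infeasible).
#' @examples
#' sweep_equilibrium(x_p = 0.7, a = 0, b = c(0, 1))
#' @export
sweep_equilibrium <- function(x_p, a = 0, b = 0, j_d = 1) {
  stopifnot(is.numeric(x_p), length(x_p) >= 1L, all(is.finite(x_p)),
            all(x_p > 0))
  grid <- expand.grid(x_p = x_p, a = a, b = b, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  out <- data.frame(grid, j_d = j_d, x_s = NA_real_, x_d = NA_real_,
                    y = NA_real_, p = NA_real_, feasible = FALSE)
  for (i in seq_len(n)) {
    eq <- tryCatch(
      solve_equilibrium(circuit_params(a = grid$a[i], b = grid$b[i],
                                       j_d = j_d),
                        x_p = grid$x_p[i]),
      error = function(e) NULL)
    if (!is.null(eq)) {
      out$x_s[i] <- eq$x_s; out$x_d[i] <- eq$x_d
      out$y[i] <- eq$y; out$p[i] <- eq$p
      out$feasible[i] <- TRUE
    }
  }
  out
}

#' Percent change in DA release
#'
#' `100 * (y_with - y_without) / y_without`, e.g. the enhancement of
#' equilibrium DA release when a D2 receptor effect is switched on.
#'
#' @param y_with,y_without DA release with and without the effect
#'   (`y_without` > 0).
#' @return Percent change.
#' @export
enhancement_percent <- function(y_with, y_without) {
  stopifnot(is.numeric(y_with), is.numeric(y_without))
  if (any(y_without <= 0))
    stop("'y_without' must be strictly positive", call. = FALSE)
  100 * (y_with - y_without) / y_without
}

#' Integrate the circuit dynamics
#'
#' Fixed-step 4th-order Runge-Kutta integration (via [deSolve::ode()],
#' method `"rk4"`) of [dynamics_rhs()].  With the linear activation and a
#' stable parameterization the trajectory converges to the algebraic
#' equilibrium of [solve_equilibrium()].
#'
#' @param params a [circuit_params()].
#' @param initial named or positional numeric vector `c(x_p, x_s, x_d, y)`.
#' @param pfc_input constant external drive to the PFC.
#' @param t_end end time (> 0).
#' @param dt time step; default `min(tau)/20`.
#' @param bound divergence guard: the integration aborts if any state
#'   exceeds this magnitude.
#' @return An object of class `circuit_trajectory`: a data frame with
#'   columns `time`, `x_p`, `x_s`, `x_d`, `y`.
#' @export
simulate_circuit <- function(params, initial = c(0, 0, 0, 0), pfc_input = 0,
                             t_end = 50, dt = NULL, bound = 1e6) {
  stopifnot(inherits(params, "circuit_params"),
            is.numeric(initial), length(initial) == 4L,
            t_end > 0)
  if (is.null(dt)) dt <- min(params$tau_s, params$tau_d, params$tau_y) / 20
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  times <- seq(0, t_end, by = dt)
  rhs <- function(t, state, parms) list(dynamics_rhs(state, params, pfc_input))
  sol <- deSolve::ode(y = c(x_p = unname(initial[1L]),
                            x_s = unname(initial[2L]),
                            x_d = unname(initial[3L]),
                            y   = unname(initial[4L])),
                      times = times, func = rhs, parms = NULL,
                      method = "rk4")
  traj <- as.data.frame(sol)
  if (any(!is.finite(as.matrix(traj))) ||
      max(abs(as.matrix(traj[-1L]))) > bound)
    stop("trajectory diverged beyond the configured bound; ",
         "the parameterization appears unstable", call. = FALSE)
  structure(traj, class = c("circuit_trajectory", "data.frame"))
}

#' @export
plot.circuit_trajectory <- function(x, ...) {
  m <- as.matrix(x[, c("x_p", "x_s", "x_d", "y")])
  graphics::matplot(x$time, m, type = "l", lty = 1, lwd = 1.5,
                    xlab = "time", ylab = "normalized state", ...)
  graphics::legend("bottomright", legend = c("X_p", "X_s", "X_d", "Y"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}
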