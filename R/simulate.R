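# basal active-MEK level used to clamp the constant-MEK variant during
# pre-equilibration: two-site steady state with D = 0 (feedback inert)
.basal_m2 <- function(params) {
  r <- params$a_M * params$S_basal / params$d_M
  r^2 / (1 + r + r^2)
}

.m2_clamp_for <- function(params, variant, pre = FALSE) {
  if (!.variant_constmek(variant)) return(0)
  if (pre) .basal_m2(params) else params$M2_const
}

#' Pre-stimulus steady state
#'
#' Equilibrates the model at the basal input strength `S_basal` (no
#' inhibitors), by long-time integration followed by a damped Newton polish on
#' the reduced system (conservation of total MEK and total ERK eliminates two
#' coordinates).  The returned state satisfies the steady-state condition to a
#' right-hand-side max-norm below 1e-10.
#'
#' @param params an [erk_params()] object.
#' @param variant model variant tag.
#' @return Named numeric state vector (see [erk_rhs()] for components).
#' @export
#' @examples
#' s0 <- initial_state(theta_ref())
#' max(abs(erk_rhs(0, s0, theta_ref(), u = theta_ref()$S_basal)))
initial_state <- function(params, variant = "full") {
  validate_erk_params(params)
  p <- .variant_params(params, variant)
  u <- p$S_basal
  m2c <- .m2_clamp_for(p, variant, pre = TRUE)

  y0 <- setNames(numeric(length(.erk_state_names)), .erk_state_names)
  y0["M0"] <- 1
  y0["E0c"] <- 1
  if (.variant_constmek(variant)) {
    r <- p$a_M * u / p$d_M
    y0["M0"] <- 1 / (1 + r + r^2)
    y0["M1"] <- r * y0["M0"]
    y0["M2"] <- m2c
  }

  # long-time integration toward the attractor
  pv <- .parm_vector(p, u = u, importin = .variant_importin(variant),
                     const_mek = .variant_constmek(variant), m2_clamp = m2c)
  sol <- deSolve::ode(y = y0, times = c(0, 10000), func = "erk_derivs",
                      parms = pv, dllname = "erkshuttle", initfunc = "erk_init",
                      method = "lsoda", rtol = 1e-10, atol = 1e-12,
                      maxsteps = 100000)
  y <- pmax(sol[nrow(sol), .erk_state_names], 0)

  rhs_at <- function(st) erk_rhs(0, st, p, u = u, variant = variant, m2_clamp = m2c)

  # reduced unknowns: conservation gives M0 and E0c; inert coordinates dropped
  unknowns <- c("M1", "M2", "D", "E1c", "E2c", "EBc", "E0n", "E1n", "E2n",
                "EBn", "Pc", "Pn")
  if (.variant_importin(variant)) unknowns <- c(unknowns, "EIn")
  if (.variant_constmek(variant)) unknowns <- setdiff(unknowns, c("M1", "M2", "D"))
  if (p$fb_mode > 0.5) unknowns <- setdiff(unknowns, "D")  # D inert in Hill mode

  rebuild <- function(x) {
    st <- y
    st[unknowns] <- x
    if (!.variant_constmek(variant)) st["M0"] <- 1 - st["M1"] - st["M2"]
    erk_pools <- c("E1c", "E2c", "EBc", "E0n", "E1n", "E2n", "EBn", "EIn")
    st["E0c"] <- 1 - sum(st[erk_pools])
    st
  }
  resid <- function(x) unname(rhs_at(rebuild(x))[unknowns])

  x <- unname(y[unknowns])
  r0 <- resid(x)
  for (iter in 1:25) {
    if (max(abs(r0)) < 1e-12) break
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(1e-8, 1e-6 * abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (resid(xp) - r0) / h
    }
    step <- tryCatch(solve(J, -r0), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      rn <- tryCatch(resid(xn), error = function(e) NULL)
      ok <- !is.null(rn) && all(is.finite(rn)) && max(abs(rn)) < max(abs(r0))
      if (ok || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (!ok) break
    x <- xn; r0 <- rn
  }
  st <- rebuild(x)
  st[abs(st) < 1e-15] <- 0

  res <- max(abs(rhs_at(st)))
  if (res > 1e-10) {
    abort(paste0("steady-state solve did not converge (residual ", signif(res, 3),
                 ") for parameter set: ",
                 paste(sprintf("%s=%.3g", names(p), unlist(p)), collapse = ", ")))
  }
  st
}

#' Simulate the model under a protocol
#'
#' Integrates the model with an adaptive stiff solver (deSolve's `lsoda`,
#' relative tolerance 1e-8, absolute 1e-10) from the pre-stimulus steady
#' state, restarting the integration exactly at every protocol event time
#' (input-strength changes and inhibitor additions), with no event smoothing.
#'
#' @param params an [erk_params()] object.
#' @param protocol an [erk_protocol()] object; its `variant` selects the model
#'   variant unless overridden by `variant`.
#' @param t_grid output time grid (min), within `[0, t_end]`.
#' @param variant optional variant override.
#' @param y0 optional initial state (defaults to [initial_state()]).
#' @param rtol,atol integration tolerances.
#' @return A tibble of class `erk_trajectory`: column `time_min` followed by
#'   one column per state component; the parameter set and protocol are
#'   attached as attributes.
#' @export
#' @examples
#' tr <- erk_simulate(theta_ref(), protocol_step(S = 1, t_end = 30))
#' head(tr)
erk_simulate <- function(params, protocol, t_grid = NULL, variant = NULL,
                         y0 = NULL, rtol = 1e-8, atol = 1e-10) {
  variant <- variant %||% protocol$variant
  p <- .variant_params(params, variant)
  if (is.null(t_grid)) t_grid <- seq(0, protocol$t_end, by = 0.5)
  t_grid <- sort(unique(t_grid))
  if (min(t_grid) < 0 || max(t_grid) > protocol$t_end) {
    abort("t_grid must lie within [0, t_end]")
  }
  if (is.null(y0)) y0 <- initial_state(p, variant)
  m2c <- .m2_clamp_for(p, variant, pre = FALSE)
  if (.variant_constmek(variant)) y0["M2"] <- m2c

  out <- matrix(NA_real_, nrow = length(t_grid), ncol = length(.erk_state_names),
                dimnames = list(NULL, .erk_state_names))
  if (t_grid[1] == 0) out[1, ] <- y0

  y <- y0
  for (seg in .protocol_segments(protocol)) {
    if (seg$to <= seg$from) next
    inner <- t_grid[t_grid > seg$from & t_grid <= seg$to]
    times <- sort(unique(c(seg$from, inner, seg$to)))
    pv <- .parm_vector(p, u = seg$u, inh = seg$inh, pho = seg$pho,
                       importin = .variant_importin(variant),
                       const_mek = .variant_constmek(variant), m2_clamp = m2c)
    sol <- tryCatch(
      deSolve::ode(y = y, times = times, func = "erk_derivs", parms = pv,
                   dllname = "erkshuttle", initfunc = "erk_init",
                   method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000),
      error = function(e) e
    )
    if (inherits(sol, "error") || nrow(sol) < length(times) ||
        anyNA(sol[nrow(sol), ])) {
      abort(paste0("integration failed near t = ", seg$from, " min for parameter set: ",
                   paste(sprintf("%s=%.3g", names(p), unlist(p)), collapse = ", ")))
    }
    if (length(inner)) {
      out[match(inner, t_grid), ] <- sol[match(inner, times), .erk_state_names]
    }
    y <- sol[nrow(sol), .erk_state_names]
  }

  traj <- as_tibble(cbind(data.frame(time_min = t_grid), as.data.frame(out)))
  attr(traj, "params") <- p
  attr(traj, "protocol") <- protocol
  attr(traj, "variant") <- variant
  class(traj) <- c("erk_trajectory", class(traj))
  traj
}

#' Fixed-step RK4 simulation (oracle)
#'
#' Integrates the same model with the classical fourth-order Runge-Kutta
#' method at a fixed step, using the pure-R right-hand side.  Intended as an
#' independent cross-check of the adaptive compiled-code integrator, not for
#' production use.
#'
#' @inheritParams erk_simulate
#' @param dt fixed step size (min).
#' @return A tibble shaped like the result of [erk_simulate()].
#' @export
erk_simulate_rk4 <- function(params, protocol, t_grid = NULL, dt = 0.001,
                             variant = NULL, y0 = NULL) {
  variant <- variant %||% protocol$variant
  p <- .variant_params(params, variant)
  if (is.null(t_grid)) t_grid <- seq(0, protocol$t_end, by = 0.5)
  t_grid <- sort(unique(t_grid))
  if (is.null(y0)) y0 <- initial_state(p, variant)
  m2c <- .m2_clamp_for(p, variant, pre = FALSE)
  if (.variant_constmek(variant)) y0["M2"] <- m2c

  out <- matrix(NA_real_, nrow = length(t_grid), ncol = length(.erk_state_names),
                dimnames = list(NULL, .erk_state_names))
  if (t_grid[1] == 0) out[1, ] <- y0

  y <- y0
  for (seg in .protocol_segments(protocol)) {
    if (seg$to <= seg$from) next
    f <- function(st) erk_rhs(0, st, p, u = seg$u, inh = seg$inh, pho = seg$pho,
                              variant = variant, m2_clamp = m2c)
    marks <- sort(unique(c(seg$from, t_grid[t_grid > seg$from & t_grid <= seg$to],
                           seg$to)))
    for (i in seq_len(length(marks) - 1L)) {
      span <- marks[i + 1L] - marks[i]
      nsub <- max(1L, ceiling(span / dt))
      h <- span / nsub
      for (k in seq_len(nsub)) {
        k1 <- f(y)
        k2 <- f(y + h / 2 * k1)
        k3 <- f(y + h / 2 * k2)
        k4 <- f(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      if (marks[i + 1L] %in% t_grid) out[match(marks[i + 1L], t_grid), ] <- y
    }
  }

  traj <- as_tibble(cbind(data.frame(time_min = t_grid), as.data.frame(out)))
  attr(traj, "params") <- p
  attr(traj, "protocol") <- protocol
  attr(traj, "variant") <- variant
  class(traj) <- c("erk_trajectory", class(traj))
  traj
}

#' Export a trajectory to CSV
#'
#' @param traj an `erk_trajectory` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(as_tibble(as.data.frame(traj)), path)
  invisible(path)
}
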