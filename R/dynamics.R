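#' Chemostat external conditions
#'
#' @param d Dilution rate (1/time), > 0.
#' @param c_supply Supply concentration vector (one entry per external
#'   chemical), components >= 0.
#' @param r Biomass per cell volume (biomass/volume), > 0; converts impact
#'   fluxes (per cell volume) into medium consumption rates.
#' @return Object of class `chemostat_setup`.
#' @export
chemostat_setup <- function(d, c_supply, r = 1) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("dilution rate d must be a single positive number")
  c_supply <- as.numeric(c_supply)
  if (any(!is.finite(c_supply)) || any(c_supply < 0))
    stop("supply concentrations must be finite and >= 0")
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("r (biomass per cell volume) must be a single positive number")
  structure(list(d = d, c_supply = c_supply, r = r), class = "chemostat_setup")
}

#' Linked-chemostat (spatial chain) setup
#'
#' `k_tot` identical chemostats in a line exchange both medium (chemicals)
#' and cells (biomass) with their nearest neighbours at leakage rate `l`
#' (discrete Laplacian, no-flux boundaries).
#'
#' @param k_tot Number of vessels, >= 1.
#' @param l Leakage rate (1/time), >= 0.
#' @param setup A [chemostat_setup()] applied to every vessel.
#' @return Object of class `chain_setup`.
#' @export
chain_setup <- function(k_tot, l, setup) {
  k_tot <- as.integer(k_tot)
  if (k_tot < 1L) stop("k_tot must be >= 1")
  if (!is.numeric(l) || length(l) != 1L || l < 0) stop("l must be >= 0")
  stopifnot(inherits(setup, "chemostat_setup"))
  structure(list(k_tot = k_tot, l = l, setup = setup), class = "chain_setup")
}

#' Community state
#'
#' @param m Species biomass densities (biomass/volume), >= 0.
#' @param conc Chemical environment vector, >= 0.
#' @param t Time stamp (default 0).
#' @return Object of class `community_state`.
#' @export
community_state <- function(m, conc, t = 0) {
  m <- as.numeric(m); conc <- as.numeric(conc)
  if (any(!is.finite(m)) || any(m < 0)) stop("biomasses must be finite and >= 0")
  if (any(!is.finite(conc)) || any(conc < 0)) stop("concentrations must be finite and >= 0")
  structure(list(m = m, conc = conc, t = t), class = "community_state")
}

## Growth rates and impact fluxes for a whole community at one environment.
## strategies: list of allocation vectors. Returns list(g = vector,
## I = matrix species x chemicals). Vectorized over species for the
## closed-form models; internal-state models loop.
community_rates <- function(model, conc, strategies) {
  conc <- pmax(conc, 0)
  n <- length(strategies)
  if (n == 0L)
    return(list(g = numeric(0), I = matrix(0, 0L, model$n_chemicals)))
  if (model$name %in% c("substitutable", "essential", "substitutable_assim")) {
    S <- do.call(rbind, lapply(strategies, as.numeric))
    p <- model$n_chemicals
    v <- par_vec(model$params$v, p); K <- par_vec(model$params$K, p)
    mon <- monod(conc, K)
    if (model$name == "substitutable") {
      w <- par_vec(model$params$w, p)
      U <- S * rep(v * mon, each = n)
      list(g = as.numeric(U %*% w), I = U)
    } else if (model$name == "essential") {
      U <- S * rep(v * mon, each = n)
      list(g = apply(U, 1L, min), I = U)
    } else {
      w <- par_vec(model$params$w, p)
      v_as <- par_vec(model$params$v_as, p)
      U <- S[, 1:3, drop = FALSE] * rep(v * mon, each = n)
      Cap <- S[, 4:6, drop = FALSE] * rep(v_as, each = n)
      list(g = as.numeric(pmin(U, Cap) %*% w), I = U)
    }
  } else {
    g <- numeric(n)
    I <- matrix(0, n, model$n_chemicals)
    for (i in seq_len(n)) {
      ev <- eval_model(model, conc, as.numeric(strategies[[i]]))
      g[i] <- ev$g; I[i, ] <- ev$I
    }
    list(g = g, I = I)
  }
}

## Right-hand side of the chemostat ODE, shared by simulate and steady_state.
## y = c(m, conc). Negative excursions are damped: consumption uses
## pmax(m, 0) and fluxes are evaluated at pmax(conc, 0).
chemostat_rhs <- function(t, y, parms) {
  n_s <- parms$n_s; n_c <- parms$n_c
  m <- y[seq_len(n_s)]
  conc <- pmax(y[n_s + seq_len(n_c)], 0)
  rates <- community_rates(parms$model, conc, parms$strategies)
  dm <- m * (rates$g - parms$setup$d)
  cons <- if (n_s) as.numeric(crossprod(pmax(m, 0), rates$I)) / parms$setup$r else 0
  dc <- parms$setup$d * (parms$setup$c_supply - conc) - cons
  list(c(dm, dc))
}

#' Simulate chemostat population and environment dynamics
#'
#' Integrates `dm/dt = m (g(c, alpha) - d)` for every species together with
#' `dc_i/dt = d (c_supply_i - c_i) - sum_sigma m_sigma / r * I_i(c, alpha_sigma)`
#' using an adaptive-step stiff integrator. Species whose biomass falls below
#' the extinction threshold are clamped to zero and logged as events.
#'
#' @param setup A [chemostat_setup()].
#' @param model A `metabolic_model`.
#' @param strategies List of allocation vectors (one per species).
#' @param state0 A [community_state()] (dimensions must match).
#' @param t_end End time of the integration.
#' @param n_out Number of output time points (default 201).
#' @param rtol,atol Relative / absolute integrator tolerances.
#' @param extinction Biomass threshold below which a species is removed
#'   (default 1e-9).
#' @return Object of class `chemostat_trajectory`: `times`, `m` (time x
#'   species matrix), `conc` (time x chemical matrix), `events` (data.frame
#'   time/species/event), plus the call ingredients.
#' @export
simulate_chemostat <- function(setup, model, strategies, state0, t_end,
                               n_out = 201L, rtol = 1e-8, atol = 1e-10,
                               extinction = 1e-9) {
  stopifnot(inherits(setup, "chemostat_setup"), inherits(model, "metabolic_model"))
  strategies <- lapply(strategies, function(s) check_strategy(model, s))
  if (length(state0$m) != length(strategies))
    stop("state0 has ", length(state0$m), " biomasses for ",
         length(strategies), " strategies")
  if (length(state0$conc) != model$n_chemicals)
    stop("state0 environment does not match the model's chemicals")
  if (length(setup$c_supply) != model$n_chemicals)
    stop("supply vector does not match the model's chemicals")
  t0 <- state0$t
  if (t_end <= t0) stop("t_end must exceed state0$t")
  times <- seq(t0, t_end, length.out = max(2L, n_out))
  parms <- list(model = model, setup = setup, strategies = strategies,
                n_s = length(strategies), n_c = model$n_chemicals)
  y <- c(state0$m, state0$conc)
  ## integrate in blocks so extinction clamping can act mid-run
  n_blocks <- min(20L, max(1L, length(times) - 1L))
  idx_breaks <- unique(round(seq(1L, length(times), length.out = n_blocks + 1L)))
  out <- matrix(NA_real_, length(times), length(y))
  out[1L, ] <- y
  events <- list()
  for (b in seq_len(length(idx_breaks) - 1L)) {
    ii <- idx_breaks[b]:idx_breaks[b + 1L]
    sol <- deSolve::ode(y = y, times = times[ii], func = chemostat_rhs,
                        parms = parms, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 1e5)
    if (attr(sol, "istate")[1L] < 0)
      stop("integrator failure at t = ", utils::tail(sol[, 1L], 1L))
    out[ii, ] <- sol[, -1L, drop = FALSE]
    y <- sol[nrow(sol), -1L]
    dead <- which(y[seq_len(parms$n_s)] < extinction & y[seq_len(parms$n_s)] != 0)
    if (length(dead)) {
      y[dead] <- 0
      out[idx_breaks[b + 1L], dead] <- 0
      for (s in dead)
        events[[length(events) + 1L]] <-
          data.frame(time = times[idx_breaks[b + 1L]], species = s,
                     event = "extinction")
    }
    y[parms$n_s + seq_len(parms$n_c)] <- pmax(y[parms$n_s + seq_len(parms$n_c)], 0)
  }
  m_out <- out[, seq_len(parms$n_s), drop = FALSE]
  c_out <- pmax(out[, parms$n_s + seq_len(parms$n_c), drop = FALSE], 0)
  if (parms$n_s) colnames(m_out) <- paste0("m", seq_len(parms$n_s))
  colnames(c_out) <- model$chem_names
  structure(list(times = times, m = m_out, conc = c_out,
                 events = if (length(events)) do.call(rbind, events) else
                   data.frame(time = numeric(), species = integer(),
                              event = character()),
                 model = model, setup = setup, strategies = strategies),
            class = "chemostat_trajectory")
}

#' @export
print.chemostat_trajectory <- function(x, ...) {
  cat("<chemostat_trajectory> ", ncol(x$m), " species, ",
      ncol(x$conc), " chemicals, t in [", min(x$times), ", ",
      max(x$times), "]\n", sep = "")
  cat("  final biomass: ", paste(signif(x$m[nrow(x$m), ], 4), collapse = ", "),
      "\n  final environment: ",
      paste(signif(x$conc[nrow(x$conc), ], 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x A `chemostat_trajectory`.
#' @param ... Unused.
#' @return data.frame with columns `time`, `variable`, `value`.
#' @export
as.data.frame.chemostat_trajectory <- function(x, ...) {
  wide <- cbind(x$m, x$conc)
  data.frame(time = rep(x$times, ncol(wide)),
             variable = rep(colnames(wide), each = length(x$times)),
             value = as.numeric(wide))
}

## Max |dy/dt| of the community system at a state vector.
rhs_norm <- function(y, parms) max(abs(chemostat_rhs(0, y, parms)[[1L]]))

#' Community steady state of a chemostat
#'
#' Integrates the community until the derivative norm falls below `tol_deriv`
#' over a trailing window, then polishes the survivors' fixed point with a
#' damped Newton step on the algebraic system (growth = dilution for every
#' survivor; nutrient mass balance for every chemical). Oscillatory systems
#' that never settle are reported as non-converged rather than raising an
#' error.
#'
#' @inheritParams simulate_chemostat
#' @param state0 Optional [community_state()]; default seeds every species at
#'   biomass 0.01 into the supply environment.
#' @param tol_deriv Convergence threshold on `max |dy/dt|` (default 1e-8).
#' @param t_cap Time cap after which non-convergence is reported (default
#'   `2e4 / d`).
#' @param extinction Biomass threshold for the survivor set.
#' @return Object of class `chemostat_steady_state`: `m`, `conc`,
#'   `survivors` (indices with `m >` threshold), `residual` (max |dy/dt|),
#'   `converged`, `t` (integration time used).
#' @export
steady_state <- function(setup, model, strategies, state0 = NULL,
                         tol_deriv = 1e-8, t_cap = 2e4 / setup$d,
                         extinction = 1e-9, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(setup, "chemostat_setup"), inherits(model, "metabolic_model"))
  strategies <- lapply(strategies, function(s) check_strategy(model, s))
  n_s <- length(strategies); n_c <- model$n_chemicals
  if (is.null(state0))
    state0 <- community_state(rep(0.01, n_s), setup$c_supply)
  parms <- list(model = model, setup = setup, strategies = strategies,
                n_s = n_s, n_c = n_c)
  y <- c(state0$m, state0$conc)
  t <- 0; chunk <- 20 / setup$d
  converged <- FALSE
  while (t < t_cap) {
    sol <- deSolve::ode(y = y, times = c(t, t + chunk), func = chemostat_rhs,
                        parms = parms, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 1e5)
    y <- sol[nrow(sol), -1L]
    t <- t + chunk
    y[seq_len(n_s)][y[seq_len(n_s)] < extinction] <- 0
    y[n_s + seq_len(n_c)] <- pmax(y[n_s + seq_len(n_c)], 0)
    if (rhs_norm(y, parms) < tol_deriv) { converged <- TRUE; break }
    chunk <- min(chunk * 1.5, 2000 / setup$d)
  }
  m <- unname(y[seq_len(n_s)]); conc <- unname(y[n_s + seq_len(n_c)])
  if (converged) {
    polished <- polish_steady_state(setup, model, strategies, m, conc, extinction)
    m <- polished$m; conc <- polished$conc
  }
  survivors <- which(m > extinction)
  residual <- rhs_norm(c(m, conc), parms)
  structure(list(m = m, conc = stats::setNames(conc, model$chem_names),
                 survivors = survivors, residual = residual,
                 converged = converged, t = t,
                 model = model, setup = setup, strategies = strategies),
            class = "chemostat_steady_state")
}

## Damped Newton refinement of a converged state: unknowns are survivor
## biomasses and all concentrations; equations are g - d per survivor and
## the nutrient mass balance per chemical. Falls back to the integrated
## state when the polish does not reduce the residual.
polish_steady_state <- function(setup, model, strategies, m, conc, extinction) {
  surv <- which(m > extinction)
  resid_fun <- function(z) {
    mm <- m; mm[surv] <- z[seq_along(surv)]
    cc <- pmax(z[length(surv) + seq_along(conc)], 0)
    rates <- community_rates(model, cc, strategies)
    cons <- if (length(strategies))
      as.numeric(crossprod(pmax(mm, 0), rates$I)) / setup$r else 0
    c(rates$g[surv] - setup$d, setup$d * (setup$c_supply - cc) - cons)
  }
  z <- c(m[surv], conc)
  best <- z; best_norm <- max(abs(resid_fun(z)))
  for (it in 1:20) {
    r <- resid_fun(z)
    if (max(abs(r)) < 1e-12) break
    n <- length(z)
    J <- matrix(0, length(r), n)
    for (j in seq_len(n)) {
      h <- max(1e-7, 1e-7 * abs(z[j]))
      zp <- z; zp[j] <- zp[j] + h
      J[, j] <- (resid_fun(zp) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:6) {
      zn <- z + lambda * step
      if (all(zn[seq_along(surv)] >= 0) && all(is.finite(zn))) {
        rn <- max(abs(resid_fun(zn)))
        if (rn < max(abs(r))) {
          z <- zn
          if (rn < best_norm) { best <- zn; best_norm <- rn }
          improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  m[surv] <- best[seq_along(surv)]
  conc <- pmax(best[length(surv) + seq_along(conc)], 0)
  list(m = m, conc = conc)
}

#' @export
print.chemostat_steady_state <- function(x, ...) {
  cat("<chemostat_steady_state> ", if (x$converged) "converged" else
    "NOT converged (possible limit cycle)", "\n", sep = "")
  cat("  survivors: ", if (length(x$survivors))
    paste(x$survivors, collapse = ", ") else "none (washout)", "\n", sep = "")
  cat("  environment: ", paste(signif(x$conc, 5), collapse = ", "),
      "\n  residual (max |dy/dt|): ", signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

## RHS for k_tot linked chemostats: every vessel runs the local chemostat
## dynamics, and both biomass and chemicals hop between nearest neighbours
## at rate l (discrete Laplacian, no-flux boundaries).
chain_rhs <- function(t, y, parms) {
  k <- parms$k; nv <- parms$n_s + parms$n_c
  Y <- matrix(y, nrow = nv, ncol = k)
  dY <- matrix(0, nv, k)
  for (j in seq_len(k))
    dY[, j] <- chemostat_rhs(t, Y[, j], parms)[[1L]]
  if (parms$l > 0 && k > 1L) {
    lap <- Y[, c(1L, seq_len(k - 1L)), drop = FALSE] +
      Y[, c(2:k, k), drop = FALSE] - 2 * Y
    ## no-flux ends: the duplicated boundary column cancels one neighbour term
    dY <- dY + parms$l * lap
  }
  list(as.numeric(dY))
}

#' Simulate a chain of linked chemostats
#'
#' @param chain A [chain_setup()].
#' @param model A `metabolic_model`.
#' @param strategies List of allocation vectors (shared across vessels).
#' @param state0 List of [community_state()] objects, one per vessel.
#' @param t_end End time.
#' @param n_out Number of output time points.
#' @inheritParams simulate_chemostat
#' @return Object of class `chain_trajectory`: `times`, `m` (array time x
#'   species x vessel), `conc` (array time x chemical x vessel).
#' @export
simulate_chain <- function(chain, model, strategies, state0, t_end,
                           n_out = 101L, rtol = 1e-8, atol = 1e-10,
                           extinction = 1e-9) {
  stopifnot(inherits(chain, "chain_setup"))
  strategies <- lapply(strategies, function(s) check_strategy(model, s))
  k <- chain$k_tot
  if (length(state0) != k) stop("state0 must hold one community_state per vessel")
  n_s <- length(strategies); n_c <- model$n_chemicals
  parms <- list(model = model, setup = chain$setup, strategies = strategies,
                n_s = n_s, n_c = n_c, k = k, l = chain$l)
  y0 <- as.numeric(vapply(state0, function(st) c(st$m, st$conc),
                          numeric(n_s + n_c)))
  times <- seq(0, t_end, length.out = max(2L, n_out))
  sol <- deSolve::ode(y = y0, times = times, func = chain_rhs, parms = parms,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e5)
  if (attr(sol, "istate")[1L] < 0) stop("integrator failure in simulate_chain")
  arr <- array(sol[, -1L], dim = c(length(times), n_s + n_c, k))
  m <- arr[, seq_len(n_s), , drop = FALSE]
  conc <- pmax(arr[, n_s + seq_len(n_c), , drop = FALSE], 0)
  structure(list(times = times, m = m, conc = conc, model = model,
                 chain = chain, strategies = strategies),
            class = "chain_trajectory")
}
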