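## ---------------------------------------------------------------------------
## Evolutionary procedures: the rule of invasion, environment-dependent
## fitness landscapes, chains of invasion (replacement dynamics towards a
## non-invasible strategy), greedy opportunist assembly, and pairwise
## invasion graphs.
## ---------------------------------------------------------------------------

## Strictness margin on g - d: a resident at its own steady state has g = d
## exactly and must not count as invading itself.
INVASION_MARGIN <- 1e-9

#' Invasion growth rate and the rule of invasion
#'
#' `invasion_rate()` is the instantaneous growth rate of an invader strategy
#' in a fixed chemical environment (normally the steady-state environment
#' created by the resident community). `invasion_test()` applies the rule of
#' invasion: the invasion succeeds iff the resident's environment lies in
#' the invader's invasion zone, i.e. `g(c_ss, alpha_inv) > d`.
#'
#' @param model A `metabolic_model`.
#' @param invader Strategy vector of the invader.
#' @param environment Chemical environment vector, or a
#'   `chemostat_steady_state` (its environment is used; a non-converged one
#'   triggers a warning, since the rule is only valid at a resident steady
#'   state).
#' @return `invasion_rate()`: scalar growth rate. `invasion_test()`: logical.
#' @export
invasion_rate <- function(model, invader, environment) {
  if (inherits(environment, "chemostat_steady_state")) {
    if (!environment$converged)
      warning("environment is not a converged steady state; ",
              "the rule of invasion may not predict the dynamical outcome")
    environment <- environment$conc
  }
  growth_rate(model, environment, invader)
}

#' @rdname invasion_rate
#' @param d Dilution rate against which the invader must grow.
#' @export
invasion_test <- function(model, invader, environment, d) {
  invasion_rate(model, invader, environment) > d + INVASION_MARGIN
}

#' Environment-dependent fitness landscape
#'
#' Evaluates the invasion growth rate of every strategy on a grid at a fixed
#' chemical environment. The landscape deforms as the community changes the
#' environment; its argmax is the maximizing strategy and a flat landscape
#' (`flatness` ~ 0) marks effectively neutral coexistence.
#'
#' @param model A `metabolic_model`.
#' @param environment Environment vector or `chemostat_steady_state`.
#' @param strategy_grid List of strategy vectors, or a numeric vector of
#'   `alpha_1` values for two-function models (expanded to `(a, 1 - a)`).
#' @param d Reference dilution rate (stored; used for `g - d` summaries).
#' @return Object of class `fitness_landscape`: `strategies` (matrix),
#'   `rates`, `d`, `environment`, plus `argmax`, `flatness` (max - min) and,
#'   for 1-parameter sweeps, `slope_sign`.
#' @export
fitness_landscape <- function(model, environment, strategy_grid, d) {
  if (inherits(environment, "chemostat_steady_state"))
    environment <- environment$conc
  environment <- check_environment(model, environment)
  if (is.numeric(strategy_grid) && is.null(dim(strategy_grid))) {
    if (model$n_functions != 2L)
      stop("a numeric sweep is only supported for two-function models")
    strategy_grid <- lapply(strategy_grid, function(a) c(a, 1 - a))
  }
  S <- do.call(rbind, lapply(strategy_grid, function(s)
    check_strategy(model, s)))
  colnames(S) <- model$fn_names
  rates <- apply(S, 1L, function(s) eval_model(model, environment, s)$g)
  slope_sign <- if (model$n_functions == 2L && nrow(S) > 1L) {
    fit <- stats::coef(stats::lm(rates ~ S[, 1L]))[2L]
    sign(fit)
  } else NA_real_
  structure(list(strategies = S, rates = rates, d = d,
                 environment = environment,
                 argmax = S[which.max(rates), ],
                 flatness = max(rates) - min(rates),
                 slope_sign = unname(slope_sign), model = model),
            class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("<fitness_landscape> ", nrow(x$strategies), " strategies at c = (",
      paste(signif(x$environment, 4), collapse = ", "), ")\n", sep = "")
  cat("  g in [", signif(min(x$rates), 6), ", ", signif(max(x$rates), 6),
      "], flatness = ", signif(x$flatness, 3), "\n", sep = "")
  invisible(x)
}

## Single-resident steady state used by the evolutionary procedures; errors
## on washout or non-convergence with context.
resident_steady_state <- function(model, setup, s, label = "resident", ...) {
  ss <- steady_state(setup, model, list(s), ...)
  if (!ss$converged)
    stop("no steady state for the ", label,
         " (non-convergent dynamics, possibly a limit cycle)")
  if (!length(ss$survivors))
    stop(label, " washes out under this setup (g(c_supply) <= d)")
  ss
}

#' Chain of invasion towards a non-invasible strategy
#'
#' Iterated replacement by the best response: starting from `alpha0`, find
#' the resident's single-species steady-state environment, replace the
#' resident by the maximizing strategy of that environment, and repeat. The
#' fixed point — a strategy that places itself on top of the fitness
#' landscape it creates — is the non-invasible (evolutionarily stable)
#' strategy.
#'
#' @param model A `metabolic_model`.
#' @param setup A [chemostat_setup()].
#' @param alpha0 Starting strategy (must be viable: not washed out).
#' @param max_steps Iteration cap (default 100).
#' @param tol Convergence tolerance on `max |alpha - alpha_max(c_ss(alpha))|`
#'   (default 1e-6).
#' @return Object of class `invasion_chain`: `strategies` (matrix, row per
#'   resident in order), `environments` (matrix of steady-state
#'   environments), `g_max` (per step), `converged`, `ess` (final strategy if
#'   converged).
#' @export
chain_of_invasion <- function(model, setup, alpha0, max_steps = 100L,
                              tol = 1e-6) {
  s <- check_strategy(model, alpha0)
  strategies <- list(); environments <- list(); gmaxes <- numeric()
  converged <- FALSE
  for (step in seq_len(max_steps)) {
    ss <- resident_steady_state(model, setup, s,
                                label = sprintf("chain resident (step %d)", step))
    ms <- maximizing_strategy(model, ss$conc)
    strategies[[step]] <- s
    environments[[step]] <- ss$conc
    gmaxes[step] <- ms$g_max
    if (max(abs(ms$strategy - s)) < tol) { converged <- TRUE; break }
    s <- strategy(ms$strategy / sum(ms$strategy))
  }
  S <- do.call(rbind, strategies); colnames(S) <- model$fn_names
  E <- do.call(rbind, environments); colnames(E) <- model$chem_names
  structure(list(strategies = S, environments = E, g_max = gmaxes,
                 converged = converged,
                 ess = if (converged) S[nrow(S), ] else NULL,
                 model = model, setup = setup),
            class = "invasion_chain")
}

#' @export
print.invasion_chain <- function(x, ...) {
  cat("<invasion_chain> ", nrow(x$strategies), " residents, ",
      if (x$converged) "converged to a non-invasible strategy" else
        "not converged", "\n", sep = "")
  if (x$converged)
    cat("  ESS: (", paste(signif(x$ess, 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Greedy opportunist community assembly
#'
#' Repeatedly equilibrates the community, finds the opportunist (the
#' maximizing strategy of the current steady-state environment), and adds it
#' at infinitesimal biomass whenever it grows faster than dilution;
#' terminates when no strategy beats dilution, i.e. when the community's
#' environment has reached the maximal growth contour and the fitness
#' landscape is flat at the top. Residents driven extinct along the way are
#' pruned and logged.
#'
#' @param model A `metabolic_model`.
#' @param setup A [chemostat_setup()].
#' @param alpha_init Initial resident strategy.
#' @param max_additions Cap on opportunist additions (default 30).
#' @param margin Termination margin on `g_max - d` (default 1e-6).
#' @param invader_biomass Introduction biomass (default 1e-6).
#' @param ... Passed to [steady_state()].
#' @return Object of class `assembly_record`: `consortium` (list of
#'   surviving strategies), `additions` (data.frame: step, gap `g_max - d` at
#'   addition, strategy components), `survivor_history` (list), final
#'   `steady_state` and `flatness_gap` (`g_max - d` at termination).
#' @export
greedy_assembly <- function(model, setup, alpha_init, max_additions = 30L,
                            margin = 1e-6, invader_biomass = 1e-6, ...) {
  strategies <- list(check_strategy(model, alpha_init))
  m <- 0.01
  state <- community_state(m, setup$c_supply)
  additions <- list(); survivor_history <- list()
  ss <- NULL
  for (step in 0:max_additions) {
    ss <- steady_state(setup, model, strategies, state, ...)
    if (!ss$converged)
      stop("assembly aborted: community failed to reach a steady state")
    if (step == 0L && !length(ss$survivors))
      stop("alpha_init washes out under this setup")
    ## prune extinct residents
    if (length(ss$survivors) < length(strategies)) {
      strategies <- strategies[ss$survivors]
      ss$m <- ss$m[ss$survivors]
    }
    survivor_history[[step + 1L]] <- strategies
    ms <- maximizing_strategy(model, ss$conc)
    gap <- ms$g_max - setup$d
    if (gap <= margin || step == max_additions) break
    additions[[length(additions) + 1L]] <-
      data.frame(step = step + 1L, gap = gap,
                 t(stats::setNames(as.numeric(ms$strategy), model$fn_names)))
    strategies <- c(strategies, list(strategy(ms$strategy / sum(ms$strategy))))
    state <- community_state(c(ss$m[seq_len(length(strategies) - 1L)],
                               invader_biomass), ss$conc)
  }
  structure(list(consortium = strategies,
                 additions = if (length(additions)) do.call(rbind, additions)
                   else data.frame(step = integer(), gap = numeric()),
                 survivor_history = survivor_history,
                 steady_state = ss,
                 flatness_gap = maximizing_strategy(model, ss$conc)$g_max -
                   setup$d,
                 model = model, setup = setup),
            class = "assembly_record")
}

#' @export
print.assembly_record <- function(x, ...) {
  cat("<assembly_record> ", nrow(x$additions), " opportunists added, ",
      length(x$consortium), " final species\n", sep = "")
  cat("  final g_max - d: ", signif(x$flatness_gap, 3), "\n", sep = "")
  invisible(x)
}

#' Pairwise invasion graph
#'
#' Computes every strategy's single-resident steady state and applies the
#' rule of invasion to all ordered pairs. An edge i -> j means strategy j
#' invades the environment created by strategy i. Pair motifs are classified
#' as `mutual` (coexistence candidates), `bistable` (neither invades),
#' or `one_way`; directed 3-cycles among one-way pairs are reported as
#' rock-paper-scissors candidates.
#'
#' @param model A `metabolic_model`.
#' @param setup A [chemostat_setup()].
#' @param strategies List of strategy vectors (each viable alone).
#' @param ... Passed to [steady_state()].
#' @return Object of class `invasion_graph`: `edges` (logical matrix;
#'   `edges[i, j]` = j invades i), `rates` (invasion growth rates),
#'   `environments`, `pairs` (data.frame with motif class per unordered
#'   pair), `cycles` (list of directed 3-cycles).
#' @export
invasion_graph <- function(model, setup, strategies, ...) {
  strategies <- lapply(strategies, function(s) check_strategy(model, s))
  n <- length(strategies)
  envs <- matrix(NA_real_, n, model$n_chemicals,
                 dimnames = list(NULL, model$chem_names))
  for (i in seq_len(n)) {
    ss <- resident_steady_state(model, setup, strategies[[i]],
                                label = sprintf("strategy %d", i), ...)
    envs[i, ] <- ss$conc
  }
  rates <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    rates[i, j] <- growth_rate(model, envs[i, ], strategies[[j]])
  edges <- rates > setup$d + INVASION_MARGIN
  diag(edges) <- FALSE
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cls <- if (edges[i, j] && edges[j, i]) "mutual"
    else if (!edges[i, j] && !edges[j, i]) "bistable"
    else "one_way"
    pairs[[length(pairs) + 1L]] <- data.frame(i = i, j = j, class = cls)
  }
  cycles <- list()
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
      trip <- c(i, j, k)
      fwd <- edges[i, j] && edges[j, k] && edges[k, i] &&
        !edges[j, i] && !edges[k, j] && !edges[i, k]
      rev <- edges[j, i] && edges[k, j] && edges[i, k] &&
        !edges[i, j] && !edges[j, k] && !edges[k, i]
      if (fwd || rev) cycles[[length(cycles) + 1L]] <- trip
    }
  }
  structure(list(edges = edges, rates = rates, environments = envs,
                 pairs = if (length(pairs)) do.call(rbind, pairs) else
                   data.frame(i = integer(), j = integer(), class = character()),
                 cycles = cycles, strategies = strategies,
                 model = model, setup = setup),
            class = "invasion_graph")
}

#' @export
print.invasion_graph <- function(x, ...) {
  n <- length(x$strategies)
  cat("<invasion_graph> ", n, " strategies, ", sum(x$edges), " invasion edges\n",
      sep = "")
  if (nrow(x$pairs)) print(table(x$pairs$class))
  if (length(x$cycles))
    cat("  directed 3-cycles: ",
        paste(vapply(x$cycles, paste, character(1), collapse = "->"),
              collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Verify an invasion prediction dynamically
#'
#' Introduces the invader at small biomass into the resident community's
#' steady state and integrates for a short horizon; returns whether the
#' invader's biomass increased, for spot-checking the geometric rule of
#' invasion against the ODE dynamics.
#'
#' @param model A `metabolic_model`.
#' @param setup A [chemostat_setup()].
#' @param residents List of resident strategies (at their joint steady state).
#' @param invader Invader strategy.
#' @param horizon Integration time after introduction (default 1).
#' @param invader_biomass Introduction biomass (default 1e-6).
#' @return List with `grew` (logical), `ratio` (final/initial invader
#'   biomass), `predicted` (rule-of-invasion test result).
#' @export
verify_invasion <- function(model, setup, residents, invader, horizon = 1,
                            invader_biomass = 1e-6) {
  ss <- steady_state(setup, model, residents)
  if (!ss$converged) stop("resident community has no steady state")
  predicted <- invasion_test(model, invader, ss$conc, setup$d)
  st <- community_state(c(ss$m, invader_biomass), ss$conc)
  tr <- simulate_chemostat(setup, model, c(residents, list(invader)), st,
                           t_end = horizon, n_out = 2L,
                           extinction = 0)  # keep the tiny inoculum alive
  final <- unname(tr$m[nrow(tr$m), length(residents) + 1L])
  list(grew = final > invader_biomass, ratio = final / invader_biomass,
       predicted = predicted)
}
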