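## ---------------------------------------------------------------------------
## Scenario configuration, fixture library, result writers.
## A Scenario is a plain named list that fully determines a run; it
## round-trips losslessly through YAML.
## ---------------------------------------------------------------------------

PROCEDURES <- c("simulate", "steady_state", "contour", "landscape", "invade",
                "chain", "assemble", "graph", "spatial")

#' Construct and validate a scenario
#'
#' A scenario bundles everything needed to reproduce a run: the model and
#' its kinetic parameters, the chemostat external conditions, the strategy
#' set, the initial state, the procedure to run with its options, and a
#' seed. All quantities are dimensionless model units.
#'
#' @param name Scenario name (used for output labelling).
#' @param model Model name (see [model_names()]).
#' @param params Named list of kinetic parameter overrides.
#' @param d Dilution rate.
#' @param c_supply Supply concentration vector.
#' @param r Biomass per cell volume (default 1).
#' @param strategies List of allocation vectors.
#' @param m0 Initial biomasses (default 0.01 each).
#' @param c0 Initial environment (default `c_supply`).
#' @param procedure One of `r paste(PROCEDURES, collapse=", ")`.
#' @param options Named list of procedure-specific options (e.g. `t_end`,
#'   `window`, `resolution`, `k_tot`, `l`, `alpha0`, `invader`).
#' @param seed Integer seed for any randomized choices (default 1).
#' @return Object of class `scenario`.
#' @export
scenario <- function(name, model, params = list(), d, c_supply, r = 1,
                     strategies = list(), m0 = NULL, c0 = NULL,
                     procedure = "simulate", options = list(), seed = 1L) {
  if (!procedure %in% PROCEDURES)
    stop("unknown procedure '", procedure, "'; must be one of: ",
         paste(PROCEDURES, collapse = ", "))
  mod <- make_model(model, params)  # validates model + params
  setup <- chemostat_setup(d, c_supply, r)  # validates conditions
  strategies <- lapply(strategies, function(s) check_strategy(mod, s))
  if (is.null(m0)) m0 <- rep(0.01, length(strategies))
  if (is.null(c0)) c0 <- c_supply
  if (length(m0) != length(strategies))
    stop("m0 must have one biomass per strategy")
  structure(list(name = name, model = model, params = params,
                 d = d, c_supply = c_supply, r = r,
                 strategies = strategies, m0 = m0, c0 = c0,
                 procedure = procedure, options = options,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, ": ", x$procedure, " | model ", x$model,
      " | d = ", x$d, " | ", length(x$strategies), " strategies\n", sep = "")
  invisible(x)
}

#' Read / write scenarios as YAML
#'
#' Scenario files are human-editable structured text; all quantities are
#' dimensionless model units (rates in 1/time, concentrations in units of
#' the Monod constants).
#'
#' @param path File path.
#' @return `read_scenario()`: a `scenario`. `write_scenario()`: `path`,
#'   invisibly.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  required <- c("name", "model", "d", "c_supply", "procedure")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("scenario file is missing required key(s): ",
         paste(missing, collapse = ", "))
  scenario(name = raw$name, model = raw$model,
           params = if (is.null(raw$params)) list() else raw$params,
           d = raw$d, c_supply = as.numeric(raw$c_supply),
           r = if (is.null(raw$r)) 1 else raw$r,
           strategies = lapply(raw$strategies, as.numeric),
           m0 = if (is.null(raw$m0)) NULL else as.numeric(raw$m0),
           c0 = if (is.null(raw$c0)) NULL else as.numeric(raw$c0),
           procedure = raw$procedure,
           options = if (is.null(raw$options)) list() else raw$options,
           seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' @rdname read_scenario
#' @param sc A `scenario`.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  out <- unclass(sc)
  out$strategies <- lapply(out$strategies, as.numeric)
  yaml::write_yaml(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Fixture library: named scenarios mirroring the figure setups of the
## bundled models (default parameterizations).
## ---------------------------------------------------------------------------

## Strategies of the rock-paper-scissors trio: species i grows on nutrient i
## (import 0.275 + assimilation 0.275) and wastefully imports nutrient i+1
## (0.45, no assimilation capacity), which is what fuels the cyclic invasion.
rps_strategy <- function(i, own_import = 0.275, own_assim = 0.275) {
  a <- numeric(6L)
  a[i] <- own_import
  a[3L + i] <- own_assim
  a[(i %% 3L) + 1L] <- 1 - own_import - own_assim
  a
}

.fixtures <- function() list(
  ## Successful vs failed invasion of an essential-nutrient resident,
  ## decided purely by the supply condition.
  fig1_invasion = scenario(
    "fig1_invasion", "essential", d = 0.25, c_supply = c(4, 40),
    strategies = list(c(0.35, 0.65), c(0.65, 0.35)),
    procedure = "invade",
    options = list(resident = 1L, invader = 2L,
                   alt_c_supply = c(10, 10))),
  ## Mutual invasion and coexistence of two substitutable-nutrient
  ## specialists; the joint environment flattens the fitness landscape.
  fig2_coexist = scenario(
    "fig2_coexist", "substitutable", d = 0.5, c_supply = c(4, 4),
    strategies = list(c(0.6, 0.4), c(0.2, 0.8)),
    procedure = "steady_state",
    options = list(landscape_sweep = TRUE)),
  ## Greedy opportunist assembly over 10 substitutable nutrients starting
  ## from a random interior strategy.
  fig2_assembly10 = scenario(
    "fig2_assembly10", "substitutable", params = list(p = 10L),
    d = 0.5, c_supply = rep(5, 10), procedure = "assemble",
    options = list(random_init = TRUE), seed = 1L),
  ## Bistable pair of essential-nutrient specialists under symmetric supply.
  fig3_bistable = scenario(
    "fig3_bistable", "essential", d = 0.25, c_supply = c(10, 10),
    strategies = list(c(0.65, 0.35), c(0.35, 0.65)),
    procedure = "graph"),
  ## Chain of invasion from alpha_a = 0.35 towards the non-invasible 0.5.
  fig3_chain = scenario(
    "fig3_chain", "essential", d = 0.25, c_supply = c(10, 10),
    strategies = list(c(0.35, 0.65)),
    procedure = "chain"),
  ## Interconversion model: maximal growth contour at d = 0.2 whose
  ## discontinuities host two-species non-invasible cartels.
  fig4_cartel = scenario(
    "fig4_cartel", "interconvert", d = 0.2, c_supply = c(0.6, 0.05),
    procedure = "contour",
    options = list(type = "maximal", window = c(1e-3, 1, 1e-3, 1),
                   resolution = 41L)),
  ## Secretion model at low dilution: polluter-cleaner coexistence.
  fig5_lowD = scenario(
    "fig5_lowD", "secretion", d = 0.4, c_supply = c(8, 0),
    procedure = "contour",
    options = list(type = "maximal", window = c(1e-3, 10, 1e-3, 10),
                   resolution = 41L)),
  ## Secretion model at high dilution.
  fig5_highD = scenario(
    "fig5_highD", "secretion", d = 0.6, c_supply = c(8, 0),
    procedure = "contour",
    options = list(type = "maximal", window = c(1e-3, 10, 1e-3, 10),
                   resolution = 41L)),
  ## Rock-paper-scissors trio on three substitutable nutrients with a
  ## serial import/assimilation bottleneck: sustained oscillations.
  s4_rps = scenario(
    "s4_rps", "substitutable_assim", d = 0.2, c_supply = rep(10, 3),
    strategies = lapply(1:3, rps_strategy),
    m0 = c(0.02, 0.01, 0.015),
    procedure = "simulate", options = list(t_end = 6000, n_out = 3001)),
  ## 20 linked chemostats at leakage 1 seeded with the bistable pair at
  ## opposite ends: spontaneous spatial gradient. Uptake here is fast
  ## (v = 10, d = 2.5) so that local competitive exclusion outpaces the
  ## fixed leakage rate; at slower kinetic scales leakage homogenizes the
  ## chain and the gradient is only transient.
  s6_chain = scenario(
    "s6_chain", "essential", params = list(v = 10),
    d = 2.5, c_supply = c(10, 10),
    strategies = list(c(0.35, 0.65), c(0.65, 0.35)),
    procedure = "spatial",
    options = list(k_tot = 20L, l = 1, t_end = 400,
                   seed_vessels = c(1L, 20L)))
)

#' Bundled scenario fixtures
#'
#' `fixture(name)` returns a fully resolved scenario from the bundled
#' library; `fixture_names()` lists them.
#'
#' @param name Fixture name.
#' @return A `scenario`.
#' @export
fixture <- function(name) {
  fx <- .fixtures()
  if (!name %in% names(fx))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fx), collapse = ", "))
  fx[[name]]
}

#' @rdname fixture
#' @export
fixture_names <- function() names(.fixtures())

## ---------------------------------------------------------------------------
## Scenario runner and writers
## ---------------------------------------------------------------------------

write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

#' Run a scenario and write its result bundle
#'
#' Dispatches on the scenario's procedure, writes tidy CSV tables and a JSON
#' summary to `out_dir` together with a manifest (resolved configuration,
#' package version, seed), and returns the computed objects invisibly.
#' Identical (scenario, seed) pairs produce identical outputs.
#'
#' @param sc A `scenario` (or fixture name).
#' @param out_dir Output directory (created if missing); NULL skips writing.
#' @return Invisibly, a list with the computed result (`result`), a summary
#'   list (`summary`), and the output paths (`files`).
#' @export
run_scenario <- function(sc, out_dir = NULL) {
  if (is.character(sc)) sc <- fixture(sc)
  stopifnot(inherits(sc, "scenario"))
  set.seed(sc$seed)
  model <- make_model(sc$model, sc$params)
  setup <- chemostat_setup(sc$d, sc$c_supply, sc$r)
  opt <- sc$options
  state0 <- if (length(sc$strategies))
    community_state(sc$m0, sc$c0) else community_state(numeric(), sc$c0)
  files <- character(); tables <- list()
  res <- NULL
  summary <- list(scenario = sc$name, procedure = sc$procedure)

  if (sc$procedure == "simulate") {
    res <- simulate_chemostat(setup, model, sc$strategies, state0,
                              t_end = opt$t_end %||% 100,
                              n_out = opt$n_out %||% 201L)
    tables$trajectory <- as.data.frame(res)
    summary$final_biomass <- as.numeric(res$m[nrow(res$m), ])
    summary$final_environment <- as.numeric(res$conc[nrow(res$conc), ])
    summary$extinctions <- nrow(res$events)
  } else if (sc$procedure == "steady_state") {
    res <- steady_state(setup, model, sc$strategies, state0)
    summary$converged <- res$converged
    summary$survivors <- res$survivors
    summary$environment <- as.numeric(res$conc)
    summary$biomass <- as.numeric(res$m)
    summary$residual <- res$residual
    if (isTRUE(opt$landscape_sweep) && model$n_functions == 2L) {
      fl <- fitness_landscape(model, res, seq(0, 1, 0.02), setup$d)
      tables$landscape <- data.frame(alpha1 = fl$strategies[, 1L],
                                     rate = fl$rates)
      summary$landscape_flatness <- fl$flatness
    }
  } else if (sc$procedure == "contour") {
    window <- matrix(as.numeric(opt$window %||% c(1e-3, 10, 1e-3, 10)),
                     2L, 2L, byrow = TRUE)
    if ((opt$type %||% "growth") == "maximal") {
      res <- maximal_growth_contour(model, sc$d, window,
                                    resolution = opt$resolution %||% 41L)
      tables$contour <- data.frame(index = seq_len(nrow(res$points)),
                                   c1 = res$points[, 1L], c2 = res$points[, 2L],
                                   residual = res$residuals,
                                   class = res$class_labels,
                                   discontinuity = seq_len(nrow(res$points)) %in%
                                     res$discontinuities$index)
      summary$classes <- unique(res$class_labels)
      summary$n_discontinuities <- nrow(res$discontinuities)
    } else {
      res <- growth_contour(model, sc$strategies[[1L]], sc$d, window,
                            resolution = opt$resolution %||% 101L)
      tables$contour <- data.frame(index = seq_len(nrow(res$points)),
                                   c1 = res$points[, 1L], c2 = res$points[, 2L],
                                   residual = res$residuals)
      summary$n_points <- nrow(res$points)
    }
  } else if (sc$procedure == "landscape") {
    env <- as.numeric(opt$environment %||% sc$c_supply)
    sweep <- if (model$n_functions == 2L) seq(0, 1, 0.02) else
      lapply(seq_len(opt$n_probes %||% 200L), function(i) random_simplex(model$n_functions))
    res <- fitness_landscape(model, env, sweep, setup$d)
    tables$landscape <- data.frame(res$strategies, rate = res$rates)
    summary$flatness <- res$flatness
    summary$argmax <- as.numeric(res$argmax)
  } else if (sc$procedure == "invade") {
    resident <- sc$strategies[[opt$resident %||% 1L]]
    invader <- sc$strategies[[opt$invader %||% 2L]]
    ss <- steady_state(setup, model, list(resident))
    ok <- invasion_test(model, invader, ss, setup$d)
    summary$invasion <- ok
    summary$invasion_rate <- invasion_rate(model, invader, ss)
    summary$resident_environment <- as.numeric(ss$conc)
    if (!is.null(opt$alt_c_supply)) {
      setup2 <- chemostat_setup(sc$d, as.numeric(opt$alt_c_supply), sc$r)
      ss2 <- steady_state(setup2, model, list(resident))
      summary$alt_invasion <- invasion_test(model, invader, ss2, setup2$d)
      summary$alt_invasion_rate <- invasion_rate(model, invader, ss2)
    }
  } else if (sc$procedure == "chain") {
    res <- chain_of_invasion(model, setup, sc$strategies[[1L]],
                             max_steps = opt$max_steps %||% 100L)
    tables$chain <- data.frame(step = seq_len(nrow(res$strategies)),
                               res$strategies, res$environments,
                               g_max = res$g_max)
    summary$converged <- res$converged
    summary$steps <- nrow(res$strategies)
    if (res$converged) summary$ess <- as.numeric(res$ess)
  } else if (sc$procedure == "assemble") {
    init <- if (isTRUE(opt$random_init))
      random_simplex(model$n_functions) else sc$strategies[[1L]]
    res <- greedy_assembly(model, setup, init,
                           max_additions = opt$max_additions %||% 30L)
    tables$assembly_log <- res$additions
    summary$n_additions <- nrow(res$additions)
    summary$n_final_species <- length(res$consortium)
    summary$flatness_gap <- res$flatness_gap
  } else if (sc$procedure == "graph") {
    res <- invasion_graph(model, setup, sc$strategies)
    el <- which(res$edges, arr.ind = TRUE)
    tables$invasion_edges <- data.frame(
      resident = el[, 1L], invader = el[, 2L],
      rate = res$rates[el])
    summary$motifs <- as.list(table(res$pairs$class))
    summary$n_cycles <- length(res$cycles)
  } else if (sc$procedure == "spatial") {
    k_tot <- opt$k_tot %||% 2L
    ch <- chain_setup(k_tot, opt$l %||% 0, setup)
    seeds <- opt$seed_vessels %||% seq_len(min(k_tot, length(sc$strategies)))
    state0 <- lapply(seq_len(k_tot), function(k) {
      m <- numeric(length(sc$strategies))
      hit <- which(seeds == k)
      if (length(hit)) m[hit] <- sc$m0[hit]
      community_state(m, sc$c0)
    })
    res <- simulate_chain(ch, model, sc$strategies, state0,
                          t_end = opt$t_end %||% 100,
                          n_out = opt$n_out %||% 51L)
    n <- length(res$times)
    prof <- do.call(rbind, lapply(seq_len(k_tot), function(k)
      data.frame(vessel = k,
                 t(stats::setNames(res$m[n, , k],
                                   paste0("m", seq_along(sc$strategies)))),
                 t(stats::setNames(res$conc[n, , k], model$chem_names)))))
    tables$profile <- prof
    summary$final_profile <- prof
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], p, row.names = FALSE)
      files <- c(files, p)
    }
    sp <- file.path(out_dir, "summary.json")
    write_json(summary, sp); files <- c(files, sp)
    manifest <- list(scenario = unclass(sc),
                     package = as.character(utils::packageVersion("chemoscape")),
                     seed = sc$seed)
    manifest$scenario$strategies <- lapply(sc$strategies, as.numeric)
    mp <- file.path(out_dir, "run_manifest.json")
    write_json(manifest, mp); files <- c(files, mp)
  }
  invisible(list(result = res, summary = summary, tables = tables,
                 files = files))
}

#' Uniform random point on the allocation simplex
#'
#' Stick-breaking (normalized exponentials) draw, uniform on the simplex;
#' used for random initial strategies and probe strategies.
#'
#' @param n Number of components.
#' @return Numeric vector summing to 1.
#' @export
random_simplex <- function(n) {
  e <- stats::rexp(n)
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
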