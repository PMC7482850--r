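## Shared fixtures for the test suite: symmetric default models and the
## reference external conditions used across tests.

sym_essential <- function() make_model("essential")
sym_substitutable <- function(p = 2L) make_model("substitutable", list(p = p))

ess_setup <- function() chemostat_setup(d = 0.25, c_supply = c(10, 10))
sub_setup <- function() chemostat_setup(d = 0.5, c_supply = c(4, 4))

## Red/Blue pairs of the two-nutrient stories
ess_red <- c(0.65, 0.35); ess_blue <- c(0.35, 0.65)
sub_red <- c(0.6, 0.4);   sub_blue <- c(0.2, 0.8)

## draw a uniform simplex point deterministically
rsimplex <- function(n) {
  e <- stats::rexp(n)
  e / sum(e)
}

## brute-force simplex maximum of g(c, .) on a barycentric grid with
## `steps` subdivisions per unit; the independent oracle for
## maximizing_strategy()
brute_force_gmax <- function(model, conc, steps) {
  n <- model$n_functions
  if (n == 2L) {
    a <- seq(0, 1, length.out = steps + 1L)
    return(max(vapply(a, function(ai)
      growth_rate(model, conc, c(ai, 1 - ai)), numeric(1))))
  }
  ## enumerate integer compositions of `steps` into n parts
  compositions <- function(total, parts) {
    if (parts == 1L) return(matrix(total, 1L, 1L))
    out <- list()
    for (k in 0:total) {
      rest <- compositions(total - k, parts - 1L)
      out[[k + 1L]] <- cbind(k, rest)
    }
    do.call(rbind, out)
  }
  comp <- compositions(steps, n) / steps
  if (model$name %in% c("substitutable", "essential", "substitutable_assim")) {
    rates <- community_rates(model, conc, asplit(comp, 1L))
    return(max(rates$g))
  }
  max(apply(comp, 1L, function(a) eval_model(model, conc, a)$g))
}
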