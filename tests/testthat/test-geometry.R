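win2 <- function(lo, hi) rbind(c(lo, hi), c(lo, hi))

test_that("growth contours sit on the level set and respect model geometry", {
  ess <- sym_essential()
  gc <- growth_contour(ess, c(0.5, 0.5), d = 0.25, win2(0.05, 10),
                       resolution = 61L)
  expect_gt(nrow(gc$points), 10L)
  expect_lt(max(gc$residuals), 1e-6)
  ## L-shape: the corner of the min-rule contour lies on the diagonal; every
  ## point has both coordinates >= the corner concentration 0.5*c/(1+c)=0.25
  corner <- 0.25 / (0.5 - 0.25)  # c with 0.5 * c/(1+c) = 0.25
  expect_true(all(gc$points >= corner - 1e-3))
  expect_lt(min(abs(gc$points[, 1L] - corner)), 0.05)
  expect_lt(min(abs(gc$points[, 2L] - corner)), 0.05)
  ## substitutable contours of any two strategies share the common point
  ## where both Monod terms equal d
  sub <- sym_substitutable()
  cstar <- 0.5 / (1 - 0.5)
  for (s in list(c(0.6, 0.4), c(0.2, 0.8), c(0.95, 0.05)))
    expect_equal(growth_rate(sub, c(cstar, cstar), s), 0.5, tolerance = 1e-12)
  g1 <- growth_contour(sub, c(0.6, 0.4), 0.5, win2(0.05, 10), resolution = 81L)
  expect_lt(min(sqrt((g1$points[, 1L] - cstar)^2 + (g1$points[, 2L] - cstar)^2)),
            0.1)
  ## unattainable level: empty contour, not an error
  g_empty <- growth_contour(sub, c(0.5, 0.5), 2, win2(0.05, 10))
  expect_identical(nrow(g_empty$points), 0L)
  expect_error(growth_contour(sub, c(0.5, 0.5), 0.5, rbind(c(-1, 1), c(0, 1))),
               ">= 0")
})

test_that("flux-balance curves start at the supply and bend monotonically", {
  sub <- sym_substitutable(); setup <- sub_setup()
  fbc <- flux_balance_curve(sub, sub_red, setup, m_grid = seq(0, 3, 0.25))
  expect_equal(unname(fbc$points[1L, ]), setup$c_supply)  # m = 0 exactly
  expect_lt(max(fbc$residuals), 1e-8)
  ## consumption grows with biomass: concentrations non-increasing in m
  expect_true(all(diff(fbc$points[, 1L]) <= 1e-10))
  expect_true(all(diff(fbc$points[, 2L]) <= 1e-10))
  ## the contour/flux-balance intersection is the dynamical steady state
  ss <- steady_state(setup, sub, list(sub_red))
  fbs <- flux_balance_curve(sub, sub_red, setup, m_grid = ss$m[1L])
  expect_equal(unname(fbs$points[1L, ]), unname(ss$conc), tolerance = 1e-5)
  expect_lt(abs(growth_rate(sub, fbs$points[1L, ], sub_red) - setup$d), 1e-5)
})

test_that("supply lines close the loop with chemostat dynamics", {
  ess <- sym_essential(); d <- 0.25
  ## anchor on Blue's growth contour: a-limited at alpha_a = 0.35
  ca <- stats::uniroot(function(c) 0.35 * c / (1 + c) - d, c(0.1, 100),
                       tol = 1e-12)$root
  c0 <- c(ca, 3)
  expect_lt(abs(growth_rate(ess, c0, ess_blue) - d), 1e-9)
  sl <- supply_line(ess, ess_blue, c0, d)
  expect_equal(sl$point(0), c0)  # zero biomass: supply point is c0 itself
  m_pick <- 2.5
  setup <- chemostat_setup(d, sl$point(m_pick))
  ss <- steady_state(setup, ess, list(ess_blue))
  expect_equal(unname(ss$conc), c0, tolerance = 1e-4)
  expect_equal(ss$m[1L], m_pick, tolerance = 1e-4)
  ## off-contour anchors are rejected
  expect_error(supply_line(ess, ess_blue, c(10, 10), d), "not on the growth contour")
  ## cone membership: positive combinations of the two rays are inside,
  ## others outside; both lines anchored at the shared point c0, where a
  ## second (b-limited) strategy also grows at exactly d
  slA <- supply_line(ess, ess_blue, c0, d)
  ab <- 1 - d / (3 / (1 + 3))  # alpha with (1 - alpha) * monod(c0[2]) = d
  expect_lt(abs(growth_rate(ess, c0, c(ab, 1 - ab)) - d), 1e-9)
  slB <- supply_line(ess, c(ab, 1 - ab), c0, d, m_max = 10)
  inside <- c0 + 1.3 * slA$direction + 0.7 * slB$direction
  outside <- c0 - 0.5 * slA$direction + 0.7 * slB$direction
  expect_true(in_supply_cone(slA, slB, inside))
  expect_false(in_supply_cone(slA, slB, outside))
})

test_that("maximizing strategies are analytic where possible and match brute force", {
  sub <- sym_substitutable()
  ms <- maximizing_strategy(sub, c(2, 1))
  expect_equal(unname(ms$strategy), c(1, 0))  # all-or-none on the better nutrient
  ess <- sym_essential()
  mse <- maximizing_strategy(ess, c(3, 3))
  expect_equal(unname(mse$strategy), c(0.5, 0.5))  # symmetric environment
  ## ties on the substitutable diagonal flag degeneracy
  expect_true(maximizing_strategy(sub, c(2, 2))$degenerate)
  ## brute-force oracle on random environments, all five models
  set.seed(31)
  models <- list(sym_substitutable(), sym_essential(),
                 make_model("substitutable_assim"),
                 make_model("interconvert"), make_model("secretion"))
  steps <- c(200L, 200L, 8L, 12L, 12L)
  for (i in seq_along(models)) {
    m <- models[[i]]
    for (k in 1:5) {
      conc <- stats::runif(m$n_chemicals, 0.05, 5)
      ms <- maximizing_strategy(m, conc)
      bf <- brute_force_gmax(m, conc, steps[i])
      expect_gte(ms$g_max, bf - 1e-6)
      ## and the argmax really attains its reported value
      expect_equal(growth_rate(m, conc, as.numeric(ms$strategy) /
                                 sum(ms$strategy)), ms$g_max, tolerance = 1e-9)
    }
  }
})

test_that("the maximal growth contour envelopes all strategies with labelled sectors", {
  ic <- make_model("interconvert")
  mgc <- maximal_growth_contour(ic, d = 0.2, win2(0.02, 1), resolution = 25L)
  expect_gt(nrow(mgc$points), 8L)
  expect_lt(max(mgc$residuals), 1e-6)
  ## three sectors with two slope discontinuities between them
  expect_setequal(unique(mgc$class_labels),
                  c("conv_ab+imp_b", "imp_a+imp_b", "conv_ba+imp_a"))
  expect_identical(nrow(mgc$discontinuities), 2L)
  ## envelope property: no probe strategy beats d on the contour
  set.seed(41)
  idx <- sample(nrow(mgc$points), 8L)
  for (i in idx) {
    for (k in 1:25) {
      probe <- rsimplex(4L)
      expect_lt(growth_rate(ic, mgc$points[i, ], probe), 0.2 + 1e-6)
    }
  }
  ## envelope dominance and nesting via monotonicity of g_max on a grid
  gm <- vapply(seq(0.05, 1, length.out = 10), function(r)
    g_max(ic, c(r, 0.8 * r)), numeric(1))
  expect_true(all(diff(gm) > 0))
})

test_that("maximizing-class regions partition chemical space connectedly", {
  se <- make_model("secretion")
  res <- 11L
  cm <- class_map(se, win2(1e-2, 10), resolution = res)
  expect_setequal(unique(cm$class), c("ATP1+exp", "ATP2+imp", "ATP1+ATP2"))
  ## each class's cells form one 4-connected component (flood fill)
  lab <- matrix(match(cm$class, unique(cm$class)), res, res)
  for (cl in 1:3) {
    cells <- which(lab == cl, arr.ind = TRUE)
    comp <- rep(NA_integer_, nrow(cells))
    key <- paste(cells[, 1L], cells[, 2L])
    frontier <- 1L; comp[1L] <- 1L
    repeat {
      grew <- FALSE
      for (i in which(is.na(comp))) {
        nb <- rbind(cells[i, ] + c(0, 1), cells[i, ] - c(0, 1),
                    cells[i, ] + c(1, 0), cells[i, ] - c(1, 0))
        if (any(paste(nb[, 1L], nb[, 2L]) %in% key[!is.na(comp)])) {
          comp[i] <- 1L; grew <- TRUE
        }
      }
      if (!grew) break
    }
    expect_false(anyNA(comp), label = paste("class", cl, "connected"))
  }
})

test_that("c_opt lies on the maximal contour and balances the supply fluxes", {
  ess <- sym_essential()
  mgc <- maximal_growth_contour(ess, d = 0.25, win2(0.1, 8), resolution = 41L)
  setup <- chemostat_setup(0.25, c(6, 4))
  co <- c_opt(mgc, setup)
  expect_lt(co$mismatch, 1e-2)
  expect_lt(abs(g_max(ess, co$c_opt) - 0.25), 1e-3)
  ## the non-invasible resident then recreates c_opt from this supply
  ms <- maximizing_strategy(ess, co$c_opt)
  ss <- steady_state(setup, ess, list(as.numeric(ms$strategy)))
  expect_equal(unname(ss$conc), unname(co$c_opt), tolerance = 0.05)
})
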