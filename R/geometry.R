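## ---------------------------------------------------------------------------
## Chemical-space geometry: growth contours, flux-balance curves, supply
## lines, maximizing strategies and the maximal growth contour.
## All extracted contours are restricted to 2-D chemical spaces; the
## higher-dimensional models are handled pointwise (growth_rate /
## maximizing_strategy), which is all the multi-nutrient analyses need.
## ---------------------------------------------------------------------------

check_window <- function(window) {
  window <- as.matrix(window)
  if (!all(dim(window) == c(2L, 2L)))
    stop("window must be a 2x2 matrix: rows = chemicals, columns = (min, max)")
  if (any(window < 0)) stop("window bounds must be >= 0")
  if (any(window[, 2L] <= window[, 1L]))
    stop("window upper bounds must exceed lower bounds")
  window
}

## grid coordinates for one axis; log-spaced when possible (concentrations
## span decades), linear when the lower bound is 0.
axis_grid <- function(lo, hi, n, log_spacing) {
  if (log_spacing && lo > 0) exp(seq(log(lo), log(hi), length.out = n))
  else seq(lo, hi, length.out = n)
}

## Refine one marching-squares vertex onto the level set f(c) = level by
## bisection along the coordinate axis with the larger |df|.
refine_on_axis <- function(f, pt, level, h, tol = 1e-6) {
  g0 <- f(pt)
  if (abs(g0 - level) < 0.1 * tol) return(pt)
  d1 <- abs(f(pt + c(h[1L], 0)) - g0)
  d2 <- abs(f(pt + c(0, h[2L])) - g0)
  ax <- if (d1 >= d2) 1L else 2L
  dir <- numeric(2L); dir[ax] <- 1
  ## bracket the crossing
  s0 <- sign(g0 - level)
  step <- h[ax]
  lo_pt <- pt; hi_pt <- pt
  found <- FALSE
  for (k in 1:30) {
    cand_up <- pt + dir * step
    cand_dn <- pt - dir * min(step, pt[ax])
    if (sign(f(cand_up) - level) != s0) { lo_pt <- pt; hi_pt <- cand_up; found <- TRUE; break }
    if (sign(f(cand_dn) - level) != s0) { lo_pt <- cand_dn; hi_pt <- pt; found <- TRUE; break }
    step <- step * 2
  }
  if (!found) return(pt)
  s_lo <- sign(f(lo_pt) - level)
  for (k in 1:40) {
    mid <- (lo_pt + hi_pt) / 2
    fm <- f(mid)
    if (abs(fm - level) < 0.1 * tol) return(mid)
    if (sign(fm - level) == s_lo) lo_pt <- mid else hi_pt <- mid
  }
  (lo_pt + hi_pt) / 2
}

## Shared contour-extraction engine: marching squares (grDevices::contourLines)
## on an optionally log-spaced grid, then per-point bisection refinement.
extract_contour <- function(f, level, window, resolution, log_spacing = TRUE,
                            tol = 1e-6) {
  window <- check_window(window)
  x <- axis_grid(window[1L, 1L], window[1L, 2L], resolution, log_spacing)
  y <- axis_grid(window[2L, 1L], window[2L, 2L], resolution, log_spacing)
  Z <- matrix(NA_real_, resolution, resolution)
  for (i in seq_len(resolution))
    for (j in seq_len(resolution))
      Z[i, j] <- f(c(x[i], y[j]))
  segs <- grDevices::contourLines(x = x, y = y, z = Z, levels = level)
  if (!length(segs))
    return(list(points = matrix(numeric(), 0L, 2L), residuals = numeric(),
                grid = list(x = x, y = y, z = Z)))
  pts <- do.call(rbind, lapply(segs, function(s) cbind(s$x, s$y)))
  h <- c(stats::median(diff(x)), stats::median(diff(y)))
  ref <- t(apply(pts, 1L, function(p) refine_on_axis(f, p, level, h, tol)))
  resid <- apply(ref, 1L, function(p) abs(f(p) - level))
  keep <- resid < tol
  list(points = ref[keep, , drop = FALSE], residuals = resid[keep],
       grid = list(x = x, y = y, z = Z))
}

#' Growth contour (zero-net-growth isocline) of a strategy
#'
#' The level set `g(c, alpha) = d` in 2-D chemical space: all environments
#' that support steady-state growth of the strategy at dilution rate `d`.
#' Extraction is by marching squares on a (by default log-spaced) grid,
#' followed by bisection refinement of every vertex along a grid axis to a
#' residual below `tol`. An unattainable level returns an empty contour.
#'
#' @param model A `metabolic_model` with 2 external chemicals.
#' @param s Strategy vector.
#' @param d Contoured growth rate (typically the dilution rate).
#' @param window 2x2 matrix, rows = chemicals, columns = (min, max).
#' @param resolution Grid points per axis (default 101).
#' @param log_spacing Use log-spaced grid (default TRUE; requires positive
#'   lower bounds, otherwise falls back to linear).
#' @param tol Residual tolerance after refinement (default 1e-6).
#' @return Object of class `growth_contour`: `points` (n x 2 matrix),
#'   `residuals`, `d`, `window`.
#' @export
growth_contour <- function(model, s, d, window, resolution = 101L,
                           log_spacing = TRUE, tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  if (model$n_chemicals != 2L)
    stop("growth_contour requires a 2-D chemical space")
  s <- check_strategy(model, s)
  ext <- extract_contour(function(cc) eval_model(model, pmax(cc, 0), s)$g,
                         d, window, resolution, log_spacing, tol)
  structure(list(points = ext$points, residuals = ext$residuals, d = d,
                 window = check_window(window), strategy = s, model = model),
            class = "growth_contour")
}

#' Flux-balance curve of a single resident
#'
#' The one-parameter family of environments, indexed by biomass `m`, that
#' satisfy the nutrient mass balance `d (c_supply - c) = (m/r) I(c, alpha)`.
#' Solved by a damped Newton iteration continued from the previous biomass
#' value; the curve is truncated (with a warning) at the first biomass for
#' which no nonnegative solution exists.
#'
#' @param model A `metabolic_model`.
#' @param s Strategy vector.
#' @param setup A [chemostat_setup()].
#' @param m_grid Increasing vector of biomass values >= 0.
#' @param tol Residual tolerance (default 1e-8).
#' @return Object of class `flux_balance_curve`: `m` (biomass values kept),
#'   `points` (environment per biomass), `residuals`.
#' @export
flux_balance_curve <- function(model, s, setup, m_grid, tol = 1e-8) {
  stopifnot(inherits(setup, "chemostat_setup"))
  s <- check_strategy(model, s)
  if (any(m_grid < 0)) stop("m_grid must be >= 0")
  m_grid <- sort(m_grid)
  nc <- model$n_chemicals
  pts <- matrix(NA_real_, length(m_grid), nc)
  res <- rep(NA_real_, length(m_grid))
  cc <- setup$c_supply
  ok_until <- 0L
  for (k in seq_along(m_grid)) {
    m <- m_grid[k]
    fb <- function(c_try) {
      c_try <- pmax(c_try, 0)
      setup$d * (setup$c_supply - c_try) -
        (m / setup$r) * eval_model(model, c_try, s)$I
    }
    sol <- newton_nonneg(fb, cc, tol)
    if (is.null(sol)) {
      warning("flux-balance curve truncated at m = ", signif(m, 6),
              " (no nonnegative solution)")
      break
    }
    cc <- sol$x
    pts[k, ] <- cc
    res[k] <- sol$resid
    ok_until <- k
  }
  keep <- seq_len(ok_until)
  structure(list(m = m_grid[keep], points = pts[keep, , drop = FALSE],
                 residuals = res[keep], setup = setup, strategy = s,
                 model = model),
            class = "flux_balance_curve")
}

## Damped Newton with numerical Jacobian on a small nonnegative system.
## Returns list(x, resid) or NULL on failure.
newton_nonneg <- function(f, x0, tol, max_iter = 60L) {
  x <- pmax(x0, 0)
  r <- f(x)
  for (it in seq_len(max_iter)) {
    nr <- max(abs(r))
    if (nr < tol) return(list(x = x, resid = nr))
    n <- length(x)
    J <- matrix(0, length(r), n)
    for (j in seq_len(n)) {
      h <- max(1e-8, 1e-8 * abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (f(xp) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1; moved <- FALSE
    for (k in 1:40) {
      xn <- pmax(x + lambda * step, 0)
      rn <- f(xn)
      if (all(is.finite(rn)) && max(abs(rn)) < max(abs(r))) {
        x <- xn; r <- rn; moved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!moved) return(NULL)
  }
  nr <- max(abs(f(x)))
  if (nr < tol) list(x = x, resid = nr) else NULL
}

#' Supply line of a strategy through an environment point
#'
#' The ray of supply concentrations for which the strategy's single-species
#' steady state lands exactly on `c0`:
#' `c_supply(m) = c0 + (m / (r d)) * I(c0, alpha)`, parametrized by the
#' steady-state biomass `m >= 0`.
#'
#' @param model A `metabolic_model`.
#' @param s Strategy vector.
#' @param c0 Anchor environment; must lie on the strategy's growth contour at
#'   `d` (|g - d| <= 1e-3), since only then is `c0` a steady-state
#'   environment.
#' @param d Dilution rate.
#' @param r Biomass per cell volume (default 1).
#' @param m_max Extent of the ray (default 100).
#' @return Object of class `supply_line`: `origin`, `direction`
#'   (`I(c0, s)/(r d)`), `m_max`, and `point(m)` giving the supply point for
#'   biomass `m`.
#' @export
supply_line <- function(model, s, c0, d, r = 1, m_max = 100) {
  s <- check_strategy(model, s)
  c0 <- check_environment(model, c0)
  g0 <- eval_model(model, c0, s)$g
  if (abs(g0 - d) > 1e-3)
    stop("c0 is not on the growth contour at d: |g - d| = ",
         signif(abs(g0 - d), 3))
  dir <- unname(eval_model(model, c0, s)$I) / (r * d)
  point <- function(m) {
    if (any(m < 0)) stop("supply-line parameter m must be >= 0")
    if (length(m) == 1L) c0 + m * dir
    else t(vapply(m, function(mm) c0 + mm * dir, numeric(length(c0))))
  }
  structure(list(origin = c0, direction = dir, d = d, r = r, m_max = m_max,
                 point = point, strategy = s, model = model),
            class = "supply_line")
}

#' Membership in the supply cone spanned by two supply lines
#'
#' At a discontinuity of the maximal growth contour two maximizing strategies
#' share the anchor environment; supply points inside the cone spanned by
#' their supply lines force the two strategies to co-create the anchor
#' environment (optimal coexistence region).
#'
#' @param line1,line2 [supply_line()] objects sharing the same origin.
#' @param c_supply Candidate supply point.
#' @param tol Slack on the nonnegativity of the cone coordinates.
#' @return TRUE when `c_supply = origin + m1 * dir1 + m2 * dir2` with
#'   `m1, m2 >= -tol`.
#' @export
in_supply_cone <- function(line1, line2, c_supply, tol = 1e-9) {
  if (max(abs(line1$origin - line2$origin)) > 1e-6)
    stop("supply lines must share their origin (a contour discontinuity)")
  A <- cbind(line1$direction, line2$direction)
  rhs <- as.numeric(c_supply) - line1$origin
  coeff <- tryCatch(solve(A, rhs), error = function(e) return(NULL))
  if (is.null(coeff)) return(FALSE)
  all(coeff >= -tol)
}

## ---------------------------------------------------------------------------
## Maximizing strategies and the maximal growth contour
## ---------------------------------------------------------------------------

#' Growth-maximizing strategy at an environment
#'
#' The simplex argmax of `g(c, .)` at a fixed chemical environment, together
#' with the maximal growth rate `g_max(c)`. For models whose growth is linear
#' in the strategy (`substitutable`) or reducible per nutrient
#' (`substitutable_assim`) or a two-term balance (`essential`) the argmax is
#' analytic. The internal-state models (`interconvert`, `secretion`) are
#' maximized numerically: an exhaustive 1-D search over every two-component
#' face of the simplex, plus multi-start Nelder-Mead over the full simplex to
#' catch interior optima.
#'
#' @param model A `metabolic_model`.
#' @param conc Environment vector.
#' @param interior For the numerically maximized models, also run the
#'   multi-start interior search (default TRUE); FALSE restricts the search
#'   to simplex faces and vertices, which is where these models' optima lie,
#'   and is used for dense grid scans.
#' @return List with `strategy` (allocation vector), `g_max`, `degenerate`
#'   (TRUE when several distinct strategies tie within 1e-9).
#' @export
maximizing_strategy <- function(model, conc, interior = TRUE) {
  conc <- check_environment(model, conc)
  switch(model$name,
    substitutable = {
      p <- model$params$p
      v <- par_vec(model$params$v, p); K <- par_vec(model$params$K, p)
      w <- par_vec(model$params$w, p)
      score <- w * v * monod(conc, K)
      best <- max(score)
      tied <- which(score > best - 1e-9)
      alpha <- numeric(p); alpha[tied[1L]] <- 1
      list(strategy = stats::setNames(alpha, model$fn_names), g_max = best,
           degenerate = length(tied) > 1L)
    },
    essential = {
      v <- par_vec(model$params$v, 2L); K <- par_vec(model$params$K, 2L)
      f <- v * monod(conc, K)
      if (sum(f) == 0)
        return(list(strategy = stats::setNames(c(0.5, 0.5), model$fn_names),
                    g_max = 0, degenerate = TRUE))
      alpha_a <- f[2L] / (f[1L] + f[2L])
      g <- f[1L] * f[2L] / (f[1L] + f[2L])
      list(strategy = stats::setNames(c(alpha_a, 1 - alpha_a), model$fn_names),
           g_max = g, degenerate = any(f == 0))
    },
    substitutable_assim = {
      v <- par_vec(model$params$v, 3L); K <- par_vec(model$params$K, 3L)
      v_as <- par_vec(model$params$v_as, 3L); w <- par_vec(model$params$w, 3L)
      f <- v * monod(conc, K)
      ## per-unit-budget rate on nutrient i with the optimal import/assim split
      rate <- ifelse(f + v_as > 0, w * f * v_as / (f + v_as), 0)
      best <- max(rate)
      tied <- which(rate > best - 1e-9)
      i <- tied[1L]
      alpha <- numeric(6L)
      if (best > 0) {
        beta <- v_as[i] / (f[i] + v_as[i])  # import share on the chosen nutrient
        alpha[i] <- beta; alpha[3L + i] <- 1 - beta
      } else alpha[c(1L, 4L)] <- 0.5
      list(strategy = stats::setNames(alpha, model$fn_names), g_max = best,
           degenerate = length(tied) > 1L || best == 0)
    },
    maximize_numeric(model, conc, interior)
  )
}

## Numeric simplex argmax for the internal-state models: all C(n,2) faces by
## 1-D golden-section (stats::optimize), every vertex, and Nelder-Mead over a
## softmax chart of the simplex from several starts.
maximize_numeric <- function(model, conc, interior = TRUE) {
  n <- model$n_functions
  gfun <- function(alpha) eval_model(model, conc, alpha)$g
  cand <- list()
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    cand[[length(cand) + 1L]] <- list(alpha = e, g = gfun(e))
  }
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    face <- function(beta) {
      a <- numeric(n); a[j] <- beta; a[k] <- 1 - beta
      gfun(a)
    }
    op <- stats::optimize(face, c(0, 1), maximum = TRUE, tol = 1e-10)
    a <- numeric(n); a[j] <- op$maximum; a[k] <- 1 - op$maximum
    cand[[length(cand) + 1L]] <- list(alpha = a, g = op$objective)
  }
  if (interior) {
    best_face <- cand[[which.max(vapply(cand, `[[`, numeric(1), "g"))]]
    ## interior search via softmax chart
    starts <- list(rep(1 / n, n),
                   0.7 * best_face$alpha + 0.3 * rep(1 / n, n))
    for (st in starts) {
      th0 <- log(pmax(st, 1e-8)); th0 <- th0[-n] - th0[n]
      obj <- function(th) {
        e <- exp(c(th, 0) - max(c(th, 0)))
        -gfun(e / sum(e))
      }
      op <- stats::optim(th0, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 500))
      e <- exp(c(op$par, 0) - max(c(op$par, 0)))
      a <- e / sum(e)
      ## snap near-zero components to exactly zero and renormalize
      a[a < 1e-9] <- 0; a <- a / sum(a)
      cand[[length(cand) + 1L]] <- list(alpha = a, g = gfun(a))
    }
  }
  gs <- vapply(cand, `[[`, numeric(1), "g")
  best <- max(gs)
  tied <- which(gs > best - 1e-9)
  supports <- unique(lapply(cand[tied], function(cc) which(cc$alpha > ACTIVE_THRESHOLD)))
  pick <- cand[[tied[which.max(gs[tied])]]]
  list(strategy = stats::setNames(pick$alpha, model$fn_names),
       g_max = pick$g, degenerate = length(supports) > 1L)
}

#' Maximal growth rate envelope
#'
#' @param model A `metabolic_model`.
#' @param conc Environment vector.
#' @return `g_max(c)`, the growth rate of the maximizing strategy.
#' @export
g_max <- function(model, conc) maximizing_strategy(model, conc)$g_max

#' Class label of a strategy (its active support)
#'
#' @param model A `metabolic_model`.
#' @param s Strategy vector.
#' @return Single string: the sorted names of the components above the
#'   activity threshold (1e-6), joined by "+".
#' @export
strategy_class <- function(model, s) {
  act <- model$fn_names[as.numeric(s) > ACTIVE_THRESHOLD]
  paste(sort(act), collapse = "+")
}

#' Maximal growth contour with maximizing strategies and class labels
#'
#' The level set of the envelope `g_max(c) = d` in 2-D chemical space: all
#' environments supporting a maximal growth rate of exactly `d`. Every
#' refined contour point is annotated with its maximizing strategy and the
#' class label (support pattern) of that strategy; indices where the class
#' changes between adjacent points mark the contour's slope discontinuities,
#' each localized by bisection along the connecting segment.
#'
#' @inheritParams growth_contour
#' @param arc_tol Bisection resolution (in chemical-space distance) for
#'   locating class-boundary points (default 1e-4).
#' @return Object of class `maximal_contour`: `points`, `residuals`,
#'   `strategies` (matrix, row per point), `class_labels`, `discontinuities`
#'   (data.frame: index, boundary point, flanking labels).
#' @export
maximal_growth_contour <- function(model, d, window, resolution = 41L,
                                   log_spacing = TRUE, tol = 1e-6,
                                   arc_tol = 1e-4) {
  stopifnot(inherits(model, "metabolic_model"))
  if (model$n_chemicals != 2L)
    stop("maximal_growth_contour requires a 2-D chemical space")
  f <- function(cc) maximizing_strategy(model, pmax(cc, 0), interior = FALSE)$g_max
  ext <- extract_contour(f, d, window, resolution, log_spacing, tol)
  pts <- ext$points
  npt <- nrow(pts)
  strat <- matrix(NA_real_, npt, model$n_functions,
                  dimnames = list(NULL, model$fn_names))
  labels <- character(npt)
  for (i in seq_len(npt)) {
    ms <- maximizing_strategy(model, pts[i, ], interior = FALSE)
    strat[i, ] <- ms$strategy
    labels[i] <- strategy_class(model, ms$strategy)
  }
  disc <- list()
  if (npt > 1L) {
    for (i in seq_len(npt - 1L)) {
      if (labels[i] != labels[i + 1L] &&
          sqrt(sum((pts[i, ] - pts[i + 1L, ])^2)) < Inf) {
        lo <- pts[i, ]; hi <- pts[i + 1L, ]
        lab_lo <- labels[i]
        while (sqrt(sum((hi - lo)^2)) > arc_tol) {
          mid <- (lo + hi) / 2
          lab_mid <- strategy_class(model,
                                    maximizing_strategy(model, mid,
                                                        interior = FALSE)$strategy)
          if (lab_mid == lab_lo) lo <- mid else hi <- mid
        }
        bp <- (lo + hi) / 2
        disc[[length(disc) + 1L]] <-
          data.frame(index = i, c1 = bp[1L], c2 = bp[2L],
                     class_before = labels[i], class_after = labels[i + 1L])
      }
    }
  }
  structure(list(points = pts, residuals = ext$residuals,
                 strategies = strat, class_labels = labels,
                 discontinuities = if (length(disc)) do.call(rbind, disc) else
                   data.frame(index = integer(), c1 = numeric(),
                              c2 = numeric(), class_before = character(),
                              class_after = character()),
                 d = d, window = check_window(window), model = model),
            class = "maximal_contour")
}

#' @export
print.maximal_contour <- function(x, ...) {
  cat("<maximal_contour> d = ", x$d, ", ", nrow(x$points), " points\n",
      sep = "")
  cat("  classes: ", paste(unique(x$class_labels), collapse = " | "), "\n",
      sep = "")
  cat("  discontinuities: ", nrow(x$discontinuities), "\n", sep = "")
  invisible(x)
}

#' Maximizing-strategy class map over a chemical-space window
#'
#' Scans a grid over the window and reports the class label (active support
#' of the maximizing strategy) at every grid point; used to count and map the
#' distinct classes of a model's strategy space (e.g. importer/converter
#' sectors, polluter/cleaner/generalist sectors).
#'
#' @inheritParams growth_contour
#' @return data.frame with columns `c1`, `c2`, `g_max`, `class`.
#' @export
class_map <- function(model, window, resolution = 31L, log_spacing = TRUE) {
  window <- check_window(window)
  x <- axis_grid(window[1L, 1L], window[1L, 2L], resolution, log_spacing)
  y <- axis_grid(window[2L, 1L], window[2L, 2L], resolution, log_spacing)
  out <- expand.grid(c1 = x, c2 = y, KEEP.OUT.ATTRS = FALSE)
  out$g_max <- NA_real_; out$class <- NA_character_
  for (i in seq_len(nrow(out))) {
    ms <- maximizing_strategy(model, c(out$c1[i], out$c2[i]), interior = FALSE)
    out$g_max[i] <- ms$g_max
    out$class[i] <- strategy_class(model, ms$strategy)
  }
  out
}

#' Optimal environment on the maximal growth contour for a supply condition
#'
#' Intersects the maximal growth contour with the flux-balance relation
#' evaluated with the local maximizing strategy (the maximal flux-balance
#' curve): for every contour point the biomass implied by each nutrient's
#' mass balance is computed, and the point minimizing the spread between
#' the per-nutrient biomasses (refined along the polyline) is returned as
#' `c_opt`, the environment a non-invasible resident must create.
#'
#' @param mgc A `maximal_contour`.
#' @param setup A [chemostat_setup()].
#' @return List with `c_opt`, `index` (nearest contour point), `m`
#'   (implied biomass), `mismatch` (per-nutrient biomass spread).
#' @export
c_opt <- function(mgc, setup) {
  stopifnot(inherits(mgc, "maximal_contour"), inherits(setup, "chemostat_setup"))
  model <- mgc$model
  mism <- function(cc) {
    ms <- maximizing_strategy(model, cc, interior = FALSE)
    I <- eval_model(model, cc, ms$strategy)$I
    supply_flux <- setup$d * (setup$c_supply - cc)
    ok <- I > 1e-12
    if (!any(ok)) return(list(mismatch = Inf, m = NA_real_))
    ms_i <- supply_flux[ok] * setup$r / I[ok]
    list(mismatch = if (sum(ok) > 1L) max(ms_i) - min(ms_i) else
           max(0, -min(ms_i)), m = mean(ms_i))
  }
  vals <- apply(mgc$points, 1L, function(p) mism(p)$mismatch)
  i <- which.min(vals)
  ## golden-section refine along the two adjacent segments
  lo <- max(1L, i - 1L); hi <- min(nrow(mgc$points), i + 1L)
  seg <- function(t) {
    if (t <= 1) mgc$points[lo, ] * (1 - t) + mgc$points[i, ] * t
    else mgc$points[i, ] * (2 - t) + mgc$points[hi, ] * (t - 1)
  }
  op <- stats::optimize(function(t) mism(seg(t))$mismatch, c(0, 2), tol = 1e-8)
  cc <- seg(op$minimum)
  mm <- mism(cc)
  list(c_opt = cc, index = i, m = mm$m, mismatch = mm$mismatch)
}
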