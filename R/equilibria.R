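## Fixed points and stability of the two- and three-strategy replicator
## dynamics, and the mapping from parameter sets to qualitative regimes.

## Payoff-difference function on an edge of the simplex. `edge` names the
## two strategies present; t in [0, 1] is the frequency of the first.
edge_state <- function(edge, t) {
  switch(edge,
         "C-D"  = c(t, 1 - t, 0),
         "C-CD" = c(t, 0, 1 - t),
         "D-CD" = c(0, t, 1 - t),
         stop("unknown edge"))
}

edge_gap <- function(edge, t, params) {
  pay <- expected_payoffs_raw(edge_state(edge, t), params)
  switch(edge,
         "C-D"  = pay[1] - pay[2],
         "C-CD" = pay[1] - pay[3],
         "D-CD" = pay[2] - pay[3])
}

## Bracketed root refinement: uniroot at machine tolerance, then bisection
## polish until the payoff gap itself is below 1e-12.
refine_root <- function(f, lo, hi) {
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  if (abs(f(root)) <= 1e-12) return(root)
  a <- lo; b <- hi; fa <- f(a)
  for (i in 1:200) {
    mid <- (a + b) / 2
    fm <- f(mid)
    if (abs(fm) <= 1e-12 || (b - a) < 1e-16) return(mid)
    if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
  }
  mid
}

#' Fixed points and stability of the two-strategy dynamics
#'
#' Evaluates the payoff gap `g(x) = P_C(x) - P_D(x)` on a uniform grid over
#' `[0, 1]`, brackets every sign change, and bisects each bracket to
#' `|g| < 1e-12`. The boundaries `x = 0` and `x = 1` are always fixed points
#' of `dx/dt = x (1 - x) g(x)`; `x = 0` is stable iff `g(0) < 0`, `x = 1`
#' stable iff `g(1) > 0`, and an interior root is stable iff `g` crosses
#' from positive to negative.
#'
#' @param params A [qs_params()] object.
#' @param grid_resolution Number of grid intervals for bracketing (>= 100;
#'   default 1000).
#' @return A data frame with columns `x` and `stability`
#'   (`"stable"`/`"unstable"`), ordered by `x`.
#' @examples
#' find_equilibria_two_strategy(qs_params(p = 0.6, q = 0, Delta = 0))
#' @export
find_equilibria_two_strategy <- function(params, grid_resolution = 1000) {
  stopifnot("grid_resolution must be >= 100" = grid_resolution >= 100)
  g <- function(x) edge_gap("C-D", x, params)
  xs <- seq(0, 1, length.out = grid_resolution + 1)
  gv <- vapply(xs, g, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(grid_resolution)) {
    if (gv[i] == 0 && i > 1) roots <- c(roots, xs[i])
    else if (gv[i] * gv[i + 1] < 0)
      roots <- c(roots, refine_root(g, xs[i], xs[i + 1]))
  }
  slope_sign <- function(x0) {
    h <- 1e-6
    sign(g(min(x0 + h, 1)) - g(max(x0 - h, 0)))
  }
  out <- data.frame(
    x = c(0, roots, 1),
    stability = c(
      if (gv[1] < 0) "stable" else "unstable",
      vapply(roots, function(r)
        if (slope_sign(r) < 0) "stable" else "unstable", character(1)),
      if (gv[length(gv)] > 0) "stable" else "unstable"
    )
  )
  out[order(out$x), , drop = FALSE]
}

## --- three-strategy machinery ---------------------------------------------

## Reduced coordinates (x, y) with z = 1 - x - y.
## The polynomial payoff sums extend smoothly to slightly negative
## frequencies, so finite differences at boundary points stay central
## (no clipping here — clipping would halve boundary eigenvalues).
reduced_rhs <- function(xy, params) {
  s <- c(xy[1], xy[2], 1 - xy[1] - xy[2])
  pay <- expected_payoffs_raw(s, params)
  c(s[1] * (pay[1] - pay[4]), s[2] * (pay[2] - pay[4]))
}

## Central finite-difference Jacobian of the reduced dynamics, step 1e-6.
reduced_jacobian <- function(xy, params, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (reduced_rhs(xy + e, params) - reduced_rhs(xy - e, params)) /
      (2 * h)
  }
  J
}

## Eigenvalue-based stability label. An eigenvalue counts as "zero real
## part" when |Re| < 1e-6 * max(1, |lambda|); any such eigenvalue makes the
## point neutral-within-tolerance (expected for center-like interior points).
classify_stability <- function(eig) {
  neutral <- abs(Re(eig)) < 1e-6 * pmax(1, Mod(eig))
  if (any(neutral)) return("neutral-within-tolerance")
  re <- Re(eig)
  if (all(re < 0)) "stable"
  else if (all(re > 0)) "unstable"
  else "saddle"
}

equilibrium_report <- function(state, kind, params) {
  eig <- eigen(reduced_jacobian(state[1:2], params),
               only.values = TRUE)$values
  eig <- as.complex(eig)
  list(location = c(x = state[1], y = state[2], z = state[3]),
       kind = kind, eigenvalues = eig,
       stability = classify_stability(eig))
}

## Damped Newton solve of the interior fixed-point conditions
## P_C - P_D = 0, P_C - P_CD = 0 in reduced coordinates.
payoff_gaps_interior <- function(xy, params) {
  s <- c(xy[1], xy[2], 1 - xy[1] - xy[2])
  pay <- expected_payoffs_raw(s, params)
  c(pay[1] - pay[2], pay[1] - pay[3])
}

newton_interior <- function(start, params, maxit = 60) {
  xy <- start
  for (i in seq_len(maxit)) {
    F <- payoff_gaps_interior(xy, params)
    if (max(abs(F)) < 1e-13) return(xy)
    J <- matrix(0, 2, 2)
    h <- 1e-7
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      J[, j] <- (payoff_gaps_interior(xy + e, params) -
                   payoff_gaps_interior(xy - e, params)) / (2 * h)
    }
    step <- tryCatch(solve(J, F), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      cand <- xy - lambda * step
      if (cand[1] > 0 && cand[2] > 0 && sum(cand) < 1 &&
          max(abs(payoff_gaps_interior(cand, params))) < max(abs(F)))
        break
      lambda <- lambda / 2
      if (lambda < 1e-6) return(NULL)
    }
    xy <- xy - lambda * step
  }
  if (max(abs(payoff_gaps_interior(xy, params))) < 1e-12) xy else NULL
}

#' Fixed points and stability of the three-strategy dynamics
#'
#' Reports every fixed point of the replicator system on the simplex: the
#' three vertices (always fixed points), edge-interior points found by
#' one-dimensional root bracketing of the pairwise payoff gaps on each edge,
#' and interior points found by a multistart damped-Newton solve of
#' `P_C = P_D = P_CD` in reduced `(x, y)` coordinates from a triangular grid
#' of starts (step 0.05). Starts that fail to converge are skipped.
#' Duplicates within L-infinity distance 1e-6 are dropped, keeping the first
#' found. Stability comes from the eigenvalues of the central
#' finite-difference Jacobian of the reduced dynamics; eigenvalues with a
#' real part below the neutrality tolerance yield the label
#' `"neutral-within-tolerance"` rather than a forced stable/unstable call.
#'
#' @param params A [qs_params()] object.
#' @return An object of class `qs_equilibria`: list of reports, each with
#'   `location`, `kind` (`"vertex"`/`"edge"`/`"interior"`), `eigenvalues`
#'   (complex, length 2), and `stability`.
#' @examples
#' find_equilibria_three_strategy(qs_params())
#' @export
find_equilibria_three_strategy <- function(params) {
  reports <- list(
    equilibrium_report(c(1, 0, 0), "vertex", params),
    equilibrium_report(c(0, 1, 0), "vertex", params),
    equilibrium_report(c(0, 0, 1), "vertex", params)
  )
  locs <- lapply(reports, function(r) unname(r$location))
  add_point <- function(state, kind) {
    for (l in locs) if (max(abs(l - state)) < 1e-6) return(invisible())
    locs[[length(locs) + 1]] <<- state
    reports[[length(reports) + 1]] <<- equilibrium_report(state, kind, params)
  }
  for (edge in c("C-D", "C-CD", "D-CD")) {
    f <- function(t) edge_gap(edge, t, params)
    ts <- seq(0, 1, length.out = 1001)
    fv <- vapply(ts, f, numeric(1))
    for (i in seq_len(1000)) {
      if (fv[i] * fv[i + 1] < 0)
        add_point(edge_state(edge, refine_root(f, ts[i], ts[i + 1])), "edge")
      else if (fv[i] == 0 && i > 1)
        add_point(edge_state(edge, ts[i]), "edge")
    }
  }
  starts <- expand.grid(x = seq(0.05, 0.95, by = 0.05),
                        y = seq(0.05, 0.95, by = 0.05))
  starts <- starts[starts$x + starts$y <= 0.95, , drop = FALSE]
  for (i in seq_len(nrow(starts))) {
    sol <- newton_interior(c(starts$x[i], starts$y[i]), params)
    if (!is.null(sol) && sol[1] > 1e-6 && sol[2] > 1e-6 &&
        1 - sol[1] - sol[2] > 1e-6)
      add_point(c(sol[1], sol[2], 1 - sol[1] - sol[2]), "interior")
  }
  structure(reports, class = "qs_equilibria", params = params)
}

#' @export
print.qs_equilibria <- function(x, ...) {
  cat(sprintf("Replicator fixed points (%d found)\n", length(x)))
  for (r in x) {
    cat(sprintf("  %-8s (%.6f, %.6f, %.6f)  %s\n", r$kind,
                r$location[1], r$location[2], r$location[3], r$stability))
  }
  invisible(x)
}

#' @export
summary.qs_equilibria <- function(object, ...) {
  data.frame(
    x = vapply(object, function(r) unname(r$location[1]), numeric(1)),
    y = vapply(object, function(r) unname(r$location[2]), numeric(1)),
    z = vapply(object, function(r) unname(r$location[3]), numeric(1)),
    kind = vapply(object, function(r) r$kind, character(1)),
    re1 = vapply(object, function(r) Re(r$eigenvalues[1]), numeric(1)),
    re2 = vapply(object, function(r) Re(r$eigenvalues[2]), numeric(1)),
    stability = vapply(object, function(r) r$stability, character(1))
  )
}

#' Map a parameter set to its qualitative dynamical regime
#'
#' Deterministic classification from the stable-equilibrium set: a unique
#' stable full-defection state gives `"defection-only"`; stable full
#' defection plus stable full cooperation gives `"coordination"`; a unique
#' stable full-cooperation state gives `"cooperation-only"`. With no stable
#' attractor at all, a trajectory from the canonical interior start
#' `(0.4, 0.3, 0.3)` is integrated to `t = 2000` and checked by
#' [detect_oscillation()]: sustained oscillating coexistence gives
#' `"oscillatory-coexistence"`. Everything else is `"other"`.
#'
#' @param params A [qs_params()] object.
#' @param model `"three"` (default) classifies the full three-strategy
#'   system; `"two"` classifies the cooperator-defector restriction from
#'   [find_equilibria_two_strategy()].
#' @return An object of class `qs_regime`: list with `label` and
#'   `stable_equilibria`.
#' @examples
#' classify_regime(qs_params(p = 0.1), model = "two")$label  # defection-only
#' @export
classify_regime <- function(params, model = c("three", "two")) {
  model <- match.arg(model)
  if (model == "two") {
    eq <- find_equilibria_two_strategy(params)
    stable_x <- eq$x[eq$stability == "stable"]
    at0 <- any(abs(stable_x) < 1e-9)
    at1 <- any(abs(stable_x - 1) < 1e-9)
    interior <- any(stable_x > 1e-9 & stable_x < 1 - 1e-9)
    label <-
      if (interior) "other"
      else if (at0 && at1) "coordination"
      else if (at0) "defection-only"
      else if (at1) "cooperation-only"
      else "other"
    stable <- eq[eq$stability == "stable", , drop = FALSE]
    return(structure(list(label = label, stable_equilibria = stable),
                     class = "qs_regime"))
  }
  eq <- find_equilibria_three_strategy(params)
  stable <- Filter(function(r) r$stability == "stable", eq)
  is_vertex_at <- function(r, v) max(abs(unname(r$location) - v)) < 1e-9
  n <- length(stable)
  label <- if (n == 1 && is_vertex_at(stable[[1]], c(0, 1, 0))) {
    "defection-only"
  } else if (n == 1 && is_vertex_at(stable[[1]], c(1, 0, 0))) {
    "cooperation-only"
  } else if (n == 2 &&
             any(vapply(stable, is_vertex_at, logical(1), v = c(0, 1, 0))) &&
             any(vapply(stable, is_vertex_at, logical(1), v = c(1, 0, 0)))) {
    "coordination"
  } else if (n == 0) {
    traj <- integrate_replicator(c(0.4, 0.3, 0.3), params, t_end = 2000)
    osc <- detect_oscillation(traj)
    if (osc$oscillating && osc$coexistence) "oscillatory-coexistence"
    else "other"
  } else "other"
  structure(list(label = label, stable_equilibria = stable),
            class = "qs_regime")
}

#' @export
print.qs_regime <- function(x, ...) {
  cat(sprintf("Dynamical regime: %s (%d stable equilibria)\n",
              x$label,
              if (is.data.frame(x$stable_equilibria))
                nrow(x$stable_equilibria)
              else length(x$stable_equilibria)))
  invisible(x)
}
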