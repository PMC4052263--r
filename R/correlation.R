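#' Closed-form correlation length of the homogeneous chain
#'
#' The linear response of the circular-chain steady state to a small
#' perturbation obeys the recurrence `C(l) = qp * (C(l+2) + 2 C(l) +
#' C(l-2))` over even distances, where `p` and `q` are the nearest-
#' neighbour response coefficients of [derived_params()]. Its decaying
#' exponential solution `C(l) = exp(-l / l0)` has
#' `l0 = 1 / arcosh(1 / (2 sqrt(qp)))`, valid for `qp < 1/4`. At
#' `alpha = 0` no perturbation propagates (`qp = 0`, `l0 = 0`).
#'
#' @param params a [kinetic_params()] object.
#' @return A list with `l0` and the `derived` parameter list
#'   (`b_tilde`, `p`, `q`, `qp`, ...).
#' @examples
#' correlation_length_closed_form(kinetic_params())$l0
#' @export
correlation_length_closed_form <- function(params) {
  dp <- derived_params(params)
  if (dp$qp >= 0.25)
    stop("closed-form correlation length is only valid for qp < 1/4; qp = ",
         format(dp$qp), call. = FALSE)
  l0 <- if (dp$qp == 0) 0 else 1 / acosh(1 / (2 * sqrt(dp$qp)))
  list(l0 = l0, derived = dp)
}

#' Recurrence coefficient qp in the equal-generation case
#'
#' When the miRNA and target generation rates are equal (`g_R = g_T = g`),
#' the product `qp` depends only on the stoichiometric factor `alpha` and
#' the composite parameter `X = b_tilde * g / (d_R * d_T)`:
#' `1 / sqrt(qp) = (1 / (2 sqrt(alpha) X)) * (1 + 2 X (1 + alpha) +
#' sqrt((2 X (1 - alpha) + 1)^2 + 8 alpha X))`.
#'
#' The prefactor carries `sqrt(alpha)`: writing `u = d_R + 2 alpha
#' b_tilde T` and `v = d_T + 2 b_tilde R`, the steady state satisfies
#' `u v = d_R d_T / 2 * (1 + 2 X (1 + alpha) + sqrt(...))` while
#' `sqrt(qp) = sqrt(alpha) b_tilde g / (u v)`, so only this form is
#' consistent with the definitions of `p` and `q` (and with the chain
#' simulations; both routes are cross-checked in the test suite). At
#' `alpha = 1` the distinction vanishes.
#'
#' @param alpha stoichiometric factor, positive.
#' @param X composite parameter, positive.
#' @return The value of `qp`.
#' @examples
#' qp_equal_generation(1, 1)  # 1/16
#' @export
qp_equal_generation <- function(alpha, X) {
  stopifnot(alpha > 0, X > 0)
  inv_sqrt <- (1 / (2 * sqrt(alpha) * X)) *
    (1 + 2 * X * (1 + alpha) + sqrt((2 * X * (1 - alpha) + 1)^2 + 8 * alpha * X))
  inv_sqrt^-2
}

#' Solve the correlation recurrence by truncated linear system
#'
#' Brute-force solution of `C(0) = 1`, `C(l) = qp * (C(l+2) + 2 C(l) +
#' C(l-2))` for even `l >= 2`, with the far boundary condition
#' `C(L_big) = 0` imposed well beyond the requested range. Serves as an
#' independent numerical oracle for the closed-form exponential solution.
#'
#' @param qp recurrence coefficient, `0 <= qp < 1/4`.
#' @param L largest distance requested (even).
#' @param L_big truncation distance (default `4 * L + 400`).
#' @return A data.frame with columns `distance` (`0, 2, ..., L`) and `C`.
#' @export
recurrence_solve <- function(qp, L = 20, L_big = NULL) {
  if (qp < 0 || qp >= 0.25)
    stop("recurrence requires 0 <= qp < 1/4; got ", format(qp), call. = FALSE)
  L <- 2 * floor(L / 2)
  if (is.null(L_big)) L_big <- 4 * L + 400
  ell <- seq(0, L, by = 2)
  if (qp == 0)
    return(data.frame(distance = ell, C = c(1, rep(0, length(ell) - 1))))
  n <- L_big / 2 + 1  # unknowns C(0), C(2), ..., C(L_big)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1; rhs[1] <- 1
  for (k in 2:(n - 1)) {
    A[k, k - 1] <- qp
    A[k, k] <- 2 * qp - 1
    A[k, k + 1] <- qp
  }
  A[n, n] <- 1
  x <- solve(A, rhs)
  data.frame(distance = ell, C = x[seq_along(ell)])
}

#' Fit a correlation length to a profile
#'
#' Least-squares fit of `log C(l)` against even distance `l`, excluding
#' values at or below a numerical floor (default `1e-10`) that would bias
#' the fit toward the floating-point noise plateau. Requires at least
#' three usable points. Returns `l0 = -1 / slope` and fit diagnostics.
#'
#' @param profile a `correlation_profile` or a data.frame with columns
#'   `distance` and `C`.
#' @param floor values of `C` at or below this are excluded.
#' @return A list with `l0`, `slope`, `intercept`, `r_squared`,
#'   `n_points` and `range` (distances used).
#' @export
fit_correlation_length <- function(profile, floor = 1e-10) {
  df <- if (inherits(profile, "correlation_profile")) profile$profile else profile
  stopifnot(all(c("distance", "C") %in% names(df)))
  use <- is.finite(df$C) & df$C > floor
  df <- df[use, , drop = FALSE]
  if (nrow(df) < 3)
    stop("fewer than 3 usable points above the floor", call. = FALSE)
  fit <- stats::lm(log(df$C) ~ df$distance)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("profile does not decay; cannot fit a correlation length",
         call. = FALSE)
  list(l0 = -1 / slope, slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(df$distance, log(df$C))^2,
       n_points = nrow(df), range = range(df$distance))
}

# bipartite graph distances from a source node (edge counts)
node_distances <- function(system, source) {
  g <- as_igraph(system$topology)
  d <- igraph::distances(g, v = source)[1, ]
  stats::setNames(as.numeric(d), igraph::V(g)$name)
}

#' Numerical correlation function of a perturbed system
#'
#' Measures how a small steady-state perturbation at a source node
#' propagates to same-side responders. The source's generation rate is
#' reduced by a factor found by 1-D root solving so that the source level
#' drops by exactly `delta_fraction` (relative); the system is relaxed to
#' its new steady state, and each responder at even distance `l` reports
#' `C(l) = (dX_l / X_l) / (dX_0 / X_0)` where `X` is the free level on the
#' source's side. `C(0) = 1` by construction.
#'
#' @param system a `reaction_system` (chain or network).
#' @param source node id to perturb (an mRNA for target-side profiles, a
#'   miRNA for regulator-side profiles).
#' @param delta_fraction requested relative decrease of the source level
#'   (default 0.01; must be below 0.5, the linear-response regime).
#' @param max_distance optional cap on responder distance.
#' @return An object of class `correlation_profile`: a list with
#'   `profile` (data.frame `node`, `distance`, `C`, mean-aggregated
#'   `by_distance`), the `source`, the achieved generation `factor` and
#'   `delta_fraction`.
#' @export
correlation_function_numerical <- function(system, source,
                                           delta_fraction = 0.01,
                                           max_distance = Inf) {
  stopifnot(inherits(system, "reaction_system"))
  if (delta_fraction <= 0 || delta_fraction >= 0.5)
    stop("delta_fraction must lie in (0, 0.5): the correlation function ",
         "is defined in the linear-response regime", call. = FALSE)
  is_mirna <- source %in% system$mirnas
  if (!is_mirna && !(source %in% system$mrnas))
    stop("unknown node: ", source, call. = FALSE)
  base <- steady_state(system)
  lvl <- function(state) if (is_mirna) state$R else state$T
  x0 <- lvl(base)[[source]]
  if (x0 <= 0) stop("source has zero steady-state level", call. = FALSE)

  drop_at <- function(factor) {
    st <- steady_state(perturb_generation_rate(system, source, factor),
                       state0 = base)
    (x0 - lvl(st)[[source]]) / x0
  }
  lo <- 1 - 2 * delta_fraction
  while (drop_at(lo) < delta_fraction && lo > 1e-6) lo <- 1 - 2 * (1 - lo)
  factor <- stats::uniroot(function(f) drop_at(f) - delta_fraction,
                           c(lo, 1), tol = 1e-10)$root
  pert <- steady_state(perturb_generation_rate(system, source, factor),
                       state0 = base)

  dist <- node_distances(system, source)
  side <- if (is_mirna) system$mirnas else system$mrnas
  dist <- dist[side]
  keep <- is.finite(dist) & dist <= max_distance
  nodes <- names(dist)[keep]
  denom <- (x0 - lvl(pert)[[source]]) / x0
  Cv <- ((lvl(base)[nodes] - lvl(pert)[nodes]) / lvl(base)[nodes]) / denom
  Cv[nodes == source] <- 1
  prof <- data.frame(node = nodes, distance = unname(dist[keep]),
                     C = unname(Cv), stringsAsFactors = FALSE)
  prof <- prof[order(prof$distance, prof$node), , drop = FALSE]
  rownames(prof) <- NULL
  by_d <- stats::aggregate(C ~ distance, data = prof, FUN = mean)
  structure(list(profile = prof, by_distance = by_d, source = source,
                 factor = factor, delta_fraction = delta_fraction),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("<correlation_profile> source %s, delta %.3g, %d responders\n",
              x$source, x$delta_fraction, nrow(x$profile)))
  print(utils::head(x$by_distance, 8))
  invisible(x)
}

#' Sweep a kinetic parameter and track the correlation length
#'
#' Evaluates the correlation length over a parameter grid, analytically
#' (closed form, flagging grid points outside the `qp < 1/4` validity
#' domain) and/or numerically (exponential fit to the correlation function
#' of a homogeneous circular chain). The special name `"delta_g"` sweeps
#' the generation-rate difference, holding `g_R` fixed and setting
#' `g_T = g_R - delta_g`.
#'
#' @param base_params a [kinetic_params()] object.
#' @param name parameter to sweep (`"b"`, `"g"`, `"alpha"`, `"d_R"`,
#'   `"d_T"`, `"u_C"`, `"d_C"`, `"g_R"`, `"g_T"`, or `"delta_g"`;
#'   `"g"` sets `g_R` and `g_T` together).
#' @param grid numeric grid of parameter values.
#' @param mode `"analytic"`, `"numerical"` or `"both"`.
#' @param chain_N chain size for numerical mode.
#' @param delta_fraction perturbation size for numerical mode.
#' @return A data.frame of class `sweep_result` with columns `value`,
#'   `l0_analytic`, `qp`, `valid` and (numerical modes) `l0_fitted`.
#' @export
parameter_sweep <- function(base_params, name, grid,
                            mode = c("analytic", "numerical", "both"),
                            chain_N = 60, delta_fraction = 0.01) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(grid), length(grid) >= 1, !is.unsorted(grid))
  apply_value <- function(v) {
    if (name == "g") return(update_params(base_params, g_R = v, g_T = v))
    if (name == "delta_g")
      return(update_params(base_params, g_T = base_params$g_R - v))
    args <- stats::setNames(list(v), name)
    do.call(update_params, c(list(base_params), args))
  }
  out <- data.frame(value = grid, l0_analytic = NA_real_, qp = NA_real_,
                    valid = TRUE)
  if (mode != "analytic") out$l0_fitted <- NA_real_
  for (k in seq_along(grid)) {
    prm <- apply_value(grid[k])
    dp <- derived_params(prm)
    out$qp[k] <- dp$qp
    if (dp$qp < 0.25) {
      out$l0_analytic[k] <- if (dp$qp == 0) 0 else
        1 / acosh(1 / (2 * sqrt(dp$qp)))
    } else {
      out$valid[k] <- FALSE
    }
    if (mode != "analytic") {
      sys <- build_chain(chain_N, prm, boundary = "circular")
      src <- "T0"
      prof <- correlation_function_numerical(sys, src, delta_fraction,
                                             max_distance = chain_N)
      fit <- tryCatch(fit_correlation_length(prof$by_distance),
                      error = function(e) NULL)
      if (!is.null(fit)) out$l0_fitted[k] <- fit$l0
    }
  }
  attr(out, "parameter") <- name
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Correlation values between all same-side node pairs of a network
#'
#' Runs one computational perturbation experiment per source node: the
#' source miRNA's generation rate is multiplied by `factor` (default 9/10),
#' the system is relaxed to its new steady state, and the correlation value
#' `(dR_j / R_j) / (dR_source / R_source)` is recorded for every miRNA
#' responder, grouped by bipartite distance (2-sep, 4-sep, ...).
#' Disconnected responders are reported as unreachable and excluded from
#' the per-distance averages.
#'
#' @param system a `reaction_system`.
#' @param sources miRNA ids to perturb (default: all miRNAs).
#' @param factor generation-rate multiplier for the source (default 0.9).
#' @return A list with `values` (data.frame `source`, `responder`,
#'   `distance`, `C`), `by_distance` (mean `C` per distance, unreachable
#'   excluded) and `unreachable` (data.frame of skipped pairs).
#' @export
network_correlation_matrix <- function(system, sources = NULL, factor = 0.9) {
  stopifnot(inherits(system, "reaction_system"))
  if (is.null(sources)) sources <- system$mirnas
  stopifnot(all(sources %in% system$mirnas))
  base <- steady_state(system)
  rows <- list(); unreach <- list()
  for (src in sources) {
    pert <- steady_state(perturb_generation_rate(system, src, factor),
                         state0 = base)
    denom <- (base$R[[src]] - pert$R[[src]]) / base$R[[src]]
    dist <- node_distances(system, src)[system$mirnas]
    Cv <- ((base$R - pert$R) / base$R) / denom
    Cv[src] <- 1
    ok <- is.finite(dist)
    rows[[src]] <- data.frame(source = src, responder = system$mirnas[ok],
                              distance = unname(dist[ok]),
                              C = unname(Cv[ok]), stringsAsFactors = FALSE)
    if (any(!ok))
      unreach[[src]] <- data.frame(source = src,
                                   responder = system$mirnas[!ok],
                                   stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  by_d <- stats::aggregate(C ~ distance, data = values, FUN = mean)
  list(values = values, by_distance = by_d,
       unreachable = if (length(unreach))
         do.call(rbind, c(unreach, list(make.row.names = FALSE)))
       else NULL)
}
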