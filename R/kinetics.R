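#' System state: free miRNA, free target and complex levels
#'
#' @param R named numeric vector of free miRNA levels (one per miRNA node).
#' @param T named numeric vector of free target levels (one per mRNA node).
#' @param C numeric vector of complex levels, one per edge of the system
#'   that the state belongs to (ordered as `system$edges`).
#' @return An object of class `system_state`.
#' @export
system_state <- function(R, T, C) {
  structure(list(R = R, T = T, C = C), class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %d miRNAs, %d targets, %d complexes\n",
              length(x$R), length(x$T), length(x$C)))
  invisible(x)
}

zero_state <- function(system) {
  system_state(
    R = stats::setNames(numeric(length(system$mirnas)), system$mirnas),
    T = stats::setNames(numeric(length(system$mrnas)), system$mrnas),
    C = numeric(nrow(system$edges)))
}

check_state <- function(system, state) {
  if (!inherits(state, "system_state"))
    stop("state must be a system_state", call. = FALSE)
  if (length(state$R) != length(system$mirnas) ||
      length(state$T) != length(system$mrnas) ||
      length(state$C) != nrow(system$edges))
    stop("state dimensions do not match the system (",
         length(state$R), "/", length(state$T), "/", length(state$C),
         " vs ", length(system$mirnas), "/", length(system$mrnas), "/",
         nrow(system$edges), ")", call. = FALSE)
  invisible(state)
}

pack_state <- function(state) c(state$R, state$T, state$C)

unpack_state <- function(system, x) {
  nR <- length(system$mirnas); nT <- length(system$mrnas)
  system_state(
    R = stats::setNames(x[seq_len(nR)], system$mirnas),
    T = stats::setNames(x[nR + seq_len(nT)], system$mrnas),
    C = unname(x[nR + nT + seq_len(nrow(system$edges))]))
}

# sum x over groups idx (1..n), returning a length-n vector
edge_sum <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Mass-action right-hand side
#'
#' Time derivative of a [system_state()] under the mass-action model: for
#' each miRNA `i`, `dR_i/dt = g_Ri - sum_j b R_i T_j +
#' sum_j (u_C + (1-alpha) d_C) C_ij - d_Ri R_i`; for each target `j`,
#' `dT_j/dt = g_Tj - sum_i b R_i T_j + sum_i u_C C_ij - d_Tj T_j`; and for
#' each complex, `dC_ij/dt = b R_i T_j - (u_C + d_C) C_ij`. Sums run over
#' network neighbours; a single pair and the chain are special cases.
#'
#' @param system a `reaction_system`.
#' @param state a [system_state()] matching the system.
#' @return A `system_state` holding the derivatives.
#' @export
rhs <- function(system, state) {
  check_state(system, state)
  e <- system$edges
  nR <- length(system$mirnas); nT <- length(system$mrnas)
  flux <- e$b * state$R[e$i] * state$T[e$j]
  dR <- system$g_R - system$d_R * state$R -
    edge_sum(flux, e$i, nR) +
    edge_sum((e$u_C + (1 - e$alpha) * e$d_C) * state$C, e$i, nR)
  dT <- system$g_T - system$d_T * state$T -
    edge_sum(flux, e$j, nT) +
    edge_sum(e$u_C * state$C, e$j, nT)
  dC <- flux - (e$u_C + e$d_C) * state$C
  system_state(R = dR, T = dT, C = dC)
}

rhs_vec <- function(system, x) pack_state(rhs(system, unpack_state(system, x)))

max_abs_rhs <- function(system, state) {
  max(abs(pack_state(rhs(system, state))), 0)
}

#' Steady state of an isolated miRNA-target pair
#'
#' Unique nonnegative fixed point of the single-pair mass-action model.
#' Writing `b_tilde = b d_C / (u_C + d_C)`, the fixed point satisfies
#' `T = g_T / (d_T + b_tilde R)` and `R = g_R / (d_R + alpha b_tilde T)`,
#' with complex level `C = b R T / (u_C + d_C)`. The target level solves a
#' quadratic; the nonnegative root is returned. For `alpha = 0` the miRNA
#' decouples (`R = g_R / d_R` exactly).
#'
#' @param params a [kinetic_params()] object with `d_R > 0` and `d_T > 0`.
#' @return A [system_state()] with one miRNA (`R1`), one target (`T0`) and
#'   one complex.
#' @examples
#' pair_steady_state(kinetic_params(b = 0))  # decoupled: g/d levels
#' @export
pair_steady_state <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$d_R <= 0 || params$d_T <= 0)
    stop("pair_steady_state requires d_R > 0 and d_T > 0", call. = FALSE)
  bt <- b_tilde(params)
  a <- params$alpha
  if (bt == 0) {
    Tst <- params$g_T / params$d_T
    Rst <- params$g_R / params$d_R
  } else if (a == 0) {
    Rst <- params$g_R / params$d_R
    Tst <- params$g_T / (params$d_T + bt * Rst)
  } else {
    # alpha*bt*dT * T^2 + (dR dT + bt gR - alpha bt gT) T - gT dR = 0
    # conjugate form of the positive quadratic root: stable as alpha -> 0
    A <- a * bt * params$d_T
    B <- params$d_R * params$d_T + bt * params$g_R - a * bt * params$g_T
    Tst <- 2 * params$g_T * params$d_R /
      (B + sqrt(B^2 + 4 * A * params$g_T * params$d_R))
    Rst <- params$g_R / (params$d_R + a * bt * Tst)
  }
  Cst <- if (params$b == 0) 0 else
    params$b * Rst * Tst / (params$u_C + params$d_C)
  system_state(R = c(R1 = Rst), T = c(T0 = Tst), C = Cst)
}

#' Closed-form steady state of the homogeneous circular chain
#'
#' Shared steady-state levels of all targets and all miRNAs on a
#' homogeneous chain with circular boundary conditions (or equivalently in
#' the bulk of a long chain), where every node has two partners. The target
#' level solves `2 alpha b_tilde d_T T^2 + (d_R d_T + 2 b_tilde (g_R -
#' alpha g_T)) T - g_T d_R = 0` (nonnegative root), and
#' `R = g_R / (d_R + 2 alpha b_tilde T)`. The `alpha -> 0` limit
#' (`T = g_T / (d_T + 2 b_tilde g_R / d_R)`, `R = g_R / d_R`) and the
#' decoupled `b = 0` case are handled explicitly.
#'
#' @param params a [kinetic_params()] object with `d_T > 0`.
#' @return A list with components `T` and `R`.
#' @examples
#' chain_steady_state_closed_form(
#'   kinetic_params(g_R = 1, g_T = 1, d_R = 1, d_T = 1, b = 1,
#'                  u_C = 0, d_C = 1, alpha = 1))  # T = R = 0.5
#' @export
chain_steady_state_closed_form <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$d_T <= 0)
    stop("chain_steady_state_closed_form requires d_T > 0", call. = FALSE)
  bt <- b_tilde(params)
  a <- params$alpha
  if (bt == 0)
    return(list(T = params$g_T / params$d_T, R = params$g_R / params$d_R))
  if (a == 0) {
    if (params$d_R <= 0)
      stop("alpha = 0 requires d_R > 0", call. = FALSE)
    Rst <- params$g_R / params$d_R
    return(list(T = params$g_T / (params$d_T + 2 * bt * Rst), R = Rst))
  }
  B <- 2 * bt * (params$g_R - a * params$g_T) + params$d_R * params$d_T
  # conjugate form of the quadratic root: stable as alpha -> 0
  Tst <- 2 * params$g_T * params$d_R /
    (B + sqrt(B^2 + 8 * a * bt * params$g_T * params$d_R * params$d_T))
  Rst <- params$g_R / (params$d_R + 2 * a * bt * Tst)
  list(T = Tst, R = Rst)
}

#' Integrate the mass-action ODEs
#'
#' Integrates the system with an adaptive solver (`deSolve::lsoda`) from
#' `state0` to `t_end`, returning the trajectory on `times` (default: 201
#' points spanning `[0, t_end]`). Tiny negative excursions within the
#' integration tolerance are clipped to zero; excursions below
#' `-100 * atol` raise an error.
#'
#' @param system a `reaction_system`.
#' @param state0 initial [system_state()].
#' @param t_end final time (s), positive.
#' @param times optional explicit time grid (must start at 0).
#' @param atol,rtol absolute/relative integrator tolerances.
#' @return An object of class `trajectory`: a list with `times`, a matrix
#'   `states` (rows = times, columns = packed state), the `system`, and a
#'   `converged` flag (max residual of the final state below
#'   `1e-10 + 1e-8 * max level`).
#' @export
integrate_system <- function(system, state0, t_end, times = NULL,
                             atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(system, "reaction_system"), t_end > 0)
  check_state(system, state0)
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE))
  f <- function(t, y, parms) list(rhs_vec(system, y))
  out <- deSolve::ode(y = pack_state(state0), times = times, func = f,
                      parms = NULL, method = "lsoda",
                      atol = atol, rtol = rtol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed; last valid time ",
         max(out[, 1], na.rm = TRUE), call. = FALSE)
  states <- out[, -1, drop = FALSE]
  if (min(states) < -100 * atol)
    stop("integration produced a negative level beyond tolerance (min ",
         format(min(states)), ")", call. = FALSE)
  states[states < 0] <- 0
  final <- unpack_state(system, states[nrow(states), ])
  res <- max_abs_rhs(system, final)
  scale <- max(states[nrow(states), ], 0)
  structure(list(times = times, states = states, system = system,
                 converged = res < 1e-10 + 1e-8 * scale,
                 final_residual = res),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over [0, %g], %s (residual %.2e)\n",
              length(x$times), max(x$times),
              if (x$converged) "converged" else "not converged",
              x$final_residual))
  invisible(x)
}

#' Extract a node's level series from a trajectory
#'
#' @param trajectory a [integrate_system()] result.
#' @param node node id.
#' @return Numeric vector of levels along `trajectory$times`.
#' @export
trajectory_levels <- function(trajectory, node) {
  sys <- trajectory$system
  nR <- length(sys$mirnas); nT <- length(sys$mrnas)
  idx <- if (node %in% sys$mirnas) match(node, sys$mirnas)
  else if (node %in% sys$mrnas) nR + match(node, sys$mrnas)
  else stop("unknown node: ", node, call. = FALSE)
  unname(trajectory$states[, idx])
}

#' Export a trajectory as a tidy table
#'
#' @param trajectory a [integrate_system()] result.
#' @param path optional path; when given, written as TSV.
#' @return (Invisibly, when writing) a data.frame with columns `time`,
#'   `node_id`, `species_kind` (`R`, `T` or `C`) and `level`.
#' @export
trajectory_table <- function(trajectory, path = NULL) {
  sys <- trajectory$system
  nR <- length(sys$mirnas); nT <- length(sys$mrnas)
  ids <- c(sys$mirnas, sys$mrnas,
           paste0(sys$edges$mirna, "|", sys$edges$mrna))
  kinds <- c(rep("R", nR), rep("T", nT), rep("C", nrow(sys$edges)))
  df <- data.frame(
    time = rep(trajectory$times, times = length(ids)),
    node_id = rep(ids, each = length(trajectory$times)),
    species_kind = rep(kinds, each = length(trajectory$times)),
    level = as.vector(trajectory$states),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

# Newton iteration on the reduced (R, T) system: at steady state the
# complexes satisfy C = b R T / (u_C + d_C), which collapses the balance
# equations to
#   g_R - d_R R - sum_j alpha b~ R T_j = 0
#   g_T - d_T T - sum_i     b~ R_i T  = 0
# with analytic Jacobian. Returns NULL on failure.
newton_steady <- function(system, R0, T0, tol = 1e-12, max_iter = 60) {
  e <- system$edges
  nR <- length(system$mirnas); nT <- length(system$mrnas)
  denom <- e$u_C + e$d_C
  if (any(denom == 0 & e$b > 0)) return(NULL)
  bt <- ifelse(e$b == 0, 0, e$b * e$d_C / pmax(denom, .Machine$double.xmin))
  abt <- e$alpha * bt
  fval <- function(Rv, Tv) {
    c(system$g_R - system$d_R * Rv - Rv * edge_sum(abt * Tv[e$j], e$i, nR),
      system$g_T - system$d_T * Tv - Tv * edge_sum(bt * Rv[e$i], e$j, nT))
  }
  x <- pmax(c(R0, T0), 0)
  f <- fval(x[1:nR], x[nR + 1:nT])
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol * max(1, max(x))) break
    Rv <- x[1:nR]; Tv <- x[nR + 1:nT]
    J <- matrix(0, nR + nT, nR + nT)
    diag(J)[1:nR] <- -system$d_R - edge_sum(abt * Tv[e$j], e$i, nR)
    diag(J)[nR + 1:nT] <- -system$d_T - edge_sum(bt * Rv[e$i], e$j, nT)
    for (k in seq_len(nrow(e))) {
      J[e$i[k], nR + e$j[k]] <- J[e$i[k], nR + e$j[k]] - abt[k] * Rv[e$i[k]]
      J[nR + e$j[k], e$i[k]] <- J[nR + e$j[k], e$i[k]] - bt[k] * Tv[e$j[k]]
    }
    step <- tryCatch(solve(J, -f), error = function(err) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    fn <- f
    repeat {
      xn <- pmax(x + lam * step, 0)
      fn <- fval(xn[1:nR], xn[nR + 1:nT])
      if (max(abs(fn)) < max(abs(f)) || lam < 1e-8) break
      lam <- lam / 2
    }
    if (lam < 1e-8 && max(abs(fn)) >= max(abs(f))) return(NULL)
    x <- xn; f <- fn
  }
  if (max(abs(f)) > 1e-8 * max(1, max(x))) return(NULL)
  Rv <- stats::setNames(x[1:nR], system$mirnas)
  Tv <- stats::setNames(x[nR + 1:nT], system$mrnas)
  Cc <- ifelse(e$b == 0, 0,
               e$b * Rv[e$i] * Tv[e$j] / pmax(denom, .Machine$double.xmin))
  system_state(R = Rv, T = Tv, C = unname(Cc))
}

#' Relax a system to steady state
#'
#' Finds the steady state of the mass-action system. A damped Newton
#' iteration on the reduced free-level equations (complexes eliminated
#' algebraically) is tried first, seeded from `state0` or from the
#' decoupled `g/d` levels; if it fails, the ODEs are integrated over
#' successively doubled horizons until the residual criterion is met.
#' Convergence is declared when `max |rhs| < atol + rtol * (level scale)`,
#' a mixed criterion chosen because parameter sweeps span several decades
#' of level scales.
#'
#' @param system a `reaction_system`.
#' @param state0 optional initial [system_state()] guess.
#' @param atol,rtol residual tolerances (defaults `1e-10`, `1e-8`).
#' @param max_time maximum ODE relaxation horizon for the fallback.
#' @return A [system_state()] at steady state.
#' @export
steady_state <- function(system, state0 = NULL, atol = 1e-10, rtol = 1e-8,
                         max_time = 1e6) {
  stopifnot(inherits(system, "reaction_system"))
  if (is.null(state0)) {
    dR <- pmax(system$d_R, 1e-12); dT <- pmax(system$d_T, 1e-12)
    R0 <- system$g_R / dR; T0 <- system$g_T / dT
  } else {
    check_state(system, state0)
    R0 <- state0$R; T0 <- state0$T
  }
  st <- newton_steady(system, R0, T0)
  ok <- function(s) {
    !is.null(s) &&
      max_abs_rhs(system, s) < atol + rtol * max(pack_state(s), 0)
  }
  if (ok(st)) return(st)
  # ODE relaxation fallback
  cur <- if (is.null(state0)) zero_state(system) else state0
  t_end <- 50 / max(min(c(system$d_R, system$d_T)[c(system$d_R, system$d_T) > 0],
                        Inf), 1e-3)
  t_end <- min(max(t_end, 10), max_time)
  repeat {
    traj <- integrate_system(system, cur, t_end,
                             times = c(0, t_end / 2, t_end))
    cur <- unpack_state(system, traj$states[nrow(traj$states), ])
    st <- newton_steady(system, cur$R, cur$T)
    if (ok(st)) return(st)
    if (ok(cur)) return(cur)
    if (t_end >= max_time)
      stop("steady_state did not converge within max_time; residual ",
           format(max_abs_rhs(system, cur)), call. = FALSE)
    t_end <- min(t_end * 4, max_time)
  }
}

#' Response time of a node after a perturbation
#'
#' The time at which a node's level first reaches halfway between its old
#' and new steady-state levels, obtained from a trajectory by linear
#' interpolation between sample points. If the level never crosses the
#' midpoint, `NA` is returned with a warning.
#'
#' @param trajectory a [integrate_system()] result starting at the old
#'   steady state with the perturbation applied.
#' @param node node id.
#' @param old_level,new_level levels before and after the perturbation
#'   (must differ).
#' @return Time in seconds (or `NA`).
#' @export
response_time <- function(trajectory, node, old_level, new_level) {
  if (old_level == new_level)
    stop("old and new levels must differ", call. = FALSE)
  lv <- trajectory_levels(trajectory, node)
  mid <- (old_level + new_level) / 2
  up <- new_level > old_level
  hit <- if (up) lv >= mid else lv <= mid
  k <- which(hit)[1]
  if (is.na(k)) {
    warning("level of ", node, " never crosses the midpoint")
    return(NA_real_)
  }
  if (k == 1) return(trajectory$times[1])
  t0 <- trajectory$times[k - 1]; t1 <- trajectory$times[k]
  y0 <- lv[k - 1]; y1 <- lv[k]
  t0 + (mid - y0) / (y1 - y0) * (t1 - t0)
}

#' Relative response times along a perturbed system
#'
#' Computes each node's [response_time()] normalized by the response time
#' of the perturbation source, so the source itself scores 1.
#'
#' @param trajectory trajectory of the perturbed system started from the
#'   old steady state.
#' @param source source node id.
#' @param nodes node ids to evaluate (default: all free species).
#' @param old_state,new_state [system_state()]s before/after perturbation.
#' @return A data.frame with columns `node`, `time`, `relative`.
#' @export
relative_response_time <- function(trajectory, source, nodes = NULL,
                                   old_state, new_state) {
  sys <- trajectory$system
  if (is.null(nodes)) nodes <- c(sys$mirnas, sys$mrnas)
  lvl <- function(state, node) {
    if (node %in% sys$mirnas) state$R[[node]] else state$T[[node]]
  }
  times <- vapply(nodes, function(nd)
    response_time(trajectory, nd, lvl(old_state, nd), lvl(new_state, nd)),
    numeric(1))
  t_src <- response_time(trajectory, source, lvl(old_state, source),
                         lvl(new_state, source))
  data.frame(node = nodes, time = unname(times),
             relative = unname(times) / t_src,
             stringsAsFactors = FALSE, row.names = NULL)
}
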