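#' Kinetic parameters for one miRNA-target context
#'
#' Bundles the mass-action rate constants describing one miRNA-target
#' interaction context: generation rates of the free miRNA (`g_R`) and free
#' target (`g_T`), the binding rate `b`, the complex unbinding rate `u_C`,
#' degradation rates of free miRNA, free target and complex
#' (`d_R`, `d_T`, `d_C`), and the stoichiometric factor `alpha`.
#'
#' `alpha` interpolates between the catalytic regime (`alpha = 0`, the miRNA
#' is recycled when the complex degrades) and the stoichiometric regime
#' (`alpha = 1`, miRNA and target are degraded together). Levels are on an
#' arbitrary dimensionless scale, so `b` carries units of (level s)^-1 and
#' all other rates s^-1.
#'
#' The defaults are the package-wide reference parameter set: a symmetric,
#' fully stoichiometric context (`g_R = g_T = 1`, `b = 1`, `u_C = 0.1`,
#' `d_C = 1`, `d_R = d_T = 0.17`, `alpha = 1`) chosen so that the chain
#' correlation length is about 2 distance units (see the package vignette).
#'
#' @param g_R,g_T generation rates (level/s), nonnegative.
#' @param b binding rate ((level s)^-1), nonnegative.
#' @param u_C complex unbinding rate (s^-1), nonnegative.
#' @param d_R,d_T,d_C degradation rates (s^-1), nonnegative.
#' @param alpha stoichiometric factor in `[0, 1]`.
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params()
#' b_tilde(p)
#' @export
kinetic_params <- function(g_R = 1, g_T = 1, b = 1, u_C = 0.1, d_C = 1,
                           d_R = 0.17, d_T = 0.17, alpha = 1) {
  p <- list(g_R = g_R, g_T = g_T, b = b, u_C = u_C, d_C = d_C,
            d_R = d_R, d_T = d_T, alpha = alpha)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  rates <- c("g_R", "g_T", "b", "u_C", "d_C", "d_R", "d_T", "alpha")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("kinetic parameter '", nm, "' must be a single number", call. = FALSE)
    if (v < 0)
      stop("kinetic parameter '", nm, "' must be nonnegative, got ", v,
           call. = FALSE)
  }
  if (p$alpha > 1)
    stop("stoichiometric factor alpha must lie in [0, 1], got ", p$alpha,
         call. = FALSE)
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  g_R=%g g_T=%g b=%g u_C=%g d_C=%g d_R=%g d_T=%g alpha=%g\n",
              x$g_R, x$g_T, x$b, x$u_C, x$d_C, x$d_R, x$d_T, x$alpha))
  invisible(x)
}

#' Modify a kinetic parameter set
#'
#' Returns a copy of `params` with the named components replaced, after
#' re-validation.
#'
#' @param params a [kinetic_params()] object.
#' @param ... named components to replace, e.g. `alpha = 0.5`.
#' @return A `kinetic_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad))
    stop("unknown kinetic parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  params[names(repl)] <- repl
  do.call(kinetic_params, unclass(params))
}

#' Effective binding rate
#'
#' The binding rate discounted by complex dissociation,
#' `b_tilde = b * d_C / (u_C + d_C)`: only the fraction of complexes that
#' degrade (rather than unbind) removes molecules from the free pools. When
#' `b = 0` the value is 0 regardless of `u_C + d_C`.
#'
#' @param params a [kinetic_params()] object.
#' @return A single nonnegative number, at most `params$b`.
#' @export
b_tilde <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$b == 0) return(0)
  denom <- params$u_C + params$d_C
  if (denom == 0)
    stop("u_C + d_C = 0 with b > 0: complexes neither unbind nor degrade, ",
         "no steady state exists", call. = FALSE)
  params$b * params$d_C / denom
}

#' Derived parameters of the chain steady state
#'
#' Computes the quantities the correlation-length theory is written in:
#' the effective binding rate `b_tilde`, the homogeneous-chain steady-state
#' levels `T` and `R`, the linear-response coefficients
#' `p = -alpha * b_tilde * g_R / (d_R + 2 alpha b_tilde T)^2` and
#' `q = -b_tilde * g_T / (d_T + 2 b_tilde R)^2` (both nonpositive), their
#' product `qp >= 0`, and, when `g_R == g_T`, the composite parameter
#' `X = b_tilde * g / (d_R * d_T)`.
#'
#' `p` and `q` are evaluated at the circular-chain steady state of
#' [chain_steady_state_closed_form()].
#'
#' @param params a [kinetic_params()] object.
#' @return A list with components `b_tilde`, `T`, `R`, `p`, `q`, `qp`, `X`
#'   (`X` is `NA` unless `g_R == g_T`).
#' @export
derived_params <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  bt <- b_tilde(params)
  ss <- chain_steady_state_closed_form(params)
  p <- -params$alpha * bt * params$g_R / (params$d_R + 2 * params$alpha * bt * ss$T)^2
  q <- -bt * params$g_T / (params$d_T + 2 * bt * ss$R)^2
  X <- if (isTRUE(all.equal(params$g_R, params$g_T)) &&
           params$d_R > 0 && params$d_T > 0) {
    bt * params$g_R / (params$d_R * params$d_T)
  } else NA_real_
  list(b_tilde = bt, T = ss$T, R = ss$R, p = p, q = q, qp = p * q, X = X)
}
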