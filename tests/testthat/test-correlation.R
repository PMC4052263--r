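test_that("recurrence oracle reproduces the exponential closed form", {
  # boundary condition
  expect_equal(recurrence_solve(0.1, L = 10)$C[1], 1)
  # qp = 0: no propagation
  r0 <- recurrence_solve(0, L = 6)
  expect_equal(r0$C, c(1, 0, 0, 0))
  # qp = 1/16: C(2) = exp(-2 * arcosh(2))
  r <- recurrence_solve(1 / 16, L = 10)
  expect_equal(r$C[2], exp(-2 * acosh(2)), tolerance = 1e-6)
  fit <- fit_correlation_length(r)
  expect_equal(fit$l0, 1 / acosh(2), tolerance = 1e-6)
  expect_error(recurrence_solve(0.3, L = 4), "1/4")
})

test_that("closed-form correlation length matches hand evaluation at alpha=1, X=1", {
  qp <- qp_equal_generation(1, 1)
  expect_equal(qp, 1 / 16, tolerance = 1e-12)
  # raw-parameter route with g_R = g_T chosen so that X = 1
  p <- kinetic_params(g_R = 1, g_T = 1, b = 1, u_C = 0, d_C = 1,
                      d_R = 1, d_T = 1, alpha = 1)
  dp <- derived_params(p)
  expect_equal(dp$X, 1)
  expect_equal(dp$qp, 1 / 16, tolerance = 1e-12)
  cl <- correlation_length_closed_form(p)
  expect_equal(cl$l0, 1 / acosh(2), tolerance = 1e-9)
})

test_that("equal-generation qp agrees with the general route across parameters", {
  set.seed(7)
  for (rep in 1:10) {
    p <- random_params()
    p <- update_params(p, g_T = p$g_R)  # equal generation
    dp <- derived_params(p)
    expect_equal(qp_equal_generation(p$alpha, dp$X), dp$qp,
                 tolerance = 1e-10)
  }
  # X -> 0 limit: no propagation
  expect_lt(qp_equal_generation(1, 1e-8), 1e-15)
})

test_that("alpha = 0 kills propagation in closed form and in simulation", {
  p0 <- kinetic_params(alpha = 0)
  cl <- correlation_length_closed_form(p0)
  expect_equal(cl$l0, 0)
  expect_equal(cl$derived$qp, 0)

  sys <- build_chain(30, p0, boundary = "circular")
  prof <- correlation_function_numerical(sys, "T0", 0.01, max_distance = 10)
  far <- prof$profile$C[prof$profile$distance >= 2]
  expect_lt(max(abs(far)), 1e-6)
})

test_that("fit recovers an exact exponential decay", {
  df <- data.frame(distance = seq(0, 20, 2), C = exp(-seq(0, 20, 2) / 2))
  fit <- fit_correlation_length(df)
  expect_equal(fit$l0, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_correlation_length(df[1:2, ]), "3 usable")
})

test_that("closed form, recurrence oracle and chain simulation form a tight triangle", {
  p <- kinetic_params()
  dp <- derived_params(p)
  l0_closed <- correlation_length_closed_form(p)$l0
  l0_rec <- fit_correlation_length(recurrence_solve(dp$qp, L = 30))$l0
  expect_equal(l0_rec, l0_closed, tolerance = 1e-6)

  sys <- build_chain(100, p, boundary = "circular")
  prof <- correlation_function_numerical(sys, "T0", 0.01, max_distance = 40)
  expect_equal(prof$by_distance$C[prof$by_distance$distance == 0], 1)
  l0_num <- fit_correlation_length(prof$by_distance)$l0
  expect_equal(l0_num, l0_closed, tolerance = 0.05)
  # positive, non-increasing profile on the homogeneous chain
  expect_true(all(prof$by_distance$C > 0))
  expect_true(all(diff(prof$by_distance$C) <= 1e-12))
})

test_that("the correlation function is perturbation-size independent in the linear regime", {
  p <- kinetic_params()
  sys <- build_chain(40, p, boundary = "circular")
  p1 <- correlation_function_numerical(sys, "T0", 0.01, max_distance = 10)
  p2 <- correlation_function_numerical(sys, "T0", 0.02, max_distance = 10)
  m1 <- p1$by_distance$C[p1$by_distance$distance > 0]
  m2 <- p2$by_distance$C[p2$by_distance$distance > 0]
  expect_lt(max(abs(m1 - m2) / m1), 0.01)
  expect_error(correlation_function_numerical(sys, "T0", 0.6), "0.5")
})

test_that("sweeps reproduce the known monotonic directions of the correlation length", {
  p <- kinetic_params()
  dirs <- list(b = "+", g = "+", alpha = "+", d_R = "-", d_T = "-", u_C = "-")
  grids <- list(b = seq(0.2, 2, length.out = 6),
                g = seq(0.3, 3, length.out = 6),
                alpha = seq(0.1, 1, length.out = 6),
                d_R = seq(0.05, 1, length.out = 6),
                d_T = seq(0.05, 1, length.out = 6),
                u_C = seq(0, 2, length.out = 6))
  for (nm in names(dirs)) {
    sw <- parameter_sweep(p, nm, grids[[nm]])
    l0 <- sw$l0_analytic[sw$valid]
    if (dirs[[nm]] == "+") expect_true(all(diff(l0) >= -1e-12), label = nm)
    else expect_true(all(diff(l0) <= 1e-12), label = nm)
  }
  # alpha sweep peaks at the stoichiometric case
  swa <- parameter_sweep(p, "alpha", seq(0.1, 1, length.out = 6))
  expect_equal(which.max(swa$l0_analytic), nrow(swa))
  # propagation strengthens as generation rates approach each other
  swd <- parameter_sweep(p, "delta_g", seq(0, 0.6, length.out = 6))
  expect_true(all(diff(swd$l0_analytic) <= 0))
})

test_that("analytic and fitted correlation lengths agree across random parameters", {
  set.seed(123)
  done <- 0
  while (done < 8) {
    p <- random_params()
    dp <- derived_params(p)
    if (dp$qp >= 0.25 || dp$qp < 1e-6) next
    done <- done + 1
    l0_closed <- correlation_length_closed_form(p)$l0
    l0_rec <- fit_correlation_length(
      recurrence_solve(dp$qp, L = 30))$l0
    expect_equal(l0_rec, l0_closed, tolerance = 1e-6)
    sys <- build_chain(60, p, boundary = "circular")
    prof <- correlation_function_numerical(sys, "T0", 0.01,
                                           max_distance = 20)
    l0_num <- tryCatch(fit_correlation_length(prof$by_distance)$l0,
                       error = function(e) NA_real_)
    if (is.finite(l0_num))
      expect_equal(l0_num, l0_closed, tolerance = 0.05)
  }
})

test_that("network correlation values attenuate with bipartite distance", {
  topo <- example_subnetwork()
  sys <- build_network(topo, kinetic_params(),
                       generation_mode = "degree_proportional")
  m <- network_correlation_matrix(sys, factor = 0.9)
  expect_equal(m$values$C[m$values$source == m$values$responder],
               rep(1, length(unique(m$values$source))))
  by_src <- split(m$values, m$values$source)
  for (src in names(by_src)) {
    v <- by_src[[src]]
    m2 <- mean(v$C[v$distance == 2])
    m4 <- mean(v$C[v$distance == 4])
    expect_gt(m2, m4)
  }
  # group means decay overall
  bd <- m$by_distance[m$by_distance$distance > 0, ]
  expect_true(all(diff(bd$C) < 0))
})

test_that("heterogeneous parameters can amplify individual pair responses", {
  # over a seeded ensemble of systems with node-to-node rate heterogeneity,
  # some individual 2-/4-sep correlation values far exceed their group mean
  topo <- example_subnetwork()
  set.seed(31)
  found <- FALSE
  for (rep in 1:5) {
    sys <- build_network(topo, kinetic_params(),
                         generation_mode = "degree_proportional")
    jitter <- function(x) x * exp(stats::rnorm(length(x), 0, 0.8))
    sys$g_R <- jitter(sys$g_R); sys$g_T <- jitter(sys$g_T)
    sys$d_R <- jitter(sys$d_R); sys$d_T <- jitter(sys$d_T)
    sys$edges$b <- jitter(sys$edges$b)
    m <- network_correlation_matrix(sys, factor = 0.9)
    v <- m$values[m$values$distance %in% c(2, 4), ]
    grp_mean <- stats::ave(v$C, v$distance, FUN = mean)
    if (any(v$C > 5 * grp_mean)) { found <- TRUE; break }
  }
  expect_true(found)
})
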