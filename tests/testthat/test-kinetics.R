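test_that("pair steady state handles decoupled and catalytic limits", {
  p0 <- kinetic_params(b = 0, g_R = 2, g_T = 3, d_R = 0.5, d_T = 0.25)
  ss <- pair_steady_state(p0)
  expect_equal(unname(ss$T), 12)
  expect_equal(unname(ss$R), 4)
  expect_equal(ss$C, 0)

  pc <- kinetic_params(alpha = 0, b = 1.7, g_R = 2, d_R = 0.5)
  ss <- pair_steady_state(pc)
  expect_identical(unname(ss$R), 2 / 0.5)  # catalytic miRNA unaffected

  expect_error(pair_steady_state(kinetic_params(d_R = 0)), "d_R")
})

test_that("symmetric pair fixed point is the golden-ratio solution", {
  # x = 1/(1+x) has root (sqrt(5)-1)/2; confirmed independently by bisection
  f <- function(x) x - 1 / (1 + x)
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  p <- kinetic_params(g_R = 1, g_T = 1, d_R = 1, d_T = 1, d_C = 1,
                      u_C = 0, b = 1, alpha = 1)
  ss <- pair_steady_state(p)
  expect_equal(unname(ss$R), lo, tolerance = 1e-12)
  expect_equal(unname(ss$T), (sqrt(5) - 1) / 2, tolerance = 1e-12)
  expect_equal(ss$C, 1 - (sqrt(5) - 1) / 2, tolerance = 1e-10)
})

test_that("chain construction matches the alternating topology", {
  sys1 <- build_chain(1, kinetic_params())
  expect_length(sys1$mirnas, 1)
  expect_length(sys1$mrnas, 1)
  expect_identical(nrow(sys1$edges), 1L)

  sys3 <- build_chain(3, kinetic_params(), boundary = "open")
  expect_setequal(c(sys3$mirnas, sys3$mrnas),
                  c("T0", "R1", "T2", "R3", "T4", "R5"))
  expect_identical(nrow(sys3$edges), 5L)
  sys3c <- build_chain(3, kinetic_params(), boundary = "circular")
  expect_identical(nrow(sys3c$edges), 6L)

  sysc <- build_chain(100, kinetic_params(), boundary = "circular")
  degs <- table(c(sysc$edges$mirna, sysc$edges$mrna))
  expect_true(all(degs == 2))
})

test_that("rhs vanishes at fixed points and at the empty system", {
  sys <- build_chain(1, kinetic_params())
  z <- system_state(R = c(R1 = 0), T = c(T0 = 0), C = 0)
  sys0 <- sys; sys0$g_R[] <- 0; sys0$g_T[] <- 0
  expect_equal(max(abs(unlist(rhs(sys0, z)))), 0)

  p <- kinetic_params(g_R = 1.3, g_T = 0.8, b = 1.1, u_C = 0.2,
                      d_C = 0.9, d_R = 0.4, d_T = 0.3, alpha = 0.7)
  ss <- pair_steady_state(p)
  sysp <- build_chain(1, p)
  expect_lt(max(abs(unlist(rhs(sysp, ss)))), 1e-12)
})

test_that("binding-only systems conserve total miRNA and target mass", {
  p <- kinetic_params(g_R = 0, g_T = 0, b = 1, u_C = 0, d_C = 0,
                      d_R = 0, d_T = 0, alpha = 1)
  sys <- build_chain(2, p, boundary = "open")
  start <- system_state(
    R = stats::setNames(c(0.8, 0.3), sys$mirnas),
    T = stats::setNames(c(1.2, 0.5), sys$mrnas),
    C = rep(0.1, nrow(sys$edges)))
  traj <- integrate_system(sys, start, t_end = 20)
  totals <- function(state) {
    e <- sys$edges
    list(R = state$R + vapply(seq_along(sys$mirnas), function(i)
           sum(state$C[e$i == i]), numeric(1)),
         T = state$T + vapply(seq_along(sys$mrnas), function(j)
           sum(state$C[e$j == j]), numeric(1)))
  }
  first <- totals(unpack_state_for_test(sys, traj$states[1, ]))
  last <- totals(unpack_state_for_test(sys, traj$states[nrow(traj$states), ]))
  expect_equal(unname(unlist(last)), unname(unlist(first)), tolerance = 1e-6)
})

test_that("integration reproduces the linear closed form and stays put at steady state", {
  p <- kinetic_params(b = 0, g_T = 2, d_T = 0.5)
  sys <- build_chain(1, p)
  start <- system_state(R = c(R1 = p$g_R / p$d_R), T = c(T0 = 0), C = 0)
  traj <- integrate_system(sys, start, t_end = 10)
  expect_equal(trajectory_levels(traj, "T0"),
               (2 / 0.5) * (1 - exp(-0.5 * traj$times)), tolerance = 1e-6)

  p2 <- kinetic_params()
  sys2 <- build_chain(2, p2)
  ss <- steady_state(sys2)
  traj2 <- integrate_system(sys2, ss, t_end = 5)
  expect_lt(max(abs(sweep(traj2$states, 2,
                          traj2$states[1, ]))), 1e-6)
})

test_that("steady_state agrees with closed forms and ignores the start point", {
  p <- kinetic_params(g_R = 0.9, g_T = 1.4, b = 0.8, u_C = 0.3, d_C = 1.1,
                      d_R = 0.35, d_T = 0.22, alpha = 0.8)
  sys <- build_chain(1, p)
  ss <- steady_state(sys)
  ref <- pair_steady_state(p)
  expect_equal(unname(ss$R), unname(ref$R), tolerance = 1e-8)
  expect_equal(unname(ss$T), unname(ref$T), tolerance = 1e-8)

  sysc <- build_chain(100, p, boundary = "circular")
  ssc <- steady_state(sysc)
  cf <- chain_steady_state_closed_form(p)
  expect_equal(max(abs(ssc$T - cf$T)) / cf$T, 0, tolerance = 1e-6)
  expect_equal(max(abs(ssc$R - cf$R)) / cf$R, 0, tolerance = 1e-6)

  far <- system_state(
    R = stats::setNames(rep(37, length(sysc$mirnas)), sysc$mirnas),
    T = stats::setNames(rep(0.001, length(sysc$mrnas)), sysc$mrnas),
    C = rep(5, nrow(sysc$edges)))
  ss2 <- steady_state(sysc, state0 = far)
  expect_equal(unname(ss2$T), unname(ssc$T), tolerance = 1e-6)

  zsys <- build_chain(2, kinetic_params(g_R = 0, g_T = 0))
  zss <- steady_state(zsys)
  expect_equal(max(abs(unlist(zss[c("R", "T")])), abs(zss$C)), 0,
               tolerance = 1e-9)
})

test_that("chain closed form matches hand substitution and handles limits", {
  p <- kinetic_params(g_R = 1, g_T = 1, d_R = 1, d_T = 1, b = 1,
                      u_C = 0, d_C = 1, alpha = 1)
  cf <- chain_steady_state_closed_form(p)
  expect_equal(cf$T, 0.5, tolerance = 1e-12)
  expect_equal(cf$R, 0.5, tolerance = 1e-12)

  p0 <- kinetic_params(b = 0, g_R = 2, g_T = 3, d_R = 0.4, d_T = 0.5)
  cf0 <- chain_steady_state_closed_form(p0)
  expect_equal(cf0$T, 6)
  expect_equal(cf0$R, 5)

  # alpha -> 0 limit is continuous
  pa <- kinetic_params(alpha = 1e-10)
  p00 <- kinetic_params(alpha = 0)
  expect_equal(chain_steady_state_closed_form(pa)$T,
               chain_steady_state_closed_form(p00)$T, tolerance = 1e-6)
})

test_that("perturbing generation rates rescales exactly one node", {
  sys <- build_chain(3, kinetic_params())
  same <- perturb_generation_rate(sys, "T2", 1)
  expect_identical(same$g_T, sys$g_T)
  down <- perturb_generation_rate(sys, "R3", 0.9)
  expect_equal(down$g_R[["R3"]], 0.9 * sys$g_R[["R3"]])
  expect_identical(down$g_R[names(down$g_R) != "R3"],
                   sys$g_R[names(sys$g_R) != "R3"])
  ko <- perturb_generation_rate(sys, "T0", 0)
  expect_identical(ko$g_T[["T0"]], 0)
  expect_error(perturb_generation_rate(sys, "nope", 0.5), "unknown node")
})

test_that("a source depletion raises all miRNAs and lowers all other targets", {
  p <- kinetic_params()
  sys <- build_chain(15, p, boundary = "open")
  base <- steady_state(sys)
  pert <- perturb_generation_rate(sys, "T14", 0.8)
  newss <- steady_state(pert, state0 = base)
  expect_true(all(newss$R > base$R))
  others <- setdiff(names(base$T), "T14")
  expect_true(all(newss$T[others] < base$T[others]))
})

test_that("levels stay nonnegative along relaxation trajectories", {
  set.seed(42)
  for (rep in 1:3) {
    p <- random_params()
    sys <- build_chain(4, p, boundary = "circular")
    start <- system_state(
      R = stats::setNames(stats::runif(4, 0, 3), sys$mirnas),
      T = stats::setNames(stats::runif(4, 0, 3), sys$mrnas),
      C = stats::runif(nrow(sys$edges), 0, 1))
    traj <- integrate_system(sys, start, t_end = 50)
    expect_gte(min(traj$states), 0)
  }
})

test_that("response times interpolate midpoint crossings and grow with distance", {
  # pure exponential relaxation: response time = ln(2)/d
  p <- kinetic_params(b = 0, g_T = 1, d_T = 0.25)
  sys <- build_chain(1, p)
  start <- system_state(R = c(R1 = p$g_R / p$d_R), T = c(T0 = 0), C = 0)
  traj <- integrate_system(sys, start, t_end = 40,
                           times = seq(0, 40, length.out = 400))
  expect_equal(response_time(traj, "T0", 0, 4), log(2) / 0.25,
               tolerance = 1e-3)

  pd <- kinetic_params()
  N <- 30
  sys <- build_chain(N, pd, boundary = "open")
  src <- "T30"
  base <- steady_state(sys)
  pert <- perturb_generation_rate(sys, src, 0.9)
  newss <- steady_state(pert, state0 = base)
  traj <- integrate_system(pert, base, t_end = 400,
                           times = seq(0, 400, length.out = 801))
  nodes <- ifelse(30:38 %% 2 == 0, paste0("T", 30:38), paste0("R", 30:38))
  rt <- relative_response_time(traj, src, nodes, base, newss)
  expect_equal(rt$relative[1], 1)
  expect_true(all(diff(rt$relative) >= 0))
})
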