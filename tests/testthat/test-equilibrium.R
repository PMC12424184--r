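test_that("degenerate systems short-circuit to trivial/binary solutions", {
  # no ligand
  st <- solve_equilibrium(ternary_system(1e-6, 1e-6, 0, 1e-6, 1e-6, 10))
  expect_equal(st$A, 1e-6)
  expect_equal(st$B, 1e-6)
  expect_equal(st$ALB, 0)
  expect_equal(st$AL, 0)
  expect_equal(st$BL, 0)

  # nothing to bind: all ligand stays free
  st2 <- solve_equilibrium(ternary_system(0, 0, 1e-6, 1e-6, 1e-6, 10))
  expect_equal(st2$L, 1e-6)
  expect_equal(solve_free_ligand(ternary_system(0, 0, 1e-6, 1e-6, 1e-6, 1)),
               1e-6)

  # A_tot = 0 reduces to the exact binary isotherm in B and L
  K <- 5e-7; bt <- 2e-6; lt <- 1e-6
  st3 <- solve_equilibrium(ternary_system(0, bt, lt, 1e-6, K, 10))
  s <- bt + lt + K
  bl_exact <- (s - sqrt(s^2 - 4 * bt * lt)) / 2
  expect_equal(st3$BL, bl_exact, tolerance = 1e-12)
  expect_equal(st3$ALB, 0)
  expect_equal(st3$AL, 0)
  expect_equal(st3$B + st3$BL, bt, tolerance = 1e-12)
})

test_that("free-ligand solve agrees with the full mass-action oracle", {
  sys <- ternary_system(1e-6, 1e-6, 2e-6, 1e-6, 1e-6, 10)
  orc <- oracle_equilibrium(1e-6, 1e-6, 2e-6, 1e-6, 1e-6, 10)
  expect_lt(rel_err(solve_free_ligand(sys), orc$L), 1e-8)
})

test_that("equilibrium matches the brute-force oracle on random systems", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    sys <- random_system()
    st <- solve_equilibrium(sys)
    orc <- oracle_equilibrium(sys$A_tot, sys$B_tot, sys$L_tot,
                              sys$K_AL, sys$K_BL, sys$alpha)
    for (sp in c("A", "B", "L", "AL", "BL", "ALB"))
      worst <- max(worst, rel_err(st[[sp]], orc[[sp]],
                                  floor = 1e-30))
    expect_lte(st$residual_mass, 1e-8)
    expect_lte(st$residual_K, 1e-8)
  }
  expect_lt(worst, 1e-6)
})

test_that("ternary fraction is ALB over the limiting total, in [0, 1]", {
  sys <- ternary_system(1e-6, 1e-6, 2e-6, 1e-6, 1e-6, 10)
  st <- solve_equilibrium(sys)
  orc <- oracle_equilibrium(1e-6, 1e-6, 2e-6, 1e-6, 1e-6, 10)
  expect_equal(ternary_fraction(st, sys), orc$ALB / 1e-6, tolerance = 1e-8)
  expect_gte(ternary_fraction(st, sys), 0)
  expect_lte(ternary_fraction(st, sys), 1)
  expect_error(
    ternary_fraction(st, ternary_system(0, 1e-6, 1e-6, 1e-6, 1e-6, 1)),
    "undefined-fraction")
})

test_that("species concentrations are invariant under A<->B relabeling", {
  set.seed(7)
  for (i in 1:20) {
    sys <- random_system()
    st <- solve_equilibrium(sys)
    sw <- solve_equilibrium(ternary_system(sys$B_tot, sys$A_tot, sys$L_tot,
                                           sys$K_BL, sys$K_AL, sys$alpha))
    expect_equal(sw$ALB, st$ALB, tolerance = 1e-9)
    expect_equal(sw$A, st$B, tolerance = 1e-9)
    expect_equal(sw$AL, st$BL, tolerance = 1e-9)
    expect_equal(sw$L, st$L, tolerance = 1e-9)
  }
})

test_that("ALB is strictly increasing in alpha, all else fixed", {
  alphas <- c(0.1, 1, 10, 100, 1000)
  albs <- vapply(alphas, function(a)
    solve_equilibrium(ternary_system(1e-6, 2e-6, 1.5e-6, 5e-7, 2e-6, a))$ALB,
    numeric(1))
  expect_true(all(diff(albs) > 0))
})

test_that("titration reproduces single-dose solves and vanishes at extremes", {
  sys <- ternary_system(1e-6, 1e-6, 0, 2e-7, 2e-7, 10)
  curve <- titration(sys, 1e-6)
  st <- solve_equilibrium(ternary_system(1e-6, 1e-6, 1e-6, 2e-7, 2e-7, 10))
  expect_equal(curve$table$ALB, st$ALB, tolerance = 1e-10)
  expect_equal(curve$f3, ternary_fraction(
    st, ternary_system(1e-6, 1e-6, 1e-6, 2e-7, 2e-7, 10)), tolerance = 1e-10)

  wide <- titration(sys, dose_grid(1e-12, 1, 60))
  expect_true(all(curve$f3 >= 0 & curve$f3 <= 1))
  # ternary complex dissolves at both dose extremes
  expect_lt(wide$table$ALB[1] / max(wide$table$ALB), 1e-3)
  expect_lt(wide$table$ALB[60] / max(wide$table$ALB), 1e-3)
  expect_error(titration(sys, c(2e-6, 1e-6)), "strictly increasing")
})

test_that("hook: curve peaks near the closed-form dose, higher alpha helps", {
  base <- function(a) ternary_system(1e-6, 1e-6, 1e-6, 2e-7, 2e-7, a)
  grid <- dose_grid(1e-9, 1e-3, 200)
  c1 <- titration(base(1), grid)
  c100 <- titration(base(100), grid)
  # rise-and-fall of the ternary concentration around the Eq-7 dose
  ipk <- which.max(c1$table$ALB)
  expect_gt(ipk, 1)
  expect_lt(ipk, length(grid))
  expect_lt(rel_err(grid[ipk], optimal_total_ligand(base(1))), 0.05)
  # at 100x the optimal dose the cooperative system retains more ternary
  i_high <- which.min(abs(grid - 100 * optimal_total_ligand(base(1))))
  expect_gt(c100$f3[i_high], c1$f3[i_high])
})

test_that("hook severity decreases with cooperativity and is 0 when flat", {
  grid <- dose_grid(1e-9, 1e-3, 120)
  sev <- vapply(c(1, 3, 10, 30, 100), function(a)
    hook_severity(titration(ternary_system(1e-6, 1e-6, 1e-6, 2e-7, 2e-7, a),
                            grid)),
    numeric(1))
  expect_true(all(diff(sev) < 0))
  expect_gt(sev[1], sev[5])

  # flat synthetic curve => severity 0
  flat <- titration(ternary_system(1e-6, 1e-6, 1e-6, 2e-7, 2e-7, 1),
                    dose_grid(1e-9, 1e-3, 50))
  flat$table$ALB[] <- 1e-7
  flat$f3[] <- 0.1
  expect_equal(hook_severity(flat), 0)

  short <- titration(ternary_system(1e-6, 1e-6, 1e-6, 2e-7, 2e-7, 1),
                     dose_grid(5e-7, 2e-6, 10))
  expect_error(hook_severity(short), "insufficient-range")
})

test_that("closed-form optima match numeric argmax over random systems", {
  expect_equal(optimal_free_ligand(1e-6, 1e-6), 1e-6)
  expect_equal(optimal_free_ligand(4e-6, 1e-6), 2e-6)
  expect_error(optimal_free_ligand(0, 1e-6), "invalid-parameter")

  # symmetric 1 uM system: L_tot_opt = 1 + 0.5 + 0.5 uM
  sys0 <- ternary_system(1e-6, 1e-6, 0, 1e-6, 1e-6, 1)
  expect_equal(optimal_total_ligand(sys0), 2e-6)
  # alpha-independence
  lt_opts <- vapply(c(1, 10, 100), function(a)
    optimal_total_ligand(ternary_system(1e-6, 1e-6, 0, 2e-7, 8e-7, a)),
    numeric(1))
  expect_equal(lt_opts[1], lt_opts[2])
  expect_equal(lt_opts[1], lt_opts[3])

  set.seed(11)
  for (i in 1:20) {
    sys <- random_system()
    # free-ligand optimum: argmax of [ALB] over free L
    L_opt <- optimal_free_ligand(sys$K_AL, sys$K_BL)
    o <- stats::optimize(function(L) ternarycoop:::alb_at_free_ligand(sys, L),
                         lower = L_opt / 100, upper = L_opt * 100,
                         maximum = TRUE, tol = L_opt * 1e-9)
    expect_lt(rel_err(o$maximum, L_opt), 1e-6)
    # total-ligand optimum: argmax of [ALB] over L_tot
    lt_opt <- optimal_total_ligand(sys)
    o2 <- stats::optimize(function(lt)
      solve_equilibrium(ternary_system(sys$A_tot, sys$B_tot, lt,
                                       sys$K_AL, sys$K_BL, sys$alpha))$ALB,
      lower = lt_opt / 50, upper = lt_opt * 50,
      maximum = TRUE, tol = lt_opt * 1e-7)
    expect_lt(rel_err(o2$maximum, lt_opt), 1e-4)
  }
})

test_that("optimal fraction saturates, grows with alpha, equals peak f3", {
  # saturation limit
  f_sat <- optimal_fraction(ternary_system(1e-6, 1e-6, 0, 1e-6, 1e-6, 1e12))
  expect_equal(f_sat, 1, tolerance = 1e-3)
  # monotone in alpha for the symmetric 1 uM parameter set
  fs <- vapply(c(1, 10, 100), function(a)
    optimal_fraction(ternary_system(1e-6, 1e-6, 0, 1e-6, 1e-6, a)),
    numeric(1))
  expect_true(all(diff(fs) > 0))
  # agrees with f3 at the titration peak of [ALB]
  sys <- ternary_system(1e-6, 1e-6, 0, 2e-7, 8e-7, 25)
  lt_opt <- optimal_total_ligand(sys)
  curve <- titration(sys, dose_grid(lt_opt / 30, lt_opt * 30, 400))
  expect_equal(optimal_fraction(sys),
               curve$f3[which.max(curve$table$ALB)], tolerance = 1e-4)
})

test_that("response surface is symmetric in the Kd axes and rises with alpha", {
  ks <- c(1e-7, 1e-6, 1e-5)
  s1 <- response_surface(1e-6, 1e-6, ks, ks, mode = "K_K",
                         fixed = list(alpha = 10))
  expect_equal(s1, t(s1), tolerance = 1e-12)
  s2 <- response_surface(1e-6, 1e-6, ks, ks, mode = "K_K",
                         fixed = list(alpha = 100))
  expect_true(all(s2 > s1))
  # 1x1 grid equals a direct optimal_fraction call
  s3 <- response_surface(1e-6, 1e-6, 1e-6, 1e-6, mode = "K_K",
                         fixed = list(alpha = 10))
  expect_equal(as.numeric(s3),
               optimal_fraction(ternary_system(1e-6, 1e-6, 0, 1e-6, 1e-6, 10)))
  # K_alpha mode
  s4 <- response_surface(1e-6, 1e-6, ks, c(1, 10), mode = "K_alpha",
                         fixed = list(K_AL = 1e-6))
  expect_true(all(s4[, 2] > s4[, 1]))
  expect_error(response_surface(1e-6, 1e-6, ks, ks, mode = "K_K"),
               "invalid-parameter")
})

test_that("invalid system parameters are rejected", {
  expect_error(ternary_system(-1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 1),
               "invalid-parameter")
  expect_error(ternary_system(1e-6, 1e-6, 1e-6, 0, 1e-6, 1),
               "invalid-parameter")
  expect_error(ternary_system(1e-6, 1e-6, 1e-6, 1e-6, 1e-6, -2),
               "invalid-parameter")
  expect_error(ternary_system(NA, 1e-6, 1e-6, 1e-6, 1e-6, 1),
               "invalid-parameter")
  expect_error(solve_free_ligand(ternary_system(1e-6, 1e-6, 1e-6,
                                                1e-6, 1e-6, 1),
                                 rel_tol = 0.1),
               "invalid-parameter")
})
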