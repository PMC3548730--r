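# Algebraic equilibria, stability and the bifurcation sweep.

test_that("environmental equilibrium solves the published quadratic", {
  p <- default_parameters("none")
  # independent oracle: quadratic formula on hand-assembled coefficients
  a <- 1.5 * 1
  b <- 1 * 1 - 1.5 * 0.3 - 1 * (2.92 - 1)
  cc <- -1 * 0.3
  expect_equal(c(a, b, cc), c(1.5, -1.37, -0.3))
  Ce_oracle <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  E_oracle <- 1 / (1.5 * Ce_oracle + 1)

  eq <- environmental_equilibrium(p, 0)
  expect_equal(eq$values[["C_e"]], Ce_oracle, tolerance = 1e-12)
  expect_equal(eq$values[["E"]], E_oracle, tolerance = 1e-12)
  expect_equal(eq$values[["C_e"]], 1.096, tolerance = 1e-3)
  expect_equal(eq$values[["E"]], 0.378, tolerance = 1e-3)
  expect_equal(eq$stability, "asymptotically_stable")
  expect_lt(eq$residual, 1e-10)
})

test_that("environmental Jacobian eigenvalues match the characteristic polynomial", {
  p <- default_parameters("none")
  for (Fbar in c(0, 50, 100, 350)) {
    eq <- environmental_equilibrium(p, Fbar)
    cp <- environmental_char_poly(p, Fbar)
    roots <- polyroot(cp)
    expect_equal(sort(Re(eq$eigenvalues)), sort(Re(roots)), tolerance = 1e-10)
    expect_equal(sort(Im(eq$eigenvalues)), sort(Im(roots)), tolerance = 1e-10)
    # reduced-form coefficients are all positive: stability for any drug level
    expect_true(all(cp > 0))
  }
})

test_that("environmental equilibrium is monotone in the drug level", {
  p <- default_parameters("none")
  grid <- seq(0, 350, by = 1)
  eqs <- lapply(grid, function(f) environmental_equilibrium(p, f)$values)
  Ce <- vapply(eqs, `[[`, numeric(1), "C_e")
  E <- vapply(eqs, `[[`, numeric(1), "E")
  expect_true(all(diff(Ce) < 0))
  expect_true(all(diff(E) > 0))
})

test_that("elementary graft equilibrium and its stability condition", {
  p <- default_parameters("none")
  eq <- elementary_graft_equilibrium(p, 0)
  expect_equal(unname(eq$values), c(0, 0, 0.3))
  # published parameters violate the stability condition: 2*1 > 0.15*0.3
  expect_false(elementary_stability_condition(p))
  expect_equal(eq$stability, "unstable")
  # the instability is in the S direction only
  expect_equal(sort(Re(eq$eigenvalues)),
               sort(c(2 - 0.045, -0.91, -1)))

  # slow-regenerating graft: condition holds, all eigenvalues negative
  p2 <- model_parameters(k_s = 0.01)
  expect_true(elementary_stability_condition(p2))
  eq2 <- elementary_graft_equilibrium(p2, 0)
  expect_equal(eq2$stability, "asymptotically_stable")
  expect_equal(sort(Re(eq2$eigenvalues)),
               sort(c(0.01 - 0.045, -0.91, -1)))
})

test_that("graft cubic coefficients follow their closed forms", {
  p <- default_parameters("none")
  cub0 <- graft_cubic(p, 0)
  expect_equal(cub0$gamma_3, 0.02 * 0.15 * 0.7 * 7)
  expect_equal(cub0$gamma_0, 2 * 0.3 * 0.7)
  expect_gt(cub0$gamma_3, 0)
  expect_gt(cub0$gamma_0, 0)
  # only the middle coefficients depend on the drug
  cub350 <- graft_cubic(p, 350)
  expect_equal(cub350$gamma_3, cub0$gamma_3)
  expect_equal(cub350$gamma_0, cub0$gamma_0)
  expect_false(isTRUE(all.equal(cub350$gamma_2, cub0$gamma_2)))
  expect_false(isTRUE(all.equal(cub350$gamma_1, cub0$gamma_1)))
})

test_that("graft equilibrium is the unique positive triple and is stable", {
  p <- default_parameters("none")
  eq <- graft_equilibrium(p, 0)
  expect_true(all(eq$values > 0))
  expect_lt(eq$values[["S"]], p$S_star)
  expect_equal(eq$stability, "asymptotically_stable")
  expect_lt(eq$residual, 1e-8)

  # independent root oracle: bracketed scalar root search on the cubic,
  # restricted to C_l < k_s/k_xsc (where S stays positive)
  cub <- graft_cubic(p, 0)
  fcub <- function(x) ((cub$gamma_3 * x + cub$gamma_2) * x + cub$gamma_1) * x +
    cub$gamma_0
  root <- uniroot(fcub, c(1e-6, p$k_s / p$k_xsc - 1e-9), tol = 1e-12)$root
  expect_equal(eq$values[["C_l"]], root, tolerance = 1e-7)

  # a regime with no positive triple raises the structural error
  expect_error(graft_equilibrium(model_parameters(k_s = 0.01), 0),
               class = "graftsim_bifurcation_error")
})

test_that("non-regenerating subsystems settle at their trivial equilibria", {
  p <- default_parameters("none")
  nr <- nonregenerating_equilibria(p, 0)
  expect_equal(unname(nr$direct$values), c(0, 0.3))
  expect_equal(unname(nr$indirect_nonregenerating$values), c(0, 0, 0.3))
  expect_equal(nr$direct$stability, "asymptotically_stable")
  expect_equal(nr$indirect_nonregenerating$stability, "asymptotically_stable")
  expect_lt(nr$direct$residual, 1e-10)

  # long-horizon relaxation from the post-transplant impulse
  sim <- relax_sim(p, 0, t_end = 90)
  fin <- final_state(sim)
  expect_equal(unname(fin[c("U", "C_u")]), c(0, 0.3), tolerance = 1e-4)
  expect_equal(unname(fin[c("Y", "Z", "C_z")]), c(0, 0, 0.3), tolerance = 1e-4)
})

test_that("ODE relaxation agrees with the algebraic graft equilibrium", {
  p <- default_parameters("none")
  for (Fbar in c(0, 100, 350)) {
    sim <- relax_sim(p, Fbar, t_end = 90)
    eq <- graft_equilibrium(p, Fbar)
    got <- final_state(sim)[c("S", "L", "C_l")]
    expect_equal(unname(got), unname(eq$values), tolerance = 1e-3)
  }
})

test_that("relaxation agreement persists under random parameter perturbation", {
  set.seed(42)
  base <- default_parameters("none")
  perturbable <- sensitivity_parameters()
  for (i in 1:20) {
    fac <- runif(length(perturbable), 0.9, 1.1)
    over <- as.list(unlist(base[perturbable]) * fac)
    over$kappa_f <- 0  # drug level is set through F_bar below
    p <- do.call(model_parameters, over)
    Fbar <- sample(c(0, 100, 350), 1)
    eq <- tryCatch(graft_equilibrium(p, Fbar), error = function(e) NULL)
    expect_false(is.null(eq))  # regime preserved within +-10%
    sim <- relax_sim(p, Fbar, t_end = 120)
    got <- final_state(sim)[c("S", "L", "C_l")]
    # check convergence before comparing (slow modes may need longer)
    d <- model_rhs(final_state(sim), 0, p, delivery_rate = Fbar * p$k_xf)
    if (max(abs(d[c("S", "L", "C_l")])) < 1e-6) {
      expect_equal(unname(got), unname(eq$values), tolerance = 1e-3)
    }
  }
})

test_that("bifurcation sweep: S saturates upward, graft T-cells decline", {
  p <- default_parameters("none")
  grid <- seq(0, 350, by = 5)
  bs <- bifurcation_sweep(p, grid)
  expect_equal(nrow(bs), length(grid))
  expect_true(all(bs$stable))
  expect_true(all(diff(bs$S_bar) >= 0))
  expect_true(all(diff(bs$Cl_bar) <= 0))
  # saturation: increments shrink and the curve stays below carrying capacity
  expect_lt(bs$S_bar[nrow(bs)] - bs$S_bar[nrow(bs) - 1],
            bs$S_bar[2] - bs$S_bar[1])
  expect_lt(bs$S_bar[nrow(bs)], p$S_star)
  expect_gt(bs$S_bar[1], 0)
  # monotone ordering at the three published dose levels
  s <- function(f) bs$S_bar[bs$F == f]
  expect_true(s(0) < s(100) && s(100) < s(350))
  # first row consistency
  eq0 <- graft_equilibrium(p, 0)
  expect_equal(bs$S_bar[1], eq0$values[["S"]])
  expect_error(bifurcation_sweep(p, c(3, 2, 1)), class = "graftsim_config_error")
})
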