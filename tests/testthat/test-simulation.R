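# Impulsive-event simulation: transplant jumps, therapy schedules, infection.

test_that("transplant events carry the published impulse magnitudes", {
  p_mod <- default_parameters("moderate")
  ev <- transplant_events(p_mod, scenario_protocol("moderate"))[[1]]
  expect_equal(ev$time, 40)
  expect_equal(ev$increments, c(S = 1000, U = 1000, Y = 1000, F = 100))

  ev_none <- transplant_events(default_parameters("none"),
                               scenario_protocol("none"))[[1]]
  expect_false("F" %in% names(ev_none$increments))

  ev_high <- transplant_events(default_parameters("high"),
                               scenario_protocol("high"))[[1]]
  expect_equal(ev_high$increments[["F"]], 350)

  # loading dose can be disabled
  proto <- therapy_protocol("continuous", 36500, loading_dose = FALSE)
  expect_false("F" %in% names(transplant_events(p_mod, proto)[[1]]$increments))
})

test_that("delivery schedule is the expected piecewise-constant infusion", {
  p <- default_parameters("moderate")
  cont <- delivery_schedule(therapy_protocol("continuous", 36500), p)
  expect_equal(cont(c(39, 40, 41)), c(0, 0, 36500))

  interm <- delivery_schedule(therapy_protocol("intermittent", 36500, period = 1), p)
  expect_equal(interm(c(40.5, 41.5, 42.5, 43.5)), c(36500, 0, 36500, 0))

  none <- delivery_schedule(therapy_protocol("none"), p)
  expect_equal(none(c(30, 45, 60)), c(0, 0, 0))

  expect_error(therapy_protocol("intermittent", 36500, period = 0),
               class = "graftsim_config_error")
})

test_that("pre-transplant window stays at the basal immune state", {
  sim <- simulate_transplant(default_parameters("none"),
                             scenario_protocol("none"),
                             t_end = 45, output_step = 0.05)
  df <- as.data.frame(sim)
  pre <- df[df$time < 40, ]
  for (col in c("S", "L", "U", "Y", "Z", "F")) {
    expect_equal(max(abs(pre[[col]])), 0)
  }
  for (col in c("C_l", "C_u", "C_z")) {
    expect_equal(pre[[col]], rep(0.3, nrow(pre)), tolerance = 1e-8)
  }
  # summed T-cell concentration just before transplantation ~ 2e3 cells/ul
  last_pre <- pre[nrow(pre), ]
  expect_equal(last_pre$C_e + last_pre$C_l + last_pre$C_u + last_pre$C_z,
               2.0, tolerance = 0.05)
})

test_that("continuous therapy holds the drug at its closed-form steady level", {
  sim <- simulate_transplant(default_parameters("moderate"),
                             scenario_protocol("moderate"),
                             t_end = 60, output_step = 0.05)
  df <- as.data.frame(sim)
  post <- df[df$time >= 40, ]
  expect_lt(max(abs(post$F - 100)), 1e-6)
  expect_equal(max(df$F[df$time < 40]), 0)
})

test_that("without therapy the graft subsystem relaxes to its positive equilibrium", {
  sim <- simulate_transplant(default_parameters("none"),
                             scenario_protocol("none"),
                             t_end = 60, output_step = 0.1)
  eq <- graft_equilibrium(default_parameters("none"), 0)
  got <- final_state(sim)[c("S", "L", "C_l")]
  expect_equal(unname(got), unname(eq$values), tolerance = 1e-4)
})

test_that("trajectories are nonnegative in all three therapy scenarios", {
  for (sc in c("none", "moderate", "high")) {
    sim <- simulate_transplant(default_parameters(sc), scenario_protocol(sc),
                               t_end = 60, output_step = 0.1)
    expect_gte(min(sim$trajectories), 0)
  }
})

test_that("directly presented antigen is nonincreasing after the impulse", {
  sim <- simulate_transplant(default_parameters("none"),
                             scenario_protocol("none"),
                             t_end = 60, output_step = 0.05)
  U <- sim$trajectories[sim$times >= 40, "U"]
  expect_true(all(diff(U) <= 1e-9))
})

test_that("suppressing the graft impulse leaves the other blocks untouched", {
  p0 <- default_parameters("moderate")
  p1 <- p0; p1$S_tau <- 0
  proto <- scenario_protocol("moderate")
  s0 <- simulate_transplant(p0, proto, t_end = 50, output_step = 0.1)
  s1 <- simulate_transplant(p1, proto, t_end = 50, output_step = 0.1)
  outside <- setdiff(state_names(), c("S", "L", "C_l"))
  scale <- pmax(abs(s0$trajectories[, outside]), 1)
  expect_lt(max(abs(s0$trajectories[, outside] - s1$trajectories[, outside]) /
                  scale),
            1e-6)
  expect_gt(max(abs(s0$trajectories[, "S"] - s1$trajectories[, "S"])), 1)
})

test_that("trajectories are independent of the output grid resolution", {
  p <- default_parameters("moderate")
  proto <- scenario_protocol("moderate")
  s1 <- simulate_transplant(p, proto, t_end = 46, output_step = 0.1)
  s2 <- simulate_transplant(p, proto, t_end = 46, output_step = 0.05)
  common <- intersect(round(s1$times, 9), round(s2$times, 9))
  i1 <- match(common, round(s1$times, 9))
  i2 <- match(common, round(s2$times, 9))
  scale <- pmax(abs(s1$trajectories[i1, ]), 1)
  expect_lt(max(abs(s1$trajectories[i1, ] - s2$trajectories[i2, ]) / scale),
            1e-6)
})

test_that("intermittent therapy produces the expected drug square response", {
  proto <- therapy_protocol("intermittent", 36500, period = 1)
  sim <- simulate_transplant(default_parameters("moderate"), proto,
                             t_end = 46, output_step = 0.05)
  # drug equilibrates within days (k_xf = 365/year): near 100 mid-on-phase,
  # near 0 mid-off-phase
  expect_equal(trajectory_at(sim, "F", 40.5), 100, tolerance = 1e-6)
  expect_lt(trajectory_at(sim, "F", 41.5), 1e-6)
  expect_equal(trajectory_at(sim, "F", 42.5), 100, tolerance = 1e-6)
})

test_that("infection challenge: transient response, slower clearance under drug", {
  p <- default_parameters("none")
  proto_none <- scenario_protocol("none")

  # a zero-size infection changes nothing
  s_plain <- simulate_transplant(p, proto_none, t_end = 50, output_step = 0.1)
  s_zero <- infection_challenge(p, proto_none, delta_E = 0, t_end = 50,
                                output_step = 0.1)
  expect_equal(s_zero$trajectories, s_plain$trajectories, tolerance = 1e-10)

  s_inf <- infection_challenge(p, proto_none, t_infection = 42, delta_E = 10,
                               t_end = 50, output_step = 0.02)
  # T-cells rise above their pre-infection level
  ce_pre <- trajectory_at(s_inf, "C_e", 41.9)
  expect_gt(max(s_inf$trajectories[s_inf$times > 42, "C_e"]), ce_pre * 1.2)

  # recovery of E to within 5% of its pre-infection level is slower under
  # high-dose therapy
  recovery_time <- function(sim) {
    base <- trajectory_at(sim, "E", 41.9)
    tt <- sim$times[sim$times > 42]
    E <- sim$trajectories[sim$times > 42, "E"]
    idx <- which(abs(E - base) / base < 0.05)[1]
    if (is.na(idx)) Inf else tt[idx] - 42
  }
  p_high <- default_parameters("high")
  s_high <- infection_challenge(p_high, scenario_protocol("high"),
                                t_infection = 42, delta_E = 10,
                                t_end = 50, output_step = 0.02)
  expect_lt(recovery_time(s_inf), recovery_time(s_high))

  expect_error(infection_challenge(p, proto_none, delta_E = -1),
               class = "graftsim_domain_error")
  expect_error(infection_challenge(p, proto_none, t_infection = 39),
               class = "graftsim_config_error")
})
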