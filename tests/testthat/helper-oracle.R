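# Shared helpers: independent oracles and small utilities.

# Term-by-term transcription of the model equations, written independently of
# model_rhs() (explicit arithmetic per component, no shared code path).
oracle_rhs <- function(st, p, kf = 0) {
  kcac <- p$k_cacF * exp(-p$lambda * st[["F"]])
  c(E   = p$k_e - p$k_xec * st[["C_e"]] * st[["E"]] - p$k_xe * st[["E"]],
    S   = p$k_s * st[["S"]] * (1 - st[["S"]] / p$S_star) -
          p$k_xsc * st[["C_l"]] * st[["S"]],
    L   = p$k_ls * st[["S"]] - p$k_xlc * st[["C_l"]] * st[["L"]] -
          p$k_xl * st[["L"]],
    U   = -p$k_xuc * st[["C_u"]] * st[["U"]] - p$k_xu * st[["U"]],
    Y   = -p$k_xyc * st[["C_z"]] * st[["Y"]] - p$k_xy * st[["Y"]],
    Z   = p$k_zy * st[["Y"]] - p$k_xzc * st[["C_z"]] * st[["Z"]] -
          p$k_xz * st[["Z"]],
    C_e = p$k_c + kcac * st[["C_e"]] * st[["E"]] -
          p$k_xce * st[["E"]] * st[["C_e"]] - p$k_xc * st[["C_e"]],
    C_l = p$k_c + kcac * st[["C_l"]] * st[["L"]] -
          p$k_xcs * st[["S"]] * st[["C_l"]] -
          p$k_xcl * st[["L"]] * st[["C_l"]] - p$k_xc * st[["C_l"]],
    C_u = p$k_c + kcac * st[["C_u"]] * st[["U"]] -
          p$k_xcu * st[["U"]] * st[["C_u"]] - p$k_xc * st[["C_u"]],
    C_z = p$k_c + kcac * st[["C_z"]] * st[["Z"]] -
          p$k_xcy * st[["Y"]] * st[["C_z"]] -
          p$k_xcz * st[["Z"]] * st[["C_z"]] - p$k_xc * st[["C_z"]],
    F   = kf - p$k_xf * st[["F"]])
}

make_state <- function(...) {
  st <- setNames(numeric(11), state_names())
  over <- c(...)
  st[names(over)] <- over
  st
}

# Relax the full system to equilibrium under a constant drug level F_bar
# (delivery rate chosen so that the steady drug level equals F_bar).
relax_sim <- function(params, F_bar, t_end = 90, output_step = 0.5, ...) {
  p <- params
  p$kappa_f <- F_bar * p$k_xf
  proto <- if (F_bar > 0) {
    therapy_protocol("continuous", kappa_f = p$kappa_f)
  } else {
    therapy_protocol("none")
  }
  simulate_transplant(p, proto, t_end = t_end, output_step = output_step, ...)
}

final_state <- function(sim) {
  setNames(as.numeric(sim$trajectories[nrow(sim$trajectories), ]),
           colnames(sim$trajectories))
}
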