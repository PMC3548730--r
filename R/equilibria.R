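# Algebraic equilibria and local stability of the four decoupled subsystems,
# at a fixed post-transplant drug level F_bar.
#
# - environmental (E, C_e): C_e* solves a quadratic whose second-order
#   coefficient is positive and zero-order negative, so exactly one positive
#   root exists for any positive parameters; always locally stable.
# - graft (S, L, C_l): besides the elementary rejection endpoint
#   (0, 0, k_c/k_xc), the positive equilibria solve a cubic in C_l with S and
#   L recovered by back-substitution; in the published parameter regime there
#   is exactly one positive triple and it is locally asymptotically stable for
#   every F in the therapeutic range.
# - direct (U, C_u) and indirect non-regenerating (Y, Z, C_z): trivial
#   equilibria with all antigen cleared and T-cells at k_c/k_xc.

.stability_tol <- 1e-9

classify_stability <- function(eigenvalues) {
  m <- max(Re(eigenvalues))
  if (m < -.stability_tol) "asymptotically_stable"
  else if (m > .stability_tol) "unstable"
  else "marginal"
}

new_equilibrium_point <- function(subsystem, values, drug_level, eigenvalues,
                                  residual) {
  structure(list(subsystem = subsystem,
                 values = values,
                 drug_level = drug_level,
                 eigenvalues = eigenvalues,
                 stability = classify_stability(eigenvalues),
                 residual = residual),
            class = "equilibrium_point")
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat("Equilibrium (", x$subsystem, " subsystem) at F = ", x$drug_level,
      " ng/ml: ", x$stability, "\n", sep = "")
  print(x$values)
  cat("max Re(eigenvalue):", max(Re(x$eigenvalues)), "\n")
  invisible(x)
}

# Subsystem right-hand sides used for residual checks (the smooth system with
# the drug held at F_bar); each mirrors the corresponding block of model_rhs.
.subsystem_rhs <- function(subsystem, values, params, F_bar) {
  kcac <- drug_effect(F_bar, params)
  p <- params
  switch(subsystem,
    environmental = {
      E <- values[["E"]]; C_e <- values[["C_e"]]
      c(p$k_e - p$k_xec * C_e * E - p$k_xe * E,
        p$k_c + kcac * C_e * E - p$k_xce * E * C_e - p$k_xc * C_e)
    },
    graft = {
      S <- values[["S"]]; L <- values[["L"]]; C_l <- values[["C_l"]]
      c(p$k_s * S * (1 - S / p$S_star) - p$k_xsc * C_l * S,
        p$k_ls * S - p$k_xlc * C_l * L - p$k_xl * L,
        p$k_c + kcac * C_l * L - p$k_xcs * S * C_l - p$k_xcl * L * C_l - p$k_xc * C_l)
    },
    direct = {
      U <- values[["U"]]; C_u <- values[["C_u"]]
      c(-p$k_xuc * C_u * U - p$k_xu * U,
        p$k_c + kcac * C_u * U - p$k_xcu * U * C_u - p$k_xc * C_u)
    },
    indirect_nonregenerating = {
      Y <- values[["Y"]]; Z <- values[["Z"]]; C_z <- values[["C_z"]]
      c(-p$k_xyc * C_z * Y - p$k_xy * Y,
        p$k_zy * Y - p$k_xzc * C_z * Z - p$k_xz * Z,
        p$k_c + kcac * C_z * Z - p$k_xcy * Y * C_z - p$k_xcz * Z * C_z - p$k_xc * C_z)
    },
    stop_config(paste0("unknown subsystem: ", subsystem)))
}

#' Equilibrium of the environmental antigen subsystem
#'
#' Solves the steady state of the (E, C_e) block at drug level `F_bar`.
#' The T-cell steady state is the unique positive root of the quadratic
#' `k_xec*k_xc*C^2 + (k_xe*k_xc - k_xec*k_c - k_e*(k_cac(F) - k_xce))*C -
#' k_xe*k_c = 0`, and `E = k_e / (k_xec*C_e + k_xe)`. Because the quadratic's
#' leading coefficient is positive and its constant term negative, the
#' positive root always exists; the Jacobian has characteristic polynomial
#' with all-positive coefficients, so the point is always locally
#' asymptotically stable. Increasing the drug lowers C_e* and raises E*.
#'
#' @param params A [model_parameters()] object.
#' @param F_bar Constant drug level, ng/ml.
#' @return An `equilibrium_point` (components `E`, `C_e`).
#' @export
environmental_equilibrium <- function(params, F_bar = 0) {
  if (!is.finite(F_bar) || F_bar < 0) stop_domain("F_bar must be >= 0")
  p <- params
  kcac <- drug_effect(F_bar, p)
  a <- p$k_xec * p$k_xc
  b <- p$k_xe * p$k_xc - p$k_xec * p$k_c - p$k_e * (kcac - p$k_xce)
  c0 <- -p$k_xe * p$k_c
  disc <- b^2 - 4 * a * c0
  stopifnot(disc >= 0)  # guaranteed: c0 < 0 for positive parameters
  C_e <- (-b + sqrt(disc)) / (2 * a)
  stopifnot(C_e > 0)
  E <- p$k_e / (p$k_xec * C_e + p$k_xe)
  J <- matrix(c(-p$k_xec * C_e - p$k_xe, -p$k_xec * E,
                (kcac - p$k_xce) * C_e, (kcac - p$k_xce) * E - p$k_xc),
              nrow = 2, byrow = TRUE)
  values <- c(E = E, C_e = C_e)
  res <- .subsystem_rhs("environmental", values, p, F_bar)
  new_equilibrium_point("environmental", values, F_bar,
                        eigen(J, only.values = TRUE)$values, max(abs(res)))
}

#' Characteristic polynomial of the environmental Jacobian
#'
#' Coefficients (constant, linear, quadratic) of the characteristic
#' polynomial at the environmental equilibrium, in the reduced all-positive
#' form obtained by using the equilibrium relations. Used as an independent
#' cross-check of the Jacobian eigenvalues.
#'
#' @inheritParams environmental_equilibrium
#' @return Numeric vector `c(c0, c1, c2)` with `c2 = 1`.
#' @export
environmental_char_poly <- function(params, F_bar = 0) {
  eq <- environmental_equilibrium(params, F_bar)
  C_e <- eq$values[["C_e"]]
  p <- params
  c(p$k_xe * p$k_c / C_e + p$k_xc * p$k_xec * C_e,
    p$k_xec * C_e + p$k_xe + p$k_c / C_e,
    1)
}

#' Elementary (rejection) equilibrium of the graft subsystem
#'
#' The rejection endpoint (S = 0, L = 0, C_l = k_c/k_xc): all graft antigen
#' eliminated, T-cells at their basal level. The Jacobian there is triangular
#' with eigenvalues `k_s - k_xsc*k_c/k_xc`, `-k_xlc*k_c/k_xc - k_xl`, `-k_xc`;
#' the point is locally asymptotically stable iff `k_s*k_xc < k_xsc*k_c`
#' (see [elementary_stability_condition()]). For the published parameters the
#' condition fails, so the graft can persist at the positive equilibrium.
#'
#' @inheritParams environmental_equilibrium
#' @return An `equilibrium_point` (components `S`, `L`, `C_l`).
#' @export
elementary_graft_equilibrium <- function(params, F_bar = 0) {
  if (!is.finite(F_bar) || F_bar < 0) stop_domain("F_bar must be >= 0")
  p <- params
  Cl <- p$k_c / p$k_xc
  values <- c(S = 0, L = 0, C_l = Cl)
  eig <- c(p$k_s - p$k_xsc * Cl, -p$k_xlc * Cl - p$k_xl, -p$k_xc)
  res <- .subsystem_rhs("graft", values, p, F_bar)
  new_equilibrium_point("graft", values, F_bar, as.complex(eig), max(abs(res)))
}

#' Stability condition for the elementary graft equilibrium
#'
#' `TRUE` iff `k_s * k_xc < k_xsc * k_c`, the condition under which the
#' rejection endpoint (S = 0, L = 0, C_l = k_c/k_xc) is locally
#' asymptotically stable.
#'
#' @param params A [model_parameters()] object.
#' @return Logical scalar.
#' @examples
#' elementary_stability_condition(default_parameters("none"))  # FALSE: 2 > 0.045
#' @export
elementary_stability_condition <- function(params) {
  params$k_s * params$k_xc < params$k_xsc * params$k_c
}

#' Coefficients of the graft equilibrium cubic
#'
#' The positive equilibria of the (S, L, C_l) subsystem satisfy
#' `g3*C^3 + g2*C^2 + g1*C + g0 = 0` in `C = C_l`, with
#' `S = S_star*(k_s - k_xsc*C)/k_s` and `L = k_ls*S/(k_xl + k_xlc*C)`.
#' `g3` and `g0` are positive and drug-independent; only `g2` and `g1`
#' depend on `F` through the clonal-expansion coefficient.
#'
#' @inheritParams environmental_equilibrium
#' @return A `graft_cubic` object: list with `gamma_3`..`gamma_0`.
#' @export
graft_cubic <- function(params, F_bar = 0) {
  if (!is.finite(F_bar) || F_bar < 0) stop_domain("F_bar must be >= 0")
  p <- params
  a <- drug_effect(F_bar, p) - p$k_xcl  # net expansion coefficient on L contact
  g3 <- p$k_xcs * p$k_xsc * p$k_xlc * p$S_star
  g2 <- p$k_xsc * p$k_xl * p$k_xcs * p$S_star -
    p$k_ls * p$k_xsc * p$S_star * a -
    p$k_xcs * p$k_s * p$k_xlc * p$S_star -
    p$k_xc * p$k_s * p$k_xlc
  g1 <- p$k_s * p$k_c * p$k_xlc +
    p$k_ls * p$k_s * p$S_star * a -
    p$k_xcs * p$k_s * p$k_xl * p$S_star -
    p$k_xc * p$k_s * p$k_xl
  g0 <- p$k_s * p$k_c * p$k_xl
  structure(list(gamma_3 = g3, gamma_2 = g2, gamma_1 = g1, gamma_0 = g0),
            class = "graft_cubic")
}

#' @export
print.graft_cubic <- function(x, ...) {
  cat("Graft equilibrium cubic: ",
      x$gamma_3, "C^3 + ", x$gamma_2, "C^2 + ", x$gamma_1, "C + ", x$gamma_0,
      " = 0\n", sep = "")
  invisible(x)
}

# Jacobian of the graft subsystem at a point, with the drug held at F_bar.
.graft_jacobian <- function(values, params, F_bar) {
  p <- params
  kcac <- drug_effect(F_bar, p)
  S <- values[["S"]]; L <- values[["L"]]; C_l <- values[["C_l"]]
  matrix(c(
    p$k_s - 2 * p$k_s * S / p$S_star - p$k_xsc * C_l, 0, -p$k_xsc * S,
    p$k_ls, -p$k_xlc * C_l - p$k_xl, -p$k_xlc * L,
    -p$k_xcs * C_l, (kcac - p$k_xcl) * C_l,
    (kcac - p$k_xcl) * L - p$k_xcs * S - p$k_xc
  ), nrow = 3, byrow = TRUE)
}

#' Positive equilibrium of the graft subsystem
#'
#' Finds all roots of the equilibrium cubic ([graft_cubic()]),
#' back-substitutes each real root into the expressions for S and L, and
#' keeps the triples with all three components positive. In the published
#' parameter regime exactly one such triple exists for every drug level in
#' the therapeutic range; its S component measures the surviving graft tissue.
#' If zero or several positive triples are found the bifurcation structure
#' differs from that regime and an error of class
#' `graftsim_bifurcation_error` is raised (a signal, not a bug).
#'
#' @inheritParams environmental_equilibrium
#' @return An `equilibrium_point` (components `S`, `L`, `C_l`) classified by
#'   the eigenvalues of the full 3x3 Jacobian.
#' @export
graft_equilibrium <- function(params, F_bar = 0) {
  cub <- graft_cubic(params, F_bar)
  p <- params
  roots <- polyroot(c(cub$gamma_0, cub$gamma_1, cub$gamma_2, cub$gamma_3))
  real <- Re(roots[abs(Im(roots)) < 1e-9 * pmax(1, abs(Re(roots)))])
  triples <- list()
  for (C_l in real[real > 1e-12]) {
    S <- p$S_star * (p$k_s - p$k_xsc * C_l) / p$k_s
    L <- p$k_ls * S / (p$k_xl + p$k_xlc * C_l)
    if (S > 1e-12 && L > 1e-12) {
      triples[[length(triples) + 1]] <- c(S = S, L = L, C_l = C_l)
    }
  }
  if (length(triples) != 1) {
    stop(errorCondition(
      paste0("bifurcation structure changed: ", length(triples),
             " positive graft equilibria at F_bar = ", F_bar,
             " (expected exactly 1)"),
      class = c("graftsim_bifurcation_error", "error", "condition")))
  }
  values <- triples[[1]]
  J <- .graft_jacobian(values, p, F_bar)
  res <- .subsystem_rhs("graft", values, p, F_bar)
  new_equilibrium_point("graft", values, F_bar,
                        eigen(J, only.values = TRUE)$values, max(abs(res)))
}

#' Trivial equilibria of the non-regenerating antigen subsystems
#'
#' The directly presented antigen subsystem settles at (U = 0,
#' C_u = k_c/k_xc) and the indirectly presented non-regenerating subsystem at
#' (Y = 0, Z = 0, C_z = k_c/k_xc): both antigen pools are cleared completely
#' because nothing regenerates them. Both points are locally asymptotically
#' stable for any nonnegative drug level (their Jacobians are triangular with
#' negative diagonal).
#'
#' @inheritParams environmental_equilibrium
#' @return Named list of two `equilibrium_point`s: `direct` and
#'   `indirect_nonregenerating`.
#' @export
nonregenerating_equilibria <- function(params, F_bar = 0) {
  if (!is.finite(F_bar) || F_bar < 0) stop_domain("F_bar must be >= 0")
  p <- params
  Cbar <- p$k_c / p$k_xc

  u_vals <- c(U = 0, C_u = Cbar)
  u_eig <- c(-p$k_xuc * Cbar - p$k_xu, -p$k_xc)
  u_res <- .subsystem_rhs("direct", u_vals, p, F_bar)

  yz_vals <- c(Y = 0, Z = 0, C_z = Cbar)
  yz_eig <- c(-p$k_xyc * Cbar - p$k_xy, -p$k_xzc * Cbar - p$k_xz, -p$k_xc)
  yz_res <- .subsystem_rhs("indirect_nonregenerating", yz_vals, p, F_bar)

  list(direct = new_equilibrium_point("direct", u_vals, F_bar,
                                      as.complex(u_eig), max(abs(u_res))),
       indirect_nonregenerating = new_equilibrium_point(
         "indirect_nonregenerating", yz_vals, F_bar,
         as.complex(yz_eig), max(abs(yz_res))))
}

#' Bifurcation sweep of the graft equilibrium over drug level
#'
#' Evaluates [graft_equilibrium()] on a grid of drug concentrations. With
#' increasing drug the surviving graft antigen S rises along a saturation
#' curve toward the carrying capacity while the graft-specific T-cell level
#' falls.
#'
#' @param params A [model_parameters()] object.
#' @param F_grid Increasing nonnegative drug levels, ng/ml (default 0..350,
#'   step 1, the therapeutic range).
#' @return Data frame with columns `F`, `S_bar`, `L_bar`, `Cl_bar`,
#'   `max_re_eig`, `stable`.
#' @export
bifurcation_sweep <- function(params, F_grid = seq(0, 350, by = 1)) {
  if (any(!is.finite(F_grid)) || any(F_grid < 0) || is.unsorted(F_grid, strictly = TRUE)) {
    stop_config("F_grid must be nonnegative and strictly increasing")
  }
  rows <- lapply(F_grid, function(Fb) {
    eq <- graft_equilibrium(params, Fb)
    data.frame(F = Fb,
               S_bar = eq$values[["S"]],
               L_bar = eq$values[["L"]],
               Cl_bar = eq$values[["C_l"]],
               max_re_eig = max(Re(eq$eigenvalues)),
               stable = eq$stability == "asymptotically_stable")
  })
  do.call(rbind, rows)
}
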