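#' Define a ternary protein--ligand--protein system
#'
#' A ternary system consists of two proteins `A` and `B` and a dual-binding
#' ligand `L` (a molecular glue, PPI stabilizer or bifunctional degrader).
#' Species `A`, `B`, `L`, `AL`, `BL` and `ALB` interconvert under mass action
#' with binary dissociation constants \eqn{K_{A-L}}, \eqn{K_{B-L}} and a
#' dimensionless cooperativity \eqn{\alpha}, defined so that the effective
#' ternary dissociation constant is
#' \deqn{K_3 = \frac{[A][L][B]}{[ALB]} = \alpha^{-1} K_{A-L} K_{B-L}.}
#' \eqn{\alpha > 1} means the second protein facilitates ligand binding
#' (positive cooperativity), \eqn{\alpha < 1} impedes it. No direct A--B
#' binary species is modelled: the proteins are assumed non-interacting in
#' the equilibrium network.
#'
#' @param A_tot,B_tot,L_tot total concentrations in molar (>= 0).
#' @param K_AL,K_BL binary dissociation constants in molar (> 0).
#' @param alpha dimensionless cooperativity (> 0).
#' @return An object of class `ternary_system`.
#' @examples
#' sys <- ternary_system(A_tot = 1e-6, B_tot = 1e-6, L_tot = 2e-6,
#'                       K_AL = 1e-6, K_BL = 1e-6, alpha = 10)
#' solve_equilibrium(sys)
#' @export
ternary_system <- function(A_tot, B_tot, L_tot, K_AL, K_BL, alpha = 1) {
  vals <- c(A_tot = A_tot, B_tot = B_tot, L_tot = L_tot,
            K_AL = K_AL, K_BL = K_BL, alpha = alpha)
  if (!all(is.finite(vals)))
    stop("invalid-parameter: all system parameters must be finite numbers")
  if (A_tot < 0 || B_tot < 0 || L_tot < 0)
    stop("invalid-parameter: total concentrations must be non-negative")
  if (K_AL <= 0 || K_BL <= 0)
    stop("invalid-parameter: dissociation constants must be strictly positive")
  if (alpha <= 0)
    stop("invalid-parameter: cooperativity alpha must be strictly positive")
  structure(list(A_tot = A_tot, B_tot = B_tot, L_tot = L_tot,
                 K_AL = K_AL, K_BL = K_BL, alpha = alpha),
            class = "ternary_system")
}

#' @export
print.ternary_system <- function(x, ...) {
  cat("Ternary complex system (mass-action equilibrium)\n")
  cat(sprintf("  totals [M]:  A_tot = %.6g  B_tot = %.6g  L_tot = %.6g\n",
              x$A_tot, x$B_tot, x$L_tot))
  cat(sprintf("  Kd [M]:      K_AL = %.6g  K_BL = %.6g\n", x$K_AL, x$K_BL))
  cat(sprintf("  cooperativity alpha = %.6g\n", x$alpha))
  invisible(x)
}

## [ALB] at a given free-ligand concentration L, from the quadratic
## [ALB] = (C - sqrt(C^2 - 4 A_tot B_tot)) / 2 with
## C = A_tot + B_tot + (L + K_AL)(L + K_BL) / (alpha L).
## C >= A_tot + B_tot >= 2 sqrt(A_tot B_tot) so the discriminant is
## non-negative up to rounding; tiny negative values are clipped.
alb_at_free_ligand <- function(system, L) {
  if (L <= 0 || system$A_tot <= 0 || system$B_tot <= 0) return(0)
  C <- system$A_tot + system$B_tot +
    (L + system$K_AL) * (L + system$K_BL) / (system$alpha * L)
  disc <- C^2 - 4 * system$A_tot * system$B_tot
  if (disc < 0) {
    if (disc > -1e-12 * C^2) disc <- 0
    else stop("internal-consistency: negative discriminant in ternary quadratic")
  }
  ## (C - sqrt(disc))/2 loses precision when 4ab << C^2; the conjugate form
  ## 2ab / (C + sqrt(disc)) is stable in that regime.
  2 * system$A_tot * system$B_tot / (C + sqrt(disc))
}

## Total ligand implied by a free-ligand concentration L (ligand mass balance)
ltot_at_free_ligand <- function(system, L) {
  ALB <- alb_at_free_ligand(system, L)
  fA <- L / (L + system$K_AL)
  fB <- L / (L + system$K_BL)
  L + fA * system$A_tot + fB * system$B_tot + (1 - fA - fB) * ALB
}

#' Solve for the free-ligand concentration
#'
#' Finds the free monomeric ligand concentration `[L]` whose implied total
#' (free ligand plus ligand bound in `AL`, `BL` and `ALB`) reproduces
#' `L_tot`. The implied total is continuous in `[L]`, zero at `[L] = 0` and
#' at least `[L]` itself, so the root is bracketed on `[0, L_tot]`; a
#' safeguarded Brent solve (in log space when the dynamic range
#' `L_tot / min(K)` exceeds 1e3) locates it.
#'
#' @param system a [ternary_system()].
#' @param rel_tol relative tolerance on the ligand mass balance (default
#'   1e-10; must lie in (0, 1e-3]).
#' @return Free ligand concentration in molar, in `[0, L_tot]`.
#' @export
solve_free_ligand <- function(system, rel_tol = 1e-10) {
  stopifnot(inherits(system, "ternary_system"))
  if (!is.finite(rel_tol) || rel_tol <= 0 || rel_tol > 1e-3)
    stop("invalid-parameter: rel_tol must lie in (0, 1e-3]")
  L_tot <- system$L_tot
  if (L_tot == 0) return(0)
  if (system$A_tot == 0 && system$B_tot == 0) return(L_tot)

  f <- function(L) ltot_at_free_ligand(system, L) - L_tot
  f_upper <- f(L_tot)
  if (f_upper < 0)
    stop("solver-failure: ligand mass balance not bracketed on [0, L_tot] ",
         sprintf("(f(L_tot) = %.3g)", f_upper))
  if (f_upper == 0) return(L_tot)

  scale <- max(L_tot, .Machine$double.xmin)
  wide_range <- L_tot / min(system$K_AL, system$K_BL) > 1e3
  ## safeguarded bisection to machine precision; log-space when the dose
  ## spans many decades of the binding transitions
  if (wide_range) {
    lo <- log(L_tot) - log(1e18); hi <- log(L_tot)
    for (i in 1:90) {
      mid <- (lo + hi) / 2
      if (f(exp(mid)) < 0) lo <- mid else hi <- mid
    }
    L <- exp((lo + hi) / 2)
  } else {
    lo <- 0; hi <- L_tot
    for (i in 1:110) {
      mid <- (lo + hi) / 2
      if (mid == lo || mid == hi) break
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    L <- (lo + hi) / 2
  }
  ## The achievable residual is bounded below by rounding of the mass
  ## balance itself; accept the larger of the requested tolerance and
  ## that floor.
  fA <- L / (L + system$K_AL); fB <- L / (L + system$K_BL)
  floor_abs <- 64 * .Machine$double.eps *
    (L + fA * system$A_tot + fB * system$B_tot +
       abs(1 - fA - fB) * alb_at_free_ligand(system, L) + L_tot)
  if (abs(f(L)) > max(rel_tol * scale, floor_abs))
    stop(sprintf(
      "solver-failure: ligand mass balance residual %.3g exceeds tolerance %.3g",
      abs(f(L)), max(rel_tol * scale, floor_abs)))
  L
}

#' Solve the full ternary mass-action equilibrium
#'
#' Computes all six species concentrations. The ternary concentration
#' follows the closed-form quadratic in the free ligand, and the remaining
#' species follow from the conservation laws:
#' `A = (A_tot - ALB) / (1 + L/K_AL)`, `AL = A L / K_AL`, and symmetrically
#' for `B`. Degenerate systems (any total equal to zero) reduce to the
#' corresponding binary isotherm or trivial solution without invoking the
#' root solver.
#'
#' @param system a [ternary_system()].
#' @param rel_tol relative tolerance passed to [solve_free_ligand()].
#' @return An object of class `equilibrium_state`: a list with species
#'   concentrations `A`, `B`, `L`, `AL`, `BL`, `ALB` (molar) and diagnostics
#'   `residual_mass`, `residual_K` (maximum relative violation of the
#'   conservation laws and of the three equilibrium relations).
#' @export
solve_equilibrium <- function(system, rel_tol = 1e-10) {
  stopifnot(inherits(system, "ternary_system"))
  with(system, {
    if (L_tot == 0) {
      return(new_equilibrium_state(A_tot, B_tot, 0, 0, 0, 0, system))
    }
    if (A_tot == 0 && B_tot == 0) {
      return(new_equilibrium_state(0, 0, L_tot, 0, 0, 0, system))
    }
    if (A_tot == 0) {
      bl <- binary_bound(B_tot, L_tot, K_BL)
      return(new_equilibrium_state(0, B_tot - bl, L_tot - bl, 0, bl, 0, system))
    }
    if (B_tot == 0) {
      al <- binary_bound(A_tot, L_tot, K_AL)
      return(new_equilibrium_state(A_tot - al, 0, L_tot - al, al, 0, 0, system))
    }
    L <- solve_free_ligand(system, rel_tol)
    ALB <- alb_at_free_ligand(system, L)
    A <- (A_tot - ALB) / (1 + L / K_AL)
    B <- (B_tot - ALB) / (1 + L / K_BL)
    new_equilibrium_state(A, B, L, A * L / K_AL, B * L / K_BL, ALB, system)
  })
}

## exact bound concentration for a binary P + L <-> PL isotherm
binary_bound <- function(P_tot, L_tot, K) {
  s <- P_tot + L_tot + K
  ## conjugate form, stable when the bound fraction is small
  2 * P_tot * L_tot / (s + sqrt(s^2 - 4 * P_tot * L_tot))
}

new_equilibrium_state <- function(A, B, L, AL, BL, ALB, system) {
  conc <- c(A = A, B = B, L = L, AL = AL, BL = BL, ALB = ALB)
  conc[conc < 0 & conc > -1e-12 * max(system$A_tot, system$B_tot, system$L_tot)] <- 0
  if (any(conc < 0))
    stop("internal-consistency: negative species concentration")
  sc <- max(system$A_tot, system$B_tot, system$L_tot, .Machine$double.xmin)
  res_mass <- max(
    abs(conc["A"] + conc["AL"] + conc["ALB"] - system$A_tot),
    abs(conc["B"] + conc["BL"] + conc["ALB"] - system$B_tot),
    abs(conc["L"] + conc["AL"] + conc["BL"] + conc["ALB"] - system$L_tot)) / sc
  rel_k <- function(lhs, rhs) {
    d <- max(abs(lhs), abs(rhs))
    if (d == 0) 0 else abs(lhs - rhs) / d
  }
  res_k <- max(
    rel_k(conc["AL"] * system$K_AL, conc["A"] * conc["L"]),
    rel_k(conc["BL"] * system$K_BL, conc["B"] * conc["L"]),
    rel_k(conc["ALB"] * system$K_AL * system$K_BL,
          system$alpha * conc["A"] * conc["B"] * conc["L"]))
  structure(c(as.list(conc),
              list(residual_mass = unname(res_mass),
                   residual_K = unname(res_k))),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Ternary equilibrium state [M]\n")
  for (s in c("A", "B", "L", "AL", "BL", "ALB"))
    cat(sprintf("  %-4s %.10g\n", s, x[[s]]))
  cat(sprintf("  residual_mass = %.3g, residual_K = %.3g\n",
              x$residual_mass, x$residual_K))
  invisible(x)
}

#' Fraction of ternary-complex formation
#'
#' \eqn{f_3 = [ALB] / \min([A_{tot}], [B_{tot}], [L_{tot}])}: the fraction of
#' the limiting species sequestered in the ternary complex, bounded by 1.
#'
#' @param state an `equilibrium_state` from [solve_equilibrium()].
#' @param system the [ternary_system()] that produced it.
#' @return Dimensionless fraction in `[0, 1]`.
#' @export
ternary_fraction <- function(state, system) {
  stopifnot(inherits(state, "equilibrium_state"),
            inherits(system, "ternary_system"))
  m <- min(system$A_tot, system$B_tot, system$L_tot)
  if (m <= 0)
    stop("undefined-fraction: a limiting total concentration is zero")
  min(state$ALB / m, 1)
}

#' Titrate total ligand against a ternary system
#'
#' Solves the equilibrium across a grid of total ligand concentrations and
#' reports the ternary fraction at each dose. The characteristic rise and
#' fall of `f3` with increasing dose (the hook or prozone effect) arises
#' from binary `AL`/`BL` species outcompeting the ternary complex at high
#' ligand excess.
#'
#' @param system_base a [ternary_system()]; its `L_tot` is ignored.
#' @param L_tot_grid strictly increasing, positive vector of total ligand
#'   concentrations (molar).
#' @return An object of class `titration_curve`: list with `L_tot_grid`,
#'   `states` (list of `equilibrium_state`), `f3`, and a `table` data frame
#'   with columns `L_tot, L, A, B, AL, BL, ALB, f3`.
#' @export
titration <- function(system_base, L_tot_grid) {
  stopifnot(inherits(system_base, "ternary_system"))
  if (length(L_tot_grid) < 1 || any(!is.finite(L_tot_grid)) ||
      any(L_tot_grid <= 0) || is.unsorted(L_tot_grid, strictly = TRUE))
    stop("invalid-parameter: L_tot_grid must be strictly increasing and positive")
  states <- vector("list", length(L_tot_grid))
  f3 <- numeric(length(L_tot_grid))
  for (i in seq_along(L_tot_grid)) {
    sys_i <- ternary_system(system_base$A_tot, system_base$B_tot,
                            L_tot_grid[i], system_base$K_AL,
                            system_base$K_BL, system_base$alpha)
    st <- tryCatch(solve_equilibrium(sys_i),
                   error = function(e) stop(sprintf(
                     "titration failed at L_tot = %.6g M: %s",
                     L_tot_grid[i], conditionMessage(e))))
    states[[i]] <- st
    f3[i] <- ternary_fraction(st, sys_i)
  }
  tab <- data.frame(
    L_tot = L_tot_grid,
    L = vapply(states, `[[`, numeric(1), "L"),
    A = vapply(states, `[[`, numeric(1), "A"),
    B = vapply(states, `[[`, numeric(1), "B"),
    AL = vapply(states, `[[`, numeric(1), "AL"),
    BL = vapply(states, `[[`, numeric(1), "BL"),
    ALB = vapply(states, `[[`, numeric(1), "ALB"),
    f3 = f3)
  structure(list(L_tot_grid = L_tot_grid, states = states, f3 = f3,
                 system = system_base, table = tab),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve: %d doses, L_tot %.3g-%.3g M, peak f3 = %.4g\n",
              length(x$L_tot_grid), min(x$L_tot_grid), max(x$L_tot_grid),
              max(x$f3)))
  invisible(x)
}

#' Optimal free-ligand concentration
#'
#' The free ligand concentration maximising `[ALB]` is the geometric mean
#' of the two binary dissociation constants,
#' \eqn{[L]^{opt} = \sqrt{K_{A-L} K_{B-L}}}, independent of cooperativity
#' and of the protein totals.
#'
#' @param K_AL,K_BL binary dissociation constants (molar, > 0).
#' @return Optimal free-ligand concentration in molar.
#' @export
optimal_free_ligand <- function(K_AL, K_BL) {
  if (!is.finite(K_AL) || !is.finite(K_BL) || K_AL <= 0 || K_BL <= 0)
    stop("invalid-parameter: dissociation constants must be positive")
  sqrt(K_AL * K_BL)
}

#' Optimal total ligand concentration
#'
#' The total ligand dose at which the ternary complex concentration peaks:
#' \deqn{[L_{tot}]^{opt} = \sqrt{K_{A-L} K_{B-L}}
#'   + \frac{[A_{tot}]}{1 + \sqrt{K_{A-L}/K_{B-L}}}
#'   + \frac{[B_{tot}]}{1 + \sqrt{K_{B-L}/K_{A-L}}}.}
#' It depends only on the binary affinities and the totals, not on the
#' cooperativity.
#'
#' @param system a [ternary_system()] (its `L_tot` is ignored).
#' @return Optimal total ligand concentration in molar.
#' @export
optimal_total_ligand <- function(system) {
  stopifnot(inherits(system, "ternary_system"))
  with(system,
       sqrt(K_AL * K_BL) +
         A_tot / (1 + sqrt(K_AL / K_BL)) +
         B_tot / (1 + sqrt(K_BL / K_AL)))
}

#' Optimal ternary fraction
#'
#' Evaluates the ternary fraction at the optimal dose: `[ALB]` from the
#' closed-form quadratic at free ligand \eqn{[L]^{opt} = \sqrt{K_{A-L}
#' K_{B-L}}}, divided by the maximal attainable ternary concentration
#' `min(A_tot, B_tot, L_tot_opt)`. Non-decreasing in alpha.
#'
#' @param system a [ternary_system()] (its `L_tot` is ignored).
#' @return `f3_opt`, dimensionless in `[0, 1]`.
#' @export
optimal_fraction <- function(system) {
  stopifnot(inherits(system, "ternary_system"))
  L_opt <- optimal_free_ligand(system$K_AL, system$K_BL)
  ALB_opt <- alb_at_free_ligand(system, L_opt)
  m <- min(system$A_tot, system$B_tot, optimal_total_ligand(system))
  if (m <= 0)
    stop("undefined-fraction: a limiting total concentration is zero")
  min(ALB_opt / m, 1)
}

#' Hook-effect severity of a titration curve
#'
#' Quantifies the prozone drop past the optimum as
#' `1 - f3(10 * L_peak) / f3_peak`, where `L_peak` is the dose maximising
#' the ternary-complex concentration `[ALB]` (the quantity whose peak
#' defines the optimal dose; on the post-peak side, where the limiting
#' species is a protein, the `f3` ratio and the `[ALB]` ratio coincide).
#' 0 means a flat post-peak plateau; values near 1 mean the ternary
#' complex is almost completely dissolved one decade past the optimum.
#'
#' @param curve a [titration()] result whose grid extends at least 10x
#'   beyond the peak dose.
#' @return Severity in `[0, 1]`.
#' @export
hook_severity <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  alb <- curve$table$ALB
  ipk <- which.max(alb)
  L_pk <- curve$L_tot_grid[ipk]
  target <- 10 * L_pk
  if (max(curve$L_tot_grid) < target)
    stop("insufficient-range: titration grid must extend to 10x the peak dose")
  f_pk <- curve$f3[ipk]
  if (f_pk <= 0) return(0)
  ## interpolate f3 at 10x the peak dose on a log-dose axis
  f_10 <- stats::approx(log(curve$L_tot_grid), curve$f3, xout = log(target))$y
  min(max(1 - f_10 / f_pk, 0), 1)
}

#' Response surface of the optimal ternary fraction
#'
#' Evaluates `f3_opt` over a 2-D parameter grid: either the two binary
#' dissociation constants at fixed alpha (`mode = "K_K"`), or `K_BL` and
#' alpha at fixed `K_AL` (`mode = "K_alpha"`).
#'
#' @param A_tot,B_tot protein totals (molar).
#' @param axis1,axis2 numeric grids for the two varied parameters:
#'   `(K_AL, K_BL)` in `"K_K"` mode, `(K_BL, alpha)` in `"K_alpha"` mode.
#' @param mode `"K_K"` or `"K_alpha"`.
#' @param fixed named list giving the held parameter: `alpha` in `"K_K"`
#'   mode, `K_AL` in `"K_alpha"` mode.
#' @return Matrix of `f3_opt` values, `length(axis1)` rows by
#'   `length(axis2)` columns, with the grids in `dimnames`.
#' @export
response_surface <- function(A_tot, B_tot, axis1, axis2,
                             mode = c("K_K", "K_alpha"), fixed = list()) {
  mode <- match.arg(mode)
  if (mode == "K_K" && is.null(fixed$alpha))
    stop("invalid-parameter: K_K mode requires fixed$alpha")
  if (mode == "K_alpha" && is.null(fixed$K_AL))
    stop("invalid-parameter: K_alpha mode requires fixed$K_AL")
  out <- matrix(NA_real_, nrow = length(axis1), ncol = length(axis2),
                dimnames = list(signif(axis1, 6), signif(axis2, 6)))
  for (i in seq_along(axis1)) for (j in seq_along(axis2)) {
    sys <- if (mode == "K_K")
      ternary_system(A_tot, B_tot, L_tot = 1, K_AL = axis1[i],
                     K_BL = axis2[j], alpha = fixed$alpha)
    else
      ternary_system(A_tot, B_tot, L_tot = 1, K_AL = fixed$K_AL,
                     K_BL = axis1[i], alpha = axis2[j])
    out[i, j] <- optimal_fraction(sys)
  }
  out
}

#' Logarithmic dose grid
#'
#' Convenience constructor for a strictly increasing log-spaced grid of
#' total ligand concentrations.
#'
#' @param from,to grid endpoints in molar (> 0).
#' @param n number of points (>= 2).
#' @return Numeric vector of length `n`.
#' @export
dose_grid <- function(from, to, n = 60L) {
  if (from <= 0 || to <= from || n < 2)
    stop("invalid-parameter: need 0 < from < to and n >= 2")
  exp(seq(log(from), log(to), length.out = n))
}
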