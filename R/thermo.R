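#' Thermodynamic context
#'
#' Holds the temperature and the standard-state concentration used to
#' interconvert cooperativities, dissociation constants and free energies.
#' The thermal energy is \eqn{\beta^{-1} = k_B T} with
#' \eqn{k_B = 0.0083145} kJ/mol/K, so at the default 298 K,
#' \eqn{k_B T \approx 2.478} kJ/mol.
#'
#' @param temperature temperature in kelvin (> 0), default 298.
#' @param c0 standard-state concentration in molar; fixed at 1 by
#'   convention.
#' @return An object of class `thermo_context` with fields `temperature`,
#'   `c0`, and `kT` (kJ/mol).
#' @export
thermo_context <- function(temperature = 298, c0 = 1.0) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("invalid-parameter: temperature must be positive")
  if (!is.finite(c0) || c0 <= 0)
    stop("invalid-parameter: c0 must be positive")
  structure(list(temperature = temperature, c0 = c0,
                 kT = KB_KJ_MOL_K * temperature),
            class = "thermo_context")
}

## Boltzmann constant in kJ/mol/K
KB_KJ_MOL_K <- 0.0083145

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("Thermo context: T = %g K, kT = %.6g kJ/mol, c0 = %g M\n",
              x$temperature, x$kT, x$c0))
  invisible(x)
}

#' Cooperative free energy from cooperativity
#'
#' \eqn{\Delta G_\alpha = -k_B T \ln\alpha}. Positive cooperativity
#' (\eqn{\alpha > 1}) corresponds to a favourable (negative) cooperative
#' free energy.
#'
#' @param alpha dimensionless cooperativity (> 0).
#' @param ctx a [thermo_context()].
#' @return Free energy in kJ/mol.
#' @export
dg_from_alpha <- function(alpha, ctx = thermo_context()) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("invalid-parameter: alpha must be strictly positive")
  -ctx$kT * log(alpha)
}

#' Cooperativity from cooperative free energy
#'
#' Inverse of [dg_from_alpha()]: \eqn{\alpha = e^{-\beta \Delta G_\alpha}}.
#'
#' @param dG free energy in kJ/mol.
#' @param ctx a [thermo_context()].
#' @return Dimensionless cooperativity.
#' @export
alpha_from_dg <- function(dG, ctx = thermo_context()) {
  if (any(!is.finite(dG))) stop("invalid-parameter: dG must be finite")
  exp(-dG / ctx$kT)
}

#' Dissociation constant from binding free energy
#'
#' \eqn{K = c_0 e^{\beta \Delta G}}: a more negative binding free energy
#' gives a smaller (tighter) dissociation constant.
#'
#' @param dG binding free energy in kJ/mol.
#' @param ctx a [thermo_context()].
#' @return Dissociation constant in molar.
#' @export
kd_from_dg <- function(dG, ctx = thermo_context()) {
  if (any(!is.finite(dG))) stop("invalid-parameter: dG must be finite")
  out <- ctx$c0 * exp(dG / ctx$kT)
  if (any(!is.finite(out))) stop("range error: dG overflows exp()")
  out
}

#' Binding free energy from dissociation constant
#'
#' Inverse of [kd_from_dg()]: \eqn{\Delta G = k_B T \ln(K / c_0)}.
#'
#' @param K dissociation constant in molar (> 0).
#' @param ctx a [thermo_context()].
#' @return Binding free energy in kJ/mol.
#' @export
dg_from_kd <- function(K, ctx = thermo_context()) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("invalid-parameter: K must be strictly positive")
  ctx$kT * log(K / ctx$c0)
}

#' Effective ternary dissociation constant from cooperativity
#'
#' \eqn{K_3 = \alpha^{-1} K_{A-L} K_{B-L}} (units M squared). In energy
#' space this is the additivity
#' \eqn{\Delta G_3 = \Delta G_{A-L} + \Delta G_{B-L} + \Delta G_\alpha}.
#'
#' @param K_AL,K_BL binary dissociation constants (molar, > 0).
#' @param alpha dimensionless cooperativity (> 0).
#' @param ctx a [thermo_context()] (unused numerically; kept for interface
#'   symmetry with [k3_from_phi()]).
#' @return Effective ternary dissociation constant in molar squared.
#' @export
k3_from_alpha <- function(K_AL, K_BL, alpha, ctx = thermo_context()) {
  if (any(!is.finite(c(K_AL, K_BL, alpha))) || K_AL <= 0 || K_BL <= 0 ||
      alpha <= 0)
    stop("invalid-parameter: K_AL, K_BL, alpha must be strictly positive")
  K_AL * K_BL / alpha
}

#' Reduced cooperativity from cooperativity and intrinsic PPIs
#'
#' The reduced cooperativity \eqn{\phi} removes the asymmetry of
#' \eqn{\alpha} by correcting for the intrinsic protein--protein binding
#' free energy: \eqn{\Delta G_\phi = \Delta G_\alpha - \Delta G_{A-B}},
#' \eqn{\phi = e^{-\beta \Delta G_\phi}}. \eqn{\phi} captures only the
#' non-pairwise-additive part of ternary binding: it is 1 for a
#' nonperturbative ligand (whose cooperativity merely reveals the intrinsic
#' PPIs) and equals the c0-scaled \eqn{K_{A-B}} for a noncooperative one.
#'
#' @param alpha dimensionless cooperativity (> 0).
#' @param dG_AB intrinsic protein--protein binding free energy (kJ/mol).
#' @param ctx a [thermo_context()].
#' @return A list of class `cooperativity_value` with fields `alpha`,
#'   `dG_alpha`, `phi`, `dG_phi`.
#' @export
phi_from_alpha <- function(alpha, dG_AB, ctx = thermo_context()) {
  if (!is.finite(dG_AB)) stop("invalid-parameter: dG_AB must be finite")
  dG_alpha <- dg_from_alpha(alpha, ctx)
  dG_phi <- dG_alpha - dG_AB
  structure(list(alpha = alpha, dG_alpha = dG_alpha,
                 phi = exp(-dG_phi / ctx$kT), dG_phi = dG_phi),
            class = "cooperativity_value")
}

#' @export
print.cooperativity_value <- function(x, ...) {
  cat(sprintf("alpha = %.6g (dG_alpha = %.4f kJ/mol)", x$alpha, x$dG_alpha))
  if (!is.null(x$phi))
    cat(sprintf("; phi = %.6g (dG_phi = %.4f kJ/mol)", x$phi, x$dG_phi))
  cat("\n")
  invisible(x)
}

#' Effective ternary dissociation constant from reduced cooperativity
#'
#' \eqn{K_3 = \phi^{-1} (K_{A-B}/c_0) K_{A-L} K_{B-L}}; the division by
#' `c0` keeps `K3` in molar squared (the dimensionless reduced
#' cooperativity absorbs the standard state). Consistent with
#' [k3_from_alpha()] whenever \eqn{\alpha = \phi\, c_0 / K_{A-B}}.
#'
#' @param K_AL,K_BL,K_AB dissociation constants (molar, > 0).
#' @param phi dimensionless reduced cooperativity (> 0).
#' @param ctx a [thermo_context()].
#' @return Effective ternary dissociation constant in molar squared.
#' @export
k3_from_phi <- function(K_AL, K_BL, K_AB, phi, ctx = thermo_context()) {
  if (any(!is.finite(c(K_AL, K_BL, K_AB, phi))) ||
      any(c(K_AL, K_BL, K_AB, phi) <= 0))
    stop("invalid-parameter: all arguments must be strictly positive")
  (K_AB / ctx$c0) * K_AL * K_BL / phi
}

#' Cooperativity of a nonperturbative ligand
#'
#' A nonperturbative ligand binds without distorting the proteins' favoured
#' binary state, so its induced PPIs equal the intrinsic ones and the
#' cooperativity reduces to \eqn{\alpha = c_0 / K_{A-B}}: even a weak
#' intrinsic protein--protein affinity of 10 mM already corresponds to a
#' cooperativity of 100.
#'
#' @param K_AB intrinsic protein--protein dissociation constant (molar, > 0).
#' @param ctx a [thermo_context()].
#' @return Dimensionless cooperativity.
#' @export
alpha_nonperturbative <- function(K_AB, ctx = thermo_context()) {
  if (!is.finite(K_AB) || K_AB <= 0)
    stop("invalid-parameter: K_AB must be strictly positive")
  ctx$c0 / K_AB
}

#' Induced PPIs from geometric perturbation costs
#'
#' The induced protein--protein binding free energy (between the
#' ligand-stabilized conformations) relates to the intrinsic one through
#' the geometric confinement costs:
#' \deqn{\Delta G_{A-B}^{induced} = \Delta G_{A-B} + \Delta G_{geo,AB}^s
#'   - (\Delta G_{geo,A}^s + \Delta G_{geo,B}^s).}
#' Geometric costs are non-negative (free ensembles are always at least as
#' favourable as confined ones).
#'
#' @param dG_AB intrinsic protein--protein binding free energy (kJ/mol).
#' @param geo_A,geo_B,geo_AB unary and binary geometric perturbation costs
#'   (kJ/mol, each >= 0).
#' @return Induced PPI free energy in kJ/mol.
#' @export
induced_ppi_from_geometry <- function(dG_AB, geo_A, geo_B, geo_AB) {
  if (any(!is.finite(c(dG_AB, geo_A, geo_B, geo_AB))))
    stop("invalid-parameter: all energies must be finite")
  if (geo_A < 0 || geo_B < 0 || geo_AB < 0)
    stop("invariant-violation: geometric costs must be non-negative")
  dG_AB + geo_AB - geo_A - geo_B
}

#' Classify the geometric perturbation type of a ligand
#'
#' Four regimes of ligand-modulated PPIs:
#' * `nonperturbative` — no geometric cost at all; induced PPIs equal the
#'   intrinsic ones.
#' * `noncooperative` — the ligand separates the proteins back to the
#'   binary state; induced PPIs vanish.
#' * `binary-perturbative` — only the inter-protein pose is altered
#'   (`geo_AB > 0`, unary costs zero); induced PPIs must be weaker than
#'   intrinsic.
#' * `unary-perturbative` — intramolecular distortion of at least one
#'   protein; induced PPIs can be stronger or weaker than intrinsic.
#'
#' @param geo_A,geo_B,geo_AB geometric costs (kJ/mol, each >= 0).
#' @param dG_induced induced PPI free energy (kJ/mol).
#' @param tol tie tolerance in kJ/mol (default 0.1, well below thermal
#'   noise but above rounding).
#' @return One of `"nonperturbative"`, `"noncooperative"`,
#'   `"binary-perturbative"`, `"unary-perturbative"`.
#' @export
classify_perturbation <- function(geo_A, geo_B, geo_AB, dG_induced,
                                  tol = 0.1) {
  if (any(!is.finite(c(geo_A, geo_B, geo_AB, dG_induced, tol))))
    stop("invalid-parameter: all energies must be finite")
  if (geo_A < 0 || geo_B < 0 || geo_AB < 0)
    stop("invariant-violation: geometric costs must be non-negative")
  if (geo_A <= tol && geo_B <= tol && geo_AB <= tol) return("nonperturbative")
  if (abs(dG_induced) <= tol) return("noncooperative")
  if (geo_AB > tol && geo_A + geo_B <= tol) return("binary-perturbative")
  "unary-perturbative"
}

#' Assemble a cooperative free-energy ledger
#'
#' The exact decomposition of the cooperative free energy:
#' \deqn{\Delta G_\alpha = \Delta G_{A-B}^{induced} +
#'   \Delta\Delta G_{\phi,solv}^s + \Delta G_{\phi,gas}^s +
#'   \Delta\Delta G_{\alpha,geo}^s,}
#' where the first two terms form the rapid two-term approximation (the
#' gas-phase correlation and ligand-geometric terms are dropped for rigid
#' ligands with independent binding interfaces).
#'
#' @param dG_induced_PPI induced PPI free energy (kJ/mol).
#' @param ddG_coop_solv cooperative (non-additive) solvation term (kJ/mol).
#' @param dG_gas_coop gas-phase cooperative correlation term (kJ/mol).
#' @param ddG_alpha_geo net ligand-associated geometric cost (kJ/mol).
#' @param dG_AB_intrinsic optional intrinsic PPI free energy (kJ/mol),
#'   enables reduced-cooperativity reporting.
#' @param geo_A,geo_B,geo_AB optional stabilized-space geometric costs
#'   (kJ/mol, each >= 0).
#' @return An object of class `free_energy_ledger`.
#' @export
free_energy_ledger <- function(dG_induced_PPI, ddG_coop_solv = 0,
                               dG_gas_coop = 0, ddG_alpha_geo = 0,
                               dG_AB_intrinsic = NULL,
                               geo_A = NULL, geo_B = NULL, geo_AB = NULL) {
  terms <- c(dG_induced_PPI, ddG_coop_solv, dG_gas_coop, ddG_alpha_geo)
  if (any(!is.finite(terms)))
    stop("invalid-parameter: ledger terms must be finite energies")
  geo <- c(geo_A, geo_B, geo_AB)
  if (length(geo) && any(geo < 0))
    stop("invariant-violation: geometric costs must be non-negative")
  structure(list(dG_induced_PPI = dG_induced_PPI,
                 ddG_coop_solv = ddG_coop_solv,
                 dG_gas_coop = dG_gas_coop,
                 ddG_alpha_geo = ddG_alpha_geo,
                 dG_AB_intrinsic = dG_AB_intrinsic,
                 geo_A = geo_A, geo_B = geo_B, geo_AB = geo_AB),
            class = "free_energy_ledger")
}

#' Cooperativity from a free-energy ledger
#'
#' Sums the ledger exactly (four terms) and approximately (induced PPIs +
#' cooperative solvation only), converting both to cooperativities. The
#' approximation gap is, by construction, exactly the magnitude of the two
#' dropped terms.
#'
#' @param ledger a [free_energy_ledger()].
#' @param ctx a [thermo_context()].
#' @return A list with `dG_alpha`, `alpha`, `dG_alpha_approx`,
#'   `alpha_approx`, `gap` (kJ/mol), and — when the ledger carries the
#'   intrinsic PPI term — `phi` and `dG_phi`.
#' @export
ledger_alpha <- function(ledger, ctx = thermo_context()) {
  stopifnot(inherits(ledger, "free_energy_ledger"))
  need <- c("dG_induced_PPI", "ddG_coop_solv", "dG_gas_coop", "ddG_alpha_geo")
  if (any(vapply(ledger[need], is.null, logical(1))))
    stop("incomplete-ledger: missing decomposition terms")
  dG_alpha <- ledger$dG_induced_PPI + ledger$ddG_coop_solv +
    ledger$dG_gas_coop + ledger$ddG_alpha_geo
  dG_approx <- ledger$dG_induced_PPI + ledger$ddG_coop_solv
  out <- list(dG_alpha = dG_alpha,
              alpha = alpha_from_dg(dG_alpha, ctx),
              dG_alpha_approx = dG_approx,
              alpha_approx = alpha_from_dg(dG_approx, ctx),
              gap = abs(ledger$dG_gas_coop + ledger$ddG_alpha_geo))
  if (!is.null(ledger$dG_AB_intrinsic)) {
    out$dG_phi <- dG_alpha - ledger$dG_AB_intrinsic
    out$phi <- exp(-out$dG_phi / ctx$kT)
  }
  out
}

#' Apparent cooperativity from a simulated EC50 shift
#'
#' Experimentally, apparent cooperativity is read off as the shift of a
#' ligand-binding EC50 for protein A when the partner protein B is present
#' at a saturating concentration. This simulates both titrations with the
#' equilibrium model: the bound fraction of A, `(AL + ALB)/A_tot`, is
#' computed over a dose grid with `B_tot = 0` (binary reference) and with
#' `B_tot = saturating_partner_conc`, each EC50 is located by monotone
#' linear interpolation on the log-dose axis at half the curve's plateau,
#' and the ratio `EC50_binary / EC50_ternary` is returned. For a
#' noncooperative ligand (alpha = 1) the ratio is 1 up to grid tolerance;
#' it grows with alpha but saturates below alpha in the binding-depletion
#' regime.
#'
#' @param system_base a [ternary_system()] supplying `A_tot`, the binary
#'   Kd's and alpha; its `B_tot` and `L_tot` are ignored.
#' @param saturating_partner_conc concentration of protein B (molar); a
#'   warning is emitted below 10x `K_BL`.
#' @param grid strictly increasing dose grid of `L_tot` values (molar). It
#'   must span the plateau of both curves.
#' @return The dimensionless EC50 ratio (apparent cooperativity).
#' @export
apparent_cooperativity <- function(system_base, saturating_partner_conc,
                                   grid) {
  stopifnot(inherits(system_base, "ternary_system"))
  if (saturating_partner_conc < 10 * system_base$K_BL)
    warning("saturating_partner_conc is below 10x K_BL; ",
            "partner may not be saturating")
  fbound <- function(B_tot) {
    vapply(grid, function(Lt) {
      sys <- ternary_system(system_base$A_tot, B_tot, Lt,
                            system_base$K_AL, system_base$K_BL,
                            system_base$alpha)
      st <- solve_equilibrium(sys)
      (st$AL + st$ALB) / system_base$A_tot
    }, numeric(1))
  }
  ec50 <- function(fb) {
    plateau <- max(fb)
    if (plateau < 0.5 || utils::tail(fb, 1) < 0.95 * plateau)
      stop("insufficient-range: bound-fraction plateau not reached on grid")
    half <- plateau / 2
    i <- which(fb >= half)[1]
    if (i == 1) stop("insufficient-range: grid starts above the EC50")
    ## linear interpolation on log10 dose between the bracketing grid points
    x <- log10(grid[(i - 1):i]); y <- fb[(i - 1):i]
    10^(x[1] + (half - y[1]) * (x[2] - x[1]) / (y[2] - y[1]))
  }
  ec50(fbound(0)) / ec50(fbound(saturating_partner_conc))
}
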