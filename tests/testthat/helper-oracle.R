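# Independent oracles used across the suite.

# Brute-force simultaneous solve of the six-species mass-action system by
# nested monotone 1-D root finding, algebraically distinct from the
# package's closed-form quadratic path:
#   inner: given free L, free B solves B*(1 + L/K_BL + a*A(B)*L/(K_AL*K_BL))
#          = B_tot with A(B) = A_tot/(1 + L/K_AL + a*B*L/(K_AL*K_BL))
#   outer: free L solves the ligand mass balance.
oracle_equilibrium <- function(A_tot, B_tot, L_tot, K_AL, K_BL, alpha) {
  species <- function(L, B) {
    A <- A_tot / (1 + L / K_AL + alpha * B * L / (K_AL * K_BL))
    list(A = A, B = B, L = L,
         AL = A * L / K_AL, BL = B * L / K_BL,
         ALB = alpha * A * B * L / (K_AL * K_BL))
  }
  solve_B <- function(L) {
    if (B_tot == 0) return(0)
    g <- function(B) {
      A <- A_tot / (1 + L / K_AL + alpha * B * L / (K_AL * K_BL))
      B * (1 + L / K_BL + alpha * A * L / (K_AL * K_BL)) - B_tot
    }
    stats::uniroot(g, c(0, B_tot), tol = B_tot * 1e-16,
                   maxiter = 5000L)$root
  }
  if (L_tot == 0) {
    return(list(A = A_tot, B = B_tot, L = 0, AL = 0, BL = 0, ALB = 0))
  }
  h <- function(L) {
    s <- species(L, solve_B(L))
    s$L + s$AL + s$BL + s$ALB - L_tot
  }
  u <- stats::uniroot(function(u) h(exp(u)),
                      c(log(L_tot) - 50, log(L_tot) + 1e-9),
                      tol = 1e-15, maxiter = 5000L)
  L <- exp(u$root)
  species(L, solve_B(L))
}

# Random valid systems for property sweeps (log-uniform K in [1 nM, 1 mM],
# alpha in [0.01, 1000], totals in [10 nM, 100 uM]).
random_system <- function() {
  ternary_system(
    A_tot = 10^stats::runif(1, -8, -4),
    B_tot = 10^stats::runif(1, -8, -4),
    L_tot = 10^stats::runif(1, -8, -4),
    K_AL = 10^stats::runif(1, -9, -3),
    K_BL = 10^stats::runif(1, -9, -3),
    alpha = 10^stats::runif(1, -2, 3))
}

rel_err <- function(x, y, floor = 0) abs(x - y) / pmax(abs(x), abs(y), floor)

# Kendall tau-b by direct enumeration over all C(n,2) pairs, written
# independently of the package's pair-counting implementation (different
# tie bookkeeping path).
brute_force_tau <- function(x, y) {
  n <- length(x)
  num <- 0
  tied_x <- 0; tied_y <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    num <- num + sx * sy
    if (sx == 0) tied_x <- tied_x + 1
    if (sy == 0) tied_y <- tied_y + 1
  }
  n0 <- n * (n - 1) / 2
  num / sqrt((n0 - tied_x) * (n0 - tied_y))
}
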