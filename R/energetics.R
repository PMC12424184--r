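## Subsystems of the single-trajectory decomposition: every frame of a
## ternary-complex trajectory is re-scored as the full complex, the three
## two-body subsystems, and the three monomers.
SUBSYSTEMS <- c("ALB", "AL", "BL", "AB", "A", "B", "L")

#' Validate a per-frame subsystem energy table
#'
#' A frame energy table holds, for every trajectory frame of every
#' replicate of one or more ternary complexes, a gas-phase potential energy
#' `E_gas` and an implicit-solvent solvation energy `G_solv` for each of
#' the seven subsystems `ALB, AL, BL, AB, A, B, L` (all evaluated on the
#' ternary-trajectory frame: the single-trajectory approximation). Units
#' are kJ/mol.
#'
#' @param table a data frame with columns `complex_id`, `replicate_id`,
#'   `frame_index`, `subsystem`, `E_gas`, `G_solv`.
#' @return The table, invisibly, after validation.
#' @export
validate_frame_table <- function(table) {
  need <- c("complex_id", "replicate_id", "frame_index", "subsystem",
            "E_gas", "G_solv")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("schema error: missing columns ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(table$subsystem), SUBSYSTEMS)
  if (length(bad))
    stop("schema error: unknown subsystem labels ", paste(bad, collapse = ", "))
  if (any(!is.finite(table$E_gas)) || any(!is.finite(table$G_solv)))
    stop("invalid-input: non-finite energies in table")
  key <- interaction(table$complex_id, table$replicate_id, table$frame_index,
                     drop = TRUE)
  counts <- table(key)
  if (any(counts != length(SUBSYSTEMS))) {
    off <- names(counts)[counts != length(SUBSYSTEMS)][1]
    stop("schema error: frame ", off, " does not carry all seven subsystems ",
         "exactly once")
  }
  per_frame <- tapply(table$subsystem, key,
                      function(s) length(unique(s)) == length(SUBSYSTEMS))
  if (!all(per_frame))
    stop("schema error: duplicated subsystem within a frame")
  invisible(table)
}

#' Per-frame protein--protein interaction energy
#'
#' Gas-phase interaction energy between the two proteins evaluated on a
#' ternary frame: `E_AB - E_A - E_B`.
#'
#' @param E_AB,E_A,E_B gas-phase energies (kJ/mol) of the AB subsystem and
#'   the two protein monomers on the same frame.
#' @return Interaction energy in kJ/mol (vectorised).
#' @export
interaction_energy_frame <- function(E_AB, E_A, E_B) {
  if (any(!is.finite(c(E_AB, E_A, E_B))))
    stop("invalid-input: energies must be finite")
  E_AB - E_A - E_B
}

#' Per-frame protein--protein desolvation energy
#'
#' Non-additive solvation on binding: `G_AB - G_A - G_B`; zero when
#' solvation is exactly additive over the two proteins.
#'
#' @param G_AB,G_A,G_B solvation energies (kJ/mol) on the same frame.
#' @return Desolvation energy in kJ/mol (vectorised).
#' @export
desolvation_AB_frame <- function(G_AB, G_A, G_B) {
  if (any(!is.finite(c(G_AB, G_A, G_B))))
    stop("invalid-input: energies must be finite")
  G_AB - G_A - G_B
}

## reshape one complex's rows into per-subsystem column matrices keyed by
## (replicate, frame); returns list(rep = replicate per row, E = matrix,
## G = matrix) with one row per frame and one column per subsystem
frame_matrices <- function(tab) {
  key <- paste(tab$replicate_id, tab$frame_index, sep = "\r")
  frames <- unique(key)
  E <- matrix(NA_real_, length(frames), length(SUBSYSTEMS),
              dimnames = list(NULL, SUBSYSTEMS))
  G <- E
  idx <- match(key, frames)
  jdx <- match(tab$subsystem, SUBSYSTEMS)
  E[cbind(idx, jdx)] <- tab$E_gas
  G[cbind(idx, jdx)] <- tab$G_solv
  rep_of_frame <- tab$replicate_id[match(frames, key)]
  list(rep = rep_of_frame, E = E, G = G)
}

#' Induced-PPI estimate from a frame energy table
#'
#' Estimates the induced protein--protein binding free energy as the frame
#' average (per replicate) of the gas-phase interaction energy plus the
#' protein--protein desolvation energy, neglecting the binary entropy
#' contribution:
#' \deqn{\Delta G_{A-B}^{induced} = \langle E_{AB} - E_A - E_B
#'   \rangle + \langle \Delta G_{solv,AB} - \Delta G_{solv,A} -
#'   \Delta G_{solv,B} \rangle.}
#'
#' @param table a validated frame energy table (single or multiple
#'   complexes).
#' @param by_replicate if `TRUE` (default) return one value per replicate;
#'   if `FALSE`, pool all frames.
#' @return A data frame with columns `complex_id`, `replicate_id` (absent
#'   when pooling) and `induced_ppi` (kJ/mol).
#' @export
induced_ppi_estimate <- function(table, by_replicate = TRUE) {
  validate_frame_table(table)
  per_complex(table, by_replicate, function(m) {
    interaction_energy_frame(m$E[, "AB"], m$E[, "A"], m$E[, "B"]) +
      desolvation_AB_frame(m$G[, "AB"], m$G[, "A"], m$G[, "B"])
  }, "induced_ppi")
}

#' Cooperative-solvation estimate from a frame energy table
#'
#' Estimates the non-additive (three-body) part of ternary desolvation as
#' the frame average (per replicate) of
#' \deqn{G_{ALB} - G_{AL} - G_{BL} - G_{AB} + G_A + G_B + G_L}
#' over the solvation energies. Identically zero, frame by frame, when the
#' ternary solvation is pairwise additive — the regime of spatially
#' separated protein--ligand interfaces.
#'
#' @inheritParams induced_ppi_estimate
#' @return A data frame with columns `complex_id`, `replicate_id` (absent
#'   when pooling) and `coop_solv` (kJ/mol).
#' @export
coop_solvation_estimate <- function(table, by_replicate = TRUE) {
  validate_frame_table(table)
  per_complex(table, by_replicate, function(m) {
    m$G[, "ALB"] - m$G[, "AL"] - m$G[, "BL"] - m$G[, "AB"] +
      m$G[, "A"] + m$G[, "B"] + m$G[, "L"]
  }, "coop_solv")
}

per_complex <- function(table, by_replicate, frame_fun, value_name) {
  res <- lapply(split(table, table$complex_id), function(tab) {
    m <- frame_matrices(tab)
    v <- frame_fun(m)
    if (by_replicate) {
      means <- tapply(v, m$rep, mean)
      data.frame(complex_id = tab$complex_id[1],
                 replicate_id = names(means),
                 value = as.numeric(means), row.names = NULL)
    } else {
      data.frame(complex_id = tab$complex_id[1], value = mean(v))
    }
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  names(out)[names(out) == "value"] <- value_name
  out
}

#' Approximated cooperative free energy for each complex
#'
#' Combines the induced-PPI and cooperative-solvation estimators into the
#' two-term approximation of the cooperative free energy,
#' \eqn{\Delta G_\alpha \approx \Delta G_{A-B}^{induced} +
#' \Delta\Delta G_{\phi,solv}^s}, with replicate statistics. Replicate
#' means are the independent statistical unit (frames within a trajectory
#' are autocorrelated): the SEM is the sample standard deviation of the
#' per-replicate means divided by `sqrt(N)`.
#'
#' @param table a validated frame energy table.
#' @param ctx a [thermo_context()] used to report the implied cooperativity.
#' @return A data frame of class `coop_estimate` with one row per complex:
#'   `complex_id`, `induced_ppi_mean`, `induced_ppi_sem`, `coop_solv_mean`,
#'   `coop_solv_sem`, `dG_alpha_approx`, `alpha_approx`, `n_replicates`.
#'   SEMs are `NA` (with a warning) for single-replicate tables.
#' @export
estimate_complex <- function(table, ctx = thermo_context()) {
  ind <- induced_ppi_estimate(table, by_replicate = TRUE)
  sol <- coop_solvation_estimate(table, by_replicate = TRUE)
  ids <- unique(ind$complex_id)
  rows <- lapply(ids, function(id) {
    iv <- ind$induced_ppi[ind$complex_id == id]
    sv <- sol$coop_solv[sol$complex_id == id]
    n <- length(iv)
    if (n < 2) {
      warning("complex ", id, ": single replicate, SEM undefined")
      sem_i <- NA_real_; sem_s <- NA_real_
    } else {
      sem_i <- stats::sd(iv) / sqrt(n)
      sem_s <- stats::sd(sv) / sqrt(n)
    }
    dg <- mean(iv) + mean(sv)
    data.frame(complex_id = id,
               induced_ppi_mean = mean(iv), induced_ppi_sem = sem_i,
               coop_solv_mean = mean(sv), coop_solv_sem = sem_s,
               dG_alpha_approx = dg,
               alpha_approx = alpha_from_dg(dg, ctx),
               n_replicates = n)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  class(out) <- c("coop_estimate", class(out))
  out
}

#' Kendall rank correlation by explicit pair counting
#'
#' Tie-adjusted (tau-b) Kendall correlation computed by enumerating all
#' pairs: \eqn{\tau_b = (C - D)/\sqrt{(n_0 - t_x)(n_0 - t_y)}} with
#' concordant `C`, discordant `D`, `n0 = n(n-1)/2` and tie counts per
#' margin.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return Kendall tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  C <- 0L; D <- 0L; tx <- 0L; ty <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1L; ty <- ty + 1L }
    else if (dx == 0) tx <- tx + 1L
    else if (dy == 0) ty <- ty + 1L
    else if (sign(dx) == sign(dy)) C <- C + 1L
    else D <- D + 1L
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tx) * (n0 - ty))
  if (denom == 0) stop("insufficient-data: all values tied in one margin")
  (C - D) / denom
}

#' Compare predicted cooperative free energies with experiment
#'
#' Matches predicted complexes to experimental cooperativities by
#' `complex_id`, converts the experimental alphas to free energies via
#' \eqn{\Delta G_\alpha = -k_B T \ln\alpha}, and reports the Kendall rank
#' correlation (explicit pair counting) together with ordinary
#' least-squares fits in both orientations — the experimental energy
#' regressed on the prediction and vice versa — since either convention is
#' found in benchmarking practice.
#'
#' @param estimates a [estimate_complex()] result (or any data frame with
#'   `complex_id` and `dG_alpha_approx`).
#' @param experiments a data frame with columns `complex_id`, `alpha_exp`
#'   (> 0) and optionally `alpha_kind` (`"absolute"` or `"apparent"`,
#'   carried through so callers can filter).
#' @param ctx a [thermo_context()].
#' @return A list with the matched table (`data`), `n`, `kendall_tau`, and
#'   the two fits `fit_exp_on_pred` and `fit_pred_on_exp`, each a list with
#'   `intercept` and `slope`.
#' @export
compare_to_experiment <- function(estimates, experiments,
                                  ctx = thermo_context()) {
  if (!all(c("complex_id", "alpha_exp") %in% names(experiments)))
    stop("schema error: experiments needs complex_id and alpha_exp columns")
  if (any(experiments$alpha_exp <= 0))
    stop("invalid-parameter: alpha_exp must be strictly positive")
  m <- merge(estimates[, c("complex_id", "dG_alpha_approx")], experiments,
             by = "complex_id")
  if (nrow(m) < 3)
    stop("insufficient-data: need at least 3 matched complexes, got ",
         nrow(m))
  m$dG_alpha_exp <- dg_from_alpha(m$alpha_exp, ctx)
  tau <- kendall_tau(m$dG_alpha_approx, m$dG_alpha_exp)
  co1 <- stats::coef(stats::lm(dG_alpha_exp ~ dG_alpha_approx, data = m))
  co2 <- stats::coef(stats::lm(dG_alpha_approx ~ dG_alpha_exp, data = m))
  list(data = m, n = nrow(m), kendall_tau = tau,
       fit_exp_on_pred = list(intercept = unname(co1[1]),
                              slope = unname(co1[2])),
       fit_pred_on_exp = list(intercept = unname(co2[1]),
                              slope = unname(co2[2])))
}
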