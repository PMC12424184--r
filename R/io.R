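#' Parse a quantity with a unit suffix
#'
#' Converts a string such as `"0.2uM"`, `"10mM"`, `"1kcal/mol"` or
#' `"298K"` into canonical units: molar for concentrations, kJ/mol for
#' energies (kcal/mol converts with the exact factor 4.184), kelvin for
#' temperatures. A bare number is taken to already be in canonical units.
#'
#' @param text string: a number with an optional unit suffix.
#' @param kind one of `"concentration"`, `"energy"`, `"temperature"`.
#' @return Numeric scalar in canonical units.
#' @export
parse_quantity <- function(text, kind = c("concentration", "energy",
                                          "temperature")) {
  kind <- match.arg(kind)
  text <- trimws(text)
  m <- regmatches(text,
                  regexec("^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*(.*)$",
                          text))[[1]]
  if (length(m) == 0)
    stop("parse error: '", text, "' is not a number with optional unit")
  value <- as.numeric(m[2])
  unit <- m[3]
  factors <- switch(kind,
    concentration = c("M" = 1, "mM" = 1e-3, "uM" = 1e-6, "µM" = 1e-6,
                      "nM" = 1e-9, "pM" = 1e-12),
    energy = c("kJ/mol" = 1, "kcal/mol" = 4.184),
    temperature = c("K" = 1))
  if (unit == "") return(value)
  if (!unit %in% names(factors))
    stop("parse error: unknown ", kind, " unit '", unit, "'; accepted: ",
         paste(names(factors), collapse = ", "))
  value * unname(factors[unit])
}

#' Read / write a frame energy table as CSV
#'
#' RFC-4180 CSV with header; numeric columns are written with 17
#' significant digits so reader and writer round-trip bit-exactly.
#'
#' @param path file path.
#' @return `read_frame_table` returns a validated frame energy table.
#' @export
read_frame_table <- function(path) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_frame_table(tab)
  tab
}

#' @rdname read_frame_table
#' @param table a frame energy table.
#' @export
write_frame_table <- function(table, path) {
  validate_frame_table(table)
  write_csv17(table, path)
}

#' Read an experimental cooperativity table
#'
#' CSV with columns `complex_id`, `alpha_exp` and optionally `alpha_kind`
#' (`"absolute"` for Kd-ratio measurements, `"apparent"` for EC50/IC50
#' shifts).
#'
#' @param path file path.
#' @return Data frame of experimental records.
#' @export
read_experiment_table <- function(path) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("complex_id", "alpha_exp") %in% names(tab)))
    stop("schema error: need columns complex_id, alpha_exp")
  if (any(!is.finite(tab$alpha_exp)) || any(tab$alpha_exp <= 0))
    stop("invalid-parameter: alpha_exp must be positive and finite")
  if (is.null(tab$alpha_kind)) tab$alpha_kind <- "absolute"
  tab
}

## CSV writer: atomic (write to temp then rename), 17 significant digits
write_csv17 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  tmp <- paste0(path, ".tmp")
  utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a titration curve to CSV
#'
#' Columns `L_tot, L, A, B, AL, BL, ALB, f3`, all concentrations in molar,
#' 17 significant digits.
#'
#' @param curve a [titration()] result.
#' @param path output file path.
#' @export
write_titration_csv <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  write_csv17(curve$table, path)
}
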