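# Kinetic, binding and standardisation constants used by the diagnostic
# equations and the feedback model, plus unit normalisation of lab values.

# Molar masses used for mass <-> molar unit conversion.
#   T4 (levothyroxine, C15H11I4NO4): 776.87 g/mol
#   T3 / reverse T3 (C15H12I3NO4):   651.0 g/mol
.MM_T4 <- 776.87
.MM_T3 <- 651.0

#' Constant parameters for the diagnostic calculations and the feedback model
#'
#' Returns the set of kinetic, dilution, protein-binding and standardisation
#' constants shared by all structure-parameter calculators and by the
#' nonlinear feedback model. The defaults are the published reference values
#' for adult humans; any of them can be overridden by name.
#'
#' Plasma concentrations of the carrier proteins thyroxine-binding globulin
#' (TBG) and transthyretin (TBPA) are not kinetic constants but population
#' standard values; they are kept here so that calculators fall back on them
#' when a subject-specific measurement is absent. Note that in non-thyroidal
#' illness, where carrier protein levels are reduced, using the defaults
#' overestimates SPINA-GT and SPINA-GD — override them per subject when
#' protein measurements are available.
#'
#' @param ... named overrides of individual constants, e.g. `D_T = 3`.
#'
#' @return An object of class `spina_constants`: a named list with elements
#' \describe{
#'   \item{beta_loglin}{coefficient of the log-linear TSH model, per pmol/L
#'     of FT4 (dimensionless slope; negative).}
#'   \item{alpha_T}{dilution factor for T4, 1/L (reciprocal apparent volume
#'     of distribution).}
#'   \item{beta_T}{clearance exponent for T4, 1/s.}
#'   \item{D_T}{half-maximal TSH for thyroid stimulation (EC50), mU/L.}
#'   \item{K41}{T4–TBG association constant, L/mol.}
#'   \item{K42}{T4–TBPA association constant, L/mol.}
#'   \item{alpha_31}{dilution factor for T3, 1/L.}
#'   \item{beta_31}{clearance exponent for T3, 1/s.}
#'   \item{K_M1}{Michaelis constant of type 1 deiodinase, mol/L.}
#'   \item{K30}{T3–TBG association constant, L/mol.}
#'   \item{tshi_mean, tshi_sd}{standardisation mean and SD of the TSH index.}
#'   \item{TBG_default, TBPA_default}{standard plasma carrier protein
#'     concentrations, mol/L.}
#' }
#'
#' @examples
#' k <- model_constants()
#' k$D_T                     # 2.75 mU/L
#' model_constants(TBG_default = 2e-7)$TBG_default
#' @export
model_constants <- function(...) {
  k <- list(
    beta_loglin  = -0.1345,
    alpha_T      = 0.1,
    beta_T       = 1.1e-6,
    D_T          = 2.75,
    K41          = 2e10,
    K42          = 2e8,
    alpha_31     = 0.026,
    beta_31      = 8e-6,
    K_M1         = 5e-7,
    K30          = 2e9,
    tshi_mean    = 2.7,
    tshi_sd      = 0.676,
    # Standard euthyroid plasma carrier protein levels (not kinetic
    # constants; overridable per subject).
    TBG_default  = 3e-7,
    TBPA_default = 4.5e-6
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(k))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown constant(s): ", paste(bad, collapse = ", "),
           "; valid names are: ", paste(names(k), collapse = ", "))
    }
    k[names(dots)] <- dots
  }
  validate_constants(k)
  structure(k, class = "spina_constants")
}

validate_constants <- function(k) {
  num <- vapply(k, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("constants must be finite scalars: ",
         paste(names(k)[!num], collapse = ", "))
  }
  pos <- setdiff(names(k), "beta_loglin")
  neg <- pos[vapply(pos, function(nm) k[[nm]] <= 0, logical(1))]
  if (length(neg)) {
    stop("constants must be strictly positive: ", paste(neg, collapse = ", "),
         " (beta_loglin is the only constant allowed to be negative)")
  }
  invisible(k)
}

#' @export
print.spina_constants <- function(x, ...) {
  cat("<spina_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read model constants from a key/value configuration file
#'
#' Reads a plain-text configuration in the form `symbol = value [unit]`
#' (one constant per line, `#` comments allowed) and returns a validated
#' [model_constants()] object. The unit token is informational and checked
#' only for presence, not converted, so a configuration must state values in
#' the canonical units documented in [model_constants()]. Decimal commas
#' (e.g. `2,75`) are accepted and parsed as decimal points. A shipped example
#' for adult humans is available via
#' `system.file("extdata", "constants_human.txt", package = "thyrostasis")`.
#'
#' @param path path to the configuration file.
#' @return A `spina_constants` object.
#' @export
read_constants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("cannot parse constants line: '", ln, "'")
    key <- trimws(parts[1])
    val_tok <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]][1]
    val <- suppressWarnings(as.numeric(gsub(",", ".", val_tok, fixed = TRUE)))
    if (is.na(val)) stop("non-numeric value for '", key, "': '", val_tok, "'")
    over[[key]] <- val
  }
  do.call(model_constants, over)
}

# Supported unit labels per quantity and their factor to the canonical unit
# (TSH mIU/L; free hormones pmol/L; total hormones and rT3 nmol/L).
# Mass-unit factors follow from the molar masses above, e.g. for FT4
#   1 ng/dL = 10 ng/L = 1e-8 g/L / 776.87 g/mol = 12.872 pmol/L.
.unit_table <- function() {
  list(
    tsh = c("mIU/L" = 1, "uIU/mL" = 1, "µIU/mL" = 1, "mU/L" = 1),
    ft4 = c("pmol/L" = 1, "ng/dL" = 1e4 / .MM_T4),
    ft3 = c("pmol/L" = 1, "pg/mL" = 1e3 / .MM_T3),
    tt4 = c("nmol/L" = 1, "ug/dL" = 1e4 / .MM_T4, "µg/dL" = 1e4 / .MM_T4,
            "ng/dL" = 1e2 / .MM_T4, "ng/mL" = 1e3 / .MM_T4),
    tt3 = c("nmol/L" = 1, "ug/dL" = 1e4 / .MM_T3, "µg/dL" = 1e4 / .MM_T3,
            "ng/dL" = 1e2 / .MM_T3, "ng/mL" = 1e3 / .MM_T3),
    rt3 = c("nmol/L" = 1, "ug/dL" = 1e4 / .MM_T3, "µg/dL" = 1e4 / .MM_T3,
            "ng/dL" = 1e2 / .MM_T3, "ng/mL" = 1e3 / .MM_T3)
  )
}

#' Convert a lab value to its canonical unit
#'
#' Canonical units are mIU/L for TSH, pmol/L for free hormones and nmol/L for
#' total hormones and reverse T3. Mass units are converted via the molar
#' masses of T4 (776.87 g/mol) and T3/rT3 (651.0 g/mol). Normalisation is
#' idempotent: a value already in the canonical unit is returned unchanged.
#'
#' @param raw_value numeric vector of measured values (non-negative).
#' @param quantity one of `"tsh"`, `"ft4"`, `"ft3"`, `"tt4"`, `"tt3"`,
#'   `"rt3"` (case-insensitive).
#' @param unit unit label the value is expressed in; see Details.
#'
#' @details Supported labels: TSH `mIU/L`, `mU/L`, `uIU/mL`; FT4 `pmol/L`,
#' `ng/dL`; FT3 `pmol/L`, `pg/mL`; TT4/TT3/rT3 `nmol/L`, `ug/dL`, `ng/dL`,
#' `ng/mL`.
#'
#' @return Numeric vector in the canonical unit for `quantity`.
#' @examples
#' normalize_units(1.2, "ft4", "ng/dL")   # 15.45 pmol/L
#' normalize_units(2.1, "tsh", "uIU/mL")  # 2.1 mIU/L
#' @export
normalize_units <- function(raw_value, quantity, unit) {
  stopifnot(is.numeric(raw_value))
  if (any(raw_value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  tab <- .unit_table()
  quantity <- tolower(quantity)
  if (!quantity %in% names(tab)) {
    stop("unknown quantity '", quantity, "'; supported: ",
         paste(names(tab), collapse = ", "))
  }
  units <- tab[[quantity]]
  # accept a micro sign spelled as "u"
  key <- match(unit, names(units))
  if (is.na(key)) {
    stop("unknown unit '", unit, "' for ", quantity, "; supported labels: ",
         paste(unique(names(units)), collapse = ", "))
  }
  raw_value * unname(units[key])
}

#' Convert a picomolar concentration to SI (mol/L)
#'
#' The diagnostic equations apply their binding and kinetic constants to
#' concentrations in mol/L while lab panels carry pmol/L; this is the single
#' scaling used on that path (exact power-of-ten, exactly invertible).
#'
#' @param panel_value numeric vector in pmol/L, non-negative.
#' @return The same values in mol/L.
#' @examples
#' to_si_concentration(15)  # 1.5e-11 mol/L
#' @export
to_si_concentration <- function(panel_value) {
  stopifnot(is.numeric(panel_value))
  if (any(panel_value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative")
  }
  panel_value * 1e-12
}
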