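# Calculated structure parameters of thyroid homeostasis: SPINA-GT, SPINA-GD,
# SPINA-GTS, hormone ratios, TTSI, TSH index and its standardised form.
#
# GT and GD invert the steady-state transfer functions of thyroid and
# peripheral deiodination, so that a (TSH, FT4) or (FT4, FT3) pair plus the
# binding/kinetic constants yields the organ's maximal secretion or
# conversion rate. All concentrations are converted to mol/L internally; GT
# is reported in pmol/s and GD in nmol/s, the conventional reporting scales.

#' Sum activity of peripheral deiodinases (SPINA-GD)
#'
#' Maximum stimulated T3 production rate of the step-up deiodinases, inferred
#' from an FT4/FT3 pair at equilibrium:
#' \deqn{\hat G_D = \frac{\beta_{31} (K_{M1} + [FT4]) (1 + K_{30}[TBG]) [FT3]}
#'                       {\alpha_{31} [FT4]}}
#' with concentrations in mol/L. Typical euthyroid values are 20–40 nmol/s.
#' With standard (rather than measured) TBG the result is overestimated in
#' non-thyroidal illness.
#'
#' @param ft4 free T4 in pmol/L, strictly positive.
#' @param ft3 free T3 in pmol/L, non-negative.
#' @param tbg plasma thyroxine-binding globulin in mol/L; `NULL` uses
#'   `constants$TBG_default`.
#' @param constants a [model_constants()] object.
#' @return SPINA-GD in nmol/s (vectorised over the hormone arguments).
#' @examples
#' spina_gd(ft4 = 15, ft3 = 4.1)
#' @export
spina_gd <- function(ft4, ft3, tbg = NULL, constants = model_constants()) {
  k <- constants
  if (is.null(tbg)) tbg <- k$TBG_default
  stopifnot(is.numeric(ft4), is.numeric(ft3), is.numeric(tbg))
  if (any(!is.finite(ft4)) || any(ft4 <= 0)) {
    stop("spina_gd: ft4 must be finite and strictly positive ",
         "(it appears in the denominator)")
  }
  if (any(ft3 < 0)) stop("spina_gd: ft3 must be non-negative")
  ft4_si <- to_si_concentration(ft4)
  ft3_si <- to_si_concentration(ft3)
  gd_mol <- k$beta_31 * (k$K_M1 + ft4_si) * (1 + k$K30 * tbg) * ft3_si /
    (k$alpha_31 * ft4_si)
  gd_mol * 1e9
}

#' Thyroid's secretory capacity (SPINA-GT)
#'
#' Maximum amount of T4 the thyroid can secrete per unit time under
#' stimulated conditions, inferred from a TSH/FT4 pair at equilibrium:
#' \deqn{\hat G_T = \frac{\beta_T (D_T + [TSH]) (1 + K_{41}[TBG] +
#'       K_{42}[TBPA]) [FT4]}{\alpha_T [TSH]}}
#' with FT4 in mol/L and TSH in mU/L. Typical euthyroid values are
#' 1.4–8.7 pmol/s.
#'
#' Undetectable ("< x") TSH must be resolved upstream; the calculator
#' refuses zero TSH rather than imputing a censored value.
#'
#' @param tsh serum TSH in mIU/L, strictly positive.
#' @param ft4 free T4 in pmol/L, non-negative.
#' @param tbg plasma TBG in mol/L; `NULL` uses the standard value.
#' @param tbpa plasma transthyretin in mol/L; `NULL` uses the standard value.
#' @inheritParams spina_gd
#' @return SPINA-GT in pmol/s (vectorised).
#' @examples
#' spina_gt(tsh = 1.5, ft4 = 15)
#' @export
spina_gt <- function(tsh, ft4, tbg = NULL, tbpa = NULL,
                     constants = model_constants()) {
  k <- constants
  if (is.null(tbg)) tbg <- k$TBG_default
  if (is.null(tbpa)) tbpa <- k$TBPA_default
  stopifnot(is.numeric(tsh), is.numeric(ft4))
  if (any(!is.finite(tsh)) || any(tsh <= 0)) {
    stop("spina_gt: tsh must be finite and strictly positive; censored ",
         "(undetectable) TSH cannot be used for GT")
  }
  if (any(ft4 < 0)) stop("spina_gt: ft4 must be non-negative")
  ft4_si <- to_si_concentration(ft4)
  gt_mol <- k$beta_T * (k$D_T + tsh) * (1 + k$K41 * tbg + k$K42 * tbpa) *
    ft4_si / (k$alpha_T * tsh)
  gt_mol * 1e12
}

#' Specific thyroid secretory capacity (SPINA-GTS)
#'
#' SPINA-GT per millilitre of (sonographically determined) thyroid volume:
#' the maximum T4 output 1 mL of thyroid tissue can produce per second.
#'
#' @param gt SPINA-GT in pmol/s.
#' @param volume thyroid volume in mL, strictly positive.
#' @return GTS in pmol/s per mL (vectorised).
#' @export
spina_gts <- function(gt, volume) {
  stopifnot(is.numeric(gt), is.numeric(volume))
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    stop("spina_gts: thyroid volume must be strictly positive")
  }
  gt / volume
}

#' Molar T3/T4 and T3/rT3 ratios
#'
#' The T3/T4 ratio is a crude index of deiodination; it can be formed from
#' free hormones or from total hormones, but not across families. The T3/rT3
#' ratio gauges the relative contribution of step-up (outer-ring) versus
#' step-down (inner-ring) deiodination; it is formed from FT3 (pmol/L) and
#' rT3 (nmol/L) after harmonising both to a common molar scale.
#'
#' @param panel a one-row data frame / list with canonical-unit fields among
#'   `ft3`, `ft4`, `tt3`, `tt4`, `rt3` (see [hormone_panel()]).
#' @param family which measurement family to use for T3/T4: `"auto"` prefers
#'   free hormones and falls back on totals.
#' @return A list with `t3_t4_ratio`, `t3_rt3_ratio` (either may be `NA` when
#'   inputs are missing) and `flags` recording which family was used.
#' @examples
#' hormone_ratios(list(ft3 = 4.5, ft4 = 16))
#' @export
hormone_ratios <- function(panel, family = c("auto", "free", "total")) {
  family <- match.arg(family)
  g <- function(nm) {
    v <- panel[[nm]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v)
  }
  ft3 <- g("ft3"); ft4 <- g("ft4"); tt3 <- g("tt3"); tt4 <- g("tt4")
  rt3 <- g("rt3")
  flags <- character(0)

  use_free <- switch(family,
    free  = TRUE,
    total = FALSE,
    auto  = is.finite(ft3) && is.finite(ft4)
  )
  if (use_free) {
    num <- ft3; den <- ft4; flags <- c(flags, "t3_t4 from free hormones")
  } else {
    num <- tt3; den <- tt4; flags <- c(flags, "t3_t4 from total hormones")
  }
  if (is.finite(num) && is.finite(den)) {
    if (den == 0) stop("hormone_ratios: zero T4 denominator")
    t3_t4 <- num / den
  } else {
    t3_t4 <- NA_real_
    flags <- flags[-length(flags)]
  }

  if (is.finite(ft3) && is.finite(rt3)) {
    if (rt3 == 0) stop("hormone_ratios: zero rT3 denominator")
    # FT3 is pmol/L, rT3 nmol/L: bring rT3 to pmol/L before dividing.
    t3_rt3 <- ft3 / (rt3 * 1e3)
  } else {
    t3_rt3 <- NA_real_
  }
  list(t3_t4_ratio = t3_t4, t3_rt3_ratio = t3_rt3, flags = flags)
}

#' Thyrotroph T4 Sensitivity Index (TTSI)
#'
#' Screening statistic for thyroid hormone resistance,
#' \eqn{TTSI = 100 \cdot [TSH] \cdot [FT4] / l_u}, where \eqn{l_u} is the
#' assay's upper reference limit for FT4. A subject with TSH of 1 mU/L and
#' FT4 exactly at the upper limit scores 100. There is no default for
#' `lu` — it is assay-dependent and must be supplied.
#'
#' @param tsh serum TSH in mIU/L.
#' @param ft4 free T4 in pmol/L.
#' @param lu upper FT4 reference limit in pmol/L, strictly positive.
#' @return TTSI (dimensionless, vectorised).
#' @examples
#' ttsi(tsh = 1, ft4 = 21, lu = 21)  # 100
#' @export
ttsi <- function(tsh, ft4, lu) {
  if (missing(lu) || is.null(lu) || any(is.na(lu))) {
    stop("ttsi: the upper FT4 reference limit 'lu' is assay-dependent and ",
         "has no default; it must be supplied")
  }
  stopifnot(is.numeric(tsh), is.numeric(ft4), is.numeric(lu))
  if (any(lu <= 0)) stop("ttsi: lu must be strictly positive")
  if (any(tsh < 0) || any(ft4 < 0)) stop("ttsi: hormone values must be >= 0")
  100 * tsh * ft4 / lu
}

#' Jostel's TSH index
#'
#' Log-linear measure of thyrotropic pituitary function,
#' \eqn{TSHI = \ln[TSH] - \beta\,[FT4]}, with FT4 in pmol/L and
#' \eqn{\beta = -0.1345} per pmol/L, i.e. the index *rises* with FT4: a TSH
#' that stays high despite high FT4 signals a vigorous thyrotropic response.
#' Low values flag thyrotropic (central) insufficiency.
#'
#' @inheritParams spina_gt
#' @param constants a [model_constants()] object; `beta_loglin` and the
#'   standardisation moments are taken from it.
#' @return TSHI (dimensionless, vectorised).
#' @seealso [stshi()] for the z-standardised form.
#' @examples
#' tshi(tsh = 1.5, ft4 = 15)
#' @export
tshi <- function(tsh, ft4, constants = model_constants()) {
  stopifnot(is.numeric(tsh), is.numeric(ft4))
  if (any(!is.finite(tsh)) || any(tsh <= 0)) {
    stop("tshi: tsh must be strictly positive (logarithm undefined at 0)")
  }
  if (any(ft4 < 0)) stop("tshi: ft4 must be non-negative")
  log(tsh) - constants$beta_loglin * ft4
}

#' Standardised TSH index
#'
#' z-standardisation of [tshi()] against its population mean (2.7) and
#' standard deviation (0.676): \eqn{sTSHI = (TSHI - 2.7)/0.676}.
#'
#' @param tshi_value raw TSH index value(s).
#' @inheritParams tshi
#' @return sTSHI (dimensionless, vectorised).
#' @export
stshi <- function(tshi_value, constants = model_constants()) {
  stopifnot(is.numeric(tshi_value))
  if (any(!is.finite(tshi_value))) stop("stshi: tshi_value must be finite")
  (tshi_value - constants$tshi_mean) / constants$tshi_sd
}

#' Repeatability of a repeatedly measured parameter
#'
#' Variance-component repeatability
#' \eqn{e = \sigma^2_{inter} / (\sigma^2_{intra} + \sigma^2_{inter})}:
#' the share of total variance attributable to stable between-subject
#' differences. Values near 1 mark a parameter that behaves like an
#' individual constant; values near 0 mark a parameter dominated by
#' within-subject fluctuation.
#'
#' Components are estimated by the one-way random-effects method of moments:
#' \eqn{\hat\sigma^2_{intra} = MS_{within}} and
#' \eqn{\hat\sigma^2_{inter} = \max(0, (MS_{between} - MS_{within})/n_0)}
#' with \eqn{n_0 = (N - \sum_i k_i^2/N)/(s-1)} the effective replicate count
#' (equal to the common \eqn{k} for balanced designs). The estimate is
#' clipped to \eqn{[0, 1]}.
#'
#' @param values numeric vector of measurements.
#' @param subjects subject identifier parallel to `values`.
#' @return A list with `e`, `var_inter`, `var_intra`, `n_subjects`,
#'   `n_measurements` and a character vector `flags` (contains
#'   `"degenerate: zero total variance"` when every measurement is
#'   identical, in which case `e` is defined as 0).
#' @examples
#' set.seed(1)
#' subj <- rep(1:20, each = 2)
#' x <- rnorm(20)[subj] + rnorm(40, sd = 0.3)
#' repeatability(x, subj)$e
#' @export
repeatability <- function(values, subjects) {
  stopifnot(is.numeric(values), length(values) == length(subjects))
  keep <- is.finite(values) & !is.na(subjects)
  values <- values[keep]
  subjects <- factor(subjects[keep])
  k_i <- as.integer(table(subjects))
  s <- nlevels(subjects)
  if (s < 2L || any(k_i < 2L)) {
    stop("repeatability: need >= 2 subjects, each with >= 2 measurements")
  }
  N <- length(values)
  grand <- mean(values)
  means <- tapply(values, subjects, mean)
  ss_b <- sum(k_i * (means - grand)^2)
  ss_w <- sum((values - means[subjects])^2)
  ms_b <- ss_b / (s - 1)
  ms_w <- ss_w / (N - s)
  n0 <- (N - sum(k_i^2) / N) / (s - 1)
  var_intra <- ms_w
  var_inter <- max(0, (ms_b - ms_w) / n0)
  flags <- character(0)
  tot <- var_intra + var_inter
  if (tot == 0) {
    e <- 0
    flags <- c(flags, "degenerate: zero total variance")
  } else {
    e <- min(1, max(0, var_inter / tot))
  }
  list(e = e, var_inter = var_inter, var_intra = var_intra,
       n_subjects = s, n_measurements = N, flags = flags)
}
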