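# Forward nonlinear model of the pituitary-thyroid feedback loop.
#
# Transfer functions:
#   thyroid:    FT4 = alpha_T GT TSH / (beta_T (D_T + TSH) (1 + K41 TBG + K42 TBPA))
#               -- Michaelis-Menten in TSH, damped by plasma protein binding;
#                  the exact inverse of the SPINA-GT estimator.
#   periphery:  FT3 = alpha_31 GD FT4 / (beta_31 (K_M1 + FT4) (1 + K30 TBG))
#               -- the exact inverse of the SPINA-GD estimator.
#   pituitary:  TSH = GH TRH / ((DH + TRH) (1 + LS FT3c)), FT3c = GD2 c2 FT4
#               -- Michaelis-Menten TRH drive with noncompetitive divisive
#                  inhibition by centrally produced (type 2 deiodinase) T3.
#                  The central deiodination step is linearised in FT4, since
#                  serum FT4 (tens of pmol/L) is far below any plausible
#                  Michaelis constant of D2.
#
# Calibration (performed once in the constructor): GH, LS and c2 are fixed
# so that the euthyroid reference configuration has its equilibrium at
# TSH = 1.5 mU/L, FT4 = 15 pmol/L, with GD = 25 nmol/s, central T3 equal to
# peripheral FT3 at reference, and an effective pituitary inhibition slope
# LS * c2 = 0.8 L/pmol chosen jointly with the reference-region spreads (see
# build_region) so that the shipped region reproduces the published worked
# classifications.

.TSH_REF <- 1.5   # mU/L, euthyroid reference equilibrium
.FT4_REF <- 15    # pmol/L
.GD_REF  <- 25    # nmol/s
.PIT_SLOPE <- 0.8 # L/pmol, effective divisive-inhibition slope LS * c2

#' Parameters of the pituitary-thyroid feedback model
#'
#' Constructs a validated parameter set for the nonlinear feedback loop.
#' Called with no arguments it returns the calibrated euthyroid reference
#' configuration, whose solved equilibrium is TSH = 1.5 mU/L,
#' FT4 = 15 pmol/L (with FT3 about 4.1 pmol/L). The thyroid secretory
#' capacity of that reference, about 3.23 pmol/s, is derived by evaluating
#' the SPINA-GT estimator at the reference pair, so that forward model and
#' estimator are exact inverses.
#'
#' @param g_t thyroid secretory capacity, pmol/s.
#' @param g_d peripheral deiodinase sum activity, nmol/s.
#' @param g_h pituitary (thyrotroph) secretory capacity, mU/L-scaled
#'   secretion units fixed by calibration.
#' @param d_h half-maximal TRH drive constant (dimensionless drive units).
#' @param trh_drive constant hypothalamic drive; 1 = euthyroid.
#' @param l_s central divisive-inhibition strength per pmol/L of central T3.
#' @param g_d2 central type 2 deiodinase activity scaling; 1 = euthyroid.
#'   Values above 1 (central hyperdeiodination) suppress TSH — the
#'   thyrotropic-adaptation lever.
#' @param c2 central deiodination slope: central T3 per pmol/L FT4 at
#'   `g_d2 = 1`.
#' @param tau_t4,tau_t3,tau_tsh first-order time constants of the plasma
#'   pools, seconds. Defaults correspond to half-lives of about 7 days (T4),
#'   1 day (T3) and 50 minutes (TSH).
#' @param tbg,tbpa plasma carrier protein levels, mol/L (standard values by
#'   default).
#' @param constants a [model_constants()] object.
#' @return An object of class `feedback_parameters` (named list).
#' @examples
#' p <- feedback_parameters()
#' solve_equilibrium(p)
#' @export
feedback_parameters <- function(g_t = NULL, g_d = .GD_REF, g_h = NULL,
                                d_h = 1, trh_drive = 1, l_s = NULL,
                                g_d2 = 1, c2 = NULL,
                                tau_t4 = 7 * 86400 / log(2),
                                tau_t3 = 86400 / log(2),
                                tau_tsh = 50 * 60 / log(2),
                                tbg = NULL, tbpa = NULL,
                                constants = model_constants()) {
  k <- constants
  if (is.null(tbg)) tbg <- k$TBG_default
  if (is.null(tbpa)) tbpa <- k$TBPA_default
  # reference GT: the capacity whose thyroid curve passes through the
  # euthyroid reference point
  if (is.null(g_t)) g_t <- spina_gt(.TSH_REF, .FT4_REF, tbg, tbpa, k)
  if (is.null(c2)) {
    # central T3 per unit FT4, anchored to peripheral FT3 at reference
    ft3_ref <- .peripheral_ft3_raw(.FT4_REF, .GD_REF, tbg, k)
    c2 <- ft3_ref / .FT4_REF
  }
  if (is.null(l_s)) l_s <- .PIT_SLOPE / c2
  if (is.null(g_h)) {
    g_h <- .TSH_REF * (1 + l_s * c2 * .FT4_REF) * (d_h + trh_drive) / trh_drive
  }
  p <- list(g_t = g_t, g_d = g_d, g_h = g_h, d_h = d_h,
            trh_drive = trh_drive, l_s = l_s, g_d2 = g_d2, c2 = c2,
            tau_t4 = tau_t4, tau_t3 = tau_t3, tau_tsh = tau_tsh,
            tbg = tbg, tbpa = tbpa, constants = k)
  num <- setdiff(names(p), "constants")
  bad <- num[vapply(num, function(nm) {
    v <- p[[nm]]; !is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0
  }, logical(1))]
  if (length(bad)) {
    stop("feedback_parameters: strictly positive scalars required for: ",
         paste(bad, collapse = ", "))
  }
  structure(p, class = "feedback_parameters")
}

#' @export
print.feedback_parameters <- function(x, ...) {
  cat("<feedback_parameters>\n")
  cat(sprintf("  g_t  %.4f pmol/s   g_d %.2f nmol/s   g_h %.3f\n",
              x$g_t, x$g_d, x$g_h))
  cat(sprintf("  g_d2 %.3f   trh_drive %.3f   l_s %.4f   c2 %.4f\n",
              x$g_d2, x$trh_drive, x$l_s, x$c2))
  cat(sprintf("  tau (s): T4 %.0f  T3 %.0f  TSH %.0f\n",
              x$tau_t4, x$tau_t3, x$tau_tsh))
  invisible(x)
}

# raw transfers (scalar params given explicitly, used by calibration and the
# integrator so scheduled parameters can be swapped in)
.thyroid_response_raw <- function(tsh, g_t, tbg, tbpa, k) {
  k$alpha_T * g_t * tsh /
    (k$beta_T * (k$D_T + tsh) * (1 + k$K41 * tbg + k$K42 * tbpa))
}

.peripheral_ft3_raw <- function(ft4, g_d, tbg, k) {
  ft4_si <- ft4 * 1e-12
  k$alpha_31 * (g_d * 1e-9) * ft4_si /
    (k$beta_31 * (k$K_M1 + ft4_si) * (1 + k$K30 * tbg)) * 1e12
}

.pituitary_response_raw <- function(ft4, g_h, d_h, trh, l_s, c2, g_d2) {
  ft3_c <- g_d2 * c2 * ft4
  g_h * trh / ((d_h + trh) * (1 + l_s * ft3_c))
}

#' Thyroid characteristic: FT4 secreted at a given TSH
#'
#' Michaelis-Menten response of the thyroid to TSH stimulation, damped by
#' plasma protein binding; saturates at high TSH with EC50 `D_T`
#' (2.75 mU/L). Exact inverse of [spina_gt()]: for any `tsh > 0`,
#' `spina_gt(tsh, thyroid_response(tsh, p))` returns `p$g_t`.
#'
#' @param tsh TSH in mU/L (vectorised), non-negative.
#' @param params a [feedback_parameters()] object.
#' @return FT4 in pmol/L.
#' @export
thyroid_response <- function(tsh, params = feedback_parameters()) {
  stopifnot(inherits(params, "feedback_parameters"), all(tsh >= 0))
  .thyroid_response_raw(tsh, params$g_t, params$tbg, params$tbpa,
                        params$constants)
}

#' Peripheral deiodination: FT3 produced from a given FT4
#'
#' Michaelis-Menten conversion of T4 to T3 by the step-up deiodinases.
#' Because serum FT4 is five orders of magnitude below the Michaelis
#' constant `K_M1`, the response is nearly linear over the physiological
#' range. Exact inverse of [spina_gd()].
#'
#' @param ft4 FT4 in pmol/L (vectorised), non-negative.
#' @inheritParams thyroid_response
#' @return FT3 in pmol/L.
#' @export
peripheral_ft3 <- function(ft4, params = feedback_parameters()) {
  stopifnot(inherits(params, "feedback_parameters"), all(ft4 >= 0))
  .peripheral_ft3_raw(ft4, params$g_d, params$tbg, params$constants)
}

#' Pituitary characteristic: TSH released at a given FT4
#'
#' Thyrotroph response: Michaelis-Menten TRH drive subject to noncompetitive
#' divisive inhibition by central T3, which is produced from serum FT4 by
#' pituitary type 2 deiodinase (`g_d2` scales that step). Strictly
#' decreasing in FT4; maximal (`g_h * trh / (d_h + trh)`) at FT4 = 0.
#'
#' @param ft4 FT4 in pmol/L (vectorised), non-negative.
#' @inheritParams thyroid_response
#' @return TSH in mU/L.
#' @export
pituitary_response <- function(ft4, params = feedback_parameters()) {
  stopifnot(inherits(params, "feedback_parameters"), all(ft4 >= 0))
  .pituitary_response_raw(ft4, params$g_h, params$d_h, params$trh_drive,
                          params$l_s, params$c2, params$g_d2)
}

#' Solve the feedback loop for its equilibrium point
#'
#' Finds the steady state (the "setpoint") where the pituitary and thyroid
#' characteristics intersect, by bracketed bisection on log TSH over
#' \eqn{[10^{-6}, 10^{3}]} mU/L. The composed map
#' `pituitary_response(thyroid_response(tsh))` is strictly decreasing in
#' `tsh` while the identity is increasing, so the fixed point is unique.
#'
#' @inheritParams thyroid_response
#' @param tol bisection tolerance on log10 TSH.
#' @param max_iter maximum bisection iterations.
#' @return A list of class `equilibrium_point` with `tsh` (mU/L), `ft4`
#'   (pmol/L), `ft3` (pmol/L), `ft3_central` (pmol/L), `converged` and
#'   `residual` (fixed-point residual in mU/L).
#' @examples
#' eq <- solve_equilibrium(feedback_parameters())
#' c(eq$tsh, eq$ft4)  # 1.5, 15
#' @export
solve_equilibrium <- function(params = feedback_parameters(), tol = 1e-10,
                              max_iter = 200L) {
  stopifnot(inherits(params, "feedback_parameters"))
  f <- function(log_tsh) {
    tsh <- 10^log_tsh
    ft4 <- thyroid_response(tsh, params)
    pituitary_response(ft4, params) - tsh
  }
  lo <- -6; hi <- 3
  flo <- f(lo); fhi <- f(hi)
  if (!(flo > 0 && fhi < 0)) {
    return(structure(list(tsh = NA_real_, ft4 = NA_real_, ft3 = NA_real_,
                          ft3_central = NA_real_, converged = FALSE,
                          residual = NA_real_),
                     class = "equilibrium_point"))
  }
  iter <- 0L
  while (hi - lo > tol && iter < max_iter) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  tsh <- 10^((lo + hi) / 2)
  ft4 <- thyroid_response(tsh, params)
  ft3 <- peripheral_ft3(ft4, params)
  res <- abs(pituitary_response(ft4, params) - tsh)
  structure(list(tsh = tsh, ft4 = ft4, ft3 = ft3,
                 ft3_central = params$g_d2 * params$c2 * ft4,
                 converged = iter < max_iter, residual = res),
            class = "equilibrium_point")
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_point> TSH %.4g mU/L  FT4 %.4g pmol/L  FT3 %.4g pmol/L%s\n",
    x$tsh, x$ft4, x$ft3,
    if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}
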