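# Bivariate (TSH, FT4) reference region built from percentile characteristic
# curves of pituitary and thyroid, and classification of lab panels into
# homeostatic patterns.
#
# The region is the intersection of two bands: the pituitary band (between
# the TSH-FT4 response curves of a thyrotroph capacity G_H at its low and
# high population percentiles) and the thyroid band (between the FT4-TSH
# response curves of a thyroid capacity G_T at its percentiles). Because the
# pituitary curves are strictly decreasing and the thyroid curves strictly
# increasing, the intersection is a single kite-shaped area whose four
# corners are curve intersections.
#
# The shipped default log-normal spreads of G_T and G_H are a calibration:
# the percentile data behind the published region are not public, so the
# spreads were fixed once such that (a) the implied univariate bands are
# about TSH 0.4-4 mU/L and FT4 10-22 pmol/L, and (b) the four published
# worked classifications reproduce — (6, 13) euthyroid, (6, 10) primary
# hypothyroid, (0.5, 11) central hypothyroid, (0.5, 16) euthyroid (TSH,
# FT4). See the calibration script in tools/ and the methods vignette.

.GT_SDLOG <- 0.464  # calibrated spread of thyroid capacity G_T
.GH_SDLOG <- 0.67   # calibrated spread of thyrotroph capacity G_H
.UNIVARIATE_TSH <- c(0.4, 4)   # mU/L, conventional univariate band
.UNIVARIATE_FT4 <- c(10, 22)   # pmol/L

#' Default log-normal capacity distributions
#'
#' Population distributions of thyroid (`g_t`) and pituitary (`g_h`)
#' secretory capacities used to build the default reference region. Medians
#' are the calibrated euthyroid reference capacities; the log-scale spreads
#' are the shipped region calibration.
#'
#' @param params a [feedback_parameters()] object supplying the medians.
#' @return A list with elements `g_t` and `g_h`, each `c(meanlog, sdlog)`.
#' @export
default_capacity_distributions <- function(params = feedback_parameters()) {
  list(g_t = c(meanlog = log(params$g_t), sdlog = .GT_SDLOG),
       g_h = c(meanlog = log(params$g_h), sdlog = .GH_SDLOG))
}

.with_params <- function(params, ...) {
  over <- list(...)
  for (nm in names(over)) params[[nm]] <- over[[nm]]
  class(params) <- "feedback_parameters"
  params
}

#' Build the bihormonal TSH-FT4 reference region
#'
#' Instantiates the pituitary transfer at the `lo` and `hi` percentiles of
#' the `gh_distribution` and the thyroid transfer at the percentiles of the
#' `gt_distribution`, samples each characteristic on a grid (FT4 on
#' \[1, 60\] pmol/L for the pituitary, TSH log-spaced on \[0.01, 100\] mU/L
#' for the thyroid), locates the four corner intersections by bisection and
#' assembles the closed kite polygon by walking the boundary arcs between
#' corners.
#'
#' @param gt_distribution `c(meanlog, sdlog)` of the log-normal thyroid
#'   capacity (pmol/s).
#' @param gh_distribution `c(meanlog, sdlog)` of the log-normal pituitary
#'   capacity (calibrated secretion units).
#' @param percentiles lower and upper percentile (in percent) defining the
#'   region; must straddle 50.
#' @param params a [feedback_parameters()] object for everything that is not
#'   a capacity.
#' @param n_grid points per characteristic curve.
#' @return An object of class `reference_region`: curves, corners, polygon,
#'   the univariate comparison rectangle and the calibration metadata.
#' @examples
#' region <- build_region()
#' classify_panel(tsh = 6, ft4 = 13, region = region)
#' @export
build_region <- function(gt_distribution = NULL, gh_distribution = NULL,
                         percentiles = c(2.5, 97.5),
                         params = feedback_parameters(), n_grid = 512) {
  defaults <- default_capacity_distributions(params)
  if (is.null(gt_distribution)) gt_distribution <- defaults$g_t
  if (is.null(gh_distribution)) gh_distribution <- defaults$g_h
  lo <- percentiles[1] / 100; hi <- percentiles[2] / 100
  if (!(lo > 0 && lo < 0.5 && hi > 0.5 && hi < 1)) {
    stop("build_region: percentiles must satisfy 0 < lo < 50 < hi < 100")
  }
  q <- function(d, p) stats::qlnorm(p, d[[1]], d[[2]])
  gt_lo <- q(gt_distribution, lo); gt_hi <- q(gt_distribution, hi)
  gh_lo <- q(gh_distribution, lo); gh_hi <- q(gh_distribution, hi)

  pit <- function(ft4, g_h) {
    pituitary_response(ft4, .with_params(params, g_h = g_h))
  }
  thy <- function(tsh, g_t) {
    thyroid_response(tsh, .with_params(params, g_t = g_t))
  }

  ft4_grid <- seq(1, 60, length.out = n_grid)
  tsh_grid <- 10^seq(log10(0.01), log10(100), length.out = n_grid)
  curves <- list(
    pituitary_lo = tibble::tibble(ft4 = ft4_grid, tsh = pit(ft4_grid, gh_lo)),
    pituitary_hi = tibble::tibble(ft4 = ft4_grid, tsh = pit(ft4_grid, gh_hi)),
    thyroid_lo   = tibble::tibble(tsh = tsh_grid, ft4 = thy(tsh_grid, gt_lo)),
    thyroid_hi   = tibble::tibble(tsh = tsh_grid, ft4 = thy(tsh_grid, gt_hi))
  )

  # corner: intersection of one pituitary and one thyroid curve; solved on
  # tsh, where ft4(thyroid) - ft4(pituitary inverse) is strictly increasing
  corner <- function(g_h, g_t) {
    f <- function(tsh) {
      ft4_t <- thy(tsh, g_t)
      pit(ft4_t, g_h) - tsh
    }
    # f is strictly decreasing in tsh; positive at tiny tsh
    r <- stats::uniroot(f, lower = 1e-6, upper = 1e3, tol = 1e-8)
    tsh <- r$root
    c(ft4 = thy(tsh, g_t), tsh = tsh)
  }
  corners <- list(
    hi_lo = corner(gh_hi, gt_lo),  # high TSH / low FT4 corner
    hi_hi = corner(gh_hi, gt_hi),
    lo_hi = corner(gh_lo, gt_hi),
    lo_lo = corner(gh_lo, gt_lo)
  )

  # walk the four boundary arcs: thyroid-lo from corner hi_lo down to lo_lo,
  # pituitary-lo across to lo_hi, thyroid-hi up to hi_hi, pituitary-hi back
  arc_thy <- function(g_t, tsh_from, tsh_to, n = 128) {
    tsh <- exp(seq(log(tsh_from), log(tsh_to), length.out = n))
    cbind(ft4 = thy(tsh, g_t), tsh = tsh)
  }
  arc_pit <- function(g_h, ft4_from, ft4_to, n = 128) {
    ft4 <- seq(ft4_from, ft4_to, length.out = n)
    cbind(ft4 = ft4, tsh = pit(ft4, g_h))
  }
  poly <- rbind(
    arc_thy(gt_lo, corners$hi_lo["tsh"], corners$lo_lo["tsh"]),
    arc_pit(gh_lo, corners$lo_lo["ft4"], corners$lo_hi["ft4"]),
    arc_thy(gt_hi, corners$lo_hi["tsh"], corners$hi_hi["tsh"]),
    arc_pit(gh_hi, corners$hi_hi["ft4"], corners$hi_lo["ft4"])
  )
  polygon <- tibble::tibble(ft4 = poly[, "ft4"], tsh = poly[, "tsh"])

  structure(list(
    curves = curves, corners = corners, polygon = polygon,
    capacities = list(gt_lo = gt_lo, gt_hi = gt_hi,
                      gh_lo = gh_lo, gh_hi = gh_hi),
    distributions = list(g_t = gt_distribution, g_h = gh_distribution),
    percentiles = percentiles,
    univariate = list(tsh = .UNIVARIATE_TSH, ft4 = .UNIVARIATE_FT4),
    params = params
  ), class = "reference_region")
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf("<reference_region> percentiles %.1f-%.1f\n",
              x$percentiles[1], x$percentiles[2]))
  cat(sprintf("  G_T %.3g-%.3g pmol/s   G_H %.3g-%.3g\n",
              x$capacities$gt_lo, x$capacities$gt_hi,
              x$capacities$gh_lo, x$capacities$gh_hi))
  cn <- do.call(rbind, x$corners)
  cat(sprintf("  corners (FT4, TSH): %s\n",
              paste(sprintf("(%.1f, %.2f)", cn[, 1], cn[, 2]), collapse = " ")))
  invisible(x)
}

# boundary evaluations used by the membership test
.region_bounds <- function(region, tsh, ft4) {
  p <- region$params; cap <- region$capacities
  list(
    tsh_lo = pituitary_response(ft4, .with_params(p, g_h = cap$gh_lo)),
    tsh_hi = pituitary_response(ft4, .with_params(p, g_h = cap$gh_hi)),
    ft4_lo = thyroid_response(tsh, .with_params(p, g_t = cap$gt_lo)),
    ft4_hi = thyroid_response(tsh, .with_params(p, g_t = cap$gt_hi))
  )
}

#' Classify a (TSH, FT4) pair against the bihormonal reference region
#'
#' A pair inside the region (boundary inclusive — clinically conservative)
#' is `euthyroid`. Outside, the violated boundary determines the pattern,
#' with pituitary violations taking precedence over thyroid violations in
#' ambiguous corners:
#' \itemize{
#'   \item TSH above the high pituitary curve: the pituitary reports hormone
#'     deficit. FT4 below the low thyroid curve confirms a failing gland
#'     (`primary-hypothyroid-pattern`); FT4 consistent with a normally
#'     responding thyroid marks inappropriate TSH excess
#'     (`central-hyperthyroid-pattern`).
#'   \item TSH below the low pituitary curve: FT4 both above the high
#'     thyroid curve and frankly elevated (above the univariate upper
#'     limit) marks autonomous overproduction
#'     (`primary-hyperthyroid-pattern`); otherwise the TSH is
#'     inappropriately low for the FT4 (`central-hypothyroid-pattern`).
#'     The absolute-FT4 qualifier is needed because the static thyroid band
#'     collapses toward zero FT4 as TSH vanishes, so at suppressed TSH it
#'     carries no information and the pituitary violation must win.
#'   \item TSH within the pituitary band but FT4 outside the thyroid band:
#'     `primary-hypothyroid-pattern` below, `primary-hyperthyroid-pattern`
#'     above.
#' }
#'
#' @param tsh TSH in mU/L (vectorised), positive.
#' @param ft4 FT4 in pmol/L (vectorised), positive.
#' @param region a [build_region()] result.
#' @return Character vector of category labels.
#' @examples
#' region <- build_region()
#' classify_panel(c(6, 6, 0.5, 0.5), c(13, 10, 11, 16), region)
#' @export
classify_panel <- function(tsh, ft4, region) {
  stopifnot(inherits(region, "reference_region"),
            all(tsh > 0), all(ft4 > 0), length(tsh) == length(ft4))
  b <- .region_bounds(region, tsh, ft4)
  eps <- 1e-9
  ge <- function(x, y) x >= y * (1 - eps)
  le <- function(x, y) x <= y * (1 + eps)
  in_pit <- ge(tsh, b$tsh_lo) & le(tsh, b$tsh_hi)
  in_thy <- ge(ft4, b$ft4_lo) & le(ft4, b$ft4_hi)
  out <- character(length(tsh))
  out[in_pit & in_thy] <- "euthyroid"
  hi_p <- !le(tsh, b$tsh_hi)
  lo_p <- !ge(tsh, b$tsh_lo)
  out[hi_p & !ge(ft4, b$ft4_lo)] <- "primary-hypothyroid-pattern"
  out[hi_p & ge(ft4, b$ft4_lo)] <- "central-hyperthyroid-pattern"
  hyper <- !le(ft4, pmax(b$ft4_hi, region$univariate$ft4[2]))
  out[lo_p & hyper] <- "primary-hyperthyroid-pattern"
  out[lo_p & !hyper] <- "central-hypothyroid-pattern"
  rest <- in_pit & !in_thy
  out[rest & !ge(ft4, b$ft4_lo)] <- "primary-hypothyroid-pattern"
  out[rest & !le(ft4, b$ft4_hi)] <- "primary-hyperthyroid-pattern"
  out
}

#' Sweep a capacity parameter and classify the resulting equilibria
#'
#' Solves the feedback equilibrium for each value of `g_t` or `g_h` on a
#' grid and classifies the resulting (TSH, FT4) pair, tracing the
#' development of primary dysfunction (falling `g_t`) or thyrotropic
#' insufficiency (falling `g_h`). Each row also carries the univariate
#' pattern relative to the conventional rectangular bands, which
#' distinguishes subclinical stages (one hormone out of band) from overt
#' ones (both out).
#'
#' @param params baseline [feedback_parameters()].
#' @param parameter `"g_t"` or `"g_h"`.
#' @param grid positive parameter values to sweep.
#' @param region a [build_region()] result (built from `params` by default).
#' @return A tibble with `value`, `tsh`, `ft4`, `ft3`, `converged`,
#'   `category` and `univariate_pattern`, ordered as `grid`.
#' @examples
#' phenotype_sweep(parameter = "g_t",
#'                 grid = feedback_parameters()$g_t * c(1, 0.5, 0.2))
#' @export
phenotype_sweep <- function(params = feedback_parameters(),
                            parameter = c("g_t", "g_h"), grid,
                            region = NULL) {
  parameter <- match.arg(parameter)
  stopifnot(is.numeric(grid), all(grid > 0))
  if (is.null(region)) region <- build_region(params = params)
  n <- length(grid)
  res <- tibble::tibble(value = grid, tsh = NA_real_, ft4 = NA_real_,
                        ft3 = NA_real_, converged = FALSE,
                        category = NA_character_,
                        univariate_pattern = NA_character_)
  for (i in seq_len(n)) {
    p_i <- params
    p_i[[parameter]] <- grid[i]
    class(p_i) <- "feedback_parameters"
    eq <- solve_equilibrium(p_i)
    res$converged[i] <- isTRUE(eq$converged)
    if (!res$converged[i]) next
    res$tsh[i] <- eq$tsh; res$ft4[i] <- eq$ft4; res$ft3[i] <- eq$ft3
    res$category[i] <- classify_panel(eq$tsh, eq$ft4, region)
    res$univariate_pattern[i] <- .univariate_pattern(eq$tsh, eq$ft4,
                                                     region$univariate)
  }
  res
}

.univariate_pattern <- function(tsh, ft4, bands) {
  tsh_in <- tsh >= bands$tsh[1] & tsh <= bands$tsh[2]
  ft4_in <- ft4 >= bands$ft4[1] & ft4 <= bands$ft4[2]
  if (tsh_in && ft4_in) return("euthyroid")
  if (!tsh_in && ft4_in) {
    return(if (tsh > bands$tsh[2]) "subclinical-hypothyroid"
           else "subclinical-hyperthyroid")
  }
  if (tsh > bands$tsh[2] || ft4 < bands$ft4[1]) return("overt-hypothyroid")
  "overt-hyperthyroid"
}

#' Serialise a reference region to JSON
#'
#' Writes curves, corners, polygon vertices and calibration metadata so a
#' region can be rebuilt or plotted outside R. Requires the `jsonlite`
#' package.
#'
#' @param region a [build_region()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_region_json <- function(region, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_region_json requires the 'jsonlite' package")
  }
  payload <- list(
    percentiles = region$percentiles,
    capacities = region$capacities,
    distributions = region$distributions,
    univariate = region$univariate,
    corners = lapply(region$corners, as.list),
    polygon = region$polygon,
    curves = region$curves
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
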