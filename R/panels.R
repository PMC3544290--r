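# Lab-panel containers and the vectorised cohort calculator.

.panel_fields <- c("tsh", "ft4", "ft3", "rt3", "tt4", "tt3",
                   "tbg", "tbpa", "thyroid_volume", "ft4_upper_ref")

#' A single subject's thyroid lab panel
#'
#' Validating constructor for one subject's measurements with units already
#' resolved to the canonical scales (TSH mIU/L, free hormones pmol/L, totals
#' and rT3 nmol/L, carrier proteins mol/L, volume mL). Only `tsh` and `ft4`
#' are commonly required; every other field is optional and may be `NA`.
#'
#' @param tsh serum TSH, mIU/L.
#' @param ft4 free T4, pmol/L.
#' @param ft3 free T3, pmol/L.
#' @param rt3 reverse T3, nmol/L.
#' @param tt4,tt3 total T4 / T3, nmol/L.
#' @param tbg,tbpa subject carrier protein levels, mol/L (default to the
#'   population standard values during calculation when absent).
#' @param thyroid_volume sonographic thyroid volume, mL.
#' @param ft4_upper_ref assay upper reference limit for FT4 (`lu`), pmol/L.
#' @return A one-row tibble of class `hormone_panel`.
#' @examples
#' hormone_panel(tsh = 1.8, ft4 = 14.2, ft3 = 4.3)
#' @export
hormone_panel <- function(tsh = NA_real_, ft4 = NA_real_, ft3 = NA_real_,
                          rt3 = NA_real_, tt4 = NA_real_, tt3 = NA_real_,
                          tbg = NA_real_, tbpa = NA_real_,
                          thyroid_volume = NA_real_,
                          ft4_upper_ref = NA_real_) {
  p <- tibble::tibble(
    tsh = as.numeric(tsh), ft4 = as.numeric(ft4), ft3 = as.numeric(ft3),
    rt3 = as.numeric(rt3), tt4 = as.numeric(tt4), tt3 = as.numeric(tt3),
    tbg = as.numeric(tbg), tbpa = as.numeric(tbpa),
    thyroid_volume = as.numeric(thyroid_volume),
    ft4_upper_ref = as.numeric(ft4_upper_ref)
  )
  for (nm in .panel_fields) {
    v <- p[[nm]]
    if (any(is.finite(v) & v < 0)) stop("hormone_panel: ", nm, " must be >= 0")
  }
  class(p) <- c("hormone_panel", class(p))
  p
}

#' Read a cohort of hormone panels from CSV
#'
#' Expects one row per measurement with a subset of the documented columns
#' (`subject_id`, `visit`, `tsh`, `ft4`, `ft3`, `rt3`, `tt4`, `tt3`, `tbg`,
#' `tbpa`, `volume`, `lu`). Hormone columns may be recorded in any supported
#' unit; pass the label through `units` and they are normalised on read
#' (see [normalize_units()]).
#'
#' @param path CSV file path.
#' @param units optional named character vector mapping hormone columns to
#'   the unit they are recorded in, e.g. `c(ft4 = "ng/dL")`. Unlisted
#'   columns are assumed canonical.
#' @return A tibble in canonical units.
#' @export
read_panels <- function(path, units = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- tibble::as_tibble(df)
  if (!is.null(units)) {
    for (nm in names(units)) {
      if (!nm %in% names(df)) stop("read_panels: no column '", nm, "'")
      df[[nm]] <- normalize_units(df[[nm]], nm, units[[nm]])
    }
  }
  df
}

#' Compute every available structure parameter for a cohort of panels
#'
#' Applies the calculators of this package row-wise to a data frame of lab
#' panels in canonical units and appends result columns. A parameter column
#' is `NA` exactly where a required input is absent; rows falling back on
#' standard carrier-protein values are flagged.
#'
#' @param panels data frame with columns among `tsh`, `ft4`, `ft3`, `rt3`,
#'   `tt4`, `tt3`, `tbg`, `tbpa`, `volume` (or `thyroid_volume`), `lu` (or
#'   `ft4_upper_ref`).
#' @param lu scalar upper FT4 reference limit (pmol/L) used for TTSI when the
#'   panel carries none.
#' @param constants a [model_constants()] object.
#' @return `panels` with columns `gt` (pmol/s), `gd` (nmol/s), `gts`
#'   (pmol/s/mL), `t3_t4_ratio`, `t3_rt3_ratio`, `ttsi`, `tshi`, `stshi` and
#'   a semicolon-joined `flags` column appended.
#' @examples
#' calc_panels(tibble::tibble(tsh = c(1.2, 3.4), ft4 = c(16, 11),
#'                            ft3 = c(4.5, 3.9)))
#' @export
calc_panels <- function(panels, lu = NULL, constants = model_constants()) {
  df <- tibble::as_tibble(panels)
  n <- nrow(df)
  col <- function(nm, alias = NULL) {
    if (nm %in% names(df)) return(as.numeric(df[[nm]]))
    if (!is.null(alias) && alias %in% names(df)) return(as.numeric(df[[alias]]))
    rep(NA_real_, n)
  }
  tsh <- col("tsh"); ft4 <- col("ft4"); ft3 <- col("ft3"); rt3 <- col("rt3")
  tt4 <- col("tt4"); tt3 <- col("tt3")
  tbg <- col("tbg"); tbpa <- col("tbpa")
  vol <- col("volume", "thyroid_volume")
  lu_col <- col("lu", "ft4_upper_ref")
  if (!is.null(lu)) lu_col[is.na(lu_col)] <- lu

  flags <- vector("list", n)
  tbg_eff <- ifelse(is.finite(tbg), tbg, constants$TBG_default)
  tbpa_eff <- ifelse(is.finite(tbpa), tbpa, constants$TBPA_default)

  out <- tibble::tibble(
    gt = NA_real_, gd = NA_real_, gts = NA_real_,
    t3_t4_ratio = NA_real_, t3_rt3_ratio = NA_real_,
    ttsi = NA_real_, tshi = NA_real_, stshi = NA_real_
  )[rep(1L, n), ]

  ok_gt <- is.finite(tsh) & tsh > 0 & is.finite(ft4)
  out$gt[ok_gt] <- spina_gt(tsh[ok_gt], ft4[ok_gt], tbg_eff[ok_gt],
                            tbpa_eff[ok_gt], constants)
  ok_gd <- is.finite(ft4) & ft4 > 0 & is.finite(ft3)
  out$gd[ok_gd] <- spina_gd(ft4[ok_gd], ft3[ok_gd], tbg_eff[ok_gd], constants)
  ok_v <- !is.na(out$gt) & is.finite(vol) & vol > 0
  out$gts[ok_v] <- spina_gts(out$gt[ok_v], vol[ok_v])

  ok_fr <- is.finite(ft3) & is.finite(ft4) & ft4 > 0
  out$t3_t4_ratio[ok_fr] <- ft3[ok_fr] / ft4[ok_fr]
  ok_tr <- !ok_fr & is.finite(tt3) & is.finite(tt4) & tt4 > 0
  out$t3_t4_ratio[ok_tr] <- tt3[ok_tr] / tt4[ok_tr]
  ok_r <- is.finite(ft3) & is.finite(rt3) & rt3 > 0
  out$t3_rt3_ratio[ok_r] <- ft3[ok_r] / (rt3[ok_r] * 1e3)

  ok_tt <- is.finite(tsh) & is.finite(ft4) & is.finite(lu_col) & lu_col > 0
  out$ttsi[ok_tt] <- ttsi(tsh[ok_tt], ft4[ok_tt], lu_col[ok_tt])
  ok_ti <- is.finite(tsh) & tsh > 0 & is.finite(ft4)
  out$tshi[ok_ti] <- tshi(tsh[ok_ti], ft4[ok_ti], constants)
  out$stshi[ok_ti] <- stshi(out$tshi[ok_ti], constants)

  for (i in seq_len(n)) {
    f <- character(0)
    if ((ok_gt[i] || ok_gd[i]) && !is.finite(tbg[i])) f <- c(f, "default TBG used")
    if (ok_gt[i] && !is.finite(tbpa[i])) f <- c(f, "default TBPA used")
    if (ok_tr[i]) f <- c(f, "t3_t4 from total hormones")
    if (ok_fr[i]) f <- c(f, "t3_t4 from free hormones")
    flags[[i]] <- f
  }
  out$flags <- vapply(flags, paste, character(1), collapse = ";")
  tibble::as_tibble(cbind(df, out))
}
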