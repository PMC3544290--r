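# Synthetic cohorts of hormone panels with known ground truth.
#
# Each subject owns stable secretory capacities drawn from log-normal
# population distributions; each visit observes the subject's feedback
# equilibrium through multiplicative log-normal intra-individual variation
# (pulsatility, circadian phase, physiological drift) and assay noise.
# Because the generating capacities are retained, every estimator in the
# package can be checked against its truth.

#' Specification of a synthetic repeated-measures cohort
#'
#' Defaults emulate a small repeatability study: 20 healthy volunteers with
#' two visits each. Capacity distributions default to the shipped region
#' calibration; intra-individual CVs default to published-assay-magnitude
#' placeholders (TSH 20%, FT4 8%, FT3 8%) — TSH varies most within a subject
#' because it is secreted in pulses — with 5% analytical (assay) noise on
#' top. These noise figures are implementation defaults, not literature
#' estimates of any particular assay.
#'
#' @param n_subjects number of subjects.
#' @param visits_per_subject measurements per subject.
#' @param gt_distribution,gh_distribution,gd_distribution `c(meanlog,
#'   sdlog)` log-normal capacity distributions; `NULL` uses the shipped
#'   defaults.
#' @param intra_cv named numeric `c(tsh=, ft4=, ft3=)` intra-individual
#'   coefficients of variation.
#' @param assay_cv named numeric `c(tsh=, ft4=, ft3=)` analytical CVs.
#' @param seed integer seed (mandatory: cohorts are reproducible objects).
#' @param params baseline [feedback_parameters()] for everything that is
#'   not a capacity.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, visits_per_subject = 2,
                        gt_distribution = NULL, gh_distribution = NULL,
                        gd_distribution = NULL,
                        intra_cv = c(tsh = 0.20, ft4 = 0.08, ft3 = 0.08),
                        assay_cv = c(tsh = 0.05, ft4 = 0.05, ft3 = 0.05),
                        seed, params = feedback_parameters()) {
  if (missing(seed) || is.null(seed)) stop("cohort_spec: seed is mandatory")
  defaults <- default_capacity_distributions(params)
  if (is.null(gt_distribution)) gt_distribution <- defaults$g_t
  if (is.null(gh_distribution)) gh_distribution <- defaults$g_h
  if (is.null(gd_distribution)) {
    gd_distribution <- c(meanlog = log(params$g_d), sdlog = 0.3)
  }
  for (nm in c("tsh", "ft4", "ft3")) {
    if (is.na(intra_cv[nm]) || is.na(assay_cv[nm])) {
      stop("cohort_spec: intra_cv and assay_cv need entries for tsh/ft4/ft3")
    }
  }
  if (any(intra_cv < 0) || any(assay_cv < 0)) {
    stop("cohort_spec: CVs must be >= 0")
  }
  stopifnot(n_subjects >= 1, visits_per_subject >= 1)
  structure(list(
    n_subjects = n_subjects, visits_per_subject = visits_per_subject,
    gt_distribution = gt_distribution, gh_distribution = gh_distribution,
    gd_distribution = gd_distribution,
    intra_cv = intra_cv, assay_cv = assay_cv,
    seed = as.integer(seed), params = params
  ), class = "cohort_spec")
}

.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}

#' Generate a synthetic cohort with its truth table
#'
#' Per subject, draws stable capacities (`g_t`, `g_h`, `g_d`) from the
#' specified log-normal distributions and solves the feedback equilibrium
#' (subjects whose equilibrium fails to converge are re-drawn, up to a retry
#' cap). Per visit, the equilibrium hormone levels are observed through
#' multiplicative log-normal intra-individual and assay noise. Both noise
#' factors have unit mean.
#'
#' @param spec a [cohort_spec()].
#' @param max_retries re-draw cap per subject for failed equilibria.
#' @return A list with `panels` (tibble: `subject_id`, `visit`, `tsh`,
#'   `ft4`, `ft3`) and `truth` (tibble: `subject_id`, `g_t`, `g_h`, `g_d`,
#'   `eq_tsh`, `eq_ft4`, `eq_ft3` — the noiseless equilibrium).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 5, seed = 1))
#' coh$panels
#' @export
generate_cohort <- function(spec, max_retries = 5L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects; v <- spec$visits_per_subject
  truth <- tibble::tibble(
    subject_id = seq_len(n), g_t = NA_real_, g_h = NA_real_, g_d = NA_real_,
    eq_tsh = NA_real_, eq_ft4 = NA_real_, eq_ft3 = NA_real_
  )
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      g_t <- stats::rlnorm(1, spec$gt_distribution[[1]], spec$gt_distribution[[2]])
      g_h <- stats::rlnorm(1, spec$gh_distribution[[1]], spec$gh_distribution[[2]])
      g_d <- stats::rlnorm(1, spec$gd_distribution[[1]], spec$gd_distribution[[2]])
      p_i <- spec$params
      p_i$g_t <- g_t; p_i$g_h <- g_h; p_i$g_d <- g_d
      class(p_i) <- "feedback_parameters"
      eq <- solve_equilibrium(p_i)
      if (isTRUE(eq$converged)) { ok <- TRUE; break }
    }
    if (!ok) stop("generate_cohort: equilibrium failed after retries for ",
                  "subject ", i)
    truth$g_t[i] <- g_t; truth$g_h[i] <- g_h; truth$g_d[i] <- g_d
    truth$eq_tsh[i] <- eq$tsh; truth$eq_ft4[i] <- eq$ft4
    truth$eq_ft3[i] <- eq$ft3
  }
  panels <- tibble::tibble(
    subject_id = rep(seq_len(n), each = v),
    visit = rep(seq_len(v), times = n),
    tsh = rep(truth$eq_tsh, each = v),
    ft4 = rep(truth$eq_ft4, each = v),
    ft3 = rep(truth$eq_ft3, each = v)
  )
  m <- nrow(panels)
  for (nm in c("tsh", "ft4", "ft3")) {
    panels[[nm]] <- panels[[nm]] *
      .ln_noise(m, spec$intra_cv[[nm]]) * .ln_noise(m, spec$assay_cv[[nm]])
  }
  list(panels = panels, truth = truth)
}
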