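test_that("SPINA-GD matches an independent hand evaluation and handles edges", {
  # frozen from plain arithmetic on the defining equation (helper oracle):
  # ft4 = 15, ft3 = 5, TBG = 3e-7 -> 30.8214 nmol/s
  expect_equal(spina_gd(15, 5), oracle_gd(15, 5))
  expect_equal(spina_gd(15, 5), 30.8214374, tolerance = 1e-7)
  # zero numerator
  expect_identical(spina_gd(12, 0), 0)
  # subject-specific TBG changes the binding correction
  expect_equal(spina_gd(15, 5, tbg = 2e-7), oracle_gd(15, 5, tbg = 2e-7))
  expect_error(spina_gd(0, 5), "strictly positive")
})

test_that("SPINA-GT matches the oracle, decreases in TSH and saturates", {
  expect_equal(spina_gt(1.5, 15), oracle_gt(1.5, 15))
  expect_equal(spina_gt(1.5, 15), 3.2262175, tolerance = 1e-7)
  expect_identical(spina_gt(2, 0), 0)
  # monotone decreasing in TSH at fixed FT4 ...
  tshs <- c(0.1, 0.5, 1.5, 5, 20, 100)
  gts <- spina_gt(tshs, 15)
  expect_true(all(diff(gts) < 0))
  # ... toward the protein-binding asymptote beta_T (1+K41 TBG+K42 TBPA) FT4/alpha_T
  asym <- 1.1e-6 * (1 + 2e10 * 3e-7 + 2e8 * 4.5e-6) * 15e-12 / 0.1 * 1e12
  expect_equal(spina_gt(1e6, 15), asym, tolerance = 1e-5)
  expect_error(spina_gt(0, 15), "strictly positive")
})

test_that("forward-model round trips recover the generating capacities", {
  p <- feedback_parameters()
  # thyroid: FT4 generated with a known GT at a given TSH inverts exactly
  for (gt in c(0.8, 3, 7)) {
    p_gt <- feedback_parameters(g_t = gt)
    for (tsh in c(0.2, 1.5, 30)) {
      ft4 <- thyroid_response(tsh, p_gt)
      expect_equal(spina_gt(tsh, ft4), gt, tolerance = 1e-9)
    }
  }
  # periphery: FT3 generated with GD = 25 nmol/s inverts exactly
  ft3 <- peripheral_ft3(15, p)
  expect_equal(spina_gd(15, ft3), p$g_d, tolerance = 1e-9)
})

test_that("specific capacity GTS is GT per unit volume", {
  expect_identical(spina_gts(3, 1), 3)
  expect_identical(spina_gts(3, 15), 0.2)
  expect_identical(spina_gts(0, 15), 0)
  expect_error(spina_gts(3, 0), "positive")
  expect_error(spina_gts(3, -2), "positive")
})

test_that("hormone ratios respect measurement families and molar scales", {
  r <- hormone_ratios(list(ft3 = 5, ft4 = 15))
  expect_equal(r$t3_t4_ratio, 1 / 3)
  expect_true(any(grepl("free", r$flags)))
  r <- hormone_ratios(list(tt3 = 2, tt4 = 100))
  expect_equal(r$t3_t4_ratio, 0.02)
  expect_true(any(grepl("total", r$flags)))
  # FT3 5 pmol/L vs rT3 0.25 nmol/L = 250 pmol/L
  r <- hormone_ratios(list(ft3 = 5, ft4 = 15, rt3 = 0.25))
  expect_equal(r$t3_rt3_ratio, 0.02)
  # free requested but absent: no cross-family mixing, result is NA
  r <- hormone_ratios(list(tt3 = 2, tt4 = 100), family = "free")
  expect_true(is.na(r$t3_t4_ratio))
  expect_error(hormone_ratios(list(ft3 = 5, ft4 = 0)), "denominator")
})

test_that("TTSI is the scaled TSH-FT4 product, linear in each argument", {
  expect_identical(ttsi(1, 21, 21), 100)
  expect_identical(ttsi(0, 15, 20), 0)
  expect_identical(ttsi(2, 20, 20), 200)
  # linear in tsh and ft4, inverse-linear in lu
  base <- ttsi(1.3, 17, 21)
  expect_equal(ttsi(2 * 1.3, 17, 21), 2 * base)
  expect_equal(ttsi(1.3, 3 * 17, 21), 3 * base)
  expect_equal(ttsi(1.3, 17, 2 * 21), base / 2)
  expect_error(ttsi(1, 15), "lu")
  expect_error(ttsi(1, 15, 0), "positive")
})

test_that("TSH index is log-linear with the published slope", {
  expect_identical(tshi(1, 0), 0)
  expect_equal(tshi(exp(1), 0), 1)
  # finite-difference slope wrt FT4 at fixed TSH equals -beta = +0.1345
  h <- 1e-3
  slope <- (tshi(1.5, 15 + h) - tshi(1.5, 15 - h)) / (2 * h)
  expect_equal(slope, 0.1345)
  expect_error(tshi(0, 15), "positive")
  expect_error(tshi(-2, 15), "positive")
})

test_that("standardised TSH index centres and scales as published", {
  expect_identical(stshi(2.7), 0)
  expect_equal(stshi(2.7 + 0.676), 1)
  expect_equal(stshi(2.7 - 2 * 0.676), -2)
  # a normal sample with the standardisation moments maps to ~N(0, 1)
  set.seed(11)
  n <- 1e4
  z <- stshi(rnorm(n, mean = 2.7, sd = 0.676))
  expect_lt(abs(mean(z)), 3 / sqrt(n))
  expect_lt(abs(sd(z) - 1), 3 / sqrt(n))
})

test_that("repeatability estimates variance components sensibly", {
  # constant within subject, different between subjects: e = 1
  subj <- rep(1:5, each = 3)
  vals <- c(1, 1, 1, 2, 2, 2, 5, 5, 5, 9, 9, 9, 3, 3, 3)
  expect_identical(repeatability(vals, subj)$e, 1)
  # globally constant: defined as 0 with a degeneracy flag
  r0 <- repeatability(rep(4, 10), rep(1:5, each = 2))
  expect_identical(r0$e, 0)
  expect_true(any(grepl("degenerate", r0$flags)))
  # equal within- and between-subject variance: e ~ 0.5 (oracle = the
  # generating variances; n = 200 subjects x 2 visits)
  set.seed(7)
  n_s <- 200
  subj <- rep(seq_len(n_s), each = 2)
  mu <- rnorm(n_s, sd = 1)
  x <- mu[subj] + rnorm(2 * n_s, sd = 1)
  est <- repeatability(x, subj)
  expect_equal(est$e, 0.5, tolerance = 0.15)
  # degenerate designs are refused
  expect_error(repeatability(c(1, 2), c(1, 1)), ">= 2 subjects")
  expect_error(repeatability(c(1, 2, 3), c(1, 2, 3)), ">= 2 measurements")
})

test_that("the cohort calculator equals scalar application row by row", {
  panels <- tibble::tibble(
    tsh = c(1.2, 3.4, 0.8), ft4 = c(16, 11, 19), ft3 = c(4.5, 3.9, 5.2),
    volume = c(12, NA, 18), lu = 21
  )
  res <- calc_panels(panels)
  for (i in seq_len(nrow(panels))) {
    expect_equal(res$gt[i], spina_gt(panels$tsh[i], panels$ft4[i]))
    expect_equal(res$gd[i], spina_gd(panels$ft4[i], panels$ft3[i]))
    expect_equal(res$ttsi[i], ttsi(panels$tsh[i], panels$ft4[i], 21))
    expect_equal(res$tshi[i], tshi(panels$tsh[i], panels$ft4[i]))
    expect_equal(res$stshi[i], stshi(res$tshi[i]))
  }
  expect_equal(res$gts[1], res$gt[1] / 12)
  expect_true(is.na(res$gts[2]))  # absent volume -> absent GTS
  expect_true(all(grepl("default TBG", res$flags)))
})

test_that("panels read from CSV normalise units on the way in", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = 1:2, tsh = c(1.5, 2), ft4 = c(1.2, 0.9)),
            f, row.names = FALSE)
  df <- read_panels(f, units = c(ft4 = "ng/dL"))
  expect_equal(df$ft4, c(1.2, 0.9) * 1e4 / 776.87)
  expect_equal(df$tsh, c(1.5, 2))
  unlink(f)
})
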