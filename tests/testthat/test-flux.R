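make_trace <- function(values, assay = "ECAR",
                       compounds = c("glucose", "oligomycin", "2-DG")) {
  flux_trace("s", "c", assay, seq(3, by = 6, length.out = length(values)),
             values, data.frame(time_min = c(18, 36, 54),
                                compound = compounds))
}

test_that("segmentation assigns points to half-open phase intervals", {
  tr <- make_trace(c(1, 2, 3, 11, 12, 13, 21, 22, 23, 31, 32, 33))
  seg <- segment_trace(tr)
  expect_equal(seg$mean, c(2, 12, 22, 32))
  expect_equal(seg$first, c(1, 11, 21, 31))
  expect_equal(seg$last, c(3, 13, 23, 33))
  expect_equal(seg$compound_before,
               c("baseline", "glucose", "oligomycin", "2-DG"))
  # a point exactly at an injection time joins the following phase
  tr2 <- flux_trace("s", "c", "OCR", c(1, 2, 18, 19, 36, 40, 54, 60),
                    1:8, data.frame(time_min = c(18, 36, 54),
                                    compound = c("o", "f", "r")))
  expect_equal(segment_trace(tr2)$n_points, rep(2L, 4))
})

test_that("segmentation requires exactly three injections", {
  tr <- make_trace(1:12)
  tr$injections <- tr$injections[1:2, ]
  expect_error(segment_trace(tr), "exactly 3")
})

test_that("glycolysis parameters follow the stress-test arithmetic", {
  tr <- make_trace(c(7, 7.5, 8, 28, 30, 29, 45, 44, 43, 9, 8, 8))
  gp <- glyco_params(segment_trace(tr))
  expect_equal(gp$non_glycolytic, 8)
  expect_equal(gp$glycolysis, 22)
  expect_equal(gp$glycolytic_capacity, 37)
  expect_equal(gp$glycolytic_reserve, 15)
  expect_false(gp$flagged)
  # capacity below glycolysis: negative reserve reported and flagged
  tr2 <- make_trace(c(8, 8, 8, 30, 30, 30, 25, 25, 25, 8, 8, 8))
  gp2 <- glyco_params(segment_trace(tr2))
  expect_equal(gp2$glycolytic_reserve, -5)
  expect_true(gp2$flagged)
  # assay guard
  ocr <- make_trace(1:12, assay = "OCR",
                    compounds = c("oligomycin", "FCCP", "rot/AA"))
  expect_error(glyco_params(segment_trace(ocr)), "ECAR")
})

test_that("mitochondrial parameters follow the stress-test arithmetic", {
  tr <- make_trace(c(95, 98, 100, 42, 40, 41, 150, 148, 145, 12, 10, 11),
                   assay = "OCR",
                   compounds = c("oligomycin", "FCCP", "rot/AA"))
  mp <- mito_params(segment_trace(tr))
  expect_equal(mp$non_mito, 10)
  expect_equal(mp$basal, 90)
  expect_equal(mp$atp_linked, 60)
  expect_equal(mp$proton_leak, 30)
  expect_equal(mp$maximal, 140)
  expect_equal(mp$spare_capacity, 50)
  expect_equal(mp$coupling_efficiency, 60 / 90)
  expect_false(mp$flagged)
  # fully coupled limit: oligomycin floor equals the non-mito floor
  tr2 <- make_trace(c(100, 100, 100, 10, 10, 10, 150, 150, 150,
                      10, 10, 10), assay = "OCR",
                    compounds = c("oligomycin", "FCCP", "rot/AA"))
  mp2 <- mito_params(segment_trace(tr2))
  expect_equal(mp2$proton_leak, 0)
  expect_equal(mp2$coupling_efficiency, 1)
  # rot/AA floor above baseline: degenerate, flagged, coupling undefined
  tr3 <- make_trace(c(50, 50, 50, 40, 40, 40, 60, 60, 60, 80, 80, 80),
                    assay = "OCR",
                    compounds = c("oligomycin", "FCCP", "rot/AA"))
  mp3 <- mito_params(segment_trace(tr3))
  expect_true(mp3$flagged)
  expect_true(mp3$basal < 0)
  expect_true(is.na(mp3$coupling_efficiency))
  expect_error(mito_params(segment_trace(make_trace(1:12))), "OCR")
})

test_that("viability normalization scales rates and preserves identities", {
  tr <- make_trace(c(7, 7.5, 8, 28, 30, 29, 45, 44, 43, 9, 8, 8))
  gp <- normalize_flux(glyco_params(segment_trace(tr)), 0.5)
  expect_equal(gp$glycolysis, 44)
  expect_equal(gp$glycolytic_reserve,
               gp$glycolytic_capacity - gp$glycolysis)
  mtr <- make_trace(c(95, 98, 100, 42, 40, 41, 150, 148, 145,
                      12, 10, 11), assay = "OCR",
                    compounds = c("oligomycin", "FCCP", "rot/AA"))
  mp <- mito_params(segment_trace(mtr))
  mp_n <- normalize_flux(mp, 0.25)
  expect_equal(mp_n$coupling_efficiency, mp$coupling_efficiency)
  expect_equal(mp_n$basal, mp$basal / 0.25)
  expect_error(normalize_flux(mp, 0), "> 0")
})

test_that("stress-test identities hold to machine precision on random
           valid traces, including flagged ones", {
  set.seed(31)
  for (i in 1:200) {
    b <- runif(1, 0, 20); g <- runif(1, 0, 40)
    cap <- g + runif(1, 0, 30)
    gp <- glyco_params(segment_trace(simulate_flux_trace(
      glyco_truth(b, g, cap), cv = runif(1, 0, 0.3), seed = i)))
    expect_identical(gp$glycolytic_reserve,
                     gp$glycolytic_capacity - gp$glycolysis)
    nm <- runif(1, 0, 20); leak <- runif(1, 0, 30)
    bas <- leak + runif(1, 0, 80); mx <- bas + runif(1, 0, 60)
    mp <- mito_params(segment_trace(simulate_flux_trace(
      mito_truth(nm, bas, leak, mx), cv = runif(1, 0, 0.3),
      seed = i + 1000)))
    expect_identical(mp$spare_capacity, mp$maximal - mp$basal)
    expect_identical(mp$basal, mp$atp_linked + mp$proton_leak)
    if (!mp$flagged) {
      expect_gte(mp$coupling_efficiency, 0)
      expect_lte(mp$coupling_efficiency, 1)
    }
  }
})

test_that("noiseless simulated traces invert exactly to their truth", {
  gt <- glyco_truth(8, 22, 37)
  gp <- glyco_params(segment_trace(simulate_flux_trace(gt, cv = 0)))
  expect_equal(unlist(gp[1, names(gt$params)]), gt$params)
  mt <- mito_truth(10, 90, 30, 140)
  mp <- mito_params(segment_trace(simulate_flux_trace(mt, cv = 0)))
  expect_equal(unlist(mp[1, names(mt$params)]), mt$params)
})

test_that("parameters ignore extra trailing points that do not move the
           final-phase extrema", {
  v <- c(95, 98, 100, 42, 40, 41, 150, 148, 145, 12, 10, 11)
  base <- mito_params(segment_trace(make_trace(
    v, assay = "OCR", compounds = c("oligomycin", "FCCP", "rot/AA"))))
  v2 <- c(v, 10.5, 11.5)  # above the phase minimum of 10
  ext <- mito_params(segment_trace(make_trace(
    v2, assay = "OCR", compounds = c("oligomycin", "FCCP", "rot/AA"))))
  expect_equal(ext, base)
})

test_that("noisy Monte-Carlo recovery with mean statistics is unbiased", {
  gt <- glyco_truth(8, 22, 37)
  est <- vapply(1:200, function(s) {
    seg <- segment_trace(simulate_flux_trace(gt, cv = 0.05, seed = s))
    glyco_params(seg, baseline_stat = "mean", post_stat = "mean")$glycolysis
  }, 1.0)
  expect_equal(mean(est), 22, tolerance = 0.02)
})

test_that("a metformin-like condition pair recovers the glycolysis fold
           change", {
  ctrl <- glyco_truth(8, 10, 25)
  met <- glyco_truth(8, 23, 27.5)  # 2.3-fold glycolysis induction
  g_ctrl <- mean(vapply(1:30, function(s) {
    glyco_params(segment_trace(simulate_flux_trace(ctrl, cv = 0.05,
                                                   seed = s)),
                 baseline_stat = "mean", post_stat = "mean")$glycolysis
  }, 1.0))
  g_met <- mean(vapply(1:30, function(s) {
    glyco_params(segment_trace(simulate_flux_trace(met, cv = 0.05,
                                                   seed = 100 + s)),
                 baseline_stat = "mean", post_stat = "mean")$glycolysis
  }, 1.0))
  expect_equal(g_met / g_ctrl, 2.3, tolerance = 0.05)
})

test_that("energy phenotype quadrants compare to the reference condition", {
  d <- tibble::tibble(
    condition = c("ref", "quiet", "glyc", "aero", "ener"),
    ocr = c(100, 40, 50, 200, 150),
    ecar = c(30, 15, 45, 15, 60))
  out <- energy_phenotype(d, "ref")
  expect_equal(as.character(out$quadrant),
               c("energetic", "quiescent", "glycolytic", "aerobic",
                 "energetic"))
  # condition equal to the reference is energetic (boundary >=)
  expect_equal(as.character(out$quadrant[1]), "energetic")
  expect_error(energy_phenotype(d, "missing"), "reference")
})
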