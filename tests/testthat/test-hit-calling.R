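test_that("plate normalization divides by the negative-control mean", {
  fx <- tiny_plate(neg = c(100, 110, 90), mimics = c(m1 = 70))
  norm <- normalize_plate(fx$measurements, fx$map)
  expect_equal(norm$value[norm$kind == "mimic"], 0.70)
  # negative-control normalized mean is exactly 1
  expect_equal(mean(norm$value[norm$kind == "neg_control"]), 1)
})

test_that("normalization is invariant to positive rescaling and maps a
           flat plate to 1", {
  fx <- tiny_plate()
  norm <- normalize_plate(fx$measurements, fx$map)
  doubled <- fx$measurements
  doubled$raw_count <- doubled$raw_count * 2
  expect_equal(normalize_plate(doubled, fx$map)$value, norm$value)
  flat <- fx$measurements
  flat$raw_count <- 250
  expect_equal(normalize_plate(flat, fx$map)$value,
               rep(1, nrow(flat)))
})

test_that("normalization fails without usable negative controls", {
  fx <- tiny_plate()
  zeroed <- fx$measurements
  zeroed$raw_count[fx$map$kind == "neg_control"] <- 0
  expect_error(normalize_plate(zeroed, fx$map), "non-positive")
  no_neg_meas <- fx$measurements[fx$map$kind != "neg_control", ]
  expect_error(normalize_plate(no_neg_meas, fx$map),
               "no measured negative-control")
})

test_that("Z' factor matches its closed form and limits", {
  expect_equal(zprime(1, 0, 0.2, 0), 1)
  expect_equal(zprime(1.0, 0.1, 0.2, 0.05), 1 - 0.45 / 0.8)  # 0.4375
  expect_error(zprime(1, 0.1, 1, 0.1), "equal")
  expect_true(zprime(1, 0.3, 0.9, 0.3) < 0)  # overlapping controls
})

test_that("per-plate QC flags low-separation plates without dropping them", {
  set.seed(1)
  sim <- simulate_screen(screen_config(n_mimics = 50, well_cv = 0.05,
                                       seed = 8))
  qc <- plate_qc(normalize_screen(sim$plate_maps, sim$measurements))
  expect_equal(nrow(qc), length(unique(sim$plate_maps$plate_id)))
  expect_true(all(qc$zprime <= 1))
  expect_equal(qc$flagged, qc$zprime < 0)
})

test_that("replicate Spearman matches a brute-force rank oracle", {
  a <- setNames(c(1, 2, 3, 4, 5, 6), paste0("m", 1:6))
  expect_equal(replicate_correlation(a, a), 1)
  expect_equal(replicate_correlation(a, setNames(rev(a), names(a))), -1)
  # 6-point vectors with a tie, restricted to the shared ids
  x <- setNames(c(0.9, 0.8, 0.8, 0.4, 0.6, 0.3), paste0("m", 1:6))
  y <- setNames(c(1.0, 0.7, 0.9, 0.5, 0.4, 0.35, 0.2),
                paste0("m", c(1:6, 9)))
  shared <- intersect(names(x), names(y))
  expect_equal(replicate_correlation(x, y),
               spearman_oracle(x[shared], y[shared]))
  expect_error(replicate_correlation(a[1:2], a[1:2]), "at least 3")
  flat <- setNames(rep(1, 6), names(a))
  expect_error(replicate_correlation(a, flat), "zero variance")
})

test_that("replicate aggregation and ratio follow the two-arm design", {
  viab <- tibble::tibble(
    mimic_id = "m1",
    arm = c("drug", "drug", "vehicle", "vehicle"),
    replicate = c(1, 2, 1, 2),
    value = c(0.6, 0.7, 1.0, 1.0))
  out <- aggregate_and_ratio(viab)
  expect_equal(out$ratio, 0.65)
  # identical arms give ratio 1
  same <- viab; same$value <- c(0.8, 0.9, 0.8, 0.9)
  expect_equal(aggregate_and_ratio(same)$ratio, 1)
  # the drug-effect multiplier rescales the ratio
  expect_equal(aggregate_and_ratio(viab, drug_effect = 0.8)$ratio,
               0.52)
  expect_error(aggregate_and_ratio(viab[viab$arm == "drug", ]),
               "missing the vehicle arm")
  zero <- viab; zero$value[3:4] <- 0
  expect_error(aggregate_and_ratio(zero), "vehicle-arm mean")
})

test_that("hit threshold is boundary-inclusive and monotone", {
  rec <- tibble::tibble(mimic_id = c("a", "b", "c"),
                        vehicle_viability = 1, drug_viability = 1,
                        ratio = c(0.70, 0.701, 0.2))
  hits <- call_preliminary_hits(rec, 0.70)
  expect_equal(hits$preliminary_hit, c(TRUE, FALSE, TRUE))
  expect_error(call_preliminary_hits(rec, 0), "\\(0, 1\\]")
  expect_error(call_preliminary_hits(rec, 1.2), "\\(0, 1\\]")
  # hit sets are nested as the threshold grows
  set.seed(42)
  rnd <- tibble::tibble(mimic_id = sprintf("m%03d", 1:100),
                        vehicle_viability = 1, drug_viability = 1,
                        ratio = runif(100, 0.3, 1.2))
  thresholds <- seq(0.3, 1, by = 0.1)
  sets <- lapply(thresholds, function(t) {
    rnd$mimic_id[call_preliminary_hits(rnd, t)$preliminary_hit]
  })
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("stratification rules read the annotation table as specified", {
  rec <- call_preliminary_hits(tibble::tibble(
    mimic_id = c("hitA", "hitB", "hitC", "hitD", "miss"),
    vehicle_viability = 1, drug_viability = 1,
    ratio = c(0.5, 0.5, 0.5, 0.5, 0.9)))
  ann <- tibble::tibble(
    mimic_id = c("hitA", "hitB", "hitC", "hitD", "miss"),
    rpm_treated = c(4.1, 3.9, 10, 10, 100),
    rpm_untreated = c(0, 3.9, 10, 10, 100),
    family = c(NA, NA, "mir-17", "mir-17", NA),
    cluster = NA_character_,
    metformin_regulated = FALSE,
    cancer_pathway = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  out <- stratify_hits(rec, ann)
  # abundance boundary: > 4 rpm in either condition
  expect_equal(out$rule1, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  # family shared with another preliminary hit
  expect_equal(out$rule2, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$selected, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  # selected implies preliminary hit even for well-annotated misses
  expect_false(any(out$selected & !out$preliminary_hit))
  # conjunctive logic needs all four rules
  expect_equal(sum(stratify_hits(rec, ann, "all")$selected), 0L)
  expect_error(stratify_hits(rec, ann, "sometimes"))
})

test_that("preliminary hits without annotations warn and get all-false flags", {
  rec <- call_preliminary_hits(tibble::tibble(
    mimic_id = "orphan", vehicle_viability = 1, drug_viability = 1,
    ratio = 0.4))
  ann <- tibble::tibble(mimic_id = "other", rpm_treated = 10,
                        rpm_untreated = 10, family = NA_character_,
                        cluster = NA_character_,
                        metformin_regulated = TRUE,
                        cancer_pathway = TRUE)
  expect_warning(out <- stratify_hits(rec, ann), "no annotation")
  expect_false(out$rule1 | out$rule2 | out$rule3 | out$rule4)
  expect_false(out$selected)
})

test_that("spiked synergists are recovered and null calls stay within
           the expected false-positive band", {
  cfg <- screen_config(n_mimics = 300, n_synergists = 8,
                       synergist_interaction = 0.5, well_cv = 0.10,
                       n_replicates = 2, seed = 1)
  sim <- simulate_screen(cfg)
  pipe <- run_screen_pipeline(sim)
  hits <- call_preliminary_hits(
    aggregate_and_ratio(pipe$viability, pipe$drug_effect))
  d <- dplyr::inner_join(hits, sim$truth, by = "mimic_id")
  expect_gte(sum(d$preliminary_hit & d$is_synergist), 7L)

  # Independent oracle for the null false-positive probability: simulate
  # the ratio's noise model directly (duplicate well means over 16-well
  # control means per arm, times the drug effect).
  set.seed(99)
  M <- 20000
  sdlog <- sqrt(log(1 + cfg$well_cv^2))
  rmean <- function(k) {
    colMeans(matrix(rlnorm(k * M, -sdlog^2 / 2, sdlog), nrow = k))
  }
  null_ratio <- cfg$v_drug_true *
    (rmean(2) / rmean(16)) / (rmean(2) / rmean(16)) *
    (rmean(32) / rmean(32))  # drug-effect estimate noise
  p0 <- mean(null_ratio <= 0.70)
  n_null <- sum(!d$is_synergist)
  fp <- sum(d$preliminary_hit & !d$is_synergist)
  # observed false positives not significantly above expectation
  expect_lte(fp, qbinom(0.999, n_null, p0 + 0.01))
})
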