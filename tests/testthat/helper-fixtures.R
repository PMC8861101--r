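# Minimal hand-built screen fixtures, constructed in code.

# One small plate: 3 negative controls, 1 positive control, a mock and
# a few mimic wells.  Raw counts chosen for easy mental arithmetic.
tiny_plate <- function(plate_id = "p1", arm = "vehicle", replicate = 1,
                       neg = c(100, 110, 90), pos = 10, mock = 95,
                       mimics = c(m1 = 70, m2 = 100)) {
  wells <- c("A1", "A2", "A3", "B1", "B2",
             paste0("C", seq_along(mimics)))
  kind <- c(rep("neg_control", 3), "pos_control", "mock",
            rep("mimic", length(mimics)))
  map <- tibble::tibble(
    plate_id = plate_id, well = wells, kind = kind,
    mimic_id = c(rep(NA_character_, 5), names(mimics)),
    arm = arm, replicate = replicate)
  meas <- tibble::tibble(
    plate_id = plate_id, well = wells,
    raw_count = c(neg, pos, mock, unname(mimics)))
  list(map = map, measurements = meas)
}

# A two-arm screen built from tiny plates with per-mimic raw counts
# supplied as named vectors, one per (arm, replicate).
tiny_screen <- function(vehicle_reps, drug_reps, neg_vehicle = 100,
                        neg_drug = 80) {
  plates <- list()
  for (r in seq_along(vehicle_reps)) {
    plates[[length(plates) + 1]] <- tiny_plate(
      plate_id = sprintf("veh_%d", r), arm = "vehicle", replicate = r,
      neg = rep(neg_vehicle, 3), pos = 0.1 * neg_vehicle,
      mimics = vehicle_reps[[r]])
  }
  for (r in seq_along(drug_reps)) {
    plates[[length(plates) + 1]] <- tiny_plate(
      plate_id = sprintf("drug_%d", r), arm = "drug", replicate = r,
      neg = rep(neg_drug, 3), pos = 0.1 * neg_drug,
      mimics = drug_reps[[r]])
  }
  list(plate_maps = dplyr::bind_rows(lapply(plates, `[[`, "map")),
       measurements = dplyr::bind_rows(lapply(plates, `[[`,
                                              "measurements")))
}

# Independent Spearman oracle: average ranks by pairwise counting, then
# the explicit Pearson product-moment formula on those ranks.
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i])
      ties <- sum(v == v[i])
      less + (ties + 1) / 2
    }, 1.0)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(rx)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) *
                (sum(ry^2) - n * mean(ry)^2))
  num / den
}

run_screen_pipeline <- function(sim) {
  norm <- normalize_screen(sim$plate_maps, sim$measurements)
  drug_eff <- estimate_drug_effect(sim$plate_maps, sim$measurements)
  viab <- mimic_viability(norm)
  list(normalized = norm, drug_effect = drug_eff, viability = viab)
}
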