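#' Normalize one plate's raw counts to its negative-control mean
#'
#' Each well's value is its raw count divided by the mean raw count of the
#' plate's negative-control wells, so the negative-control mean maps to
#' exactly 1 and any positive rescaling of the plate leaves the result
#' unchanged.  On drug-arm plates the scrambled control experiences the
#' drug too, so this step removes the drug effect along with plate-level
#' artefacts; [estimate_drug_effect()] recovers it.
#'
#' @param measurements measurements tibble restricted to one plate.
#' @param plate_map plate-map tibble restricted to the same plate.
#' @return A tibble with the plate map's columns plus `raw_count` and
#'   `value` (normalized viability).
#' @export
normalize_plate <- function(measurements, plate_map) {
  pm <- tibble::as_tibble(plate_map)
  if (length(unique(pm$plate_id)) != 1L) {
    stop("normalize_plate expects a single plate", call. = FALSE)
  }
  d <- dplyr::inner_join(pm, tibble::as_tibble(measurements),
                         by = c("plate_id", "well"))
  neg <- d$raw_count[d$kind == "neg_control"]
  if (length(neg) == 0L) {
    stop("plate ", pm$plate_id[1],
         " has no measured negative-control wells", call. = FALSE)
  }
  mu <- mean(neg)
  if (!is.finite(mu) || mu <= 0) {
    stop("plate ", pm$plate_id[1],
         " has a non-positive negative-control mean; cannot normalize",
         call. = FALSE)
  }
  d$value <- d$raw_count / mu
  d
}

#' Normalize every plate of a screen
#'
#' Applies [normalize_plate()] plate by plate.
#'
#' @param plate_maps,measurements tibbles as returned by
#'   [read_plate_data()] or [simulate_screen()].
#' @return One tibble of per-well normalized values across all plates.
#' @export
normalize_screen <- function(plate_maps, measurements) {
  pm <- tibble::as_tibble(plate_maps)
  dplyr::bind_rows(lapply(unique(pm$plate_id), function(pid) {
    normalize_plate(measurements[measurements$plate_id == pid, ],
                    pm[pm$plate_id == pid, ])
  }))
}

#' Z'-factor screening-window statistic
#'
#' `1 - 3 * (sigma_pos + sigma_neg) / |mu_pos - mu_neg|`.  Values near 1
#' indicate a wide separation band between the lethal and neutral
#' controls; values below 0 mean the bands overlap.
#'
#' @param mu_neg,sigma_neg mean and SD of the negative (neutral) control.
#' @param mu_pos,sigma_pos mean and SD of the positive (lethal) control.
#' @return The Z' factor (always <= 1).
#' @export
zprime <- function(mu_neg, sigma_neg, mu_pos, sigma_pos) {
  if (any(c(sigma_neg, sigma_pos) < 0)) {
    stop("control SDs must be >= 0", call. = FALSE)
  }
  if (mu_pos == mu_neg) {
    stop("Z' undefined: positive and negative control means are equal",
         call. = FALSE)
  }
  1 - 3 * (sigma_pos + sigma_neg) / abs(mu_pos - mu_neg)
}

#' Per-plate control statistics and Z' factor
#'
#' Computes control means/SDs on normalized values for every plate and
#' the resulting Z'.  Plates with Z' < 0 are flagged, not dropped.
#'
#' @param normalized output of [normalize_screen()].
#' @return A tibble: `plate_id, arm, replicate, mu_neg, sigma_neg, mu_pos,
#'   sigma_pos, zprime, flagged`.
#' @export
plate_qc <- function(normalized) {
  normalized |>
    dplyr::group_by(.data$plate_id, .data$arm, .data$replicate) |>
    dplyr::summarise(
      mu_neg = mean(.data$value[.data$kind == "neg_control"]),
      sigma_neg = sd(.data$value[.data$kind == "neg_control"]),
      mu_pos = mean(.data$value[.data$kind == "pos_control"]),
      sigma_pos = sd(.data$value[.data$kind == "pos_control"]),
      .groups = "drop") |>
    dplyr::mutate(
      sigma_pos = ifelse(is.na(.data$sigma_pos), 0, .data$sigma_pos),
      zprime = mapply(zprime, .data$mu_neg, .data$sigma_neg,
                      .data$mu_pos, .data$sigma_pos),
      flagged = .data$zprime < 0)
}

#' Spearman correlation between two replicates of a screen
#'
#' Rank correlation (average ranks for ties) over the mimics present in
#' both named vectors.
#'
#' @param rep_a,rep_b named numeric vectors of per-mimic values.
#' @return Spearman's rho.
#' @export
replicate_correlation <- function(rep_a, rep_b) {
  if (is.null(names(rep_a)) || is.null(names(rep_b))) {
    stop("replicate vectors must be named by mimic id", call. = FALSE)
  }
  shared <- intersect(names(rep_a), names(rep_b))
  if (length(shared) < 3L) {
    stop("need at least 3 shared mimics; got ", length(shared),
         call. = FALSE)
  }
  a <- rep_a[shared]; b <- rep_b[shared]
  if (sd(a) == 0 || sd(b) == 0) {
    stop("zero variance in a replicate vector", call. = FALSE)
  }
  cor(a, b, method = "spearman")
}

#' Estimate the drug-alone viability from negative controls
#'
#' Per-plate normalization referenced each arm to its own (arm-treated)
#' scrambled control, so the drug effect must be measured directly:
#' the ratio of the mean drug-arm negative-control raw count to the mean
#' vehicle-arm one (per-plate control means averaged within arm, so every
#' plate weighs equally and mean-1 plate effects cancel in expectation).
#'
#' @param plate_maps,measurements screen tibbles.
#' @return Estimated drug-alone viability (scalar).
#' @export
estimate_drug_effect <- function(plate_maps, measurements) {
  d <- dplyr::inner_join(tibble::as_tibble(plate_maps),
                         tibble::as_tibble(measurements),
                         by = c("plate_id", "well"))
  neg <- d[d$kind == "neg_control", ]
  if (nrow(neg) == 0L) stop("no negative-control wells", call. = FALSE)
  per_plate <- neg |>
    dplyr::group_by(.data$plate_id, .data$arm) |>
    dplyr::summarise(mu = mean(.data$raw_count), .groups = "drop")
  arm_mu <- tapply(per_plate$mu, per_plate$arm, mean)
  if (!all(c("drug", "vehicle") %in% names(arm_mu))) {
    stop("both arms are required to estimate the drug effect",
         call. = FALSE)
  }
  if (arm_mu[["vehicle"]] <= 0) {
    stop("vehicle-arm negative-control mean must be > 0", call. = FALSE)
  }
  unname(arm_mu[["drug"]] / arm_mu[["vehicle"]])
}

#' Per-mimic, per-arm, per-replicate normalized viability
#'
#' @param normalized output of [normalize_screen()].
#' @return A tibble: `mimic_id, arm, replicate, value, n_wells`.
#' @export
mimic_viability <- function(normalized) {
  normalized |>
    dplyr::filter(.data$kind == "mimic") |>
    dplyr::group_by(.data$mimic_id, .data$arm, .data$replicate) |>
    dplyr::summarise(value = mean(.data$value), n_wells = dplyr::n(),
                     .groups = "drop")
}

#' Average replicates within arm and form the drug/vehicle ratio
#'
#' Per mimic, replicate values are averaged within each arm and the hit
#' ratio is `drug / vehicle * drug_effect`.  With the default
#' `drug_effect = 1` this is the plain ratio of plate-relative
#' viabilities; passing the value from [estimate_drug_effect()]
#' re-expresses the numerator relative to the untreated control, so a
#' mimic with no effect and no interaction sits at the drug-alone
#' viability (e.g. 0.8 for an IC20 dose) and the hit threshold reads as
#' "combined viability at most 70% of the untreated control".
#'
#' @param viability output of [mimic_viability()].
#' @param drug_effect drug-alone viability multiplier applied to the
#'   drug arm (default 1).
#' @return A tibble: `mimic_id, vehicle_viability, drug_viability, ratio`,
#'   where `drug_viability` is the drug-arm mean times `drug_effect`.
#' @export
aggregate_and_ratio <- function(viability, drug_effect = 1) {
  wide <- viability |>
    dplyr::group_by(.data$mimic_id, .data$arm) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "value")
  for (needed in c("drug", "vehicle")) {
    if (!needed %in% names(wide) || anyNA(wide[[needed]])) {
      bad <- if (!needed %in% names(wide)) wide$mimic_id else
        wide$mimic_id[is.na(wide[[needed]])]
      stop("mimic(s) missing the ", needed, " arm: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (any(wide$vehicle == 0)) {
    stop("vehicle-arm mean viability is 0 for: ",
         paste(wide$mimic_id[wide$vehicle == 0], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    mimic_id = wide$mimic_id,
    vehicle_viability = wide$vehicle,
    drug_viability = wide$drug * drug_effect,
    ratio = wide$drug / wide$vehicle * drug_effect)
}

#' Call preliminary hits by ratio threshold
#'
#' A mimic is a preliminary hit when its drug/vehicle viability ratio is
#' at or below the threshold (boundary inclusive).  The default 0.70
#' corresponds to sensitizers that push combined viability to at most
#' 70% of the untreated control.
#'
#' @param records output of [aggregate_and_ratio()].
#' @param threshold hit cut in (0, 1].
#' @return `records` with a logical `preliminary_hit` column.
#' @export
call_preliminary_hits <- function(records, threshold = 0.70) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  records$preliminary_hit <- records$ratio <= threshold
  records
}

#' Stratify preliminary hits with annotation rules
#'
#' Four rules refine the preliminary hit list:
#' 1. abundance: > 4 reads per million in either treated or untreated
#'    cells;
#' 2. family/cluster: shares a miRNA family or genomic cluster with at
#'    least one other preliminary hit;
#' 3. literature: reported as drug-regulated;
#' 4. pathway: involved in cancer-related pathways/ontologies.
#'
#' `logic` combines them: `"gate_any"` (default) requires the abundance
#' gate plus any of rules 2-4; `"all"` requires all four; `"any"` any
#' one.  Only preliminary hits can be selected.
#'
#' @param records output of [call_preliminary_hits()].
#' @param annotations tibble as from [read_annotations()].
#' @param logic rule-combination keyword.
#' @return `records` with logical columns `rule1..rule4` and `selected`.
#' @export
stratify_hits <- function(records, annotations,
                          logic = c("gate_any", "all", "any")) {
  logic <- match.arg(logic)
  ann <- tibble::as_tibble(annotations)
  d <- dplyr::left_join(records, ann, by = "mimic_id")
  missing_ann <- d$preliminary_hit & !(d$mimic_id %in% ann$mimic_id)
  if (any(missing_ann)) {
    warning("no annotation for preliminary hit(s): ",
            paste(d$mimic_id[missing_ann], collapse = ", "),
            "; all rule flags set FALSE", call. = FALSE)
  }
  rule1 <- (d$rpm_treated > 4 | d$rpm_untreated > 4)
  rule1[is.na(rule1)] <- FALSE

  hits <- d[d$preliminary_hit, ]
  shares_with_other_hit <- function(values) {
    v <- values[!is.na(values)]
    counts <- table(v)
    out <- !is.na(values) & counts[values] >= 2
    out[is.na(out)] <- FALSE
    out
  }
  rule2 <- rep(FALSE, nrow(d))
  if (nrow(hits) > 0) {
    fam_shared <- shares_with_other_hit(hits$family)
    clu_shared <- shares_with_other_hit(hits$cluster)
    rule2[d$preliminary_hit] <- fam_shared | clu_shared
  }
  rule3 <- !is.na(d$metformin_regulated) & d$metformin_regulated
  rule4 <- !is.na(d$cancer_pathway) & d$cancer_pathway

  selected <- switch(logic,
    gate_any = rule1 & (rule2 | rule3 | rule4),
    all = rule1 & rule2 & rule3 & rule4,
    any = rule1 | rule2 | rule3 | rule4)
  records$rule1 <- rule1
  records$rule2 <- rule2
  records$rule3 <- rule3
  records$rule4 <- rule4
  records$selected <- records$preliminary_hit & selected
  records
}
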