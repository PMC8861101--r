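CDI_CLASSES <- c("strong_synergy", "synergy", "additive", "antagonism")

#' Coefficient of drug interaction
#'
#' `CDI = AB / (A * B)` where `A` is the perturbagen-alone viability,
#' `B` the drug-alone viability and `AB` the combination viability, all
#' normalized to the same untreated control.  CDI = 1 under exact
#' multiplicative (Bliss-style) independence, < 1 synergy, > 1
#' antagonism.
#'
#' @param v_mimic,v_drug,v_combo viabilities `A`, `B`, `AB` (vectorized).
#' @return Numeric vector of CDI values.
#' @export
compute_cdi <- function(v_mimic, v_drug, v_combo) {
  if (any(v_mimic <= 0) || any(v_drug <= 0)) {
    stop("v_mimic and v_drug must be > 0", call. = FALSE)
  }
  v_combo / (v_mimic * v_drug)
}

#' Classify a CDI value into interaction bins
#'
#' Bins (boundaries inclusive on the left-hand class):
#' CDI <= 0.7 strong synergy; 0.7 < CDI <= 1 synergy; 1 < CDI <= 1.1
#' additive; CDI > 1.1 antagonism.
#'
#' @param cdi numeric vector of CDI values (> 0).
#' @return Factor with levels `strong_synergy, synergy, additive,
#'   antagonism`.
#' @export
classify_cdi <- function(cdi) {
  if (any(!is.finite(cdi)) || any(cdi <= 0)) {
    stop("cdi must be finite and > 0", call. = FALSE)
  }
  cut(cdi, breaks = c(0, 0.7, 1, 1.1, Inf), labels = CDI_CLASSES,
      right = TRUE)
}

#' Replicate-level CDI table with significance
#'
#' For each mimic the point CDI is computed from replicate means
#' (`mean(drug) / mean(vehicle)`, the drug effect cancelling), and
#' per-replicate CDIs -- replicates paired by index across arms -- feed a
#' two-sided one-sample t-test against 1.  Mimics with fewer than 2
#' paired replicates, or zero replicate variance, get `p_value = NA`
#' with a warning.
#'
#' @param viability output of [mimic_viability()] (per-mimic, per-arm,
#'   per-replicate plate-relative values).
#' @param drug_effect drug-alone viability `B`, normally from
#'   [estimate_drug_effect()] (drug-arm negative controls).
#' @return A tibble sorted by ascending CDI: `mimic_id, v_mimic, v_drug,
#'   v_combo, cdi, klass, p_value, n_replicates`.
#' @export
cdi_table <- function(viability, drug_effect) {
  if (drug_effect <= 0) stop("drug_effect must be > 0", call. = FALSE)
  wide <- viability |>
    dplyr::select("mimic_id", "arm", "replicate", "value") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "value")
  if (!all(c("drug", "vehicle") %in% names(wide))) {
    stop("both arms are required", call. = FALSE)
  }
  res <- wide |>
    dplyr::group_by(.data$mimic_id) |>
    dplyr::summarise(
      v_mimic = mean(.data$vehicle, na.rm = TRUE),
      v_combo_rel = mean(.data$drug, na.rm = TRUE),
      rep_cdis = list(.data$drug[!is.na(.data$drug) &
                                   !is.na(.data$vehicle)] /
                        .data$vehicle[!is.na(.data$drug) &
                                        !is.na(.data$vehicle)]),
      .groups = "drop")
  if (any(res$v_mimic <= 0)) {
    stop("non-positive vehicle-arm viability for: ",
         paste(res$mimic_id[res$v_mimic <= 0], collapse = ", "),
         call. = FALSE)
  }
  p_of <- function(cdis) {
    if (length(cdis) < 2L || sd(cdis) == 0) return(NA_real_)
    t.test(cdis, mu = 1)$p.value
  }
  few <- vapply(res$rep_cdis, length, 1L) < 2L
  novar <- !few & vapply(res$rep_cdis, function(x) sd(x) == 0, TRUE)
  if (any(few)) {
    warning("fewer than 2 paired replicates; p_value NA for: ",
            paste(res$mimic_id[few], collapse = ", "), call. = FALSE)
  }
  if (any(novar)) {
    warning("zero replicate variance; p_value NA for: ",
            paste(res$mimic_id[novar], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    mimic_id = res$mimic_id,
    v_mimic = res$v_mimic,
    v_drug = drug_effect,
    v_combo = res$v_combo_rel * drug_effect,
    cdi = res$v_combo_rel / res$v_mimic,
    p_value = vapply(res$rep_cdis, p_of, 1.0),
    n_replicates = vapply(res$rep_cdis, length, 1L))
  out$klass <- classify_cdi(out$cdi)
  out <- out[order(out$cdi), c("mimic_id", "v_mimic", "v_drug", "v_combo",
                               "cdi", "klass", "p_value", "n_replicates")]
  out
}

#' Drug-alone viability implied by a published (A, AB, CDI) triple
#'
#' Inverts the CDI definition: `B = AB / (A * CDI)`.
#'
#' @param v_mimic,v_combo,cdi viabilities and CDI (vectorized).
#' @return Implied drug-alone viability `B`.
#' @export
implied_drug_viability <- function(v_mimic, v_combo, cdi) {
  if (any(v_mimic <= 0) || any(cdi <= 0)) {
    stop("v_mimic and cdi must be > 0", call. = FALSE)
  }
  v_combo / (v_mimic * cdi)
}

#' Recompute published CDIs with a leave-one-out drug reference
#'
#' The packaged secondary-screen example prints `A`, `AB` and the CDI but
#' not the drug-alone viability `B`.  `B` is back-calculated per row as
#' `AB / (A * CDI)`; for each row the CDI is then recomputed using the
#' mean implied `B` of the *other* rows, so the recomputation never uses
#' the row's own printed CDI.
#'
#' @param fixture tibble in the layout of [load_secondary_cdi()].
#' @return The fixture plus columns `b_implied`, `b_loo`,
#'   `cdi_recomputed` and `klass` (classification of the recomputed CDI).
#' @export
recompute_published_cdi <- function(fixture = load_secondary_cdi()) {
  b <- implied_drug_viability(fixture$v_mimic, fixture$v_combo,
                              fixture$cdi)
  n <- length(b)
  b_loo <- (sum(b) - b) / (n - 1)
  cdi_rec <- compute_cdi(fixture$v_mimic, b_loo, fixture$v_combo)
  dplyr::mutate(fixture, b_implied = b, b_loo = b_loo,
                cdi_recomputed = cdi_rec,
                klass = classify_cdi(cdi_rec))
}
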