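#' Segment a stress-test trace into its four phases
#'
#' A point at time t belongs to phase k iff t lies in
#' `[injection_k, injection_{k+1})` (half-open; the baseline phase starts
#' at minus infinity), so a point exactly at an injection time is
#' assigned to the following phase.
#'
#' @param trace a [flux_trace()] with exactly 3 injections.
#' @return A 4-row tibble: `phase_index` (0-3), `compound_before`
#'   (`"baseline"` or the compound injected before the phase), `mean,
#'   min, max, first, last, n_points`; the trace's assay is kept as the
#'   `"assay"` attribute.
#' @export
segment_trace <- function(trace) {
  if (!inherits(trace, "flux_trace")) {
    stop("trace must be a flux_trace", call. = FALSE)
  }
  inj <- trace$injections
  if (nrow(inj) != 3L) {
    stop("a stress test has exactly 3 injections; got ", nrow(inj),
         call. = FALSE)
  }
  phase <- findInterval(trace$time_min, inj$time_min)
  counts <- tabulate(phase + 1L, nbins = 4L)
  if (any(counts < 2L)) {
    stop("phase(s) with fewer than 2 points: ",
         paste(which(counts < 2L) - 1L, collapse = ", "), call. = FALSE)
  }
  stats <- lapply(0:3, function(k) {
    v <- trace$value[phase == k]
    tibble::tibble(
      phase_index = k,
      compound_before = if (k == 0) "baseline" else inj$compound[k],
      mean = mean(v), min = min(v), max = max(v),
      first = v[1L], last = v[length(v)], n_points = length(v))
  })
  out <- dplyr::bind_rows(stats)
  attr(out, "assay") <- trace$assay
  attr(out, "sample_id") <- trace$sample_id
  attr(out, "condition") <- trace$condition
  out
}

check_assay <- function(phases, expected) {
  assay <- attr(phases, "assay")
  if (!is.null(assay) && assay != expected) {
    stop("expected an ", expected, " trace, got ", assay, call. = FALSE)
  }
}

#' Glycolysis stress-test parameters from segmented ECAR phases
#'
#' Definitions (kit-report conventions; point statistics configurable):
#' non-glycolytic acidification = `baseline_stat` of the baseline phase;
#' glycolysis = `post_stat` of the post-glucose phase minus
#' non-glycolytic; glycolytic capacity = `post_stat` of the
#' post-oligomycin phase minus non-glycolytic; glycolytic reserve =
#' capacity - glycolysis (exact identity).  Negative derived rates are
#' flagged, never clamped.
#'
#' @param phases output of [segment_trace()] for a
#'   glucose/oligomycin/2-DG schedule.
#' @param baseline_stat,post_stat which phase statistic to use
#'   (defaults: last point before the first injection, maximum after).
#' @return One-row tibble: `non_glycolytic, glycolysis,
#'   glycolytic_capacity, glycolytic_reserve, flagged`.
#' @export
glyco_params <- function(phases, baseline_stat = "last",
                         post_stat = "max") {
  check_assay(phases, "ECAR")
  b <- phases[[baseline_stat]][1L]
  glyc <- phases[[post_stat]][2L] - b
  cap <- phases[[post_stat]][3L] - b
  tibble::tibble(
    non_glycolytic = b, glycolysis = glyc, glycolytic_capacity = cap,
    glycolytic_reserve = cap - glyc,
    flagged = b < 0 | glyc < 0 | cap < glyc)
}

#' Mitochondrial stress-test parameters from segmented OCR phases
#'
#' Definitions (kit-report conventions): non-mitochondrial respiration =
#' min of the post-rotenone/antimycin A phase; basal = last baseline
#' point - non-mito; ATP-linked = last baseline point - min of the
#' post-oligomycin phase; proton leak = post-oligomycin min - non-mito;
#' maximal = post-FCCP max - non-mito; spare capacity = maximal - basal;
#' coupling efficiency = ATP-linked / basal (undefined when basal <= 0).
#' Degenerate traces (basal <= 0 or unordered extrema) are flagged, not
#' clamped.
#'
#' Under multiplicative measurement noise the extremum statistics are
#' biased away from the plateau level (the max of several noisy points
#' overshoots it); `baseline_stat`/`post_stat` switch all four phases to
#' phase means for unbiased recovery in simulation studies.
#'
#' @param phases output of [segment_trace()] for an
#'   oligomycin/FCCP/rotenone-antimycin schedule.
#' @param baseline_stat statistic of the baseline phase (`"last"` or
#'   `"mean"`).
#' @param post_stat `"extremum"` (kit convention: oligomycin min, FCCP
#'   max, rotenone/antimycin min) or `"mean"` for all post-injection
#'   phases.
#' @return One-row tibble: `non_mito, basal, atp_linked, proton_leak,
#'   maximal, spare_capacity, coupling_efficiency, flagged`.
#' @export
mito_params <- function(phases, baseline_stat = c("last", "mean"),
                        post_stat = c("extremum", "mean")) {
  check_assay(phases, "OCR")
  baseline_stat <- match.arg(baseline_stat)
  post_stat <- match.arg(post_stat)
  if (post_stat == "extremum") {
    non_mito <- phases$min[4L]
    oligo_min <- phases$min[2L]
    fccp_max <- phases$max[3L]
  } else {
    non_mito <- phases$mean[4L]
    oligo_min <- phases$mean[2L]
    fccp_max <- phases$mean[3L]
  }
  base_last <- phases[[baseline_stat]][1L]
  atp <- base_last - oligo_min
  leak <- oligo_min - non_mito
  basal <- atp + leak  # identity basal = ATP-linked + leak, exact
  maximal <- fccp_max - non_mito
  tibble::tibble(
    non_mito = non_mito, basal = basal, atp_linked = atp,
    proton_leak = leak, maximal = maximal,
    spare_capacity = maximal - basal,
    coupling_efficiency = if (basal > 0) atp / basal else NA_real_,
    flagged = basal <= 0 | leak < 0 | atp < 0 | maximal < basal)
}

#' Normalize flux parameters to a viability denominator
#'
#' Divides every rate by the condition's viability (e.g. from a crystal
#' violet companion assay) so conditions with different cell numbers are
#' comparable.  Ratio-type quantities (coupling efficiency) and flags are
#' untouched; additive identities (reserve, spare capacity) are preserved
#' because all their terms are scaled alike.
#'
#' @param params one-row tibble from [glyco_params()] or [mito_params()].
#' @param viability positive scalar.
#' @return `params` with rate columns divided by `viability`.
#' @export
normalize_flux <- function(params, viability) {
  if (!is.numeric(viability) || length(viability) != 1L ||
      !is.finite(viability) || viability <= 0) {
    stop("viability must be a single number > 0", call. = FALSE)
  }
  rate_cols <- intersect(
    c("non_glycolytic", "glycolysis", "glycolytic_capacity",
      "glycolytic_reserve", "non_mito", "basal", "atp_linked",
      "proton_leak", "maximal", "spare_capacity"),
    names(params))
  params[rate_cols] <- lapply(params[rate_cols], function(x) x / viability)
  params
}

#' Bioenergetic phenotype (energy-map quadrant) per condition
#'
#' Compares each condition's baseline OCR and ECAR with a reference
#' condition's values: both below the reference gives quiescent, OCR
#' below with ECAR at/above gives glycolytic, OCR at/above with ECAR
#' below gives aerobic, both at/above gives energetic (boundaries use
#' >=, so the reference itself is energetic).
#'
#' @param conditions tibble with columns `condition`, `ocr`, `ecar`
#'   (baseline rates, typically viability-normalized).
#' @param reference name of the reference condition (usually the
#'   untreated control).
#' @return `conditions` plus a `quadrant` factor.
#' @export
energy_phenotype <- function(conditions, reference) {
  d <- tibble::as_tibble(conditions)
  if (!all(c("condition", "ocr", "ecar") %in% names(d))) {
    stop("conditions needs columns condition, ocr, ecar", call. = FALSE)
  }
  ref <- d[d$condition == reference, ]
  if (nrow(ref) != 1L) {
    stop("reference condition not found (or not unique): ", reference,
         call. = FALSE)
  }
  hi_ocr <- d$ocr >= ref$ocr
  hi_ecar <- d$ecar >= ref$ecar
  d$quadrant <- factor(
    ifelse(hi_ocr & hi_ecar, "energetic",
           ifelse(hi_ocr, "aerobic",
                  ifelse(hi_ecar, "glycolytic", "quiescent"))),
    levels = c("quiescent", "glycolytic", "aerobic", "energetic"))
  d
}
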