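# Log-normal multipliers with mean exactly 1: sdlog = sqrt(log(1 + cv^2)),
# meanlog = -sdlog^2/2.  cv = 0 degenerates to the constant 1.
lnorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

lnorm_mult_sdlog <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration for the synthetic viability screen
#'
#' Defaults reproduce the screen design the package models: a 2063-mimic
#' library in 384-well plates, two arms (2.5 mM drug versus vehicle), two
#' replicate plates per arm, drug-alone viability 0.8 (an IC20 dose), a
#' lethal positive control at 0.1 of baseline, and multiplicative
#' log-normal well noise.
#'
#' @param n_mimics library size.
#' @param n_replicates replicate plates per arm.
#' @param v_drug_true drug-alone viability multiplier in (0, 1].
#' @param baseline expected cells/well for an untreated, unperturbed well.
#' @param well_cv coefficient of variation of per-well log-normal noise.
#' @param plate_sd SD (log scale) of the per-plate log-normal effect.
#' @param edge_effect deterministic multiplier applied to outer-ring wells.
#' @param n_neg,n_pos,n_mock control wells per plate (neg >= 3, pos >= 1).
#' @param n_synergists number of mimics spiked with a true interaction
#'   below 1.
#' @param synergist_interaction true CDI assigned to spiked synergists.
#' @param v_mimic_true mimic-alone viability multiplier(s) in (0, 1.5];
#'   scalar or length-`n_mimics` vector, recycled.
#' @param synergy_cut true-CDI cut below which a mimic counts as a true
#'   synergist in the returned truth table.
#' @param pos_lethality viability multiplier of the positive (lethal)
#'   control.
#' @param seed integer root seed; all randomness in [simulate_screen()]
#'   derives from it.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_mimics = 2063, n_replicates = 2,
                          v_drug_true = 0.8, baseline = 1000,
                          well_cv = 0.10, plate_sd = 0.05,
                          edge_effect = 1, n_neg = 16, n_pos = 8,
                          n_mock = 8, n_synergists = 0,
                          synergist_interaction = 0.5, v_mimic_true = 1,
                          synergy_cut = 0.7, pos_lethality = 0.1,
                          seed = 1) {
  if (n_mimics < 1) stop("n_mimics must be >= 1", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (v_drug_true <= 0 || v_drug_true > 1) {
    stop("v_drug_true must be in (0, 1]", call. = FALSE)
  }
  if (well_cv < 0 || plate_sd < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (edge_effect <= 0) stop("edge_effect must be > 0", call. = FALSE)
  if (n_neg < 3) {
    stop("configuration error: at least 3 negative-control wells per ",
         "plate are required (normalization is impossible without them)",
         call. = FALSE)
  }
  if (n_pos < 1) stop("at least 1 positive-control well per plate",
                      call. = FALSE)
  if (n_mock < 0) stop("n_mock must be >= 0", call. = FALSE)
  n_ctrl <- n_neg + n_pos + n_mock
  if (n_ctrl >= 384L) {
    stop("controls exceed plate capacity (", n_ctrl, " >= 384)",
         call. = FALSE)
  }
  if (any(v_mimic_true <= 0) || any(v_mimic_true > 1.5)) {
    stop("v_mimic_true must be in (0, 1.5]", call. = FALSE)
  }
  if (n_synergists < 0 || n_synergists > n_mimics) {
    stop("n_synergists must be in 0..n_mimics", call. = FALSE)
  }
  if (synergist_interaction <= 0) {
    stop("synergist_interaction must be > 0", call. = FALSE)
  }
  structure(list(
    n_mimics = as.integer(n_mimics), n_replicates = as.integer(n_replicates),
    v_drug_true = v_drug_true, baseline = baseline, well_cv = well_cv,
    plate_sd = plate_sd, edge_effect = edge_effect,
    n_neg = as.integer(n_neg), n_pos = as.integer(n_pos),
    n_mock = as.integer(n_mock), n_synergists = as.integer(n_synergists),
    synergist_interaction = synergist_interaction,
    v_mimic_true = v_mimic_true, synergy_cut = synergy_cut,
    pos_lethality = pos_lethality, seed = as.integer(seed)
  ), class = "screen_config")
}

# Fixed plate layout: control wells scattered at an even stride across the
# row-major well sequence (so controls sample interior and edge positions
# alike), remaining wells available for mimics.  Identical on every plate.
plate_layout <- function(config) {
  wells <- all_wells_row_major()
  n_ctrl <- config$n_neg + config$n_pos + config$n_mock
  ctrl_pos <- unique(as.integer(round(seq(8, 377, length.out = n_ctrl))))
  while (length(ctrl_pos) < n_ctrl) {  # collisions after rounding
    extra <- setdiff(seq_len(384L), ctrl_pos)[1L]
    ctrl_pos <- sort(c(ctrl_pos, extra))
  }
  kind <- rep("mimic_slot", 384L)
  kind[ctrl_pos[seq_len(config$n_neg)]] <- "neg_control"
  kind[ctrl_pos[config$n_neg + seq_len(config$n_pos)]] <- "pos_control"
  if (config$n_mock > 0) {
    kind[ctrl_pos[config$n_neg + config$n_pos +
                    seq_len(config$n_mock)]] <- "mock"
  }
  list(wells = wells, kind = kind, mimic_slots = which(kind == "mimic_slot"))
}

#' Simulate a two-arm replicated viability screen with known truth
#'
#' Generates plate maps, well measurements and mimic annotations for a
#' drug/vehicle screen under a multiplicative effects model.  The expected
#' raw count of a mimic well is
#' `baseline * plate_effect * edge_effect * v_mimic_true * m`, where `m`
#' is 1 in the vehicle arm and `v_drug_true * interaction_true` in the
#' drug arm; negative controls and mocks get multiplier 1 (vehicle) or
#' `v_drug_true` (drug), the lethal positive control `pos_lethality` times
#' the arm multiplier.  Per-well noise is log-normal with mean 1 and the
#' configured CV.  `interaction_true` is the mimic's true coefficient of
#' drug interaction, so downstream CDI estimation is parameter recovery.
#'
#' The whole simulation is a deterministic function of `config` (including
#' its `seed`).
#'
#' @param config a [screen_config()].
#' @return A list: `plate_maps`, `measurements`, `annotations` (tibbles)
#'   and `truth` (tibble with `mimic_id`, `v_mimic_true`,
#'   `interaction_true`, `is_synergist`).
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_config")) {
    stop("config must come from screen_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_mimics
  mimic_id <- sprintf("mimic_%05d", seq_len(n))
  interaction_true <- rep(1, n)
  if (config$n_synergists > 0) {
    spike <- sort(sample.int(n, config$n_synergists))
    interaction_true[spike] <- config$synergist_interaction
  }
  v_mimic <- rep_len(config$v_mimic_true, n)
  truth <- tibble::tibble(
    mimic_id = mimic_id, v_mimic_true = v_mimic,
    interaction_true = interaction_true,
    is_synergist = interaction_true <= config$synergy_cut)

  layout <- plate_layout(config)
  capacity <- length(layout$mimic_slots)
  n_chunks <- ceiling(n / capacity)
  chunk_of <- rep(seq_len(n_chunks), each = capacity, length.out = n)

  maps <- list(); meas <- list(); k <- 0L
  for (arm in c("vehicle", "drug")) {
    for (rep_i in seq_len(config$n_replicates)) {
      for (ch in seq_len(n_chunks)) {
        k <- k + 1L
        plate_id <- sprintf("%s_R%d_P%02d", arm, rep_i, ch)
        ids <- mimic_id[chunk_of == ch]
        kind <- layout$kind
        well_mimic <- rep(NA_character_, 384L)
        slots <- layout$mimic_slots[seq_along(ids)]
        well_mimic[slots] <- ids
        kind[kind == "mimic_slot"] <- "empty"
        kind[slots] <- "mimic"
        maps[[k]] <- tibble::tibble(
          plate_id = plate_id, well = layout$wells, kind = kind,
          mimic_id = well_mimic, arm = arm, replicate = rep_i)
      }
    }
  }
  plate_maps <- dplyr::bind_rows(maps)

  plate_ids <- unique(plate_maps$plate_id)
  plate_eff <- setNames(lnorm_mult_sdlog(length(plate_ids),
                                         config$plate_sd), plate_ids)
  edge <- ifelse(is_edge_well(all_wells_row_major()), config$edge_effect, 1)
  names(edge) <- all_wells_row_major()

  v_m <- setNames(v_mimic, mimic_id)
  i_t <- setNames(interaction_true, mimic_id)
  role_mult <- function(kind, mid, arm) {
    armf <- ifelse(arm == "drug", config$v_drug_true, 1)
    out <- numeric(length(kind))
    out[kind == "empty"] <- 0
    sel <- kind %in% c("neg_control", "mock")
    out[sel] <- armf[sel]
    sel <- kind == "pos_control"
    out[sel] <- config$pos_lethality * armf[sel]
    sel <- kind == "mimic"
    inter <- ifelse(arm[sel] == "drug", i_t[mid[sel]], 1)
    out[sel] <- v_m[mid[sel]] * armf[sel] * inter
    out
  }
  mult <- role_mult(plate_maps$kind, plate_maps$mimic_id, plate_maps$arm)
  expected <- config$baseline * plate_eff[plate_maps$plate_id] *
    edge[plate_maps$well] * mult
  noise <- lnorm_mult(nrow(plate_maps), config$well_cv)
  measurements <- tibble::tibble(
    plate_id = plate_maps$plate_id, well = plate_maps$well,
    raw_count = as.numeric(expected * noise))

  # Annotation table: abundances and biology flags independent of the
  # simulated viability effects (stratification is a separate question
  # from synergy truth).
  n_fam <- max(1L, n %/% 8L)
  annotations <- tibble::tibble(
    mimic_id = mimic_id,
    rpm_treated = round(rlnorm(n, meanlog = log(20), sdlog = 1.8), 3),
    rpm_untreated = round(rlnorm(n, meanlog = log(20), sdlog = 1.8), 3),
    family = sprintf("fam_%04d", sample.int(n_fam, n, replace = TRUE)),
    cluster = sprintf("clu_%04d", sample.int(n_fam, n, replace = TRUE)),
    metformin_regulated = runif(n) < 0.2,
    cancer_pathway = runif(n) < 0.3)

  list(plate_maps = plate_maps, measurements = measurements,
       annotations = annotations, truth = truth)
}

#' True parameters for a simulated glycolysis stress test
#'
#' Implies four ECAR plateau levels: baseline at `non_glycolytic`,
#' post-glucose at `non_glycolytic + glycolysis`, post-oligomycin at
#' `non_glycolytic + glycolytic_capacity`, post-2-DG back at
#' `non_glycolytic`.
#'
#' @param non_glycolytic,glycolysis,glycolytic_capacity rates (mpH/min),
#'   all >= 0 with `glycolytic_capacity >= glycolysis`.
#' @return An object of class `flux_truth`.
#' @export
glyco_truth <- function(non_glycolytic, glycolysis, glycolytic_capacity) {
  if (any(c(non_glycolytic, glycolysis, glycolytic_capacity) < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (glycolytic_capacity < glycolysis) {
    stop("inconsistent truth: glycolytic_capacity < glycolysis",
         call. = FALSE)
  }
  structure(list(
    assay = "ECAR",
    params = c(non_glycolytic = non_glycolytic, glycolysis = glycolysis,
               glycolytic_capacity = glycolytic_capacity,
               glycolytic_reserve = glycolytic_capacity - glycolysis),
    levels = c(non_glycolytic, non_glycolytic + glycolysis,
               non_glycolytic + glycolytic_capacity, non_glycolytic),
    compounds = c("glucose", "oligomycin", "2-DG")
  ), class = "flux_truth")
}

#' True parameters for a simulated mitochondrial stress test
#'
#' Implies four OCR plateau levels: baseline at `non_mito + basal`,
#' post-oligomycin at `non_mito + proton_leak`, post-FCCP at
#' `non_mito + maximal`, post-rotenone/antimycin A at `non_mito`.
#' ATP-linked respiration is `basal - proton_leak` by construction.
#'
#' @param non_mito,basal,proton_leak,maximal rates (pmol O2/min), with
#'   `0 <= proton_leak <= basal <= maximal`.
#' @return An object of class `flux_truth`.
#' @export
mito_truth <- function(non_mito, basal, proton_leak, maximal) {
  if (any(c(non_mito, basal, proton_leak, maximal) < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (maximal < basal) {
    stop("inconsistent truth: maximal < basal", call. = FALSE)
  }
  if (proton_leak > basal) {
    stop("inconsistent truth: proton_leak > basal", call. = FALSE)
  }
  structure(list(
    assay = "OCR",
    params = c(non_mito = non_mito, basal = basal,
               atp_linked = basal - proton_leak, proton_leak = proton_leak,
               maximal = maximal, spare_capacity = maximal - basal,
               coupling_efficiency =
                 if (basal > 0) (basal - proton_leak) / basal else NA_real_),
    levels = c(non_mito + basal, non_mito + proton_leak,
               non_mito + maximal, non_mito),
    compounds = c("oligomycin", "FCCP", "rotenone/antimycin A")
  ), class = "flux_truth")
}

#' Simulate a four-phase stress-test flux trace
#'
#' Phase plateau levels are exactly those implied by `truth`; measurement
#' noise is multiplicative log-normal with mean 1 and the given CV.
#' Points are evenly spaced (`spacing` minutes apart) with the three
#' injections placed between phases.
#'
#' @param truth a [glyco_truth()] or [mito_truth()].
#' @param cv measurement noise CV (0 for a noiseless trace).
#' @param n_points measurement points per phase (>= 2).
#' @param spacing minutes between consecutive points.
#' @param seed integer seed.
#' @param sample_id,condition identifiers stored on the trace.
#' @param compounds optional length-3 character vector overriding the
#'   schedule implied by the assay.
#' @return A [flux_trace()].
#' @export
simulate_flux_trace <- function(truth, cv = 0, n_points = 3, spacing = 6,
                                seed = 1, sample_id = "sim",
                                condition = "sim", compounds = NULL) {
  if (!inherits(truth, "flux_truth")) {
    stop("truth must come from glyco_truth() or mito_truth()",
         call. = FALSE)
  }
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  compounds <- compounds %||% truth$compounds
  if (length(compounds) != 3L) {
    stop("a stress test uses exactly 3 injections", call. = FALSE)
  }
  set.seed(seed)
  phase_len <- n_points * spacing
  time_min <- unlist(lapply(0:3, function(k) {
    k * phase_len + spacing * seq_len(n_points) - spacing / 2
  }))
  inj_times <- (1:3) * phase_len
  level <- rep(truth$levels, each = n_points)
  value <- level * lnorm_mult(length(level), cv)
  flux_trace(sample_id, condition, truth$assay, time_min, value,
             data.frame(time_min = inj_times, compound = compounds))
}

#' Simulate a DNA-content sample from a three-component mixture
#'
#' Events are drawn from a mixture of a Gaussian G0/G1 peak at `g1_mean`
#' (relative SD `cv`), a Gaussian G2/M peak at exactly `2 * g1_mean`
#' (same relative SD), and a uniform S-phase component between the two
#' peak means.
#'
#' @param fractions numeric length-3 vector `(g1, s, g2m)`, each >= 0,
#'   summing to 1 (tolerance 1e-9).
#' @param g1_mean G0/G1 peak position (arbitrary fluorescence units).
#' @param cv relative SD of the Gaussian peaks.
#' @param n_events number of events (>= 1).
#' @param seed integer seed.
#' @return Numeric vector of `n_events` fluorescence values.
#' @export
simulate_dna_sample <- function(fractions, g1_mean = 50, cv = 0.03,
                                n_events = 20000, seed = 1) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0)) {
    stop("fractions must be 3 non-negative numbers (g1, s, g2m)",
         call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (tolerance 1e-9); got ",
         format(sum(fractions)), call. = FALSE)
  }
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  if (g1_mean <= 0 || cv < 0) {
    stop("g1_mean must be > 0 and cv >= 0", call. = FALSE)
  }
  set.seed(seed)
  comp <- sample.int(3L, n_events, replace = TRUE, prob = fractions)
  out <- numeric(n_events)
  n1 <- sum(comp == 1L); n2 <- sum(comp == 2L); n3 <- sum(comp == 3L)
  out[comp == 1L] <- rnorm(n1, g1_mean, cv * g1_mean)
  out[comp == 2L] <- runif(n2, g1_mean, 2 * g1_mean)
  out[comp == 3L] <- rnorm(n3, 2 * g1_mean, cv * 2 * g1_mean)
  pmax(out, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
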