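#' Significance stars for p-values
#'
#' Bins: `ns` for p > 0.05, `*` for p <= 0.05, `**` for p <= 0.01,
#' `***` for p <= 0.001 and `****` for p <= 0.0001 (each labelled bound
#' inclusive).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 0.0001, "****",
                ifelse(p <= 0.001, "***",
                       ifelse(p <= 0.01, "**",
                              ifelse(p <= 0.05, "*", "ns")))))
}

#' Two-group fold-change test
#'
#' Fold change is `mean(group_a) / mean(group_b)`; significance comes
#' from a two-sided Welch (unequal-variance) two-sample t-test, the
#' default wherever a comparison involves small replicate groups with no
#' evidence of equal variances.
#'
#' @param group_a,group_b numeric replicate vectors (>= 2 values each).
#' @param label comparison label carried into the result.
#' @return One-row tibble: `label, fold_change, percent_change, p_value,
#'   stars, n_a, n_b`.
#' @export
fold_change_test <- function(group_a, group_b, label = "") {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (mean(group_b) == 0) {
    stop("reference group mean is 0; fold change undefined",
         call. = FALSE)
  }
  p <- tryCatch(t.test(group_a, group_b)$p.value, error = function(e) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) 1 else 0
  })
  fc <- mean(group_a) / mean(group_b)
  tibble::tibble(
    label = label, fold_change = fc,
    percent_change = (fc - 1) * 100, p_value = p,
    stars = significance_stars(p),
    n_a = length(group_a), n_b = length(group_b))
}

#' Configuration for the end-to-end pipeline
#'
#' @param seed integer root seed; stage seeds are derived at fixed
#'   offsets (screen: seed, flux: seed + 1000, cell cycle: seed + 2000).
#' @param out_dir directory for the TSV outputs (created if missing).
#' @param stages character vector of stages to run, a subset of
#'   `c("screen", "synergy", "flux", "cellcycle")`.
#' @param screen a [screen_config()]; its seed is overridden by the
#'   derived screen seed.
#' @param hit_threshold preliminary hit ratio cut.
#' @param stratify_logic rule-combination keyword for [stratify_hits()].
#' @param flux_truths named list of per-condition truth parameter lists,
#'   each with elements `glyco` ([glyco_truth()]) and `mito`
#'   ([mito_truth()]).
#' @param flux_viability named numeric vector of per-condition viability
#'   denominators (required when the flux stage is enabled).
#' @param flux_cv flux measurement noise CV.
#' @param flux_reference reference condition for the energy phenogram.
#' @param cellcycle_fractions named list of per-group `(g1, s, g2m)`
#'   fraction vectors.
#' @param cellcycle_n_reps replicate samples per group.
#' @param cellcycle_n_events events per simulated sample.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(
    seed = 1, out_dir = tempfile("synergyscreen_run_"),
    stages = c("screen", "synergy", "flux", "cellcycle"),
    screen = screen_config(n_mimics = 300, n_synergists = 8),
    hit_threshold = 0.70, stratify_logic = "gate_any",
    flux_truths = list(
      control = list(glyco = glyco_truth(8, 10, 25),
                     mito = mito_truth(10, 90, 30, 140)),
      metformin = list(glyco = glyco_truth(8, 23, 27.5),
                       mito = mito_truth(10, 26.1, 6.9, 47.6))),
    flux_viability = c(control = 1, metformin = 0.8),
    flux_cv = 0.05, flux_reference = "control",
    cellcycle_fractions = list(
      vehicle = c(0.60, 0.25, 0.15),
      metformin = c(0.64, 0.21, 0.15)),
    cellcycle_n_reps = 3, cellcycle_n_events = 10000) {
  stages <- match.arg(stages, c("screen", "synergy", "flux", "cellcycle"),
                      several.ok = TRUE)
  if ("synergy" %in% stages && !"screen" %in% stages) {
    stop("the synergy stage needs the screen stage", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv_file <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages -- screen simulation + normalization + QC +
#' hit calling, CDI synergy scoring, flux trace simulation + parameter
#' extraction + phenogram, and cell-cycle simulation + mixture fitting +
#' group comparison -- writing one TSV per output plus a `manifest.tsv` of
#' files and MD5 checksums.  Given the same configuration (including
#' seed) the outputs are byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the output directory, the manifest
#'   tibble and the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must come from pipeline_config()", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  results <- list()

  if ("screen" %in% config$stages) {
    scfg <- config$screen
    scfg$seed <- config$seed
    sim <- simulate_screen(scfg)
    norm <- normalize_screen(sim$plate_maps, sim$measurements)
    drug_eff <- estimate_drug_effect(sim$plate_maps, sim$measurements)
    viab <- mimic_viability(norm)
    hits <- aggregate_and_ratio(viab, drug_eff) |>
      call_preliminary_hits(config$hit_threshold) |>
      stratify_hits(sim$annotations, config$stratify_logic)
    qc_plates <- plate_qc(norm)
    rep_cor <- dplyr::bind_rows(lapply(c("drug", "vehicle"), function(a) {
      sub <- viab[viab$arm == a, ]
      reps <- sort(unique(sub$replicate))
      pairs <- utils::combn(reps, 2, simplify = FALSE)
      dplyr::bind_rows(lapply(pairs, function(pr) {
        va <- setNames(sub$value[sub$replicate == pr[1]],
                       sub$mimic_id[sub$replicate == pr[1]])
        vb <- setNames(sub$value[sub$replicate == pr[2]],
                       sub$mimic_id[sub$replicate == pr[2]])
        tibble::tibble(arm = a, rep_a = pr[1], rep_b = pr[2],
                       spearman = replicate_correlation(va, vb))
      }))
    }))
    qc <- dplyr::bind_rows(
      qc_plates |>
        dplyr::transmute(metric = "zprime", id = .data$plate_id,
                         value = .data$zprime),
      rep_cor |>
        dplyr::transmute(
          metric = "replicate_spearman",
          id = sprintf("%s_r%d_vs_r%d", .data$arm, .data$rep_a,
                       .data$rep_b),
          value = .data$spearman))
    files <- c(files,
               write_tsv_file(fmt_num(hits), file.path(config$out_dir,
                                                       "hits.tsv")),
               write_tsv_file(fmt_num(qc), file.path(config$out_dir,
                                                     "qc.tsv")))
    results$screen <- list(sim = sim, normalized = norm,
                           viability = viab, drug_effect = drug_eff,
                           hits = hits, qc_plates = qc_plates,
                           replicate_correlations = rep_cor)
    if ("synergy" %in% config$stages) {
      cdi <- cdi_table(viab, drug_eff)
      files <- c(files, write_tsv_file(fmt_num(cdi),
                                       file.path(config$out_dir,
                                                 "cdi.tsv")))
      results$cdi <- cdi
    }
  }

  if ("flux" %in% config$stages) {
    if (is.null(config$flux_viability)) {
      stop("flux stage enabled but flux_viability is NULL", call. = FALSE)
    }
    miss <- setdiff(names(config$flux_truths),
                    names(config$flux_viability))
    if (length(miss)) {
      stop("no viability value for flux condition(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    fseed <- config$seed + 1000L
    conds <- names(config$flux_truths)
    glyco <- list(); mito <- list(); pheno <- list()
    for (i in seq_along(conds)) {
      cond <- conds[i]
      viab_i <- config$flux_viability[[cond]]
      gt <- config$flux_truths[[cond]]$glyco
      mt <- config$flux_truths[[cond]]$mito
      gtr <- simulate_flux_trace(gt, cv = config$flux_cv,
                                 seed = fseed + 2L * i,
                                 sample_id = paste0(cond, "_ecar"),
                                 condition = cond)
      mtr <- simulate_flux_trace(mt, cv = config$flux_cv,
                                 seed = fseed + 2L * i + 1L,
                                 sample_id = paste0(cond, "_ocr"),
                                 condition = cond)
      gseg <- segment_trace(gtr); mseg <- segment_trace(mtr)
      glyco[[i]] <- dplyr::bind_cols(
        tibble::tibble(condition = cond),
        normalize_flux(glyco_params(gseg), viab_i))
      mito[[i]] <- dplyr::bind_cols(
        tibble::tibble(condition = cond),
        normalize_flux(mito_params(mseg), viab_i))
      pheno[[i]] <- tibble::tibble(
        condition = cond,
        ocr = mseg$last[1L] / viab_i,
        ecar = gseg$last[1L] / viab_i)
    }
    glyco <- dplyr::bind_rows(glyco); mito <- dplyr::bind_rows(mito)
    phen <- energy_phenotype(dplyr::bind_rows(pheno),
                             config$flux_reference)
    files <- c(files,
               write_tsv_file(fmt_num(glyco),
                              file.path(config$out_dir, "glyco.tsv")),
               write_tsv_file(fmt_num(mito),
                              file.path(config$out_dir, "mito.tsv")),
               write_tsv_file(fmt_num(phen),
                              file.path(config$out_dir,
                                        "phenogram.tsv")))
    results$flux <- list(glyco = glyco, mito = mito, phenogram = phen)
  }

  if ("cellcycle" %in% config$stages) {
    cseed <- config$seed + 2000L
    groups <- names(config$cellcycle_fractions)
    fits <- list()
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      fits[[g]] <- dplyr::bind_rows(lapply(
        seq_len(config$cellcycle_n_reps), function(r) {
          ev <- simulate_dna_sample(
            config$cellcycle_fractions[[g]],
            n_events = config$cellcycle_n_events,
            seed = cseed + 10L * gi + r)
          fit_cell_cycle(ev, sample_id = sprintf("%s_rep%d", g, r))
        }))
    }
    fractions <- dplyr::bind_rows(fits)
    files <- c(files,
               write_tsv_file(fmt_num(fractions),
                              file.path(config$out_dir,
                                        "fractions.tsv")))
    results$cellcycle <- list(fractions = fits)
    if (length(groups) >= 2L) {
      comp <- compare_fractions(fits[[1L]], fits[[2L]])
      comp <- dplyr::mutate(comp,
                            group_a = groups[1L], group_b = groups[2L],
                            .before = 1L)
      files <- c(files,
                 write_tsv_file(fmt_num(comp),
                                file.path(config$out_dir,
                                          "comparisons.tsv")))
      results$cellcycle$comparisons <- comp
    }
  }

  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  write_tsv_file(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 results = results))
}

# Fixed-width numeric formatting so TSV output is locale-independent and
# byte-stable for identical values.
fmt_num <- function(d) {
  d[] <- lapply(d, function(x) {
    if (is.double(x)) sprintf("%.10g", x) else x
  })
  d
}
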