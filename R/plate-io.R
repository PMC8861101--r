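WELL_ROLES <- c("mimic", "neg_control", "pos_control", "mock", "empty")
SCREEN_ARMS <- c("drug", "vehicle")

#' Validate a long-format plate map
#'
#' A plate map is a tibble with one row per well and columns `plate_id`,
#' `well`, `kind` (one of mimic, neg_control, pos_control, mock, empty),
#' `mimic_id` (`NA` unless `kind == "mimic"`), `arm` (drug/vehicle) and
#' `replicate` (positive integer).  Arm and replicate are properties of the
#' whole plate: treatment was applied per plate, not per well.
#'
#' Checks: valid 16x24 addresses, no duplicate (plate, well), `mimic_id`
#' present iff the well carries a mimic, a single arm/replicate per plate,
#' and at least 3 negative-control and 1 positive-control well per plate.
#'
#' @param plate_map data frame as described above.
#' @return The validated map (invisibly canonicalized well addresses).
#' @export
validate_plate_map <- function(plate_map) {
  req <- c("plate_id", "well", "kind", "mimic_id", "arm", "replicate")
  miss <- setdiff(req, names(plate_map))
  if (length(miss)) stop("plate map is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pm <- tibble::as_tibble(plate_map)
  pm$well <- canonical_well(pm$well)
  pm$mimic_id <- as.character(pm$mimic_id)
  pm$mimic_id[!is.na(pm$mimic_id) & pm$mimic_id == ""] <- NA_character_
  if (!all(pm$kind %in% WELL_ROLES)) {
    stop("unknown well kind(s): ",
         paste(unique(setdiff(pm$kind, WELL_ROLES)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(pm$arm %in% SCREEN_ARMS)) {
    stop("arm must be one of: ", paste(SCREEN_ARMS, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(pm$replicate)) || any(pm$replicate < 1) ||
      any(pm$replicate != as.integer(pm$replicate))) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  key <- paste(pm$plate_id, pm$well)
  if (anyDuplicated(key)) {
    stop("duplicate (plate_id, well) in plate map: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  is_mimic <- pm$kind == "mimic"
  if (any(is_mimic & is.na(pm$mimic_id))) {
    stop("mimic wells must carry a mimic_id", call. = FALSE)
  }
  if (any(!is_mimic & !is.na(pm$mimic_id))) {
    stop("mimic_id present on a non-mimic well", call. = FALSE)
  }
  for (pid in unique(pm$plate_id)) {
    sub <- pm[pm$plate_id == pid, ]
    if (length(unique(sub$arm)) != 1L || length(unique(sub$replicate)) != 1L) {
      stop("plate ", pid, " mixes arms or replicates; arm/replicate are ",
           "plate-level properties", call. = FALSE)
    }
    if (sum(sub$kind == "neg_control") < 3L) {
      stop("plate ", pid, " has fewer than 3 negative-control wells",
           call. = FALSE)
    }
    if (sum(sub$kind == "pos_control") < 1L) {
      stop("plate ", pid, " has no positive-control well", call. = FALSE)
    }
  }
  pm
}

#' Read and cross-validate plate maps and well measurements
#'
#' Reads the two screen CSVs: a plate map (columns `plate_id, well, kind,
#' mimic_id, arm, replicate`) and per-well raw readouts (columns
#' `plate_id, well, raw_count`, cells per well).  Every measurement must
#' refer to a mapped well, raw counts must be non-negative, and (plate,
#' well) must be unique in each table.
#'
#' @param map_path path to the plate-map CSV.
#' @param measurements_path path to the measurements CSV.
#' @return A list with elements `plate_maps` and `measurements` (tibbles).
#' @export
read_plate_data <- function(map_path, measurements_path) {
  for (p in c(map_path, measurements_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  pm <- validate_plate_map(read.csv(map_path, stringsAsFactors = FALSE))
  meas <- tibble::as_tibble(
    read.csv(measurements_path, stringsAsFactors = FALSE))
  req <- c("plate_id", "well", "raw_count")
  miss <- setdiff(req, names(meas))
  if (length(miss)) stop("measurements CSV is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  meas$well <- canonical_well(meas$well)
  if (any(!is.finite(meas$raw_count)) || any(meas$raw_count < 0)) {
    stop("raw_count must be finite and >= 0", call. = FALSE)
  }
  mkey <- paste(meas$plate_id, meas$well)
  if (anyDuplicated(mkey)) {
    stop("duplicate (plate_id, well) in measurements: ",
         paste(unique(mkey[duplicated(mkey)]), collapse = ", "),
         call. = FALSE)
  }
  unmapped <- !(mkey %in% paste(pm$plate_id, pm$well))
  if (any(unmapped)) {
    stop("measurement(s) for unmapped well(s): ",
         paste(mkey[unmapped], collapse = ", "), call. = FALSE)
  }
  list(plate_maps = pm, measurements = meas)
}

#' Write plate maps and measurements back to the screen CSV dialect
#'
#' Raw counts are written with 17 significant digits so that a
#' write-then-read cycle reproduces every record exactly.
#'
#' @param plate_maps,measurements tibbles as returned by [read_plate_data()]
#'   or [simulate_screen()].
#' @param map_path,measurements_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_plate_data <- function(plate_maps, measurements,
                             map_path, measurements_path) {
  pm <- validate_plate_map(plate_maps)
  write.csv(pm, map_path, row.names = FALSE, quote = FALSE, na = "")
  meas <- measurements
  meas$raw_count <- sprintf("%.17g", meas$raw_count)
  write.csv(meas, measurements_path, row.names = FALSE, quote = FALSE)
  invisible(c(map_path, measurements_path))
}

#' Read a mimic annotation table
#'
#' Columns: `mimic_id`, `rpm_treated`, `rpm_untreated` (small-RNA-seq
#' abundance in reads per million under drug / vehicle), `family`,
#' `cluster` (empty for unknown), and 0/1 flags `metformin_regulated`
#' and `cancer_pathway`.
#'
#' @param path path to the annotations CSV.
#' @return A tibble with logical flag columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  req <- c("mimic_id", "rpm_treated", "rpm_untreated", "family", "cluster",
           "metformin_regulated", "cancer_pathway")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotations CSV is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(ann$rpm_treated < 0, na.rm = TRUE) ||
      any(ann$rpm_untreated < 0, na.rm = TRUE)) {
    stop("reads-per-million values must be >= 0", call. = FALSE)
  }
  for (col in c("family", "cluster")) {
    ann[[col]] <- as.character(ann[[col]])
    ann[[col]][!is.na(ann[[col]]) & ann[[col]] == ""] <- NA_character_
  }
  ann$metformin_regulated <- as.logical(as.integer(ann$metformin_regulated))
  ann$cancer_pathway <- as.logical(as.integer(ann$cancer_pathway))
  ann
}

#' Read per-event DNA-content values
#'
#' One row per detected event: columns `sample_id`, `fluorescence`
#' (arbitrary units, >= 0).
#'
#' @param path path to the DNA-content CSV.
#' @return A named list of numeric event vectors, one per sample.
#' @export
read_dna_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "fluorescence")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("DNA-content CSV is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(d$fluorescence)) || any(d$fluorescence < 0)) {
    stop("fluorescence values must be finite and >= 0", call. = FALSE)
  }
  split(d$fluorescence, d$sample_id)
}

#' Published secondary-screen synergy results (packaged example)
#'
#' The packaged worked example: 12 metformin-sensitizing miRNA mimics with
#' their mean viability under mimic alone (`v_mimic`), mimic plus drug
#' (`v_combo`) -- both normalized to the non-targeting-control mean -- and
#' the published coefficient of drug interaction (`cdi`).  The drug-alone
#' viability was not published alongside and can be back-calculated as
#' `v_combo / (v_mimic * cdi)`; see [recompute_published_cdi()].
#'
#' @return A 12-row tibble with columns `mimic_id`, `v_mimic`, `v_combo`,
#'   `cdi`, in the published order.
#' @export
load_secondary_cdi <- function() {
  path <- system.file("extdata", "secondary_screen_cdi.csv",
                      package = "synergyscreen", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
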