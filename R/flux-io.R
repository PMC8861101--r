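#' Construct an extracellular-flux trace
#'
#' A flux trace is one sample's ECAR (mpH/min) or OCR (pmol O2/min) time
#' series together with its injection schedule.  Stress tests use exactly
#' three serial injections, giving four phases; validity only requires
#' that times be strictly increasing, injections strictly increasing and
#' inside the measured time span, and every phase hold at least two points.
#'
#' @param sample_id,condition identifiers for the sample and its treatment
#'   condition.
#' @param assay `"ECAR"` or `"OCR"`.
#' @param time_min numeric vector of measurement times (minutes), strictly
#'   increasing.
#' @param value numeric vector of rates, same length as `time_min`.
#' @param injections data frame with columns `time_min` and `compound`.
#' @return An object of class `flux_trace`.
#' @export
flux_trace <- function(sample_id, condition, assay, time_min, value,
                       injections) {
  assay <- match.arg(assay, c("ECAR", "OCR"))
  time_min <- as.numeric(time_min); value <- as.numeric(value)
  if (length(time_min) != length(value)) {
    stop("time_min and value must have equal length", call. = FALSE)
  }
  if (any(diff(time_min) <= 0)) {
    stop("measurement times must be strictly increasing for sample ",
         sample_id, call. = FALSE)
  }
  injections <- as.data.frame(injections)
  if (!all(c("time_min", "compound") %in% names(injections))) {
    stop("injections need columns time_min and compound", call. = FALSE)
  }
  it <- injections$time_min
  if (length(it) && any(diff(it) <= 0)) {
    stop("injection times must be strictly increasing", call. = FALSE)
  }
  if (length(it) && (min(it) <= min(time_min) || max(it) >= max(time_min))) {
    stop("injections must fall strictly within the measured time span",
         call. = FALSE)
  }
  phase <- findInterval(time_min, it)
  if (any(tabulate(phase + 1L, nbins = length(it) + 1L) < 2L)) {
    stop("every phase needs at least 2 measurement points", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id),
         condition = as.character(condition),
         assay = assay, time_min = time_min, value = value,
         injections = injections),
    class = "flux_trace")
}

#' @export
print.flux_trace <- function(x, ...) {
  cat(sprintf("<flux_trace> %s [%s] %s: %d points, %d injections (%s)\n",
              x$sample_id, x$condition, x$assay, length(x$time_min),
              nrow(x$injections), paste(x$injections$compound,
                                        collapse = ", ")))
  invisible(x)
}

#' Read long-format flux traces from CSV
#'
#' Expects columns `sample_id, condition, assay, time_min, value`; one
#' trace is built per (sample_id, assay) with the supplied injection
#' schedule attached to each.
#'
#' @param path path to the flux CSV.
#' @param injections data frame with columns `time_min` and `compound`
#'   (the run's injection schedule, shared by all traces).
#' @return A list of [flux_trace()] objects.
#' @export
read_flux_traces <- function(path, injections) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "assay", "time_min", "value")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("flux CSV is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(d$assay), c("ECAR", "OCR"))
  if (length(bad)) stop("unknown assay label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  keys <- unique(d[, c("sample_id", "assay")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$sample_id == keys$sample_id[i] & d$assay == keys$assay[i], ]
    cond <- unique(sub$condition)
    if (length(cond) != 1L) {
      stop("sample ", keys$sample_id[i], " maps to several conditions",
           call. = FALSE)
    }
    flux_trace(keys$sample_id[i], cond, keys$assay[i],
               sub$time_min, sub$value, injections)
  })
}
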