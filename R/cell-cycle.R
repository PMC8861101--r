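# Locate candidate G1/G2M peaks from a kernel density estimate.  The
# G2/M peak sits near twice the G1 position; if the dominant mode has a
# credible companion at half its position, the dominant mode is G2/M.
locate_g1_peak <- function(events) {
  d <- density(events, n = 1024)
  i <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (!length(i)) i <- which.max(d$y)
  px <- d$x[i]; py <- d$y[i]
  keep <- py > 0.05 * max(py)
  px <- px[keep]; py <- py[keep]
  main <- px[which.max(py)]
  g1 <- main
  lower <- abs(px - main / 2) / (main / 2) < 0.25
  if (any(lower) && max(py[lower]) > 0.2 * max(py)) {
    g1 <- px[lower][which.max(py[lower])]
  }
  has_g2m <- any(abs(px - 2 * g1) / (2 * g1) < 0.25 & px > 1.5 * g1)
  list(g1 = g1, has_g2m_peak = has_g2m)
}

#' Fit cell-cycle phase fractions to a DNA-content sample
#'
#' Models the post-filter fluorescence distribution as a three-component
#' mixture: a Gaussian G0/G1 peak, a Gaussian G2/M peak whose mean is
#' constrained to 1.8-2.2 times the G1 mean, and a uniform S-phase
#' component spanning the interval between the two peak means.  Weights
#' and component parameters are estimated by maximum likelihood (EM) from
#' a density-mode start.  Debris and doublets -- events outside 0.3-2.8
#' times the initial G1 peak estimate -- are excluded before fitting.
#' Fractions are the fitted component weights (of post-filter events) and
#' sum to 1 exactly.
#'
#' Samples without a detectable G2/M peak are fitted anyway and flagged,
#' as are fits where the G2/M:G1 mean ratio sticks at a constraint bound.
#'
#' @param events numeric vector of per-event fluorescence values (>= 0).
#' @param sample_id identifier carried into the result.
#' @param min_events minimum events required for fitting.
#' @param g2m_ratio_bounds allowed G2M/G1 mean ratio interval.
#' @param debris_bounds multiples of the G1 peak kept before fitting.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return One-row tibble: `sample_id, g1, s, g2m, g1_peak_mean,
#'   g2m_peak_mean, cv_g1, fit_quality` (RMS residual between the
#'   histogram and the fitted density), `flagged, n_events_used`.
#' @export
fit_cell_cycle <- function(events, sample_id = "sample",
                           min_events = 1000,
                           g2m_ratio_bounds = c(1.8, 2.2),
                           debris_bounds = c(0.3, 2.8),
                           max_iter = 500, tol = 1e-10) {
  ev <- as.numeric(events)
  ev <- ev[is.finite(ev)]
  if (any(ev < 0)) stop("fluorescence values must be >= 0", call. = FALSE)
  if (length(ev) < min_events) {
    stop("need at least ", min_events, " events; got ", length(ev),
         call. = FALSE)
  }
  if (diff(range(ev)) == 0 || sd(ev) < 1e-12 * mean(ev)) {
    stop("degenerate sample: events are (nearly) a single value",
         call. = FALSE)
  }
  pk <- locate_g1_peak(ev)
  g1_0 <- pk$g1
  ev <- ev[ev >= debris_bounds[1] * g1_0 & ev <= debris_bounds[2] * g1_0]
  n <- length(ev)
  if (n < min_events / 2) {
    stop("too few events remain after debris/doublet filtering",
         call. = FALSE)
  }

  mu1 <- g1_0; mu2 <- 2 * g1_0
  s1 <- 0.05 * mu1; s2 <- 0.05 * mu2
  w <- c(g1 = 0.5, s = 0.2, g2m = 0.3)
  ll_old <- -Inf
  clamped <- FALSE
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(ev, mu1, s1)
    ds <- w[2] * dunif(ev, mu1, mu2)
    d2 <- w[3] * dnorm(ev, mu2, s2)
    tot <- d1 + ds + d2
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r1 <- d1 / tot; rs <- ds / tot; r2 <- d2 / tot
    w <- c(mean(r1), mean(rs), mean(r2))
    w <- pmax(w, 1e-12); w <- w / sum(w)
    if (sum(r1) > 0) {
      mu1 <- sum(r1 * ev) / sum(r1)
      s1 <- sqrt(sum(r1 * (ev - mu1)^2) / sum(r1))
    }
    s1 <- max(s1, 1e-4 * mu1)
    if (sum(r2) > 0) {
      mu2_free <- sum(r2 * ev) / sum(r2)
      mu2 <- min(max(mu2_free, g2m_ratio_bounds[1] * mu1),
                 g2m_ratio_bounds[2] * mu1)
      clamped <- mu2 != mu2_free
      s2 <- sqrt(sum(r2 * (ev - mu2)^2) / sum(r2))
    }
    s2 <- max(s2, 1e-4 * mu2)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  w <- w / sum(w)
  w[3] <- max(0, 1 - w[1] - w[2])  # sum pinned to 1 after normalization

  # residual between histogram density and fitted mixture density
  h <- graphics::hist(ev, breaks = 64, plot = FALSE)
  fitted <- w[1] * dnorm(h$mids, mu1, s1) +
    w[2] * dunif(h$mids, mu1, mu2) + w[3] * dnorm(h$mids, mu2, s2)
  fit_quality <- sqrt(mean((h$density - fitted)^2))

  tibble::tibble(
    sample_id = as.character(sample_id),
    g1 = unname(w[1]), s = unname(w[2]), g2m = unname(w[3]),
    g1_peak_mean = mu1, g2m_peak_mean = mu2, cv_g1 = s1 / mu1,
    fit_quality = fit_quality,
    flagged = clamped || !pk$has_g2m_peak,
    n_events_used = n)
}

#' Compare phase fractions between two groups of samples
#'
#' Per phase (G0/G1, S, G2/M): difference of group means in percentage
#' points with a two-sided Welch two-sample t-test.  Both groups need at
#' least 2 replicate samples.
#'
#' @param group_a,group_b tibbles of [fit_cell_cycle()] rows (one row
#'   per replicate sample).
#' @return A tibble: `phase, mean_a, mean_b, diff_points, p_value`.
#' @export
compare_fractions <- function(group_a, group_b) {
  if (nrow(group_a) < 2L || nrow(group_b) < 2L) {
    stop("each group needs at least 2 replicate samples", call. = FALSE)
  }
  one <- function(phase) {
    a <- group_a[[phase]]; b <- group_b[[phase]]
    p <- tryCatch(t.test(a, b)$p.value, error = function(e) {
      # both groups constant: no within-group variance to test against
      if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    })
    tibble::tibble(phase = phase, mean_a = mean(a), mean_b = mean(b),
                   diff_points = (mean(a) - mean(b)) * 100, p_value = p)
  }
  dplyr::bind_rows(lapply(c("g1", "s", "g2m"), one))
}
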