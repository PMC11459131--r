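# Change-point detection of discrete unfolding steps.
#
# Engine: binary segmentation with an l2 cost around a per-segment linear
# trend. Within a candidate segment the extension-versus-time record is
# modelled as a straight line; splitting is accepted when the reduction in
# summed squared error exceeds a noise-scaled penalty. Discontinuities at the
# accepted change points are then measured from short local linear fits on
# either side, and only steps at least `min_step` in magnitude are reported
# as events. Smooth curvature (the low-force entropic toe of the model)
# produces change points whose fitted discontinuity is near zero; these are
# discarded by the size filter.

# SSE of a linear fit on x[i..j] for vectors of segment bounds, via
# cumulative sums. Returns 0 for segments shorter than 3 samples.
.make_sse <- function(t, x) {
  ct <- c(0, cumsum(t)); ctt <- c(0, cumsum(t * t))
  cx <- c(0, cumsum(x)); cxx <- c(0, cumsum(x * x))
  ctx <- c(0, cumsum(t * x))
  function(i, j) {
    n <- j - i + 1
    st <- ct[j + 1] - ct[i]; stt <- ctt[j + 1] - ctt[i]
    sx <- cx[j + 1] - cx[i]; sxx <- cxx[j + 1] - cxx[i]
    stx <- ctx[j + 1] - ctx[i]
    det <- n * stt - st * st
    slope <- ifelse(det > 0, (n * stx - st * sx) / det, 0)
    icept <- (sx - slope * st) / n
    sse <- sxx - icept * sx - slope * stx
    pmax(sse, 0)
  }
}

# Binary segmentation on (t, x); returns sorted indices cp such that a change
# occurs between samples cp and cp + 1 (indices local to t/x).
.binseg_linear <- function(t, x, min_size = 20L, penalty, max_cp = 40L) {
  n <- length(x)
  sse <- .make_sse(t, x)
  cps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue) && length(cps) < max_cp) {
    seg <- queue[[1L]]; queue <- queue[-1L]
    lo <- seg[1L]; hi <- seg[2L]
    if (hi - lo + 1L < 2L * min_size) next
    m <- seq(lo + min_size - 1L, hi - min_size)
    gain <- sse(lo, hi) - (sse(rep(lo, length(m)), m) +
                             sse(m + 1L, rep(hi, length(m))))
    best <- which.max(gain)
    if (gain[best] > penalty) {
      cp <- m[best]
      cps <- c(cps, cp)
      queue <- c(queue, list(c(lo, cp)), list(c(cp + 1L, hi)))
    }
  }
  sort(cps)
}

# Discontinuity at each change point from local linear fits over at most
# `window` samples on either side (clipped at neighbouring change points).
.measure_steps <- function(t, x, cps, window = 30L) {
  bounds <- c(0L, cps, length(x))
  vapply(seq_along(cps), function(i) {
    cp <- cps[i]
    li <- max(bounds[i] + 1L, cp - window + 1L)
    ri <- min(bounds[i + 2L], cp + window)
    lt <- t[li:cp]; lx <- x[li:cp]
    rt <- t[(cp + 1L):ri]; rx <- x[(cp + 1L):ri]
    tb <- (t[cp] + t[cp + 1L]) / 2
    right <- .linfit_at(rt, rx, tb)
    left <- .linfit_at(lt, lx, tb)
    right - left
  }, numeric(1))
}

.linfit_at <- function(tt, xx, t0) {
  if (length(xx) < 2L || diff(range(tt)) == 0) return(mean(xx))
  tc <- tt - mean(tt)
  slope <- sum(tc * (xx - mean(xx))) / sum(tc * tc)
  mean(xx) + slope * (t0 - mean(tt))
}

#' Detect unfolding steps in a force-ramp cycle
#'
#' Runs change-point detection separately on the extension and relaxation
#' phases of a cycle and reports discrete steps in the end-to-end distance.
#' Steps that increase extension are unfolding events; steps that decrease it
#' (refolding during the ramp) are reported with negative `size_nm`.
#'
#' @param cycle A `"force_ramp_cycle"`.
#' @param min_step Minimum reported step magnitude, nm.
#' @param penalty Model-selection penalty on the squared-error gain of a
#'   split; `NULL` (default) chooses `25 * sigma^2 * log(n)` with `sigma`
#'   estimated robustly from first differences (floored at 0.05 nm so
#'   noiseless traces terminate).
#' @param min_seg Minimum change-point spacing, samples.
#' @param window Half-width, in samples, of the local fits used to measure
#'   step sizes and of the median window for the event force.
#' @return A data frame with one row per event: `cycle_index`, `phase`,
#'   `index` (last sample before the step, in trace coordinates), `time_s`,
#'   `force_pN` (median force in a +/-5-sample window) and `size_nm`.
#' @export
detect_events <- function(cycle, min_step = 1.5, penalty = NULL,
                          min_seg = 20L, window = 30L) {
  phases <- split_phases(cycle)
  if (nrow(phases$extension) + nrow(phases$relaxation) < 50L) {
    stop("cycle has fewer than 50 ramp samples", call. = FALSE)
  }
  out <- list()
  for (ph in names(phases)) {
    p <- phases[[ph]]
    if (nrow(p) < 2L * min_seg) next
    t <- p$time_s; x <- p$extension_nm; f <- p$force_pN
    if (is.null(penalty)) {
      d <- diff(x)
      sigma <- max(mad(d) / sqrt(2), 0.05)
      pen <- 25 * sigma^2 * log(length(x))
    } else {
      pen <- penalty
    }
    cps <- .binseg_linear(t, x, min_size = min_seg, penalty = pen)
    if (!length(cps)) next
    steps <- .measure_steps(t, x, cps, window = window)
    keep <- abs(steps) >= min_step
    if (!any(keep)) next
    cps <- cps[keep]; steps <- steps[keep]
    force_at <- vapply(cps, function(cp) {
      w <- max(1L, cp - 5L):min(length(f), cp + 5L)
      median(f[w])
    }, numeric(1))
    out[[ph]] <- data.frame(
      cycle_index = cycle$meta$cycle_index %||% NA_integer_,
      phase = ph,
      index = p$index[cps],
      time_s = t[cps],
      force_pN = force_at,
      size_nm = steps,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(cycle_index = integer(), phase = character(),
                      index = integer(), time_s = numeric(),
                      force_pN = numeric(), size_nm = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$index), , drop = FALSE]
}

#' Cut a cycle into segments between unfolding events
#'
#' Splits each phase of a cycle at the detected events, giving `n + 1`
#' segments for `n` events in a phase. Segments are numbered in ascending
#' order of force: for the extension phase that is temporal order, for the
#' relaxation phase it is reverse temporal order.
#'
#' @param cycle A `"force_ramp_cycle"`.
#' @param events Event table from [detect_events()] for this cycle, sorted by
#'   sample index.
#' @return A data frame with one row per segment: `cycle_index`, `phase`,
#'   `ordinal`, `start`, `end` (inclusive trace indices) and `n_samples`.
#'   Segments tile each phase without overlap.
#' @export
segment_cycle <- function(cycle, events) {
  phases <- split_phases(cycle)
  n <- nrow(cycle$samples)
  if (nrow(events) && (any(events$index < 1L) || any(events$index >= n))) {
    stop("event indices out of range", call. = FALSE)
  }
  out <- list()
  for (ph in names(phases)) {
    p <- phases[[ph]]
    lo <- p$index[1L]; hi <- p$index[nrow(p)]
    ev <- sort(events$index[events$phase == ph])
    starts <- c(lo, ev + 1L)
    ends <- c(ev, hi)
    ord <- seq_along(starts)
    if (ph == "relaxation") ord <- rev(ord)  # ascending force
    out[[ph]] <- data.frame(
      cycle_index = cycle$meta$cycle_index %||% NA_integer_,
      phase = ph, ordinal = ord,
      start = starts, end = ends,
      n_samples = ends - starts + 1L,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Total unfolding length in one phase of a cycle
#'
#' Sum of the positive (unfolding) step sizes among a cycle's events in the
#' given phase; refolding steps (negative sizes) are excluded. Zero when no
#' events occurred.
#'
#' @param events Event table from [detect_events()].
#' @param phase `"extension"` (default) or `"relaxation"`.
#' @return Total unfolding length, nm.
#' @export
total_unfolding_per_cycle <- function(events, phase = "extension") {
  sizes <- events$size_nm[events$phase == phase & events$size_nm > 0]
  if (!length(sizes)) 0 else sum(sizes)
}

#' Gaussian-mixture decomposition of event sizes
#'
#' Fits a univariate Gaussian mixture (unequal variances) to a set of event
#' sizes and returns the component means with standard errors and mixing
#' weights, sorted by mean. Components whose means are within two combined
#' standard errors of a neighbour are flagged as overlapping (a sign the
#' requested number of components exceeds the structure in the data).
#'
#' @param sizes Numeric vector of event sizes, nm.
#' @param n_components Number of mixture components; at least 1, and
#'   `length(sizes) >= 10 * n_components`.
#' @return A data frame with columns `mean`, `sem` (standard error of the
#'   component mean), `sd` (component width), `weight` and `n_eff` (effective
#'   member count), one row per component in ascending mean order, with
#'   attribute `overlapping` (logical): `TRUE` when neighbouring component
#'   means are closer than twice their combined widths.
#' @export
event_size_distribution <- function(sizes, n_components = 2) {
  if (n_components < 1) stop("'n_components' must be at least 1", call. = FALSE)
  sizes <- sizes[is.finite(sizes)]
  if (length(sizes) < 10 * n_components) {
    stop("need at least 10 events per mixture component", call. = FALSE)
  }
  if (sd(sizes) == 0) {
    if (n_components > 1) {
      stop("event sizes are all identical; cannot fit ", n_components,
           " components", call. = FALSE)
    }
    res <- data.frame(mean = sizes[1], sem = 0, sd = 0, weight = 1,
                      n_eff = length(sizes))
    attr(res, "overlapping") <- FALSE
    return(res)
  }
  fit <- mclust::Mclust(sizes, G = n_components,
                        modelNames = if (n_components == 1) "X" else "V",
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  sig <- rep_len(sig, n_components)
  w <- as.numeric(fit$parameters$pro %||% 1)
  n_eff <- if (n_components == 1) length(sizes) else colSums(fit$z)
  sem <- sig / sqrt(pmax(n_eff, 1))
  ord <- order(mu)
  res <- data.frame(mean = mu[ord], sem = sem[ord], sd = sig[ord],
                    weight = w[ord], n_eff = n_eff[ord])
  overlap <- FALSE
  if (n_components > 1) {
    # separation criterion on component widths: an over-fitted split of a
    # unimodal population leaves neighbouring means within the cluster scale
    dmu <- diff(res$mean)
    comb <- sqrt(res$sd[-1]^2 + head(res$sd, -1)^2)
    overlap <- any(dmu <= 2 * comb)
  }
  attr(res, "overlapping") <- overlap
  res
}
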