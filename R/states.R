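# Conformational-state analysis: one-dimensional clustering of fitted
# maximal entropic extensions, k-nearest-neighbour assignment of segments,
# transition maps, occupancy and refolding statistics.

# Exact 1-D k-means by dynamic programming over the sorted values
# (the Ckmeans.1d.dp construction): clusters are contiguous runs of the
# sorted data, and the partition minimising total within-cluster sum of
# squares is found globally. Deterministic and order-invariant, and immune
# to the initialisation failures of heuristic k-means on clusters of very
# unequal size. Returns cluster labels in ascending-mean order.
.kmeans_1d_exact <- function(x, k) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  if (length(unique(xs)) < k) {
    stop("fewer than ", k, " distinct values: clusters would be empty",
         call. = FALSE)
  }
  s1 <- c(0, cumsum(xs)); s2 <- c(0, cumsum(xs^2))
  cost <- function(i, j) {  # within-SS of xs[i..j], vectorised over i
    nn <- j - i + 1
    sm <- s1[j + 1] - s1[i]
    pmax(s2[j + 1] - s2[i] - sm^2 / nn, 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- cost(1L, seq_len(n))
  for (m in 2:k) {
    for (j in m:n) {
      i <- m:j
      v <- D[m - 1, i - 1] + cost(i, j)
      best <- which.min(v)
      D[m, j] <- v[best]
      B[m, j] <- i[best]
    }
  }
  labels_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else B[m, j]
    labels_sorted[i:j] <- m
    j <- i - 1L
  }
  labels <- integer(n)
  labels[o] <- labels_sorted
  labels
}

#' Define conformational states from relaxation-phase extensions
#'
#' Clusters pooled relaxation-phase maximal entropic extensions (`x_e` from
#' per-segment fits) into `n_states` one-dimensional k-means classes, labels
#' states in ascending mean order, and retains the labelled values as the
#' reference set for k-nearest-neighbour classification of further segments.
#' The within-cluster sum of squares is minimised exactly by dynamic
#' programming over the sorted values, so the result is deterministic,
#' order-invariant and globally optimal.
#'
#' @param x_e Numeric vector of fitted maximal entropic extensions, nm; at
#'   least `10 * n_states` values.
#' @param n_states Number of states (default 6).
#' @return An object of class `"state_model"`: `n_states`, `means` (nm,
#'   strictly increasing), `sems` (sample SEM of member values), `counts`,
#'   and `reference` (data frame of `x_e`, `state`).
#' @export
define_states <- function(x_e, n_states = 6) {
  x_e <- x_e[is.finite(x_e)]
  if (length(x_e) < 10 * n_states) {
    stop("need at least ", 10 * n_states, " fitted values", call. = FALSE)
  }
  state <- .kmeans_1d_exact(x_e, n_states)
  means <- vapply(seq_len(n_states), function(s) mean(x_e[state == s]),
                  numeric(1))
  sems <- vapply(seq_len(n_states), function(s) {
    v <- x_e[state == s]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  }, numeric(1))
  counts <- tabulate(state, n_states)
  if (any(diff(means) <= 0)) {
    stop("state means are not strictly increasing; clustering degenerate",
         call. = FALSE)
  }
  structure(list(n_states = as.integer(n_states), means = means,
                 sems = sems, counts = counts,
                 reference = data.frame(x_e = x_e, state = state)),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("State model with %d states (n = %d reference values)\n",
              x$n_states, nrow(x$reference)))
  for (s in seq_len(x$n_states)) {
    cat(sprintf("  state %d: x_E = %.1f +/- %.2f nm (n = %d)\n",
                s, x$means[s], x$sems[s], x$counts[s]))
  }
  invisible(x)
}

#' Assign segments to states by k-nearest neighbours
#'
#' Classifies each query extension by majority vote among the `k` labelled
#' reference values nearest in `|x_E|` distance. Distance ties at the
#' neighbourhood cut and vote ties are both broken toward the lower state
#' (conservative about claiming unfolding).
#'
#' @param model A [define_states()] model.
#' @param x_e Query value(s), nm.
#' @param k Number of neighbours (default 3).
#' @return Integer state id(s) in `1..n_states`.
#' @export
classify_segment <- function(model, x_e, k = 3) {
  if (!inherits(model, "state_model")) {
    stop("'model' must be a trained state_model", call. = FALSE)
  }
  ref <- model$reference
  if (is.null(ref) || !nrow(ref)) stop("untrained model", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > nrow(ref)) stop("invalid 'k'", call. = FALSE)
  # sort references by value then state so candidate scans are deterministic
  o <- order(ref$x_e, ref$state)
  rx <- ref$x_e[o]; rs <- ref$state[o]
  n <- length(rx)
  vapply(x_e, function(q) {
    pos <- findInterval(q, rx)
    lo <- max(1L, pos - k + 1L); hi <- min(n, pos + k)
    cand <- lo:hi
    d <- abs(rx[cand] - q)
    sel <- cand[order(d, rs[cand])][seq_len(k)]
    votes <- tabulate(rs[sel], model$n_states)
    which.max(votes)  # first maximum = lowest state on a tie
  }, numeric(1)) |> as.integer()
}

#' Differences between successive state means
#'
#' Successive differences of the state mean extensions with standard errors
#' propagated in quadrature; the gaps are interpreted as the contour released
#' by linker, partial-domain or full-domain unfolding.
#'
#' @param model A [define_states()] model.
#' @return A data frame with `from_state`, `to_state`, `delta_nm`, `sem_nm`.
#' @export
state_differences <- function(model) {
  if (!inherits(model, "state_model")) {
    stop("'model' must be a trained state_model", call. = FALSE)
  }
  n <- model$n_states
  data.frame(
    from_state = seq_len(n - 1L),
    to_state = 2:n,
    delta_nm = diff(model$means),
    sem_nm = sqrt(model$sems[-n]^2 + model$sems[-1]^2)
  )
}

#' Interstate transition map and occupancy
#'
#' Counts transitions between consecutive segment ordinals within each cycle
#' and phase, and tallies per-state occupancy as the fraction of segments in
#' each state (optionally weighted by segment sample counts).
#'
#' @param segments Data frame of classified segments with columns
#'   `cycle_uid` (unique cycle identifier), `phase`, `ordinal`, `state` and,
#'   if `time_weighted`, `n_samples`. No `state` may be `NA`.
#' @param phase Phase(s) whose segments enter the map; default
#'   `"extension"`, where trajectories run in ascending force.
#' @param time_weighted Weight occupancy by samples rather than segments.
#' @return An object of class `"transition_map"`: `counts` (n_states x
#'   n_states matrix of from/to counts), `by_ordinal` (data frame with
#'   `ordinal_from`, `from_state`, `to_state`, `n`), `occupancy` (fractions
#'   summing to 1), `n_segments` and `n_cycles`.
#' @param n_states Number of states labelling the rows/columns.
#' @export
build_transition_map <- function(segments, n_states = max(segments$state),
                                 phase = "extension",
                                 time_weighted = FALSE) {
  need <- c("cycle_uid", "phase", "ordinal", "state")
  miss <- setdiff(need, names(segments))
  if (length(miss)) {
    stop("'segments' is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  seg <- segments[segments$phase %in% phase, , drop = FALSE]
  if (anyNA(seg$state)) stop("unclassified segments present", call. = FALSE)
  if (!nrow(seg)) stop("no segments in the requested phase", call. = FALSE)
  seg <- seg[order(seg$cycle_uid, seg$phase, seg$ordinal), , drop = FALSE]

  counts <- matrix(0L, n_states, n_states,
                   dimnames = list(from = seq_len(n_states),
                                   to = seq_len(n_states)))
  by_ord <- list()
  key <- paste(seg$cycle_uid, seg$phase)
  same <- key[-1] == key[-length(key)] &
    seg$ordinal[-1] == seg$ordinal[-nrow(seg)] + 1L
  from <- seg$state[-nrow(seg)][same]
  to <- seg$state[-1][same]
  ord_from <- seg$ordinal[-nrow(seg)][same]
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  if (length(from)) {
    by_ord <- aggregate(list(n = rep(1L, length(from))),
                        by = list(ordinal_from = ord_from,
                                  from_state = from, to_state = to), sum)
  } else {
    by_ord <- data.frame(ordinal_from = integer(), from_state = integer(),
                         to_state = integer(), n = integer())
  }

  w <- if (time_weighted) seg$n_samples else rep(1, nrow(seg))
  occ <- vapply(seq_len(n_states),
                function(s) sum(w[seg$state == s]) / sum(w), numeric(1))
  names(occ) <- seq_len(n_states)

  structure(list(counts = counts, by_ordinal = by_ord, occupancy = occ,
                 n_segments = nrow(seg),
                 n_cycles = length(unique(key))),
            class = "transition_map")
}

#' @export
print.transition_map <- function(x, ...) {
  cat(sprintf("Transition map: %d segments over %d cycle-phases, %d transitions\n",
              x$n_segments, x$n_cycles, sum(x$counts)))
  cat("Occupancy:", paste(sprintf("%d: %.2f", seq_along(x$occupancy),
                                  x$occupancy), collapse = ", "), "\n")
  invisible(x)
}

#' Extent of full inter-cycle refolding
#'
#' A cycle qualifies when the molecule reaches at least `state_threshold`
#' (by default state 3, i.e. at least one full domain opened) and a
#' subsequent cycle exists; it counts as a full refolding when the first
#' segment of that next cycle is in state `refold_max_state` or below (state
#' 1 or 2: no domain-scale unfolding remains). The percentage is computed
#' per dataset and summarized as mean and SEM across datasets; when no
#' dataset has a qualifying cycle the summary is undefined (`NA`), which is
#' a value, not an error.
#'
#' @param cycle_states Data frame with one row per cycle: `dataset`,
#'   `cycle` (temporal order within dataset), `first_state` (state of the
#'   first extension-phase segment) and `max_state` (highest state reached).
#' @param state_threshold Minimum peak state for a cycle to qualify.
#' @param refold_max_state Highest start state still counted as refolded.
#' @return A list of class `"refolding_summary"`: `percent` (mean, or `NA`
#'   when undefined), `sem`, `n_datasets`, `n_qualifying` and `per_dataset`.
#' @export
refolding_summary <- function(cycle_states, state_threshold = 3,
                              refold_max_state = 2) {
  need <- c("dataset", "cycle", "first_state", "max_state")
  miss <- setdiff(need, names(cycle_states))
  if (length(miss)) {
    stop("'cycle_states' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  per <- lapply(split(cycle_states, cycle_states$dataset), function(d) {
    d <- d[order(d$cycle), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    # a cycle qualifies only when its immediate successor is present
    qual <- which(d$max_state[-nrow(d)] >= state_threshold &
                    d$cycle[-1L] == d$cycle[-nrow(d)] + 1L)
    if (!length(qual)) return(NULL)
    refolded <- d$first_state[qual + 1L] <= refold_max_state
    data.frame(dataset = d$dataset[1], n_qualifying = length(qual),
               percent = 100 * mean(refolded), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(per) || !nrow(per)) {
    return(structure(list(percent = NA_real_, sem = NA_real_,
                          n_datasets = 0L, n_qualifying = 0L,
                          per_dataset = NULL),
                     class = "refolding_summary"))
  }
  structure(list(
    percent = mean(per$percent),
    sem = if (nrow(per) > 1) sd(per$percent) / sqrt(nrow(per)) else NA_real_,
    n_datasets = nrow(per),
    n_qualifying = sum(per$n_qualifying),
    per_dataset = per
  ), class = "refolding_summary")
}

#' @export
print.refolding_summary <- function(x, ...) {
  if (is.na(x$percent)) {
    cat("Full refolding: undefined (no qualifying cycles)\n")
  } else {
    cat(sprintf("Full refolding: %.1f%% +/- %.1f (SEM), N = %d datasets, %d qualifying cycles\n",
                x$percent, x$sem, x$n_datasets, x$n_qualifying))
  }
  invisible(x)
}

#' Entropic stiffness of each state as a function of force
#'
#' For every classified segment and force bin, fits a local line to
#' extension versus force and takes the inverse slope as the stiffness of
#' that segment at that force; stiffnesses are then averaged over segments
#' within each state and bin. Bins with no qualifying segments are simply
#' absent from the output. On noiseless model-generated data the result
#' equals the analytic `dF/dx`, which rises with force toward the enthalpic
#' stiffness and falls with the state's maximal entropic extension.
#'
#' @param samples Data frame with one row per sample of every classified
#'   segment: columns `state`, `segment_uid`, `force_pN`, `extension_nm`.
#' @param breaks Force bin edges, pN (ascending).
#' @param min_points Minimum samples a segment needs inside a bin.
#' @return A data frame with `state`, `force_mid` (bin centre, pN),
#'   `stiffness` (pN/nm), `sem` and `n` (segments contributing).
#' @export
entropic_stiffness_by_state <- function(samples, breaks = seq(0, 60, by = 5),
                                        min_points = 5L) {
  need <- c("state", "segment_uid", "force_pN", "extension_nm")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("'samples' is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bin <- findInterval(samples$force_pN, breaks,
                      rightmost.closed = TRUE)
  ok <- bin >= 1L & bin < length(breaks)
  sm <- samples[ok, , drop = FALSE]
  bin <- bin[ok]
  rows <- list()
  for (b in sort(unique(bin))) {
    sb <- sm[bin == b, , drop = FALSE]
    for (st in sort(unique(sb$state))) {
      ss <- sb[sb$state == st, , drop = FALSE]
      ks <- vapply(split(ss, ss$segment_uid), function(d) {
        if (nrow(d) < min_points || diff(range(d$force_pN)) <= 0) {
          return(NA_real_)
        }
        fc <- d$force_pN - mean(d$force_pN)
        slope <- sum(fc * (d$extension_nm - mean(d$extension_nm))) /
          sum(fc * fc)
        if (!is.finite(slope) || slope <= 0) NA_real_ else 1 / slope
      }, numeric(1))
      ks <- ks[is.finite(ks)]
      if (!length(ks)) next
      rows[[length(rows) + 1L]] <- data.frame(
        state = st,
        force_mid = (breaks[b] + breaks[b + 1L]) / 2,
        stiffness = mean(ks),
        sem = if (length(ks) > 1) sd(ks) / sqrt(length(ks)) else NA_real_,
        n = length(ks)
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(state = integer(), force_mid = numeric(),
                      stiffness = numeric(), sem = numeric(), n = integer()))
  }
  res <- do.call(rbind, rows)
  res[order(res$state, res$force_mid), , drop = FALSE]
}
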