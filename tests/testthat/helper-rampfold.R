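# Shared fixtures, built in code.

# A bare force-ramp cycle from an explicit force schedule and extension trace.
make_cycle <- function(force, extension, dt = 1e-3, cycle_index = 1L) {
  n <- length(force)
  peak <- which.max(force)
  structure(list(
    samples = data.frame(time_s = (seq_len(n) - 1L) * dt,
                         force_pN = force, extension_nm = extension,
                         phase = rep(c("extension", "relaxation"),
                                     c(peak, n - peak)),
                         stringsAsFactors = FALSE),
    meta = list(dataset_id = "fix", cycle_index = cycle_index,
                construct = "wild-type", calcium = "3 mM"),
    events = NULL, start_folded = NULL, end_folded = NULL
  ), class = "force_ramp_cycle")
}

# Triangular force ramp (resting -> peak -> resting) sampled at `rate` Hz.
triangle_force <- function(resting = 1, peak = 60, loading_rate = 20,
                           rate = 1000) {
  n_up <- floor((peak - resting) / loading_rate * rate) + 1L
  up <- resting + loading_rate * (seq_len(n_up) - 1L) / rate
  c(up, rev(up[-n_up]))
}

# Model-generated cycle with optional discrete steps: `steps` is a data frame
# with columns force (where the step occurs, pN, on the extension phase) and
# gain (added to x_E from that sample on). Ground-truth events carry the
# realized extension jump, as the simulator's logs do.
make_eq1_cycle <- function(params, steps = NULL, noise_sd = 0,
                           peak = 60, loading_rate = 20, rate = 1000) {
  force <- triangle_force(1, peak, loading_rate, rate)
  n <- length(force)
  x_e <- rep(params$x_e, n)
  events <- NULL
  if (!is.null(steps)) {
    for (i in seq_len(nrow(steps))) {
      idx <- which(force >= steps$force[i])[1]
      x_e[idx:n] <- x_e[idx:n] + steps$gain[i]
      events <- rbind(events, data.frame(
        phase = "extension", index = idx, time_s = (idx - 1L) * 1e-3,
        force_pN = force[idx],
        size_nm = steps$gain[i] * force[idx] / (force[idx] + params$f_half),
        gain_nm = steps$gain[i], unit = sprintf("u%d", i),
        stringsAsFactors = FALSE))
    }
  }
  extension <- x_e * force / (force + params$f_half) + force / params$k
  if (noise_sd > 0) extension <- extension + rnorm(n, 0, noise_sd)
  cyc <- make_cycle(force, extension)
  cyc$events <- events
  cyc
}

# Naive brute-force kNN oracle with the same deterministic tie rules as the
# classifier: order candidates by distance then state, majority vote, lowest
# state on a vote tie.
knn_oracle <- function(model, queries, k = 3) {
  ref <- model$reference
  vapply(queries, function(q) {
    o <- order(abs(ref$x_e - q), ref$state)
    sel <- ref$state[o[seq_len(k)]]
    votes <- tabulate(sel, model$n_states)
    which.max(votes)
  }, numeric(1))
}
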