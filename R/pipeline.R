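#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]: which
#' construct/Ca2+ presets to simulate (or which dataset directories to
#' read), how many datasets and cycles per condition, and the analysis
#' parameters. May also be loaded from a JSON document with the same fields.
#'
#' @param conditions Data frame with columns `construct` and `calcium`, one
#'   row per condition; defaults to all six preset combinations.
#' @param n_datasets Simulated datasets per condition (Table-style summaries
#'   average over datasets).
#' @param n_cycles Force-ramp cycles per dataset.
#' @param protocol A [ramp_protocol()].
#' @param min_step Event-detection threshold, nm.
#' @param force_threshold Enthalpic-stiffness force threshold, pN.
#' @param n_states Number of conformational states.
#' @param k_nn Neighbours for state assignment.
#' @param input_dirs Optional named list mapping `"construct / calcium"` to
#'   character vectors of dataset directories to read instead of simulating.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(conditions = NULL, n_datasets = 4L,
                            n_cycles = 25L, protocol = ramp_protocol(),
                            min_step = 1.5, force_threshold = 30,
                            n_states = 6L, k_nn = 3L, input_dirs = NULL) {
  if (is.null(conditions)) {
    conditions <- expand.grid(construct = .constructs,
                              calcium = .calcium_levels,
                              stringsAsFactors = FALSE)
  }
  if (!all(c("construct", "calcium") %in% names(conditions))) {
    stop("'conditions' needs columns construct and calcium", call. = FALSE)
  }
  for (i in seq_len(nrow(conditions))) {
    .check_labels(conditions$construct[i], conditions$calcium[i])
  }
  if (n_datasets < 1L || n_cycles < 1L) {
    stop("'n_datasets' and 'n_cycles' must be positive", call. = FALSE)
  }
  if (min_step <= 0 || force_threshold <= 0 || n_states < 2L || k_nn < 1L) {
    stop("invalid analysis parameters", call. = FALSE)
  }
  structure(list(conditions = conditions,
                 n_datasets = as.integer(n_datasets),
                 n_cycles = as.integer(n_cycles),
                 protocol = protocol, min_step = min_step,
                 force_threshold = force_threshold,
                 n_states = as.integer(n_states), k_nn = as.integer(k_nn),
                 input_dirs = input_dirs),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path Path to a JSON document whose fields mirror the arguments of
#'   [pipeline_config()].
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  proto <- if (!is.null(doc$protocol)) {
    do.call(ramp_protocol, as.list(doc$protocol))
  } else {
    ramp_protocol()
  }
  pipeline_config(
    conditions = doc$conditions,
    n_datasets = doc$n_datasets %||% 4L,
    n_cycles = doc$n_cycles %||% 25L,
    protocol = proto,
    min_step = doc$min_step %||% 1.5,
    force_threshold = doc$force_threshold %||% 30,
    n_states = doc$n_states %||% 6L,
    k_nn = doc$k_nn %||% 3L,
    input_dirs = doc$input_dirs
  )
}

#' Run the full force-ramp analysis pipeline
#'
#' Simulates (or ingests) datasets for each configured condition, detects
#' unfolding events, estimates the per-condition enthalpic stiffness, fits
#' the force-extension model to every inter-event segment, defines
#' conformational states from the pooled relaxation-phase fits, classifies
#' all segments, and summarizes interstate transitions, occupancy, refolding
#' and per-state stiffness.
#'
#' @param config A [pipeline_config()] (or a path to its JSON form).
#' @param seed Integer seed controlling all simulation randomness.
#' @param out_dir Optional directory: when given, every result table is
#'   written as tab-delimited text together with a JSON run manifest
#'   recording the seed and parameters, sufficient to reproduce every table.
#' @return (Invisibly) a list with `events`, `fits`, `stiffness` (per
#'   condition), `state_model`, `state_diffs`, `segments` (classified),
#'   `transition_maps`, `occupancy`, `refolding`, `stiffness_by_state`,
#'   `heatmaps` and `ground_truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must be a pipeline_config", call. = FALSE)
  }
  set.seed(as.integer(seed))

  conds <- config$conditions
  cond_key <- paste(conds$construct, conds$calcium, sep = " / ")

  datasets <- list()
  for (i in seq_len(nrow(conds))) {
    key <- cond_key[i]
    if (!is.null(config$input_dirs) && !is.null(config$input_dirs[[key]])) {
      datasets[[key]] <- lapply(config$input_dirs[[key]], read_dataset)
    } else {
      preset <- condition_presets(conds$construct[i], conds$calcium[i],
                                  protocol = config$protocol)
      datasets[[key]] <- lapply(seq_len(config$n_datasets), function(d) {
        simulate_dataset(preset, config$n_cycles,
                         dataset_id = sprintf("%s/ds%02d", key, d))
      })
    }
  }

  # --- per-condition enthalpic stiffness ------------------------------
  stiffness <- list()
  for (key in cond_key) {
    cycles <- unlist(lapply(datasets[[key]], function(d) d$cycles),
                     recursive = FALSE)
    stiffness[[key]] <- enthalpic_stiffness(
      cycles, force_threshold = config$force_threshold)
  }

  # --- event detection and segment fitting (one pass per cycle) -------
  all_events <- list(); all_gt <- list(); fit_rows <- list()
  for (key in cond_key) {
    k_fixed <- stiffness[[key]]$value
    for (ds in datasets[[key]]) {
      for (cyc in ds$cycles) {
        ev <- detect_events(cyc, min_step = config$min_step)
        if (nrow(ev)) {
          evx <- ev
          evx$dataset <- ds$meta$dataset_id
          evx$construct <- ds$meta$construct
          evx$calcium <- ds$meta$calcium
          all_events[[length(all_events) + 1L]] <- evx
        }
        if (!is.null(cyc$events) && nrow(cyc$events)) {
          gt <- cyc$events
          gt$cycle_index <- cyc$meta$cycle_index
          gt$dataset <- ds$meta$dataset_id
          gt$construct <- ds$meta$construct
          gt$calcium <- ds$meta$calcium
          all_gt[[length(all_gt) + 1L]] <- gt
        }
        segs <- segment_cycle(cyc, ev)
        fits <- .fit_cycle_segments(cyc, segs, k_fixed)
        if (!nrow(fits)) next
        fits$dataset <- ds$meta$dataset_id
        fits$construct <- ds$meta$construct
        fits$calcium <- ds$meta$calcium
        fits$cycle_uid <- paste(ds$meta$dataset_id, fits$cycle_index)
        # carry segment bounds for downstream per-sample summaries
        m <- match(paste(fits$phase, fits$ordinal),
                   paste(segs$phase, segs$ordinal))
        fits$start <- segs$start[m]
        fits$end <- segs$end[m]
        fit_rows[[length(fit_rows) + 1L]] <- fits
      }
    }
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame()
  ground_truth <- if (length(all_gt)) do.call(rbind, all_gt) else NULL
  if (!length(fit_rows)) stop("no segment could be fitted", call. = FALSE)
  fits <- do.call(rbind, fit_rows)
  rownames(fits) <- NULL

  # --- state definition and classification ----------------------------
  relax_xe <- fits$x_e[fits$phase == "relaxation"]
  model <- define_states(relax_xe, n_states = config$n_states)
  fits$state <- classify_segment(model, fits$x_e, k = config$k_nn)

  # --- transition maps, occupancy, refolding --------------------------
  transition_maps <- list(); occupancy <- list(); refolding <- list()
  for (key in cond_key) {
    seg_c <- fits[paste(fits$construct, fits$calcium, sep = " / ") == key, ]
    tm <- build_transition_map(seg_c, n_states = config$n_states)
    transition_maps[[key]] <- tm
    occupancy[[key]] <- tm$occupancy

    per_cycle <- lapply(split(seg_c, seg_c$cycle_uid), function(d) {
      first <- d$state[d$phase == "extension" & d$ordinal == 1L]
      data.frame(dataset = d$dataset[1], cycle = d$cycle_index[1],
                 first_state = if (length(first)) first[1] else NA_integer_,
                 max_state = max(d$state), stringsAsFactors = FALSE)
    })
    cyc_df <- do.call(rbind, per_cycle)
    cyc_df <- cyc_df[complete.cases(cyc_df), , drop = FALSE]
    refolding[[key]] <- refolding_summary(cyc_df)
  }

  # --- per-state entropic stiffness (pooled over conditions) -----------
  sample_rows <- list()
  for (key in cond_key) {
    for (ds in datasets[[key]]) {
      for (cyc in ds$cycles) {
        uid <- paste(ds$meta$dataset_id, cyc$meta$cycle_index)
        fsub <- fits[fits$cycle_uid == uid & fits$phase == "extension", ,
                     drop = FALSE]
        for (j in seq_len(nrow(fsub))) {
          idx <- fsub$start[j]:fsub$end[j]
          sample_rows[[length(sample_rows) + 1L]] <- data.frame(
            state = fsub$state[j],
            segment_uid = paste(uid, fsub$phase[j], fsub$ordinal[j]),
            force_pN = cyc$samples$force_pN[idx],
            extension_nm = cyc$samples$extension_nm[idx]
          )
        }
      }
    }
  }
  stiff_by_state <- if (length(sample_rows)) {
    entropic_stiffness_by_state(do.call(rbind, sample_rows))
  } else data.frame()

  heatmaps <- lapply(cond_key, function(key) {
    build_heatmap(unlist(lapply(datasets[[key]], function(d) d$cycles),
                         recursive = FALSE))
  })
  names(heatmaps) <- cond_key

  result <- list(
    events = events, fits = fits, stiffness = stiffness,
    state_model = model, state_diffs = state_differences(model),
    transition_maps = transition_maps, occupancy = occupancy,
    refolding = refolding, stiffness_by_state = stiff_by_state,
    heatmaps = heatmaps, ground_truth = ground_truth,
    config = config, seed = as.integer(seed)
  )

  if (!is.null(out_dir)) .write_report(result, out_dir)
  invisible(result)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (cn in names(df)[num]) out[[cn]] <- sprintf("%.10g", df[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(result$events, file.path(out_dir, "events.tsv"))
  .write_tsv(result$fits, file.path(out_dir, "segment_fits.tsv"))

  sm <- result$state_model
  .write_tsv(data.frame(state = seq_len(sm$n_states), mean_x_e = sm$means,
                        sem = sm$sems, n = sm$counts),
             file.path(out_dir, "state_model.tsv"))
  .write_tsv(result$state_diffs, file.path(out_dir, "state_differences.tsv"))

  trans <- do.call(rbind, lapply(names(result$transition_maps), function(key) {
    tm <- result$transition_maps[[key]]
    idx <- which(tm$counts > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(condition = key, from_state = idx[, 1], to_state = idx[, 2],
               n = tm$counts[idx], stringsAsFactors = FALSE)
  }))
  .write_tsv(trans %||% data.frame(), file.path(out_dir, "transitions.tsv"))

  occ <- do.call(rbind, lapply(names(result$occupancy), function(key) {
    data.frame(condition = key, state = seq_along(result$occupancy[[key]]),
               fraction = as.numeric(result$occupancy[[key]]),
               stringsAsFactors = FALSE)
  }))
  .write_tsv(occ, file.path(out_dir, "occupancy.tsv"))

  refold <- do.call(rbind, lapply(names(result$refolding), function(key) {
    r <- result$refolding[[key]]
    data.frame(condition = key, percent = r$percent, sem = r$sem,
               n_datasets = r$n_datasets, n_qualifying = r$n_qualifying,
               stringsAsFactors = FALSE)
  }))
  .write_tsv(refold, file.path(out_dir, "refolding.tsv"))

  .write_tsv(result$stiffness_by_state,
             file.path(out_dir, "stiffness_by_state.tsv"))

  stiff <- do.call(rbind, lapply(names(result$stiffness), function(key) {
    s <- result$stiffness[[key]]
    data.frame(condition = key, k = s$value, sem = s$sem, n = s$n,
               stringsAsFactors = FALSE)
  }))
  .write_tsv(stiff, file.path(out_dir, "enthalpic_stiffness.tsv"))

  for (key in names(result$heatmaps)) {
    hm <- result$heatmaps[[key]]
    fname <- paste0("heatmap_", gsub("[^A-Za-z0-9]+", "_", key), ".tsv")
    write.table(hm$counts, file.path(out_dir, fname), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }

  cfg <- result$config
  manifest <- list(
    package = "rampfold",
    version = as.character(utils::packageVersion("rampfold")),
    seed = result$seed,
    parameters = list(
      conditions = cfg$conditions, n_datasets = cfg$n_datasets,
      n_cycles = cfg$n_cycles, protocol = unclass(cfg$protocol),
      min_step = cfg$min_step, force_threshold = cfg$force_threshold,
      n_states = cfg$n_states, k_nn = cfg$k_nn
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
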