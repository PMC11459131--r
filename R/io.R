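.cycle_columns <- c("time_s", "force_pN", "extension_nm", "phase")

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a force-ramp dataset to a directory
#'
#' Text format of record: one tab-delimited table per cycle with columns
#' `time_s`, `force_pN`, `extension_nm`, `phase`, a combined
#' `ground_truth_events.tsv` for simulated data, and a JSON metadata sidecar
#' (`metadata.json`) naming the dataset, labels, protocol and cycle files.
#' Numbers are written with 17 significant digits so the round-trip through
#' [read_dataset()] is lossless.
#'
#' @param dataset A `"ramp_dataset"` (e.g. from [simulate_dataset()]).
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  if (!inherits(dataset, "ramp_dataset")) {
    stop("'dataset' must be a ramp_dataset", call. = FALSE)
  }
  if (length(dataset$cycles) < 1L) stop("empty dataset", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  files <- character(length(dataset$cycles))
  gt <- list()
  for (i in seq_along(dataset$cycles)) {
    cyc <- dataset$cycles[[i]]
    files[i] <- sprintf("cycle_%04d.tsv", i)
    s <- cyc$samples
    out <- data.frame(time_s = .fmt_num(s$time_s),
                      force_pN = .fmt_num(s$force_pN),
                      extension_nm = .fmt_num(s$extension_nm),
                      phase = s$phase, stringsAsFactors = FALSE)
    write.table(out, file.path(path, files[i]), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(cyc$events) && nrow(cyc$events)) {
      gt[[length(gt) + 1L]] <- cbind(cycle_index = i, cyc$events)
    }
  }
  gt_df <- if (length(gt)) do.call(rbind, gt) else
    data.frame(cycle_index = integer(), phase = character(),
               index = integer(), time_s = numeric(), force_pN = numeric(),
               size_nm = numeric(), gain_nm = numeric(), unit = character(),
               stringsAsFactors = FALSE)
  gt_out <- gt_df
  for (cn in c("time_s", "force_pN", "size_nm", "gain_nm")) {
    gt_out[[cn]] <- .fmt_num(gt_df[[cn]])
  }
  write.table(gt_out, file.path(path, "ground_truth_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  meta <- list(
    format = "rampfold-dataset-v1",
    dataset_id = dataset$meta$dataset_id,
    construct = dataset$meta$construct,
    calcium = dataset$meta$calcium,
    n_cycles = length(dataset$cycles),
    cycle_files = files,
    ground_truth_file = "ground_truth_events.tsv"
  )
  if (!is.null(dataset$config)) {
    cfg <- dataset$config
    meta$config <- list(
      params = cfg$params[c("x_e", "f_half", "k")],
      noise_sd = cfg$noise_sd,
      protocol = unclass(cfg$protocol),
      ladder = as.data.frame(cfg$ladder)
    )
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a force-ramp dataset written by [write_dataset()]
#'
#' @param path Directory containing `metadata.json` and cycle tables.
#' @return A `"ramp_dataset"`.
#' @export
read_dataset <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) {
    stop("no metadata.json in '", path, "'", call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  files <- meta$cycle_files
  if (is.null(files) || length(files) < 1L) {
    stop("dataset lists no cycles (empty dataset is invalid)", call. = FALSE)
  }

  gt_all <- NULL
  gt_file <- file.path(path, meta$ground_truth_file %||% "")
  if (nzchar(meta$ground_truth_file %||% "") && file.exists(gt_file)) {
    gt_all <- read.delim(gt_file, stringsAsFactors = FALSE)
  }

  cycles <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- file.path(path, files[i])
    if (!file.exists(f)) stop("missing cycle file '", files[i], "'",
                              call. = FALSE)
    tab <- read.delim(f, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.cycle_columns, names(tab))
    if (length(missing_cols)) {
      stop("cycle file '", files[i], "' is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    ev <- if (!is.null(gt_all)) {
      sub <- gt_all[gt_all$cycle_index == i, , drop = FALSE]
      rownames(sub) <- NULL
      sub[setdiff(names(sub), "cycle_index")]
    } else NULL
    cycles[[i]] <- structure(list(
      samples = tab[.cycle_columns],
      meta = list(dataset_id = meta$dataset_id, cycle_index = i,
                  construct = meta$construct, calcium = meta$calcium),
      events = ev,
      start_folded = NULL, end_folded = NULL
    ), class = "force_ramp_cycle")
  }

  structure(list(cycles = cycles, config = NULL,
                 meta = list(dataset_id = meta$dataset_id,
                             construct = meta$construct,
                             calcium = meta$calcium,
                             n_cycles = length(cycles))),
            class = "ramp_dataset")
}

#' Split a cycle into its extension and relaxation phases
#'
#' Locates the force maximum on a median-filtered copy of the force trace
#' (window 5 samples, robust to noise spikes) and splits there: samples up to
#' and including the peak are the extension phase, the remainder the
#' relaxation phase.
#'
#' @param cycle A `"force_ramp_cycle"`.
#' @param min_range Minimum peak-to-trough force range, pN, below which no
#'   ramp is deemed present.
#' @return A list with data frames `extension` and `relaxation`, each
#'   carrying an `index` column of positions in the original trace.
#' @export
split_phases <- function(cycle, min_range = 1) {
  s <- cycle$samples
  n <- nrow(s)
  if (n < 3L) stop("cycle too short to split", call. = FALSE)
  f_s <- if (n >= 5L) runmed(s$force_pN, 5) else s$force_pN
  if (diff(range(f_s)) < min_range) {
    stop("no identifiable force peak: force range below ", min_range, " pN",
         call. = FALSE)
  }
  # the median filter flattens the apex; refine on the raw force nearby
  ps <- which.max(f_s)
  w <- max(1L, ps - 3L):min(n, ps + 3L)
  peak <- w[which.max(s$force_pN[w])]
  if (peak <= 1L || peak >= n) {
    stop("no identifiable force peak inside the trace", call. = FALSE)
  }
  s$index <- seq_len(n)
  list(extension = s[1:peak, , drop = FALSE],
       relaxation = s[(peak + 1L):n, , drop = FALSE])
}

#' Occupancy heatmap over extension and force
#'
#' Bins every ramp sample of every cycle -- superimposing extension and
#' relaxation phases -- on a two-dimensional (extension, force) grid. Highly
#' occupied bins correspond to frequently visited conformational states.
#'
#' @param cycles A `"ramp_dataset"`, a single cycle, or a list of cycles.
#' @param bin_width_force Force bin width, pN; positive.
#' @param bin_width_ext Extension bin width, nm; positive.
#' @return An object of class `"ramp_heatmap"`: `counts` (matrix, extension
#'   bins by force bins), `ext_edges`, `force_edges` and `n` (total samples
#'   binned; equals `sum(counts)`).
#' @export
build_heatmap <- function(cycles, bin_width_force = 0.5, bin_width_ext = 1) {
  if (bin_width_force <= 0 || bin_width_ext <= 0) {
    stop("bin widths must be positive", call. = FALSE)
  }
  cycles <- .as_cycle_list(cycles)
  if (!length(cycles)) stop("need at least one cycle", call. = FALSE)
  ext <- unlist(lapply(cycles, function(c) c$samples$extension_nm))
  frc <- unlist(lapply(cycles, function(c) c$samples$force_pN))

  ext_edges <- seq(floor(min(ext) / bin_width_ext) * bin_width_ext,
                   ceiling(max(ext) / bin_width_ext) * bin_width_ext +
                     bin_width_ext, by = bin_width_ext)
  force_edges <- seq(floor(min(frc) / bin_width_force) * bin_width_force,
                     ceiling(max(frc) / bin_width_force) * bin_width_force +
                       bin_width_force, by = bin_width_force)
  ei <- findInterval(ext, ext_edges, rightmost.closed = TRUE)
  fi <- findInterval(frc, force_edges, rightmost.closed = TRUE)
  counts <- matrix(0L, nrow = length(ext_edges) - 1L,
                   ncol = length(force_edges) - 1L)
  tab <- table(factor(ei, levels = seq_len(nrow(counts))),
               factor(fi, levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, ext_edges = ext_edges,
                 force_edges = force_edges, n = length(ext)),
            class = "ramp_heatmap")
}

.as_cycle_list <- function(cycles) {
  if (inherits(cycles, "ramp_dataset")) return(cycles$cycles)
  if (inherits(cycles, "force_ramp_cycle")) return(list(cycles))
  if (is.list(cycles) &&
      all(vapply(cycles, inherits, logical(1), "force_ramp_cycle"))) {
    return(cycles)
  }
  stop("expected a ramp_dataset, a force_ramp_cycle, or a list of cycles",
       call. = FALSE)
}

#' @export
print.ramp_heatmap <- function(x, ...) {
  cat(sprintf("Occupancy heatmap: %d x %d bins, %d samples\n",
              nrow(x$counts), ncol(x$counts), x$n))
  invisible(x)
}

#' @export
plot.ramp_heatmap <- function(x, log_counts = TRUE, ...) {
  z <- t(x$counts)
  if (log_counts) z <- log1p(z)
  fm <- (x$force_edges[-1] + head(x$force_edges, -1)) / 2
  em <- (x$ext_edges[-1] + head(x$ext_edges, -1)) / 2
  image(fm, em, z, xlab = "Force (pN)", ylab = "Extension (nm)", ...)
  invisible(x)
}

#' @export
plot.force_ramp_cycle <- function(x, ...) {
  up <- x$samples$phase == "extension"
  plot(x$samples$force_pN[up], x$samples$extension_nm[up], type = "l",
       xlab = "Force (pN)", ylab = "Extension (nm)", ...)
  lines(x$samples$force_pN[!up], x$samples$extension_nm[!up], col = 2)
  invisible(x)
}
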