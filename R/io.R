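#' Read and write recordings in HDF5
#'
#' Recordings are stored in an HDF5 container with a `data` dataset
#' (channels x samples) and attributes `fs_hz`, `channel_ids` and `t0_s`.
#' Chunked HDF5 storage is used because full-scale recordings (60 channels,
#' 5 min at 25 kHz) run to gigabytes. By default values are stored as
#' float64 so a write-read round trip is bit-exact; `dtype = "float32"`
#' halves the file size for large raw recordings at reduced precision.
#'
#' @param rec an [mea_recording()].
#' @param path file path (overwritten if it exists).
#' @param dtype `"float64"` (default, lossless) or `"float32"`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `mea_recording`.
#' @export
write_recording <- function(rec, path, dtype = c("float64", "float32")) {
  stopifnot(inherits(rec, "mea_recording"))
  dtype <- match.arg(dtype)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  storage <- if (dtype == "float32") "H5T_IEEE_F32LE" else "H5T_IEEE_F64LE"
  d <- dim(rec$data)
  chunk <- c(d[1], min(d[2], 65536L))
  rhdf5::h5createDataset(path, "data", dims = d, chunk = chunk,
                         H5type = storage, level = 4)
  rhdf5::h5write(rec$data, path, "data")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "data")
  rhdf5::h5writeAttribute(rec$fs_hz, did, "fs_hz")
  rhdf5::h5writeAttribute(rec$channel_ids, did, "channel_ids")
  rhdf5::h5writeAttribute(rec$t0_s, did, "t0_s")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  at <- rhdf5::h5readAttributes(path, "data")
  for (field in c("fs_hz", "channel_ids")) {
    if (is.null(at[[field]]))
      stop("recording container lacks required attribute `", field, "`")
  }
  data <- rhdf5::h5read(path, "data")
  rhdf5::H5close()
  if (!all(is.finite(data))) stop("recording contains non-finite data")
  mea_recording(matrix(as.numeric(data), nrow = nrow(data)),
                as.numeric(at$fs_hz), as.character(at$channel_ids),
                t0_s = if (is.null(at$t0_s)) 0 else as.numeric(at$t0_s))
}

#' Spike, burst, graph and metric tables as CSV
#'
#' Deterministic CSV writers/readers (UTF-8, `.` decimal, full double
#' precision so round trips agree to better than 9 significant digits).
#' Rows are ordered by channel then time. Graph files list each unordered
#' pair once; a duplicate unordered pair is an error on read and write.
#'
#' @param trains list of `mea_spike_train` (or a data.frame with
#'   `channel_id`, `spike_time_s`).
#' @param path file path.
#' @return writers return `path` invisibly; readers return a data.frame.
#' @export
write_spike_table <- function(trains, path) {
  df <- if (is.data.frame(trains)) trains
        else do.call(rbind, lapply(trains, function(tr)
          if (length(tr$times_s) == 0) NULL else
          data.frame(channel_id = tr$channel_id, spike_time_s = tr$times_s,
                     stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(channel_id = character(0), spike_time_s = numeric(0))
  df <- df[order(df$channel_id, df$spike_time_s), , drop = FALSE]
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("channel_id", "spike_time_s") %in% names(df)))
  df$channel_id <- as.character(df$channel_id)
  df[order(df$channel_id, df$spike_time_s), , drop = FALSE]
}

#' @rdname write_spike_table
#' @param burst_sets list of `mea_burst_set`.
#' @export
write_burst_table <- function(burst_sets, path) {
  df <- do.call(rbind, lapply(burst_sets, function(b)
    if (nrow(b$intervals) == 0) NULL else
    data.frame(channel_id = b$channel_id,
               start_s = b$intervals[, 1], end_s = b$intervals[, 2],
               n_spikes = b$spike_counts, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(channel_id = character(0), start_s = numeric(0),
                     end_s = numeric(0), n_spikes = integer(0))
  df <- df[order(df$channel_id, df$start_s), , drop = FALSE]
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spike_table
#' @param graph an `mea_graph`.
#' @export
write_graph <- function(graph, path) {
  e <- graph$edges
  df <- data.frame(channel_a = pmin(e$a, e$b), channel_b = pmax(e$a, e$b),
                   weight = e$weight, stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("channel_a", "channel_b")]))
    stop("duplicate unordered pair in graph")
  df <- df[order(df$channel_a, df$channel_b), , drop = FALSE]
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_graph <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("channel_a", "channel_b", "weight") %in% names(df)))
  key <- paste(pmin(df$channel_a, df$channel_b),
               pmax(df$channel_a, df$channel_b))
  if (anyDuplicated(key)) stop("duplicate unordered pair in graph file")
  df
}

#' @rdname write_spike_table
#' @param metrics a metric table: data.frame with `recording_id`,
#'   `channel_id` (or `"ALL"` for network-level rows), `metric_name`, `value`.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(all(c("recording_id", "channel_id", "metric_name", "value")
                %in% names(metrics)))
  check_metric_names(metrics$metric_name)
  df <- metrics[order(metrics$recording_id, metrics$channel_id,
                      metrics$metric_name), , drop = FALSE]
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("recording_id", "channel_id", "metric_name", "value")
                %in% names(df)))
  check_metric_names(df$metric_name)
  df
}

# registered metric vocabulary
metric_vocabulary <- function() {
  bands <- mea_bands()$name
  c("spike_rate", "burst_rate", "isi_cv", "pct_connected", "weight",
    "period_s", paste0("relpow_", bands), "lfp_peak_amp",
    paste0("mi_", rep(c("delta", "theta"), each = 2),
           "_", c("low_gamma", "upper_gamma")))
}

check_metric_names <- function(x) {
  bad <- setdiff(unique(x), metric_vocabulary())
  if (length(bad))
    stop("unregistered metric name(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

# full-precision numeric formatting for deterministic CSVs
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Simulation configs and ground truth as JSON
#'
#' @param config an `mea_sim_config`; `truth` an `mea_ground_truth`.
#' @param path file path.
#' @return readers return the reconstructed object.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$band_amplitudes <- as.list(x$band_amplitudes) # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$band_amplitudes <- unlist(x$band_amplitudes)
  if (is.null(x$network_event_period_s)) x$network_event_period_s <- NA_real_
  do.call(simulation_config, x)
}

#' @rdname write_sim_config
#' @param truth an `mea_ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$config <- unclass(x$config)
  x$burst_intervals <- lapply(x$burst_intervals, function(m)
    as.data.frame(m))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
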