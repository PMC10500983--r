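#' Multichannel EMG container
#'
#' In-memory container pairing an EMG matrix with its sampling rate,
#' montage, and a provenance block (seeds, configuration echoes) so that
#' every artifact is traceable.
#'
#' @param data Numeric matrix `channels x samples`, uV.
#' @param fs Sampling rate, Hz (> 0).
#' @param grid Optional [grid_spec]; when given, the channel count must
#'   equal the number of present electrodes.
#' @param provenance Named list of provenance metadata.
#' @return An object of class `emg_container`.
#' @export
emg_container <- function(data, fs, grid = NULL, provenance = list()) {
  stopifnot(is.matrix(data), is.numeric(fs), fs > 0)
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "grid_spec"))
    if (nrow(data) != grid$n)
      stop(sprintf("EMG has %d channels but montage has %d electrodes",
                   nrow(data), grid$n))
  }
  structure(list(data = data, fs = fs, grid = grid,
                 provenance = provenance),
            class = "emg_container")
}

#' @export
print.emg_container <- function(x, ...) {
  cat(sprintf("EMG container: %d channels x %d samples at %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$fs,
              if (is.null(x$grid)) "" else sprintf(" (%d-electrode montage)",
                                                   x$grid$n)))
  invisible(x)
}

#' Save an EMG container
#'
#' Serializes the container (data, montage, provenance) to a single
#' file via RDS.
#'
#' @param container An [emg_container] (a [synthetic_emg] is converted).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_emg <- function(container, path) {
  if (inherits(container, "synthetic_emg"))
    container <- emg_container(container$data, container$fs, container$grid,
                               provenance = list(snr_db = container$snr_db))
  stopifnot(inherits(container, "emg_container"))
  saveRDS(container, path)
  invisible(path)
}

#' Load multichannel EMG
#'
#' Reads either a serialized [emg_container] (`format = "container"`) or
#' a delimited text file (`format = "delimited"`: one column per
#' channel, one row per sample, with a header row; `fs` required).
#' Channel/montage consistency is enforced when a grid is supplied.
#'
#' @param path Input file path.
#' @param format `"container"` or `"delimited"`.
#' @param fs Sampling rate, Hz (delimited format).
#' @param grid Optional [grid_spec] to validate (and attach to) the
#'   recording.
#' @param sep Field separator for the delimited format (default `","`).
#' @return An [emg_container].
#' @export
load_emg <- function(path, format = c("container", "delimited"),
                     fs = NULL, grid = NULL, sep = ",") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "container") {
    obj <- readRDS(path)
    if (!inherits(obj, "emg_container"))
      stop("not an EMG container file: ", path)
    if (!is.null(grid)) obj <- emg_container(obj$data, obj$fs, grid,
                                             obj$provenance)
    return(obj)
  }
  tab <- read.csv(path, sep = sep, header = TRUE)
  if (is.null(fs)) stop("'fs' is required for delimited input")
  emg_container(t(as.matrix(tab)), fs = fs, grid = grid,
                provenance = list(source = path))
}

#' Write a montage to a JSON file
#'
#' @param grid A [grid_spec].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "grid_spec"))
  obj <- list(rows = grid$rows, cols = grid$cols, ied = grid$ied,
              missing = if (nrow(grid$missing)) grid$missing else NULL,
              origin = grid$origin)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a montage from a JSON file
#'
#' @param path Path to a file written by [write_grid_json].
#' @return A [grid_spec].
#' @export
read_grid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_spec(obj$rows, obj$cols, obj$ied,
            missing = if (!is.null(obj$missing))
              matrix(unlist(obj$missing), ncol = 2, byrow = !is.matrix(obj$missing))
            else NULL,
            origin = obj$origin)
}

#' Write spike trains to CSV
#'
#' One row per discharge: `unit_id`, `time_s` (plus `pnr_db` and
#' `cov_isi` for decomposition results).
#'
#' @param x A `decomposition_result`, [simulate_discharges] result, or
#'   list of numeric time vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(x, path) {
  if (inherits(x, "decomposition_result")) {
    rows <- lapply(seq_along(x$trains), function(k)
      if (length(x$trains[[k]]$times))
        data.frame(unit_id = k, time_s = x$trains[[k]]$times,
                   pnr_db = x$trains[[k]]$pnr,
                   cov_isi = x$trains[[k]]$cov_isi))
  } else {
    times <- if (inherits(x, "spike_train_set")) x$times else x
    rows <- lapply(seq_along(times), function(k)
      if (length(times[[k]]))
        data.frame(unit_id = k, time_s = times[[k]]))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(unit_id = integer(0),
                                      time_s = numeric(0))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' @param path Path to a file with columns `unit_id`, `time_s`.
#' @return A list of discharge-time vectors indexed by unit.
#' @export
read_spike_csv <- function(path) {
  tab <- read.csv(path)
  stopifnot(all(c("unit_id", "time_s") %in% names(tab)))
  ids <- sort(unique(tab$unit_id))
  setNames(lapply(ids, function(u) sort(tab$time_s[tab$unit_id == u])),
           as.character(ids))
}
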