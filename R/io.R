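#' Read a newline-delimited spike-time file
#'
#' One spike time in seconds per line. Epoch bounds and labels come from a
#' metadata table (see [read_spike_metadata()]).
#'
#' @param path file path.
#' @param epoch,state,identity passed to [spike_train()]; `epoch` defaults
#'   to the span of the file's spike times.
#' @return a [spike_train()].
#' @export
read_spike_times <- function(path, epoch = NULL, state = "SWA",
                             identity = NA_character_) {
  times <- scan(path, what = numeric(), quiet = TRUE)
  if (is.null(epoch)) epoch <- range(times)
  spike_train(times, epoch = epoch, state = state, identity = identity)
}

#' Read a spike metadata table
#'
#' Tab-separated table with columns `neuron_id`, `state`, `epoch_start`,
#' `epoch_end`, `identity`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_spike_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a delimited signal file with a sampling-rate header
#'
#' First line `# fs_hz=<rate> channel=<label>`, then one sample per line.
#'
#' @param path file path.
#' @return a [sampled_signal()].
#' @export
read_signal <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("fs_hz=([0-9.]+)", hdr))[[1]]
  if (length(m) < 2L) stop("missing 'fs_hz=' header line")
  fs <- as.numeric(m[2])
  ch <- regmatches(hdr, regexec("channel=([^ ]+)", hdr))[[1]]
  channel <- if (length(ch) >= 2L) ch[2] else "ECoG"
  samples <- scan(path, what = numeric(), skip = 1L, quiet = TRUE)
  sampled_signal(samples, fs, channel = channel)
}

#' Write a signal to a delimited file with a sampling-rate header
#'
#' @param s a [sampled_signal()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signal <- function(s, path) {
  writeLines(c(sprintf("# fs_hz=%g channel=%s", s$fs, s$channel),
               format(s$samples, trim = TRUE)), path)
  invisible(path)
}

#' Read contour vertex and plane metadata tables
#'
#' Vertices: tab-separated `plane_id`, `order`, `x_um`, `y_um`. Metadata
#' (optional): `plane_id`, `bregma_mm`, `lateral_dir`, `dorsal_dir`.
#'
#' @param vertex_path vertex table path.
#' @param meta_path optional plane metadata table path.
#' @return list of [plane_contour()] objects, one per plane.
#' @export
read_contours <- function(vertex_path, meta_path = NULL) {
  v <- utils::read.delim(vertex_path, stringsAsFactors = FALSE)
  meta <- if (!is.null(meta_path)) utils::read.delim(meta_path) else NULL
  lapply(split(v, v$plane_id), function(pl) {
    pl <- pl[order(pl$order), ]
    id <- pl$plane_id[1]
    if (!is.null(meta) && id %in% meta$plane_id) {
      mrow <- meta[meta$plane_id == id, ]
      plane_contour(cbind(pl$x_um, pl$y_um), plane_id = id,
                    bregma_mm = mrow$bregma_mm,
                    lateral_dir = mrow$lateral_dir,
                    dorsal_dir = mrow$dorsal_dir)
    } else {
      plane_contour(cbind(pl$x_um, pl$y_um), plane_id = id)
    }
  })
}

#' Read a counted-neuron table
#'
#' Tab-separated `id`, `plane_id`, `x_um`, `y_um` plus 0/1 marker-flag
#' columns (PV, Scgn, ...).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_neurons <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
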