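#' Write / read flat-binary recordings
#'
#' Recordings are stored SpikeGLX-style: a flat little-endian int16 binary
#' of interleaved channel frames (one frame = all channels at one sample)
#' plus a plain-text `key=value` metadata sidecar (`<path>.meta`) carrying
#' the sampling rate, channel count, µV-per-bit scale, frame count, row
#' pitch, and one `ch=` line per channel with its id, x, y and
#' reference-flag.
#'
#' @param traces a [probe_traces()] object (µV).
#' @param geometry the matching [probe_geometry()].
#' @param path output path of the binary file.
#' @param scale_uv_per_bit quantisation step; the default spans the data
#'   range over the int16 range.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns `list(traces, geometry)`.
#' @export
write_recording <- function(traces, geometry, path,
                            scale_uv_per_bit = NULL) {
  stopifnot(ncol(traces$data) == nrow(geometry))
  sc <- traces$scale_uv %||% 1
  mx <- max(abs(traces$data)) * sc
  if (is.null(scale_uv_per_bit)) scale_uv_per_bit <- max(mx, 1e-9) / 32000
  q <- round(t(traces$data) * (sc / scale_uv_per_bit))  # channel-fastest
  q <- pmax(pmin(q, 32767), -32768)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2, endian = "little")
  meta <- c(
    sprintf("nSavedChans=%d", nrow(geometry)),
    sprintf("sampleRateHz=%.10g", traces$fs_hz),
    sprintf("nFrames=%d", nrow(traces$data)),
    sprintf("scaleUvPerBit=%.12g", scale_uv_per_bit),
    sprintf("rowPitchUm=%.10g", attr(geometry, "row_pitch_um")),
    "dtype=int16",
    sprintf("ch=%d,%g,%g,%d", geometry$channel_id, geometry$x_um,
            geometry$y_um, as.integer(geometry$is_reference))
  )
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path,
                                    call. = FALSE)
  lines <- readLines(meta_path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  val <- function(k) kv[[match(k, keys)]][2]
  nch <- as.integer(val("nSavedChans"))
  fs <- as.numeric(val("sampleRateHz"))
  nfr <- as.integer(val("nFrames"))
  scale <- as.numeric(val("scaleUvPerBit"))
  pitch <- as.numeric(val("rowPitchUm"))
  chs <- do.call(rbind, lapply(lines[keys == "ch"], function(l) {
    as.numeric(strsplit(sub("^ch=", "", l), ",")[[1]])
  }))
  if (nrow(chs) != nch) stop("metadata lists ", nrow(chs),
                             " channels but nSavedChans=", nch, call. = FALSE)
  actual <- file.size(path) / (2 * nch)
  if (actual != nfr) {
    stop(sprintf("binary holds %.1f frames but metadata says %d frames",
                 actual, nfr), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nfr * nch, size = 2, endian = "little")
  data <- t(matrix(raw, nch, nfr)) * scale
  geom <- probe_geometry(chs[, 1], chs[, 2], chs[, 3], chs[, 4] > 0,
                         row_pitch_um = pitch)
  list(traces = probe_traces(data, fs), geometry = geom)
}

#' Write / read spike-sorting output
#'
#' Sorting results use a Kilosort-style directory of plain-text tables:
#' `spike_times.tsv` (sample index), `spike_clusters.tsv` (cluster id per
#' spike) and `cluster_info.tsv` (`cluster_id`, `group` with values
#' `good`/`mua`). `read_sorting()` joins them into a sorted-unit tibble;
#' `good` maps to quality `single`, `mua` to `multi`, and clusters missing
#' from the label table default to `multi` with a warning. A single tabular
#' file with columns `time_s`, `cluster_id` (and optional `group`) is also
#' accepted.
#'
#' @param path sorting directory or single TSV file.
#' @param fs_hz sampling rate used to convert sample indices to seconds
#'   (directory layout only).
#' @param duration_s recording duration, for mean rates.
#' @return a sorted-unit tibble (`unit_id`, `quality`, `spike_times`,
#'   `mean_rate_hz`).
#' @export
read_sorting <- function(path, fs_hz = 30000, duration_s = NULL) {
  if (dir.exists(path)) {
    st <- scan(file.path(path, "spike_times.tsv"), what = numeric(),
               quiet = TRUE)
    cl <- scan(file.path(path, "spike_clusters.tsv"), what = integer(),
               quiet = TRUE)
    stopifnot(length(st) == length(cl))
    info_path <- file.path(path, "cluster_info.tsv")
    info <- if (file.exists(info_path)) {
      utils::read.delim(info_path, stringsAsFactors = FALSE)
    } else data.frame(cluster_id = integer(), group = character())
    times_s <- st / fs_hz
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("time_s", "cluster_id") %in% names(tab)))
    times_s <- tab$time_s
    cl <- tab$cluster_id
    info <- if ("group" %in% names(tab)) {
      unique(data.frame(cluster_id = tab$cluster_id, group = tab$group))
    } else data.frame(cluster_id = integer(), group = character())
  }
  ids <- sort(unique(cl))
  grp <- info$group[match(ids, info$cluster_id)]
  if (anyNA(grp) && length(ids)) {
    warning(sum(is.na(grp)), " unlabeled cluster(s) defaulted to multi")
    grp[is.na(grp)] <- "mua"
  }
  if (is.null(duration_s)) duration_s <- if (length(times_s)) max(times_s) else 1
  units <- tibble::tibble(
    unit_id = seq_along(ids),
    cluster_id = ids,
    quality = ifelse(grp == "good", "single", "multi"),
    spike_times = lapply(ids, function(i) sort(times_s[cl == i])),
    mean_rate_hz = vapply(ids, function(i) sum(cl == i) / duration_s,
                          numeric(1))
  )
  attr(units, "duration_s") <- duration_s
  class(units) <- c("sorted_units", class(units))
  units
}

#' @rdname read_sorting
#' @param units a sorted-unit tibble.
#' @param dir output directory (created if needed).
#' @export
write_sorting <- function(units, dir, fs_hz = 30000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- unlist(units$spike_times)
  cl <- rep(units$unit_id, lengths(units$spike_times))
  ord <- order(st)
  writeLines(format(round(st[ord] * fs_hz), scientific = FALSE),
             file.path(dir, "spike_times.tsv"))
  writeLines(as.character(cl[ord]), file.path(dir, "spike_clusters.tsv"))
  utils::write.table(
    data.frame(cluster_id = units$unit_id,
               group = ifelse(units$quality == "single", "good", "mua")),
    file.path(dir, "cluster_info.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read / write stimulus event tables
#'
#' Tab-separated with columns `onset_s`, `condition`, `eye`.
#'
#' @param path file path.
#' @export
read_events <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("onset_s" %in% names(tab))
  if (is.null(tab$condition)) tab$condition <- "stim"
  if (is.null(tab$eye)) tab$eye <- "dominant"
  tibble::as_tibble(tab[c("onset_s", "condition", "eye")])
}

#' @rdname read_events
#' @param events events tibble.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a profile tibble as tidy TSV
#'
#' @param profile any profile tibble.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
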