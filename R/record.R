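# Waveform data model and record I/O.
#
# Time convention: seconds as float from record start; sample indices are
# 1-based in R code; window intervals are half-open [start, start + 32).

#' Construct a timestamped NIBP sample
#'
#' @param t seconds from record start.
#' @param sys,dias,map systolic / diastolic / mean pressure (mmHg).
#' @param derived `TRUE` when sampled from the ABP waveform rather than a
#'   cuff reading.
#' @return a `nibp_sample` list.
#' @export
nibp_sample <- function(t, sys, dias, map = (sys + 2 * dias) / 3,
                        derived = FALSE) {
  stopifnot(is.finite(t), is.finite(sys), is.finite(dias), is.finite(map),
            sys > 0, dias > 0, map > 0)
  if (!(sys >= map && map >= dias))
    stop("invalid NIBP sample: require sys >= map >= dias (got ",
         sys, " / ", map, " / ", dias, ")")
  structure(list(t = t, sys = sys, dias = dias, map = map,
                 derived = isTRUE(derived)),
            class = "nibp_sample")
}

#' Construct a multichannel waveform record
#'
#' @param record_id opaque identifier.
#' @param fs sampling rate in Hz.
#' @param channels named list of numeric vectors; names among
#'   `ecg`, `ppg`, `abp`. `abp` may be absent (inference mode).
#' @param start_time record start offset in seconds (t = 0 at record start).
#' @param nibp_events list of [nibp_sample()] with non-decreasing times.
#' @return a `waveform_record`.
#' @export
waveform_record <- function(record_id, fs, channels, start_time = 0,
                            nibp_events = list()) {
  stopifnot(is.character(record_id), length(record_id) == 1, fs > 0)
  known <- c("ecg", "ppg", "abp")
  if (!all(names(channels) %in% known))
    stop("unknown channel names: ",
         paste(setdiff(names(channels), known), collapse = ", "))
  if (!all(c("ecg", "ppg") %in% names(channels)))
    stop("record must contain at least ecg and ppg channels")
  lens <- lengths(channels)
  if (length(unique(lens)) != 1)
    stop("channel length mismatch: ",
         paste(sprintf("%s=%d", names(lens), lens), collapse = ", "))
  if (length(nibp_events)) {
    tt <- vapply(nibp_events, `[[`, numeric(1), "t")
    if (is.unsorted(tt)) stop("nibp_events timestamps must be non-decreasing")
  }
  structure(list(record_id = record_id, fs = fs, channels = channels,
                 start_time = start_time, nibp_events = nibp_events),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record '%s': %s, %.1f s at %g Hz, %d NIBP events>\n",
              x$record_id, paste(names(x$channels), collapse = "/"),
              length(x$channels[[1]]) / x$fs, x$fs, length(x$nibp_events)))
  invisible(x)
}

#' Default channel-name mapping for monitor exports
#'
#' Maps common bedside-monitor signal names onto the canonical
#' `ecg` / `ppg` / `abp` channels. Matching is case-insensitive; unmapped
#' channels are ignored with a warning.
#' @return named character vector (monitor name -> canonical name).
#' @export
default_channel_map <- function() {
  c("ii" = "ecg", "ecg" = "ecg", "mlii" = "ecg", "v" = "ecg",
    "pleth" = "ppg", "ppg" = "ppg",
    "abp" = "abp", "art" = "abp", "arterial" = "abp")
}

map_channels <- function(raw, channel_map) {
  out <- list()
  for (nm in names(raw)) {
    canon <- unname(channel_map[tolower(nm)])
    if (is.na(canon) || is.null(canon)) {
      warning("ignoring unmapped channel '", nm, "'", call. = FALSE)
      next
    }
    if (!is.null(out[[canon]]))
      stop("duplicate mapping: channel '", nm, "' maps to already-present '",
           canon, "'")
    out[[canon]] <- raw[[nm]]
  }
  if (!all(c("ecg", "ppg") %in% names(out)))
    stop("channel-mapping error: need ecg and ppg; available signals were: ",
         paste(names(raw), collapse = ", "))
  out
}

#' Read a waveform record
#'
#' Two on-disk layouts are supported: the package's tabular interchange format
#' (a CSV whose first line is `# abpwave record <id> fs=<hz>`, one column per
#' channel), and single-segment WFDB records in format 16 (a `.hea` header
#' plus 16-bit little-endian interleaved `.dat` samples, gain/baseline applied
#' per signal; signal names are taken from the header description field).
#'
#' @param path file path; for WFDB, the header path or record stem.
#' @param format `"tabular"` or `"wfdb"`.
#' @param channel_map named vector mapping raw signal names to
#'   `ecg`/`ppg`/`abp` (see [default_channel_map()]).
#' @param fs fallback sampling rate if the tabular header lacks one.
#' @return a [waveform_record()]; missing `abp` is permitted.
#' @export
load_record <- function(path, format = c("tabular", "wfdb"),
                        channel_map = default_channel_map(), fs = NULL) {
  format <- match.arg(format)
  if (format == "tabular") load_record_tabular(path, channel_map, fs)
  else load_record_wfdb(path, channel_map)
}

load_record_tabular <- function(path, channel_map, fs) {
  first <- readLines(path, n = 1L)
  record_id <- tools::file_path_sans_ext(basename(path))
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("record ([^ ]+) fs=([0-9.]+)", first))[[1]]
    if (length(m) == 3) {
      record_id <- m[2]
      fs <- as.numeric(m[3])
    }
  }
  if (is.null(fs)) stop("sampling rate not found in header; pass fs=")
  df <- utils::read.csv(path, skip = skip)
  raw <- as.list(df)
  waveform_record(record_id, fs, map_channels(raw, channel_map))
}

#' Write a record in the tabular interchange format
#'
#' Samples are written with 17 significant digits so that a write-then-read
#' round trip reproduces them bit-exactly.
#' @param record a [waveform_record()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_tabular <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# abpwave record %s fs=%.10g", record$record_id,
                     record$fs), con)
  df <- as.data.frame(lapply(record$channels, function(x)
    sprintf("%.17g", x)))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- minimal WFDB (format 16, single segment) ------------------------------

load_record_wfdb <- function(path, channel_map = default_channel_map()) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  head <- strsplit(trimws(lines[1]), "[ /]+")[[1]]
  nsig <- as.integer(head[2]); fs <- as.numeric(head[3])
  nsamp <- as.integer(head[4])
  sig <- lapply(lines[1 + seq_len(nsig)], function(l)
    strsplit(trimws(l), " +")[[1]])
  fmt <- vapply(sig, `[[`, character(1), 2)
  if (!all(fmt == "16"))
    stop("unsupported WFDB sample format(s): ",
         paste(unique(fmt), collapse = ", "), " (only 16 supported)")
  datfile <- file.path(dirname(hea), sig[[1]][1])
  raw <- readBin(datfile, "integer", n = nsig * nsamp, size = 2,
                 signed = TRUE, endian = "little")
  adc <- matrix(raw, nrow = nsig)
  channels <- list()
  for (i in seq_len(nsig)) {
    gspec <- sig[[i]][3]
    gm <- regmatches(gspec, regexec("^([-0-9.eE+]+)(\\(([-0-9.eE+]+)\\))?", gspec))[[1]]
    gain <- as.numeric(gm[2]); if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (gm[4] != "") as.numeric(gm[4]) else 0
    desc <- paste(sig[[i]][-seq_len(min(8, length(sig[[i]]) - 1))],
                  collapse = " ")
    if (desc == "") desc <- paste0("sig", i)
    channels[[desc]] <- (adc[i, ] - baseline) / gain
  }
  lens <- lengths(channels)
  if (length(unique(lens)) != 1) stop("channel length mismatch in WFDB record")
  waveform_record(tools::file_path_sans_ext(basename(hea)), fs,
                  map_channels(channels, channel_map))
}

#' Write a record as a minimal WFDB (format 16) pair
#'
#' Each channel is quantized with a per-channel gain chosen to use the 16-bit
#' range; gains and baselines are stored in the header, so reading back
#' recovers the samples to quantization precision.
#' @param record a [waveform_record()].
#' @param stem output path stem (writes `<stem>.hea` and `<stem>.dat`).
#' @param names optional raw signal names (description field), one per
#'   channel; defaults to WFDB-style names (II / PLETH / ABP).
#' @return `stem`, invisibly.
#' @export
write_record_wfdb <- function(record, stem,
                              names = c(ecg = "II", ppg = "PLETH",
                                        abp = "ABP")) {
  chans <- record$channels
  nsig <- length(chans); nsamp <- length(chans[[1]])
  gains <- numeric(nsig); baselines <- integer(nsig)
  adc <- matrix(0L, nrow = nsig, ncol = nsamp)
  for (i in seq_along(chans)) {
    x <- chans[[i]]
    lo <- min(x); hi <- max(x)
    span <- max(hi - lo, 1e-12)
    gain <- 60000 / span
    baseline <- round(-(lo + hi) / 2 * gain)
    a <- round(x * gain + baseline)
    stopifnot(all(a >= -32768 & a <= 32767))
    gains[i] <- gain; baselines[i] <- baseline
    adc[i, ] <- as.integer(a)
  }
  hea <- paste0(stem, ".hea")
  dat <- paste0(stem, ".dat")
  lines <- sprintf("%s %d %.10g %d", basename(stem), nsig, record$fs, nsamp)
  for (i in seq_along(chans)) {
    lines <- c(lines, sprintf("%s 16 %.10g(%d)/mV 16 0 %d 0 0 %s",
                              basename(dat), gains[i], baselines[i],
                              adc[i, 1], names[[names(chans)[i]]]))
  }
  writeLines(lines, hea)
  writeBin(as.integer(adc), dat, size = 2, endian = "little")
  invisible(stem)
}

#' Read an NIBP event list from CSV
#'
#' Expected columns: `t_s`, `sys`, `dias`, `map` (map optional).
#' @param path CSV path.
#' @return list of [nibp_sample()].
#' @export
read_nibp_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_s", "sys", "dias") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    if ("map" %in% names(df) && is.finite(df$map[i]))
      nibp_sample(df$t_s[i], df$sys[i], df$dias[i], df$map[i])
    else nibp_sample(df$t_s[i], df$sys[i], df$dias[i])
  })
}

#' Write an NIBP event list to CSV
#' @param nibp list of [nibp_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nibp_csv <- function(nibp, path) {
  df <- data.frame(t_s = vapply(nibp, `[[`, numeric(1), "t"),
                   sys = vapply(nibp, `[[`, numeric(1), "sys"),
                   dias = vapply(nibp, `[[`, numeric(1), "dias"),
                   map = vapply(nibp, `[[`, numeric(1), "map"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Slice a record into 32-s windows at a 16-s step
#'
#' Windows are views over the record (index ranges), so long records are not
#' duplicated; the final partial window is discarded.
#'
#' @param record a [waveform_record()] at 100 Hz.
#' @param window_s window duration (s).
#' @param step_s step between window starts (s).
#' @return data.frame with one row per window: `record_id`, `start_t`,
#'   `i0`, `i1` (1-based inclusive sample range).
#' @export
slice_windows <- function(record, window_s = 32, step_s = 16) {
  fs <- record$fs
  if (fs != 100) stop("slice_windows expects a preprocessed record at 100 Hz")
  wlen <- window_s * fs
  if (wlen != round(wlen)) stop("window_s x fs must be an integer")
  n <- length(record$channels[[1]])
  T <- n / fs
  if (T < window_s)
    return(data.frame(record_id = character(), start_t = numeric(),
                      i0 = integer(), i1 = integer()))
  k <- floor((T - window_s) / step_s) + 1
  start_t <- (seq_len(k) - 1) * step_s
  i0 <- as.integer(round(start_t * fs)) + 1L
  data.frame(record_id = record$record_id, start_t = start_t,
             i0 = i0, i1 = i0 + as.integer(wlen) - 1L)
}

#' Extract one window's samples for a channel
#' @param record a [waveform_record()].
#' @param win one row of [slice_windows()] output.
#' @param channel channel name.
#' @return numeric vector of samples.
#' @export
window_samples <- function(record, win, channel) {
  record$channels[[channel]][win$i0:win$i1]
}
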