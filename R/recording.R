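#' Multichannel recording
#'
#' Container for one modality's multichannel time series. Rows are channels,
#' columns are samples. The modality tag constrains downstream operations:
#' only `NIRS_INTENSITY` recordings may enter [mbll()], and the fusion
#' pipeline expects `EEG` and `HBO`/`HBR` streams.
#'
#' @param data Numeric matrix, channels x samples. All values must be finite.
#' @param fs Sampling rate in Hz, > 0.
#' @param channel_names Character vector of unique names, one per row.
#'   Auto-generated (`"ch01"`, `"ch02"`, ...) when `NULL`.
#' @param modality One of `"EEG"`, `"NIRS_INTENSITY"`, `"HBO"`, `"HBR"`.
#' @param units Free-form unit string (e.g. `"uV"`, `"uM"`).
#' @return An object of class `"recording"`.
#' @examples
#' rec <- recording(matrix(rnorm(20), 2, 10), fs = 10, modality = "EEG")
#' n_channels(rec)
#' @export
recording <- function(data, fs,
                      channel_names = NULL,
                      modality = c("EEG", "NIRS_INTENSITY", "HBO", "HBR"),
                      units = "") {
  modality <- match.arg(modality)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("recording data must be finite (found NA/NaN/Inf)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(data)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") must equal the channel count (", nrow(data), ")")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         modality = modality, units = units),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f s)%s\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @rdname recording
#' @param rec A `recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Trial onset/label annotation
#'
#' Task-trial timing for a recording: each trial is a rest period followed by
#' a task period. Onsets are 0-based sample indices of task starts on the
#' sample grid of rate `fs`; windows are half-open `[onset, onset + len)`.
#'
#' @param onsets Non-negative, strictly increasing integer sample indices
#'   (0-based) of task starts.
#' @param labels Class identifiers, one per onset.
#' @param rest_duration_s,task_duration_s Durations in seconds, > 0.
#' @param fs Sampling rate (Hz) of the grid the onsets index.
#' @return An object of class `"trial_annotation"`.
#' @seealso [annotation_resample()] to move onsets onto another sample grid.
#' @export
trial_annotation <- function(onsets, labels, rest_duration_s, task_duration_s, fs) {
  onsets <- as.integer(round(onsets))
  if (any(onsets < 0)) stop("onsets must be non-negative sample indices")
  if (is.unsorted(onsets, strictly = TRUE))
    stop("onsets must be strictly increasing")
  if (length(labels) != length(onsets))
    stop("labels and onsets must have the same length")
  if (rest_duration_s <= 0 || task_duration_s <= 0)
    stop("rest and task durations must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  structure(
    list(onsets = onsets, labels = labels,
         rest_duration_s = rest_duration_s,
         task_duration_s = task_duration_s, fs = fs),
    class = "trial_annotation"
  )
}

#' @export
print.trial_annotation <- function(x, ...) {
  cat(sprintf("<trial_annotation> %d trial(s), %d class(es), rest %g s / task %g s @ %g Hz\n",
              length(x$onsets), length(unique(x$labels)),
              x$rest_duration_s, x$task_duration_s, x$fs))
  invisible(x)
}

#' Move an annotation onto a different sample grid
#'
#' Onset times in seconds are preserved; sample indices are re-rounded on the
#' target grid. Needed because concurrently recorded EEG and fNIRS run at
#' different native rates.
#'
#' @param ann A [trial_annotation()].
#' @param fs Target sampling rate in Hz.
#' @return A `trial_annotation` on the `fs` grid.
#' @export
annotation_resample <- function(ann, fs) {
  stopifnot(inherits(ann, "trial_annotation"))
  trial_annotation(round(ann$onsets / ann$fs * fs), ann$labels,
                   ann$rest_duration_s, ann$task_duration_s, fs)
}

#' Trial-segmented epochs
#'
#' @param data 3-D numeric array, trials x channels x samples.
#' @param labels Class id per trial.
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional channel names (length = dim 2).
#' @return An object of class `"epochs"`.
#' @export
epochs <- function(data, labels, fs, channel_names = NULL) {
  if (length(dim(data)) != 3L)
    stop("epochs data must be a 3-D array (trials x channels x samples)")
  if (dim(data)[1] != length(labels))
    stop("trial count (", dim(data)[1], ") must equal label count (",
         length(labels), ")")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length must equal the channel dimension")
  structure(
    list(data = data, labels = labels, fs = fs,
         channel_names = as.character(channel_names)),
    class = "epochs"
  )
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs> %d trial(s) x %d channel(s) x %d samples @ %g Hz; classes: %s\n",
              d[1], d[2], d[3], x$fs,
              paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' @rdname epochs
#' @param x An `epochs` object.
#' @export
n_trials <- function(x) dim(x$data)[1]

# ---- delimited matrix I/O -------------------------------------------------

# Tokenize one delimited line; sep is "," or "\t".
.split_line <- function(line, sep) trimws(strsplit(line, sep, fixed = TRUE)[[1]])

#' Read a recording from a delimited text matrix
#'
#' The file is a numeric matrix with rows = channels and columns = samples,
#' comma- or tab-separated (auto-detected), with an optional header row of
#' channel names. Lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz.
#' @param modality Modality tag, see [recording()].
#' @param units Unit string.
#' @return A [recording()].
#' @export
read_recording <- function(path, fs, modality = "EEG", units = "") {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data lines in ", path)
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  toks <- lapply(lines, .split_line, sep = sep)
  widths <- lengths(toks)
  first_num <- suppressWarnings(as.numeric(toks[[1]]))
  has_header <- all(is.na(first_num)) && !any(toupper(toks[[1]]) %in% c("NAN", "NA", "INF", "-INF"))
  channel_names <- NULL
  if (has_header) {
    channel_names <- toks[[1]]
    toks <- toks[-1]
    widths <- widths[-1]
    if (length(toks) == 0L) stop("header but no data rows in ", path)
  }
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, ": row widths ", paste(unique(widths), collapse = ", "))
  vals <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite cell at row %d, column %d: '%s'",
                   i, bad[[1]], toks[[i]][bad[[1]]]))
    v
  })
  data <- do.call(rbind, vals)
  if (has_header) {
    # header names one column per channel row
    if (length(channel_names) != nrow(data))
      stop("header has ", length(channel_names), " names but file has ",
           nrow(data), " channel rows")
  }
  recording(data, fs, channel_names = channel_names,
            modality = modality, units = units)
}

#' Write a recording to a delimited text matrix
#'
#' Values are written at full double precision (`%.17g`) so that
#' `read_recording(write_recording(rec))` round-trips bit-for-bit.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_names, collapse = sep), con)
  for (i in seq_len(nrow(rec$data)))
    writeLines(paste(sprintf("%.17g", rec$data[i, ]), collapse = sep), con)
  invisible(path)
}

#' Read / write a trial annotation as TSV
#'
#' Two columns `onset` (0-based sample index) and `label`, with the durations
#' and rate stored in `#`-comment metadata lines.
#'
#' @param ann A [trial_annotation()].
#' @param path File path.
#' @return `read_annotation` returns a `trial_annotation`; `write_annotation`
#'   returns `path` invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "trial_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rest_duration_s=%.17g", ann$rest_duration_s),
    sprintf("# task_duration_s=%.17g", ann$task_duration_s),
    sprintf("# fs=%.17g", ann$fs),
    "onset\tlabel",
    paste(ann$onsets, ann$labels, sep = "\t")
  ), con)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (!length(m)) stop("missing annotation metadata: ", key)
    as.numeric(sub(".*=", "", m[[1]]))
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  stopifnot(length(body) >= 2L)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  trial_annotation(
    onsets = as.numeric(vapply(rows, `[[`, "", 1L)),
    labels = vapply(rows, `[[`, "", 2L),
    rest_duration_s = get_meta("rest_duration_s"),
    task_duration_s = get_meta("task_duration_s"),
    fs = get_meta("fs")
  )
}

#' Adapter interface for MATLAB v5 dataset containers
#'
#' The public hybrid-BCI datasets ship their recordings as MATLAB v5 `.mat`
#' containers. This package works entirely from delimited text matrices (see
#' [read_recording()]); an adapter converting a `.mat` container is
#' deliberately left as an interface only. An implementation must return the
#' same structure [gen_hybrid()] produces: a list with `eeg`, `hbo`, `hbr`
#' [recording()]s and per-modality [trial_annotation()]s. Export the arrays
#' to delimited text (one file per modality plus an annotation TSV) and use
#' the text readers instead.
#'
#' @param path Path to a `.mat` container.
#' @return Never returns; signals an error describing the expected contract.
#' @export
read_mat_adapter <- function(path) {
  stop("MATLAB container adapters are not implemented; export '", path,
       "' to delimited text (one matrix per modality, rows = channels) and ",
       "use read_recording() / read_annotation()")
}

#' Segment a recording into trial epochs
#'
#' Each onset yields one task epoch of `round(task_duration_s * fs)` samples,
#' taken from the half-open window `[onset, onset + len)` (0-based indexing).
#' With `include_rest = TRUE`, a rest epoch of the same length ending at each
#' onset (`[onset - len, onset)`) is additionally extracted and labelled
#' `rest_label`, exploiting the symmetric rest/task trial layout.
#'
#' @param rec A [recording()].
#' @param ann A [trial_annotation()] on the same sample grid (`ann$fs` must
#'   equal `rec$fs`).
#' @param include_rest Also extract a rest epoch per trial?
#' @param rest_label Label assigned to rest epochs.
#' @return An [epochs()] object; trials in onset order (rest epochs, when
#'   requested, appended after the task epochs).
#' @export
epoch <- function(rec, ann, include_rest = FALSE, rest_label = "rest") {
  stopifnot(inherits(rec, "recording"), inherits(ann, "trial_annotation"))
  if (abs(ann$fs - rec$fs) > 1e-9)
    stop("annotation grid (", ann$fs, " Hz) does not match recording (",
         rec$fs, " Hz); use annotation_resample() first")
  len <- round(ann$task_duration_s * rec$fs)
  N <- n_samples(rec)
  bad <- which(ann$onsets + len > N)
  if (length(bad))
    stop(sprintf("trial %d window [%d, %d) exceeds recording length %d",
                 bad[[1]], ann$onsets[bad[[1]]], ann$onsets[bad[[1]]] + len, N))
  starts <- ann$onsets
  labels <- ann$labels
  if (include_rest) {
    rbad <- which(ann$onsets - len < 0)
    if (length(rbad))
      stop(sprintf("rest window for trial %d starts before sample 0", rbad[[1]]))
    starts <- c(starts, ann$onsets - len)
    labels <- c(as.character(labels), rep(rest_label, length(ann$onsets)))
  }
  out <- array(0, dim = c(length(starts), n_channels(rec), len))
  for (i in seq_along(starts))
    out[i, , ] <- rec$data[, (starts[i] + 1L):(starts[i] + len), drop = FALSE]
  epochs(out, labels, rec$fs, channel_names = rec$channel_names)
}
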