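# Directory-based interchange container. Layout (documented in README):
#   meta.json   — type, fs_hz, dims, channel names, t0_s, package version
#   data.bin    — float64 little-endian, channel-major (continuous) or
#                 trial-channel-major (epochs)
#   events.tsv  — event table (continuous) / event_table (epochs), optional
#   labels.tsv  — per-trial label + bad flag (epochs only)

#' Write an EEG container
#'
#' Serializes an `eeg_continuous` or `eeg_epochs` object into a directory
#' holding a JSON header, a raw float64 payload and TSV tables; the round
#' trip through [read_container()] is lossless (bit-for-bit on doubles).
#'
#' @param x An `eeg_continuous` or `eeg_epochs`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = "cilisten-container", version = 1L,
               package_version = as.character(utils::packageVersion("cilisten")))
  if (inherits(x, "eeg_continuous")) {
    meta$type <- "continuous"
    meta$fs_hz <- x$fs_hz
    meta$channel_names <- x$channel_names
    meta$dims <- dim(x$data)
    payload <- as.numeric(x$data)
    if (!is.null(x$events)) {
      utils::write.table(x$events, file.path(path, "events.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  } else if (inherits(x, "eeg_epochs")) {
    meta$type <- "epochs"
    meta$fs_hz <- x$fs_hz
    meta$t0_s <- x$t0_s
    meta$channel_names <- x$channel_names
    meta$dims <- dim(x$data)
    payload <- as.numeric(x$data)
    utils::write.table(
      data.frame(trial = seq_along(x$labels), label = x$labels,
                 bad = x$bad_mask),
      file.path(path, "labels.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    if (!is.null(x$event_table)) {
      utils::write.table(x$event_table, file.path(path, "events.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"))
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(payload, con, size = 8, endian = "little")
  invisible(path)
}

#' Read an EEG container
#'
#' @param path Directory written by [write_container()].
#' @param require_events Error when the container lacks an event table
#'   (useful before epoching).
#' @return The stored `eeg_continuous` or `eeg_epochs`.
#' @export
read_container <- function(path, require_events = FALSE) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a container: missing meta.json in ", path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "cilisten-container")) {
    stop("malformed container: unexpected format field in meta.json")
  }
  bin_path <- file.path(path, "data.bin")
  if (!file.exists(bin_path)) stop("malformed container: missing data.bin")
  n_vals <- prod(meta$dims)
  con <- file(bin_path, "rb")
  payload <- readBin(con, "double", n = n_vals, size = 8, endian = "little")
  close(con)
  if (length(payload) != n_vals) {
    stop("malformed container: data.bin truncated (", length(payload), " of ",
         n_vals, " values)")
  }
  ev_path <- file.path(path, "events.tsv")
  events <- if (file.exists(ev_path)) {
    utils::read.delim(ev_path, stringsAsFactors = FALSE)
  } else NULL
  if (require_events && is.null(events)) {
    stop("container lacks an events table (events.tsv)")
  }
  if (meta$type == "continuous") {
    eeg_continuous(matrix(payload, meta$dims[1], meta$dims[2]), meta$fs_hz,
                   meta$channel_names, events)
  } else if (meta$type == "epochs") {
    lab_path <- file.path(path, "labels.tsv")
    if (!file.exists(lab_path)) {
      stop("malformed container: epochs require labels.tsv")
    }
    lab <- utils::read.delim(lab_path, stringsAsFactors = FALSE)
    eeg_epochs(array(payload, meta$dims), meta$fs_hz, meta$t0_s,
               as.character(lab$label), meta$channel_names,
               bad_mask = as.logical(lab$bad), event_table = events)
  } else {
    stop("malformed container: unknown type '", meta$type, "'")
  }
}

# --- BrainVision (.vhdr/.vmrk/.eeg) read-only support -----------------------

parse_ini_sections <- function(lines) {
  out <- list()
  sec <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character(0)
    } else if (!is.null(sec) && grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[sec]][key] <- val
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Minimal reader for the BrainVision triad: the `.vhdr` text header, the
#' `.vmrk` marker file, and the binary `.eeg` payload (multiplexed
#' IEEE_FLOAT_32 or INT_16 with per-channel resolution). Stimulus markers
#' become the event table; marker positions (1-based in the file format) are
#' converted to the package's 0-based `onset_sample` convention.
#'
#' @param vhdr_path Path to the `.vhdr` header.
#' @param marker_types Marker types imported as events (default
#'   `"Stimulus"`).
#' @return An `eeg_continuous` with events columns `onset_sample` and
#'   `description`.
#' @export
read_brainvision <- function(vhdr_path, marker_types = "Stimulus") {
  if (!file.exists(vhdr_path)) stop("header not found: ", vhdr_path)
  hdr <- parse_ini_sections(readLines(vhdr_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("malformed .vhdr: missing [Common Infos] section")
  need <- c("DataFile", "MarkerFile", "NumberOfChannels", "SamplingInterval")
  if (!all(need %in% names(ci))) {
    stop("malformed .vhdr: [Common Infos] lacks ",
         paste(setdiff(need, names(ci)), collapse = ", "))
  }
  orientation <- toupper(ci["DataOrientation"] %||% "MULTIPLEXED")
  if (orientation != "MULTIPLEXED") {
    stop("only MULTIPLEXED BrainVision data is supported")
  }
  n_ch <- as.integer(ci["NumberOfChannels"])
  fs <- 1e6 / as.numeric(ci["SamplingInterval"])
  fmt <- toupper(hdr[["Binary Infos"]]["BinaryFormat"] %||% "IEEE_FLOAT_32")

  ch <- hdr[["Channel Infos"]]
  if (is.null(ch) || length(ch) < n_ch) {
    stop("malformed .vhdr: [Channel Infos] incomplete")
  }
  ch_fields <- strsplit(unname(ch[seq_len(n_ch)]), ",")
  ch_names <- vapply(ch_fields, `[`, character(1), 1)
  resolution <- vapply(ch_fields, function(f) {
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))

  dirn <- dirname(vhdr_path)
  eeg_path <- file.path(dirn, ci["DataFile"])
  if (!file.exists(eeg_path)) stop("data file not found: ", eeg_path)
  sz <- file.size(eeg_path)
  con <- file(eeg_path, "rb")
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "double", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
            endian = "little")
  } else {
    close(con)
    stop("unsupported BinaryFormat: ", fmt)
  }
  close(con)
  n_smp <- length(raw_vals) %/% n_ch
  data <- matrix(raw_vals[seq_len(n_smp * n_ch)], n_ch, n_smp) * resolution

  vmrk_path <- file.path(dirn, ci["MarkerFile"])
  events <- NULL
  if (file.exists(vmrk_path)) {
    mk <- parse_ini_sections(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
    if (!is.null(mk)) {
      fields <- strsplit(unname(mk), ",")
      type <- vapply(fields, `[`, character(1), 1)
      keep <- type %in% marker_types
      if (any(keep)) {
        events <- data.frame(
          onset_sample = vapply(fields[keep], function(f)
            as.integer(f[3]), integer(1)) - 1L,
          description = vapply(fields[keep], `[`, character(1), 2),
          stringsAsFactors = FALSE)
      }
    }
  }
  eeg_continuous(data, fs, ch_names, events)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
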