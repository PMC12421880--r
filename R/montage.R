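#' Standard 64-channel EEG montage
#'
#' Builds the 64-channel 10-10 montage used throughout the package, with
#' idealized unit-sphere electrode positions, per-channel hemisphere
#' assignment, and the pre-registered electrode sets: nine fronto-central
#' channels for auditory evoked activity and two mirror-symmetric sets of
#' twelve occipito-parietal channels per hemisphere for alpha lateralization.
#'
#' Positions are generated from the 10-10 angular system rather than digitized:
#' midline channels sit on the nasion-inion arc in 18 degree steps from the
#' vertex, the outer ring runs from Fp1/Fp2 to O1/O2 in 18 degree azimuthal
#' steps, the sub-temporal 9/10 channels lie 18 degrees below the ring, and
#' interior channels are spherical interpolations between their midline and
#' outer-ring row ends. This preserves exact left/right mirror symmetry, which
#' the lateralization analyses rely on.
#'
#' @return An object of class `eeg_montage`: a data frame with columns
#'   `name`, `x`, `y`, `z` (unit-sphere coordinates; x right, y anterior,
#'   z superior) and `hemisphere` (`"left"`, `"right"`, `"midline"`), with an
#'   attribute `sets`, a named list of channel-name vectors
#'   (`frontocentral_9`, `op_left_12`, `op_right_12`, `temporal_left`,
#'   `temporal_right`).
#' @examples
#' m <- montage_64()
#' montage_set(m, "frontocentral_9")
#' @export
montage_64 <- function() {
  deg <- pi / 180
  vec <- function(theta, az) {
    # theta: inclination from vertex (deg); az: azimuth from front midline,
    # negative = left (deg)
    c(
      x = sin(theta * deg) * sin(az * deg),
      y = sin(theta * deg) * cos(az * deg),
      z = cos(theta * deg)
    )
  }
  slerp <- function(a, b, f) {
    om <- acos(max(-1, min(1, sum(a * b))))
    v <- (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
    v / sqrt(sum(v^2))
  }

  pos <- list()
  # midline (18 deg steps along nasion-inion arc; +y anterior)
  midline <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0, CPz = -18, Pz = -36,
               POz = -54, Oz = -72)
  for (nm in names(midline)) {
    th <- abs(midline[[nm]])
    pos[[nm]] <- vec(th, if (midline[[nm]] >= 0) 0 else 180)
  }
  # outer ring: azimuth from front midline, inclination bulges to 90 deg at
  # the temporal line
  ring_az <- c(Fp1 = -18, Fp2 = 18, AF7 = -36, AF8 = 36, F7 = -54, F8 = 54,
               FT7 = -72, FT8 = 72, T7 = -90, T8 = 90, TP7 = -108, TP8 = 108,
               P7 = -126, P8 = 126, PO7 = -144, PO8 = 144, O1 = -162,
               O2 = 162)
  for (nm in names(ring_az)) {
    az <- ring_az[[nm]]
    pos[[nm]] <- vec(72 + 18 * sin(abs(az) * deg), az)
  }
  # sub-temporal row (9/10 channels), 18 deg below the ring
  sub_az <- c(FT9 = -72, FT10 = 72, TP9 = -108, TP10 = 108)
  for (nm in names(sub_az)) {
    az <- sub_az[[nm]]
    pos[[nm]] <- vec(90 + 18 * sin(abs(az) * deg), az)
  }
  # interior rows: spherical interpolation midline -> outer ring
  rows <- list(
    AF = list(mid = "AFz", left = "AF7", right = "AF8",
              frac = c(`3` = 0.5)),
    F  = list(mid = "Fz", left = "F7", right = "F8",
              frac = c(`1` = 0.25, `3` = 0.5, `5` = 0.75)),
    FC = list(mid = "FCz", left = "FT7", right = "FT8",
              frac = c(`1` = 0.25, `3` = 0.5, `5` = 0.75)),
    C  = list(mid = "Cz", left = "T7", right = "T8",
              frac = c(`1` = 0.25, `3` = 0.5, `5` = 0.75)),
    CP = list(mid = "CPz", left = "TP7", right = "TP8",
              frac = c(`1` = 0.25, `3` = 0.5, `5` = 0.75)),
    P  = list(mid = "Pz", left = "P7", right = "P8",
              frac = c(`1` = 0.25, `3` = 0.5, `5` = 0.75)),
    PO = list(mid = "POz", left = "PO7", right = "PO8",
              frac = c(`3` = 0.5))
  )
  for (row in names(rows)) {
    r <- rows[[row]]
    for (k in names(r$frac)) {
      f <- r$frac[[k]]
      pos[[paste0(row, k)]] <- slerp(pos[[r$mid]], pos[[r$left]], f)
      pos[[paste0(row, as.integer(k) + 1)]] <-
        slerp(pos[[r$mid]], pos[[r$right]], f)
    }
  }

  name <- names(pos)
  stopifnot(length(name) == 64)
  xyz <- do.call(rbind, pos)
  hemi <- vapply(name, channel_hemisphere, character(1))
  m <- data.frame(name = name, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  hemisphere = hemi, row.names = NULL,
                  stringsAsFactors = FALSE)
  attr(m, "sets") <- list(
    frontocentral_9 = c("Fz", "F1", "F2", "FCz", "FC1", "FC2",
                        "Cz", "C1", "C2"),
    op_left_12 = c("TP9", "TP7", "CP5", "CP3", "CP1", "P7", "P5", "P3",
                   "P1", "PO7", "PO3", "O1"),
    op_right_12 = c("TP10", "TP8", "CP6", "CP4", "CP2", "P8", "P6", "P4",
                    "P2", "PO8", "PO4", "O2"),
    temporal_left = c("FT9", "FT7", "T7", "TP7", "TP9"),
    temporal_right = c("FT10", "FT8", "T8", "TP8", "TP10")
  )
  class(m) <- c("eeg_montage", "data.frame")
  m
}

#' Hemisphere of a 10-10 channel name
#'
#' Channels with an odd trailing number are left-hemispheric, even right,
#' `z` midline.
#' @param name Channel name, e.g. `"FC5"` or `"TP10"`.
#' @return `"left"`, `"right"` or `"midline"`.
#' @export
channel_hemisphere <- function(name) {
  if (grepl("z$", name)) return("midline")
  num <- as.integer(sub("^[A-Za-z]+", "", name))
  if (is.na(num)) stop("cannot parse channel name: ", name)
  if (num %% 2 == 1) "left" else "right"
}

#' Retrieve a named electrode set from a montage
#'
#' @param montage An `eeg_montage`.
#' @param set Name of the set (e.g. `"frontocentral_9"`, `"op_left_12"`).
#' @return Character vector of channel names.
#' @export
montage_set <- function(montage, set) {
  sets <- attr(montage, "sets")
  if (is.null(sets[[set]])) {
    stop("unknown electrode set: ", set, "; available: ",
         paste(names(sets), collapse = ", "))
  }
  s <- sets[[set]]
  missing <- setdiff(s, montage$name)
  if (length(missing) > 0) {
    stop("electrode set '", set, "' references channels absent from montage: ",
         paste(missing, collapse = ", "))
  }
  s
}

#' Mirror a channel name across the midline
#'
#' Swaps odd and even trailing numbers (`P3` becomes `P4`, `TP9` becomes
#' `TP10`); midline names are returned unchanged.
#' @param name Channel name.
#' @return Mirrored channel name.
#' @export
mirror_channel <- function(name) {
  vapply(name, function(nm) {
    if (grepl("z$", nm)) return(nm)
    row <- sub("[0-9]+$", "", nm)
    num <- as.integer(sub("^[A-Za-z]+", "", nm))
    paste0(row, if (num %% 2 == 1) num + 1 else num - 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Positions of a subset of montage channels
#'
#' @param montage An `eeg_montage`.
#' @param channels Character vector of channel names.
#' @return Numeric matrix (channels x 3) of unit-sphere coordinates.
#' @keywords internal
montage_positions <- function(montage, channels = montage$name) {
  idx <- match(channels, montage$name)
  if (anyNA(idx)) {
    stop("channels not in montage: ",
         paste(channels[is.na(idx)], collapse = ", "))
  }
  p <- as.matrix(montage[idx, c("x", "y", "z")])
  rownames(p) <- channels
  p
}

# Gaussian spatial weight profile centered on a scalp location, used by the
# synthesis module to mix sources into channels.
topography_gaussian <- function(montage, center_channel, width) {
  p <- montage_positions(montage)
  ctr <- p[match(center_channel, montage$name), ]
  d2 <- rowSums((p - matrix(ctr, nrow(p), 3, byrow = TRUE))^2)
  w <- exp(-d2 / (2 * width^2))
  names(w) <- montage$name
  w
}
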