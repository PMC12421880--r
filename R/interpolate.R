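# Spherical-spline scalp interpolation (Perrin-style): the potential is
# modeled as v(r) = c0 + sum_i c_i g(r . r_i) with
# g(x) = (1/4pi) sum_l (2l+1) / (l (l+1))^m P_l(x).

legendre_matrix <- function(x, lmax) {
  # P_l(x) for l = 1..lmax via the three-term recurrence; x a vector
  P <- matrix(0, length(x), lmax)
  P[, 1] <- x
  if (lmax >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  if (lmax >= 3) {
    for (l in 3:lmax) {
      P[, l] <- ((2 * l - 1) * x * P[, l - 1] - (l - 1) * P[, l - 2]) / l
    }
  }
  P
}

spline_g <- function(cosang, m = 4, lmax = 20) {
  P <- legendre_matrix(pmin(1, pmax(-1, cosang)), lmax)
  l <- seq_len(lmax)
  w <- (2 * l + 1) / (l * (l + 1))^m
  as.numeric(P %*% w) / (4 * pi)
}

#' Interpolate missing channels by spherical splines
#'
#' Reconstructs the listed channels from the remaining ones with a spherical
#' spline fitted on the unit-sphere electrode positions, sample by sample
#' (vectorized over samples). This is the standard treatment for electrodes
#' that could not be connected over the implant/hearing-aid site.
#'
#' @param e An `eeg_epochs`.
#' @param missing Character vector of channel names to reconstruct; empty
#'   input returns `e` unchanged.
#' @param montage The montage supplying positions.
#' @param m Spline stiffness order (default 4).
#' @param lmax Number of Legendre terms (default 20).
#' @param lambda Ridge regularization added to the spline system
#'   (default 1e-8).
#' @return `eeg_epochs` with the missing channels replaced by their spline
#'   reconstruction.
#' @export
interpolate_channels <- function(e, missing, montage, m = 4, lmax = 20,
                                 lambda = 1e-8) {
  stopifnot(inherits(e, "eeg_epochs"))
  if (length(missing) == 0) return(e)
  if (!all(missing %in% e$channel_names)) {
    stop("missing channels not present in the data: ",
         paste(setdiff(missing, e$channel_names), collapse = ", "))
  }
  if (length(missing) > 0.25 * length(e$channel_names)) {
    stop("refusing to interpolate more than 25% of channels")
  }
  good_ch <- setdiff(e$channel_names, missing)
  if (length(good_ch) < 3) stop("need at least 3 source channels")
  pg <- montage_positions(montage, good_ch)
  pb <- montage_positions(montage, missing)
  G <- matrix(spline_g(tcrossprod(pg), m, lmax), nrow(pg))
  Gb <- matrix(spline_g(tcrossprod(pb, pg), m, lmax), nrow(pb))
  n <- nrow(pg)
  A <- rbind(cbind(G + diag(lambda, n), rep(1, n)), c(rep(1, n), 0))
  gi <- match(good_ch, e$channel_names)
  bi <- match(missing, e$channel_names)
  d <- e$data
  for (i in seq_len(dim(d)[1])) {
    V <- d[i, gi, , drop = TRUE]
    if (is.null(dim(V))) V <- matrix(V, nrow = length(gi))
    sol <- solve(A, rbind(V, 0))                   # (n+1) x samples
    d[i, bi, ] <- Gb %*% sol[seq_len(n), , drop = FALSE] +
      matrix(sol[n + 1, ], length(bi), ncol(V), byrow = TRUE)
  }
  e$data <- d
  e
}
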