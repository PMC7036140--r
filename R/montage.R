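#' Channel labels of the 21-electrode 10-20 montage
#'
#' Canonical order used throughout the package.
#'
#' @return Character vector of 21 labels.
#' @export
eeg_channels_1020 <- function() {
  c("O2", "O1", "P4", "P3", "C4", "C3", "F4", "F3", "Fp2", "Fp1",
    "T6", "T5", "T4", "T3", "F8", "F7", "Pz", "Cz", "Fz", "A2", "A1")
}

#' Standard 10-20 electrode montage on the unit sphere
#'
#' Spherical coordinates of the 21 electrodes (including the A1/A2
#' earlobes, placed below the temporal ring) with the usual 10/20 arc
#' construction: `theta` is the inclination from the vertex (Cz),
#' `phi` the azimuth from the nasion (positive to the right).
#' Cartesian coordinates use x to the right, y to the front, z up;
#' all points have unit norm.
#'
#' @return A tibble `(channel, theta, phi, x, y, z)` in canonical
#'   channel order.
#' @export
standard_montage_1020 <- function() {
  deg <- list(
    # circumferential ring (10% up from the nasion-inion line)
    Fp1 = c(72, -18), Fp2 = c(72, 18),
    F7  = c(72, -54), F8  = c(72, 54),
    T3  = c(72, -90), T4  = c(72, 90),
    T5  = c(72, -126), T6 = c(72, 126),
    O1  = c(72, -162), O2 = c(72, 162),
    # midline
    Fz = c(36, 0), Cz = c(0, 0), Pz = c(36, 180),
    # inner lateral sites
    F3 = c(48, -39), F4 = c(48, 39),
    C3 = c(36, -90), C4 = c(36, 90),
    P3 = c(48, -141), P4 = c(48, 141),
    # earlobes, below the temporal ring
    A1 = c(108, -90), A2 = c(108, 90)
  )
  ord <- eeg_channels_1020()
  theta <- vapply(deg[ord], `[`, 0, 1) * pi / 180
  phi <- vapply(deg[ord], `[`, 0, 2) * pi / 180
  tibble(
    channel = ord,
    theta = theta, phi = phi,
    x = sin(theta) * sin(phi),
    y = sin(theta) * cos(phi),
    z = cos(theta)
  )
}

# adjacency from great-circle separation on the montage sphere
montage_adjacent <- function(montage, channels, max_angle = 0.8) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  rownames(pos) <- montage$channel
  cosang <- pos %*% t(pos)
  ang <- acos(pmin(pmax(cosang, -1), 1))
  adj <- lapply(channels, function(ch) {
    nb <- montage$channel[ang[ch, ] > 0 & ang[ch, ] < max_angle]
    setdiff(nb, channels)
  })
  sort(unique(unlist(adj)))
}
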