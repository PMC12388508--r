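#' Geometry descriptors of a four-Calpha backbone fragment
#'
#' Reduces the conformation of four consecutive Calpha atoms to four numbers:
#' the three "long" inter-Calpha distances d13 = |Ca(i)-Ca(i+2)|,
#' d14 = |Ca(i)-Ca(i+3)| and d24 = |Ca(i+1)-Ca(i+3)|, plus `chi`, the signed
#' projection of Ca(i+3) onto the unit normal of the plane through the first
#' three Calpha. The sign of `chi` encodes the handedness of the fragment:
#' mirror-reflecting the fragment negates `chi` and leaves the distances
#' unchanged. The descriptor is invariant under rigid-body rotation and
#' translation, which is what makes alignment-free encoding possible.
#'
#' @param ca A 4 x 3 numeric matrix of Calpha coordinates (Angstrom), rows in
#'   chain order.
#' @return A named numeric vector `c(d13, d14, d24, chi)`.
#' @export
#' @examples
#' helix <- ideal_helix_coords(4)
#' fragment_descriptors(helix)
fragment_descriptors <- function(ca) {
  ca <- as.matrix(ca)
  if (!all(dim(ca) == c(4, 3)) || !all(is.finite(ca))) {
    abort("`ca` must be a 4 x 3 matrix of finite coordinates")
  }
  v1 <- ca[2, ] - ca[1, ]
  v2 <- ca[3, ] - ca[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-9) abort("undefined chirality descriptor: first three Calpha are collinear")
  c(d13 = sqrt(sum((ca[3, ] - ca[1, ])^2)),
    d14 = sqrt(sum((ca[4, ] - ca[1, ])^2)),
    d24 = sqrt(sum((ca[4, ] - ca[2, ])^2)),
    chi = sum((ca[4, ] - ca[1, ]) * nrm) / nn)
}

#' Descriptors for all sliding windows of a Calpha trace
#'
#' @param coords An m x 3 matrix of consecutive Calpha coordinates (m >= 4).
#' @return An (m - 3) x 4 matrix, one row per window, columns
#'   `d13, d14, d24, chi`.
#' @export
sliding_descriptors <- function(coords) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (m < 4) abort("need at least 4 Calpha positions")
  t(vapply(seq_len(m - 3L),
           function(i) fragment_descriptors(coords[i:(i + 3L), ]),
           numeric(4)))
}

#' Ideal alpha-helix Calpha coordinates
#'
#' Parametric helix used by the synthetic generator and as a geometric test
#' oracle: radius 2.3 Angstrom, rise 1.5 Angstrom per residue, 100 degrees of
#' rotation per residue (the textbook alpha-helix parameters).
#'
#' @param n Number of residues.
#' @param radius,rise,twist_deg Helix parameters.
#' @return An n x 3 coordinate matrix.
#' @export
ideal_helix_coords <- function(n, radius = 2.3, rise = 1.5, twist_deg = 100) {
  i <- seq_len(n) - 1L
  th <- i * twist_deg * pi / 180
  cbind(x = radius * cos(th), y = radius * sin(th), z = rise * i)
}
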