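#' Wrap angles into [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval \code{[-180, 180)}.
#' @export
wrap180 <- function(x) {
  ((x + 180) %% 360) - 180
}

# Wrap into (-180, 180]; used for angle differences so that +/-180 maps to
# a single value and |wrap| <= 180.
wrap_signed <- function(x) {
  180 - ((180 - x) %% 360)
}

#' Dihedral angle of four points
#'
#' Signed torsion angle in degrees following the IUPAC convention: looking
#' down the b-c bond, the angle is positive when the far bond is rotated
#' clockwise from the near bond.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, or n x 3 matrices for a vectorised
#'   call.
#' @return dihedral angle(s) in degrees, in \code{[-180, 180)}.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  }
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  ang <- atan2(rowSums(rowcross(n1, n2) * b2u),
               rowSums(n1 * n2)) * 180 / pi
  unname(wrap180(ang))
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Optimal-superposition coordinate RMSD
#'
#' Kabsch least-squares superposition of two coordinate sets followed by
#' root-mean-square deviation.
#'
#' @param a,b n x 3 coordinate matrices with matched rows.
#' @return RMSD in Angstrom after optimal rigid-body superposition.
#' @export
kabsch_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  ca <- scale(a, scale = FALSE)
  cb <- scale(b, scale = FALSE)
  s <- svd(crossprod(cb, ca))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((ca %*% rot - cb)^2)))
}

# FNV-1a hash of a character scalar; used to stamp reports with a short
# configuration fingerprint.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
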