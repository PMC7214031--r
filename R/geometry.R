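#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors in angstrom.
#' @return The distance in angstrom.
#' @examples
#' point_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
point_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

#' Angles of coordinating atoms relative to the nearest atom
#'
#' The reference vector runs from the halide to its nearest coordinating atom
#' (ties broken by the smallest (chain, residue number, atom name) key). For
#' every coordinating atom the returned angle is the one between the reference
#' vector and the halide-to-atom vector, in degrees in \[0, 180\]; the nearest
#' atom's own angle is 0. With a single coordinating atom the result is `0`.
#'
#' @param halide Numeric 3-vector, halide position.
#' @param coords Numeric matrix (n x 3) of coordinating-atom positions.
#' @param tie_keys Optional character vector used only to break exact distance
#'   ties when choosing the reference atom (smallest key wins); defaults to
#'   the row index.
#' @return Numeric vector of angles in degrees, aligned with the rows of
#'   `coords`.
#' @examples
#' site_angles(c(0, 0, 0), rbind(c(3, 0, 0), c(0, 3.2, 0))) # 0, 90
#' @export
site_angles <- function(halide, coords, tie_keys = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  stopifnot(n >= 1)
  v <- sweep(coords, 2, halide)
  d <- sqrt(rowSums(v^2))
  if (any(d < 1e-9)) {
    stop(sprintf("atom %d coincides with the halide: degenerate geometry",
                 which(d < 1e-9)[1]), call. = FALSE)
  }
  if (is.null(tie_keys)) tie_keys <- sprintf("%09d", seq_len(n))
  # distances tied at coordinate precision defer to the key, so the
  # reference choice is stable across translated copies of a site
  ref_idx <- order(round(d, 6), tie_keys)[1]
  ref <- v[ref_idx, ] / d[ref_idx]
  cosang <- (v %*% ref)[, 1] / d
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  ang[ref_idx] <- 0
  ang
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mov` onto `ref` by a proper rotation
#' (no reflection) plus translation, paired by index.
#'
#' @param ref,mov Numeric matrices (n x 3), n >= 2, paired by row.
#' @return An object of class `superposition`: a list with `rmsd` (angstrom),
#'   `rotation` (3 x 3 proper orthogonal matrix) and `translation` (3-vector),
#'   such that `mov %*% t(rotation) + translation` best fits `ref`.
#' @examples
#' ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' superpose(ref, ref + 5)$rmsd # 0
#' @export
superpose <- function(ref, mov) {
  ref <- matrix(as.numeric(ref), ncol = 3)
  mov <- matrix(as.numeric(mov), ncol = 3)
  stopifnot(nrow(ref) == nrow(mov), nrow(ref) >= 2)
  cr <- colMeans(ref)
  cm <- colMeans(mov)
  P <- sweep(mov, 2, cm)
  Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)  # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Q)^2)))
  translation <- as.numeric(cr - R %*% cm)
  structure(
    list(rmsd = rmsd, rotation = R, translation = translation),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' @rdname tidy.halide_census
#' @export
tidy.superposition <- function(x, ...) {
  tibble::tibble(
    rmsd = x$rmsd,
    det_rotation = det(x$rotation),
    translation_x = x$translation[1],
    translation_y = x$translation[2],
    translation_z = x$translation[3]
  )
}
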