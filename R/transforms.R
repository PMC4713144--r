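#' 6-DOF rigid spatial transform
#'
#' Parameterised by three rotation angles in degrees (applied as
#' `Rz %*% Ry %*% Rx`), a translation in mm, and a centre of rotation in mm.
#' A transform maps a world point `x` to `R (x - c) + c + t`. Throughout the
#' package transforms are used as pull-backs: resampling onto a target grid
#' evaluates the source image at `transform(p_target)` (ITK convention), so
#' the transform returned by [register_rigid()] maps fixed-image world points
#' into moving-image world space.
#'
#' @param rotation numeric length-3, rotation angles about x, y, z in degrees.
#' @param translation numeric length-3, mm.
#' @param center numeric length-3, centre of rotation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rot (%.3f, %.3f, %.3f) deg, trans (%.3f, %.3f, %.3f) mm, center (%.1f, %.1f, %.1f) mm\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cc <- cos(r[3]); sc <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  Rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Affine (A, b) form: x -> A x + b.
transform_affine <- function(tf) {
  A <- rotation_matrix(tf$rotation)
  b <- tf$center + tf$translation - as.numeric(A %*% tf$center)
  list(A = A, b = b)
}

# Recover Rz-Ry-Rx Euler angles (degrees) from a rotation matrix; valid away
# from the |pitch| = 90 deg gimbal, far outside the <= 10 deg range used here.
euler_from_matrix <- function(A) {
  b <- asin(max(-1, min(1, -A[3, 1])))
  a <- atan2(A[3, 2], A[3, 3])
  c <- atan2(A[2, 1], A[1, 1])
  c(a, b, c) * 180 / pi
}

affine_to_rigid <- function(A, b) {
  rigid_transform(rotation = euler_from_matrix(A), translation = as.numeric(b),
                  center = c(0, 0, 0))
}

#' Apply a rigid transform to world points
#' @param tf a [rigid_transform()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(tf, pts) {
  af <- transform_affine(tf)
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(af$A), 2, af$b, "+")
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(f, g)` returns the transform `x -> f(g(x))`;
#' `invert_transform(t)` returns the inverse map.
#' @param f,g,tf [rigid_transform()] objects.
#' @export
compose_transforms <- function(f, g) {
  af <- transform_affine(f); ag <- transform_affine(g)
  affine_to_rigid(af$A %*% ag$A, as.numeric(af$A %*% ag$b) + af$b)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(tf) {
  af <- transform_affine(tf)
  Ai <- t(af$A)
  affine_to_rigid(Ai, -as.numeric(Ai %*% af$b))
}

#' Read and write rigid transforms as plain text
#'
#' Key:value text format with three lines: `rotation_deg`, `translation_mm`,
#' `center_mm`, each followed by three whitespace-separated numbers.
#' @param tf a [rigid_transform()].
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  lines <- c(
    paste("rotation_deg:", paste(format(tf$rotation, digits = 17), collapse = " ")),
    paste("translation_mm:", paste(format(tf$translation, digits = 17), collapse = " ")),
    paste("center_mm:", paste(format(tf$center, digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  get3 <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(ln) != 1L) stop("transform file missing field: ", key)
    as.numeric(strsplit(trimws(sub(paste0("^", key, ":"), "", ln)), "\\s+")[[1]])
  }
  rigid_transform(get3("rotation_deg"), get3("translation_mm"), get3("center_mm"))
}
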