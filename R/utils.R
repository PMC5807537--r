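#' Rigid-body transform
#'
#' A proper rigid transform (rotation followed by translation) applied to
#' Nx3 coordinate matrices, used for opening-model construction and probe
#' posing.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz Nx3 numeric matrix.
#' @param tr `rigid_transform`.
#' @param center optional pivot; rotation is applied about this point.
#' @return transformed Nx3 matrix.
#' @export
apply_transform <- function(xyz, tr, center = c(0, 0, 0)) {
  stopifnot(inherits(tr, "rigid_transform"))
  xyz <- as.matrix(xyz)
  ctr <- matrix(center, nrow(xyz), 3, byrow = TRUE)
  sweep(t(tr$rotation %*% t(xyz - ctr)), 2, -tr$translation) + ctr
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform\n  rotation:\n")
  print(round(x$rotation, 4))
  cat("  translation:", paste(round(x$translation, 3), collapse = ", "), "\n")
  invisible(x)
}

# Uniform random rotation matrices via unit quaternions (Shoemake).
# Draws from the session RNG so callers control seeding.
random_rotations <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  q <- cbind(sqrt(1 - u1) * sin(2 * pi * u2),
             sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3),
             sqrt(u1) * cos(2 * pi * u3))
  out <- matrix(0, n, 9)
  for (i in seq_len(n)) {
    x <- q[i, 1]; y <- q[i, 2]; z <- q[i, 3]; w <- q[i, 4]
    out[i, ] <- c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  }
  out
}

# One random rotation as a 3x3 matrix.
random_rotation_matrix <- function() {
  matrix(random_rotations(1L)[1L, ], 3, 3, byrow = TRUE)
}

# Rotation matrix from axis-angle (Rodrigues). angle in radians.
axis_angle_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Run `expr` under a local, restorable RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 1009 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
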