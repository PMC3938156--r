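#' Build a gradient table
#'
#' A gradient table pairs each frame of a diffusion acquisition with its
#' b-value (s/mm^2) and unit gradient direction. Directions of
#' diffusion-weighted frames (b > 0) are renormalized to unit length;
#' b = 0 frames may carry a zero vector.
#'
#' @param bvals Numeric vector of b-values, one per frame.
#' @param bvecs Numeric matrix, n x 3, of gradient directions (rows).
#' @return A tibble of class `dentract_gradients` with columns
#'   `bval`, `gx`, `gy`, `gz`.
#' @examples
#' gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(3, 4, 0)))
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3) abort("`bvecs` must have 3 columns (x, y, z).")
  if (length(bvals) != nrow(bvecs)) {
    abort(sprintf("count mismatch: %d b-values but %d directions.",
                  length(bvals), nrow(bvecs)))
  }
  if (anyNA(bvals) || anyNA(bvecs)) abort("non-numeric entry in gradient table.")
  if (!any(bvals == 0)) abort("gradient table needs at least one b = 0 frame.")
  dwi <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(dwi & nrm == 0)) abort("zero direction at a b > 0 frame.")
  bvecs[dwi, ] <- bvecs[dwi, , drop = FALSE] / nrm[dwi]
  out <- tibble(bval = as.numeric(bvals),
                gx = bvecs[, 1], gy = bvecs[, 2], gz = bvecs[, 3])
  class(out) <- c("dentract_gradients", class(out))
  out
}

#' Read an FSL-style bvals/bvecs pair
#'
#' `bvals` is one whitespace-separated row of b-values; `bvecs` holds three
#' rows (the x, y and z components). Directions are renormalized on read;
#' the sign convention of the file is kept as-is.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A [gradient_table()].
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = character(), quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3) abort("bvecs file must contain exactly 3 rows.")
  comp <- lapply(rows, function(r) strsplit(trimws(r), "\\s+")[[1]])
  if (length(unique(lengths(comp))) != 1) abort("ragged bvecs rows.")
  num <- suppressWarnings(as.numeric(bvals))
  if (anyNA(num)) abort("non-numeric token in bvals file.")
  vec <- suppressWarnings(vapply(comp, as.numeric, numeric(length(comp[[1]]))))
  if (anyNA(vec)) abort("non-numeric token in bvecs file.")
  bvecs <- matrix(as.numeric(vec), ncol = 3)
  if (length(num) != nrow(bvecs)) {
    abort(sprintf("count mismatch: %d b-values but %d directions.",
                  length(num), nrow(bvecs)))
  }
  gradient_table(num, bvecs)
}

#' Write a gradient table as FSL bvals/bvecs files
#' @param gtab A [gradient_table()].
#' @param bval_path,bvec_path Output paths.
#' @export
write_gradient_table <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bval, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  m <- rbind(gtab$gx, gtab$gy, gtab$gz)
  writeLines(apply(m, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(NULL)
}

bvec_matrix <- function(gtab) cbind(gtab$gx, gtab$gy, gtab$gz)

#' Approximately uniform antipodally-symmetric directions on the sphere
#'
#' Starts from a spherical Fibonacci layout on the hemisphere and relaxes it
#' by electrostatic repulsion between all antipodal pairs, the standard
#' layout for single-shell diffusion sampling schemes. Deterministic.
#'
#' @param n Number of directions.
#' @param n_iter Repulsion iterations.
#' @return An n x 3 matrix of unit row vectors.
#' @export
sphere_directions <- function(n, n_iter = 80) {
  stopifnot(n >= 1)
  # Fibonacci hemisphere start
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n                      # upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  v <- cbind(r * cos(phi), r * sin(phi), z)
  step <- 0.1
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n, 3)
    for (a in seq_len(n)) {
      d1 <- sweep(v, 2, v[a, ])            # v - v_a
      d2 <- sweep(-v, 2, v[a, ])           # -v - v_a (antipodes)
      r1 <- pmax(rowSums(d1^2), 1e-6)
      r2 <- pmax(rowSums(d2^2), 1e-6)
      f <- -d1 / r1^1.5 - d2 / r2^1.5
      f[a, ] <- 0
      frc[a, ] <- colSums(f)
    }
    v <- v + step * frc / n
    v <- v / sqrt(rowSums(v^2))
    step <- step * 0.97
  }
  t(apply(v, 1, canonical_axis))
}

#' Default study-style acquisition scheme
#'
#' One b = 0 frame followed by `n_dirs` unique directions at the given
#' b-value, mirroring a 55-direction single-shell clinical protocol.
#'
#' @param n_dirs Number of diffusion-weighted directions (default 55).
#' @param bval b-value in s/mm^2 (default 1000).
#' @return A [gradient_table()].
#' @export
default_gradient_table <- function(n_dirs = 55, bval = 1000) {
  dirs <- sphere_directions(n_dirs)
  gradient_table(c(0, rep(bval, n_dirs)), rbind(c(0, 0, 0), dirs))
}
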