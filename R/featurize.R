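# Rototranslationally and strand-permutation invariant featurization:
# interstrand base-center distances, symmetrized over the strand-swap
# permutation, then reciprocal-transformed.

#' Interbase distance matrix of a single frame
#'
#' `d[i, j]` is the Euclidean distance (nm) between the center of base
#' `i` on strand 1 and base `j` on strand 2. The matrix is not generally
#' symmetric: rows index strand 1, columns strand 2.
#'
#' @param frame one trajectory frame, array `[2][10][3]` in nm.
#' @return 10 x 10 distance matrix (nm).
#' @export
interbase_distance_matrix <- function(frame) {
  stopifnot(length(dim(frame)) == 3L, dim(frame)[1L] == 2L)
  if (!all(is.finite(frame))) stop("non-finite coordinates in frame")
  s1 <- matrix(frame[1L, , ], dim(frame)[2L], 3L)
  s2 <- matrix(frame[2L, , ], dim(frame)[2L], 3L)
  dx <- outer(s1[, 1L], s2[, 1L], `-`)
  dy <- outer(s1[, 2L], s2[, 2L], `-`)
  dz <- outer(s1[, 3L], s2[, 3L], `-`)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Symmetrized reciprocal feature vector
#'
#' Enforces strand-swap invariance by replacing each of the 45 unordered
#' off-diagonal pairs `(i, j)`/`(j, i)` with their mean, leaving the 10
#' diagonal entries (self-invariant under the swap) unchanged, then maps
#' every entry through `x -> 1 / max(x, epsilon)`. The result is the
#' 100-element feature vector in row-major `(i, j)` order.
#'
#' @param d 10 x 10 interbase distance matrix (nm).
#' @param epsilon floor (nm) preventing reciprocal blow-up on degenerate
#'   inputs; templates never approach it on valid data.
#' @return Numeric vector of length 100, units 1/nm.
#' @export
symmetrized_reciprocal_features <- function(d, epsilon = 0.05) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), epsilon > 0)
  if (any(d < 0)) stop("negative distances")
  sym <- (d + t(d)) / 2
  diag(sym) <- diag(d)
  as.vector(t(1 / pmax(sym, epsilon)))   # row-major over (i, j)
}

#' Featurize trajectories
#'
#' Vectorized computation of the symmetrized reciprocal distance features
#' for every frame of one or more trajectories.
#'
#' @param trajectory a `duplex_trajectory` or a list of them.
#' @param epsilon distance floor in nm (see
#'   [symmetrized_reciprocal_features()]).
#' @param include_intramolecular append the 45 within-strand base-pair
#'   distances (strand-swap symmetrized, reciprocal) as extra columns.
#'   Off by default: they add no kinetic variance for these systems and
#'   the flag exists for experimentation.
#' @return For a single trajectory, a `feature_series`: numeric matrix
#'   `n_frames x 100` (or 145 with intramolecular terms) with attribute
#'   `dt_save`; for a list, a list of such matrices.
#' @export
featurize_trajectory <- function(trajectory, epsilon = 0.05,
                                 include_intramolecular = FALSE) {
  if (inherits(trajectory, "relaxation_ensemble"))
    trajectory <- trajectory$trajectories
  if (is.list(trajectory) && !inherits(trajectory, "duplex_trajectory"))
    return(lapply(trajectory, featurize_trajectory, epsilon = epsilon,
                  include_intramolecular = include_intramolecular))
  fr <- trajectory$frames
  n <- dim(fr)[1L]
  stopifnot(epsilon > 0)
  f <- matrix(0, n, 100L)
  # columns of f in row-major (i, j) order; symmetrize with the (j, i) pair
  for (i in 1:10) for (j in 1:10) {
    dij <- sqrt((fr[, 1L, i, 1L] - fr[, 2L, j, 1L])^2 +
                (fr[, 1L, i, 2L] - fr[, 2L, j, 2L])^2 +
                (fr[, 1L, i, 3L] - fr[, 2L, j, 3L])^2)
    f[, (i - 1L) * 10L + j] <- dij
  }
  for (i in 1:10) for (j in 1:10) {
    if (j <= i) next
    a <- (i - 1L) * 10L + j; b <- (j - 1L) * 10L + i
    m <- (f[, a] + f[, b]) / 2
    f[, a] <- m; f[, b] <- m
  }
  f <- 1 / pmax(f, epsilon)
  if (include_intramolecular) {
    g <- matrix(0, n, 45L)
    col <- 0L
    for (i in 1:9) for (j in (i + 1L):10) {
      col <- col + 1L
      d1 <- sqrt((fr[, 1L, i, 1L] - fr[, 1L, j, 1L])^2 +
                 (fr[, 1L, i, 2L] - fr[, 1L, j, 2L])^2 +
                 (fr[, 1L, i, 3L] - fr[, 1L, j, 3L])^2)
      d2 <- sqrt((fr[, 2L, i, 1L] - fr[, 2L, j, 1L])^2 +
                 (fr[, 2L, i, 2L] - fr[, 2L, j, 2L])^2 +
                 (fr[, 2L, i, 3L] - fr[, 2L, j, 3L])^2)
      g[, col] <- (d1 + d2) / 2       # strand-swap invariant
    }
    f <- cbind(f, 1 / pmax(g, epsilon))
  }
  attr(f, "dt_save") <- trajectory$dt_save
  class(f) <- c("feature_series", class(f))
  f
}

# Raw (unsymmetrized) native-pair distances for selected strand-1
# positions: pair i is (strand-1 base i, strand-2 base 11-i). Used for
# first-passage event detection, where the two terminal pairs are
# physically distinct and must not be averaged together.
.native_pair_distance <- function(frames, pairs) {
  out <- matrix(0, dim(frames)[1L], length(pairs))
  for (m in seq_along(pairs)) {
    i <- pairs[m]; j <- 11L - i
    out[, m] <- sqrt((frames[, 1L, i, 1L] - frames[, 2L, j, 1L])^2 +
                     (frames[, 1L, i, 2L] - frames[, 2L, j, 2L])^2 +
                     (frames[, 1L, i, 3L] - frames[, 2L, j, 3L])^2)
  }
  out
}
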