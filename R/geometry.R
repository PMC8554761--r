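# Coordinate templates for the synthetic generator.
#
# Antiparallel strands on a straight ladder: strand-1 base i sits at
# x = (i-1)*rise, y = +gap/2; strand-2 base j at x = (10-j)*rise,
# y = -gap/2, so native pair (i, 11-i) is vertically aligned at
# separation `gap`. A register offset k translates strand 2 by k*rise
# along the ladder axis (positive k = 5' shift). F4 fans one four-base
# terminal run open; D places the strands with minimum interbase distance
# >= 3 nm (randomized relative orientation is applied at simulation time).

# Base template: [2 strands][10 bases][3 xyz] in nm for a register offset.
.ladder_template <- function(offset = 0) {
  g <- .GEOM
  tpl <- array(0, dim = c(2, 10, 3))
  tpl[1, , 1] <- (0:9) * g$rise
  tpl[1, , 2] <- +g$pair_gap / 2
  tpl[2, , 1] <- (9:0 + offset) * g$rise
  tpl[2, , 2] <- -g$pair_gap / 2
  tpl
}

# F4 template: register 0 with native pairs `run` (strand-1 positions)
# fanned open past the contact cutoff; partner bases move oppositely.
.f4_template <- function(run) {
  g <- .GEOM
  tpl <- .ladder_template(0)
  disp <- g$f4_disp0 + g$f4_dispinc * (seq_along(run) - 1L)
  # displacement grows into the run, measured from the intact boundary
  ord <- if (run[1L] > 5L) run else rev(run)
  for (m in seq_along(ord)) {
    i <- ord[m]
    tpl[1, i, 2] <- tpl[1, i, 2] + disp[m]
    tpl[2, 11L - i, 2] <- tpl[2, 11L - i, 2] - disp[m]
  }
  tpl
}

# D template: strand 2 displaced along +z far enough that every interbase
# distance exceeds 3 nm even before the per-dwell random reorientation.
.d_template <- function() {
  g <- .GEOM
  tpl <- .ladder_template(0)
  tpl[2, , 3] <- tpl[2, , 3] + g$d_sep
  tpl
}

# Templates for a state set, as a list of [2][10][3] arrays. For F4 both
# open-run variants are stored; the generator picks one per dwell.
state_templates <- function(seq, states) {
  out <- list()
  for (s in states) {
    out[[s]] <- switch(s,
      H     = .ladder_template(0),
      `5S2` = .ladder_template(2),
      `3S2` = .ladder_template(-2),
      `5S4` = .ladder_template(4),
      `3S4` = .ladder_template(-4),
      F4    = {
        if (!has_gc_core(seq))
          stop("state F4 requires a central G:C core; sequence ",
               seq$bases, " has none")
        list(.f4_template(7:10), .f4_template(1:4))
      },
      D     = .d_template(),
      stop("no coordinate template for state ", s))
  }
  out
}

# Uniform random rotation matrix (Arvo's method via quaternions).
.random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Uniform random unit vector.
.random_direction <- function() {
  z <- runif(1, -1, 1)
  phi <- runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

# n uniform random unit quaternions, columns (x, y, z, w).
.random_quaternions <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

# n uniform random unit vectors (rows).
.random_directions <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}
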