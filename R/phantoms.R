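# Analytic 3D phantoms: voxelized solids with closed-form (or quadrature)
# oracles for volume, surface area, dural contact area and SI. These are the
# oracle bed for the geometry pipeline: every measured quantity can be
# compared against ground truth that does not pass through the mesh code.

PHANTOM_FAMILIES <- c("ball", "ellipsoid", "cube", "lobulated_ball", "clipped_ball")

#' Specify an analytic phantom
#'
#' @param family One of `"ball"`, `"ellipsoid"`, `"cube"`,
#'   `"lobulated_ball"`, `"clipped_ball"`.
#' @param radius Ball radius in mm (ball, lobulated_ball, clipped_ball).
#' @param semi_axes Length-3 semi-axes in mm (ellipsoid); at least two must
#'   be equal for the closed-form area oracle.
#' @param side Cube edge length in mm.
#' @param clip_depth Signed depth d of the ball centre inside the brain
#'   boundary plane (mm, `|d| < radius`); the tumor is the ball clipped by
#'   the half-space, its flat face lies on the dura.
#' @param amplitude Lobulation amplitude as a fraction of the base radius
#'   (`< 1`, keeps the solid star-shaped).
#' @param n_bumps Number of Gaussian bumps on the lobulated ball.
#' @param bump_width Angular bump width sigma in radians.
#' @param spacing Isotropic voxel spacing in mm.
#' @param margin Brain-mask clearance around the tumor in mm.
#' @param seed Integer seed for the stochastic lobulated family.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(family, radius = 10, semi_axes = c(15, 10, 10),
                         side = 10, clip_depth = 5, amplitude = 0.15,
                         n_bumps = 6, bump_width = 0.5, spacing = 1,
                         margin = 6, seed = 1L) {
  family <- match.arg(family, PHANTOM_FAMILIES)
  if (spacing <= 0) ts_validation_error("'spacing' must be > 0")
  if (margin <= 0) ts_validation_error("'margin' must be > 0")
  if (family %in% c("ball", "lobulated_ball", "clipped_ball") && radius <= 0) {
    ts_validation_error("'radius' must be > 0")
  }
  if (family == "ellipsoid" && (length(semi_axes) != 3L || any(semi_axes <= 0))) {
    ts_validation_error("'semi_axes' must be three positive lengths")
  }
  if (family == "cube" && side <= 0) ts_validation_error("'side' must be > 0")
  if (family == "clipped_ball" && abs(clip_depth) >= radius) {
    ts_validation_error("'clip_depth' must satisfy |d| < radius")
  }
  if (family == "lobulated_ball") {
    if (amplitude < 0 || amplitude >= 1) {
      ts_validation_error("'amplitude' must lie in [0, 1) (fraction of radius)")
    }
    if (n_bumps < 1 || bump_width <= 0) {
      ts_validation_error("'n_bumps' must be >= 1 and 'bump_width' > 0")
    }
  }
  structure(list(family = family, radius = radius, semi_axes = semi_axes,
                 side = side, clip_depth = clip_depth, amplitude = amplitude,
                 n_bumps = n_bumps, bump_width = bump_width, spacing = spacing,
                 margin = margin, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Closed-form ellipsoid area for two equal axes (prolate/oblate spheroid).
spheroid_area <- function(semi_axes) {
  s <- sort(semi_axes, decreasing = TRUE)
  eq <- function(x, y) abs(x - y) < 1e-9 * max(x, y)
  if (eq(s[1], s[2]) && eq(s[2], s[3])) return(4 * pi * s[1]^2)
  if (eq(s[2], s[3])) {          # prolate: a > b = c
    a <- s[1]; b <- s[2]
    e <- sqrt(1 - b^2 / a^2)
    return(2 * pi * b^2 * (1 + (a / (b * e)) * asin(e)))
  }
  if (eq(s[1], s[2])) {          # oblate: a = b > c
    a <- s[1]; c_ <- s[3]
    e <- sqrt(1 - c_^2 / a^2)
    return(2 * pi * a^2 * (1 + ((1 - e^2) / e) * atanh(e)))
  }
  ts_validation_error(
    "ellipsoid area oracle requires at least two equal semi-axes")
}

# Lobulated radius function r(theta, phi) and its oracle surface area /
# volume via dense midpoint quadrature on the sphere.
lobulated_radius_fn <- function(r0, amplitude, centers, bump_width) {
  force(r0); force(amplitude); force(centers); force(bump_width)
  function(theta, phi) {
    st <- sin(theta)
    x <- st * cos(phi); y <- st * sin(phi); z <- cos(theta)
    bump <- 0
    for (i in seq_len(nrow(centers))) {
      cosd <- x * centers[i, 1] + y * centers[i, 2] + z * centers[i, 3]
      ang <- acos(pmin(pmax(cosd, -1), 1))
      bump <- bump + exp(-ang^2 / (2 * bump_width^2))
    }
    r0 * (1 + amplitude * bump)
  }
}

lobulated_oracle <- function(rfn, n_theta = 600L, n_phi = 1200L) {
  dt <- pi / n_theta; dp <- 2 * pi / n_phi
  theta <- (seq_len(n_theta) - 0.5) * dt
  phi <- (seq_len(n_phi) - 0.5) * dp
  G <- outer(theta, phi, rfn)
  # central differences in the periodic phi direction, one-sided at the
  # theta poles (r is smooth there; the sin(theta) weight kills the error)
  r_t <- (rbind(G[2, , drop = FALSE], G[3:n_theta, , drop = FALSE], G[n_theta, , drop = FALSE]) -
            rbind(G[1, , drop = FALSE], G[1:(n_theta - 2), , drop = FALSE],
                  G[n_theta - 1, , drop = FALSE])) /
    c(dt, rep(2 * dt, n_theta - 2), dt)
  G_shift_f <- G[, c(2:n_phi, 1)]
  G_shift_b <- G[, c(n_phi, 1:(n_phi - 1))]
  r_p <- (G_shift_f - G_shift_b) / (2 * dp)
  st <- sin(theta)
  dA <- sqrt(G^4 * st^2 + G^2 * r_t^2 * st^2 + G^2 * r_p^2)
  list(area = sum(dA) * dt * dp,
       volume = sum((G^3 / 3) * st) * dt * dp)
}

# Voxelize: voxel centre membership on a centred axis-aligned lattice.
phantom_lattice <- function(half_extent, spacing) {
  n <- as.integer(ceiling(2 * half_extent / spacing))
  ax <- (seq_len(n) - 0.5) * spacing - n * spacing / 2
  tf <- diag(4)
  tf[1:3, 1:3] <- diag(rep(spacing, 3))
  tf[1:3, 4] <- ax[1]
  list(n = n, ax = ax, tf = tf)
}

#' Build a phantom segmentation pair with its analytic oracle
#'
#' Voxelizes the requested solid by voxel-centre membership, builds an
#' enclosing brain mask (a ball with `margin` clearance, or the half-space
#' the clipped ball abuts), and returns the validated pair together with the
#' oracle record of volume, total area A, dural contact area B, CSA and SI.
#' Oracles are closed forms except the lobulated family, whose area/volume
#' come from dense spherical quadrature of the radial function.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `pair` (a `segmentation_pair`) and `oracle`
#'   (list: `volume_mm3`, `area_mm2`, `dural_area_mm2`, `csa_mm2`, `si`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  mg <- spec$margin

  if (spec$family == "clipped_ball") {
    r <- spec$radius; d <- spec$clip_depth
    half <- r + mg + 2 * sp
    lat <- phantom_lattice(half, sp)
    ax <- lat$ax
    X2 <- outer(outer(ax^2, ax^2, "+"), rep(0, lat$n), "+")
    Z <- outer(outer(rep(0, lat$n), rep(0, lat$n), "+"), ax, "+")
    ball <- X2 + outer(outer(rep(0, lat$n), rep(0, lat$n), "+"), ax^2, "+") <= r^2
    halfspace <- Z <= d
    tumor <- array(as.integer(ball & halfspace), dim = rep(lat$n, 3))
    brain <- array(as.integer(halfspace), dim = rep(lat$n, 3))
    zone <- 2 * pi * r * (r + d)
    disc <- pi * (r^2 - d^2)
    h <- r + d
    vol <- pi * h^2 * (3 * r - h) / 3
    oracle <- list(volume_mm3 = vol, area_mm2 = zone + disc,
                   dural_area_mm2 = disc, csa_mm2 = zone,
                   si = (zone + disc) / equal_volume_sphere_area(vol))
  } else {
    # interior families: tumor centred at origin, brain = enclosing ball
    if (spec$family == "ball") {
      rmax <- spec$radius
      inside_fn <- function(X, Y, Z) X^2 + Y^2 + Z^2 <= spec$radius^2
      A <- 4 * pi * spec$radius^2
      V <- 4 * pi * spec$radius^3 / 3
    } else if (spec$family == "cube") {
      rmax <- spec$side * sqrt(3) / 2
      hs <- spec$side / 2
      inside_fn <- function(X, Y, Z) {
        pmax(abs(X), pmax(abs(Y), abs(Z))) <= hs
      }
      A <- 6 * spec$side^2
      V <- spec$side^3
    } else if (spec$family == "ellipsoid") {
      rmax <- max(spec$semi_axes)
      sa <- spec$semi_axes
      inside_fn <- function(X, Y, Z) {
        (X / sa[1])^2 + (Y / sa[2])^2 + (Z / sa[3])^2 <= 1
      }
      A <- spheroid_area(sa)
      V <- 4 * pi * prod(sa) / 3
    } else { # lobulated_ball
      rng <- with_seed(spec$seed, {
        z <- stats::runif(spec$n_bumps, -1, 1)
        th <- stats::runif(spec$n_bumps, 0, 2 * pi)
        cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
      })
      amp <- spec$amplitude
      rfn <- lobulated_radius_fn(spec$radius, amp, rng, spec$bump_width)
      # worst-case radius: overlapping bumps could stack
      rmax <- spec$radius * (1 + amp * spec$n_bumps)
      inside_fn <- function(X, Y, Z) {
        rho <- sqrt(X^2 + Y^2 + Z^2)
        theta <- acos(ifelse(rho > 0, pmin(pmax(Z / pmax(rho, 1e-300), -1), 1), 1))
        phi <- atan2(Y, X)
        rho <= rfn(theta, phi)
      }
      quad <- lobulated_oracle(rfn)
      A <- quad$area
      V <- quad$volume
    }
    half <- rmax + mg + 2 * sp
    lat <- phantom_lattice(half, sp)
    ax <- lat$ax
    n <- lat$n
    X <- array(ax, dim = c(n, n, n))
    Y <- aperm(X, c(2, 1, 3))
    Z <- aperm(X, c(3, 2, 1))
    tumor <- array(as.integer(inside_fn(X, Y, Z)), dim = c(n, n, n))
    brain_r <- rmax + mg
    brain <- array(as.integer(X^2 + Y^2 + Z^2 <= brain_r^2), dim = c(n, n, n))
    oracle <- list(volume_mm3 = V, area_mm2 = A, dural_area_mm2 = 0,
                   csa_mm2 = A, si = A / equal_volume_sphere_area(V))
  }

  tumor_grid <- volume_grid(tumor, rep(sp, 3), lat$tf, label = "tumor")
  brain_grid <- volume_grid(brain, rep(sp, 3), lat$tf, label = "brain")
  pair <- validate_pair(tumor_grid, brain_grid,
                        provenance = sprintf("phantom:%s", spec$family))
  list(pair = pair, oracle = oracle, spec = spec)
}
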