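# Shared in-code fixtures: tiny reference molecules built from exact
# coordinates, used across the module tests.

water_geometry <- function() {
  geometry(c("O", "H", "H"),
           rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2399, 0.9266, 0)),
           total_charge = 0L, title = "water")
}

ethane_geometry <- function() {
  h1 <- rbind(c(-0.36, 1.03, 0), c(-0.36, -0.515, 0.89),
              c(-0.36, -0.515, -0.89))
  h2 <- sweep(-h1, 2L, c(1.54, 0, 0), `+`)
  geometry(c("C", "C", rep("H", 6L)),
           rbind(c(0, 0, 0), c(1.54, 0, 0), h1, h2),
           title = "ethane")
}

benzene_geometry <- function() {
  ang <- (0:5) * pi / 3
  cs <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hs <- cbind(2.47 * cos(ang), 2.47 * sin(ang), 0)
  geometry(c(rep("C", 6L), rep("H", 6L)), rbind(cs, hs), title = "benzene")
}

# n directly bonded metal atoms in a straight chain
metal_chain_geometry <- function(n, element = "Ru", spacing = 2.4) {
  geometry(rep(element, n), cbind(spacing * (seq_len(n) - 1L), 0, 0),
           title = sprintf("%d-metal chain", n))
}

# random 3x3 symmetric matrix with entries in [-1, 1]
random_symmetric3 <- function() {
  m <- matrix(stats::runif(9L, -1, 1), 3L, 3L)
  (m + t(m)) / 2
}

# independent eigenvalue oracle: roots of the characteristic cubic
# lambda^3 - tr lambda^2 + m2 lambda - det, solved by polyroot()
charpoly_eigenvalues <- function(m) {
  tr <- sum(diag(m))
  m2 <- (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) +
    (m[1, 1] * m[3, 3] - m[1, 3] * m[3, 1]) +
    (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2])
  dt <- det(m)
  sort(Re(polyroot(c(-dt, m2, -tr, 1))))
}

# rigid rotation of a geometry + the congruence transform of its Hessian
rotate_system <- function(geom, hessian, rot) {
  g2 <- geometry(geom$elements, geom$coordinates %*% t(rot),
                 total_charge = geom$total_charge, title = geom$title)
  big <- kronecker(diag(geom$n_atoms), rot)
  h2 <- cartesian_hessian(big %*% hessian$matrix %*% t(big),
                          hessian$n_atoms)
  list(geometry = g2, hessian = h2)
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  a <- q[1L]; b <- q[2L]; c <- q[3L]; d <- q[4L]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}

# closed-form angle constant of a planar-star spring model, output units
star_angle_closed_form <- function(star, a, b, c) {
  bond_row <- function(i) which(star$topology$bonds[, 1L] == min(i, b) &
                                  star$topology$bonds[, 2L] == max(i, b))
  r <- function(i) sqrt(sum((star$geometry$coordinates[i, ] -
                               star$geometry$coordinates[b, ])^2)) /
    0.529177211
  inv <- 1 / (r(a)^2 * star$model$k_perp[bond_row(a)]) +
    1 / (r(c)^2 * star$model$k_perp[bond_row(c)])
  2 * 627.509474 / inv
}
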