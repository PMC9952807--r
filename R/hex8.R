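# Trilinear hexahedron (hex8) kernels for axis-aligned box elements.
# Voigt order: (xx, yy, zz, yz, xz, xy) with engineering shear strains.

hex8_local <- cbind(
  xi   = c(-1,  1,  1, -1, -1,  1, 1, -1),
  eta  = c(-1, -1,  1,  1, -1, -1, 1,  1),
  zeta = c(-1, -1, -1, -1,  1,  1, 1,  1))

# Isotropic elasticity matrix (6 x 6), E in Pa.
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Strain-displacement matrix (6 x 24) at local coords for a box element of
# size (hx, hy, hz).
hex8_B <- function(xi, eta, zeta, hx, hy, hz) {
  l <- hex8_local
  dNdx <- l[, 1] * (1 + eta * l[, 2]) * (1 + zeta * l[, 3]) / 8 * (2 / hx)
  dNdy <- l[, 2] * (1 + xi * l[, 1]) * (1 + zeta * l[, 3]) / 8 * (2 / hy)
  dNdz <- l[, 3] * (1 + xi * l[, 1]) * (1 + eta * l[, 2]) / 8 * (2 / hz)
  B <- matrix(0, 6, 24)
  ix <- 3 * (1:8) - 2
  B[1, ix] <- dNdx
  B[2, ix + 1] <- dNdy
  B[3, ix + 2] <- dNdz
  B[4, ix + 1] <- dNdz; B[4, ix + 2] <- dNdy
  B[5, ix] <- dNdz;     B[5, ix + 2] <- dNdx
  B[6, ix] <- dNdy;     B[6, ix + 1] <- dNdx
  B
}

gauss2 <- c(-1, 1) / sqrt(3)

# Element stiffness (24 x 24) for a box element; exact for trilinear boxes
# with 2x2x2 Gauss.
hex8_ke <- function(hx, hy, hz, D) {
  detJ <- hx * hy * hz / 8
  ke <- matrix(0, 24, 24)
  for (a in gauss2) for (b in gauss2) for (c in gauss2) {
    B <- hex8_B(a, b, c, hx, hy, hz)
    ke <- ke + crossprod(B, D %*% B) * detJ
  }
  ke
}

# Equivalent nodal forces (24) for a uniform eigenstrain eps0 (Voigt, 6):
# f = int B' D eps0 dV.
hex8_fe_eigen <- function(hx, hy, hz, D, eps0) {
  detJ <- hx * hy * hz / 8
  sig0 <- D %*% eps0
  fe <- numeric(24)
  for (a in gauss2) for (b in gauss2) for (c in gauss2)
    fe <- fe + crossprod(hex8_B(a, b, c, hx, hy, hz), sig0) * detJ
  as.numeric(fe)
}

# Consistent mass matrix of a bilinear rectangular facet, times area.
# Node order must follow the facet corner ordering used in hex_face_local
# (a closed loop), for which adjacency is (1-2, 2-3, 3-4, 4-1).
facet_mass <- function(area) {
  M <- matrix(c(4, 2, 1, 2,
                2, 4, 2, 1,
                1, 2, 4, 2,
                2, 1, 2, 4) / 36, 4, 4)
  M * area
}
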