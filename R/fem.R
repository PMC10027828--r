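# Stabilized equal-order finite elements for incompressible flow.
#
# Linear (P1) velocity and pressure on triangles with SUPG/PSPG
# stabilization; the viscous term uses the full stress-divergence form
# mu (grad u + grad u^T) : grad w so the natural outlet condition is zero
# traction.  Convection and the Casson viscosity are evaluated at the
# previous Picard iterate (element-wise constants); the Darcy sink mu/k
# enters implicitly as a reaction term on SAC cells.  Unknown ordering:
# [u_1..u_n, v_1..v_n, p_1..p_n].

# Duplicate-safe accumulation of contributions into a dense vector
# (plain `out[idx] <- out[idx] + val` drops repeated indices).
.accumulate <- function(idx, val, length_out) {
  out <- numeric(length_out)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# Precompute geometry-dependent assembly data for a mesh.
.fem_setup <- function(mesh) {
  nodes <- mesh$nodes; tri <- mesh$tri
  n <- nrow(nodes); m <- nrow(tri)
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  A <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  inv2A <- 1 / (2 * A)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) * inv2A   # d(phi_l)/dx
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) * inv2A  # d(phi_l)/dy
  h <- sqrt(4 * A / sqrt(3))                      # equivalent element size
  sac <- mesh$region == "SAC"

  # fixed sparsity pattern: 9 blocks of 9 entries per element
  i3 <- rep(1:3, each = 3); j3 <- rep(1:3, times = 3)
  ti <- t(tri)  # 3 x m
  row_loc <- matrix(0L, m, 9L); col_loc <- matrix(0L, m, 9L)
  for (q in 1:9) {
    row_loc[, q] <- tri[, i3[q]]
    col_loc[, q] <- tri[, j3[q]]
  }
  blk <- function(roff, coff) list(i = as.integer(row_loc + roff),
                                   j = as.integer(col_loc + coff))
  pat <- list(uu = blk(0L, 0L), uv = blk(0L, n), up = blk(0L, 2L * n),
              vu = blk(n, 0L), vv = blk(n, n), vp = blk(n, 2L * n),
              pu = blk(2L * n, 0L), pv = blk(2L * n, n),
              pp = blk(2L * n, 2L * n))
  I <- unlist(lapply(pat, `[[`, "i"), use.names = FALSE)
  J <- unlist(lapply(pat, `[[`, "j"), use.names = FALSE)

  # wall facet data for shear extraction
  bnd <- mesh$boundary
  ex <- nodes[bnd$n2, 1] - nodes[bnd$n1, 1]
  ey <- nodes[bnd$n2, 2] - nodes[bnd$n1, 2]
  elen <- sqrt(ex^2 + ey^2)
  list(mesh = mesh, n = n, m = m, A = A, b = b, c = cc, h = h, sac = sac,
       I = I, J = J, i3 = i3, j3 = j3,
       edge_len = elen, edge_nx = ey / elen, edge_ny = -ex / elen)
}

# Element-wise current-iterate quantities needed by assembly and WSS.
.fem_element_state <- function(fem, u, v) {
  tri <- fem$mesh$tri
  uE <- matrix(u[tri], ncol = 3L); vE <- matrix(v[tri], ncol = 3L)
  ux <- rowSums(fem$b * uE); uy <- rowSums(fem$c * uE)
  vx <- rowSums(fem$b * vE); vy <- rowSums(fem$c * vE)
  list(uE = uE, vE = vE,
       ubar = rowMeans(uE), vbar = rowMeans(vE),
       ux = ux, uy = uy, vx = vx, vy = vy,
       gdot = shear_rate_components(ux, uy, vx, vy))
}

# Assemble the linearized system A x = rhs about iterate (u, v, p).
# dti = 1/dt for implicit Euler steps, 0 for steady solves; for BDF2 the
# caller passes dti = 3/(2 dt) and a combined history field.
.fem_assemble <- function(fem, u, v, rheology, porous, rho, dti,
                          hist_u = NULL, hist_v = NULL) {
  m <- fem$m; n <- fem$n
  A <- fem$A; b <- fem$b; cc <- fem$c
  es <- .fem_element_state(fem, u, v)
  mu <- apparent_viscosity(es$gdot, rheology)
  sigma <- numeric(m)
  k <- if (is.null(porous)) Inf else porous$permeability
  if (is.finite(k) && any(fem$sac)) sigma[fem$sac] <- mu[fem$sac] / k

  adv <- es$ubar * b + es$vbar * cc            # m x 3: u*.grad(phi_l)
  spd <- sqrt(es$ubar^2 + es$vbar^2)
  tau <- rho / sqrt((2 * rho * dti)^2 + (2 * rho * spd / fem$h)^2 +
                      (4 * mu / fem$h^2)^2 + sigma^2)
  react <- rho * dti + sigma
  A3 <- A / 3

  i3 <- fem$i3; j3 <- fem$j3
  V <- matrix(0, m, 9L * 9L)  # columns: 9 blocks x 9 local entries
  off <- function(blkno) (blkno - 1L) * 9L
  for (q in 1:9) {
    i <- i3[q]; j <- j3[q]
    mass_ij <- A / 12 * (1 + (i == j))
    supg_col <- react * A3 + rho * A * adv[, j]
    # uu (block 1) and vv (block 5): reaction + convection + viscous + SUPG
    common <- react * mass_ij + rho * A3 * adv[, j] + tau * adv[, i] * supg_col
    V[, off(1L) + q] <- common + mu * A * (2 * b[, i] * b[, j] + cc[, i] * cc[, j])
    V[, off(5L) + q] <- common + mu * A * (b[, i] * b[, j] + 2 * cc[, i] * cc[, j])
    V[, off(2L) + q] <- mu * A * cc[, i] * b[, j]          # uv
    V[, off(4L) + q] <- mu * A * b[, i] * cc[, j]          # vu
    V[, off(3L) + q] <- -A3 * b[, i] + tau * A * adv[, i] * b[, j]   # up
    V[, off(6L) + q] <- -A3 * cc[, i] + tau * A * adv[, i] * cc[, j] # vp
    V[, off(7L) + q] <- A3 * b[, j] + (tau / rho) * b[, i] * supg_col  # pu
    V[, off(8L) + q] <- A3 * cc[, j] + (tau / rho) * cc[, i] * supg_col # pv
    V[, off(9L) + q] <- (tau / rho) * A * (b[, i] * b[, j] + cc[, i] * cc[, j]) # pp
  }

  rhs <- numeric(3L * n)
  if (dti > 0) {
    tri <- fem$mesh$tri
    hE_u <- matrix(hist_u[tri], ncol = 3L)
    hE_v <- matrix(hist_v[tri], ncol = 3L)
    su <- rowSums(hE_u); sv <- rowSums(hE_v)   # sum over local nodes
    # per-element contribution matrices (m x 3, column = local node):
    # Galerkin consistent mass (M_e uh)_i = A/12 (sum_j uh_j + uh_i),
    # plus SUPG/PSPG consistency terms on the history field
    C_u <- rho * dti * A / 12 * (su + hE_u) + (tau * rho * dti * A3 * su) * adv
    C_v <- rho * dti * A / 12 * (sv + hE_v) + (tau * rho * dti * A3 * sv) * adv
    C_p <- (tau * dti * A3 * su) * b + (tau * dti * A3 * sv) * cc
    tf <- as.integer(tri)
    rhs <- .accumulate(c(tf, tf + n, tf + 2L * n), c(C_u, C_v, C_p), 3L * n)
  }

  Amat <- Matrix::sparseMatrix(i = fem$I, j = fem$J, x = as.vector(V),
                               dims = c(3L * n, 3L * n))
  list(A = Amat, rhs = rhs, mu = mu, sigma = sigma)
}
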