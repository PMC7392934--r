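# Parametric triangle meshes used by the phantom generator and tests.
# All return `surface_mesh` objects in mm, outward-oriented.

#' Icosphere mesh
#' @param radius mm. @param center 3-vector, mm.
#' @param subdivisions subdivision depth (0 = icosahedron).
#' @export
mesh_icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    newf <- matrix(0L, 4L * nf, 3L)
    edge_mid <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(sort(c(i, j)), collapse = "-")
      idx <- edge_mid[[key]]
      if (is.null(idx)) {
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        idx <- nrow(v)
        edge_mid[[key]] <- idx
      }
      idx
    }
    for (t in seq_len(nf)) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(4 * t - 3):(4 * t), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  surface_mesh(sweep(v * radius, 2L, center, "+"), f)
}

#' Ellipsoid mesh (scaled icosphere)
#' @param semi semi-axes `c(a, b, c)`, mm. @param center 3-vector, mm.
#' @param R 3 x 3 rotation (local axes as columns).
#' @param subdivisions icosphere depth.
#' @export
mesh_ellipsoid <- function(semi, center = c(0, 0, 0), R = diag(3),
                           subdivisions = 3) {
  m <- mesh_icosphere(1, c(0, 0, 0), subdivisions)
  v <- sweep(m$vertices, 2L, semi, "*") %*% t(R)
  surface_mesh(sweep(v, 2L, center, "+"), m$faces)
}

#' Closed cylinder mesh along a local z-axis
#' @param radius mm. @param length mm (total).
#' @param center 3-vector, mm. @param R rotation, local z = cylinder axis.
#' @param n segments around the circumference.
#' @export
mesh_cylinder <- function(radius, length, center = c(0, 0, 0), R = diag(3),
                          n = 48) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- cbind(radius * cos(th), radius * sin(th))
  v <- rbind(cbind(ring, -length / 2), cbind(ring, length / 2),
             c(0, 0, -length / 2), c(0, 0, length / 2))
  bot <- 2L * n + 1L; top <- 2L * n + 2L
  side <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- i %% n + 1L
    rbind(c(i, j, n + i), c(j, n + j, n + i))
  }))
  caps <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- i %% n + 1L
    rbind(c(bot, j, i), c(top, n + i, n + j))
  }))
  v <- sweep(v %*% t(R), 2L, center, "+")
  surface_mesh(v, rbind(side, caps))
}

#' Box mesh
#' @param half half-extents `c(hx, hy, hz)`, mm.
#' @param center 3-vector, mm. @param R rotation.
#' @export
mesh_box <- function(half = c(0.5, 0.5, 0.5), center = c(0, 0, 0),
                     R = diag(3)) {
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s), 2L, half, "*")
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = -1
             c(5, 6, 7), c(6, 8, 7),   # z = +1
             c(1, 2, 5), c(2, 6, 5),   # y = -1
             c(3, 7, 4), c(4, 7, 8),   # y = +1
             c(1, 5, 3), c(3, 5, 7),   # x = -1
             c(2, 4, 6), c(4, 8, 6))   # x = +1
  surface_mesh(sweep(v %*% t(R), 2L, center, "+"), f)
}

#' Flat elliptical disk mesh in a local x-y plane
#'
#' Triangulated with concentric rings; semi-axes `a >= b` along local x, y.
#' @param a,b semi-axes, mm. @param center 3-vector, mm. @param R rotation.
#' @param n_rings,n_seg radial rings and angular segments.
#' @export
mesh_elliptical_disk <- function(a, b, center = c(0, 0, 0), R = diag(3),
                                 n_rings = 12, n_seg = 48) {
  verts <- matrix(c(0, 0, 0), 1L, 3L)
  ring_index <- list()
  for (r in seq_len(n_rings)) {
    t <- r / n_rings
    th <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
    ring_index[[r]] <- nrow(verts) + seq_len(n_seg)
    verts <- rbind(verts, cbind(a * t * cos(th), b * t * sin(th), 0))
  }
  faces <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
    j <- i %% n_seg + 1L
    c(1L, ring_index[[1]][i], ring_index[[1]][j])
  }))
  for (r in seq_len(n_rings - 1L)) {
    inner <- ring_index[[r]]; outer <- ring_index[[r + 1L]]
    quads <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
      j <- i %% n_seg + 1L
      rbind(c(inner[i], outer[i], outer[j]), c(inner[i], outer[j], inner[j]))
    }))
    faces <- rbind(faces, quads)
  }
  surface_mesh(sweep(verts %*% t(R), 2L, center, "+"), faces)
}

#' Spherical-cap mesh (open surface)
#'
#' Cap of a sphere of radius `R_sph` with cap height `h`, apex up along
#' local +z, rim in the plane z = 0.  Closed forms: area `2*pi*R_sph*h`,
#' rim radius `sqrt(2*R_sph*h - h^2)`, projected (rim-plane) area
#' `pi*(2*R_sph*h - h^2)`.
#'
#' @param R_sph sphere radius, mm. @param h cap height, mm (`0 < h <= R_sph`).
#' @param center rim-centre position, mm. @param R rotation.
#' @param n_rings,n_seg resolution.
#' @export
mesh_spherical_cap <- function(R_sph, h, center = c(0, 0, 0), R = diag(3),
                               n_rings = 24, n_seg = 64) {
  stopifnot(h > 0, h <= R_sph)
  phi_max <- acos(1 - h / R_sph)    # polar angle of the rim
  z0 <- R_sph - h                   # sphere centre sits at -z0 below the rim
  verts <- matrix(c(0, 0, h), 1L, 3L)
  ring_index <- list()
  for (r in seq_len(n_rings)) {
    phi <- phi_max * r / n_rings
    th <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
    ring_index[[r]] <- nrow(verts) + seq_len(n_seg)
    verts <- rbind(verts, cbind(R_sph * sin(phi) * cos(th),
                                R_sph * sin(phi) * sin(th),
                                R_sph * cos(phi) - z0))
  }
  faces <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
    j <- i %% n_seg + 1L
    c(1L, ring_index[[1]][i], ring_index[[1]][j])
  }))
  for (r in seq_len(n_rings - 1L)) {
    inner <- ring_index[[r]]; outer <- ring_index[[r + 1L]]
    quads <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
      j <- i %% n_seg + 1L
      rbind(c(inner[i], outer[i], outer[j]), c(inner[i], outer[j], inner[j]))
    }))
    faces <- rbind(faces, quads)
  }
  surface_mesh(sweep(verts %*% t(R), 2L, center, "+"), faces)
}

#' Hemisphere mesh (open), radius `r`, apex along +z
#' @param r radius, mm. @param center rim-centre, mm. @param R rotation.
#' @param n_rings,n_seg resolution.
#' @export
mesh_hemisphere <- function(r, center = c(0, 0, 0), R = diag(3),
                            n_rings = 24, n_seg = 64) {
  mesh_spherical_cap(r, r, center, R, n_rings, n_seg)
}
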