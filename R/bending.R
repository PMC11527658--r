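# Virtual bending test: the final axisymmetric state is revolved into a 3D
# tetrahedral model of a 150 mm construct (fixator explanted), element
# properties are mapped from the 2D callus field, a pure bending moment is
# applied through rigid end plates, and bending stiffness is reported as
# moment / mid-span transverse deflection.

# cross-section for the bending construct: bone fragments extended to the
# full construct length, meshed at h_bone; callus region meshed at h_callus
.bending_cross_section <- function(geometry, length = 150,
                                   h_bone = 1, h_callus = 0.5) {
  L2 <- length / 2
  c2 <- geometry$callus_length / 2
  g2 <- geometry$gap_width_uncompressed / 2
  ri <- geometry$cortex_inner_radius
  ro <- geometry$bone_outer_radius
  hb <- h_bone / .EDGE_FACTOR
  hc <- h_callus / .EDGE_FACTOR

  # piecewise z stations: coarse outside the callus, fine inside
  seg <- function(a, b, h, drop_last = TRUE) {
    s <- .stations(c(a, b), h)
    if (drop_last) s[-length(s)] else s
  }
  zs <- c(seg(-L2, -c2, hb), seg(-c2, -g2, hc), seg(-g2, g2, hc),
          seg(g2, c2, hc), seg(c2, L2, hb, drop_last = FALSE))
  nr <- max(2L, round((ro - ri) / hb))
  rs <- seq(ri, ro, length.out = nr + 1)

  z_in <- function(a, b) zs[zs >= a - 1e-9 & zs <= b + 1e-9]
  blk <- function(b, region) { b$region <- region; b }
  blocks <- list(
    blk(.block_grid(rs, z_in(-L2, -g2)), "bone_fragment"),
    blk(.block_grid(rs, z_in(g2, L2)), "bone_fragment"),
    blk(.block_grid(rs, z_in(-g2, g2)), "callus")
  )
  zc <- z_in(-c2, c2)
  chains <- lapply(zc, function(z) {
    R <- geometry$profile(z)
    if (R - ro < 0.5 * hc) return(ro)
    n <- max(1L, round((R - ro) / hc))
    seq(ro, R, length.out = n + 1)
  })
  for (i in seq_len(length(zc) - 1)) {
    if (length(chains[[i]]) == 1 && length(chains[[i + 1]]) == 1) next
    blocks[[length(blocks) + 1]] <-
      blk(.zipper(chains[[i]], zc[i], chains[[i + 1]], zc[i + 1]), "callus")
  }
  all_nodes <- do.call(rbind, lapply(blocks, `[[`, "nodes"))
  offs <- cumsum(c(0L, vapply(blocks, function(b) nrow(b$nodes), 0L)))
  all_tris <- do.call(rbind, mapply(function(b, o) b$triangles + o,
                                    blocks, offs[-length(offs)],
                                    SIMPLIFY = FALSE))
  region <- unlist(mapply(function(b) rep(b$region, nrow(b$triangles)),
                          blocks, SIMPLIFY = FALSE), use.names = FALSE)
  key <- paste(round(all_nodes[, 1], 6), round(all_nodes[, 2], 6))
  uniq <- !duplicated(key)
  nodes <- all_nodes[uniq, , drop = FALSE]
  remap <- match(key, key[uniq])
  tris <- matrix(remap[all_tris], ncol = 3)
  mesh <- .finalize_mesh(nodes, tris, region)
  mesh$geometry <- geometry
  mesh
}

#' Revolve an (r, z) triangle mesh into a 3D tetrahedral mesh
#'
#' Each cross-section triangle becomes `n_seg` wedge prisms around the
#' axis, each split into three tetrahedra with the global-index diagonal
#' rule so that shared prism faces receive matching diagonals and the mesh
#' is conforming. All cross-section nodes must have r > 0.
#'
#' @param mesh An `axisym_mesh` (cross section).
#' @param n_seg Number of circumferential segments (>= 3).
#' @return List of class `tet_mesh`: `nodes` (n x 3, mm), `tets` (m x 4,
#'   positive volume), `region` (per tet, inherited from the cross-section
#'   element), `source_elem` (cross-section element id per tet), `volume`.
#' @export
revolve_mesh <- function(mesh, n_seg = 24) {
  stopifnot(n_seg >= 3, all(mesh$nodes[, 1] > 0))
  n2 <- nrow(mesh$nodes)
  theta <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  r <- mesh$nodes[, 1]; z <- mesh$nodes[, 2]
  nodes <- cbind(
    x = as.vector(outer(r, cos(theta))),
    y = as.vector(outer(r, sin(theta))),
    z = rep(z, times = n_seg)
  )
  ring <- function(k) ((k - 1L) %% n_seg) * n2 # node-id offset of ring k
  tri <- mesh$triangles
  m <- nrow(tri)
  tets <- vector("list", n_seg)
  region <- rep(mesh$region, each = 3)
  src <- rep(seq_len(m), each = 3)
  for (k in seq_len(n_seg)) {
    lo <- ring(k); hi <- ring(k + 1L)
    prisms <- cbind(tri + lo, tri + hi) # columns: a b c | d e f (d above a)
    tets[[k]] <- .split_prisms(prisms)
  }
  tets <- do.call(rbind, tets)
  region <- rep(rep(mesh$region, each = 3), times = n_seg)
  src <- rep(rep(seq_len(m), each = 3), times = n_seg)
  vol <- .tet_volumes(nodes, tets)
  neg <- vol < 0
  if (any(neg)) {
    tmp <- tets[neg, 3]; tets[neg, 3] <- tets[neg, 4]; tets[neg, 4] <- tmp
    vol <- abs(vol)
  }
  if (any(vol <= 0)) stop("revolution produced a degenerate tetrahedron")
  structure(list(nodes = nodes, tets = tets, region = region,
                 source_elem = src, volume = vol),
            class = "tet_mesh")
}

# split triangular prisms (a,b,c | d,e,f) into 3 tets each using the
# smallest-global-index rule, which guarantees conforming quad-face diagonals
.split_prisms <- function(p) {
  m <- nrow(p)
  # flip prisms whose smallest global index lies on the top face, so that
  # after rotation vertex `a` is the prism's global minimum (the diagonal
  # rule is only consistent across shared faces with this normalisation)
  flip <- pmin(p[, 4], p[, 5], p[, 6]) < pmin(p[, 1], p[, 2], p[, 3])
  p[flip, ] <- p[flip, c(4, 5, 6, 1, 2, 3), drop = FALSE]
  # rotate so the smallest vertex index of the bottom/top pair set is first
  min_col <- max.col(-cbind(pmin(p[, 1], p[, 4]), pmin(p[, 2], p[, 5]),
                            pmin(p[, 3], p[, 6])), ties.method = "first")
  rot1 <- min_col == 2L; rot2 <- min_col == 3L
  p[rot1, ] <- p[rot1, c(2, 3, 1, 5, 6, 4), drop = FALSE]
  p[rot2, ] <- p[rot2, c(3, 1, 2, 6, 4, 5), drop = FALSE]
  a <- p[, 1]; b <- p[, 2]; c <- p[, 3]; d <- p[, 4]; e <- p[, 5]; f <- p[, 6]
  # the quad face (b,c,f,e): diagonal through min(b,f) vs min(c,e)
  use_bf <- pmin(b, f) < pmin(c, e)
  t1 <- cbind(a, b, c, f)
  t1[!use_bf, ] <- cbind(a, b, c, e)[!use_bf, ]
  t2 <- cbind(a, b, f, e)
  t2[!use_bf, ] <- cbind(a, e, c, f)[!use_bf, ]
  t3 <- cbind(a, e, f, d)
  t3[!use_bf, ] <- cbind(a, e, f, d)[!use_bf, ]
  out <- matrix(0L, 3L * m, 4L)
  out[seq(1, 3 * m, 3), ] <- t1
  out[seq(2, 3 * m, 3), ] <- t2
  out[seq(3, 3 * m, 3), ] <- t3
  out
}

.tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  u <- nodes[tets[, 2], , drop = FALSE] - a
  v <- nodes[tets[, 3], , drop = FALSE] - a
  w <- nodes[tets[, 4], , drop = FALSE] - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("<tet_mesh>", nrow(x$nodes), "nodes,", nrow(x$tets), "tets, volume",
      sprintf("%.0f mm^3\n", sum(x$volume)))
  invisible(x)
}

#' Map 2D element fields onto query points
#'
#' Element fields of the axisymmetric healing model are piecewise constant,
#' so a point in the (r, z) plane receives the value of the nearest 2D
#' element centroid (bucket-grid accelerated). Points outside the 2D
#' centroid cloud (hull) naturally fall back to the nearest centroid.
#'
#' @param centroids Two-column matrix of 2D element centroids (r, z).
#' @param values Matrix (or vector) of per-element values, rows aligned
#'   with `centroids`.
#' @param query Two-column matrix of (r, z) query points.
#' @return Matrix (or vector) of mapped values, one row per query point.
#' @export
map_field_nearest <- function(centroids, values, query) {
  vec <- is.null(dim(values))
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(centroids))
  h <- max(diff(range(centroids[, 1])), diff(range(centroids[, 2]))) / 50
  key <- function(i, j) paste(i, j)
  buckets <- split(seq_len(nrow(centroids)),
                   key(floor(centroids[, 1] / h), floor(centroids[, 2] / h)))
  qi <- floor(query[, 1] / h); qj <- floor(query[, 2] / h)
  qcell <- key(qi, qj)
  idx <- integer(nrow(query))
  # queries sharing a bucket cell share their candidate set: search ring by
  # ring (plus one guard ring so the true nearest cannot hide next door)
  for (qsel in split(seq_len(nrow(query)), qcell)) {
    ci <- qi[qsel[1]]; cj <- qj[qsel[1]]
    cand <- integer(0); ring <- 0L
    while (length(cand) == 0) {
      ks <- as.vector(outer(ci + (-ring:ring), cj + (-ring:ring), key))
      cand <- unlist(buckets[ks], use.names = FALSE)
      ring <- ring + 1L
    }
    ks <- as.vector(outer(ci + (-ring:ring), cj + (-ring:ring), key))
    cand <- unlist(buckets[ks], use.names = FALSE)
    d2 <- outer(query[qsel, 1], centroids[cand, 1], `-`)^2 +
      outer(query[qsel, 2], centroids[cand, 2], `-`)^2
    idx[qsel] <- cand[max.col(-d2, ties.method = "first")]
  }
  out <- values[idx, , drop = FALSE]
  if (vec) out[, 1] else out
}

#' Build the 3D virtual bending model from a healing result
#'
#' The bone fragments are extended axially to a 150 mm construct, the final
#' callus is revolved with them into a tetrahedral mesh, and each callus
#' tetrahedron receives the Young's modulus and Poisson's ratio of the 2D
#' callus element nearest (in the collapsed (r, z) cylindrical coordinates)
#' to its centroid. The fixator is absent (explanted before the test).
#'
#' @param result A [run_healing()] result.
#' @param length Construct length, mm.
#' @param bone_edge,callus_edge Target tetrahedron edge lengths, mm.
#' @param coarse Scale factor applied to both edge lengths (use > 1 for
#'   desk-scale runs; the full 0.5 mm callus resolution is a
#'   multi-million-element model).
#' @param n_seg Circumferential segments; default matches the in-plane edge
#'   length at the periosteal radius.
#' @return List of class `bending_model`: `mesh` (`tet_mesh`), `E`, `nu`
#'   per tet, `length`.
#' @export
build_bending_model <- function(result, length = 150,
                                bone_edge = 1, callus_edge = 0.5,
                                coarse = 1, n_seg = NULL) {
  stopifnot(inherits(result, "healing_result"), coarse > 0)
  hb <- bone_edge * coarse; hc <- callus_edge * coarse
  geom <- result$mesh$geometry
  cs <- .bending_cross_section(geom, length = length,
                               h_bone = hb, h_callus = hc)
  if (is.null(n_seg)) {
    n_seg <- max(12L, round(2 * pi * geom$bone_outer_radius / hc))
  }
  tm <- revolve_mesh(cs, n_seg = n_seg)
  # tet centroids in collapsed (r, z)
  cx <- (tm$nodes[tm$tets[, 1], ] + tm$nodes[tm$tets[, 2], ] +
         tm$nodes[tm$tets[, 3], ] + tm$nodes[tm$tets[, 4], ]) / 4
  rz <- cbind(sqrt(cx[, 1]^2 + cx[, 2]^2), cx[, 3])
  tiss <- result$config$tissues
  E <- rep(tiss$E[tiss$tissue == "lamellar"], nrow(tm$tets))
  nu <- rep(tiss$nu[tiss$tissue == "lamellar"], nrow(tm$tets))
  cal3 <- which(tm$region == "callus")
  cal2 <- result$adjacency$callus_elements
  cent2 <- cbind(result$mesh$rbar[cal2], result$mesh$zbar[cal2])
  vals <- cbind(result$E[cal2], result$nu[cal2])
  if (length(cal3)) {
    mapped <- map_field_nearest(cent2, vals, rz[cal3, , drop = FALSE])
    stopifnot(all(is.finite(mapped)))
    E[cal3] <- mapped[, 1]; nu[cal3] <- mapped[, 2]
  }
  structure(list(mesh = tm, E = E, nu = nu, length = length,
                 n_seg = n_seg, group = result$config$group),
            class = "bending_model")
}

#' @export
print.bending_model <- function(x, ...) {
  cat("<bending_model>", nrow(x$mesh$tets), "tets,", x$n_seg,
      "circumferential segments, length", x$length, "mm\n")
  invisible(x)
}

# vectorised linear-tet stiffness triplets (dofs: node n -> 3n-2, 3n-1, 3n)
.assemble_tets <- function(mesh, E, nu) {
  tets <- mesh$tets
  n <- nrow(mesh$nodes)
  a <- mesh$nodes[tets[, 1], , drop = FALSE]
  u <- mesh$nodes[tets[, 2], , drop = FALSE] - a
  v <- mesh$nodes[tets[, 3], , drop = FALSE] - a
  w <- mesh$nodes[tets[, 4], , drop = FALSE] - a
  det6 <- 6 * mesh$volume
  # gradients of N2..N4 = rows of inv([u v w]^T); N1 = -(N2+N3+N4)
  cross <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                                p[, 3] * q[, 1] - p[, 1] * q[, 3],
                                p[, 1] * q[, 2] - p[, 2] * q[, 1])
  g2 <- cross(v, w) / det6
  g3 <- cross(w, u) / det6
  g4 <- cross(u, v) / det6
  g1 <- -(g2 + g3 + g4)
  bx <- cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1])
  by <- cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2])
  bz <- cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3])
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  Vw <- mesh$volume
  m <- nrow(tets)
  eldof <- matrix(0L, m, 12)
  for (i in 1:4) {
    eldof[, 3 * i - 2] <- 3L * tets[, i] - 2L
    eldof[, 3 * i - 1] <- 3L * tets[, i] - 1L
    eldof[, 3 * i] <- 3L * tets[, i]
  }
  # B rows: exx eyy ezz gxy gyz gzx; column (i, dir)
  Bcol <- function(i, dir) {
    z <- numeric(m)
    switch(dir,
           x = list(bx[, i], z, z, by[, i], z, bz[, i]),
           y = list(z, by[, i], z, bx[, i], bz[, i], z),
           z = list(z, z, bz[, i], z, by[, i], bx[, i]))
  }
  cols <- vector("list", 12)
  k <- 0L
  for (i in 1:4) for (dir in c("x", "y", "z")) {
    k <- k + 1L
    cols[[k]] <- Bcol(i, dir)
  }
  g <- c(2, 2, 2, 1, 1, 1)
  vvec <- lapply(cols, function(cc) cc[[1]] + cc[[2]] + cc[[3]])
  ii <- vector("list", 144); jj <- vector("list", 144); xx <- vector("list", 144)
  k <- 0L
  for (aa in 1:12) {
    ca <- cols[[aa]]
    for (bb in 1:12) {
      cb <- cols[[bb]]
      k <- k + 1L
      s <- numeric(m)
      for (p in 1:6) s <- s + g[p] * ca[[p]] * cb[[p]]
      xx[[k]] <- Vw * (lam * vvec[[aa]] * vvec[[bb]] + mu * s)
      ii[[k]] <- eldof[, aa]; jj[[k]] <- eldof[, bb]
    }
  }
  list(i = unlist(ii), j = unlist(jj), x = unlist(xx), ndof = 3L * n)
}

#' Virtual bending test
#'
#' Applies a pure bending moment through rigid end plates: every node of
#' each end face is rigidly tied (small-rotation rigid body) to a control
#' node on the axis. The distal control node is fixed in 5 degrees of
#' freedom (free: rotation about the bending axis); the proximal control
#' node is additionally free in axial translation. Equal and opposite
#' moments about the transverse x-axis act on the two control nodes.
#' Bending stiffness is the applied moment (converted to N m) divided by
#' the transverse in-plane deflection at the callus node nearest the
#' construct centre.
#'
#' @param model A [build_bending_model()] model, or a bare `tet_mesh` with
#'   `E`/`nu` supplied.
#' @param moment Applied bending moment, N mm.
#' @param E,nu Optional per-tet properties overriding the model's.
#' @param probe_node Optional node index for the deflection probe
#'   (defaults to the callus node nearest the construct centre; for a
#'   homogeneous tube, the node nearest the centre).
#' @return List of class `bending_result`: `stiffness` (N m/mm),
#'   `deflection` (mm, in-plane transverse at the probe), `probe_node`,
#'   `moment` (N mm), `u` (full displacement vector).
#' @export
virtual_bend <- function(model, moment = 1500, E = NULL, nu = NULL,
                         probe_node = NULL) {
  if (inherits(model, "bending_model")) {
    tm <- model$mesh
    if (is.null(E)) E <- model$E
    if (is.null(nu)) nu <- model$nu
  } else {
    tm <- model
    if (is.null(E) || is.null(nu)) stop("E and nu required for a bare mesh")
    if (length(E) == 1) E <- rep(E, nrow(tm$tets))
    if (length(nu) == 1) nu <- rep(nu, nrow(tm$tets))
  }
  zr <- range(tm$nodes[, 3])
  tol <- 1e-8
  distal <- which(abs(tm$nodes[, 3] - zr[1]) < tol)
  proximal <- which(abs(tm$nodes[, 3] - zr[2]) < tol)
  asm <- .assemble_tets(tm, E, nu)
  ndof <- asm$ndof
  n <- nrow(tm$nodes)

  # reduced dofs: free nodes (3 each) + 2 control nodes:
  # distal ctrl: theta_x only; proximal ctrl: u_z and theta_x
  endn <- c(distal, proximal)
  free_nodes <- setdiff(seq_len(n), endn)
  nfree <- length(free_nodes)
  nred <- 3L * nfree + 3L # + distal theta_x, proximal u_z, proximal theta_x
  d_thx <- 3L * nfree + 1L
  p_uz <- 3L * nfree + 2L
  p_thx <- 3L * nfree + 3L

  # transformation triplets: u_full = A u_red
  fi <- c(3L * free_nodes - 2L, 3L * free_nodes - 1L, 3L * free_nodes)
  fj <- c(3L * seq_len(nfree) - 2L, 3L * seq_len(nfree) - 1L,
          3L * seq_len(nfree))
  fx <- rep(1, 3L * nfree)
  # rigid tie, small rotations about x through the control point (0,0,z_end):
  # u_x = 0, u_y = -theta_x * (z - z_c) = 0 at the face, u_z = theta_x * y
  # (face lies at z = z_c, so in-plane stays rigid; u_z tilts the plate)
  ti <- c(3L * distal, 3L * proximal, 3L * proximal)
  tj <- c(rep(d_thx, length(distal)), rep(p_uz, length(proximal)),
          rep(p_thx, length(proximal)))
  tx <- c(tm$nodes[distal, 2], rep(1, length(proximal)),
          tm$nodes[proximal, 2])
  A <- Matrix::sparseMatrix(i = c(fi, ti), j = c(fj, tj), x = c(fx, tx),
                            dims = c(ndof, nred))
  K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                            dims = c(ndof, ndof))
  Kr <- Matrix::forceSymmetric(Matrix::t(A) %*% K %*% A)
  f <- numeric(nred)
  f[p_thx] <- moment
  f[d_thx] <- -moment
  fac <- Matrix::Cholesky(Kr, LDL = FALSE)
  ur <- as.numeric(Matrix::solve(fac, f))
  u <- as.numeric(A %*% ur)

  if (is.null(probe_node)) {
    cal_nodes <- unique(as.vector(tm$tets[tm$region == "callus", ]))
    cand <- if (length(cal_nodes)) cal_nodes else seq_len(n)
    d2 <- rowSums(tm$nodes[cand, , drop = FALSE]^2)
    probe_node <- cand[which.min(d2)]
  }
  defl <- abs(u[3L * probe_node - 1L]) # bending plane: moment about x -> y
  structure(list(stiffness = (moment / 1000) / defl,
                 deflection = defl, probe_node = probe_node,
                 moment = moment, u = u,
                 rotation_distal = ur[d_thx], rotation_proximal = ur[p_thx]),
            class = "bending_result")
}

#' @export
print.bending_result <- function(x, ...) {
  cat(sprintf("<bending_result> M = %.0f N mm, deflection %.4f mm, stiffness %.2f N m/mm\n",
              x$moment, x$deflection, x$stiffness))
  invisible(x)
}
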