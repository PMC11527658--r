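# Meshing of the axisymmetric (r, z) cross-section with linear triangles.
#
# The cortex and the inter-cortical gap are structured grids of right
# triangles; the external callus, whose radial thickness varies with z, is
# built column-by-column and stitched between adjacent columns with a
# two-pointer "zipper" triangulation. Everything is deterministic: node
# ordering depends only on the geometry and the target edge length.

# Structured triangles give edge populations h, h, h*sqrt(2) in roughly equal
# numbers, so the grid spacing is set below the requested mean edge length.
.EDGE_FACTOR <- (2 + sqrt(2)) / 3

.stations <- function(breaks, h) {
  out <- numeric(0)
  for (i in seq_len(length(breaks) - 1)) {
    a <- breaks[i]; b <- breaks[i + 1]
    n <- max(1L, round((b - a) / h))
    s <- seq(a, b, length.out = n + 1)
    out <- c(out, if (i < length(breaks) - 1) s[-length(s)] else s)
  }
  out
}

# structured block on rs x zs -> local nodes + triangles
.block_grid <- function(rs, zs) {
  nr <- length(rs); nz <- length(zs)
  nodes <- cbind(r = rep(rs, times = nz), z = rep(zs, each = nr))
  idx <- function(i, j) (j - 1L) * nr + i
  i <- rep(seq_len(nr - 1), times = nz - 1)
  j <- rep(seq_len(nz - 1), each = nr - 1)
  a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  tris <- rbind(cbind(a, b, c), cbind(a, c, d))
  list(nodes = nodes, triangles = tris)
}

# zipper triangulation of the strip between two radial node chains
.zipper <- function(p_r, z1, q_r, z2) {
  p <- length(p_r); q <- length(q_r)
  tris <- matrix(0L, nrow = (p - 1) + (q - 1), ncol = 3)
  k <- 0L; i <- 1L; j <- 1L
  while (i < p || j < q) {
    adv_p <- if (i < p && j < q) {
      abs(p_r[i + 1L] - q_r[j]) <= abs(q_r[j + 1L] - p_r[i])
    } else i < p
    k <- k + 1L
    if (adv_p) {
      tris[k, ] <- c(i, i + 1L, p + j)            # P_i, P_{i+1}, Q_j
      i <- i + 1L
    } else {
      tris[k, ] <- c(i, p + j + 1L, p + j)        # P_i, Q_{j+1}, Q_j
      j <- j + 1L
    }
  }
  list(
    nodes = rbind(cbind(p_r, z1), cbind(q_r, z2)),
    triangles = tris[seq_len(k), , drop = FALSE]
  )
}

#' Mesh the fracture geometry with linear triangles
#'
#' Produces a conforming triangulation of both bone fragments and the callus
#' domain with a mean element edge length close to `target_edge`
#' (0.35 mm by default). Element regions are labelled `bone_fragment` or
#' `callus`; per-element area, centroid radius and a characteristic length
#' `sqrt(2*area)` (the short-leg length of a right triangle) are precomputed.
#'
#' @param geometry A [fracture_geometry()].
#' @param target_edge Target mean edge length, mm.
#' @return Object of class `axisym_mesh` with fields `nodes` (n x 2, mm),
#'   `triangles` (m x 3 node indices, positively oriented in (r, z)),
#'   `region`, `area` (mm^2), `rbar` (centroid radius, mm), `char_length`
#'   (mm) and `target_edge`.
#' @export
generate_mesh <- function(geometry, target_edge = 0.35) {
  stopifnot(inherits(geometry, "fracture_geometry"), target_edge > 0)
  h <- target_edge / .EDGE_FACTOR
  L2 <- geometry$modelled_length / 2
  c2 <- geometry$callus_length / 2
  g2 <- geometry$gap_width_uncompressed / 2
  ri <- geometry$cortex_inner_radius
  ro <- geometry$bone_outer_radius

  zs <- .stations(c(-L2, -c2, -g2, g2, c2, L2), h)
  nr <- max(2L, round((ro - ri) / h))
  rs <- seq(ri, ro, length.out = nr + 1)

  blocks <- list()
  z_in <- function(a, b) zs[zs >= a - 1e-9 & zs <= b + 1e-9]
  blk <- function(b, region) { b$region <- region; b }
  blocks[[1]] <- blk(.block_grid(rs, z_in(-L2, -g2)), "bone_fragment")
  blocks[[2]] <- blk(.block_grid(rs, z_in(g2, L2)), "bone_fragment")
  blocks[[3]] <- blk(.block_grid(rs, z_in(-g2, g2)), "callus")

  # external callus: one radial chain per z station, zipped column to column
  zc <- z_in(-c2, c2)
  chains <- lapply(zc, function(z) {
    R <- geometry$profile(z)
    if (R - ro < 0.5 * h) return(ro)
    n <- max(1L, round((R - ro) / h))
    seq(ro, R, length.out = n + 1)
  })
  for (i in seq_len(length(zc) - 1)) {
    if (length(chains[[i]]) == 1 && length(chains[[i + 1]]) == 1) next
    blocks[[length(blocks) + 1]] <-
      blk(.zipper(chains[[i]], zc[i], chains[[i + 1]], zc[i + 1]), "callus")
  }

  # concatenate blocks, merge coincident nodes
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
  mesh$target_edge <- target_edge
  mesh$geometry <- geometry
  mesh
}

# orient triangles positively, attach derived element quantities
.finalize_mesh <- function(nodes, tris, region) {
  r <- nodes[, 1]; z <- nodes[, 2]
  sa <- function(t) {
    ((r[t[, 2]] - r[t[, 1]]) * (z[t[, 3]] - z[t[, 1]]) -
     (r[t[, 3]] - r[t[, 1]]) * (z[t[, 2]] - z[t[, 1]])) / 2
  }
  a <- sa(tris)
  flip <- a < 0
  if (any(flip)) {
    tmp <- tris[flip, 2]; tris[flip, 2] <- tris[flip, 3]; tris[flip, 3] <- tmp
    a <- abs(a)
  }
  if (any(a <= 0)) stop("meshing produced a degenerate (zero-area) element")
  colnames(nodes) <- c("r", "z")
  structure(
    list(
      nodes = nodes,
      triangles = tris,
      region = region,
      area = a,
      rbar = (r[tris[, 1]] + r[tris[, 2]] + r[tris[, 3]]) / 3,
      zbar = (z[tris[, 1]] + z[tris[, 2]] + z[tris[, 3]]) / 3,
      char_length = sqrt(2 * a)
    ),
    class = "axisym_mesh"
  )
}

#' Structured mesh of a plain hollow cylinder
#'
#' A tube of cortical wall only (no gap, no callus), mainly used to verify
#' the finite-element solvers against closed-form bar and beam solutions.
#'
#' @param length Axial length, mm; the tube spans z in `[-length/2, length/2]`.
#' @param r_inner,r_outer Wall radii, mm.
#' @param target_edge Target mean element edge length, mm.
#' @return An `axisym_mesh` with all elements labelled `bone_fragment`.
#' @export
tube_mesh <- function(length, r_inner, r_outer, target_edge = 1) {
  stopifnot(length > 0, r_outer > r_inner, r_inner >= 0, target_edge > 0)
  h <- target_edge / .EDGE_FACTOR
  nr <- max(2L, round((r_outer - r_inner) / h))
  rs <- seq(r_inner, r_outer, length.out = nr + 1)
  zs <- .stations(c(-length / 2, length / 2), h)
  b <- .block_grid(rs, zs)
  mesh <- .finalize_mesh(b$nodes, b$triangles, rep("bone_fragment", nrow(b$triangles)))
  mesh$target_edge <- target_edge
  mesh
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat("<axisym_mesh>", nrow(x$nodes), "nodes,", nrow(x$triangles), "triangles\n")
  tab <- table(x$region)
  for (nm in names(tab)) cat(sprintf("  %s: %d elements\n", nm, tab[[nm]]))
  es <- mesh_edge_stats(x)
  cat(sprintf("  mean edge %.3f mm, total area %.1f mm^2\n",
              es["mean"], sum(x$area)))
  invisible(x)
}

#' Edge-length statistics of a triangle mesh
#'
#' @param mesh An `axisym_mesh`.
#' @return Named vector: `mean`, `min`, `max` over unique edges (mm), `n_edges`.
#' @export
mesh_edge_stats <- function(mesh) {
  t <- mesh$triangles
  e <- rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- sqrt(rowSums((mesh$nodes[e[, 1], ] - mesh$nodes[e[, 2], ])^2))
  c(mean = mean(d), min = min(d), max = max(d), n_edges = nrow(e))
}

#' Share-a-node element adjacency
#'
#' For every callus element, the set of elements (callus or bone fragment)
#' sharing at least one node with it. The relation is symmetric and an
#' element is never its own neighbour. Bone-fragment elements are included
#' in the neighbour sets: they seed the ossification front by counting as
#' fully ossified tissue in the controller.
#'
#' @param mesh An `axisym_mesh`.
#' @return Object of class `neighbor_map`: list with `callus_elements`
#'   (global element indices) and `neighbors` (parallel list of global
#'   element index vectors).
#' @export
build_adjacency <- function(mesh) {
  tris <- mesh$triangles
  m <- nrow(tris)
  node_elems <- split(rep(seq_len(m), times = 3), as.vector(tris))
  callus <- which(mesh$region == "callus")
  nbrs <- lapply(callus, function(e) {
    ids <- unlist(node_elems[as.character(tris[e, ])], use.names = FALSE)
    sort(unique(ids[ids != e]))
  })
  structure(list(callus_elements = callus, neighbors = nbrs),
            class = "neighbor_map")
}

#' @export
print.neighbor_map <- function(x, ...) {
  cat("<neighbor_map>", length(x$callus_elements), "callus elements, mean",
      sprintf("%.1f", mean(lengths(x$neighbors))), "neighbours\n")
  invisible(x)
}
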