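#' Fixation-group presets
#'
#' The six fracture cases simulated by the model: all combinations of
#' compressed-state gap widths 1, 2 and 6 mm with allowed inter-fragmentary
#' strains (IFS) of 7% and 31%, as used in the ovine metatarsal osteotomy
#' experiments the model is compared against.
#'
#' @format A data frame with columns `group`, `gap_width` (mm, compressed
#'   state) and `ifs` (dimensionless fraction).
#' @export
group_presets <- function() {
  data.frame(
    group     = c("A", "B", "C", "D", "E", "F"),
    gap_width = c(1, 1, 2, 2, 6, 6),
    ifs       = c(0.07, 0.31, 0.07, 0.31, 0.07, 0.31),
    stringsAsFactors = FALSE
  )
}

#' Derive the geometry parameters of a fixation group
#'
#' The gap widths of the experimental groups are reported in the loaded
#' (compressed) state; the unloaded model must be built with the gap scaled
#' up by the allowed inter-fragmentary strain, and the fixator's free axial
#' travel equals the movement permitted before the fixator re-engages:
#' \deqn{GW_{unc} = GW_{comp} (1 + IFS), \qquad s_{free} = GW_{comp} \cdot IFS.}
#'
#' @param group Preset letter `"A"`..`"F"` (see [group_presets()]), or `NULL`
#'   to supply raw parameters.
#' @param gap_width Compressed-state gap width, mm (> 0). Ignored when a
#'   preset is given.
#' @param ifs Allowed inter-fragmentary strain, dimensionless in [0, 1).
#' @return An object of class `group_config` with fields
#'   `gap_width_compressed`, `ifs_allowed`, `gap_width_uncompressed`,
#'   `free_travel` and `group`.
#' @examples
#' group_config("B")$gap_width_uncompressed  # 1.31 mm
#' group_config(gap_width = 6, ifs = 0.31)$free_travel  # 1.86 mm
#' @export
group_config <- function(group = NULL, gap_width = NULL, ifs = NULL) {
  if (!is.null(group)) {
    presets <- group_presets()
    i <- match(toupper(group), presets$group)
    if (is.na(i)) {
      stop("unknown group '", group, "'; expected one of ",
           paste(presets$group, collapse = ", "))
    }
    gap_width <- presets$gap_width[i]
    ifs <- presets$ifs[i]
  } else {
    if (is.null(gap_width) || is.null(ifs)) {
      stop("either a group preset or both gap_width and ifs must be given")
    }
  }
  if (!is.numeric(gap_width) || length(gap_width) != 1L || gap_width <= 0) {
    stop("gap_width must be a single positive number (mm)")
  }
  if (!is.numeric(ifs) || length(ifs) != 1L || ifs < 0 || ifs >= 1) {
    stop("ifs must be a single number in [0, 1)")
  }
  structure(
    list(
      group = if (is.null(group)) NA_character_ else toupper(group),
      gap_width_compressed = gap_width,
      ifs_allowed = ifs,
      gap_width_uncompressed = gap_width * (1 + ifs),
      free_travel = gap_width * ifs
    ),
    class = "group_config"
  )
}

#' @export
print.group_config <- function(x, ...) {
  cat("<group_config>",
      if (!is.na(x$group)) paste0("group ", x$group) else "custom", "\n")
  cat(sprintf("  gap width (compressed):   %.3f mm\n", x$gap_width_compressed))
  cat(sprintf("  allowed IFS:              %.0f%%\n", 100 * x$ifs_allowed))
  cat(sprintf("  gap width (uncompressed): %.3f mm\n", x$gap_width_uncompressed))
  cat(sprintf("  fixator free travel:      %.3f mm\n", x$free_travel))
  invisible(x)
}

#' Parametric fracture + callus geometry
#'
#' Builds the axisymmetric geometry of a transverse mid-diaphyseal osteotomy:
#' two hollow-cylinder bone fragments (outer radius 8 mm, cortex 2 mm) over a
#' modelled length of 80 mm, separated by the uncompressed gap, surrounded by
#' a standardised callus domain of maximal radius 24 mm and axial length
#' 52 mm that tapers onto the periosteal surface. The outer callus profile is
#' a cosine arc by default and may be overridden with any function
#' `R(z)` satisfying `R(+-callus_length/2) = bone_outer_radius` and
#' `R(0) = callus_radius`.
#'
#' @param config A [group_config()] (or a group letter, passed through).
#' @param bone_outer_radius Outer cortex radius, mm.
#' @param cortex_thickness Cortical wall thickness, mm.
#' @param modelled_length Total modelled construct length, mm.
#' @param callus_radius Maximal callus radius, mm.
#' @param callus_length Axial extent of the callus domain, mm.
#' @param profile Optional function `z -> outer callus radius` (mm).
#' @return Object of class `fracture_geometry`.
#' @export
fracture_geometry <- function(config,
                              bone_outer_radius = 8,
                              cortex_thickness = 2,
                              modelled_length = 80,
                              callus_radius = 24,
                              callus_length = 52,
                              profile = NULL) {
  if (is.character(config)) config <- group_config(config)
  stopifnot(inherits(config, "group_config"))
  gwu <- config$gap_width_uncompressed
  if (bone_outer_radius <= 0 || cortex_thickness <= 0 ||
      cortex_thickness >= bone_outer_radius) {
    stop("invalid cortex dimensions")
  }
  if (callus_length <= gwu) stop("callus_length must exceed the uncompressed gap")
  if (modelled_length <= callus_length) {
    stop("modelled_length must exceed callus_length")
  }
  if (callus_radius <= bone_outer_radius) {
    stop("callus_radius must exceed bone_outer_radius")
  }
  if (is.null(profile)) {
    r0 <- bone_outer_radius
    dr <- callus_radius - r0
    cl <- callus_length
    profile <- function(z) r0 + dr * cos(pi * z / cl)
  }
  geom <- structure(
    list(
      config = config,
      bone_outer_radius = bone_outer_radius,
      cortex_inner_radius = bone_outer_radius - cortex_thickness,
      cortex_thickness = cortex_thickness,
      modelled_length = modelled_length,
      callus_radius = callus_radius,
      callus_length = callus_length,
      gap_width_uncompressed = gwu,
      profile = profile
    ),
    class = "fracture_geometry"
  )
  # sanity: profile attaches to the periosteum at the callus ends
  ends <- profile(c(-callus_length / 2, 0, callus_length / 2))
  if (abs(ends[1] - bone_outer_radius) > 1e-6 ||
      abs(ends[3] - bone_outer_radius) > 1e-6) {
    stop("callus profile must equal bone_outer_radius at z = +-callus_length/2")
  }
  if (ends[2] > callus_radius + 1e-6) stop("callus profile exceeds callus_radius")
  geom
}

#' @export
print.fracture_geometry <- function(x, ...) {
  cat("<fracture_geometry>\n")
  cat(sprintf("  cortex: r %.1f-%.1f mm, construct length %.0f mm\n",
              x$cortex_inner_radius, x$bone_outer_radius, x$modelled_length))
  cat(sprintf("  callus: max radius %.0f mm, length %.0f mm\n",
              x$callus_radius, x$callus_length))
  cat(sprintf("  uncompressed gap: %.3f mm\n", x$gap_width_uncompressed))
  invisible(x)
}

#' Closed outline polyline of the callus domain
#'
#' The callus region is the union of the inter-cortical gap annulus
#' (between the fragment cut faces, across the cortex wall) and the external
#' callus between the periosteal surface and the outer profile. Its boundary
#' is returned as a simple closed polyline in (r, z), traversed
#' counter-clockwise, suitable for analytic area checks.
#'
#' @param geometry A [fracture_geometry()].
#' @param n Number of profile sampling intervals.
#' @return A closed two-column matrix (r, z); first row equals last row.
#' @export
callus_outline <- function(geometry, n = 200) {
  g2 <- geometry$gap_width_uncompressed / 2
  c2 <- geometry$callus_length / 2
  ri <- geometry$cortex_inner_radius
  ro <- geometry$bone_outer_radius
  zp <- seq(-c2, c2, length.out = n + 1)
  rp <- geometry$profile(zp)
  # CCW in (r, z): inner gap wall up is replaced by going around the domain:
  # (ri,-g2) -> (ro,-g2) -> (ro,-c2) -> profile -> (ro,c2) -> (ro,g2) -> (ri,g2) -> close
  pts <- rbind(
    c(ri, -g2),
    c(ro, -g2),
    c(ro, -c2),
    cbind(rp, zp),
    c(ro, c2),
    c(ro, g2),
    c(ri, g2)
  )
  pts <- pts[!duplicated(round(pts, 9)), , drop = FALSE]
  pts <- rbind(pts, pts[1, ])
  colnames(pts) <- c("r", "z")
  # orientation: traversal above runs along z increasing at large r -> CCW in
  # (r,z) requires positive shoelace area; flip if needed
  if (polygon_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
  pts
}

#' Shoelace area of a closed polyline
#'
#' @param poly Two-column matrix; first and last rows may coincide.
#' @return Signed area (positive for counter-clockwise traversal).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  m <- length(x)
  if (x[1] == x[m] && y[1] == y[m]) { x <- x[-m]; y <- y[-m]; m <- m - 1 }
  j <- c(m, seq_len(m - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Analytic areas of the geometry regions
#'
#' Cross-section (r, z) areas of the two bone fragments and the callus
#' domain, the latter via the shoelace formula on a finely sampled outline.
#'
#' @param geometry A [fracture_geometry()].
#' @param n Profile sampling intervals for the callus outline.
#' @return Named numeric vector, mm^2: `bone_fragment`, `callus`.
#' @export
region_areas <- function(geometry, n = 4000) {
  g2 <- geometry$gap_width_uncompressed / 2
  frag <- 2 * geometry$cortex_thickness * (geometry$modelled_length / 2 - g2)
  cal <- abs(polygon_area(callus_outline(geometry, n = n)))
  c(bone_fragment = frag, callus = cal)
}
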