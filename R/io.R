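# Export and configuration plumbing: legacy-VTK writers for meshes and
# fields, CSV histories, YAML round-tripping of the controller defaults.

#' Write an unstructured mesh with fields as a legacy VTK file
#'
#' Supports both `axisym_mesh` (triangles, written as z = 0 planar cells)
#' and `tet_mesh` objects. Cell data (one value per element) and point data
#' (one per node) are written as scalar fields.
#'
#' @param mesh An `axisym_mesh` or `tet_mesh`.
#' @param file Output path (`.vtk`).
#' @param cell_data Named list of per-element numeric vectors.
#' @param point_data Named list of per-node numeric vectors.
#' @return The file path, invisibly.
#' @export
write_vtk <- function(mesh, file, cell_data = list(), point_data = list()) {
  if (inherits(mesh, "axisym_mesh")) {
    pts <- cbind(mesh$nodes[, 1], mesh$nodes[, 2], 0)
    cells <- mesh$triangles
    ctype <- 5L # VTK_TRIANGLE
  } else if (inherits(mesh, "tet_mesh")) {
    pts <- mesh$nodes
    cells <- mesh$tets
    ctype <- 10L # VTK_TETRA
  } else {
    stop("unsupported mesh class")
  }
  n <- nrow(pts); m <- nrow(cells); k <- ncol(cells)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "callusim export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(pts, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, m * (k + 1)), con)
  utils::write.table(cbind(k, cells - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(ctype, m)), con)
  wr_fields <- function(fields, nvals, heading) {
    if (!length(fields)) return(invisible())
    writeLines(sprintf("%s %d", heading, nvals), con)
    for (nm in names(fields)) {
      v <- fields[[nm]]
      if (is.character(v) || is.factor(v)) v <- as.integer(factor(v))
      stopifnot(length(v) == nvals)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(v, digits = 10, trim = TRUE), con)
    }
  }
  wr_fields(cell_data, m, "CELL_DATA")
  wr_fields(point_data, n, "POINT_DATA")
  invisible(file)
}

#' Write the IFM history of a healing run as CSV
#'
#' @param result A [run_healing()] result.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_ifm_csv <- function(result, file) {
  cv <- result$convergence_iteration
  df <- data.frame(
    iteration = seq_along(result$ifm),
    ifm_mm = result$ifm,
    converged = if (is.na(cv)) FALSE else seq_along(result$ifm) >= cv
  )
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Controller and scenario defaults as a plain list
#'
#' The complete default parameter set: group presets, tissue constants,
#' membership functions, rule table, controller rates, spring and load.
#' Serialisable to YAML via [dump_defaults()].
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    groups = group_presets(),
    load_N = 500,
    iterations = 150,
    target_edge_mm = 0.35,
    kappa = formals(healing_config)$kappa,
    n_smooth = 5,
    chondro_delay = 7,
    ref_length_mm = 0.35,
    spring = list(k_stiff = 4600, k_free = 10, transition_force = 100),
    tissues = tissue_properties(),
    membership = membership_defaults(),
    rules = rule_table_default(),
    bending = list(length_mm = 150, bone_edge_mm = 1, callus_edge_mm = 0.5,
                   moment_Nmm = 1500)
  )
}

#' Dump the shipped defaults to a YAML file
#'
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
dump_defaults <- function(file = "callusim-defaults.yaml") {
  cfg <- default_config()
  cfg$groups <- as.list(cfg$groups)
  cfg$tissues <- as.list(cfg$tissues)
  cfg$kappa <- eval(cfg$kappa)
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' Read a YAML config written by [dump_defaults()]
#'
#' @param file Path to a YAML config.
#' @return Nested list.
#' @export
read_config <- function(file) {
  yaml::read_yaml(file)
}

#' Run the full six-group campaign
#'
#' Runs [run_healing()] for each requested group with shared parameter
#' overrides and returns a summary table (plus the result objects).
#'
#' @param groups Group letters.
#' @param ... Passed to [healing_config()].
#' @param quiet Suppress per-group progress.
#' @return List with `summary` (data frame: group, gap width, IFS,
#'   initial/final IFM, convergence iteration) and `results`.
#' @export
run_campaign <- function(groups = c("A", "B", "C", "D", "E", "F"), ...,
                         quiet = TRUE) {
  results <- list()
  rows <- list()
  for (g in groups) {
    cfg <- healing_config(group = g, ...)
    res <- run_healing(cfg, quiet = quiet)
    results[[g]] <- res
    rows[[g]] <- data.frame(
      group = g,
      gap_width = cfg$group$gap_width_compressed,
      ifs = cfg$group$ifs_allowed,
      ifm_initial = res$ifm[1],
      ifm_final = res$ifm[length(res$ifm)],
      converged = res$converged,
      convergence_iteration = res$convergence_iteration
    )
  }
  list(summary = do.call(rbind, rows), results = results)
}
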