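# Shared fixtures and independent oracles, all built in code.

# nodes on the boundary of a triangle mesh (edges used by exactly one element)
boundary_nodes <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(key) == 1))
  unique(as.vector(e[key %in% once, ]))
}

# O(n^2) brute-force share-a-node adjacency oracle
brute_adjacency <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  sets <- lapply(seq_len(m), function(e) tr[e, ])
  callus <- which(mesh$region == "callus")
  nbrs <- lapply(callus, function(e) {
    hits <- vapply(seq_len(m), function(o) {
      o != e && length(intersect(sets[[e]], sets[[o]])) > 0
    }, logical(1))
    which(hits)
  })
  list(callus_elements = callus, neighbors = nbrs)
}

# scalar, loop-everything rule-activation oracle with its own trapezoid code
oracle_trap <- function(x, p) {
  if (x < p[1] || x > p[4]) return(0)
  if (x >= p[2] && x <= p[3]) return(1)
  if (x < p[2]) return((x - p[1]) / (p[2] - p[1]))
  (p[4] - x) / (p[4] - p[3])
}
oracle_activation <- function(rule, inputs_row, mfs) {
  fam <- c(bone = "tissue", cart = "tissue", nbone = "tissue",
           ncart = "tissue", eps_min = "eps_min", eps_max = "eps_max",
           eps_dist = "eps_dist")
  act <- 1
  for (var in names(rule$clauses)) {
    cats <- rule$clauses[[var]]
    best <- 0
    for (cat in cats) {
      best <- max(best, oracle_trap(inputs_row[[var]], mfs[[fam[[var]]]][[cat]]))
    }
    act <- min(act, best)
  }
  act
}

# a small fracture mesh reused by several files
coarse_mesh <- function(group = "B", edge = 2.5) {
  generate_mesh(fracture_geometry(group_config(group)), target_edge = edge)
}

# desk-scale healing configuration
coarse_config <- function(group = "A", edge = 1.2, iterations = 40,
                          snapshot_every = 0, ...) {
  healing_config(group = group, target_edge = edge, iterations = iterations,
                 snapshot_every = snapshot_every, ...)
}
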