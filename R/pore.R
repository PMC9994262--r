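# Pore bottleneck estimation: the widest passage between two points
# through an atomic wall, reported as the diameter of the smallest sphere
# that fits along the best route (a grid max-min optimisation; a
# functional stand-in for Voronoi-diagram tunnel tools, validated on
# analytic scenes).

# a small published vdW radii set (Bondi 1964 values, A)
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Van der Waals radii table
#'
#' Bondi-style radii for the elements the shell models contain.
#'
#' @param element Character vector of element symbols.
#' @return Radii in Angstrom (1.7 for unknown elements).
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Construct a pore scene
#'
#' @param centers Numeric matrix (n x 3) of atom centres, Angstrom.
#' @param radii Per-atom van der Waals radii, Angstrom (> 0).
#' @param start,end Endpoints of the passage (3-vectors); must lie outside
#'   all atom spheres.
#' @param bbox Optional 2 x 3 matrix (rows = lower, upper corner); default
#'   is the atom bounding box inflated by 2 A, expanded to include the
#'   endpoints.
#' @return An object of class `pore_scene`.
#' @export
pore_scene <- function(centers, radii, start, end, bbox = NULL) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3L, length(radii) == nrow(centers),
            length(start) == 3L, length(end) == 3L)
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  clr <- function(p) {
    if (!nrow(centers)) return(Inf)
    min(sqrt(colSums((t(centers) - p)^2)) - radii)
  }
  if (clr(start) <= 0 || clr(end) <= 0)
    stop("start/end point lies inside an atom sphere", call. = FALSE)
  if (is.null(bbox)) {
    lo <- pmin(apply(centers, 2, min) - 2, pmin(start, end) - 1)
    hi <- pmax(apply(centers, 2, max) + 2, pmax(start, end) + 1)
    bbox <- rbind(lo, hi)
  }
  bbox <- as.matrix(bbox)
  structure(list(centers = centers, radii = radii,
                 start = as.numeric(start), end = as.numeric(end),
                 bbox = bbox),
            class = "pore_scene")
}

#' @export
print.pore_scene <- function(x, ...) {
  cat(sprintf("Pore scene: %d atoms, box %.1f x %.1f x %.1f A\n",
              nrow(x$centers), diff(x$bbox[, 1]), diff(x$bbox[, 2]),
              diff(x$bbox[, 3])))
  invisible(x)
}

#' Read a pore scene from a delimited atom table
#'
#' Whitespace/tab-delimited columns `x y z element` or `x y z radius`.
#'
#' @param path File path.
#' @param start,end Passage endpoints.
#' @return A [pore_scene()].
#' @export
read_pore_scene <- function(path, start, end) {
  tab <- utils::read.table(path, header = TRUE)
  r <- if ("radius" %in% names(tab)) tab$radius else vdw_radius(tab$element)
  pore_scene(as.matrix(tab[, c("x", "y", "z")]), r, start, end)
}

# grid node coordinates and clearance values for a scene; axes are centred
# on the box midpoint so symmetric scenes have nodes on their symmetry
# planes (improves agreement with analytic bottlenecks)
scene_grid <- function(scene, spacing) {
  axis_nodes <- function(lo, hi) {
    mid <- (lo + hi) / 2
    n <- floor((hi - lo) / 2 / spacing)
    mid + (-n:n) * spacing
  }
  gx <- axis_nodes(scene$bbox[1, 1], scene$bbox[2, 1])
  gy <- axis_nodes(scene$bbox[1, 2], scene$bbox[2, 2])
  gz <- axis_nodes(scene$bbox[1, 3], scene$bbox[2, 3])
  if (length(gx) < 2 || length(gy) < 2 || length(gz) < 2)
    stop("grid too coarse for the scene box", call. = FALSE)
  list(gx = gx, gy = gy, gz = gz, dim = c(length(gx), length(gy), length(gz)))
}

#' Clearance field of a pore scene on a regular grid
#'
#' At each grid node, the clearance is the distance to the nearest atom
#' surface: `min over atoms (|node - centre| - radius)`; negative inside
#' an atom.
#'
#' @param scene A [pore_scene()].
#' @param spacing Grid spacing in Angstrom (default 0.25).
#' @return A list with the grid axes (`gx`, `gy`, `gz`) and a 3D array
#'   `clearance`.
#' @export
clearance_field <- function(scene, spacing = 0.25) {
  stopifnot(inherits(scene, "pore_scene"), spacing > 0)
  g <- scene_grid(scene, spacing)
  nodes <- as.matrix(expand.grid(x = g$gx, y = g$gy, z = g$gz))
  if (nrow(scene$centers) == 0L) {
    clr <- rep(sqrt(sum((scene$bbox[2, ] - scene$bbox[1, ])^2)), nrow(nodes))
  } else {
    clr <- rep(Inf, nrow(nodes))
    for (a in seq_len(nrow(scene$centers))) {
      d <- sqrt((nodes[, 1] - scene$centers[a, 1])^2 +
                (nodes[, 2] - scene$centers[a, 2])^2 +
                (nodes[, 3] - scene$centers[a, 3])^2) - scene$radii[a]
      clr <- pmin(clr, d)
    }
  }
  list(gx = g$gx, gy = g$gy, gz = g$gz,
       clearance = array(clr, dim = g$dim))
}

# nearest grid node index (1-based linear) for a point
nearest_node <- function(field, p) {
  i <- which.min(abs(field$gx - p[1]))
  j <- which.min(abs(field$gy - p[2]))
  k <- which.min(abs(field$gz - p[3]))
  c(i, j, k)
}

# 26-neighbour offsets
neighbor_offsets <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
}

# flood fill over nodes with clearance >= thr from a start node; returns
# logical array of reached nodes (vectorised BFS over the 26 offsets)
flood_reach <- function(clr, thr, start_ijk) {
  d <- dim(clr)
  open <- clr >= thr
  if (!open[start_ijk[1], start_ijk[2], start_ijk[3]]) return(array(FALSE, d))
  reach <- array(FALSE, d)
  reach[start_ijk[1], start_ijk[2], start_ijk[3]] <- TRUE
  offs <- neighbor_offsets()
  frontier <- matrix(start_ijk, nrow = 1)
  while (nrow(frontier)) {
    nxt <- NULL
    for (oi in seq_len(nrow(offs))) {
      cand <- sweep(frontier, 2, offs[oi, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1) + d[1] * d[2] * (cand[, 3] - 1)
      new <- open[lin] & !reach[lin]
      if (any(new)) {
        reach[lin[new]] <- TRUE
        nxt <- rbind(nxt, cand[new, , drop = FALSE])
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else unique(nxt)
  }
  reach
}

#' Widest path through a pore scene
#'
#' Max-min optimisation on the clearance grid: among all 26-connected
#' paths from start to end, the one maximising the minimum clearance. The
#' bottleneck diameter is twice that minimum -- the diameter of the
#' smallest sphere that must squeeze through on the best route. The
#' implementation binary-searches the connectivity threshold over the
#' sorted node clearances, which yields the same optimum as priority-first
#' search and is deterministic for a fixed grid.
#'
#' @param scene A [pore_scene()].
#' @param spacing Grid spacing in Angstrom (default 0.25).
#' @return An object of class `tunnel_result`: `path` (matrix of node
#'   coordinates), `clearance` (along the path), `bottleneck` (Angstrom).
#' @export
widest_path <- function(scene, spacing = 0.25) {
  stopifnot(inherits(scene, "pore_scene"))
  field <- clearance_field(scene, spacing)
  clr <- field$clearance
  s <- nearest_node(field, scene$start)
  e <- nearest_node(field, scene$end)
  cs <- clr[s[1], s[2], s[3]]; ce <- clr[e[1], e[2], e[3]]
  if (cs <= 0 || ce <= 0)
    stop("grid too coarse: start/end node has non-positive clearance",
         call. = FALSE)
  if (all(s == e)) {
    p <- matrix(c(field$gx[s[1]], field$gy[s[2]], field$gz[s[3]]), 1)
    return(structure(list(path = p, clearance = cs, bottleneck = 2 * cs),
                     class = "tunnel_result"))
  }
  # binary search the bottleneck threshold over sorted node clearances
  lv <- sort(unique(as.numeric(clr[clr > 0 & clr <= min(cs, ce)])))
  lo <- 1L; hi <- length(lv); best <- NA_integer_
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    reach <- flood_reach(clr, lv[mid], s)
    if (reach[e[1], e[2], e[3]]) { best <- mid; lo <- mid + 1L }
    else hi <- mid - 1L
  }
  if (is.na(best))
    stop("start and end are not connected by a positive-clearance path",
         call. = FALSE)
  thr <- lv[best]
  # extract one realising path: BFS on the >= thr subgraph
  path <- bfs_path(clr, thr, s, e)
  pc <- apply(path, 1, function(n) clr[n[1], n[2], n[3]])
  coords <- cbind(field$gx[path[, 1]], field$gy[path[, 2]], field$gz[path[, 3]])
  structure(list(path = coords, clearance = pc, bottleneck = 2 * thr),
            class = "tunnel_result")
}

# shortest (fewest-steps) path on the >= thr subgraph via BFS with parents
bfs_path <- function(clr, thr, s, e) {
  d <- dim(clr)
  lin <- function(m) m[, 1] + d[1] * (m[, 2] - 1) + d[1] * d[2] * (m[, 3] - 1)
  open <- clr >= thr
  parent <- integer(prod(d))
  sl <- lin(matrix(s, 1)); el <- lin(matrix(e, 1))
  parent[sl] <- -1L
  offs <- neighbor_offsets()
  frontier <- matrix(s, nrow = 1)
  while (nrow(frontier) && parent[el] == 0L) {
    nxt <- NULL
    fl <- lin(frontier)
    for (oi in seq_len(nrow(offs))) {
      cand <- sweep(frontier, 2, offs[oi, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      if (!any(ok)) next
      cand <- cand[ok, , drop = FALSE]
      cl <- lin(cand)
      new <- open[cl] & parent[cl] == 0L
      if (any(new)) {
        parent[cl[new]] <- fl[ok][new]
        nxt <- rbind(nxt, cand[new, , drop = FALSE])
      }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else unique(nxt)
  }
  if (parent[el] == 0L) stop("path extraction failed", call. = FALSE)
  # walk back
  unlin <- function(l) {
    l0 <- l - 1
    c(l0 %% d[1] + 1, (l0 %/% d[1]) %% d[2] + 1, l0 %/% (d[1] * d[2]) + 1)
  }
  nodes <- list(); cur <- el
  while (cur != -1L) {
    nodes[[length(nodes) + 1L]] <- unlin(cur)
    cur <- parent[cur]
  }
  do.call(rbind, rev(nodes))
}

#' @export
print.tunnel_result <- function(x, ...) {
  cat(sprintf("Tunnel: %d path nodes, bottleneck diameter %.3f A\n",
              nrow(x$path), x$bottleneck))
  invisible(x)
}

#' Survey several routes through a slit
#'
#' Runs [widest_path()] independently for each start/end pair and reports
#' the per-route bottlenecks with a min/max summary.
#'
#' @param scene A [pore_scene()] (its own start/end are ignored).
#' @param pairs List of `list(start =, end =)` pairs (k >= 1).
#' @param spacing Grid spacing in Angstrom (default 0.25).
#' @return A list with `results` (list of `tunnel_result`), `bottlenecks`
#'   (sorted ascending) and `range` (min, max).
#' @export
slit_survey <- function(scene, pairs, spacing = 0.25) {
  stopifnot(inherits(scene, "pore_scene"), length(pairs) >= 1)
  results <- lapply(pairs, function(pr) {
    sc <- pore_scene(scene$centers, scene$radii, pr$start, pr$end,
                     bbox = scene$bbox)
    widest_path(sc, spacing)
  })
  b <- vapply(results, function(r) r$bottleneck, numeric(1))
  list(results = results, bottlenecks = sort(b), range = range(b))
}
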