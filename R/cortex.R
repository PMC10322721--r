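#' Toy cortical surface with parcellation and network labels
#'
#' Builds a closed triangulated sphere (a subdivided icosahedron), grows
#' `n_areas` spatially contiguous parcels on it by round-robin breadth-first
#' expansion from farthest-point-sampled seed vertices (a geodesic Voronoi
#' construction), and overlays a coarser 7-network labelling built the same
#' way. The sphere stands in for a cortical hemisphere: it is boundary-free,
#' so parcel geometry has no edge artifacts.
#'
#' @param n_areas Number of cortical areas (parcels), at least 8.
#' @param mesh_resolution Icosphere subdivision level; the mesh has
#'   `10 * 4^mesh_resolution + 2` vertices. The resolution must provide at
#'   least 20 vertices per requested area.
#' @param seed Integer seed; the construction is a pure function of
#'   `(n_areas, mesh_resolution, seed)`.
#' @param radius Sphere radius in mm (default 30, desk-scale hemisphere).
#'
#' @return An object of class `toy_cortex`: a list with `vertices` (V x 3
#'   matrix, mm), `triangles` (T x 3 integer matrix, 1-based),
#'   `parcel_labels` (length-V integer vector in `1:n_areas`),
#'   `network_labels` (length-V integer in `1:7`, named via
#'   `network_names`), `vertex_areas` (mm^2, barycentric-lumped triangle
#'   areas), `parcel_centroids` (`n_areas` x 3, vertex-area-weighted), and
#'   `area_ids` (character ids `"A001"...`).
#' @examples
#' cx <- generate_toy_cortex(n_areas = 8, mesh_resolution = 2, seed = 1)
#' table(cx$parcel_labels)
#' @export
generate_toy_cortex <- function(n_areas, mesh_resolution, seed, radius = 30) {
  stopifnot(n_areas >= 8, mesh_resolution >= 0)
  mesh <- icosphere(mesh_resolution, radius = radius)
  nv <- nrow(mesh$vertices)
  if (nv < 20L * n_areas) {
    stop("mesh_resolution ", mesh_resolution, " yields ", nv,
         " vertices; need at least 20 per area (", 20L * n_areas,
         " for ", n_areas, " areas)")
  }
  adj <- mesh_adjacency(mesh$triangles, nv)
  varea <- vertex_areas(mesh$vertices, mesh$triangles)

  withr_seed(seed, {
    parcel <- grow_parcels(mesh$vertices, adj, n_areas)
  })
  withr_seed(derive_seed(seed, 1L), {
    network <- grow_parcels(mesh$vertices, adj, 7L)
  })

  area_ids <- sprintf("A%03d", seq_len(n_areas))
  centroids <- parcel_centroids(mesh$vertices, parcel, varea, n_areas)
  rownames(centroids) <- area_ids

  structure(
    list(
      vertices = mesh$vertices,
      triangles = mesh$triangles,
      parcel_labels = parcel,
      network_labels = network,
      network_names = c("visual", "somatomotor", "dorsal_attention",
                        "salience", "limbic", "frontoparietal",
                        "default_mode"),
      vertex_areas = varea,
      parcel_centroids = centroids,
      area_ids = area_ids,
      seed = seed
    ),
    class = "toy_cortex"
  )
}

#' @export
print.toy_cortex <- function(x, ...) {
  cat("<toy_cortex> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, ",
      length(x$area_ids), " areas, 7 networks\n", sep = "")
  invisible(x)
}

#' Pairwise centroid distance matrix for a parcellation
#'
#' Euclidean distances (mm) between parcel centroids; symmetric with a zero
#' diagonal. This is the distance structure the variogram-matched surrogate
#' generator consumes.
#'
#' @param cortex A [generate_toy_cortex()] object, or a numeric matrix of
#'   centroid coordinates (rows = areas).
#' @return A symmetric A x A matrix with `dimnames` set to area ids.
#' @export
distance_matrix <- function(cortex) {
  cent <- if (inherits(cortex, "toy_cortex")) cortex$parcel_centroids
          else as.matrix(cortex)
  d <- as.matrix(stats::dist(cent))
  dimnames(d) <- list(rownames(cent), rownames(cent))
  d
}

## ---- internal mesh machinery -------------------------------------------

# Subdivided icosahedron, vertices pushed to the sphere of given radius.
icosphere <- function(level, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  tri <- rbind(
    c(1, 12, 6),  c(1, 6, 2),   c(1, 2, 8),   c(1, 8, 11),  c(1, 11, 12),
    c(2, 6, 10),  c(6, 12, 5),  c(12, 11, 3), c(11, 8, 7),  c(8, 2, 9),
    c(4, 10, 5),  c(4, 5, 3),   c(4, 3, 7),   c(4, 7, 9),   c(4, 9, 10),
    c(5, 10, 6),  c(3, 5, 12),  c(7, 3, 11),  c(9, 7, 8),   c(10, 9, 2)
  )
  for (i in seq_len(level)) {
    res <- subdivide(v, tri)
    v <- res$v
    tri <- res$tri
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  list(vertices = v, triangles = tri)
}

subdivide <- function(v, tri) {
  edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  midpoints <- new.env(hash = TRUE)
  verts <- v
  get_mid <- function(a, b) {
    k <- edge_key(a, b)
    idx <- midpoints[[k]]
    if (is.null(idx)) {
      verts <<- rbind(verts, (v[a, ] + v[b, ]) / 2)
      idx <- nrow(verts)
      midpoints[[k]] <- idx
    }
    idx
  }
  out <- matrix(0L, nrow = 4L * nrow(tri), ncol = 3)
  for (t in seq_len(nrow(tri))) {
    a <- tri[t, 1]; b <- tri[t, 2]; c <- tri[t, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
    out[4 * t - 3, ] <- c(a, ab, ca)
    out[4 * t - 2, ] <- c(b, bc, ab)
    out[4 * t - 1, ] <- c(c, ca, bc)
    out[4 * t, ] <- c(ab, bc, ca)
  }
  list(v = verts, tri = out)
}

mesh_adjacency <- function(tri, nv) {
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  edges <- rbind(edges, edges[, c(2, 1)])
  edges <- unique(edges)
  split(edges[, 2], factor(edges[, 1], levels = seq_len(nv)))
}

# One third of each incident triangle's area per vertex (barycentric lumping).
vertex_areas <- function(v, tri) {
  e1 <- v[tri[, 2], ] - v[tri[, 1], ]
  e2 <- v[tri[, 3], ] - v[tri[, 1], ]
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  ta <- sqrt(rowSums(cr^2)) / 2
  va <- numeric(nrow(v))
  for (j in 1:3) {
    acc <- tapply(ta, tri[, j], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc / 3
  }
  va
}

# Farthest-point seed sampling then simultaneous BFS: contiguous, roughly
# balanced geodesic-Voronoi parcels. Uses the RNG for the first seed vertex.
grow_parcels <- function(v, adj, k) {
  nv <- nrow(v)
  seeds <- integer(k)
  seeds[1] <- sample.int(nv, 1)
  dmin <- sqrt(colSums((t(v) - v[seeds[1], ])^2))
  if (k > 1) {
    for (i in 2:k) {
      seeds[i] <- which.max(dmin)
      dmin <- pmin(dmin, sqrt(colSums((t(v) - v[seeds[i], ])^2)))
    }
  }
  label <- integer(nv)
  label[seeds] <- seq_len(k)
  frontier <- as.list(seeds)
  while (any(label == 0L)) {
    progressed <- FALSE
    for (i in seq_len(k)) {
      if (length(frontier[[i]]) == 0) next
      nbr <- unique(unlist(adj[frontier[[i]]], use.names = FALSE))
      nbr <- nbr[label[nbr] == 0L]
      if (length(nbr)) {
        label[nbr] <- i
        progressed <- TRUE
      }
      frontier[[i]] <- nbr
    }
    if (!progressed) break
  }
  # closed connected mesh: every vertex is reachable
  stopifnot(all(label > 0L))
  label
}

parcel_centroids <- function(v, label, varea, k) {
  w <- rowsum(v * varea, label)
  tot <- rowsum(varea, label)
  cent <- w / as.numeric(tot)
  cent[seq_len(k), , drop = FALSE]
}

## ---- seed plumbing ------------------------------------------------------

# All randomness flows from one integer seed; sub-stage seeds are derived
# deterministically (fixed multiplier schedule, kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
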