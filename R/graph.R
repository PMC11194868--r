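#' Area adjacency graph
#'
#' An `area_graph` holds the contiguity structure of a set of small areas:
#' ordered area identifiers, a per-area set of neighbour indices, and
#' (optionally) the planar polygon of each area. Adjacency is symmetric and
#' irreflexive.
#'
#' @param ids character vector of unique area identifiers.
#' @param nb list of integer vectors; `nb[[i]]` are the indices of the
#'   neighbours of area `i` (1-based, no self-neighbours).
#' @param polygons optional list of two-column coordinate matrices, one
#'   closed ring per area.
#' @return An object of class `area_graph`.
#' @export
area_graph <- function(ids, nb, polygons = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("area ids must be unique", call. = FALSE)
  n <- length(ids)
  if (length(nb) != n) stop("`nb` must have one entry per area", call. = FALSE)
  nb <- lapply(nb, function(x) sort(unique(as.integer(x))))
  for (i in seq_len(n)) {
    if (any(nb[[i]] == i)) stop("self-adjacency is not allowed (area ", ids[i], ")",
                                call. = FALSE)
    if (length(nb[[i]]) && (min(nb[[i]]) < 1L || max(nb[[i]]) > n))
      stop("neighbour index out of range for area ", ids[i], call. = FALSE)
  }
  ## enforce symmetry
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]]))
        stop("adjacency is not symmetric: ", ids[i], " -> ", ids[j], call. = FALSE)
    }
  }
  if (!is.null(polygons) && length(polygons) != n)
    stop("`polygons` must have one entry per area", call. = FALSE)
  structure(list(ids = ids, nb = nb, polygons = polygons),
            class = "area_graph")
}

#' @method print area_graph
#' @export
print.area_graph <- function(x, ...) {
  deg <- lengths(x$nb)
  cat("Area adjacency graph\n")
  cat("  areas:     ", length(x$ids), "\n", sep = "")
  cat("  edges:     ", sum(deg) / 2, " (undirected)\n", sep = "")
  cat("  degree:    min ", if (length(deg)) min(deg) else 0,
      ", mean ", round(mean(deg), 2),
      ", max ", if (length(deg)) max(deg) else 0, "\n", sep = "")
  cat("  polygons:  ", if (is.null(x$polygons)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' @export
length.area_graph <- function(x) length(x$ids)

#' Regular lattice of unit squares with queen adjacency
#'
#' Generates a `rows` by `cols` grid of unit-square areas. Cells sharing an
#' edge or a corner are neighbours (queen contiguity), so interior cells have
#' eight neighbours. Serves as a stand-in for real small-area geography with
#' the same contiguity statistics.
#'
#' @param rows,cols positive integers; `rows * cols >= 2`.
#' @return An `area_graph` with polygons attached.
#' @examples
#' g <- generate_lattice(3, 3)
#' lengths(g$nb)[5]  # centre cell has 8 neighbours
#' @export
generate_lattice <- function(rows, cols) {
  if (length(rows) != 1L || length(cols) != 1L ||
      !is.finite(rows) || !is.finite(cols) ||
      rows < 1 || cols < 1 || rows != floor(rows) || cols != floor(cols))
    stop("`rows` and `cols` must be positive integers", call. = FALSE)
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  if (n < 2L) stop("lattice must contain at least 2 areas", call. = FALSE)
  idx <- function(r, c) (r - 1L) * cols + c
  nb <- vector("list", n)
  polys <- vector("list", n)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      i <- idx(r, c)
      nbr <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= rows && cc >= 1L && cc <= cols)
          nbr <- c(nbr, idx(rr, cc))
      }
      nb[[i]] <- sort(nbr)
      x0 <- c - 1; y0 <- r - 1
      polys[[i]] <- cbind(x = c(x0, x0 + 1, x0 + 1, x0, x0),
                          y = c(y0, y0, y0 + 1, y0 + 1, y0))
    }
  }
  area_graph(sprintf("A%04d", seq_len(n)), nb, polys)
}

#' Queen-contiguity adjacency from polygons
#'
#' Two areas are neighbours if their boundaries share at least one point —
#' a common vertex or a vertex lying on the other polygon's edge — within a
#' snapping tolerance. This is queen contiguity: corner contact counts.
#'
#' @param polygons list of closed-ring coordinate matrices (two columns),
#'   or an `area_graph` carrying polygons.
#' @param ids area identifiers; taken from the graph if one is supplied.
#' @param tol snapping tolerance in coordinate units (default `1e-8`).
#' @return An `area_graph` with the supplied polygons attached.
#' @export
queen_contiguity <- function(polygons, ids = NULL, tol = 1e-8) {
  if (inherits(polygons, "area_graph")) {
    if (is.null(polygons$polygons))
      stop("graph carries no polygons", call. = FALSE)
    ids <- polygons$ids
    polygons <- polygons$polygons
  }
  n <- length(polygons)
  if (is.null(ids)) ids <- sprintf("A%04d", seq_len(n))
  for (i in seq_len(n)) {
    p <- polygons[[i]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 4L || anyNA(p))
      stop("invalid geometry for area ", ids[i], call. = FALSE)
  }
  digits <- max(0L, ceiling(-log10(tol)))
  ## pass 1: shared snapped vertices
  keys <- lapply(polygons, function(p) {
    q <- round(p[-nrow(p), , drop = FALSE], digits)
    paste(q[, 1], q[, 2], sep = "|")
  })
  vert_owner <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    for (k in unique(keys[[i]])) {
      assign(k, c(get0(k, envir = vert_owner, ifnotfound = integer(0)), i),
             envir = vert_owner)
    }
  }
  adj <- vector("list", n)
  for (k in ls(vert_owner)) {
    owners <- unique(get(k, envir = vert_owner))
    if (length(owners) > 1L) {
      for (i in owners) adj[[i]] <- c(adj[[i]], setdiff(owners, i))
    }
  }
  ## pass 2: vertex of one polygon lying on an edge of another (T-junctions)
  bb <- t(vapply(polygons, function(p)
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])), numeric(4)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j %in% adj[[i]]) next
      if (bb[i, 1] > bb[j, 2] + tol || bb[j, 1] > bb[i, 2] + tol ||
          bb[i, 3] > bb[j, 4] + tol || bb[j, 3] > bb[i, 4] + tol) next
      if (.any_vertex_on_boundary(polygons[[i]], polygons[[j]], tol) ||
          .any_vertex_on_boundary(polygons[[j]], polygons[[i]], tol)) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  area_graph(ids, lapply(adj, function(x) sort(unique(x))), polygons)
}

## does any vertex of ring `a` lie on an edge of ring `b` (within tol)?
.any_vertex_on_boundary <- function(a, b, tol) {
  va <- a[-nrow(a), , drop = FALSE]
  nb_ <- nrow(b) - 1L
  for (e in seq_len(nb_)) {
    p1 <- b[e, ]; p2 <- b[e + 1L, ]
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) next
    t_ <- ((va[, 1] - p1[1]) * dx + (va[, 2] - p1[2]) * dy) / len2
    t_ <- pmin(1, pmax(0, t_))
    px <- p1[1] + t_ * dx; py <- p1[2] + t_ * dy
    d2 <- (va[, 1] - px)^2 + (va[, 2] - py)^2
    if (any(d2 <= tol * tol)) return(TRUE)
  }
  FALSE
}

#' Connected components of an area graph
#'
#' @param graph an `area_graph`.
#' @return integer vector of component labels (1-based).
#' @export
graph_components <- function(graph) {
  n <- length(graph$ids)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in graph$nb[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' Induced subgraph on a subset of areas
#'
#' @param graph an `area_graph`.
#' @param keep logical or integer index of areas to retain.
#' @return An `area_graph` on the retained areas.
#' @export
subset_graph <- function(graph, keep) {
  idx <- seq_along(graph$ids)[keep]
  map <- integer(length(graph$ids))
  map[idx] <- seq_along(idx)
  nb <- lapply(graph$nb[idx], function(v) map[v[map[v] > 0L]])
  area_graph(graph$ids[idx], nb,
             if (is.null(graph$polygons)) NULL else graph$polygons[idx])
}

#' Read adjacency from a two-column edge-list CSV
#'
#' The file must have columns `from` and `to` holding area identifiers; each
#' undirected edge may appear once or twice. Areas appearing in `ids` but in
#' no edge become isolated nodes.
#'
#' @param path CSV file path.
#' @param ids optional full set of area identifiers (ordering authority).
#' @return An `area_graph`.
#' @export
read_edges <- function(path, ids = NULL) {
  ed <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(ed)))
    stop("edge list must have columns 'from' and 'to'", call. = FALSE)
  if (is.null(ids)) ids <- sort(unique(c(as.character(ed$from), as.character(ed$to))))
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  i <- pos[as.character(ed$from)]; j <- pos[as.character(ed$to)]
  if (anyNA(i) || anyNA(j))
    stop("edge list refers to unknown area ids", call. = FALSE)
  nb <- vector("list", n)
  for (k in seq_along(i)) {
    if (i[k] == j[k]) next
    nb[[i[k]]] <- c(nb[[i[k]]], j[k])
    nb[[j[k]]] <- c(nb[[j[k]]], i[k])
  }
  area_graph(ids, nb)
}

#' Write adjacency as a two-column edge-list CSV
#'
#' Each undirected edge is written once, `from < to` in area order.
#'
#' @param graph an `area_graph`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(graph, path) {
  from <- character(0); to <- character(0)
  for (i in seq_along(graph$ids)) {
    js <- graph$nb[[i]]
    js <- js[js > i]
    if (length(js)) {
      from <- c(from, rep(graph$ids[i], length(js)))
      to <- c(to, graph$ids[js])
    }
  }
  utils::write.csv(data.frame(from = from, to = to), path, row.names = FALSE)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Accepts Polygon (outer ring used) and single-polygon MultiPolygon
#' features; each feature must carry an `area_id` property.
#'
#' @param path GeoJSON file path.
#' @param tol snapping tolerance passed to [queen_contiguity()].
#' @return An `area_graph` with queen adjacency derived from the polygons.
#' @export
read_geojson <- function(path, tol = 1e-8) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  ids <- character(0); polys <- list()
  for (f in gj$features) {
    id <- f$properties$area_id
    if (is.null(id)) stop("feature lacks an 'area_id' property", call. = FALSE)
    geom <- f$geometry
    coords <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    m <- do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    colnames(m) <- c("x", "y")
    ids <- c(ids, as.character(id))
    polys[[length(polys) + 1L]] <- m
  }
  queen_contiguity(polys, ids, tol = tol)
}

#' Write area polygons (and optional per-area properties) as GeoJSON
#'
#' @param graph an `area_graph` carrying polygons.
#' @param path output path.
#' @param properties optional data frame of extra per-area properties
#'   (one row per area, in graph order).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(graph, path, properties = NULL) {
  if (is.null(graph$polygons)) stop("graph carries no polygons", call. = FALSE)
  if (!is.null(properties) && nrow(properties) != length(graph$ids))
    stop("`properties` must have one row per area", call. = FALSE)
  feats <- lapply(seq_along(graph$ids), function(i) {
    p <- graph$polygons[[i]]
    props <- list(area_id = graph$ids[i])
    if (!is.null(properties)) {
      for (nm in names(properties)) props[[nm]] <- properties[i, nm]
    }
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p)),
                                                   function(k) c(p[k, 1], p[k, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
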