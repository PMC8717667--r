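#' Build an areal adjacency graph
#'
#' Constructs the neighbourhood structure underlying all conditional
#' autoregressive (CAR) model components: region labels, the symmetric
#' binary adjacency indicator \eqn{a_{ij}}, and neighbour counts
#' \eqn{N_i = \sum_j a_{ij}}.
#'
#' Two sources are supported. An *edge list* is a two-column data frame of
#' region-id pairs (each row one shared border). A *polygon collection* is a
#' GeoJSON-style list of features; neighbours are declared by queen
#' contiguity, i.e. whenever two polygon boundaries share at least one
#' vertex (coordinates compared after rounding to `tol` digits).
#'
#' @param source a two-column data.frame of region-id pairs, or a list of
#'   polygon features as returned by [read_polygons()].
#' @param region_ids optional character vector fixing the region set and
#'   order; defaults to the sorted ids present in `source`.
#' @param allow_islands if `FALSE` (default) a region with no neighbours
#'   raises a warning and is flagged; model-fitting functions reject flagged
#'   graphs.
#' @return an object of class `adjacency_graph` with elements `region_ids`,
#'   `edges` (two-column character matrix, each unordered pair once),
#'   `n_neighbors` (named integer vector \eqn{N_i}), `neighbors` (named list
#'   of character vectors), and `islands` (character vector, possibly empty).
#' @examples
#' g <- build_adjacency_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
#' g$n_neighbors
#' @export
build_adjacency_graph <- function(source, region_ids = NULL,
                                  allow_islands = FALSE) {
  if (is.data.frame(source)) {
    if (nrow(source) == 0L && is.null(region_ids)) {
      stop("empty edge list and no region_ids supplied")
    }
    e1 <- as.character(source[[1L]])
    e2 <- as.character(source[[2L]])
    if (any(e1 == e2)) {
      stop("self-edge in edge list: ", paste(unique(e1[e1 == e2]), collapse = ", "))
    }
    ids <- if (is.null(region_ids)) sort(unique(c(e1, e2))) else as.character(region_ids)
    edges <- unique(cbind(pmin(e1, e2), pmax(e1, e2)))
  } else if (is.list(source)) {
    poly <- source
    ids0 <- vapply(poly, function(f) as.character(f$id), character(1L))
    if (anyDuplicated(ids0)) stop("duplicate region id in polygon collection")
    ids <- if (is.null(region_ids)) ids0 else as.character(region_ids)
    edges <- .queen_edges(poly)
  } else {
    stop("source must be an edge-list data.frame or a polygon feature list")
  }
  if (anyDuplicated(ids)) stop("duplicate region id")
  if (length(edges) && !all(c(edges) %in% ids)) {
    stop("edge references unknown region: ",
         paste(setdiff(unique(c(edges)), ids), collapse = ", "))
  }
  nb <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) nb[[id]] <- character(0L)
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1L]; b <- edges[k, 2L]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
    nb <- lapply(nb, function(x) sort(unique(x)))
  }
  n_nb <- vapply(nb, length, integer(1L))
  islands <- ids[n_nb == 0L]
  if (length(islands) && !allow_islands) {
    warning("island region(s) with no neighbours: ",
            paste(islands, collapse = ", "))
  }
  structure(list(region_ids = ids,
                 edges = if (length(edges)) edges else matrix(character(0), 0, 2),
                 n_neighbors = n_nb,
                 neighbors = nb,
                 islands = islands),
            class = "adjacency_graph")
}

# queen contiguity: polygons sharing >= 1 (rounded) boundary vertex
.queen_edges <- function(features, tol = 9L) {
  ids <- vapply(features, function(f) as.character(f$id), character(1L))
  keys <- lapply(features, function(f) {
    xy <- f$coords
    unique(paste(round(xy[, 1L], tol), round(xy[, 2L], tol)))
  })
  n <- length(ids)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (any(keys[[i]] %in% keys[[j]])) {
        out[[length(out) + 1L]] <- c(ids[i], ids[j])
      }
    }
  }
  if (!length(out)) return(matrix(character(0), 0, 2))
  do.call(rbind, out)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Areal adjacency graph:", length(x$region_ids), "regions,",
      nrow(x$edges), "edges\n")
  cat("Neighbour counts:", paste(range(x$n_neighbors), collapse = "-"), "\n")
  if (length(x$islands)) cat("Islands:", paste(x$islands, collapse = ", "), "\n")
  invisible(x)
}

#' Dense binary adjacency matrix \eqn{a_{ij}} of a graph
#' @param graph an `adjacency_graph`.
#' @return symmetric 0/1 matrix with zero diagonal, dimnames = region ids.
#' @export
adjacency_matrix <- function(graph) {
  ids <- graph$region_ids
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    i <- match(graph$edges[, 1L], ids)
    j <- match(graph$edges[, 2L], ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Number of connected components of an adjacency graph
#' @param graph an `adjacency_graph`.
#' @return integer; isolated regions count as their own component.
#' @export
n_components <- function(graph) {
  ids <- graph$region_ids
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  for (s in ids) {
    if (!is.na(comp[[s]])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- k
      queue <- c(queue, graph$neighbors[[v]][is.na(comp[graph$neighbors[[v]]])])
    }
  }
  k
}

#' Read / write an edge list as two-column delimited text
#'
#' Format: header line, then one `region_id_1<TAB>region_id_2` row per edge.
#' @param path file path.
#' @return `read_edge_list`: a data.frame suitable for
#'   [build_adjacency_graph()].
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, colClasses = "character")
}

#' @rdname read_edge_list
#' @param graph an `adjacency_graph` to write.
#' @export
write_edge_list <- function(graph, path) {
  df <- data.frame(region_id_1 = graph$edges[, 1L],
                   region_id_2 = graph$edges[, 2L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Minimal reader for Polygon / MultiPolygon features; only boundary
#' vertices are retained (sufficient for queen contiguity).
#'
#' @param path path to a GeoJSON file.
#' @param id_property name of the feature property holding the region id.
#' @return list of features, each `list(id=, coords=)` with `coords` a
#'   two-column matrix of boundary vertices.
#' @export
read_polygons <- function(path, id_property = "region_id") {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  lapply(feats, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature missing id property '", id_property, "'")
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type))
    xy <- do.call(rbind, lapply(rings, function(r) {
      do.call(rbind, lapply(r, function(pt) c(pt[[1L]], pt[[2L]])))
    }))
    list(id = as.character(id), coords = xy)
  })
}
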