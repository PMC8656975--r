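#' Construct a tract adjacency graph
#'
#' An `adjacency_graph` stores the symmetric neighbourhood structure over
#' census tracts that underlies every spatial prior and weight matrix in the
#' package. Edges are undirected, self-loops are forbidden, and every edge
#' endpoint must be a known tract.
#'
#' @param tract_ids character vector of unique tract identifiers.
#' @param edges two-column character matrix (or data.frame) of tract-id pairs;
#'   each row is one undirected edge. Duplicate and reversed pairs collapse.
#' @param coords optional data.frame with columns `tract_id`, `row`, `col`
#'   giving lattice coordinates (used for map drawing and GeoJSON export).
#' @return An object of class `adjacency_graph`: a list with `tract_ids`,
#'   `nbr` (list of integer neighbour indices per tract), `n`, and `coords`.
#' @export
adjacency_graph <- function(tract_ids, edges, coords = NULL) {
  tract_ids <- as.character(tract_ids)
  if (anyDuplicated(tract_ids)) stop("duplicate tract ids", call. = FALSE)
  n <- length(tract_ids)
  nbr <- rep(list(integer(0)), n)
  names(nbr) <- tract_ids
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns", call. = FALSE)
    a <- match(as.character(edges[, 1]), tract_ids)
    b <- match(as.character(edges[, 2]), tract_ids)
    if (anyNA(a) || anyNA(b)) stop("edge endpoint not a known tract id", call. = FALSE)
    if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(cbind(lo, hi))
    lo <- lo[keep]; hi <- hi[keep]
    for (k in seq_along(lo)) {
      nbr[[lo[k]]] <- c(nbr[[lo[k]]], hi[k])
      nbr[[hi[k]]] <- c(nbr[[hi[k]]], lo[k])
    }
    nbr <- lapply(nbr, function(v) sort(unique(v)))
  }
  structure(list(tract_ids = tract_ids, nbr = nbr, n = n, coords = coords),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph:", x$n, "tracts,", n_edges(x), "edges,",
      max(graph_components(x)), "connected component(s)\n")
  invisible(x)
}

#' Number of undirected edges in a graph
#' @param graph an `adjacency_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(graph) {
  sum(lengths(graph$nbr)) %/% 2L
}

#' Edge list of a graph
#' @param graph an `adjacency_graph`.
#' @return two-column integer matrix of tract indices with `i < j` per row.
#' @export
edge_list <- function(graph) {
  i <- rep(seq_len(graph$n), lengths(graph$nbr))
  j <- unlist(graph$nbr, use.names = FALSE)
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

#' Neighbour counts per tract
#' @param graph an `adjacency_graph`.
#' @return named integer vector of degrees.
#' @export
tract_degrees <- function(graph) {
  d <- lengths(graph$nbr)
  names(d) <- graph$tract_ids
  d
}

#' Connected components of a graph
#'
#' @param graph an `adjacency_graph`.
#' @return integer vector of component labels (1-based) per tract, in
#'   `tract_ids` order.
#' @export
graph_components <- function(graph) {
  n <- graph$n
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, graph$nbr[[v]][comp[graph$nbr[[v]]] == 0L])
    }
  }
  comp
}

#' Build a regular lattice of census tracts
#'
#' Generates an `n_rows` by `n_cols` grid with rook (shared edge) or queen
#' (shared edge or corner) contiguity. Tract ids are deterministic,
#' `"r{row}c{col}"`.
#'
#' @param n_rows,n_cols positive integers.
#' @param contiguity `"rook"` or `"queen"`.
#' @return An `adjacency_graph` with lattice coordinates attached.
#' @examples
#' make_lattice(2, 2, "rook")
#' @export
make_lattice <- function(n_rows, n_cols, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  if (length(n_rows) != 1 || length(n_cols) != 1 ||
      n_rows < 1 || n_cols < 1 || n_rows != floor(n_rows) || n_cols != floor(n_cols))
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  ids <- sprintf("r%dc%d", grid$row, grid$col)
  idx <- function(r, c) (r - 1L) * n_cols + c
  steps <- rbind(c(0L, 1L), c(1L, 0L))
  if (contiguity == "queen") steps <- rbind(steps, c(1L, 1L), c(1L, -1L))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(steps))) {
    dr <- steps[k, 1]; dc <- steps[k, 2]
    r <- grid$row; c <- grid$col
    ok <- r + dr >= 1 & r + dr <= n_rows & c + dc >= 1 & c + dc <= n_cols
    from <- c(from, idx(r[ok], c[ok]))
    to <- c(to, idx(r[ok] + dr, c[ok] + dc))
  }
  adjacency_graph(ids, cbind(ids[from], ids[to]),
                  coords = data.frame(tract_id = ids, row = grid$row,
                                      col = grid$col,
                                      stringsAsFactors = FALSE))
}

#' Write a GAL spatial-weights file
#'
#' Standard plain-text exchange format: a header line `0 n <name> tract_id`
#' followed, for each tract, by a line `<id> <degree>` and a line listing its
#' neighbour ids.
#'
#' @param graph an `adjacency_graph`.
#' @param file path to write.
#' @param name dataset name placed in the header.
#' @export
write_gal <- function(graph, file, name = "carmap") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("0", graph$n, name, "tract_id"), con)
  for (i in seq_len(graph$n)) {
    nb <- graph$nbr[[i]]
    writeLines(paste(graph$tract_ids[i], length(nb)), con)
    writeLines(paste(graph$tract_ids[nb], collapse = " "), con)
  }
  invisible(file)
}

#' Read a GAL spatial-weights file
#'
#' @param file path to a GAL file as written by [write_gal()] (or GeoDa).
#' @return An `adjacency_graph`. Asymmetric neighbour listings are
#'   symmetrized.
#' @export
read_gal <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %% 2 == 0]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[2])
  ids <- character(n)
  nbrs <- vector("list", n)
  pos <- 2L
  for (i in seq_len(n)) {
    hd <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    ids[i] <- hd[1]
    d <- as.integer(hd[2])
    nbrs[[i]] <- if (d > 0) strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]] else character(0)
    pos <- pos + 2L
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(nbrs[[i]])) cbind(ids[i], nbrs[[i]]) else NULL
  }))
  adjacency_graph(ids, edges)
}

#' Intrinsic CAR precision structure matrix
#'
#' Builds the graph Laplacian `Q = D - W` (`D` diagonal neighbour counts, `W`
#' binary adjacency) that scales the intrinsic CAR prior. `Q` is symmetric,
#' rows sum to zero, and its rank is `n` minus the number of connected
#' components.
#'
#' @param graph an `adjacency_graph`.
#' @param allow_islands if `FALSE` (default), tracts with zero neighbours are
#'   an error — the intrinsic CAR prior is undefined on them.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`).
#' @export
build_icar_precision <- function(graph, allow_islands = FALSE) {
  d <- lengths(graph$nbr)
  if (!allow_islands && any(d == 0))
    stop("isolated tract(s): ", paste(graph$tract_ids[d == 0], collapse = ", "),
         "; the intrinsic CAR prior is undefined on islands", call. = FALSE)
  el <- edge_list(graph)
  n <- graph$n
  if (nrow(el)) {
    Q <- Matrix::sparseMatrix(i = c(seq_len(n), el[, 1]),
                              j = c(seq_len(n), el[, 2]),
                              x = c(as.numeric(d), rep(-1, nrow(el))),
                              dims = c(n, n), symmetric = TRUE)
  } else {
    Q <- Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n), x = as.numeric(d),
                              dims = c(n, n), symmetric = TRUE)
  }
  dimnames(Q) <- list(graph$tract_ids, graph$tract_ids)
  Q
}

#' Export lattice tract polygons as GeoJSON
#'
#' Writes a FeatureCollection of unit-square polygons (one Feature per tract,
#' `tract_id` property), for graphs built by [make_lattice()]. Additional
#' per-tract attributes can be attached as properties.
#'
#' @param graph an `adjacency_graph` with lattice coordinates.
#' @param file path to write.
#' @param properties optional named list of per-tract vectors (each of length
#'   `graph$n`, in `tract_ids` order) attached to the features.
#' @export
write_lattice_geojson <- function(graph, file, properties = NULL) {
  if (is.null(graph$coords))
    stop("graph has no lattice coordinates; GeoJSON export needs make_lattice()",
         call. = FALSE)
  co <- graph$coords[match(graph$tract_ids, graph$coords$tract_id), ]
  feats <- lapply(seq_len(graph$n), function(i) {
    x0 <- co$col[i] - 1; x1 <- co$col[i]
    y0 <- -co$row[i]; y1 <- -(co$row[i] - 1)
    props <- list(tract_id = graph$tract_ids[i])
    for (nm in names(properties)) props[[nm]] <- properties[[nm]][i]
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(x0, y0), c(x1, y0), c(x1, y1),
                                                 c(x0, y1), c(x0, y0)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
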