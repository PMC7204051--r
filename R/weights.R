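#' Tract adjacency list
#'
#' Internal constructor/validator for the adjacency structure shared by the
#' weights builders. Ids are put in a canonical (C-locale radix) sort order so
#' every downstream matrix has a reproducible row order.
#'
#' @param ids Character vector of unique tract identifiers.
#' @param neighbors Named list (names = ids) of character vectors of
#'   neighboring ids.
#' @return List of class \code{"tract_adjacency"} with elements \code{ids}
#'   and \code{neighbors} (both in canonical order).
#' @export
tract_adjacency <- function(ids, neighbors) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate tract ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ids <- sort(ids, method = "radix")
  neighbors <- neighbors[ids]
  neighbors <- lapply(neighbors, function(nb)
    sort(unique(as.character(nb)), method = "radix"))
  names(neighbors) <- ids
  for (id in ids) {
    nb <- neighbors[[id]]
    if (id %in% nb) stop("self-neighbor at tract ", id, call. = FALSE)
    missing <- setdiff(nb, ids)
    if (length(missing))
      stop("neighbor ids not in id set: ", paste(missing, collapse = ", "),
           call. = FALSE)
    for (j in nb)
      if (!(id %in% neighbors[[j]]))
        stop("asymmetric adjacency between ", id, " and ", j, call. = FALSE)
  }
  structure(list(ids = ids, neighbors = neighbors),
            class = "tract_adjacency")
}

#' @export
print.tract_adjacency <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat("Queen/contiguity adjacency:", length(x$ids), "tracts,",
      sum(deg) / 2, "links, ", sum(deg == 0), "island(s)\n")
  invisible(x)
}

#' Queen contiguity on a rectangular grid
#'
#' Adjacency of a \code{rows} x \code{cols} lattice of unit squares under the
#' queen criterion (all 8 surrounding cells are neighbors), built directly
#' from the index arithmetic without constructing geometries. Useful for
#' synthetic studies and as an oracle-free fast path.
#'
#' @param rows,cols Positive grid dimensions.
#' @param ids Optional character ids in row-major cell order; defaults to
#'   zero-padded \code{"t00001"}-style labels whose radix sort equals the
#'   row-major order.
#' @return A \code{\link{tract_adjacency}}.
#' @examples
#' adj <- grid_queen_contiguity(3, 3)
#' lengths(adj$neighbors)   # corners 3, edges 5, center 8
#' @export
grid_queen_contiguity <- function(rows, cols, ids = NULL) {
  if (rows < 1 || cols < 1)
    stop("'rows' and 'cols' must be positive", call. = FALSE)
  n <- rows * cols
  if (is.null(ids)) ids <- sprintf("t%05d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("need one id per cell", call. = FALSE)
  cell <- function(r, c) ids[(r - 1) * cols + c]
  neighbors <- vector("list", n)
  names(neighbors) <- ids
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    nb <- character(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= rows && cc >= 1 && cc <= cols)
        nb <- c(nb, cell(rr, cc))
    }
    neighbors[[cell(r, c)]] <- nb
  }
  tract_adjacency(ids, neighbors)
}

#' Queen contiguity from polygon geometries
#'
#' Builds the queen-contiguity adjacency of a polygon coverage: two tracts
#' are neighbors when their boundaries share at least one point. The
#' predicate matches boundary vertices exactly (coordinates compared after
#' optional snapping to a grid of size \code{snap}), the approach standard
#' for topologically clean tract coverages where shared boundaries share
#' vertices.
#'
#' @param geojson Path to a GeoJSON FeatureCollection of Polygon or
#'   MultiPolygon features, or an already-parsed list (as from
#'   \code{jsonlite::read_json}).
#' @param id_property Name of the feature property holding the tract id
#'   (also looked up in the feature's top-level \code{id}).
#' @param snap Snapping tolerance for coordinate comparison; 0 (default)
#'   compares exact coordinates.
#' @return A \code{\link{tract_adjacency}}.
#' @export
queen_contiguity <- function(geojson, id_property = "id", snap = 0) {
  gj <- if (is.character(geojson))
    jsonlite::read_json(geojson, simplifyVector = FALSE) else geojson
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0L)
    stop("empty or invalid FeatureCollection", call. = FALSE)

  get_id <- function(f, i) {
    id <- f$properties[[id_property]]
    if (is.null(id)) id <- f$id
    if (is.null(id)) stop("feature ", i, " has no '", id_property,
                          "' property", call. = FALSE)
    as.character(id)
  }
  ids <- vapply(seq_along(feats), function(i) get_id(feats[[i]], i),
                character(1))
  if (anyDuplicated(ids))
    stop("duplicate tract ids in GeoJSON: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  key_fun <- function(xy) {
    if (snap > 0) xy <- round(xy / snap) * snap
    paste(format(xy[1], digits = 15), format(xy[2], digits = 15))
  }
  vertex_keys <- function(f, id) {
    geom <- f$geometry
    if (is.null(geom) || is.null(geom$type) ||
        !(geom$type %in% c("Polygon", "MultiPolygon")))
      stop("invalid geometry for tract ", id,
           " (need Polygon or MultiPolygon)", call. = FALSE)
    rings <- if (geom$type == "Polygon") geom$coordinates
             else do.call(c, geom$coordinates)
    keys <- unlist(lapply(rings, function(ring)
      vapply(ring, function(pt) key_fun(as.numeric(pt[1:2])), character(1))))
    if (length(keys) == 0L)
      stop("invalid geometry for tract ", id, " (no coordinates)",
           call. = FALSE)
    unique(keys)
  }

  keys <- lapply(seq_along(feats),
                 function(i) vertex_keys(feats[[i]], ids[i]))
  vert2feat <- split(rep(seq_along(feats), lengths(keys)), unlist(keys))
  neighbors <- lapply(seq_along(feats), function(i) character(0))
  for (group in vert2feat) {
    if (length(group) < 2) next
    for (i in group)
      neighbors[[i]] <- c(neighbors[[i]], ids[setdiff(group, i)])
  }
  names(neighbors) <- ids
  tract_adjacency(ids, neighbors)
}

#' Row-standardized spatial weights
#'
#' Turns an adjacency into the row-standardized weights matrix
#' \eqn{w_{ij} = 1/|N(i)|} for neighbors, 0 elsewhere. Tracts with no
#' neighbors (islands) keep an all-zero row and are reported with a warning;
#' whether to keep or drop them is the estimator's decision (the pipeline
#' drops them by default).
#'
#' @param adjacency A \code{\link{tract_adjacency}}.
#' @return List of class \code{"spatial_weights"}: \code{ids}, sparse matrix
#'   \code{W} (\code{Matrix::dgCMatrix}), \code{standardized = TRUE},
#'   \code{islands} (character vector) and the originating \code{adjacency}.
#' @export
row_standardize <- function(adjacency) {
  stopifnot(inherits(adjacency, "tract_adjacency"))
  ids <- adjacency$ids
  n <- length(ids)
  deg <- lengths(adjacency$neighbors)
  islands <- ids[deg == 0]
  i_idx <- rep(seq_len(n), deg)
  j_idx <- match(unlist(adjacency$neighbors, use.names = FALSE), ids)
  x <- 1 / deg[i_idx]
  W <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x, dims = c(n, n),
                            dimnames = list(ids, ids))
  if (length(islands))
    warning(length(islands), " island tract(s) with zero weight rows: ",
            paste(utils::head(islands, 5), collapse = ", "),
            if (length(islands) > 5) ", ...", call. = FALSE)
  structure(list(ids = ids, W = W, standardized = TRUE,
                 islands = islands, adjacency = adjacency),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Row-standardized spatial weights:", length(x$ids), "tracts,",
      length(x$islands), "island(s)\n")
  invisible(x)
}

#' Eigenvalues of a row-standardized weights matrix
#'
#' Computes the spectrum of \eqn{W} through the symmetric similarity
#' transform \eqn{D^{-1/2} A D^{-1/2}} (A the binary adjacency, D the degree
#' diagonal), which is similar to \eqn{W = D^{-1} A} and guarantees a real
#' spectrum. Islands contribute eigenvalue 0. For a connected, row-stochastic
#' W the eigenvalues lie in \eqn{(-1, 1]} with maximum exactly 1.
#'
#' @param w A \code{\link{row_standardize}} result.
#' @return Numeric vector of eigenvalues, decreasing.
#' @export
weights_eigenvalues <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  adj <- w$adjacency
  deg <- lengths(adj$neighbors)
  pos <- deg > 0
  ev0 <- rep(0, sum(!pos))
  if (!any(pos)) return(ev0)
  n <- length(adj$ids)
  i_idx <- rep(seq_len(n), deg)
  j_idx <- match(unlist(adj$neighbors, use.names = FALSE), adj$ids)
  A <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1, dims = c(n, n))
  A <- A[pos, pos, drop = FALSE]
  dhalf <- 1 / sqrt(deg[pos])
  S <- as.matrix(A) * outer(dhalf, dhalf)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sort(c(ev, ev0), decreasing = TRUE)
}

#' Spatial lag of a tract-level variable
#'
#' \eqn{Wx}: under row standardization, each tract's value is replaced by the
#' mean of its neighbors' values (islands get 0).
#'
#' @param w A \code{\link{row_standardize}} result.
#' @param x Numeric vector (or matrix, lagged column-wise) aligned to
#'   \code{w$ids}.
#' @return Numeric vector or matrix of lagged values.
#' @export
spatial_lag <- function(w, x) {
  stopifnot(inherits(w, "spatial_weights"))
  n <- length(w$ids)
  if (is.matrix(x) || inherits(x, "Matrix")) {
    if (nrow(x) != n) stop("'x' must have one row per tract", call. = FALSE)
    out <- as.matrix(w$W %*% x)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) != n) stop("'x' must have one value per tract", call. = FALSE)
  as.numeric(w$W %*% x)
}

#' Restrict an adjacency to a subset of tracts
#'
#' Keeps only the given tracts and intersects every neighbor set with them,
#' the operation used after reliability filtering (re-standardize the result
#' with \code{\link{row_standardize}}).
#'
#' @param adjacency A \code{\link{tract_adjacency}}.
#' @param keep_ids Ids to retain.
#' @return A \code{\link{tract_adjacency}} on the subset.
#' @export
subset_adjacency <- function(adjacency, keep_ids) {
  stopifnot(inherits(adjacency, "tract_adjacency"))
  keep_ids <- as.character(keep_ids)
  missing <- setdiff(keep_ids, adjacency$ids)
  if (length(missing))
    stop("unknown tract ids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  nb <- lapply(adjacency$neighbors[keep_ids],
               function(v) intersect(v, keep_ids))
  tract_adjacency(keep_ids, nb)
}

#' Read a GAL neighbor file
#'
#' Reads the plain-text GAL exchange format: a header line with the number of
#' observations, then for each observation a line \code{"id k"} followed by a
#' line listing its k neighbor ids.
#'
#' @param path File path.
#' @return A \code{\link{tract_adjacency}}.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[length(header)])
  if (is.na(n)) stop("invalid GAL header", call. = FALSE)
  ids <- character(n)
  neighbors <- vector("list", n)
  pos <- 2L
  for (k in seq_len(n)) {
    hd <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    ids[k] <- hd[1]
    cnt <- as.integer(hd[2])
    if (cnt > 0) {
      neighbors[[k]] <- strsplit(trimws(lines[pos + 1L]), "\\s+")[[1]]
      pos <- pos + 2L
    } else {
      neighbors[[k]] <- character(0)
      pos <- pos + 1L
    }
  }
  names(neighbors) <- ids
  tract_adjacency(ids, neighbors)
}

#' Write a GAL neighbor file
#'
#' Inverse of \code{\link{read_gal}}; the round-trip is bit-exact for
#' canonical adjacencies.
#'
#' @param adjacency A \code{\link{tract_adjacency}}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_gal <- function(adjacency, path) {
  stopifnot(inherits(adjacency, "tract_adjacency"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(length(adjacency$ids)), con)
  for (id in adjacency$ids) {
    nb <- adjacency$neighbors[[id]]
    writeLines(paste(id, length(nb)), con)
    if (length(nb)) writeLines(paste(nb, collapse = " "), con)
  }
  invisible(path)
}
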