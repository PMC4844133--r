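#' Great-circle distance by the haversine formula
#'
#' Distance in kilometres between points given in decimal degrees, on a
#' sphere of mean radius 6371 km by default.
#'
#' @param lat1,lon1 Coordinates of the first point, decimal degrees.
#' @param lat2,lon2 Coordinates of the second point, decimal degrees.
#' @param radius Sphere radius in km.
#' @return Great-circle distance in km. Vectorised over coordinates.
#' @examples
#' haversine_km(0, 0, 0, 180)  # half the circumference, pi * 6371
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius = 6371) {
  if (radius <= 0) stop("radius must be positive")
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius * asin(sqrt(a))
}

check_coords <- function(lat, lon, allow_na = FALSE) {
  if (allow_na) {
    keep <- !(is.na(lat) | is.na(lon))
    lat <- lat[keep]; lon <- lon[keep]
  }
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("coordinates must be finite")
  if (any(abs(lat) > 90)) stop("latitude out of range [-90, 90]")
  if (any(abs(lon) > 180)) stop("longitude out of range [-180, 180]")
  invisible(TRUE)
}

# strip everything but dim/dimnames so container attributes (class, units,
# kind) never ride along into derived matrices
plain_matrix <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

#' Node set: the sampled countries
#'
#' A light container for the ordered country identifiers a matrix or panel
#' is aligned to, with optional centroid coordinates.
#'
#' @param ids Character vector of unique country identifiers.
#' @param lat,lon Optional numeric centroid coordinates per id, decimal
#'   degrees. Centroid overrides (e.g. shifting a very large country's
#'   centroid toward its population) are simply supplied here by the caller.
#' @param language Optional language label per id.
#' @return An object of class `node_set`.
#' @export
node_set <- function(ids, lat = NULL, lon = NULL, language = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("node ids must be unique")
  if (!is.null(lat) || !is.null(lon)) {
    if (length(lat) != length(ids) || length(lon) != length(ids))
      stop("lat/lon must have one value per id")
    check_coords(lat, lon, allow_na = TRUE)
  }
  structure(
    list(ids = ids, lat = lat, lon = lon, language = language),
    class = "node_set"
  )
}

#' @export
print.node_set <- function(x, ...) {
  cat("node_set:", length(x$ids), "nodes",
      if (!is.null(x$lat)) "(with coordinates)" else "(no coordinates)", "\n")
  invisible(x)
}

#' Pairwise distance matrix
#'
#' Validates and tags a symmetric nonnegative pairwise distance matrix
#' (divergence times in years, or geographic distances in km).
#'
#' @param values Square numeric matrix with matching row/column names.
#' @param units `"years"` or `"km"`.
#' @return An object of class `distance_matrix` (the matrix, with a
#'   `units` attribute).
#' @export
distance_matrix <- function(values, units = c("years", "km")) {
  units <- match.arg(units)
  values <- plain_matrix(as.matrix(values))
  n <- nrow(values)
  if (n != ncol(values)) stop("distance matrix must be square")
  if (is.null(rownames(values))) rownames(values) <- paste0("n", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values)))
    stop("row and column labels must match")
  if (any(!is.finite(values))) stop("distances must be finite")
  if (any(values < 0)) stop("distances must be nonnegative")
  if (any(abs(values - t(values)) > 1e-8 * max(1, max(values))))
    stop("distance matrix must be symmetric")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, units = units, class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix:", nrow(x), "x", ncol(x), "in", attr(x, "units"), "\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' Pairwise spatial distance matrix from country centroids
#'
#' @param nodes A [node_set] whose every id carries coordinates.
#' @param radius Sphere radius in km.
#' @return A [distance_matrix] in km.
#' @export
spatial_distance_matrix <- function(nodes, radius = 6371) {
  if (is.null(nodes$lat) || is.null(nodes$lon))
    stop("all nodes need coordinates for a spatial distance matrix")
  miss <- which(is.na(nodes$lat) | is.na(nodes$lon))
  if (length(miss))
    stop("missing coordinates for node(s): ",
         paste(nodes$ids[miss], collapse = ", "))
  n <- length(nodes$ids)
  d <- matrix(0, n, n, dimnames = list(nodes$ids, nodes$ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      d[i, j] <- haversine_km(nodes$lat[i], nodes$lon[i],
                              nodes$lat[j], nodes$lon[j], radius)
      d[j, i] <- d[i, j]
    }
  }
  distance_matrix(d, units = "km")
}

#' Weight matrix for network autoregression
#'
#' Two kinds are used: distance-derived affinities (expected correlations in
#' \eqn{[0,1]}, diagonal 1) and row-normalized binary adjacencies (each
#' node's neighbour weights sum to 1; isolate rows are all zero).
#'
#' @param values Square numeric matrix, labelled.
#' @param kind `"affinity"` or `"row_normalized_adjacency"`.
#' @param label Short matrix label, e.g. `"SoL_aff"`, `"S_prox"`, `"L_adj"`,
#'   `"S_adj"`.
#' @return An object of class `weight_matrix`.
#' @export
weight_matrix <- function(values, kind = c("affinity", "row_normalized_adjacency"),
                          label = "W") {
  kind <- match.arg(kind)
  values <- plain_matrix(as.matrix(values))
  if (nrow(values) != ncol(values)) stop("weight matrix must be square")
  if (is.null(rownames(values))) rownames(values) <- paste0("n", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (any(values < -1e-12)) stop("weights must be nonnegative")
  if (kind == "affinity") {
    if (any(values > 1 + 1e-9)) stop("affinity weights must lie in [0, 1]")
    if (any(abs(diag(values) - 1) > 1e-9)) stop("affinity diagonal must be 1")
  } else {
    rs <- rowSums(values)
    bad <- abs(rs) > 1e-9 & abs(rs - 1) > 1e-9
    if (any(bad)) stop("row-normalized adjacency rows must sum to 0 or 1")
  }
  structure(values, kind = kind, label = label,
            class = c("weight_matrix", "matrix", "array"))
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("weight_matrix '", attr(x, "label"), "' (", attr(x, "kind"), "): ",
      nrow(x), " x ", ncol(x), "\n", sep = "")
  invisible(x)
}

#' Distance-to-affinity transform
#'
#' Converts pairwise distances into expected autocorrelations by the linear
#' transform \eqn{(\max(D) - D_{ij}) / \max(D)}: identical nodes get weight
#' 1, the maximally distant pair gets 0. The transform is invariant to
#' rescaling the distances.
#'
#' @param d A [distance_matrix].
#' @param label Label for the resulting matrix.
#' @return A [weight_matrix] of kind `"affinity"`.
#' @export
distance_to_affinity <- function(d, label = "aff") {
  dmax <- max(d)
  if (dmax <= 0)
    stop("degenerate distance matrix: max distance is zero")
  w <- (dmax - plain_matrix(d)) / dmax
  weight_matrix(w, kind = "affinity", label = label)
}

#' Binary adjacency from a divergence-time matrix
#'
#' Nodes are adjacent when their distance is strictly below `threshold`
#' (default 1000 years, a proxy for mutual intelligibility between
#' languages). Distances within `tol` of the threshold count as not less.
#'
#' @param d A [distance_matrix].
#' @param threshold Adjacency threshold, same units as `d`.
#' @param tol Floating-point guard band at the threshold.
#' @return Binary matrix with zero diagonal (plain matrix; pass through
#'   [row_normalize()] before modelling).
#' @export
adjacency_from_distance <- function(d, threshold = 1000, tol = 1e-9) {
  if (threshold <= 0) stop("threshold must be positive")
  dm <- plain_matrix(d)
  a <- 1 * ((dm < threshold) & ((threshold - dm) > tol))
  diag(a) <- 0
  a
}

#' Row-normalize an adjacency matrix
#'
#' Divides each nonzero row by its sum, the standard weight transform for
#' network autoregression. Isolate rows (no neighbours) are left at zero.
#'
#' @param a Nonnegative square matrix (typically binary adjacency).
#' @param label Label for the resulting matrix.
#' @return A [weight_matrix] of kind `"row_normalized_adjacency"`.
#' @export
row_normalize <- function(a, label = "adj") {
  a <- as.matrix(a)
  if (any(a < 0)) stop("adjacency entries must be nonnegative")
  rs <- rowSums(a)
  w <- a / ifelse(rs > 0, rs, 1)
  weight_matrix(w, kind = "row_normalized_adjacency", label = label)
}

#' Subset a weight matrix to retained nodes
#'
#' Affinity matrices are subset as-is, so affinities keep the full-sample
#' scale and stay comparable across time bins; row-normalized adjacencies
#' are subset and then re-row-normalized, so a node whose only neighbours
#' dropped out becomes an isolate (zero row).
#'
#' @param w A [weight_matrix].
#' @param keep Character vector of node ids (or integer indices) to retain.
#' @return A [weight_matrix] on the retained nodes.
#' @export
subset_weights <- function(w, keep) {
  if (length(keep) == 0) stop("keep must be a nonempty subset of nodes")
  if (is.character(keep) && !all(keep %in% rownames(w)))
    stop("unknown node id(s): ",
         paste(setdiff(keep, rownames(w)), collapse = ", "))
  sub <- plain_matrix(w)[keep, keep, drop = FALSE]
  if (attr(w, "kind") == "affinity") {
    weight_matrix(sub, kind = "affinity", label = attr(w, "label"))
  } else {
    row_normalize(sub, label = attr(w, "label"))
  }
}

#' Read / write labelled square matrices
#'
#' CSV dialect: header row of node labels, first column of row labels equal
#' to the column labels.
#'
#' @param path File path.
#' @param units Units tag to attach on read.
#' @return `read_matrix_csv` returns a [distance_matrix].
#' @export
read_matrix_csv <- function(path, units = c("years", "km")) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  distance_matrix(as.matrix(df), units = match.arg(units))
}

#' @param m Matrix to write (rows ordered by node id for bit-stable output).
#' @rdname read_matrix_csv
#' @export
write_matrix_csv <- function(m, path) {
  m <- as.matrix(m)
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centroid override table
#'
#' Key-value CSV with columns `id, lat, lon`.
#'
#' @param path File path.
#' @return Data frame of centroids.
#' @export
read_centroids_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("id", "lat", "lon") %in% names(df)))
  check_coords(df$lat, df$lon)
  df
}
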