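#' Build an orthogonal two-partition pooling design on a grid
#'
#' Items are laid on an R x C grid in input order (row-major). Partition
#' X pools are the grid rows (clusters `X_1..X_R`, each of size <= C);
#' partition Y pools are the columns (`Y_1..Y_C`, each of size <= R).
#' For a full grid (n = R*C) every X pool shares exactly one item with
#' every Y pool, so a compound is identified by the intersection of the
#' one X pool and one Y pool in which it scores. The screen this models
#' used 90 alkynes on a 9 x 10 grid: nine X clusters of 10 and ten Y
#' clusters of 9.
#'
#' @param item_ids character vector of unique item ids (length n).
#' @param rows,cols grid dimensions R, C with R*C >= n >= 1.
#' @param shuffle permute item placement before gridding.
#' @param seed RNG seed used when `shuffle = TRUE`.
#' @return an object of class `pooling_design`: list with `item_ids`,
#'   `grid_shape`, `partition_x`, `partition_y` (named lists of id
#'   vectors), and `grid` (R x C character matrix, NA for empty cells).
#' @export
build_grid_design <- function(item_ids, rows, cols, shuffle = FALSE, seed = 1L) {
  item_ids <- as.character(item_ids)
  n <- length(item_ids)
  if (n < 1) stop("need at least one item")
  if (anyDuplicated(item_ids)) stop("item ids must be unique")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1 || cols < 1) stop("grid dimensions must be positive")
  if (rows * cols < n) {
    stop("grid too small: ", rows, "x", cols, " holds ", rows * cols,
         " items but ", n, " supplied (deficit ", n - rows * cols, ")")
  }
  placed <- item_ids
  if (shuffle) {
    set.seed(seed)
    placed <- sample(placed)
  }
  grid <- matrix(NA_character_, nrow = rows, ncol = cols)
  grid[cbind(((seq_len(n) - 1L) %/% cols) + 1L,
             ((seq_len(n) - 1L) %% cols) + 1L)] <- placed
  px <- lapply(seq_len(rows), function(i) grid[i, !is.na(grid[i, ])])
  py <- lapply(seq_len(cols), function(j) grid[!is.na(grid[, j]), j])
  names(px) <- paste0("X_", seq_len(rows))
  names(py) <- paste0("Y_", seq_len(cols))
  structure(
    list(item_ids = item_ids, grid_shape = c(rows = rows, cols = cols),
         partition_x = px, partition_y = py, grid = grid),
    class = "pooling_design"
  )
}

#' @export
print.pooling_design <- function(x, ...) {
  cat("<pooling_design> ", length(x$item_ids), " items on a ",
      x$grid_shape[["rows"]], "x", x$grid_shape[["cols"]], " grid; ",
      length(x$partition_x), " X clusters, ", length(x$partition_y),
      " Y clusters\n", sep = "")
  invisible(x)
}

#' Verify orthogonality of a two-partition pooling design
#'
#' Exhaustively computes all pairwise X x Y pool intersections. A design
#' is valid when every item occurs exactly once per partition and no X
#' pool shares more than one item with any Y pool (so singleton
#' intersections identify items uniquely).
#'
#' @param design a `pooling_design`.
#' @return list of class `orthogonality_report`: `max_pair_overlap`,
#'   `n_singleton_intersections`, `per_item_cluster_coordinates`
#'   (data.frame `item, x_cluster, y_cluster`), `valid`.
#' @export
verify_orthogonality <- function(design) {
  px <- design$partition_x
  py <- design$partition_y
  items <- design$item_ids
  overlaps <- matrix(0L, nrow = length(px), ncol = length(py),
                     dimnames = list(names(px), names(py)))
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      overlaps[i, j] <- length(intersect(px[[i]], py[[j]]))
    }
  }
  cover_x <- table(factor(unlist(px), levels = items))
  cover_y <- table(factor(unlist(py), levels = items))
  covered_once <- all(cover_x == 1L) && all(cover_y == 1L)
  coords <- data.frame(
    item = items,
    x_cluster = vapply(items, function(it) {
      hit <- which(vapply(px, function(cl) it %in% cl, logical(1)))
      if (length(hit) == 1) names(px)[hit] else NA_character_
    }, character(1)),
    y_cluster = vapply(items, function(it) {
      hit <- which(vapply(py, function(cl) it %in% cl, logical(1)))
      if (length(hit) == 1) names(py)[hit] else NA_character_
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      max_pair_overlap = max(overlaps),
      n_singleton_intersections = sum(overlaps == 1L),
      overlap_matrix = overlaps,
      per_item_cluster_coordinates = coords,
      valid = covered_once && max(overlaps) <= 1L
    ),
    class = "orthogonality_report"
  )
}

#' @export
print.orthogonality_report <- function(x, ...) {
  cat("<orthogonality_report> valid=", x$valid,
      "; max overlap=", x$max_pair_overlap,
      "; singleton intersections=", x$n_singleton_intersections, "\n", sep = "")
  invisible(x)
}

#' Resolve candidate identities from hit pools by intersection
#'
#' Returns the union over all hit (X_i, Y_j) pairs of the pool
#' intersections: on a full grid, one hit row and one hit column
#' pinpoint a single item.
#'
#' @param design a `pooling_design`.
#' @param hit_x_clusters,hit_y_clusters integer indices or cluster
#'   names (`"X_3"`, `"Y_7"`); empty sets give an empty result.
#' @return character vector of candidate item ids (possibly empty).
#' @export
deconvolve_candidates <- function(design, hit_x_clusters, hit_y_clusters) {
  xi <- .cluster_index(hit_x_clusters, design$partition_x, "X")
  yj <- .cluster_index(hit_y_clusters, design$partition_y, "Y")
  if (length(xi) == 0 || length(yj) == 0) return(character(0))
  out <- character(0)
  for (i in xi) for (j in yj) {
    out <- union(out, intersect(design$partition_x[[i]], design$partition_y[[j]]))
  }
  out
}

.cluster_index <- function(idx, partition, axis) {
  if (length(idx) == 0) return(integer(0))
  if (is.character(idx)) {
    pos <- match(idx, names(partition))
    if (anyNA(pos)) {
      stop(axis, " cluster label(s) not in design: ",
           paste(idx[is.na(pos)], collapse = ", "))
    }
    return(pos)
  }
  idx <- as.integer(idx)
  if (any(idx < 1 | idx > length(partition))) {
    stop(axis, " cluster index out of range 1..", length(partition))
  }
  idx
}

#' Write a pooling design to JSON
#' @param design a `pooling_design`.
#' @param path output file.
#' @export
write_design <- function(design, path) {
  jsonlite::write_json(
    list(grid_shape = as.list(design$grid_shape),
         item_ids = design$item_ids,
         partition_x = design$partition_x,
         partition_y = design$partition_y),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read a pooling design from JSON
#' @param path file written by [write_design()].
#' @return a `pooling_design`.
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  px <- lapply(x$partition_x, as.character)
  py <- lapply(x$partition_y, as.character)
  rows <- as.integer(x$grid_shape$rows); cols <- as.integer(x$grid_shape$cols)
  grid <- matrix(NA_character_, nrow = rows, ncol = cols)
  for (i in seq_along(px)) for (id in px[[i]]) {
    j <- which(vapply(py, function(cl) id %in% cl, logical(1)))[1]
    grid[i, j] <- id
  }
  structure(
    list(item_ids = as.character(x$item_ids),
         grid_shape = c(rows = rows, cols = cols),
         partition_x = px, partition_y = py, grid = grid),
    class = "pooling_design"
  )
}
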