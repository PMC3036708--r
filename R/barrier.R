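#' Residuals of F_ST regressed on geographic distance
#'
#' Ordinary least squares of the off-diagonal upper-triangle F_ST values on
#' the great-circle distance between population centroids; the residuals,
#' reassembled into a symmetric zero-diagonal matrix, measure genetic
#' differentiation in excess of what geography predicts and are the input
#' to barrier detection.
#'
#' @param fst_matrix a \code{square_distance_matrix} of kind \code{"fst"}.
#' @param centroids data.frame with \code{name}, \code{lat}, \code{lon}
#'   covering the matrix ids (>= 3 populations).
#' @return list with \code{residuals} (a \code{square_distance_matrix} of
#'   kind \code{"fst"}), \code{fit} (the \code{lm}), and \code{geo_km}.
#' @export
residual_fst <- function(fst_matrix, centroids) {
  ids <- fst_matrix$ids
  if (length(ids) < 3) stop("need >= 3 populations")
  idx <- match(ids, centroids$name)
  if (anyNA(idx)) stop("centroid missing for population(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  cen <- centroids[idx, , drop = FALSE]
  geo <- great_circle_matrix(
    data.frame(sample_id = ids, lat = cen$lat, lon = cen$lon))
  g <- .ut(geo$values); f <- .ut(fst_matrix$values)
  if (stats::sd(g) == 0) stop("constant geographic distances; regression undefined")
  fit <- stats::lm(f ~ g)
  R <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  R[upper.tri(R)] <- stats::residuals(fit)
  R <- R + t(R)
  list(residuals = square_distance_matrix(R, ids, "fst"), fit = fit,
       geo_km = geo)
}

# Delaunay triangulation via deldir; returns the triangle index matrix and
# an edge table with adjacency (each edge borders 1 or 2 triangles).
.delaunay_edges <- function(centroids) {
  dd <- try(deldir::deldir(centroids$lon, centroids$lat,
                           suppressMsge = TRUE), silent = TRUE)
  if (inherits(dd, "try-error"))
    stop("Delaunay triangulation failed (collinear centroids?)")
  tri <- try(deldir::triMat(dd), silent = TRUE)
  if (inherits(tri, "try-error") || is.null(tri) || length(tri) == 0)
    stop("Delaunay triangulation failed (collinear centroids?)")
  if (!is.matrix(tri)) tri <- matrix(tri, ncol = 3)  # single triangle
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edges <- new.env()
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    for (e in list(c(v[1], v[2]), c(v[1], v[3]), c(v[2], v[3]))) {
      k <- ekey(e[1], e[2])
      edges[[k]] <- c(edges[[k]], t)
    }
  }
  keys <- ls(edges)
  ij <- do.call(rbind, strsplit(keys, " "))
  data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
             t1 = vapply(keys, function(k) edges[[k]][1], 1L),
             t2 = vapply(keys, function(k)
               if (length(edges[[k]]) > 1) edges[[k]][2] else NA_integer_, 1L),
             row.names = NULL) -> et
  list(triangles = tri, edges = et)
}

#' Monmonier maximum-difference barriers between population centroids
#'
#' Delaunay-triangulates the centroids and weights each triangulation edge
#' with the (residual) genetic distance of its endpoint pair.  A barrier
#' starts across the maximum-weight unused edge and extends from both ends:
#' at each step it crosses the adjacent not-yet-crossed edge of maximal
#' weight of the triangle it is traversing, stopping when it crosses a
#' convex-hull edge or is blocked by an already-crossed edge.  Ties are
#' broken by the lower sorted population-pair index.  Repeated
#' \code{n_barriers} times; no edge is crossed by two barriers.
#'
#' @param residuals a \code{square_distance_matrix} (typically from
#'   \code{\link{residual_fst}}).
#' @param centroids data.frame with \code{name}, \code{lat}, \code{lon}
#'   (>= 3, not collinear).
#' @param n_barriers number of barriers to trace (>= 1).
#' @return list of class \code{barrier_result}: \code{barriers} (list of
#'   data.frames \code{pop_a}, \code{pop_b}, \code{residual}, in crossing
#'   order) and \code{strength} (mean crossed residual per barrier),
#'   ordered by decreasing strength.
#' @export
monmonier_barriers <- function(residuals, centroids, n_barriers = 1) {
  if (n_barriers < 1) stop("n_barriers must be >= 1")
  ids <- residuals$ids
  idx <- match(ids, centroids$name)
  if (anyNA(idx)) stop("centroid missing for population(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  cen <- centroids[idx, , drop = FALSE]
  de <- .delaunay_edges(cen)
  et <- de$edges
  et$w <- residuals$values[cbind(et$i, et$j)]
  et <- et[order(et$i, et$j), , drop = FALSE]  # deterministic tie order
  used <- rep(FALSE, nrow(et))
  edge_of_triangle <- function(t) which(et$t1 == t | (!is.na(et$t2) & et$t2 == t))
  barriers <- list()
  for (bnum in seq_len(n_barriers)) {
    cand <- which(!used)
    if (length(cand) == 0) break
    e0 <- cand[order(-et$w[cand], cand)][1]
    used[e0] <- TRUE
    crossed <- e0
    # extend from both sides of the starting edge
    for (side in c("t1", "t2")) {
      t_cur <- et[[side]][e0]
      entry <- e0
      while (!is.na(t_cur)) {
        adj <- setdiff(edge_of_triangle(t_cur), entry)
        adj <- adj[!used[adj]]
        if (length(adj) == 0) break  # blocked by an existing barrier
        nxt <- adj[order(-et$w[adj], adj)][1]
        used[nxt] <- TRUE
        crossed <- if (side == "t1") c(crossed, nxt) else c(nxt, crossed)
        # move through the crossed edge into the next triangle
        t_new <- if (!is.na(et$t2[nxt]) && et$t2[nxt] != t_cur) et$t2[nxt]
                 else if (et$t1[nxt] != t_cur) et$t1[nxt] else NA_integer_
        if (is.na(t_new)) break  # crossed a convex-hull edge
        entry <- nxt
        t_cur <- t_new
      }
    }
    barriers[[bnum]] <- data.frame(pop_a = ids[et$i[crossed]],
                                   pop_b = ids[et$j[crossed]],
                                   residual = et$w[crossed])
  }
  strength <- vapply(barriers, function(b) mean(b$residual), 1)
  ord <- order(-strength)
  structure(list(barriers = barriers[ord], strength = strength[ord]),
            class = "barrier_result")
}

#' @export
print.barrier_result <- function(x, ...) {
  cat("barrier_result:", length(x$barriers), "barrier(s)\n")
  for (b in seq_along(x$barriers)) {
    edges <- x$barriers[[b]]
    cat(sprintf("  barrier %d (strength %.4g): %s\n", b, x$strength[b],
                paste(paste0(edges$pop_a, "-", edges$pop_b), collapse = ", ")))
  }
  invisible(x)
}

#' Export barriers as a TSV of crossed edges
#'
#' @param br a \code{barrier_result}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_barriers <- function(br, path) {
  rows <- do.call(rbind, lapply(seq_along(br$barriers), function(b)
    cbind(br$barriers[[b]], barrier_rank = b)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
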