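#' Find contiguous low-order regions (candidate defect sites)
#'
#' Defects sit where the nematic order parameter S is low, but low order
#' does not by itself imply a defect -- in confluent layers cells can be
#' nearly isotropic, so disordered patches are common. This function finds
#' the maximal connected components of the sub-threshold node set
#' `{S < s_th}` and returns each with the centre of mass of its member
#' nodes; those centroids become ROI centres for classification. The
#' default threshold `s_th = 0.15` keeps regions distinct without letting
#' them coalesce.
#'
#' @param order an [order_parameter_field()] result.
#' @param s_th order-parameter threshold, in (0, 1).
#' @param connectivity 8 (default, includes diagonals) or 4.
#' @return a data.frame with one row per region: `x`, `y` (centroid),
#'   `min_S`, `size` (node count), plus a `nodes` list-column of member
#'   node indices (`cbind(i, j)` matrices). Empty data.frame when nothing
#'   is below threshold.
#' @export
find_low_order_regions <- function(order, s_th = 0.15, connectivity = 8L) {
  if (!inherits(order, "order_field"))
    stop_nemadef("`order` must be an order_field", "nemadef_invalid_input")
  if (!is.numeric(s_th) || s_th <= 0 || s_th >= 1)
    stop_nemadef("`s_th` must lie strictly between 0 and 1",
                 "nemadef_parameter_error")
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  labels <- label_components(order$S < s_th, order$periodic,
                             diag = connectivity == "8")
  if (max(labels) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), min_S = numeric(0),
                      size = integer(0)))
  }
  nx <- length(order$x); ny <- length(order$y)
  sub <- which(labels > 0L)
  i <- ((sub - 1L) %% nx) + 1L
  j <- ((sub - 1L) %/% nx) + 1L
  lab <- labels[sub]
  res <- lapply(seq_len(max(lab)), function(k) {
    sel <- lab == k
    ik <- i[sel]; jk <- j[sel]
    ctr <- region_centroid(order$x[ik], order$y[jk], order$box, order$periodic)
    list(x = ctr[1], y = ctr[2], min_S = min(order$S[cbind(ik, jk)]),
         size = sum(sel), nodes = cbind(i = ik, j = jk))
  })
  out <- data.frame(x = vapply(res, `[[`, 0, "x"),
                    y = vapply(res, `[[`, 0, "y"),
                    min_S = vapply(res, `[[`, 0, "min_S"),
                    size = vapply(res, function(r) as.integer(r$size), 0L))
  out$nodes <- lapply(res, `[[`, "nodes")
  out[order(-out$size), , drop = FALSE]
}

## Connected-component labelling of a logical matrix via the adjacency
## graph of TRUE nodes (igraph does the traversal). Handles periodic wrap
## and 4- or 8-connectivity.
label_components <- function(mask, periodic, diag = TRUE) {
  nx <- nrow(mask); ny <- ncol(mask)
  labels <- matrix(0L, nx, ny)
  on <- which(mask)
  if (!length(on)) return(labels)
  id <- matrix(NA_integer_, nx, ny)
  id[on] <- seq_along(on)
  offs <- rbind(c(1L, 0L), c(0L, 1L))
  if (diag) offs <- rbind(offs, c(1L, 1L), c(1L, -1L))
  i <- ((on - 1L) %% nx) + 1L
  j <- ((on - 1L) %/% nx) + 1L
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    i2 <- i + offs[k, 1L]
    j2 <- j + offs[k, 2L]
    if (periodic) {
      i2 <- ((i2 - 1L) %% nx) + 1L
      j2 <- ((j2 - 1L) %% ny) + 1L
      keep <- rep(TRUE, length(i2))
    } else {
      keep <- i2 >= 1L & i2 <= nx & j2 >= 1L & j2 <= ny
    }
    if (!any(keep)) next
    nb <- id[cbind(i2[keep], j2[keep])]
    src <- id[cbind(i[keep], j[keep])]
    ok <- !is.na(nb)
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(src[ok], nb[ok])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, c(list(matrix(0L, 0, 2)), edges)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(on) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  labels[on] <- as.integer(comp)
  labels
}

## Centre of mass of node coordinates; on a torus the mean is taken on the
## circle for each axis so regions straddling the wrap get sensible centres.
region_centroid <- function(xs, ys, box, periodic) {
  if (!periodic) return(c(mean(xs), mean(ys)))
  circ_mean <- function(v, L) {
    a <- v / L * 2 * pi
    (atan2(mean(sin(a)), mean(cos(a))) / (2 * pi) * L) %% L
  }
  c(circ_mean(xs, box[1]), circ_mean(ys, box[2]))
}

#' Crop a square director region of interest (ROI)
#'
#' Crops a `side_points` x `side_points` patch of directors spanning
#' `roi_span`, centred on a candidate point, by nearest-grid-node lookup
#' on the fine grid (the ROI grid is a sub-sampling of the fine grid, no
#' re-interpolation). The physical span should contain roughly 5-7 cells:
#' large enough to capture a defect core, small enough to isolate a single
#' defect.
#'
#' @param grid a [build_director_grid()] result.
#' @param center numeric length-2 ROI centre (length units).
#' @param side_points odd integer, patch side in nodes (default 9).
#' @param roi_span physical side length; default 6 cell diameters.
#' @param label optional class label attached to the ROI.
#' @param source_id provenance string.
#' @return an object of class `defect_roi`: `theta` (`side_points^2`
#'   matrix, `[i, j]` = x, y), `center`, `spacing` (ROI node step),
#'   `label`, `source_id`.
#' @export
extract_roi <- function(grid, center, side_points = 9L, roi_span = NULL,
                        label = NULL, source_id = NA_character_) {
  if (!inherits(grid, "director_grid"))
    stop_nemadef("`grid` must be a director_grid", "nemadef_invalid_input")
  side_points <- as.integer(side_points)
  if (side_points < 3L || side_points %% 2L == 0L)
    stop_nemadef("`side_points` must be an odd integer >= 3",
                 "nemadef_parameter_error")
  if (is.null(roi_span)) roi_span <- 6 * grid$cell_d
  step <- roi_span / (side_points - 1L)
  offs <- (seq_len(side_points) - (side_points + 1L) / 2) * step
  px <- center[1] + offs
  py <- center[2] + offs
  if (!grid$periodic &&
      (min(px) < min(grid$x) - grid$spacing[1] / 2 ||
       max(px) > max(grid$x) + grid$spacing[1] / 2 ||
       min(py) < min(grid$y) - grid$spacing[2] / 2 ||
       max(py) > max(grid$y) + grid$spacing[2] / 2))
    stop_nemadef("ROI crosses a non-periodic domain boundary",
                 "nemadef_boundary_error")
  ii <- nearest_index(px, grid$x, grid$box[1], grid$periodic, grid$spacing[1])
  jj <- nearest_index(py, grid$y, grid$box[2], grid$periodic, grid$spacing[2])
  theta <- grid$theta[ii, jj, drop = FALSE]
  new_roi(theta, center = center, spacing = step, label = label,
          source_id = source_id)
}

nearest_index <- function(p, nodes, L, periodic, step) {
  if (periodic) {
    (round((p %% L) / step) %% length(nodes)) + 1L
  } else {
    pmin(pmax(round(p / step) + 1L, 1L), length(nodes))
  }
}

new_roi <- function(theta, center = c(NA_real_, NA_real_), spacing = NA_real_,
                    label = NULL, source_id = NA_character_) {
  structure(list(theta = theta, center = as.numeric(center),
                 spacing = spacing, label = label, source_id = source_id),
            class = "defect_roi")
}

#' @export
print.defect_roi <- function(x, ...) {
  cat(sprintf("<defect_roi> %d x %d directors, centre (%.3g, %.3g), step %.3g%s\n",
              nrow(x$theta), ncol(x$theta), x$center[1], x$center[2],
              x$spacing,
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' @export
plot.defect_roi <- function(x, len = 0.8, ...) {
  n <- nrow(x$theta)
  offs <- (seq_len(n) - (n + 1) / 2)
  px <- rep(offs, times = n); py <- rep(offs, each = n)
  th <- as.vector(x$theta)
  h <- len / 2
  graphics::plot(NA, xlim = range(offs) + c(-1, 1), ylim = range(offs) + c(-1, 1),
                 asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  graphics::segments(px - h * cos(th), py - h * sin(th),
                     px + h * cos(th), py + h * sin(th))
  invisible(x)
}
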