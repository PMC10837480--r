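#' Defect class labels
#'
#' The fixed three-class alphabet used throughout the package, in the
#' order `+1/2`, `none`, `-1/2`. The order is serialized with trained
#' models to prevent label-permutation bugs.
#'
#' @return character vector of length 3.
#' @export
defect_classes <- function() c("+1/2", "none", "-1/2")

#' Boundary loop of an ROI
#'
#' The perimeter nodes of a square director patch in counter-clockwise
#' order, starting at the bottom-left corner. A `side_points` patch yields
#' `4 * (side_points - 1)` directors (32 for the standard 9x9 ROI).
#'
#' @param roi a [extract_roi()] result (or any `defect_roi`).
#' @return numeric vector of directors in loop order, class
#'   `boundary_loop`.
#' @export
boundary_loop <- function(roi) {
  th <- if (inherits(roi, "defect_roi")) roi$theta else roi
  n <- nrow(th)
  if (is.null(n) || n < 3L || ncol(th) != n)
    stop_nemadef("ROI must be a square patch at least 3 x 3",
                 "nemadef_invalid_input")
  # theta[i, j]: i along x, j along y; bottom edge is j = 1
  loop <- c(th[1:n, 1],            # bottom, left -> right
            th[n, 2:n],            # right, bottom -> top
            th[(n - 1):1, n],      # top, right -> left
            th[1, (n - 1):2])      # left, top -> bottom
  structure(loop, class = "boundary_loop")
}

#' Winding charge of a director loop
#'
#' Accumulates the rotation of the nematic field along a closed
#' counter-clockwise loop. Each successive director difference is wrapped
#' into `(-pi/2, pi/2]` (differences of directors are only defined modulo
#' pi; an exact pi/2 jump is kept positive so ties break
#' deterministically). Because the loop is closed, the total rotation T is
#' always an integer multiple of pi; the charge is `k = T / (2 pi)`, and
#' the generic nematic defects carry `k = +1/2` (comet) or `k = -1/2`
#' (trefoil). The field rotating with the loop direction gives a positive
#' charge.
#'
#' @param loop a [boundary_loop()] or numeric vector of directors in loop
#'   order (closed implicitly: the first element follows the last).
#' @param tol acceptance tolerance in charge units; `|k - 1/2| < tol` is
#'   `+1/2`, `|k + 1/2| < tol` is `-1/2`, `|k| < tol` is `none`, anything
#'   else `other`.
#' @return the class label, with attributes `charge` (numeric k) and
#'   `rotation` (T in radians).
#' @export
winding_charge <- function(loop, tol = 0.1) {
  th <- as.numeric(loop)
  if (length(th) < 3L)
    stop_nemadef("loop needs at least 3 directors", "nemadef_invalid_input")
  d <- wrap_half_pi(diff(c(th, th[1L])))
  total <- sum(d)
  k <- total / (2 * pi)
  lab <- if (abs(k - 0.5) < tol) "+1/2"
         else if (abs(k + 0.5) < tol) "-1/2"
         else if (abs(k) < tol) "none"
         else "other"
  structure(lab, charge = k, rotation = total)
}

#' Classify an ROI by its boundary winding number
#'
#' The off-lattice baseline classifier: the winding number of the director
#' field around the edge of the ROI. Uses only perimeter information,
#' which is why disordered non-defect regions can fool it -- the contrast
#' the CNN classifier is designed to exploit.
#'
#' @inheritParams boundary_loop
#' @inheritParams winding_charge
#' @return class label (`+1/2`, `none`, `-1/2`, or `other`) with `charge`
#'   and `rotation` attributes.
#' @export
classify_roi_winding <- function(roi, tol = 0.1) {
  winding_charge(boundary_loop(roi), tol = tol)
}

#' Legacy on-lattice winding-number detection
#'
#' The predefined-lattice method used before off-lattice detection: the
#' winding number is evaluated on a small square loop of fine-grid nodes
#' around each node of a coarse lattice, and lattice nodes with charge
#' +-1/2 are reported as defects *at the lattice point*. Positional error
#' is therefore bounded by the lattice, up to `lattice_spacing / sqrt(2)`.
#'
#' @param grid a [build_director_grid()] result.
#' @param lattice_spacing coarse lattice step (length units); must be at
#'   least the fine-grid spacing.
#' @param loop_span physical side of the square evaluation loop; defaults
#'   to `lattice_spacing`.
#' @return a `data.frame` of defect records: `x`, `y`, `class`, `charge`,
#'   `method = "winding-on-lattice"`.
#' @export
classify_on_lattice <- function(grid, lattice_spacing, loop_span = lattice_spacing,
                                tol = 0.1) {
  if (!inherits(grid, "director_grid"))
    stop_nemadef("`grid` must be a director_grid", "nemadef_invalid_input")
  if (lattice_spacing < max(grid$spacing))
    stop_nemadef("`lattice_spacing` must be at least the grid spacing",
                 "nemadef_parameter_error")
  side <- max(3L, 2L * round(loop_span / (2 * min(grid$spacing))) + 1L)
  lx <- seq(lattice_spacing / 2, grid$box[1] - lattice_spacing / 2,
            by = lattice_spacing)
  ly <- seq(lattice_spacing / 2, grid$box[2] - lattice_spacing / 2,
            by = lattice_spacing)
  rec <- list()
  for (cx in lx) for (cy in ly) {
    roi <- tryCatch(
      extract_roi(grid, c(cx, cy), side_points = side, roi_span = loop_span),
      nemadef_boundary_error = function(e) NULL)
    if (is.null(roi)) next
    lab <- classify_roi_winding(roi, tol = tol)
    if (lab %in% c("+1/2", "-1/2")) {
      rec[[length(rec) + 1L]] <- data.frame(
        x = cx, y = cy, class = as.character(lab),
        charge = attr(lab, "charge"), method = "winding-on-lattice")
    }
  }
  if (!length(rec)) {
    return(data.frame(x = numeric(0), y = numeric(0), class = character(0),
                      charge = numeric(0), method = character(0)))
  }
  do.call(rbind, rec)
}
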