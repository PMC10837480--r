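#' Detect and classify nematic defects in a cell frame
#'
#' The full pipeline: build the smoothed director field and order
#' parameter on a fine grid, find contiguous low-order regions, crop a
#' 9x9 director ROI at each region centroid, classify each ROI (by
#' boundary winding number or by a trained CNN), and estimate the
#' polarity of +1/2 detections. The legacy `winding-on-lattice` method
#' bypasses candidate detection and scans a predefined coarse lattice.
#'
#' @param frame a [cell_frame()].
#' @param method `"winding"` (default), `"cnn"`, or
#'   `"winding-on-lattice"`.
#' @param model a trained [train_defect_cnn()] model (required for
#'   `method = "cnn"`).
#' @param spacing,window fine-grid parameters, see
#'   [build_director_grid()].
#' @param s_th low-order threshold, see [find_low_order_regions()].
#' @param connectivity region connectivity (8 or 4).
#' @param side_points,roi_span ROI geometry, see [extract_roi()].
#' @param tol winding acceptance tolerance in charge units.
#' @param lattice_spacing coarse lattice step for the on-lattice method
#'   (default 2 cell diameters).
#' @param keep_all if `TRUE`, candidate ROIs classified `none`/`other`
#'   are kept in the table (useful for scoring candidates against ground
#'   truth); by default only defects are returned.
#' @return a data.frame of defect records: `x`, `y`, `class`, `charge`
#'   (winding paths), `p_pos`, `p_none`, `p_neg` (CNN path), `psi`
#'   (+1/2 polarity or `NA`), `min_S`, `region_size`, `method`.
#' @export
detect_defects <- function(frame, method = c("winding", "cnn", "winding-on-lattice"),
                           model = NULL, spacing = NULL, window = NULL,
                           s_th = 0.15, connectivity = 8L,
                           side_points = 9L, roi_span = NULL, tol = 0.1,
                           lattice_spacing = NULL, keep_all = FALSE) {
  method <- match.arg(method)
  grid <- build_director_grid(frame, spacing = spacing, window = window)
  empty <- data.frame(x = numeric(0), y = numeric(0), class = character(0),
                      charge = numeric(0), p_pos = numeric(0),
                      p_none = numeric(0), p_neg = numeric(0),
                      psi = numeric(0), min_S = numeric(0),
                      region_size = integer(0), method = character(0))
  if (method == "winding-on-lattice") {
    if (is.null(lattice_spacing)) lattice_spacing <- 2 * grid$cell_d
    rec <- classify_on_lattice(grid, lattice_spacing, tol = tol)
    if (!nrow(rec)) return(empty)
    rec$p_pos <- rec$p_none <- rec$p_neg <- NA_real_
    rec$psi <- NA_real_
    rec$min_S <- NA_real_; rec$region_size <- NA_integer_
    rec$psi[rec$class == "+1/2"] <-
      vapply(which(rec$class == "+1/2"),
             function(r) polarity_or_na(grid, c(rec$x[r], rec$y[r])), 0)
    return(rec[, names(empty)])
  }
  if (method == "cnn" && !inherits(model, "defect_cnn"))
    stop_nemadef("method = \"cnn\" needs a trained defect_cnn model",
                 "nemadef_parameter_error")
  order <- order_parameter_field(grid)
  regions <- find_low_order_regions(order, s_th = s_th,
                                    connectivity = connectivity)
  if (!nrow(regions)) return(empty)
  rows <- lapply(seq_len(nrow(regions)), function(r) {
    roi <- tryCatch(
      extract_roi(grid, c(regions$x[r], regions$y[r]),
                  side_points = side_points, roi_span = roi_span),
      nemadef_boundary_error = function(e) {
        warning(sprintf("candidate at (%.2f, %.2f) crosses the domain boundary; skipped",
                        regions$x[r], regions$y[r]))
        NULL
      })
    if (is.null(roi)) return(NULL)
    out <- data.frame(x = regions$x[r], y = regions$y[r],
                      class = NA_character_, charge = NA_real_,
                      p_pos = NA_real_, p_none = NA_real_, p_neg = NA_real_,
                      psi = NA_real_, min_S = regions$min_S[r],
                      region_size = regions$size[r], method = method)
    if (method == "winding") {
      lab <- classify_roi_winding(roi, tol = tol)
      out$class <- as.character(lab)
      out$charge <- attr(lab, "charge")
    } else {
      p <- predict(model, roi, type = "prob")
      out$class <- model$classes[max.col(p)]
      out$p_pos <- p[1, 1]; out$p_none <- p[1, 2]; out$p_neg <- p[1, 3]
    }
    if (out$class == "+1/2")
      out$psi <- polarity_or_na(grid, c(out$x, out$y))
    out
  })
  rec <- do.call(rbind, rows)
  if (is.null(rec)) return(empty)
  if (!keep_all) rec <- rec[rec$class %in% c("+1/2", "-1/2"), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

polarity_or_na <- function(grid, core) {
  tryCatch(defect_polarity(grid, core),
           nemadef_polarity_error = function(e) {
             warning("polarity undefined at a +1/2 detection; recorded as NA")
             NA_real_
           })
}
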