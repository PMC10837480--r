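#' Cell frame: one segmented snapshot of a confluent layer
#'
#' A `cell_frame` holds the per-cell output of standard segmentation
#' software for a single image or simulation snapshot: the x and y
#' coordinates of each cell's centre of mass, the orientation of its long
#' axis in radians (a nematic quantity, stored reduced modulo pi), and
#' optionally per-cell velocity components used for defect-property
#' averaging.
#'
#' @param cells data.frame with columns `x`, `y`, `theta` and optionally
#'   `vx`, `vy`.
#' @param box numeric length-2, the domain extents `(Lx, Ly)`; cells live in
#'   `[0, Lx) x [0, Ly)`.
#' @param periodic logical; `TRUE` for simulation data on a torus, `FALSE`
#'   for experimental images.
#' @return an object of class `cell_frame`.
#' @seealso [read_cell_frames()], [build_director_grid()], [generate_frame()]
#' @export
cell_frame <- function(cells, box, periodic = FALSE) {
  if (!is.data.frame(cells) || !all(c("x", "y", "theta") %in% names(cells)))
    stop_nemadef("`cells` must be a data.frame with columns x, y, theta",
                 "nemadef_invalid_input")
  if (nrow(cells) < 3L)
    stop_nemadef("a frame needs at least 3 cells to interpolate a field",
                 "nemadef_invalid_input")
  box <- as.numeric(box)
  if (length(box) != 2L || any(!is.finite(box)) || any(box <= 0))
    stop_nemadef("`box` must be two positive lengths (Lx, Ly)",
                 "nemadef_parameter_error")
  cells$theta <- reduce_mod_pi(cells$theta)
  if (periodic) {
    cells$x <- cells$x %% box[1]
    cells$y <- cells$y %% box[2]
  } else if (any(cells$x < 0 | cells$x > box[1] | cells$y < 0 | cells$y > box[2])) {
    stop_nemadef("cell centroids fall outside the box", "nemadef_invalid_input")
  }
  structure(list(cells = cells, box = box, periodic = isTRUE(periodic)),
            class = "cell_frame")
}

#' @export
print.cell_frame <- function(x, ...) {
  cat(sprintf("<cell_frame> %d cells in %.3g x %.3g box (%s)%s\n",
              nrow(x$cells), x$box[1], x$box[2],
              if (x$periodic) "periodic" else "bounded",
              if ("vx" %in% names(x$cells)) ", with velocities" else ""))
  invisible(x)
}

#' Typical cell diameter of a frame
#'
#' Estimated from the number density as `sqrt(box area / n cells)`; used as
#' the natural length unit for grid spacing, smoothing windows and ROI
#' spans.
#'
#' @param frame a [cell_frame()].
#' @return scalar length.
#' @export
cell_diameter <- function(frame) {
  sqrt(prod(frame$box) / nrow(frame$cells))
}

#' Read cell frames from delimited text
#'
#' Reads the delimited-text export format of segmentation pipelines: a
#' header line naming at least `x,y,theta`, optional `vx,vy`, and an
#' optional `frame` column when several snapshots share one file. Lines
#' starting with `#` are metadata comments (the package's own writers
#' record the box, seed and config hash there).
#'
#' @param path file path.
#' @param box numeric length-2 domain size; if `NULL`, taken from a
#'   `# box: Lx Ly` comment in the file, else inferred from the data extent
#'   (with a warning).
#' @param periodic logical.
#' @param degrees if `TRUE`, `theta` is converted from degrees to radians.
#' @param sep field separator, default `","`.
#' @return a list of [cell_frame()] objects, one per frame.
#' @export
read_cell_frames <- function(path, box = NULL, periodic = FALSE,
                             degrees = FALSE, sep = ",") {
  header <- grep("^#", readLines(path, n = 50L), value = TRUE)
  if (is.null(box)) {
    bl <- grep("^#\\s*box:", header, value = TRUE)
    if (length(bl)) {
      box <- as.numeric(strsplit(trimws(sub("^#\\s*box:", "", bl[1])), "\\s+")[[1]])
    }
  }
  pl <- grep("^#\\s*periodic:", header, value = TRUE)
  if (length(pl)) periodic <- isTRUE(as.logical(trimws(sub("^#\\s*periodic:", "", pl[1]))))
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  miss <- setdiff(c("x", "y", "theta"), names(d))
  if (length(miss))
    stop_nemadef(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
                 "nemadef_invalid_input")
  if (degrees) d$theta <- d$theta * pi / 180
  if (is.null(box)) {
    box <- c(max(d$x), max(d$y)) * 1.001
    warning("no box size given or recorded; inferred from data extent")
  }
  frames <- if ("frame" %in% names(d)) split(d, d$frame) else list(d)
  lapply(frames, function(f) {
    cell_frame(f[, intersect(c("x", "y", "theta", "vx", "vy"), names(f))],
               box = box, periodic = periodic)
  })
}

#' Write a cell frame to delimited text
#'
#' @param frame a [cell_frame()].
#' @param path output file path.
#' @param meta named list of extra metadata written as `# key: value`
#'   comment lines (e.g. seed, config hash).
#' @return `path`, invisibly.
#' @export
write_cell_frame <- function(frame, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box: %.17g %.17g", frame$box[1], frame$box[2]), con)
  writeLines(sprintf("# periodic: %s", frame$periodic), con)
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(frame$cells, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
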