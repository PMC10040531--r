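# Idealized 2D atrium + appendage geometry on a masked Cartesian grid.
#
# The atrial body is a straight channel (pulmonary-vein inlets on the left
# boundary, mitral outlet at the right end of a downstream extension). The
# appendage is one or more rectangular pouches hanging below the channel
# floor, optionally tilted by a bend angle. The neck plane (the channel
# floor, y = 0) defines LAA membership: every fluid cell with center below
# y = 0 belongs to the appendage mask.
#
# Cell-label codes used throughout the package (and in src/):
#   0 = WALL, 1 = FLUID, 2 = OUTLET, 3 + k = k-th inlet (k = 0, 1, ...).
# The grid is cell-centered with half-open rasterization [x, x + h); R
# matrices are 1-based, so R cell (i, j) corresponds to the 0-based cell
# (i - 1, j - 1) of the stated convention, with the origin at the lower
# left corner of the channel.

.CELL_WALL <- 0L
.CELL_FLUID <- 1L
.CELL_OUTLET <- 2L
.CELL_INLET0 <- 3L

#' Geometry specification for an idealized atrium + appendage domain
#'
#' @param channel_length Length of the atrial channel proper, m.
#' @param channel_height Channel height, m.
#' @param pouch_depth Appendage pouch depth along its axis, m (0 = no pouch).
#' @param pouch_neck_width Pouch neck (ostium) width, m.
#' @param pouch_bend_angle Tilt of the pouch axis from vertical, degrees.
#' @param n_lobes Number of pouch lobes (>= 1).
#' @param n_inlets Number of pulmonary-vein inlets on the upstream boundary.
#' @param inlet_widths Widths of the inlets, m; default `channel_height / 8`
#'   each.
#' @param outlet_extension_length Downstream outlet extension, m (default 5
#'   channel heights, to keep the outlet boundary away from the pouch).
#' @param h Cell size, m. The neck must be resolved by at least 4 cells.
#' @return An object of class `geometry_spec`.
#' @examples
#' geometry_spec(pouch_depth = 0.006)
#' @export
geometry_spec <- function(channel_length = 0.03,
                          channel_height = 0.01,
                          pouch_depth = 0.006,
                          pouch_neck_width = 0.005,
                          pouch_bend_angle = 0,
                          n_lobes = 1L,
                          n_inlets = 4L,
                          inlet_widths = NULL,
                          outlet_extension_length = 5 * channel_height,
                          h = channel_height / 12) {
  if (is.null(inlet_widths)) inlet_widths <- rep(channel_height / 8, n_inlets)
  spec <- structure(list(
    channel_length = channel_length, channel_height = channel_height,
    pouch_depth = pouch_depth, pouch_neck_width = pouch_neck_width,
    pouch_bend_angle = pouch_bend_angle, n_lobes = as.integer(n_lobes),
    n_inlets = as.integer(n_inlets), inlet_widths = inlet_widths,
    outlet_extension_length = outlet_extension_length, h = h),
    class = "geometry_spec")
  validate_geometry_spec(spec)
  spec
}

validate_geometry_spec <- function(spec) {
  with(spec, {
    stopifnot(channel_length > 0, channel_height > 0, h > 0,
              pouch_depth >= 0, outlet_extension_length >= 0,
              n_lobes >= 1L, n_inlets >= 1L,
              length(inlet_widths) == n_inlets, all(inlet_widths > 0),
              sum(inlet_widths) <= channel_height)
    if (pouch_depth > 0) {
      stopifnot(pouch_neck_width > 0, pouch_neck_width < channel_length,
                abs(pouch_bend_angle) < 90)
      if (pouch_neck_width / h < 4)
        stop("configuration error: pouch neck resolved by fewer than 4 cells")
    }
  })
  invisible(spec)
}

#' Rasterize a geometry specification onto a masked Cartesian grid
#'
#' @param spec A [geometry_spec()] object.
#' @return An object of class `laa_grid`: a list with `nx`, `ny`, `h`, the
#'   integer cell-label matrix `lab` (see package conventions), the logical
#'   appendage mask `laa`, the physical coordinates of cell centers
#'   (`xc`, `yc`) and the originating `spec`.
#' @examples
#' g <- build_geometry(geometry_spec())
#' table(g$lab)
#' @export
build_geometry <- function(spec) {
  validate_geometry_spec(spec)
  h <- spec$h
  nL <- round(spec$channel_length / h)
  nE <- round(spec$outlet_extension_length / h)
  nH <- round(spec$channel_height / h)
  th <- spec$pouch_bend_angle * pi / 180

  # vertical extent of the (possibly bent) pouch rectangle below y = 0
  d_vert <- if (spec$pouch_depth > 0)
    spec$pouch_depth * cos(th) + 0.5 * spec$pouch_neck_width * abs(sin(th))
  else 0
  nP <- ceiling(d_vert / h - 1e-12)

  nx <- nL + nE + 2L           # + inlet ghost column + outlet ghost column
  ny <- nP + nH + 2L           # + bottom and top ghost rows
  xc <- (seq_len(nx) - 1.5) * h
  yc <- (seq_len(ny) - 1.5 - nP) * h

  lab <- matrix(.CELL_WALL, nx, ny)
  jch <- (nP + 2L):(nP + nH + 1L)     # channel rows
  lab[2:(nL + nE + 1L), jch] <- .CELL_FLUID

  # pouch lobes: rotated rectangles hanging from the channel floor
  if (spec$pouch_depth > 0) {
    centers <- spec$channel_length * seq_len(spec$n_lobes) /
      (spec$n_lobes + 1)
    ok <- centers > spec$pouch_neck_width / 2 + h &
      centers < spec$channel_length - spec$pouch_neck_width / 2 - h
    if (!all(ok))
      stop("configuration error: pouch lobes do not fit under the channel")
    jp <- if (nP > 0) 2:(nP + 1L) else integer(0)   # pouch rows
    for (l in seq_len(spec$n_lobes)) {
      thl <- th * (-1)^(l - 1)       # alternate bend direction per lobe
      ax <- sin(thl); ay <- -cos(thl)
      for (j in jp) for (i in 2:(nL + 1L)) {
        dx <- xc[i] - centers[l]; dy <- yc[j]
        s <- dx * ax + dy * ay                  # along pouch axis
        t <- dx * cos(thl) + dy * sin(thl)      # across pouch axis
        if (s >= 0 && s < spec$pouch_depth &&
            abs(t) <= spec$pouch_neck_width / 2)
          lab[i, j] <- .CELL_FLUID
      }
    }
  }

  # inlets on the left ghost column, stacked bottom-up with equal gaps
  gap <- (spec$channel_height - sum(spec$inlet_widths)) / (spec$n_inlets + 1)
  lo <- gap + c(0, cumsum(spec$inlet_widths + gap))[seq_len(spec$n_inlets)]
  n_in <- 0L
  for (k in seq_len(spec$n_inlets)) {
    jk <- jch[yc[jch] >= lo[k] & yc[jch] < lo[k] + spec$inlet_widths[k]]
    jk <- jk[lab[2L, jk] == .CELL_FLUID]
    if (length(jk) == 0)
      stop("configuration error: inlet ", k, " unresolved at cell size h")
    lab[1L, jk] <- .CELL_INLET0 + (k - 1L)
    n_in <- n_in + length(jk)
  }

  # outlet on the right ghost column
  jo <- jch[lab[nL + nE + 1L, jch] == .CELL_FLUID]
  lab[nx, jo] <- .CELL_OUTLET

  laa <- lab == .CELL_FLUID & outer(rep(TRUE, nx), yc < 0)
  if (spec$pouch_depth > 0 && !any(laa))
    stop("configuration error: pouch specified but no appendage cells")
  grid <- structure(list(nx = nx, ny = ny, h = h, lab = lab, laa = laa,
                         xc = xc, yc = yc, spec = spec),
                    class = "laa_grid")
  ncomp <- laa_components(grid)
  if (spec$pouch_depth > 0 && ncomp != spec$n_lobes)
    warning("appendage mask has ", ncomp, " connected components for ",
            spec$n_lobes, " lobes (resolution too coarse for the bend?)")
  grid
}

#' @export
print.laa_grid <- function(x, ...) {
  cat("<laa_grid> ", x$nx, "x", x$ny, " cells, h = ", signif(x$h, 4),
      " m\n  fluid: ", sum(x$lab == .CELL_FLUID),
      "  appendage: ", sum(x$laa),
      "  inlets: ", length(unique(x$lab[x$lab >= .CELL_INLET0])), "\n",
      sep = "")
  invisible(x)
}

#' Appendage area
#'
#' Area covered by the appendage mask: `h^2` times the number of masked
#' cells (the 2D analogue of the appendage volume used to average the
#' tracer concentration).
#'
#' @param grid An `laa_grid`.
#' @return Area in m^2.
#' @export
laa_area <- function(grid) {
  stopifnot(inherits(grid, "laa_grid"))
  grid$h^2 * sum(grid$laa)
}

# Number of 4-connected components of the appendage mask (BFS flood fill).
laa_components <- function(grid) {
  m <- grid$laa
  seen <- matrix(FALSE, nrow(m), ncol(m))
  ncomp <- 0L
  idx <- which(m, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    if (seen[idx[r, 1], idx[r, 2]]) next
    ncomp <- ncomp + 1L
    queue <- list(idx[r, ])
    seen[idx[r, 1], idx[r, 2]] <- TRUE
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        i <- c0[1] + d[1]; j <- c0[2] + d[2]
        if (i >= 1 && i <= nrow(m) && j >= 1 && j <= ncol(m) &&
            m[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          queue[[length(queue) + 1]] <- c(i, j)
        }
      }
    }
  }
  ncomp
}

#' Write a grid (and optional cell fields) as a legacy VTK structured file
#'
#' Exports cell labels, the appendage mask and any additional cell-centered
#' scalar fields as an ASCII legacy-VTK STRUCTURED_POINTS dataset readable
#' by ParaView.
#'
#' @param grid An `laa_grid`.
#' @param file Output path.
#' @param fields Named list of `nx x ny` numeric matrices to append as
#'   additional CELL_DATA scalars.
#' @return `file`, invisibly.
#' @export
write_vtk_grid <- function(grid, file, fields = list()) {
  stopifnot(inherits(grid, "laa_grid"))
  con <- file(file, "w")
  on.exit(close(con))
  nx <- grid$nx; ny <- grid$ny
  writeLines(c("# vtk DataFile Version 3.0",
               "laawash masked grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx + 1L, ny + 1L),
               sprintf("ORIGIN %g %g 0", grid$xc[1] - grid$h / 2,
                       grid$yc[1] - grid$h / 2),
               sprintf("SPACING %g %g 1", grid$h, grid$h),
               sprintf("CELL_DATA %d", nx * ny)), con)
  emit <- function(name, m) {
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(formatC(as.vector(m), format = "g"), collapse = "\n"),
               con)
  }
  emit("label", grid$lab)
  emit("laa", grid$laa * 1)
  for (nm in names(fields)) emit(nm, fields[[nm]])
  invisible(file)
}
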