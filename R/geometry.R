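#' Hexagonal cell shape (regular or axially elongated)
#'
#' Cells are hexagons with perimeter 2*pi, parametrised by the arclength
#' width `delta` of the two edges facing the horizontal axis (contact-
#' surface midpoints at theta = 0 and pi).  The four oblique edges each have
#' width `delta_p = (pi - delta)/2`, so that `2*delta + 4*delta_p = 2*pi`.
#' Edge midpoints sit at theta = 0, (pi+delta)/4, (3pi-delta)/4, pi,
#' -(3pi-delta)/4, -(pi+delta)/4 (arclength midpoints of the contact
#' surfaces in the cell's own boundary coordinate).
#'
#' @param delta arc width of the axis-facing edges, radians, in (0, pi).
#'   `delta = pi/3` is the regular hexagon.
#' @return object of class `hex_cell_shape` with fields `delta`, `delta_p`,
#'   `midpoints` (length 6, order E, NE, NW, W, SW, SE) and `widths`.
#' @export
#' @examples
#' hex_shape(pi / 3)$midpoints  # multiples of pi/3
hex_shape <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) == 1)
  if (delta <= 0 || delta >= pi) stop("delta must lie in (0, pi)")
  delta_p <- (pi - delta) / 2
  mids <- c(0, (pi + delta) / 4, (3 * pi - delta) / 4, pi,
            -(3 * pi - delta) / 4, -(pi + delta) / 4)
  structure(list(delta = delta, delta_p = delta_p,
                 midpoints = wrap_angle(mids),
                 widths = c(delta, delta_p, delta_p, delta, delta_p,
                            delta_p)),
            class = "hex_cell_shape")
}

# Neighbour offsets for the six hex directions on an odd-row-offset grid.
# Order matches hex_shape: E, NE, NW, W, SW, SE.
.hex_offsets <- function(row) {
  if (row %% 2 == 0) {
    list(E = c(0, 1), NE = c(1, 0), NW = c(1, -1), W = c(0, -1),
         SW = c(-1, -1), SE = c(-1, 0))
  } else {
    list(E = c(0, 1), NE = c(1, 1), NW = c(1, 0), W = c(0, -1),
         SW = c(-1, 0), SE = c(-1, 1))
  }
}

.tissue_from_cells <- function(cells, shape, periodic_dims = NULL,
                               kind = "custom") {
  # cells: data.frame(row, col); periodic_dims: c(rows, cols) or NULL
  key <- paste(cells$row, cells$col)
  if (anyDuplicated(key)) stop("duplicate cells in tissue specification")
  index <- seq_len(nrow(cells))
  names(index) <- key
  eN <- list()
  dirs <- c("E", "NE", "NW", "W", "SW", "SE")
  from <- integer(0); to <- integer(0); dir_id <- integer(0)
  for (i in index) {
    r <- cells$row[i]; c0 <- cells$col[i]
    off <- .hex_offsets(r)
    for (d in seq_along(dirs)) {
      rr <- r + off[[d]][1]; cc <- c0 + off[[d]][2]
      if (!is.null(periodic_dims)) {
        # NA marks a non-periodic dimension (e.g. the single row of a
        # periodic chain must not wrap onto itself)
        if (!is.na(periodic_dims[1])) rr <- rr %% periodic_dims[1]
        if (!is.na(periodic_dims[2])) cc <- cc %% periodic_dims[2]
      }
      j <- index[paste(rr, cc)]
      if (!is.na(j) && j != i) {
        from <- c(from, i); to <- c(to, j); dir_id <- c(dir_id, d)
      }
    }
  }
  edges <- data.frame(i = from, j = to,
                      eta = shape$midpoints[dir_id],
                      d = shape$widths[dir_id],
                      alpha = rep(0, length(from)))
  n_nb <- tabulate(edges$i, nbins = nrow(cells))
  structure(list(cells = cells, edges = edges, shape = shape,
                 boundary = n_nb < 6L, kind = kind,
                 periodic = !is.null(periodic_dims)),
            class = "tissue_graph")
}

#' Build a tissue graph
#'
#' Constructs the directed contact-edge graph for one of the supported cell
#' alignments.  Every edge `i -> j` carries the contact-surface midpoint
#' `eta_ij` (radians, in the boundary coordinate of cell `i`), its width
#' `d_ij`, and a coupling heterogeneity factor `alpha_ij` (default 0).  The
#' reverse edge always exists with `eta_ji = wrap(eta_ij + pi)` and
#' `d_ji = d_ij`.
#'
#' @param spec a list with element `kind` plus kind-specific fields:
#' \describe{
#'   \item{`chain`}{`n` cells in a horizontal row; fields `n`,
#'     `boundary` (`"open"` or `"periodic"`), optional `delta`.}
#'   \item{`hex_sheet`}{`rows x cols` hexagonal sheet; fields `rows`,
#'     `cols`, `boundary`, optional `delta`.  Periodic sheets require an
#'     even number of rows.}
#'   \item{`winding`}{an arbitrary connected set of lattice cells given as a
#'     two-column matrix/data.frame `path` of (row, col) positions; edges
#'     are created between every adjacent pair.}
#' }
#'   An optional element `heterogeneity = list(alpha =, eta =, tol =)`
#'   applies [apply_heterogeneity()] to the result.
#' @return object of class `tissue_graph` with fields `cells` (data.frame
#'   `row`, `col`), `edges` (data.frame `i`, `j`, `eta`, `d`, `alpha`),
#'   `shape`, `boundary` (logical per cell) and `kind`.
#' @seealso [tissue_chain()], [tissue_hex_sheet()], [tissue_winding()]
#' @export
#' @examples
#' tg <- build_tissue(list(kind = "chain", n = 2))
#' tg$edges
build_tissue <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  delta <- if (is.null(spec$delta)) pi / 3 else spec$delta
  tg <- switch(spec$kind,
    chain = tissue_chain(spec$n,
                         boundary = if (is.null(spec$boundary)) "open"
                                    else spec$boundary,
                         delta = delta),
    hex_sheet = tissue_hex_sheet(spec$rows, spec$cols,
                                 boundary = if (is.null(spec$boundary))
                                   "open" else spec$boundary,
                                 delta = delta),
    winding = tissue_winding(spec$path, delta = delta),
    stop("unknown tissue kind: ", spec$kind))
  if (!is.null(spec$heterogeneity)) {
    h <- spec$heterogeneity
    tg <- apply_heterogeneity(tg, alpha = h$alpha, eta = h$eta,
                              tol = if (is.null(h$tol)) 1e-9 else h$tol)
  }
  tg
}

#' @rdname build_tissue
#' @param n,rows,cols lattice dimensions.
#' @param boundary `"open"` or `"periodic"`.
#' @param delta axis-facing edge width, see [hex_shape()].
#' @export
tissue_chain <- function(n, boundary = c("open", "periodic"),
                         delta = pi / 3) {
  boundary <- match.arg(boundary)
  stopifnot(n >= 1)
  shape <- hex_shape(delta)
  cells <- data.frame(row = rep(0L, n), col = 0:(n - 1))
  if (boundary == "periodic" && n >= 3) {
    # wrap only the columns; single row
    tg <- .tissue_from_cells(cells, shape, periodic_dims = c(NA, n),
                             kind = "chain")
  } else {
    tg <- .tissue_from_cells(cells, shape, NULL, kind = "chain")
  }
  tg
}

#' @rdname build_tissue
#' @export
tissue_hex_sheet <- function(rows, cols, boundary = c("open", "periodic"),
                             delta = pi / 3) {
  boundary <- match.arg(boundary)
  stopifnot(rows >= 1, cols >= 1)
  if (boundary == "periodic" && rows %% 2 != 0) {
    stop("periodic hex sheets need an even number of rows ",
         "(offset parity must match across the seam)")
  }
  shape <- hex_shape(delta)
  cells <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))[, c(2, 1)]
  cells <- data.frame(row = cells$row, col = cells$col)
  .tissue_from_cells(cells, shape,
                     periodic_dims = if (boundary == "periodic")
                       c(rows, cols) else NULL,
                     kind = "hex_sheet")
}

#' @rdname build_tissue
#' @param path two-column matrix or data.frame of (row, col) lattice
#'   positions.
#' @export
tissue_winding <- function(path, delta = pi / 3) {
  path <- as.data.frame(path)
  stopifnot(ncol(path) == 2)
  names(path) <- c("row", "col")
  shape <- hex_shape(delta)
  .tissue_from_cells(path, shape, NULL, kind = "winding")
}

#' Disjoint union of tissue graphs
#'
#' Concatenates tissues into one graph with no edges between the parts.
#' Useful for simulating independent replicas of a small motif (e.g. many
#' two-cell systems under noise) in a single vectorised run.
#'
#' @param tissues list of `tissue_graph` objects sharing a cell shape.
#' @return a `tissue_graph`.
#' @export
tissue_disjoint_union <- function(tissues) {
  stopifnot(length(tissues) >= 1)
  offs <- 0L
  cells <- list(); edges <- list(); boundary <- logical(0)
  for (s in seq_along(tissues)) {
    tg <- tissues[[s]]
    stopifnot(inherits(tg, "tissue_graph"))
    cl <- tg$cells
    cl$row <- cl$row + 1000L * (s - 1L)  # keep (row, col) keys unique
    cells[[s]] <- cl
    e <- tg$edges
    e$i <- e$i + offs; e$j <- e$j + offs
    edges[[s]] <- e
    boundary <- c(boundary, tg$boundary)
    offs <- offs + nrow(cl)
  }
  structure(list(cells = do.call(rbind, cells),
                 edges = do.call(rbind, edges),
                 shape = tissues[[1]]$shape, boundary = boundary,
                 kind = "union", periodic = FALSE),
            class = "tissue_graph")
}

#' Apply coupling heterogeneity to selected contact surfaces
#'
#' Sets `alpha_ij = alpha` on every directed edge whose midpoint `eta_ij`
#' matches one of the target angles (within `tol`), and on its reverse edge,
#' so that the heterogeneity stays symmetric (`alpha_ij = alpha_ji`).  The
#' edge selector matching no edge is an error.
#'
#' @param tissue a `tissue_graph`.
#' @param alpha heterogeneity value (the coupling becomes
#'   `epsilon * (1 + alpha)` on the selected surfaces).
#' @param eta vector of target midpoints, radians.  An edge is selected when
#'   its own `eta_ij` (or, through the automatic symmetrisation, the reverse
#'   edge's) matches an entry.  The default `c(0, pi)` selects the surfaces
#'   along the vertical axis.
#' @param tol angular matching tolerance.
#' @return the modified `tissue_graph`.
#' @export
apply_heterogeneity <- function(tissue, alpha, eta = c(0, pi), tol = 1e-9) {
  stopifnot(inherits(tissue, "tissue_graph"))
  e <- tissue$edges
  sel <- rep(FALSE, nrow(e))
  for (a in eta) {
    sel <- sel | abs(wrap_angle(e$eta - a)) < tol
  }
  if (!any(sel)) stop("heterogeneity selector matched no edges")
  # symmetrise: if (i,j) is selected, select its reverse edge (j,i) too
  rev_idx <- match(paste(e$j, e$i), paste(e$i, e$j))
  sel[rev_idx[sel]] <- TRUE
  e$alpha[sel] <- alpha
  tissue$edges <- e
  tissue
}

#' @export
print.tissue_graph <- function(x, ...) {
  cat("<tissue_graph>", x$kind, "\n")
  cat("  cells:   ", nrow(x$cells),
      " (", sum(x$boundary), " boundary)\n", sep = "")
  cat("  edges:   ", nrow(x$edges), " directed\n", sep = "")
  cat("  delta:   ", signif(x$shape$delta, 6), "\n", sep = "")
  invisible(x)
}
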