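#' Generate a synthetic cell-field geometry
#'
#' Places `n_cells` disc-shaped cells in the imaged field, each with a
#' nucleus disc and a set of punctate endolysosomes in the cytoplasm, by
#' seeded rejection sampling. The layout mimics what the quantification
#' pipeline segments: endolysosomes strictly inside the cytoplasm, nuclei
#' strictly inside cells, a plasma-membrane rim at the cell edge.
#'
#' Pixel coordinates are 1-based (row, col) matrix indices; a pixel belongs
#' to a disc when its centre lies within the disc radius.
#'
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed; the same seed reproduces the same geometry.
#' @param image_shape Image size in pixels, `c(rows, cols)`.
#' @param pm_thickness_px Plasma-membrane rim width in pixels.
#' @param n_el_range Range (min, max) of endolysosomes per cell.
#' @param el_radius_range Endolysosome radius range in pixels (min >= 2).
#' @param max_tries Rejection-sampling retry budget per placed object.
#' @return An object of class `cell_geometry`: the image shape, rim width,
#'   a `cells` tibble (centre, radius, nucleus centre and radius) and an
#'   `endolysosomes` tibble (cell id, centre, radius).
#' @examples
#' geo <- generate_geometry(2, seed = 7, image_shape = c(128, 128))
#' geo$cells
#' @export
generate_geometry <- function(n_cells,
                              seed = 1L,
                              image_shape = c(512, 512),
                              pm_thickness_px = 3,
                              n_el_range = c(6, 10),
                              el_radius_range = c(2, 4.5),
                              max_tries = 2000L) {
  if (!is.numeric(n_cells) || n_cells < 1) {
    abort("`n_cells` must be >= 1.", class = "retroflux_domain_error")
  }
  if (el_radius_range[1] < 2) {
    abort("Endolysosome radii must be >= 2 px.", class = "retroflux_domain_error")
  }
  side <- min(image_shape)
  # cell radius shrinks with crowding so dense fields remain placeable
  r_hi <- side * min(0.21, 0.30 / sqrt(n_cells))
  r_lo <- 0.75 * r_hi

  withr::with_seed(seed, {
    cells <- list()
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        r <- stats::runif(1, r_lo, r_hi)
        cy <- stats::runif(1, r + 2, image_shape[1] - r - 2)
        cx <- stats::runif(1, r + 2, image_shape[2] - r - 2)
        clear <- all(vapply(cells, function(cl) {
          sqrt((cl$cy - cy)^2 + (cl$cx - cx)^2) > cl$r + r + 4
        }, logical(1)))
        if (clear) {
          nr <- 0.34 * r
          ncy <- cy + stats::runif(1, -0.15 * r, 0.15 * r)
          ncx <- cx + stats::runif(1, -0.15 * r, 0.15 * r)
          cells[[i]] <- list(cell_id = i, cy = cy, cx = cx, r = r,
                             nuc_cy = ncy, nuc_cx = ncx, nuc_r = nr)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort("Could not place all cells within the retry budget.",
              class = "retroflux_placement_error")
      }
    }

    els <- list()
    for (cl in cells) {
      n_el <- sample(seq(n_el_range[1], n_el_range[2]), 1)
      for (j in seq_len(n_el)) {
        placed <- FALSE
        for (k in seq_len(max_tries)) {
          er <- stats::runif(1, el_radius_range[1], el_radius_range[2])
          # uniform in the annulus between nucleus and inner rim
          ang <- stats::runif(1, 0, 2 * pi)
          d_lo <- cl$nuc_r + er + 1.5
          d_hi <- cl$r - pm_thickness_px - er - 1.5
          if (d_hi <= d_lo) next
          d <- sqrt(stats::runif(1, d_lo^2, d_hi^2))
          ey <- cl$cy + d * sin(ang)
          ex <- cl$cx + d * cos(ang)
          # distances measured from the nucleus centre, not the cell centre
          if (sqrt((ey - cl$nuc_cy)^2 + (ex - cl$nuc_cx)^2) < cl$nuc_r + er + 1.5) next
          if (sqrt((ey - cl$cy)^2 + (ex - cl$cx)^2) + er > cl$r - pm_thickness_px - 1.5) next
          clear <- all(vapply(els, function(e) {
            sqrt((e$cy - ey)^2 + (e$cx - ex)^2) > e$r + er + 1
          }, logical(1)))
          if (clear) {
            els[[length(els) + 1L]] <- list(cell_id = cl$cell_id, el_id = length(els) + 1L,
                                            cy = ey, cx = ex, r = er)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort("Could not place all endolysosomes within the retry budget.",
                class = "retroflux_placement_error")
        }
      }
    }

    structure(
      list(
        image_shape = as.integer(image_shape),
        pm_thickness_px = pm_thickness_px,
        cells = bind_rows(map(cells, as_tibble)),
        endolysosomes = bind_rows(map(els, as_tibble))
      ),
      class = "cell_geometry"
    )
  })
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> %d x %d px, %d cells, %d endolysosomes\n",
              x$image_shape[1], x$image_shape[2],
              nrow(x$cells), nrow(x$endolysosomes)))
  invisible(x)
}

# logical mask of a union of discs on the pixel grid
disc_mask <- function(image_shape, cy, cx, r) {
  m <- matrix(FALSE, image_shape[1], image_shape[2])
  rows <- matrix(seq_len(image_shape[1]), image_shape[1], image_shape[2])
  cols <- matrix(seq_len(image_shape[2]), image_shape[1], image_shape[2], byrow = TRUE)
  for (i in seq_along(cy)) {
    m <- m | ((rows - cy[i])^2 + (cols - cx[i])^2 <= r[i]^2)
  }
  m
}

#' Rasterize the ground-truth compartment masks of a geometry
#'
#' Builds mutually exclusive masks for endolysosomes (EL), nuclei (N), the
#' plasma-membrane rim (PM) and cytosol (CYTO), plus the whole-cell mask,
#' with precedence EL > N > PM > CYTO.
#'
#' @param geometry A [generate_geometry()] object.
#' @return A named list of logical matrices `EL`, `N`, `PM`, `CYTO`, `CELL`.
#' @export
geometry_masks <- function(geometry) {
  stopifnot(inherits(geometry, "cell_geometry"))
  sh <- geometry$image_shape
  cells <- geometry$cells
  cell_outer <- disc_mask(sh, cells$cy, cells$cx, cells$r)
  cell_inner <- disc_mask(sh, cells$cy, cells$cx, cells$r - geometry$pm_thickness_px)
  nuc <- disc_mask(sh, cells$nuc_cy, cells$nuc_cx, cells$nuc_r)
  el <- if (nrow(geometry$endolysosomes) > 0) {
    disc_mask(sh, geometry$endolysosomes$cy, geometry$endolysosomes$cx,
              geometry$endolysosomes$r)
  } else {
    matrix(FALSE, sh[1], sh[2])
  }
  pm <- cell_outer & !cell_inner
  # precedence EL > N > PM > CYTO
  N <- nuc & !el
  PM <- pm & !el & !N
  CYTO <- cell_outer & !el & !N & !PM
  list(EL = el, N = N, PM = PM, CYTO = CYTO, CELL = cell_outer)
}
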