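# Insole geometry: 64 sensitive elements on a 10 mm lattice.
# x = medial-lateral (mm), y = antero-posterior (mm): y = 0 toe end,
# y = 250 heel end. Each cell covers 1 cm^2.

#' Validate a sensor layout
#'
#' @param layout data.frame with columns `cell_id`, `x_mm`, `y_mm`, `area_cm2`.
#' @return the layout, invisibly, or an error.
#' @export
validate_layout <- function(layout) {
  req <- c("cell_id", "x_mm", "y_mm", "area_cm2")
  if (!is.data.frame(layout) || !all(req %in% names(layout))) {
    stop("layout must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(layout) != 64L) stop("layout must have exactly 64 cells", call. = FALSE)
  if (anyDuplicated(layout$cell_id)) stop("cell ids must be unique", call. = FALSE)
  if (any(layout$y_mm < 0 | layout$y_mm > 250)) {
    stop("y_mm must lie in [0, 250] (0 = toe, 250 = heel)", call. = FALSE)
  }
  if (any(layout$area_cm2 != 1)) {
    stop("each cell covers 1 cm^2 (spatial resolution of the insole)",
         call. = FALSE)
  }
  if (anyDuplicated(layout[, c("x_mm", "y_mm")])) {
    stop("no two cells may share the same (x_mm, y_mm)", call. = FALSE)
  }
  invisible(layout)
}

#' Default foot-shaped 64-cell layout
#'
#' The device does not prescribe cell coordinates, so this is a package
#' convention: 64 cells on a 10 mm square lattice arranged in a foot outline
#' spanning y in \[0, 250\] mm (toe to heel), denser under the heel and the
#' forefoot where plantar load concentrates, sparser along the arch and toes.
#' Deterministic; always overridable by a layout file
#' (see [read_layout_json()]).
#'
#' @return a `sensor_layout` data.frame with columns
#'   `cell_id` (0-63), `x_mm`, `y_mm`, `area_cm2` (= 1).
#' @export
default_layout <- function() {
  # rows from heel (y = 245) to toe (y = 15); count + leftmost x per row
  rows <- data.frame(
    y  = c(245, 235, 225, 215, 205,                 # heel
           195, 185, 175, 165, 155, 145, 135,       # arch
           125, 115, 105, 95, 85, 75,               # forefoot
           65, 55, 45, 35, 25, 15),                 # toes
    n  = c(2, 3, 4, 4, 3,
           2, 2, 2, 2, 2, 2, 2,
           3, 4, 5, 4, 4, 2,
           2, 2, 2, 2, 2, 2),
    x0 = c(35, 35, 25, 25, 35,
           45, 45, 45, 45, 45, 45, 45,
           35, 25, 25, 25, 25, 35,
           35, 35, 35, 35, 35, 35))
  xs <- unlist(mapply(function(n, x0) x0 + 10 * (seq_len(n) - 1),
                      rows$n, rows$x0, SIMPLIFY = FALSE))
  ys <- rep(rows$y, rows$n)
  layout <- data.frame(cell_id = seq_along(xs) - 1L,
                       x_mm = xs, y_mm = ys, area_cm2 = 1)
  class(layout) <- c("sensor_layout", "data.frame")
  validate_layout(layout)
  layout
}
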