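#' Area-of-interest specifications
#'
#' An AOI is a rectangle (top-left and bottom-right corners), an ellipse
#' (centre and semi-axes) or a polygon (ordered vertices), in screen
#' pixels. Boundaries count as inside for every shape. Polygon
#' self-intersection is not checked.
#'
#' @param x1,y1,x2,y2 Rectangle corners, requiring `x1 < x2`, `y1 < y2`.
#' @param cx,cy,a,b Ellipse centre and semi-axes (`a`, `b` > 0).
#' @param x,y Polygon vertex coordinates (at least 3 vertices).
#' @return A list with class `aoi_spec`.
#' @export
#' @examples
#' aoi_rectangle(0, 0, 100, 50)
#' aoi_ellipse(50, 50, 20, 10)
#' aoi_polygon(c(0, 10, 5), c(0, 0, 8))
aoi_rectangle <- function(x1, y1, x2, y2) {
  if (!(x1 < x2 && y1 < y2)) {
    rlang::abort("rectangle AOI requires x1 < x2 and y1 < y2")
  }
  structure(list(shape = "rectangle", x1 = x1, y1 = y1, x2 = x2, y2 = y2),
            class = "aoi_spec")
}

#' @rdname aoi_rectangle
#' @export
aoi_ellipse <- function(cx, cy, a, b) {
  if (!(a > 0 && b > 0)) rlang::abort("ellipse AOI requires positive semi-axes")
  structure(list(shape = "ellipse", cx = cx, cy = cy, a = a, b = b),
            class = "aoi_spec")
}

#' @rdname aoi_rectangle
#' @export
aoi_polygon <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("polygon x and y differ in length")
  if (length(x) < 3) rlang::abort("polygon AOI requires at least 3 vertices")
  structure(list(shape = "polygon", x = as.numeric(x), y = as.numeric(y)),
            class = "aoi_spec")
}

#' @export
print.aoi_spec <- function(x, ...) {
  cat("<aoi_spec>", x$shape, "\n")
  switch(x$shape,
    rectangle = cat(sprintf("  (%g,%g) - (%g,%g)\n", x$x1, x$y1, x$x2, x$y2)),
    ellipse = cat(sprintf("  centre (%g,%g), semi-axes (%g,%g)\n", x$cx, x$cy, x$a, x$b)),
    polygon = cat(sprintf("  %d vertices\n", length(x$x)))
  )
  invisible(x)
}

#' Point containment in an AOI
#'
#' Rectangle: `x1 <= x <= x2` and `y1 <= y <= y2`. Ellipse:
#' `((x-cx)/a)^2 + ((y-cy)/b)^2 <= 1`. Polygon: ray-casting parity with an
#' on-edge short-circuit so that boundary points count as inside.
#' Vectorised over points.
#'
#' @param aoi An `aoi_spec`.
#' @param x,y Point coordinates (vectors of equal length).
#' @return Logical vector.
#' @export
contains_point <- function(aoi, x, y) {
  if (!inherits(aoi, "aoi_spec")) rlang::abort("`aoi` must be an aoi_spec")
  if (length(x) != length(y)) rlang::abort("x and y differ in length")
  switch(aoi$shape,
    rectangle = x >= aoi$x1 & x <= aoi$x2 & y >= aoi$y1 & y <= aoi$y2,
    ellipse = ((x - aoi$cx) / aoi$a)^2 + ((y - aoi$cy) / aoi$b)^2 <= 1,
    polygon = vapply(seq_along(x), function(i) {
      point_in_polygon(x[i], y[i], aoi$x, aoi$y)
    }, logical(1)),
    rlang::abort(paste0("unknown AOI shape: ", aoi$shape))
  )
}

# ray casting with boundary counted inside
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # on-edge short-circuit: point collinear with and between the vertices
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    if (abs(cross) < 1e-9 &&
        px >= min(xi, xj) - 1e-9 && px <= max(xi, xj) + 1e-9 &&
        py >= min(yi, yj) - 1e-9 && py <= max(yi, yj) + 1e-9) {
      return(TRUE)
    }
    if ((yi > py) != (yj > py)) {
      x_cross <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

aoi_coordinates <- function(aoi) {
  switch(aoi$shape,
    rectangle = c(aoi$x1, aoi$y1, aoi$x2, aoi$y2),
    ellipse = c(aoi$cx, aoi$cy, aoi$a, aoi$b),
    polygon = as.numeric(rbind(aoi$x, aoi$y))
  )
}

aoi_from_coordinates <- function(shape, coords, where = "AOI") {
  if (shape == "rectangle") {
    if (length(coords) != 4) {
      rlang::abort(paste0(where, ": rectangle needs 4 numbers (x1,y1,x2,y2), got ",
                          length(coords)))
    }
    aoi_rectangle(coords[1], coords[2], coords[3], coords[4])
  } else if (shape == "ellipse") {
    if (length(coords) != 4) {
      rlang::abort(paste0(where, ": ellipse needs 4 numbers (cx,cy,a,b), got ",
                          length(coords)))
    }
    aoi_ellipse(coords[1], coords[2], coords[3], coords[4])
  } else if (shape == "polygon") {
    if (length(coords) < 6 || length(coords) %% 2 != 0) {
      rlang::abort(paste0(where, ": polygon needs an even number (>= 6) of ",
                          "coordinates, got ", length(coords)))
    }
    aoi_polygon(coords[seq(1, length(coords), by = 2)],
                coords[seq(2, length(coords), by = 2)])
  } else {
    rlang::abort(paste0(where, ": unknown shape token '", shape, "'"))
  }
}

#' Read / write per-stimulus AOI definitions
#'
#' The AOI CSV has columns `stimulus`, `shape` and `coordinates`, where
#' `coordinates` is a single (quoted) field holding a flat
#' semicolon-or-space-free comma-free list: numbers separated by spaces.
#' Rectangle: `x1 y1 x2 y2`; ellipse: `cx cy a b`; polygon:
#' `x1 y1 x2 y2 ...` (vertex pairs). A later row for the same stimulus
#' overrides an earlier one with a warning.
#'
#' @param path CSV file path.
#' @param aois Named list of `aoi_spec` objects (names = stimulus names).
#' @return `load_aoi_table()` returns a named list of `aoi_spec`;
#'   `write_aoi_table()` returns `path` invisibly.
#' @export
load_aoi_table <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("stimulus", "shape", "coordinates")
  if (!all(need %in% names(tab))) {
    rlang::abort("AOI CSV must have columns stimulus, shape, coordinates")
  }
  out <- list()
  for (i in seq_len(nrow(tab))) {
    stim <- tab$stimulus[i]
    coords <- suppressWarnings(as.numeric(strsplit(trimws(tab$coordinates[i]), "\\s+")[[1]]))
    if (anyNA(coords)) {
      rlang::abort(paste0("AOI CSV row ", i, ": non-numeric coordinates"))
    }
    spec <- aoi_from_coordinates(tab$shape[i], coords, where = paste0("AOI CSV row ", i))
    if (stim %in% names(out)) {
      rlang::warn(paste0("duplicate AOI for stimulus '", stim, "'; later row overrides"))
    }
    out[[stim]] <- spec
  }
  out
}

#' @rdname load_aoi_table
#' @export
write_aoi_table <- function(aois, path) {
  if (is.null(names(aois)) || any(names(aois) == "")) {
    rlang::abort("`aois` must be a named list (names = stimulus names)")
  }
  tab <- tibble(
    stimulus = names(aois),
    shape = purrr::map_chr(aois, "shape"),
    coordinates = purrr::map_chr(aois, ~ paste(aoi_coordinates(.x), collapse = " "))
  )
  readr::write_csv(tab, path)
  invisible(path)
}

#' Parse an AOI from a compact command-line style string
#'
#' Accepts `rect:x1,y1,x2,y2`, `ellipse:cx,cy,a,b`,
#' `poly:x1,y1,x2,y2,...`, or `file:aois.csv` (which returns the named
#' list from [load_aoi_table()]).
#'
#' @param text The flag value.
#' @return An `aoi_spec`, or a named list of them for `file:`.
#' @export
parse_aoi_flag <- function(text) {
  m <- stringr::str_match(text, "^(rect|ellipse|poly|file):(.+)$")
  if (is.na(m[1, 1])) rlang::abort("unrecognised AOI flag; expected shape:coords")
  kind <- m[1, 2]
  rest <- m[1, 3]
  if (kind == "file") return(load_aoi_table(rest))
  coords <- suppressWarnings(as.numeric(strsplit(rest, ",")[[1]]))
  if (anyNA(coords)) rlang::abort("non-numeric AOI coordinates in flag")
  shape <- c(rect = "rectangle", ellipse = "ellipse", poly = "polygon")[[kind]]
  aoi_from_coordinates(shape, coords, where = "AOI flag")
}
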