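## Arena and zone geometry.  All coordinates are in cm with the origin at the
## arena lower-left corner and y increasing upwards.

#' Axis-aligned rectangle polygon
#'
#' @param x0,x1,y0,y1 rectangle extents in cm.
#' @return data.frame with columns `x`, `y` (4 vertices, counter-clockwise).
#' @export
rect_poly <- function(x0, x1, y0, y1) {
  data.frame(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Vectorised point-in-polygon test
#'
#' Even-odd rule; points exactly on the polygon boundary count as inside
#' (closed polygons).
#'
#' @param px,py point coordinates (cm).
#' @param poly data.frame with columns `x`, `y` listing the vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  xs <- poly$x
  ys <- poly$y
  np <- length(xs)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- np
  for (i in seq_len(np)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    inbox <- px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
      py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    onedge <- onedge | (abs(cross) < 1e-9 & inbox)
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside | onedge
}

#' Arena dimensions (cm)
#'
#' Floor dimensions of the supported assay arenas: 34 x 34 open field,
#' 47 x 47 latency-to-enter box, 70 x 25 predator-exposure corridor, elevated
#' plus maze with 30 x 7 arms (67 x 67 bounding box), and a 42 x 20
#' two-chamber place-test box.
#'
#' @param arena one of `"open_field"`, `"epm"`, `"lte"`, `"corridor"`,
#'   `"rtpt"`.
#' @return numeric c(width, height) of the bounding box, cm.
#' @export
arena_dims <- function(arena) {
  switch(match.arg(arena, c("open_field", "epm", "lte", "corridor", "rtpt")),
    open_field = c(34, 34),
    epm        = c(67, 67),
    lte        = c(47, 47),
    corridor   = c(70, 25),
    rtpt       = c(42, 20)
  )
}

#' Construct the default zone map for an assay arena
#'
#' Zones are named polygons in arena coordinates (cm).  Defaults: open-field
#' corner zones are squares of 25% side length and the center is the central
#' 50% square; the corridor threat zone is the third nearest the rat wall and
#' the safe zone the third nearest the safe wall; the latency-to-enter burrow
#' is a 13 x 7 cm box in the upper-left corner with the holding zone in the
#' opposite corner; the place-test box is split into two equal chambers.
#'
#' @param arena arena name, see [arena_dims()].
#' @return object of class `zonemap`: list with `arena` (name), `bounds`
#'   (arena polygon), `zones` (named list of polygons), and, where defined,
#'   `threat_point` (cm), `safe_wall_x` and `rat_wall_x`.
#' @export
make_zonemap <- function(arena) {
  arena <- match.arg(arena, c("open_field", "epm", "lte", "corridor", "rtpt"))
  d <- arena_dims(arena)
  zm <- list(arena = arena, bounds = rect_poly(0, d[1], 0, d[2]),
             zones = list(), threat_point = NULL,
             safe_wall_x = NULL, rat_wall_x = NULL)
  if (arena == "open_field") {
    s <- d[1]; cs <- s / 4; c0 <- s / 4; c1 <- 3 * s / 4
    zm$zones <- list(
      corner_sw = rect_poly(0, cs, 0, cs),
      corner_se = rect_poly(s - cs, s, 0, cs),
      corner_nw = rect_poly(0, cs, s - cs, s),
      corner_ne = rect_poly(s - cs, s, s - cs, s),
      center    = rect_poly(c0, c1, c0, c1)
    )
  } else if (arena == "lte") {
    s <- d[1]; cs <- s / 4
    zm$zones <- list(
      burrow       = rect_poly(0, 13, s - 7, s),
      corner_ne    = rect_poly(s - cs, s, s - cs, s),
      corner_sw    = rect_poly(0, cs, 0, cs),
      corner_se    = rect_poly(s - cs, s, 0, cs),
      holding_zone = rect_poly(s - cs, s, 0, cs)
    )
  } else if (arena == "corridor") {
    L <- d[1]; W <- d[2]
    zm$zones <- list(
      threat_zone = rect_poly(2 * L / 3, L, 0, W),
      safe_zone   = rect_poly(0, L / 3, 0, W)
    )
    zm$threat_point <- c(L, W / 2)
    zm$safe_wall_x <- 0
    zm$rat_wall_x <- L
  } else if (arena == "epm") {
    aw <- 7; al <- 30; c0 <- al; c1 <- al + aw; s <- 2 * al + aw
    zm$bounds <- data.frame(
      x = c(c0, c1, c1, s, s, c1, c1, c0, c0, 0, 0, c0),
      y = c(0, 0, c0, c0, c1, c1, s, s, c1, c1, c0, c0)
    )
    zm$zones <- list(
      open_arm_left     = rect_poly(0, c0, c0, c1),
      open_arm_right    = rect_poly(c1, s, c0, c1),
      closed_arm_bottom = rect_poly(c0, c1, 0, c0),
      closed_arm_top    = rect_poly(c0, c1, c1, s),
      epm_center        = rect_poly(c0, c1, c0, c1)
    )
  } else if (arena == "rtpt") {
    L <- d[1]; W <- d[2]
    zm$zones <- list(
      stim_chamber   = rect_poly(0, L / 2, 0, W),
      nostim_chamber = rect_poly(L / 2, L, 0, W)
    )
  }
  class(zm) <- "zonemap"
  zm
}

#' Test zone membership for a set of positions
#'
#' @param x,y positions (cm).
#' @param zonemap a [make_zonemap()] object.
#' @param zone zone name.
#' @return logical vector; boundary points count as inside.
#' @export
in_zone <- function(x, y, zonemap, zone) {
  .assert(zone %in% names(zonemap$zones),
          sprintf("unknown zone '%s' for arena '%s'", zone, zonemap$arena))
  point_in_polygon(x, y, zonemap$zones[[zone]])
}

#' Write / read zone maps as JSON
#'
#' @param zonemap a `zonemap` object.
#' @param path file path.
#' @return `read_zonemap` returns a `zonemap` object.
#' @export
write_zonemap <- function(zonemap, path) {
  obj <- list(arena = zonemap$arena, bounds = zonemap$bounds,
              zones = zonemap$zones, threat_point = zonemap$threat_point,
              safe_wall_x = zonemap$safe_wall_x, rat_wall_x = zonemap$rat_wall_x)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_zonemap
#' @export
read_zonemap <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  zm <- list(arena = obj$arena,
             bounds = as.data.frame(obj$bounds),
             zones = lapply(obj$zones, as.data.frame),
             threat_point = if (is.null(obj$threat_point)) NULL else as.numeric(obj$threat_point),
             safe_wall_x = if (is.null(obj$safe_wall_x)) NULL else as.numeric(obj$safe_wall_x),
             rat_wall_x = if (is.null(obj$rat_wall_x)) NULL else as.numeric(obj$rat_wall_x))
  class(zm) <- "zonemap"
  zm
}
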