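# Screen geometry and region-of-interest (ROI) model.
#
# Coordinate convention: origin at the top-left screen corner, x rightward,
# y downward, pixel units, 0-based. Rectangles are half-open in both axes:
# a point (px, py) lies inside {x, y, w, h} iff x <= px < x + w and
# y <= py < y + h, so abutting rectangles never double-claim a boundary.

#' Screen geometry for pixel/visual-angle conversion
#'
#' Describes the display and viewing distance used to convert between pixel
#' and degree-of-visual-angle units. Defaults correspond to a 41.0 x 31.0 cm
#' (20.1") display at 1600 x 1200 px viewed from 560 mm.
#'
#' @param width_mm,height_mm Physical display size in millimetres.
#' @param width_px,height_px Display resolution in pixels.
#' @param distance_mm Eye-to-screen distance in millimetres.
#' @return An object of class `screen_geometry`.
#' @examples
#' scr <- screen_geometry()
#' px_to_deg(1064, "x", scr)
#' @export
screen_geometry <- function(width_mm = 410, height_mm = 310,
                            width_px = 1600, height_px = 1200,
                            distance_mm = 560) {
  vals <- c(width_mm, height_mm, width_px, height_px, distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all screen geometry fields must be strictly positive", call. = FALSE)
  }
  structure(
    list(width_mm = width_mm, height_mm = height_mm,
         width_px = width_px, height_px = height_px,
         distance_mm = distance_mm),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g mm, %g x %g px, viewed at %g mm\n",
              x$width_mm, x$height_mm, x$width_px, x$height_px, x$distance_mm))
  invisible(x)
}

mm_per_px <- function(screen, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") screen$width_mm / screen$width_px
  else screen$height_mm / screen$height_px
}

#' Convert a pixel extent to degrees of visual angle
#'
#' Uses the full arctangent form for an extent centred on the line of sight:
#' `angle = 2 * atan(extent_mm / (2 * distance))`. [deg_to_px()] is the exact
#' inverse.
#'
#' @param extent_px Extent in pixels (vectorised, must be non-negative).
#' @param axis `"x"` or `"y"`; pixel pitch can differ between axes.
#' @param screen A [screen_geometry()].
#' @return Extent in degrees of visual angle.
#' @export
px_to_deg <- function(extent_px, axis = c("x", "y"), screen = screen_geometry()) {
  axis <- match.arg(axis)
  if (any(extent_px < 0, na.rm = TRUE)) {
    stop("extent_px must be non-negative", call. = FALSE)
  }
  mm <- extent_px * mm_per_px(screen, axis)
  2 * atan(mm / (2 * screen$distance_mm)) * 180 / pi
}

#' @rdname px_to_deg
#' @param extent_deg Extent in degrees of visual angle.
#' @export
deg_to_px <- function(extent_deg, axis = c("x", "y"), screen = screen_geometry()) {
  axis <- match.arg(axis)
  if (any(extent_deg < 0, na.rm = TRUE)) {
    stop("extent_deg must be non-negative", call. = FALSE)
  }
  mm <- 2 * screen$distance_mm * tan(extent_deg / 2 * pi / 180)
  mm / mm_per_px(screen, axis)
}

# Gaze direction of a screen position, as the angle subtended from the
# screen centre (where the line of sight is assumed orthogonal). Used to
# express positions in degrees before differentiating into velocities.
pos_to_deg <- function(x_px, y_px, screen = screen_geometry()) {
  cx <- screen$width_px / 2
  cy <- screen$height_px / 2
  tibble::tibble(
    theta_x = atan((x_px - cx) * mm_per_px(screen, "x") / screen$distance_mm) * 180 / pi,
    theta_y = atan((y_px - cy) * mm_per_px(screen, "y") / screen$distance_mm) * 180 / pi
  )
}

#' Construct an ROI set
#'
#' Bundles a screen geometry with a table of labelled axis-aligned
#' rectangles. A label may span several rows (e.g. a two-rectangle "ears"
#' region); the rows are treated as one region of their total area.
#'
#' @param rois A data frame with columns `label`, `role` (one of `"feature"`,
#'   `"corner"`, `"center"`, `"face"`), `x`, `y`, `w`, `h` in pixels.
#' @param screen A [screen_geometry()].
#' @return An object of class `roiset`: a tibble of rectangles with the
#'   screen attached as an attribute.
#' @export
roiset <- function(rois, screen = screen_geometry()) {
  rois <- tibble::as_tibble(rois)
  needed <- c("label", "role", "x", "y", "w", "h")
  missing_cols <- setdiff(needed, names(rois))
  if (length(missing_cols) > 0) {
    stop("roi table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(rois$w <= 0 | rois$h <= 0)) {
    stop("roi rectangles must have positive width and height", call. = FALSE)
  }
  structure(rois[needed], screen = screen, class = c("roiset", class(rois)))
}

#' @rdname roiset
#' @export
roi_screen <- function(rois) attr(rois, "screen")

#' Default feature/corner/centre ROI layout
#'
#' Places four equal-area feature rectangles (forehead, chin, ears, nose)
#' over a face bounding box, mirroring the canonical layout for four
#' identities each distinguished by one feature. The ears region is two
#' disjoint rectangles of half width each, so all four labels have exactly
#' the same total pixel area. Also adds the face bounding box, a central
#' region, and four corner regions used for name-prior fixation checks.
#'
#' Exact placement within the box is proportional and fully overridable by
#' constructing a [roiset()] directly; the downstream analyses depend only
#' on labels, not on placement.
#'
#' @param face_bbox Named vector or list with `x`, `y`, `w`, `h` of the face
#'   bounding box in pixels. The default centres a 1064 x 736 px face on the
#'   default screen.
#' @param screen A [screen_geometry()].
#' @return A [roiset()].
#' @examples
#' rois <- build_default_roiset()
#' classify_point(800, 300, rois)
#' @export
build_default_roiset <- function(face_bbox = NULL, screen = screen_geometry()) {
  if (is.null(face_bbox)) {
    face_bbox <- c(x = (screen$width_px - 1064) / 2,
                   y = (screen$height_px - 736) / 2,
                   w = 1064, h = 736)
  }
  bb <- as.list(face_bbox)
  if (any(unlist(bb[c("w", "h")]) <= 0)) {
    stop("face bounding box must have positive size", call. = FALSE)
  }
  # Common feature-ROI size: equal areas are exact by construction.
  rw <- 2 * floor(0.18 * bb$w)    # even, so the ears halves are integral
  rh <- floor(0.20 * bb$h)
  if (rw < 2 || rh < 1) {
    stop("face bounding box too small to host the default ROIs", call. = FALSE)
  }
  cx <- bb$x + bb$w / 2
  cy <- bb$y + bb$h / 2
  margin_x <- floor(0.02 * bb$w)
  top_y <- bb$y + floor(0.04 * bb$h)
  bot_y <- bb$y + bb$h - floor(0.04 * bb$h) - rh

  feat <- tibble::tibble(
    label = c("forehead", "chin", "nose", "ears", "ears"),
    role = "feature",
    x = c(cx - rw / 2, cx - rw / 2, cx - rw / 2,
          bb$x + margin_x, bb$x + bb$w - margin_x - rw / 2),
    y = c(top_y, bot_y, cy - rh / 2, cy - rh / 2, cy - rh / 2),
    w = c(rw, rw, rw, rw / 2, rw / 2),
    h = rh
  )
  # Disjointness can fail only for degenerate boxes; refuse rather than
  # silently overlap.
  if (feat$y[3] <= top_y + rh || bot_y <= feat$y[3] + rh ||
      feat$x[3] <= feat$x[4] + rw / 2 || feat$x[5] <= feat$x[3] + rw) {
    stop("face bounding box too small to host disjoint default ROIs",
         call. = FALSE)
  }

  corner_w <- floor(screen$width_px * 0.25)
  corner_h <- floor(screen$height_px * 0.25)
  corners <- tibble::tibble(
    label = c("corner_tl", "corner_tr", "corner_bl", "corner_br"),
    role = "corner",
    x = c(screen$width_px * 0.125, screen$width_px * 0.625,
          screen$width_px * 0.125, screen$width_px * 0.625),
    y = c(screen$height_px * 0.125, screen$height_px * 0.125,
          screen$height_px * 0.625, screen$height_px * 0.625),
    w = corner_w, h = corner_h
  )
  extra <- tibble::tibble(
    label = c("face", "center"),
    role = c("face", "center"),
    x = c(bb$x, screen$width_px / 2 - 100),
    y = c(bb$y, screen$height_px / 2 - 100),
    w = c(bb$w, 200), h = c(bb$h, 200)
  )
  roiset(dplyr::bind_rows(feat, corners, extra), screen = screen)
}

#' Classify points into ROIs
#'
#' Assigns each point the label of the containing rectangle among rows with
#' the requested role. Rectangles are half-open (left/top edges inclusive,
#' right/bottom exclusive), so a point on a shared boundary belongs to
#' exactly one rectangle.
#'
#' @param x_px,y_px Point coordinates in pixels (vectorised).
#' @param rois A [roiset()].
#' @param role Which ROI roles to consider; defaults to the feature ROIs.
#' @return A character vector of labels, `NA` where a point falls outside
#'   all considered rectangles.
#' @export
classify_point <- function(x_px, y_px, rois, role = "feature") {
  if (length(y_px) != length(x_px)) {
    stop("x_px and y_px must have equal length", call. = FALSE)
  }
  rect <- rois[rois$role %in% role, , drop = FALSE]
  out <- rep(NA_character_, length(x_px))
  for (i in seq_len(nrow(rect))) {
    hit <- !is.na(x_px) & !is.na(y_px) &
      x_px >= rect$x[i] & x_px < rect$x[i] + rect$w[i] &
      y_px >= rect$y[i] & y_px < rect$y[i] + rect$h[i]
    out[hit & is.na(out)] <- rect$label[i]
  }
  out
}

roi_center <- function(rois, lab) {
  rect <- rois[rois$label == lab, , drop = FALSE]
  # For multi-rectangle labels, the centre of the first rectangle: targets
  # sampled through roi_sample_point() handle the general case.
  c(x = rect$x[1] + rect$w[1] / 2, y = rect$y[1] + rect$h[1] / 2)
}

# Sample a point inside a labelled region, away from the edges so that
# measurement noise does not push it out (inner fraction of each rectangle,
# area-weighted across rectangles of the label).
roi_sample_point <- function(rois, lab, inner = 0.7) {
  rect <- rois[rois$label == lab, , drop = FALSE]
  if (nrow(rect) == 0) stop("unknown ROI label: ", lab, call. = FALSE)
  areas <- rect$w * rect$h
  i <- if (nrow(rect) == 1) 1 else sample.int(nrow(rect), 1, prob = areas)
  pad_x <- rect$w[i] * (1 - inner) / 2
  pad_y <- rect$h[i] * (1 - inner) / 2
  c(x = stats::runif(1, rect$x[i] + pad_x, rect$x[i] + rect$w[i] - pad_x),
    y = stats::runif(1, rect$y[i] + pad_y, rect$y[i] + rect$h[i] - pad_y))
}

#' Read or write an ROI configuration file
#'
#' The YAML layout has a `screen` block (width_mm, height_mm, width_px,
#' height_px, distance_mm) and a `rois` list of `{label, role, x, y, w, h}`
#' entries; both are validated on load.
#'
#' @param path File path.
#' @return `read_roiset()` returns a [roiset()]; `write_roiset()` invisibly
#'   returns `path`.
#' @export
read_roiset <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$screen) || is.null(cfg$rois)) {
    stop("roi config must contain 'screen' and 'rois' blocks", call. = FALSE)
  }
  scr <- do.call(screen_geometry, cfg$screen)
  rois <- dplyr::bind_rows(lapply(cfg$rois, tibble::as_tibble))
  roiset(rois, screen = scr)
}

#' @rdname read_roiset
#' @param rois A [roiset()] to serialise.
#' @export
write_roiset <- function(rois, path) {
  scr <- roi_screen(rois)
  cfg <- list(
    screen = scr[c("width_mm", "height_mm", "width_px", "height_px",
                   "distance_mm")],
    rois = lapply(seq_len(nrow(rois)), function(i) as.list(rois[i, ]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
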