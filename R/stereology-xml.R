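# Fractionator sessions: building them from point patterns and round-tripping
# them through a minimal, versioned stereology XML dialect.
#
# Dialect (version 1):
#   <stereology_session version="1">
#     <outline unit="mm"> <vertex x="" y=""/> ... </outline>
#     <grid cell_area_um2="" origin_x_mm="" origin_y_mm="" spacing_mm=""/>
#     <frame area_um2=""/>
#     <sites cell_class=""> <site x_mm="" y_mm="" count=""/> ... </sites>
#   </stereology_session>
# Outline vertices in mm; frame and grid-cell areas in um^2; `count` is the
# marker tally (sum Q contribution) of the counting frame centred at the site.

#' Construct a fractionator session
#'
#' @param outline Closed polygon tibble (`x_mm`, `y_mm`).
#' @param sites Tibble with `x_mm`, `y_mm`, `marker_count` (non-negative
#'   integers) and optionally `cell_class`.
#' @param grid_cell_area_um2 Area represented by one grid point (um^2).
#' @param frame_area_um2 Counting-frame area (um^2), <= grid cell area.
#' @param cell_class Class label recorded on the session.
#' @return A list of class `eyespec_fractionator_session`.
#' @seealso [build_fractionator_session()], [fractionator_total()]
#' @export
fractionator_session <- function(outline, sites, grid_cell_area_um2,
                                 frame_area_um2, cell_class = "total") {
  if (!is.data.frame(outline) || nrow(outline) < 3L) {
    abort("Outline must be a polygon with at least three vertices.",
          class = "eyespec_invalid_geometry")
  }
  if (frame_area_um2 <= 0 || grid_cell_area_um2 <= 0 ||
      frame_area_um2 > grid_cell_area_um2) {
    abort("Need 0 < frame_area_um2 <= grid_cell_area_um2.",
          class = "eyespec_invalid_session")
  }
  if (any(sites$marker_count < 0) ||
      any(sites$marker_count != round(sites$marker_count))) {
    abort("Marker counts must be non-negative integers.",
          class = "eyespec_invalid_session")
  }
  if (!"cell_class" %in% names(sites)) sites$cell_class <- cell_class
  structure(
    list(outline = as_tibble(outline[, c("x_mm", "y_mm")]),
         sites = as_tibble(sites[, c("x_mm", "y_mm", "marker_count", "cell_class")]),
         grid_cell_area_um2 = grid_cell_area_um2,
         frame_area_um2 = frame_area_um2,
         cell_class = cell_class),
    class = "eyespec_fractionator_session"
  )
}

#' Sample a point pattern with the optical fractionator design
#'
#' Superimposes a square counting grid with a randomized origin (uniform
#' within one grid cell, seeded) on the outline; every grid point inside the
#' outline becomes a sampling site where markers are tallied inside a square
#' counting frame of area `frame_area_um2` centred on the site (half-open
#' edges, so tiled frames never double-count). The area sampling fraction is
#' `asf = frame_area / grid_cell_area`.
#'
#' @param retina An `eyespec_retina`, or a points tibble (`x_mm`, `y_mm`).
#' @param grid_cell_area_um2 Grid cell area (um^2); the grid spacing is its
#'   square root.
#' @param frame_area_um2 Counting-frame area (um^2).
#' @param seed Integer seed for the grid origin.
#' @param cell_class Restrict counting to this point label (`"total"` counts
#'   all points); also recorded on the session.
#' @param outline Outline polygon (required when `retina` is a bare tibble).
#' @return An `eyespec_fractionator_session`.
#' @examples
#' r <- simulate_retina(4000, 2000, seed = 1)
#' s <- build_fractionator_session(r, seed = 1)
#' fractionator_total(s)
#' @export
build_fractionator_session <- function(retina, grid_cell_area_um2 = 250000,
                                       frame_area_um2 = 2500, seed = 1,
                                       cell_class = "total", outline = NULL) {
  if (inherits(retina, "eyespec_retina")) {
    outline <- retina$outline
    points <- retina$points
  } else {
    points <- as_tibble(retina)
    if (is.null(outline)) {
      abort("Supply `outline` when passing a bare points table.",
            class = "eyespec_invalid_geometry")
    }
  }
  if (frame_area_um2 > grid_cell_area_um2) {
    abort("Frame area must not exceed the grid cell area.",
          class = "eyespec_invalid_session")
  }
  if (cell_class != "total") {
    points <- points[points$cell_class == cell_class, ]
  }
  spacing_mm <- sqrt(grid_cell_area_um2) * 1e-3
  side_mm <- sqrt(frame_area_um2) * 1e-3
  vx <- outline$x_mm; vy <- outline$y_mm
  bbox <- c(min(vx), max(vx), min(vy), max(vy))
  withr::with_seed(seed, {
    origin <- c(bbox[1] + runif(1) * spacing_mm, bbox[3] + runif(1) * spacing_mm)
  })
  gx <- seq(origin[1] - spacing_mm, bbox[2] + spacing_mm, by = spacing_mm)
  gy <- seq(origin[2] - spacing_mm, bbox[4] + spacing_mm, by = spacing_mm)
  grid <- expand.grid(x_mm = gx, y_mm = gy)
  inside <- point_in_polygon(grid$x_mm, grid$y_mm, vx, vy)
  grid <- grid[inside, , drop = FALSE]
  # tally points in the half-open frame centred at each site
  counts <- integer(nrow(grid))
  if (nrow(points) > 0 && nrow(grid) > 0) {
    # map each point to its nearest grid node; inside frame if within side/2
    ix <- round((points$x_mm - origin[1]) / spacing_mm)
    iy <- round((points$y_mm - origin[2]) / spacing_mm)
    sx <- origin[1] + ix * spacing_mm
    sy <- origin[2] + iy * spacing_mm
    in_frame <- (points$x_mm - sx) >= -side_mm / 2 & (points$x_mm - sx) < side_mm / 2 &
      (points$y_mm - sy) >= -side_mm / 2 & (points$y_mm - sy) < side_mm / 2
    # integer linear index over the grid lattice
    gix <- round((grid$x_mm - origin[1]) / spacing_mm)
    giy <- round((grid$y_mm - origin[2]) / spacing_mm)
    span <- max(gix) - min(gix) + 2L
    key_site <- (giy - min(giy)) * span + (gix - min(gix))
    key_pt <- (iy[in_frame] - min(giy)) * span + (ix[in_frame] - min(gix))
    counts <- as.integer(tabulate(match(key_pt, key_site), nbins = nrow(grid)))
  }
  fractionator_session(
    outline = outline,
    sites = tibble(x_mm = grid$x_mm, y_mm = grid$y_mm, marker_count = counts,
                   cell_class = cell_class),
    grid_cell_area_um2 = grid_cell_area_um2,
    frame_area_um2 = frame_area_um2,
    cell_class = cell_class
  )
}

#' Write a fractionator session to stereology XML
#'
#' Serialises a session to the package's minimal, versioned stereology XML
#' dialect (coordinates in mm, areas in um^2); [parse_stereology_xml()]
#' round-trips it losslessly.
#'
#' @param session An `eyespec_fractionator_session` (or an `eyespec_retina`,
#'   in which case a session is first built with
#'   [build_fractionator_session()] and the extra arguments).
#' @param path Output file path; with `NULL` the `xml2` document is returned.
#' @param ... Passed to [build_fractionator_session()] when `session` is a
#'   retina.
#' @return `path` (invisibly) or an `xml_document`.
#' @export
write_stereology_xml <- function(session, path = NULL, ...) {
  if (inherits(session, "eyespec_retina")) {
    session <- build_fractionator_session(session, ...)
  }
  stopifnot(inherits(session, "eyespec_fractionator_session"))
  num <- function(x) sprintf("%.12g", x)
  doc <- xml2::xml_new_root("stereology_session", version = "1")
  out_node <- xml2::xml_add_child(doc, "outline", unit = "mm")
  for (i in seq_len(nrow(session$outline))) {
    xml2::xml_add_child(out_node, "vertex",
                        x = num(session$outline$x_mm[i]),
                        y = num(session$outline$y_mm[i]))
  }
  spacing <- sqrt(session$grid_cell_area_um2) * 1e-3
  xml2::xml_add_child(doc, "grid",
                      cell_area_um2 = num(session$grid_cell_area_um2),
                      spacing_mm = num(spacing))
  xml2::xml_add_child(doc, "frame", area_um2 = num(session$frame_area_um2))
  sites_node <- xml2::xml_add_child(doc, "sites",
                                    cell_class = session$cell_class)
  for (i in seq_len(nrow(session$sites))) {
    xml2::xml_add_child(sites_node, "site",
                        x_mm = num(session$sites$x_mm[i]),
                        y_mm = num(session$sites$y_mm[i]),
                        count = sprintf("%d", as.integer(session$sites$marker_count[i])))
  }
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Parse a stereology XML session
#'
#' Reads the package's stereology dialect back into a
#' `eyespec_fractionator_session`, validating geometry and counts; schema
#' violations raise an error naming the offending element path.
#'
#' @param x A file path, XML string, or `xml_document`.
#' @return An `eyespec_fractionator_session`.
#' @export
parse_stereology_xml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  root <- xml2::xml_find_first(doc, "/stereology_session")
  if (is.na(xml2::xml_attr(root, "version"))) {
    abort("Not a stereology_session document (missing /stereology_session@version).",
          class = "eyespec_schema_error")
  }
  verts <- xml2::xml_find_all(doc, "/stereology_session/outline/vertex")
  if (length(verts) < 3L) {
    abort("Missing or degenerate outline at /stereology_session/outline.",
          class = "eyespec_schema_error")
  }
  outline <- tibble(
    x_mm = as.numeric(xml2::xml_attr(verts, "x")),
    y_mm = as.numeric(xml2::xml_attr(verts, "y"))
  )
  grid_node <- xml2::xml_find_first(doc, "/stereology_session/grid")
  frame_node <- xml2::xml_find_first(doc, "/stereology_session/frame")
  grid_area <- as.numeric(xml2::xml_attr(grid_node, "cell_area_um2"))
  frame_area <- as.numeric(xml2::xml_attr(frame_node, "area_um2"))
  if (!is.finite(grid_area) || !is.finite(frame_area)) {
    abort("Missing area at /stereology_session/grid@cell_area_um2 or /stereology_session/frame@area_um2.",
          class = "eyespec_schema_error")
  }
  if (frame_area > grid_area) {
    abort("Frame exceeds grid cell at /stereology_session/frame@area_um2.",
          class = "eyespec_schema_error")
  }
  sites_node <- xml2::xml_find_first(doc, "/stereology_session/sites")
  site_nodes <- xml2::xml_find_all(doc, "/stereology_session/sites/site")
  counts <- as.numeric(xml2::xml_attr(site_nodes, "count"))
  if (length(counts) > 0 &&
      (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))) {
    abort("Non-integer marker count at /stereology_session/sites/site@count.",
          class = "eyespec_schema_error")
  }
  cls <- xml2::xml_attr(sites_node, "cell_class")
  if (is.na(cls)) cls <- "total"
  fractionator_session(
    outline = outline,
    sites = tibble(
      x_mm = as.numeric(xml2::xml_attr(site_nodes, "x_mm")),
      y_mm = as.numeric(xml2::xml_attr(site_nodes, "y_mm")),
      marker_count = as.integer(counts),
      cell_class = cls
    ),
    grid_cell_area_um2 = grid_area,
    frame_area_um2 = frame_area,
    cell_class = cls
  )
}
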