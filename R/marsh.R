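# MarshGeometry container and GeoJSON interchange.

#' Habitat zone labels, ordered by proximity to the sea wall
#'
#' Zones follow saltmarsh elevation zonation: the non-saltmarsh transition
#' strip along the sea wall, the mid-marsh redshank zone (Puccinellia /
#' Festuca), the Elytrigia redshank zone, and the low-elevation non-redshank
#' zone (Atriplex / pioneer vegetation).
#'
#' @export
zone_levels <- c("non_saltmarsh", "mid_marsh_redshank",
                 "elytrigia_redshank", "non_redshank")

#' Construct a marsh geometry
#'
#' All coordinates are planar metres on a local grid. Creeks must lie inside
#' the boundary and not overlap each other; zone polygons must lie inside the
#' boundary.
#'
#' @param boundary Polygon matrix (implicitly closed).
#' @param seawall Polyline matrix (>= 2 vertices) along the landward edge.
#' @param creeks List of creek polygon matrices.
#' @param zones Named list (names from [zone_levels]) of lists of polygon
#'   matrices.
#' @param marsh_id Identifier carried into outputs.
#' @return An object of class `marsh_geometry`.
#' @export
marsh_geometry <- function(boundary, seawall, creeks = list(),
                           zones = list(), marsh_id = "M") {
  stopifnot(is.matrix(boundary), ncol(boundary) == 2, nrow(boundary) >= 3,
            is.matrix(seawall), ncol(seawall) == 2, nrow(seawall) >= 2)
  if (length(zones) && !all(names(zones) %in% zone_levels))
    stop("unknown zone labels: ",
         paste(setdiff(names(zones), zone_levels), collapse = ", "))
  structure(list(boundary = boundary, seawall = seawall, creeks = creeks,
                 zones = zones, marsh_id = marsh_id),
            class = "marsh_geometry")
}

#' Usable marsh area (boundary minus creeks)
#'
#' @param marsh A `marsh_geometry`.
#' @return Area in square metres.
#' @export
usable_area_m2 <- function(marsh) {
  poly_area(marsh$boundary) - sum(vapply(marsh$creeks, poly_area, 0))
}

#' @export
print.marsh_geometry <- function(x, ...) {
  cat("marsh_geometry", x$marsh_id, "\n")
  cat(sprintf("  boundary area: %.2f ha\n", poly_area(x$boundary) / 1e4))
  cat(sprintf("  creeks: %d (%.2f ha)\n", length(x$creeks),
              sum(vapply(x$creeks, poly_area, 0)) / 1e4))
  for (z in names(x$zones)) {
    a <- sum(vapply(x$zones[[z]], poly_area, 0)) / 1e4
    cat(sprintf("  zone %-20s %.2f ha (%d polygons)\n", z, a,
                length(x$zones[[z]])))
  }
  invisible(x)
}

.poly_to_coords <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  list(lapply(seq_len(nrow(ring)),
              function(i) c(ring[i, 1], ring[i, 2])))
}

.feature <- function(geom_type, coords, props) {
  list(type = "Feature",
       geometry = list(type = geom_type, coordinates = coords),
       properties = props)
}

#' Write a marsh geometry to GeoJSON
#'
#' Coordinates are planar metres on the local analysis grid (a local
#' projected pseudo-CRS, recorded in the collection's `crs_note` property),
#' not geographic degrees.
#'
#' @param marsh A `marsh_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marsh_geojson <- function(marsh, path) {
  feats <- list(.feature("Polygon", .poly_to_coords(marsh$boundary),
                         list(kind = "boundary", marsh_id = marsh$marsh_id)))
  sw <- lapply(seq_len(nrow(marsh$seawall)),
               function(i) c(marsh$seawall[i, 1], marsh$seawall[i, 2]))
  feats <- c(feats, list(.feature("LineString", sw, list(kind = "seawall"))))
  for (i in seq_along(marsh$creeks))
    feats <- c(feats, list(.feature("Polygon",
                                    .poly_to_coords(marsh$creeks[[i]]),
                                    list(kind = "creek", creek_id = i))))
  for (z in names(marsh$zones))
    for (p in marsh$zones[[z]])
      feats <- c(feats, list(.feature("Polygon", .poly_to_coords(p),
                                      list(kind = "zone", zone = z))))
  fc <- list(type = "FeatureCollection",
             crs_note = "local planar grid, metres",
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.coords_to_poly <- function(coords) {
  ring <- do.call(rbind, lapply(coords[[1]], function(p) unlist(p)[1:2]))
  n <- nrow(ring)
  if (n > 1 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  colnames(ring) <- c("x", "y")
  ring
}

#' Read a marsh geometry from GeoJSON
#'
#' Expects the feature layout written by [write_marsh_geojson()].
#'
#' @param path GeoJSON file path.
#' @return A `marsh_geometry`.
#' @export
read_marsh_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  boundary <- NULL; seawall <- NULL; creeks <- list()
  zones <- stats::setNames(vector("list", 0), character(0))
  marsh_id <- "M"
  for (f in fc$features) {
    kind <- f$properties$kind
    if (identical(kind, "boundary")) {
      boundary <- .coords_to_poly(f$geometry$coordinates)
      marsh_id <- f$properties$marsh_id %||% "M"
    } else if (identical(kind, "seawall")) {
      seawall <- do.call(rbind, lapply(f$geometry$coordinates,
                                       function(p) unlist(p)[1:2]))
      colnames(seawall) <- c("x", "y")
    } else if (identical(kind, "creek")) {
      creeks[[length(creeks) + 1L]] <- .coords_to_poly(f$geometry$coordinates)
    } else if (identical(kind, "zone")) {
      z <- f$properties$zone
      zones[[z]] <- c(zones[[z]], list(.coords_to_poly(f$geometry$coordinates)))
    }
  }
  if (is.null(boundary) || is.null(seawall))
    stop("GeoJSON is missing a boundary or seawall feature: ", path)
  marsh_geometry(boundary, seawall, creeks, zones, marsh_id)
}
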