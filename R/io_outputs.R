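# Writers for grids, activity surfaces and risk maps (GeoJSON + long CSV).

.cell_feature <- function(x0, y0, s, props) {
  .feature("Polygon", .poly_to_coords(rect_poly(x0, x0 + s, y0, y0 + s)),
           props)
}

#' Write a grid-shaped surface to GeoJSON
#'
#' One polygon feature per included cell, carrying the supplied per-cell
#' properties.
#'
#' @param cells A `marsh_grid` (or `risk_map`) data frame with `x0, y0`.
#' @param path Output path.
#' @param props Data frame of extra per-row properties (optional).
#' @param header Named list merged into the FeatureCollection (e.g. seed,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_cells_geojson <- function(cells, path, props = NULL, header = list()) {
  s <- attr(cells, "cell_size_m") %||% 50
  keep <- if ("included" %in% names(cells)) cells$included else TRUE
  d <- as.data.frame(cells)[keep, , drop = FALSE]
  if (!is.null(props)) d <- cbind(d, props[keep, , drop = FALSE])
  drop_cols <- c("x0", "y0", "cx", "cy", "ix", "iy")
  feats <- lapply(seq_len(nrow(d)), function(i) {
    pr <- as.list(d[i, setdiff(names(d), drop_cols), drop = FALSE])
    .cell_feature(d$x0[i], d$y0[i], s, pr)
  })
  fc <- c(list(type = "FeatureCollection",
               crs_note = "local planar grid, metres"),
          header, list(features = feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an activity surface as long-format CSV
#'
#' Columns `cell_id, week, n, activity_ha` (week empty for pooled surfaces).
#'
#' @param activity An `activity_grid`.
#' @param path Output path.
#' @param header Named list written as `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(header))
    writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  utils::write.csv(activity$counts, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format activity CSV (comment lines ignored)
#'
#' @param path File written by [write_activity_csv()].
#' @return Data frame `cell_id, week, n, activity_ha`.
#' @export
read_activity_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
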