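#' Read an annotation file
#'
#' Annotations are stored as JSON:
#' ```
#' {"spacing_mm": 0.5,
#'  "levels": [{"level": "C5/6",
#'              "upper_endplate": {"polyline_mm": [[x,y], ...],
#'                                 "body_side_hint_mm": [x,y]},
#'              "lower_endplate": {...},
#'              "exclusions_mm": [[[x,y], ...], ...]}],
#'  "csf_polygon_mm": [[x,y], ...]}
#' ```
#' All coordinates are in mm. `exclusions_mm` is an optional list of
#' polygons (e.g. Schmorl nodes) removed from that level's endplate bands.
#'
#' @param path JSON file.
#' @return A list with `spacing_mm`, `levels` (named list; each element has
#'   `upper`/`lower` [endplate_annotation()]s and `exclusions`, a list of
#'   polygon matrices) and `csf` (a [csf_region()], or `NULL`).
#' @export
read_annotations <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  levels <- list()
  for (entry in j$levels) {
    lab <- entry$level
    mk <- function(side, role) {
      endplate_annotation(
        lab, role,
        polyline = as_coord_matrix(side$polyline_mm),
        body_side_hint = as.numeric(unlist(side$body_side_hint_mm)))
    }
    exc <- entry$exclusions_mm
    exc <- if (is.null(exc)) list() else lapply(exc, as_coord_matrix)
    levels[[lab]] <- list(
      upper = mk(entry$upper_endplate, "upper_endplate"),
      lower = mk(entry$lower_endplate, "lower_endplate"),
      exclusions = exc)
  }
  csf <- if (!is.null(j$csf_polygon_mm)) csf_region(as_coord_matrix(j$csf_polygon_mm))
  list(spacing_mm = j$spacing_mm, levels = levels, csf = csf)
}

as_coord_matrix <- function(x) {
  do.call(rbind, lapply(x, function(p) as.numeric(unlist(p))))
}

#' Write an annotation file
#'
#' Inverse of [read_annotations()]; see that page for the JSON schema.
#'
#' @param annotations list shaped as returned by [read_annotations()] (the
#'   phantom ground truth from [generate_phantom()] also qualifies).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  lv <- lapply(names(annotations$levels), function(lab) {
    e <- annotations$levels[[lab]]
    out <- list(
      level = lab,
      upper_endplate = list(
        polyline_mm = unname(e$upper$polyline),
        body_side_hint_mm = unname(e$upper$body_side_hint)),
      lower_endplate = list(
        polyline_mm = unname(e$lower$polyline),
        body_side_hint_mm = unname(e$lower$body_side_hint)))
    if (length(e$exclusions)) out$exclusions_mm <- lapply(e$exclusions, unname)
    out
  })
  payload <- list(spacing_mm = annotations$spacing_mm, levels = lv)
  if (!is.null(annotations$csf)) {
    payload$csf_polygon_mm <- unname(annotations$csf$polygon)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
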