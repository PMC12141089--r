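#' Read region polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of named Polygon (or single-part
#' MultiPolygon) features into a [RegionSet-class]. Only outer rings are
#' used; feature order in the file fixes the tie-break priority for
#' [assignRegion()]. The region name is taken from the first of the
#' `name`, `NAME` or `region` properties found.
#'
#' @param path GeoJSON file path.
#' @return a [RegionSet-class].
#' @export
readRegions <- function(path) {
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) stop("unreadable region polygon file '",
                                          path, "': ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(gj$features))
    stop("region file is not a GeoJSON FeatureCollection", call. = FALSE)
  nms <- character()
  polys <- list()
  for (f in gj$features) {
    props <- f$properties
    nm <- props$name %||% props$NAME %||% props$region
    if (is.null(nm))
      stop("region feature without a name property", call. = FALSE)
    geom <- f$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = {
        if (length(geom$coordinates) != 1)
          stop("multi-part MultiPolygon regions are not supported",
               call. = FALSE)
        geom$coordinates[[1]][[1]]
      },
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    m <- do.call(rbind, lapply(ring, function(pt)
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
    nms <- c(nms, nm)
    polys <- c(polys, list(m))
  }
  RegionSet(nms, polys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a RegionSet as GeoJSON
#'
#' @param regions a [RegionSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRegions <- function(regions, path) {
  feats <- lapply(seq_along(regions@polygons), function(i) {
    p <- regions@polygons[[i]]
    ring <- rbind(p, p[1L, , drop = FALSE])
    list(type = "Feature",
         properties = list(name = regions@regionNames[i]),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(k) as.numeric(ring[k, ])))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
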