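#' @import data.table
NULL

#' Default column-name mappings for EBD-style tables
#'
#' Header dialects of eBird Basic Dataset exports vary by snapshot, so the
#' mapping from logical field to column name is configurable everywhere a
#' table is read. These return the mapping for the dialect this package
#' writes.
#'
#' @return named character vector: logical field -> column name.
#' @export
ebdObservationColumns <- function() {
  c(checklist_id = "SAMPLING EVENT IDENTIFIER",
    species      = "SPECIES CODE",
    count        = "OBSERVATION COUNT")
}

#' @rdname ebdObservationColumns
#' @export
ebdEventColumns <- function() {
  c(checklist_id     = "SAMPLING EVENT IDENTIFIER",
    group_id         = "GROUP IDENTIFIER",
    protocol         = "PROTOCOL TYPE",
    date             = "OBSERVATION DATE",
    duration_minutes = "DURATION MINUTES",
    distance_km      = "EFFORT DISTANCE KM",
    n_observers      = "NUMBER OBSERVERS",
    lat              = "LATITUDE",
    lon              = "LONGITUDE",
    complete         = "ALL SPECIES REPORTED")
}

.checkColumns <- function(found, colMap, mandatory) {
  missing <- colMap[mandatory][!colMap[mandatory] %in% found]
  if (length(missing)) {
    stop("configuration error: mandatory column(s) absent from file: ",
         paste(sprintf("'%s' (field %s)", missing, names(missing)),
               collapse = ", "), call. = FALSE)
  }
}

.normalizeProtocol <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("other", length(x))
  for (p in c("stationary", "traveling", "incidental", "historical"))
    out[x == p] <- p
  out
}

#' Read a species' observation rows from an EBD-style table
#'
#' Reads the tab-separated observation table, keeps rows matching
#' `speciesCode` exactly, and parses counts. The eBird "X" convention (a
#' detection with unrecorded count) is parsed as `NA` with the row still
#' counting as a detection.
#'
#' @param path tab-separated file with a header row.
#' @param speciesCode exact species code to keep.
#' @param colMap named character vector mapping logical fields
#'   (`checklist_id`, `species`, `count`) to column names; see
#'   [ebdObservationColumns()].
#' @return a data.table with columns `checklist_id`, `species_code`,
#'   `count` (integer, `NA` = unknown "X").
#' @export
readObservations <- function(path, speciesCode,
                             colMap = ebdObservationColumns()) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = NULL)
  .checkColumns(names(dt), colMap, c("checklist_id", "species", "count"))
  dt <- dt[dt[[colMap["species"]]] == speciesCode, ]
  raw <- dt[[colMap["count"]]]
  count <- rep(NA_integer_, length(raw))
  isX <- toupper(trimws(raw)) == "X"
  num <- suppressWarnings(as.numeric(raw))
  badRow <- which(!isX & (is.na(num) | num < 0 | num != floor(num)))
  if (length(badRow)) {
    stop("unparseable count value(s) at row(s): ",
         paste(utils::head(badRow, 10L), collapse = ", "),
         " (expected a nonnegative integer or 'X')", call. = FALSE)
  }
  count[!isX] <- as.integer(num[!isX])
  data.table(checklist_id = dt[[colMap["checklist_id"]]],
             species_code = speciesCode,
             count = count)
}

#' Read the sampling-event (checklist) table
#'
#' @param path tab-separated file with a header row.
#' @param colMap named character vector mapping logical fields to column
#'   names; see [ebdEventColumns()].
#' @return a data.table with one row per checklist: `checklist_id`,
#'   `group_id` (NA when not shared), normalised `protocol`, `date`,
#'   `duration_minutes`, `distance_km`, `n_observers`, `lat`, `lon`,
#'   `complete`.
#' @export
readSamplingEvents <- function(path, colMap = ebdEventColumns()) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = NULL)
  mandatory <- c("checklist_id", "protocol", "date", "lat", "lon", "complete")
  .checkColumns(names(dt), colMap, mandatory)
  getcol <- function(field, default = NA_character_) {
    if (colMap[field] %in% names(dt)) dt[[colMap[field]]]
    else rep(default, nrow(dt))
  }
  blankToNA <- function(x) { x[trimws(x) == ""] <- NA_character_; x }
  asNum <- function(x) suppressWarnings(as.numeric(blankToNA(x)))
  out <- data.table(
    checklist_id = dt[[colMap["checklist_id"]]],
    group_id = blankToNA(getcol("group_id")),
    protocol = .normalizeProtocol(dt[[colMap["protocol"]]]),
    date = as.Date(dt[[colMap["date"]]]),
    duration_minutes = asNum(getcol("duration_minutes")),
    distance_km = asNum(getcol("distance_km")),
    n_observers = as.integer(asNum(getcol("n_observers"))),
    lat = asNum(dt[[colMap["lat"]]]),
    lon = asNum(dt[[colMap["lon"]]]),
    complete = dt[[colMap["complete"]]] %in% c("1", "TRUE", "true", "T"))
  if (anyDuplicated(out$checklist_id))
    stop("duplicate checklist_id in sampling-event table", call. = FALSE)
  out
}

#' Zero-fill sampling events against a species observation table
#'
#' Produces one checklist record per sampling event with an explicit
#' detection flag: events without a matching observation row become
#' non-detections with count 0. This is what turns a presence-only
#' observation table into presence/absence data usable for occupancy
#' scoring.
#'
#' @param events sampling events from [readSamplingEvents()].
#' @param obs observation rows from [readObservations()].
#' @return a data.table: all event columns plus `detected` and `count`
#'   (0 when not detected; `NA` = unknown "X" when detected).
#' @export
zeroFill <- function(events, obs) {
  events <- as.data.table(events)
  obs <- as.data.table(obs)
  if (nrow(obs)) {
    orphan <- setdiff(obs$checklist_id, events$checklist_id)
    if (length(orphan)) {
      stop("observation(s) reference unknown checklist id(s): ",
           paste(utils::head(sort(orphan), 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  out <- copy(events)
  idx <- match(out$checklist_id, obs$checklist_id)
  out[, detected := !is.na(idx)]
  out[, count := 0L]
  hit <- which(!is.na(idx))
  if (length(hit)) out[hit, count := obs$count[idx[hit]]]
  out[]
}

#' Collapse shared (group) checklists to one record per group
#'
#' Checklists submitted by several observers of the same birding event
#' share a group identifier; keeping all of them would pseudo-replicate
#' one sampling event. Records sharing a non-missing `group_id` are
#' collapsed to the member with the lexicographically lowest
#' `checklist_id`; the group's detection flag is the OR over members and
#' effort fields are taken from the representative.
#'
#' @param records zero-filled checklist records.
#' @return a data.table with one record per group (ungrouped records pass
#'   through unchanged).
#' @export
collapseShared <- function(records) {
  records <- as.data.table(records)
  if (!nrow(records) || all(is.na(records$group_id))) return(records[])
  solo <- records[is.na(group_id)]
  grp <- records[!is.na(group_id)]
  setorder(grp, group_id, checklist_id)
  agg <- grp[, {
    det <- any(detected)
    cnt <- if (!det) 0L else {
      known <- count[detected & !is.na(count)]
      if (length(known)) max(known) else NA_integer_
    }
    c(.SD[1L, !c("detected", "count")], list(detected = det, count = cnt))
  }, by = group_id]
  setcolorder(agg, names(records))
  out <- rbind(solo, agg, use.names = TRUE)
  setorder(out, checklist_id)
  out[]
}

#' Write tables in the EBD-style tab-separated dialect
#'
#' `writeSamplingEvents()` and `writeObservations()` emit the dialect
#' [readSamplingEvents()] and [readObservations()] read;
#' `writeChecklists()` emits a zero-filled checklist table (the same
#' dialect plus `DETECTED` and `OBSERVATION COUNT` columns).
#'
#' @param events,obs,records tables as produced by this package.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSamplingEvents <- function(events, path) {
  out <- data.table(
    `SAMPLING EVENT IDENTIFIER` = events$checklist_id,
    `GROUP IDENTIFIER` = ifelse(is.na(events$group_id), "", events$group_id),
    `PROTOCOL TYPE` = tools::toTitleCase(events$protocol),
    `OBSERVATION DATE` = format(events$date, "%Y-%m-%d"),
    `DURATION MINUTES` = events$duration_minutes,
    `EFFORT DISTANCE KM` = events$distance_km,
    `NUMBER OBSERVERS` = events$n_observers,
    `LATITUDE` = sprintf("%.6f", events$lat),
    `LONGITUDE` = sprintf("%.6f", events$lon),
    `ALL SPECIES REPORTED` = as.integer(events$complete))
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeSamplingEvents
#' @param speciesCode species code written to the species column.
#' @export
writeObservations <- function(obs, path, speciesCode = NULL) {
  sp <- if (is.null(speciesCode)) obs$species_code else speciesCode
  out <- data.table(
    `SAMPLING EVENT IDENTIFIER` = obs$checklist_id,
    `SPECIES CODE` = sp,
    `OBSERVATION COUNT` = ifelse(is.na(obs$count), "X",
                                 as.character(obs$count)))
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeSamplingEvents
#' @export
writeChecklists <- function(records, path) {
  out <- data.table(
    `SAMPLING EVENT IDENTIFIER` = records$checklist_id,
    `GROUP IDENTIFIER` = ifelse(is.na(records$group_id), "", records$group_id),
    `PROTOCOL TYPE` = tools::toTitleCase(records$protocol),
    `OBSERVATION DATE` = format(records$date, "%Y-%m-%d"),
    `DURATION MINUTES` = records$duration_minutes,
    `EFFORT DISTANCE KM` = records$distance_km,
    `NUMBER OBSERVERS` = records$n_observers,
    `LATITUDE` = sprintf("%.6f", records$lat),
    `LONGITUDE` = sprintf("%.6f", records$lon),
    `ALL SPECIES REPORTED` = as.integer(records$complete),
    `DETECTED` = as.integer(records$detected),
    `OBSERVATION COUNT` = ifelse(records$detected & is.na(records$count), "X",
                                 as.character(records$count)))
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read back a zero-filled checklist table written by [writeChecklists()]
#'
#' @param path file written by `writeChecklists()`.
#' @return a checklist record data.table.
#' @export
readChecklists <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = NULL)
  blankToNA <- function(x) { x[trimws(x) == ""] <- NA_character_; x }
  asNum <- function(x) suppressWarnings(as.numeric(blankToNA(x)))
  raw <- dt$`OBSERVATION COUNT`
  count <- suppressWarnings(as.integer(raw))
  count[toupper(trimws(raw)) == "X"] <- NA_integer_
  data.table(
    checklist_id = dt$`SAMPLING EVENT IDENTIFIER`,
    group_id = blankToNA(dt$`GROUP IDENTIFIER`),
    protocol = .normalizeProtocol(dt$`PROTOCOL TYPE`),
    date = as.Date(dt$`OBSERVATION DATE`),
    duration_minutes = asNum(dt$`DURATION MINUTES`),
    distance_km = asNum(dt$`EFFORT DISTANCE KM`),
    n_observers = as.integer(asNum(dt$`NUMBER OBSERVERS`)),
    lat = asNum(dt$LATITUDE),
    lon = asNum(dt$LONGITUDE),
    complete = dt$`ALL SPECIES REPORTED` == "1",
    detected = dt$DETECTED == "1",
    count = count)
}
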