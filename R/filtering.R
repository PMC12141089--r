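#' Apply checklist inclusion rules
#'
#' Applies the quality filters to zero-filled checklist records and
#' returns both the surviving records and a per-rule exclusion report.
#' Rules are evaluated in a fixed order — protocol, completeness,
#' distance, duration, season, year — and each excluded record is counted
#' once, at its first failing rule, so the report is additive:
#' `sum(report$n_excluded) + nrow(kept) == nrow(records)`.
#'
#' Membership in `kept` does not depend on the rule order (a record is
#' kept iff it passes every rule); only the attribution of exclusions
#' does. Thresholds keep boundary values: a traveling checklist of
#' exactly `maxDistanceKm` or a checklist of exactly `maxDurationHours`
#' is kept. Records with missing duration are excluded under the duration
#' rule (their effort cannot be quantified); missing distance excludes
#' only traveling records.
#'
#' @param records zero-filled checklist records ([zeroFill()]).
#' @param cfg a [FilterConfig-class] object.
#' @return a list with elements `kept` (data.table of surviving records)
#'   and `report` (data.table with columns `rule`, `n_excluded`).
#' @export
applyFilters <- function(records, cfg = FilterConfig()) {
  stopifnot(is(cfg, "FilterConfig"))
  validObject(cfg)
  records <- as.data.table(records)
  n <- nrow(records)
  if (!n) {
    return(list(kept = records,
                report = data.table(rule = .filterRules(), n_excluded = 0L)))
  }
  md <- format(records$date, "%m-%d")
  yr <- as.integer(format(records$date, "%Y"))
  fail <- cbind(
    protocol = !(records$protocol %in% cfg@allowedProtocols),
    completeness = if (cfg@requireComplete) !records$complete else
      rep(FALSE, n),
    distance = records$protocol == "traveling" &
      (is.na(records$distance_km) | records$distance_km > cfg@maxDistanceKm),
    duration = is.na(records$duration_minutes) |
      records$duration_minutes > cfg@maxDurationHours * 60,
    season = is.na(md) | md < cfg@seasonStart | md > cfg@seasonEnd,
    year = is.na(yr) | yr < cfg@yearRange[1] | yr > cfg@yearRange[2])
  firstFail <- integer(n)
  for (j in seq_len(ncol(fail)))
    firstFail[firstFail == 0L & fail[, j]] <- j
  counts <- tabulate(firstFail, nbins = ncol(fail))
  list(kept = records[firstFail == 0L],
       report = data.table(rule = .filterRules(), n_excluded = counts))
}

.filterRules <- function() {
  c("protocol", "completeness", "distance", "duration", "season", "year")
}

#' Write a filter exclusion report
#'
#' @param report report data.table from [applyFilters()].
#' @param path output path (tab-separated).
#' @return the path, invisibly.
#' @export
writeFilterReport <- function(report, path) {
  fwrite(report, path, sep = "\t")
  invisible(path)
}
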