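utils::globalVariables(c(
  ".", ".N", ".SD", "cell", "cell_col", "cell_row", "checklist_id",
  "count", "detected", "group_id", "n_checklists", "n_detections",
  "n_years", "region", "shift", "significant", "species_code", "x", "y",
  "year", "cumulative_km", "direction"))

# FNV-1a 32-bit hash of a character scalar; used to stamp run metadata so
# an output file can be matched to the exact configuration that made it.
.fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte because b < 256
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    # multiply mod 2^32 in 16-bit halves to stay inside exact doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h < 2^32: render as hex in two 16-bit halves (sprintf %x needs integers)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.configHash <- function(cfg) {
  .fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 10))
}

.logMsg <- function(level, threshold, ...) {
  lv <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (lv[[level]] >= lv[[threshold]])
    message(format(Sys.time(), "%H:%M:%S "), toupper(level), " ", ...)
  invisible(NULL)
}
utils::globalVariables(c("cellCol", "cellRow", "centerLon", "centerLat", "centerX", "centerY"))
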