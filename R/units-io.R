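#' Set of sorted single units
#'
#' Spike times plus per-unit metadata for a session. `meta` carries one row
#' per unit (unit_id, region, depth_um, and, once computed, quality-control
#' metrics and the RS/NS/WS cell class); `spikes` is a list of ascending
#' spike-time vectors named by unit_id; `waveforms` optionally carries the
#' mean spike waveform per unit at `waveform_fs`.
#'
#' @param spikes Named list of numeric spike-time vectors (seconds).
#' @param meta data.frame with at least `unit_id`, `region`, `depth_um`.
#' @param waveforms Optional named list of numeric waveform vectors.
#' @param waveform_fs Waveform sampling rate, Hz (30000 in the protocol).
#' @param span Recording span `[0, span)` in seconds; spike times must fall
#'   inside it. Defaults to the last spike time.
#' @return A `unit_set` object.
#' @export
unit_set <- function(spikes, meta, waveforms = NULL, waveform_fs = 30000,
                     span = NULL) {
  meta <- as.data.frame(meta)
  if (!all(c("unit_id", "region", "depth_um") %in% names(meta)))
    pfc_abort("meta needs columns unit_id, region, depth_um",
              "pfc_validation_error")
  meta$unit_id <- as.character(meta$unit_id)
  if (anyDuplicated(meta$unit_id))
    pfc_abort("unit_ids must be unique", "pfc_validation_error")
  if (!all(meta$region %in% REGIONS))
    pfc_abort("unit region must be IL, PL or CG", "pfc_validation_error")
  orphans <- setdiff(names(spikes), meta$unit_id)
  if (length(orphans))
    pfc_abort(paste("spike-table unit_ids missing from metadata:",
                    paste(orphans, collapse = ", ")), "pfc_validation_error")
  missing_spk <- setdiff(meta$unit_id, names(spikes))
  if (length(missing_spk)) {
    message(sprintf("%d unit(s) have metadata but no spikes; kept with empty trains",
                    length(missing_spk)))
    for (u in missing_spk) spikes[[u]] <- numeric(0)
  }
  spikes <- spikes[meta$unit_id]
  for (u in meta$unit_id) {
    st <- spikes[[u]]
    if (any(st < 0)) pfc_abort("negative spike times", "pfc_validation_error")
    if (is.unsorted(st)) spikes[[u]] <- sort(st)
  }
  if (is.null(span))
    span <- max(c(0, unlist(spikes, use.names = FALSE)))
  if (any(unlist(spikes, use.names = FALSE) > span))
    pfc_abort("spike times beyond the recording span", "pfc_validation_error")
  if (!is.null(waveforms)) {
    bad <- setdiff(names(waveforms), meta$unit_id)
    if (length(bad))
      pfc_abort("waveforms for unknown unit_ids", "pfc_validation_error")
  }
  structure(list(spikes = spikes, meta = meta, waveforms = waveforms,
                 waveform_fs = waveform_fs, span = as.numeric(span)),
            class = "unit_set")
}

#' @export
print.unit_set <- function(x, ...) {
  cat(sprintf("<unit_set> %d units, %d spikes, span %.1f s\n",
              nrow(x$meta), length(unlist(x$spikes, use.names = FALSE)),
              x$span))
  print(table(x$meta$region))
  invisible(x)
}

n_units <- function(units) nrow(units$meta)

# Subset a unit_set by logical/integer index into meta rows.
subset_units <- function(units, idx) {
  meta <- units$meta[idx, , drop = FALSE]
  out <- units
  out$meta <- meta
  out$spikes <- units$spikes[meta$unit_id]
  if (!is.null(units$waveforms))
    out$waveforms <- units$waveforms[intersect(names(units$waveforms),
                                               meta$unit_id)]
  out
}

#' Read / write spike tables (CSV)
#'
#' Two plain-text tables: `<path>` with columns `unit_id, spike_time_s`, and
#' a companion `units_path` with per-unit metadata (`unit_id, region,
#' depth_um`, optionally QC and class columns). Metadata rows without spikes
#' are retained as empty trains with a message; spike rows without metadata
#' are a validation error.
#'
#' @param path Spike-table CSV path.
#' @param units_path Unit-metadata CSV path; defaults to `units.csv` next to
#'   `path`.
#' @param span Optional recording span in seconds (see [unit_set()]).
#' @return `read_spikes` returns a [unit_set()]; `write_spikes` returns
#'   `path` invisibly.
#' @export
read_spikes <- function(path, units_path = file.path(dirname(path), "units.csv"),
                        span = NULL) {
  spk <- as.data.frame(data.table::fread(path))
  if (!all(c("unit_id", "spike_time_s") %in% names(spk)))
    pfc_abort("spike table needs columns unit_id, spike_time_s",
              "pfc_format_error")
  meta <- as.data.frame(data.table::fread(units_path))
  spk$unit_id <- as.character(spk$unit_id)
  spikes <- split(spk$spike_time_s, spk$unit_id)
  unit_set(spikes, meta, span = span)
}

#' @param units A [unit_set()].
#' @rdname read_spikes
#' @export
write_spikes <- function(units, path,
                         units_path = file.path(dirname(path), "units.csv")) {
  stopifnot(inherits(units, "unit_set"))
  spk <- data.frame(
    unit_id = rep(names(units$spikes), lengths(units$spikes)),
    spike_time_s = unlist(units$spikes, use.names = FALSE))
  data.table::fwrite(spk, path)
  data.table::fwrite(units$meta, units_path)
  invisible(path)
}
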