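#' Multi-channel LFP recording
#'
#' Continuous local field potential as a samples x channels matrix in
#' microvolts with per-channel geometry. Channels carry the medial prefrontal
#' subregion (IL, PL, CG, ordered ventral to dorsal along the probe), the
#' depth in micrometres measured upward from the ventral boundary of that
#' region, and a normalized depth that concatenates the three regions onto
#' [0, 3): IL = [0, 1), PL = [1, 2), CG = [2, 3).
#'
#' @param data Numeric matrix, samples x channels, microvolts.
#' @param fs Sampling rate, Hz (2500 in the study protocol).
#' @param channels data.frame with columns `depth_um`, `region`
#'   (IL/PL/CG/other) and either a `normalized_depth` column or region sizes
#'   supplied via `region_sizes_um` to compute it.
#' @param region_sizes_um Named numeric (IL, PL, CG), micrometre extent of
#'   each region, used to compute `normalized_depth` when absent.
#' @return An `lfp_recording` object.
#' @export
lfp_recording <- function(data, fs, channels, region_sizes_um = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    pfc_abort("fs must be a positive scalar", "pfc_validation_error")
  channels <- as.data.frame(channels)
  if (!all(c("depth_um", "region") %in% names(channels)))
    pfc_abort("channels must have columns depth_um and region",
              "pfc_validation_error")
  if (nrow(channels) != ncol(data))
    pfc_abort(sprintf("channel metadata rows (%d) != data columns (%d)",
                      nrow(channels), ncol(data)), "pfc_validation_error")
  if (!all(channels$region %in% c(REGIONS, "other")))
    pfc_abort("channel region must be IL, PL, CG or other",
              "pfc_validation_error")
  if (any(!is.finite(channels$depth_um)))
    pfc_abort("channel depths must be finite", "pfc_validation_error")
  if (is.null(channels$normalized_depth)) {
    if (is.null(region_sizes_um))
      pfc_abort("supply channels$normalized_depth or region_sizes_um",
                "pfc_validation_error")
    channels$normalized_depth <- normalized_depth(channels, region_sizes_um)
  }
  nd <- channels$normalized_depth[channels$region %in% REGIONS]
  if (length(nd) > 1 && is.unsorted(nd) && is.unsorted(rev(nd)))
    pfc_abort("normalized_depth must be monotone along the probe",
              "pfc_validation_error")
  structure(list(data = data, fs = fs, channels = channels),
            class = "lfp_recording")
}

#' Normalized dorso-ventral depth
#'
#' Maps per-channel (region, depth-from-ventral-boundary) pairs onto a common
#' [0, 3) axis by normalising each depth by its region's extent: IL occupies
#' [0, 1), PL [1, 2) and CG [2, 3). Channels outside the three regions get NA.
#'
#' @param channels data.frame with `region` and `depth_um`.
#' @param region_sizes_um Named numeric vector with entries IL, PL, CG.
#' @return Numeric vector of normalized depths.
#' @export
normalized_depth <- function(channels, region_sizes_um) {
  if (!all(REGIONS %in% names(region_sizes_um)))
    pfc_abort("region_sizes_um must name IL, PL and CG", "pfc_validation_error")
  offset <- c(IL = 0, PL = 1, CG = 2)
  out <- rep(NA_real_, nrow(channels))
  in_reg <- channels$region %in% REGIONS
  r <- channels$region[in_reg]
  out[in_reg] <- offset[r] +
    channels$depth_um[in_reg] / region_sizes_um[r]
  out
}

n_channels <- function(lfp) ncol(lfp$data)

# Extract the sample window of a block (half-open [t_start, t_end)).
block_samples <- function(lfp, t_start, t_end) {
  i0 <- floor(t_start * lfp$fs) + 1
  i1 <- floor(t_end * lfp$fs)
  if (i0 < 1 || i1 > nrow(lfp$data))
    pfc_abort("block window outside the recording", "pfc_validation_error")
  i0:i1
}

#' Read / write an LFP recording (HDF5 container)
#'
#' Layout: dataset `/lfp` (samples x channels, int16), attributes `fs` and
#' `uv_per_bit` on `/lfp`, and a `/channels` table with `depth_um`, `region`
#' and `normalized_depth`. Data are quantised to int16 at the stored
#' microvolt-per-bit scale.
#'
#' @param path HDF5 file path.
#' @return `read_lfp` returns an [lfp_recording()]; `write_lfp` returns
#'   `path` invisibly.
#' @export
read_lfp <- function(path) {
  if (!file.exists(path)) pfc_abort("no such file", "pfc_format_error")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  cont <- rhdf5::h5ls(path)$name
  if (!"lfp" %in% cont) pfc_abort("file has no 'lfp' dataset", "pfc_format_error")
  att <- rhdf5::h5readAttributes(path, "lfp")
  if (is.null(att$fs)) pfc_abort("lfp dataset lacks an fs attribute",
                                 "pfc_format_error")
  if (is.null(att$uv_per_bit))
    pfc_abort("lfp dataset lacks a uv_per_bit attribute", "pfc_format_error")
  if (!"channels" %in% cont)
    pfc_abort("file has no 'channels' table", "pfc_format_error")
  raw <- rhdf5::h5read(path, "lfp")
  channels <- as.data.frame(rhdf5::h5read(path, "channels"))
  channels[] <- lapply(channels, as.vector)
  lfp_recording(raw * as.numeric(att$uv_per_bit), as.numeric(att$fs), channels)
}

#' @param lfp An [lfp_recording()].
#' @param uv_per_bit Quantisation step for int16 storage, microvolts per bit.
#' @rdname read_lfp
#' @export
write_lfp <- function(lfp, path, uv_per_bit = NULL) {
  stopifnot(inherits(lfp, "lfp_recording"))
  if (is.null(uv_per_bit)) {
    m <- max(abs(lfp$data), 1e-12)
    uv_per_bit <- m / 32000
  }
  q <- round(lfp$data / uv_per_bit)
  if (max(abs(q)) > 32767)
    pfc_abort("uv_per_bit too fine for the data range", "pfc_validation_error")
  storage.mode(q) <- "integer"
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  rhdf5::h5createDataset(path, "lfp", dims = dim(q),
                         H5type = "H5T_NATIVE_SHORT",
                         chunk = c(min(nrow(q), 65536L), ncol(q)), level = 4)
  rhdf5::h5write(q, path, "lfp")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "lfp")
  rhdf5::h5writeAttribute(lfp$fs, did, "fs")
  rhdf5::h5writeAttribute(uv_per_bit, did, "uv_per_bit")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  ch <- lfp$channels
  ch$region <- as.character(ch$region)
  rhdf5::h5write(ch, path, "channels")
  invisible(path)
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  print(table(x$channels$region))
  invisible(x)
}
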