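# Array-based interchange format: one directory per recording holding a JSON
# header (fs, run type, markers, montage) and a TSV sample matrix.

#' Write / read a recording as a plain-text container
#'
#' The directory holds `header.json` (sampling rate, run type, markers,
#' montage table) and `data.tsv` (samples x channels, tab-separated with a
#' channel-name header row).
#'
#' @param recording An `eeg_recording`.
#' @param path Directory path (created if missing).
#' @return `read_recording` returns an `eeg_recording`.
#' @export
write_recording <- function(recording, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  mnt <- recording$montage
  header <- list(
    fs = recording$fs,
    run_type = recording$run_type,
    markers = recording$markers,
    montage = list(channels = mnt$channels,
                   x = unname(mnt$pos[, 1]), y = unname(mnt$pos[, 2]),
                   region = unname(mnt$region),
                   impedance = unname(mnt$impedance))
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  utils::write.table(t(recording$data), file.path(path, "data.tsv"),
                     sep = "\t", row.names = FALSE,
                     col.names = rownames(recording$data), quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  dat <- utils::read.table(file.path(path, "data.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  m <- header$montage
  pos <- cbind(x = m$x, y = m$y); rownames(pos) <- m$channels
  d <- as.matrix(dist(pos))
  neighbors <- lapply(m$channels, function(cc) m$channels[d[cc, ] > 0 & d[cc, ] < 1.01])
  names(neighbors) <- m$channels
  reg <- m$region; names(reg) <- m$channels
  imp <- m$impedance; names(imp) <- m$channels
  montage <- structure(list(channels = m$channels, pos = pos,
                            neighbors = neighbors, region = reg,
                            impedance = imp, preset = "file"),
                       class = "bci_montage")
  markers <- header$markers
  if (!is.null(markers) && length(markers) && nrow(as.data.frame(markers))) {
    markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  } else {
    markers <- NULL
  }
  new_recording(t(as.matrix(dat)), header$fs, markers, montage, header$run_type)
}
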