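#' Electrode montage presets
#'
#' Builds a montage from a named preset of the extended 10-10 scheme. The
#' default `"motor27"` preset covers the sensorimotor strip (FC/C/CP rows,
#' lateral positions 5,3,1,z,2,4,6) plus a parietal and parieto-occipital row,
#' the channel subset used for parameter selection and classification.
#'
#' Positions are unitless head-circle coordinates on a regular grid with unit
#' inter-electrode spacing. Neighbor maps (for the surface-Laplacian
#' derivation) contain the orthogonal grid neighbors at unit distance, so the
#' central motor channels C3, Cz and C4 each have M = 4 neighbors. Each
#' channel carries exactly one region tag out of left-motor, central-motor,
#' right-motor and parieto-occipital.
#'
#' @param layout_preset Preset name; currently `"motor27"`.
#' @param impedances Optional named numeric vector (kOhm) overriding the 5 kOhm
#'   default for the named channels.
#' @return An object of class `bci_montage`: list with `channels`, `pos`
#'   (n x 2 matrix), `neighbors` (named list), `region` (named character),
#'   `impedance` (named numeric, kOhm).
#' @examples
#' mnt <- make_montage("motor27")
#' mnt$neighbors$C3
#' @export
make_montage <- function(layout_preset = "motor27", impedances = NULL) {
  if (!identical(layout_preset, "motor27")) {
    stopf("unknown montage preset '%s' (available: motor27)", layout_preset)
  }
  cols <- c("5" = -3, "3" = -2, "1" = -1, "z" = 0, "2" = 1, "4" = 2, "6" = 3)
  rows <- c(FC = 1, C = 0, CP = -1)
  chan <- character(0); px <- numeric(0); py <- numeric(0); reg <- character(0)
  for (r in names(rows)) {
    for (k in names(cols)) {
      chan <- c(chan, paste0(r, k))
      px <- c(px, cols[[k]]); py <- c(py, rows[[r]])
      reg <- c(reg, if (cols[[k]] < 0) "left-motor"
               else if (cols[[k]] > 0) "right-motor" else "central-motor")
    }
  }
  # parietal / parieto-occipital rows
  ppo <- list(P3 = c(-2, -2), P1 = c(-1, -2), Pz = c(0, -2), P2 = c(1, -2), P4 = c(2, -2),
              POz = c(0, -3))
  chan <- c(chan, names(ppo))
  px <- c(px, vapply(ppo, `[`, 0, 1)); py <- c(py, vapply(ppo, `[`, 0, 2))
  reg <- c(reg, rep("parieto-occipital", length(ppo)))
  pos <- cbind(x = px, y = py)
  rownames(pos) <- chan
  names(reg) <- chan

  d <- as.matrix(dist(pos))
  neighbors <- lapply(chan, function(cc) chan[d[cc, ] > 0 & d[cc, ] < 1.01])
  names(neighbors) <- chan

  imp <- rep(5, length(chan)); names(imp) <- chan
  if (!is.null(impedances)) {
    bad <- setdiff(names(impedances), chan)
    if (length(bad)) stopf("impedance override for unknown channel(s): %s",
                           paste(bad, collapse = ", "))
    imp[names(impedances)] <- impedances
  }
  structure(list(channels = chan, pos = pos, neighbors = neighbors,
                 region = reg, impedance = imp, preset = layout_preset),
            class = "bci_montage")
}

#' @export
print.bci_montage <- function(x, ...) {
  cat(sprintf("<bci_montage> preset '%s': %d channels\n", x$preset, length(x$channels)))
  tab <- table(x$region)
  cat("  regions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# channels belonging to the motor strip (candidates for band/CSP work)
motor_channels <- function(montage) {
  montage$channels[montage$region %in% c("left-motor", "central-motor", "right-motor")]
}

parietal_channels <- function(montage) {
  montage$channels[montage$region == "parieto-occipital"]
}

#' Write / read a montage as a plain-text table
#'
#' Columns: name, x, y, region, impedance_kohm; neighbor maps are rebuilt from
#' positions on read (unit-distance grid neighbors).
#'
#' @param montage A `bci_montage`.
#' @param path File path.
#' @return `read_montage` returns a `bci_montage`.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(name = montage$channels, x = montage$pos[, 1], y = montage$pos[, 2],
                   region = unname(montage$region),
                   impedance_kohm = unname(montage$impedance))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  pos <- cbind(x = df$x, y = df$y); rownames(pos) <- df$name
  d <- as.matrix(dist(pos))
  neighbors <- lapply(df$name, function(cc) df$name[d[cc, ] > 0 & d[cc, ] < 1.01])
  names(neighbors) <- df$name
  reg <- df$region; names(reg) <- df$name
  imp <- df$impedance_kohm; names(imp) <- df$name
  structure(list(channels = df$name, pos = pos, neighbors = neighbors,
                 region = reg, impedance = imp, preset = "file"),
            class = "bci_montage")
}
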