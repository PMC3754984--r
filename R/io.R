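# Readers and writers for the instrument-style angular-scan ASCII
# dialect and for stack definition files.
#
# Angular-scan dialect (versioned in the header):
#   # spr-angular-scan v1
#   # wavelength_nm: 670
#   # angle_offset_deg: 2.16        (optional)
#   # source: <free text>           (optional)
#   # t= 0.000000
#   60.000000 0.812345
#   ...
# One "# t=" block per scan; every block must share the same angle
# grid; timestamps ascend.  Angles and reflectance are fixed-point with
# six decimals, so write -> read -> write is byte-identical.

.scan_magic <- "# spr-angular-scan v1"
.stack_magic <- "# spr-stack v1"

#' Write a series of angular scans to an instrument-style ASCII file
#'
#' @param spectra List of [angular_spectrum()] objects sharing one
#'   angle grid; timestamps (default: block index) must ascend.
#' @param path Output file path.
#' @param wavelength Wavelength recorded in the header (nm).
#' @param angle_offset Optional instrument angle-axis offset recorded
#'   in the header; `NULL` to take it from the first spectrum.
#' @param source Free-text provenance line.
#' @return Invisibly, `path`.
#' @export
write_angular_scans <- function(spectra, path, wavelength = 670,
                                angle_offset = NULL, source = "sprcell") {
  if (!is.list(spectra) || length(spectra) == 0L)
    stop("no spectra to write", call. = FALSE)
  ok <- vapply(spectra, inherits, logical(1), what = "angular_spectrum")
  if (!all(ok)) stop("spectra must be angular_spectrum objects",
                     call. = FALSE)
  grid <- spectra[[1L]]$angles
  same <- vapply(spectra, function(s)
    length(s$angles) == length(grid) && all(s$angles == grid), logical(1))
  if (!all(same))
    stop("all blocks must share an identical angle grid", call. = FALSE)
  ts <- vapply(seq_along(spectra), function(i) {
    t <- spectra[[i]]$timestamp
    if (is.null(t)) as.numeric(i - 1L) else t
  }, numeric(1))
  if (any(diff(ts) <= 0) && length(ts) > 1L)
    stop("timestamps must be strictly ascending", call. = FALSE)
  if (is.null(angle_offset))
    angle_offset <- attr(spectra[[1L]], "angle_offset")
  con <- file(path, "wb")   # binary mode: LF endings on every platform
  on.exit(close(con))
  hdr <- c(.scan_magic, sprintf("# wavelength_nm: %.6f", wavelength))
  if (!is.null(angle_offset))
    hdr <- c(hdr, sprintf("# angle_offset_deg: %.6f", angle_offset))
  hdr <- c(hdr, paste0("# source: ", source))
  writeLines(hdr, con, sep = "\n")
  for (i in seq_along(spectra)) {
    writeLines(sprintf("# t= %.6f", ts[i]), con, sep = "\n")
    writeLines(sprintf("%.6f %.6f", grid, spectra[[i]]$reflectance), con,
               sep = "\n")
  }
  invisible(path)
}

#' Read an instrument-style angular-scan file
#'
#' @param path File in the angular-scan dialect written by
#'   [write_angular_scans()].
#' @return A list of [angular_spectrum()] objects with timestamps;
#'   header metadata (`wavelength`, `angle_offset`, `source`) is
#'   attached as attributes.  Malformed blocks are reported with their
#'   line numbers.
#' @export
read_angular_scans <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty angular-scan file: ", path,
                                call. = FALSE)
  if (lines[1L] != .scan_magic)
    stop("not an angular-scan file (missing '", .scan_magic, "'): ", path,
         call. = FALSE)
  meta <- list(wavelength = NA_real_, angle_offset = NULL, source = NULL)
  i <- 2L
  while (i <= length(lines) && startsWith(lines[i], "#") &&
         !startsWith(lines[i], "# t=")) {
    kv <- sub("^#\\s*", "", lines[i])
    if (startsWith(kv, "wavelength_nm:"))
      meta$wavelength <- as.numeric(sub("wavelength_nm:\\s*", "", kv))
    if (startsWith(kv, "angle_offset_deg:"))
      meta$angle_offset <- as.numeric(sub("angle_offset_deg:\\s*", "", kv))
    if (startsWith(kv, "source:"))
      meta$source <- sub("source:\\s*", "", kv)
    i <- i + 1L
  }
  starts <- which(startsWith(lines, "# t="))
  if (length(starts) == 0L)
    stop("no scan blocks ('# t=') found in ", path, call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  spectra <- vector("list", length(starts))
  grid <- NULL
  last_t <- -Inf
  for (b in seq_along(starts)) {
    t <- as.numeric(sub("# t=\\s*", "", lines[starts[b]]))
    if (is.na(t) || t <= last_t)
      stop("block at line ", starts[b],
           ": timestamps must be numeric and ascending", call. = FALSE)
    last_t <- t
    body <- lines[(starts[b] + 1L):ends[b]]
    body <- body[nzchar(body)]
    if (length(body) < 3L)
      stop("block at line ", starts[b], ": fewer than 3 samples",
           call. = FALSE)
    m <- matrix(as.numeric(unlist(strsplit(body, "[ \t]+"))),
                ncol = 2L, byrow = TRUE)
    if (anyNA(m))
      stop("block at line ", starts[b], ": non-numeric sample",
           call. = FALSE)
    if (any(diff(m[, 1L]) <= 0))
      stop("block at line ", starts[b],
           ": angles must be strictly ascending", call. = FALSE)
    if (is.null(grid)) grid <- m[, 1L]
    else if (length(grid) != nrow(m) || any(grid != m[, 1L]))
      stop("block at line ", starts[b],
           ": angle grid differs from the first block", call. = FALSE)
    sp <- angular_spectrum(m[, 1L], m[, 2L], timestamp = t)
    if (!is.null(meta$angle_offset))
      attr(sp, "angle_offset") <- meta$angle_offset
    spectra[[b]] <- sp
  }
  attributes(spectra) <- c(attributes(spectra), meta)
  spectra
}

#' Write a stack definition file
#'
#' Structured text: one `layer:` record per layer (name, n, k,
#' thickness in nm or `inf`), plus `wavelength_nm` and the optional
#' instrument angle offset.  Values are serialized with 17 significant
#' digits, so read/write round trips are lossless.
#'
#' @param stack A [layer_stack()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "layer_stack"))
  num <- function(x) sprintf("%.17g", x)
  lines <- c(.stack_magic,
             paste0("wavelength_nm: ", num(stack$wavelength)))
  off <- attr(stack, "angle_offset")
  if (!is.null(off)) lines <- c(lines,
                                paste0("angle_offset_deg: ", num(off)))
  for (l in stack$layers) {
    th <- if (is_semi_infinite(l)) "inf" else num(l$thickness)
    lines <- c(lines, paste("layer:", l$name, num(l$n), num(l$k), th))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a stack definition file
#'
#' @param path File written by [write_stack()] (or hand-authored in the
#'   same dialect).
#' @return A [layer_stack()]; an `angle_offset_deg` header becomes the
#'   stack's `"angle_offset"` attribute.
#' @export
read_stack <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1L] != .stack_magic)
    stop("not a stack file (missing '", .stack_magic, "'): ", path,
         call. = FALSE)
  wavelength <- NULL
  offset <- NULL
  layers <- list()
  for (i in seq_along(lines)[-1L]) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (startsWith(ln, "wavelength_nm:")) {
      wavelength <- as.numeric(sub("wavelength_nm:\\s*", "", ln))
    } else if (startsWith(ln, "angle_offset_deg:")) {
      offset <- as.numeric(sub("angle_offset_deg:\\s*", "", ln))
    } else if (startsWith(ln, "layer:")) {
      parts <- strsplit(sub("layer:\\s*", "", ln), "[ \t]+")[[1L]]
      if (length(parts) != 4L)
        stop("line ", i, ": layer record needs name n k thickness",
             call. = FALSE)
      th <- if (identical(parts[4L], "inf")) Inf else as.numeric(parts[4L])
      layers[[length(layers) + 1L]] <-
        optical_layer(parts[1L], as.numeric(parts[2L]),
                      as.numeric(parts[3L]), th)
    } else {
      stop("line ", i, ": unrecognized record '", ln, "'", call. = FALSE)
    }
  }
  if (is.null(wavelength))
    stop("stack file lacks a wavelength_nm record: ", path, call. = FALSE)
  s <- layer_stack(layers, wavelength = wavelength)
  if (!is.null(offset)) attr(s, "angle_offset") <- offset
  s
}

#' Read an injection table
#'
#' CSV with columns `start_s`, `end_s`, `label`, `concentration`.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_injections <- function(path) {
  inj <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s")
  if (!all(need %in% names(inj)))
    stop("injection file must contain columns start_s and end_s",
         call. = FALSE)
  inj
}
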