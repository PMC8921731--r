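# Minimal C3D motion-capture file support (Intel/PC processor type).
# The subset implemented covers what marker-trajectory exchange needs:
# the 3D point section with float or scaled-integer storage, the POINT
# parameter group (USED, FRAMES, RATE, SCALE, DATA_START, UNITS, LABELS)
# and invalid-sample flags carried in the residual word.  Analog channels
# are ignored on read and written as absent.

C3D_BLOCK <- 512L

c3d_read_param_section <- function(raw, param_block) {
  off <- (param_block - 1L) * C3D_BLOCK
  if (length(raw) < off + 4L) {
    stop_antkin("truncated C3D parameter section", "format_error")
  }
  proc <- as.integer(raw[off + 4L])
  if (proc != 84L) {
    stop_antkin(sprintf(
      "unsupported C3D processor type %d (only Intel/PC = 84)", proc),
      "format_error")
  }
  pos <- off + 5L  # first group/parameter record (1-based index into raw)
  groups <- list()   # id -> name
  params <- list()   # "GROUP:PARAM" -> value
  repeat {
    if (pos + 1L > length(raw)) break
    nname <- readBin(raw[pos], "integer", size = 1, signed = TRUE)
    gid <- readBin(raw[pos + 1L], "integer", size = 1, signed = TRUE)
    if (nname == 0L) break
    nchr <- abs(nname)
    name <- rawToChar(raw[(pos + 2L):(pos + 1L + nchr)])
    p <- pos + 2L + nchr
    offset <- readBin(raw[p:(p + 1L)], "integer", size = 2,
                      signed = TRUE, endian = "little")
    if (gid < 0L) {  # group record
      groups[[as.character(-gid)]] <- name
    } else {         # parameter record
      q <- p + 2L
      type <- readBin(raw[q], "integer", size = 1, signed = TRUE)
      ndim <- as.integer(raw[q + 1L])
      dims <- if (ndim > 0) as.integer(raw[(q + 2L):(q + 1L + ndim)]) else
        integer(0)
      nel <- prod(c(1L, dims))
      dstart <- q + 2L + ndim
      esz <- switch(as.character(type), `-1` = 1L, `1` = 1L, `2` = 2L,
                    `4` = 4L, stop_antkin("bad C3D parameter type",
                                          "format_error"))
      bytes <- raw[dstart:(dstart + nel * esz - 1L)]
      val <- switch(as.character(type),
        `-1` = {
          s <- rawToChar(bytes)
          if (length(dims) >= 2L) {
            w <- dims[1]
            vapply(seq_len(dims[2]), function(i)
              trimws(substr(s, (i - 1) * w + 1, i * w)), "")
          } else trimws(s)
        },
        `1` = readBin(bytes, "integer", n = nel, size = 1, signed = TRUE),
        `2` = readBin(bytes, "integer", n = nel, size = 2, signed = TRUE,
                      endian = "little"),
        `4` = readBin(bytes, "double", n = nel, size = 4,
                      endian = "little"))
      params[[paste0(gid, ":", name)]] <- val
    }
    if (offset == 0L) break
    pos <- p + offset
  }
  # resolve numeric group ids to names
  out <- list()
  for (key in names(params)) {
    gid <- sub(":.*", "", key)
    pname <- sub("^[^:]*:", "", key)
    gname <- groups[[gid]]
    if (is.null(gname)) gname <- paste0("G", gid)
    out[[paste0(toupper(gname), ":", toupper(pname))]] <- params[[key]]
  }
  out
}

#' Read a C3D motion-capture file
#'
#' Reads marker labels, sampling rate and 3D point data from a C3D file
#' (Intel processor type; float or scaled-integer point storage).
#' Coordinates are normalized to mm using `POINT:UNITS`; samples whose
#' residual word is negative are flagged missing.  Analog channels are
#' ignored.
#'
#' @param path C3D file path.
#' @return a [marker_trial()].
#' @export
read_c3d <- function(path) {
  if (!file.exists(path)) {
    stop_antkin(sprintf("no such file: %s", path), "format_error")
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < C3D_BLOCK || as.integer(raw[2]) != 80L) {
    stop_antkin("not a C3D file (bad magic byte)", "format_error")
  }
  param_block <- as.integer(raw[1])
  u16 <- function(i) readBin(raw[(2 * i - 1):(2 * i)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  f32 <- function(i) readBin(raw[(2 * i - 1):(2 * i + 2)], "double",
                             size = 4, endian = "little")
  npoints <- u16(2)
  first_frame <- u16(4)
  last_frame <- u16(5)
  scale <- f32(7)
  data_start <- u16(9)
  rate <- f32(11)

  pars <- c3d_read_param_section(raw, param_block)
  if (!is.null(pars[["POINT:USED"]])) npoints <- pars[["POINT:USED"]][1]
  if (!is.null(pars[["POINT:RATE"]])) rate <- pars[["POINT:RATE"]][1]
  if (!is.null(pars[["POINT:SCALE"]])) scale <- pars[["POINT:SCALE"]][1]
  if (!is.null(pars[["POINT:DATA_START"]])) {
    data_start <- pars[["POINT:DATA_START"]][1]
  }
  nframes <- last_frame - first_frame + 1L
  units <- pars[["POINT:UNITS"]]
  ufac <- if (is.null(units)) 1 else switch(tolower(units[1]),
    mm = 1, m = 1000, cm = 10,
    stop_antkin(sprintf("unknown C3D point units '%s'", units[1]),
                "unit_error"))
  labels <- pars[["POINT:LABELS"]]
  if (is.null(labels) || length(labels) < npoints) {
    labels <- sprintf("M%03d", seq_len(npoints))
  }
  labels <- labels[seq_len(npoints)]
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "_")
  }

  off <- (data_start - 1L) * C3D_BLOCK
  is_float <- scale < 0
  wsz <- if (is_float) 4L else 2L
  need <- off + nframes * npoints * 4L * wsz
  if (length(raw) < need) {
    stop_antkin("truncated C3D point data section", "format_error")
  }
  nvals <- nframes * npoints * 4L
  vals <- if (is_float) {
    readBin(raw[(off + 1L):need], "double", n = nvals, size = 4,
            endian = "little")
  } else {
    readBin(raw[(off + 1L):need], "integer", n = nvals, size = 2,
            signed = TRUE, endian = "little")
  }
  dim(vals) <- c(4L, npoints, nframes)
  coords <- vals[1:3, , , drop = FALSE]
  resid <- vals[4, , ]
  if (!is_float) coords <- coords * abs(scale)
  data <- aperm(coords, c(3, 2, 1)) * ufac
  missing <- t(matrix(resid < 0, npoints, nframes))
  data[is.na(data) | !is.finite(data)] <- 0
  marker_trial(data, labels, rate, missing = missing)
}

c3d_param_record <- function(gid, name, type, dims, data_raw, last = FALSE) {
  name_raw <- charToRaw(name)
  body <- c(as.raw(type %% 256L), as.raw(length(dims)),
            as.raw(dims), data_raw, as.raw(0L))  # trailing 0 = no description
  offset <- if (last) 0L else 2L + length(body)
  c(as.raw(length(name_raw)), as.raw(gid %% 256L), name_raw,
    writeBin(as.integer(offset), raw(), size = 2, endian = "little"),
    body)
}

c3d_group_record <- function(gid, name) {
  name_raw <- charToRaw(name)
  offset <- 2L + 1L  # offset word + empty description
  c(as.raw(length(name_raw)), as.raw((256L - gid) %% 256L), name_raw,
    writeBin(as.integer(offset), raw(), size = 2, endian = "little"),
    as.raw(0L))
}

#' Write a trial as a C3D file
#'
#' Writes an Intel-format C3D with floating-point point storage, mm units
#' and no analog channels.  Missing samples get a residual word of -1.
#'
#' @param trial a [marker_trial()].
#' @param path output path.
#' @param units coordinate units to declare and write (`"mm"` or `"m"`).
#' @return `path`, invisibly.
#' @export
write_c3d <- function(trial, path, units = c("mm", "m")) {
  stopifnot(inherits(trial, "marker_trial"))
  units <- match.arg(units)
  ufac <- if (units == "m") 1 / 1000 else 1
  nf <- n_frames(trial); nm <- length(trial$marker_names)
  if (nf > 65535L) stop_antkin("trial too long for C3D header", "invalid_input")

  f32raw <- function(x) writeBin(as.numeric(x), raw(), size = 4,
                                 endian = "little")
  i16raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")

  width <- max(4L, max(nchar(trial$marker_names)))
  lab_chr <- vapply(trial$marker_names, function(s)
    formatC(s, width = -width), "")
  labels_raw <- charToRaw(paste(lab_chr, collapse = ""))

  records <- c(
    c3d_group_record(1L, "POINT"),
    c3d_param_record(1L, "USED", 2L, integer(0), i16raw(nm)),
    c3d_param_record(1L, "FRAMES", 2L, integer(0), i16raw(min(nf, 32767L))),
    c3d_param_record(1L, "SCALE", 4L, integer(0), f32raw(-1)),
    c3d_param_record(1L, "RATE", 4L, integer(0), f32raw(trial$rate)),
    c3d_param_record(1L, "UNITS", -1L, nchar(units), charToRaw(units)),
    c3d_param_record(1L, "LABELS", -1L, c(width, nm), labels_raw),
    c3d_group_record(2L, "ANALOG"),
    c3d_param_record(2L, "USED", 2L, integer(0), i16raw(0), last = FALSE)
  )
  # DATA_START depends on the parameter section length; reserve the record
  # then compute
  param_head <- as.raw(c(1L, 80L, 0L, 84L))  # block count patched below
  fixed_len <- length(param_head) + length(records)
  ds_record_len <- length(c3d_param_record(1L, "DATA_START", 2L, integer(0),
                                           i16raw(0), last = TRUE))
  n_param_blocks <- ceiling((fixed_len + ds_record_len) / C3D_BLOCK)
  data_start <- 2L + n_param_blocks
  records <- c(records,
               c3d_param_record(1L, "DATA_START", 2L, integer(0),
                                i16raw(data_start), last = TRUE))
  param_head[3] <- as.raw(n_param_blocks)
  param_section <- c(param_head, records)
  pad <- n_param_blocks * C3D_BLOCK - length(param_section)
  param_section <- c(param_section, raw(pad))

  header <- raw(C3D_BLOCK)
  header[1] <- as.raw(2L)   # parameter section starts at block 2
  header[2] <- as.raw(80L)
  header[3:4] <- i16raw(nm)          # points per frame
  header[5:6] <- i16raw(0L)          # analog measurements per frame
  header[7:8] <- i16raw(1L)          # first frame
  header[9:10] <- i16raw(nf)         # last frame
  header[11:12] <- i16raw(10L)       # max interpolation gap
  header[13:16] <- f32raw(-1)        # scale (negative: float data)
  header[17:18] <- i16raw(data_start)
  header[19:20] <- i16raw(1L)        # analog samples per frame
  header[21:24] <- f32raw(trial$rate)

  vals <- numeric(4L * nm * nf)
  idx <- 1L
  for (i in seq_len(nf)) {
    for (k in seq_len(nm)) {
      if (trial$missing[i, k]) {
        vals[idx:(idx + 3L)] <- c(0, 0, 0, -1)
      } else {
        vals[idx:(idx + 2L)] <- trial$data[i, k, ] * ufac
        vals[idx + 3L] <- 0
      }
      idx <- idx + 4L
    }
  }
  data_raw <- writeBin(vals, raw(), size = 4, endian = "little")
  dpad <- (C3D_BLOCK - length(data_raw) %% C3D_BLOCK) %% C3D_BLOCK
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, param_section, data_raw, raw(dpad)), con)
  invisible(path)
}
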