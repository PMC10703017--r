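# Reading and writing EEG recordings.
#
# EDF (16-bit) and BDF (24-bit, Biosemi) are implemented directly on top of
# readBin/writeBin: both formats are fixed-layout ASCII headers followed by
# little-endian integer sample records, quantized between per-channel
# physical and digital ranges. An RDS variant is provided as a lossless
# native mirror for intermediate artifacts.

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

fmt_num <- function(x, width) {
  s <- formatC(x, digits = width - 2L, width = width, format = "g", flag = "-")
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

edf_digital_range <- function(format) {
  if (format == "bdf") c(-8388608, 8388607) else c(-32768, 32767)
}

#' Write an EEG recording to disk
#'
#' Supports `"edf"` (16-bit), `"bdf"` (24-bit) and `"rds"` (lossless native
#' serialization). EDF/BDF quantize each channel linearly between its
#' physical minimum and maximum, so a write/read round trip reproduces the
#' data to within one quantization step; the RDS route is exact. The subject
#' id and class label are stored in the patient and recording header fields
#' (EDF/BDF) or carried verbatim (RDS).
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param format `"edf"`, `"bdf"` or `"rds"`; default inferred from the
#'   file extension.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- tolower(format %||% tools::file_ext(path))
  if (!format %in% c("edf", "bdf", "rds")) {
    stop(sprintf("unsupported EEG format '%s' for %s", format, path),
         call. = FALSE)
  }
  if (format == "rds") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  data <- rec$data
  ns <- nrow(data)
  n <- ncol(data)
  dig <- edf_digital_range(format)
  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  # the header stores the physical range in 8 ASCII characters; quantize
  # against the values as they will actually be read back
  pmin_ <- vapply(pmin_, function(v) as.numeric(trimws(fmt_num(v, 8L))), 0)
  pmax_ <- vapply(pmax_, function(v) as.numeric(trimws(fmt_num(v, 8L))), 0)
  scale <- (pmax_ - pmin_) / (dig[2] - dig[1])
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "bdf") {
    writeBin(as.raw(255L), con)
    writeChar(pad_ascii("BIOSEMI", 7L), con, nchars = 7L, eos = NULL)
  } else {
    writeChar(pad_ascii("0", 8L), con, nchars = 8L, eos = NULL)
  }
  writeChar(pad_ascii(rec$subject_id, 80L), con, nchars = 80L, eos = NULL)
  writeChar(pad_ascii(sprintf("label=%s", ifelse(is.na(rec$label), "NA",
                                                 rec$label)), 80L),
            con, nchars = 80L, eos = NULL)
  writeChar(pad_ascii("01.01.00", 8L), con, nchars = 8L, eos = NULL)
  writeChar(pad_ascii("00.00.00", 8L), con, nchars = 8L, eos = NULL)
  writeChar(pad_ascii(header_bytes, 8L), con, nchars = 8L, eos = NULL)
  writeChar(pad_ascii(if (format == "bdf") "24BIT" else "", 44L), con,
            nchars = 44L, eos = NULL)
  writeChar(pad_ascii(1L, 8L), con, nchars = 8L, eos = NULL)   # one record
  writeChar(fmt_num(n / rec$fs, 8L), con, nchars = 8L, eos = NULL)
  writeChar(pad_ascii(ns, 4L), con, nchars = 4L, eos = NULL)
  for (lab in rec$channel_names) {
    writeChar(pad_ascii(lab, 16L), con, nchars = 16L, eos = NULL)
  }
  rep_field <- function(value, width) {
    for (i in seq_len(ns)) writeChar(pad_ascii(value, width), con,
                                     nchars = width, eos = NULL)
  }
  rep_field("", 80L)                               # transducer
  rep_field("uV", 8L)                              # physical dimension
  for (v in pmin_) writeChar(fmt_num(v, 8L), con, nchars = 8L, eos = NULL)
  for (v in pmax_) writeChar(fmt_num(v, 8L), con, nchars = 8L, eos = NULL)
  rep_field(dig[1], 8L)
  rep_field(dig[2], 8L)
  rep_field("", 80L)                               # prefiltering
  rep_field(n, 8L)                                 # samples per record
  rep_field("", 32L)
  for (ch in seq_len(ns)) {
    d <- round((data[ch, ] - pmin_[ch]) / scale[ch]) + dig[1]
    d <- pmin(pmax(d, dig[1]), dig[2])
    if (format == "bdf") {
      u <- as.integer(d)
      u <- ifelse(u < 0, u + 16777216L, u)         # two's complement, 24 bit
      b <- rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L)
      writeBin(as.raw(as.vector(b)), con)
    } else {
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_ascii <- function(con, nchars) {
  out <- readChar(con, nchars, useBytes = TRUE)
  if (nchar(out, type = "bytes") < nchars) {
    stop("unexpected end of file while reading header", call. = FALSE)
  }
  trimws(out)
}

#' Read an EEG recording from disk
#'
#' Parses EDF/BDF headers and sample records written by [write_eeg()] (and,
#' for EDF/BDF, any single-record file following the standard layout), or
#' loads an RDS-serialized recording. Subject id and label are recovered
#' from the header when present and can be overridden from a cohort
#' manifest row.
#'
#' @param path input file.
#' @param format `"edf"`, `"bdf"` or `"rds"`; default inferred from the
#'   extension.
#' @param subject_id,label optional overrides (e.g. from a manifest).
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path, format = NULL, subject_id = NULL, label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("EEG file not found: %s", path), call. = FALSE)
  }
  format <- tolower(format %||% tools::file_ext(path))
  if (format == "rds") {
    rec <- readRDS(path)
    if (!inherits(rec, "eeg_recording")) {
      stop(sprintf("format error in %s: not a serialized eeg_recording", path),
           call. = FALSE)
    }
  } else if (format %in% c("edf", "bdf")) {
    rec <- tryCatch(read_edf_impl(path, format),
                    error = function(e) {
                      stop(sprintf("format error in %s: %s", path,
                                   conditionMessage(e)), call. = FALSE)
                    })
  } else {
    stop(sprintf("unsupported EEG format '%s' for %s", format, path),
         call. = FALSE)
  }
  if (!is.null(subject_id)) rec$subject_id <- subject_id
  if (!is.null(label)) rec$label <- as.integer(label)
  rec
}

read_edf_impl <- function(path, format) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (format == "bdf") {
    magic <- readBin(con, "raw", 1L)
    ident <- read_ascii(con, 7L)
    if (as.integer(magic) != 255L || ident != "BIOSEMI") {
      stop("not a BDF file (missing BIOSEMI identifier)")
    }
  } else {
    ver <- read_ascii(con, 8L)
    if (ver != "0") stop("not an EDF file (bad version field)")
  }
  patient <- read_ascii(con, 80L)
  recording <- read_ascii(con, 80L)
  read_ascii(con, 8L); read_ascii(con, 8L)          # date, time
  header_bytes <- as.integer(read_ascii(con, 8L))
  read_ascii(con, 44L)
  n_records <- as.integer(read_ascii(con, 8L))
  rec_dur <- as.numeric(read_ascii(con, 8L))
  ns <- as.integer(read_ascii(con, 4L))
  if (is.na(ns) || ns < 1L || is.na(n_records) || n_records < 1L) {
    stop("ambiguous header (bad signal or record count)")
  }
  fields <- function(width) vapply(seq_len(ns),
                                   function(i) read_ascii(con, width), "")
  labels <- fields(16L)
  fields(80L)
  fields(8L)
  pmin_ <- as.numeric(fields(8L))
  pmax_ <- as.numeric(fields(8L))
  dmin <- as.numeric(fields(8L))
  dmax <- as.numeric(fields(8L))
  fields(80L)
  spr <- as.integer(fields(8L))
  fields(32L)
  if (header_bytes != 256L + 256L * ns) stop("header size mismatch")
  bytes_per <- if (format == "bdf") 3L else 2L
  expected <- header_bytes + n_records * sum(spr) * bytes_per
  if (file.size(path) < expected) {
    stop(sprintf("truncated file (expected %d bytes, found %d)",
                 expected, file.size(path)))
  }
  data <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      if (format == "bdf") {
        b <- as.integer(readBin(con, "raw", 3L * spr[ch]))
        dim(b) <- c(3L, spr[ch])
        d <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
        d <- ifelse(d >= 8388608L, d - 16777216L, d)
      } else {
        d <- readBin(con, "integer", spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      }
      if (length(d) < spr[ch]) stop("truncated data record")
      scale <- (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      data[ch, cols] <- (d - dmin[ch]) * scale + pmin_[ch]
    }
  }
  fs <- spr[1] / rec_dur
  label <- NA_integer_
  m <- regmatches(recording, regexec("label=([01])", recording))[[1]]
  if (length(m) == 2L) label <- as.integer(m[2])
  eeg_recording(data, fs, labels, subject_id = patient, label = label)
}

#' Read a cohort from a manifest
#'
#' Loads every recording listed in a `manifest.csv` produced by
#' [generate_cohort()], attaching each row's subject id and label.
#'
#' @param manifest_path path to the manifest CSV
#'   (columns subject_id, label, path).
#' @return list of [eeg_recording()] named by subject id.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "label", "path")
  if (!all(needed %in% names(manifest))) {
    stop("manifest must have columns subject_id, label, path", call. = FALSE)
  }
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) {
      p <- file.path(dirname(manifest_path), basename(p))
    }
    read_eeg(p, subject_id = manifest$subject_id[i], label = manifest$label[i])
  })
  names(recs) <- manifest$subject_id
  recs
}
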