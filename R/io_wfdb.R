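#' Write an alarm record in WFDB format-16 layout
#'
#' Writes `<id>.hea` (ASCII header) and `<id>.dat` (interleaved 16-bit
#' little-endian samples) in the bedside-monitor challenge layout.  A gain is
#' chosen per channel so the digitized signal spans most of the int16 range;
#' reading the record back reproduces each sample to within one quantization
#' step of that gain.
#'
#' @param record An [alarm_record()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the header file.
#' @export
write_alarm_record <- function(record, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$record_id
  nsig <- length(record$channels)
  n <- record$n_samples
  hea <- sprintf("%s %d %g %d", id, nsig, record$fs, n)
  dig <- matrix(0L, nrow = nsig, ncol = n)
  for (i in seq_len(nsig)) {
    ch <- record$channels[[i]]
    rng <- max(abs(ch$samples))
    gain <- if (rng > 0) max(1, floor(26000 / rng)) else 200
    d <- as.integer(round(ch$samples * gain))
    d[d > 32767L] <- 32767L
    d[d < -32768L] <- -32768L
    dig[i, ] <- d
    units <- switch(ch$kind, ABP = "mmHg", ECG = "mV", PPG = "NU")
    hea <- c(hea, sprintf("%s.dat 16 %d(0)/%s 16 0 %d 0 0 %s",
                          id, gain, units, d[1], ch$name))
  }
  writeLines(hea, file.path(dir, paste0(id, ".hea")))
  con <- file(file.path(dir, paste0(id, ".dat")), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(dig)), con, size = 2, endian = "little")
  invisible(file.path(dir, paste0(id, ".hea")))
}

parse_gain_spec <- function(tok, line_no, path) {
  # forms: "200", "200/mV", "200(0)/mV"
  m <- regmatches(tok, regexec("^(-?[0-9.]+)(\\(([-0-9]+)\\))?(/(.*))?$", tok))[[1]]
  if (!length(m))
    stop("malformed header ", path, ": cannot parse gain field '", tok,
         "' on line ", line_no)
  gain <- as.numeric(m[2])
  baseline <- if (nzchar(m[4])) as.numeric(m[4]) else 0
  units <- if (nzchar(m[6])) m[6] else "a.u."
  if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
  list(gain = gain, baseline = baseline, units = units)
}

#' Read an alarm record from disk
#'
#' Understands two dialects: the WFDB format-16 header+signal pair written by
#' [write_alarm_record()] (and by the public challenge data), and a plain CSV
#' fallback written by [write_alarm_record_csv()].  Channel kinds are
#' classified from the signal names via [channel_kind()]; the alarm type is
#' decoded from the first character of the record id; the truth label is
#' looked up in `answers` when given.
#'
#' @param header_path Path to the `.hea` (or `.csv`) file.
#' @param answers Optional named label vector from [load_answers()].
#' @return An [alarm_record()].
#' @export
read_alarm_record <- function(header_path, answers = NULL) {
  if (grepl("\\.csv$", header_path))
    return(read_alarm_record_csv(header_path, answers))
  if (!grepl("\\.hea$", header_path))
    stop("expected a .hea (or .csv) file, got: ", header_path)
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  lines <- readLines(header_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("malformed header ", header_path, ": empty file")
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4)
    stop("malformed header ", header_path, ": record line '", lines[1],
         "' needs <id> <nsig> <fs> <nsamples>")
  id <- top[1]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  if (anyNA(c(nsig, fs, n)) || nsig < 1)
    stop("malformed header ", header_path, ": record line '", lines[1], "'")
  if (n < 1)
    stop("malformed header ", header_path, ": record declares ", n, " samples")
  if (length(lines) < 1 + nsig)
    stop("malformed header ", header_path, ": expected ", nsig,
         " signal lines, found ", length(lines) - 1)
  arrhythmia <- decode_alarm_type(id)

  dat_path <- NULL
  specs <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    ln <- lines[1 + i]
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 3)
      stop("malformed header ", header_path, ": signal line '", ln, "'")
    if (tok[2] != "16")
      stop("unsupported WFDB signal format '", tok[2], "' on line '", ln,
           "' (only format 16 is supported)")
    g <- parse_gain_spec(tok[3], 1 + i, header_path)
    specs[[i]] <- list(file = tok[1], gain = g$gain, baseline = g$baseline,
                       name = tok[length(tok)])
    dat_path <- file.path(dirname(header_path), tok[1])
  }
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = nsig * n, size = 2, endian = "little",
                 signed = TRUE)
  if (length(raw) < nsig * n)
    stop("signal file ", dat_path, " truncated: expected ", nsig * n,
         " samples, found ", length(raw))
  dig <- matrix(raw, nrow = nsig)
  channels <- lapply(seq_len(nsig), function(i) {
    sp <- specs[[i]]
    new_channel(sp$name, (dig[i, ] - sp$baseline) / sp$gain, fs)
  })
  label <- lookup_label(id, answers)
  alarm_record(id, channels, arrhythmia = arrhythmia, label = label)
}

lookup_label <- function(id, answers) {
  if (is.null(answers) || !id %in% names(answers)) "UNKNOWN"
  else unname(answers[[id]])
}

#' Write / read the CSV record dialect
#'
#' Dependency-light fixture format: two comment lines carrying the record id
#' and sampling rate, then one column per channel named as in the monitor
#' header.  Lossless up to the printed precision (15 significant digits).
#'
#' @param record An [alarm_record()].
#' @param path Output `.csv` path.
#' @return Invisibly, `path`.
#' @export
write_alarm_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# record_id: %s", record$record_id),
               sprintf("# fs: %.10g", record$fs)), con)
  mat <- vapply(record$channels, function(ch) ch$samples,
                numeric(record$n_samples))
  colnames(mat) <- vapply(record$channels, function(ch) ch$name, "")
  writeLines(paste(colnames(mat), collapse = ","), con)
  body <- apply(mat, 1, function(r) paste(sprintf("%.15g", r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_alarm_record_csv
#' @param answers Optional named label vector from [load_answers()].
#' @export
read_alarm_record_csv <- function(path, answers = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  id <- sub("^#\\s*record_id:\\s*", "", grep("record_id", meta, value = TRUE)[1])
  fs <- as.numeric(sub("^#\\s*fs:\\s*", "", grep("fs:", meta, value = TRUE)[1]))
  if (is.na(fs)) stop("malformed CSV record ", path, ": missing fs line")
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE)
  channels <- lapply(names(dat), function(nm) new_channel(nm, dat[[nm]], fs))
  alarm_record(id, channels, label = lookup_label(id, answers))
}

#' Read and write feature tables
#'
#' Feature tables are CSV files ("." decimal, UTF-8) with a leading comment
#' line recording the arrhythmia type, then the provenance columns
#' `record_id`, `window_start`, `label`, followed by one column per feature.
#' Values round-trip within 1e-12 relative error; missing values are written
#' as `NA`.
#'
#' @param table A `feature_table` (see [extract_features()]).
#' @param path Output path.
#' @return `read_feature_table()` returns the `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  nms <- feature_names(table)
  if (anyDuplicated(nms))
    stop("duplicate feature names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# arrhythmia: %s", attr(table, "arrhythmia")), con)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  df[df == "NA"] <- "NA"
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(df, sep = ",")), con)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  arr <- sub("^#\\s*arrhythmia:\\s*", "",
             grep("^#\\s*arrhythmia:", lines, value = TRUE)[1])
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  nms <- setdiff(names(df), c("record_id", "window_start", "label"))
  if (anyDuplicated(names(df)))
    stop("duplicate feature names in ", path)
  for (nm in nms) df[[nm]] <- as.numeric(df[[nm]])
  new_feature_table(df, arrhythmia = arr)
}

#' Load an alarm answers table
#'
#' Two-column ASCII table `record_id,label` with labels 0 (false alarm) or
#' 1 (true alarm), as distributed with the challenge training set.
#'
#' @param path Path to the answers file.
#' @return Named character vector mapping record id to `TRUE_ALARM` /
#'   `FALSE_ALARM`; empty for an empty file.
#' @export
load_answers <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  out <- character(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[,\\s]+")[[1]]
    if (length(tok) != 2 || !tok[2] %in% c("0", "1"))
      stop("unparseable answers row ", i, ": '", lines[i],
           "' (expected 'record_id,0|1')")
    ids[i] <- tok[1]
    out[i] <- if (tok[2] == "1") "TRUE_ALARM" else "FALSE_ALARM"
  }
  stats::setNames(out, ids)
}

#' Write predictions or answers in the two-column convention
#'
#' @param labels Named character vector (`TRUE_ALARM`/`FALSE_ALARM`) keyed by
#'   record id.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_answers <- function(labels, path) {
  writeLines(sprintf("%s,%d", names(labels),
                     as.integer(labels == "TRUE_ALARM")), path)
  invisible(path)
}
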