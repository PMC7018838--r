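# Fixed text formats. One row per sample, UTF-8, '.' decimal separator.
#   trace CSV:    t,fs,ex,ey,ez,qw,qx,qy,qz,conf        (header mandatory)
#   labels CSV:   t,label        label in {FIX,PUR,SAC,NONE}
#   velocity CSV: t,we,wh,we_az,wh_az,we_el,wh_el,conf
# Readers also accept yaw,pitch,roll columns (degrees, intrinsic Z-Y-X) in
# place of the quaternion columns, and the label aliases BLINK/UNLABELLED
# (mapped to NONE on input, never written on output).

LABEL_ALIASES <- c(BLINK = "NONE", UNLABELLED = "NONE")

#' Read a gaze trace from CSV
#'
#' Expects columns `t,fs,ex,ey,ez,qw,qx,qy,qz,conf` (or `yaw,pitch,roll` in
#' degrees instead of the four quaternion columns). Direction vectors within
#' 1e-3 of unit norm are renormalized; anything further off is an error.
#'
#' @param path path to a trace CSV file.
#' @param subject_id,task_id identifiers attached to the trace.
#' @return a [gaze_trace].
#' @export
read_trace <- function(path, subject_id = "", task_id = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) stop("malformed trace CSV '", path, "': ",
                                          conditionMessage(e)))
  need <- c("t", "fs", "ex", "ey", "ez", "conf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace CSV missing column(s): ", paste(miss, collapse = ", "))
  if (all(c("qw", "qx", "qy", "qz") %in% names(df))) {
    head <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  } else if (all(c("yaw", "pitch") %in% names(df))) {
    roll <- if ("roll" %in% names(df)) df$roll else 0
    head <- quat_from_euler(df$yaw, df$pitch, roll)
  } else {
    stop("trace CSV needs qw,qx,qy,qz or yaw,pitch[,roll] columns")
  }
  num_cols <- c(need, intersect(c("qw", "qx", "qy", "qz", "yaw", "pitch", "roll"),
                                names(df)))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("malformed value in column '%s' at data row %d of %s",
                   cl, if (is.na(bad)) 1L else bad, path))
    }
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' at data row %d of %s",
                   cl, which(is.na(v))[1], path))
  }
  dt <- diff(df$t)
  if (any(dt <= 0))
    stop(sprintf("non-monotonic timestamps at data row %d of %s",
                 which(dt <= 0)[1] + 1L, path))
  gaze_trace(df$t, as.matrix(df[, c("ex", "ey", "ez")]), head, df$conf,
             fs = df$fs[1], subject_id = subject_id, task_id = task_id)
}

#' Write a gaze trace to CSV
#'
#' @param trace a [gaze_trace].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gaze_trace"))
  df <- data.frame(t = trace$timestamps, fs = trace$fs,
                   ex = trace$eih[, 1], ey = trace$eih[, 2], ez = trace$eih[, 3],
                   qw = trace$head[, 1], qx = trace$head[, 2],
                   qy = trace$head[, 3], qz = trace$head[, 4],
                   conf = trace$confidence)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label sequence from CSV
#'
#' Expects columns `t,label`. Tokens `BLINK` and `UNLABELLED` are accepted
#' and mapped to `NONE`; unknown tokens are an error.
#'
#' @param path path to a labels CSV.
#' @param fs sampling rate; inferred from the `t` column when `NULL`.
#' @param source_id labeller/classifier identifier.
#' @return a [label_sequence].
#' @export
read_labels <- function(path, fs = NULL, source_id = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, colClasses = c(t = "numeric", label = "character"))
  if (!all(c("t", "label") %in% names(df)))
    stop("labels CSV must have columns t,label")
  if (nrow(df) == 0) {
    warning("empty label file: ", path)
    return(label_sequence(character(0), fs = if (is.null(fs)) NA_real_ else fs,
                          source_id = source_id))
  }
  lab <- toupper(trimws(df$label))
  ali <- lab %in% names(LABEL_ALIASES)
  lab[ali] <- LABEL_ALIASES[lab[ali]]
  bad <- setdiff(unique(lab), GAZE_ALPHABET)
  if (length(bad))
    stop("unknown label token(s) in ", path, ": ", paste(bad, collapse = ", "))
  if (is.null(fs)) fs <- 1 / median(diff(df$t))
  label_sequence(lab, fs = fs, source_id = source_id)
}

#' Write a label sequence to CSV
#'
#' Always emits canonical tokens (`FIX`, `PUR`, `SAC`, `NONE`); aliases are
#' input-only.
#'
#' @param seq a [label_sequence].
#' @param path output path.
#' @param timestamps optional sample times; defaults to `(0:(n-1))/fs`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(seq, path, timestamps = NULL) {
  stopifnot(inherits(seq, "label_sequence"))
  n <- length(seq)
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1L) / label_fs(seq)
  df <- data.frame(t = timestamps, label = as_label_chr(seq))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a velocity trace to CSV
#'
#' Columns `t,we,wh,we_az,wh_az,we_el,wh_el,conf`; masked (low-confidence)
#' samples are written as-is, the mask being recoverable from `conf` and the
#' configured threshold.
#'
#' @param vel a [velocity_trace].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_velocity <- function(vel, path) {
  stopifnot(inherits(vel, "velocity_trace"))
  df <- data.frame(t = vel$timestamps, we = vel$we, wh = vel$wh,
                   we_az = vel$we_az, wh_az = vel$wh_az,
                   we_el = vel$we_el, wh_el = vel$wh_el, conf = vel$conf)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a velocity trace from CSV
#'
#' @param path path to a velocity CSV written by [write_velocity].
#' @param fs sampling rate; inferred from timestamps when `NULL`.
#' @param confidence_threshold mask threshold applied to the `conf` column.
#' @return a [velocity_trace].
#' @export
read_velocity <- function(path, fs = NULL, confidence_threshold = 0.3) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  need <- c("t", "we", "wh", "we_az", "wh_az", "we_el", "wh_el", "conf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("velocity CSV missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(fs)) fs <- 1 / median(diff(df$t))
  velocity_trace(df$t, fs, df$we, df$wh, df$we_az, df$wh_az, df$we_el,
                 df$wh_el, df$conf,
                 confidence_threshold = confidence_threshold)
}
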