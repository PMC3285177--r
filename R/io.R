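# Trial I/O: TRC (standard biomechanics marker format) and long-format CSV.
# TRC has no metadata slots, so trial metadata (subject, condition, outcome,
# launch time) round-trips through a JSON sidecar; CSV carries the same
# metadata in '#'-prefixed header comments.

trial_meta <- function(trial) {
  list(subject = trial$subject, trial_id = trial$trial_id,
       outcome = trial$outcome, launch_time = trial$launch_time,
       rate = trial$rate,
       condition = if (!is.null(trial$condition)) {
         trial$condition[c("T", "Z", "T_label", "Z_label", "height", "label")]
       })
}

apply_meta <- function(trial, meta) {
  trial$subject <- meta$subject %||% NA_character_
  trial$trial_id <- meta$trial_id %||% NA_character_
  trial$outcome <- meta$outcome %||% NA_character_
  trial$launch_time <- meta$launch_time %||% 0
  trial$condition <- meta$condition
  trial
}

#' Write a trial to disk
#'
#' `"trc"` writes a standard TRC marker file (positions in m, the ball as a
#' pseudo-marker named BALL) plus a `<path>.meta.json` sidecar with the trial
#' metadata; `"csv"` writes long format (`time, marker, x, y, z`) with the
#' metadata as `#`-prefixed JSON header lines.
#'
#' @param trial A `catch_trial`.
#' @param path Output file path.
#' @param format `"trc"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, format = c("trc", "csv")) {
  format <- match.arg(format)
  names_all <- c(MARKER_NAMES, "BALL")
  series <- c(trial$markers, list(BALL = trial$ball))
  nfr <- length(trial$times)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.7f", x))
  if (format == "trc") {
    nm <- length(names_all)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
    writeLines("DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames", con)
    writeLines(sprintf("%g\t%g\t%d\t%d\tm\t%g\t1\t%d",
                       trial$rate, trial$rate, nfr, nm, trial$rate, nfr), con)
    writeLines(paste0("Frame#\tTime\t",
                      paste(vapply(names_all, function(n) paste0(n, "\t\t"), ""),
                            collapse = "")), con)
    writeLines(paste0("\t\t", paste(vapply(seq_len(nm), function(j)
      sprintf("X%d\tY%d\tZ%d", j, j, j), ""), collapse = "\t")), con)
    writeLines("", con)
    block <- do.call(cbind, lapply(series, identity))
    lines <- vapply(seq_len(nfr), function(i) {
      paste(c(i, sprintf("%.7f", trial$times[i]), fmt(block[i, ])),
            collapse = "\t")
    }, "")
    writeLines(lines, con)
    jsonlite::write_json(trial_meta(trial), paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# meta ", jsonlite::toJSON(trial_meta(trial),
                                                  auto_unbox = TRUE, digits = NA,
                                                  null = "null")), con)
    writeLines("time,marker,x,y,z", con)
    for (j in seq_along(series)) {
      m <- series[[j]]
      writeLines(sprintf("%.7f,%s,%s,%s,%s", trial$times, names_all[j],
                         fmt(m[, 1]), fmt(m[, 2]), fmt(m[, 3])), con)
    }
  }
  invisible(path)
}

#' Read a trial from disk
#'
#' Validates the sampling rate (100 Hz unless overridden), uniform
#' timestamps, and the presence of all required markers.
#'
#' @param path File path written by [write_trial()].
#' @param format `"trc"` or `"csv"`; guessed from the extension by default.
#' @param expected_rate Required sampling rate (Hz); `NULL` disables the
#'   check.
#' @return A `catch_trial`.
#' @export
read_trial <- function(path, format = NULL, expected_rate = 100) {
  format <- format %||% (if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv")
  if (format == "trc") {
    hdr <- readLines(path, n = 5)
    if (!grepl("^PathFileType", hdr[1])) {
      ck_stop("malformed TRC header: missing PathFileType line", "catchkin_format")
    }
    vals <- strsplit(hdr[3], "\t")[[1]]
    rate <- as.numeric(vals[1]); nfr <- as.integer(vals[3]); nm <- as.integer(vals[4])
    mk_line <- strsplit(hdr[4], "\t")[[1]]
    names_all <- mk_line[mk_line != "" & !mk_line %in% c("Frame#", "Time")]
    if (length(names_all) != nm) ck_stop("malformed TRC header: marker count mismatch", "catchkin_format")
    dat <- read.table(path, skip = 6, sep = "\t", header = FALSE,
                      colClasses = "numeric", fill = TRUE,
                      na.strings = c("", "NA"))
    times <- dat[[2]]
    series <- lapply(seq_len(nm), function(j) {
      as.matrix(dat[, 2 + (j - 1) * 3 + 1:3])
    })
    names(series) <- names_all
    meta_path <- paste0(path, ".meta.json")
    meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  } else {
    first <- readLines(path, n = 1)
    meta <- if (grepl("^# meta ", first)) {
      jsonlite::fromJSON(sub("^# meta ", "", first), simplifyVector = TRUE)
    } else list()
    dat <- read.table(path, sep = ",", header = TRUE, comment.char = "#",
                      na.strings = c("", "NA"))
    times <- sort(unique(dat$time))
    series <- lapply(split(dat, dat$marker), function(d) {
      d <- d[order(d$time), ]
      if (!isTRUE(all.equal(d$time, times))) {
        ck_stop("non-uniform or inconsistent timestamps across markers", "catchkin_format")
      }
      as.matrix(d[, c("x", "y", "z")])
    })
    rate <- 1 / median(diff(times))
  }
  if (length(times) > 1) {
    steps <- diff(times)
    if (max(steps) - min(steps) > 1e-4) {
      ck_stop("non-uniform timestamps", "catchkin_format")
    }
    rate <- 1 / median(steps)
  }
  if (!is.null(expected_rate) && abs(rate - expected_rate) > 0.5) {
    ck_stop(sprintf("sampling rate %.3g Hz does not match the expected %g Hz",
                    rate, expected_rate), "catchkin_rate")
  }
  miss <- setdiff(c(MARKER_NAMES, "BALL"), names(series))
  if (length(miss)) {
    ck_stop(paste("missing required markers:", paste(miss, collapse = ", ")),
            "catchkin_missing_marker")
  }
  rownames_null <- function(m) { dimnames(m) <- NULL; m }
  trial <- structure(list(
    times = times, rate = rate,
    markers = lapply(series[MARKER_NAMES], rownames_null),
    ball = rownames_null(series$BALL),
    launch_time = 0, condition = NULL, outcome = NA_character_,
    subject = NA_character_, trial_id = NA_character_, truth = NULL),
    class = "catch_trial")
  apply_meta(trial, meta)
}

#' Write the cohort manifest and ground-truth ledger
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_cohort_manifest <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  led <- cohort$ledger$trials
  manifest <- led[, c("trial_id", "subject", "label", "T", "Z", "height",
                      "trial", "outcome")]
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  lpath <- file.path(dir, "ledger.json")
  jsonlite::write_json(list(trials = led, submovements = cohort$ledger$submovements),
                       lpath, digits = NA, dataframe = "rows")
  invisible(c(manifest = mpath, ledger = lpath))
}
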