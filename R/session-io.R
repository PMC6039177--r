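# Event-log file dialect. The canonical on-disk forms are:
#  * csv:  events as (time_s, kind, payload_json) plus a JSON metadata
#          sidecar at <path>.meta.json
#  * json: a single JSON document holding metadata and the event array.
# Times are printed with "%.17g" so doubles round-trip exactly and two
# writes of the same session are byte-identical.

fmt_time <- function(x) sprintf("%.17g", x)

csv_meta_path <- function(path) paste0(path, ".meta.json")

session_meta <- function(s) {
  list(subject_id = s$subject_id, phase = s$phase, duration = s$duration,
       restriction_train = s$restriction_train,
       restriction_test = s$restriction_test, treatment = s$treatment)
}

#' Write a session to disk
#'
#' Output is deterministic: fixed field order, full-precision times, so two
#' writes of the same session are byte-identical.
#'
#' @param session A [session()].
#' @param path Output file path. For the `csv` dialect a metadata sidecar is
#'   written next to it at `<path>.meta.json`.
#' @param dialect `"csv"` (event table + JSON sidecar) or `"json"`
#'   (single document).
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path, dialect = c("csv", "json")) {
  stopifnot(inherits(session, "lick_session"))
  dialect <- match.arg(dialect)
  ev <- session$events
  if (dialect == "csv") {
    lines <- c("time_s,kind,payload_json",
               if (nrow(ev)) sprintf("%s,%s,%s", fmt_time(ev$time), ev$kind,
                                     ifelse(is.na(ev$payload), "",
                                            ev$payload)))
    writeLines(lines, path)
    jsonlite::write_json(session_meta(session), csv_meta_path(path),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  } else {
    # times as %.17g decimal strings: doubles round-trip exactly, which
    # plain JSON numbers do not guarantee
    doc <- c(session_meta(session),
             list(events = data.frame(
               time_s = fmt_time(ev$time), kind = ev$kind,
               payload_json = ev$payload, stringsAsFactors = FALSE)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a session from disk
#'
#' Events are returned sorted by time (stably; the on-disk order need not be
#' sorted). Rows whose event code is not in [event_kinds()] are preserved
#' with a warning, never silently dropped; [validate_cohort()] will flag
#' them downstream.
#'
#' @param path File written by [write_session()] (or hand-built in the same
#'   dialect).
#' @param dialect `"csv"` or `"json"`.
#' @return A [session()].
#' @export
read_session <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "csv") {
    lines <- readLines(path)
    if (!length(lines) || lines[1] != "time_s,kind,payload_json") {
      stop("malformed session file (bad or missing header): ", path,
           call. = FALSE)
    }
    body <- lines[-1]
    body <- body[nzchar(body)]
    parts <- strsplit(body, ",", fixed = TRUE)
    n_fields <- lengths(parts)
    if (any(n_fields < 2)) {
      stop("malformed row at line ", which(n_fields < 2)[1] + 1L, " of ",
           path, call. = FALSE)
    }
    time <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    if (anyNA(time)) {
      stop("unparseable time at line ", which(is.na(time))[1] + 1L, " of ",
           path, call. = FALSE)
    }
    kind <- vapply(parts, `[`, "", 2L)
    payload <- vapply(parts, function(p) {
      if (length(p) >= 3) paste(p[-(1:2)], collapse = ",") else ""
    }, "")
    payload[!nzchar(payload)] <- NA_character_
    meta <- jsonlite::read_json(csv_meta_path(path))
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    meta <- doc[setdiff(names(doc), "events")]
    ev <- doc$events
    if (is.null(ev) || !NROW(ev)) {
      time <- numeric(0); kind <- character(0); payload <- character(0)
    } else {
      time <- as.numeric(ev$time_s)
      kind <- as.character(ev$kind)
      payload <- if (is.null(ev$payload_json)) {
        rep(NA_character_, length(time))
      } else as.character(ev$payload_json)
    }
  }
  if (length(time) && any(time < 0)) {
    stop("negative event time in ", path, call. = FALSE)
  }
  unknown <- setdiff(unique(kind), event_kinds())
  if (length(unknown)) {
    warning("unknown event kind(s) preserved: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  null_na <- function(x, cast) if (is.null(x) || is.na(x)) cast(NA) else x
  session(
    subject_id = as.character(meta$subject_id),
    phase = as.character(meta$phase),
    duration = as.numeric(meta$duration),
    restriction_train = as.numeric(null_na(meta$restriction_train, as.numeric)),
    restriction_test = as.numeric(null_na(meta$restriction_test, as.numeric)),
    treatment = as.character(meta$treatment),
    events = events_frame(time, kind, payload, allow_unknown = TRUE))
}

#' Write a cohort to a directory
#'
#' Writes one session file per session (named
#' `<subject>_<index>_<phase>.csv`, index in chronological order) plus a
#' `design.csv` table.
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect Passed to [write_session()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = "csv") {
  stopifnot(inherits(cohort, "lick_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counter <- list()
  for (s in cohort$sessions) {
    k <- (counter[[s$subject_id]] %||% 0L) + 1L
    counter[[s$subject_id]] <- k
    ext <- if (dialect == "csv") "csv" else "json"
    write_session(s, file.path(dir, sprintf("%s_%03d_%s.%s", s$subject_id,
                                            k, s$phase, ext)), dialect)
  }
  utils::write.csv(cohort$design, file.path(dir, "design.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir Directory containing session files and `design.csv`.
#' @param dialect `"csv"` or `"json"`.
#' @return A [cohort()].
#' @export
read_cohort <- function(dir, dialect = "csv") {
  design <- utils::read.csv(file.path(dir, "design.csv"),
                            stringsAsFactors = FALSE)
  design$subject_id <- as.character(design$subject_id)
  ext <- if (dialect == "csv") "\\.csv$" else "\\.json$"
  files <- sort(list.files(dir, pattern = ext, full.names = TRUE))
  files <- files[basename(files) != "design.csv"]
  files <- files[!grepl("\\.meta\\.json$", files)]
  sessions <- lapply(files, read_session, dialect = dialect)
  cohort(sessions, design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
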