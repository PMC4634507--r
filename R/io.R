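# File formats -------------------------------------------------------------
#
# Trajectory CSV: columns frame,point,x,y — one row per landmark per frame,
#   frame 0-based, point 1..49.
# Segment JSON: subject_id, label, fps, segments = [{label, start, end}]
#   with half-open [start, end) frame ranges.
# Feature CSV: subject_id, combo, forehead_index, mouth_index, label.
# CV report JSON / cohort manifest JSON: written with full double precision.

#' Write a recording to a trajectory CSV and a segment JSON
#'
#' @param rec a [recording()].
#' @param dir output directory (created if needed).
#' @param stem file stem; defaults to the subject id. Files are
#'   `<stem>_trajectory.csv` and `<stem>_segments.json`.
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(rec, dir, stem = rec$subject_id) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_frames(rec)
  df <- data.frame(
    frame = rep(0:(n - 1L), each = 49L),
    point = rep(1:49, times = n),
    x = as.vector(rec$points[, 1, ]),
    y = as.vector(rec$points[, 2, ])
  )
  traj <- file.path(dir, paste0(stem, "_trajectory.csv"))
  write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
            traj, row.names = FALSE, quote = FALSE)
  seg <- file.path(dir, paste0(stem, "_segments.json"))
  meta <- list(
    subject_id = rec$subject_id, label = rec$label, fps = rec$fps,
    segments = lapply(names(rec$segments), function(lab)
      list(label = lab, start = rec$segments[[lab]][1],
           end = rec$segments[[lab]][2]))
  )
  jsonlite::write_json(meta, seg, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(trajectory = traj, segments = seg))
}

#' Read a recording from a trajectory CSV and a segment JSON
#'
#' Validates both files against the recording invariants: 49 finite points
#' per frame, contiguous 0-based frame indices, three non-empty pairwise
#' disjoint segments referencing existing frames.
#'
#' @param trajectory_csv,segments_json file paths.
#' @return A [recording()].
#' @export
read_recording <- function(trajectory_csv, segments_json) {
  df <- read.csv(trajectory_csv)
  need <- c("frame", "point", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns frame,point,x,y", call. = FALSE)
  frames <- sort(unique(df$frame))
  n <- length(frames)
  if (!identical(as.integer(frames), 0:(n - 1L)))
    stop("frame indices must be contiguous starting at 0", call. = FALSE)
  if (nrow(df) != 49L * n)
    stop("expected 49 points per frame, got ", nrow(df), " rows for ",
         n, " frames", call. = FALSE)
  if (!all(df$point %in% 1:49))
    stop("point indices must be in 1..49", call. = FALSE)
  ord <- order(df$frame, df$point)
  df <- df[ord, ]
  if (!all(df$point == rep(1:49, times = n)))
    stop("every frame must contain each point index exactly once", call. = FALSE)
  pts <- array(NA_real_, c(49, 2, n))
  pts[, 1, ] <- df$x
  pts[, 2, ] <- df$y

  meta <- jsonlite::read_json(segments_json, simplifyVector = FALSE)
  for (field in c("subject_id", "label", "fps", "segments"))
    if (is.null(meta[[field]]))
      stop("segment file missing field '", field, "'", call. = FALSE)
  segs <- list()
  for (s in meta$segments) {
    if (is.null(s$label) || is.null(s$start) || is.null(s$end))
      stop("each segment needs label, start, end", call. = FALSE)
    segs[[s$label]] <- c(as.integer(s$start), as.integer(s$end))
  }
  recording(meta$subject_id, pts, segs, meta$label, fps = meta$fps)
}

#' Write a synthetic cohort to disk
#'
#' One trajectory CSV + segment JSON per subject plus a `manifest.json`
#' recording the generating spec and per-subject severities.
#'
#' @param cohort list of recordings from [generate_cohort()].
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) write_recording(rec, dir)
  manifest <- attr(cohort, "manifest")
  spec <- attr(cohort, "spec")
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(spec = unclass(spec), subjects = manifest),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return List of [recording()]s with the manifest as attribute.
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- man$subjects$subject_id
  recs <- lapply(ids, function(id)
    read_recording(file.path(dir, paste0(id, "_trajectory.csv")),
                   file.path(dir, paste0(id, "_segments.json"))))
  names(recs) <- ids
  attr(recs, "manifest") <- man$subjects
  recs
}

#' Write / read an asymmetry feature table
#'
#' @param table data.frame from [extract_feature_table()].
#' @param path CSV path.
#' @return `write_feature_table`: the path, invisibly;
#'   `read_feature_table`: the data.frame.
#' @export
write_feature_table <- function(table, path) {
  need <- c("subject_id", "combo", "forehead_index", "mouth_index", "label")
  stopifnot(all(need %in% names(table)))
  write.csv(format(table[, need], digits = 17, scientific = FALSE,
                   trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "combo", "forehead_index", "mouth_index", "label")
  if (!all(need %in% names(df)))
    stop("feature table must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  df
}

#' Write / read a cross-validation report (JSON)
#'
#' @param report a `cv_report` from [loocv()], or a list of them.
#' @param path JSON path.
#' @return `write_cv_report`: the path, invisibly; `read_cv_report`: a list.
#' @export
write_cv_report <- function(report, path) {
  if (inherits(report, "cv_report")) report <- list(report = report)
  if (is.null(names(report)))
    names(report) <- sprintf("report%02d", seq_along(report))
  blocks <- lapply(report, function(r) {
    r <- unclass(r)
    r$confusion <- as.list(r$confusion)   # keep tp/fp/fn/tn names in JSON
    r
  })
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cv_report
#' @export
read_cv_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Recognized keys: `combo`, `method`, `svm_c`, `priors`, `zero_rule`,
#' `freeze_axes`, `out_dir`, `verbose`. Unknown keys are an error (with the
#' offending key named); values are validated against their domain.
#'
#' @param path config file path.
#' @param overrides named list that takes precedence over file values
#'   (e.g. parsed CLI flags).
#' @return Named list of validated settings (defaults filled in).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(combo = "forehead_region+mouth_axis", method = "lda",
                   svm_c = 1, priors = "frequency", zero_rule = "one",
                   freeze_axes = FALSE, out_dir = ".", verbose = FALSE)
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("config line not of the form key = value: '", ln, "'",
             call. = FALSE)
      vals[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- defaults
  cfg[names(vals)] <- vals
  cfg$combo <- canonical_combo(cfg$combo)
  cfg$method <- match.arg(cfg$method, c("lda", "svm_linear"))
  cfg$svm_c <- as.numeric(cfg$svm_c)
  if (!is.finite(cfg$svm_c) || cfg$svm_c <= 0)
    stop("config: svm_c must be a positive number", call. = FALSE)
  cfg$priors <- match.arg(cfg$priors, c("frequency", "equal"))
  cfg$zero_rule <- match.arg(cfg$zero_rule, c("one", "nan"))
  cfg$freeze_axes <- as.logical(cfg$freeze_axes)
  cfg$verbose <- as.logical(cfg$verbose)
  if (is.na(cfg$freeze_axes) || is.na(cfg$verbose))
    stop("config: freeze_axes and verbose must be TRUE/FALSE", call. = FALSE)
  cfg
}
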