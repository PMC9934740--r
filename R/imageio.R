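#' 4D dynamic image series
#'
#' @param data 4D numeric array, dimensions (x, y, z, t), signal in a.u.
#' @param time Strictly increasing frame times in minutes, length = 4th dim.
#' @param n_baseline_frames Number of pre-infusion frames (>= 1).
#' @param polarity `+1` or `-1` (sign of tracer-induced signal change).
#' @param voxel_size Length-3 voxel size in mm.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, time, n_baseline_frames = 1L, polarity = 1L,
                           voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, t); got ",
         length(dim(data)), " dimensions")
  if (dim(data)[4] != length(time))
    stop("time axis length (", length(time),
         ") does not match frame count (", dim(data)[4], ")")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("time axis must be strictly increasing")
  if (n_baseline_frames < 1L) stop("n_baseline_frames must be >= 1")
  if (!polarity %in% c(-1L, 1L)) stop("polarity must be +1 or -1")
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(data = data, time = as.numeric(time),
                 n_baseline_frames = as.integer(n_baseline_frames),
                 polarity = as.integer(polarity),
                 voxel_size = as.numeric(voxel_size)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic series: %dx%dx%d voxels x %d frames (%.3g-%.3g min)\n",
              d[1], d[2], d[3], d[4], min(x$time), max(x$time)))
  cat(sprintf("  voxel %s mm, %d baseline frame(s), polarity %+d\n",
              paste(signif(x$voxel_size, 4), collapse = "x"),
              x$n_baseline_frames, x$polarity))
  invisible(x)
}

#' 3D integer ROI label map
#'
#' @param labels 3D integer array; 0 is reserved for background.
#' @param names Named character vector mapping label (as name) to ROI name;
#'   every nonzero label in the array must be present.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, names = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels < 0)) stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  if (is.null(names))
    names <- stats::setNames(sprintf("roi_%02d", present), present)
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing))
    stop("labels without a name: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = names), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  labs <- sort(unique(as.integer(x$labels)))
  cat(sprintf("Label map: %dx%dx%d voxels, %d ROI(s)\n",
              d[1], d[2], d[3], sum(labs != 0)))
  invisible(x)
}

#' Write / read a dynamic series as NIfTI plus JSON sidecar
#'
#' The volume is stored as a 4D NIfTI-1 file in double precision (lossless
#' round trip); the time axis (minutes), baseline frame count, polarity and
#' voxel size go to a JSON sidecar next to it.
#'
#' @param series A [dynamic_series()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param sidecar_path JSON sidecar path; defaults to `path` with the NIfTI
#'   extension replaced by `.json`.
#' @return `path`, invisibly (writer); a [dynamic_series()] (reader).
#' @export
write_dynamic_series <- function(series, path,
                                 sidecar_path = sidecar_for(path)) {
  stopifnot(inherits(series, "dynamic_series"))
  img <- RNifti::asNifti(series$data,
                         pixdim = c(series$voxel_size,
                                    diff(series$time[1:2])))
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(time_min = series$time,
         n_baseline_frames = series$n_baseline_frames,
         polarity = series$polarity,
         voxel_size_mm = series$voxel_size),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_for <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname write_dynamic_series
#' @export
read_dynamic_series <- function(path, sidecar_path = sidecar_for(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar_path)) stop("missing sidecar: ", sidecar_path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI volume, got ", length(dim(arr)), "D: ", path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("time_min", "n_baseline_frames", "polarity", "voxel_size_mm"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "': ",
                                 sidecar_path)
  if (any(diff(meta$time_min) <= 0))
    stop("sidecar field 'time_min' is not strictly increasing")
  dynamic_series(arr, time = meta$time_min,
                 n_baseline_frames = meta$n_baseline_frames,
                 polarity = meta$polarity, voxel_size = meta$voxel_size_mm)
}

#' Write / read a label map as NIfTI plus JSON name table
#'
#' @param labels A [label_map()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param names_path JSON path for the label-to-name map.
#' @return `path`, invisibly (writer); a [label_map()] (reader).
#' @export
write_label_map <- function(labels, path, names_path = sidecar_for(path)) {
  stopifnot(inherits(labels, "label_map"))
  RNifti::writeNifti(RNifti::asNifti(labels$labels), path,
                     datatype = "int32")
  jsonlite::write_json(as.list(labels$names), names_path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path, names_path = sidecar_for(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(img), dim = dim(img))
  nm <- NULL
  if (file.exists(names_path)) {
    lst <- jsonlite::read_json(names_path, simplifyVector = TRUE)
    nm <- stats::setNames(as.character(unlist(lst)), names(lst))
  }
  label_map(arr, names = nm)
}

#' Write / read ROI curves as TSV
#'
#' Long format with columns `roi_id`, `roi_name`, `time_min`, `signal`;
#' collection-level metadata is kept in `#`-prefixed header lines so the
#' round trip is lossless.
#'
#' @param curves A [roi_curves()].
#' @param path Output TSV path.
#' @return `path` invisibly (writer); a [roi_curves()] (reader). Reading an
#'   empty table returns an empty collection with a warning.
#' @export
write_curves_tsv <- function(curves, path) {
  stopifnot(inherits(curves, "roi_curves"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_baseline_frames\t%d", curves$n_baseline_frames),
    sprintf("# polarity\t%d", curves$polarity),
    sprintf("# baseline_subtracted\t%d", as.integer(curves$baseline_subtracted)),
    sprintf("# normalized\t%d", as.integer(curves$normalized)),
    sprintf("# reference_roi\t%d", curves$reference_roi),
    sprintf("# reference_max\t%s",
            formatC(curves$reference_max, digits = 17, format = "g"))), con)
  df <- data.frame(
    roi_id = rep(curves$roi_id, each = length(curves$time)),
    roi_name = rep(curves$roi_name, each = length(curves$time)),
    time_min = sprintf("%.17g", rep(curves$time, ncol(curves$signal))),
    signal = sprintf("%.17g", as.vector(curves$signal)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_tsv
#' @export
read_curves_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- list()
  for (ln in readLines(path)) {
    if (!startsWith(ln, "# ")) break
    kv <- strsplit(sub("^# ", "", ln), "\t")[[1]]
    hdr[[kv[1]]] <- suppressWarnings(as.numeric(kv[2]))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty curve table: ", path)
    return(roi_curves(numeric(0), matrix(numeric(0), 0, 0),
                      roi_id = integer(0), roi_name = character(0),
                      n_baseline_frames = 0L))
  }
  ids <- unique(df$roi_id)
  first <- df[df$roi_id == ids[1], ]
  time <- first$time_min
  sig <- matrix(NA_real_, length(time), length(ids))
  nms <- character(length(ids))
  for (k in seq_along(ids)) {
    sub <- df[df$roi_id == ids[k], ]
    if (nrow(sub) != length(time))
      stop("roi_id ", ids[k], " has a different number of time points")
    if (anyDuplicated(sub$time_min))
      stop("duplicate roi_id/time rows for roi_id ", ids[k])
    sig[, k] <- sub$signal
    nms[k] <- sub$roi_name[1]
  }
  roi_curves(time, sig, roi_id = ids, roi_name = nms,
             n_baseline_frames = as.integer(hdr$n_baseline_frames %||% 1L),
             polarity = as.integer(hdr$polarity %||% 1L),
             baseline_subtracted = (hdr$baseline_subtracted %||% 0) == 1,
             normalized = (hdr$normalized %||% 0) == 1,
             reference_roi = as.integer(hdr$reference_roi %||% NA),
             reference_max = hdr$reference_max %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tMIP map as NIfTI
#'
#' @param tmip 3D array as returned by [compute_tmip()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tmip <- function(tmip, path) {
  RNifti::writeNifti(RNifti::asNifti(unclass(tmip)), path,
                     datatype = "double")
  invisible(path)
}
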