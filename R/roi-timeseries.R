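#' ROI time-series container
#'
#' Wraps a frames-by-ROIs numeric matrix with its acquisition metadata. This
#' is the unit of data every preprocessing and clustering step consumes: `T`
#' frames (rows) sampled every `tr` seconds across `R` regions of interest
#' (columns).
#'
#' @param data Numeric matrix, frames in rows, ROIs in columns. `T >= 2`,
#'   no missing values.
#' @param subject_id Subject identifier.
#' @param tr Repetition time in seconds.
#' @param band A [band_definition()] or `"broadband"` for unfiltered data.
#' @param roi_names Optional character vector of ROI labels; defaults to the
#'   matrix column names or `roi_001` style labels.
#' @return A `roi_ts` object.
#' @export
roi_timeseries <- function(data, subject_id = "subject", tr = 2.0,
                           band = "broadband", roi_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric", call. = FALSE)
  if (nrow(data) < 2) stop("need at least 2 frames", call. = FALSE)
  if (ncol(data) < 1) stop("need at least 1 ROI", call. = FALSE)
  if (anyNA(data)) {
    idx <- which(is.na(data), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at frame %d, ROI %d", idx[1], idx[2]),
         call. = FALSE)
  }
  if (is.null(roi_names)) {
    roi_names <- colnames(data)
    if (is.null(roi_names)) {
      roi_names <- sprintf("roi_%03d", seq_len(ncol(data)))
    }
  }
  colnames(data) <- roi_names
  structure(
    list(data = data, subject_id = subject_id, tr = tr, band = band,
         roi_names = roi_names),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  band <- if (inherits(x$band, "band_definition")) x$band$name else x$band
  cat(sprintf("<roi_ts %s: %d frames x %d ROIs, TR = %g s, band = %s>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr, band))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Read an ROI-by-time matrix from TSV/CSV
#'
#' Expects frames as rows and ROIs as columns, with a single header row of
#' ROI names. Tab- and comma-separated files are detected from the extension
#' (`.csv` means comma; anything else is read as tab-separated). All cells
#' must be numeric; missing or blank cells are a hard error naming the
#' offending row and column, since a silent NA would corrupt every downstream
#' state assignment.
#'
#' @param path File path.
#' @param tr Repetition time in seconds.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A [roi_timeseries()] object tagged `"broadband"`.
#' @export
load_roi_timeseries <- function(path, tr = 2.0, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"")
  if (nrow(df) < 2) stop("need at least 2 frames, got ", nrow(df),
                         call. = FALSE)
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | !nzchar(trimws(df[[j]])))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value at row %d, column '%s'",
                   bad[1], colnames(df)[j]), call. = FALSE)
    }
    mat[, j] <- v
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  }
  roi_timeseries(mat, subject_id = subject_id, tr = tr)
}

#' Write an ROI time series as TSV
#'
#' Inverse of [load_roi_timeseries()]: one header row of ROI names, frames as
#' rows, tab-separated, full double precision so a round trip is
#' bit-identical.
#'
#' @param ts A `roi_ts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  df <- as.data.frame(ts$data)
  names(df) <- ts$roi_names
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract ROI time series from a 4D image and a label atlas
#'
#' Averages the 4D BOLD image over the voxels of each nonzero atlas label at
#' every frame, producing one column per label (labels sorted ascending;
#' label 0 is background). The atlas must share the image's spatial grid.
#'
#' @param image_4d Path to a 4D NIfTI image (or an array already in memory).
#' @param atlas Path to an integer-labelled 3D NIfTI atlas (or an array).
#' @param tr Repetition time in seconds; if `NULL`, taken from the image
#'   header (`pixdim[4]`).
#' @param subject_id Subject identifier.
#' @return A [roi_timeseries()] with one column per atlas label, named
#'   `roi_<label>`.
#' @export
extract_roi_timeseries <- function(image_4d, atlas, tr = NULL,
                                   subject_id = "subject") {
  if (is.character(image_4d)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI files requires the RNifti package", call. = FALSE)
    }
    img <- RNifti::readNifti(image_4d)
    if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
    image_4d <- as.array(img)
  }
  if (is.character(atlas)) {
    atlas <- as.array(RNifti::readNifti(atlas))
  }
  if (length(dim(image_4d)) != 4) stop("image must be 4D", call. = FALSE)
  if (!identical(dim(image_4d)[1:3], dim(atlas)[1:3])) {
    stop("atlas grid does not match image grid", call. = FALSE)
  }
  if (is.null(tr)) tr <- 2.0
  labels <- sort(unique(as.vector(atlas)))
  labels <- labels[labels != 0]
  if (!length(labels)) stop("atlas has no nonzero labels", call. = FALSE)
  n_t <- dim(image_4d)[4]
  vox <- matrix(image_4d, ncol = n_t)  # voxels x frames
  atlas_vec <- as.vector(atlas)
  out <- matrix(NA_real_, n_t, length(labels),
                dimnames = list(NULL, sprintf("roi_%d", labels)))
  for (i in seq_along(labels)) {
    sel <- atlas_vec == labels[i]
    if (!any(sel)) stop("atlas label ", labels[i], " covers no voxels",
                        call. = FALSE)
    out[, i] <- colMeans(vox[sel, , drop = FALSE])
  }
  roi_timeseries(out, subject_id = subject_id, tr = tr)
}
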