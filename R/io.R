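#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti keeping data and orientation metadata
#' together.  Volumes are written in double precision so that data
#' round-trips losslessly; pass `datatype = "float"` for single-precision
#' storage.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: list with `data` (plain numeric array) and `image`
#'   (the `niftiImage` carrying the affine/orientation record).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, image = img)
}

#' @rdname read_volume
#' @param data numeric array, or a `niftiImage`.
#' @param reference optional `niftiImage` (or list from [read_volume()])
#'   supplying orientation metadata.
#' @param datatype storage type, `"double"` (default, lossless) or
#'   `"float"`.
#' @export
write_volume <- function(data, path, reference = NULL,
                         datatype = c("double", "float")) {
  datatype <- match.arg(datatype)
  if (is.list(reference) && !is.null(reference$image)) {
    reference <- reference$image
  }
  img <- RNifti::asNifti(data, reference = reference)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a covariate table
#'
#' CSV reader with a declared missing-value convention: empty strings and
#' `"NA"` both parse as missing.  Columns in which some non-missing entries
#' are numeric and others are not are rejected (with the first offending row
#' named) rather than silently coerced.
#'
#' @param path CSV path.
#' @param required character vector of columns that must be present.
#' @return data.frame with typed columns and NA for missing entries.
#' @export
read_covariates <- function(path, required = character()) {
  if (!file.exists(path)) stop("no such covariate file: ", path)
  tab <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("covariate table is missing required columns: ",
         paste(miss, collapse = ", "))
  }
  for (nm in names(tab)) {
    col <- tab[[nm]]
    if (is.character(col)) {
      obs <- !is.na(col)
      num <- suppressWarnings(as.numeric(col))
      is_num <- !is.na(num)
      if (any(is_num & obs) && any(!is_num & obs)) {
        bad <- which(obs & !is_num)[1L]
        stop("mixed-type column '", nm, "' (first non-numeric entry at row ",
             bad, ")")
      }
      if (all(is_num[obs])) tab[[nm]] <- num
    }
  }
  tab
}

#' Write an evaluation report
#'
#' Data frames are written as CSV; lists as pretty-printed JSON with scalars
#' unboxed.
#' @param report data.frame or list.
#' @param path output path; format chosen by `.csv` / `.json` extension.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (!is.data.frame(report)) report <- as.data.frame(report)
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
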