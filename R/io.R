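#' Write a grayordinate-by-time matrix with a sidecar
#'
#' Canonical plain-text container: a TSV of full-precision (`%.17g`) values,
#' one row per grayordinate, plus a JSON sidecar (`<path>.json`) recording
#' the TR, dimensions, and any extra provenance fields. Full precision makes
#' the write/read round trip bitwise exact.
#'
#' @param mat Grayordinate-by-time numeric matrix.
#' @param path Output TSV path.
#' @param tr_seconds Repetition time stored in the sidecar.
#' @param ... Extra scalar fields for the sidecar (seed, config hash, ...).
#' @return `path`, invisibly.
#' @export
write_bold <- function(mat, path, tr_seconds, ...) {
  mat <- as.matrix(mat)
  txt <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, path)
  meta <- c(list(tr_seconds = tr_seconds, n_grayordinates = nrow(mat),
                 n_timepoints = ncol(mat)), list(...))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a grayordinate-by-time matrix, discarding initial volumes
#'
#' Reads the plain-matrix container written by [write_bold()] and removes
#' the leading volumes (default 10) that are discarded from every run. The
#' TR comes from the sidecar when present, else from `tr_seconds`.
#'
#' @param path TSV path.
#' @param discard_initial Leading volumes to drop (default 10).
#' @param tr_seconds TR override when no sidecar exists.
#' @return Grayordinate-by-time matrix with attributes `tr_seconds` and
#'   `meta`.
#' @export
read_bold <- function(path, discard_initial = 10, tr_seconds = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(nii|dtseries\\.nii)$", path)) {
    stop("unsupported format for '", path,
         "'; supported: plain TSV matrix container (see write_bold)")
  }
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  tr <- if (!is.null(meta$tr_seconds)) meta$tr_seconds else tr_seconds
  if (is.null(tr)) stop("TR not found in sidecar; pass tr_seconds")
  if (discard_initial >= ncol(mat)) stop("discard_initial leaves no volumes")
  if (discard_initial > 0) mat <- mat[, -seq_len(discard_initial),
                                      drop = FALSE]
  attr(mat, "tr_seconds") <- tr
  attr(mat, "meta") <- meta
  mat
}

#' Read a grayordinate-to-parcel atlas
#'
#' Reads a TSV with columns `grayordinate` and `parcel` (and optionally
#' `hemisphere`). Hemisphere defaults to the `L_`/`R_` label prefix, else
#' `"subcortical"`. Each parcel is tagged with a perceptual ROI group
#' (`visual`, `auditory`, `audiovisual`) from the bundled ROI list; labels
#' absent from the list are retained and tagged `"other"`. Duplicate
#' grayordinate rows are rejected.
#'
#' @param path Atlas TSV path.
#' @param roi_groups Optional data frame with columns `label`, `roi_group`
#'   overriding the bundled list.
#' @return Object of class `parcel_atlas`: list with `table` (grayordinate,
#'   parcel, hemisphere, roi_group) and `parcels`.
#' @export
read_atlas <- function(path, roi_groups = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("grayordinate", "parcel") %in% names(tab))) {
    stop("atlas TSV needs columns 'grayordinate' and 'parcel'")
  }
  if (anyDuplicated(tab$grayordinate)) {
    stop("duplicate grayordinate labels in atlas")
  }
  if (!"hemisphere" %in% names(tab)) {
    tab$hemisphere <- ifelse(grepl("^L_", tab$parcel), "L",
                             ifelse(grepl("^R_", tab$parcel), "R",
                                    "subcortical"))
  }
  if (is.null(roi_groups)) {
    roi_groups <- utils::read.table(
      system.file("extdata", "roi_groups.tsv", package = "stackenc"),
      sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  }
  base <- sub("^[LR]_", "", tab$parcel)
  tab$roi_group <- roi_groups$roi_group[match(base, roi_groups$label)]
  tab$roi_group[is.na(tab$roi_group)] <- "other"
  structure(list(table = tab, parcels = unique(tab$parcel)),
            class = "parcel_atlas")
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat(sprintf("<parcel_atlas> %d grayordinates, %d parcels\n",
              nrow(x$table), length(x$parcels)))
  invisible(x)
}

#' Write / read a feature matrix as TSV with a metadata sidecar
#'
#' @param fm A [feature_matrix()].
#' @param path Output TSV path (header row = column names); a JSON sidecar
#'   `<path>.json` stores the space tag, TR, and provenance flags.
#' @return `path` invisibly (`write_features`); a [feature_matrix()]
#'   (`read_features`).
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.table(fm$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(
    list(space_tag = fm$space_tag, tr_seconds = fm$tr_seconds,
         convolved = fm$convolved, standardized = fm$standardized),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  feature_matrix(vals, meta$space_tag, meta$tr_seconds,
                 convolved = isTRUE(meta$convolved),
                 standardized = isTRUE(meta$standardized))
}

#' Read a confounds table and extract framewise displacement
#'
#' Accepts an fMRIPrep-style TSV with a `framewise_displacement` column
#' (a leading `n/a` is treated as 0, the conventional first-volume value) or
#' a six-column rigid-body motion TSV, from which FD is computed with
#' [framewise_displacement()].
#'
#' @param path Confounds TSV path.
#' @param rotation_radius_mm Radius used when FD must be computed.
#' @return Nonnegative per-volume FD series.
#' @export
read_confounds_fd <- function(path, rotation_radius_mm = 50) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "n/a")
  if ("framewise_displacement" %in% names(tab)) {
    fd <- as.numeric(tab$framewise_displacement)
    fd[is.na(fd)] <- 0
    return(fd)
  }
  mot_cols <- intersect(c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z"), names(tab))
  if (length(mot_cols) == 6) {
    return(framewise_displacement(as.matrix(tab[, mot_cols]),
                                  rotation_radius_mm))
  }
  stop("confounds TSV needs a 'framewise_displacement' column or the six ",
       "rigid-body columns trans_x..rot_z")
}

#' Read / write a phenotype table
#' @param path TSV path.
#' @return Data frame (`read_phenotype`); `path` invisibly
#'   (`write_phenotype`).
#' @export
read_phenotype <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_phenotype
#' @param phenotypes Data frame to write.
#' @export
write_phenotype <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
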