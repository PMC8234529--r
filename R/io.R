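## File I/O: multi-page TIFF image sequences with JSON ground-truth
## sidecars, and the tabular Ct schema (CSV with columns group, sample,
## gene, ct).

#' Write an image sequence as a multi-page TIFF
#'
#' One page per frame, 8-bit grayscale by default. An optional metadata list
#' is written beside the image as a JSON sidecar (same path with extension
#' \code{.json}); ground truths survive a write/read round trip.
#'
#' @param frames list of numeric matrices in [0, 1]
#' @param path output file (.tif/.tiff)
#' @param meta optional list serialized as a JSON sidecar
#' @param bits 8 (CCD-camera-like export) or 32 for loss-free float
#' @return invisibly, the path
#' @export
write_image_sequence <- function(frames, path, meta = NULL, bits = 8L) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(all(vapply(frames, is.matrix, logical(1))))
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = as.integer(bits))
  if (!is.null(meta)) {
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an image sequence (multi-page TIFF or PNG)
#'
#' @param path image file; \code{.png} is read as a single frame
#' @return list with \code{frames} (list of matrices in [0, 1]) and
#'   \code{meta} (sidecar contents, or NULL)
#' @export
read_image_sequence <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package")
    frames <- list(as_frame(png::readPNG(path)))
  } else {
    raw <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(raw)) raw <- list(raw)
    frames <- lapply(raw, as_frame)
  }
  meta <- NULL
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  list(frames = frames, meta = meta)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write / read a Ct table CSV
#'
#' Schema: columns \code{group}, \code{sample} (biological replicate id),
#' \code{gene}, \code{ct} (threshold cycle). Technical replicates appear as
#' repeated rows.
#' @param ct_table data.frame in the Ct schema
#' @param path CSV path
#' @return the path (write) or the validated data.frame (read)
#' @export
write_ct_table <- function(ct_table, path) {
  validate_ct_table(ct_table)
  write.csv(ct_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(df)
}

validate_ct_table <- function(df) {
  need <- c("group", "sample", "gene", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$ct) || any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be finite and positive")
  df
}
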