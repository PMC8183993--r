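# 16-bit TIFF I/O for field images and label maps, and the screen's CSV
# surface. tiff stores [0,1]; intensities are scaled by 65535 on the way
# through so pixel values round-trip exactly at integer grey levels.

field_tiff_name <- function(plate, well, field, channel) {
  sprintf("%s_%s_f%d_%s.tif", plate, well, field, channel)
}

#' Write one field as two 16-bit TIFFs
#'
#' File names follow `{plate}_{well}_f{field}_{channel}.tif` with channels
#' `nuclei` and `opp`.
#'
#' @param field `field_image`.
#' @param dir output directory (created if missing).
#' @param plate,well,field_idx identifiers used in the file names.
#' @return invisibly, the two file paths.
#' @export
write_field_tiff <- function(field, dir, plate, well, field_idx) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c(field_tiff_name(plate, well, field_idx, "nuclei"),
                            field_tiff_name(plate, well, field_idx, "opp")))
  tiff::writeTIFF(round(field$nuclei) / 65535, paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(round(field$opp) / 65535, paths[2], bits.per.sample = 16L)
  invisible(paths)
}

#' Read one field from its two 16-bit TIFFs
#'
#' @inheritParams write_field_tiff
#' @param dir directory holding the files written by [write_field_tiff()].
#' @return `field_image`.
#' @export
read_field_tiff <- function(dir, plate, well, field_idx) {
  rd <- function(channel) {
    p <- file.path(dir, field_tiff_name(plate, well, field_idx, channel))
    round(tiff::readTIFF(p) * 65535)
  }
  field_image(rd("nuclei"), rd("opp"))
}

#' Write a label map as a 16-bit TIFF
#'
#' @param labels `label_map` (or integer matrix); labels above 65535 are
#'   rejected.
#' @param path output file.
#' @export
write_label_tiff <- function(labels, path) {
  m <- as_int_matrix(labels)
  if (max(m) > 65535L) stop("label map exceeds 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a protein quantification table
#'
#' CSV with `protein_id` and `treated_*` / `control_*` replicate columns of
#' log2 intensities.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_protein_quant <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(x)) stop("missing protein_id column")
  x
}

# compound_scores carries list columns; collapse them for the CSV surface.
flatten_scores <- function(scores) {
  out <- scores[, !vapply(scores, is.list, logical(1)), drop = FALSE]
  out$plate_ids <- vapply(scores$plate_ids, paste, "", collapse = ";")
  out$opp_values <- vapply(scores$opp_values,
                           function(v) paste(format(v, digits = 10), collapse = ";"), "")
  out$viability_values <- vapply(scores$viability_values,
                                 function(v) paste(format(v, digits = 10), collapse = ";"), "")
  as.data.frame(out)
}

write_table <- function(x, dir, name) {
  write.csv(x, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}
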