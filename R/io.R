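# Text-based interchange formats: ASCII PGM (P2) as the lossless array
# format, label/score CSVs mirroring the per-lesion score tables, JSON
# provenance sidecars, and run manifests with content hashes.

#' Write a grayscale image as ASCII PGM (P2)
#'
#' @param pixels integer-valued matrix (or a [raw_image()])
#' @param path output path
#' @param maxval maximum gray value header field (defaults to the
#'   image's bit-depth ceiling)
#' @return `path`, invisibly
#' @export
write_pgm <- function(pixels, path, maxval = NULL) {
  img <- NULL
  if (inherits(pixels, "raw_image")) { img <- pixels; pixels <- img$pixels }
  if (is.null(maxval))
    maxval <- if (!is.null(img)) 2^img$bit_depth - 1
              else max(2^ceiling(log2(max(pixels, 1) + 1)) - 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)),
               as.character(maxval)), con)
  write(t(pixels), con, ncolumns = ncol(pixels))
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path PGM file
#' @param photometric photometric tag to attach (PGM itself carries none)
#' @return a [raw_image()]
#' @export
read_pgm <- function(path, photometric = "monochrome2") {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (txt[1] != "P2") stop("only ASCII PGM (P2) is supported")
  w <- as.integer(txt[2]); h <- as.integer(txt[3])
  maxval <- as.numeric(txt[4])
  vals <- as.numeric(txt[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch")
  raw_image(matrix(vals, h, w, byrow = TRUE), photometric,
            bit_depth = max(1L, ceiling(log2(maxval + 1))))
}

#' Write per-lesion scores as CSV
#'
#' Columns mirror the label table format of phantom score submissions:
#' case id, grid cell, lesion type, rank, score ("NA" for the ambiguous
#' label).
#'
#' @param case_ids vector of case identifiers (recycled per 16 lesions)
#' @param scores list (or matrix) of 16-vectors of scores
#' @param path output CSV path
#' @param layout layout map
#' @return the data frame written, invisibly
#' @export
write_labels_csv <- function(case_ids, scores, path,
                             layout = phantom_layout()) {
  if (is.matrix(scores)) scores <- asplit(scores, 1)
  stopifnot(length(case_ids) == length(scores))
  df <- do.call(rbind, lapply(seq_along(case_ids), function(i)
    data.frame(case_id = case_ids[i], cell = 1:16,
               lesion_type = layout$cells$lesion_type,
               rank = layout$cells$rank,
               score = scores[[i]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a per-lesion score CSV
#' @param path CSV written by [write_labels_csv()]
#' @return data frame with one row per case x lesion
#' @export
read_labels_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the JSON provenance sidecar of a standardized image
#' @param std a `standardized_image`
#' @param path output path (conventionally `<image>.json`)
#' @return `path`, invisibly
#' @export
write_provenance <- function(std, path) {
  jsonlite::write_json(std$provenance, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Append rows to a run manifest
#'
#' Each output file is recorded with its md5 hash and the md5 of the
#' generating configuration, so reruns can be compared byte-for-byte.
#' @param files character vector of file paths
#' @param config list describing the run configuration
#' @param path manifest CSV path (created or appended)
#' @return the manifest data frame, invisibly
#' @export
manifest_add <- function(files, config, path) {
  cfg_hash <- config_hash(config)
  rows <- data.frame(file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     config_hash = cfg_hash)
  exists <- file.exists(path)
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !exists, append = exists, qmethod = "double")
  invisible(rows)
}

#' @keywords internal
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
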