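#' Band-intensity matrix with kingdom labels
#'
#' The central data container: a samples x bands matrix of nonnegative DGGE
#' band intensities, each band labelled bacteria or fungi. Bands act as
#' operational taxonomic proxies; a zero intensity means the band is absent
#' from that sample's gel lane.
#'
#' @param intensities Numeric matrix (samples in rows, bands in columns) with
#'   unique row and column names; all values must be finite and >= 0.
#' @param kingdom Named character vector mapping every band id to
#'   `"bacteria"` or `"fungi"`.
#'
#' @return An object of class `"band_matrix"`: a list with elements
#'   `intensities` and `kingdom` (reordered to match the column order).
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("b1", "f1")))
#' band_matrix(m, c(b1 = "bacteria", f1 = "fungi"))
band_matrix <- function(intensities, kingdom) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensity matrix must carry sample (row) and band (column) names")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate sample ids in band matrix")
  if (anyDuplicated(colnames(intensities)))
    stop("duplicate band ids in band matrix")
  if (any(!is.finite(intensities)))
    stop("band intensities must be finite")
  if (any(intensities < 0))
    stop("band intensities must be nonnegative")
  kingdom <- unlist(kingdom)
  if (is.null(names(kingdom)) || anyDuplicated(names(kingdom)))
    stop("kingdom must be a uniquely named vector over band ids")
  missing <- setdiff(colnames(intensities), names(kingdom))
  if (length(missing))
    stop("no kingdom label for band(s): ", paste(missing, collapse = ", "))
  kingdom <- as.character(kingdom[colnames(intensities)])
  names(kingdom) <- colnames(intensities)
  if (!all(kingdom %in% c("bacteria", "fungi")))
    stop("kingdom labels must be 'bacteria' or 'fungi'")
  structure(list(intensities = intensities, kingdom = kingdom),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("<band_matrix> %d samples x %d bands (%d bacteria, %d fungi)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$kingdom == "bacteria"), sum(x$kingdom == "fungi")))
  invisible(x)
}

#' @rdname band_matrix
#' @param x A `band_matrix`.
#' @export
sample_ids <- function(x) rownames(x$intensities)

#' @rdname band_matrix
#' @export
band_ids <- function(x) colnames(x$intensities)

#' Read a band matrix from TSV files
#'
#' The intensity file is a TSV with a header row of band ids and sample ids in
#' the first column; the kingdom file is a two-column TSV (`band_id`,
#' `kingdom`). This matches how gel-lane tables are transcribed from image
#' analysis software.
#'
#' @param path Path to the samples x bands intensity TSV.
#' @param kingdom_path Path to the band_id/kingdom TSV.
#' @return A validated [band_matrix()].
#' @seealso [write_band_matrix()]
#' @export
read_band_matrix <- function(path, kingdom_path) {
  if (!file.exists(path)) stop("band matrix file not found: ", path)
  if (!file.exists(kingdom_path))
    stop("kingdom label file not found: ", kingdom_path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("band matrix must have at least one band column")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("band intensities failed to parse as numbers")
  rownames(m) <- ids
  ktab <- read.delim(kingdom_path, stringsAsFactors = FALSE)
  if (ncol(ktab) < 2) stop("kingdom file must have two columns")
  kingdom <- setNames(as.character(ktab[[2]]), as.character(ktab[[1]]))
  band_matrix(m, kingdom)
}

#' Write a band matrix to TSV files
#'
#' Inverse of [read_band_matrix()]; the write is deterministic so identical
#' inputs give byte-identical files.
#'
#' @param x A `band_matrix`.
#' @inheritParams read_band_matrix
#' @return Invisibly, the two paths written.
#' @export
write_band_matrix <- function(x, path, kingdom_path) {
  stopifnot(inherits(x, "band_matrix"))
  df <- data.frame(sample_id = sample_ids(x), x$intensities,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  kdf <- data.frame(band_id = band_ids(x), kingdom = unname(x$kingdom))
  write.table(kdf, kingdom_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, kingdom_path))
}
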