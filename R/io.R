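#' @importFrom Biostrings readDNAStringSet writeXStringSet
NULL

SCAN_COLUMNS <- c("row", "col", "section", "chamber_dna", "button_dna",
                  "button_protein", "bg_chamber", "bg_button_dna",
                  "bg_button_protein")

#' Read / write a chamber-level scan table
#'
#' Tab-delimited with header `row col section chamber_dna button_dna
#' button_protein bg_chamber bg_button_dna bg_button_protein`, one record
#' per mapped chip cell, 1-based coordinates. Extra columns (e.g. layout
#' annotation) are tolerated and preserved.
#'
#' @param path file path
#' @return data.frame
#' @export
read_scan_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(SCAN_COLUMNS %in% names(x)))
    qpid_stop("qpid_io", "scan table missing columns: %s",
              paste(setdiff(SCAN_COLUMNS, names(x)), collapse = ", "))
  if (any(x$chamber_dna < 0 | x$button_dna < 0 | x$button_protein < 0))
    qpid_stop("qpid_io", "scan intensities must be non-negative")
  x
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_scan_table
#' @param scan scan table data.frame
#' @export
write_scan_table <- function(scan, path) write_tsv(scan, path)

#' Read a two-column calibration series (`conc_uM intensity`)
#' @param path file path
#' @return data.frame
#' @export
read_calibration_points <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("conc_uM", "intensity") %in% names(x)))
    qpid_stop("qpid_io", "calibration file needs columns conc_uM, intensity")
  x
}

#' Read / write narrowPeak (BED6+4) peak files
#'
#' Coordinates are 0-based half-open as in the BED convention; missing
#' optional columns are filled with placeholders.
#'
#' @param path file path
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `signalValue`, `pValue`, `qValue`, `peak`
#' @export
read_narrowpeak <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 3L) qpid_stop("qpid_io", "peak file needs >= 3 columns")
  pad <- list(".", 0L, ".", 0, -1, -1, -1L)
  for (j in seq_len(10 - ncol(x)))
    x[[ncol(x) + 1L]] <- pad[[ncol(x) - 2L]]
  names(x) <- cols[seq_len(ncol(x))]
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  if (any(x$start >= x$end))
    qpid_stop("qpid_io", "peak intervals must satisfy start < end")
  rownames(x) <- NULL
  x
}

#' @rdname read_narrowpeak
#' @param peaks peak data.frame
#' @export
write_narrowpeak <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write genomes and site libraries as FASTA
#' @param path file path
#' @return named character vector of sequences
#' @export
read_fasta_seqs <- function(path) {
  x <- readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta_seqs
#' @param seqs named character vector
#' @export
write_fasta_seqs <- function(seqs, path) {
  writeXStringSet(DNAStringSet(seqs), path)
  invisible(path)
}

#' Read / write a pentamer shape table
#'
#' Tab-delimited `pentamer mgw prot roll_left roll_right helt_left
#' helt_right` with header; validated on read.
#'
#' @param path file path
#' @return validated shape table data.frame
#' @export
read_shape_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_shape_table(x)
  x
}

#' @rdname read_shape_table
#' @param table shape table data.frame
#' @export
write_shape_table <- function(table, path) write_tsv(table, path)

#' Write / read feature vectors with a layout header
#'
#' Tab-delimited matrix (one row per oligo) preceded by a 3-line header
#' recording the core width `w`, flank `k` and the frozen block order.
#'
#' @param vectors named list of `qpid_fvec`
#' @param path file path
#' @export
write_feature_vectors <- function(vectors, path) {
  w <- attr(vectors[[1]], "w"); k <- attr(vectors[[1]], "k")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# w=%d", w), sprintf("# k=%d", k),
               sprintf("# blocks=%s", paste(SHAPE_BLOCKS, collapse = ","))),
             con)
  m <- do.call(rbind, lapply(vectors, as.numeric))
  df <- data.frame(id = names(vectors), m, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_vectors
#' @export
read_feature_vectors <- function(path) {
  hdr <- readLines(path, n = 3L)
  w <- as.integer(sub("# w=", "", hdr[1], fixed = TRUE))
  k <- as.integer(sub("# k=", "", hdr[2], fixed = TRUE))
  x <- read.delim(path, skip = 3L, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(x)), function(i)
    structure(as.numeric(x[i, -1]), w = w, k = k,
              block_order = SHAPE_BLOCKS, class = "qpid_fvec"))
  names(out) <- x$id
  out
}

#' Write a Kd results table
#'
#' Tab-delimited `protein oligo kd_uM kd_se rmax status n_points`.
#' In the human-readable rendering censored-weak entries print '-'.
#'
#' @param kd_table data.frame from [fit_all_kd()]
#' @param path file path
#' @param human render censored entries as '-' and round values
#' @export
write_kd_table <- function(kd_table, path, human = FALSE) {
  if (human) {
    kd_table$kd_uM <- ifelse(kd_table$status %in% c("censored_weak", "failed"),
                             "-", as.character(signif(kd_table$kd_uM, 3)))
    kd_table$kd_se <- signif(kd_table$kd_se, 3)
    kd_table$rmax <- signif(kd_table$rmax, 3)
  }
  write_tsv(kd_table, path)
}
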