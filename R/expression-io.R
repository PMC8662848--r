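#' Read a genes-by-samples expression matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Cells equal to one of the
#' missing-value tokens `"NA"`, `"NaN"` or the empty string become `NA` in the
#' returned matrix; imputation is a separate explicit step (see
#' [knn_impute()]), never silent.
#'
#' @param path Path to the file.
#' @param delimiter Field separator, default tab.
#' @param transpose If `TRUE` the file is samples-by-genes and is transposed
#'   on read so that genes end up in rows.
#' @return A numeric matrix with gene identifiers as `rownames` and sample
#'   identifiers as `colnames`. Missing cells are `NA`; `is.na()` of the
#'   result is the missingness mask.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3\tNA"), tf)
#' x <- read_expression(tf)
#' dim(x)
#' sum(is.na(x))
#' @export
read_expression <- function(path, delimiter = "\t", transpose = FALSE) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path)
  }
  nf <- count.fields(path, sep = delimiter, quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged expression file: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1L])
  }
  dat <- read.table(path, header = TRUE, sep = delimiter, quote = "",
                    comment.char = "", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(dat) < 2L) {
    stop("expression file needs an ID column plus at least one sample column")
  }
  ids <- dat[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate gene ID in expression file: ", dup[1L])
  }
  sample_ids <- colnames(dat)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID in expression header: ",
         sample_ids[duplicated(sample_ids)][1L])
  }
  chr <- as.matrix(dat[, -1L, drop = FALSE])
  missing_mask <- chr %in% c("NA", "NaN", "") | is.na(chr)
  vals <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(vals) & !missing_mask)
  if (length(bad)) {
    stop("non-numeric expression cell: '", chr[bad[1L]], "'")
  }
  vals[missing_mask] <- NA_real_
  x <- matrix(vals, nrow = length(ids), dimnames = list(ids, sample_ids))
  if (transpose) x <- t(x)
  message("read expression matrix: ", nrow(x), " genes x ", ncol(x),
          " samples (", sum(is.na(x)), " missing)")
  x
}
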