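# Standard-format readers and writers: TSV matrices with a header row of
# sample ids, dosage TSV, BED intervals, JSON for truth/manifests.

#' Write a numeric matrix as TSV (header row = sample ids)
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param row_label Name of the first (row id) column.
#' @export
write_matrix_tsv <- function(mat, path, row_label = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write genotype dosages and the variant table as TSV
#' @param genotypes A `genotype_matrix`.
#' @param dosage_path,info_path Output paths.
#' @export
write_dosage_tsv <- function(genotypes, dosage_path, info_path) {
  write_matrix_tsv(genotypes$dosage, dosage_path, row_label = "variant_id")
  utils::write.table(genotypes$info, info_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dosage_path)
}

#' Read genotype dosages written by [write_dosage_tsv()]
#' @param dosage_path,info_path Input paths.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(dosage_path, info_path) {
  structure(
    list(dosage = read_matrix_tsv(dosage_path),
         info = utils::read.delim(info_path, stringsAsFactors = FALSE)),
    class = "genotype_matrix"
  )
}

#' Write an interval table as BED
#' @param df data.frame with chrom, start, end and optional extra columns.
#' @param path Output path.
#' @param extra_cols Extra columns to append after the first three.
#' @export
write_bed <- function(df, path, extra_cols = setdiff(names(df),
                                                     c("chrom", "start", "end"))) {
  out <- df[, c("chrom", "start", "end", extra_cols), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first three columns chrom/start/end, extras kept)
#' @param path Input path.
#' @param extra_names Names for columns beyond the third.
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end")
  extras <- if (ncol(df) > 3) {
    if (is.null(extra_names)) sprintf("V%d", 4:ncol(df)) else extra_names
  } else character()
  names(df) <- c(base, extras)[seq_len(ncol(df))]
  df
}
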