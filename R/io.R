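# Plain-text interchange: tab-separated genotype matrix + 3-column marker
# map, and tidy phenotype / BLUE tables as CSV.

#' Write genotypes as matrix + map files
#'
#' \code{<prefix>_genotypes.tsv}: lines x markers codes with a leading
#' \code{line} column; \code{<prefix>_map.tsv}: marker, chrom, pos.
#'
#' @param geno a \linkS4class{GenotypeData}.
#' @param prefix file path prefix.
#' @return invisibly, the two file paths.
#' @export
writeGenotypes <- function(geno, prefix) {
  gf <- paste0(prefix, "_genotypes.tsv")
  mf <- paste0(prefix, "_map.tsv")
  df <- data.frame(line = lineIds(geno), genoCodes(geno), check.names = FALSE)
  write.table(df, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(markerMap(geno), mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genotypes = gf, map = mf))
}

#' Read genotypes written by \code{\link{writeGenotypes}}
#'
#' @param prefix file path prefix.
#' @return A \linkS4class{GenotypeData}.
#' @export
readGenotypes <- function(prefix) {
  df <- read.table(paste0(prefix, "_genotypes.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE)
  map <- read.table(paste0(prefix, "_map.tsv"), header = TRUE, sep = "\t",
                    colClasses = c(marker = "character"))
  codes <- as.matrix(df[, -1, drop = FALSE])
  rownames(codes) <- df$line
  GenotypeData(codes, map)
}

#' Write / read tidy phenotype tables
#'
#' Long-format CSV with columns line, trial, block, row, column, trait,
#' value.
#'
#' @param pheno phenotype data.frame.
#' @param path CSV path.
#' @return \code{writePhenotypes}: the path, invisibly;
#'   \code{readPhenotypes}: the data.frame.
#' @export
writePhenotypes <- function(pheno, path) {
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
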