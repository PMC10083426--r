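# Readers/writers for the plain-text formats the pipeline exchanges:
# TSV dosage matrices, VCF genotypes, CSV trial/BLUE/GEBV tables, TSV GRMs
# and JSON component/report files.

#' Write a genotype matrix as a TSV dosage table
#'
#' Rows are lines, the header holds marker ids, missing calls are `NA`.
#' @param geno A `genotype_matrix`.
#' @param path Output file.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(line = geno$line_ids, geno$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV dosage table written by [write_dosage_tsv()]
#' @param path Input file.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  genotype_matrix(df[[1]], colnames(d), d)
}

#' Write genotypes as a minimal VCF
#'
#' Biallelic sites on a placeholder chromosome, unphased GT calls
#' (`0/0`, `0/1`, `1/1`, `./.` for missing). Dosages must be integer.
#' @param geno A `genotype_matrix`.
#' @param path Output file (uncompressed `.vcf`).
#' @export
write_vcf <- function(geno, path) {
  d <- geno$dosages
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE)) {
    stop("VCF output requires integer dosages (write before imputation)")
  }
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=gsresp",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$line_ids), collapse = "\t"))
  m <- ncol(d)
  gt <- matrix("./.", nrow(d), m)
  obs <- !is.na(d)
  gt[obs] <- gt_codes[round(d[obs]) + 1L]
  body <- vapply(seq_len(m), function(j) {
    paste(c("1", j, geno$marker_ids[j], "A", "T", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read biallelic SNP dosages from a VCF
#'
#' Uses \pkg{vcfR}; the alternate-allele dosage is the sum of the GT allele
#' indices. Multiallelic sites are rejected with an explicit error.
#' @param path VCF file.
#' @return A `genotype_matrix` (lines x markers).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) stop("multiallelic site(s) present; only biallelic SNPs are supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  parse_gt <- function(x) {
    x[x %in% c(".", "./.", ".|.")] <- NA
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(z) {
      if (length(z) == 1 && is.na(z)) return(NA_real_)
      s <- suppressWarnings(as.numeric(z))
      if (anyNA(s)) NA_real_ else sum(s)
    }, numeric(1))
  }
  d <- t(apply(gt, 1, parse_gt))          # markers x lines -> keep then t()
  d <- t(d)
  marker_ids <- rownames(gt)
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(d)))
  genotype_matrix(colnames(gt), marker_ids, d)
}

#' Write / read a GRM as TSV with an id column
#' @param grm A `grm`.
#' @param path File path.
#' @export
write_grm_tsv <- function(grm, path) {
  df <- data.frame(id = grm$line_ids, grm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  dimnames(G) <- list(df[[1]], df[[1]])
  structure(list(line_ids = df[[1]], values = G), class = "grm")
}

#' Write / read long-format BLUE tables and trial tables as CSV
#' @param x Table to write.
#' @param path File path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @param class_out Class prepended to the returned data.frame.
#' @export
read_table_csv <- function(path, class_out = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(class_out)) class(df) <- c(class_out, "data.frame")
  df
}

#' Write variance components (or any report list) as JSON
#' @param x List to serialize.
#' @param path File path.
#' @export
write_components_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
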