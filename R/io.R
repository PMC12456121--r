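# Readers and writers for the plain-text formats the workflow exchanges:
# genotype dosage TSV (lines x markers), minimal VCF, plot-level phenotype
# CSV, environmental-covariate CSV, and square labeled kernel CSV.

#' Read a genotype dosage matrix
#'
#' TSV format: first column line ids, remaining columns one per marker
#' (header row of marker ids), entries 0/1/2 or NA. VCF: GT fields are
#' mapped 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, missing -> NA; multi-allelic
#' records are skipped and counted (attribute \code{n_multiallelic}).
#' Heterozygous calls in nominally inbred panels are kept as 1 with a
#' warning.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"vcf"} (default guessed from the
#'   extension).
#' @return lines x markers numeric matrix with dimnames.
#' @export
read_genotypes <- function(path, format = NULL) {
  stop_if(!file.exists(path), "file not found: ", path)
  format <- format %||%
    (if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv")
  if (format == "tsv") {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE)
    G <- as.matrix(tab)
    storage.mode(G) <- "double"
    bad <- which(!(G %in% c(0, 1, 2) | is.na(G)))
    stop_if(length(bad), sprintf(
      "malformed dosage at data row %d (values must be 0/1/2/NA)",
      ((bad[1] - 1) %% nrow(G)) + 1))
    stop_if(anyDuplicated(rownames(G)) > 0, "duplicate line ids")
    return(G)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", vcfR::getALT(v))
  n_multi <- sum(multi)
  if (n_multi > 0)
    message(n_multi, " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v[!multi, ], element = "GT")
  to_dose <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0")] <- 0
    out[x %in% c("0/1", "1/0")] <- 1
    out[x %in% c("1/1")] <- 2
    out
  }
  G <- t(apply(gt, 1, to_dose))
  colnames(G) <- colnames(gt)
  G <- t(G)   # lines x markers
  colnames(G) <- rownames(gt)
  if (any(G == 1, na.rm = TRUE))
    warning("heterozygous calls present; kept as dosage 1")
  attr(G, "n_multiallelic") <- n_multi
  G
}

#' Write a genotype dosage TSV
#' @param G lines x markers matrix with dimnames.
#' @param path output path.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(line = rownames(G), G, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plot-level phenotype table
#'
#' CSV with columns \code{env, rep, row, col, genotype} plus one or more
#' numeric trait columns. Duplicate (env, row, col) coordinates and
#' non-numeric trait entries are rejected with the offending row.
#'
#' @param path CSV path.
#' @param trait trait column that must be present and numeric.
#' @return validated data.frame.
#' @export
read_phenotypes <- function(path, trait = "y") {
  stop_if(!file.exists(path), "file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
  need <- c("env", "rep", "row", "col", "genotype", trait)
  missing_cols <- setdiff(need, names(tab))
  stop_if(length(missing_cols),
          "missing required columns: ", paste(missing_cols, collapse = ", "))
  key <- paste(tab$env, tab$row, tab$col)
  dup <- which(duplicated(key))
  stop_if(length(dup), sprintf(
    "duplicate plot coordinate (env=%s, row=%s, col=%s) at data row %d",
    tab$env[dup[1]], tab$row[dup[1]], tab$col[dup[1]], dup[1]))
  yv <- suppressWarnings(as.numeric(tab[[trait]]))
  bad <- which(is.na(yv) & !is.na(tab[[trait]]) & tab[[trait]] != "NA")
  stop_if(length(bad), sprintf(
    "non-numeric trait value '%s' at data row %d", tab[[trait]][bad[1]],
    bad[1]))
  tab[[trait]] <- yv
  tab
}

#' Read an environment x covariate table
#'
#' CSV with environment ids in the first column and numeric covariates in
#' the rest; no missing values allowed.
#'
#' @param path CSV path.
#' @return data.frame with environment rownames.
#' @export
read_ecs <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = ",", row.names = 1,
                    check.names = FALSE)
  stop_if(ncol(tab) < 1, "need at least one covariate column")
  stop_if(!all(vapply(tab, is.numeric, logical(1))),
          "covariates must be numeric")
  stop_if(anyNA(tab), "missing covariate values not allowed")
  tab
}

#' Write a square labeled kernel CSV
#' @param K square matrix with dimnames.
#' @param path output path.
#' @export
write_kernel <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square labeled kernel CSV
#' @param path CSV path.
#' @return square matrix with dimnames.
#' @export
read_kernel <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", row.names = 1,
                    check.names = FALSE)
  as.matrix(tab)
}
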