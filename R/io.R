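#' Read a genotype matrix
#'
#' Reads genotypes either from a VCF (diploid GT fields mapped to -1/0/1 for
#' homozygous-reference / heterozygous / homozygous-alternate, phased or
#' unphased, missing preserved as `NA`; non-biallelic records are skipped and
#' counted) or from a delimited matrix (header row of marker ids, first
#' column genotype ids).  VCF parsing goes through the VariantAnnotation
#' package.
#'
#' @param path input file.
#' @param format `"vcf"`, `"matrix"`, or `"auto"` (by file extension).
#' @return genotype x marker matrix coded -1/0/1 (fractional values allowed
#'   for pre-imputed matrices) with attribute `map` (chromosome/position, VCF
#'   only, 1-based) and `n_skipped` (non-biallelic record count, VCF only).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  if (format == "matrix") {
    tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    return(.check_markers(as.matrix(tab), allow_missing = TRUE))
  }
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(vcf))
  biallelic <- nalt == 1L
  n_skipped <- sum(!biallelic)
  vcf <- vcf[biallelic, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0")] <- -1
    out[g %in% c("0/1", "1/0")] <- 0
    out[g %in% c("1/1")] <- 1
    out
  }
  M <- t(apply(gt, 1, code))
  dimnames(M) <- dimnames(gt)
  M <- t(M)  # genotypes in rows
  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  map <- data.frame(marker = colnames(M),
                    chrom = as.character(rr$seqnames), pos = rr$start)
  structure(M, map = map, n_skipped = n_skipped)
}

#' Write a genotype matrix
#'
#' Writes either a delimited -1/0/1 matrix (genotype ids in the first
#' column, marker ids in the header) or a minimal unphased VCF (GT field
#' only, positions taken from the matrix's `map` attribute or defaulting to
#' consecutive positions on one chromosome; REF/ALT set to placeholder
#' alleles A/G).
#'
#' @param markers genotype x marker matrix coded -1/0/1 (`NA` allowed).
#' @param path output file.
#' @param format `"matrix"` or `"vcf"`.
#' @export
write_genotypes <- function(markers, path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  markers <- .check_markers(markers, allow_missing = TRUE)
  if (format == "matrix") {
    utils::write.csv(as.data.frame(markers), path, row.names = TRUE)
    return(invisible(path))
  }
  map <- attr(markers, "map")
  m <- ncol(markers)
  if (is.null(map))
    map <- data.frame(marker = colnames(markers), chrom = "1", pos = seq_len(m))
  gt_code <- c(`-1` = "0/0", `0` = "0/1", `1` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=gptrial",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(markers)), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    g <- markers[, j]
    gs <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(map$chrom[j], map$pos[j], colnames(markers)[j], "A", "G", ".",
            "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a plot-level phenotype table
#'
#' Comma-separated table with header; required columns `genotype`, `site`,
#' `year`, `rep`, `block`; every remaining numeric column is treated as a
#' trait (missing values allowed).  Duplicate (genotype, site, year, rep)
#' rows are an error.
#'
#' @param path input CSV.
#' @return phenotype data.frame with attribute `traits` (trait column names)
#'   and `missingness` (per-trait missing fraction).
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("genotype", "site", "year", "rep", "block")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(tab[c("genotype", "site", "year", "rep")], sep = "|"))
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (genotype, site, year, rep) rows: ",
         paste(utils::head(dup, 5), collapse = "; "))
  }
  traits <- setdiff(names(tab), req)
  traits <- traits[vapply(tab[traits], is.numeric, logical(1))]
  if (length(traits) == 0L) stop("no numeric trait column found")
  structure(tab, traits = traits,
            missingness = vapply(tab[traits], function(x) mean(is.na(x)),
                                 numeric(1)))
}

#' Write a plot-level phenotype table
#'
#' @param data phenotype data.frame.
#' @param path output CSV.
#' @export
write_phenotypes <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Rule-based outlier filtering
#'
#' Deterministic stand-in for visual outlier screening: within each trait by
#' site by year cell, plot values outside `median +/- k * IQR` are set to
#' missing.  `k = Inf` leaves the data unchanged.
#'
#' @param data phenotype data.frame.
#' @param traits trait columns to screen (default: every numeric non-design
#'   column).
#' @param k IQR multiplier (default 3).
#' @return the filtered data.frame with attribute `outlier_report`
#'   (data.frame of removed counts per trait x site x year).
#' @export
outlier_filter <- function(data, traits = NULL, k = 3) {
  req <- c("genotype", "site", "year", "rep", "block")
  if (is.null(traits)) {
    traits <- setdiff(names(data), req)
    traits <- traits[vapply(data[traits], is.numeric, logical(1))]
  }
  report <- list()
  for (tr in traits) {
    cells <- split(seq_len(nrow(data)),
                   list(data$site, data$year), drop = TRUE)
    for (nm in names(cells)) {
      ii <- cells[[nm]]
      v <- data[[tr]][ii]
      if (all(is.na(v))) next
      md <- stats::median(v, na.rm = TRUE)
      iqr <- stats::IQR(v, na.rm = TRUE)
      bad <- !is.na(v) & (v < md - k * iqr | v > md + k * iqr)
      if (is.infinite(k)) bad <- rep(FALSE, length(v))
      data[[tr]][ii[bad]] <- NA
      report[[paste(tr, nm, sep = ".")]] <-
        data.frame(trait = tr, cell = nm, removed = sum(bad),
                   n = sum(!is.na(v)))
    }
  }
  attr(data, "outlier_report") <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  data
}

#' Write a machine-readable provenance record
#'
#' Records what produced an output directory: a hash of the configuration,
#' the seed, the package and R versions and a timestamp, as JSON.
#'
#' @param path output JSON file.
#' @param config any serialisable configuration object.
#' @param seed the seed used.
#' @export
write_provenance <- function(path, config, seed) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  v <- utf8ToInt(txt)
  rec <- list(
    config_hash = sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max),
    seed = seed,
    package = as.character(utils::packageVersion("gptrial")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
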