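## File formats: PLINK1 bed/bim/fam, tab-delimited summary statistics and
## phenotype tables, ground-truth JSON. The bed codec is implemented here
## directly (variant-major, magic bytes 0x6c 0x1b 0x01; 2-bit codes
## 00 = hom a1, 01 = missing, 10 = het, 11 = hom a2). Dosages throughout the
## package count copies of the bim a1 allele.

GWAS_COLS <- c("SNP", "CHR", "BP", "A1", "A2", "EAF", "BETA", "SE", "P",
               "N", "INFO")

#' Write genotypes to a PLINK1 bed/bim/fam triplet
#'
#' @param dosages n x m matrix of 0/1/2 a1-allele counts (NA = missing),
#'   with sample ids as rownames and variant ids as colnames.
#' @param variants data.frame with snp_id, chrom, pos, a1, a2 matching the
#'   dosage columns.
#' @param prefix output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return invisibly, the three file paths.
#' @export
write_plink <- function(dosages, variants, prefix) {
  stopifnot(ncol(dosages) == nrow(variants))
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop_data("unwritable directory: ", dir)
  n <- nrow(dosages); m <- ncol(dosages)
  ## dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code_of <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  npad <- ceiling(n / 4) * 4
  bed <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(bed), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), bed)
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    d <- dosages[, j]
    codes <- rep(0L, npad)
    codes[seq_len(n)] <- ifelse(is.na(d), 1L, code_of[as.character(d)])
    bytes <- as.integer(colSums(matrix(codes, nrow = 4) * mult))
    writeBin(as.raw(bytes), bed)
  }
  bim <- data.frame(variants$chrom, variants$snp_id, 0, variants$pos,
                    variants$a1, variants$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- rownames(dosages) %||% sprintf("S%05d", seq_len(n))
  fam <- data.frame(ids, ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a PLINK1 bed/bim/fam triplet
#'
#' @param prefix path prefix of the triplet.
#' @return list with `dosages` (a1-allele counts, samples x variants) and
#'   `variants` (data.frame snp_id, chrom, pos, a1, a2).
#' @export
read_plink <- function(prefix) {
  bedf <- paste0(prefix, ".bed")
  if (!file.exists(bedf)) stop_data("missing bed file: ", bedf)
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b || raw[3] != 0x01)
    stop_data("not a variant-major PLINK1 bed file: ", bedf)
  bpv <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpv * m) stop_data("bed size inconsistent with bim/fam")
  ## decode all variants at once: bytes -> 4 two-bit codes (low bits first)
  bytes <- matrix(body, nrow = bpv, ncol = m)
  dose_of <- c(2L, NA_integer_, 1L, 0L)   # codes 0..3
  G <- matrix(NA_integer_, n, m)
  shifts <- c(1L, 4L, 16L, 64L)
  for (s in 1:4) {
    codes <- (bytes %/% shifts[s]) %% 4L
    rows <- seq(s, by = 4, length.out = bpv)
    rows <- rows[rows <= n]
    G[rows, ] <- dose_of[codes[seq_along(rows), , drop = FALSE] + 1L]
  }
  dimnames(G) <- list(fam[[2]], bim$snp_id)
  list(dosages = G,
       variants = bim[, c("snp_id", "chrom", "pos", "a1", "a2")])
}

#' Read base GWAS summary statistics
#'
#' Whitespace/tab-delimited with header SNP CHR BP A1 A2 EAF BETA SE P N INFO.
#' @param path file path.
#' @return data.frame with the standard columns.
#' @export
read_base_gwas <- function(path) {
  if (!file.exists(path)) stop_data("missing summary-statistics file: ", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(GWAS_COLS, names(df))
  if (length(missing))
    stop_data("summary statistics lack columns: ",
              paste(missing, collapse = ", "))
  df
}

#' Read a phenotype/covariate table
#'
#' Tab-delimited with header FID IID then trait/covariate columns; missing
#' values coded NA.
#' @param path file path.
#' @return data.frame with a `sample_id` column (from IID).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_data("missing phenotype file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("FID", "IID") %in% names(df)))
    stop_data("phenotype file must start with FID and IID columns")
  df$sample_id <- as.character(df$IID)
  df[, c("sample_id", setdiff(names(df), c("FID", "IID", "sample_id"))),
     drop = FALSE]
}

#' Write a simulated study to disk
#'
#' Writes the PLINK triplet, tab-delimited base summary statistics and
#' phenotype/covariate table, and a ground-truth JSON.
#'
#' @param cohort cohort data.frame from [simulate_cohort()].
#' @param dosages dosage matrix aligned with `cohort$sample_id`.
#' @param variants variant metadata.
#' @param base_gwas base GWAS data.frame.
#' @param dir output directory (created if absent).
#' @param true_params optional ground truth list, written as `truth.json`.
#' @return named character vector of the files written.
#' @export
write_dataset <- function(cohort, dosages, variants, base_gwas, dir,
                          true_params = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) stop_data("unwritable directory: ", dir)
  ## bim contract: positions strictly increasing within chromosome
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  dosages <- dosages[, variants$snp_id, drop = FALSE]
  prefix <- file.path(dir, "target")
  write_plink(dosages[cohort$sample_id, , drop = FALSE], variants, prefix)

  gw <- file.path(dir, "base_gwas.tsv")
  utils::write.table(base_gwas[, GWAS_COLS], gw, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ph <- file.path(dir, "phenotypes.tsv")
  pheno <- cbind(FID = cohort$sample_id, IID = cohort$sample_id,
                 cohort[, setdiff(names(cohort), "sample_id"), drop = FALSE])
  utils::write.table(pheno, ph, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  paths <- c(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
             fam = paste0(prefix, ".fam"), base_gwas = gw, phenotypes = ph)
  if (!is.null(true_params)) {
    tj <- file.path(dir, "truth.json")
    jsonlite::write_json(true_params, tj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, truth = tj)
  }
  paths
}
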