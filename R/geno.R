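#' Genotype matrix container
#'
#' Bundles a lines-by-SNPs dosage matrix (count of alt alleles, 0/1/2, `NA`
#' for missing) with per-SNP metadata. Inbred lines carry only dosages
#' \{0, 2, NA\}; hybrids and F2 individuals may carry 1 (heterozygous).
#'
#' @param dosage numeric matrix, lines in rows, SNPs in columns. Row names are
#'   line ids and column names SNP ids (generated when absent).
#' @param snps tibble with columns `snp_id`, `chrom`, `pos_bp` and optionally
#'   `ref`, `alt`. Row order must match the columns of `dosage`.
#' @param ploidy_class one of `"inbred"`, `"hybrid"`, `"f2"`.
#' @return An object of class `krn_geno`: a list with elements `dosage`,
#'   `snps`, `ploidy_class`.
#' @export
geno <- function(dosage, snps, ploidy_class = c("inbred", "hybrid", "f2")) {
  ploidy_class <- match.arg(ploidy_class)
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("L%03d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp_id
  snps <- tibble::as_tibble(snps)
  if (!all(c("snp_id", "chrom", "pos_bp") %in% names(snps))) {
    stop("`snps` needs columns snp_id, chrom, pos_bp", call. = FALSE)
  }
  if (nrow(snps) != ncol(dosage)) {
    stop("snp metadata rows must match dosage columns", call. = FALSE)
  }
  if (!identical(as.character(snps$snp_id), colnames(dosage))) {
    stop("snp_id order must match dosage column names", call. = FALSE)
  }
  bad_pos <- snps |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos_bp) > 0) || dplyr::n() == 1) |>
    dplyr::pull(.data$ok)
  if (!all(bad_pos)) {
    stop("pos_bp must be strictly increasing within each chromosome", call. = FALSE)
  }
  vals <- dosage[!is.na(dosage)]
  if (ploidy_class == "inbred" && !all(vals %in% c(0, 2))) {
    stop("inbred dosages must be 0, 2 or NA", call. = FALSE)
  }
  if (length(vals) && (min(vals) < 0 || max(vals) > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  structure(
    list(dosage = dosage, snps = snps, ploidy_class = ploidy_class),
    class = "krn_geno"
  )
}

#' @export
print.krn_geno <- function(x, ...) {
  cat(sprintf(
    "<krn_geno> %d %s lines x %d SNPs on %d chromosome(s)\n",
    nrow(x$dosage), x$ploidy_class, ncol(x$dosage),
    dplyr::n_distinct(x$snps$chrom)
  ))
  invisible(x)
}

#' @export
dim.krn_geno <- function(x) dim(x$dosage)

line_ids <- function(g) rownames(g$dosage)

#' Per-SNP minor allele frequency
#'
#' Computed on non-missing calls; the alt-allele frequency is
#' `mean(dosage) / 2` and the MAF folds it at 0.5.
#'
#' @param g a [geno()] object.
#' @return tibble with `snp_id`, `alt_freq`, `maf`, `n_called`.
#' @export
maf <- function(g) {
  d <- g$dosage
  n_called <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  tibble::tibble(
    snp_id = colnames(d),
    alt_freq = unname(p),
    maf = unname(pmin(p, 1 - p)),
    n_called = unname(n_called)
  )
}

# mean-impute missing dosages, column-wise; used by kinship/scans/LD
impute_dosage <- function(d) {
  nas <- which(is.na(d))
  if (!length(nas)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  d[nas] <- mu[((nas - 1L) %/% nrow(d)) + 1L]
  d
}

#' Subset a genotype object
#'
#' @param g a [geno()] object.
#' @param lines,snps character vectors of ids (or logical/integer indices);
#'   `NULL` keeps all.
#' @return a [geno()] object.
#' @export
geno_subset <- function(g, lines = NULL, snps = NULL) {
  d <- g$dosage
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  meta <- g$snps
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    meta <- meta[match(colnames(d), meta$snp_id), ]
  }
  geno(d, meta, g$ploidy_class)
}
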