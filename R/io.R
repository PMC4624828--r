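#' Read and write genotype tables
#'
#' The HapMap-style dosage table is tab-delimited with columns `snp_id`,
#' `chrom`, `pos_bp`, `ref`, `alt` followed by one column per line holding
#' the alt-allele dosage (0/1/2, empty for missing).
#'
#' @param g a [geno()] object.
#' @param path file path.
#' @return `write_geno_hapmap()` returns `path` invisibly;
#'   `read_geno_hapmap()` returns a [geno()] object.
#' @export
write_geno_hapmap <- function(g, path) {
  meta <- g$snps
  if (!"ref" %in% names(meta)) meta$ref <- "A"
  if (!"alt" %in% names(meta)) meta$alt <- "B"
  tab <- dplyr::bind_cols(
    meta[, c("snp_id", "chrom", "pos_bp", "ref", "alt")],
    tibble::as_tibble(t(g$dosage))
  )
  readr::write_tsv(tab, path, na = "")
  invisible(path)
}

#' @rdname write_geno_hapmap
#' @param ploidy_class passed to [geno()].
#' @export
read_geno_hapmap <- function(path, ploidy_class = "inbred") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos_bp", "ref", "alt")
  d <- t(as.matrix(tab[, setdiff(names(tab), meta_cols)]))
  colnames(d) <- tab$snp_id
  geno(d, tab[, meta_cols], ploidy_class)
}

#' Write genotypes as VCF
#'
#' Inbred dosages 0/2 become homozygous `0/0` / `1/1` calls, dosage 1 is
#' `0/1`, missing is `./.`. Requires the vcfR package; the file is
#' bgzip-compressed when `path` ends in `.gz`.
#'
#' @param g a [geno()] object.
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(g, path) {
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- g$dosage
  gt <- matrix("./.", ncol(d), nrow(d),
               dimnames = list(NULL, rownames(d)))
  for (code in names(gt_codes)) {
    gt[t(d) == as.numeric(code)] <- gt_codes[[code]]
  }
  meta <- g$snps
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"),
    vapply(seq_len(nrow(meta)), function(i) {
      paste(c(meta$chrom[i], meta$pos_bp[i], meta$snp_id[i],
              meta$ref[i] %||% "A", meta$alt[i] %||% "B", ".", "PASS", ".",
              "GT", gt[i, ]), collapse = "\t")
    }, character(1))
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' @rdname write_geno_vcf
#' @param ploidy_class passed to [geno()].
#' @export
read_geno_vcf <- function(path, ploidy_class = "inbred") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt %in% c("1/1", "1|1")] <- 2
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  snps <- tibble::tibble(
    snp_id = fix$ID, chrom = fix$CHROM, pos_bp = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  geno(t(dos), snps, ploidy_class)
}

#' Write a simulation truth object as JSON lines
#'
#' One JSON record per causal locus plus one per line (subpopulation label),
#' for downstream recovery checks without loading R objects.
#'
#' @param sim a `panel_sim` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_jsonl <- function(sim, path) {
  arch <- sim$architecture
  recs <- c(
    lapply(seq_len(nrow(arch)), function(i) {
      list(kind = "causal", snp_id = arch$snp_id[i], a = arch$a[i],
           d = arch$d[i])
    }),
    lapply(seq_len(nrow(sim$truth$subpop)), function(i) {
      list(kind = "line", line_id = sim$truth$subpop$line_id[i],
           subpop = sim$truth$subpop$subpop[i])
    })
  )
  writeLines(vapply(recs, jsonlite::toJSON, character(1), auto_unbox = TRUE),
             path)
  invisible(path)
}
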