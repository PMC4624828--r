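#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosage vectors (composite LD, appropriate
#' for inbred panels), on pairwise-complete observations.
#'
#' @param x,y numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) {
    stop("zero dosage variance; r2 undefined", call. = FALSE)
  }
  cor(x[ok], y[ok])^2
}

#' Build LD blocks and the tagSNP marker bank
#'
#' Greedy, significance-seeded assignment: the most significant unassigned
#' SNP becomes the tag of a new block and absorbs every unassigned SNP on the
#' same chromosome within `max_bp_window` whose dosage `r2` with it exceeds
#' `r2_threshold`; iterate until every SNP belongs to exactly one block. Each
#' block's tag is its most significant member by construction, and the bank
#' is the list of all tags sorted by decreasing significance (ties by
#' chromosome then position).
#'
#' @param g a [geno()] object.
#' @param assoc an `assoc_scan` tibble covering all SNPs of `g`.
#' @param r2_threshold LD threshold (strictly greater than).
#' @param max_bp_window maximum physical distance from the tag considered
#'   for membership; `Inf` makes blocks chromosome-bounded only.
#' @return list of class `tagsnp_bank` with
#'   * `blocks`: tibble `block_id`, `chrom`, `tag_snp`, `n_snps`, `snp_ids`
#'     (list column),
#'   * `bank`: tibble `rank`, `snp_id`, `chrom`, `pos_bp`, `neg_log10_p`.
#' @export
build_bank <- function(g, assoc, r2_threshold = 0.2, max_bp_window = 1e6) {
  assoc <- tibble::as_tibble(assoc)
  if (!setequal(assoc$snp_id, g$snps$snp_id)) {
    stop("association results must cover exactly the SNPs of `g`",
         call. = FALSE)
  }
  ord <- assoc |>
    dplyr::arrange(dplyr::desc(.data$neg_log10_p), .data$chrom, .data$pos_bp)
  d <- impute_dosage(g$dosage)
  pos <- setNames(g$snps$pos_bp, g$snps$snp_id)

  n <- nrow(ord)
  assigned <- rep(FALSE, n)
  block_of <- integer(n)
  tags <- character(0)
  snp_col <- match(ord$snp_id, colnames(d))
  for (i in seq_len(n)) {
    if (assigned[i]) next
    tag <- ord$snp_id[i]
    tags <- c(tags, tag)
    b <- length(tags)
    cand <- which(!assigned & ord$chrom == ord$chrom[i] &
                    abs(ord$pos_bp - ord$pos_bp[i]) <= max_bp_window)
    if (length(cand) > 1) {
      r2 <- as.vector(cor(d[, snp_col[i]],
                          d[, snp_col[cand], drop = FALSE]))^2
      take <- cand[r2 > r2_threshold | cand == i]
    } else {
      take <- i
    }
    assigned[take] <- TRUE
    block_of[take] <- b
  }
  blocks <- tibble::tibble(
    block_id = sprintf("block_%05d", seq_along(tags)),
    tag_snp = tags,
    chrom = ord$chrom[match(tags, ord$snp_id)],
    n_snps = tabulate(block_of, length(tags)),
    snp_ids = split(ord$snp_id, block_of)[as.character(seq_along(tags))]
  )
  bank <- ord |>
    dplyr::filter(.data$snp_id %in% tags) |>
    dplyr::transmute(rank = dplyr::row_number(), .data$snp_id, .data$chrom,
                     .data$pos_bp, .data$neg_log10_p)
  structure(list(blocks = blocks, bank = bank), class = "tagsnp_bank")
}

#' @export
print.tagsnp_bank <- function(x, ...) {
  cat(sprintf("<tagsnp_bank> %d blocks over %d SNPs; top tag: %s\n",
              nrow(x$blocks), sum(x$blocks$n_snps), x$bank$snp_id[1]))
  invisible(x)
}
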