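#' Haldane map function and its inverse
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under the Haldane (no-interference) model, `r = (1 - exp(-2d/100)) / 2`,
#' and back.
#'
#' @param d_cM genetic distance(s) in centimorgans, `>= 0`.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distances must be non-negative", call. = FALSE)
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' @rdname haldane
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @export
inverse_haldane <- function(r) {
  if (any(r < 0 | r >= 0.5)) {
    stop("recombination fractions must lie in [0, 0.5)", call. = FALSE)
  }
  -50 * log(1 - 2 * r)
}

#' Build a genetic map tibble
#'
#' @param marker_ids character marker names.
#' @param chrom chromosome labels, one per marker.
#' @param pos_cM map positions (non-decreasing within chromosome).
#' @param pos_bp optional physical positions (1-based).
#' @return tibble with columns `marker_id`, `chrom`, `pos_cM`, `pos_bp`.
#' @export
genetic_map <- function(marker_ids, chrom, pos_cM, pos_bp = NA_real_) {
  m <- tibble::tibble(
    marker_id = as.character(marker_ids), chrom = chrom,
    pos_cM = pos_cM, pos_bp = pos_bp
  )
  if (anyDuplicated(m$marker_id)) stop("duplicate marker ids", call. = FALSE)
  ok <- m |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos_cM)) |>
    dplyr::pull(.data$ok)
  if (!all(ok)) stop("pos_cM must be non-decreasing within chromosome", call. = FALSE)
  m
}

#' Simulate a gamete from a heterozygous parent
#'
#' Draws one recombinant haplotype from a pair of parental haplotypes by a
#' Haldane crossover process (no interference): the transmitted haplotype
#' switches between the two parental strands between adjacent markers with
#' probability `haldane(d)` for an inter-marker distance of `d` cM, and
#' chromosomes segregate independently.
#'
#' @param hap1,hap2 numeric vectors, one allele per marker (any coding).
#' @param map a [genetic_map()] tibble whose rows parallel the haplotypes.
#' @return numeric vector of transmitted alleles, one per marker.
#' @export
meiosis_gamete <- function(hap1, hap2, map) {
  stopifnot(length(hap1) == nrow(map), length(hap2) == nrow(map))
  out <- numeric(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    d <- diff(map$pos_cM[idx])
    if (any(d < 0)) stop("negative inter-marker distance", call. = FALSE)
    r <- haldane(d)
    strand <- cumsum(c(
      sample(c(0L, 1L), 1L),
      as.integer(runif(length(r)) < r)
    )) %% 2L
    out[idx] <- ifelse(strand == 0L, hap1[idx], hap2[idx])
  }
  out
}
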