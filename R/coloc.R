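#' Build a genomic-interval tibble
#'
#' @param source_id identifiers.
#' @param chrom chromosome labels.
#' @param start_bp,end_bp 1-based closed interval bounds.
#' @param source_kind `"qtl"`, `"locus"` or `"snp_hotspot"`.
#' @param provenance study/population label used for distinct counting.
#' @param genome optional genome-build tag carried as an attribute.
#' @return tibble of class `genomic_intervals`.
#' @export
genomic_intervals <- function(source_id, chrom, start_bp, end_bp,
                              source_kind = "qtl", provenance = source_id,
                              genome = NULL) {
  if (any(start_bp > end_bp)) stop("start_bp > end_bp", call. = FALSE)
  out <- tibble::tibble(
    source_id = as.character(source_id), source_kind = source_kind,
    chrom = chrom, start_bp = start_bp, end_bp = end_bp,
    provenance = as.character(provenance)
  )
  attr(out, "genome") <- genome
  class(out) <- c("genomic_intervals", class(out))
  out
}

#' Sliding-window QTL hotspot scan
#'
#' Tiles each chromosome with windows of `window_bp` every `step_bp`, counts
#' the source intervals overlapping each window (closed-interval overlap; by
#' default intervals sharing a provenance label count once), keeps windows
#' reaching `min_count`, and merges overlapping or abutting qualifying
#' windows into maximal runs (reporting the maximum single-window count of
#' the run).
#'
#' @param intervals a [genomic_intervals()] tibble (QTL intervals projected
#'   to physical coordinates).
#' @param chrom_lengths tibble `chrom`, `length_bp`.
#' @param window_bp,step_bp window size and stride.
#' @param min_count minimum distinct detections for a hotspot.
#' @param distinct_provenance count distinct provenance labels rather than
#'   raw intervals.
#' @return tibble of class `hotspots`: `chrom`, `start_bp`, `end_bp`,
#'   `count`, `n_windows`.
#' @export
hotspot_scan <- function(intervals, chrom_lengths, window_bp = 1e7,
                         step_bp = 5e6, min_count = 2,
                         distinct_provenance = TRUE) {
  intervals <- tibble::as_tibble(intervals)
  chrom_lengths <- tibble::as_tibble(chrom_lengths)
  chk <- dplyr::left_join(intervals, chrom_lengths, by = "chrom")
  if (anyNA(chk$length_bp)) {
    stop("interval on a chromosome absent from chrom_lengths", call. = FALSE)
  }
  if (any(chk$end_bp > chk$length_bp)) {
    stop("interval extends beyond its chromosome", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(chrom_lengths)), function(ci) {
    ch <- chrom_lengths$chrom[ci]
    len <- chrom_lengths$length_bp[ci]
    starts <- seq(1, max(len - window_bp + 1, 1), by = step_bp)
    last <- max(starts) + window_bp - 1
    if (last < len) starts <- c(starts, len - window_bp + 1)
    ends <- pmin(starts + window_bp - 1, len)
    iv <- intervals[intervals$chrom == ch, ]
    counts <- vapply(seq_along(starts), function(w) {
      hit <- iv$start_bp <= ends[w] & iv$end_bp >= starts[w]
      if (distinct_provenance) {
        dplyr::n_distinct(iv$provenance[hit])
      } else {
        sum(hit)
      }
    }, numeric(1))
    tibble::tibble(chrom = ch, start_bp = starts, end_bp = ends,
                   count = counts)
  })
  wins <- dplyr::bind_rows(rows) |>
    dplyr::filter(.data$count >= min_count)
  if (!nrow(wins)) {
    out <- tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), count = numeric(),
                          n_windows = integer())
  } else {
    out <- wins |>
      dplyr::group_by(.data$chrom) |>
      dplyr::arrange(.data$start_bp, .by_group = TRUE) |>
      dplyr::mutate(run = cumsum(.data$start_bp > dplyr::lag(
        cummax(.data$end_bp), default = -Inf
      ) + 1)) |>
      dplyr::group_by(.data$chrom, .data$run) |>
      dplyr::summarise(start_bp = min(.data$start_bp),
                       end_bp = max(.data$end_bp),
                       count = max(.data$count),
                       n_windows = dplyr::n(), .groups = "drop") |>
      dplyr::select(-"run") |>
      dplyr::arrange(.data$chrom, .data$start_bp)
  }
  class(out) <- c("hotspots", class(out))
  out
}

interval_hit <- function(chrom, pos, targets) {
  if (is.null(targets) || !nrow(targets)) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(targets$chrom == chrom[i] &
          targets$start_bp <= pos[i] & targets$end_bp >= pos[i])
  }, logical(1))
}

#' Co-localize association loci with QTLs, hotspots and external intervals
#'
#' A locus co-localizes with a target set when any of its member SNP
#' positions falls inside a target interval (1-based closed). Reports
#' per-locus flags and the overall fraction of loci supported by at least
#' one target class.
#'
#' @param loci an [group_loci()] result (needs `locus_id`, `chrom`,
#'   `members` with per-SNP `pos_bp`).
#' @param qtls optional `common_qtl` tibble (or any tibble with `chrom`,
#'   `start_bp`, `end_bp`).
#' @param hotspots optional [hotspot_scan()] result.
#' @param external optional [genomic_intervals()] (e.g. SNP hotspots from
#'   another mapping population).
#' @param genome optional genome-build tag; if both this and an input's
#'   `genome` attribute are set and differ, an error is raised.
#' @return list of class `coloc_result`: `table` (per-locus flags and
#'   `cross_validated`), `fraction` (supported loci / all loci).
#' @export
colocalize <- function(loci, qtls = NULL, hotspots = NULL, external = NULL,
                       genome = NULL) {
  for (tgt in list(qtls, hotspots, external)) {
    tg <- attr(tgt, "genome")
    if (!is.null(genome) && !is.null(tg) && !identical(genome, tg)) {
      stop("genome builds differ: ", genome, " vs ", tg, call. = FALSE)
    }
  }
  loci <- tibble::as_tibble(loci)
  flags <- purrr::pmap_dfr(
    loci[, c("locus_id", "chrom", "members")],
    function(locus_id, chrom, members) {
      pos <- members$pos_bp
      ch <- rep(chrom, length(pos))
      tibble::tibble(
        locus_id = locus_id,
        overlaps_qtl = any(interval_hit(ch, pos, qtls)),
        in_qtl_hotspot = any(interval_hit(ch, pos, hotspots)),
        in_external = any(interval_hit(ch, pos, external))
      )
    }
  )
  flags$cross_validated <- flags$overlaps_qtl | flags$in_qtl_hotspot |
    flags$in_external
  structure(list(table = flags, fraction = mean(flags$cross_validated)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d/%d loci cross-validated (%.1f%%)\n",
              sum(x$table$cross_validated), nrow(x$table), 100 * x$fraction))
  invisible(x)
}
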