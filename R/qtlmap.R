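#' F2 QTL genotype probabilities given flanking markers
#'
#' Conditional probabilities of the three QTL genotypes at a test position,
#' given the observed F2 genotypes at the flanking markers and the Haldane
#' recombination fractions implied by the flanking distances. The F2 plant is
#' treated as two independent gametes from the doubly heterozygous F1, with
#' no crossover interference; a missing marker is marginalized, so with both
#' flanks missing the prior 1:2:1 is returned.
#'
#' @param left,right flanking marker genotypes: `"AA"`, `"AB"`, `"BB"` or
#'   `NA` (missing). `A` denotes the allele of the high-trait parent.
#' @param d_left,d_right distances (cM) from the test position to the left
#'   and right markers, `>= 0`.
#' @return numeric vector `c(pQQ, pQq, pqq)` (`Q` = high-parent allele).
#' @export
qtl_genotype_probs <- function(left, right, d_left, d_right) {
  tab <- f2_cond_table(d_left, d_right)
  li <- geno_code_index(left)
  ri <- geno_code_index(right)
  tab[li, ri, ]
}

# index 1..3 for AA/AB/BB counts 2/1/0, 4 for missing
geno_code_index <- function(gcode) {
  if (is.na(gcode)) return(4L)
  i <- match(gcode, c("AA", "AB", "BB"))
  if (is.na(i)) stop("marker genotype must be AA, AB, BB or NA", call. = FALSE)
  i
}

# joint/conditional table of P(Q genotype | L genotype, R genotype):
# dims [L state (AA,AB,BB,missing), R state (...), Q genotype (QQ,Qq,qq)]
f2_cond_table <- function(d_left, d_right) {
  if (d_left < 0 || d_right < 0) {
    stop("flanking distances must be non-negative", call. = FALSE)
  }
  r1 <- haldane(d_left)
  r2 <- haldane(d_right)
  # gamete (l, q, r) alleles in {1 = high parent, 0}; prob 1/2 * t1 * t2
  gam <- expand.grid(l = 0:1, q = 0:1, r = 0:1)
  t1 <- ifelse(gam$l == gam$q, 1 - r1, r1)
  t2 <- ifelse(gam$q == gam$r, 1 - r2, r2)
  pg <- 0.5 * t1 * t2
  joint <- array(0, c(3, 3, 3))   # [L count, R count, Q count] as 2,1,0 -> idx 1..3
  for (i in seq_len(8)) {
    for (j in seq_len(8)) {
      L <- gam$l[i] + gam$l[j]
      R <- gam$r[i] + gam$r[j]
      Q <- gam$q[i] + gam$q[j]
      joint[3 - L, 3 - R, 3 - Q] <- joint[3 - L, 3 - R, 3 - Q] + pg[i] * pg[j]
    }
  }
  out <- array(0, c(4, 4, 3))
  out[1:3, 1:3, ] <- joint
  out[4, 1:3, ] <- apply(joint, c(2, 3), sum)   # L missing: marginalize
  out[1:3, 4, ] <- apply(joint, c(1, 3), sum)
  out[4, 4, ] <- apply(joint, 3, sum)
  norm <- apply(out, c(1, 2), sum)
  sweep(out, c(1, 2), norm, "/")
}

f23_marker_counts <- function(pop) {
  m <- matrix(match(pop$genotypes, c("BB", "AB", "AA")) - 1L,
              nrow(pop$genotypes), ncol(pop$genotypes),
              dimnames = dimnames(pop$genotypes))
  m
}

f23_env_values <- function(pop, env = NULL) {
  fm <- pop$family_means
  if (!is.null(env)) fm <- fm[fm$environment == env, ]
  if (!nrow(fm)) stop("no family means for environment ", env, call. = FALSE)
  y <- fm |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(value = mean(.data$value))
  setNames(y$value, y$family)[rownames(pop$genotypes)]
}

#' Composite interval mapping scan by Haley-Knott regression
#'
#' At every grid position, the F2:3 family means are regressed on the
#' additive expectation `x* = pQQ - pqq` and the family-mean dominance
#' expectation `z* = pQq / 2` (random selfing halves the dominance
#' deviation, so the `z*` coefficient is the dominance effect on the F2
#' scale), plus the additive codes of any background cofactor markers not
#' within `window_cM` of the test position.
#' `LOD = (n/2) log10(RSS_reduced / RSS_full)`.
#'
#' @param pop an [simulate_f23()] population (or a compatible list with
#'   `genotypes`, `map`, `family_means`).
#' @param env environment label to scan (default: mean over environments).
#' @param step_cM grid step.
#' @param cofactors character vector of cofactor marker ids (e.g. from
#'   [select_cofactors()]); `NULL` gives simple interval mapping.
#' @param window_cM cofactors within this distance of the test position are
#'   excluded from the model.
#' @return tibble of class `lod_profile`: `chrom`, `pos_cM`, `lod`, `a_hat`,
#'   `d_hat`, `rss_full`, `rss_reduced`; attributes `n`, `rss_null`,
#'   `cofactors`, `map`.
#' @export
hk_scan <- function(pop, env = NULL, step_cM = 1, cofactors = NULL,
                    window_cM = 5) {
  map <- pop$map
  y <- f23_env_values(pop, env)
  counts <- f23_marker_counts(pop)
  n <- length(y)
  if (!is.null(cofactors) && !all(cofactors %in% map$marker_id)) {
    stop("cofactors must be map markers", call. = FALSE)
  }
  cof_x <- NULL
  if (length(cofactors)) {
    cof_x <- impute_dosage(counts[, cofactors, drop = FALSE] - 1)
  }
  rss_null <- sum((y - mean(y))^2)

  rows <- lapply(unique(map$chrom), function(ch) {
    mm <- map[map$chrom == ch, ]
    midx <- match(mm$marker_id, colnames(counts))
    grid <- seq(min(mm$pos_cM), max(mm$pos_cM), by = step_cM)
    if (tail(grid, 1) < max(mm$pos_cM)) grid <- c(grid, max(mm$pos_cM))
    res <- t(vapply(grid, function(t_pos) {
      il <- max(which(mm$pos_cM <= t_pos))
      ir <- min(which(mm$pos_cM >= t_pos))
      tab <- f2_cond_table(t_pos - mm$pos_cM[il], mm$pos_cM[ir] - t_pos)
      lg <- counts[, midx[il]]
      rg <- counts[, midx[ir]]
      lstate <- ifelse(is.na(lg), 4L, 3L - lg)
      rstate <- ifelse(is.na(rg), 4L, 3L - rg)
      pQQ <- tab[cbind(lstate, rstate, 1L)]
      pQq <- tab[cbind(lstate, rstate, 2L)]
      pqq <- tab[cbind(lstate, rstate, 3L)]
      xstar <- pQQ - pqq
      zstar <- pQq / 2
      use_cof <- NULL
      if (length(cofactors)) {
        far <- !(map$chrom[match(cofactors, map$marker_id)] == ch &
                   abs(map$pos_cM[match(cofactors, map$marker_id)] - t_pos) <
                     window_cM)
        if (any(far)) use_cof <- cof_x[, far, drop = FALSE]
      }
      xr <- cbind(rep(1, n), use_cof)
      rss_r <- sum(lm.fit(xr, y)$residuals^2)
      xf <- cbind(xr, xstar = xstar, zstar = zstar)
      ff <- lm.fit(xf, y)
      rss_f <- sum(ff$residuals^2)
      cf <- coef(ff)
      lod <- max((n / 2) * log10(rss_r / max(rss_f, 1e-300)), 0)
      c(pos = t_pos, lod = lod,
        a_hat = unname(cf["xstar"]), d_hat = unname(cf["zstar"]),
        rss_full = rss_f, rss_reduced = rss_r)
    }, numeric(6)))
    tibble::tibble(chrom = ch, pos_cM = res[, "pos"], lod = res[, "lod"],
                   a_hat = res[, "a_hat"], d_hat = res[, "d_hat"],
                   rss_full = res[, "rss_full"],
                   rss_reduced = res[, "rss_reduced"])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n") <- n
  attr(out, "rss_null") <- rss_null
  attr(out, "cofactors") <- cofactors
  attr(out, "map") <- map
  class(out) <- c("lod_profile", class(out))
  out
}

#' Forward-stepwise cofactor selection
#'
#' Regresses family means on marker additive codes, adding at each step the
#' marker with the smallest partial p-value while it is below `alpha`, up to
#' `max_cofactors` markers.
#'
#' @inheritParams hk_scan
#' @param max_cofactors cap on the number of cofactors.
#' @param alpha entry threshold on the partial t-test p-value.
#' @return character vector of selected marker ids (possibly empty).
#' @export
select_cofactors <- function(pop, env = NULL, max_cofactors = 5,
                             alpha = 0.01) {
  if (max_cofactors < 1) return(character(0))
  y <- f23_env_values(pop, env)
  x <- impute_dosage(f23_marker_counts(pop) - 1)
  poly_ok <- apply(x, 2, var) > 1e-10
  x <- x[, poly_ok, drop = FALSE]
  chosen <- character(0)
  repeat {
    base <- cbind(1, x[, chosen, drop = FALSE])
    qb <- qr(base)
    ry <- qr.resid(qb, y)
    cand <- setdiff(colnames(x), chosen)
    if (!length(cand)) break
    rx <- qr.resid(qb, x[, cand, drop = FALSE])
    sxx <- colSums(rx^2)
    ok <- sxx > 1e-10
    if (!any(ok)) break
    b <- colSums(rx * ry)[ok] / sxx[ok]
    df <- length(y) - ncol(base) - 1
    rss <- sum(ry^2) - b^2 * sxx[ok]
    tval <- b / sqrt((rss / df) / sxx[ok])
    p <- 2 * pt(-abs(tval), df)
    if (min(p) >= alpha) break
    chosen <- c(chosen, names(which.min(p)))
    if (length(chosen) >= max_cofactors) break
  }
  chosen
}

#' Call QTL peaks from a LOD profile
#'
#' Local maxima above `threshold` become QTL records; two maxima on one
#' chromosome are distinct peaks only if separated by a valley dropping at
#' least `valley_drop` LOD below the lower of the two, or by at least
#' `min_sep_cM`. Each record carries the flanking map markers of its peak,
#' the effects at the peak, the physical interval spanned by the flanking
#' markers (1-based, closed), the variance explained
#' `PVE = 1 - RSS_full / RSS_null` at the peak, and the [gene_action()]
#' class.
#'
#' @param profile an [hk_scan()] result.
#' @param threshold LOD threshold.
#' @param valley_drop required LOD drop between distinct peaks.
#' @param min_sep_cM alternative separation distance between distinct peaks.
#' @param population,environment optional labels stored on the records.
#' @return tibble of class `qtl_records`: `qtl_id`, `population`,
#'   `environment`, `chrom`, `peak_cM`, `flank_left`, `flank_right`,
#'   `start_bp`, `end_bp`, `lod`, `a`, `d`, `pve`, `da_ratio`,
#'   `gene_action`. Empty when nothing exceeds the threshold.
#' @export
call_qtl <- function(profile, threshold = 2.5, valley_drop = 1,
                     min_sep_cM = 20, population = NA_character_,
                     environment = NA_character_) {
  map <- attr(profile, "map")
  rss_null <- attr(profile, "rss_null")
  recs <- list()
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch, ]
    lod <- pr$lod
    cand <- which(lod >= threshold &
                    lod >= dplyr::lag(lod, default = -Inf) &
                    lod >= dplyr::lead(lod, default = -Inf))
    cand <- cand[order(-lod[cand])]
    kept <- integer(0)
    for (i in cand) {
      distinct <- vapply(kept, function(k) {
        seg <- lod[min(i, k):max(i, k)]
        valley <- min(seg)
        (abs(pr$pos_cM[i] - pr$pos_cM[k]) >= min_sep_cM) ||
          (valley <= min(lod[i], lod[k]) - valley_drop)
      }, logical(1))
      if (all(distinct)) kept <- c(kept, i)
    }
    mm <- map[map$chrom == ch, ]
    for (i in sort(kept)) {
      pos <- pr$pos_cM[i]
      il <- max(which(mm$pos_cM <= pos))
      ir <- min(which(mm$pos_cM >= pos))
      if (ir == il && ir < nrow(mm)) ir <- il + 1
      ga <- gene_action(pr$a_hat[i], pr$d_hat[i])
      recs[[length(recs) + 1]] <- tibble::tibble(
        population = population, environment = environment,
        chrom = ch, peak_cM = pos,
        flank_left = mm$marker_id[il], flank_right = mm$marker_id[ir],
        start_bp = min(mm$pos_bp[c(il, ir)]),
        end_bp = max(mm$pos_bp[c(il, ir)]),
        lod = pr$lod[i], a = pr$a_hat[i], d = pr$d_hat[i],
        pve = min(max(1 - pr$rss_full[i] / rss_null, 0), 1),
        da_ratio = ga$da_ratio, gene_action = ga$gene_action
      )
    }
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out)) {
    out <- out |>
      dplyr::arrange(.data$chrom, .data$peak_cM) |>
      dplyr::mutate(qtl_id = sprintf("q%s-%d", .data$chrom,
                                     dplyr::row_number()),
                    .before = 1)
  } else {
    out <- tibble::tibble(qtl_id = character(), population = character(),
                          environment = character(), chrom = character(),
                          peak_cM = numeric(), flank_left = character(),
                          flank_right = character(), start_bp = numeric(),
                          end_bp = numeric(), lod = numeric(), a = numeric(),
                          d = numeric(), pve = numeric(),
                          da_ratio = numeric(), gene_action = character())
  }
  class(out) <- c("qtl_records", class(out))
  out
}

#' Degree of dominance and gene-action class
#'
#' `|d/a|` on the Stuber scale: additive (`a`) when the ratio is at most
#' 0.20, partial dominance (`pd`) up to 0.80, and dominant/overdominant
#' (`d`, merged) above 0.80. The ratio is classified unrounded and reported
#' rounded to 2 decimals. A zero additive effect with non-zero dominance is
#' class `d` with an infinite ratio; both zero is an error.
#'
#' @param a,d additive and dominance effects (vectorized).
#' @return tibble with `da_ratio` (2 dp) and `gene_action`.
#' @export
gene_action <- function(a, d) {
  if (any(a == 0 & d == 0)) {
    stop("gene action undefined when a and d are both zero", call. = FALSE)
  }
  ratio <- abs(d / a)
  cls <- dplyr::case_when(
    ratio <= 0.20 ~ "a",
    ratio <= 0.80 ~ "pd",
    TRUE ~ "d"
  )
  tibble::tibble(da_ratio = round(ratio, 2), gene_action = cls)
}

#' Cluster QTL records into common QTLs
#'
#' Single-linkage merge of records whose physical intervals (1-based,
#' closed) overlap on the same chromosome; the merged interval is the union
#' span. Records detected repeatedly across populations/environments thus
#' collapse into one common QTL.
#'
#' @param records a `qtl_records` tibble (needs `chrom`, `start_bp`,
#'   `end_bp`).
#' @return tibble of class `common_qtl`: `common_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_members`, `members` (list of `qtl_id`s), `populations`,
#'   `environments`.
#' @export
cluster_common_qtl <- function(records) {
  records <- tibble::as_tibble(records)
  if (!nrow(records)) stop("no QTL records to cluster", call. = FALSE)
  if (anyNA(records$start_bp) || anyNA(records$end_bp)) {
    stop("records lack physical coordinates", call. = FALSE)
  }
  out <- records |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start_bp, .by_group = TRUE) |>
    dplyr::mutate(
      cluster = cumsum(.data$start_bp > dplyr::lag(
        cummax(.data$end_bp), default = -Inf
      ))
    ) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      start_bp = min(.data$start_bp), end_bp = max(.data$end_bp),
      n_members = dplyr::n(),
      members = list(.data$qtl_id),
      populations = paste(sort(unique(stats::na.omit(.data$population))),
                          collapse = ","),
      environments = paste(sort(unique(stats::na.omit(.data$environment))),
                           collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$chrom, .data$start_bp) |>
    dplyr::mutate(common_id = sprintf("cq%s-%d", .data$chrom,
                                      dplyr::row_number()), .before = 1)
  class(out) <- c("common_qtl", class(out))
  out
}
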