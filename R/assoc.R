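#' Filter SNPs by minor allele frequency
#'
#' @param g a [geno()] object.
#' @param floor minimum MAF (computed on non-missing calls) to retain.
#' @return a [geno()] object with the passing SNPs, order preserved.
#' @export
maf_filter <- function(g, floor = 0.05) {
  fr <- maf(g)
  keep <- fr$snp_id[!is.na(fr$maf) & fr$maf >= floor]
  if (!length(keep)) stop("no SNP passes the MAF filter", call. = FALSE)
  geno_subset(g, snps = keep)
}

#' Marker-based kinship matrix
#'
#' VanRaden-type centered cross-product: dosages are mean-imputed and
#' centered by twice the allele frequency, `K = Z Z' / c` with the scale `c`
#' chosen so the mean diagonal equals 1. Monomorphic SNPs must be filtered
#' beforehand.
#'
#' @param g a [geno()] object (MAF-filtered).
#' @return symmetric line-by-line matrix with mean diagonal 1.
#' @export
kinship <- function(g) {
  d <- impute_dosage(g$dosage)
  p <- colMeans(d) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNPs present; apply maf_filter() first", call. = FALSE)
  }
  z <- sweep(d, 2, 2 * p)
  k <- tcrossprod(z)
  k / mean(diag(k))
}

#' Population-structure covariates
#'
#' Builds the three structure adjustments used in association scans: a `Q`
#' membership matrix (k-1 indicator/proportion columns derived from
#' subpopulation labels), the top principal-component scores of the centered
#' dosage matrix, and the marker [kinship()] matrix.
#'
#' @param g a [geno()] object.
#' @param subpop optional tibble `line_id`, `subpop`; when supplied, `Q` has
#'   one column per non-reference subpopulation.
#' @param n_pca number of PCA axes to keep (default 10).
#' @return list with elements `Q` (or `NULL`), `pca`, `K`.
#' @export
structure_covariates <- function(g, subpop = NULL, n_pca = 10) {
  d <- impute_dosage(g$dosage)
  Q <- NULL
  if (!is.null(subpop)) {
    subpop <- tibble::as_tibble(subpop)
    lab <- factor(subpop$subpop[match(line_ids(g), subpop$line_id)])
    mm <- stats::model.matrix(~lab)[, -1, drop = FALSE]
    colnames(mm) <- paste0("Q_", levels(lab)[-1])
    rownames(mm) <- line_ids(g)
    Q <- mm
    attr(Q, "label") <- "Q"
  }
  n_pca <- min(n_pca, nrow(d) - 1, ncol(d))
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE, rank. = n_pca)
  pca <- pc$x
  rownames(pca) <- line_ids(g)
  attr(pca, "label") <- "PCA"
  list(Q = Q, pca = pca, K = kinship(g))
}

align_y <- function(y, g) {
  if (is.data.frame(y)) {
    if (!all(c("line_id", "value") %in% names(y))) {
      stop("phenotype must have columns line_id, value (or be a named vector)",
           call. = FALSE)
    }
    y <- setNames(y$value, y$line_id)
  }
  ids <- line_ids(g)
  if (is.null(names(y))) {
    if (length(y) != length(ids)) stop("unnamed y of wrong length", call. = FALSE)
    names(y) <- ids
  }
  missing <- setdiff(ids, names(y))
  if (length(missing)) {
    stop("phenotype missing for ", length(missing), " line(s)", call. = FALSE)
  }
  y[ids]
}

covariate_matrix <- function(covariates, g) {
  if (is.null(covariates)) return(NULL)
  cm <- as.matrix(covariates)
  if (!is.null(rownames(cm))) cm <- cm[line_ids(g), , drop = FALSE]
  if (nrow(cm) != nrow(g$dosage)) {
    stop("covariate rows must match lines", call. = FALSE)
  }
  cm
}

model_tag <- function(base, covariates) {
  if (is.null(covariates)) return(base)
  lbl <- attr(covariates, "label") %||% "cov"
  paste0(base, "+", lbl)
}

# shared single-SNP OLS machinery on (possibly whitened) data.
# Returns effect/se/t/p per column of D given nuisance design X0.
single_snp_ols <- function(X0, y, D, df) {
  qx <- qr(X0)
  ry <- qr.resid(qx, y)
  rd <- qr.resid(qx, D)
  sxx <- colSums(rd^2)
  sxy <- colSums(rd * ry)
  mono <- sxx < 1e-10
  b <- ifelse(mono, 0, sxy / pmax(sxx, 1e-300))
  rss <- pmax(sum(ry^2) - b^2 * sxx, 0)
  s2 <- rss / df
  se <- ifelse(mono, NA_real_, sqrt(s2 / pmax(sxx, 1e-300)))
  tval <- ifelse(mono, 0, b / se)
  p <- ifelse(mono, 1, 2 * pt(-abs(tval), df))
  p <- pmax(p, .Machine$double.xmin)
  list(effect = b, se = se, p = p, monomorphic = mono,
       pve_vs_null = ifelse(mono, 0, b^2 * sxx / sum(ry^2)))
}

assoc_result <- function(g, model, fit) {
  fr <- maf(g)
  out <- tibble::tibble(
    snp_id = g$snps$snp_id,
    chrom = g$snps$chrom,
    pos_bp = g$snps$pos_bp,
    model = model,
    effect = unname(fit$effect),
    se = unname(fit$se),
    p_value = unname(fit$p),
    neg_log10_p = -log10(unname(fit$p)),
    maf = fr$maf,
    pve = unname(fit$pve_vs_null),
    monomorphic = unname(fit$monomorphic)
  )
  class(out) <- c("assoc_scan", class(out))
  out
}

#' Single-SNP association scan by ordinary least squares
#'
#' Regresses the phenotype on each SNP dosage in turn, adjusting for an
#' optional covariate matrix (subpopulation `Q` or principal components);
#' p-values are two-sided t-tests on the dosage coefficient. Missing dosages
#' are mean-imputed per SNP. The reported `pve` is the structure-corrected
#' variance explained, `1 - RSS1/RSS0`, with the scan covariates in both
#' models.
#'
#' @param g a [geno()] object.
#' @param y phenotype: named numeric vector or tibble `line_id`, `value`.
#' @param covariates optional line-by-covariate matrix (e.g. the `Q` or
#'   `pca` element of [structure_covariates()]).
#' @return an `assoc_scan` tibble: `snp_id`, `chrom`, `pos_bp`, `model`,
#'   `effect`, `se`, `p_value`, `neg_log10_p`, `maf`, `pve`, `monomorphic`.
#' @export
glm_scan <- function(g, y, covariates = NULL) {
  y <- align_y(y, g)
  cm <- covariate_matrix(covariates, g)
  D <- impute_dosage(g$dosage)
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), cm)
  df <- length(y) - ncol(X0) - 1
  fit <- single_snp_ols(X0, y, D, df)
  assoc_result(g, model_tag("GLM", covariates), fit)
}

#' Single-SNP mixed-linear-model scan (P3D/EMMAX)
#'
#' Fits the polygenic null model `y = X b + u + e`, `u ~ N(0, K s2_g)`, once
#' by REML (profiled over the variance ratio on the spectrum of `K`), then
#' tests each SNP by generalized least squares with the variance components
#' fixed (the P3D approximation); Wald p-values from the t distribution.
#' With a zero kinship matrix the model collapses to [glm_scan()] exactly.
#'
#' @inheritParams glm_scan
#' @param K kinship matrix (symmetric PSD), as from [kinship()].
#' @param per_snp_reml if `TRUE`, re-estimate the variance ratio under each
#'   SNP model (exact, slower).
#' @return an `assoc_scan` tibble (see [glm_scan()]).
#' @export
mlm_scan <- function(g, y, K, covariates = NULL, per_snp_reml = FALSE) {
  y <- align_y(y, g)
  cm <- covariate_matrix(covariates, g)
  D <- impute_dosage(g$dosage)
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), cm)
  n <- length(y)

  K <- K[line_ids(g), line_ids(g)]
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values), 1)) {
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  }
  dvals <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X0)
  Ds <- crossprod(U, D)

  delta <- reml_delta(ys, Xs, dvals)
  w <- sqrt(1 / (delta * dvals + 1))
  fit <- if (!per_snp_reml) {
    single_snp_ols(Xs * w, ys * w, Ds * w, n - ncol(X0) - 1)
  } else {
    cols <- seq_len(ncol(Ds))
    res <- lapply(cols, function(j) {
      dj <- reml_delta(ys, cbind(Xs, Ds[, j]), dvals)
      wj <- sqrt(1 / (dj * dvals + 1))
      f <- single_snp_ols(Xs * wj, ys * wj, Ds[, j, drop = FALSE] * wj,
                          n - ncol(X0) - 1)
      lapply(f, function(x) x[1])
    })
    lapply(setNames(names(res[[1]]), names(res[[1]])),
           function(nm) vapply(res, function(r) r[[nm]], numeric(1)))
  }
  # PVE is defined on the unwhitened scale against the structure covariates
  ols <- single_snp_ols(X0, y, D, n - ncol(X0) - 1)
  fit$pve_vs_null <- ols$pve_vs_null
  assoc_result(g, model_tag("MLM", covariates), fit)
}

# REML estimate of delta = s2_g / s2_e on the eigenspectrum of K.
reml_delta <- function(ys, Xs, dvals) {
  if (sum(dvals) < 1e-12) return(0)
  n <- length(ys)
  p <- qr(Xs)$rank
  crit <- function(log_delta) {
    delta <- exp(log_delta)
    w <- sqrt(1 / (delta * dvals + 1))
    xw <- Xs * w
    rss <- sum(qr.resid(qr(xw), ys * w)^2)
    s2 <- rss / (n - p)
    as.numeric((n - p) * log(s2) + sum(log(delta * dvals + 1)) +
                 determinant(crossprod(xw))$modulus)
  }
  opt <- optimize(crit, c(-12, 12))
  # accept a boundary solution (no or all polygenic variance) silently
  exp(opt$minimum)
}

#' Effective number of independent tests (Li-Ji)
#'
#' Per chromosome, takes the eigenvalues `lambda_i` of the SNP-SNP Pearson
#' correlation matrix and sums `f(lambda) = I(lambda >= 1) +
#' (lambda - floor(lambda))`; the genome-wide Meff is the sum over
#' chromosomes. Working chromosome-wise keeps the correlation matrices at a
#' tractable size; fully independent SNPs contribute 1 each, so Meff equals
#' the SNP count when all correlations vanish and never exceeds it.
#'
#' @param g a [geno()] object, or a numeric lines-by-SNPs matrix.
#' @param chrom optional chromosome labels when `g` is a bare matrix
#'   (default: one block).
#' @return effective test count (scalar).
#' @export
meff_li_ji <- function(g, chrom = NULL) {
  if (inherits(g, "krn_geno")) {
    d <- impute_dosage(g$dosage)
    chrom <- g$snps$chrom
  } else {
    d <- as.matrix(g)
    if (is.null(chrom)) chrom <- rep("chr1", ncol(d))
  }
  if (any(matrixStats_colVars(d) < 1e-12)) {
    stop("zero-variance SNP; filter monomorphic SNPs first", call. = FALSE)
  }
  sum(vapply(split(seq_len(ncol(d)), chrom), function(idx) {
    ev <- abs(eigen(cor(d[, idx, drop = FALSE]), symmetric = TRUE,
                    only.values = TRUE)$values)
    ev <- round(ev, 10)  # keep integer eigenvalues on the right side of floor()
    sum((ev >= 1) + (ev - floor(ev)))
  }, numeric(1)))
}

matrixStats_colVars <- function(d) {
  n <- nrow(d)
  (colSums(d^2) - n * colMeans(d)^2) / (n - 1)
}

#' Bonferroni-family significance thresholds
#'
#' For each `alpha`, returns the `-log10(p)` cutoffs `alpha / Meff`
#' (Bonferroni on the effective test count) and `alpha / (0.1 N)` (the
#' reference correction on a tenth of the marker count).
#'
#' @param meff effective number of tests (e.g. from [meff_li_ji()]).
#' @param n_snps total SNP count `N`.
#' @param alphas type-I error rates.
#' @return tibble of class `threshold_set`: `threshold` (label), `alpha`,
#'   `divisor`, `p_cutoff`, `neg_log10_p`.
#' @export
assoc_thresholds <- function(meff, n_snps, alphas = c(0.05, 0.1)) {
  stopifnot(meff > 0, n_snps > 0)
  out <- tibble::tibble(
    threshold = c(sprintf("%.2f/Meff", alphas), sprintf("%.2f/0.1N", alphas)),
    alpha = rep(alphas, 2),
    divisor = c(rep(meff, length(alphas)), rep(0.1 * n_snps, length(alphas)))
  ) |>
    dplyr::mutate(
      p_cutoff = .data$alpha / .data$divisor,
      neg_log10_p = -log10(.data$p_cutoff)
    ) |>
    dplyr::arrange(dplyr::desc(.data$neg_log10_p))
  class(out) <- c("threshold_set", class(out))
  out
}

#' Structure-corrected proportion of variance explained
#'
#' `R2 = 1 - RSS1 / RSS0`, where RSS0 is the residual sum of squares of the
#' phenotype on the structure covariates (plus intercept) and RSS1 adds the
#' SNP dosage column(s); clipped to `[0, 1]`.
#'
#' @param y phenotype: named numeric vector or tibble `line_id`, `value`.
#' @param g a [geno()] object.
#' @param snps character vector of SNP ids to fit jointly.
#' @param Q optional structure covariate matrix.
#' @return proportion in `[0, 1]`.
#' @export
pve <- function(y, g, snps, Q = NULL) {
  yv <- align_y(y, g)
  cm <- covariate_matrix(Q, g)
  X0 <- cbind(rep(1, length(yv)), cm)
  rss0 <- sum(qr.resid(qr(X0), yv)^2)
  if (rss0 <= 0) stop("null-model RSS is zero; PVE undefined", call. = FALSE)
  D <- impute_dosage(g$dosage[, snps, drop = FALSE])
  rss1 <- sum(qr.resid(qr(cbind(X0, D)), yv)^2)
  min(max(1 - rss1 / rss0, 0), 1)
}

#' Group significant SNPs into associated genomic loci
#'
#' Greedy LD clustering: the most significant unassigned SNP seeds a locus
#' and absorbs every unassigned significant SNP on the same chromosome whose
#' squared dosage correlation with the seed exceeds `r2_threshold`; repeat
#' until all are assigned. Ties in significance break by (chrom, pos).
#'
#' @param sig_snps `assoc_scan` rows deemed significant (may carry an
#'   `environment` column; duplicated SNPs keep their best record).
#' @param g a [geno()] object containing the SNPs.
#' @param r2_threshold LD threshold (membership requires `r2 >` this value).
#' @return tibble of class `assoc_loci`: `locus_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `seed_snp`, `max_pve`, `environments`, `members`
#'   (list column of member tibbles).
#' @export
group_loci <- function(sig_snps, g, r2_threshold = 0.2) {
  sig <- tibble::as_tibble(sig_snps)
  if (!nrow(sig)) stop("no significant SNPs to group", call. = FALSE)
  if (!"environment" %in% names(sig)) sig$environment <- NA_character_
  env_of <- sig |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(environments = paste(
      sort(unique(stats::na.omit(.data$environment))), collapse = ","
    ))
  sig <- sig |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::slice_max(.data$neg_log10_p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::left_join(env_of, by = "snp_id") |>
    dplyr::arrange(dplyr::desc(.data$neg_log10_p), .data$chrom, .data$pos_bp)
  d <- impute_dosage(g$dosage[, sig$snp_id, drop = FALSE])

  assigned <- rep(FALSE, nrow(sig))
  loci <- list()
  while (!all(assigned)) {
    seed <- which(!assigned)[1]
    cand <- which(!assigned & sig$chrom == sig$chrom[seed])
    r2 <- as.vector(cor(d[, seed], d[, cand, drop = FALSE]))^2
    take <- cand[r2 > r2_threshold | cand == seed]
    assigned[take] <- TRUE
    mem <- sig[take, c("snp_id", "pos_bp", "neg_log10_p", "pve")]
    loci[[length(loci) + 1]] <- tibble::tibble(
      chrom = sig$chrom[seed],
      start_bp = min(mem$pos_bp), end_bp = max(mem$pos_bp),
      n_snps = nrow(mem),
      seed_snp = sig$snp_id[seed],
      max_pve = if (all(is.na(mem$pve))) NA_real_ else max(mem$pve, na.rm = TRUE),
      environments = paste(sort(unique(unlist(
        strsplit(sig$environments[take], ",")
      ))), collapse = ","),
      members = list(mem)
    )
  }
  out <- dplyr::bind_rows(loci) |>
    dplyr::arrange(.data$chrom, .data$start_bp) |>
    dplyr::mutate(locus_id = sprintf("locus_%02d", dplyr::row_number()),
                  .before = 1)
  class(out) <- c("assoc_loci", class(out))
  out
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(chisq(p)) / qchisq(0.5, 1)` over the scan's p-values;
#' a quality-control diagnostic (about 1 for a well-calibrated scan).
#'
#' @param p numeric vector of p-values.
#' @return scalar inflation factor.
#' @export
lambda_gc <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, 1)
}
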