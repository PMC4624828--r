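#' Ridge-regression BLUP of marker effects
#'
#' Fits `y = 1 mu + M u + e` with `u ~ N(0, I s2_u)`, `e ~ N(0, I s2_e)`.
#' Marker columns are centered by their training means. Variance components
#' are estimated by REML profiled over the ratio on the eigenvalue spectrum
#' of `M M'` (the equivalent GBLUP kinship), so no per-iteration inversion is
#' needed; effects are then recovered through the ridge identity
#' `u = M' (M M' + lambda I)^{-1} (y - 1 mu)`, `lambda = s2_e / s2_u`.
#'
#' @param M training lines-by-markers dosage matrix (0/1/2 coding; hybrids
#'   as 1 at heterozygous SNPs), or a [geno()] object.
#' @param y training phenotypes: named vector or tibble `line_id`, `value`.
#' @param lambda optional fixed ridge parameter; skips REML when given.
#' @return object of class `rrblup`: `mu`, `effects` (named), `sigma2_u`,
#'   `sigma2_e`, `lambda`, `center`, `marker_ids`, `line_ids`, `fitted`.
#' @export
rrblup <- function(M, y, lambda = NULL) {
  if (inherits(M, "krn_geno")) M <- M$dosage
  M <- as.matrix(M)
  if (is.data.frame(y)) y <- setNames(y$value, y$line_id)
  if (!is.null(names(y)) && !is.null(rownames(M))) y <- y[rownames(M)]
  n <- nrow(M)
  if (n < 2) stop("need at least two training lines", call. = FALSE)
  if (anyNA(y)) stop("training phenotypes contain NA", call. = FALSE)
  center <- colMeans(M, na.rm = TRUE)
  Z <- sweep(impute_dosage(M), 2, center)

  if (sum(Z^2) == 0) stop("all-zero marker matrix after centering", call. = FALSE)
  if (var(y) < 1e-12) {
    # constant phenotype: intercept only, effects collapse to zero
    return(new_rrblup(mean(y), rep(0, ncol(Z)), 1e-12, 0, Inf, center, M, y,
                      rep(mean(y), n)))
  }

  G <- tcrossprod(Z)
  if (is.null(lambda)) {
    eig <- eigen(G, symmetric = TRUE)
    dvals <- pmax(eig$values, 0)
    ys <- drop(crossprod(eig$vectors, y))
    Xs <- crossprod(eig$vectors, matrix(1, n, 1))
    delta <- reml_delta(ys, Xs, dvals)        # delta = s2_u / s2_e
    w <- 1 / (delta * dvals + 1)
    mu <- sum(w * Xs * ys) / sum(w * Xs^2)
    rss <- sum(w * (ys - Xs * mu)^2)
    sigma2_e <- rss / (n - 1)
    sigma2_u <- delta * sigma2_e
    lambda <- if (delta > 0) 1 / delta else Inf
  } else {
    mu <- gls_intercept(G, lambda, y)
    sigma2_u <- NA_real_
    sigma2_e <- NA_real_
  }
  if (is.finite(lambda)) {
    alpha <- solve(G + lambda * diag(n), y - mu)
    u <- drop(crossprod(Z, alpha))
    fitted <- mu + drop(G %*% alpha)
  } else {
    u <- rep(0, ncol(Z))
    fitted <- rep(mu, n)
  }
  new_rrblup(mu, u, sigma2_u, sigma2_e, lambda, center, M, y, fitted)
}

gls_intercept <- function(G, lambda, y) {
  vinv_1 <- solve(G + lambda * diag(nrow(G)), rep(1, nrow(G)))
  sum(vinv_1 * y) / sum(vinv_1)
}

new_rrblup <- function(mu, u, s2u, s2e, lambda, center, M, y, fitted) {
  ids <- colnames(M) %||% sprintf("m%d", seq_along(u))
  structure(list(
    mu = unname(mu),
    effects = setNames(u, ids),
    sigma2_u = s2u, sigma2_e = s2e, lambda = lambda,
    center = setNames(center, ids),
    marker_ids = ids,
    line_ids = rownames(M),
    fitted = setNames(fitted, rownames(M)),
    y = y
  ), class = "rrblup")
}

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf(
    "<rrblup> %d markers, %d training lines; lambda = %.4g (s2_u = %.4g, s2_e = %.4g)\n",
    length(x$effects), length(x$fitted), x$lambda, x$sigma2_u, x$sigma2_e
  ))
  invisible(x)
}

#' Predict line values from an RR-BLUP fit
#'
#' `yhat = mu + M_new u`, with `M_new` centered by the training column
#' means; hybrids (dosage 1 at heterozygous SNPs) share the additive coding.
#'
#' @param object an [rrblup()] fit.
#' @param newdata lines-by-markers matrix or [geno()] object whose columns
#'   cover the fit's markers.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.rrblup <- function(object, newdata, ...) {
  if (inherits(newdata, "krn_geno")) newdata <- newdata$dosage
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$marker_ids, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks fitted markers: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  }
  Z <- sweep(impute_dosage(newdata[, object$marker_ids, drop = FALSE]),
             2, object$center)
  drop(object$mu + Z %*% object$effects)
}

#' @describeIn rrblup one row per marker effect.
#' @param x an `rrblup` object.
#' @param ... unused.
#' @method tidy rrblup
#' @export
tidy.rrblup <- function(x, ...) {
  tibble::tibble(marker_id = x$marker_ids, effect = unname(x$effects))
}

#' @describeIn rrblup one-row model summary.
#' @method glance rrblup
#' @export
glance.rrblup <- function(x, ...) {
  tibble::tibble(
    n_markers = length(x$effects), n_train = length(x$fitted),
    mu = x$mu, sigma2_u = x$sigma2_u, sigma2_e = x$sigma2_e,
    lambda = x$lambda
  )
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted and observed values.
#'
#' @param pred,obs numeric vectors (aligned; named vectors are matched by
#'   name when both carry names).
#' @return correlation in `[-1, 1]`.
#' @export
accuracy <- function(pred, obs) {
  if (!is.null(names(pred)) && !is.null(names(obs))) {
    common <- intersect(names(pred), names(obs))
    pred <- pred[common]
    obs <- obs[common]
  }
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 3) stop("need at least 3 prediction pairs", call. = FALSE)
  if (var(pred[ok]) == 0 || var(obs[ok]) == 0) {
    stop("zero variance; accuracy undefined", call. = FALSE)
  }
  cor(pred[ok], obs[ok])
}

#' Marker sets from the tagSNP bank
#'
#' Strategy `"top"` takes the first `k` tags of the significance-sorted bank
#' (deterministic); strategy `"random"` draws `k` tags without replacement,
#' `n_samplings` times per size.
#'
#' @param bank a [build_bank()] result (or its `bank` tibble).
#' @param sizes marker-set sizes.
#' @param strategy `"top"` or `"random"`.
#' @param n_samplings inner samplings per size for `"random"`.
#' @param seed integer seed (random strategy).
#' @return tibble `strategy`, `size`, `sampling`, `snp_ids` (list column).
#' @export
make_marker_sets <- function(bank, sizes, strategy = c("top", "random"),
                             n_samplings = 5, seed = 1L) {
  strategy <- match.arg(strategy)
  if (inherits(bank, "tagsnp_bank")) bank <- bank$bank
  if (any(sizes > nrow(bank))) {
    stop("marker-set size exceeds bank size (", nrow(bank), ")", call. = FALSE)
  }
  if (strategy == "top") {
    tibble::tibble(
      strategy = "top", size = as.integer(sizes), sampling = 1L,
      snp_ids = lapply(sizes, function(k) bank$snp_id[seq_len(k)])
    )
  } else {
    set.seed(seed)
    tidyr::expand_grid(size = as.integer(sizes),
                       sampling = seq_len(n_samplings)) |>
      dplyr::mutate(
        strategy = "random", .before = 1,
        snp_ids = lapply(.data$size, function(k) sample(bank$snp_id, k))
      )
  }
}

#' Design of a whole-genome prediction experiment
#'
#' Captures the marker-set strategies and sizes, the training-set rule and
#' the validation-population rule of a prediction run.
#'
#' @param strategies subset of `c("top", "random")`.
#' @param sizes marker-set sizes to evaluate.
#' @param n_repeats outer repetitions (training/validation redraws).
#' @param n_samplings inner samplings per size for the random strategy.
#' @param ts_spec training-set rule: `list(type = "random_half")`,
#'   `list(type = "fixed_size", k = 100)` or
#'   `list(type = "subpop", label = "pop1")`.
#' @param vp_spec validation rule: `list(type = "holdout")` (panel complement
#'   of the TS), optionally `list(type = "subpop", label = "pop2")`.
#' @param predict_hybrids also predict the hybrid set when one is supplied.
#' @param seed integer seed.
#' @return list of class `experiment_design`.
#' @export
experiment_design <- function(strategies = c("top", "random"),
                              sizes = c(17, 300, 1000),
                              n_repeats = 100, n_samplings = 5,
                              ts_spec = list(type = "random_half"),
                              vp_spec = list(type = "holdout"),
                              predict_hybrids = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "experiment_design")
}

draw_ts <- function(ids, subpop, ts_spec) {
  pool <- ids
  if (identical(ts_spec$type, "subpop")) {
    pool <- subpop$line_id[subpop$subpop == ts_spec$label]
  }
  k <- switch(ts_spec$type,
    random_half = floor(length(pool) / 2),
    fixed_size = ts_spec$k,
    subpop = floor(length(pool) / 2),
    stop("unknown ts_spec type", call. = FALSE)
  )
  sample(pool, k)
}

draw_vp <- function(ids, ts, subpop, vp_spec) {
  vp <- switch(vp_spec$type,
    holdout = setdiff(ids, ts),
    subpop = setdiff(subpop$line_id[subpop$subpop == vp_spec$label], ts),
    stop("unknown vp_spec type", call. = FALSE)
  )
  if (length(intersect(vp, ts))) stop("TS and VP overlap", call. = FALSE)
  vp
}

#' Run a marker-set / training-set prediction experiment
#'
#' For each outer repeat, draws a training set and validation population per
#' the design, then for every marker set fits [rrblup()] on the training
#' lines and records the Pearson [accuracy()] on the validation lines (and
#' on the hybrid set, when given) for every phenotype column. Random-strategy
#' accuracies are averaged over the inner samplings within a repeat; the
#' curves report the mean and sd over repeats.
#'
#' @param g panel [geno()] object.
#' @param bank a [build_bank()] result.
#' @param phenos tibble with `line_id` plus one column per phenotype
#'   (environment means and/or BLUP).
#' @param design an [experiment_design()].
#' @param hybrids optional list with elements `geno` ([geno()]) and `y`
#'   (named vector or tibble `line_id`, `value`) for hybrid validation.
#' @param subpop optional tibble `line_id`, `subpop` for subpopulation
#'   training/validation rules.
#' @return tibble of class `pred_curves`: `strategy`, `size`, `phenotype`,
#'   `mean_r`, `sd_r`, `n_repeats`.
#' @export
run_experiment <- function(g, bank, phenos, design, hybrids = NULL,
                           subpop = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  phenos <- tibble::as_tibble(phenos)
  pheno_cols <- setdiff(names(phenos), "line_id")
  ids <- intersect(line_ids(g), phenos$line_id)
  ymat <- as.matrix(phenos[match(ids, phenos$line_id), pheno_cols,
                           drop = FALSE])
  rownames(ymat) <- ids
  hy <- NULL
  if (!is.null(hybrids) && design$predict_hybrids) {
    hy <- hybrids$y
    if (is.data.frame(hy)) hy <- setNames(hy$value, hy$line_id)
  }

  sets <- dplyr::bind_rows(lapply(design$strategies, function(s) {
    make_marker_sets(bank, design$sizes, s,
                     n_samplings = design$n_samplings,
                     seed = sample.int(2^30, 1))
  }))

  per_repeat <- lapply(seq_len(design$n_repeats), function(rep_i) {
    ts <- draw_ts(ids, subpop, design$ts_spec)
    vp <- draw_vp(ids, ts, subpop, design$vp_spec)
    res <- purrr::pmap_dfr(sets, function(strategy, size, sampling, snp_ids) {
      Mtr <- g$dosage[ts, snp_ids, drop = FALSE]
      rows <- lapply(pheno_cols, function(ph) {
        ytr <- ymat[ts, ph]
        keep <- !is.na(ytr)
        fit <- rrblup(Mtr[keep, , drop = FALSE], ytr[keep])
        out <- list(tibble::tibble(
          strategy = strategy, size = size, sampling = sampling,
          phenotype = ph,
          r = accuracy(predict(fit, g$dosage[vp, snp_ids, drop = FALSE]),
                       ymat[vp, ph])
        ))
        if (!is.null(hy)) {
          out <- c(out, list(tibble::tibble(
            strategy = strategy, size = size, sampling = sampling,
            phenotype = paste0("hybrids:", ph),
            r = accuracy(
              predict(fit, hybrids$geno$dosage[, snp_ids, drop = FALSE]), hy
            )
          )))
        }
        dplyr::bind_rows(out)
      })
      dplyr::bind_rows(rows)
    })
    res |>
      dplyr::group_by(.data$strategy, .data$size, .data$phenotype) |>
      dplyr::summarise(r = mean(.data$r), .groups = "drop") |>
      dplyr::mutate(repeat_i = rep_i)
  })

  out <- dplyr::bind_rows(per_repeat) |>
    dplyr::group_by(.data$strategy, .data$size, .data$phenotype) |>
    dplyr::summarise(
      mean_r = mean(.data$r), sd_r = sd(.data$r),
      n_repeats = dplyr::n(), .groups = "drop"
    )
  attr(out, "per_repeat") <- dplyr::bind_rows(per_repeat)
  class(out) <- c("pred_curves", class(out))
  out
}
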