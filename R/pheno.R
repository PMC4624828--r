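#' Per-environment means and across-environment BLUP of line values
#'
#' Replicates are first averaged within (line, environment); the line value
#' across environments is then the best linear unbiased prediction from the
#' mixed model `value ~ environment (fixed) + line (random)`, fitted by REML
#' (lme4). The returned `blup` is on the trait scale: the fixed-effect grand
#' mean (averaged over environment levels) plus the line's predicted random
#' effect, so it is directly comparable with environment means. With a single
#' environment the BLUP falls back to the line mean.
#'
#' @param tab tibble with columns `line_id`, `environment`, `replicate`,
#'   `value`.
#' @return tibble with one row per line: `line_id`, `n_env_observed`, `blup`,
#'   and one `mean_<environment>` column per environment.
#' @export
env_means_and_blup <- function(tab) {
  tab <- check_pheno(tab)
  cell <- tab |>
    dplyr::group_by(.data$line_id, .data$environment) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  wide <- cell |>
    dplyr::mutate(environment = paste0("mean_", .data$environment)) |>
    tidyr::pivot_wider(names_from = "environment", values_from = "value")
  n_env <- dplyr::count(cell, .data$line_id, name = "n_env_observed")

  if (dplyr::n_distinct(cell$environment) < 2) {
    blup <- cell |> dplyr::group_by(.data$line_id) |>
      dplyr::summarise(blup = mean(.data$value))
  } else {
    fit <- lme4::lmer(value ~ environment + (1 | line_id), data = cell,
                      REML = TRUE)
    fe <- lme4::fixef(fit)
    env_fe <- c(0, fe[-1])                      # effect of each env level
    grand <- unname(fe[1] + mean(env_fe))
    re <- lme4::ranef(fit)$line_id
    blup <- tibble::tibble(line_id = rownames(re),
                           blup = grand + re[["(Intercept)"]])
  }
  wide |>
    dplyr::left_join(n_env, by = "line_id") |>
    dplyr::left_join(blup, by = "line_id") |>
    dplyr::relocate("line_id", "n_env_observed", "blup")
}

check_pheno <- function(tab) {
  tab <- tibble::as_tibble(tab)
  need <- c("line_id", "environment", "value")
  if (!all(need %in% names(tab))) {
    stop("phenotype table needs columns line_id, environment, value",
         call. = FALSE)
  }
  bad <- !is.finite(tab$value)
  if (any(bad)) {
    warning(sum(bad), " non-finite phenotype value(s) dropped")
    tab <- tab[!bad, ]
  }
  if (!nrow(tab)) stop("no usable phenotype records", call. = FALSE)
  tab
}

#' Variance components of a replicated multi-environment trial
#'
#' Fits `value ~ environment (fixed) + (1|line) + (1|line:environment)` by
#' REML (lme4) on replicate-level data and returns the genetic, genotype-by-
#' environment and residual variance components. For balanced data an
#' expected-mean-squares ANOVA estimator is available as a cross-check
#' (`method = "anova"`): `s2_e = MSE`, `s2_ge = (MS_int - MSE) / r`,
#' `s2_g = (MS_line - MS_int) / (n r)`, truncated at zero. With a single
#' environment or a single replicate the interaction is not identifiable and
#' `sigma2_ge` is returned as `NA`.
#'
#' @param tab tibble with columns `line_id`, `environment`, `replicate`,
#'   `value`.
#' @param method `"reml"` (default) or `"anova"` (balanced data only).
#' @return list of class `variance_components`: `sigma2_g`, `sigma2_ge`,
#'   `sigma2_e`, `n_env`, `n_reps`, `method`.
#' @export
variance_components <- function(tab, method = c("reml", "anova")) {
  method <- match.arg(method)
  tab <- check_pheno(tab)
  n_env <- dplyr::n_distinct(tab$environment)
  n_reps <- tab |>
    dplyr::count(.data$line_id, .data$environment) |>
    dplyr::pull(.data$n) |> mean()
  has_int <- n_env > 1 && n_reps > 1

  if (method == "anova") {
    tab$line_id <- factor(tab$line_id)
    tab$environment <- factor(tab$environment)
    r <- round(n_reps)
    if (has_int) {
      ms <- anova(aov(value ~ environment + line_id + line_id:environment,
                      data = tab))[, "Mean Sq"]
      # rows: environment, line, line:environment, residual
      s2_e <- ms[4]
      s2_ge <- max((ms[3] - ms[4]) / r, 0)
      s2_g <- max((ms[2] - ms[3]) / (n_env * r), 0)
    } else {
      ms <- anova(aov(value ~ environment + line_id, data = tab))[, "Mean Sq"]
      s2_e <- ms[3]
      s2_ge <- NA_real_
      s2_g <- max((ms[2] - ms[3]) / (n_env * r), 0)
    }
  } else {
    if (has_int) {
      fit <- suppressMessages(lme4::lmer(
        value ~ environment + (1 | line_id) + (1 | line_id:environment),
        data = tab, REML = TRUE
      ))
      vc <- as.data.frame(lme4::VarCorr(fit))
      s2_g <- vc$vcov[vc$grp == "line_id"]
      s2_ge <- vc$vcov[vc$grp == "line_id:environment"]
      s2_e <- vc$vcov[vc$grp == "Residual"]
    } else {
      fit <- suppressMessages(lme4::lmer(
        value ~ environment + (1 | line_id), data = tab, REML = TRUE
      ))
      vc <- as.data.frame(lme4::VarCorr(fit))
      s2_g <- vc$vcov[vc$grp == "line_id"]
      s2_ge <- NA_real_
      s2_e <- vc$vcov[vc$grp == "Residual"]
    }
  }
  structure(list(sigma2_g = unname(s2_g), sigma2_ge = unname(s2_ge),
                 sigma2_e = unname(s2_e), n_env = n_env,
                 n_reps = n_reps, method = method),
            class = "variance_components")
}

#' Repeatability across environments and replicates
#'
#' `H2 = s2_g / (s2_g + s2_e / (n r))` where `n` is the number of
#' environments and `r` the number of replicates; the genotype-by-environment
#' component does not enter this definition.
#'
#' @param vc a [variance_components()] object, or a list with fields
#'   `sigma2_g`, `sigma2_e`, `n_env`, `n_reps`.
#' @return repeatability in `[0, 1]`.
#' @export
repeatability <- function(vc) {
  check_vc(vc, need_ge = FALSE)
  denom <- vc$sigma2_g + vc$sigma2_e / (vc$n_env * vc$n_reps)
  if (denom == 0) stop("all variance components are zero", call. = FALSE)
  vc$sigma2_g / denom
}

#' Broad-sense heritability on a family-mean basis
#'
#' `Hb2 = s2_g / (s2_g + s2_ge / n + s2_e / (n r))`.
#'
#' @inheritParams repeatability
#' @return heritability in `[0, 1]`.
#' @export
broad_sense_h2 <- function(vc) {
  check_vc(vc, need_ge = TRUE)
  denom <- vc$sigma2_g + vc$sigma2_ge / vc$n_env +
    vc$sigma2_e / (vc$n_env * vc$n_reps)
  if (denom == 0) stop("all variance components are zero", call. = FALSE)
  vc$sigma2_g / denom
}

check_vc <- function(vc, need_ge) {
  need <- c("sigma2_g", "sigma2_e", "n_env", "n_reps")
  if (need_ge) need <- c(need, "sigma2_ge")
  if (!all(need %in% names(vc))) {
    stop("variance components need fields ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(vc[need])
  if (anyNA(vals)) stop("variance component is NA", call. = FALSE)
  if (any(vals < 0)) stop("negative variance component", call. = FALSE)
  if (vc$n_env < 1 || vc$n_reps < 1) {
    stop("n_env and n_reps must be >= 1", call. = FALSE)
  }
  invisible(vc)
}
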