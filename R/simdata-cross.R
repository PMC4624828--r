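#' Simulate an F2:3 mapping population
#'
#' Crosses two homozygous parents, selfs the F1, and genotypes each F2 plant
#' at the map markers; the phenotype attached to each F2 is the mean of its
#' selfed F3 family. At a causal locus with additive effect `a` and dominance
#' `d`, the F2:3 family-mean genotypic value is `a*x + d*h/2` with
#' `x in \{-1, 0, +1\}` (count of high-parent alleles minus 1) and `h` the F2
#' heterozygosity indicator — random selfing halves the dominance deviation
#' relative to the F2 plant itself. Environment effects and a residual with
#' standard deviation `resid_sd / sqrt(n_reps)` (replicate means) are added.
#'
#' @param parents a [geno()] object (or subset) containing exactly the two
#'   parent lines, homozygous at every marker; the first row is the
#'   high-trait parent (allele coded `A`).
#' @param map a [genetic_map()] whose `marker_id`s name columns of `parents`.
#' @param arch architecture tibble (`snp_id`, `a`, `d`) with attribute `mu`;
#'   causal ids must be map markers.
#' @param n_families number of F2 plants (= F2:3 families).
#' @param n_env,n_reps phenotyping layout.
#' @param env_effect_sd,resid_sd noise standard deviations (trait units).
#' @param seed integer seed.
#' @return list of class `f23_pop`: `parent_ids`, `map`, `genotypes`
#'   (families x markers, codes `"AA"`, `"AB"`, `"BB"`), `family_means`
#'   (tibble `family`, `environment`, `value`), `n_reps`, `truth`.
#' @export
simulate_f23 <- function(parents, map, arch, n_families,
                         n_env = 1, n_reps = 3,
                         env_effect_sd = 0.3, resid_sd = 1.0, seed = 1L) {
  stopifnot(inherits(parents, "krn_geno"), nrow(parents$dosage) == 2)
  set.seed(seed)
  d <- parents$dosage[, map$marker_id, drop = FALSE]
  if (anyNA(d) || !all(d %in% c(0, 2))) {
    stop("parents must be homozygous (dosage 0 or 2) at all markers",
         call. = FALSE)
  }
  # haplotype alleles: 1 = allele from the high parent (row 1), 0 otherwise.
  # The F1 is heterozygous wherever the parents differ; where they agree the
  # locus is monomorphic and every descendant keeps that genotype.
  hap_high <- rep(1, nrow(map))
  hap_low <- ifelse(d[1, ] == d[2, ], 1, 0)

  geno_codes <- matrix("AA", n_families, nrow(map),
                       dimnames = list(sprintf("F%03d", seq_len(n_families)),
                                       map$marker_id))
  n_high <- matrix(0L, n_families, nrow(map))
  for (i in seq_len(n_families)) {
    g1 <- meiosis_gamete(hap_high, hap_low, map)
    g2 <- meiosis_gamete(hap_high, hap_low, map)
    n_high[i, ] <- as.integer(g1 + g2)
  }
  geno_codes[] <- c("BB", "AB", "AA")[n_high + 1L]

  mu <- attr(arch, "mu") %||% 0
  gv <- rep(mu, n_families)
  if (nrow(arch) > 0) {
    if (!all(arch$snp_id %in% map$marker_id)) {
      stop("architecture loci must be map markers", call. = FALSE)
    }
    idx <- match(arch$snp_id, map$marker_id)
    x <- n_high[, idx, drop = FALSE] - 1
    h <- (n_high[, idx, drop = FALSE] == 1) + 0
    gv <- gv + drop(x %*% arch$a) + drop(h %*% (arch$d / 2))
  }

  env_labels <- sprintf("env%d", seq_len(n_env))
  env_eff <- setNames(rnorm(n_env, 0, env_effect_sd), env_labels)
  fm <- tidyr::expand_grid(family = rownames(geno_codes),
                           environment = env_labels)
  fm$value <- gv[match(fm$family, rownames(geno_codes))] +
    env_eff[fm$environment] +
    rnorm(nrow(fm), 0, resid_sd / sqrt(n_reps))

  structure(list(
    parent_ids = rownames(parents$dosage),
    map = map,
    genotypes = geno_codes,
    family_means = fm,
    n_reps = n_reps,
    truth = list(architecture = arch, genetic_values = gv,
                 env_effects = env_eff, seed = seed)
  ), class = "f23_pop")
}

#' Simulate biparental single-cross hybrids
#'
#' Each hybrid's dosage is the parental mean, `(d_p1 + d_p2) / 2` per SNP
#' (1 wherever the inbred parents differ); its phenotype comes from the
#' additive-plus-dominance architecture with Gaussian noise.
#'
#' @param panel a [geno()] object of inbred lines.
#' @param parent_pairs tibble/data frame with columns `p1`, `p2` (line ids).
#' @param arch architecture tibble (`snp_id`, `a`, `d`) with attribute `mu`.
#' @param noise_sd phenotype noise standard deviation (trait units).
#' @param seed integer seed.
#' @return list of class `hybrid_sim`: `geno` ([geno()] with
#'   `ploidy_class = "hybrid"`), `pheno` (tibble `line_id`, `environment`,
#'   `replicate`, `value`), `parent_pairs`.
#' @export
simulate_hybrids <- function(panel, parent_pairs, arch,
                             noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(panel, "krn_geno"))
  set.seed(seed)
  parent_pairs <- tibble::as_tibble(parent_pairs)
  unknown <- setdiff(unique(c(parent_pairs$p1, parent_pairs$p2)),
                     line_ids(panel))
  if (length(unknown)) {
    stop("unknown parent id(s): ", paste(head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  d <- (panel$dosage[parent_pairs$p1, , drop = FALSE] +
          panel$dosage[parent_pairs$p2, , drop = FALSE]) / 2
  rownames(d) <- sprintf("%s_x_%s", parent_pairs$p1, parent_pairs$p2)
  hg <- geno(d, panel$snps, "hybrid")
  gv <- genetic_value(hg, arch)
  pheno <- tibble::tibble(
    line_id = rownames(d), environment = "env1", replicate = 1L,
    value = gv + rnorm(nrow(d), 0, noise_sd)
  )
  structure(list(geno = hg, pheno = pheno, parent_pairs = parent_pairs),
            class = "hybrid_sim")
}
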