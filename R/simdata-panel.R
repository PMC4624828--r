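#' Configuration for the synthetic association panel
#'
#' Defaults emulate a diverse maize inbred panel of the kind used for kernel
#' row number association mapping: 513 lines in four subpopulations, ten
#' chromosomes carrying roughly 49,000 SNPs, a trait controlled by a few tens
#' of loci with mostly low-frequency positive alleles, phenotyped in five
#' environments with two replicates at a repeatability near 0.94. Tests and
#' examples override `n_lines`/`snps_per_chrom` downwards; the statistical
#' structure is unchanged.
#'
#' Subpopulation allele frequencies follow a Balding-Nichols model around a
#' shared ancestral frequency with divergence `fst`; linkage disequilibrium
#' comes from a Markov haplotype-copying model over `n_founders` founder
#' haplotypes per subpopulation, with a copying-switch rate of `ld_decay_rho`
#' per bp (larger values mean faster LD decay).
#'
#' @param n_lines number of inbred lines.
#' @param n_subpops number of subpopulations.
#' @param subpop_proportions simplex weights, one per subpopulation.
#' @param fst Balding-Nichols divergence, in (0, 1).
#' @param n_chrom,snps_per_chrom,chrom_length_bp genome layout.
#' @param ld_decay_rho per-bp haplotype-copying switch rate.
#' @param n_founders founder haplotypes per subpopulation.
#' @param n_qtl number of causal SNPs.
#' @param qtl_effect_scheme list: `type` `"geometric"` (fields `scale`,
#'   `ratio`; the j-th absolute effect is `scale * ratio^(j-1)`) or
#'   `"normal"` (field `sd`).
#' @param qtl_maf_range numeric length 2; causal SNPs are sampled among SNPs
#'   whose realized MAF falls in this range (low-frequency large effects).
#' @param mu trait intercept (rows/ear).
#' @param n_env,n_reps phenotyping layout.
#' @param target_repeatability if non-`NULL`, `gxe_sd` and `resid_sd` are
#'   jointly rescaled so the expected repeatability
#'   `Vg / (Vg + Vge/n + Ve/(n r))` equals this value given the realized
#'   genetic variance.
#' @param env_effect_sd,gxe_sd,resid_sd standard deviations (trait units) of
#'   environment main effects, line-by-environment interaction, and
#'   replicate-level residual.
#' @param seed integer seed; all randomness derives from it.
#' @return a `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_lines = 513, n_subpops = 4,
                             subpop_proportions = NULL, fst = 0.2,
                             n_chrom = 10, snps_per_chrom = 4896,
                             chrom_length_bp = 2.3e8,
                             ld_decay_rho = 2e-6, n_founders = 40,
                             n_qtl = 30,
                             qtl_effect_scheme = list(
                               type = "geometric", scale = 0.8, ratio = 0.92
                             ),
                             qtl_maf_range = c(0.05, 0.3),
                             mu = 13.3,
                             n_env = 5, n_reps = 2,
                             target_repeatability = 0.94,
                             env_effect_sd = 0.5, gxe_sd = 0.3,
                             resid_sd = 1.0, seed = 1L) {
  if (is.null(subpop_proportions)) {
    subpop_proportions <- rep(1 / n_subpops, n_subpops)
  }
  if (length(subpop_proportions) != n_subpops ||
      abs(sum(subpop_proportions) - 1) > 1e-8) {
    stop("subpop_proportions must be a length-n_subpops simplex", call. = FALSE)
  }
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)", call. = FALSE)
  if (n_qtl > n_chrom * snps_per_chrom) {
    stop("n_qtl exceeds the number of SNPs", call. = FALSE)
  }
  if (!is.null(target_repeatability) &&
      (target_repeatability <= 0 || target_repeatability > 1)) {
    stop("target_repeatability must lie in (0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "panel_sim_config")
}

# mosaic of founder haplotypes: founder index is a Markov chain along the
# chromosome with switch probability 1 - exp(-rho * gap_bp)
copy_haplotype <- function(founders, pos_bp, rho) {
  p_switch <- 1 - exp(-rho * diff(pos_bp))
  n_f <- nrow(founders)
  switches <- c(TRUE, runif(length(p_switch)) < p_switch)
  seg_id <- cumsum(switches)
  seg_founder <- sample.int(n_f, max(seg_id), replace = TRUE)
  founders[cbind(seg_founder[seg_id], seq_along(pos_bp))]
}

#' Simulate a structured inbred association panel
#'
#' Generates fully homozygous line genotypes with subpopulation structure
#' (Balding-Nichols allele frequencies) and tunable LD (founder-haplotype
#' copying), plants an additive trait architecture on low-frequency SNPs,
#' and phenotypes every line in `n_env` environments with `n_reps`
#' replicates. The additive genetic value uses the \{-1, +1\} scaling of
#' homozygote dosage, `g = mu + sum_j a_j x_j` with `x = dosage - 1`.
#'
#' @param config a [panel_sim_config()].
#' @return list of class `panel_sim` with elements
#'   * `geno`: [geno()] object (inbred),
#'   * `architecture`: tibble of causal SNPs (`snp_id`, `a`, `d`) plus
#'     attribute `mu`,
#'   * `pheno`: tibble `line_id`, `environment`, `replicate`, `value`,
#'   * `truth`: list with `subpop` (tibble `line_id`, `subpop`),
#'     `env_effects`, realized variance pieces and the config.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  n_snp_total <- config$n_chrom * config$snps_per_chrom

  snps <- tibble::tibble(
    chrom = rep(sprintf("chr%d", seq_len(config$n_chrom)),
                each = config$snps_per_chrom),
    pos_bp = as.vector(vapply(
      seq_len(config$n_chrom),
      function(i) sort(sample.int(config$chrom_length_bp,
                                  config$snps_per_chrom)),
      numeric(config$snps_per_chrom)
    ))
  )
  snps$snp_id <- sprintf("%s_%d", snps$chrom, snps$pos_bp)
  snps <- snps[, c("snp_id", "chrom", "pos_bp")]
  snps$ref <- "A"
  snps$alt <- "B"

  # Balding-Nichols subpopulation frequencies around a shared ancestral p
  p_anc <- runif(n_snp_total, 0.1, 0.9)
  shape <- (1 - config$fst) / config$fst
  p_sub <- vapply(
    seq_len(config$n_subpops),
    function(k) stats::rbeta(n_snp_total, p_anc * shape, (1 - p_anc) * shape),
    numeric(n_snp_total)
  )

  subpop <- sample(rep(seq_len(config$n_subpops),
                       times = round(config$subpop_proportions * config$n_lines))
                   [seq_len(config$n_lines)])
  subpop[is.na(subpop)] <- config$n_subpops

  chrom_idx <- split(seq_len(n_snp_total), snps$chrom)
  founders <- lapply(seq_len(config$n_subpops), function(k) {
    matrix(as.integer(runif(config$n_founders * n_snp_total) < rep(
      p_sub[, k], each = config$n_founders
    )), nrow = config$n_founders)
  })

  dosage <- matrix(0L, config$n_lines, n_snp_total,
                   dimnames = list(sprintf("L%03d", seq_len(config$n_lines)),
                                   snps$snp_id))
  for (i in seq_len(config$n_lines)) {
    f <- founders[[subpop[i]]]
    hap <- numeric(n_snp_total)
    for (idx in chrom_idx) {
      hap[idx] <- copy_haplotype(f[, idx, drop = FALSE], snps$pos_bp[idx],
                                 config$ld_decay_rho)
    }
    dosage[i, ] <- 2L * as.integer(hap)
  }
  g <- geno(dosage, snps, "inbred")

  # causal loci among SNPs whose realized MAF is in the configured range
  arch <- tibble::tibble(snp_id = character(), a = numeric(), d = numeric())
  if (config$n_qtl > 0) {
    fr <- maf(g)
    pool <- fr$snp_id[fr$maf >= config$qtl_maf_range[1] &
                        fr$maf <= config$qtl_maf_range[2]]
    if (length(pool) < config$n_qtl) {
      stop("not enough SNPs in qtl_maf_range to place the QTL", call. = FALSE)
    }
    causal <- sample(pool, config$n_qtl)
    sc <- config$qtl_effect_scheme
    a_abs <- switch(sc$type,
      geometric = sc$scale * sc$ratio^(seq_len(config$n_qtl) - 1),
      normal = abs(rnorm(config$n_qtl, 0, sc$sd)),
      stop("unknown qtl_effect_scheme type", call. = FALSE)
    )
    arch <- tibble::tibble(
      snp_id = causal,
      a = a_abs * sample(c(-1, 1), config$n_qtl, replace = TRUE),
      d = 0
    )
  }
  attr(arch, "mu") <- config$mu

  gv <- genetic_value(g, arch)
  v_g <- var(gv)

  # rescale error variances to hit the target repeatability in expectation
  gxe_sd <- config$gxe_sd
  resid_sd <- config$resid_sd
  if (!is.null(config$target_repeatability) && config$n_qtl > 0 && v_g > 0) {
    H <- config$target_repeatability
    err <- gxe_sd^2 / config$n_env +
      resid_sd^2 / (config$n_env * config$n_reps)
    if (err == 0) {
      if (H < 1) {
        stop("target_repeatability < 1 is infeasible with zero error variances",
             call. = FALSE)
      }
    } else {
      c2 <- v_g * (1 / H - 1) / err
      gxe_sd <- gxe_sd * sqrt(c2)
      resid_sd <- resid_sd * sqrt(c2)
    }
  }

  env_labels <- sprintf("env%d", seq_len(config$n_env))
  env_eff <- setNames(rnorm(config$n_env, 0, config$env_effect_sd), env_labels)
  gxe <- matrix(rnorm(config$n_lines * config$n_env, 0, gxe_sd),
                config$n_lines, config$n_env,
                dimnames = list(rownames(dosage), env_labels))
  pheno <- tidyr::expand_grid(
    line_id = rownames(dosage),
    environment = env_labels,
    replicate = seq_len(config$n_reps)
  )
  pheno$value <- gv[pheno$line_id] + env_eff[pheno$environment] +
    gxe[cbind(pheno$line_id, pheno$environment)] +
    rnorm(nrow(pheno), 0, resid_sd)

  truth <- list(
    subpop = tibble::tibble(line_id = rownames(dosage),
                            subpop = sprintf("pop%d", subpop)),
    env_effects = env_eff,
    genetic_values = gv,
    var_genetic = v_g,
    gxe_sd = gxe_sd,
    resid_sd = resid_sd,
    config = config
  )
  structure(list(geno = g, architecture = arch, pheno = pheno, truth = truth),
            class = "panel_sim")
}

# additive + dominance genetic value on the {-1,0,+1} / het scale
genetic_value <- function(g, arch) {
  mu <- attr(arch, "mu") %||% 0
  gv <- rep(mu, nrow(g$dosage))
  names(gv) <- rownames(g$dosage)
  if (nrow(arch) == 0) return(gv)
  miss <- setdiff(arch$snp_id, colnames(g$dosage))
  if (length(miss)) {
    stop("causal SNPs absent from genotype matrix: ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  d <- g$dosage[, arch$snp_id, drop = FALSE]
  x <- d - 1
  h <- as.numeric(d == 1)
  dim(h) <- dim(d)
  gv + drop(x %*% arch$a) + drop(h %*% arch$d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
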