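toy_geno <- function(d, chrom = NULL, pos = NULL) {
  n_snp <- ncol(d)
  if (is.null(chrom)) chrom <- rep("chr1", n_snp)
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000
  colnames(d) <- sprintf("s%03d", seq_len(n_snp))
  geno(d, tibble::tibble(snp_id = colnames(d), chrom = chrom, pos_bp = pos),
       ploidy_class = "f2")
}

test_that("MAF filtering drops rare and monomorphic SNPs, keeps order", {
  d <- cbind(rep(2, 10),                      # monomorphic, MAF 0
             c(0, rep(2, 9)),                 # MAF 0.10
             c(0, 0, 0, rep(2, 7)))           # MAF 0.30
  g <- toy_geno(d)
  kept <- maf_filter(g, 0.05)
  expect_equal(kept$snps$snp_id, c("s002", "s003"))
  expect_equal(maf_filter(g, 0)$snps$snp_id, g$snps$snp_id)
  expect_error(maf_filter(g, 0.49), "no SNP")
})

test_that("kinship is symmetric, scaled to unit mean diagonal, and sees duplicates", {
  sim <- quick_panel(n_lines = 60, n_chrom = 1, snps_per_chrom = 200,
                     n_qtl = 0, seed = 21, target_repeatability = NULL)
  g <- maf_filter(sim$geno)
  # duplicate a line
  d <- g$dosage
  d[2, ] <- d[1, ]
  g2 <- geno(d, g$snps)
  K <- kinship(g2)
  expect_equal(K, t(K))
  expect_equal(mean(diag(K)), 1)
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-10)
  expect_identical(K, kinship(g2))
  # independent equal-frequency SNPs: off-diagonal near zero
  set.seed(9)
  d0 <- matrix(2 * rbinom(200 * 2000, 1, 0.5), 200, 2000,
               dimnames = list(sprintf("L%03d", 1:200), NULL))
  K0 <- kinship(toy_geno(d0))
  expect_lt(abs(mean(K0[upper.tri(K0)])), 0.01)
})

test_that("an exact linear phenotype pins its SNP with the full effect", {
  sim <- quick_panel(n_lines = 100, n_chrom = 1, snps_per_chrom = 150,
                     n_qtl = 0, seed = 31, target_repeatability = NULL)
  g <- maf_filter(sim$geno)
  snp <- g$snps$snp_id[10]
  y <- setNames(3.5 * g$dosage[, snp], rownames(g$dosage))
  scan <- glm_scan(g, y)
  hit <- scan[scan$snp_id == snp, ]
  expect_equal(hit$effect, 3.5, tolerance = 1e-8)
  expect_equal(hit$p_value, .Machine$double.xmin)
  # adding a constant changes no p-value
  scan2 <- glm_scan(g, y + 100)
  expect_equal(scan$p_value, scan2$p_value)
  # output covers every SNP and -log10 p matches p
  expect_equal(nrow(scan), ncol(g$dosage))
  expect_equal(scan$neg_log10_p, -log10(scan$p_value), tolerance = 1e-10)
})

test_that("the null type-I error of the OLS scan is calibrated at alpha 0.05", {
  rates <- vapply(1:20, function(s) {
    set.seed(600 + s)
    d <- matrix(2 * rbinom(100 * 500, 1, 0.4), 100, 500,
                dimnames = list(sprintf("L%03d", 1:100), NULL))
    y <- setNames(rnorm(100), rownames(d))
    scan <- glm_scan(toy_geno(d), y)
    mean(scan$p_value < 0.05)
  }, numeric(1))
  expect_gt(mean(rates), 0.04)
  expect_lt(mean(rates), 0.06)
})

test_that("the mixed-model scan collapses to OLS when polygenic variance is absent", {
  sim <- quick_panel(n_lines = 80, n_chrom = 1, snps_per_chrom = 120,
                     n_qtl = 3, seed = 41)
  g <- maf_filter(sim$geno)
  ymn <- sim$pheno |>
    dplyr::group_by(line_id) |>
    dplyr::summarise(v = mean(value))
  y <- setNames(ymn$v, ymn$line_id)
  K0 <- matrix(0, nrow(g$dosage), nrow(g$dosage),
               dimnames = list(rownames(g$dosage), rownames(g$dosage)))
  expect_equal(mlm_scan(g, y, K0)$p_value, glm_scan(g, y)$p_value,
               tolerance = 1e-8)
})

test_that("MLM with kinship and Q controls structured confounding that inflates OLS", {
  lams <- vapply(1:5, function(s) {
    sim <- quick_panel(n_lines = 200, n_chrom = 2, snps_per_chrom = 300,
                       n_qtl = 0, fst = 0.2, seed = 700 + s,
                       target_repeatability = NULL)
    g <- maf_filter(sim$geno)
    set.seed(s)
    labs <- sim$truth$subpop
    shift <- ifelse(labs$subpop[match(rownames(g$dosage), labs$line_id)] ==
                      "pop1", 0.5, -0.5)
    y <- setNames(shift + rnorm(nrow(g$dosage), 0, 1), rownames(g$dosage))
    sc <- structure_covariates(g, subpop = labs, n_pca = 5)
    c(lambda_gc(glm_scan(g, y)$p_value),
      lambda_gc(mlm_scan(g, y, sc$K, covariates = sc$Q)$p_value))
  }, numeric(2))
  expect_gt(mean(lams[1, ]), 1.1)
  expect_gt(mean(lams[1, ]) - mean(lams[2, ]), 0.1)
  expect_lt(abs(mean(lams[2, ]) - 1), 0.1)
})

test_that("Li-Ji Meff matches hand eigen-decompositions and never exceeds N", {
  # orthogonal columns: correlation is the identity, Meff = p
  x <- c(1, 1, -1, -1, 1, -1, 1, -1)
  z <- c(1, -1, 1, -1, 1, 1, -1, -1)
  w <- c(1, -1, -1, 1, 1, -1, -1, 1)
  m <- cbind(x, z, w)
  expect_equal(meff_li_ji(m), 3)
  # perfectly correlated pair: eigenvalues {2, 0} -> Meff = 1
  expect_equal(meff_li_ji(cbind(x, x + 0)), 1)
  # r = 0.5 pair: eigenvalues {1.5, 0.5} -> Meff = 2 (Li-Ji step behaviour)
  y05 <- 0.5 * x + sqrt(0.75) * z
  expect_equal(meff_li_ji(cbind(x, y05)), 2, tolerance = 1e-10)
  expect_error(meff_li_ji(cbind(x, rep(1, 8))), "zero-variance")
  # random dosages: p-2 <= Meff <= p, summed per chromosome
  set.seed(3)
  d <- matrix(2 * rbinom(500 * 40, 1, 0.5), 500, 40)
  expect_lte(meff_li_ji(d, chrom = rep(c("a", "b"), each = 20)), 40)
})

test_that("threshold arithmetic reproduces the four Bonferroni-family cutoffs", {
  th <- assoc_thresholds(48498.7009, 48962)
  expect_equal(round(th$neg_log10_p, 2), c(5.99, 5.69, 4.99, 4.69))
  expect_equal(th$threshold,
               c("0.05/Meff", "0.10/Meff", "0.05/0.1N", "0.10/0.1N"))
  expect_equal(assoc_thresholds(1, 10)$neg_log10_p[1], -log10(0.05),
               tolerance = 1e-10)
  # documented ordering whenever Meff >= N/2
  expect_true(all(diff(th$neg_log10_p) <= 0))
})

test_that("structure-corrected PVE behaves at its boundaries and in between", {
  sim <- quick_panel(n_lines = 120, n_chrom = 1, snps_per_chrom = 200,
                     n_qtl = 0, seed = 51, target_repeatability = NULL)
  g <- maf_filter(sim$geno)
  sc <- structure_covariates(g, subpop = sim$truth$subpop, n_pca = 2)
  snp <- g$snps$snp_id[5]
  # y an exact function of Q and the SNP -> PVE = 1
  y1 <- setNames(drop(sc$Q %*% rep(1, ncol(sc$Q))) + 2 * g$dosage[, snp],
                 rownames(g$dosage))
  expect_equal(pve(y1, g, snp, Q = sc$Q), 1)
  # a SNP orthogonal to the Q-residuals of y -> PVE = 0
  set.seed(8)
  r_snp <- qr.resid(qr(cbind(1, sc$Q)), g$dosage[, snp])
  y_raw <- rnorm(nrow(g$dosage))
  ry <- qr.resid(qr(cbind(1, sc$Q)), y_raw)
  y0 <- setNames(y_raw - r_snp * sum(ry * r_snp) / sum(r_snp^2),
                 rownames(g$dosage))
  expect_lt(pve(y0, g, snp, Q = sc$Q), 1e-10)
  # large-sample calibration near the generating R2 = 0.10
  set.seed(12)
  d <- matrix(2 * rbinom(10000 * 2, 1, 0.5), 10000, 2,
              dimnames = list(sprintf("L%05d", 1:10000), NULL))
  gbig <- toy_geno(d)
  x <- d[, 1]
  vx <- 0.25 * var(x)
  e <- rnorm(10000, 0, sqrt(vx * 0.9 / 0.1))
  yb <- setNames(0.5 * x + e, rownames(d))
  expect_lt(abs(pve(yb, gbig, "s001") - 0.10), 0.01)
})

test_that("greedy locus grouping matches a brute-force application of the rule", {
  sim <- quick_panel(n_lines = 200, n_chrom = 2, snps_per_chrom = 150,
                     n_qtl = 5, seed = 61)
  g <- maf_filter(sim$geno)
  ymn <- sim$pheno |>
    dplyr::group_by(line_id) |>
    dplyr::summarise(v = mean(value))
  scan <- glm_scan(g, setNames(ymn$v, ymn$line_id))
  sig <- dplyr::slice_max(scan, neg_log10_p, n = 12)
  loci <- group_loci(sig, g, r2_threshold = 0.2)
  # every SNP appears in exactly one locus
  members <- unlist(lapply(loci$members, function(m) m$snp_id))
  expect_setequal(members, sig$snp_id)
  expect_equal(anyDuplicated(members), 0L)
  # members sit on the seed's chromosome and exceed r2 with the seed
  for (i in seq_len(nrow(loci))) {
    seed_snp <- loci$seed_snp[i]
    for (m in loci$members[[i]]$snp_id) {
      expect_equal(g$snps$chrom[g$snps$snp_id == m], loci$chrom[i])
      if (m != seed_snp) {
        expect_gt(ld_r2(g$dosage[, seed_snp], g$dosage[, m]), 0.2)
      }
    }
  }
  # brute-force replay of the greedy rule gives the same partition
  ord <- dplyr::arrange(sig, dplyr::desc(neg_log10_p), chrom, pos_bp)
  remaining <- ord$snp_id
  expected_blocks <- list()
  while (length(remaining)) {
    seed_snp <- remaining[1]
    ch <- ord$chrom[ord$snp_id == seed_snp]
    same <- remaining[ord$chrom[match(remaining, ord$snp_id)] == ch]
    r2 <- vapply(same, function(s)
      ld_r2(g$dosage[, seed_snp], g$dosage[, s]), numeric(1))
    take <- union(seed_snp, same[r2 > 0.2])
    expected_blocks[[length(expected_blocks) + 1]] <- sort(take)
    remaining <- setdiff(remaining, take)
  }
  got_blocks <- lapply(loci$members, function(m) sort(m$snp_id))
  expect_setequal(
    vapply(got_blocks, paste, character(1), collapse = "|"),
    vapply(expected_blocks, paste, character(1), collapse = "|")
  )
})

test_that("separate chromosomes and perfect LD give the expected locus counts", {
  d <- cbind(c(0, 0, 2, 2, 0, 2), c(0, 0, 2, 2, 0, 2), c(2, 0, 0, 2, 2, 0))
  g <- toy_geno(d, chrom = c("chr1", "chr1", "chr2"))
  sig <- tibble::tibble(
    snp_id = g$snps$snp_id, chrom = g$snps$chrom, pos_bp = g$snps$pos_bp,
    neg_log10_p = c(6, 5, 7), pve = c(0.1, 0.05, 0.2)
  )
  loci <- group_loci(sig, g)
  expect_equal(nrow(loci), 2)
  expect_equal(sort(loci$n_snps), c(1, 2))
})
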