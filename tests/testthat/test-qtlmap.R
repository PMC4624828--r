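test_that("the Haldane map function and its inverse round-trip", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(10), 0.0906, tolerance = 1e-3)
  x <- seq(0, 200, by = 7)
  expect_equal(inverse_haldane(haldane(x)), x, tolerance = 1e-10)
  expect_error(inverse_haldane(0.5), "0.5")
  expect_error(haldane(-1), "non-negative")
})

# independent brute-force enumeration over the 4 gamete classes per side
enumerate_probs <- function(left, right, d_left, d_right) {
  r1 <- (1 - exp(-2 * d_left / 100)) / 2
  r2 <- (1 - exp(-2 * d_right / 100)) / 2
  p_q <- numeric(3)
  for (l1 in 0:1) for (q1 in 0:1) for (r1a in 0:1) {
    for (l2 in 0:1) for (q2 in 0:1) for (r2a in 0:1) {
      pr <- 0.5 * (if (l1 == q1) 1 - r1 else r1) *
        (if (q1 == r1a) 1 - r2 else r2) *
        0.5 * (if (l2 == q2) 1 - r1 else r1) *
        (if (q2 == r2a) 1 - r2 else r2)
      lg <- c("BB", "AB", "AA")[l1 + l2 + 1]
      rg <- c("BB", "AB", "AA")[r1a + r2a + 1]
      ok_l <- is.na(left) || lg == left
      ok_r <- is.na(right) || rg == right
      if (ok_l && ok_r) p_q[3 - (q1 + q2)] <- p_q[3 - (q1 + q2)] + pr
    }
  }
  p_q / sum(p_q)
}

test_that("flanking-marker genotype probabilities match exhaustive enumeration", {
  expect_equal(qtl_genotype_probs("AA", "AA", 0, 10), c(1, 0, 0))
  expect_equal(qtl_genotype_probs(NA, NA, 5, 5), c(0.25, 0.5, 0.25))
  cases <- expand.grid(l = c("AA", "AB", "BB", NA), r = c("AA", "AB", "BB", NA),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    for (dd in list(c(10, 10), c(3, 17), c(0, 25))) {
      got <- qtl_genotype_probs(cases$l[i], cases$r[i], dd[1], dd[2])
      want <- enumerate_probs(cases$l[i], cases$r[i], dd[1], dd[2])
      expect_equal(unname(got), want, tolerance = 1e-12)
    }
  }
  expect_error(qtl_genotype_probs("AA", "AA", -1, 5), "non-negative")
})

test_that("a noiseless QTL at a marker is mapped exactly with its effects", {
  map <- tiny_map(n_chrom = 1)
  parents <- tiny_parents(map)
  pop <- simulate_f23(parents, map, marker_arch("m04", a = 0.8, d = 0.3),
                      n_families = 300, env_effect_sd = 0, resid_sd = 0,
                      seed = 3)
  prof <- hk_scan(pop)
  peak <- prof[which.max(prof$lod), ]
  expect_equal(peak$pos_cM, map$pos_cM[map$marker_id == "m04"])
  expect_equal(peak$a_hat, 0.8, tolerance = 1e-6)
  expect_equal(peak$d_hat, 0.3, tolerance = 1e-6)
  q <- call_qtl(prof, threshold = 2.5)
  top <- q[which.max(q$lod), ]
  expect_equal(top$peak_cM, map$pos_cM[map$marker_id == "m04"])
  expect_equal(top$a, 0.8, tolerance = 1e-6)
  expect_equal(top$gene_action, "pd")
  # with realistic noise a single planted QTL yields a single record
  popn <- simulate_f23(parents, map, marker_arch("m04", a = 0.8, d = 0.3),
                       n_families = 300, env_effect_sd = 0, resid_sd = 1,
                       seed = 4)
  qn <- call_qtl(hk_scan(popn, cofactors = select_cofactors(popn)),
                 threshold = 2.5)
  expect_equal(nrow(qn), 1)
  expect_true(qn$flank_left %in% c("m03", "m04") &&
                qn$flank_right %in% c("m04", "m05"))
})

test_that("simple interval mapping at a marker equals the direct regression LR", {
  map <- tiny_map(n_chrom = 1)
  parents <- tiny_parents(map)
  pop <- simulate_f23(parents, map, marker_arch("m06", a = 0.5, d = 0.1),
                      n_families = 200, resid_sd = 1, seed = 8)
  prof <- hk_scan(pop)
  y <- setNames(pop$family_means$value, pop$family_means$family)
  y <- y[rownames(pop$genotypes)]
  cnt <- match(pop$genotypes[, "m06"], c("BB", "AB", "AA")) - 1
  fit <- lm(y ~ I(cnt - 1) + I((cnt == 1) / 2))
  rss_f <- sum(residuals(fit)^2)
  rss_0 <- sum((y - mean(y))^2)
  lod_direct <- length(y) / 2 * log10(rss_0 / rss_f)
  at_marker <- prof[prof$pos_cM == map$pos_cM[map$marker_id == "m06"], ]
  expect_equal(at_marker$lod, lod_direct, tolerance = 1e-8)
})

test_that("LOD profiles are invariant to affine transformation of the phenotype", {
  map <- tiny_map(n_chrom = 1)
  parents <- tiny_parents(map)
  pop <- simulate_f23(parents, map, marker_arch("m03", a = 0.6), 150,
                      resid_sd = 1, seed = 12)
  prof1 <- hk_scan(pop)
  pop2 <- pop
  pop2$family_means$value <- 3 * pop2$family_means$value - 40
  prof2 <- hk_scan(pop2)
  expect_equal(prof1$lod, prof2$lod, tolerance = 1e-8)
})

test_that("cofactor selection finds a strong QTL marker and honours its cap", {
  map <- tiny_map(n_chrom = 2)
  parents <- tiny_parents(map)
  pop <- simulate_f23(parents, map, marker_arch("m05", a = 1.2), 250,
                      resid_sd = 0.8, seed = 14)
  cof <- select_cofactors(pop)
  idx <- match(cof[1], map$marker_id)
  expect_lte(abs(map$pos_cM[idx] - map$pos_cM[map$marker_id == "m05"]), 10)
  expect_equal(select_cofactors(pop, max_cofactors = 0), character(0))
  # null population: usually no cofactor survives p < 0.01
  n_sel <- vapply(1:10, function(s) {
    popn <- simulate_f23(parents, map, marker_arch("m05", 0), 150,
                         resid_sd = 1, seed = 100 + s)
    length(select_cofactors(popn))
  }, numeric(1))
  expect_lte(mean(n_sel > 0), 0.5)
})

test_that("two well-separated QTLs are resolved and agree with a grid oracle", {
  map <- tiny_map(n_chrom = 1, n_mark = 11)
  parents <- tiny_parents(map)
  arch <- marker_arch(c("m02", "m09"), a = c(1, 0.9), d = c(0, 0))
  pop <- simulate_f23(parents, map, arch, 300, resid_sd = 0.8, seed = 21)
  prof <- hk_scan(pop, cofactors = select_cofactors(pop))
  q <- call_qtl(prof, threshold = 2.5)
  expect_equal(nrow(q), 2)
  # two-QTL grid oracle: best pair of marker positions by joint regression
  y <- f23_values <- setNames(pop$family_means$value,
                              pop$family_means$family)[rownames(pop$genotypes)]
  cnt <- matrix(match(pop$genotypes, c("BB", "AB", "AA")) - 1,
                nrow(pop$genotypes))
  best <- c(NA, NA)
  best_rss <- Inf
  for (i in 1:10) for (j in (i + 1):11) {
    rss <- sum(residuals(lm(y ~ cnt[, i] + cnt[, j]))^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- map$pos_cM[c(i, j)]
    }
  }
  expect_lte(abs(sort(q$peak_cM)[1] - best[1]), 10)
  expect_lte(abs(sort(q$peak_cM)[2] - best[2]), 10)
  # sub-threshold profiles return no QTL
  expect_equal(nrow(call_qtl(prof, threshold = 1e6)), 0)
})

test_that("degree of dominance reproduces the published worked examples", {
  ex <- gene_action(c(0.56, -0.01, 0.41, 1, 0.73), c(0.06, 0.48, -0.03, 0, -0.29))
  expect_equal(ex$da_ratio, c(0.11, 48, 0.07, 0, 0.40))
  expect_equal(ex$gene_action, c("a", "d", "a", "a", "pd"))
  expect_equal(gene_action(0, 0.5)$gene_action, "d")
  expect_error(gene_action(0, 0), "both zero")
})

test_that("common-QTL clustering is single-linkage on interval overlap", {
  recs <- tibble::tibble(
    qtl_id = sprintf("q%d", 1:5),
    population = c("NS", "TM", "TW", "NS", "TM"),
    environment = "e1",
    chrom = c("c1", "c1", "c1", "c1", "c2"),
    start_bp = c(1e6, 4e6, 9e6, 30e6, 1e6),
    end_bp = c(5e6, 10e6, 12e6, 35e6, 2e6)
  )
  cc <- cluster_common_qtl(recs)
  expect_equal(nrow(cc), 3)
  chain <- cc[cc$chrom == "c1" & cc$n_members == 3, ]
  expect_equal(chain$start_bp, 1e6)
  expect_equal(chain$end_bp, 12e6)
  expect_setequal(chain$members[[1]], c("q1", "q2", "q3"))
  # graph connected-components oracle
  ov <- function(i, j) recs$chrom[i] == recs$chrom[j] &&
    recs$start_bp[i] <= recs$end_bp[j] && recs$start_bp[j] <= recs$end_bp[i]
  comp <- seq_len(5)
  for (i in 1:5) for (j in 1:5) {
    if (ov(i, j)) comp[comp == comp[j]] <- comp[i]
  }
  expect_equal(nrow(cc), length(unique(comp)))
  # identical intervals merge; disjoint stay apart
  two <- cluster_common_qtl(recs[c(1, 1), ] |>
                              dplyr::mutate(qtl_id = c("x", "y")))
  expect_equal(nrow(two), 1)
  expect_error(cluster_common_qtl(dplyr::mutate(recs, start_bp = NA)),
               "physical")
})
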