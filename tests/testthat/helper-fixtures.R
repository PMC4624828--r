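# shared in-code fixtures; everything is generated, nothing read from disk

# small structured panel for scan/bank tests
quick_panel <- function(n_lines = 150, n_chrom = 2, snps_per_chrom = 400,
                        n_qtl = 8, n_subpops = 2, fst = 0.2, seed = 42,
                        target_repeatability = 0.9, ...) {
  simulate_panel(panel_sim_config(
    n_lines = n_lines, n_subpops = n_subpops, fst = fst,
    n_chrom = n_chrom, snps_per_chrom = snps_per_chrom,
    chrom_length_bp = 5e7, n_qtl = n_qtl,
    target_repeatability = target_repeatability, seed = seed, ...
  ))
}

# 2-chromosome SSR-like map, 11 markers per chromosome at 10 cM spacing
tiny_map <- function(n_chrom = 2, n_mark = 11, spacing_cM = 10,
                     bp_per_cM = 1e6) {
  genetic_map(
    sprintf("m%02d", seq_len(n_chrom * n_mark)),
    rep(sprintf("c%d", seq_len(n_chrom)), each = n_mark),
    rep(seq(0, by = spacing_cM, length.out = n_mark), n_chrom),
    pos_bp = rep(1 + seq(0, by = spacing_cM, length.out = n_mark) * bp_per_cM,
                 n_chrom)
  )
}

# homozygous high/low parents over a map (high parent all dosage 2)
tiny_parents <- function(map, monomorphic_at = character(0)) {
  d <- rbind(P1 = rep(2, nrow(map)), P2 = rep(0, nrow(map)))
  colnames(d) <- map$marker_id
  d["P2", monomorphic_at] <- 2
  pos <- map$pos_bp
  if (anyNA(pos)) pos <- 1 + map$pos_cM * 1e6
  geno(d, tibble::tibble(snp_id = map$marker_id, chrom = map$chrom,
                         pos_bp = pos))
}

marker_arch <- function(snp_id, a, d = 0, mu = 13) {
  out <- tibble::tibble(snp_id = snp_id, a = a, d = d)
  attr(out, "mu") <- mu
  out
}

# Hudson method-of-moments Fst from two subpopulation genotype blocks
hudson_fst <- function(d1, d2) {
  p1 <- colMeans(d1) / 2
  p2 <- colMeans(d2) / 2
  n1 <- nrow(d1)
  n2 <- nrow(d2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
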