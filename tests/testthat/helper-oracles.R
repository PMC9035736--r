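# Independent brute-force re-implementations used as oracles. Deliberately
# naive (per-site loops, literal clause evaluation) and kept free of any code
# path they are checking.

oracle_hard_filter_keep <- function(sites, cfg) {
  vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    m <- c(s$qual, s$qd, s$fs, s$mq, s$sor)
    if (any(is.na(m))) return(FALSE)
    fail <- if (s$variant_class == "SNP") {
      s$qual < cfg$snp_qual_min || s$qd < cfg$snp_qd_min ||
        s$fs > cfg$snp_fs_max || s$mq < cfg$snp_mq_min || s$sor > cfg$snp_sor_max
    } else {
      s$qual < cfg$indel_qual_min || s$qd < cfg$indel_qd_min ||
        s$fs > cfg$indel_fs_max || s$sor > cfg$indel_sor_max || s$mq < cfg$indel_mq_min
    }
    !fail
  }, logical(1))
}

# window-scan formulation: slide a window_bp-long window over every start
# position; any window holding >= cluster_size SNPs condemns them all
oracle_cluster_keep <- function(sites, cluster_size, window_bp) {
  drop <- rep(FALSE, nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch & sites$variant_class == "SNP")
    pos <- sites$pos[idx]
    for (s in pos) {
      inside <- which(pos >= s & pos <= s + window_bp - 1)
      if (length(inside) >= cluster_size) drop[idx[inside]] <- TRUE
    }
  }
  !drop
}

oracle_cohort_keep <- function(sites, cfg) {
  vapply(seq_len(nrow(sites)), function(i) {
    g <- sites$gt[i, ]
    n_called <- sum(g != "MISSING")
    if (grepl(",", sites$alt[i]) || sites$ref[i] == sites$alt[i]) return(FALSE)
    if (sites$mean_depth[i] < cfg$min_mean_depth) return(FALSE)
    if (n_called / length(g) < cfg$max_missing) return(FALSE)
    if (n_called == 0) return(FALSE)
    alt <- sum(g == "HET") + 2 * sum(g == "HOM_ALT")
    p <- alt / (2 * n_called)
    min(p, 1 - p) >= cfg$maf_min
  }, logical(1))
}

oracle_major_genotype <- function(genotypes, threshold) {
  called <- genotypes[genotypes != "MISSING"]
  if (length(called) == 0) return("NONE")
  tab <- table(factor(called, levels = c("HOM_REF", "HET", "HOM_ALT")))
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if (length(winners) > 1) return("NONE")
  if (top / length(genotypes) > threshold) winners else "NONE"
}

# small deterministic simulated cohort for oracle comparisons
sim_fixture <- function(sites_per_chromosome = 500, seed = 11, ...) {
  simulate_dataset(sim_params(sites_per_chromosome = sites_per_chromosome,
                              seed = seed, ...))
}
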