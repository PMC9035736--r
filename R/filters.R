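#' Variant filtering thresholds
#'
#' Collects the site-level hard-filter thresholds (GATK-style filter
#' expressions, applied separately to SNPs and indels), the SNP-cluster
#' parameters, and the cohort-level thresholds (VCFtools-style). Defaults are
#' the standard hard-filtering recommendations: SNPs fail on
#' `QUAL < 30 || QD < 2 || FS > 60 || MQ < 40 || SOR > 4`, indels on
#' `QUAL < 30 || QD < 2 || FS > 200 || SOR > 10 || MQ < 40`; SNP clusters of 3
#' within 10 bp are removed; cohort filters keep biallelic sites with mean
#' depth >= 5, minor-allele frequency >= 0.05 and at least half the genotypes
#' called.
#'
#' @param snp_qual_min,snp_qd_min,snp_fs_max,snp_mq_min,snp_sor_max SNP
#'   hard-filter clause thresholds; comparisons are strict as written above.
#' @param indel_qual_min,indel_qd_min,indel_fs_max,indel_sor_max,indel_mq_min
#'   Indel hard-filter clause thresholds.
#' @param cluster_size,cluster_window_bp SNP-cluster rule: any
#'   `cluster_size` SNPs whose 1-based positional span (`max - min + 1`) is at
#'   most `cluster_window_bp` are all removed.
#' @param min_mean_depth Minimum mean per-sample depth (inclusive).
#' @param maf_min Minimum minor-allele frequency over non-missing alleles
#'   (inclusive).
#' @param max_missing Minimum fraction of called genotypes (VCFtools
#'   `--max-missing` semantics: `0.5` keeps sites with at most 50% missing).
#' @return A list of class `filter_config`.
#' @export
#' @examples
#' filter_config()
filter_config <- function(snp_qual_min = 30.0, snp_qd_min = 2.0,
                          snp_fs_max = 60.0, snp_mq_min = 40.0,
                          snp_sor_max = 4.0,
                          indel_qual_min = 30.0, indel_qd_min = 2.0,
                          indel_fs_max = 200.0, indel_sor_max = 10.0,
                          indel_mq_min = 40.0,
                          cluster_size = 3L, cluster_window_bp = 10L,
                          min_mean_depth = 5, maf_min = 0.05,
                          max_missing = 0.5) {
  cfg <- list(
    snp_qual_min = snp_qual_min, snp_qd_min = snp_qd_min,
    snp_fs_max = snp_fs_max, snp_mq_min = snp_mq_min, snp_sor_max = snp_sor_max,
    indel_qual_min = indel_qual_min, indel_qd_min = indel_qd_min,
    indel_fs_max = indel_fs_max, indel_sor_max = indel_sor_max,
    indel_mq_min = indel_mq_min,
    cluster_size = check_count(cluster_size, "cluster_size", min = 2),
    cluster_window_bp = check_count(cluster_window_bp, "cluster_window_bp", min = 1),
    min_mean_depth = min_mean_depth, maf_min = maf_min, max_missing = max_missing
  )
  num <- setdiff(names(cfg), c("cluster_size", "cluster_window_bp"))
  ok <- vapply(cfg[num], function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
               logical(1))
  stop_not(all(ok), "non-finite threshold(s): %s", paste(num[!ok], collapse = ", "))
  structure(cfg, class = "filter_config")
}

#' Hard-filter sites on call annotations
#'
#' Removes each SNP for which any clause of the SNP filter expression holds
#' and each indel for which any clause of the indel expression holds, with
#' strict comparisons as written in [filter_config()]. A site missing one of
#' the annotations named in its expression is removed (conservative reading
#' of missing annotations) and counted in a single warning.
#'
#' @param sites Site tibble as returned by [read_vcf()].
#' @param config A [filter_config()].
#' @return The surviving sites, order preserved.
#' @export
hard_filter_sites <- function(sites, config = filter_config()) {
  stopifnot(is.data.frame(sites))
  is_snp <- sites$variant_class == "SNP"
  snp_fail <- sites$qual < config$snp_qual_min | sites$qd < config$snp_qd_min |
    sites$fs > config$snp_fs_max | sites$mq < config$snp_mq_min |
    sites$sor > config$snp_sor_max
  indel_fail <- sites$qual < config$indel_qual_min | sites$qd < config$indel_qd_min |
    sites$fs > config$indel_fs_max | sites$sor > config$indel_sor_max |
    sites$mq < config$indel_mq_min
  fail <- ifelse(is_snp, snp_fail, indel_fail)
  n_na <- sum(is.na(fail))
  if (n_na > 0) {
    warning(sprintf("%d site(s) with missing filter annotations were removed", n_na),
            call. = FALSE)
    fail[is.na(fail)] <- TRUE
  }
  sites[!fail, , drop = FALSE]
}

#' Remove clustered SNPs
#'
#' Removes every SNP belonging to a run of at least `cluster_size` SNPs whose
#' positional span (`max - min + 1`, 1-based inclusive) is at most
#' `window_bp` on one chromosome. Indels neither trigger nor suffer removal.
#' Input must be sorted by chromosome and position.
#'
#' @param sites Site tibble as returned by [read_vcf()].
#' @param cluster_size,window_bp Cluster rule parameters.
#' @return The surviving sites, order preserved.
#' @export
#' @examples
#' s <- tibble::tibble(chrom = "chr1", pos = c(100L, 105L, 109L, 200L),
#'                     variant_class = "SNP")
#' snp_cluster_filter(s)$pos
snp_cluster_filter <- function(sites, cluster_size = 3L, window_bp = 10L) {
  stopifnot(is.data.frame(sites))
  cluster_size <- check_count(cluster_size, "cluster_size", min = 2)
  window_bp <- check_count(window_bp, "window_bp", min = 1)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    stop_not(!is.unsorted(p), "sites on %s are not sorted by position", ch)
  }
  drop <- rep(FALSE, nrow(sites))
  snp_idx <- which(sites$variant_class == "SNP")
  for (ch in unique(sites$chrom)) {
    idx <- snp_idx[sites$chrom[snp_idx] == ch]
    k <- cluster_size
    if (length(idx) < k) next
    p <- sites$pos[idx]
    for (i in seq_len(length(idx) - k + 1L)) {
      if (p[i + k - 1L] - p[i] + 1L <= window_bp) drop[idx[i:(i + k - 1L)]] <- TRUE
    }
  }
  sites[!drop, , drop = FALSE]
}

#' Cohort-level site filters
#'
#' Keeps sites that are biallelic (single ALT allele differing from REF), have
#' mean per-sample depth at least `min_mean_depth`, minor-allele frequency at
#' least `maf_min` among non-missing alleles, and a called-genotype fraction
#' of at least `max_missing` (so at most `1 - max_missing` missing). Sites
#' with all genotypes missing are removed, not an error.
#'
#' @inheritParams hard_filter_sites
#' @return The surviving sites, order preserved.
#' @export
cohort_filter <- function(sites, config = filter_config()) {
  stopifnot(is.data.frame(sites), "gt" %in% names(sites))
  sites[cohort_keep(sites, sites$gt, sites$mean_depth, config), , drop = FALSE]
}

# Logical keep vector for the cohort criteria, over an arbitrary genotype
# matrix (one cohort, or the three cohorts pooled for merged-mode filtering).
cohort_keep <- function(sites, gt, mean_depth, config) {
  n <- ncol(gt)
  n_called <- rowSums(gt != "MISSING")
  alt_alleles <- rowSums(gt == "HET") + 2 * rowSums(gt == "HOM_ALT")
  p_alt <- ifelse(n_called > 0, alt_alleles / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  keep <- !grepl(",", sites$alt) & sites$ref != sites$alt &
    mean_depth >= config$min_mean_depth &
    n_called / n >= config$max_missing &
    !is.na(maf) & maf >= config$maf_min
  keep[is.na(keep)] <- FALSE
  keep
}
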