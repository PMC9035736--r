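#' Build a cohort variant summary from class counts
#'
#' The bookkeeping layer behind [summarize_variants()]: given transition,
#' transversion, insertion and deletion counts it derives the totals, the
#' Ts/Tv ratio and the transition percentage. With zero transversions the
#' ratio is undefined and reported as `NA`.
#'
#' @param n_transitions,n_transversions,n_insertions,n_deletions Non-negative
#'   counts.
#' @return A one-row tibble of class `cohort_variant_summary` with columns
#'   `n_snps`, `n_transitions`, `n_transversions`, `tstv_ratio`,
#'   `transition_pct`, `n_indels`, `n_insertions`, `n_deletions`. Ratio and
#'   percentage are kept at full precision; [print()] shows 2 decimals.
#' @export
#' @examples
#' variant_summary(n_transitions = 15147780, n_transversions = 6141770,
#'                 n_insertions = 1082694, n_deletions = 1306121)
variant_summary <- function(n_transitions = 0, n_transversions = 0,
                            n_insertions = 0, n_deletions = 0) {
  for (nm in c("n_transitions", "n_transversions", "n_insertions", "n_deletions")) {
    check_count(get(nm), nm, min = 0)
  }
  n_snps <- n_transitions + n_transversions
  out <- tibble::tibble(
    n_snps = n_snps,
    n_transitions = n_transitions,
    n_transversions = n_transversions,
    tstv_ratio = if (n_transversions > 0) n_transitions / n_transversions else NA_real_,
    transition_pct = if (n_snps > 0) 100 * n_transitions / n_snps else NA_real_,
    n_indels = n_insertions + n_deletions,
    n_insertions = n_insertions,
    n_deletions = n_deletions
  )
  class(out) <- c("cohort_variant_summary", class(out))
  out
}

#' Summarise a set of variant sites
#'
#' Classifies every SNP as transition or transversion and every indel as
#' insertion or deletion, and returns the cohort summary (counts, Ts/Tv
#' ratio, transition percentage).
#'
#' @param sites Site tibble with `ref`, `alt` and `variant_class` columns
#'   (as from [read_vcf()]).
#' @return A `cohort_variant_summary` tibble; see [variant_summary()].
#' @export
#' @examples
#' sim <- simulate_dataset(sim_params(sites_per_chromosome = 50))
#' summarize_variants(read_vcf(sim$ancestor_b_vcf))
summarize_variants <- function(sites) {
  stopifnot(is.data.frame(sites),
            all(c("ref", "alt", "variant_class") %in% names(sites)))
  snp <- sites$variant_class == "SNP"
  subst <- if (any(snp)) classify_substitution(sites$ref[snp], sites$alt[snp]) else character()
  variant_summary(
    n_transitions = sum(subst == "TRANSITION"),
    n_transversions = sum(subst == "TRANSVERSION"),
    n_insertions = sum(sites$variant_class == "INSERTION"),
    n_deletions = sum(sites$variant_class == "DELETION")
  )
}

#' @export
print.cohort_variant_summary <- function(x, ...) {
  cat("Cohort variant summary\n")
  cat(sprintf("  SNPs: %d (transitions %d, transversions %d)\n",
              x$n_snps, x$n_transitions, x$n_transversions))
  cat(sprintf("  Ts/Tv: %s   transition share: %s\n",
              ifelse(is.na(x$tstv_ratio), "undefined", sprintf("%.2f", x$tstv_ratio)),
              ifelse(is.na(x$transition_pct), "-", sprintf("%.2f%%", x$transition_pct))))
  cat(sprintf("  indels: %d (insertions %d, deletions %d)\n",
              x$n_indels, x$n_insertions, x$n_deletions))
  invisible(x)
}

#' Summarise ancestry attribution at site and gene level
#'
#' Tallies the origin-assigned sites and the per-gene categories into the
#' run-level summary, split by variant class when the assignments carry one.
#'
#' @param assignments Site-level table from [assign_ancestry()].
#' @param gene_summaries Per-gene table from [aggregate_gene_ancestry()]
#'   (optionally with a `variant_class` column for the split).
#' @return A tibble with one row per variant class (plus a `TOTAL` row when
#'   split): `n_sites_ancestor_a`, `n_sites_ancestor_b`, `n_genes_a_only`,
#'   `n_genes_b_only`, `n_genes_both`, `n_genes_total`.
#' @export
summarize_ancestry <- function(assignments, gene_summaries) {
  stopifnot(is.data.frame(assignments), is.data.frame(gene_summaries))
  one <- function(a, g, label) {
    tibble::tibble(
      variant_class = label,
      n_sites_ancestor_a = sum(a$origin == "ANCESTOR_A", na.rm = TRUE),
      n_sites_ancestor_b = sum(a$origin == "ANCESTOR_B", na.rm = TRUE),
      n_genes_a_only = sum(g$category == "A_ONLY"),
      n_genes_b_only = sum(g$category == "B_ONLY"),
      n_genes_both = sum(g$category == "BOTH"),
      n_genes_total = nrow(g)
    )
  }
  split_by_class <- "variant_class" %in% names(assignments) &&
    "variant_class" %in% names(gene_summaries)
  if (!split_by_class) {
    return(one(assignments, gene_summaries, "ALL"))
  }
  classes <- sort(unique(c(assignments$variant_class, gene_summaries$variant_class)))
  per <- purrr::map_dfr(classes, function(cl) {
    one(assignments[assignments$variant_class == cl, , drop = FALSE],
        gene_summaries[gene_summaries$variant_class == cl, , drop = FALSE], cl)
  })
  dplyr::bind_rows(per, one(assignments, gene_summaries, "TOTAL"))
}

#' Estimate genome size from a k-mer spectrum
#'
#' The closed-form k-mer estimate `G = K_num / K_depth`, where `K_num` is the
#' total number of k-mers counted in the reads and `K_depth` the k-mer
#' coverage depth (typically the main peak of the 17-mer frequency
#' distribution).
#'
#' @param k_num Total number of k-mers (non-negative).
#' @param k_depth K-mer depth (strictly positive).
#' @return Estimated genome size in bases.
#' @export
#' @examples
#' estimate_genome_size(1000, 10)
estimate_genome_size <- function(k_num, k_depth) {
  stop_not(is.numeric(k_num) && length(k_num) == 1 && is.finite(k_num) && k_num >= 0,
           "`k_num` must be a single non-negative number")
  stop_not(is.numeric(k_depth) && length(k_depth) == 1 && is.finite(k_depth) && k_depth > 0,
           "`k_depth` must be a single positive number")
  k_num / k_depth
}
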