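#' Run the full ancestral-attribution pipeline
#'
#' End-to-end orchestration over three VCF cohorts and a gene annotation:
#' per-cohort variant filtering (hard filters, SNP-cluster filter, cohort
#' filters), ancestor major-genotype calling, informative-site detection,
#' offspring screening, per-site origin assignment, gene-window aggregation
#' (SNPs and indels aggregated separately) and run-level summaries. With
#' `out_dir` set, the per-site and per-gene tables, the per-stage filter log
#' and the summaries are written as TSV; identical inputs give identical
#' outputs.
#'
#' @param ancestor_a_vcf,ancestor_b_vcf,offspring_vcf,gff3 Input paths.
#' @param filter_config A [filter_config()].
#' @param cohort_filter_mode `"merged"` (default) applies the cohort-level
#'   criteria (biallelic, mean depth, MAF, missingness) to the pooled samples
#'   of all three cohorts after site alignment, as in a jointly called
#'   multi-breed call set — within-cohort monomorphic sites (exactly the
#'   ancestor-informative ones) then survive the MAF rule through their
#'   between-breed polymorphism. `"per_cohort"` applies them to each cohort
#'   separately before alignment.
#' @param thresholds An [ancestry_thresholds()].
#' @param window_bp Gene-assignment window (see [assign_sites_to_genes()]).
#' @param out_dir Optional output directory for TSV reports.
#' @return An object of class `ancestry_run`: a list with `assignments`
#'   (per-site origins), `site_genes` (site x gene pairs), `gene_summary`
#'   (per-gene counts and category, with `variant_class`), `ancestry_summary`,
#'   `variant_summary` (post-filter, per cohort), `filter_log` (per stage and
#'   cohort: `stage`, `cohort`, `n_in`, `n_removed`, `n_out`) and the
#'   configuration used.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_params(sites_per_chromosome = 80))
#' run <- run_ancestry_pipeline(sim$ancestor_a_vcf, sim$ancestor_b_vcf,
#'                              sim$offspring_vcf, sim$gff3)
#' run
run_ancestry_pipeline <- function(ancestor_a_vcf, ancestor_b_vcf, offspring_vcf,
                                  gff3,
                                  filter_config = crossorigin::filter_config(),
                                  thresholds = ancestry_thresholds(),
                                  window_bp = 1000,
                                  cohort_filter_mode = c("merged", "per_cohort"),
                                  out_dir = NULL) {
  cohorts <- list(
    ancestor_a = ancestor_a_vcf,
    ancestor_b = ancestor_b_vcf,
    offspring = offspring_vcf
  )
  cohort_filter_mode <- match.arg(cohort_filter_mode)
  log <- list()
  filtered <- purrr::imap(cohorts, function(path, nm) {
    raw <- read_vcf(path)
    hard <- hard_filter_sites(raw, filter_config)
    clustered <- snp_cluster_filter(hard, filter_config$cluster_size,
                                    filter_config$cluster_window_bp)
    final <- if (cohort_filter_mode == "per_cohort") {
      cohort_filter(clustered, filter_config)
    } else {
      clustered
    }
    log[[nm]] <<- tibble::tibble(
      stage = c("hard_filter", "snp_cluster_filter",
                if (cohort_filter_mode == "per_cohort") "cohort_filter"),
      cohort = nm,
      n_in = c(nrow(raw), nrow(hard),
               if (cohort_filter_mode == "per_cohort") nrow(clustered)),
      n_out = c(nrow(hard), nrow(clustered),
                if (cohort_filter_mode == "per_cohort") nrow(final))
    )
    final
  })

  aligned <- align_cohorts(filtered$ancestor_a, filtered$ancestor_b,
                           filtered$offspring)
  if (cohort_filter_mode == "merged") {
    # allele-frequency / depth / missingness criteria over the pooled samples
    # of all three cohorts, as in a jointly called multi-breed call set
    pooled <- cbind(aligned$gt_a, aligned$gt_b, aligned$gt_o)
    keep <- cohort_keep(aligned, pooled, aligned$mean_depth, filter_config)
    log$merged <- tibble::tibble(
      stage = "cohort_filter", cohort = "merged",
      n_in = nrow(aligned), n_out = sum(keep)
    )
    aligned <- aligned[keep, , drop = FALSE]
  }
  filter_log <- dplyr::mutate(dplyr::bind_rows(log),
                              n_removed = .data$n_in - .data$n_out,
                              .before = "n_out")

  assignments <- assign_ancestry_aligned(aligned, thresholds)
  genes <- read_gff3(gff3)
  assigned <- assignments[!is.na(assignments$origin) &
                            assignments$origin != "UNASSIGNED", , drop = FALSE]
  site_genes <- assign_sites_to_genes(assigned, genes, window_bp)

  gene_summary <- if (nrow(site_genes) == 0) {
    dplyr::mutate(aggregate_gene_ancestry(site_genes),
                  variant_class = character(), .before = 1)
  } else {
    site_genes |>
      dplyr::mutate(variant_class = ifelse(.data$variant_class == "SNP", "SNP", "INDEL")) |>
      dplyr::group_by(.data$variant_class) |>
      dplyr::group_modify(~ aggregate_gene_ancestry(.x)) |>
      dplyr::ungroup()
  }

  assignments_cls <- dplyr::mutate(
    assignments,
    variant_class = ifelse(.data$variant_class == "SNP", "SNP", "INDEL")
  )
  ancestry_summary <- summarize_ancestry(assignments_cls, gene_summary)
  vsum <- purrr::map(filtered, summarize_variants)

  run <- structure(list(
    assignments = assignments,
    site_genes = site_genes,
    gene_summary = gene_summary,
    ancestry_summary = ancestry_summary,
    variant_summary = vsum,
    filter_log = filter_log,
    thresholds = thresholds,
    filter_config = filter_config,
    window_bp = window_bp
  ), class = "ancestry_run")

  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$assignments, file.path(out_dir, "assignments.tsv"), progress = FALSE)
  readr::write_tsv(run$site_genes, file.path(out_dir, "site_genes.tsv"), progress = FALSE)
  readr::write_tsv(run$gene_summary, file.path(out_dir, "gene_summary.tsv"), progress = FALSE)
  readr::write_tsv(run$ancestry_summary, file.path(out_dir, "ancestry_summary.tsv"), progress = FALSE)
  readr::write_tsv(run$filter_log, file.path(out_dir, "filter_log.tsv"), progress = FALSE)
  s <- run$ancestry_summary[run$ancestry_summary$variant_class == "TOTAL", ]
  readr::write_lines(c(
    "ancestral-attribution run log",
    sprintf("sites aligned across cohorts: %d", nrow(run$assignments)),
    sprintf("informative sites: %d", sum(run$assignments$informative)),
    sprintf("sites attributed: A=%d B=%d",
            s$n_sites_ancestor_a, s$n_sites_ancestor_b),
    sprintf("genes: A_only=%d B_only=%d both=%d total=%d",
            s$n_genes_a_only, s$n_genes_b_only, s$n_genes_both, s$n_genes_total),
    "",
    "filter stages:",
    sprintf("  %-20s %-10s in=%d removed=%d out=%d",
            run$filter_log$stage, run$filter_log$cohort, run$filter_log$n_in,
            run$filter_log$n_removed, run$filter_log$n_out)
  ), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.ancestry_run <- function(x, ...) {
  s <- x$ancestry_summary[x$ancestry_summary$variant_class == "TOTAL", ]
  if (nrow(s) == 0) s <- x$ancestry_summary[1, ]
  cat("<ancestry_run>\n")
  cat(sprintf("  sites aligned: %d   informative: %d\n",
              nrow(x$assignments), sum(x$assignments$informative)))
  cat(sprintf("  attributed sites: ancestor A %d, ancestor B %d\n",
              s$n_sites_ancestor_a, s$n_sites_ancestor_b))
  cat(sprintf("  genes: %d A-only, %d B-only, %d both (%d total)\n",
              s$n_genes_a_only, s$n_genes_b_only, s$n_genes_both, s$n_genes_total))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ancestry run
#'
#' @param x An `ancestry_run`.
#' @param type `"genes"` (default) for the per-gene summary, `"sites"` for
#'   per-site origin assignments, `"site_genes"` for the site-by-gene pairs.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ancestry_run <- function(x, type = c("genes", "sites", "site_genes"), ...) {
  switch(match.arg(type),
         genes = x$gene_summary,
         sites = tibble::as_tibble(x$assignments),
         site_genes = x$site_genes)
}

#' One-row summary of an ancestry run
#'
#' @param x An `ancestry_run`.
#' @param ... Unused.
#' @return A one-row tibble with site, attribution and gene-category totals.
#' @exportS3Method generics::glance
glance.ancestry_run <- function(x, ...) {
  s <- x$ancestry_summary[x$ancestry_summary$variant_class == "TOTAL", ]
  if (nrow(s) == 0) s <- x$ancestry_summary[1, ]
  tibble::tibble(
    n_sites = nrow(x$assignments),
    n_informative = sum(x$assignments$informative),
    n_sites_ancestor_a = s$n_sites_ancestor_a,
    n_sites_ancestor_b = s$n_sites_ancestor_b,
    n_genes_a_only = s$n_genes_a_only,
    n_genes_b_only = s$n_genes_b_only,
    n_genes_both = s$n_genes_both,
    n_genes_total = s$n_genes_total
  )
}
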