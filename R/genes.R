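#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features with their `ID` attribute, keeping 1-based
#' inclusive coordinates.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path) {
  stop_not(file.exists(path), "GFF3 not found: %s", path)
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  if (nrow(g) > 0) g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(), strand = character()))
  }
  ids <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
  bad <- which(is.na(ids) | ids == "")
  stop_not(length(bad) == 0,
           "gene feature(s) without an ID attribute (e.g. %s:%d)",
           as.character(g$seqid[bad[1]]), g$start[bad[1]])
  tibble::tibble(
    gene_id = ids,
    chrom = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = dplyr::coalesce(as.character(g$strand), ".")
  )
}

#' Map origin-assigned sites to genes through a centered window
#'
#' A site is assigned to every gene whose body intersects the closed window
#' `[pos - window_bp/2, pos + window_bp/2]` on the same chromosome — the
#' "1,000 bp centered on the site" rule, so a site within 500 bp of a gene
#' (default window) counts as that gene's. Sites overlapping several genes
#' are assigned to all of them.
#'
#' @param sites Tibble with at least `chrom` and `pos` (typically the output
#'   of [assign_ancestry()]).
#' @param genes Gene models from [read_gff3()].
#' @param window_bp Non-negative window width in bp centered on the site.
#' @return `sites` repeated once per overlapping gene, with a `gene_id`
#'   column; sites touching no gene are absent.
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 1400, end = 1500)
#' assign_sites_to_genes(tibble::tibble(chrom = "chr1", pos = 1000), genes)
assign_sites_to_genes <- function(sites, genes, window_bp = 1000) {
  stopifnot(is.data.frame(sites), is.data.frame(genes))
  stop_not(is.numeric(window_bp) && length(window_bp) == 1 && window_bp >= 0,
           "`window_bp` must be a single non-negative number")
  out_cols <- c(setdiff(names(sites), "gt"), "gene_id")
  if (nrow(sites) == 0 || nrow(genes) == 0) {
    empty <- sites[0, setdiff(names(sites), "gt"), drop = FALSE]
    empty$gene_id <- character()
    return(tibble::as_tibble(empty))
  }
  half <- window_bp / 2
  lv <- union(unique(sites$chrom), unique(genes$chrom))
  site_r <- GenomicRanges::GRanges(
    factor(sites$chrom, levels = lv),
    IRanges::IRanges(start = floor(sites$pos - half), end = ceiling(sites$pos + half))
  )
  gene_r <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lv),
    IRanges::IRanges(start = genes$start, end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(site_r, gene_r)
  out <- sites[S4Vectors::queryHits(hits), setdiff(names(sites), "gt"), drop = FALSE]
  out$gene_id <- genes$gene_id[S4Vectors::subjectHits(hits)]
  tibble::as_tibble(out[, out_cols])
}

#' Aggregate site-level origins to per-gene ancestry categories
#'
#' Counts, for each gene, the sites attributed to each ancestor and derives
#' the gene's category: `A_ONLY` / `B_ONLY` when all its sites trace to one
#' ancestor, `BOTH` when both ancestors contribute. Genes with no assigned
#' site are omitted; `UNASSIGNED` or `NA` origins are ignored.
#'
#' @param site_genes Output of [assign_sites_to_genes()]: one row per
#'   (site, gene) pair with an `origin` column.
#' @return A tibble: `gene_id`, `n_sites_a`, `n_sites_b`, `category`.
#' @export
aggregate_gene_ancestry <- function(site_genes) {
  stopifnot(is.data.frame(site_genes))
  if (nrow(site_genes) == 0) {
    return(tibble::tibble(gene_id = character(), n_sites_a = integer(),
                          n_sites_b = integer(), category = character()))
  }
  stopifnot(all(c("gene_id", "origin") %in% names(site_genes)))
  site_genes |>
    dplyr::filter(.data$origin %in% c("ANCESTOR_A", "ANCESTOR_B")) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_sites_a = sum(.data$origin == "ANCESTOR_A"),
      n_sites_b = sum(.data$origin == "ANCESTOR_B"),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$n_sites_a > 0 & .data$n_sites_b > 0 ~ "BOTH",
      .data$n_sites_a > 0 ~ "A_ONLY",
      TRUE ~ "B_ONLY"
    ))
}
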