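#' Major-genotype and screening thresholds
#'
#' The proportion rules of the attribution procedure: an ancestor cohort's
#' major genotype must exceed 75% of the cohort (for 18 individuals the
#' smallest qualifying count is 14), the offspring major genotype must exceed
#' 60% (4 of 6), and offspring sites with more than 50% missing genotypes are
#' screened out before calling. All proportions are computed over the full
#' cohort size, missing genotypes included in the denominator.
#'
#' @param ancestor_major_prop,offspring_major_prop,offspring_max_missing
#'   Proportions in (0, 1); comparisons against them are strict.
#' @return A list of class `ancestry_thresholds`.
#' @export
#' @examples
#' ancestry_thresholds()
ancestry_thresholds <- function(ancestor_major_prop = 0.75,
                                offspring_major_prop = 0.60,
                                offspring_max_missing = 0.50) {
  th <- list(
    ancestor_major_prop = check_proportion(ancestor_major_prop, "ancestor_major_prop", closed = FALSE),
    offspring_major_prop = check_proportion(offspring_major_prop, "offspring_major_prop", closed = FALSE),
    offspring_max_missing = check_proportion(offspring_max_missing, "offspring_max_missing", closed = FALSE)
  )
  structure(th, class = "ancestry_thresholds")
}

#' Call the major genotype of one cohort at one site
#'
#' The candidate is the most frequent called genotype class
#' (`HOM_REF`/`HET`/`HOM_ALT`); it is accepted as the major genotype only when
#' its count over the *full* cohort size strictly exceeds `threshold`
#' (`count / n > threshold`). Ties for the highest count, or no called
#' genotype at all, give `"NONE"`. `MISSING` is never a candidate but stays in
#' the denominator.
#'
#' @param genotypes Character vector of genotype codes for one site.
#' @param threshold Strict proportion threshold in (0, 1).
#' @return A one-row tibble: `major_genotype` (code or `"NONE"`),
#'   `major_proportion` (candidate count / cohort size), `missing_fraction`,
#'   `is_homozygous_major`.
#' @export
#' @examples
#' call_major_genotype(c(rep("HOM_REF", 14), rep("HET", 4)), 0.75)
call_major_genotype <- function(genotypes, threshold = 0.75) {
  stop_not(length(genotypes) > 0, "`genotypes` must be non-empty")
  check_proportion(threshold, "threshold", closed = FALSE)
  call_major_genotypes(matrix(genotypes, nrow = 1), threshold)
}

#' Call major genotypes for every site of a cohort
#'
#' Vectorised form of [call_major_genotype()] over a sites x samples genotype
#' matrix.
#'
#' @param gt Character matrix of genotype codes (sites x samples).
#' @param threshold Strict proportion threshold in (0, 1).
#' @return A tibble with one row per site (columns as in
#'   [call_major_genotype()]).
#' @export
call_major_genotypes <- function(gt, threshold = 0.75) {
  check_gt_matrix(gt)
  stop_not(ncol(gt) > 0, "`gt` must have at least one sample")
  n <- ncol(gt)
  counts <- cbind(
    HOM_REF = rowSums(gt == "HOM_REF"),
    HET = rowSums(gt == "HET"),
    HOM_ALT = rowSums(gt == "HOM_ALT")
  )
  top <- apply(counts, 1, max)
  n_top <- rowSums(counts == top)
  cand <- GT_CALLED[max.col(counts, ties.method = "first")]
  major <- ifelse(n_top > 1 | top == 0 | top / n <= threshold, "NONE", cand)
  tibble::tibble(
    major_genotype = major,
    major_proportion = top / n,
    missing_fraction = rowSums(gt == "MISSING") / n,
    is_homozygous_major = major %in% GT_HOMOZYGOUS
  )
}

#' Detect ancestor-informative sites
#'
#' A site is informative when both ancestor cohorts have a major genotype,
#' both major genotypes are homozygous, and they differ from each other — the
#' "homozygous, mutually inconsistent" rule that makes offspring alleles
#' traceable.
#'
#' @param calls_a,calls_b Major-genotype call tibbles for the two ancestor
#'   cohorts, aligned to the same site list (equal row counts).
#' @return Logical vector, one element per site.
#' @export
detect_informative_sites <- function(calls_a, calls_b) {
  stop_not(nrow(calls_a) == nrow(calls_b),
           "call tables are misaligned: %d vs %d sites", nrow(calls_a), nrow(calls_b))
  calls_a$is_homozygous_major & calls_b$is_homozygous_major &
    calls_a$major_genotype != calls_b$major_genotype
}

#' Screen an offspring site and return its usable genotype
#'
#' Returns `"NONE"` when the missing fraction exceeds
#' `offspring_max_missing`; otherwise calls the major genotype at
#' `offspring_major_prop` and returns it only when it exists and is
#' homozygous (heterozygous majors are screened out).
#'
#' @param genotypes Character vector of offspring genotype codes at one site.
#' @param thresholds An [ancestry_thresholds()] object.
#' @return A genotype code (`HOM_REF`/`HOM_ALT`) or `"NONE"`.
#' @export
#' @examples
#' screen_offspring_site(c(rep("HOM_ALT", 4), "HOM_REF", "MISSING"))
screen_offspring_site <- function(genotypes, thresholds = ancestry_thresholds()) {
  stop_not(length(genotypes) > 0, "`genotypes` must be non-empty")
  screen_offspring_sites(matrix(genotypes, nrow = 1), thresholds)
}

#' Screen every offspring site of a genotype matrix
#'
#' Vectorised form of [screen_offspring_site()].
#'
#' @param gt Character matrix of genotype codes (sites x samples).
#' @inheritParams screen_offspring_site
#' @return Character vector of genotype codes or `"NONE"`, one per site.
#' @export
screen_offspring_sites <- function(gt, thresholds = ancestry_thresholds()) {
  check_gt_matrix(gt)
  calls <- call_major_genotypes(gt, thresholds$offspring_major_prop)
  too_missing <- calls$missing_fraction > thresholds$offspring_max_missing
  ifelse(too_missing | !calls$is_homozygous_major, "NONE", calls$major_genotype)
}

#' Assign the ancestral origin of an offspring genotype
#'
#' At an informative site (both ancestor majors homozygous and different),
#' the offspring's homozygous major genotype is traced to the ancestor whose
#' major it matches: `ANCESTOR_A` if it equals `major_a`, `ANCESTOR_B` if it
#' equals `major_b`, `UNASSIGNED` if it matches neither.
#'
#' @param offspring_gt,major_a,major_b Genotype codes (vectors of equal
#'   length); all must be homozygous and `major_a[i] != major_b[i]`.
#' @return Character vector in
#'   `"ANCESTOR_A"`/`"ANCESTOR_B"`/`"UNASSIGNED"`.
#' @export
#' @examples
#' assign_origin("HOM_ALT", major_a = "HOM_ALT", major_b = "HOM_REF")
assign_origin <- function(offspring_gt, major_a, major_b) {
  stop_not(length(major_a) == length(offspring_gt) && length(major_b) == length(offspring_gt),
           "inputs must have equal length")
  stop_not(all(major_a %in% GT_HOMOZYGOUS) && all(major_b %in% GT_HOMOZYGOUS) &&
             all(major_a != major_b),
           "sites must be informative: homozygous, differing ancestor majors")
  stop_not(all(offspring_gt %in% GT_HOMOZYGOUS),
           "`offspring_gt` must be homozygous (screen sites first)")
  ifelse(offspring_gt == major_a, "ANCESTOR_A",
         ifelse(offspring_gt == major_b, "ANCESTOR_B", "UNASSIGNED"))
}

#' Attribute offspring sites to their ancestor of origin
#'
#' Runs the full site-level attribution over three cohorts: aligns sites
#' across the two ancestor tables and the offspring table (by chromosome,
#' position and alleles; sites absent from any cohort are dropped with a
#' message), calls ancestor major genotypes at the 75% rule, keeps
#' ancestor-informative sites, screens offspring sites (missingness then the
#' 60% homozygous-major rule), and assigns each surviving site to an
#' ancestor.
#'
#' @param ancestor_a,ancestor_b,offspring Site tibbles from [read_vcf()]
#'   (typically after filtering).
#' @param thresholds An [ancestry_thresholds()] object.
#' @return A tibble with one row per aligned site: the site columns, the two
#'   ancestor calls (`major_a`, `major_b`), `informative`, the screened
#'   `offspring_gt` (code or `"NONE"`), and `origin` (`ANCESTOR_A`,
#'   `ANCESTOR_B` or `UNASSIGNED` for screened informative sites, `NA`
#'   otherwise).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_params(sites_per_chromosome = 60))
#' assign_ancestry(read_vcf(sim$ancestor_a_vcf), read_vcf(sim$ancestor_b_vcf),
#'                 read_vcf(sim$offspring_vcf))
assign_ancestry <- function(ancestor_a, ancestor_b, offspring,
                            thresholds = ancestry_thresholds()) {
  aligned <- align_cohorts(ancestor_a, ancestor_b, offspring)
  assign_ancestry_aligned(aligned, thresholds)
}

# Inner-join the three cohorts on chrom/pos/ref/alt, renaming the genotype
# matrix columns to gt_a / gt_b / gt_o. Sites absent from any cohort are
# dropped with a message.
align_cohorts <- function(ancestor_a, ancestor_b, offspring) {
  key <- c("chrom", "pos", "ref", "alt")
  slim <- function(x, nm) {
    stopifnot(is.data.frame(x), all(c(key, "gt") %in% names(x)))
    out <- x[, c(key, "variant_class"[("variant_class" %in% names(x))],
                 "mean_depth"[("mean_depth" %in% names(x) && nm == "gt_a")], "gt")]
    names(out)[names(out) == "gt"] <- nm
    out
  }
  aligned <- dplyr::inner_join(
    slim(ancestor_a, "gt_a"),
    dplyr::select(slim(ancestor_b, "gt_b"), -dplyr::any_of("variant_class")),
    by = key
  )
  aligned <- dplyr::inner_join(
    aligned,
    dplyr::select(slim(offspring, "gt_o"), -dplyr::any_of("variant_class")),
    by = key
  )
  n_dropped <- max(nrow(ancestor_a), nrow(ancestor_b), nrow(offspring)) - nrow(aligned)
  if (n_dropped > 0) {
    message(sprintf("%d site(s) absent from at least one cohort were dropped", n_dropped))
  }
  aligned
}

assign_ancestry_aligned <- function(aligned, thresholds = ancestry_thresholds()) {
  if (nrow(aligned) == 0) {
    return(dplyr::mutate(
      dplyr::select(aligned, -dplyr::any_of(c("gt_a", "gt_b", "gt_o"))),
      major_a = character(), major_b = character(), informative = logical(),
      offspring_gt = character(), origin = character()
    ))
  }

  calls_a <- call_major_genotypes(aligned$gt_a, thresholds$ancestor_major_prop)
  calls_b <- call_major_genotypes(aligned$gt_b, thresholds$ancestor_major_prop)
  informative <- detect_informative_sites(calls_a, calls_b)
  offspring_gt <- screen_offspring_sites(aligned$gt_o, thresholds)

  assignable <- informative & offspring_gt != "NONE"
  origin <- rep(NA_character_, nrow(aligned))
  if (any(assignable)) {
    origin[assignable] <- assign_origin(
      offspring_gt[assignable],
      calls_a$major_genotype[assignable],
      calls_b$major_genotype[assignable]
    )
  }

  out <- aligned[, setdiff(names(aligned), c("gt_a", "gt_b", "gt_o"))]
  out$major_a <- calls_a$major_genotype
  out$major_b <- calls_b$major_genotype
  out$informative <- informative
  out$offspring_gt <- offspring_gt
  out$origin <- origin
  out
}
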