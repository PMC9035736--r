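#' Simulation parameters for a two-ancestor composite cohort
#'
#' Bundles and validates the parameters of [simulate_dataset()]. The defaults
#' describe a small composite-breed study: two diverged ancestor cohorts of 3
#' and 18 resequenced individuals, and 6 offspring whose genotypes behave like
#' transcriptome-derived calls (heavy missingness away from genes).
#'
#' @param n_ancestor_a,n_ancestor_b,n_offspring Cohort sizes.
#' @param n_chromosomes,sites_per_chromosome,genes_per_chromosome Layout of the
#'   simulated genome. Genes are non-overlapping intervals; chromosome length
#'   scales with the number of sites (about one site per 150 bp).
#' @param fraction_informative Expected fraction of sites at which the two
#'   ancestor cohorts are (near-)fixed for different homozygous genotypes.
#' @param fraction_indel Expected fraction of sites emitted as indels rather
#'   than SNPs.
#' @param admixture_proportion Expected fraction of informative loci whose
#'   offspring genotypes derive from ancestor A.
#' @param fixation Probability that an individual in a cohort carries that
#'   cohort's fixed genotype at an informative site; the remainder is drawn as
#'   a drifted genotype (mostly heterozygous). `1` gives fully fixed ancestors.
#' @param missing_rate_genic,missing_rate_intergenic Per-genotype missing
#'   probabilities applied to the offspring cohort, by whether the site falls
#'   inside a gene body. The intergenic rate must be at least the genic rate
#'   (transcriptome-like coverage).
#' @param seed Integer seed; identical seeds give byte-identical output files.
#'
#' @return A validated list of class `sim_params`.
#' @export
#' @examples
#' sim_params(sites_per_chromosome = 100)
sim_params <- function(n_ancestor_a = 3,
                       n_ancestor_b = 18,
                       n_offspring = 6,
                       n_chromosomes = 2,
                       sites_per_chromosome = 1000,
                       genes_per_chromosome = 20,
                       fraction_informative = 0.5,
                       fraction_indel = 0.1,
                       admixture_proportion = 0.25,
                       fixation = 0.95,
                       missing_rate_genic = 0.05,
                       missing_rate_intergenic = 0.7,
                       seed = 1L) {
  p <- list(
    n_ancestor_a = check_count(n_ancestor_a, "n_ancestor_a"),
    n_ancestor_b = check_count(n_ancestor_b, "n_ancestor_b"),
    n_offspring = check_count(n_offspring, "n_offspring"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    sites_per_chromosome = check_count(sites_per_chromosome, "sites_per_chromosome"),
    genes_per_chromosome = check_count(genes_per_chromosome, "genes_per_chromosome"),
    fraction_informative = check_proportion(fraction_informative, "fraction_informative"),
    fraction_indel = check_proportion(fraction_indel, "fraction_indel"),
    admixture_proportion = check_proportion(admixture_proportion, "admixture_proportion"),
    fixation = check_proportion(fixation, "fixation"),
    missing_rate_genic = check_proportion(missing_rate_genic, "missing_rate_genic"),
    missing_rate_intergenic = check_proportion(missing_rate_intergenic, "missing_rate_intergenic"),
    seed = check_count(seed, "seed", min = 0)
  )
  stop_not(p$missing_rate_intergenic >= p$missing_rate_genic,
           "`missing_rate_intergenic` must be >= `missing_rate_genic`")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Simulate a two-ancestor composite-breed dataset
#'
#' Generates two ancestor cohorts, a composite offspring cohort with a known
#' per-locus ancestral origin, a gene annotation, and a truth table, and
#' writes them as VCF v4.2 / GFF3 / TSV. At informative sites the two ancestor
#' cohorts are fixed (or near-fixed, see `fixation`) for different homozygous
#' genotypes; every offspring locus draws its genotypes from the cohort named
#' by its true origin. INFO metrics (DP, QD, FS, MQ, SOR) and QUAL are sampled
#' from distributions that straddle the usual hard-filter thresholds so both
#' filter branches are exercised.
#'
#' @param params A [sim_params()] object.
#' @param dir Output directory (created if needed).
#' @return A list of class `sim_dataset` with elements `ancestor_a_vcf`,
#'   `ancestor_b_vcf`, `offspring_vcf`, `gff3`, `truth_path` (file paths),
#'   `truth` (tibble: `chrom`, `pos`, `true_origin`, `genic`, `gene_ids`),
#'   `genes` (tibble of gene models) and `params`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_params(sites_per_chromosome = 50, seed = 7))
#' sim$truth
simulate_dataset <- function(params = sim_params(), dir = tempfile("simcross")) {
  stop_not(inherits(params, "sim_params"), "`params` must be a `sim_params` object")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  sim <- withr::with_seed(params$seed, simulate_core(params))

  paths <- list(
    ancestor_a_vcf = file.path(dir, "ancestor_a.vcf"),
    ancestor_b_vcf = file.path(dir, "ancestor_b.vcf"),
    offspring_vcf = file.path(dir, "offspring.vcf"),
    gff3 = file.path(dir, "genes.gff3"),
    truth_path = file.path(dir, "truth.tsv")
  )
  write_vcf_file(sim$sites, sim$gt_a, paths$ancestor_a_vcf, sim$contigs)
  write_vcf_file(sim$sites, sim$gt_b, paths$ancestor_b_vcf, sim$contigs)
  write_vcf_file(sim$sites, sim$gt_o, paths$offspring_vcf, sim$contigs)
  write_gff3(sim$genes, paths$gff3)
  readr::write_tsv(sim$truth, paths$truth_path, progress = FALSE)

  structure(
    c(paths, list(truth = sim$truth, genes = sim$genes, params = params)),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", nrow(x$truth), "sites,", nrow(x$genes), "genes\n")
  cat("  dir:", dirname(x$ancestor_a_vcf), "\n")
  invisible(x)
}

# Core generator; assumes the RNG seed has been set by the caller.
simulate_core <- function(p) {
  chrom_len <- p$sites_per_chromosome * 150L
  chroms <- sprintf("chr%d", seq_len(p$n_chromosomes))
  contigs <- tibble::tibble(chrom = chroms, length = chrom_len)

  genes <- purrr::map_dfr(chroms, function(ch) simulate_genes(ch, chrom_len, p))
  per_chrom <- purrr::map(chroms, function(ch) {
    simulate_chromosome(ch, chrom_len, genes[genes$chrom == ch, , drop = FALSE], p)
  })

  list(
    sites = purrr::map_dfr(per_chrom, "sites"),
    gt_a = do.call(rbind, purrr::map(per_chrom, "gt_a")),
    gt_b = do.call(rbind, purrr::map(per_chrom, "gt_b")),
    gt_o = do.call(rbind, purrr::map(per_chrom, "gt_o")),
    truth = purrr::map_dfr(per_chrom, "truth"),
    genes = genes,
    contigs = contigs
  )
}

simulate_genes <- function(chrom, chrom_len, p) {
  n <- p$genes_per_chromosome
  slot <- chrom_len %/% n
  stop_not(slot >= 12, "chromosome too short for %d genes; raise sites_per_chromosome", n)
  start <- (seq_len(n) - 1L) * slot + sample.int(max(slot %/% 4L, 1L), n, replace = TRUE)
  len <- sample(seq(max(slot %/% 4L, 2L), max(slot %/% 2L, 3L)), n, replace = TRUE)
  end <- pmin(start + len - 1L, seq_len(n) * slot - 1L)
  tibble::tibble(
    gene_id = sprintf("%s_g%03d", chrom, seq_len(n)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

simulate_chromosome <- function(chrom, chrom_len, genes, p) {
  n <- p$sites_per_chromosome
  pos <- sort(sample.int(chrom_len, n))

  # gene overlap of the site itself (gene body), used for the genic flag
  idx <- findInterval(pos, genes$start)
  hit <- idx >= 1L & pos <= genes$end[pmax(idx, 1L)]
  gene_ids <- ifelse(hit, genes$gene_id[pmax(idx, 1L)], "")

  alleles <- simulate_alleles(n, p$fraction_indel)
  informative <- runif(n) < p$fraction_informative
  # which cohort carries the ALT homozygote at an informative site
  a_is_alt <- runif(n) < 0.5
  fixed_a <- ifelse(a_is_alt, "HOM_ALT", "HOM_REF")
  fixed_b <- ifelse(a_is_alt, "HOM_REF", "HOM_ALT")
  p_alt <- runif(n, 0.1, 0.9)   # shared ALT frequency at uninformative sites

  origin <- ifelse(
    informative,
    ifelse(runif(n) < p$admixture_proportion, "ANCESTOR_A", "ANCESTOR_B"),
    "UNINFORMATIVE"
  )
  fixed_o <- ifelse(origin == "ANCESTOR_A", fixed_a, fixed_b)

  gt_a <- draw_cohort(n, p$n_ancestor_a, informative, fixed_a, p$fixation, p_alt, "A")
  gt_b <- draw_cohort(n, p$n_ancestor_b, informative, fixed_b, p$fixation, p_alt, "B")
  gt_o <- draw_cohort(n, p$n_offspring, informative, fixed_o, p$fixation, p_alt, "O")

  miss_rate <- ifelse(hit, p$missing_rate_genic, p$missing_rate_intergenic)
  mask <- matrix(runif(n * p$n_offspring), nrow = n) < miss_rate
  gt_o[mask] <- "MISSING"

  info <- simulate_info(n, p$n_ancestor_a + p$n_ancestor_b + p$n_offspring)

  sites <- tibble::tibble(
    chrom = chrom, pos = pos,
    ref = alleles$ref, alt = alleles$alt,
    variant_class = alleles$variant_class,
    qual = info$qual, qd = info$qd, fs = info$fs,
    mq = info$mq, sor = info$sor, depth = info$depth
  )
  truth <- tibble::tibble(
    chrom = chrom, pos = pos,
    true_origin = origin, genic = hit, gene_ids = gene_ids
  )
  list(sites = sites, gt_a = gt_a, gt_b = gt_b, gt_o = gt_o, truth = truth)
}

simulate_alleles <- function(n, fraction_indel) {
  bases <- c("A", "C", "G", "T")
  ref1 <- sample(bases, n, replace = TRUE)
  # transitions dominate real variant calls (Ts/Tv around 2.4-2.5); draw the
  # transition partner with probability 0.71, a transversion otherwise
  transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
  alt1 <- ifelse(
    runif(n) < 0.71,
    transition_partner[ref1],
    vapply(ref1, function(b) sample(setdiff(bases, c(b, transition_partner[b])), 1),
           character(1))
  )
  is_indel <- runif(n) < fraction_indel
  is_ins <- is_indel & runif(n) < 0.5
  is_del <- is_indel & !is_ins
  tail_seq <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  tails <- vapply(sample(1:3, n, replace = TRUE), tail_seq, character(1))
  ref <- ifelse(is_del, paste0(ref1, tails), ref1)
  alt <- ifelse(is_ins, paste0(ref1, tails), ifelse(is_del, ref1, alt1))
  tibble::tibble(
    ref = ref, alt = alt,
    variant_class = ifelse(is_ins, "INSERTION", ifelse(is_del, "DELETION", "SNP"))
  )
}

# Genotypes for one cohort: at informative sites each individual carries the
# cohort's fixed genotype with probability `fixation`, otherwise a drifted one
# (HET 80% / opposite homozygote 20%); uninformative sites are Hardy-Weinberg
# draws at the shared ALT frequency.
draw_cohort <- function(n_sites, n_samples, informative, fixed, fixation, p_alt, prefix) {
  gt <- matrix("", nrow = n_sites, ncol = n_samples,
               dimnames = list(NULL, sprintf("%s%02d", prefix, seq_len(n_samples))))
  u <- matrix(runif(n_sites * n_samples), nrow = n_sites)
  opposite <- ifelse(fixed == "HOM_ALT", "HOM_REF", "HOM_ALT")
  fixed_m <- matrix(fixed, nrow = n_sites, ncol = n_samples)
  opp_m <- matrix(opposite, nrow = n_sites, ncol = n_samples)
  drift <- ifelse(u < fixation + 0.8 * (1 - fixation), "HET", opp_m)
  inf_gt <- ifelse(u < fixation, fixed_m, drift)

  q <- matrix(p_alt, nrow = n_sites, ncol = n_samples)
  v <- matrix(runif(n_sites * n_samples), nrow = n_sites)
  hwe <- ifelse(v < (1 - q)^2, "HOM_REF", ifelse(v < (1 - q)^2 + 2 * q * (1 - q), "HET", "HOM_ALT"))

  gt[informative, ] <- inf_gt[informative, ]
  gt[!informative, ] <- hwe[!informative, ]
  gt
}

# QUAL and INFO metrics drawn so that a small fraction of sites fails each of
# the usual hard-filter clauses (QUAL<30, QD<2, FS>60/200, MQ<40, SOR>4/10,
# mean depth < 5).
simulate_info <- function(n, n_samples_total) {
  mean_dp <- pmax(rnorm(n, mean = 12, sd = 3), 0)
  list(
    qual = round(rgamma(n, shape = 4, scale = 30), 2),
    qd = round(rnorm(n, mean = 18, sd = 7), 2),
    fs = round(rexp(n, rate = 1 / 15), 2),
    mq = round(rnorm(n, mean = 52, sd = 5), 2),
    sor = round(rgamma(n, shape = 2, scale = 0.7), 3),
    depth = as.integer(round(mean_dp * n_samples_total))
  )
}

# VCF v4.2 emitter. Reading goes through vcfR; writing is a line formatter so
# the simulator controls every byte (determinism contract).
write_vcf_file <- function(sites, gt, path, contigs) {
  gt_str <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1", MISSING = "./.")
  samples <- colnames(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crossorigin-simulator",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, contigs$length),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth across samples\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias phred score\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric odds ratio of strand bias\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )
  info <- sprintf("DP=%d;QD=%.2f;FS=%.2f;MQ=%.2f;SOR=%.3f",
                  as.integer(sites$depth), sites$qd, sites$fs, sites$mq, sites$sor)
  gt_cols <- apply(matrix(gt_str[gt], nrow = nrow(gt)), 1, paste, collapse = "\t")
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                sprintf("%.2f", sites$qual), "PASS", info, "GT", gt_cols,
                sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature per row with an `ID` attribute, 1-based inclusive
#' coordinates. Genes must be sorted and non-overlapping within a chromosome
#' (the simulator's guarantee); violations are an error.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand` (`+`, `-` or `.`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gff3")
#' write_gff3(tibble::tibble(gene_id = "g1", chrom = "chr1", start = 100, end = 500), f)
#' readLines(f)
write_gff3 <- function(genes, path) {
  needed <- c("gene_id", "chrom", "start", "end")
  stop_not(is.data.frame(genes) && all(needed %in% names(genes)),
           "`genes` must have columns %s", paste(needed, collapse = ", "))
  if (!"strand" %in% names(genes)) genes$strand <- "."
  stop_not(all(genes$start >= 1) && all(genes$start <= genes$end),
           "gene intervals must satisfy 1 <= start <= end")
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    stop_not(!is.unsorted(g$start, strictly = FALSE),
             "genes on %s are not sorted by start", ch)
    if (nrow(g) > 1) {
      stop_not(all(g$start[-1] > g$end[-nrow(g)]),
               "genes on %s overlap; the writer requires disjoint intervals", ch)
    }
  }
  lines <- sprintf("%s\tcrossorigin\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, as.integer(genes$start), as.integer(genes$end),
                   genes$strand, genes$gene_id)
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}
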