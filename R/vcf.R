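#' Read a VCF cohort into a tidy genotype table
#'
#' Parses a VCF (v4.2) with `vcfR` and returns one row per site with the INFO
#' metrics used by the hard filters plus a genotype matrix column. Genotypes
#' are collapsed to codes: `0/0` → `HOM_REF`, `0/1`/`1/0` → `HET`, `1/1` →
#' `HOM_ALT`, anything with a missing allele → `MISSING`; phase separators
#' (`|`) are treated as unphased; genotypes referring to a second ALT allele
#' are coded `MISSING` (such sites fall to the biallelic cohort filter).
#'
#' @param path Path to a VCF file (optionally gzipped).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class` (`SNP`/`INSERTION`/`DELETION`), `qual`, `qd`, `fs`, `mq`,
#'   `sor`, `depth` (INFO/DP), `mean_depth` (`depth / n_samples`) and a
#'   character matrix column `gt` (sites x samples) of genotype codes.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_params(sites_per_chromosome = 40))
#' read_vcf(sim$offspring_vcf)
read_vcf <- function(path) {
  stop_not(file.exists(path), "VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  stop_not(nrow(v@gt) == 0 || any(grepl("GT", v@gt[, "FORMAT"])),
           "VCF %s has no GT field in FORMAT", path)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(code_genotype(gt_raw), nrow = nrow(gt_raw),
               dimnames = list(NULL, colnames(gt_raw)))

  info_num <- function(tag) {
    suppressWarnings(vcfR::extract.info(v, element = tag, as.numeric = TRUE))
  }
  depth <- info_num("DP")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref,
    alt = alt,
    variant_class = classify_variant(ref, alt),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    qd = info_num("QD"),
    fs = info_num("FS"),
    mq = info_num("MQ"),
    sor = info_num("SOR"),
    depth = depth,
    mean_depth = depth / ncol(gt),
    gt = gt
  )
}

# "0/0" style strings -> genotype codes; NA, "." alleles and allele indices
# beyond 1 all become MISSING.
code_genotype <- function(x) {
  out <- rep("MISSING", length(x))
  ok <- !is.na(x)
  parts <- strsplit(x[ok], "[/|]")
  out[ok] <- vapply(parts, function(a) {
    if (length(a) != 2 || any(a == ".") || !all(a %in% c("0", "1"))) return("MISSING")
    c("HOM_REF", "HET", "HOM_ALT")[sum(a == "1") + 1L]
  }, character(1))
  out
}

#' Classify variants by allele length
#'
#' `SNP` when both alleles are single bases, `INSERTION` when the ALT allele
#' is longer than REF, `DELETION` when shorter. Multi-allelic ALT fields
#' (comma-separated) are classified from their first allele and left for the
#' biallelic cohort filter to discard.
#'
#' @param ref,alt Character vectors of REF and ALT alleles.
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_variant(c("A", "A", "ATT"), c("G", "AT", "A"))
classify_variant <- function(ref, alt) {
  alt1 <- sub(",.*", "", alt)
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt1) == 1 ~ "SNP",
    nchar(alt1) > nchar(ref) ~ "INSERTION",
    nchar(alt1) < nchar(ref) ~ "DELETION",
    TRUE ~ "SNP"
  )
}

#' Classify a single-base substitution as transition or transversion
#'
#' A transition swaps purine for purine (A<->G) or pyrimidine for pyrimidine
#' (C<->T); everything else among the 12 ordered base pairs is a transversion.
#'
#' @param ref,alt Character vectors of single bases in `A/C/G/T`; `ref[i]`
#'   must differ from `alt[i]`.
#' @return Character vector of `"TRANSITION"` / `"TRANSVERSION"`.
#' @export
#' @examples
#' classify_substitution(c("A", "C"), c("G", "A"))
classify_substitution <- function(ref, alt) {
  stop_not(length(ref) == length(alt), "`ref` and `alt` must have equal length")
  stop_not(all(ref %in% c("A", "C", "G", "T")) && all(alt %in% c("A", "C", "G", "T")),
           "alleles must be single bases in A/C/G/T")
  stop_not(all(ref != alt), "`ref` and `alt` must differ at every position")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "TRANSITION", "TRANSVERSION")
}
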