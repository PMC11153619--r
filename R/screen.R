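#' Screen configuration for allele-balance genotype classification
#'
#' Thresholds for classifying a pool (or deeply sequenced individual) as
#' homozygous or heterozygous from its alternate-allele read fraction, and the
#' heterogamety mode of the screen. Defaults are the pool-seq screen settings:
#' total depth at least 15 reads in each pool, homozygosity when the alternate
#' fraction is at most 7% (or at least 93%), heterozygosity when it lies in
#' the inclusive 45-55% window.
#'
#' @param mode `"XY"` (male heterogamety: males heterozygous, females
#'   homozygous) or `"ZW"` (the same conditions with the sexes interchanged).
#' @param min_depth Minimum total read depth (sum of the DP4 quadruple) for a
#'   call; below it the class is `LOW_DEPTH`.
#' @param hom_max_frac Maximum alternate fraction for `HOM_REF`; `1 -
#'   hom_max_frac` is the minimum for `HOM_ALT`.
#' @param het_low,het_high Inclusive bounds of the heterozygosity window on
#'   the alternate fraction.
#' @return A `screen_config` list.
#' @export
screen_config <- function(mode = c("XY", "ZW"), min_depth = 15L,
                          hom_max_frac = 0.07, het_low = 0.45,
                          het_high = 0.55) {
  mode <- match.arg(mode)
  stopifnot(min_depth >= 1,
            hom_max_frac > 0, hom_max_frac < het_low,
            het_low <= het_high, het_high < 1 - hom_max_frac)
  structure(list(mode = mode, min_depth = as.integer(min_depth),
                 hom_max_frac = hom_max_frac, het_low = het_low,
                 het_high = het_high),
            class = "screen_config")
}

#' Genotype classes
#'
#' The five classes assigned to one pool (or sample) at one variant site:
#' `HOM_REF`, `HOM_ALT`, `HET`, `LOW_DEPTH` (total depth below `min_depth`),
#' and `AMBIGUOUS` (adequate depth but the alternate fraction falls in none of
#' the declared windows).
#'
#' @format Character vector of the five class labels.
#' @export
GENOTYPE_CLASSES <- c("HOM_REF", "HOM_ALT", "HET", "LOW_DEPTH", "AMBIGUOUS")

#' Classify a genotype from an alternate-allele fraction and depth
#'
#' The shared window rule used both for pools and for individual amplicon
#' samples: `LOW_DEPTH` if `depth < min_depth`; else `HOM_REF` if the fraction
#' is at most `hom_max_frac`, `HOM_ALT` if at least `1 - hom_max_frac`, `HET`
#' if inside `[het_low, het_high]` (all bounds inclusive), else `AMBIGUOUS`.
#'
#' @param fraction Alternate-allele fraction(s) in `[0, 1]`.
#' @param depth Total read depth(s), recycled against `fraction`.
#' @param cfg A [screen_config()].
#' @return Character vector of [GENOTYPE_CLASSES].
#' @export
classify_fraction <- function(fraction, depth, cfg = screen_config()) {
  n <- max(length(fraction), length(depth))
  fraction <- rep_len(fraction, n)
  depth <- rep_len(depth, n)
  out <- rep("AMBIGUOUS", n)
  out[fraction <= cfg$hom_max_frac + .EPS] <- "HOM_REF"
  out[fraction >= 1 - cfg$hom_max_frac - .EPS] <- "HOM_ALT"
  het <- fraction >= cfg$het_low - .EPS & fraction <= cfg$het_high + .EPS
  out[het] <- "HET"
  out[depth < cfg$min_depth] <- "LOW_DEPTH"
  out
}

#' Classify a pool genotype from a DP4 quadruple
#'
#' Total depth is the sum of the strand-resolved quadruple (ref-fwd, ref-rev,
#' alt-fwd, alt-rev) — not a caller's DP field — and the alternate fraction is
#' `(alt_fwd + alt_rev) / total`.
#'
#' @param dp4 Numeric vector of length 4, or an n x 4 matrix (one row per
#'   site), ordered ref-fwd, ref-rev, alt-fwd, alt-rev.
#' @param cfg A [screen_config()].
#' @return Character vector of [GENOTYPE_CLASSES], one per row.
#' @export
#' @examples
#' classify_pool_genotype(c(20, 18, 1, 1))   # f = 0.05 -> HOM_REF
#' classify_pool_genotype(c(10, 10, 9, 11))  # f = 0.50 -> HET
classify_pool_genotype <- function(dp4, cfg = screen_config()) {
  if (is.null(dim(dp4))) dp4 <- matrix(dp4, ncol = 4L, byrow = TRUE)
  stopifnot(ncol(dp4) == 4L, all(dp4 >= 0))
  total <- rowSums(dp4)
  alt <- dp4[, 3L] + dp4[, 4L]
  frac <- ifelse(total > 0, alt / total, 0)
  classify_fraction(frac, total, cfg)
}

#' Screen pooled variants for the sex-linked allele-balance pattern
#'
#' Classifies both pools at every variant and retains sites matching the
#' mode's pattern: in XY mode the male pool must be `HET` and the female pool
#' `HOM_REF` or `HOM_ALT` (the reference allele may itself be the Y allele);
#' ZW mode interchanges the sexes. Variants with `LOW_DEPTH` or `AMBIGUOUS`
#' in either pool are dropped; both pools must meet `min_depth`.
#'
#' @param variants A pool-variant table as returned by [read_pool_vcf()]:
#'   columns `contig`, `pos`, `ref`, `alt`, `type`, and the eight depth
#'   columns `female_ref_fwd` ... `male_alt_rev`.
#' @param cfg A [screen_config()]; `cfg$mode` selects XY or ZW.
#' @return A list with `candidates` (the retained rows plus `female_frac`,
#'   `male_frac`, `female_class`, `male_class`), `n_input`, and `drop_counts`,
#'   a named vector of drop reasons (`low_depth`, `not_het_in_heterogametic`,
#'   `not_hom_in_homogametic`).
#' @export
screen_variants <- function(variants, cfg = screen_config()) {
  variants <- as.data.table(variants)
  ann <- annotate_genotypes(variants, cfg)
  if (cfg$mode == "XY") {
    het_class <- ann$male_class; hom_class <- ann$female_class
  } else {
    het_class <- ann$female_class; hom_class <- ann$male_class
  }
  low <- het_class == "LOW_DEPTH" | hom_class == "LOW_DEPTH"
  het_ok <- het_class == "HET"
  hom_ok <- hom_class %in% c("HOM_REF", "HOM_ALT")
  keep <- !low & het_ok & hom_ok
  drop_counts <- c(
    low_depth = sum(low),
    not_het_in_heterogametic = sum(!low & !het_ok),
    not_hom_in_homogametic = sum(!low & het_ok & !hom_ok)
  )
  list(candidates = ann[keep],
       n_input = nrow(ann),
       drop_counts = drop_counts)
}

# Add per-pool alt fractions and genotype classes to a variant table.
annotate_genotypes <- function(variants, cfg = screen_config()) {
  v <- as.data.table(variants)
  for (pool in c("female", "male")) {
    cols <- paste0(pool, c("_ref_fwd", "_ref_rev", "_alt_fwd", "_alt_rev"))
    stopifnot(all(cols %in% names(v)))
    dp4 <- as.matrix(v[, cols, with = FALSE])
    total <- rowSums(dp4)
    frac <- ifelse(total > 0, (dp4[, 3L] + dp4[, 4L]) / total, 0)
    cls <- classify_pool_genotype(dp4, cfg)
    set(v, j = paste0(pool, c("_depth", "_frac", "_class")),
        value = list(total, frac, cls))
  }
  v[]
}
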