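#' Classify one deeply sequenced individual from its allele fraction
#'
#' The same window rule as the pool classifier ([classify_fraction()]),
#' applied per individual to deep amplicon counts. The default configuration
#' reuses the pool windows (hom <= 7% / >= 93%, het 45-55%) with `min_depth`
#' raised to 30 reads, appropriate for target-enrichment depths.
#'
#' @param fraction Alternate-allele fraction(s).
#' @param depth Total read depth(s).
#' @param cfg A [screen_config()]; default [amplicon_config()].
#' @return Character vector of [GENOTYPE_CLASSES].
#' @export
call_sample_genotype <- function(fraction, depth, cfg = amplicon_config()) {
  classify_fraction(fraction, depth, cfg)
}

#' Default per-individual screen configuration for amplicon panels
#' @inheritParams screen_config
#' @return A [screen_config()] with `min_depth = 30`.
#' @export
amplicon_config <- function(min_depth = 30L, hom_max_frac = 0.07,
                            het_low = 0.45, het_high = 0.55) {
  screen_config(mode = "XY", min_depth = min_depth,
                hom_max_frac = hom_max_frac, het_low = het_low,
                het_high = het_high)
}

#' Per-species male-specific SNP discovery
#'
#' For one species' sexed samples, retains the positions that are
#' heterozygous in males while homozygous (either allele) in females.
#' `LOW_DEPTH` samples are excluded from the quorum; a site needs at least
#' one informative sample of each sex, otherwise it is excluded and counted.
#' Under strict mode (`max_discordant = 0`) every informative male must be
#' `HET` and every informative female `HOM_REF`/`HOM_ALT`; a tolerance allows
#' up to `max_discordant` discordant informative samples per sex.
#'
#' @param calls Long-format table for one species: columns `sample_id`,
#'   `sex` (`"F"`/`"M"`), `contig`, `pos`, `ref_count`, `alt_count`.
#' @param cfg Per-individual [screen_config()] (default [amplicon_config()]).
#' @param max_discordant Discordant informative samples tolerated per sex.
#' @return A list: `sites` (data.table `contig`, `pos` of retained
#'   positions), `n_sites_tested`, `n_uninformative` (sites lacking an
#'   informative sample in one sex).
#' @export
species_male_specific_snps <- function(calls, cfg = amplicon_config(),
                                       max_discordant = 0L) {
  dt <- as.data.table(calls)
  stopifnot(all(c("sex", "contig", "pos", "ref_count", "alt_count") %in%
                  names(dt)),
            all(dt$sex %in% c("F", "M")))
  dt[, depth := ref_count + alt_count]
  dt[, fraction := ifelse(depth > 0, alt_count / depth, 0)]
  dt[, class := classify_fraction(fraction, depth, cfg)]
  dt[, informative := class != "LOW_DEPTH"]
  dt[, ok := fifelse(sex == "M", class == "HET",
                     class %in% c("HOM_REF", "HOM_ALT"))]
  per_site <- dt[, .(
    m_inf = sum(informative & sex == "M"),
    f_inf = sum(informative & sex == "F"),
    m_disc = sum(informative & sex == "M" & !ok),
    f_disc = sum(informative & sex == "F" & !ok)
  ), by = .(contig, pos)]
  uninformative <- per_site$m_inf == 0L | per_site$f_inf == 0L
  retained <- !uninformative &
    per_site$m_disc <= max_discordant & per_site$f_disc <= max_discordant
  sites <- per_site[retained, .(contig, pos)]
  setorder(sites, contig, pos)
  list(sites = sites,
       n_sites_tested = nrow(per_site),
       n_uninformative = sum(uninformative))
}

#' Intersect male-specific SNP sets across species
#'
#' Counts, per position, the species in which it is male-specific and
#' stratifies by sharing level k; positions shared by at least `min_species`
#' species are the cross-taxon diagnostic candidates.
#'
#' @param sets Named list (one entry per species) of site tables with
#'   `contig`, `pos` on a shared reference coordinate system.
#' @param min_species Minimum sharing level k to retain.
#' @return A list: `report` (data.table `contig`, `pos`, `k`, `species` —
#'   all positions with their sharing level), `retained` (subset with
#'   `k >= min_species`), `by_level` (counts of positions at each k).
#' @export
intersect_across_species <- function(sets, min_species = 2L) {
  stopifnot(is.list(sets), !is.null(names(sets)), min_species >= 1)
  long <- rbindlist(lapply(names(sets), function(sp) {
    s <- as.data.table(sets[[sp]])
    if (nrow(s) == 0L)
      return(data.table(contig = character(), pos = numeric(),
                        species = character()))
    unique(s[, .(contig, pos)])[, species := sp]
  }))
  if (nrow(long) == 0L) {
    rep0 <- data.table(contig = character(), pos = numeric(), k = integer(),
                       species = character())
    return(list(report = rep0, retained = rep0,
                by_level = data.table(k = integer(), n_sites = integer())))
  }
  report <- long[, .(k = .N, species = paste(sort(species), collapse = ",")),
                 by = .(contig, pos)]
  setorder(report, contig, pos)
  by_level <- report[, .(n_sites = .N), by = k][order(k)]
  list(report = report,
       retained = report[k >= min_species],
       by_level = by_level)
}

#' Run the cross-species amplicon analysis from a long-format call table
#'
#' @param calls Long-format table: `sample_id`, `species`, `sex`, `contig`,
#'   `pos`, `ref_count`, `alt_count`.
#' @param cfg Per-individual [screen_config()].
#' @param max_discordant Per-sex discordance tolerance (0 = strict).
#' @param min_species Minimum sharing level.
#' @return A list: `per_species` (named list of
#'   [species_male_specific_snps()] results) and the
#'   [intersect_across_species()] output.
#' @export
run_amplicon_intersect <- function(calls, cfg = amplicon_config(),
                                   max_discordant = 0L, min_species = 2L) {
  dt <- as.data.table(calls)
  stopifnot("species" %in% names(dt))
  per_species <- lapply(split(dt, by = "species", sorted = TRUE),
                        species_male_specific_snps,
                        cfg = cfg, max_discordant = max_discordant)
  sets <- lapply(per_species, `[[`, "sites")
  c(list(per_species = per_species),
    intersect_across_species(sets, min_species = min_species))
}
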