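library(data.table)

## Independent oracles: each re-derives an expected result by a different
## route (brute force, enumeration, per-base expansion) than the package.

# Transitive closure of the pairwise <=max_gap relation, via graph
# components — independent of the sorted-gap implementation.
oracle_cluster <- function(pos, max_gap) {
  if (length(pos) == 0L) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  unname(lapply(split(pos, comp), sort))
}

# The three textual screen rules applied independently per variant row.
oracle_screen_keep <- function(variants, mode, min_depth = 15,
                               hom = 0.07, lo = 0.45, hi = 0.55) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    r <- as.list(variants[i])
    fd <- r$female_ref_fwd + r$female_ref_rev + r$female_alt_fwd + r$female_alt_rev
    md <- r$male_ref_fwd + r$male_ref_rev + r$male_alt_fwd + r$male_alt_rev
    if (fd < min_depth || md < min_depth) next
    ff <- (r$female_alt_fwd + r$female_alt_rev) / fd
    mf <- (r$male_alt_fwd + r$male_alt_rev) / md
    keep[i] <- if (mode == "XY") {
      (mf >= lo && mf <= hi) && (ff <= hom || ff >= 1 - hom)
    } else {
      (ff >= lo && ff <= hi) && (mf <= hom || mf >= 1 - hom)
    }
  }
  keep
}

# Span-weighted histogram of nonzero coverage values; mode = value with the
# largest total span, ties toward the smaller value.
oracle_modal <- function(track) {
  nz <- track[track$value > 0, ]
  spans <- tapply(nz$end - nz$start, nz$value, sum)
  vals <- as.numeric(names(spans))
  min(vals[spans == max(spans)])
}

# Per-base value of a single-contig track.
oracle_value_at <- function(track, base) {
  hit <- track$start <= base & base < track$end
  if (any(hit)) track$value[hit][1L] else 0
}

# Per-site amplicon rule, evaluated by explicit enumeration.
oracle_male_specific <- function(calls, min_depth = 30, hom = 0.07,
                                 lo = 0.45, hi = 0.55, max_discordant = 0) {
  cls <- function(ref, alt) {
    d <- ref + alt
    if (d < min_depth) return("LOW_DEPTH")
    f <- alt / d
    if (f >= lo && f <= hi) return("HET")
    if (f <= hom) return("HOM_REF")
    if (f >= 1 - hom) return("HOM_ALT")
    "AMBIGUOUS"
  }
  out <- list()
  for (pp in sort(unique(calls$pos))) {
    site <- calls[calls$pos == pp, ]
    cl <- mapply(cls, site$ref_count, site$alt_count)
    inf <- cl != "LOW_DEPTH"
    m <- site$sex == "M" & inf
    f <- site$sex == "F" & inf
    if (!any(m) || !any(f)) next
    if (sum(cl[m] != "HET") <= max_discordant &&
        sum(!cl[f] %in% c("HOM_REF", "HOM_ALT")) <= max_discordant)
      out[[length(out) + 1L]] <- pp
  }
  unlist(out) %||% numeric(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random pooled variant table spanning all genotype classes.
random_variants <- function(n, seed) {
  set.seed(seed)
  totals_f <- sample(0:60, n, replace = TRUE)
  totals_m <- sample(0:60, n, replace = TRUE)
  frac_f <- runif(n)
  frac_m <- runif(n)
  alt_f <- rbinom(n, totals_f, frac_f)
  alt_m <- rbinom(n, totals_m, frac_m)
  af <- rbinom(n, alt_f, 0.5); rf <- rbinom(n, totals_f - alt_f, 0.5)
  am <- rbinom(n, alt_m, 0.5); rm_ <- rbinom(n, totals_m - alt_m, 0.5)
  data.table(
    contig = "c1", pos = sort(sample.int(1e6, n)),
    ref = "A", alt = "T", type = "SNP",
    female_ref_fwd = rf, female_ref_rev = totals_f - alt_f - rf,
    female_alt_fwd = af, female_alt_rev = alt_f - af,
    male_ref_fwd = rm_, male_ref_rev = totals_m - alt_m - rm_,
    male_alt_fwd = am, male_alt_rev = alt_m - am)
}

# Swap the two pools' depth columns (relabelling the sexes).
swap_pools <- function(variants) {
  v <- data.table::copy(variants)
  fcols <- paste0("female", c("_ref_fwd", "_ref_rev", "_alt_fwd", "_alt_rev"))
  mcols <- paste0("male", c("_ref_fwd", "_ref_rev", "_alt_fwd", "_alt_rev"))
  setnames(v, c(fcols, mcols), c(paste0("tmp_", fcols), fcols))
  setnames(v, paste0("tmp_", fcols), mcols)
  v
}

# A desk-scale simulation for fast module tests (1 Mb, smaller planted
# features, same statistical structure as the defaults).
quick_sim <- function(seed, ...) {
  simulate_poolsex(sim_config(
    genome = c(chr1 = 1e6), sdr_start = 400001, sdr_length = 66000,
    sdr_n_sites = 60, y_insertion_length = 20000, seed = seed, ...))
}

cluster_members <- function(clusters) {
  unname(lapply(clusters$members, as.numeric))
}
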