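#' Configuration for the pooled-sequencing simulator
#'
#' Defines the synthetic study: two pools of `n_per_pool` diploid individuals
#' (one per sex, default 22 + 22), background population SNPs at
#' `background_snp_rate` per bp with allele frequencies uniform on
#' `maf_range`, one fully sex-linked block (default 66 kb with 100 fixed
#' X/Y-divergent sites, every male X/Y-heterozygous, every female
#' homozygous) and a Y-specific insertion carried as a separate contig
#' (default 55 kb) covered at half the diploid rate in the male pool and at a
#' small spurious fraction (default 1%) in the female pool. Read depth is
#' Poisson with mean `depth_mean` per pool and sequencing error folds into
#' the read-draw probability. `system = "ZW"` mirrors every sex-specific
#' feature onto the female pool.
#'
#' @param genome Named numeric vector of contig lengths (bp), excluding the
#'   Y-insertion contig. Default one 10-Mb contig — a desk-scale stand-in for
#'   a multi-Gb amphibian genome.
#' @param n_per_pool Diploid individuals per sex pool.
#' @param depth_mean Mean pool read depth (Poisson lambda) at the diploid
#'   rate.
#' @param error_rate Per-base miscall probability.
#' @param background_snp_rate Expected background SNPs per bp.
#' @param maf_range Uniform bounds of background population allele
#'   frequencies.
#' @param system `"XY"` (male heterogamety) or `"ZW"`.
#' @param sdr_contig,sdr_start,sdr_length Placement of the sex-determining
#'   block on the genome.
#' @param sdr_n_sites Number of fixed divergent sites planted in the block.
#' @param y_contig,y_insertion_length The hemizygous-insertion contig.
#' @param spurious_fraction Homogametic-pool coverage over the insertion,
#'   as a fraction of `depth_mean`.
#' @param coverage_bin Bedgraph emission resolution (bp): per-bin coverage
#'   is a Poisson draw of the binned read mass, bin-averaged and rounded to
#'   integer.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome = c(chr1 = 1e7), n_per_pool = 22L,
                       depth_mean = 40, error_rate = 0.002,
                       background_snp_rate = 0.002,
                       maf_range = c(0.05, 0.5),
                       system = c("XY", "ZW"),
                       sdr_contig = names(genome)[1L],
                       sdr_start = 5000001, sdr_length = 66000L,
                       sdr_n_sites = 100L,
                       y_contig = "Y_hap", y_insertion_length = 55000L,
                       spurious_fraction = 0.01,
                       coverage_bin = 100L, seed) {
  system <- match.arg(system)
  if (missing(seed) || is.null(seed))
    stop("sim_config: 'seed' is mandatory")
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("sim_config: 'genome' must be a named vector of contig lengths")
  for (f in c("error_rate", "background_snp_rate", "spurious_fraction")) {
    val <- get(f)
    if (val < 0 || val > 1) stop("sim_config: '", f, "' must be in [0,1]")
  }
  if (depth_mean <= 0) stop("sim_config: 'depth_mean' must be > 0")
  if (!sdr_contig %in% names(genome))
    stop("sim_config: 'sdr_contig' not in genome")
  sdr_end <- sdr_start + sdr_length - 1
  if (sdr_start < 1 || sdr_end > genome[[sdr_contig]])
    stop("sim_config: 'sdr' interval outside its contig")
  if (sdr_n_sites > sdr_length)
    stop("sim_config: 'sdr_n_sites' exceeds 'sdr_length'")
  if (y_contig %in% names(genome))
    stop("sim_config: 'y_contig' must not collide with a genome contig")
  structure(list(
    genome = genome, n_per_pool = as.integer(n_per_pool),
    depth_mean = depth_mean, error_rate = error_rate,
    background_snp_rate = background_snp_rate, maf_range = maf_range,
    system = system, sdr_contig = sdr_contig, sdr_start = sdr_start,
    sdr_end = sdr_end, sdr_n_sites = as.integer(sdr_n_sites),
    y_contig = y_contig, y_insertion_length = as.integer(y_insertion_length),
    spurious_fraction = spurious_fraction,
    coverage_bin = as.integer(coverage_bin), seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a two-pool sequencing experiment with a planted sex locus
#'
#' Draws, per site, each pool's allele count as Binomial(2 * n_per_pool, p)
#' (pool frequency q = k/2n), site depth D ~ Poisson(depth_mean), alternate
#' reads ~ Binomial(D, q(1-e) + (1-q)e) and a Binomial(., 0.5) strand split.
#' Divergent sites in the sex-determining block have q = 0.5 exactly in the
#' heterogametic pool and 0 in the other. The Y-insertion contig carries no
#' variants; its coverage is Poisson at depth_mean/2 in the heterogametic
#' pool and depth_mean * spurious_fraction in the other. The RNG is R's
#' Mersenne-Twister, seeded from `cfg$seed`; the same seed yields identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @return A list: `variants` (emitted variant table in the
#'   [read_pool_vcf()] layout — sites with zero alternate reads in both
#'   pools are not emitted, as a caller would not report them),
#'   `female_coverage`, `male_coverage` (bedgraph-semantics tracks), `truth`
#'   (list: `sdr` interval, `divergent_sites`, `y_insertion` interval,
#'   `background` sites with population frequencies) and `config`.
#' @export
simulate_poolsex <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n2 <- 2L * cfg$n_per_pool

  ## planted divergent sites
  div_pos <- sort(sample.int(cfg$sdr_end - cfg$sdr_start + 1L,
                             cfg$sdr_n_sites)) + cfg$sdr_start - 1L
  ## background sites per contig
  bg <- rbindlist(lapply(names(cfg$genome), function(ct) {
    len <- cfg$genome[[ct]]
    n_snp <- rbinom(1L, len, cfg$background_snp_rate)
    data.table(contig = ct, pos = sort(sample.int(len, n_snp)))
  }))
  bg <- bg[!(contig == cfg$sdr_contig & pos %in% div_pos)]
  bg[, p := runif(.N, cfg$maf_range[1L], cfg$maf_range[2L])]

  sites <- rbind(
    bg[, .(contig, pos, p, planted = FALSE)],
    data.table(contig = cfg$sdr_contig, pos = as.numeric(div_pos), p = NA_real_,
               planted = TRUE))
  setorder(sites, contig, pos)
  ns <- nrow(sites)

  ## pool allele frequencies
  qf <- numeric(ns); qm <- numeric(ns)
  bgr <- !sites$planted
  qf[bgr] <- rbinom(sum(bgr), n2, sites$p[bgr]) / n2
  qm[bgr] <- rbinom(sum(bgr), n2, sites$p[bgr]) / n2
  if (cfg$system == "XY") {
    qm[!bgr] <- 0.5; qf[!bgr] <- 0
  } else {
    qf[!bgr] <- 0.5; qm[!bgr] <- 0
  }

  draw_pool <- function(q) {
    d <- rpois(ns, cfg$depth_mean)
    pr <- q * (1 - cfg$error_rate) + (1 - q) * cfg$error_rate
    alt <- rbinom(ns, d, pr)
    ref <- d - alt
    alt_fwd <- rbinom(ns, alt, 0.5)
    ref_fwd <- rbinom(ns, ref, 0.5)
    data.table(ref_fwd = ref_fwd, ref_rev = ref - ref_fwd,
               alt_fwd = alt_fwd, alt_rev = alt - alt_fwd)
  }
  fdp <- draw_pool(qf)
  mdp <- draw_pool(qm)

  alleles <- draw_alleles(ns, sites$planted)
  variants <- data.table(
    contig = sites$contig, pos = sites$pos,
    ref = alleles$ref, alt = alleles$alt, type = alleles$type,
    female_ref_fwd = fdp$ref_fwd, female_ref_rev = fdp$ref_rev,
    female_alt_fwd = fdp$alt_fwd, female_alt_rev = fdp$alt_rev,
    male_ref_fwd = mdp$ref_fwd, male_ref_rev = mdp$ref_rev,
    male_alt_fwd = mdp$alt_fwd, male_alt_rev = mdp$alt_rev)
  emitted <- variants[female_alt_fwd + female_alt_rev +
                        male_alt_fwd + male_alt_rev >= 1L]

  ## coverage: diploid everywhere on the genome; hemizygous insertion contig
  het_is_male <- cfg$system == "XY"
  lam_het <- cfg$depth_mean / 2
  lam_hom <- cfg$depth_mean * cfg$spurious_fraction
  cov_f <- list(); cov_m <- list()
  for (ct in names(cfg$genome)) {
    cov_f[[ct]] <- sim_track(ct, cfg$genome[[ct]], cfg$depth_mean,
                             cfg$coverage_bin)
    cov_m[[ct]] <- sim_track(ct, cfg$genome[[ct]], cfg$depth_mean,
                             cfg$coverage_bin)
  }
  ylen <- cfg$y_insertion_length
  cov_f[[cfg$y_contig]] <- sim_track(cfg$y_contig, ylen,
                                     if (het_is_male) lam_hom else lam_het,
                                     cfg$coverage_bin)
  cov_m[[cfg$y_contig]] <- sim_track(cfg$y_contig, ylen,
                                     if (het_is_male) lam_het else lam_hom,
                                     cfg$coverage_bin)

  truth <- list(
    sdr = data.table(contig = cfg$sdr_contig, start = cfg$sdr_start,
                     end = cfg$sdr_end),
    divergent_sites = data.table(contig = cfg$sdr_contig,
                                 pos = as.numeric(div_pos)),
    y_insertion = data.table(contig = cfg$y_contig, start = 1,
                             end = as.numeric(ylen)),
    background = bg)
  fcov <- rbindlist(cov_f); setorder(fcov, contig, start)
  mcov <- rbindlist(cov_m); setorder(mcov, contig, start)
  list(variants = emitted,
       female_coverage = fcov,
       male_coverage = mcov,
       truth = truth, config = cfg)
}

# One pool's binned coverage over one contig: per-bin Poisson read mass,
# bin-averaged, rounded to integer depth; equal-valued adjacent bins are
# coalesced and zero bins dropped (bedgraph gap = 0).
sim_track <- function(ct, len, lambda, bin) {
  edges <- unique(c(seq(0, len, by = bin), len))
  widths <- diff(edges)
  val <- round(rpois(length(widths), lambda * widths) / widths)
  r <- rle(val)
  ends <- edges[-1L][cumsum(r$lengths)]
  starts <- c(0, ends[-length(ends)])
  tr <- data.table(contig = ct, start = starts, end = ends, value = r$values)
  tr[value > 0]
}

#' Write simulator output to a directory
#'
#' Emits `pools.vcf` (two samples, DP4 FORMAT), `female.bedgraph`,
#' `male.bedgraph`, `truth_regions.bed` (planted sex-determining block and
#' Y insertion), `truth_sites.tsv` (planted divergent and background sites)
#' and `config.txt` (key=value echo of every parameter including the seed).
#' Output is byte-deterministic given the same simulation.
#'
#' @param sim Output of [simulate_poolsex()].
#' @param dir Output directory (created if absent).
#' @return Named vector of file paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  contig_lengths <- c(cfg$genome,
                      stats::setNames(cfg$y_insertion_length, cfg$y_contig))
  paths <- c(vcf = file.path(dir, "pools.vcf"),
             female = file.path(dir, "female.bedgraph"),
             male = file.path(dir, "male.bedgraph"),
             regions = file.path(dir, "truth_regions.bed"),
             sites = file.path(dir, "truth_sites.tsv"),
             config = file.path(dir, "config.txt"))
  write_pool_vcf(sim$variants, paths[["vcf"]], contig_lengths)
  write_bedgraph(sim$female_coverage, paths[["female"]],
                 params = list(pool = "female", seed = cfg$seed))
  write_bedgraph(sim$male_coverage, paths[["male"]],
                 params = list(pool = "male", seed = cfg$seed))
  tr <- sim$truth
  writeLines(c(comment_header(),
               paste(tr$sdr$contig, format(tr$sdr$start - 1, scientific = FALSE),
                     format(tr$sdr$end, scientific = FALSE), "sdr", sep = "\t"),
               paste(tr$y_insertion$contig,
                     format(tr$y_insertion$start - 1, scientific = FALSE),
                     format(tr$y_insertion$end, scientific = FALSE),
                     "y_insertion", sep = "\t")),
             paths[["regions"]])
  sites <- rbind(
    tr$divergent_sites[, .(contig, pos, kind = "divergent", p = NA_real_)],
    tr$background[, .(contig, pos, kind = "background", p)])
  setorder(sites, contig, pos)
  fwrite(sites, paths[["sites"]], sep = "\t")
  flat <- cfg[names(cfg) != "genome"]
  flat$maf_range <- paste(cfg$maf_range, collapse = ",")
  writeLines(c(paste0("genome=", paste(names(cfg$genome), cfg$genome,
                                       sep = ":", collapse = ",")),
               paste0(names(flat), "=",
                      vapply(flat, function(x) paste(x, collapse = ","),
                             character(1L)))),
             paths[["config"]])
  invisible(paths)
}

# Random ref/alt alleles. Planted divergent sites are SNPs; background sites
# are mostly SNPs with a small admixture of INDELs and MNPs (all three are
# called upstream and screened identically).
draw_alleles <- function(n, planted,
                         type_prob = c(SNP = 0.95, INDEL = 0.03, MNP = 0.02)) {
  bases <- c("A", "C", "G", "T")
  type <- sample(names(type_prob), n, replace = TRUE, prob = type_prob)
  type[planted] <- "SNP"
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) + shift - 1L) %% 4L + 1L]
  ins <- sample(bases, n, replace = TRUE)
  is_indel <- type == "INDEL"
  alt[is_indel] <- paste0(ref[is_indel], ins[is_indel])
  is_mnp <- type == "MNP"
  ref[is_mnp] <- paste0(ref[is_mnp], ins[is_mnp])
  alt2 <- bases[(match(ins, bases) %% 4L) + 1L]
  alt[is_mnp] <- paste0(alt[is_mnp], alt2[is_mnp])
  list(ref = ref, alt = alt, type = type)
}

#' Simulate a cross-species amplicon panel with known truth
#'
#' Builds per-individual deep-amplicon allele counts for several species
#' over one target region. Sites in a shared sex-linked block are
#' male-specific (males heterozygous at fraction 0.5, females homozygous) in
#' every species; species-private sites are male-specific in exactly one
#' species; all other species are homozygous there. Per-sample depth is
#' Poisson and alternate counts Binomial with error folded in, as in
#' [simulate_poolsex()].
#'
#' @param n_species Number of species (named `sp1`, `sp2`, ...).
#' @param males,females Sexed samples per species.
#' @param region_length Target region length (bp) on contig `"target"`.
#' @param shared_block 1-based `c(start, end)` of the shared sex-linked
#'   block within the region.
#' @param n_shared_sites Male-specific sites planted in the shared block
#'   (shared by all species).
#' @param n_private_sites Per-species private male-specific sites planted
#'   outside the block.
#' @param depth_mean Per-sample Poisson depth.
#' @param error_rate Per-base miscall probability.
#' @param seed Integer seed (mandatory).
#' @return A list: `calls` (long-format table `sample_id`, `species`, `sex`,
#'   `contig`, `pos`, `ref_count`, `alt_count`) and `truth` (list:
#'   `shared_sites`, `private_sites` with their species, `shared_block`).
#' @export
make_amplicon_panel <- function(n_species = 5L, males = 4L, females = 4L,
                                region_length = 100000L,
                                shared_block = c(10001L, 20000L),
                                n_shared_sites = 20L,
                                n_private_sites = 30L,
                                depth_mean = 500, error_rate = 0.002,
                                seed) {
  if (missing(seed) || is.null(seed))
    stop("make_amplicon_panel: 'seed' is mandatory")
  stopifnot(shared_block[1L] >= 1, shared_block[2L] <= region_length,
            n_shared_sites <= shared_block[2L] - shared_block[1L] + 1)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  species <- paste0("sp", seq_len(n_species))
  shared_pos <- if (n_shared_sites > 0)
    sort(sample(shared_block[1L]:shared_block[2L], n_shared_sites))
  else integer(0)
  outside <- setdiff(seq_len(region_length),
                     shared_block[1L]:shared_block[2L])
  ## private sites drawn jointly without replacement so no position is
  ## accidentally "private" to two species
  private <- if (n_private_sites > 0) {
    priv_all <- sample(outside, n_private_sites * n_species)
    data.table(species = rep(species, each = n_private_sites),
               pos = priv_all)[order(species, pos)]
  } else data.table(species = character(), pos = integer())
  all_pos <- sort(unique(c(shared_pos, private$pos)))

  calls <- rbindlist(lapply(species, function(sp) {
    own_private <- private[species == sp, pos]
    samp <- data.table(
      sample_id = paste0(sp, "_", c(paste0("M", seq_len(males)),
                                    paste0("F", seq_len(females)))),
      sex = rep(c("M", "F"), c(males, females)))
    rbindlist(lapply(seq_len(nrow(samp)), function(i) {
      male_specific <- all_pos %in% c(shared_pos, own_private)
      q <- ifelse(male_specific & samp$sex[i] == "M", 0.5, 0)
      d <- rpois(length(all_pos), depth_mean)
      pr <- q * (1 - error_rate) + (1 - q) * error_rate
      alt <- rbinom(length(all_pos), d, pr)
      data.table(sample_id = samp$sample_id[i], species = sp,
                 sex = samp$sex[i], contig = "target", pos = all_pos,
                 ref_count = d - alt, alt_count = alt)
    }))
  }))
  list(calls = calls,
       truth = list(
         shared_sites = data.table(contig = "target", pos = shared_pos),
         private_sites = private[, .(species, contig = "target", pos)],
         shared_block = data.table(contig = "target",
                                   start = shared_block[1L],
                                   end = shared_block[2L])))
}
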