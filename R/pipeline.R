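#' Run the SNP heterozygosity scan in both heterogamety modes
#'
#' Screens a pooled variant table under the XY pattern (male heterozygous,
#' female homozygous) and the ZW pattern (interchanged), clusters each mode's
#' candidate positions by distance and ranks the clusters; the two modes'
#' top counts and their ratio diagnose the heterogametic system. Duplicate
#' positions (e.g. a SNP and an INDEL at the same coordinate) are collapsed
#' for clustering; both rows remain in the candidate tables.
#'
#' @param variants Variant table from [read_pool_vcf()] or
#'   [simulate_poolsex()].
#' @param min_depth,hom_max_frac,het_low,het_high Screen thresholds, see
#'   [screen_config()].
#' @param params A [cluster_params()].
#' @return A list: `xy`, `zw` (each with `candidates`, `drop_counts`,
#'   ranked `clusters`), `top_xy`, `top_zw`, `ratio`, `n_input`.
#' @export
run_snp_scan <- function(variants, min_depth = 15L, hom_max_frac = 0.07,
                         het_low = 0.45, het_high = 0.55,
                         params = cluster_params()) {
  one_mode <- function(mode) {
    cfg <- screen_config(mode = mode, min_depth = min_depth,
                         hom_max_frac = hom_max_frac, het_low = het_low,
                         het_high = het_high)
    scr <- screen_variants(variants, cfg)
    pos <- unique(scr$candidates[, .(contig, pos)])
    setorder(pos, contig, pos)
    clusters <- rank_clusters(cluster_positions(pos, params))
    list(candidates = scr$candidates, drop_counts = scr$drop_counts,
         clusters = clusters)
  }
  xy <- one_mode("XY")
  zw <- one_mode("ZW")
  rep <- scan_report(xy$clusters, zw$clusters)
  list(xy = xy, zw = zw, top_xy = rep$top_xy, top_zw = rep$top_zw,
       ratio = rep$ratio, n_input = nrow(as.data.table(variants)))
}

#' Do two genomic intervals overlap?
#'
#' 1-based inclusive interval overlap on the same contig.
#'
#' @param contig_a,start_a,end_a,contig_b,start_b,end_b Interval fields.
#' @return Logical.
#' @export
intervals_overlap <- function(contig_a, start_a, end_a,
                              contig_b, start_b, end_b) {
  contig_a == contig_b & start_a <= end_b & start_b <= end_a
}

#' Write a ranked cluster table as TSV
#'
#' Columns: rank, contig, start, end, count, span, density (count per kb of
#' span), preceded by a `#` comment header with tool version and parameters.
#'
#' @param clusters Ranked cluster table.
#' @param path Output path.
#' @param count_col Count column (`n_variants` or `n_bases`).
#' @param params Optional named list for the header.
#' @export
write_ranked_tsv <- function(clusters, path, count_col = "n_variants",
                             params = NULL) {
  cl <- as.data.table(clusters)
  if (!"rank" %in% names(cl)) cl <- rank_clusters(cl, count_col)
  keep <- intersect(c("rank", "contig", "start", "end", count_col, "span"),
                    names(cl))
  out <- cl[, keep, with = FALSE]
  if (nrow(out)) out[, density := get(count_col) / (span / 1000)]
  writeLines(comment_header(params), path)
  fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}
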