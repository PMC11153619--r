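#' Clustering parameters
#'
#' @param max_gap Maximum distance (bp) between consecutive member positions
#'   of one cluster; two consecutive positions join the same cluster iff their
#'   difference is at most `max_gap`. Default 9000 bp.
#' @param min_cluster_size Clusters with fewer members are suppressed
#'   (default 1: singletons are kept and ranked).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(max_gap = 9000L, min_cluster_size = 1L) {
  stopifnot(max_gap >= 0, min_cluster_size >= 1)
  structure(list(max_gap = as.numeric(max_gap),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_params")
}

#' Cluster genomic point positions by distance
#'
#' Single-linkage merge by gap on 1-based point positions: within a contig,
#' consecutive sorted positions `p[i]`, `p[i+1]` belong to the same cluster
#' iff `p[i+1] - p[i] <= max_gap`. Clusters never span contigs.
#'
#' @param positions A data.frame with columns `contig` and `pos` (1-based),
#'   sorted ascending within each contig with duplicates removed, or a bare
#'   numeric vector (taken as one unnamed contig).
#' @param params A [cluster_params()].
#' @return A data.table with one row per cluster: `contig`, `start`, `end`
#'   (1-based first and last member positions), `n_variants`, `span`
#'   (`end - start + 1`), and a list-column `members` of sorted positions.
#' @export
#' @examples
#' cluster_positions(c(1000, 9500, 20000), cluster_params(max_gap = 9000))
cluster_positions <- function(positions, params = cluster_params()) {
  if (is.numeric(positions)) {
    positions <- data.table(contig = "contig", pos = as.numeric(positions))
  }
  p <- as.data.table(positions)[, .(contig, pos = as.numeric(pos))]
  if (nrow(p) == 0L) {
    return(data.table(contig = character(), start = numeric(),
                      end = numeric(), n_variants = integer(),
                      span = numeric(), members = list()))
  }
  bad <- p[, .(unsorted = is.unsorted(pos, strictly = TRUE)), by = contig]
  if (any(bad$unsorted))
    stop("positions must be sorted ascending within contig, duplicates removed")
  p[, cluster_id := cumsum(c(1, diff(pos) > params$max_gap)), by = contig]
  cl <- p[, .(start = pos[1L], end = pos[.N], n_variants = .N,
              members = list(pos)), by = .(contig, cluster_id)]
  cl[, span := end - start + 1]
  cl <- cl[n_variants >= params$min_cluster_size]
  cl[, cluster_id := NULL]
  setcolorder(cl, c("contig", "start", "end", "n_variants", "span", "members"))
  cl[]
}

#' Rank clusters by member count
#'
#' Descending by member count; ties broken by span (descending), then by
#' (contig, start) lexicographic. Rank 1 is the top candidate region.
#'
#' @param clusters Output of [cluster_positions()] (or any table with
#'   `contig`, `start`, `span` and a count column).
#' @param count_col Name of the count column (`n_variants` for SNP clusters,
#'   `n_bases` for coverage clusters).
#' @return The table ordered by rank, with a `rank` column prepended.
#' @export
rank_clusters <- function(clusters, count_col = "n_variants") {
  cl <- as.data.table(clusters)
  if (nrow(cl) == 0L) {
    cl[, rank := integer()]
    setcolorder(cl, "rank")
    return(cl[])
  }
  setorderv(cl, c(count_col, "span", "contig", "start"),
            order = c(-1L, -1L, 1L, 1L))
  cl[, rank := seq_len(.N)]
  setcolorder(cl, "rank")
  cl[]
}

#' Compare the XY and ZW scans
#'
#' Ranks both modes' clusters and reports the ratio of the top XY member
#' count to the top ZW member count — the genome-wide contrast that separates
#' male from female heterogamety (a male-heterogametic genome shows a top XY
#' cluster several-fold above the strongest female-heterozygous signal).
#'
#' @param xy_clusters,zw_clusters Cluster tables from [cluster_positions()]
#'   run on the XY-mode and ZW-mode candidates of the same variant set.
#' @return A list with ranked `xy` and `zw` tables, `top_xy`, `top_zw`
#'   (member counts, 0 when a table is empty) and `ratio`
#'   (`top_xy / top_zw`, `NA` when either table is empty).
#' @export
scan_report <- function(xy_clusters, zw_clusters) {
  xy <- rank_clusters(xy_clusters)
  zw <- rank_clusters(zw_clusters)
  top_xy <- if (nrow(xy)) xy$n_variants[1L] else 0L
  top_zw <- if (nrow(zw)) zw$n_variants[1L] else 0L
  ratio <- if (nrow(xy) == 0L || nrow(zw) == 0L) NA_real_ else top_xy / top_zw
  list(xy = xy, zw = zw, top_xy = top_xy, top_zw = top_zw, ratio = ratio)
}
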