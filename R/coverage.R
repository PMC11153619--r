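#' Coverage-scan thresholds
#'
#' Normalized-coverage windows defining Y-hemizygous sequence: present on the
#' single Y haplotype of the male pool (half the diploid rate) and absent
#' from the female pool. Defaults: male normalized coverage in the inclusive
#' window 0.25-0.75, female normalized coverage strictly below 0.05, and the
#' same 9000-bp merge gap as the SNP scan.
#'
#' @param male_low,male_high Inclusive bounds on male normalized coverage.
#' @param female_max Strict upper bound on female normalized coverage.
#' @param max_gap Merge distance (bp) for selected-base runs.
#' @return A `coverage_thresholds` list.
#' @export
coverage_thresholds <- function(male_low = 0.25, male_high = 0.75,
                                female_max = 0.05, max_gap = 9000L) {
  stopifnot(male_low >= 0, male_low < male_high, female_max < male_low)
  structure(list(male_low = male_low, male_high = male_high,
                 female_max = female_max, max_gap = as.numeric(max_gap)),
            class = "coverage_thresholds")
}

#' Union two coverage tracks onto a common interval refinement
#'
#' Refines both tracks' breakpoints per contig (the `bedtools unionbedg`
#' operation) so every output interval carries one value from each track;
#' absent coverage is 0. Intervals where both tracks are 0 are omitted. Each
#' input's total mass (sum of value x length) is preserved.
#'
#' @param track_a,track_b Tracks as returned by [read_bedgraph()].
#' @param labels Column names for the two value columns.
#' @return data.table `contig`, `start`, `end`, `<label_a>`, `<label_b>`.
#' @export
union_tracks <- function(track_a, track_b, labels = c("value_a", "value_b")) {
  a <- validate_track(track_a)
  b <- validate_track(track_b)
  contigs <- sort(unique(c(a$contig, b$contig)))
  out <- lapply(contigs, function(ct) {
    ca <- a[contig == ct]
    cb <- b[contig == ct]
    bp <- sort(unique(c(ca$start, ca$end, cb$start, cb$end)))
    if (length(bp) < 2L) return(NULL)
    seg <- data.table(contig = ct, start = bp[-length(bp)], end = bp[-1L])
    seg[, (labels[1L]) := lookup_value(ca, start)]
    seg[, (labels[2L]) := lookup_value(cb, start)]
    seg
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    res <- data.table(contig = character(), start = numeric(),
                      end = numeric())
    res[, (labels[1L]) := numeric()]
    res[, (labels[2L]) := numeric()]
    return(res[])
  }
  res[res[[labels[1L]]] > 0 | res[[labels[2L]]] > 0]
}

# Value of a sorted single-contig track at each query start (0 off-track).
lookup_value <- function(tr, at) {
  if (nrow(tr) == 0L) return(rep(0, length(at)))
  idx <- findInterval(at, tr$start)
  val <- rep(0, length(at))
  hit <- idx > 0L
  hit[hit] <- at[hit] < tr$end[idx[hit]]
  val[hit] <- tr$value[idx[hit]]
  val
}

#' Normalize a coverage track by its modal coverage peak
#'
#' The modal value is the coverage value occupying the largest total base
#' span across the whole track, excluding 0 (ties broken toward the smaller
#' value). Dividing by it sets the diploid peak to 1.0, so a hemizygous
#' region sits near 0.5 and absent sequence near 0.
#'
#' @param track A track from [read_bedgraph()] with some value > 0.
#' @return A list: `track` (values divided by the modal value) and `modal`.
#' @export
modal_normalize <- function(track) {
  tr <- validate_track(track)
  nz <- tr[value > 0]
  if (nrow(nz) == 0L)
    stop("cannot normalize an all-zero coverage track: no modal peak")
  spans <- nz[, .(span = sum(end - start)), by = .(v = value)]
  setorder(spans, -span, v)
  m <- spans$v[1L]
  norm <- copy(tr)[, value := value / m]
  list(track = norm[], modal = m)
}

#' Select bases with the Y-hemizygous coverage signature
#'
#' A base is selected iff its male normalized coverage lies in the inclusive
#' `[male_low, male_high]` window and its female normalized coverage is
#' strictly below `female_max`. Selection is pointwise, so re-chunking the
#' input intervals cannot change the result; output is the set of maximal
#' runs of selected bases.
#'
#' @param joint Unioned normalized tracks from
#'   `union_tracks(female, male, labels = c("female", "male"))`.
#' @param thr A [coverage_thresholds()].
#' @return data.table of runs `contig`, `start`, `end` (0-based half-open).
#' @export
select_sex_specific_bases <- function(joint, thr = coverage_thresholds()) {
  j <- as.data.table(joint)
  stopifnot(all(c("female", "male") %in% names(j)))
  sel <- j[male >= thr$male_low - .EPS & male <= thr$male_high + .EPS &
             female < thr$female_max - .EPS,
           .(contig, start, end)]
  merge_adjacent_runs(sel)
}

# Coalesce book-ended intervals (end == next start) within each contig.
merge_adjacent_runs <- function(iv) {
  iv <- as.data.table(iv)
  if (nrow(iv) == 0L)
    return(data.table(contig = character(), start = numeric(), end = numeric()))
  setorder(iv, contig, start)
  iv[, run_id := cumsum(c(1, start[-1L] != end[-.N])), by = contig]
  out <- iv[, .(start = start[1L], end = end[.N]), by = .(contig, run_id)]
  out[, run_id := NULL]
  out[]
}

#' Cluster selected-base runs and count male-specific covered bases
#'
#' Runs whose gap is at most `max_gap` merge into one cluster (gap measured
#' between the 1-based last base of one run and first base of the next, the
#' same point rule as the SNP scan); `n_bases` is the number of selected
#' bases in the cluster — gaps are not counted. Clusters are ranked
#' descending by `n_bases` with the SNP-scan tie rules.
#'
#' @param runs Selected runs from [select_sex_specific_bases()] (0-based
#'   half-open, sorted, disjoint).
#' @param max_gap Merge distance in bp.
#' @return Ranked data.table: `rank`, `contig`, `start`, `end` (1-based
#'   inclusive bounds of selected bases), `n_bases`, `span`.
#' @export
cluster_selected_bases <- function(runs, max_gap = 9000) {
  rv <- as.data.table(runs)
  if (nrow(rv) == 0L) {
    empty <- data.table(rank = integer(), contig = character(),
                        start = numeric(), end = numeric(),
                        n_bases = numeric(), span = numeric())
    return(empty)
  }
  setorder(rv, contig, start)
  rv[, `:=`(s1 = start + 1, e1 = end)]  # to 1-based inclusive
  rv[, cluster_id := cumsum(c(1, s1[-1L] - e1[-.N] > max_gap)), by = contig]
  cl <- rv[, .(start = s1[1L], end = e1[.N], n_bases = sum(e1 - s1 + 1)),
           by = .(contig, cluster_id)]
  cl[, span := end - start + 1]
  cl[, cluster_id := NULL]
  rank_clusters(cl, count_col = "n_bases")
}

#' Run the full coverage scan on two pool tracks
#'
#' Combines the female and male tracks, normalizes each by its own modal
#' coverage peak, selects bases with the Y-hemizygous signature, and clusters
#' and ranks them by male-specific covered bases.
#'
#' @param female_track,male_track Raw tracks from [read_bedgraph()].
#' @param thr A [coverage_thresholds()].
#' @return A list: `modal_female`, `modal_male`, `selected` (runs),
#'   `clusters` (ranked), `n_selected_bases`.
#' @export
run_coverage_scan <- function(female_track, male_track,
                              thr = coverage_thresholds()) {
  nf <- modal_normalize(female_track)
  nm <- modal_normalize(male_track)
  joint <- union_tracks(nf$track, nm$track, labels = c("female", "male"))
  runs <- select_sex_specific_bases(joint, thr)
  clusters <- cluster_selected_bases(runs, thr$max_gap)
  list(modal_female = nf$modal, modal_male = nm$modal, selected = runs,
       clusters = clusters,
       n_selected_bases = if (nrow(runs)) sum(runs$end - runs$start) else 0)
}
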