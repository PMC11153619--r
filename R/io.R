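#' Read a two-pool VCF with per-sample allele depths
#'
#' Parses a VCF 4.x file holding one sample per sex pool and returns one row
#' per biallelic record with both pools' strand-resolved depths. Two depth
#' dialects are accepted, in order of preference: a per-sample `DP4` FORMAT
#' quadruple (ref-fwd, ref-rev, alt-fwd, alt-rev), and a per-sample `AD`
#' allelic-depth pair (ref, alt) with strands pooled as forward (`fwd =
#' count, rev = 0`). Multiallelic records and records carrying neither tag
#' are skipped and counted. INFO-level DP4 (a single-sample convention) does
#' not apply: this reader requires two named samples.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param female_label,male_label Sample column names for the two pools.
#' @return A data.table with columns `contig`, `pos` (1-based), `ref`, `alt`,
#'   `type` (`SNP`/`MNP`/`INDEL`) and `female_ref_fwd`, `female_ref_rev`,
#'   `female_alt_fwd`, `female_alt_rev`, `male_ref_fwd`, ..., with attribute
#'   `"skipped"` = named counts `c(multiallelic, no_depth)`.
#' @export
read_pool_vcf <- function(path, female_label = "female", male_label = "male") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  for (lab in c(female_label, male_label)) {
    if (!lab %in% samples)
      stop("sample '", lab, "' not found in VCF (samples: ",
           paste(samples, collapse = ", "), ")")
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop dimensions
  fix <- as.data.table(fix)
  n <- nrow(fix)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) | fix$ALT == "."

  dp4 <- tryCatch(vcfR::extract.gt(vcf, element = "DP4"),
                  error = function(e) NULL)
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)

  get_quad <- function(sample) {
    quad <- matrix(NA_real_, nrow = n, ncol = 4L)
    if (!is.null(dp4)) {
      has <- !is.na(dp4[, sample])
      if (any(has)) {
        parts <- tstrsplit(dp4[has, sample], ",", type.convert = FALSE)
        if (length(parts) == 4L)
          quad[has, ] <- vapply(parts, as.numeric, numeric(sum(has)))
      }
    }
    need <- is.na(quad[, 1L])
    if (!is.null(ad) && any(need)) {
      has <- need & !is.na(ad[, sample])
      if (any(has)) {
        parts <- tstrsplit(ad[has, sample], ",", type.convert = FALSE)
        if (length(parts) >= 2L) {
          quad[has, 1L] <- as.numeric(parts[[1L]])
          quad[has, 2L] <- 0
          quad[has, 3L] <- as.numeric(parts[[2L]])
          quad[has, 4L] <- 0
        }
      }
    }
    quad
  }
  fq <- get_quad(female_label)
  mq <- get_quad(male_label)
  no_depth <- !multi & (is.na(fq[, 1L]) | is.na(mq[, 1L]))
  keep <- !multi & !no_depth

  out <- data.table(
    contig = fix$CHROM[keep], pos = as.numeric(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep])
  out[, type := variant_type(ref, alt)]
  quad_cols <- c("_ref_fwd", "_ref_rev", "_alt_fwd", "_alt_rev")
  for (j in 1:4) set(out, j = paste0("female", quad_cols[j]),
                     value = fq[keep, j])
  for (j in 1:4) set(out, j = paste0("male", quad_cols[j]),
                     value = mq[keep, j])
  setattr(out, "skipped",
          c(multiallelic = sum(multi), no_depth = sum(no_depth)))
  out[]
}

# SNP: both alleles length 1; MNP: equal lengths > 1; INDEL: lengths differ.
variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  fifelse(lr == 1L & la == 1L, "SNP", fifelse(lr == la, "MNP", "INDEL"))
}

#' Write a two-pool VCF with DP4 FORMAT fields
#'
#' Companion writer for simulated variant tables; emits a minimal VCF 4.2
#' with two samples and a per-sample `DP4` quadruple, re-readable by
#' [read_pool_vcf()].
#'
#' @param variants Table in the [read_pool_vcf()] layout.
#' @param path Output path.
#' @param contig_lengths Optional named vector for `##contig` header lines.
#' @export
write_pool_vcf <- function(variants, path, contig_lengths = NULL) {
  v <- as.data.table(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=poolsex-", utils::packageVersion("poolsex")),
    '##FORMAT=<ID=DP4,Number=4,Type=Integer,Description="Strand-resolved ref and alt read counts: ref-fwd,ref-rev,alt-fwd,alt-rev">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "female", "male", sep = "\t"))
  quad <- function(pool) {
    cols <- paste0(pool, c("_ref_fwd", "_ref_rev", "_alt_fwd", "_alt_rev"))
    do.call(paste, c(lapply(cols, function(cc) as.integer(v[[cc]])),
                     sep = ","))
  }
  body <- if (nrow(v)) {
    paste(v$contig, format(v$pos, scientific = FALSE, trim = TRUE), ".",
          v$ref, v$alt, ".", "PASS", ".", "DP4", quad("female"),
          quad("male"), sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a bedgraph coverage track
#'
#' Four-column UCSC bedgraph (contig, 0-based start, exclusive end, value);
#' `track`, `browser` and `#` comment lines are tolerated. Intervals are
#' re-sorted per contig; overlapping intervals or negative values are fatal
#' (a malformed track). Gaps represent coverage 0.
#'
#' @param path Path to a bedgraph file (plain or gzipped).
#' @return A data.table `contig`, `start`, `end`, `value`, sorted and
#'   non-overlapping per contig.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.table(contig = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  tr <- fread(text = lines, header = FALSE,
              col.names = c("contig", "start", "end", "value"),
              colClasses = list(character = 1, numeric = 2:4))
  validate_track(tr)
}

validate_track <- function(tr) {
  tr <- as.data.table(tr)
  if (nrow(tr) == 0L) return(tr)
  if (any(tr$value < 0)) stop("bedgraph has negative coverage values")
  if (any(tr$start >= tr$end)) stop("bedgraph has empty or inverted intervals")
  setorder(tr, contig, start)
  overlap <- tr[, .(bad = .N > 1L && any(start[-1L] < end[-.N])), by = contig]
  if (any(overlap$bad)) stop("bedgraph has overlapping intervals (malformed track)")
  tr[]
}

#' Write a bedgraph coverage track
#'
#' Emits intervals sorted by (contig, start), preceded by a `#` comment
#' header recording the tool version and any parameters given.
#'
#' @param track Table with `contig`, `start`, `end`, `value`.
#' @param path Output path.
#' @param params Optional named list echoed into the header.
#' @export
write_bedgraph <- function(track, path, params = NULL) {
  tr <- validate_track(track)
  writeLines(c(comment_header(params),
               if (nrow(tr)) {
                 paste(tr$contig,
                       format(tr$start, scientific = FALSE, trim = TRUE),
                       format(tr$end, scientific = FALSE, trim = TRUE),
                       format(tr$value, scientific = FALSE, trim = TRUE),
                       sep = "\t")
               } else character()),
             path)
  invisible(path)
}

comment_header <- function(params = NULL) {
  h <- paste0("# poolsex ", utils::packageVersion("poolsex"))
  if (length(params))
    h <- c(h, paste0("# ", names(params), "=",
                     vapply(params, function(x) paste(x, collapse = ","),
                            character(1L))))
  h
}

#' Write clusters as BED
#'
#' BED4+ (contig, start, end, name, score): coordinates are converted from
#' the internal 1-based point positions to BED 0-based half-open (start - 1),
#' the score column is the member count, and rows are ordered by (contig,
#' start). Cluster names carry the rank when present.
#'
#' @param clusters A cluster table ([cluster_positions()] or
#'   [cluster_selected_bases()] output, ranked or not).
#' @param path Output path.
#' @param count_col Column written as the BED score.
#' @param params Optional named list echoed into the `#` comment header.
#' @export
write_cluster_bed <- function(clusters, path, count_col = "n_variants",
                              params = NULL) {
  cl <- as.data.table(clusters)
  hdr <- comment_header(params)
  if (nrow(cl) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  if (!"rank" %in% names(cl)) cl <- rank_clusters(cl, count_col)
  setorder(cl, contig, start)
  writeLines(c(hdr, paste(cl$contig,
                          format(cl$start - 1, scientific = FALSE, trim = TRUE),
                          format(cl$end, scientific = FALSE, trim = TRUE),
                          paste0("cluster_", cl$rank),
                          format(cl[[count_col]], scientific = FALSE, trim = TRUE),
                          sep = "\t")),
             path)
  invisible(path)
}

#' Read a cluster BED back into a table
#'
#' Inverse of [write_cluster_bed()] for the fields the pipeline consumes:
#' BED start is converted back to the 1-based first member position.
#'
#' @param path BED4+ path written by [write_cluster_bed()].
#' @param count_col Name for the score column.
#' @return data.table `contig`, `start` (1-based), `end`, `name`, count.
#' @export
read_cluster_bed <- function(path, count_col = "n_variants") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.table(contig = character(), start = numeric(),
                      end = numeric(), name = character())
    out[, (count_col) := numeric()]
    return(out[])
  }
  ncols <- length(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]])
  cols <- c("contig", "start", "end", "name", count_col)[seq_len(ncols)]
  bed <- fread(text = lines, header = FALSE, col.names = cols,
               colClasses = list(character = 1, numeric = c(2, 3)))
  if (!count_col %in% names(bed)) bed[, (count_col) := NA_real_]
  bed[, start := start + 1]
  bed[, span := end - start + 1]
  bed[]
}

#' Length of a 1-based genomic interval
#'
#' @param start,end 1-based coordinates.
#' @param inclusive If `TRUE` (default) both endpoints are bases of the
#'   interval and the length is `end - start + 1`; if `FALSE` the length is
#'   the coordinate difference `end - start`.
#' @return Numeric length in bp.
#' @export
#' @examples
#' interval_length(566783058, 566848882)          # 65825 (~66 kb)
#' interval_length(566788797, 566791468, FALSE)   # 2671
interval_length <- function(start, end, inclusive = TRUE) {
  stopifnot(all(end >= start))
  end - start + if (inclusive) 1 else 0
}
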