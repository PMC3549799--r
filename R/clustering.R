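#' Cluster filtering parameters
#'
#' @param min_reads minimum multiplicity-weighted read support per cluster
#'   (default 5).
#' @param min_conversion_fraction minimum fraction of cluster reads
#'   (multiplicity-weighted) carrying at least one T-to-C conversion;
#'   applied in PAR-CLIP mode only (default 0.20).
#' @param min_overlap minimum interval overlap (nt) for two mapped reads to
#'   join the same cluster (default 1).
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(min_reads = 5L, min_conversion_fraction = 0.20,
                           min_overlap = 1L) {
  stopifnot(min_reads >= 1L, min_conversion_fraction >= 0,
            min_conversion_fraction <= 1, min_overlap >= 1L)
  structure(list(min_reads = as.integer(min_reads),
                 min_conversion_fraction = min_conversion_fraction,
                 min_overlap = as.integer(min_overlap)),
            class = "cluster_params")
}

#' Group overlapping mapped reads into clusters
#'
#' Per UTR, single-linkage connected components of the interval-overlap
#' graph: two reads connect when their placements share at least
#' `min_overlap` nt. Every mapped read belongs to exactly one cluster;
#' cluster spans on a UTR are pairwise disjoint. Clusters are ordered by
#' (utr_id, span_start) and given deterministic ids.
#'
#' @param mapped mapped reads table from [map_reads()].
#' @param params [cluster_params()].
#' @return list with `clusters` (one row per cluster: `cluster_id`,
#'   `utr_id`, `span_start`, `span_end` 0-based half-open, `n_members`,
#'   `read_support`, `converted_support`, `conversion_read_fraction`) and
#'   `members` (the mapped table plus a `cluster_id` column).
#' @export
build_clusters <- function(mapped, params = cluster_params()) {
  if (nrow(mapped) == 0L) {
    cl <- data.frame(cluster_id = character(), utr_id = character(),
                     span_start = integer(), span_end = integer(),
                     n_members = integer(), read_support = integer(),
                     converted_support = integer(),
                     conversion_read_fraction = numeric(),
                     stringsAsFactors = FALSE)
    mapped$cluster_id <- character(0)
    return(list(clusters = cl, members = mapped))
  }
  ord <- order(mapped$utr_id, mapped$start, mapped$end)
  m <- mapped[ord, , drop = FALSE]
  # sweep: join when the new read overlaps the running span by >= min_overlap
  comp <- integer(nrow(m))
  cur <- 0L
  cur_end <- -Inf
  cur_utr <- ""
  for (i in seq_len(nrow(m))) {
    if (!identical(m$utr_id[i], cur_utr) ||
        m$start[i] > cur_end - params$min_overlap) {
      cur <- cur + 1L
      cur_utr <- m$utr_id[i]
      cur_end <- m$end[i]
    } else {
      cur_end <- max(cur_end, m$end[i])
    }
    comp[i] <- cur
  }
  has_conv <- lengths(m$conversion_pos) > 0L
  clusters <- data.frame(
    cluster_id = sprintf("cl%05d", seq_len(cur)),
    utr_id = vapply(split(m$utr_id, comp), `[`, character(1), 1),
    span_start = as.integer(tapply(m$start, comp, min)),
    span_end = as.integer(tapply(m$end, comp, max)),
    n_members = as.integer(tabulate(comp, cur)),
    read_support = as.integer(tapply(m$multiplicity, comp, sum)),
    converted_support = as.integer(tapply(m$multiplicity * has_conv, comp, sum)),
    stringsAsFactors = FALSE)
  clusters$conversion_read_fraction <-
    clusters$converted_support / clusters$read_support
  rownames(clusters) <- NULL
  m$cluster_id <- clusters$cluster_id[comp]
  rownames(m) <- NULL
  list(clusters = clusters, members = m)
}

#' Apply read-support and conversion-fraction cluster filters
#'
#' Keeps clusters with `read_support >= min_reads`; in PAR-CLIP mode a
#' cluster must additionally have at least `min_conversion_fraction` of its
#' reads (multiplicity-weighted) carrying a T-to-C conversion.
#'
#' @param clustering result of [build_clusters()].
#' @param params [cluster_params()].
#' @param parclip_mode logical; enables the conversion-fraction rule.
#' @return a clustering list of the same shape, restricted to surviving
#'   clusters.
#' @export
filter_clusters <- function(clustering, params = cluster_params(),
                            parclip_mode = TRUE) {
  cl <- clustering$clusters
  keep <- cl$read_support >= params$min_reads
  if (parclip_mode)
    keep <- keep & cl$conversion_read_fraction >= params$min_conversion_fraction
  cl <- cl[keep, , drop = FALSE]
  rownames(cl) <- NULL
  members <- clustering$members
  members <- members[members$cluster_id %in% cl$cluster_id, , drop = FALSE]
  rownames(members) <- NULL
  list(clusters = cl, members = members)
}

#' Write cluster spans as BED
#'
#' 0-based half-open intervals per BED convention; score column carries the
#' read support.
#' @param clusters cluster table from [build_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_bed <- function(clusters, path) {
  bed <- data.frame(chrom = clusters$utr_id,
                    start = clusters$span_start,
                    end = clusters$span_end,
                    name = clusters$cluster_id,
                    score = clusters$read_support,
                    strand = rep("+", nrow(clusters)),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
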