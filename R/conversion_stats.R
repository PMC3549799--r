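#' Construct a per-position conversion profile
#'
#' A profile holds, for target-site positions `1..P` (position k = the UTR
#' nucleotide pairing miRNA position k; position 1 is the 3'-most site
#' nucleotide on the mRNA, positions increase toward the mRNA 5' side),
#' the pooled converted and covering read counts and their ratio. Positions
#' never covered by a reference T have ratio `NaN`.
#'
#' @param converted integer vector of converted read counts per position.
#' @param covering integer vector of covering read counts per position.
#' @param positions position labels (default `1..length(converted)`).
#' @return a `conversion_profile` object.
#' @export
conversion_profile <- function(converted, covering,
                               positions = seq_along(converted)) {
  stopifnot(length(converted) == length(covering),
            length(positions) == length(converted),
            all(covering >= converted))
  ratio <- ifelse(covering > 0, converted / covering, NaN)
  structure(list(positions = as.integer(positions),
                 converted = as.numeric(converted),
                 covering = as.numeric(covering),
                 ratio = ratio),
            class = "conversion_profile")
}

#' @export
print.conversion_profile <- function(x, ...) {
  cat("T-to-C conversion profile over", length(x$positions), "positions\n")
  print(data.frame(position = x$positions, converted = x$converted,
                   covering = x$covering, ratio = round(x$ratio, 4)))
  invisible(x)
}

#' @export
as.data.frame.conversion_profile <- function(x, ...) {
  data.frame(position = x$positions, converted = x$converted,
             covering = x$covering, ratio = x$ratio)
}

# 0-based UTR coordinate of target-site position 1 (the nucleotide pairing
# miRNA position 1). For 8mer/7mer-A1 sites that A is the last site base;
# for 7mer-m8 it is the base 3'-adjacent to the site interval.
site_position1_coord <- function(sites) {
  ifelse(sites$seed_match_type == "7mer-m8", sites$site_end,
         sites$site_end - 1L)
}

#' Pool per-position T-to-C conversion ratios over target sites
#'
#' For each site, target positions `1..P` are mapped onto UTR coordinates
#' (position k sits k-1 nt 5' of the position-1 nucleotide on the mRNA).
#' At positions where the UTR base is T, converted and covering read
#' counts (multiplicity-weighted) are accumulated from the site's cluster
#' members and pooled across sites.
#'
#' @param sites site table from [find_seed_matches()] / [rank_mtis()].
#' @param members cluster member reads (from [filter_clusters()]).
#' @param utrs UTR table.
#' @param P number of positions (default 14, covering the seed-paired
#'   region 1-7 and the effector region 8-14).
#' @return a [conversion_profile()].
#' @export
site_conversion_profile <- function(sites, members, utrs, P = 14L) {
  P <- as.integer(P)
  converted <- numeric(P)
  covering <- numeric(P)
  if (!is.null(sites) && nrow(sites)) {
    p1 <- site_position1_coord(sites)
    by_cluster <- split(seq_len(nrow(members)), members$cluster_id)
    conv_coords <- Map(function(pos, start) pos + start,
                       members$conversion_pos, members$start)
    for (si in seq_len(nrow(sites))) {
      useq <- utrs$sequence[match(sites$utr_id[si], utrs$utr_id)]
      L <- nchar(useq)
      mem <- by_cluster[[sites$cluster_id[si]]]
      if (is.null(mem)) next
      for (k in seq_len(P)) {
        x <- p1[si] - (k - 1L)
        if (x < 0L || x >= L) next
        if (substr(useq, x + 1L, x + 1L) != "T") next
        covers <- members$start[mem] <= x & x < members$end[mem]
        if (!any(covers)) next
        mult <- members$multiplicity[mem]
        conv <- vapply(conv_coords[mem], function(cc) x %in% cc, logical(1))
        covering[k] <- covering[k] + sum(mult[covers])
        converted[k] <- converted[k] + sum(mult[covers & conv])
      }
    }
  }
  conversion_profile(converted, covering)
}

#' One-tailed regional Student's t test on a conversion profile
#'
#' Two-sample equal-variance Student's t on the per-position pooled
#' conversion ratios of two site regions, one-tailed with alternative
#' mean(region_b) > mean(region_a). Defaults compare the seed-paired
#' region (positions 1-7) against the effector region (positions 8-14),
#' where crosslink-induced conversions concentrate. Positions with
#' undefined ratio (no covering T) are excluded. When the pooled variance
#' is zero the statistic is 0 (equal means, p = 0.5) or +/-Inf.
#'
#' @param profile a [conversion_profile()].
#' @param region_a,region_b position labels of the two regions.
#' @return list with `t`, `df`, `p_value` (one-tailed, b > a), `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, and `defined` (FALSE, with NA results and
#'   a warning, when either region has fewer than 2 defined ratios).
#' @export
region_ttest <- function(profile, region_a = 1:7, region_b = 8:14) {
  a <- profile$ratio[match(region_a, profile$positions)]
  b <- profile$ratio[match(region_b, profile$positions)]
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    warning("region t test undefined: fewer than 2 defined ratios in a region")
    return(list(t = NA_real_, df = NA_real_, p_value = NA_real_,
                n_a = length(a), n_b = length(b),
                mean_a = if (length(a)) mean(a) else NA_real_,
                mean_b = if (length(b)) mean(b) else NA_real_,
                defined = FALSE))
  }
  na <- length(a); nb <- length(b)
  dfree <- na + nb - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dfree
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  d <- mean(b) - mean(a)
  tt <- if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / se
  list(t = tt, df = dfree,
       p_value = stats::pt(tt, dfree, lower.tail = FALSE),
       n_a = na, n_b = nb, mean_a = mean(a), mean_b = mean(b),
       defined = TRUE)
}

#' The standard conservation-by-seed-length strata
#' @return character vector of stratum labels.
#' @export
default_strata <- function() {
  c("CN78", "CN8", "CN7", "C78", "C8", "C7", "N78", "N8", "N7")
}

# parse a stratum label like "CN78", "C8", "N7" into its conservation and
# seed-length subsets
parse_stratum <- function(label) {
  chars <- strsplit(label, "", fixed = TRUE)[[1]]
  cons <- intersect(chars, c("C", "N"))
  lens <- intersect(chars, c("7", "8"))
  if (!length(cons) || !length(lens) ||
      !all(chars %in% c("C", "N", "7", "8")))
    stop("invalid stratum label: ", label)
  list(conservation = cons, seed_lengths = as.integer(lens))
}

#' Regional conversion t tests stratified by conservation and seed length
#'
#' For each stratum (e.g. "C8" = conserved UTRs, 8mer sites; "CN78" = no
#' restriction), the site set is restricted by UTR conservation flag and
#' seed length (7 = 7mer-A1 and 7mer-m8, 8 = 8mer), optionally to sites of
#' the `top_k` most highly expressed miRNAs, the conversion profile is
#' rebuilt and [region_ttest()] is run.
#'
#' @inheritParams site_conversion_profile
#' @param strata character vector of stratum labels (see
#'   [default_strata()]).
#' @param expression optional expression table, required for `top_k`.
#' @param top_k restrict to sites of the `top_k` most expressed miRNAs
#'   (`NULL` = no restriction; the field's convention is the top 102 when
#'   a genome-wide expression table is available).
#' @param region_a,region_b passed to [region_ttest()].
#' @return `data.frame` with one row per stratum: `stratum`, `n_sites`,
#'   `t`, `p_value` (NA for empty/undefined strata).
#' @export
stratified_tests <- function(sites, members, utrs,
                             strata = default_strata(),
                             expression = NULL, top_k = NULL,
                             P = 14L, region_a = 1:7, region_b = 8:14) {
  if (!is.null(top_k)) {
    if (is.null(expression) || !nrow(expression))
      stop("top_k requires an expression table")
    ord <- order(-expression$expression, expression$mirna_id)
    top <- expression$mirna_id[ord][seq_len(min(top_k, nrow(expression)))]
    sites <- sites[sites$mirna_id %in% top, , drop = FALSE]
  }
  conserved <- utrs$conserved[match(sites$utr_id, utrs$utr_id)]
  seed_len <- ifelse(sites$seed_match_type == "8mer", 8L, 7L)
  out <- lapply(strata, function(label) {
    sp <- parse_stratum(label)
    keep <- seed_len %in% sp$seed_lengths
    cons_keep <- rep(FALSE, nrow(sites))
    if ("C" %in% sp$conservation) cons_keep <- cons_keep | (conserved %in% TRUE)
    if ("N" %in% sp$conservation) cons_keep <- cons_keep | (conserved %in% FALSE)
    if (setequal(sp$conservation, c("C", "N"))) cons_keep <- cons_keep | is.na(conserved)
    keep <- keep & cons_keep
    sub <- sites[keep, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(stratum = label, n_sites = 0L,
                        t = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    prof <- site_conversion_profile(sub, members, utrs, P = P)
    tt <- suppressWarnings(region_ttest(prof, region_a, region_b))
    data.frame(stratum = label, n_sites = nrow(sub),
               t = tt$t, p_value = tt$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
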