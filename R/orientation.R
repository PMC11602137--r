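# Sense/antisense annotation of flank-matrix bins relative to the
# orientation of gene regions overlapping each DSB's flank window.
#
# Rules (per gene region, then summed per site):
#   plus-track bin value  -> sense if the gene is "+", else antisense
#   minus-track bin value -> sense if the gene is "-", else antisense
# Only bins lying within gene regions are used; bins outside every gene
# are 0 in both outputs. Sites whose flank overlaps no gene are dropped
# and reported. Same-strand gene regions at one site are merged before
# summation so nested/overlapping records are not double-counted; a bin
# inside two genes of opposite strands contributes to both sense and
# antisense (per-gene annotation, then summation) — this deliberately
# breaks simple plus+minus conservation and is flagged in the docs.

#' Find gene regions overlapping DSB flank windows
#'
#' One record per (site, gene) pair whose gene interval intersects the
#' site's window `[anchor - flank, anchor + flank)`, with the intersection
#' converted to bin indices (0-based half-open `[first_bin, last_bin)`;
#' a bin partially covered by a gene counts as covered).
#'
#' @param sites Site interval table.
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param flank Half-width in bp.
#' @param bin_size Bin width in bp.
#' @return `data.frame` with columns `site_id`, `gene_id`, `gene_strand`,
#'   `first_bin`, `last_bin`.
#' @export
find_gene_flank_overlaps <- function(sites, genes, flank = 2500L,
                                     bin_size = 1L) {
  flank <- as.integer(flank); bin_size <- as.integer(bin_size)
  anchors <- site_anchors(sites)
  ids <- site_ids_of(sites)
  n_bins <- 2L * flank %/% bin_size
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    w_start <- anchors[i] - flank
    w_end <- anchors[i] + flank
    hit <- which(genes$chrom == sites$chrom[i] &
                 genes$start < w_end & genes$end > w_start)
    if (!length(hit)) next
    lo <- pmax(genes$start[hit], w_start)
    hi <- pmin(genes$end[hit], w_end)
    out[[i]] <- data.frame(
      site_id = ids[i],
      gene_id = genes$gene_id[hit],
      gene_strand = genes$strand[hit],
      first_bin = as.integer(floor((lo - w_start) / bin_size)),
      last_bin = as.integer(ceiling((hi - w_start) / bin_size)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(site_id = character(), gene_id = character(),
                      gene_strand = character(), first_bin = integer(),
                      last_bin = integer(), stringsAsFactors = FALSE)
  stopifnot(all(res$first_bin >= 0L), all(res$last_bin <= n_bins),
            all(res$first_bin < res$last_bin))
  res
}

# merge same-strand bin ranges of one site into disjoint runs
merge_ranges <- function(first, last) {
  o <- order(first, last)
  first <- first[o]; last <- last[o]
  mf <- first[1]; ml <- last[1]
  out_f <- integer(); out_l <- integer()
  for (j in seq_along(first)[-1]) {
    if (first[j] <= ml) ml <- max(ml, last[j])
    else { out_f <- c(out_f, mf); out_l <- c(out_l, ml)
           mf <- first[j]; ml <- last[j] }
  }
  list(first = c(out_f, mf), last = c(out_l, ml))
}

#' Build sense and antisense matrices from stranded flank matrices
#'
#' @param plus,minus `flank_matrix` objects for the plus and minus
#'   transcript strands; must share sites, flank and bin size.
#' @param overlaps Output of [find_gene_flank_overlaps()].
#' @return List with `sense` and `antisense` `flank_matrix` objects over
#'   the retained sites and `excluded_sites`, the ids dropped for lacking
#'   any gene overlap in the flank.
#' @export
build_orientation_matrices <- function(plus, minus, overlaps) {
  stopifnot(inherits(plus, "flank_matrix"), inherits(minus, "flank_matrix"))
  if (!identical(plus$site_ids, minus$site_ids) ||
      plus$flank != minus$flank || plus$bin_size != minus$bin_size ||
      !all(dim(plus$values) == dim(minus$values)))
    stop("plus and minus matrices do not share sites/shape")
  n_bins <- ncol(plus$values)
  sense <- matrix(0, nrow(plus$values), n_bins)
  anti <- matrix(0, nrow(plus$values), n_bins)
  covered <- logical(length(plus$site_ids))
  ov_by_site <- split(overlaps, overlaps$site_id)
  for (i in seq_along(plus$site_ids)) {
    ov <- ov_by_site[[plus$site_ids[i]]]
    if (is.null(ov) || !nrow(ov)) next
    covered[i] <- TRUE
    for (s in c("+", "-")) {
      sel <- ov$gene_strand == s
      if (!any(sel)) next
      m <- merge_ranges(ov$first_bin[sel], ov$last_bin[sel])
      for (j in seq_along(m$first)) {
        bins <- (m$first[j] + 1L):m$last[j]
        if (s == "+") {
          sense[i, bins] <- sense[i, bins] + plus$values[i, bins]
          anti[i, bins] <- anti[i, bins] + minus$values[i, bins]
        } else {
          sense[i, bins] <- sense[i, bins] + minus$values[i, bins]
          anti[i, bins] <- anti[i, bins] + plus$values[i, bins]
        }
      }
    }
  }
  keep <- which(covered)
  mk <- function(vals, orientation)
    flank_matrix(vals[keep, , drop = FALSE], plus$site_ids[keep],
                 plus$anchors[keep, , drop = FALSE], plus$flank,
                 plus$bin_size, orientation,
                 (plus$clipped | minus$clipped)[keep])
  list(sense = mk(sense, "sense"), antisense = mk(anti, "antisense"),
       excluded_sites = plus$site_ids[!covered])
}

#' Sense/antisense annotation in one step
#'
#' Convenience wrapper: overlaps via [find_gene_flank_overlaps()] then
#' [build_orientation_matrices()].
#'
#' @inheritParams build_orientation_matrices
#' @param sites,genes As in [find_gene_flank_overlaps()].
#' @return See [build_orientation_matrices()].
#' @export
orient_matrices <- function(plus, minus, sites, genes) {
  ov <- find_gene_flank_overlaps(sites, genes, plus$flank, plus$bin_size)
  build_orientation_matrices(plus, minus, ov)
}
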