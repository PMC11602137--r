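# FlankMatrix: sites x bins CPM matrix anchored at DSBs. Columns run
# genomic-left-to-right over [anchor - flank, anchor + flank); bin j
# (1-based) covers offsets [-flank + (j-1)*bin_size, -flank + j*bin_size).

ORIENTATIONS <- c("plus", "minus", "sense", "antisense", "total")

#' Construct a DSB-anchored flank matrix
#'
#' @param values Numeric matrix, one row per site, `2 * flank / bin_size`
#'   columns of mean per-base CPM.
#' @param site_ids Character vector of row identities.
#' @param anchors `data.frame` with columns `chrom`, `anchor` (0-based
#'   anchor base), one row per site.
#' @param flank Half-width of the window in bp.
#' @param bin_size Bin width in bp; must divide `2 * flank`.
#' @param orientation One of `"plus"`, `"minus"`, `"sense"`, `"antisense"`,
#'   `"total"`.
#' @param clipped Logical vector flagging rows whose window ran off the
#'   contig (out-of-contig positions contribute 0).
#' @return A `flank_matrix` object.
#' @export
flank_matrix <- function(values, site_ids, anchors, flank, bin_size,
                         orientation, clipped = NULL) {
  values <- as.matrix(values)
  flank <- as.integer(flank)
  bin_size <- as.integer(bin_size)
  if (flank <= 0L) stop("flank must be > 0")
  if (bin_size < 1L || (2L * flank) %% bin_size != 0L)
    stop("bin_size must be >= 1 and divide 2*flank")
  n_bins <- 2L * flank %/% bin_size
  if (ncol(values) != n_bins)
    stop(sprintf("matrix has %d columns, expected %d", ncol(values), n_bins))
  if (nrow(values) != length(site_ids))
    stop("row count does not match site_ids")
  if (!orientation %in% ORIENTATIONS)
    stop("orientation must be one of: ", paste(ORIENTATIONS, collapse = ", "))
  if (anyDuplicated(site_ids)) stop("duplicate site_id")
  if (is.null(clipped)) clipped <- rep(FALSE, length(site_ids))
  rownames(values) <- site_ids
  colnames(values) <- bin_offsets(flank, bin_size)
  structure(list(values = values, site_ids = as.character(site_ids),
                 anchors = anchors, flank = flank, bin_size = bin_size,
                 orientation = orientation, clipped = clipped),
            class = "flank_matrix")
}

#' Bin start offsets of a flank window
#' @param flank Half-width (bp).
#' @param bin_size Bin width (bp).
#' @return Integer vector of signed bin start offsets relative to anchor.
#' @export
bin_offsets <- function(flank, bin_size) {
  seq.int(-flank, flank - bin_size, by = bin_size)
}

#' @export
print.flank_matrix <- function(x, ...) {
  cat(sprintf("flank_matrix: %d sites x %d bins (flank %d bp, bin %d bp, %s)\n",
              nrow(x$values), ncol(x$values), x$flank, x$bin_size,
              x$orientation))
  invisible(x)
}

#' @export
dim.flank_matrix <- function(x) dim(x$values)

#' Subset a flank matrix by site id
#' @param fm `flank_matrix`.
#' @param site_ids Ids to keep, in the order given.
#' @return A `flank_matrix` over the selected sites.
#' @export
subset_sites <- function(fm, site_ids) {
  idx <- match(site_ids, fm$site_ids)
  if (anyNA(idx)) stop("unknown site_id: ", site_ids[which(is.na(idx))[1]])
  flank_matrix(fm$values[idx, , drop = FALSE], fm$site_ids[idx],
               fm$anchors[idx, , drop = FALSE], fm$flank, fm$bin_size,
               fm$orientation, fm$clipped[idx])
}

#' Average a list of flank matrices element-wise
#'
#' Used to pool replicate matrices of one condition before fold-change
#' analysis; all matrices must share sites, flank, bin size and orientation.
#'
#' @param fms List of `flank_matrix` objects.
#' @return A single `flank_matrix` of element-wise means.
#' @export
average_matrices <- function(fms) {
  stopifnot(length(fms) >= 1)
  f1 <- fms[[1]]
  for (fm in fms[-1]) {
    if (!identical(fm$site_ids, f1$site_ids) ||
        fm$flank != f1$flank || fm$bin_size != f1$bin_size ||
        fm$orientation != f1$orientation)
      stop("flank matrices are not compatible")
  }
  vals <- Reduce(`+`, lapply(fms, `[[`, "values")) / length(fms)
  flank_matrix(vals, f1$site_ids, f1$anchors, f1$flank, f1$bin_size,
               f1$orientation, Reduce(`|`, lapply(fms, `[[`, "clipped")))
}

#' Write a flank matrix as TSV with a metadata sidecar header
#'
#' The file carries `#key=value` header lines (flank, bin_size,
#' orientation), then a header row of bin offsets and one row per site
#' (`site_id`, `chrom`, `anchor`, `clipped`, bin values at full precision).
#'
#' @param fm `flank_matrix`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_flank_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "flank_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#flank=%d", fm$flank),
               sprintf("#bin_size=%d", fm$bin_size),
               sprintf("#orientation=%s", fm$orientation)), con)
  writeLines(paste(c("site_id", "chrom", "anchor", "clipped",
                     colnames(fm$values)), collapse = "\t"), con)
  vals <- apply(fm$values, 1, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(fm$site_ids, fm$anchors$chrom, fm$anchors$anchor,
                   as.integer(fm$clipped), vals, sep = "\t"), con)
  invisible(path)
}

#' Read a flank matrix written by [write_flank_matrix()]
#' @param path TSV path.
#' @return A `flank_matrix` equal to the one written, to full precision.
#' @export
read_flank_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  body <- lines[!grepl("^#", lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_meta <- 4L
  rows <- fields[-1]
  if (length(rows) && any(lengths(rows) != length(header)))
    stop("matrix row length does not match header")
  vals <- t(vapply(rows, function(f)
    as.numeric(f[-seq_len(n_meta)]), numeric(length(header) - n_meta)))
  if (!length(rows)) vals <- matrix(0, 0, length(header) - n_meta)
  flank_matrix(vals,
               site_ids = vapply(rows, `[`, "", 1),
               anchors = data.frame(
                 chrom = vapply(rows, `[`, "", 2),
                 anchor = as.integer(vapply(rows, `[`, "", 3)),
                 stringsAsFactors = FALSE),
               flank = as.integer(meta[["flank"]]),
               bin_size = as.integer(meta[["bin_size"]]),
               orientation = meta[["orientation"]],
               clipped = as.logical(as.integer(vapply(rows, `[`, "", 4))))
}
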