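# Stranded reads and CPM coverage.
#
# A StrandedReadSet is an interval data.frame (every read stranded) plus a
# library_size used for CPM scaling. Coverage counts full read spans; CPM
# at position p on strand s = (# strand-s reads covering p) * 1e6 /
# library_size.

#' Construct a stranded read set
#'
#' @param reads Interval `data.frame`; every read must carry strand
#'   `"+"` or `"-"`.
#' @param library_size Total read count used for CPM normalisation;
#'   defaults to `nrow(reads)`. Must be >= the number of reads retained.
#' @return A `stranded_reads` object.
#' @export
stranded_reads <- function(reads, library_size = nrow(reads)) {
  validate_intervals(reads, require_strand = TRUE)
  if (library_size <= 0) stop("library_size must be > 0")
  if (library_size < nrow(reads))
    stop("library_size smaller than the number of reads")
  structure(list(reads = reads, library_size = as.numeric(library_size)),
            class = "stranded_reads")
}

#' @export
print.stranded_reads <- function(x, ...) {
  cat(sprintf("stranded_reads: %d reads (+: %d, -: %d), library size %g\n",
              nrow(x$reads), sum(x$reads$strand == "+"),
              sum(x$reads$strand == "-"), x$library_size))
  invisible(x)
}

#' Assign transcript strands to alignments
#'
#' Maps alignment strands to transcript strands for a stranded RNA library.
#' The reverse (dUTP-type, e.g. TruSeq Stranded) protocol inverts
#' single-end alignments (alignment `+` -> transcript `-` and vice versa);
#' for paired-end input (optional integer `mate` column with values 1/2)
#' mate-1 orientation is inverted and mate-2 preserved. The forward
#' protocol is the identity. Unstranded alignments are skipped and counted.
#'
#' @param alignments Interval `data.frame` of alignments, optionally with a
#'   `mate` column.
#' @param protocol `"reverse"` (default, dUTP-type) or `"forward"`.
#' @return A `stranded_reads` object; attribute `counts` holds the number
#'   of `+` and `-` transcript-strand reads and the skipped count.
#' @export
assign_transcript_strand <- function(alignments,
                                     protocol = c("reverse", "forward")) {
  protocol <- match.arg(protocol)
  validate_intervals(alignments)
  skip <- alignments$strand == "."
  n_skipped <- sum(skip)
  if (n_skipped)
    message(sprintf("assign_transcript_strand: skipped %d unstranded alignments",
                    n_skipped))
  al <- alignments[!skip, , drop = FALSE]
  strand <- al$strand
  if (protocol == "reverse") {
    flip <- if ("mate" %in% names(al)) al$mate == 1L else rep(TRUE, nrow(al))
    strand <- ifelse(flip, ifelse(strand == "+", "-", "+"), strand)
  }
  al$strand <- strand
  al$mate <- NULL
  rs <- stranded_reads(al, library_size = nrow(al))
  attr(rs, "counts") <- c(plus = sum(strand == "+"),
                          minus = sum(strand == "-"),
                          skipped = n_skipped)
  rs
}

#' Strand-resolved CPM coverage
#'
#' Per-chromosome, per-strand arrays of CPM-normalised per-base depth.
#' Scaling the read multiset by any positive integer factor leaves the
#' values unchanged.
#'
#' @param reads A `stranded_reads` object.
#' @param sizes Named chromosome-length vector; every read must fit.
#' @return A `stranded_coverage` object: `$cov[[chrom]]$plus` /
#'   `$minus` numeric vectors of length `sizes[chrom]`.
#' @export
cpm_coverage <- function(reads, sizes) {
  stopifnot(inherits(reads, "stranded_reads"))
  df <- reads$reads
  check_bounds(df, sizes)
  scale <- 1e6 / reads$library_size
  cov <- lapply(names(sizes), function(chrom) {
    L <- sizes[[chrom]]
    on_chrom <- df$chrom == chrom
    per_strand <- function(s) {
      sel <- on_chrom & df$strand == s
      if (!any(sel)) return(numeric(L))
      # difference-array pileup: +1 at starts, -1 at ends, then cumsum
      d <- numeric(L + 1L)
      st <- tabulate(df$start[sel] + 1L, nbins = L + 1L)
      en <- tabulate(df$end[sel] + 1L, nbins = L + 1L)
      cumsum(st - en)[seq_len(L)] * scale
    }
    list(plus = per_strand("+"), minus = per_strand("-"))
  })
  names(cov) <- names(sizes)
  structure(list(cov = cov, library_size = reads$library_size,
                 scale = scale, sizes = sizes),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat(sprintf("stranded_coverage: %d chromosome(s), library size %g\n",
              length(x$cov), x$library_size))
  invisible(x)
}

#' Collapse stranded coverage to an unstranded track
#' @param cov `stranded_coverage`.
#' @return Named list chromosome -> numeric per-base vector (plus + minus).
#' @export
total_track <- function(cov) {
  lapply(cov$cov, function(ch) ch$plus + ch$minus)
}

#' Extract one strand of a coverage object as a plain track
#' @param cov `stranded_coverage`.
#' @param strand `"plus"`, `"minus"` or `"total"`.
#' @return Named list chromosome -> numeric per-base vector.
#' @export
strand_track <- function(cov, strand = c("plus", "minus", "total")) {
  strand <- match.arg(strand)
  if (strand == "total") return(total_track(cov))
  lapply(cov$cov, function(ch) ch[[strand]])
}

#' DSB-anchored flank matrix from coverage
#'
#' Row i, column j holds the mean per-base CPM over the j-th bin of
#' `[anchor_i - flank, anchor_i + flank)`, left-to-right in genomic
#' coordinates. Window positions outside the chromosome contribute 0 and
#' the row is flagged as clipped; a window entirely off-contig yields a
#' zero row plus a warning.
#'
#' @param cov `stranded_coverage` or a plain track (named list of per-base
#'   vectors).
#' @param sites Interval table of DSB sites; anchors via [site_anchors()].
#' @param flank Half-width in bp.
#' @param bin_size Bin width in bp, must divide `2 * flank`.
#' @param strand_of_track `"plus"`, `"minus"` or `"unstranded"` — which
#'   strand of `cov` to extract (ignored for plain tracks).
#' @return A `flank_matrix` (orientation `plus`/`minus`/`total`).
#' @export
compute_flank_matrix <- function(cov, sites, flank = 2500L, bin_size = 1L,
                                 strand_of_track = c("plus", "minus",
                                                     "unstranded")) {
  strand_of_track <- match.arg(strand_of_track)
  track <- if (inherits(cov, "stranded_coverage")) {
    strand_track(cov, if (strand_of_track == "unstranded") "total"
                 else strand_of_track)
  } else cov
  flank <- as.integer(flank); bin_size <- as.integer(bin_size)
  if (flank <= 0L) stop("flank must be > 0")
  if (bin_size < 1L || (2L * flank) %% bin_size != 0L)
    stop("bin_size must divide 2*flank")
  anchors <- site_anchors(sites)
  ids <- site_ids_of(sites)
  n_bins <- 2L * flank %/% bin_size
  vals <- matrix(0, nrow(sites), n_bins)
  clipped <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    v <- track[[chrom]]
    if (is.null(v)) stop("no coverage for chromosome ", chrom)
    L <- length(v)
    w_start <- anchors[i] - flank
    w_end <- anchors[i] + flank
    if (w_end <= 0L || w_start >= L) {
      clipped[i] <- TRUE
      warning(sprintf("window of site %s lies entirely off contig %s",
                      ids[i], chrom))
      next
    }
    pos <- w_start:(w_end - 1L)
    inside <- pos >= 0L & pos < L
    base <- numeric(2L * flank)
    base[inside] <- v[pos[inside] + 1L]
    clipped[i] <- !all(inside)
    vals[i, ] <- colMeans(matrix(base, nrow = bin_size))
  }
  flank_matrix(vals, ids, data.frame(chrom = sites$chrom, anchor = anchors,
                                     stringsAsFactors = FALSE),
               flank, bin_size,
               orientation = switch(strand_of_track, plus = "plus",
                                    minus = "minus", unstranded = "total"),
               clipped = clipped)
}

# site ids: BED name column when informative, else chrom:start-end
site_ids_of <- function(sites) {
  ids <- if ("name" %in% names(sites) &&
             !all(sites$name == ".")) sites$name
  else sprintf("%s:%d-%d", sites$chrom, sites$start, sites$end)
  if (anyDuplicated(ids)) stop("duplicate site identifiers")
  ids
}

#' Sum a plain coverage track over genomic windows
#'
#' @param track Named list chromosome -> per-base numeric vector.
#' @param sites Site interval table.
#' @param window Half-width in bp: the sum spans `[anchor - window,
#'   anchor + window)`, clipped to the contig.
#' @return Numeric vector of per-site sums.
#' @export
window_track_sum <- function(track, sites, window) {
  anchors <- site_anchors(sites)
  vapply(seq_len(nrow(sites)), function(i) {
    v <- track[[sites$chrom[i]]]
    if (is.null(v)) stop("no coverage for chromosome ", sites$chrom[i])
    lo <- max(anchors[i] - window, 0L)
    hi <- min(anchors[i] + window, length(v))
    if (hi <= lo) 0 else sum(v[(lo + 1L):hi])
  }, numeric(1))
}
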