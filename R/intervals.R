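# Internal coordinate convention: BED-style 0-based half-open [start, end),
# strand one of "+", "-", "." ("." = unstranded). GTF input is converted on
# read; nothing in the package ever holds 1-based coordinates.

STRANDS <- c("+", "-", ".")

#' Construct a genomic-interval table
#'
#' Builds and validates the package's interval container: a plain
#' `data.frame` with columns `chrom`, `start`, `end`, `name`, `score`,
#' `strand` in BED 0-based half-open convention.
#'
#' @param chrom Character vector of chromosome names (passed through
#'   verbatim, no "chr" normalisation).
#' @param start,end Integer vectors; `start` is 0-based inclusive, `end`
#'   0-based exclusive, `end > start >= 0`.
#' @param name,score Optional character vectors (BED columns 4-5); kept as
#'   character so files round-trip byte-identically.
#' @param strand Character vector over `"+"`, `"-"`, `"."`.
#' @return A validated `data.frame` of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, name = ".", score = "0",
                              strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   name = as.character(name),
                   score = as.character(score),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' @param df Interval `data.frame` as built by [genomic_intervals()].
#' @param require_strand If `TRUE`, unstranded rows are an error.
#' @return `df`, invisibly, after validation.
#' @export
validate_intervals <- function(df, require_strand = FALSE) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval coordinates must be integers")
  if (any(df$start < 0))
    stop("interval start must be >= 0")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(sprintf("invalid interval (end <= start) at row %d: %s:%d-%d",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  if (!all(df$strand %in% STRANDS))
    stop("strand must be one of '+', '-', '.'")
  if (require_strand && any(df$strand == "."))
    stop("unstranded interval where a strand is required (row ",
         which(df$strand == ".")[1], ")")
  invisible(df)
}

#' Read a BED interval file
#'
#' Strict BED3/BED6 reader. Coordinates are kept in the file's native
#' 0-based half-open convention; chromosome names pass through verbatim.
#'
#' @param path Path to a BED file (>= 3 tab-separated columns).
#' @param require_strand If `TRUE`, a missing or `"."` strand column is an
#'   error; otherwise missing strand yields unstranded (`"."`) intervals.
#' @return Interval `data.frame` in file order.
#' @export
read_intervals <- function(path, require_strand = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track |browser )", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 lineno[which(nf < 3)[1]]))
  gets <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  start <- suppressWarnings(as.integer(gets(2, NA)))
  end <- suppressWarnings(as.integer(gets(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("malformed BED line %d: coordinates are not integers",
                 lineno[bad[1]]))
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("invalid interval on line %d: end <= start", lineno[bad[1]]))
  strand <- gets(6, ".")
  bad <- which(!strand %in% STRANDS)
  if (length(bad))
    stop(sprintf("malformed BED line %d: bad strand '%s'",
                 lineno[bad[1]], strand[bad[1]]))
  if (require_strand && any(strand == "."))
    stop(sprintf("line %d: strand required but missing",
                 lineno[which(strand == ".")[1]]))
  genomic_intervals(gets(1, NA), start, end,
                    name = gets(4, "."), score = gets(5, "0"),
                    strand = strand)
}

#' Write intervals as BED6
#'
#' @param df Interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path) {
  validate_intervals(df)
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else "0"
  out <- paste(df$chrom, df$start, df$end, name, score, df$strand, sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' @param path Two-column tab-separated file: chromosome name, length (bp).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (any(df$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome name")
  stats::setNames(df$length, df$chrom)
}

#' Write a chromosome-sizes table
#' @param sizes Named integer vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), as.integer(sizes), sep = "\t"), path)
  invisible(path)
}

#' Check interval bounds against chromosome sizes
#' @param df Interval table.
#' @param sizes Named vector from [read_chrom_sizes()].
#' @return `df` invisibly; errors name the first offending interval.
#' @export
check_bounds <- function(df, sizes) {
  unknown <- setdiff(unique(df$chrom), names(sizes))
  if (length(unknown))
    stop("chromosome(s) absent from sizes table: ",
         paste(unknown, collapse = ", "))
  over <- which(df$end > sizes[df$chrom])
  if (length(over))
    stop(sprintf("interval beyond chromosome end: %s:%d-%d (length %d)",
                 df$chrom[over[1]], df$start[over[1]], df$end[over[1]],
                 sizes[[df$chrom[over[1]]]]))
  invisible(df)
}

#' Preflight chromosome-name comparison between inputs
#'
#' Chromosome names are never normalised; this check surfaces silent
#' name-set disagreement (e.g. "chr1" vs "1") between two inputs.
#'
#' @param a,b Interval tables or character vectors of chromosome names.
#' @param labels Length-2 character labels used in the message.
#' @return `TRUE` invisibly if the name sets intersect; warns otherwise.
#' @export
check_chrom_names <- function(a, b, labels = c("first", "second")) {
  na <- if (is.data.frame(a)) unique(a$chrom) else unique(as.character(a))
  nb <- if (is.data.frame(b)) unique(b$chrom) else unique(as.character(b))
  if (!length(intersect(na, nb)))
    warning(sprintf("chromosome name sets of %s and %s do not overlap",
                    labels[1], labels[2]))
  invisible(length(intersect(na, nb)) > 0)
}

#' DSB anchor positions
#'
#' A site interval wider than 1 bp (e.g. an 8-bp recognition motif) is
#' anchored at `floor((start + end) / 2)`, the midpoint base.
#'
#' @param sites Interval table of DSB sites.
#' @return Integer vector of anchor positions (0-based).
#' @export
site_anchors <- function(sites) {
  as.integer(floor((sites$start + sites$end) / 2))
}

#' Read a gene annotation (BED6 or GTF)
#'
#' BED6 genes use column 4 as `gene_id`; GTF `gene` features use the
#' `gene_id` attribute (read through rtracklayer and converted to the
#' internal 0-based half-open convention). Every gene must be stranded and
#' ids must be unique.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "bed") {
    iv <- read_intervals(path, require_strand = TRUE)
    ann <- data.frame(gene_id = iv$name, chrom = iv$chrom, start = iv$start,
                      end = iv$end, strand = iv$strand,
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (!length(gr)) stop("no 'gene' features in GTF: ", path)
    if (is.null(gr$gene_id) || any(is.na(gr$gene_id)))
      stop("GTF gene feature without gene_id attribute")
    ann <- data.frame(gene_id = as.character(gr$gene_id),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  }
  if (any(!ann$strand %in% c("+", "-")))
    stop("unstranded gene in annotation: ",
         ann$gene_id[which(!ann$strand %in% c("+", "-"))[1]])
  dup <- anyDuplicated(ann$gene_id)
  if (dup) stop("duplicate gene_id: ", ann$gene_id[dup])
  validate_intervals(ann, require_strand = TRUE)
  ann
}

#' Write a gene annotation as BED6
#' @param ann Gene table from [read_gene_annotation()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_gene_annotation <- function(ann, path) {
  write_intervals(genomic_intervals(ann$chrom, ann$start, ann$end,
                                    name = ann$gene_id, score = "0",
                                    strand = ann$strand), path)
}

#' Export a coverage track as bedGraph
#'
#' Run-length encodes a per-base track (one numeric vector per chromosome)
#' into bedGraph; zero runs are omitted.
#'
#' @param track Named list, chromosome -> numeric per-base vector.
#' @param path Output path.
#' @param digits Significant digits written (default full precision).
#' @return `path` invisibly.
#' @export
write_bedgraph <- function(track, path, digits = 17) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    r <- rle(track[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(paste(chrom, starts[keep], ends[keep],
                       formatC(r$values[keep], digits = digits,
                               format = "g"), sep = "\t"), con)
  }
  invisible(path)
}
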