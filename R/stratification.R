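# Site stratification: cleavage-efficiency ranking from DSB-capture
# (BLESS-type) read counts, HR/NHEJ-propensity labelling from the
# RAD51/XRCC4 window-coverage ratio, transcription-activity classes from
# baseline sense coverage, and recognition-motif scanning.

#' Rank DSB sites by cleavage efficiency
#'
#' Counts DSB-capture reads overlapping `[anchor - window, anchor +
#' window)` per site and ranks sites in ascending order of raw read count
#' (no CPM: the capture procedure counts reads). Ties are broken by
#' `site_id` lexicographic order (stable).
#'
#' @param dsb_reads A `stranded_reads` object or plain interval table of
#'   capture reads (strand ignored).
#' @param sites Site interval table.
#' @param window Half-width in bp (default 500: the anchor +/- 500 bp
#'   counting region).
#' @return `data.frame` with `site_id`, `chrom`, `anchor`,
#'   `cleavage_reads`, `efficiency_rank` (1 = least efficiently cut).
#' @export
rank_cleavage_efficiency <- function(dsb_reads, sites, window = 500L) {
  if (inherits(dsb_reads, "stranded_reads")) dsb_reads <- dsb_reads$reads
  if (!nrow(sites)) stop("empty site list")
  if (window <= 0) stop("window must be > 0")
  anchors <- site_anchors(sites)
  ids <- site_ids_of(sites)
  counts <- vapply(seq_len(nrow(sites)), function(i) {
    lo <- anchors[i] - window
    hi <- anchors[i] + window
    sum(dsb_reads$chrom == sites$chrom[i] &
        dsb_reads$start < hi & dsb_reads$end > lo)
  }, numeric(1))
  rank <- integer(length(ids))
  rank[order(counts, ids)] <- seq_along(ids)
  data.frame(site_id = ids, chrom = sites$chrom, anchor = anchors,
             cleavage_reads = as.integer(counts), efficiency_rank = rank,
             stringsAsFactors = FALSE)
}

#' Label sites as HR- or NHEJ-prone
#'
#' `pathway_ratio` = (summed RAD51 coverage in anchor +/- `w_hr`) /
#' (summed XRCC4 coverage in anchor +/- `w_nhej`); a zero denominator
#' sorts as +Inf. The `k` largest ratios are labelled `HR_prone`, the `k`
#' smallest `NHEJ_prone`, the remainder `unlabelled`; ties break by
#' `site_id`.
#'
#' @param rad51_cov,xrcc4_cov `stranded_coverage` objects or plain tracks
#'   (named list chromosome -> per-base vector).
#' @param sites Site interval table.
#' @param w_hr RAD51 window half-width (default 4000 bp).
#' @param w_nhej XRCC4 window half-width (default 1000 bp).
#' @param k Number of sites per label (default 30); needs `2k <= n`.
#' @return `data.frame` with `site_id`, `pathway_ratio`, `pathway`.
#' @export
classify_repair_pathway <- function(rad51_cov, xrcc4_cov, sites,
                                    w_hr = 4000L, w_nhej = 1000L, k = 30L) {
  if (2L * k > nrow(sites))
    stop(sprintf("2k = %d exceeds the number of sites (%d)",
                 2L * k, nrow(sites)))
  as_track <- function(x) if (inherits(x, "stranded_coverage"))
    total_track(x) else x
  rad <- window_track_sum(as_track(rad51_cov), sites, w_hr)
  xrc <- window_track_sum(as_track(xrcc4_cov), sites, w_nhej)
  ratio <- ifelse(xrc == 0, Inf, rad / xrc)
  ids <- site_ids_of(sites)
  ord <- order(-ratio, ids)            # descending ratio, stable by id
  pathway <- rep("unlabelled", length(ids))
  pathway[ord[seq_len(k)]] <- "HR_prone"
  pathway[ord[seq.int(length(ids) - k + 1L, length(ids))]] <- "NHEJ_prone"
  data.frame(site_id = ids, pathway_ratio = ratio, pathway = pathway,
             stringsAsFactors = FALSE)
}

#' Classify sites by local transcription activity
#'
#' Per-site score = total sense CPM across the flank in the undamaged
#' (baseline) condition. The top `quantile` fraction of sites is labelled
#' `high`, the bottom fraction `low`, the rest `unlabelled`; ties break by
#' `site_id`.
#'
#' @param sense_baseline Sense `flank_matrix` from the no-damage condition.
#' @param quantile Fraction in (0, 0.5] labelled at each extreme
#'   (default 1/3: terciles).
#' @return `data.frame` with `site_id`, `activity_score`,
#'   `transcription_class`.
#' @export
classify_transcription_activity <- function(sense_baseline, quantile = 1/3) {
  stopifnot(inherits(sense_baseline, "flank_matrix"))
  if (quantile <= 0 || quantile > 0.5)
    stop("quantile must be in (0, 0.5]")
  score <- rowSums(sense_baseline$values)
  ids <- sense_baseline$site_ids
  cls <- rep("unlabelled", length(ids))
  if (all(score == 0)) {
    warning("all activity scores are zero; no transcription classes assigned")
  } else {
    n_lab <- floor(quantile * length(ids))
    ord <- order(-score, ids)
    if (n_lab >= 1) {
      cls[ord[seq_len(n_lab)]] <- "high"
      cls[ord[seq.int(length(ids) - n_lab + 1L, length(ids))]] <- "low"
    }
  }
  data.frame(site_id = ids, activity_score = score,
             transcription_class = cls, stringsAsFactors = FALSE)
}

#' Scan sequences for a recognition motif
#'
#' Reports all exact, possibly overlapping, forward-strand occurrences of
#' the motif (0-based start positions). When the motif is not its own
#' reverse complement, reverse-complement hits are also reported and
#' flagged by strand; for a palindromic motif such as the 8-bp AsiSI site
#' GCGATCGC the forward scan is already complete.
#'
#' @param sequences Character vector of DNA sequences over A/C/G/T/N
#'   (optionally named), or a `Biostrings::DNAStringSet`.
#' @param motif DNA motif string (default the AsiSI recognition sequence).
#' @return `data.frame` with `seq_name`, `position` (0-based) and
#'   `strand`; empty sequences simply contribute no hits.
#' @export
scan_motif <- function(sequences, motif = "GCGATCGC") {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
    if (is.null(names(sequences)))
      names(sequences) <- paste0("seq", seq_along(sequences))
    sequences <- Biostrings::DNAStringSet(
      ifelse(nzchar(sequences), sequences, "N"))
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  motif_d <- Biostrings::DNAString(motif)
  rc <- as.character(Biostrings::reverseComplement(motif_d))
  scan_one <- function(subject, pat, strand) {
    m <- Biostrings::matchPattern(pat, subject)
    if (!length(m)) return(NULL)
    data.frame(position = Biostrings::start(m) - 1L, strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- lapply(seq_along(sequences), function(i) {
    hits <- scan_one(sequences[[i]], motif_d, "+")
    if (!identical(rc, motif))
      hits <- rbind(hits, scan_one(sequences[[i]],
                                   Biostrings::DNAString(rc), "-"))
    if (is.null(hits)) return(NULL)
    cbind(seq_name = names(sequences)[i], hits, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(seq_name = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  attr(res, "motif") <- motif
  res
}

#' Assemble a DSB site table
#'
#' Joins efficiency ranking, pathway labels and transcription classes into
#' the per-site annotation table the figures and group comparisons use.
#'
#' @param efficiency Output of [rank_cleavage_efficiency()].
#' @param pathway Optional output of [classify_repair_pathway()].
#' @param transcription Optional output of
#'   [classify_transcription_activity()].
#' @param cut_status Optional named character vector (`cut`/`uncut`) keyed
#'   by site_id.
#' @return Merged per-site `data.frame`.
#' @export
dsb_site_table <- function(efficiency, pathway = NULL, transcription = NULL,
                           cut_status = NULL) {
  tab <- efficiency
  if (!is.null(pathway))
    tab <- merge(tab, pathway, by = "site_id", all.x = TRUE, sort = FALSE)
  if (!is.null(transcription))
    tab <- merge(tab, transcription, by = "site_id", all.x = TRUE,
                 sort = FALSE)
  if (!is.null(cut_status))
    tab$cut_status <- unname(cut_status[tab$site_id])
  tab[order(tab$efficiency_rank), , drop = FALSE]
}
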