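# Independent brute-force oracles and tiny fixture builders. Every oracle
# here is implemented without reference to the package's own code paths.

# nested-loop pileup: CPM at every base of one chromosome/strand
pileup_oracle <- function(reads, chrom, strand, L, library_size) {
  v <- numeric(L)
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != chrom || reads$strand[i] != strand) next
    for (p in (reads$start[i] + 1L):reads$end[i]) v[p] <- v[p] + 1
  }
  v * 1e6 / library_size
}

# triple-loop sense/antisense oracle over (site, bin, gene); same-strand
# gene regions count once per bin (any-cover), opposite strands both add
orientation_oracle <- function(plus_vals, minus_vals, sites, genes,
                               flank, anchors) {
  n_bins <- 2L * flank
  sense <- matrix(0, nrow(sites), n_bins)
  anti <- matrix(0, nrow(sites), n_bins)
  covered <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    w_start <- anchors[i] - flank
    for (b in seq_len(n_bins)) {
      pos <- w_start + b - 1L           # bin = single base (bin_size 1)
      in_plus <- FALSE; in_minus <- FALSE
      for (g in seq_len(nrow(genes))) {
        if (genes$chrom[g] != sites$chrom[i]) next
        if (genes$start[g] <= pos && pos < genes$end[g]) {
          if (genes$strand[g] == "+") in_plus <- TRUE else in_minus <- TRUE
        }
      }
      if (in_plus) {
        sense[i, b] <- sense[i, b] + plus_vals[i, b]
        anti[i, b] <- anti[i, b] + minus_vals[i, b]
      }
      if (in_minus) {
        sense[i, b] <- sense[i, b] + minus_vals[i, b]
        anti[i, b] <- anti[i, b] + plus_vals[i, b]
      }
      if (in_plus || in_minus) covered[i] <- TRUE
    }
    # a site also counts as covered if any gene touches any window base
    # (handled above since every bin is visited)
  }
  list(sense = sense, anti = anti, covered = covered)
}

# full-enumeration two-sided rank-sum p-value over value assignments
ranksum_enum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  stat <- function(idx) {
    xx <- pool[idx]; yy <- pool[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- stat(seq_len(n))
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, stat)
  mean(abs(u_all - n * m / 2) >= abs(obs - n * m / 2) - 1e-12)
}

# character-level sliding-window motif scan (forward strand, 0-based)
naive_motif_scan <- function(seq, motif) {
  s <- strsplit(seq, "")[[1]]
  k <- nchar(motif)
  if (length(s) < k) return(integer())
  mm <- strsplit(motif, "")[[1]]
  hit <- rep(TRUE, length(s) - k + 1L)
  for (j in seq_len(k)) hit <- hit & (s[j:(length(s) - k + j)] == mm[j])
  which(hit) - 1L
}

revcomp_chr <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# random small instance for the orientation tests: sites, genes and
# stranded flank matrices on one chromosome
random_orientation_instance <- function(max_sites = 10, max_genes = 20,
                                        max_flank = 200) {
  flank <- sample(20:max_flank, 1)
  n_sites <- sample.int(max_sites, 1)
  n_genes <- sample.int(max_genes, 1)
  L <- 10000L
  anchor <- sort(sample(seq(flank, L - flank), n_sites))
  sites <- genomic_intervals("chrA", anchor, anchor + 1L,
                             name = sprintf("s%02d", seq_len(n_sites)))
  gs <- sample.int(L - 50L, n_genes)
  ge <- pmin(gs + sample(10:2000, n_genes, replace = TRUE), L)
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                      chrom = "chrA", start = as.integer(gs),
                      end = as.integer(ge),
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      stringsAsFactors = FALSE)
  mk <- function(orientation) {
    flank_matrix(matrix(round(stats::runif(n_sites * 2 * flank) * 10, 3),
                        n_sites, 2 * flank),
                 sites$name,
                 data.frame(chrom = sites$chrom, anchor = anchor),
                 flank, 1L, orientation)
  }
  list(sites = sites, genes = genes, anchors = anchor, flank = flank,
       plus = mk("plus"), minus = mk("minus"))
}

# tiny deterministic read set on one short chromosome
tiny_reads <- function(n = 25, L = 1000L, read_len = 10L, seed = 11) {
  set.seed(seed)
  start <- sample.int(L - read_len, n, replace = TRUE)
  genomic_intervals("chrA", start, start + read_len,
                    strand = sample(c("+", "-"), n, TRUE))
}
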