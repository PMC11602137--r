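# Synthetic-data generator: genomes, genes, DSB sites and stranded read
# sets with the statistical structure the analysis assumes, plus a
# machine-readable truth record.
#
# The generative model (see the methods vignette for rationale):
#   * genes transcribe sense reads at lambda_sense reads/kb/library and a
#     weaker antisense background at lambda_antisense reads/kb (chromatin
#     RNA retains substantial unstable antisense transcription);
#   * a small class of highly expressed genes supplies most of the
#     library, as a few loci do in real chromatin RNA libraries, keeping
#     damage-induced reads a small fraction of the total so CPM scaling
#     does not distort fold changes;
#   * each cut site adds bidirectional damage-induced reads on both
#     strands with per-position expectation e_s * A * exp(-|d| / L);
#   * the knockdown condition multiplies induction on the host gene's
#     strand by kappa_sense and on the opposite strand by kappa_antisense;
#   * counts are Poisson by default (negative binomial or deterministic
#     available via `dispersion`).

CONDITIONS <- c("no_damage", "damage_control", "damage_knockdown")

#' Build a simulation configuration
#'
#' Defaults define the package's reference synthetic experiment: 100 cut +
#' 100 uncut sites hosted in genes plus 3 deliberately gene-free sites
#' (exercising the orientation exclusion rule), three replicates per
#' condition, Poisson counts, and damage induction that decays
#' exponentially from the anchor.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome (bp).
#' @param n_genes Number of regular genes (expression `lambda_gene`).
#' @param n_highexpr_genes Number of highly expressed filler genes
#'   (expression `lambda_high`); never host DSB sites.
#' @param gene_length_min,gene_length_max Gene length range (bp; min >=
#'   1200 so the DSB analysis window fits inside a host gene).
#' @param strand_prob Probability a gene is on `+`.
#' @param n_cut_sites,n_uncut_sites Numbers of cut / uncut gene-hosted
#'   sites.
#' @param n_gene_free_sites Sites placed with no gene within the flank.
#' @param efficiency_range Range of per-site cleavage efficiencies
#'   `e_s` for cut sites (uncut sites have `e_s = 0`).
#' @param lambda_gene,lambda_high Sense transcription rates, expected
#'   reads per kb per library.
#' @param lambda_antisense Antisense background rate of every gene
#'   (reads per kb per library).
#' @param noise_rate Unstructured background, reads per kb per strand.
#' @param dart_amplitude `A`: expected induced reads per bp per strand at
#'   the anchor, at `e_s = 1`.
#' @param decay_length `L`: exponential decay length of induced signal
#'   (bp).
#' @param flank Half-width (bp) of induced-signal spread and of the
#'   default analysis window.
#' @param kappa_sense,kappa_antisense Knockdown condition multipliers for
#'   induction on the host-gene strand / opposite strand.
#' @param read_length Read length (bp).
#' @param replicates Replicates per condition.
#' @param dispersion `"poisson"`, `"nb"` or `"none"` (deterministic
#'   rounded expectations, for noise-free order-recovery checks).
#' @param nb_size Negative-binomial size parameter when
#'   `dispersion = "nb"`.
#' @param bless_depth Expected DSB-capture reads per site at `e_s = 1`.
#' @param bless_window Half-width (bp) of DSB-capture read spread.
#' @param chip_depth Depth scale of the RAD51/XRCC4 tracks.
#' @param n_pathway Number of cut sites planted as HR-prone and as
#'   NHEJ-prone.
#' @param hr_ratio,mid_ratio,nhej_ratio Ranges of planted RAD51/XRCC4
#'   ratios for the three planted classes.
#' @param seed Default seed recorded in the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 6L, chromosome_length = 2e6,
                       n_genes = 1000L, n_highexpr_genes = 150L,
                       gene_length_min = 2000L, gene_length_max = 5000L,
                       strand_prob = 0.5,
                       n_cut_sites = 100L, n_uncut_sites = 100L,
                       n_gene_free_sites = 3L,
                       efficiency_range = c(0.3, 1),
                       lambda_gene = 30, lambda_high = 5700,
                       lambda_antisense = 15, noise_rate = 1,
                       dart_amplitude = 0.5, decay_length = 500,
                       flank = 2500L,
                       kappa_sense = 1.3, kappa_antisense = 2,
                       read_length = 75L, replicates = 3L,
                       dispersion = c("poisson", "nb", "none"),
                       nb_size = 10,
                       bless_depth = 500, bless_window = 500L,
                       chip_depth = 300, n_pathway = 30L,
                       hr_ratio = c(5, 10), mid_ratio = c(0.7, 1.4),
                       nhej_ratio = c(0.1, 0.2),
                       seed = 1L) {
  dispersion <- match.arg(dispersion)
  cfg <- as.list(environment())
  stopifnot(n_chromosomes >= 1, chromosome_length > 0,
            n_genes >= 0, n_highexpr_genes >= 0,
            gene_length_min >= 1200, gene_length_max >= gene_length_min,
            strand_prob >= 0, strand_prob <= 1,
            n_cut_sites >= 0, n_uncut_sites >= 0, n_gene_free_sites >= 0,
            all(efficiency_range >= 0), all(efficiency_range <= 1),
            lambda_gene >= 0, lambda_high >= 0, lambda_antisense >= 0,
            noise_rate >= 0, dart_amplitude >= 0, decay_length > 0,
            flank > 0, kappa_sense >= 0, kappa_antisense >= 0,
            read_length >= 1, replicates >= 1, nb_size > 0,
            bless_depth >= 0, chip_depth >= 0, n_pathway >= 0)
  class(cfg) <- "sim_config"
  cfg
}

mix_seed <- function(seed, key) {
  as.integer((as.numeric(seed) %% 1e7) * 131 + key) %% 2147483646L + 1L
}

rdisp <- function(n, mu, cfg) {
  switch(cfg$dispersion,
         poisson = stats::rpois(n, mu),
         nb = stats::rnbinom(n, mu = mu, size = cfg$nb_size),
         none = round(mu))
}

#' Generate a synthetic annotation: genes, DSB sites, chromosome sizes
#'
#' Genes are placed non-overlapping per chromosome (both strands share the
#' coordinate space); the tail of every chromosome is kept gene-free so
#' that deliberately gene-free sites have no gene within the flank.
#' Gene-hosted sites sit inside distinct regular genes, at least 500 bp
#' from the gene ends. Per-site cleavage efficiencies and RAD51/XRCC4
#' intensities are planted and recorded in the truth table.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; identical config + seed give identical
#'   output.
#' @return List with `genes` (gene table + expression rates), `sites`
#'   (interval table, `name` = site_id), `sizes` (named lengths) and
#'   `truth` (per-site planted values).
#' @export
generate_annotation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  L <- as.integer(cfg$chromosome_length)
  sizes <- stats::setNames(rep(L, cfg$n_chromosomes), chroms)
  reserve <- 2L * cfg$flank + 2000L        # gene-free tail per chromosome
  usable <- L - reserve
  n_gene_total <- cfg$n_genes + cfg$n_highexpr_genes

  # spread genes over chromosomes proportionally, place by randomised gaps
  genes <- NULL
  if (n_gene_total > 0) {
    per_chrom <- diff(round(seq(0, n_gene_total,
                                length.out = cfg$n_chromosomes + 1)))
    rows <- list()
    gi <- 0L
    for (ci in seq_along(chroms)) {
      n_c <- per_chrom[ci]
      if (n_c == 0) next
      len <- as.integer(round(stats::runif(n_c, cfg$gene_length_min,
                                           cfg$gene_length_max)))
      min_gap <- 100L
      slack <- usable - sum(len) - (n_c + 1L) * min_gap
      if (slack < 0)
        stop("gene placement infeasible; increase chromosome_length ",
             "or reduce n_genes")
      cuts <- sort(stats::runif(n_c))
      gaps <- min_gap + floor(diff(c(0, cuts, 1)) * slack)
      starts <- cumsum(gaps[seq_len(n_c)] ) + c(0L, cumsum(len))[seq_len(n_c)]
      rows[[ci]] <- data.frame(
        gene_id = sprintf("gene_%04d", gi + seq_len(n_c)),
        chrom = chroms[ci], start = as.integer(starts),
        end = as.integer(starts + len),
        strand = ifelse(stats::runif(n_c) < cfg$strand_prob, "+", "-"),
        stringsAsFactors = FALSE)
      gi <- gi + n_c
    }
    genes <- do.call(rbind, rows)
    stopifnot(all(genes$end <= usable))
    high <- rep(FALSE, nrow(genes))
    if (cfg$n_highexpr_genes > 0)
      high[sample.int(nrow(genes), cfg$n_highexpr_genes)] <- TRUE
    genes$highexpr <- high
    genes$lambda_sense <- ifelse(high, cfg$lambda_high, cfg$lambda_gene)
    genes$lambda_antisense <- cfg$lambda_antisense
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), highexpr = logical(),
                        lambda_sense = numeric(),
                        lambda_antisense = numeric(),
                        stringsAsFactors = FALSE)
  }

  n_hosted <- cfg$n_cut_sites + cfg$n_uncut_sites
  regular <- which(!genes$highexpr)
  hosted_as_free <- FALSE
  if (n_hosted > 0 && length(regular) == 0) {
    hosted_as_free <- TRUE                # degenerate: no genes to host
  } else if (n_hosted > length(regular)) {
    stop("not enough regular genes to host the requested sites")
  }

  margin <- 500L
  site_rows <- list()
  if (n_hosted > 0 && !hosted_as_free) {
    hosts <- sample(regular, n_hosted)
    g <- genes[hosts, ]
    anchor <- as.integer(floor(stats::runif(n_hosted, g$start + margin,
                                            g$end - margin)))
    site_rows$hosted <- data.frame(
      chrom = g$chrom, anchor = anchor,
      cut_status = rep(c("cut", "uncut"),
                       c(cfg$n_cut_sites, cfg$n_uncut_sites)),
      gene_free = FALSE, host_gene = g$gene_id, host_strand = g$strand,
      stringsAsFactors = FALSE)
  }
  n_free <- cfg$n_gene_free_sites + if (hosted_as_free) n_hosted else 0L
  free_cut <- if (hosted_as_free)
    rep(c("cut", "uncut", "uncut"),
        c(cfg$n_cut_sites, cfg$n_uncut_sites, cfg$n_gene_free_sites))
  else rep("uncut", n_free)
  if (n_free > 0) {
    ci <- rep_len(seq_len(cfg$n_chromosomes), n_free)
    lo <- L - reserve + cfg$flank
    hi <- L - cfg$flank
    site_rows$free <- data.frame(
      chrom = chroms[ci],
      anchor = as.integer(floor(stats::runif(n_free, lo, hi))),
      cut_status = free_cut, gene_free = TRUE,
      host_gene = NA_character_, host_strand = NA_character_,
      stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, site_rows)
  if (is.null(st)) stop("configuration defines no sites")
  st <- st[order(st$chrom, st$anchor), , drop = FALSE]
  st$site_id <- sprintf("site_%03d", seq_len(nrow(st)))
  st$efficiency <- ifelse(st$cut_status == "cut",
                          stats::runif(nrow(st), cfg$efficiency_range[1],
                                       cfg$efficiency_range[2]), 0)

  # plant repair-pathway ratios on cut sites; weak flat background elsewhere
  st$planted_pathway <- "unlabelled"
  st$rad51_mu <- 10
  st$xrcc4_mu <- 10
  cut_idx <- which(st$cut_status == "cut")
  if (length(cut_idx)) {
    k <- min(cfg$n_pathway, floor(length(cut_idx) / 2))
    perm <- sample(cut_idx)
    cls <- rep("mid", length(cut_idx))
    cls[seq_len(k)] <- "HR_prone"
    if (k > 0) cls[seq.int(length(cut_idx) - k + 1L, length(cut_idx))] <-
      "NHEJ_prone"
    rng <- list(HR_prone = cfg$hr_ratio, mid = cfg$mid_ratio,
                NHEJ_prone = cfg$nhej_ratio)
    ratio <- vapply(cls, function(cl)
      stats::runif(1, rng[[cl]][1], rng[[cl]][2]), numeric(1))
    st$planted_pathway[perm] <- ifelse(cls == "mid", "unlabelled", cls)
    st$rad51_mu[perm] <- cfg$chip_depth * sqrt(ratio)
    st$xrcc4_mu[perm] <- cfg$chip_depth / sqrt(ratio)
  }

  sites <- genomic_intervals(st$chrom, st$anchor - 4L, st$anchor + 4L,
                             name = st$site_id, score = "0", strand = ".")
  list(genes = genes, sites = sites, sizes = sizes,
       truth = st[, c("site_id", "chrom", "anchor", "cut_status",
                      "gene_free", "host_gene", "host_strand", "efficiency",
                      "planted_pathway", "rad51_mu", "xrcc4_mu")],
       config = cfg, seed = seed)
}

# exponential induction weights over signed offsets -flank..flank
induction_weights <- function(cfg) {
  d <- seq.int(-cfg$flank, cfg$flank)
  list(d = d, w = exp(-abs(d) / cfg$decay_length))
}

#' Simulate one stranded chrRNA-seq library
#'
#' Background sense reads per gene have expectation `lambda_sense *
#' length/1000` and fall uniformly within the gene on its strand; a weaker
#' antisense background mirrors them. In damage conditions every cut site
#' adds reads on both strands with per-position expectation
#' `e_s * A * exp(-|d|/L)`; the knockdown condition multiplies induction
#' on the host gene's strand by `kappa_sense` and on the opposite strand
#' by `kappa_antisense`.
#'
#' @param annotation Output of [generate_annotation()].
#' @param condition `"no_damage"`, `"damage_control"` or
#'   `"damage_knockdown"`.
#' @param replicate Replicate index (>= 1).
#' @param seed Integer seed; combined deterministically with condition and
#'   replicate so libraries are independent but reproducible.
#' @param config Simulation config (defaults to the annotation's).
#' @return List: `reads` (a `stranded_reads`), `truth` (per-site expected
#'   induced intensity per strand class), `condition`, `replicate`.
#' @export
simulate_chrRNA <- function(annotation, condition, replicate = 1L,
                            seed = annotation$seed,
                            config = annotation$config) {
  if (!condition %in% CONDITIONS)
    stop("unknown condition '", condition, "'; expected one of: ",
         paste(CONDITIONS, collapse = ", "))
  cfg <- config
  cond_idx <- match(condition, CONDITIONS)
  set.seed(mix_seed(seed, 10000L * cond_idx + replicate))
  rl <- as.integer(cfg$read_length)
  L <- as.integer(cfg$chromosome_length)
  genes <- annotation$genes
  tr <- annotation$truth

  acc <- list()
  emit <- function(chrom, start, strand) {
    acc[[length(acc) + 1L]] <<- list(chrom = chrom,
                                     start = as.integer(start),
                                     strand = strand)
  }

  if (nrow(genes)) {
    for (sense in c(TRUE, FALSE)) {
      lam <- if (sense) genes$lambda_sense else genes$lambda_antisense
      n_g <- rdisp(nrow(genes), lam * (genes$end - genes$start) / 1000, cfg)
      tot <- sum(n_g)
      if (tot > 0) {
        gidx <- rep.int(seq_len(nrow(genes)), n_g)
        span <- pmax(genes$end[gidx] - genes$start[gidx] - rl, 1L)
        start <- genes$start[gidx] +
          as.integer(floor(stats::runif(tot) * span))
        strand <- genes$strand[gidx]
        if (!sense) strand <- ifelse(strand == "+", "-", "+")
        emit(genes$chrom[gidx], start, strand)
      }
    }
  }
  if (cfg$noise_rate > 0) {
    for (chrom in names(annotation$sizes)) {
      for (s in c("+", "-")) {
        n <- rdisp(1, cfg$noise_rate * L / 1000, cfg)
        if (n > 0)
          emit(rep(chrom, n),
               as.integer(floor(stats::runif(n) * (L - rl))), rep(s, n))
      }
    }
  }

  iw <- induction_weights(cfg)
  w_total <- sum(iw$w)
  truth <- data.frame(site_id = tr$site_id, condition = condition,
                      mu_host_strand = 0, mu_opposite_strand = 0,
                      stringsAsFactors = FALSE)
  if (condition != "no_damage" && cfg$dart_amplitude > 0) {
    for (i in which(tr$efficiency > 0)) {
      host <- tr$host_strand[i]
      if (is.na(host)) host <- "+"        # gene-free cut site: arbitrary
      for (s in c("+", "-")) {
        mult <- if (condition == "damage_knockdown") {
          if (s == host) cfg$kappa_sense else cfg$kappa_antisense
        } else 1
        mu <- tr$efficiency[i] * cfg$dart_amplitude * mult * w_total
        if (s == host) truth$mu_host_strand[i] <- mu
        else truth$mu_opposite_strand[i] <- mu
        n <- rdisp(1, mu, cfg)
        if (n > 0) {
          d <- sample(iw$d, n, replace = TRUE, prob = iw$w)
          start <- pmin(pmax(tr$anchor[i] + d - rl %/% 2L, 0L), L - rl)
          emit(rep(tr$chrom[i], n), as.integer(start), rep(s, n))
        }
      }
    }
  }

  chrom_v <- unlist(lapply(acc, `[[`, "chrom"), use.names = FALSE)
  start_v <- unlist(lapply(acc, `[[`, "start"), use.names = FALSE)
  strand_v <- unlist(lapply(acc, `[[`, "strand"), use.names = FALSE)
  if (is.null(chrom_v)) chrom_v <- character()
  if (is.null(start_v)) start_v <- integer()
  if (is.null(strand_v)) strand_v <- character()
  reads <- data.frame(chrom = chrom_v, start = start_v,
                      end = start_v + rl, strand = strand_v,
                      stringsAsFactors = FALSE)
  list(reads = stranded_reads(reads), truth = truth,
       condition = condition, replicate = replicate)
}

#' Simulate a DSB-capture or repair-factor ChIP track
#'
#' Reads cluster around site anchors. DSB-capture (`"bless"`) intensity is
#' proportional to the planted cleavage efficiency; `"rad51"` and
#' `"xrcc4"` intensities implement the planted pathway ratios, spread over
#' the windows their classifier integrates (+/- 4 kb and +/- 1 kb).
#' With `dispersion = "none"` counts are deterministic (rounded
#' expectations, evenly spaced reads) for noise-free order recovery.
#'
#' @param annotation Output of [generate_annotation()].
#' @param kind `"bless"`, `"rad51"` or `"xrcc4"`.
#' @param seed Integer seed.
#' @param config Simulation config (defaults to the annotation's).
#' @return A `stranded_reads` object.
#' @export
simulate_track <- function(annotation, kind = c("bless", "rad51", "xrcc4"),
                           seed = annotation$seed,
                           config = annotation$config) {
  kind <- match.arg(kind)
  cfg <- config
  tr <- annotation$truth
  set.seed(mix_seed(seed, 777L + match(kind, c("bless", "rad51", "xrcc4"))))
  mu <- switch(kind,
               bless = cfg$bless_depth * tr$efficiency,
               rad51 = tr$rad51_mu,
               xrcc4 = tr$xrcc4_mu)
  w <- switch(kind, bless = cfg$bless_window, rad51 = 4000L, xrcc4 = 1000L)
  rl <- as.integer(cfg$read_length)
  L <- as.integer(cfg$chromosome_length)
  n <- rdisp(length(mu), mu, cfg)
  rows <- lapply(which(n > 0), function(i) {
    d <- if (cfg$dispersion == "none") {
      as.integer(round(seq(-w, w, length.out = n[i])))
    } else as.integer(floor(stats::runif(n[i], -w, w)))
    start <- pmin(pmax(tr$anchor[i] + d - rl %/% 2L, 0L), L - rl)
    data.frame(chrom = tr$chrom[i], start = start, end = start + rl,
               strand = "+", stringsAsFactors = FALSE)
  })
  reads <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  # zero-intensity track: an empty read set (library_size 1 keeps CPM valid)
  stranded_reads(reads, library_size = max(1, nrow(reads)))
}

#' Write annotation and truth files to a directory
#'
#' Emits `genes.bed`, `sites.bed`, `chrom.sizes` and `truth.json`.
#'
#' @param annotation Output of [generate_annotation()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_annotation <- function(annotation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_annotation(annotation$genes, file.path(dir, "genes.bed"))
  write_intervals(annotation$sites, file.path(dir, "sites.bed"))
  write_chrom_sizes(annotation$sizes, file.path(dir, "chrom.sizes"))
  jsonlite::write_json(
    list(seed = annotation$seed, sites = annotation$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
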