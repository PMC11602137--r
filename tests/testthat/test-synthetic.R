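# Small configurations keep the generator tests fast; the full-scale
# reference configuration is exercised by the acceptance suite.
small_cfg <- function(...) {
  args <- list(n_chromosomes = 2L, chromosome_length = 3e5,
               n_genes = 40L, n_highexpr_genes = 4L, lambda_high = 500,
               n_cut_sites = 8L, n_uncut_sites = 8L,
               n_gene_free_sites = 2L, replicates = 2L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

test_that("annotation generation is reproducible and seed-sensitive", {
  cfg <- small_cfg()
  a1 <- generate_annotation(cfg, seed = 5)
  a2 <- generate_annotation(cfg, seed = 5)
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$sites, a2$sites)
  expect_identical(a1$truth, a2$truth)
  a3 <- generate_annotation(cfg, seed = 6)
  expect_false(identical(a1$sites, a3$sites))
  # simulated libraries are byte-identical under the same seed
  s1 <- simulate_chrRNA(a1, "damage_control", 1, seed = 5)
  s2 <- simulate_chrRNA(a1, "damage_control", 1, seed = 5)
  expect_identical(s1$reads$reads, s2$reads$reads)
  s3 <- simulate_chrRNA(a1, "damage_control", 2, seed = 5)
  expect_false(identical(s1$reads$reads, s3$reads$reads))
})

test_that("annotation respects the declared structure", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg, seed = 9)
  g <- ann$genes
  expect_equal(nrow(g), 44)
  # genes never overlap (shared coordinate space)
  for (chrom in unique(g$chrom)) {
    gc <- g[g$chrom == chrom, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1)
      expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  tr <- ann$truth
  expect_equal(sum(tr$cut_status == "cut"), 8)
  expect_equal(sum(tr$gene_free), 2)
  expect_true(all(tr$efficiency[tr$cut_status == "cut"] > 0))
  expect_true(all(tr$efficiency[tr$cut_status == "uncut"] == 0))
  # hosted sites sit inside their host gene, away from its ends
  hosted <- tr[!tr$gene_free, ]
  gi <- match(hosted$host_gene, g$gene_id)
  expect_true(all(hosted$anchor >= g$start[gi] + 500 &
                  hosted$anchor <= g$end[gi] - 500))
  # gene-free sites really have no gene within the flank
  free <- tr[tr$gene_free, ]
  for (i in seq_len(nrow(free))) {
    near <- g$chrom == free$chrom[i] &
      g$start < free$anchor[i] + cfg$flank &
      g$end > free$anchor[i] - cfg$flank
    expect_false(any(near))
  }
})

test_that("planted gene-free sites are exactly the orientation exclusions", {
  cfg <- small_cfg(n_gene_free_sites = 1L)
  ann <- generate_annotation(cfg, seed = 13)
  sim <- simulate_chrRNA(ann, "damage_control", 1, seed = 13)
  cov <- cpm_coverage(sim$reads, ann$sizes)
  mp <- compute_flank_matrix(cov, ann$sites, cfg$flank, 1L, "plus")
  mm <- compute_flank_matrix(cov, ann$sites, cfg$flank, 1L, "minus")
  res <- orient_matrices(mp, mm, ann$sites, ann$genes)
  expect_identical(res$excluded_sites,
                   ann$truth$site_id[ann$truth$gene_free])
})

test_that("a gene-less genome leaves every site unorientable", {
  cfg <- small_cfg(n_genes = 0L, n_highexpr_genes = 0L,
                   n_gene_free_sites = 0L, noise_rate = 5)
  ann <- generate_annotation(cfg, seed = 17)
  expect_equal(nrow(ann$genes), 0)
  sim <- simulate_chrRNA(ann, "damage_control", 1, seed = 17)
  cov <- cpm_coverage(sim$reads, ann$sizes)
  mp <- compute_flank_matrix(cov, ann$sites, cfg$flank, 1L, "plus")
  mm <- compute_flank_matrix(cov, ann$sites, cfg$flank, 1L, "minus")
  res <- orient_matrices(mp, mm, ann$sites, ann$genes)
  expect_setequal(res$excluded_sites, ann$sites$name)
})

test_that("null constructions remove the damage signal", {
  # zero amplitude: damage conditions plant nothing
  cfg <- small_cfg(dart_amplitude = 0, dispersion = "none")
  ann <- generate_annotation(cfg, seed = 19)
  nd <- simulate_chrRNA(ann, "no_damage", 1, seed = 19)
  dc <- simulate_chrRNA(ann, "damage_control", 1, seed = 19)
  expect_equal(nrow(nd$reads$reads), nrow(dc$reads$reads))
  expect_true(all(dc$truth$mu_host_strand == 0))
  # unit multipliers: knockdown and control share expectations
  cfg2 <- small_cfg(kappa_sense = 1, kappa_antisense = 1)
  ann2 <- generate_annotation(cfg2, seed = 19)
  dc2 <- simulate_chrRNA(ann2, "damage_control", 1, seed = 19)
  kd2 <- simulate_chrRNA(ann2, "damage_knockdown", 1, seed = 19)
  expect_equal(dc2$truth$mu_host_strand, kd2$truth$mu_host_strand)
  expect_equal(dc2$truth$mu_opposite_strand, kd2$truth$mu_opposite_strand)
  expect_error(simulate_chrRNA(ann, "damage"), "unknown condition")
})

test_that("induced coverage at the anchor matches its closed form", {
  # isolate the induced component: no background transcription or noise
  cfg <- sim_config(n_chromosomes = 1L, chromosome_length = 1e5,
                    n_genes = 4L, n_highexpr_genes = 0L,
                    n_cut_sites = 4L, n_uncut_sites = 0L,
                    n_gene_free_sites = 0L,
                    efficiency_range = c(1, 1), lambda_gene = 0,
                    lambda_antisense = 0, noise_rate = 0,
                    dart_amplitude = 2, decay_length = 500)
  ann <- generate_annotation(cfg, seed = 23)
  rl <- cfg$read_length
  d <- -(rl %/% 2):(rl - rl %/% 2 - 1)
  expected <- cfg$dart_amplitude * sum(exp(-abs(d) / cfg$decay_length))
  n_rep <- 10
  got <- matrix(0, n_rep, nrow(ann$truth))
  for (r in seq_len(n_rep)) {
    sim <- simulate_chrRNA(ann, "damage_control", r, seed = 23)
    reads <- sim$reads$reads
    got[r, ] <- vapply(seq_len(nrow(ann$truth)), function(i) {
      a <- ann$truth$anchor[i]
      sum(reads$chrom == ann$truth$chrom[i] & reads$strand == "+" &
          reads$start <= a & reads$end > a)
    }, numeric(1))
  }
  mu_hat <- colMeans(got)
  se <- apply(got, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(mu_hat - expected) <= 3 * pmax(se, 1e-9)))
})

test_that("capture-track order recovery and degenerate tracks behave", {
  cfg <- small_cfg(dispersion = "none", bless_depth = 400)
  ann <- generate_annotation(cfg, seed = 29)
  # noise-free: recovered efficiency order is exactly the planted order
  bless <- simulate_track(ann, "bless", seed = 29)
  eff <- rank_cleavage_efficiency(bless, ann$sites, cfg$bless_window)
  planted <- rank(ann$truth$efficiency, ties.method = "first")
  cut_sel <- ann$truth$cut_status == "cut"
  expect_equal(order(eff$cleavage_reads[cut_sel]),
               order(ann$truth$efficiency[cut_sel]))
  # uncut sites emit nothing
  expect_true(all(eff$cleavage_reads[!cut_sel] == 0))
  # equal planted factors give equal ratios everywhere
  cfg2 <- small_cfg(dispersion = "none", hr_ratio = c(1, 1),
                    mid_ratio = c(1, 1), nhej_ratio = c(1, 1))
  ann2 <- generate_annotation(cfg2, seed = 29)
  rad <- cpm_coverage(simulate_track(ann2, "rad51", seed = 29), ann2$sizes)
  xrc <- cpm_coverage(simulate_track(ann2, "xrcc4", seed = 29), ann2$sizes)
  cut_sites <- ann2$sites[ann2$sites$name %in%
                          ann2$truth$site_id[cut_sel], ]
  lab <- classify_repair_pathway(rad, xrc, cut_sites, k = 1L)
  expect_lt(diff(range(lab$pathway_ratio)) / mean(lab$pathway_ratio), 0.02)
  # zero-intensity track: no reads, all counts 0
  cfg3 <- small_cfg(bless_depth = 0, n_cut_sites = 0L, n_uncut_sites = 4L)
  ann3 <- generate_annotation(cfg3, seed = 29)
  empty <- simulate_track(ann3, "bless", seed = 29)
  expect_equal(nrow(empty$reads), 0)
  eff3 <- rank_cleavage_efficiency(empty, ann3$sites)
  expect_true(all(eff3$cleavage_reads == 0))
})
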