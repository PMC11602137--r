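test_that("gene/flank overlap records match direct interval logic", {
  sites <- genomic_intervals("chrA", c(1000, 5000), c(1001, 5001),
                             name = c("s1", "s2"))
  genes <- data.frame(gene_id = c("far", "spanning", "partial"),
                      chrom = "chrA",
                      start = c(8000L, 900L, 4950L),
                      end = c(9000L, 1200L, 5050L),
                      strand = c("+", "+", "-"),
                      stringsAsFactors = FALSE)
  ov <- find_gene_flank_overlaps(sites, genes, flank = 100L, bin_size = 1L)
  expect_false("far" %in% ov$gene_id)
  span <- ov[ov$gene_id == "spanning", ]
  expect_equal(span$site_id, "s1")
  expect_equal(c(span$first_bin, span$last_bin), c(0L, 200L))
  part <- ov[ov$gene_id == "partial", ]
  expect_equal(c(part$first_bin, part$last_bin), c(50L, 150L))
})

test_that("overlap records equal an all-pairs quadratic oracle", {
  set.seed(23)
  for (rep in 1:5) {
    inst <- random_orientation_instance(max_sites = 5, max_genes = 20)
    ov <- find_gene_flank_overlaps(inst$sites, inst$genes, inst$flank, 1L)
    want <- 0L
    for (i in seq_len(nrow(inst$sites))) {
      for (g in seq_len(nrow(inst$genes))) {
        w_start <- inst$anchors[i] - inst$flank
        w_end <- inst$anchors[i] + inst$flank
        if (inst$genes$start[g] < w_end && inst$genes$end[g] > w_start) {
          want <- want + 1L
          rec <- ov[ov$site_id == inst$sites$name[i] &
                    ov$gene_id == inst$genes$gene_id[g], ]
          expect_equal(nrow(rec), 1)
          expect_equal(rec$first_bin,
                       max(inst$genes$start[g], w_start) - w_start)
          expect_equal(rec$last_bin,
                       min(inst$genes$end[g], w_end) - w_start)
        }
      }
    }
    expect_equal(nrow(ov), want)
  }
})

test_that("a single spanning gene reproduces the raw stranded rows", {
  inst <- random_orientation_instance(max_sites = 3, max_genes = 1)
  genes <- data.frame(gene_id = "g", chrom = "chrA", start = 0L,
                      end = 10000L, strand = "+",
                      stringsAsFactors = FALSE)
  res <- orient_matrices(inst$plus, inst$minus, inst$sites, genes)
  expect_equal(res$sense$values, inst$plus$values)
  expect_equal(res$antisense$values, inst$minus$values)
  expect_length(res$excluded_sites, 0)
  # flipping the gene swaps the roles
  genes$strand <- "-"
  res2 <- orient_matrices(inst$plus, inst$minus, inst$sites, genes)
  expect_equal(res2$sense$values, inst$minus$values)
  expect_equal(res2$antisense$values, inst$plus$values)
})

test_that("sites without any gene in the flank are excluded, and only those", {
  sites <- genomic_intervals("chrA", c(1000, 3000), c(1001, 3001),
                             name = c("with_gene", "lonely"))
  genes <- data.frame(gene_id = "g1", chrom = "chrA", start = 950L,
                      end = 1100L, strand = "+", stringsAsFactors = FALSE)
  mk <- function(o) flank_matrix(matrix(1, 2, 200), sites$name,
                                 data.frame(chrom = sites$chrom,
                                            anchor = site_anchors(sites)),
                                 100L, 1L, o)
  res <- orient_matrices(mk("plus"), mk("minus"), sites, genes)
  expect_equal(res$excluded_sites, "lonely")
  expect_equal(res$sense$site_ids, "with_gene")
})

test_that("sense/antisense matrices equal the triple-loop oracle", {
  set.seed(41)
  for (rep in 1:20) {
    inst <- random_orientation_instance(max_sites = 6, max_genes = 10,
                                        max_flank = 80)
    res <- orient_matrices(inst$plus, inst$minus, inst$sites, inst$genes)
    want <- orientation_oracle(inst$plus$values, inst$minus$values,
                               inst$sites, inst$genes, inst$flank,
                               inst$anchors)
    expect_equal(res$sense$values, want$sense[want$covered, , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(res$antisense$values,
                 want$anti[want$covered, , drop = FALSE],
                 ignore_attr = TRUE)
    expect_setequal(res$excluded_sites, inst$sites$name[!want$covered])
  }
})

test_that("flipping every gene strand swaps sense and antisense", {
  set.seed(43)
  for (rep in 1:10) {
    inst <- random_orientation_instance()
    res <- orient_matrices(inst$plus, inst$minus, inst$sites, inst$genes)
    flipped <- inst$genes
    flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
    res2 <- orient_matrices(inst$plus, inst$minus, inst$sites, flipped)
    expect_equal(res$sense$values, res2$antisense$values)
    expect_equal(res$antisense$values, res2$sense$values)
    expect_identical(res$excluded_sites, res2$excluded_sites)
  }
})

test_that("orientation is conserved and monotone under gene addition", {
  set.seed(47)
  inst <- random_orientation_instance(max_sites = 5, max_genes = 6)
  # disjoint genes -> single cover: sense + antisense == plus + minus on
  # gene-covered bins, 0 elsewhere
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chrA",
                      start = c(0L, 6000L), end = c(5000L, 10000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  res <- orient_matrices(inst$plus, inst$minus, inst$sites, genes)
  keep <- match(res$sense$site_ids, inst$sites$name)
  total <- inst$plus$values[keep, , drop = FALSE] +
    inst$minus$values[keep, , drop = FALSE]
  combined <- res$sense$values + res$antisense$values
  ov <- find_gene_flank_overlaps(inst$sites, genes, inst$flank, 1L)
  for (r in seq_along(res$sense$site_ids)) {
    id <- res$sense$site_ids[r]
    cov_bins <- logical(ncol(total))
    sel <- ov[ov$site_id == id, ]
    for (j in seq_len(nrow(sel)))
      cov_bins[(sel$first_bin[j] + 1):sel$last_bin[j]] <- TRUE
    expect_equal(combined[r, cov_bins], total[r, cov_bins])
    expect_true(all(combined[r, !cov_bins] == 0))
  }
  # adding one more gene never decreases any bin value
  extra <- rbind(inst$genes,
                 data.frame(gene_id = "extra", chrom = "chrA", start = 0L,
                            end = 10000L, strand = "+",
                            stringsAsFactors = FALSE))
  base <- orient_matrices(inst$plus, inst$minus, inst$sites, inst$genes)
  more <- orient_matrices(inst$plus, inst$minus, inst$sites, extra)
  common <- intersect(base$sense$site_ids, more$sense$site_ids)
  bi <- match(common, base$sense$site_ids)
  mi <- match(common, more$sense$site_ids)
  expect_true(all(more$sense$values[mi, ] >= base$sense$values[bi, ] - 1e-12))
  expect_true(all(more$antisense$values[mi, ] >=
                  base$antisense$values[bi, ] - 1e-12))
})

test_that("the result is independent of gene input order", {
  set.seed(53)
  inst <- random_orientation_instance()
  res <- orient_matrices(inst$plus, inst$minus, inst$sites, inst$genes)
  shuf <- inst$genes[sample.int(nrow(inst$genes)), ]
  res2 <- orient_matrices(inst$plus, inst$minus, inst$sites, shuf)
  expect_equal(res$sense$values, res2$sense$values)
  expect_equal(res$antisense$values, res2$antisense$values)
})
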