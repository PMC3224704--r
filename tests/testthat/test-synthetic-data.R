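small_cfg <- function(...) {
  synthetic_config(n_genes = 120, n_regulators = 8,
                   n_samples = c(20, 20, 15), ...)
}

test_that("generators are byte-identical under equal seeds", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg, 3)
  g2 <- generate_genome(cfg, 3)
  expect_identical(g1, g2)
  a1 <- generate_annotations(g1$genes, g1$truth, cfg, 4)
  a2 <- generate_annotations(g2$genes, g2$truth, cfg, 4)
  expect_identical(a1, a2)
  e1 <- generate_expression(a1$genes, g1$truth, cfg, 5)
  e2 <- generate_expression(a2$genes, g2$truth, cfg, 5)
  expect_identical(e1, e2)
  p1 <- generate_promoters(a1$genes, g1$truth, e1$edges, cfg, 6)
  p2 <- generate_promoters(a2$genes, g2$truth, e2$edges, cfg, 6)
  expect_identical(p1, p2)
})

test_that("degenerate operon length gives an all-monocistronic truth", {
  cfg <- small_cfg(operon_mean_length = 1)
  g <- generate_genome(cfg, 7)
  expect_true(all(lengths(g$truth$units) == 1L))
})

test_that("within-operon gaps are shorter than boundary gaps", {
  cfg <- synthetic_config(n_genes = 1000, n_regulators = 10)
  g <- generate_genome(cfg, 8)
  pairs <- same_strand_adjacent_pairs(g$genes)
  same <- g$truth$gene2unit[pairs$upstream] ==
    g$truth$gene2unit[pairs$downstream]
  d <- vapply(seq_len(nrow(pairs)), function(i)
    intergenic_distance(g$genes[pairs$upstream[i], ],
                        g$genes[pairs$downstream[i], ]), integer(1))
  expect_lt(mean(d[same]), mean(d[!same]))
})

test_that("annotation sharing follows the configured probability", {
  g <- generate_genome(small_cfg(), 9)
  full <- generate_annotations(g$genes, g$truth,
                               small_cfg(p_share = 1, class_unassigned_rate = 0,
                                         go_unassigned_rate = 0,
                                         class_share_between = 0), 10)
  pairs <- same_strand_adjacent_pairs(full$genes)
  same <- g$truth$gene2unit[pairs$upstream] ==
    g$truth$gene2unit[pairs$downstream]
  cs <- mapply(protein_class_score,
               full$genes[pairs$upstream, "protein_class"],
               full$genes[pairs$downstream, "protein_class"])
  expect_true(all(cs[same] == 1))
  none <- generate_annotations(g$genes, g$truth,
                               small_cfg(p_share = 0, class_unassigned_rate = 0,
                                         go_unassigned_rate = 0,
                                         class_share_between = 0), 10)
  cs0 <- mapply(protein_class_score,
                none$genes[pairs$upstream, "protein_class"],
                none$genes[pairs$downstream, "protein_class"])
  expect_lt(mean(cs0[same] == 1), 0.25)   # only chance-level collisions
})

test_that("true-operon pairs carry more gene-order conservation", {
  cfg <- synthetic_config(n_genes = 1000, n_regulators = 10)
  g <- generate_genome(cfg, 11)
  ann <- generate_annotations(g$genes, g$truth, cfg, 12)
  pairs <- same_strand_adjacent_pairs(ann$genes)
  same <- g$truth$gene2unit[pairs$upstream] ==
    g$truth$gene2unit[pairs$downstream]
  tab <- setNames(ann$conservation$genome_count,
                  paste(ann$conservation$gene_a, ann$conservation$gene_b))
  cons <- tab[paste(pairs$upstream, pairs$downstream)]
  cons[is.na(cons)] <- 0
  expect_gt(mean(cons[same]), mean(cons[!same]))
})

test_that("expression emulates co-transcription and regulator links", {
  cfg0 <- small_cfg(noise_sd = 0, absent_rate = 0)
  g <- generate_genome(cfg0, 13)
  ann <- generate_annotations(g$genes, g$truth, cfg0, 14)
  ex <- generate_expression(ann$genes, g$truth, cfg0, 15)
  expect_true(all(!vapply(ex$datasets, function(d) any(d$absent_mask),
                          logical(1))))
  # without gene noise, genes of the same unit have identical profiles
  all_vals <- do.call(cbind, lapply(ex$datasets[1:2], function(d) d$values))
  pairs <- same_strand_adjacent_pairs(ann$genes)
  same <- g$truth$gene2unit[pairs$upstream] ==
    g$truth$gene2unit[pairs$downstream]
  within <- which(same)[1:10]
  for (i in within)
    expect_equal(cor(all_vals[pairs$upstream[i], ],
                     all_vals[pairs$downstream[i], ]), 1)
  # linear hub-target links correlate strongly at the latent level
  cfg1 <- synthetic_config(n_genes = 400, n_regulators = 25,
                           n_samples = c(70, 70, 60), dep_noise_sd = 0.3)
  g1 <- generate_genome(cfg1, 16)
  a1 <- generate_annotations(g1$genes, g1$truth, cfg1, 17)
  e1 <- generate_expression(a1$genes, g1$truth, cfg1, 18)
  lin <- e1$edges[e1$edges$link == "linear", ]
  r <- vapply(seq_len(nrow(lin)), function(i)
    cor(e1$latent[lin$hub[i], ], e1$latent[lin$target[i], ]), numeric(1))
  expect_true(mean(abs(r) >= 0.8) > 0.9)
})

test_that("promoter planting is recorded and recoverable", {
  cfg <- small_cfg(motif_identity = 1)
  g <- generate_genome(cfg, 19)
  ann <- generate_annotations(g$genes, g$truth, cfg, 20)
  ex <- generate_expression(ann$genes, g$truth, cfg, 21)
  prom <- generate_promoters(ann$genes, g$truth, ex$edges, cfg, 22)
  expect_equal(nrow(prom$placements),
               length(unique(ex$edges$hub)) + nrow(ex$edges))
  ups <- upstream_sequences(prom$genome, ann$genes, g$truth,
                            unique(prom$placements$unit), cfg$upstream_length)
  # with identity 1 every placement reads back as the module consensus
  # (modulo rare overwrites when a unit sits in two modules)
  hits <- vapply(seq_len(nrow(prom$placements)), function(i) {
    pl <- prom$placements[i, ]
    substr(ups[[pl$unit]], pl$offset + 1, pl$offset + cfg$motif_width) ==
      prom$consensus[[pl$hub]]
  }, logical(1))
  expect_gt(mean(hits), 0.95)
  expect_error(generate_promoters(ann$genes, g$truth, ex$edges,
                                  small_cfg(upstream_length = 4), 23),
               "wider")
})

test_that("intergenic sequence matches the configured base composition", {
  cfg <- synthetic_config(n_genes = 150, n_regulators = 2)
  g <- generate_genome(cfg, 24)
  ann <- generate_annotations(g$genes, g$truth, cfg, 25)
  ex <- generate_expression(ann$genes, g$truth, cfg, 26)
  prom <- generate_promoters(ann$genes, g$truth, ex$edges, cfg, 27)
  chars <- strsplit(prom$genome[["chr"]], "")[[1]]
  freq <- table(factor(chars, levels = c("A", "C", "G", "T"))) / length(chars)
  expect_true(all(abs(as.numeric(freq) - cfg$background) < 0.03))
})

test_that("training pairs sampled from truth carry correct labels", {
  cfg <- small_cfg()
  g <- generate_genome(cfg, 28)
  tr <- sample_training_pairs(g$genes, g$truth, n_kop = 20, n_nop = 10,
                              seed = 29)
  same <- g$truth$gene2unit[tr$gene_a] == g$truth$gene2unit[tr$gene_b]
  expect_true(all(same[tr$label == "KOP"]))
  expect_true(all(!same[tr$label == "NOP"]))
})
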