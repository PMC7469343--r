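test_that("reference generation respects construction constraints", {
  cfg <- small_config(seed = 1)
  ref <- generate_reference(cfg)
  expect_length(ref$sequences, cfg$n_genes)
  expect_true(all(substr(ref$sequences, 1, 3) == "ATG"))
  lens <- nchar(ref$sequences)
  expect_true(all(lens %% 3 == 0))
  expect_true(all(lens >= 300 & lens <= 600))
  expect_equal(sum(ref$annotation$compartment == "mito"), 8)

  # degenerate length range
  cfg2 <- small_config(gene_length_range = c(300L, 300L), seed = 2)
  expect_true(all(nchar(generate_reference(cfg2)$sequences) == 300))

  expect_error(sim_config(gene_length_range = c(100, 50)), "multiples of 3")
  expect_error(sim_config(structure_avoidance = 1.5), "probabilities")
})

test_that("generation is byte-identical under an identical config", {
  cfg <- small_config(seed = 9)
  r1 <- generate_reference(cfg); r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  a1 <- tempfile(); a2 <- tempfile()
  write_reference(r1, f1, a1); write_reference(r2, f2, a2)
  expect_identical(readLines(f1), readLines(f2))

  t1 <- generate_truth(r1, cfg); t2 <- generate_truth(r2, cfg)
  expect_identical(t1$levels, t2$levels)
  e1 <- generate_expression(t1, cfg); e2 <- generate_expression(t2, cfg)
  expect_identical(e1$counts, e2$counts)
  p1 <- generate_pileups(r1, t1, cfg); p2 <- generate_pileups(r2, t2, cfg)
  expect_identical(p1, p2)

  # round-trip through FASTA preserves the reference
  rr <- read_reference(f1, a1)
  expect_identical(rr$sequences, r1$sequences)
})

test_that("truth levels follow the stated generative model", {
  # no regulators, no noise: per-sample level equals the base level
  cfg <- small_config(regulator_effect = 0, noise_sd = 0,
                      idle_noise_sd = 0, seed = 4)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  expect_true(all(abs(tr$levels - tr$sites$base_level) < 1e-12))
  expect_true(all(tr$levels >= 0 & tr$levels <= 1))

  # every site sits on a reference C, and the recorded 5' base matches
  for (i in seq_len(nrow(tr$sites))) {
    s <- ref$sequences[[tr$sites$gene_id[i]]]
    expect_identical(substr(s, tr$sites$pos[i], tr$sites$pos[i]), "C")
    expect_identical(substr(s, tr$sites$pos[i] - 1, tr$sites$pos[i] - 1),
                     tr$sites$five_prime[i])
  }

  # full structure avoidance: no site inside a structured region
  cfg2 <- small_config(structure_avoidance = 1, seed = 5)
  ref2 <- generate_reference(cfg2)
  tr2 <- generate_truth(ref2, cfg2)
  expect_true(all(!tr2$sites$structured))

  # 5'-T sites have higher mean levels than 5'-G sites
  cfg3 <- sim_config(n_genes = 120, n_mito_genes = 25, n_chloro_genes = 10,
                     n_sites = 200, n_pos_regulators = 5,
                     n_neg_regulators = 5, seed = 7)
  ref3 <- generate_reference(cfg3)
  tr3 <- generate_truth(ref3, cfg3)
  mlev <- rowMeans(tr3$levels)
  expect_gt(mean(mlev[tr3$sites$five_prime == "T"]),
            mean(mlev[tr3$sites$five_prime == "G"]))

  # impossible site count errors out
  cfg4 <- small_config(seed = 1)
  cfg4$n_sites <- 1e6
  expect_error(generate_truth(generate_reference(cfg4), cfg4), "eligible")
})

test_that("pileups conserve counts and reproduce levels binomially", {
  cfg <- small_config(seed = 11)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  pu <- generate_pileups(ref, tr, cfg)
  depth <- pu$A + pu$C + pu$G + pu$T
  expect_true(all(depth >= cfg$depth_range[1] & depth <= cfg$depth_range[2]))

  # error_rate = 0: non-site positions carry only the reference base
  cfg0 <- small_config(error_rate = 0, seed = 11)
  pu0 <- generate_pileups(ref, tr, cfg0)
  site_key <- paste0(tr$sites$gene_id, ":", tr$sites$pos)
  nonsite <- !(paste0(pu0$gene_id, ":", pu0$pos) %in% site_key)
  cnt <- as.matrix(pu0[, c("A", "C", "G", "T")])
  ref_count <- cnt[cbind(seq_len(nrow(cnt)), match(pu0$ref, colnames(cnt)))]
  expect_true(all(ref_count[nonsite] == rowSums(cnt)[nonsite]))

  # binomial law of large numbers at a fixed level
  set.seed(42)
  draws <- rbinom(1000, 103, 0.6) / 103
  expect_lt(abs(mean(draws) - 0.6), 0.05)
  expect_equal(rbinom(1, 103, 1), 103)  # level 1 -> fully edited
})

test_that("expression construction matches regulator truth and SE design", {
  cfg <- small_config(seed = 13)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  ex <- generate_expression(tr, cfg)
  expect_equal(dim(ex$counts), c(cfg$n_genes, length(cfg$samples)))

  rpkm <- compute_rpkm(ex$counts, ex$lengths)
  # equal counts per gene => equal RPKM across samples (given equal totals)
  eq <- compute_rpkm(matrix(100, 3, 6), rep(1000, 3),
                     total_reads = rep(1e6, 6))
  expect_true(all(abs(eq - eq[, 1]) < 1e-12))

  # positive regulator: RPKM rank order tracks its z-score vector
  pos_reg <- tr$regulators$gene_id[tr$regulators$sign == "+"][1]
  expect_identical(order(rpkm[pos_reg, ]), order(tr$regulator_z[pos_reg, ]))

  # constructed SE-pass genes pass, constructed fails fail (on log scale)
  pass <- se_filter(log2(rpkm + 0.5), ex$groups)
  names(pass) <- rownames(rpkm)
  built_pass <- names(ex$constructed_pass)[ex$constructed_pass]
  built_fail <- names(ex$constructed_pass)[!ex$constructed_pass]
  expect_gt(mean(pass[built_pass]), 0.95)
  expect_lt(mean(pass[built_fail]), 0.05)
})

test_that("hybrid alleles diverge at the configured rate with exclusive editing", {
  cfg <- small_config(seed = 17, hybrid_divergence = 0.05,
                      n_hybrid_sites = 8)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  hy <- generate_hybrid(ref, cfg, tr)

  # substitution rate within binomial error
  tot <- 0; nsub <- 0
  for (g in names(hy$alleles)) {
    a <- strsplit(hy$alleles[[g]]$A, "")[[1]]
    b <- strsplit(hy$alleles[[g]]$B, "")[[1]]
    tot <- tot + length(a); nsub <- nsub + sum(a != b)
  }
  expect_lt(abs(nsub / tot - 0.05), 3 * sqrt(0.05 * 0.95 / tot))

  # designated sites are C on both alleles and edited on exactly one
  for (i in seq_len(nrow(hy$sites))) {
    al <- hy$alleles[[hy$sites$gene_id[i]]]
    expect_identical(substr(al$A, hy$sites$pos[i], hy$sites$pos[i]), "C")
    expect_identical(substr(al$B, hy$sites$pos[i], hy$sites$pos[i]), "C")
  }
  pe <- hy$pileups
  edited_T <- ifelse(pe$edited_allele == "A", pe$T_A, pe$T_B)
  edited_C <- ifelse(pe$edited_allele == "A", pe$C_A, pe$C_B)
  other_T <- ifelse(pe$edited_allele == "A", pe$T_B, pe$T_A)
  expect_true(all(edited_C == 0 & edited_T > 0 & other_T == 0))

  # zero divergence: alleles identical, every read ambiguous
  cfg0 <- small_config(seed = 17, hybrid_divergence = 0)
  hy0 <- generate_hybrid(ref, cfg0, tr)
  g <- hy0$reads$gene_id[1]
  al <- hy0$alleles[[g]]
  expect_identical(al$A, al$B)
  r1 <- hy0$reads[1, ]
  expect_identical(
    assign_read_to_allele(r1$seq, r1$start, al$A, al$B,
                          hy0$sites$pos[hy0$sites$gene_id == g]),
    "ambiguous")
})
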