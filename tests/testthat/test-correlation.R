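test_that("RPKM follows its defining formula", {
  expect_equal(compute_rpkm(matrix(1000), 1000, total_reads = 1e6)[1, 1],
               1000)
  expect_equal(compute_rpkm(matrix(250), 500, total_reads = 2e6)[1, 1],
               250)
  # doubling all counts leaves RPKM unchanged (totals scale along)
  m <- matrix(c(10, 20, 30, 40), 2, 2)
  expect_equal(compute_rpkm(2 * m, c(500, 800)),
               compute_rpkm(m, c(500, 800)))
  expect_error(compute_rpkm(matrix(0), 1000), "total mapped")
})

test_that("SE filter compares within-group to overall standard errors", {
  groups <- rep(c("root", "shoot"), each = 3)
  expr <- rbind(c(1, 1, 1, 9, 9, 9),     # between-group only: pass
                c(1, 5, 9, 1, 5, 9),     # within-group only: fail
                c(5, 5, 5, 5, 5, 5))     # constant: strict inequality fails
  got <- se_filter(expr, groups)
  # direct-formula oracle for the middle row
  se <- function(x) sd(x) / sqrt(length(x))
  want2 <- se(expr[2, 1:3]) < se(expr[2, ]) && se(expr[2, 4:6]) < se(expr[2, ])
  expect_identical(got, c(TRUE, want2, FALSE))
  expect_false(want2)
  expect_error(se_filter(expr[, 1:4], c("a", "a", "a", "b")), ">= 2 samples")
})

test_that("Spearman screen gives exact permutation p-values", {
  lv <- rbind(s1 = c(1, 2, 3, 4, 5, 6))
  ex <- rbind(g1 = c(2, 4, 6, 8, 10, 12),
              g2 = c(12, 10, 8, 6, 4, 2),
              g3 = c(5, 5, 5, 5, 5, 5))
  r <- spearman_site_gene(lv, ex)
  expect_equal(r$rho["s1", "g1"], 1)
  expect_equal(r$p["s1", "g1"], 2 / 720)
  expect_equal(r$rho["s1", "g2"], -1)
  expect_equal(r$p["s1", "g2"], 2 / 720)
  expect_true(is.na(r$rho["s1", "g3"]))  # constant vector skipped
  expect_identical(r$skipped, 1L)

  # invariance under strictly monotone transforms
  set.seed(41)
  x <- rbind(runif(6)); y <- rbind(runif(6))
  r1 <- spearman_site_gene(x, y)
  r2 <- spearman_site_gene(exp(3 * x), y^3)
  expect_equal(r1$rho, r2$rho, ignore_attr = TRUE)
  expect_equal(r1$p, r2$p, ignore_attr = TRUE)
})

test_that("permutation p-values match the enumeration oracle, with ties", {
  set.seed(43)
  perms <- all_perms(6)
  for (rep in 1:12) {
    x <- sample(c(1, 2, 2, 3, 4, 5))          # tied values included
    y <- rnorm(6)
    r <- spearman_site_gene(rbind(x), rbind(y))
    expect_equal(r$rho[1, 1], cor(x, y, method = "spearman"))
    expect_equal(r$p[1, 1], oracle_spearman_p(x, y, perms))
  }
})

test_that("null p-values are calibrated near their nominal level", {
  set.seed(47)
  lv <- matrix(rnorm(40 * 6), 40)
  ex <- matrix(rnorm(50 * 6), 50)
  r <- spearman_site_gene(lv, ex)
  expect_lt(abs(mean(r$p <= 0.05) - 0.05), 0.02)
})

test_that("BH q-values equal the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(53)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("site and gene classification follow the documented rules", {
  mk <- function(n_pos, n_neg) {
    rho <- cbind(matrix(1, 1, n_pos + n_neg))
    rho[1, seq_len(n_neg) + n_pos] <- -1
    r <- list(rho = rho,
              significant = matrix(TRUE, 1, n_pos + n_neg))
    rownames(r$rho) <- rownames(r$significant) <- "g1:10"
    colnames(r$rho) <- colnames(r$significant) <-
      paste0("G", seq_len(n_pos + n_neg))
    r
  }
  expect_identical(classify_sites(mk(40, 3))$class, "I")
  expect_identical(classify_sites(mk(1, 0))$class, "II")
  expect_identical(classify_sites(mk(4, 30))$class, "III")
  expect_identical(classify_sites(mk(5, 3))$class, "II")  # dominance fails

  mkg <- function(m_pos, m_neg) {
    tot <- m_pos + m_neg
    rho <- matrix(c(rep(1, m_pos), rep(-1, m_neg), rep(1, 25 - tot)),
                  25, 1)
    sig <- matrix(c(rep(TRUE, tot), rep(FALSE, 25 - tot)), 25, 1)
    dimnames(rho) <- dimnames(sig) <-
      list(paste0("g", 1:25, ":", 1:25), "G1")
    list(rho = rho, significant = sig)
  }
  expect_identical(classify_genes(mkg(12, 0))$label, "positive")
  expect_identical(classify_genes(mkg(12, 13))$label, "both")
  expect_identical(classify_genes(mkg(9, 9))$label, "none")
})

test_that("class statistics handle degenerate classes", {
  sc <- data.frame(site = c("a:1", "b:2", "c:3"),
                   n_pos = c(9, 0, 0), n_neg = c(0, 0, 9),
                   class = c("I", "II", "III"))
  lv <- matrix(c(0.9, 0.8, 0.2, 0.3, 0.5, 0.5), 3, 2,
               dimnames = list(c("a:1", "b:2", "c:3"), NULL))
  st <- class_site_stats(sc, lv, c("nonsynonymous", "synonymous",
                                   "synonymous"))
  expect_true(all(is.na(st$summary$mean_sd)))  # one site per class
  expect_equal(st$summary$nonsyn_fraction, c(1, 0, 0))
  expect_equal(st$summary$mean_level[1], mean(c(0.9, 0.3)))
})

test_that("class-specific gene listing excludes mixed-class genes", {
  sc <- data.frame(site = c("gA:1", "gA:2", "gB:5", "gC:9"),
                   n_pos = 0, n_neg = 0,
                   class = c("I", "II", "I", "III"))
  out <- class_specific_genes(sc)
  expect_setequal(out$gene_id, c("gB", "gC"))  # gA mixed -> excluded
  expect_identical(out$class[out$gene_id == "gB"], "I")
})

test_that("relative profiles are zero-shifted along the expression order", {
  r <- list(significant = matrix(c(TRUE, TRUE), 2, 1,
                                 dimnames = list(c("s1", "s2"), "G1")))
  expr <- matrix(c(3, 1, 2, 6, 5, 4), 1, 6,
                 dimnames = list("G1", paste0("x", 1:6)))
  lv <- rbind(s1 = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
              s2 = c(0.3, 0.1, 0.2, 0.6, 0.5, 0.4))
  colnames(lv) <- paste0("x", 1:6)
  pr <- relative_profiles("G1", r, expr, lv)
  expect_identical(pr$sample_order, paste0("x", c(2, 3, 1, 6, 5, 4)))
  expect_true(all(pr$profiles["s1", ] == 0))      # constant -> flat zero
  expect_equal(min(pr$profiles["s2", ]), 0)
  # monotone coupling appears as a non-decreasing shifted series
  expect_true(all(diff(pr$profiles["s2", ]) >= 0))
})

test_that("5' composition pooled per gene class equals background when pooling all", {
  sig <- matrix(TRUE, 3, 1,
                dimnames = list(c("a:1", "b:2", "c:3"), "G1"))
  rho <- matrix(1, 3, 1, dimnames = dimnames(sig))
  gc <- data.frame(gene_id = "G1", m_pos = 3, m_neg = 0,
                   label = "positive")
  fp <- setNames(c("T", "T", "G"), rownames(sig))
  out <- five_prime_by_gene_class(gc, list(significant = sig, rho = rho),
                                  fp)
  pos_T <- out$fraction[out$population == "positive" & out$base == "T"]
  bg_T <- out$fraction[out$population == "bg" & out$base == "T"]
  expect_equal(pos_T, bg_T)  # pooled set is all sites here
  expect_equal(pos_T, 2 / 3)
})

test_that("term enrichment matches hypergeometric tails", {
  ann <- data.frame(gene_id = paste0("G", 1:100),
                    term = rep(c("TF", "other"), c(20, 80)))
  uni <- paste0("G", 1:100)
  # set of 10, all TFs
  out <- term_enrichment(paste0("G", 1:10), uni, ann)
  tf <- out[out$term == "TF", ]
  expect_equal(tf$p, phyper(9, 20, 80, 10, lower.tail = FALSE))
  expect_equal(tf$fold_enrichment, (10 / 10) / (20 / 100))
  # term covering the whole universe: fold 1, p 1
  ann2 <- data.frame(gene_id = uni, term = "all")
  out2 <- term_enrichment(paste0("G", 1:10), uni, ann2)
  expect_equal(out2$fold_enrichment, 1)
  expect_equal(out2$p, 1)
  expect_error(term_enrichment(character(0), uni, ann), "empty gene set")
})
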