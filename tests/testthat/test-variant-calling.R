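test_that("variation level is the exact ratio with guarded errors", {
  expect_identical(compute_variant_level(103, 103), 1)
  expect_identical(compute_variant_level(0, 31), 0)
  expect_identical(compute_variant_level(1, 20), 0.05)
  expect_error(compute_variant_level(1, 0), "zero depth")
  expect_error(compute_variant_level(5, 3), "alt_count")
})

boundary_pileup <- function() {
  rbind(
    pileup_row(pos = 1, ref = "C", C = 0, T = 9),            # depth 9: out
    pileup_row(pos = 2, ref = "C", C = 0, T = 10),           # depth 10: in
    pileup_row(pos = 3, ref = "C", C = 19, T = 1),           # level .05: out
    pileup_row(pos = 4, ref = "C", C = 18, T = 1, G = 1),    # two singletons
    pileup_row(pos = 5, ref = "C", C = 929, T = 71),         # level .071: in
    pileup_row(pos = 6, ref = "C", C = 10, T = 5, G = 5),    # multi-type
    pileup_row(pos = 7, ref = "A", A = 10, G = 4),           # A>G variant
    pileup_row(pos = 8, ref = "C", C = 80, T = 19, G = 1),   # G singleton ok
    pileup_row(pos = 9, ref = "N", A = 5, C = 5)             # unknown ref
  )
}

test_that("call_variants applies depth, level and multi-type rules", {
  expect_warning(v <- call_variants(boundary_pileup()), "unknown reference")
  expect_setequal(v$pos, c(2, 5, 7, 8))
  expect_identical(v$alt[v$pos == 2], "T")
  expect_identical(v$alt[v$pos == 7], "G")
  disc <- attr(v, "discarded")
  expect_identical(disc$pos, 6)
  expect_match(disc$reason, "multiple variation types")
  # position 4: G is a pure singleton (< 2 reads), so the site is kept?
  # level is 1/20 = 0.05, not > 0.05, so it fails the level rule instead
  expect_false(4 %in% v$pos)
})

test_that("call_variants equals the brute-force predicate scan", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 120
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    depth <- sample(5:60, n, replace = TRUE)
    pu <- do.call(rbind, lapply(seq_len(n), function(i) {
      cnt <- as.vector(stats::rmultinom(1, depth[i], c(.7, .1, .1, .1)))
      names(cnt) <- c(ref[i], sample(setdiff(c("A", "C", "G", "T"), ref[i])))
      pileup_row(pos = i, ref = ref[i], A = cnt[["A"]], C = cnt[["C"]],
                 G = cnt[["G"]], T = cnt[["T"]])
    }))
    got <- call_variants(pu)
    want <- oracle_variant_scan(pu)
    attr(got, "discarded") <- NULL
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("re-calling variants from their own counts is idempotent", {
  pu <- boundary_pileup()
  v <- suppressWarnings(call_variants(pu))
  # rebuild a pileup from the kept records and call again
  pu2 <- do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    r <- pileup_row(pos = v$pos[i], ref = v$ref[i])
    r[[v$ref[i]]] <- v$depth[i] - v$alt_count[i]
    r[[v$alt[i]]] <- v$alt_count[i]
    r
  }))
  v2 <- call_variants(pu2)
  attr(v, "discarded") <- attr(v2, "discarded") <- NULL
  rownames(v) <- rownames(v2) <- NULL
  expect_equal(v2, v)
})

test_that("variant spectrum fractions sum to one and match arithmetic", {
  v <- data.frame(ref = c(rep("C", 8), "A", "A"),
                  alt = c(rep("T", 8), "G", "G"))
  sp <- variant_spectrum(v)
  expect_equal(sum(sp), 1)
  expect_equal(unname(sp["C>T"]), 0.8)
  expect_equal(unname(sp["A>G"]), 0.2)
  expect_error(variant_spectrum(v[0, ]), "no variants")
})

test_that("editing-site selection keeps C>T only and tracks detectability", {
  pu <- rbind(
    pileup_row(pos = 10, ref = "C", C = 5, T = 15, sample = "s1"),
    pileup_row(pos = 10, ref = "C", C = 20, T = 0, sample = "s2"),
    pileup_row(pos = 20, ref = "C", C = 2, T = 18, sample = "s1"),
    pileup_row(pos = 20, ref = "C", C = 8, T = 0, sample = "s2"),  # depth 8
    pileup_row(pos = 30, ref = "G", G = 5, A = 15, sample = "s1"),
    pileup_row(pos = 30, ref = "G", G = 20, A = 0, sample = "s2"))
  ann <- data.frame(gene_id = "g1", compartment = "mito")
  v <- call_variants(pu)
  ss <- select_editing_sites(v, pu, ann)
  expect_equal(ss$sites$pos, c(10, 20))  # G>A record excluded
  expect_identical(ss$sites$detectable_all, c(TRUE, FALSE))
  # per-sample levels reported even where the site failed the filter
  expect_equal(unname(ss$levels["g1:10", ]), c(0.75, 0))
  expect_identical(ss$sites$compartment, c("mito", "mito"))

  # conflicting reference bases across samples
  bad <- rbind(pileup_row(pos = 10, ref = "C", C = 5, T = 15, sample = "s1"),
               pileup_row(pos = 10, ref = "T", T = 20, sample = "s2"))
  expect_error(select_editing_sites(v, bad, ann), "conflicting")
})

test_that("on clean generator output calls are a subset of truth with high recall", {
  cfg <- small_config(error_rate = 0, seed = 23)
  ref <- generate_reference(cfg)
  tr <- generate_truth(ref, cfg)
  pu <- generate_pileups(ref, tr, cfg)
  v <- call_variants(pu)
  called <- unique(paste0(v$gene_id, ":", v$pos))
  truth_ids <- paste0(tr$sites$gene_id, ":", tr$sites$pos)
  expect_true(all(called %in% truth_ids))
  detectable <- truth_ids[apply(tr$levels >= 0.1, 1, any)]
  expect_gte(mean(detectable %in% called), 0.95)
})
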