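test_that("PR2 coordinates match hand-computed ratios", {
  # equal usage of all four Ala codons: both coordinates 0.5
  p <- pr2_point(count_codons(rep(c("GCT", "GCC", "GCA", "GCG"), 5L)))
  expect_equal(p$at_bias, 0.5)
  expect_equal(p$gc_bias, 0.5)

  # A3 = 3, U3 = 1, G3 = C3 = 1
  p2 <- pr2_point(count_codons(c(rep("GCA", 3), "GCT", "GCG", "GCC")))
  expect_equal(p2$at_bias, 0.75)
  expect_equal(p2$gc_bias, 0.5)

  expect_error(pr2_point(count_codons(c("TTT", "TTC"))), "fourfold")
})

test_that("PR2 complement identity holds and sixfold boxes are optional", {
  for (seed in 1:10) {
    cc <- count_codons(random_seq(200, seed))
    p <- pr2_point(cc)
    expect_equal(p$at_bias + p$u3 / (p$a3 + p$u3), 1)
    p6 <- pr2_point(cc, mode = "include6fold")
    expect_gte(p6$n, p$n)
  }
  # Leu CTN codons count only in include6fold mode
  cc <- count_codons(c(rep("CTA", 4), rep(c("GCT", "GCC", "GCA", "GCG"), 2L)))
  expect_equal(pr2_point(cc)$n, 8)
  expect_equal(pr2_point(cc, mode = "include6fold")$n, 12)
})

test_that("PR2 of symmetric third-position usage concentrates at the centre", {
  spec <- generator_spec(1L, 20000L,
                         pi3 = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                         w_sel = 0, seed = 5L)
  s <- generate_cds(spec)$sequences[[1L]]
  p <- pr2_point(count_codons(s))
  expect_equal(p$at_bias, 0.5, tolerance = 0.03)
  expect_equal(p$gc_bias, 0.5, tolerance = 0.03)
})

test_that("neutrality regression recovers analytic cases", {
  gc3 <- c(30, 40, 50, 60, 70)
  # suppress the perfect-fit warning from summary.lm on exact data
  fit <- suppressWarnings(neutrality_fit(gc3, gc3))  # points on the diagonal
  expect_equal(fit$slope, 1)
  expect_equal(fit$mutation_pct, 100)
  expect_equal(fit$selection_pct, 0)

  flat <- suppressWarnings(neutrality_fit(rep(50, 5), gc3))
  expect_equal(flat$slope, 0)
  expect_equal(flat$selection_pct, 100)

  expect_equal(fit$mutation_pct + fit$selection_pct, 100)
  expect_error(neutrality_fit(c(1, 2, 3), rep(5, 3)), "degenerate")
  expect_error(neutrality_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("per-group neutrality fits match per-subset fits", {
  seqs <- lapply(1:12, function(i) {
    s <- random_seq(150, i)
    s$host <- c("a", "b")[1 + (i %% 2)]
    s
  })
  tab <- composition_table(seqs)
  by_host <- neutrality_by_group(tab, by = "host")
  direct <- neutrality_fit(tab$gc12s[tab$host == "a"],
                           tab$gc3s[tab$host == "a"])
  expect_equal(by_host$slope[by_host$group == "a"], direct$slope)
  expect_equal(by_host$r2[by_host$group == "All"],
               neutrality_fit(tab$gc12s, tab$gc3s)$r2)
})

test_that("Spearman correlations match rank-then-Pearson brute force", {
  set.seed(42)
  x <- 1:8
  tab <- data.frame(gravy = x, aroma = -x, enc = x^2,
                    gc3s = c(3, 1, 4, 1, 5, 9, 2, 6),
                    gc_pct = c(2, 7, 1, 8, 2, 8, 1, 8),
                    axis1 = rnorm(8), axis2 = rnorm(8))
  cm <- correlation_matrix(tab)
  expect_equal(cm$rho[cm$var1 == "gravy" & cm$var2 == "enc"], 1)
  expect_equal(cm$rho[cm$var1 == "aroma" & cm$var2 == "enc"], -1)
  for (i in seq_len(nrow(cm))) {
    expect_equal(cm$rho[i],
                 oracle_spearman(tab[[cm$var1[i]]], tab[[cm$var2[i]]]),
                 tolerance = 1e-12)
  }

  # tied case, n = 6
  tie <- data.frame(gravy = c(1, 2, 2, 3, 4, 5), aroma = c(2, 1, 3, 3, 5, 4),
                    enc = c(1, 1, 2, 3, 5, 4), gc3s = 1:6,
                    gc_pct = c(1, 3, 2, 5, 4, 6),
                    axis1 = c(2, 1, 4, 3, 6, 5), axis2 = 6:1)
  cmt <- correlation_matrix(tie)
  for (i in seq_len(nrow(cmt))) {
    expect_equal(cmt$rho[i],
                 oracle_spearman(tie[[cmt$var1[i]]], tie[[cmt$var2[i]]]),
                 tolerance = 1e-12)
  }
})

test_that("constant columns are flagged, stars follow the p conventions", {
  tab <- data.frame(gravy = 1:6, aroma = rep(1, 6), enc = c(2, 1, 4, 3, 6, 5),
                    gc3s = 1:6, gc_pct = 6:1, axis1 = 1:6, axis2 = 1:6)
  cm <- correlation_matrix(tab)
  con <- cm[cm$var1 == "aroma", ]
  expect_true(all(is.na(con$rho)))
  expect_true(all(con$flag == "constant"))
  perfect <- cm[cm$var1 == "gravy" & cm$var2 == "gc3s", ]
  expect_equal(perfect$rho, 1)
  expect_true(perfect$stars %in% c("*", "**"))
  expect_error(correlation_matrix(tab[1:4, ]), "at least 5")
  expect_error(correlation_matrix(tab[, 1:3]), "missing column")
})
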