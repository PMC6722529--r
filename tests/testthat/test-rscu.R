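test_that("RSCU matches the direct formula on worked examples", {
  # two-codon family with counts (3, 1): mean count 2 -> 1.5 / 0.5
  rv <- rscu(count_codons(c(rep("TTT", 3), "TTC")))
  expect_equal(unname(rv$rscu[c("TTT", "TTC")]), c(1.5, 0.5))

  # equal counts within a family: no bias, every RSCU = 1
  rv1 <- rscu(count_codons(c("GCT", "GCC", "GCA", "GCG")))
  expect_equal(unname(rv1$rscu[c("GCT", "GCC", "GCA", "GCG")]), rep(1, 4))
  expect_equal(unname(rv1$classification[c("GCT", "GCC", "GCA", "GCG")]),
               rep("normal", 4))

  # (7,1,1,1): 2.8 overrepresented, 0.4 underrepresented
  rv2 <- rscu(count_codons(c(rep("GCT", 7), "GCC", "GCA", "GCG")))
  expect_equal(unname(rv2$rscu[c("GCT", "GCC", "GCA", "GCG")]),
               c(2.8, 0.4, 0.4, 0.4))
  expect_equal(unname(rv2$classification["GCT"]), "overrepresented")
  expect_equal(unname(rv2$classification["GCC"]), "underrepresented")
})

test_that("unobserved families are undefined, not zero", {
  rv <- rscu(count_codons(c("TTT", "TTC")))
  expect_true(all(is.na(rv$rscu[c("GCT", "GCC", "GCA", "GCG")])))
  expect_equal(unname(rv$classification["GCT"]), "undefined")
})

test_that("family mean is 1 and RSCU is scale-invariant (property)", {
  for (seed in 1:20) {
    s <- random_seq(150, seed)
    rv <- rscu(count_codons(s))
    for (fam in DEGEN_FAMS) {
      v <- rv$rscu[fam]
      if (all(is.na(v))) next
      expect_equal(mean(v), 1, tolerance = 1e-12)
    }
    dup <- rscu(count_codons(coding_sequence("d", rep(s$codons, 3L))))
    expect_equal(dup$rscu, rv$rscu)
  }
})

test_that("RSCU agrees with seqinr's uco cross-check", {
  for (seed in 1:5) {
    s <- random_seq(200, seed)
    rv <- rscu(count_codons(s))
    uco_rscu <- seqinr::uco(tolower(unlist(strsplit(s$codons, ""))),
                            index = "rscu")
    names(uco_rscu) <- toupper(names(uco_rscu))
    common <- names(rv$rscu)[!is.na(rv$rscu)]
    expect_equal(unname(rv$rscu[common]), unname(uco_rscu[common]),
                 tolerance = 1e-9)
  }
})

test_that("group mean RSCU averages per-sequence vectors", {
  s <- random_seq(150, 1)
  rv <- rscu(count_codons(s))
  m_same <- mean_rscu(list(rv, rv, rv))
  expect_equal(setNames(m_same$rscu, m_same$codon_dna), rv$rscu)

  # symmetric two-sequence case for one family
  r1 <- rscu(count_codons(c(rep("TTT", 3), "TTC")))
  r2 <- rscu(count_codons(c("TTT", rep("TTC", 3))))
  m <- mean_rscu(list(r1, r2))
  expect_equal(m$rscu[m$codon_dna %in% c("TTT", "TTC")], c(1, 1))
})

test_that("mean of per-sequence RSCU differs from pooled-count RSCU", {
  # unbalanced sizes make the two modes disagree
  c1 <- count_codons(c(rep("TTT", 9), "TTC"))
  c2 <- count_codons(c("TTT", "TTC"))
  m_seq <- mean_rscu(list(rscu(c1), rscu(c2)))
  m_pool <- mean_rscu(list(c1, c2), mode = "pooled")
  v_seq <- m_seq$rscu[m_seq$codon_dna == "TTT"]
  v_pool <- m_pool$rscu[m_pool$codon_dna == "TTT"]
  expect_equal(v_seq, (1.8 + 1.0) / 2)
  expect_equal(v_pool, 10 / 6)
  expect_false(isTRUE(all.equal(v_seq, v_pool)))
})

test_that("exactly one preferred codon per observed family; ties flagged", {
  for (seed in 1:5) {
    s <- random_seq(300, seed)
    m <- mean_rscu(list(rscu(count_codons(s))))
    for (fam in DEGEN_FAMS) {
      rows <- m[m$codon_dna %in% fam, ]
      if (all(is.na(rows$rscu))) next
      expect_equal(sum(rows$preferred), 1L)
    }
  }
  # forced tie: equal counts in a two-fold family -> lexicographic first
  m <- mean_rscu(list(rscu(count_codons(c("TTT", "TTC")))))
  rows <- m[m$codon_dna %in% c("TTT", "TTC"), ]
  expect_true(rows$preferred[rows$codon_dna == "TTC"])
  expect_false(rows$preferred[rows$codon_dna == "TTT"])
  expect_true(all(rows$tie))
})

test_that("rscu_table emits one column per group plus All", {
  g1 <- lapply(1:3, function(i) rscu(count_codons(random_seq(100, i))))
  g2 <- lapply(4:6, function(i) rscu(count_codons(random_seq(100, i))))
  tab <- rscu_table(list(potato = g1, pepino = g2))
  expect_true(all(c("potato", "pepino", "All") %in% names(tab)))
  expect_equal(nrow(tab), 59L)
  expect_error(mean_rscu(list()), "empty")
})
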