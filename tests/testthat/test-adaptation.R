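test_that("host tables derive weights, family frequencies and RSCU", {
  counts <- random_host_counts(1)
  h <- host_usage_table(counts, name = "h1")
  expect_false(h$smoothed)
  expect_equal(sum(h$freq), 1000)
  for (fam in FAMS) {
    expect_equal(max(h$w[fam]), 1)
    expect_equal(sum(h$rel_freq[fam]), 1)
  }
  # host RSCU obeys family-mean-1
  for (fam in DEGEN_FAMS) expect_equal(mean(h$rscu$rscu[fam]), 1)

  # uniform table: all w = 1, host RSCU all 1
  hu <- host_usage_table(setNames(rep(10, length(SENSE)), SENSE))
  expect_true(all(hu$w == 1))
  expect_true(all(hu$rscu$rscu == 1))

  expect_error(host_usage_table(counts[-1]), "missing codon")
  neg <- counts; neg[1] <- -1
  expect_error(host_usage_table(neg), "negative")
})

test_that("zero-count host codons are pseudocount-smoothed", {
  counts <- random_host_counts(2)
  counts["GCT"] <- 0
  h <- host_usage_table(counts)
  expect_true(h$smoothed)
  expect_gt(h$w[["GCT"]], 0)
  expect_true(all(h$rel_freq > 0))
})

test_that("Kazusa fixtures parse to valid host tables", {
  for (f in c("mock_host_gcrich.kazusa.txt", "mock_host_aurich.kazusa.txt",
              "mock_host_balanced.kazusa.txt")) {
    path <- system.file("extdata", f, package = "codonbias")
    h <- load_host_table(path)
    expect_s3_class(h, "host_usage_table")
    expect_equal(sum(h$freq), 1000, tolerance = 1e-6)
  }
  # the GC-rich mock host prefers G/C-ending codons in fourfold families
  h <- load_host_table(system.file("extdata", "mock_host_gcrich.kazusa.txt",
                                   package = "codonbias"))
  pref <- preferred_codons(h)
  third <- substr(pref[c("A", "G", "P", "T", "V")], 3, 3)
  expect_gt(mean(third %in% c("G", "C")), 0.5)
})

test_that("CAI equals the geometric mean of relative adaptedness", {
  h <- strong_host()
  # all-preferred sequence: CAI = 1
  pref <- preferred_codons(h)
  seq_pref <- count_codons(rep(unname(pref), 5L))
  expect_equal(cai(seq_pref, h), 1)

  # two codons with w = 1 and w = 0.25: CAI = sqrt(0.25) = 0.5
  counts <- setNames(rep(1, length(SENSE)), SENSE)
  counts["TTT"] <- 4  # Phe family: w(TTT) = 1, w(TTC) = 0.25
  h2 <- host_usage_table(counts)
  expect_equal(cai(count_codons(c("TTT", "TTC")), h2), 0.5)

  # scale invariance under count duplication
  cc <- count_codons(random_seq(200, 3))
  cc2 <- pool_codon_counts(list(cc, cc))
  expect_equal(cai(cc2, h), cai(cc, h))
})

test_that("RCDI is 1 at host match and exceeds 1 otherwise", {
  counts <- random_host_counts(4)
  h <- host_usage_table(counts)
  # query counts exactly proportional to host within-family frequencies
  match_cc <- count_codons(rep(SENSE, 2L))
  match_cc$g[SENSE] <- counts * 6
  match_cc$g[c("ATG", "TGG")] <- 0
  match_cc$n_total <- sum(match_cc$g)
  expect_equal(rcdi(match_cc, h), 1, tolerance = 1e-12)

  # one 2-fold family, host 50/50, query uses only one codon: RCDI = 2
  counts_even <- setNames(rep(10, length(SENSE)), SENSE)
  h_even <- host_usage_table(counts_even)
  expect_equal(rcdi(count_codons(rep("TTT", 8L)), h_even), 2)

  # randomized cases: RCDI >= 1, equality iff frequencies match
  for (seed in 11:20) {
    cc <- count_codons(random_seq(150, seed))
    r <- rcdi(cc, h)
    expect_gte(r, 1 - 1e-12)
    # independent brute-force evaluation over every codon
    brute <- 0
    for (fam in DEGEN_FAMS) {
      g <- cc$g[fam]
      if (sum(g) == 0) next
      brute <- brute + sum((g / sum(g)) / h$rel_freq[fam] * g)
    }
    expect_equal(r, brute / cc$n_total, tolerance = 1e-12)
  }
})

test_that("SiD is a cosine transform of RSCU vectors", {
  h <- strong_host()
  s <- sid(h$rscu, h)
  expect_equal(s$r_cos, 1)
  expect_equal(s$sid, 0)

  # uniform virus against a biased host: strictly positive distance
  uniform_rscu <- rscu(count_codons(rep(BIAS59, 2L)))
  s2 <- sid(uniform_rscu, h)
  expect_lt(s2$r_cos, 1)
  expect_gt(s2$sid, 0)
  expect_lte(s2$sid, 0.5)  # (1 - R)/2 with R >= 0

  # alternative convention
  s3 <- sid(uniform_rscu, h, convention = "one-minus-half")
  expect_equal(s3$sid, 1 - s2$r_cos / 2)

  # brute-force cosine on random virus profiles
  for (seed in 21:30) {
    rv <- rscu(count_codons(random_seq(250, seed)))
    s4 <- sid(rv, h)
    keep <- !is.na(rv$rscu)
    expect_equal(s4$r_cos,
                 oracle_cosine(rv$rscu[keep], h$rscu$rscu[keep]),
                 tolerance = 1e-12)
  }
})

test_that("adaptation scores are invariant to host-table scaling", {
  counts <- random_host_counts(5)
  h1 <- host_usage_table(counts)
  h2 <- host_usage_table(counts * 17)
  cc <- count_codons(random_seq(200, 6))
  rv <- rscu(cc)
  expect_equal(cai(cc, h1), cai(cc, h2))
  expect_equal(rcdi(cc, h1), rcdi(cc, h2))
  expect_equal(sid(rv, h1)$sid, sid(rv, h2)$sid)
})

test_that("genes evolved toward a host score higher CAI against that host", {
  h_a <- load_host_table(system.file("extdata", "mock_host_gcrich.kazusa.txt",
                                     package = "codonbias"), name = "A")
  h_b <- load_host_table(system.file("extdata", "mock_host_aurich.kazusa.txt",
                                     package = "codonbias"), name = "B")
  spec <- generator_spec(20L, 300L, w_sel = 0.6, host_table = h_a, seed = 9L)
  seqs <- generate_cds(spec)$sequences
  cai_a <- vapply(seqs, function(s) cai(count_codons(s), h_a), numeric(1))
  cai_b <- vapply(seqs, function(s) cai(count_codons(s), h_b), numeric(1))
  expect_gt(mean(cai_a), mean(cai_b))
  expect_lt(wilcox.test(cai_a, cai_b, paired = TRUE,
                        alternative = "greater")$p.value, 0.01)
})
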