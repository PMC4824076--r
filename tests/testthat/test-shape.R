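test_that("synthetic pentamer table satisfies its contract", {
  tab <- fixture_shape_table()
  expect_equal(nrow(tab), 1024)
  expect_true(validate_shape_table(tab))
  expect_true(all(tab$mgw >= 2.8 & tab$mgw <= 6.2))
  expect_true(all(tab$prot >= -17 & tab$prot <= -1))
  expect_true(all(abs(tab$roll_left) <= 9 & abs(tab$roll_right) <= 9))
  expect_true(all(tab$helt_left >= 30 & tab$helt_left <= 40))
  # A-tract narrowing
  expect_lt(tab$mgw[tab$pentamer == "AAAAA"], mean(tab$mgw))
  expect_identical(synth_pentamer_table(5), synth_pentamer_table(5))
  expect_false(identical(synth_pentamer_table(5), synth_pentamer_table(6)))

  bad <- tab
  bad$mgw[1] <- bad$mgw[1] + 1
  expect_error(validate_shape_table(bad), class = "qpid_shape_table")
})

test_that("predict_shape window arithmetic and degenerate inputs", {
  tab <- fixture_shape_table()
  tr <- predict_shape("ACGTG", tab)
  expect_equal(which(tr$defined), 3L)
  expect_equal(tr$mgw[3], tab$mgw[tab$pentamer == "ACGTG"])
  expect_error(predict_shape("ACGN", tab), class = "qpid_invalid_sequence")
  expect_error(predict_shape("ACGTNACGT", tab), class = "qpid_invalid_sequence")

  # homopolymer: constant interior values on every track
  a20 <- predict_shape(strrep("A", 20), tab)
  interior <- 4:17
  for (col in c("mgw", "prot", "roll", "helt"))
    expect_equal(diff(range(a20[[col]][interior])), 0)
})

test_that("predict_shape is strand-symmetric on random sequences", {
  tab <- fixture_shape_table()
  set.seed(11)
  for (s in random_dna(100, 30)) {
    fw <- predict_shape(s, tab)
    rv <- predict_shape(rc_str(s), tab)
    for (col in c("mgw", "prot", "roll", "helt"))
      expect_equal(fw[[col]], rev(rv[[col]]), tolerance = 1e-12)
  }
})

test_that("predict_shape matches the naive per-position re-implementation", {
  tab <- fixture_shape_table()
  set.seed(12)
  for (s in random_dna(50, 50)) {
    fast <- predict_shape(s, tab)
    slow <- naive_predict_shape(s, tab)
    for (col in c("mgw", "prot", "roll", "helt"))
      expect_equal(fast[[col]], slow[[col]], tolerance = 1e-12)
  }
})

test_that("feature vectors have length 4(2k+w) with frozen block order", {
  tab <- fixture_shape_table()
  set.seed(13)
  seq <- random_dna(1, 60)
  v <- build_feature_vector(seq, core_start = 25, w = 5, k = 10, table = tab)
  expect_length(v, 100)
  expect_equal(attr(v, "block_order"), c("HelT", "MGW", "Roll", "ProT"))

  v2 <- build_feature_vector(seq, core_start = 25, w = 8, k = 0, table = tab)
  expect_length(v2, 32)

  for (wk in list(c(5, 3), c(8, 10), c(1, 7))) {
    vv <- build_feature_vector(seq, 25, wk[1], wk[2], tab)
    expect_length(vv, 4 * (2 * wk[2] + wk[1]))
  }
  # blocks come from the per-base tracks in order
  tr <- predict_shape(seq, tab)
  idx <- (25 - 10):(25 + 5 - 1 + 10)
  expect_equal(as.numeric(v), c(tr$helt[idx], tr$mgw[idx], tr$roll[idx],
                                tr$prot[idx]))
  expect_error(build_feature_vector(seq, core_start = 3, w = 5, k = 10,
                                    table = tab),
               class = "qpid_context")
})

test_that("reference profiles average member vectors", {
  tab <- fixture_shape_table()
  set.seed(14)
  s1 <- random_dna(1, 25); s2 <- random_dna(1, 25)
  one <- reference_profile(s1, core_start = 11, w = 5, k = 4, table = tab)
  v1 <- build_feature_vector(s1, 11, 5, 4, tab)
  expect_equal(as.numeric(one$mean), as.numeric(v1))
  expect_equal(one$n_sites, 1L)

  dup <- reference_profile(c(s1, s1), 11, 5, 4, tab)
  expect_equal(as.numeric(dup$mean), as.numeric(v1))

  # hand-averaged pair
  v2 <- build_feature_vector(s2, 11, 5, 4, tab)
  both <- reference_profile(c(s1, s2), 11, 5, 4, tab)
  expect_equal(as.numeric(both$mean), (as.numeric(v1) + as.numeric(v2)) / 2,
               tolerance = 1e-12)

  expect_error(reference_profile(c(s1, substring(s2, 1, 20)), 11, 5, 4, tab),
               class = "qpid_alignment")
})

test_that("normalized distance: identity, hand example, homogeneity", {
  expect_equal(unname(normalized_distance(structure(c(1, 2)), c(1, 2),
                                          scope = "overall")), 0)
  expect_equal(unname(normalized_distance(structure(c(1, 2)), c(3, 4),
                                          scope = "overall")), 2)
  x <- c(1, 2, 3, 4); mu <- c(0, 1, 5, 9)
  for (cc in c(0.5, 2, 10))
    expect_equal(unname(normalized_distance(cc * x, cc * mu, "overall")),
                 cc * unname(normalized_distance(x, mu, "overall")),
                 tolerance = 1e-12)
  expect_error(normalized_distance(c(1, 2), c(1, 2, 3), "overall"),
               class = "qpid_layout_mismatch")
})

test_that("per-feature distances are strand invariant", {
  tab <- fixture_shape_table()
  set.seed(15)
  sites <- random_dna(6, 25)
  prof <- reference_profile(sites[1:5], 11, 5, 4, tab)
  q <- build_feature_vector(sites[6], 11, 5, 4, tab)
  d_fw <- normalized_distance(q, prof)
  # reverse-complement everything: core at position 25 - (11 + 5 - 1) + 1
  rc_sites <- vapply(sites, rc_str, character(1))
  prof_rc <- reference_profile(rc_sites[1:5], 11, 5, 4, tab)
  q_rc <- build_feature_vector(rc_sites[6], 11, 5, 4, tab)
  d_rc <- normalized_distance(q_rc, prof_rc)
  expect_equal(d_fw, d_rc, tolerance = 1e-12)
  ov <- normalized_distance(q, prof, "overall")
  expect_equal(unname(ov),
               sqrt(sum((as.numeric(q) - as.numeric(prof$mean))^2) / 52),
               tolerance = 1e-12)
})

test_that("concordance binomial matches exhaustive enumeration", {
  expect_equal(concordance_binomial(8, 7), 9 / 256)
  expect_equal(concordance_binomial(8, 8), 1 / 256)
  expect_equal(concordance_binomial(4, 0), 1)
  for (n in c(1, 3, 5, 8, 12))
    for (k in c(0, 1, n %/% 2, n))
      expect_equal(concordance_binomial(n, k), enum_binomial_tail(n, k),
                   tolerance = 1e-12)
  expect_error(concordance_binomial(4, 5), class = "qpid_invalid_argument")
  expect_error(concordance_binomial(0, 0), class = "qpid_invalid_argument")
})

test_that("shape table and feature vector files round-trip", {
  tab <- fixture_shape_table()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_shape_table(tab, p)
  back <- read_shape_table(p)
  expect_equal(back$mgw, tab$mgw, tolerance = 1e-9)

  set.seed(16)
  seqs <- random_dna(3, 40)
  vecs <- lapply(seqs, build_feature_vector, core_start = 18, w = 5, k = 6,
                 table = tab)
  names(vecs) <- paste0("s", 1:3)
  vp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_vectors(vecs, vp)
  back_v <- read_feature_vectors(vp)
  expect_equal(names(back_v), names(vecs))
  expect_equal(as.numeric(back_v[[2]]), as.numeric(vecs[[2]]),
               tolerance = 1e-9)
  expect_equal(attr(back_v[[1]], "k"), 6L)
})
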