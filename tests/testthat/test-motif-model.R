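test_that("site collections validate their invariants", {
  s <- binding_sites(c("AC", "AG"))
  expect_s3_class(s, "cpx_sites")
  expect_identical(attr(s, "site_length"), 2L)
  expect_error(binding_sites(character()), "non-empty")
  expect_error(binding_sites(c("AC", "ACG")), "share one length")
  expect_error(binding_sites(c("ACGT", "ACNT")), "non-ACGT")
  expect_error(binding_sites(c("ACGT", "ACRT")), "non-ACGT")
})

test_that("count matrix tallies base occurrences per column", {
  cm <- count_matrix(binding_sites(c("AC", "AG")))
  expect_identical(unname(cm["A", 1]), 2L)
  expect_identical(unname(cm["C", 2]), 1L)
  expect_identical(unname(cm["G", 2]), 1L)
  expect_identical(attr(cm, "n_sites"), 2L)
  # identity case: three copies of one site
  cm2 <- count_matrix(binding_sites(rep("GTAAA", 3)))
  expect_true(all(apply(unclass(cm2), 2, max) == 3L))
  expect_true(all(colSums(unclass(cm2)) == 3L))
  # a 41-site collection has column sums all 41
  spec <- motif_spec(identity = 0.85, seed = 3)
  cm41 <- count_matrix(sample_sites(spec, 41))
  expect_true(all(colSums(unclass(cm41)) == 41L))
})

test_that("spacer expansion duplicates the middle base of the 5-bp spacer", {
  expect_identical(expand_spacer("GTAAACCGCCGTAAA"), "GTAAACCGGCCGTAAA")
  expect_identical(expand_spacer(strrep("A", 15)), strrep("A", 16))
  set.seed(42)
  for (i in 1:20) {
    s <- random_genome(15, seed = i)
    out <- expand_spacer(s)
    expect_identical(nchar(out), 16L)
    # both copies equal the original 8th base (0-based index 7)
    expect_identical(substr(out, 8, 8), substr(s, 8, 8))
    expect_identical(substr(out, 9, 9), substr(s, 8, 8))
    # removing either copy recovers the input
    expect_identical(paste0(substr(out, 1, 8), substr(out, 10, 16)), s)
  }
  expect_error(expand_spacer("ACGT"), "15-bp")
})

test_that("expanded-collection count matrix duplicates column 8", {
  sites <- sample_sites(motif_spec(identity = 0.8, seed = 9), 30)
  cm15 <- unclass(count_matrix(sites))
  cm16 <- unclass(count_matrix(expand_spacer(sites)))
  expect_equal(cm16[, 1:8], cm15[, 1:8])
  expect_equal(cm16[, 9], cm15[, 8])
  expect_equal(cm16[, 10:16], cm15[, 9:15])
})

test_that("PWM probabilities follow the pseudocount formula", {
  # single site, column base G: p(G) = 1.5/3, others 0.5/3
  pwm <- build_pwm(count_matrix(binding_sites("G")))
  expect_equal(unname(pwm["G", 1]), 1.5 / 3)
  expect_equal(unname(pwm["A", 1]), 0.5 / 3)
  # maximum-likelihood limit at beta = 0
  cm <- count_matrix(binding_sites(rep("A", 4)))
  pwm0 <- build_pwm(cm, pseudocount = 0)
  expect_equal(unname(pwm0[, 1]), c(1, 0, 0, 0))
  # hand-evaluated oracle: counts (20,10,5,6), n = 41, beta = 0.5
  expect_equal((20 + 0.5) / (41 + 2), 0.476744186046512, tolerance = 1e-12)
  sites41 <- c(rep("A", 20), rep("C", 10), rep("G", 5), rep("T", 6))
  pwm41 <- build_pwm(count_matrix(binding_sites(sites41)))
  expect_equal(unname(pwm41["A", 1]), 20.5 / 43)
  expect_equal(unname(pwm41["C", 1]), 10.5 / 43)
  # columns sum to one
  sites <- toy_sites()
  p <- build_pwm(count_matrix(sites))
  expect_true(all(abs(colSums(unclass(p)) - 1) < 1e-9))
  expect_true(all(unclass(p) > 0))
  expect_error(build_pwm(count_matrix(sites), pseudocount = -1),
               "non-negative")
})

test_that("PSSM is log2(p/q) and round-trips exactly", {
  # p = q uniform -> all scores zero
  pwm_u <- build_pwm(count_matrix(binding_sites(c("A", "C", "G", "T"))),
                     pseudocount = 0)
  expect_true(all(unclass(build_pssm(pwm_u)) == 0))
  # p(G) = 0.5 vs q = 0.25 -> exactly 1 bit
  pwm_g <- build_pwm(count_matrix(binding_sites(c("G", "G", "G", "G",
                                                  "A", "A", "C", "T"))),
                     pseudocount = 0)
  expect_equal(unname(build_pssm(pwm_g)["G", 1]), 1)
  # zero probabilities are rejected at log-odds time
  pwm0 <- build_pwm(count_matrix(binding_sites("A")), pseudocount = 0)
  expect_error(build_pssm(pwm0), "pseudocount")
  # full toy matrix equals the independently computed table
  sites <- toy_sites()
  pssm <- sites_to_pssm(sites)
  cm <- unclass(count_matrix(sites))
  expected <- log2(((cm + 0.5) / (4 + 2)) / 0.25)
  expect_equal(unclass(pssm), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # exponentiating recovers p/q to 1e-9
  p <- unclass(build_pwm(count_matrix(sites)))
  expect_equal(2^unclass(pssm) * 0.25, p, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("window scoring sums looked-up cells", {
  sites <- toy_sites()
  pssm <- sites_to_pssm(sites)
  # consensus attains the maximum achievable score
  expect_equal(score_window(pssm, consensus_sequence(pssm)),
               max_score(pssm))
  # uniform matrix scores any window zero
  pwm_u <- build_pwm(count_matrix(binding_sites(c("ACGT", "CGTA",
                                                  "GTAC", "TACG"))),
                     pseudocount = 0)
  pssm_u <- build_pssm(pwm_u)
  expect_equal(score_window(pssm_u, "GGGG"), 0)
  # agreement with an independent scoring engine on random windows
  set.seed(5)
  for (i in 1:10) {
    w <- random_genome(15, seed = 100 + i)
    expect_equal(score_window(pssm, w),
                 Biostrings::PWMscoreStartingAt(unclass(pssm),
                                                Biostrings::DNAString(w), 1))
  }
  expect_error(score_window(pssm, "ACGT"), "length")
  expect_error(score_window(pssm, "GTAAACTGACGTAAN"), "non-ACGT")
})

test_that("reverse-complement matrix mirrors forward scores bit-exactly", {
  pssm <- sites_to_pssm(toy_sites())
  rc <- reverse_complement_matrix(pssm)
  for (i in 1:10) {
    w <- random_genome(15, seed = 200 + i)
    expect_identical(score_window(pssm, rc_chr(w)), score_window(rc, w))
  }
})

test_that("consensus uses argmax with A<C<G<T tie order", {
  sites <- sample_sites(motif_spec(identity = 1, seed = 2), 10)
  cons <- consensus_sequence(build_pwm(count_matrix(sites)))
  expect_identical(substr(cons, 1, 5), "GTAAA")
  expect_identical(substr(cons, 11, 15), "GTAAA")
  # single-site training: consensus equals the site
  one <- binding_sites("GTAAACTGACGTAAA")
  expect_identical(consensus_sequence(build_pwm(count_matrix(one))),
                   "GTAAACTGACGTAAA")
  # tie 2A/2C resolves to A
  tied <- build_pwm(count_matrix(binding_sites(c("A", "A", "C", "C"))))
  expect_identical(consensus_sequence(tied), "A")
})

test_that("growing pseudocount pulls scores toward the background", {
  cm <- count_matrix(toy_sites())
  q <- uniform_background()
  dev <- vapply(c(0.5, 5, 50, 5000), function(b) {
    max(abs(unclass(build_pssm(build_pwm(cm, pseudocount = b), q))))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 0.01)
})

test_that("matrix TSV + JSON sidecar round-trips", {
  pssm <- sites_to_pssm(toy_sites())
  path <- file.path(withr::local_tempdir(), "pssm.tsv")
  write_matrix(pssm, path)
  back <- read_matrix(path)
  expect_s3_class(back, "cpx_pssm")
  expect_equal(unclass(back), unclass(pssm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "background"), attr(pssm, "background"))
})

test_that("background models are valid and composition-aware", {
  expect_equal(sum(uniform_background()), 1)
  q <- genome_background("AAAATTTTGGCC")
  expect_equal(sum(q), 1)
  expect_equal(unname(q["A"]), unname(q["T"]))  # strand symmetric
  expect_gt(q[["A"]], q[["G"]])
})
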