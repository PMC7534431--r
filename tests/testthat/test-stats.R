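test_that("chi-square reproduces the published contingency P-values", {
  # CO proportion, I-SceI vs ZFN: printed P = 0.04
  t1 <- chisq_2x2(35, 337, 55, 322)
  expect_equal(round(t1$p_value, 2), 0.04)
  # CO proportion, SNP8 vs SNP22 substrates: printed P = 0.25
  expect_equal(round(chisq_2x2(33, 438, 35, 337)$p_value, 2), 0.25)
  # downstream fraction of unidirectional tracts, SNP8 vs SNP22: P = 0.07
  expect_equal(round(chisq_2x2(100, 22, 176, 66)$p_value, 2), 0.07)
  # bidirectional fraction, I-SceI vs ZFN: P = 0.60
  expect_equal(round(chisq_2x2(35, 242, 13, 114)$p_value, 2), 0.60)
  # tract position, I-SceI vs ZFN: P = 0.22
  expect_equal(round(chisq_2x2(176, 66, 75, 39)$p_value, 2), 0.22)
  # terminal SNP removal, SNP8 vs SNP22: printed P < 0.001 on both sides
  expect_lt(chisq_2x2(124, 25, 23, 254)$p_value, 0.001)
  expect_lt(chisq_2x2(52, 97, 19, 258)$p_value, 0.001)
})

test_that("chi-square handles degenerate tables and matches stats::chisq.test", {
  flat <- chisq_2x2(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chisq_2x2(0, 0, 5, 5), "margin")
  expect_error(chisq_2x2(-1, 2, 3, 4), "non-negative")

  set.seed(14)
  for (i in 1:25) {
    t <- matrix(rpois(4, 20) + 1, 2, 2)
    for (corr in c(TRUE, FALSE)) {
      mine <- chisq_2x2(t, continuity_correction = corr)
      ref <- suppressWarnings(stats::chisq.test(t, correct = corr))
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value)
    }
  }
})

test_that("chi-square is invariant to swapping rows and columns", {
  t <- c(12, 5, 7, 19)
  base <- chisq_2x2(t[1], t[2], t[3], t[4])$p_value
  expect_equal(chisq_2x2(t[3], t[4], t[1], t[2])$p_value, base)
  expect_equal(chisq_2x2(t[2], t[1], t[4], t[3])$p_value, base)
})

test_that("chi-square ordering is consistent with exact enumeration", {
  # along each tail of the margin-conditional distribution, both the
  # chi-square p and the exact hypergeometric tail shrink as tables get
  # more extreme; on symmetric margins the full orderings agree
  check_margins <- function(r1, c1, n) {
    tabs <- fisher_enumeration(r1, c1, n)
    av <- tabs$a
    chi_p <- vapply(av, function(a) {
      chisq_2x2(a, r1 - a, c1 - a, n - r1 - c1 + a)$p_value
    }, 0)
    fis_p <- vapply(seq_along(av), function(i) {
      sum(tabs$prob[tabs$prob <= tabs$prob[i] + 1e-12])
    }, 0)
    e_a <- r1 * c1 / n
    ok <- TRUE
    for (side in list(av[av <= e_a], av[av >= e_a])) {
      ord <- order(abs(side - e_a))
      cp <- chi_p[match(side[ord], av)]
      fp <- fis_p[match(side[ord], av)]
      ok <- ok && all(diff(cp) <= 1e-9) && all(diff(fp) <= 1e-9)
    }
    list(ok = ok, chi = chi_p, fis = fis_p)
  }
  # every margin combination with totals up to 20
  all_ok <- TRUE
  for (n in c(10, 14, 20)) {
    for (r1 in 2:(n - 2)) {
      for (c1 in 2:(n - 2)) {
        all_ok <- all_ok && check_margins(r1, c1, n)$ok
      }
    }
  }
  expect_true(all_ok)
  # symmetric margins: full rank agreement between chi-square and Fisher
  res <- check_margins(10, 10, 20)
  expect_equal(rank(res$chi), rank(res$fis))
})

test_that("Mann-Whitney agrees with exhaustive enumeration for n <= 8", {
  # disjoint samples: U = 0 and the enumeration p
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, bf_mw_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(mw$method, "exact")

  # identical multisets are fully tied
  expect_equal(mann_whitney(c(5, 5, 7), c(5, 5, 7))$p_value, 1)

  set.seed(21)
  for (i in 1:40) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    if (i %% 2 == 0) {
      x <- rnorm(n1); y <- rnorm(n2)                # continuous
    } else {
      x <- sample(1:4, n1, TRUE); y <- sample(1:4, n2, TRUE)  # heavy ties
    }
    mine <- mann_whitney(x, y)
    expect_equal(mine$p_value, bf_mw_p(x, y), tolerance = 1e-12)
    if (!any(duplicated(c(x, y)))) {
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(mine$p_value, ref$p.value, tolerance = 0.02)
    }
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney large-sample approximation holds its type-I error", {
  set.seed(99)
  n_rep <- 1000
  rej <- vapply(seq_len(n_rep), function(i) {
    mann_whitney(rnorm(15), rnorm(15))$p_value < 0.05
  }, NA)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Wilson intervals behave at the boundaries and match prop.test", {
  ci0 <- proportion_ci(0, 10)
  expect_equal(unname(ci0["lower"]), 0)
  ci <- proportion_ci(35, 372)
  expect_true(ci["lower"] < 35 / 372 && 35 / 372 < ci["upper"])
  cis <- proportion_ci(50, 100)
  expect_equal(unname(cis["lower"] + cis["upper"]), 1)

  for (kn in list(c(3, 10), c(0, 7), c(7, 7), c(35, 372), c(124, 149))) {
    ref <- suppressWarnings(stats::prop.test(kn[1], kn[2], correct = FALSE))$conf.int
    mine <- proportion_ci(kn[1], kn[2])
    expect_equal(unname(mine), as.numeric(ref), tolerance = 1e-10)
  }

  # width shrinks with n at fixed k/n
  w <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- proportion_ci(n / 2, n); unname(ci["upper"] - ci["lower"])
  }, 0)
  expect_true(all(diff(w) < 0))
  expect_error(proportion_ci(1, 0), "n must be")
})

test_that("Southern ratio arithmetic recovers cut and repaired fractions", {
  # intensities realizing a 82%-cut series with 16% repaired from 3h to 6h
  s <- southern_series(
    timepoints = c(0, 0.75, 1.5, 3, 6, 12),
    recipient_intensity = c(200, 150, 80, 36, 62.24, 150),
    donor_intensity = rep(200, 6))
  r <- southern_normalize(s)
  expect_equal(r$ratio[r$time == 0], 1)
  expect_equal(cut_fraction(s), 0.82)
  expect_equal(repaired_fraction(s, 3, 6), 0.16, tolerance = 1e-10)
  expect_equal(repaired_fraction(s, 3, 6, method = "raw_difference"),
               0.3112 - 0.18, tolerance = 1e-10)

  # constant intensities: nothing cut
  flat <- southern_series(c(0, 3, 6), c(5, 5, 5), c(7, 7, 7))
  expect_equal(cut_fraction(flat), 0)
  expect_error(repaired_fraction(flat, 0, 3), "undefined")

  # invariance to rescaling all intensities
  s2 <- southern_series(s$timepoints, s$recipient_intensity * 3.7,
                        s$donor_intensity * 3.7)
  expect_equal(southern_normalize(s2)$ratio, r$ratio)

  expect_error(southern_series(c(1, 2), c(1, 1), c(1, 1)), "t = 0")
  expect_error(southern_series(c(0, 1), c(1, 1), c(1, 0)), "donor")
})
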