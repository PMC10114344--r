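test_that("pairwise tallies are exact and ordered", {
  expect_equal(unclass(pairwise_counts(c(T, T, F, F), c(T, T, F, F)))[1:4],
               list(a = 2L, b = 0L, c = 0L, d = 2L))
  expect_equal(unclass(pairwise_counts(c(T, F), c(F, T)))[1:4],
               list(a = 0L, b = 1L, c = 1L, d = 0L))
  expect_error(pairwise_counts(c(T, F), c(T)), "equal length")
  cts <- pairwise_counts(c(T, NA, F), c(T, T, F))
  expect_equal(cts$total, 2)
  expect_equal(attr(cts, "n_dropped"), 1)
})

test_that("APA/ANA/OPA and reference-based PPA/NPA follow their formulas", {
  s <- agreement_stats(concordance_counts(148, 1, 1, 150))
  expect_equal(round(s$value, 1), c(99.3, 99.3, 99.3))
  expect_equal(s$numerator, c(296, 300, 298))
  expect_equal(s$denominator, c(298, 302, 300))

  s2 <- agreement_stats(concordance_counts(39, 2, 0, 11),
                        reference_is_second = TRUE)
  v <- stats::setNames(round(s2$value, 1), s2$statistic)
  expect_equal(unname(v[c("PPA", "NPA", "OPA")]), c(100.0, 84.6, 96.2))

  s3 <- agreement_stats(concordance_counts(7, 0, 0, 13))
  expect_equal(s3$value, c(100, 100, 100))
})

test_that("APA/ANA/OPA are symmetric in the two raters (b <-> c)", {
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(5:200, 4)
      s_xy <- agreement_stats(concordance_counts(n[1], n[2], n[3], n[4]))
      s_yx <- agreement_stats(concordance_counts(n[1], n[3], n[2], n[4]))
      expect_equal(s_xy$value, s_yx$value)
      # PPA/NPA margins transpose
      p_xy <- agreement_stats(concordance_counts(n[1], n[2], n[3], n[4]),
                              reference_is_second = TRUE)
      expect_equal(p_xy$numerator[p_xy$statistic == "PPA"] /
                     p_xy$denominator[p_xy$statistic == "PPA"],
                   n[1] / (n[1] + n[3]))
    }
  })
})

test_that("zero denominators give undefined statistics, not errors", {
  s <- agreement_stats(concordance_counts(0, 0, 0, 25),
                       reference_is_second = TRUE)
  expect_true(is.na(s$value[s$statistic == "APA"]))
  expect_true(is.na(s$value[s$statistic == "PPA"]))
  expect_equal(s$value[s$statistic == "NPA"], 100)
})

test_that("the Wilson interval matches its closed form and stays in range", {
  expect_equal(round(wilson_interval(39, 39), 1),
               c(lower = 91.0, upper = 100.0))
  expect_equal(round(wilson_interval(11, 13), 1),
               c(lower = 57.8, upper = 95.7))
  expect_equal(unname(round(wilson_interval(0, 10), 1)[1]), 0.0)
  # textbook closed form at n = 50, k = 40, z = 1.959964
  z <- stats::qnorm(0.975)
  p <- 0.8; n <- 50
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  expect_equal(unname(wilson_interval(40, 50)[1]), 100 * lo)
  # width shrinks with n at fixed proportion
  w <- vapply(c(10, 40, 160, 640), function(n)
    diff(unname(wilson_interval(round(0.7 * n), n))), numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(wilson_interval(1, 0), "positive")
})

test_that("between-reader pooling over reader pairs matches the design arithmetic", {
  m <- perfect_reader_matrix(rep(c(TRUE, FALSE), each = 50))
  rep <- between_reader_precision(m)
  expect_equal(rep$n_pairs, 300)
  expect_equal(rep$statistics$value, c(100, 100, 100))
  expect_true(all(rep$statistics$meets_criterion[
    rep$statistics$statistic %in% c("APA", "ANA")]))
  expect_error(between_reader_precision(
    perfect_reader_matrix(c(TRUE, FALSE), n_readers = 1)), "2 readers")
})

test_that("a single near-miss sample reproduces the internal between-reader table", {
  # 49 all-positive samples, 50 all-negative, one sample read (+,+,-):
  # pooled counts (148, 2 discordant, 150) -> 99.3 / 99.3 / 99.3
  calls <- tibble::tibble(
    sample_id = rep(sprintf("s%03d", 1:100), each = 3),
    reader_id = rep(sprintf("reader_%d", 1:3), times = 100),
    round = 1,
    status = c(rep(TRUE, 49 * 3), c(TRUE, TRUE, FALSE),
               rep(FALSE, 50 * 3)))
  rep <- between_reader_precision(reader_score_matrix(calls))
  expect_equal(rep$counts$a, 148)
  expect_equal(rep$counts$b + rep$counts$c, 2)
  expect_equal(rep$counts$d, 150)
  expect_equal(round(rep$statistics$value, 1), c(99.3, 99.3, 99.3))
  expect_equal(rep$statistics$numerator, c(296, 300, 298))
  expect_equal(rep$statistics$denominator, c(298, 302, 300))
})

test_that("within-reader pooling matches the internal within-reader table", {
  # 3 readers x 100 samples (50+/50-); readers 1 and 2 each flip one
  # positive in round 2, reader 3 flips one negative:
  # pooled (148 pos-pos, 149 neg-neg, 3 discordant)
  truth <- rep(c(TRUE, FALSE), each = 50)
  rows <- list()
  for (r in 1:3) {
    for (rd in 1:2) {
      st <- truth
      if (rd == 2 && r <= 2) st[r] <- FALSE        # flip a positive
      if (rd == 2 && r == 3) st[60] <- TRUE        # flip a negative
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sprintf("s%03d", 1:100),
        reader_id = sprintf("reader_%d", r), round = rd, status = st)
    }
  }
  rep <- within_reader_precision(reader_score_matrix(dplyr::bind_rows(rows)))
  expect_equal(rep$statistics$numerator, c(296, 298, 297))
  expect_equal(rep$statistics$denominator, c(299, 301, 300))
  expect_equal(round(rep$statistics$value, 1), c(99.0, 99.0, 99.0))
  expect_true(all(rep$statistics$meets_criterion))

  # identical rounds -> 100% everywhere
  rep2 <- within_reader_precision(
    perfect_reader_matrix(truth, n_readers = 3, n_rounds = 2))
  expect_equal(rep2$statistics$value, c(100, 100, 100))

  # one flipped call in one reader's second round -> pooled OPA 299/300
  rows3 <- list()
  for (r in 1:3) for (rd in 1:2) {
    st <- truth
    if (r == 1 && rd == 2) st[1] <- FALSE
    rows3[[length(rows3) + 1]] <- tibble::tibble(
      sample_id = sprintf("s%03d", 1:100),
      reader_id = sprintf("reader_%d", r), round = rd, status = st)
  }
  rep3 <- within_reader_precision(reader_score_matrix(dplyr::bind_rows(rows3)))
  opa <- rep3$statistics[rep3$statistics$statistic == "OPA", ]
  expect_equal(opa$numerator / opa$denominator, 299 / 300)
  expect_error(within_reader_precision(perfect_reader_matrix(truth)),
               "2 rounds")
})

test_that("multisite pooling sums counts rather than averaging percentages", {
  site_a <- concordance_counts(44, 11, 10, 72)   # b + c = 21
  site_b <- concordance_counts(70, 0, 0, 70)
  site_c <- concordance_counts(70, 0, 0, 70)
  pooled <- multisite_pool(list(site_a, site_b, site_c))
  v <- stats::setNames(round(pooled$statistics$value, 1),
                       pooled$statistics$statistic)
  expect_equal(unname(v[c("APA", "ANA", "OPA")]), c(94.6, 95.3, 95.0))
  expect_equal(pooled$statistics$numerator, c(368, 424, 396))
  expect_equal(pooled$statistics$denominator, c(389, 445, 417))
  # mean of site OPAs would be (84.7 + 100 + 100) / 3 = 94.9, not 95.0
  site_opas <- vapply(list(site_a, site_b, site_c), function(ct)
    100 * (ct$a + ct$d) / ct$total, numeric(1))
  expect_false(isTRUE(all.equal(mean(site_opas),
                                unname(v[["OPA"]]), tolerance = 1e-6)))
  # identity on one site, order invariance
  one <- multisite_pool(list(site_a))
  expect_equal(one$counts$a, 44)
  perm <- multisite_pool(list(site_c, site_a, site_b))
  expect_equal(perm$statistics$value, pooled$statistics$value)
})

test_that("method concordance dichotomizes against the CPS reference", {
  # TAP 1% cutoff vs CPS 1: (a=39, TAP-only=2, CPS-only=0, both-neg=11)
  tap <- c(rep(2, 39), rep(1.5, 2), rep(0.2, 11))
  cps <- c(rep(2, 39), rep(0.5, 2), rep(0.5, 11))
  rep <- method_concordance(tap, cps, tap_cutoff = 1, cps_cutoff = 1)
  v <- stats::setNames(round(rep$statistics$value, 1), rep$statistics$statistic)
  expect_equal(unname(v[c("PPA", "NPA", "OPA")]), c(100.0, 84.6, 96.2))
  # TAP 5% cutoff: (35, 0, 4, 13)
  tap5 <- c(rep(7, 35), rep(3, 4), rep(0.2, 13))
  cps5 <- c(rep(2, 35), rep(2, 4), rep(0.5, 13))
  rep5 <- method_concordance(tap5, cps5, tap_cutoff = 5, cps_cutoff = 1)
  v5 <- stats::setNames(round(rep5$statistics$value, 1),
                        rep5$statistics$statistic)
  expect_equal(unname(v5[c("PPA", "NPA", "OPA")]), c(89.7, 100.0, 92.3))
  # all concordant
  repc <- method_concordance(c(2, 0.2), c(3, 0.1))
  expect_equal(repc$statistics$value[repc$statistics$statistic %in%
                                       c("PPA", "NPA", "OPA")], c(100, 100, 100))
  expect_error(method_concordance(c(1, 2), c(1, 2, 3)), "paired")
})

test_that("OPA lies between the accuracies implied on positives and negatives", {
  withr::with_seed(7, {
    for (i in 1:30) {
      n <- sample(1:100, 4, replace = TRUE)
      ct <- concordance_counts(n[1], n[2], n[3], n[4])
      s <- agreement_stats(ct)
      opa <- s$value[s$statistic == "OPA"]
      acc_pos <- 2 * ct$a / (2 * ct$a + ct$b + ct$c)
      acc_neg <- 2 * ct$d / (2 * ct$d + ct$b + ct$c)
      expect_gte(opa + 1e-9, 100 * min(acc_pos, acc_neg))
      expect_lte(opa - 1e-9, 100 * max(acc_pos, acc_neg))
    }
  })
})

test_that("cluster bootstrap: degenerate, coverage and stability behavior", {
  # constant statistic -> zero-width interval at that value
  recs <- tibble::tibble(sample_id = rep(sprintf("s%d", 1:20), each = 3),
                         x = TRUE, y = TRUE)
  ci <- cluster_bootstrap_ci(recs, "OPA", n_boot = 200, seed = 1)
  expect_equal(as.numeric(ci), c(100, 100))

  # point estimate inside the interval in >= 99% of random configurations
  withr::with_seed(11, {
    hits <- 0
    for (i in 1:100) {
      n <- 30
      x <- stats::runif(n) < 0.6
      y <- ifelse(stats::runif(n) < 0.85, x, !x)
      recs <- tibble::tibble(sample_id = sprintf("s%d", 1:n), x = x, y = y)
      est <- agreement_stats(pairwise_counts(x, y))
      opa <- est$value[est$statistic == "OPA"]
      ci <- cluster_bootstrap_ci(recs, "OPA", n_boot = 200, seed = i)
      hits <- hits + (opa >= ci[1] - 1e-9 && opa <= ci[2] + 1e-9)
    }
    expect_gte(hits, 99)
  })

  # doubling n_boot moves the bounds by < 0.5 points on the internal-study
  # reconstruction
  calls <- tibble::tibble(
    sample_id = rep(sprintf("s%03d", 1:100), each = 3),
    x = c(rep(TRUE, 49 * 3), TRUE, TRUE, FALSE, rep(FALSE, 50 * 3)),
    y = c(rep(TRUE, 49 * 3), TRUE, FALSE, FALSE, rep(FALSE, 50 * 3)))
  ci1 <- cluster_bootstrap_ci(calls, "OPA", n_boot = 1000, seed = 3)
  ci2 <- cluster_bootstrap_ci(calls, "OPA", n_boot = 2000, seed = 3)
  expect_lt(max(abs(ci1 - ci2)), 0.5)
  # deterministic given the seed
  expect_identical(ci1, cluster_bootstrap_ci(calls, "OPA", n_boot = 1000,
                                             seed = 3))
})

test_that("qualification passes at exactly 85% agreement", {
  ref <- rep(c(TRUE, FALSE), 30)
  trainee51 <- ref; trainee51[1:9] <- !trainee51[1:9]
  q <- qualification_check(trainee51, ref)
  expect_true(q$pass)
  expect_equal(q$agreement, 85)
  trainee50 <- ref; trainee50[1:10] <- !trainee50[1:10]
  q2 <- qualification_check(trainee50, ref)
  expect_false(q2$pass)
  expect_equal(round(q2$agreement, 1), 83.3)
  expect_true(qualification_check(ref, ref)$pass)
  expect_error(qualification_check(logical(0), logical(0)), "empty")
})
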