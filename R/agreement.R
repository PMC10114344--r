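# Precision-study and concordance statistics: pairwise APA/ANA/OPA,
# reference-based PPA/NPA, Wilson score and cluster-bootstrap confidence
# intervals, between-/within-reader orchestration, multisite pooling,
# method concordance, and reader qualification.

#' 2x2 concordance counts
#'
#' @param a both positive
#' @param b first only positive
#' @param c second only positive
#' @param d both negative
#' @return object of class `concordance_counts`
#' @export
concordance_counts <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d, total = a + b + c + d),
            class = "concordance_counts")
}

#' @export
print.concordance_counts <- function(x, ...) {
  cat(sprintf("<concordance_counts> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$total))
  invisible(x)
}

#' Tally pairwise concordance counts from two binary call vectors
#'
#' Pairs with a missing entry on either side are dropped; the number dropped
#' is attached as attribute `n_dropped`.
#'
#' @param x,y logical (or 0/1) vectors of positivity calls, equal length;
#'   `y` is the reference when reference-based statistics are computed
#' @return a [concordance_counts()]
#' @export
pairwise_counts <- function(x, y) {
  if (length(x) != length(y)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  x <- as.logical(x); y <- as.logical(y)
  keep <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  out <- concordance_counts(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  attr(out, "n_dropped") <- n_dropped
  out
}

.z_value <- function(confidence) stats::qnorm(1 - (1 - confidence) / 2)

#' Wilson score interval
#'
#' Closed-form binomial confidence interval; bounds stay within
#' \[0, 100\] and behave well at proportions of 0 or 1.
#'
#' @param successes,trials counts, `0 <= successes <= trials`, `trials > 0`
#' @param confidence confidence level (default 0.95)
#' @return named numeric `c(lower, upper)` in percent
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (trials <= 0) stop("trials must be positive", call. = FALSE)
  stopifnot(successes >= 0, successes <= trials)
  z <- .z_value(confidence)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  out <- 100 * c(lower = max(0, center - half), upper = min(1, center + half))
  out
}

#' Half-up decimal rounding
#'
#' Report tables round half-up (so 99.25 prints as 99.3), unlike base R's
#' round-half-even. Raw values are always retained alongside.
#' @param x numeric
#' @param digits decimal places (default 1)
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(abs(x) * m + 0.5) / m * sign(x)
}

.one_estimate <- function(statistic, num, den, confidence, ci_method,
                          threshold = NA_real_) {
  if (den == 0) {
    return(tibble::tibble(statistic = statistic, numerator = num,
                          denominator = den, value = NA_real_,
                          ci_method = ci_method, ci_lower = NA_real_,
                          ci_upper = NA_real_, threshold = threshold,
                          meets_criterion = NA))
  }
  value <- 100 * num / den
  ci <- c(NA_real_, NA_real_)
  if (identical(ci_method, "wilson")) {
    ci <- wilson_interval(num, den, confidence)
  }
  tibble::tibble(statistic = statistic, numerator = num, denominator = den,
                 value = value, ci_method = ci_method, ci_lower = ci[1],
                 ci_upper = ci[2], threshold = threshold,
                 meets_criterion = if (is.na(threshold)) NA else value >= threshold)
}

#' Agreement statistics from concordance counts
#'
#' Computes the chance-unadjusted pairwise statistics
#' `OPA = (a+d)/N`, `APA = 2a/(2a+b+c)`, `ANA = 2d/(2d+b+c)`, and — when the
#' second vector is a designated reference — `PPA = a/(a+c)` over
#' reference positives and `NPA = d/(d+b)` over reference negatives.
#' Values are percentages; report formatting rounds half-up to 1 decimal
#' while raw values are retained.
#'
#' @param counts a [concordance_counts()]
#' @param reference_is_second if `TRUE`, also compute PPA/NPA against the
#'   second (reference) margin
#' @param confidence CI level
#' @param ci_method `"wilson"` or `"none"` (cluster-bootstrap intervals need
#'   per-sample records; see [cluster_bootstrap_ci()])
#' @param thresholds optional named vector of acceptance thresholds in
#'   percent (e.g. `c(APA = 85, ANA = 85, OPA = 90)`)
#' @return tibble, one row per statistic; a zero denominator yields an
#'   undefined (NA) value rather than an error
#' @export
agreement_stats <- function(counts, reference_is_second = FALSE,
                            confidence = 0.95,
                            ci_method = c("wilson", "none"),
                            thresholds = NULL) {
  stopifnot(inherits(counts, "concordance_counts"))
  ci_method <- match.arg(ci_method)
  a <- counts$a; b <- counts$b; cc <- counts$c; d <- counts$d
  thr <- function(s) if (!is.null(thresholds) && s %in% names(thresholds))
    thresholds[[s]] else NA_real_
  rows <- list(
    .one_estimate("APA", 2 * a, 2 * a + b + cc, confidence, ci_method, thr("APA")),
    .one_estimate("ANA", 2 * d, 2 * d + b + cc, confidence, ci_method, thr("ANA")),
    .one_estimate("OPA", a + d, a + b + cc + d, confidence, ci_method, thr("OPA")))
  if (reference_is_second) {
    rows <- c(rows, list(
      .one_estimate("PPA", a, a + cc, confidence, ci_method, thr("PPA")),
      .one_estimate("NPA", d, d + b, confidence, ci_method, thr("NPA"))))
  }
  dplyr::bind_rows(rows)
}

# ---- reader score matrices --------------------------------------------------

#' Assemble a reader score matrix
#'
#' Long-format container for precision studies: one row per
#' (sample, reader, round) with the TAP score and/or the binary call.
#' When both are present the call must equal `tap_percent >= cutoff`.
#'
#' @param scores data frame with columns sample_id, reader_id, round, and
#'   `tap_percent` and/or `status` (logical positive call); optional `site`
#' @param cutoff cutoff used to derive `status` from `tap_percent` where
#'   absent
#' @return tibble of class `reader_score_matrix` (attribute `cutoff`)
#' @export
reader_score_matrix <- function(scores, cutoff = 5) {
  scores <- tibble::as_tibble(scores)
  required <- c("sample_id", "reader_id", "round")
  missing <- setdiff(required, names(scores))
  if (length(missing) > 0) {
    stop("reader scores missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"status" %in% names(scores)) {
    if (!"tap_percent" %in% names(scores)) {
      stop("need tap_percent or status", call. = FALSE)
    }
    scores$status <- scores$tap_percent >= cutoff
  } else if ("tap_percent" %in% names(scores)) {
    bad <- which(!is.na(scores$tap_percent) & !is.na(scores$status) &
                   scores$status != (scores$tap_percent >= cutoff))
    if (length(bad) > 0) {
      stop("status inconsistent with tap_percent at cutoff for row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (!"site" %in% names(scores)) scores$site <- NA_character_
  structure(scores, class = c("reader_score_matrix", class(scores)),
            cutoff = cutoff)
}

# per-sample pairwise records for round-1 reads across all unordered reader
# pairs: one row per (sample, pair) with the two calls
.between_reader_records <- function(m) {
  r1 <- m[m$round == 1, ]
  readers <- sort(unique(r1$reader_id))
  if (length(readers) < 2) {
    stop("between-reader precision needs at least 2 readers", call. = FALSE)
  }
  wide <- split(r1, r1$sample_id)
  recs <- list()
  for (sid in names(wide)) {
    s <- wide[[sid]]
    calls <- stats::setNames(s$status, s$reader_id)
    for (i in seq_along(readers)) {
      for (j in seq_along(readers)) {
        if (i < j && readers[i] %in% names(calls) &&
            readers[j] %in% names(calls)) {
          recs[[length(recs) + 1]] <- tibble::tibble(
            sample_id = sid, x = calls[[readers[i]]],
            y = calls[[readers[j]]])
        }
      }
    }
  }
  dplyr::bind_rows(recs)
}

.within_reader_records <- function(m) {
  rounds <- sort(unique(m$round))
  if (length(rounds) < 2) {
    stop("within-reader precision needs 2 rounds per reader", call. = FALSE)
  }
  recs <- list()
  for (rd in unique(m$reader_id)) {
    s1 <- m[m$reader_id == rd & m$round == rounds[1], ]
    s2 <- m[m$reader_id == rd & m$round == rounds[2], ]
    common <- intersect(s1$sample_id, s2$sample_id)
    if (length(common) == 0) {
      stop("reader ", rd, " is missing a round", call. = FALSE)
    }
    recs[[length(recs) + 1]] <- tibble::tibble(
      sample_id = common, reader_id = rd,
      x = s1$status[match(common, s1$sample_id)],
      y = s2$status[match(common, s2$sample_id)])
  }
  dplyr::bind_rows(recs)
}

.precision_report <- function(records, thresholds, confidence, ci_method,
                              n_boot, seed) {
  counts <- pairwise_counts(records$x, records$y)
  stats_tbl <- agreement_stats(
    counts, confidence = confidence,
    ci_method = if (ci_method == "wilson") "wilson" else "none",
    thresholds = thresholds)
  if (ci_method == "cluster_bootstrap") {
    for (s in stats_tbl$statistic) {
      ci <- cluster_bootstrap_ci(records, s, n_boot = n_boot, seed = seed,
                                 confidence = confidence)
      stats_tbl$ci_lower[stats_tbl$statistic == s] <- ci[1]
      stats_tbl$ci_upper[stats_tbl$statistic == s] <- ci[2]
      stats_tbl$ci_method[stats_tbl$statistic == s] <- "cluster_bootstrap"
    }
  }
  list(counts = counts, statistics = stats_tbl,
       n_pairs = counts$total, n_dropped = attr(counts, "n_dropped"))
}

#' Between-reader precision
#'
#' Pools every unordered reader pair's round-1 calls across samples into one
#' set of concordance counts (with 3 readers and N samples this yields 3N
#' pairwise comparisons), then computes APA/ANA/OPA with confidence
#' intervals and acceptance flags (APA >= 85%, ANA >= 85%).
#'
#' @param m a [reader_score_matrix()]
#' @param confidence CI level
#' @param ci_method `"wilson"` or `"cluster_bootstrap"` (samples are the
#'   resampling clusters)
#' @param n_boot,seed bootstrap controls (used when
#'   `ci_method = "cluster_bootstrap"`)
#' @return list: counts, statistics (tibble), n_pairs, n_dropped
#' @export
between_reader_precision <- function(m, confidence = 0.95,
                                     ci_method = c("wilson", "cluster_bootstrap"),
                                     n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  records <- .between_reader_records(m)
  .precision_report(records, c(APA = 85, ANA = 85), confidence, ci_method,
                    n_boot, seed)
}

#' Within-reader precision
#'
#' For each reader, pairs the round-1 and round-2 calls on the same samples;
#' pairs are pooled across readers. Acceptance flags: OPA >= 90%,
#' APA >= 85%, ANA >= 85%. A per-reader breakdown is included.
#'
#' @inheritParams between_reader_precision
#' @return list: counts, statistics, per_reader, n_pairs, n_dropped
#' @export
within_reader_precision <- function(m, confidence = 0.95,
                                    ci_method = c("wilson", "cluster_bootstrap"),
                                    n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  records <- .within_reader_records(m)
  rep <- .precision_report(records, c(APA = 85, ANA = 85, OPA = 90),
                           confidence, ci_method, n_boot, seed)
  rep$per_reader <- dplyr::bind_rows(lapply(split(records, records$reader_id),
    function(s) {
      cts <- pairwise_counts(s$x, s$y)
      tibble::tibble(reader_id = s$reader_id[1],
                     opa = 100 * (cts$a + cts$d) / cts$total,
                     n_pairs = cts$total)
    }))
  rep
}

#' Pool site-level results
#'
#' Sums the site-level concordance counts and recomputes the statistics on
#' the pooled counts (pooling, not averaging of site percentages).
#'
#' @param site_reports list of precision reports (each with a `counts`
#'   element) or of `concordance_counts`
#' @param confidence CI level
#' @return list: counts, statistics, n_pairs
#' @export
multisite_pool <- function(site_reports, confidence = 0.95) {
  if (length(site_reports) == 0) stop("no site reports", call. = FALSE)
  get_counts <- function(r) if (inherits(r, "concordance_counts")) r else r$counts
  cts <- lapply(site_reports, get_counts)
  pooled <- concordance_counts(sum(vapply(cts, `[[`, numeric(1), "a")),
                               sum(vapply(cts, `[[`, numeric(1), "b")),
                               sum(vapply(cts, `[[`, numeric(1), "c")),
                               sum(vapply(cts, `[[`, numeric(1), "d")))
  list(counts = pooled,
       statistics = agreement_stats(pooled, confidence = confidence,
                                    thresholds = c(APA = 85, ANA = 85)),
       n_pairs = pooled$total)
}

#' Concordance between TAP and CPS calls
#'
#' Dichotomizes paired TAP and CPS results and computes PPA/NPA/OPA with
#' CPS as the reference, with Wilson intervals.
#'
#' @param tap_scores numeric TAP percentages, or list of `tap_result`
#' @param cps_scores numeric CPS values, or list of `cps_result` (invalid
#'   results become NA and the pair is dropped)
#' @param tap_cutoff TAP positivity cutoff (1 or 5 conventionally)
#' @param cps_cutoff CPS positivity cutoff (conventionally 1)
#' @param confidence CI level
#' @return list: counts, statistics, n_pairs, n_dropped
#' @export
method_concordance <- function(tap_scores, cps_scores, tap_cutoff = 1,
                               cps_cutoff = 1, confidence = 0.95) {
  if (is.list(tap_scores) && length(tap_scores) > 0 &&
      inherits(tap_scores[[1]], "tap_result")) {
    tap_scores <- vapply(tap_scores, `[[`, numeric(1), "tap_percent")
  }
  if (is.list(cps_scores) && length(cps_scores) > 0 &&
      inherits(cps_scores[[1]], "cps_result")) {
    cps_scores <- vapply(cps_scores, function(r)
      if (r$valid) r$cps else NA_real_, numeric(1))
  }
  if (length(tap_scores) != length(cps_scores)) {
    stop("TAP and CPS results must be paired on the same samples",
         call. = FALSE)
  }
  counts <- pairwise_counts(tap_scores >= tap_cutoff, cps_scores >= cps_cutoff)
  list(counts = counts,
       statistics = agreement_stats(counts, reference_is_second = TRUE,
                                    confidence = confidence),
       n_pairs = counts$total, n_dropped = attr(counts, "n_dropped"))
}

#' Cluster bootstrap confidence interval for an agreement statistic
#'
#' Case-resampling percentile interval with samples as the clusters: each
#' bootstrap replicate resamples sample ids with replacement, keeping all
#' pairwise comparisons belonging to a sample together. Replicates in which
#' the statistic's denominator is zero are dropped (count logged as
#' attribute `n_degenerate`). Deterministic for a fixed seed.
#'
#' @param records tibble with columns sample_id, x, y (one row per pairwise
#'   comparison)
#' @param statistic one of `"APA"`, `"ANA"`, `"OPA"`, `"PPA"`, `"NPA"`
#' @param n_boot number of bootstrap replicates (>= 1000 recommended)
#' @param seed integer seed
#' @param confidence CI level
#' @return numeric `c(lower, upper)` in percent
#' @export
cluster_bootstrap_ci <- function(records, statistic, n_boot = 2000,
                                 seed = 1L, confidence = 0.95) {
  stopifnot(statistic %in% c("APA", "ANA", "OPA", "PPA", "NPA"),
            n_boot >= 1)
  ids <- unique(records$sample_id)
  by_sample <- split(seq_len(nrow(records)), records$sample_id)
  stat_fun <- function(rows) {
    cts <- pairwise_counts(records$x[rows], records$y[rows])
    a <- cts$a; b <- cts$b; cc <- cts$c; d <- cts$d
    switch(statistic,
           APA = if (2 * a + b + cc == 0) NA_real_ else 200 * a / (2 * a + b + cc),
           ANA = if (2 * d + b + cc == 0) NA_real_ else 200 * d / (2 * d + b + cc),
           OPA = if (cts$total == 0) NA_real_ else 100 * (a + d) / cts$total,
           PPA = if (a + cc == 0) NA_real_ else 100 * a / (a + cc),
           NPA = if (d + b == 0) NA_real_ else 100 * d / (d + b))
  }
  vals <- withr::with_seed(seed, {
    replicate(n_boot, {
      pick <- sample(ids, length(ids), replace = TRUE)
      stat_fun(unlist(by_sample[pick], use.names = FALSE))
    })
  })
  degenerate <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  alpha <- 1 - confidence
  out <- unname(stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), type = 7))
  out <- c(lower = out[1], upper = out[2])
  attr(out, "n_degenerate") <- degenerate
  out
}

#' Reader qualification check
#'
#' Pass/fail on overall agreement of a trainee's binary calls against
#' reference calls: pass iff agreement >= threshold (85% by convention; for
#' a 60-case test, 51/60 = 85% passes).
#'
#' @param trainee,reference equal-length binary call vectors
#' @param threshold pass proportion (default 0.85)
#' @return list: pass, agreement (percent), n_agree, n_total
#' @export
qualification_check <- function(trainee, reference, threshold = 0.85) {
  if (length(trainee) == 0) stop("empty call vectors", call. = FALSE)
  if (length(trainee) != length(reference)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  agree <- sum(as.logical(trainee) == as.logical(reference))
  prop <- agree / length(trainee)
  list(pass = prop >= threshold, agreement = 100 * prop,
       n_agree = agree, n_total = length(trainee))
}
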