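# Haplotype-dosage scan, permutation thresholds, support intervals.

scan_fixture <- function(seed = 50, n_lines = 30) {
  panel <- simulate_cc_panel(n_lines, c(40, 40), c(70, 70),
                             error_rate = 0.005, seed = seed)
  probs <- reconstruct_descent(panel$genotypes, panel$founders)
  ids <- names(panel$mosaics)
  set.seed(seed + 1)
  list(panel = panel, probs = probs,
       y = stats::setNames(rnorm(n_lines), ids),
       w = stats::setNames(sample(4:7, n_lines, TRUE), ids))
}

test_that("every interval's LogP matches an independent WLS oracle", {
  fx <- scan_fixture()
  sc <- scan_genome(fx$y, fx$w, fx$probs)
  for (m in seq_len(nrow(sc))) {
    P <- fx$probs$prob[, m, ]
    expect_lt(abs(sc$LogP[m] -
                    oracle_interval_logp(unname(fx$y), unname(fx$w), P)),
              1e-8)
  }
  expect_true(all(sc$LogP >= 0 & sc$LogP <= 300))
})

test_that("the scan is invariant to founder relabeling and weight scaling", {
  fx <- scan_fixture(seed = 51)
  sc <- scan_genome(fx$y, fx$w, fx$probs)

  perm <- sample(8)
  probs2 <- fx$probs
  probs2$prob <- probs2$prob[, , perm]
  expect_equal(scan_genome(fx$y, fx$w, probs2)$LogP, sc$LogP,
               tolerance = 1e-9)

  expect_equal(scan_genome(fx$y, fx$w * 10, fx$probs)$LogP, sc$LogP,
               tolerance = 1e-9)

  # equal weights reduce WLS to OLS
  w1 <- stats::setNames(rep(1, length(fx$y)), names(fx$y))
  sc_ols <- scan_genome(fx$y, w1, fx$probs)
  for (m in seq(1, nrow(sc_ols), by = 7)) {
    P <- fx$probs$prob[, m, ]
    f1 <- stats::lm(unname(fx$y) ~ P)
    f0 <- stats::lm(unname(fx$y) ~ 1)
    p <- stats::anova(f0, f1)$`Pr(>F)`[2]
    expect_equal(sc_ols$LogP[m], -log10(p), tolerance = 1e-8)
  }
})

test_that("degenerate scans are handled: constant trait, tiny panels", {
  fx <- scan_fixture(seed = 52, n_lines = 12)
  yc <- stats::setNames(rep(1, 12), names(fx$y))
  expect_warning(sc <- scan_genome(yc, fx$w, fx$probs), "zero-variance")
  expect_true(all(sc$LogP == 0))
  expect_error(scan_genome(fx$y[1:8], fx$w[1:8],
                           structure(list(prob = fx$probs$prob[1:8, , ],
                                          map = fx$probs$map),
                                     class = "cc_descent")),
               class = "ccqg_invalid_argument")
})

test_that("detection power increases with planted QTL effect size", {
  panel <- simulate_cc_panel(50, c(60, 60), c(70, 70), seed = 53)
  probs <- true_descent(panel$mosaics, panel$founders$map)
  ids <- names(panel$mosaics)
  qmark <- 30   # marker index of the planted QTL
  allele <- panel$founders$alleles[, qmark]
  f1 <- vapply(panel$mosaics, function(m)
    ccqg:::mosaic_founder_at(m, panel$founders$map$chr[qmark],
                             panel$founders$map$cM[qmark], 1L), integer(1))
  w <- stats::setNames(rep(5, 50), ids)
  set.seed(54)
  peak_lp <- vapply(c(0, 0.8, 2), function(eff) {
    mean(vapply(1:8, function(r) {
      y <- stats::setNames(eff * allele[f1] + rnorm(50), ids)
      max(scan_genome(y, w, probs)$LogP)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(peak_lp) > 0))
})

test_that("permutation thresholds follow the order-statistic and add-one rules", {
  fx <- scan_fixture(seed = 55, n_lines = 20)
  pm <- permutation_threshold(fx$y, fx$w, fx$probs, n_perm = 120,
                              alpha = c(0.05, 0.1, 0.5), seed = 9)
  expect_length(pm$max_logp, 120)
  expect_true(pm$thresholds[1] >= pm$thresholds[2])
  expect_true(pm$thresholds[2] >= pm$thresholds[3])
  srt <- sort(pm$max_logp)
  expect_equal(unname(pm$thresholds[1]), srt[ceiling(0.95 * 120)])

  # observed peak above all permutation maxima -> P = 1/(n_perm + 1)
  expect_equal(permuted_p(pm, max(pm$max_logp) + 1), 1 / 121)
  expect_equal(permuted_p(pm, -1), 1)
  # reproducible under the same seed
  pm2 <- permutation_threshold(fx$y, fx$w, fx$probs, n_perm = 120,
                               alpha = c(0.05, 0.1, 0.5), seed = 9)
  expect_identical(pm$max_logp, pm2$max_logp)

  expect_error(permutation_threshold(fx$y, fx$w, fx$probs, n_perm = 50),
               class = "ccqg_invalid_argument")
})

fake_scan <- function(logp, chr = rep("1", length(logp))) {
  structure(data.frame(marker = sprintf("m%d", seq_along(logp)),
                       chr = chr,
                       bp_start = seq(0, by = 1000L,
                                      length.out = length(logp)),
                       bp_end = seq(1000L, by = 1000L,
                                    length.out = length(logp)),
                       cM = seq_along(logp), LogP = logp,
                       df = 7L, flagged = FALSE, stringsAsFactors = FALSE),
            class = c("cc_scan", "data.frame"))
}

test_that("LogP-1 support intervals are maximal contiguous runs", {
  sc <- fake_scan(c(0, 2, 4.5, 5, 4.2, 1))
  q <- define_qtl_interval(sc, 4L)
  expect_equal(q$members, sprintf("m%d", 3:5))
  expect_equal(q$bp_start, 2000L)
  expect_equal(q$bp_end, 5000L)

  spike <- define_qtl_interval(fake_scan(c(0, 0, 5, 0, 0)), 3L)
  expect_equal(spike$members, "m3")

  expect_error(define_qtl_interval(sc, 99L), class = "ccqg_invalid_argument")

  # exhaustive contiguous-run oracle on random profiles
  set.seed(56)
  for (r in 1:100) {
    lp <- round(runif(12, 0, 6), 2)
    peak <- which.max(lp)
    got <- define_qtl_interval(fake_scan(lp), peak)
    want <- oracle_support_interval(lp, peak)
    expect_equal(match(got$members[1], sprintf("m%d", 1:12)), want[1])
    expect_equal(match(got$members[length(got$members)],
                       sprintf("m%d", 1:12)), want[2])
  }
})
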