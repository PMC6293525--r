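# HMM genome reconstruction: forward-backward posteriors, Viterbi,
# pruning, founder contributions.

test_that("forward-backward equals brute-force path enumeration", {
  set.seed(20)
  for (rep in 1:3) {
    m <- 5L
    alleles <- matrix(rbinom(8 * m, 1, 0.5), nrow = 8,
                      dimnames = list(LETTERS[1:8], sprintf("m%d", 1:m)))
    map <- genetic_map(sprintf("m%d", 1:m), rep("1", m),
                       bp = seq(1e5, 5e5, length.out = m),
                       cM = cumsum(c(0, runif(m - 1, 0.5, 8))))
    fh <- structure(list(map = map, alleles = alleles,
                         founders = LETTERS[1:8]),
                    class = "founder_haplotypes")
    calls <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE)
    geno <- structure(list(map = map,
                           calls = matrix(calls, 1, m,
                                          dimnames = list("l1", map$marker))),
                      class = "cc_geno")
    pars <- hmm_params(error_rate = 0.05, expansion = 2)
    pr <- reconstruct_descent(geno, fh, pars)
    oracle <- oracle_hmm_posterior(calls, alleles, diff(map$cM),
                                   a = 2, eps = 0.05)
    expect_equal(unname(pr$prob[1, , ]), oracle, tolerance = 1e-10)
  }
})

test_that("uninformative data returns the uniform prior", {
  fh <- simulate_founders(c(20L), c(50), seed = 21)
  geno <- structure(list(map = fh$map,
                         calls = matrix(NA_integer_, 1, 20,
                                        dimnames = list("l1", fh$map$marker))),
                    class = "cc_geno")
  pr <- reconstruct_descent(geno, fh)
  expect_equal(unname(pr$prob[1, , ]), matrix(1 / 8, 20, 8))
})

test_that("single informative marker reproduces the hand Bayes posterior", {
  # founder 3 uniquely carries the alternate allele; observed call 2
  alleles <- matrix(0L, 8, 1, dimnames = list(LETTERS[1:8], "m1"))
  alleles[3, 1] <- 1L
  map <- genetic_map("m1", "1", 1000L, 0)
  fh <- structure(list(map = map, alleles = alleles, founders = LETTERS[1:8]),
                  class = "founder_haplotypes")
  geno <- structure(list(map = map,
                         calls = matrix(2L, 1, 1,
                                        dimnames = list("l1", "m1"))),
                    class = "cc_geno")
  eps <- 0.01
  pr <- reconstruct_descent(geno, fh, hmm_params(error_rate = eps))
  # Bayes: P(f=3 | call 2) = (1-eps) / ((1-eps) + 7 * eps/2)
  hand <- c(rep(eps / 2, 8)); hand[3] <- 1 - eps
  hand <- hand / sum(hand)
  expect_equal(unname(pr$prob[1, 1, ]), hand, tolerance = 1e-12)
  expect_equal(unname(which.max(pr$prob[1, 1, ])), 3L)
})

test_that("posteriors normalize and are equivariant under founder relabeling", {
  panel <- make_small_panel(n_lines = 6, n_markers = c(80, 80), seed = 22,
                            error_rate = 0.01)
  pr <- reconstruct_descent(panel$genotypes, panel$founders)
  expect_true(all(abs(apply(pr$prob, c(1, 2), sum) - 1) < 1e-8))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))

  # permute founder labels: posteriors permute identically
  perm <- c(3L, 1L, 4L, 2L, 8L, 6L, 5L, 7L)
  fh2 <- panel$founders
  fh2$alleles <- fh2$alleles[perm, , drop = FALSE]
  pr2 <- reconstruct_descent(panel$genotypes, fh2)
  expect_equal(unname(pr2$prob), unname(pr$prob[, , perm]),
               tolerance = 1e-12)
})

test_that("reconstruction accuracy improves with markers, degrades with error", {
  set.seed(23)
  accuracy <- function(n_mark, eps_geno, eps_hmm = max(eps_geno, 0.01)) {
    panel <- simulate_cc_panel(8, n_mark, 100, error_rate = eps_geno,
                               seed = 1000 + n_mark + round(1e4 * eps_geno))
    pr <- reconstruct_descent(panel$genotypes, panel$founders,
                              hmm_params(error_rate = eps_hmm),
                              viterbi = TRUE)
    mean(vapply(seq_along(panel$mosaics), function(l) {
      fm <- ccqg:::mosaic_founders_matrix(panel$mosaics[[l]],
                                          panel$founders$map)
      mean(pr$viterbi[l, ] == fm[, 1] | pr$viterbi[l, ] == fm[, 2])
    }, numeric(1)))
  }
  dens <- vapply(c(25L, 100L, 400L), accuracy, numeric(1), eps_geno = 0.01)
  expect_true(all(diff(dens) > -0.02))
  errs <- vapply(c(0, 0.05, 0.2), function(e) accuracy(150L, e), numeric(1))
  expect_true(all(diff(errs) < 0.02))
})

test_that("pruning keeps even cM spacing and preserves contributions", {
  # array-like map: evenly spaced markers, halved to the target density
  set.seed(24)
  m_per <- 220L
  mk <- function(ch, off) data.frame(
    marker = sprintf("c%s_%03d", ch, seq_len(m_per)), chr = ch,
    bp_start = seq(0L, by = 1000L, length.out = m_per) + off,
    bp_end = seq(1000L, by = 1000L, length.out = m_per) + off,
    cM = seq(0, by = 0.4, length.out = m_per), stringsAsFactors = FALSE)
  map <- rbind(mk("1", 0L), mk("2", 0L))
  prob <- array(0, c(6, 2L * m_per, 8),
                dimnames = list(paste0("L", 1:6), map$marker, NULL))
  for (l in 1:6) {
    # segment-like founder labels (runs of 40 markers)
    f <- rep(sample.int(8, ceiling(2L * m_per / 40), TRUE),
             each = 40)[seq_len(2L * m_per)]
    prob[cbind(l, seq_len(2L * m_per), f)] <- 1
  }
  pr <- structure(list(prob = prob, map = map), class = "cc_descent")

  expect_identical(prune_intervals(pr, nrow(pr$map)), pr)
  expect_error(prune_intervals(pr, 1L), class = "ccqg_invalid_argument")

  half <- prune_intervals(pr, 240L)
  expect_lte(nrow(half$map), 252L)
  for (ch in unique(pr$map$chr)) {
    orig <- pr$map$cM[pr$map$chr == ch]
    kept <- half$map$cM[half$map$chr == ch]
    expect_equal(kept[1], orig[1])
    expect_equal(kept[length(kept)], orig[length(orig)])
    # every retained gap at most twice the median original spacing
    expect_lte(max(diff(kept)), 2 * stats::median(diff(orig)) + 1e-9)
  }
  expect_true(all(abs(apply(half$prob, c(1, 2), sum) - 1) < 1e-8))
  expect_lt(max(abs(founder_contributions(half)$overall -
                      founder_contributions(pr)$overall)), 0.01)
})

test_that("founder contributions summarize descent probabilities", {
  L <- 5; m <- 12
  map <- data.frame(marker = sprintf("m%d", 1:m), chr = "1",
                    bp_start = seq(0, by = 100L, length.out = m),
                    bp_end = seq(100L, by = 100L, length.out = m),
                    cM = seq(0, 11), stringsAsFactors = FALSE)
  unif <- structure(list(prob = array(1 / 8, c(L, m, 8)), map = map),
                    class = "cc_descent")
  fc <- founder_contributions(unif)
  expect_equal(fc$overall, rep(0.125, 8))
  expect_false(any(fc$absent))

  onehot <- array(0, c(2, m, 8))
  onehot[1, , 1] <- 1; onehot[2, , 2] <- 1
  oh <- structure(list(prob = onehot, map = map), class = "cc_descent")
  fc2 <- founder_contributions(oh)
  expect_equal(unname(fc2$overall[1]), 0.5)
  expect_true(all(fc2$absent[, 3]))
  # per-line share of an all-founder-1 line
  expect_equal(mean(onehot[1, , 1]), 1)
})
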