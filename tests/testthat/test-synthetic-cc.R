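# Synthetic CC population generator: founders, funnel breeding,
# genotyping noise, phenotype construction.

test_that("simulate_founders draws binomial alleles on a valid map", {
  # empty marker set is a valid object
  fh0 <- simulate_founders(c(0L, 0L), c(50, 50), seed = 1)
  expect_s3_class(fh0$map, "cc_map")
  expect_equal(nrow(fh0$map), 0L)
  expect_equal(ncol(fh0$alleles), 0L)

  # allele frequency within 3 binomial SD of the target
  fh <- simulate_founders(10000L, 100, allele_freq = 0.5, seed = 2)
  n_draw <- length(fh$alleles)
  expect_lt(abs(mean(fh$alleles) - 0.5), 3 * sqrt(0.25 / n_draw))
  expect_true(all(fh$alleles %in% c(0L, 1L)))
  expect_true(all(diff(fh$map$cM) >= 0))

  # determinism under a fixed seed
  expect_identical(simulate_founders(c(30, 30), c(60, 60), seed = 7),
                   simulate_founders(c(30, 30), c(60, 60), seed = 7))

  expect_error(simulate_founders(c(10), c(-1)), class = "ccqg_invalid_argument")
  expect_error(simulate_founders(c(-5), c(50)), class = "ccqg_invalid_argument")
  expect_error(simulate_founders(c(10), c(50), allele_freq = 1),
               class = "ccqg_invalid_argument")
})

test_that("breeding produces tiling mosaics with conserved founder shares", {
  fh <- simulate_founders(c(40, 40), c(90, 70), seed = 3)
  for (i in 1:15) {
    mos <- breed_cc_line(fh, seed = 100 + i)
    sh <- mosaic_founder_shares(mos)
    expect_equal(sum(sh), 1, tolerance = 1e-12)
    expect_true(all(sh >= 0))
    # segments tile each chromosome exactly
    for (hap in 1:2) for (ci in 1:2) {
      h <- mos$haplotypes[[hap]][[ci]]
      expect_equal(h$b[length(h$b)], unname(mos$chr_len[ci]))
      expect_true(all(diff(c(0, h$b)) > 0))
      expect_true(all(h$f %in% 1:8))
    }
  }
  expect_error(breed_cc_line(fh, funnel = c(1:7, 7)),
               class = "ccqg_invalid_argument")
})

test_that("a chromosome of negligible length is a single founder segment", {
  fh <- simulate_founders(c(1L, 1L), c(1e-9, 1e-9), seed = 4)
  mos <- breed_cc_line(fh, seed = 5)
  for (hap in 1:2) for (ci in 1:2)
    expect_length(mos$haplotypes[[hap]][[ci]]$f, 1L)
  expect_equal(sum(mosaic_founder_shares(mos)), 1)
})

test_that("heterozygosity decreases with inbreeding generations", {
  fh <- simulate_founders(c(2L), c(100), seed = 6)
  set.seed(60)
  het <- vapply(c(0L, 4L, 12L, 20L), function(g)
    mean(vapply(1:40, function(i)
      mosaic_heterozygosity(breed_cc_line(fh, n_inbreeding_gens = g)),
      numeric(1))), numeric(1))
  expect_true(all(diff(het) < 0))
  expect_lt(het[4], 0.05)   # F20 lines are near fully inbred
})

test_that("junction density matches a discrete-locus pedigree oracle", {
  # same pedigree structure simulated two independent ways: continuous
  # segments (package) vs founder labels at dense fixed loci (oracle)
  n_lines <- 120
  len <- 100
  n_loci <- 201
  pos <- seq(0, len, length.out = n_loci)
  r_adj <- (1 - exp(-2 * diff(pos)[1] / 100)) / 2
  fh <- simulate_founders(c(2L), len, seed = 8)

  set.seed(81)
  j_seg <- vapply(1:n_lines, function(i) {
    mos <- breed_cc_line(fh, n_inbreeding_gens = 6L)
    f <- ccqg:::mosaic_founder_at(mos, "1", pos, hap = 1L)
    count_junctions(f)
  }, numeric(1))

  set.seed(82)
  j_loc <- vapply(1:n_lines, function(i) {
    ind <- oracle_locus_line(sample.int(8), r_adj, n_loci, n_inbreed = 6L)
    count_junctions(ind[1, ])
  }, numeric(1))

  sem <- sqrt(stats::var(j_seg) / n_lines + stats::var(j_loc) / n_lines)
  expect_lt(abs(mean(j_seg) - mean(j_loc)), 3 * sem)
})

test_that("genotyping applies the stated noise model", {
  fh <- simulate_founders(c(5000L), c(120), seed = 9)
  mos <- breed_cc_line(fh, seed = 10, n_inbreeding_gens = 3L)
  # force full homozygosity so the noiseless truth is 2 x founder allele
  mos$haplotypes[[2]] <- mos$haplotypes[[1]]

  clean <- genotype_line(mos, fh, seed = 11)
  f1 <- ccqg:::mosaic_founder_at(mos, fh$map$chr, fh$map$cM, 1L)
  truth <- 2L * fh$alleles[cbind(f1, seq_len(nrow(fh$map)))]
  expect_identical(unname(clean), truth)

  expect_true(all(is.na(genotype_line(mos, fh, missing_rate = 1, seed = 12))))

  noisy <- genotype_line(mos, fh, error_rate = 0.05, seed = 13)
  frac <- mean(noisy != truth)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(truth)))

  fh2 <- simulate_founders(c(10L), c(50), seed = 14)
  expect_error(genotype_line(mos, fh2), class = "ccqg_inconsistent_input")
})

test_that("phenotype simulation honors its degenerate and variance contracts", {
  panel <- make_small_panel(n_lines = 10, n_markers = c(30, 30), seed = 15)
  K <- diag(10)
  rownames(K) <- colnames(K) <- names(panel$mosaics)

  # no genetics, no noise, no covariate effects -> identical animals
  ph0 <- simulate_phenotypes(panel$mosaics, K,
                             qtl_spec(sigma_g2 = 0, sigma_e2 = 0),
                             n_per_line = 4, seed = 16)
  expect_equal(stats::sd(ph0$trait), 0)

  # line variance only -> zero within-line variance, broad-sense H2 = 1
  ph1 <- simulate_phenotypes(panel$mosaics, K,
                             qtl_spec(sigma_g2 = 2, sigma_e2 = 0),
                             n_per_line = 4, seed = 17)
  expect_equal(anova_broad_h2(ph1$trait, ph1$line)$H2, 1)

  # non-PSD kinship rejected when genetic variance requested
  bad <- K; bad[1, 2] <- bad[2, 1] <- 2
  expect_error(simulate_phenotypes(panel$mosaics, bad,
                                   qtl_spec(sigma_g2 = 1), seed = 18),
               class = "ccqg_invalid_argument")

  expect_equal(attr(ph1, "true_h2"), 1)
})

test_that("between/within line variance matches sigma_g2 / sigma_e2", {
  L <- 150; npl <- 6
  mos <- lapply(seq_len(L), function(i)
    structure(list(line = paste0("L", i), funnel = 1:8, chr = "1",
                   chr_len = c("1" = 100),
                   haplotypes = list(list(list(b = 100, f = 1L)),
                                     list(list(b = 100, f = 1L)))),
              class = "cc_mosaic"))
  K <- diag(L); rownames(K) <- colnames(K) <- paste0("L", seq_len(L))
  ph <- simulate_phenotypes(mos, K, qtl_spec(sigma_g2 = 2, sigma_e2 = 1),
                            n_per_line = npl, seed = 19)
  within <- mean(tapply(ph$trait, ph$line, stats::var))
  between <- stats::var(tapply(ph$trait, ph$line, mean)) - within / npl
  expect_lt(abs(within - 1), 0.3)
  expect_lt(abs(between - 2), 0.6)
})
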