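# Independent oracles used to check the package's implementations.
# They share no code with the routines they verify.

# --- brute-force HMM posterior by path enumeration (<= 8 markers) -----

# emission: P(call | founder) with the same convention as the model
oracle_emission <- function(calls, alleles, eps) {
  m <- length(calls)
  e <- matrix(1, m, 8)
  for (j in seq_len(m)) {
    if (is.na(calls[j])) next
    for (f in 1:8)
      e[j, f] <- if (calls[j] == 2 * alleles[f, j]) 1 - eps else eps / 2
  }
  e
}

oracle_hmm_posterior <- function(calls, alleles, d_cm, a, eps,
                                 init = rep(1 / 8, 8)) {
  m <- length(calls)
  e <- oracle_emission(calls, alleles, eps)
  r <- pmin((1 - exp(-a * d_cm / 50)) / 2, 7 / 8)
  paths <- as.matrix(expand.grid(rep(list(1:8), m)))
  pr <- init[paths[, 1]] * e[cbind(1, paths[, 1])]
  if (m > 1) for (j in 2:m) {
    stay <- paths[, j] == paths[, j - 1]
    pr <- pr * ifelse(stay, 1 - r[j - 1], r[j - 1] / 7) *
      e[cbind(j, paths[, j])]
  }
  post <- matrix(0, m, 8)
  for (j in seq_len(m)) for (f in 1:8)
    post[j, f] <- sum(pr[paths[, j] == f])
  post / rowSums(post)
}

# --- discrete-locus pedigree simulator (junction-count oracle) --------

# founder labels at fixed loci; recombination between adjacent loci by
# Haldane map function, crossed through the same funnel + sib pedigree
oracle_locus_gamete <- function(ind, r_adj) {
  m <- ncol(ind)
  src <- integer(m)
  src[1] <- sample.int(2, 1)
  if (m > 1) {
    sw <- stats::runif(m - 1) < r_adj
    for (j in 2:m) src[j] <- if (sw[j - 1]) 3 - src[j - 1] else src[j - 1]
  }
  ind[cbind(src, seq_len(m))]
}

oracle_locus_line <- function(funnel, r_adj, n_loci, n_inbreed) {
  mk <- function(f) rbind(rep(f, n_loci), rep(f, n_loci))
  g1 <- list(rbind(rep(funnel[1], n_loci), rep(funnel[2], n_loci)),
             rbind(rep(funnel[3], n_loci), rep(funnel[4], n_loci)),
             rbind(rep(funnel[5], n_loci), rep(funnel[6], n_loci)),
             rbind(rep(funnel[7], n_loci), rep(funnel[8], n_loci)))
  cross2 <- function(a, b) rbind(oracle_locus_gamete(a, r_adj),
                                 oracle_locus_gamete(b, r_adj))
  b1 <- cross2(g1[[1]], g1[[2]])
  b2 <- cross2(g1[[3]], g1[[4]])
  s1 <- cross2(b1, b2)
  s2 <- cross2(b1, b2)
  if (n_inbreed > 0) for (g in seq_len(n_inbreed)) {
    n1 <- cross2(s1, s2)
    n2 <- cross2(s1, s2)
    s1 <- n1; s2 <- n2
  }
  s1
}

count_junctions <- function(labels) sum(labels[-1] != labels[-length(labels)])

# --- per-interval weighted-regression oracle --------------------------

oracle_interval_logp <- function(y, w, P) {
  fit1 <- stats::lm(y ~ P, weights = w)
  fit0 <- stats::lm(y ~ 1, weights = w)
  a <- stats::anova(fit0, fit1)
  p <- a$`Pr(>F)`[2]
  min(-log10(p), 300)
}

# --- 2-D grid maximum-likelihood oracle for variance components -------

oracle_vc_loglik <- function(y, Zind, K, sg2, se2) {
  n <- length(y)
  V <- sg2 * (Zind %*% K %*% t(Zind)) + diag(se2, n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ldet <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y - mu
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * (n * log(2 * pi) + ldet + sum(r * Vi_r))
}

oracle_vc_grid_h2 <- function(y, line, K, n_grid = 41) {
  ids <- rownames(K)
  Zind <- outer(as.character(line), ids, `==`) * 1
  vy <- stats::var(y)
  search <- function(sg, se) {
    best <- c(ll = -Inf, h2 = NA, sg = NA, se = NA)
    for (a in sg) for (b in se) {
      ll <- oracle_vc_loglik(y, Zind, K, a, b)
      if (ll > best["ll"])
        best <- c(ll = ll, h2 = a / (a + b), sg = a, se = b)
    }
    best
  }
  coarse <- search(seq(1e-6, 3 * vy, length.out = n_grid),
                   seq(vy / 50, 3 * vy, length.out = n_grid))
  step_sg <- 3 * vy / (n_grid - 1)
  step_se <- (3 * vy - vy / 50) / (n_grid - 1)
  fine <- search(seq(max(1e-8, coarse["sg"] - step_sg),
                     coarse["sg"] + step_sg, length.out = 25),
                 seq(max(vy / 200, coarse["se"] - step_se),
                     coarse["se"] + step_se, length.out = 25))
  fine
}

# --- exhaustive contiguous-run support interval -----------------------

oracle_support_interval <- function(logp, peak, drop = 1) {
  cut <- logp[peak] - drop
  best <- NULL
  n <- length(logp)
  for (lo in 1:peak) for (hi in peak:n) {
    if (all(logp[lo:hi] >= cut)) {
      if (is.null(best) || (hi - lo) > (best[2] - best[1]))
        best <- c(lo, hi)
    }
  }
  best
}

# --- cM-weighted founder-sharing fraction between two mosaics ---------

oracle_mosaic_sharing <- function(ma, mb, hap_a = 1, hap_b = hap_a) {
  shared <- 0
  for (ci in seq_along(ma$chr)) {
    h1 <- ma$haplotypes[[hap_a]][[ci]]
    h2 <- mb$haplotypes[[hap_b]][[ci]]
    cuts <- sort(unique(c(h1$b, h2$b)))
    starts <- c(0, cuts[-length(cuts)])
    f1 <- h1$f[findInterval(starts, h1$b) + 1]
    f2 <- h2$f[findInterval(starts, h2$b) + 1]
    shared <- shared + sum((cuts - starts)[f1 == f2])
  }
  shared / sum(ma$chr_len)
}

# --- small shared fixtures --------------------------------------------

make_small_panel <- function(n_lines = 12, n_markers = c(120, 120),
                             lens = c(80, 80), seed = 42, ...) {
  simulate_cc_panel(n_lines, n_markers, lens, seed = seed, ...)
}
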