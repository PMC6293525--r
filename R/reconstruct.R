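# Hidden Markov model reconstruction of founder mosaics.
#
# Hidden states are the 8 homozygous founder states; residual
# heterozygosity is not modelled explicitly but surfaces through the
# emission error term. Transitions between adjacent markers at map
# distance d cM use an effective recombination fraction
#   r_eff = (1 - exp(-a * d / 50)) / 2   (capped at 7/8),
# where a is a map-expansion factor accounting for the extra crossovers
# recombinant inbred lines accumulate during inbreeding; a switch goes to
# each specific other founder with probability r_eff / 7.

#' HMM parameters for genome reconstruction
#'
#' @param error_rate genotyping error rate epsilon in \[0, 0.5).
#' @param expansion map-expansion factor a > 0 scaling cM distances into
#'   RIL-effective recombination (default 2, between an F2 and a fully
#'   expanded sib-mating RIL map).
#' @param init initial distribution over the 8 founders (default
#'   uniform).
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(error_rate = 0.01, expansion = 2,
                       init = rep(1 / 8, 8L)) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop_invalid("error_rate must lie in [0, 0.5)")
  if (expansion <= 0) stop_invalid("expansion must be positive")
  if (length(init) != 8L || any(init < 0) || abs(sum(init) - 1) > 1e-8)
    stop_invalid("init must be a length-8 distribution summing to 1")
  structure(list(error_rate = error_rate, expansion = expansion,
                 init = init / sum(init)),
            class = "hmm_params")
}

# emission matrix for one line: M x 8, P(observed call | founder state).
# expected call under founder f is 2 * allele_f; a non-matching call
# (including heterozygous 1) is emitted with probability eps/2 each.
.emission <- function(calls, alleles, eps) {
  m <- length(calls)
  exp_call <- t(alleles) * 2L                 # M x 8
  e <- matrix(1, m, 8L)
  obs <- !is.na(calls)
  if (any(obs)) {
    match_ <- exp_call[obs, , drop = FALSE] == calls[obs]
    e[obs, ] <- ifelse(match_, 1 - eps, eps / 2)
  }
  e
}

.r_eff <- function(d_cm, a) pmin((1 - exp(-a * d_cm / 50)) / 2, 7 / 8)

# forward-backward for one line on one chromosome; returns list(post, ll)
.fb_chr <- function(e, r, init) {
  m <- nrow(e)
  alpha <- matrix(0, m, 8L)
  scale <- numeric(m)
  v <- init * e[1L, ]
  scale[1L] <- sum(v)
  if (scale[1L] <= 0) stop_inconsistent("impossible genotype under the HMM")
  alpha[1L, ] <- v / scale[1L]
  if (m > 1L) for (j in 2:m) {
    rr <- r[j - 1L]
    prev <- alpha[j - 1L, ]
    v <- ((1 - rr - rr / 7) * prev + (rr / 7) * sum(prev)) * e[j, ]
    scale[j] <- sum(v)
    if (scale[j] <= 0) stop_inconsistent("impossible genotype under the HMM")
    alpha[j, ] <- v / scale[j]
  }
  beta <- matrix(0, m, 8L)
  beta[m, ] <- 1
  if (m > 1L) for (j in (m - 1L):1L) {
    rr <- r[j]
    w <- beta[j + 1L, ] * e[j + 1L, ]
    beta[j, ] <- ((1 - rr - rr / 7) * w + (rr / 7) * sum(w)) / scale[j + 1L]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(post = post, ll = sum(log(scale)))
}

# Viterbi for one line on one chromosome; returns integer path
.viterbi_chr <- function(e, r, init) {
  m <- nrow(e)
  le <- log(e)
  delta <- log(init) + le[1L, ]
  back <- matrix(0L, m, 8L)
  if (m > 1L) for (j in 2:m) {
    rr <- r[j - 1L]
    stay <- log(1 - rr)
    swit <- if (rr > 0) log(rr / 7) else -Inf
    # best switch into state f comes from the overall argmax, except for
    # the argmax state itself, which can only receive the runner-up
    best1 <- which.max(delta)
    m2 <- max(delta[-best1])
    best2 <- setdiff(which(delta == m2), best1)[1L]
    sw_val <- rep(delta[best1] + swit, 8L)
    sw_val[best1] <- m2 + swit
    sw_from <- rep(best1, 8L)
    sw_from[best1] <- best2
    stay_val <- delta + stay
    from <- ifelse(stay_val >= sw_val, seq_len(8L), sw_from)
    back[j, ] <- from
    delta <- pmax(stay_val, sw_val) + le[j, ]
  }
  path <- integer(m)
  path[m] <- which.max(delta)
  if (m > 1L) for (j in (m - 1L):1L) path[j] <- back[j + 1L, path[j + 1L]]
  path
}

#' Reconstruct founder descent probabilities by HMM
#'
#' Runs a haploid 8-state forward-backward pass per line and chromosome,
#' returning the posterior probability of descent from each founder at
#' every marker interval, plus (optionally) the Viterbi founder path.
#' Missing calls are uninformative; chromosomes are independent.
#'
#' @param genotypes a `cc_geno` object (list with `map` and `calls`,
#'   lines x markers) as produced by [simulate_cc_panel()] or
#'   [read_genotypes()].
#' @param founders matching [simulate_founders()] object.
#' @param params an [hmm_params()].
#' @param viterbi also compute the most likely founder path per line.
#' @return Object of class `cc_descent`: list with `prob` (L x M x 8
#'   array), `map` (interval table: marker, chr, bp start/end 0-based
#'   half-open, cM), `founders`, `loglik` per line, and `viterbi`
#'   (L x M integer matrix) when requested.
#' @export
reconstruct_descent <- function(genotypes, founders, params = hmm_params(),
                                viterbi = FALSE) {
  map <- genotypes$map
  if (!identical(map$marker, founders$map$marker))
    stop_inconsistent("genotypes and founders do not share a map")
  calls <- genotypes$calls
  lines_ <- rownames(calls)
  m <- nrow(map)
  L <- nrow(calls)
  if (m == 0L) {
    warning("no markers: returning uniform priors")
    return(structure(list(prob = array(1 / 8, c(L, 0L, 8L)),
                          map = map, founders = founders$founders,
                          loglik = rep(0, L), viterbi = NULL,
                          params = params),
                     class = "cc_descent"))
  }
  eps <- params$error_rate
  a <- params$expansion
  chr_idx <- split(seq_len(m), factor(map$chr, levels = chromosomes(map)))
  r_list <- lapply(chr_idx, function(i)
    if (length(i) > 1L) .r_eff(diff(map$cM[i]), a) else numeric(0))
  prob <- array(NA_real_, c(L, m, 8L),
                dimnames = list(lines_, map$marker, founders$founders))
  vit <- if (viterbi) matrix(NA_integer_, L, m,
                             dimnames = list(lines_, map$marker)) else NULL
  ll <- numeric(L)
  for (l in seq_len(L)) {
    e_all <- .emission(calls[l, ], founders$alleles, eps)
    for (k in seq_along(chr_idx)) {
      i <- chr_idx[[k]]
      fb <- .fb_chr(e_all[i, , drop = FALSE], r_list[[k]], params$init)
      prob[l, i, ] <- fb$post
      ll[l] <- ll[l] + fb$ll
      if (viterbi)
        vit[l, i] <- .viterbi_chr(e_all[i, , drop = FALSE], r_list[[k]],
                                  params$init)
    }
  }
  bp <- marker_bp_intervals(map)
  interval_map <- data.frame(marker = map$marker, chr = map$chr,
                             bp_start = bp$start, bp_end = bp$end,
                             cM = map$cM, stringsAsFactors = FALSE)
  structure(list(prob = prob, map = interval_map,
                 founders = founders$founders, loglik = ll,
                 viterbi = vit, params = params),
            class = "cc_descent")
}

#' @export
print.cc_descent <- function(x, ...) {
  d <- dim(x$prob)
  cat("Descent probabilities: ", d[1], " line(s) x ", d[2],
      " interval(s) x 8 founders\n", sep = "")
  invisible(x)
}

#' True descent probabilities from simulated mosaics
#'
#' One-hot (haplotype-averaged) descent probabilities read directly off
#' the true mosaics at the markers of a map — the noiseless reference the
#' HMM posterior is judged against, and a convenient input for kinship
#' from simulation truth.
#'
#' @param mosaics list of [breed_cc_line()] mosaics.
#' @param map a [genetic_map()].
#' @return A `cc_descent` object with 0/0.5/1 probabilities.
#' @export
true_descent <- function(mosaics, map) {
  L <- length(mosaics)
  m <- nrow(map)
  ids <- vapply(mosaics, `[[`, character(1), "line")
  prob <- array(0, c(L, m, 8L), dimnames = list(ids, map$marker, NULL))
  for (l in seq_len(L)) {
    fm <- mosaic_founders_matrix(mosaics[[l]], map)
    for (hap in 1:2)
      prob[cbind(l, seq_len(m), fm[, hap])] <-
        prob[cbind(l, seq_len(m), fm[, hap])] + 0.5
  }
  bp <- marker_bp_intervals(map)
  structure(list(prob = prob,
                 map = data.frame(marker = map$marker, chr = map$chr,
                                  bp_start = bp$start, bp_end = bp$end,
                                  cM = map$cM, stringsAsFactors = FALSE),
                 founders = NULL, loglik = NULL, viterbi = NULL,
                 params = NULL),
            class = "cc_descent")
}

#' Prune descent intervals to an approximately even cM grid
#'
#' Keeps a subset of intervals per chromosome, approximately evenly
#' spaced in cM, always retaining the first and last interval of each
#' chromosome.
#'
#' @param probs a `cc_descent`.
#' @param target_count desired total number of intervals (>= number of
#'   chromosomes, <= current count).
#' @return A `cc_descent` with the retained intervals.
#' @export
prune_intervals <- function(probs, target_count) {
  map <- probs$map
  m <- nrow(map)
  chrs <- unique(map$chr)
  if (target_count > m) stop_invalid("target_count exceeds interval count")
  if (target_count < length(chrs))
    stop_invalid("target_count below the number of chromosomes")
  if (target_count == m) return(probs)
  counts <- table(factor(map$chr, levels = chrs))
  alloc <- pmax(ifelse(counts > 1L, 2L, 1L),
                round(target_count * as.numeric(counts) / m))
  keep <- integer(0)
  for (k in seq_along(chrs)) {
    i <- which(map$chr == chrs[k])
    n <- length(i)
    kk <- min(alloc[k], n)
    if (kk >= n) { keep <- c(keep, i); next }
    grid <- seq(map$cM[i[1L]], map$cM[i[n]], length.out = kk)
    sel <- unique(vapply(grid, function(g) which.min(abs(map$cM[i] - g)),
                         integer(1)))
    sel <- sort(unique(c(1L, sel, n)))
    keep <- c(keep, i[sel])
  }
  keep <- sort(unique(keep))
  structure(list(prob = probs$prob[, keep, , drop = FALSE],
                 map = map[keep, , drop = FALSE],
                 founders = probs$founders, loglik = probs$loglik,
                 viterbi = if (!is.null(probs$viterbi))
                   probs$viterbi[, keep, drop = FALSE],
                 params = probs$params),
            class = "cc_descent")
}

#' Founder contributions from descent probabilities
#'
#' Overall (cM-weighted, averaged over lines and intervals) and
#' per-interval genome shares of each founder, flagging intervals where a
#' founder's share is numerically zero (absent haplotype).
#'
#' @param probs a `cc_descent`.
#' @param zero_tol share below which a founder is flagged absent at an
#'   interval.
#' @return List with `overall` (length-8 shares summing to 1),
#'   `per_interval` (M x 8 matrix), and `absent` (logical M x 8).
#' @export
founder_contributions <- function(probs, zero_tol = 1e-8) {
  d <- dim(probs$prob)
  if (d[1] == 0L || d[2] == 0L) stop_invalid("empty descent probabilities")
  per_interval <- apply(probs$prob, c(2, 3), mean)   # M x 8
  cmw <- marker_cm_weights(probs$map)
  if (all(cmw == 0)) cmw <- rep(1, d[2])
  overall <- colSums(per_interval * cmw) / sum(cmw)
  list(overall = overall, per_interval = per_interval,
       absent = per_interval < zero_tol)
}
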