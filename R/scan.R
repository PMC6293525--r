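# Haplotype-dosage genome scan on weighted line means.
#
# At each interval the (corrected + normalized) line means are regressed
# on the 8 founder descent probabilities by weighted least squares
# (weights = animals per line), and the founder term is tested against
# the intercept-only weighted model by an F test; LogP = -log10(P).
# Because the 8 probability columns sum to 1, one column is absorbed by
# the intercept; founders absent at an interval are dropped and the
# interval flagged.

LOGP_CAP <- 300

# precompute per-interval orthonormal bases of the weighted design;
# reused across permutations
.scan_pre <- function(probs, weights, zero_tol = 1e-8) {
  d <- dim(probs$prob)
  L <- d[1]; M <- d[2]
  sw <- sqrt(weights)
  q0 <- sw / sqrt(sum(weights))
  qs <- vector("list", M)
  rank1 <- integer(M)
  flagged <- logical(M)
  for (m in seq_len(M)) {
    P <- probs$prob[, m, ]
    present <- colSums(P) > zero_tol
    flagged[m] <- any(!present)
    X <- cbind(1, P[, present, drop = FALSE][, -1L, drop = FALSE])
    qr_ <- qr(X * sw)
    r <- qr_$rank
    qs[[m]] <- qr.Q(qr_)[, seq_len(r), drop = FALSE]
    rank1[m] <- r
  }
  list(qs = qs, q0 = q0, sw = sw, rank1 = rank1, flagged = flagged,
       L = L, M = M)
}

# LogP matrix (M x ncol(Y)) for a matrix of line-mean vectors
.scan_logp <- function(pre, Y) {
  Y <- as.matrix(Y)
  sy <- Y * pre$sw
  tot <- colSums(sy^2)
  rss0 <- tot - as.numeric(crossprod(pre$q0, sy))^2
  Qcat <- do.call(cbind, pre$qs)
  proj <- crossprod(Qcat, sy)^2                      # (sum r) x nY
  grp <- rep(seq_len(pre$M), pre$rank1)
  fit <- rowsum(proj, grp)                           # M x nY
  rss1 <- pmax(rep(tot, each = pre$M) - fit, 0)
  dim(rss1) <- dim(fit)
  df1 <- pre$rank1 - 1L
  df2 <- pre$L - pre$rank1
  logp <- matrix(0, pre$M, ncol(sy))
  usable <- df1 > 0L & df2 > 0L
  if (any(usable)) {
    num <- (rss0[col(fit)] - rss1) / df1
    den <- rss1 / df2
    Fst <- num / den
    lp <- -stats::pf(Fst[usable, , drop = FALSE], df1[usable],
                     df2[usable], lower.tail = FALSE, log.p = TRUE) / log(10)
    lp[!is.finite(lp)] <- LOGP_CAP
    logp[usable, ] <- pmin(lp, LOGP_CAP)
  }
  logp
}

#' Haplotype-dosage genome scan
#'
#' @param line_means named numeric vector of per-line trait means
#'   (typically corrected + quantile-normalized, via [line_summaries()]).
#' @param weights named numeric vector of weights (animals per line).
#' @param probs a `cc_descent` over the same lines.
#' @return Object of class `cc_scan`: a `data.frame` with one row per
#'   interval (`marker`, `chr`, `bp_start`, `bp_end`, `cM`, `LogP`,
#'   `df`, `flagged`), with the trait values and weights as attributes.
#' @export
scan_genome <- function(line_means, weights, probs) {
  ids <- dimnames(probs$prob)[[1]]
  if (is.null(names(line_means)) || is.null(names(weights)))
    stop_invalid("line_means and weights must be named by line")
  if (!all(ids %in% names(line_means)) || !all(ids %in% names(weights)))
    stop_inconsistent("line means / weights do not cover all lines")
  y <- line_means[ids]
  w <- weights[ids]
  if (length(ids) < 10L) stop_invalid("need at least 10 lines")
  if (any(w <= 0)) stop_invalid("weights must be positive")
  pre <- .scan_pre(probs, w)
  if (stats::sd(y) == 0) {
    warning("zero-variance trait: LogP = 0 everywhere")
    logp <- rep(0, pre$M)
  } else {
    logp <- as.numeric(.scan_logp(pre, matrix(y, ncol = 1L)))
  }
  out <- data.frame(marker = probs$map$marker, chr = probs$map$chr,
                    bp_start = probs$map$bp_start,
                    bp_end = probs$map$bp_end, cM = probs$map$cM,
                    LogP = logp, df = pre$rank1 - 1L,
                    flagged = pre$flagged, stringsAsFactors = FALSE)
  attr(out, "line_means") <- y
  attr(out, "weights") <- w
  class(out) <- c("cc_scan", "data.frame")
  out
}

#' @export
print.cc_scan <- function(x, ...) {
  cat("Genome scan: ", nrow(x), " interval(s) on ",
      length(unique(x$chr)), " chromosome(s); max LogP = ",
      format(max(x$LogP), digits = 4), " (", x$chr[which.max(x$LogP)],
      ")\n", sep = "")
  invisible(x)
}

#' @export
plot.cc_scan <- function(x, threshold = NULL, main = "Genome scan", ...) {
  chrs <- unique(x$chr)
  offs <- 0; xpos <- numeric(nrow(x)); mids <- numeric(length(chrs))
  for (k in seq_along(chrs)) {
    i <- x$chr == chrs[k]
    xpos[i] <- x$cM[i] + offs
    mids[k] <- offs + mean(range(x$cM[i]))
    offs <- offs + max(x$cM[i]) + 5
  }
  col <- rep(c("grey25", "steelblue"), length.out = length(chrs))
  plot(xpos, x$LogP, col = col[match(x$chr, chrs)], pch = 16, cex = 0.5,
       xaxt = "n", xlab = "chromosome", ylab = "LogP", main = main, ...)
  graphics::axis(1, at = mids, labels = chrs)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "firebrick")
  invisible(x)
}

#' Permutation genome-wide significance thresholds
#'
#' Shuffles line means across lines (weights stay attached to their
#' lines), rescans the genome, and records the genome-wide maximum LogP
#' of each permutation. The level-`alpha` threshold is the empirical
#' `(1 - alpha)` quantile (order statistic `ceil((1 - alpha) * n_perm)`),
#' and the permuted P of an observed peak uses the add-one rule
#' `(1 + #\{perm max >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams scan_genome
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance levels for thresholds.
#' @param seed integer seed or `NULL`.
#' @return Object of class `cc_perm`: list with `max_logp`
#'   (per-permutation maxima), `thresholds` (named by alpha), `n_perm`,
#'   `seed`.
#' @export
permutation_threshold <- function(line_means, weights, probs,
                                  n_perm = 1000L,
                                  alpha = c(0.05, 0.1, 0.5),
                                  seed = NULL) {
  if (n_perm < 100L)
    stop_invalid("n_perm must be >= 100 for stable quantiles")
  ids <- dimnames(probs$prob)[[1]]
  y <- line_means[ids]
  w <- weights[ids]
  pre <- .scan_pre(probs, w)
  with_seed(seed, {
    Y <- vapply(seq_len(n_perm), function(i) y[sample.int(length(y))],
                numeric(length(y)))
    maxima <- apply(.scan_logp(pre, Y), 2L, max)
    srt <- sort(maxima)
    thr <- vapply(alpha, function(a)
      srt[min(n_perm, max(1L, ceiling((1 - a) * n_perm)))], numeric(1))
    structure(list(max_logp = maxima,
                   thresholds = stats::setNames(thr, paste0("alpha", alpha)),
                   alpha = alpha, n_perm = as.integer(n_perm), seed = seed),
              class = "cc_perm")
  })
}

#' @export
print.cc_perm <- function(x, ...) {
  cat("Permutation null: ", x$n_perm, " genome-wide maxima\n", sep = "")
  for (i in seq_along(x$alpha))
    cat("  threshold(alpha = ", x$alpha[i], ") = ",
        format(x$thresholds[i], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Permuted P-value of an observed peak
#'
#' @param perm a [permutation_threshold()] result.
#' @param logp observed peak LogP (vectorized).
#' @return P in `[1/(n_perm+1), 1]`.
#' @export
permuted_p <- function(perm, logp) {
  vapply(logp, function(v)
    (1 + sum(perm$max_logp >= v)) / (perm$n_perm + 1), numeric(1))
}

#' LogP-1 support interval around a QTL peak
#'
#' The support interval is the maximal contiguous run of intervals on
#' the peak's chromosome, containing the peak, whose LogP stays within
#' `drop` units of the peak LogP; bp bounds are taken from the outermost
#' member intervals (0-based half-open).
#'
#' @param scan a [scan_genome()] result.
#' @param peak marker ID or row index of the peak interval.
#' @param drop LogP drop defining the support (default 1).
#' @param perm optional [permutation_threshold()] result, used to attach
#'   a permuted P to the peak.
#' @return Object of class `cc_qtl`: list with `chr`, `peak_marker`,
#'   `peak_logp`, `bp_start`, `bp_end`, `cM_start`, `cM_end`,
#'   `members` (marker IDs) and `perm_p` (or `NA`).
#' @export
define_qtl_interval <- function(scan, peak, drop = 1, perm = NULL) {
  if (is.character(peak)) peak <- match(peak, scan$marker)
  if (is.na(peak) || peak < 1L || peak > nrow(scan))
    stop_invalid("peak not found in scan")
  ch <- scan$chr[peak]
  i <- which(scan$chr == ch)
  lp <- scan$LogP[i]
  k <- match(peak, i)
  cut <- scan$LogP[peak] - drop
  in_run <- lp >= cut
  lo <- k; while (lo > 1L && in_run[lo - 1L]) lo <- lo - 1L
  hi <- k; while (hi < length(i) && in_run[hi + 1L]) hi <- hi + 1L
  members <- i[lo:hi]
  structure(list(chr = ch, peak_marker = scan$marker[peak],
                 peak_logp = scan$LogP[peak],
                 bp_start = min(scan$bp_start[members]),
                 bp_end = max(scan$bp_end[members]),
                 cM_start = min(scan$cM[members]),
                 cM_end = max(scan$cM[members]),
                 members = scan$marker[members],
                 perm_p = if (!is.null(perm))
                   permuted_p(perm, scan$LogP[peak]) else NA_real_),
            class = "cc_qtl")
}

#' @export
print.cc_qtl <- function(x, ...) {
  cat("QTL on chromosome ", x$chr, ": peak ", x$peak_marker,
      " (LogP = ", format(x$peak_logp, digits = 4), ")\n", sep = "")
  cat("  support interval: [", x$bp_start, ", ", x$bp_end, ") bp, ",
      format(x$cM_start, digits = 4), "-", format(x$cM_end, digits = 4),
      " cM, ", length(x$members), " interval(s)\n", sep = "")
  if (!is.na(x$perm_p))
    cat("  genome-wide permuted P = ", format(x$perm_p, digits = 3),
        "\n", sep = "")
  invisible(x)
}
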