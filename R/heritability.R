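#' Kinship matrix from descent probabilities
#'
#' `K[i, j]` is the probability, averaged over intervals, that lines i
#' and j descend from the same founder:
#' `K[i,j] = (1/M) * sum_m sum_f p[i,m,f] * p[j,m,f]`.
#'
#' @param probs a `cc_descent` (from [reconstruct_descent()] or
#'   [true_descent()]).
#' @param rescale also attach a copy rescaled to unit mean diagonal
#'   (attribute `"rescaled"`).
#' @return Symmetric L x L matrix of class `cc_kinship`.
#' @export
kinship_from_descent <- function(probs, rescale = TRUE) {
  d <- dim(probs$prob)
  if (d[1] < 2L || d[2] < 1L)
    stop_invalid("need at least 2 lines and 1 interval")
  rs <- apply(probs$prob, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-6))
    stop_inconsistent("descent probabilities must sum to 1 per interval")
  A <- matrix(probs$prob, nrow = d[1])     # L x (M*8)
  K <- tcrossprod(A) / d[2]
  dimnames(K) <- list(dimnames(probs$prob)[[1]], dimnames(probs$prob)[[1]])
  if (rescale) attr(K, "rescaled") <- K / mean(diag(K))
  class(K) <- c("cc_kinship", class(K))
  K
}

# profile log-likelihood machinery: y = Xb + g + e at animal level, with
# cov(g) = sigma_g2 * Z K Z' and cov(e) = sigma_e2 * I. Parametrized by
# h2 = sigma_g2 / (sigma_g2 + sigma_e2) with the total profiled out.
.vc_loglik <- function(h2, yt, xt, dvals, reml = FALSE) {
  n <- length(yt)
  p <- ncol(xt)
  w <- h2 * dvals + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  xw <- xt / w
  xtx <- crossprod(xt, xw)
  beta <- solve(xtx, crossprod(xw, yt))
  r <- yt - xt %*% beta
  rss <- sum(r^2 / w)
  if (reml) {
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
              determinant(xtx, logarithm = TRUE)$modulus + (n - p))
  } else {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
  }
}

#' Narrow-sense heritability by maximum-likelihood variance components
#'
#' Fits the animal-level mixed model in which the phenotypic
#' variance-covariance matrix is `V = K sigma_g2 + I sigma_e2` (kinship
#' expanded over line membership: animals of lines i and j share genetic
#' covariance `sigma_g2 * K[i, j]`), by maximum likelihood over the
#' heritability ratio after an eigendecomposition of the expanded
#' relationship matrix. Narrow-sense heritability is
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`.
#'
#' @param trait numeric vector, one value per animal.
#' @param line line ID per animal; all must appear in `K`.
#' @param K kinship matrix over lines ([kinship_from_descent()]).
#' @param reml use REML instead of ML (default ML).
#' @param tol convergence tolerance on h2.
#' @return Object of class `cc_varcomp` with `sigma_g2`, `sigma_e2`,
#'   `h2`, `loglik`, `boundary` flag and fit metadata.
#' @export
fit_varcomp <- function(trait, line, K, reml = FALSE, tol = 1e-6) {
  ok <- !is.na(trait)
  y <- as.numeric(trait[ok])
  line <- as.character(line)[ok]
  n <- length(y)
  if (n < 3L) stop_invalid("need at least 3 observations")
  if (stats::sd(y) == 0)
    stop_invalid("constant trait: variance components are undefined")
  ids <- rownames(K) %||% stop_invalid("K must carry line IDs")
  if (!all(line %in% ids)) stop_invalid("K does not cover all lines")
  Ksym <- (unclass(K) + t(unclass(K))) / 2
  ev0 <- eigen(Ksym, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev0) < -1e-6 * max(abs(ev0), 1))
    stop_invalid("K is not positive semidefinite")
  Z <- outer(line, ids, `==`) * 1
  G <- Z %*% Ksym %*% t(Z)
  eg <- eigen(G, symmetric = TRUE)
  dvals <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  xt <- crossprod(eg$vectors, matrix(1, n, 1L))
  f <- function(h2) .vc_loglik(h2, yt, xt, dvals, reml = reml)
  grid <- seq(0, 1 - 1e-9, length.out = 101L)
  lls <- vapply(grid, f, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  h2 <- opt$maximum
  ll <- opt$objective
  if (f(0) >= ll) { h2 <- 0; ll <- f(0) }
  if (h2 < tol) h2 <- 0
  # back out the components on the original scale
  w <- h2 * dvals + (1 - h2)
  xw <- xt / w
  beta <- solve(crossprod(xt, xw), crossprod(xw, yt))
  rss <- sum((yt - xt %*% beta)^2 / w)
  s2 <- rss / if (reml) (n - ncol(xt)) else n
  out <- structure(list(sigma_g2 = h2 * s2, sigma_e2 = (1 - h2) * s2,
                        h2 = h2, loglik = ll,
                        boundary = (h2 <= 0 || h2 >= 1 - 1e-6),
                        method = if (reml) "REML" else "ML",
                        n = n, n_lines = length(unique(line)),
                        intercept = as.numeric(beta)),
                   class = "cc_varcomp")
  out
}

#' @export
print.cc_varcomp <- function(x, digits = 4, ...) {
  cat("Variance components (", x$method, ", ", x$n, " animals, ",
      x$n_lines, " lines)\n", sep = "")
  cat("  sigma_g2 = ", format(x$sigma_g2, digits = digits),
      ", sigma_e2 = ", format(x$sigma_e2, digits = digits), "\n", sep = "")
  cat("  narrow-sense h2 = ", format(x$h2, digits = digits),
      if (x$boundary) "  (boundary)" else "", "\n", sep = "")
  cat("  logLik = ", format(x$loglik, digits = digits + 2), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cc_varcomp <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
coef.cc_varcomp <- function(object, ...) {
  c(sigma_g2 = object$sigma_g2, sigma_e2 = object$sigma_e2,
    h2 = object$h2)
}

#' @export
logLik.cc_varcomp <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' Broad-sense heritability from one-way ANOVA
#'
#' Proportion of phenotypic variance explained by differences between
#' lines: `H2 = Vg / (Vg + Ve)` with `Ve = MS_within` and
#' `Vg = (MS_between - MS_within) / n`, `n` being the average number of
#' animals per line. A negative `Vg` is clamped to 0 (flagged).
#'
#' @param trait numeric vector, one value per animal.
#' @param line line ID per animal (>= 2 lines).
#' @return Object of class `cc_anova_h2` with the mean squares, `n`,
#'   `Vg`, `Ve`, `H2`, the ANOVA `F` and `P`, and a `clamped` flag.
#' @export
anova_broad_h2 <- function(trait, line) {
  ok <- !is.na(trait)
  y <- as.numeric(trait[ok])
  g <- factor(as.character(line)[ok])
  if (nlevels(g) < 2L) stop_invalid("need at least 2 lines")
  fit <- stats::aov(y ~ g)
  # a perfect fit (zero within-line variance) is a defined, clamped case
  tab <- suppressWarnings(stats::anova(fit))
  msb <- tab$`Mean Sq`[1L]
  msw <- tab$`Mean Sq`[2L]
  n_bar <- mean(table(g))
  vg_raw <- (msb - msw) / n_bar
  clamped <- vg_raw < 0
  vg <- max(vg_raw, 0)
  ve <- msw
  h2 <- if (vg + ve > 0) vg / (vg + ve) else 0
  structure(list(MS_between = msb, MS_within = msw, n = n_bar,
                 Vg = vg, Ve = ve, Vg_raw = vg_raw, H2 = h2,
                 F = tab$`F value`[1L], P = tab$`Pr(>F)`[1L],
                 clamped = clamped, n_lines = nlevels(g),
                 n_animals = length(y)),
            class = "cc_anova_h2")
}

#' @export
print.cc_anova_h2 <- function(x, digits = 4, ...) {
  cat("One-way ANOVA heritability (", x$n_animals, " animals, ",
      x$n_lines, " lines, mean n/line = ", format(x$n, digits = digits),
      ")\n", sep = "")
  cat("  MS_between = ", format(x$MS_between, digits = digits),
      ", MS_within = ", format(x$MS_within, digits = digits), "\n", sep = "")
  cat("  Vg = ", format(x$Vg, digits = digits),
      if (x$clamped) " (clamped from negative)" else "",
      ", Ve = ", format(x$Ve, digits = digits), "\n", sep = "")
  cat("  broad-sense H2 = ", format(x$H2, digits = digits),
      "   (F = ", format(x$F, digits = digits),
      ", P = ", format(x$P, digits = 3), ")\n", sep = "")
  invisible(x)
}
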