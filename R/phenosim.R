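#' Specify the genetic architecture of a simulated trait
#'
#' Ground-truth description used by [simulate_phenotypes()]: additive
#' founder-allelic QTL effects at named genomic positions, a polygenic
#' variance structured by kinship, residual noise, and covariate effects.
#'
#' @param qtl list of QTLs, each a list with `chr`, `cM` and `effects`
#'   (numeric length 8, phenotype units per founder allele; an animal
#'   receives the mean of its two haplotypes' founder effects).
#' @param sigma_g2 polygenic (line-level) variance, >= 0.
#' @param sigma_e2 residual variance per animal, >= 0.
#' @param beta_age slope per day of age.
#' @param beta_batch,beta_origin numeric vectors of per-level effects
#'   (recycled over levels; defaults none).
#' @param trait name of the trait column produced.
#' @return Object of class `qtl_spec`.
#' @export
qtl_spec <- function(qtl = list(), sigma_g2 = 0, sigma_e2 = 1,
                     beta_age = 0, beta_batch = NULL, beta_origin = NULL,
                     trait = "trait") {
  if (sigma_g2 < 0 || sigma_e2 < 0)
    stop_invalid("variance components must be non-negative")
  for (q in qtl) {
    if (length(q$effects) != 8L)
      stop_invalid("each QTL needs 8 founder-allelic effects")
    if (is.null(q$chr) || is.null(q$cM))
      stop_invalid("each QTL needs a chr and cM position")
  }
  structure(list(qtl = qtl, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 beta_age = beta_age, beta_batch = beta_batch,
                 beta_origin = beta_origin, trait = trait),
            class = "qtl_spec")
}

#' Simulate per-animal phenotypes for a CC panel
#'
#' Each animal's value is intercept + additive QTL effects read from its
#' line's true mosaic + a line-level polygenic deviate with covariance
#' `sigma_g2 * K` + covariate effects (age, batch, origin) + residual
#' noise `N(0, sigma_e2)`. The generating narrow-sense heritability
#' `sigma_g2 / (sigma_g2 + sigma_e2)` (QTL and covariate variance not
#' counted) is recorded in the `true_h2` attribute.
#'
#' @param mosaics list of [breed_cc_line()] mosaics (the lines).
#' @param kinship L x L kinship matrix over those lines (row order =
#'   `mosaics` order); required positive semidefinite when
#'   `sigma_g2 > 0`.
#' @param spec a [qtl_spec()].
#' @param n_per_line animals per line (scalar or per-line vector).
#' @param covariate_levels list with `age` (range, days), `n_batch`,
#'   `n_origin`.
#' @param seed integer seed or `NULL`.
#' @return `data.frame` with columns `animal`, `line`, `age`, `batch`,
#'   `origin` and one trait column; attributes `true_h2`, `spec`, `seed`.
#' @export
simulate_phenotypes <- function(mosaics, kinship, spec,
                                n_per_line = 5L,
                                covariate_levels = list(age = c(60L, 120L),
                                                        n_batch = 3L,
                                                        n_origin = 2L),
                                seed = NULL) {
  L <- length(mosaics)
  stopifnot(inherits(spec, "qtl_spec"))
  if (!is.matrix(kinship) || nrow(kinship) != L || ncol(kinship) != L)
    stop_invalid("kinship dimension must equal the number of lines")
  if (spec$sigma_g2 > 0) {
    ev <- eigen(kinship, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop_invalid("kinship matrix is not positive semidefinite")
  }
  n_per_line <- rep_len(as.integer(n_per_line), L)
  if (any(n_per_line < 1L)) stop_invalid("n_per_line must be >= 1")
  line_ids <- vapply(mosaics, `[[`, character(1), "line")
  with_seed(seed, {
    # line-level genetic values
    g <- rep(0, L)
    if (spec$sigma_g2 > 0) {
      eg <- eigen(kinship, symmetric = TRUE)
      half <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
      g <- as.numeric(half %*% stats::rnorm(L)) * sqrt(spec$sigma_g2)
    }
    qtl_line <- rep(0, L)
    for (q in spec$qtl) {
      for (i in seq_len(L)) {
        f1 <- mosaic_founder_at(mosaics[[i]], q$chr, q$cM, 1L)
        f2 <- mosaic_founder_at(mosaics[[i]], q$chr, q$cM, 2L)
        qtl_line[i] <- qtl_line[i] + (q$effects[f1] + q$effects[f2]) / 2
      }
    }
    n <- sum(n_per_line)
    line <- rep(line_ids, n_per_line)
    idx <- rep(seq_len(L), n_per_line)
    age <- sample(seq(covariate_levels$age[1], covariate_levels$age[2]),
                  n, replace = TRUE)
    nb <- covariate_levels$n_batch %||% 1L
    no <- covariate_levels$n_origin %||% 1L
    batch <- factor(sample.int(nb, n, replace = TRUE), levels = seq_len(nb),
                    labels = paste0("b", seq_len(nb)))
    origin <- factor(sample.int(no, n, replace = TRUE), levels = seq_len(no),
                     labels = paste0("o", seq_len(no)))
    bb <- rep_len(spec$beta_batch %||% 0, nlevels(batch))
    bo <- rep_len(spec$beta_origin %||% 0, nlevels(origin))
    y <- qtl_line[idx] + g[idx] +
      spec$beta_age * (age - mean(age)) +
      bb[as.integer(batch)] + bo[as.integer(origin)] +
      stats::rnorm(n, 0, sqrt(spec$sigma_e2))
    out <- data.frame(animal = sprintf("%s_a%02d", line,
                                       stats::ave(idx, idx, FUN = seq_along)),
                      line = line, age = age, batch = batch, origin = origin,
                      stringsAsFactors = FALSE)
    out[[spec$trait]] <- y
    attr(out, "true_h2") <- if (spec$sigma_g2 + spec$sigma_e2 > 0)
      spec$sigma_g2 / (spec$sigma_g2 + spec$sigma_e2) else NA_real_
    attr(out, "spec") <- spec
    attr(out, "seed") <- seed
    out
  })
}
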