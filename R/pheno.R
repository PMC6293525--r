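# Behavioral readout derivation and the preprocessing chain applied
# before heritability estimation and QTL mapping: covariate correction
# (age, batch, origin) followed by rank-based quantile normalization.
# Provenance of a trait vector is tracked in the "provenance" attribute
# ("raw" -> "corrected" -> "normalized") and the chain order is enforced.

trait_provenance <- function(x) attr(x, "provenance") %||% "raw"

set_provenance <- function(x, p) { attr(x, "provenance") <- p; x }

#' Social discrimination ratio
#'
#' Preference for a novel over a familiar conspecific,
#' `tN / (tN + tF)`, where `tN` and `tF` are the times (seconds) spent
#' exploring the novel and the familiar animal. A ratio above 0.5 marks
#' successful discrimination. When `tN + tF == 0` the ratio is
#' undefined and returned as `NA`.
#'
#' @param tN,tF non-negative exploration times in seconds (vectorized).
#' @return `data.frame` with columns `tN`, `tF`, `ratio`,
#'   `discriminated` (logical, strict `> 0.5`).
#' @examples
#' discrimination_ratio(c(30, 3, 0), c(30, 1, 12))
#' @export
discrimination_ratio <- function(tN, tF) {
  if (any(tN < 0, na.rm = TRUE) || any(tF < 0, na.rm = TRUE))
    stop_invalid("exploration times must be non-negative")
  tot <- tN + tF
  ratio <- ifelse(!is.na(tot) & tot > 0, tN / tot, NA_real_)
  data.frame(tN = tN, tF = tF, ratio = ratio,
             discriminated = !is.na(ratio) & ratio > 0.5)
}

#' Fraction of animals exceeding a threshold
#'
#' Strict exceedance (`value > threshold`) among non-missing values,
#' e.g. the fraction of animals with excessive grooming duration.
#'
#' @param values numeric vector, optionally named by animal ID.
#' @param threshold cutoff in the same units as `values`.
#' @return List with `fraction`, `exceeders` (names or indices), and
#'   `n` (non-missing count).
#' @export
exceedance_fraction <- function(values, threshold) {
  if (length(values) == 0L) stop_invalid("empty values")
  ok <- !is.na(values)
  if (!any(ok)) stop_invalid("all values missing")
  exc <- ok & values > threshold
  ids <- if (!is.null(names(values))) names(values)[exc] else which(exc)
  list(fraction = sum(exc) / sum(ok), exceeders = ids, n = sum(ok))
}

#' Correct a trait for age, batch and origin effects
#'
#' Ordinary least-squares residuals of the trait on age (numeric) and
#' the categorical covariates (treatment coding). Residuals have mean
#' zero; missing trait values propagate.
#'
#' @param trait numeric vector (one value per animal).
#' @param covariates `data.frame` with one row per animal; numeric
#'   columns enter linearly, everything else as factors. Typically
#'   columns `age`, `batch`, `origin`.
#' @return Corrected trait vector with provenance `"corrected"`.
#' @export
adjust_covariates <- function(trait, covariates) {
  n <- length(trait)
  if (!is.data.frame(covariates) || nrow(covariates) != n)
    stop_invalid("covariates must have one row per animal")
  if (trait_provenance(trait) == "normalized")
    stop_invalid("trait already normalized; correct before normalizing")
  obs <- !is.na(trait)
  if (any(!stats::complete.cases(covariates[obs, , drop = FALSE])))
    stop_invalid("covariates must be complete for all non-missing animals")
  cov_use <- covariates
  for (j in seq_along(cov_use))
    if (!is.numeric(cov_use[[j]])) {
      cov_use[[j]] <- factor(cov_use[[j]])
      if (nlevels(cov_use[[j]][obs, drop = TRUE]) >= sum(obs) && sum(obs) > 1L)
        stop(structure(class = c("ccqg_degenerate_design", "error",
                                 "condition"),
                       list(message = paste0("degenerate design: factor '",
                                             names(cov_use)[j],
                                             "' has one level per animal"),
                            call = sys.call())))
    }
  # drop constant columns (intercept absorbs them)
  keep <- vapply(cov_use, function(v)
    length(unique(v[obs])) > 1L, logical(1))
  dat <- cbind(data.frame(.y = trait), cov_use[, keep, drop = FALSE])
  fit <- stats::lm(.y ~ ., data = dat, na.action = stats::na.exclude)
  res <- as.numeric(stats::residuals(fit))
  names(res) <- names(trait)
  set_provenance(res, "corrected")
}

#' Rank-based quantile normalization
#'
#' Inverse-normal transform with Blom offsets:
#' `qnorm((rank - 0.375) / (n + 0.25))`, ties sharing their average
#' rank. The output is a monotone transform of the input; missing
#' values stay missing. A constant trait maps to all zeros (with a
#' warning).
#'
#' @param trait numeric vector with at least 3 non-missing values.
#' @return Normalized trait vector with provenance `"normalized"`.
#' @export
quantile_normalize <- function(trait) {
  obs <- !is.na(trait)
  n <- sum(obs)
  if (n < 3L) stop_invalid("need at least 3 non-missing values")
  out <- rep(NA_real_, length(trait))
  x <- trait[obs]
  if (length(unique(x)) == 1L) {
    warning("constant trait: all normalized scores are 0")
    out[obs] <- 0
  } else {
    r <- rank(x, ties.method = "average")
    out[obs] <- stats::qnorm((r - 0.375) / (n + 0.25))
  }
  names(out) <- names(trait)
  set_provenance(out, "normalized")
}

#' Per-line trait summaries
#'
#' Mean, SEM and animal count per line, ordered ascending by line mean
#' (ties broken by line ID). SEM is `NA` for single-animal lines.
#'
#' @param trait numeric vector per animal.
#' @param line line assignment per animal.
#' @return `data.frame` with columns `line`, `mean`, `sem`, `n`.
#' @export
line_summaries <- function(trait, line) {
  if (length(line) != length(trait))
    stop_invalid("every animal needs a line assignment")
  if (anyNA(line)) stop_invalid("every animal needs a line assignment")
  line <- as.character(line)
  ok <- !is.na(trait)
  sp <- split(trait[ok], line[ok])
  out <- data.frame(line = names(sp),
                    mean = vapply(sp, mean, numeric(1)),
                    sem = vapply(sp, function(v)
                      if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                      else NA_real_, numeric(1)),
                    n = vapply(sp, length, integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean, out$line), , drop = FALSE]
  rownames(out) <- NULL
  out
}
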