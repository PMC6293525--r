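#' Genotype a CC line from its mosaic
#'
#' Reads the true diploid genotype off the line's founder mosaic (dosage
#' of the alternate allele, 0/1/2) and applies array-style noise: each
#' call is replaced by a uniformly chosen different value with
#' probability `error_rate` and set missing with probability
#' `missing_rate`.
#'
#' @param mosaic a [breed_cc_line()] result.
#' @param founders the [simulate_founders()] object the mosaic was bred
#'   from (must share its map).
#' @param error_rate per-call error probability in \[0, 0.5).
#' @param missing_rate per-call missingness probability in \[0, 1\].
#' @param seed integer seed or `NULL`.
#' @return Integer vector of calls (named by marker) with `NA` for
#'   missing; one row of a genotype matrix.
#' @export
genotype_line <- function(mosaic, founders, error_rate = 0,
                          missing_rate = 0, seed = NULL) {
  map <- founders$map
  if (!identical(sort(mosaic$chr), sort(chromosomes(map))) ||
      !isTRUE(all.equal(unname(mosaic$chr_len[chromosomes(map)]),
                        unname(chr_lengths(map)))))
    stop_inconsistent("mosaic and founders do not share a genetic map")
  if (error_rate < 0 || error_rate >= 0.5)
    stop_invalid("error_rate must lie in [0, 0.5)")
  if (missing_rate < 0 || missing_rate > 1)
    stop_invalid("missing_rate must lie in [0, 1]")
  m <- nrow(map)
  if (m == 0L) return(stats::setNames(integer(0), character(0)))
  fm <- mosaic_founders_matrix(mosaic, map)
  al <- t(founders$alleles)          # M x 8
  calls <- al[cbind(seq_len(m), fm[, 1L])] + al[cbind(seq_len(m), fm[, 2L])]
  with_seed(seed, {
    if (error_rate > 0) {
      err <- stats::runif(m) < error_rate
      if (any(err)) {
        shift <- sample.int(2L, sum(err), replace = TRUE)
        calls[err] <- (calls[err] + shift) %% 3L
      }
    }
    if (missing_rate > 0)
      calls[stats::runif(m) < missing_rate] <- NA_integer_
    stats::setNames(as.integer(calls), map$marker)
  })
}
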