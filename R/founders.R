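#' Simulate eight inbred founder strains
#'
#' Generates a genetic map with markers spread uniformly at random along
#' each chromosome and draws fully homozygous biallelic founder genomes,
#' mimicking a panel of eight inbred strains genotyped on a SNP array.
#'
#' @param n_markers_per_chr integer vector, number of markers per
#'   chromosome (one entry per chromosome; may be 0).
#' @param chr_lengths_cM positive numeric vector of chromosome lengths in
#'   centimorgans, same length as `n_markers_per_chr`.
#' @param allele_freq probability in (0, 1) that a founder carries the
#'   alternate allele at a marker; alleles are drawn independently.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param founder_names optional character vector of 8 founder labels.
#' @param bp_per_cM physical scale used to lay markers on the bp axis.
#' @return An object of class `founder_haplotypes`: a list with elements
#'   `map` (a [genetic_map()]), `alleles` (8 x M 0/1 matrix, founders in
#'   rows) and `founders` (labels).
#' @examples
#' fh <- simulate_founders(c(50, 50), c(80, 60), seed = 1)
#' fh
#' @export
simulate_founders <- function(n_markers_per_chr, chr_lengths_cM,
                              allele_freq = 0.5, seed = NULL,
                              founder_names = LETTERS[1:8],
                              bp_per_cM = 5e5) {
  if (length(n_markers_per_chr) < 1L)
    stop_invalid("need at least one chromosome")
  if (length(chr_lengths_cM) != length(n_markers_per_chr))
    stop_invalid("n_markers_per_chr and chr_lengths_cM differ in length")
  if (any(n_markers_per_chr < 0) || any(n_markers_per_chr != round(n_markers_per_chr)))
    stop_invalid("marker counts must be non-negative integers")
  if (any(chr_lengths_cM <= 0))
    stop_invalid("chromosome lengths must be positive")
  if (allele_freq <= 0 || allele_freq >= 1)
    stop_invalid("allele_freq must lie in (0, 1)")
  if (length(founder_names) != 8L)
    stop_invalid("exactly 8 founder names required")

  n_chr <- length(chr_lengths_cM)
  chr_ids <- as.character(seq_len(n_chr))
  with_seed(seed, {
    pieces <- vector("list", n_chr)
    for (c_i in seq_len(n_chr)) {
      n <- n_markers_per_chr[c_i]
      cm <- sort(stats::runif(n, 0, chr_lengths_cM[c_i]))
      pieces[[c_i]] <- data.frame(chr = rep(chr_ids[c_i], n), cM = cm,
                                  stringsAsFactors = FALSE)
    }
    pos <- do.call(rbind, pieces)
    m_tot <- nrow(pos)
    if (m_tot > 0L) {
      map <- genetic_map(marker = sprintf("m%05d", seq_len(m_tot)),
                         chr = pos$chr,
                         bp = pmax(1L, as.integer(round(pos$cM * bp_per_cM))),
                         cM = pos$cM)
    } else {
      map <- genetic_map(character(0), character(0), integer(0), numeric(0))
    }
    attr(map, "chr_len") <- stats::setNames(as.numeric(chr_lengths_cM), chr_ids)
    alleles <- matrix(stats::rbinom(8L * m_tot, 1L, allele_freq), nrow = 8L,
                      dimnames = list(founder_names, map$marker))
    structure(list(map = map, alleles = alleles, founders = founder_names,
                   seed = seed),
              class = "founder_haplotypes")
  })
}

#' @export
print.founder_haplotypes <- function(x, ...) {
  cat("Founder haplotypes: 8 founders (", paste(x$founders, collapse = ", "),
      ")\n", sep = "")
  cat("  ", nrow(x$map), " markers on ", length(chromosomes(x$map)),
      " chromosome(s)\n", sep = "")
  if (nrow(x$map))
    cat("  alt-allele frequency: ",
        formatC(mean(x$alleles), digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}
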