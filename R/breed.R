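# Breeding simulator for eight-founder recombinant inbred lines.
#
# Haplotypes are stored per chromosome as run-length segments on the cM
# axis: list(b = numeric vector of segment end positions (the last entry
# equals the chromosome length), f = integer founder label per segment,
# 1-based). Gamete formation follows the Haldane model: crossover count
# Poisson(len / 100), positions uniform, no interference.

# one meiosis on one chromosome: recombine haplotypes h1/h2 into a gamete
meiosis_chr <- function(h1, h2, len) {
  n_co <- stats::rpois(1L, len / 100)
  first <- sample.int(2L, 1L)
  if (n_co == 0L) return(if (first == 1L) h1 else h2)
  pos <- sort(stats::runif(n_co, 0, len))
  bnd <- c(0, pos, len)
  n_piece <- length(bnd) - 1L
  src <- rep(c(first, 3L - first), length.out = n_piece)
  out_b <- vector("list", n_piece)
  out_f <- vector("list", n_piece)
  for (k in seq_len(n_piece)) {
    a <- bnd[k]; b <- bnd[k + 1L]
    h <- if (src[k] == 1L) h1 else h2
    i1 <- findInterval(a, h$b) + 1L            # first segment ending > a
    i2 <- findInterval(b, h$b, left.open = TRUE) + 1L  # segment containing b
    bb <- h$b[i1:i2]
    bb[length(bb)] <- b
    out_b[[k]] <- bb
    out_f[[k]] <- h$f[i1:i2]
  }
  b <- unlist(out_b, use.names = FALSE)
  f <- unlist(out_f, use.names = FALSE)
  # merge adjacent segments with the same founder
  keep <- c(f[-length(f)] != f[-1L], TRUE)
  list(b = b[keep], f = f[keep])
}

# an individual = list of two genomes; each genome = list over chromosomes
# of segment haplotypes
gamete <- function(ind, lens) {
  lapply(seq_along(lens), function(ci)
    meiosis_chr(ind[[1L]][[ci]], ind[[2L]][[ci]], lens[ci]))
}

cross <- function(mother, father, lens) {
  list(gamete(mother, lens), gamete(father, lens))
}

founder_individual <- function(f, lens) {
  hap <- lapply(lens, function(len) list(b = len, f = as.integer(f)))
  list(hap, hap)
}

#' Breed one Collaborative-Cross-style line
#'
#' Simulates the canonical eight-way funnel (four pairwise G1 crosses,
#' two four-way G2 crosses, one eight-way cross) followed by sib-mating
#' inbreeding, and returns the final individual's genome as founder
#' mosaic segments. Crossovers follow a Poisson process on the cM scale
#' (Haldane, no interference).
#'
#' @param founders a [simulate_founders()] object (only its chromosome
#'   lengths are used by the breeding process).
#' @param funnel permutation of 1..8 giving the funnel order, or `NULL`
#'   to randomize it.
#' @param n_inbreeding_gens number of sib-mating generations after the
#'   eight-way cross (0 returns the eight-way F1 itself). Lines are
#'   conventionally regarded as fully inbred from about 20 generations.
#' @param seed integer seed or `NULL`.
#' @param line_id label stored in the result.
#' @return Object of class `cc_mosaic`: list with `line`, `funnel`,
#'   `chr` (chromosome IDs), `chr_len` (cM lengths) and `haplotypes`
#'   (two genomes, each a per-chromosome list of `b`/`f` segment runs).
#' @examples
#' fh <- simulate_founders(c(20), c(100), seed = 1)
#' mos <- breed_cc_line(fh, seed = 2)
#' mosaic_founder_shares(mos)
#' @export
breed_cc_line <- function(founders, funnel = NULL, n_inbreeding_gens = 20L,
                          seed = NULL, line_id = "line1") {
  lens <- unname(chr_lengths(founders$map))
  chrs <- chromosomes(founders$map)
  if (n_inbreeding_gens < 0) stop_invalid("n_inbreeding_gens must be >= 0")
  with_seed(seed, {
    if (is.null(funnel)) funnel <- sample.int(8L)
    if (length(funnel) != 8L || !setequal(funnel, 1:8))
      stop_invalid("funnel must be a permutation of 1..8")
    funnel <- as.integer(funnel)
    # G1: four pairwise crosses of fully inbred founders (deterministic)
    g1 <- lapply(seq_len(4L), function(k) {
      a <- funnel[2L * k - 1L]; b <- funnel[2L * k]
      list(lapply(lens, function(len) list(b = len, f = a)),
           lapply(lens, function(len) list(b = len, f = b)))
    })
    # G2: two four-way crosses
    b1 <- cross(g1[[1L]], g1[[2L]], lens)
    b2 <- cross(g1[[3L]], g1[[4L]], lens)
    # G2:F1 eight-way cross; two sibs seed the inbreeding loop
    sib1 <- cross(b1, b2, lens)
    sib2 <- cross(b1, b2, lens)
    if (n_inbreeding_gens > 0L) {
      for (g in seq_len(n_inbreeding_gens)) {
        nxt1 <- cross(sib1, sib2, lens)
        nxt2 <- cross(sib1, sib2, lens)
        sib1 <- nxt1; sib2 <- nxt2
      }
    }
    structure(list(line = line_id, funnel = funnel, chr = chrs,
                   chr_len = stats::setNames(lens, chrs),
                   haplotypes = sib1, seed = seed),
              class = "cc_mosaic")
  })
}

#' @export
print.cc_mosaic <- function(x, ...) {
  n_seg <- sum(vapply(x$haplotypes, function(g)
    sum(vapply(g, function(h) length(h$f), integer(1))), integer(1)))
  cat("CC line mosaic '", x$line, "': ", length(x$chr), " chromosome(s), ",
      n_seg, " segments across both haplotypes\n", sep = "")
  cat("  funnel: ", paste(x$funnel, collapse = " "), "\n", sep = "")
  cat("  heterozygous genome fraction: ",
      formatC(mosaic_heterozygosity(x), digits = 4, format = "f"),
      "\n", sep = "")
  invisible(x)
}

# founder label of haplotype `hap` at cM positions `pos` on chromosome ci
mosaic_founder_at <- function(mosaic, chr, pos, hap = 1L) {
  ci <- match(as.character(chr), mosaic$chr)
  if (anyNA(ci)) stop_inconsistent("unknown chromosome in mosaic lookup")
  out <- integer(length(pos))
  for (c_u in unique(ci)) {
    h <- mosaic$haplotypes[[hap]][[c_u]]
    sel <- ci == c_u
    out[sel] <- h$f[findInterval(pos[sel], h$b, left.open = TRUE) + 1L]
  }
  out
}

# both haplotypes' founder labels at the markers of a map: M x 2 matrix
mosaic_founders_matrix <- function(mosaic, map) {
  cbind(mosaic_founder_at(mosaic, map$chr, map$cM, 1L),
        mosaic_founder_at(mosaic, map$chr, map$cM, 2L))
}

#' Per-founder genome shares of a mosaic
#'
#' cM-weighted fraction of the genome (averaged over the two haplotypes)
#' inherited from each founder; shares sum to 1.
#'
#' @param mosaic a [breed_cc_line()] result.
#' @return Numeric vector of length 8.
#' @export
mosaic_founder_shares <- function(mosaic) {
  tot <- numeric(8L)
  for (hap in 1:2) for (h in mosaic$haplotypes[[hap]]) {
    seg_len <- diff(c(0, h$b))
    tot <- tot + vapply(1:8, function(f) sum(seg_len[h$f == f]), numeric(1))
  }
  s <- sum(mosaic$chr_len) * 2
  if (s == 0) return(rep(1 / 8, 8L))
  tot / s
}

#' Heterozygous genome fraction of a mosaic
#'
#' cM-weighted fraction of the genome where the two haplotypes carry
#' different founder labels (residual heterozygosity of a partially
#' inbred line).
#'
#' @param mosaic a [breed_cc_line()] result.
#' @return Fraction in \[0, 1\].
#' @export
mosaic_heterozygosity <- function(mosaic) {
  het <- 0
  for (ci in seq_along(mosaic$chr)) {
    h1 <- mosaic$haplotypes[[1L]][[ci]]
    h2 <- mosaic$haplotypes[[2L]][[ci]]
    cuts <- sort(unique(c(h1$b, h2$b)))
    starts <- c(0, cuts[-length(cuts)])
    f1 <- h1$f[findInterval(starts, h1$b) + 1L]
    f2 <- h2$f[findInterval(starts, h2$b) + 1L]
    het <- het + sum((cuts - starts)[f1 != f2])
  }
  tot <- sum(mosaic$chr_len)
  if (tot == 0) 0 else het / tot
}

# segment table (cM and interpolated bp, 0-based half-open) for export
mosaic_segments <- function(mosaic, map) {
  rows <- list()
  for (ci in seq_along(mosaic$chr)) {
    ch <- mosaic$chr[ci]
    sub <- map[map$chr == ch, , drop = FALSE]
    cm2bp <- function(x) {
      if (nrow(sub) < 2L) return(as.integer(round(x * 5e5)))
      as.integer(round(stats::approx(sub$cM, sub$bp, xout = x, rule = 2,
                                     ties = "ordered")$y))
    }
    for (hap in 1:2) {
      h <- mosaic$haplotypes[[hap]][[ci]]
      start_cm <- c(0, h$b[-length(h$b)])
      rows[[length(rows) + 1L]] <- data.frame(
        line = mosaic$line, chrom = ch,
        start_bp = pmax(0L, cm2bp(start_cm) - 1L), end_bp = cm2bp(h$b),
        start_cM = start_cm, end_cM = h$b,
        founder = h$f, haplotype = hap, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a panel of CC lines with genotypes
#'
#' Convenience wrapper: simulates founders, breeds `n_lines` lines with
#' randomized funnels, and genotypes each line with the given error and
#' missingness rates.
#'
#' @inheritParams simulate_founders
#' @inheritParams breed_cc_line
#' @param n_lines number of lines.
#' @param error_rate,missing_rate genotyping noise, see [genotype_line()].
#' @param funnels optional list of funnels, one per line.
#' @return List with `founders`, `mosaics` (list of `cc_mosaic`) and
#'   `genotypes` (a `cc_geno`, see [genotype_line()]).
#' @export
simulate_cc_panel <- function(n_lines, n_markers_per_chr, chr_lengths_cM,
                              allele_freq = 0.5, n_inbreeding_gens = 20L,
                              error_rate = 0, missing_rate = 0,
                              funnels = NULL, seed = NULL) {
  with_seed(seed, {
    fh <- simulate_founders(n_markers_per_chr, chr_lengths_cM,
                            allele_freq = allele_freq)
    ids <- sprintf("CC%03d", seq_len(n_lines))
    mosaics <- vector("list", n_lines)
    calls <- matrix(NA_integer_, n_lines, nrow(fh$map),
                    dimnames = list(ids, fh$map$marker))
    for (i in seq_len(n_lines)) {
      mosaics[[i]] <- breed_cc_line(fh,
                                    funnel = if (is.null(funnels)) NULL else funnels[[i]],
                                    n_inbreeding_gens = n_inbreeding_gens,
                                    line_id = ids[i])
      calls[i, ] <- genotype_line(mosaics[[i]], fh, error_rate = error_rate,
                                  missing_rate = missing_rate)
    }
    names(mosaics) <- ids
    list(founders = fh, mosaics = mosaics,
         genotypes = structure(list(map = fh$map, calls = calls),
                               class = "cc_geno"),
         seed = seed)
  })
}
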