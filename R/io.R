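# Plain-text interfaces. Founder alleles and genotypes travel as CSV
# with markers as rows (marker, chr, bp, cM, then one column per
# founder/line; missing = NA); mosaics as BED-like TSV (0-based
# half-open bp); descent probabilities as long-format TSV; phenotypes
# as tidy CSV (one row per animal).

#' Write / read founder haplotypes
#'
#' @param founders a [simulate_founders()] object.
#' @param path file path (CSV).
#' @return `read_founders()` returns a `founder_haplotypes` object.
#' @export
write_founders <- function(founders, path) {
  df <- cbind(founders$map[, c("marker", "chr", "bp", "cM")],
              as.data.frame(t(founders$alleles)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_founders
#' @export
read_founders <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  map <- genetic_map(df$marker, df$chr, df$bp, df$cM)
  fn <- setdiff(names(df), c("marker", "chr", "bp", "cM"))
  if (length(fn) != 8L) stop_invalid("expected 8 founder columns")
  al <- t(as.matrix(df[match(map$marker, df$marker), fn]))
  dimnames(al) <- list(fn, map$marker)
  structure(list(map = map, alleles = al, founders = fn, seed = NULL),
            class = "founder_haplotypes")
}

#' Write / read a genotype matrix
#'
#' @param genotypes a `cc_geno` (list with `map`, `calls`).
#' @param path file path (CSV).
#' @return `read_genotypes()` returns a `cc_geno`.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- cbind(genotypes$map[, c("marker", "chr", "bp", "cM")],
              as.data.frame(t(genotypes$calls)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  map <- genetic_map(df$marker, df$chr, df$bp, df$cM)
  ids <- setdiff(names(df), c("marker", "chr", "bp", "cM"))
  calls <- t(as.matrix(df[match(map$marker, df$marker), ids]))
  mode(calls) <- "integer"
  dimnames(calls) <- list(ids, map$marker)
  structure(list(map = map, calls = calls), class = "cc_geno")
}

#' Write true mosaics as BED-like TSV
#'
#' Columns: chrom, start_bp, end_bp, founder, haplotype, line
#' (0-based half-open bp interpolated from the map).
#'
#' @param mosaics list of [breed_cc_line()] mosaics.
#' @param map a [genetic_map()] used for cM-to-bp interpolation.
#' @param path file path (TSV).
#' @export
write_mosaics <- function(mosaics, map, path) {
  seg <- do.call(rbind, lapply(mosaics, mosaic_segments, map = map))
  utils::write.table(seg[, c("chrom", "start_bp", "end_bp", "founder",
                             "haplotype", "line")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read descent probabilities (long TSV)
#'
#' Long format: line, marker, chrom, start, end, founder, prob.
#'
#' @param probs a `cc_descent`.
#' @param path file path (TSV).
#' @return `read_descent()` returns a `cc_descent`.
#' @export
write_descent <- function(probs, path) {
  d <- dim(probs$prob)
  founders <- dimnames(probs$prob)[[3]] %||% paste0("f", 1:8)
  long <- data.frame(
    line = rep(dimnames(probs$prob)[[1]], times = d[2] * 8L),
    marker = rep(rep(probs$map$marker, each = d[1]), times = 8L),
    chrom = rep(rep(probs$map$chr, each = d[1]), times = 8L),
    start = rep(rep(probs$map$bp_start, each = d[1]), times = 8L),
    end = rep(rep(probs$map$bp_end, each = d[1]), times = 8L),
    cM = rep(rep(probs$map$cM, each = d[1]), times = 8L),
    founder = rep(founders, each = d[1] * d[2]),
    prob = as.numeric(probs$prob),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_descent
#' @export
read_descent <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(line = "character",
                                           marker = "character",
                                           chrom = "character",
                                           founder = "character"))
  lines_ <- unique(long$line)
  markers <- unique(long$marker)
  founders <- unique(long$founder)
  prob <- array(NA_real_, c(length(lines_), length(markers), 8L),
                dimnames = list(lines_, markers, founders))
  prob[cbind(match(long$line, lines_), match(long$marker, markers),
             match(long$founder, founders))] <- long$prob
  first <- long[!duplicated(long$marker), ]
  map <- data.frame(marker = first$marker, chr = first$chrom,
                    bp_start = first$start, bp_end = first$end,
                    cM = if ("cM" %in% names(long)) first$cM else NA_real_,
                    stringsAsFactors = FALSE)
  structure(list(prob = prob, map = map, founders = founders,
                 loglik = NULL, viterbi = NULL, params = NULL),
            class = "cc_descent")
}

#' Write a genome scan / QTL table
#'
#' @param scan a [scan_genome()] result.
#' @param path file path (TSV).
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene table (BED-compatible TSV)
#'
#' Columns chrom, start, end, gene_id, score (unused), strand; start/end
#' 0-based half-open.
#'
#' @param path file path.
#' @return `data.frame` with `chrom`, `start`, `end`, `gene_id`,
#'   `strand`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[seq_len(min(6L, ncol(df)))] <-
    c("chrom", "start", "end", "gene_id", "score", "strand")[seq_len(min(6L, ncol(df)))]
  df$chrom <- as.character(df$chrom)
  df
}

#' Read a gene ranking (2-column CSV)
#'
#' @param path file path; columns gene_id, rank.
#' @return `data.frame` with `gene_id`, `rank`.
#' @export
read_ranking <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "rank")
  df
}
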