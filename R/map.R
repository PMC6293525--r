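#' Build a genetic map
#'
#' A genetic map is a data frame with one row per marker, giving its
#' chromosome, physical position (bp, 1-based) and genetic position (cM).
#' Markers are sorted by chromosome (in the order chromosomes first
#' appear) and by position within chromosome.
#'
#' @param marker character vector of unique marker IDs.
#' @param chr chromosome ID per marker.
#' @param bp integer base-pair position (1-based).
#' @param cM genetic position in centimorgans; must be non-decreasing
#'   within a chromosome, with ties allowed only at identical `bp`.
#' @return A `data.frame` of class `cc_map` with columns
#'   `marker`, `chr`, `bp`, `cM`.
#' @examples
#' genetic_map(c("m1", "m2"), chr = "1", bp = c(100L, 200L), cM = c(0, 1))
#' @export
genetic_map <- function(marker, chr, bp, cM) {
  map <- data.frame(marker = as.character(marker), chr = as.character(chr),
                    bp = as.integer(bp), cM = as.numeric(cM),
                    stringsAsFactors = FALSE)
  chr_order <- unique(map$chr)
  map <- map[order(match(map$chr, chr_order), map$cM, map$bp), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("cc_map", "data.frame")
  validate_map(map)
  map
}

validate_map <- function(map) {
  if (anyDuplicated(map$marker))
    stop_invalid("duplicated marker IDs in genetic map")
  if (any(map$cM < 0)) stop_invalid("negative cM positions")
  for (ch in unique(map$chr)) {
    sub <- map[map$chr == ch, , drop = FALSE]
    d <- diff(sub$cM)
    if (any(d < 0)) stop_invalid("cM positions decrease on chromosome ", ch)
    ties <- which(d == 0)
    if (length(ties) && any(sub$bp[ties] != sub$bp[ties + 1L]))
      stop_invalid("tied cM at distinct bp on chromosome ", ch)
  }
  invisible(map)
}

chromosomes <- function(map) unique(map$chr)

# chromosome lengths in cM; taken from an attribute when present (set by
# the simulator), otherwise the span of the mapped markers
chr_lengths <- function(map) {
  len <- attr(map, "chr_len")
  if (!is.null(len)) return(len)
  vapply(split(map$cM, factor(map$chr, levels = chromosomes(map))),
         function(x) if (length(x)) max(x) else 0, numeric(1))
}

# per-marker cM weights: half the gap to each neighbour, half-gap at the
# chromosome ends (so weights sum to the mapped span per chromosome);
# falls back to equal weights when a chromosome has a single marker
marker_cm_weights <- function(map) {
  w <- numeric(nrow(map))
  for (ch in chromosomes(map)) {
    i <- which(map$chr == ch)
    x <- map$cM[i]
    n <- length(x)
    if (n == 1L) { w[i] <- 1; next }
    gap <- diff(x)
    # half-gap to the left + half-gap to the right; chromosome ends reuse
    # their single flanking gap
    w[i] <- (c(gap[1], gap) + c(gap, gap[length(gap)])) / 2
    if (all(w[i] == 0)) w[i] <- 1   # all markers at one position
  }
  w
}

# bp interval bounds per marker, 0-based half-open, splitting at midpoints
# between adjacent markers on the same chromosome
marker_bp_intervals <- function(map) {
  start <- integer(nrow(map)); end <- integer(nrow(map))
  for (ch in chromosomes(map)) {
    i <- which(map$chr == ch)
    bp <- map$bp[i]
    n <- length(bp)
    mid <- if (n > 1L) floor((bp[-n] + bp[-1]) / 2) else integer(0)
    start[i] <- c(bp[1] - 1L, mid)
    end[i] <- c(mid, bp[n])
  }
  data.frame(start = start, end = end)
}
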