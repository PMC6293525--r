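# Mapping QTL support intervals to genes and testing whether a QTL's
# genes sit unusually high in a supplied disorder-implication ranking
# (rank 1 = most implicated). The ranking is a pre-resolved input table;
# ortholog mapping and database lookups happen upstream of this package.

#' Genes overlapping a QTL support interval
#'
#' Returns the genes whose \[start, end) span overlaps the QTL support
#' interval by at least 1 bp (0-based half-open coordinates on both
#' sides; strand ignored).
#'
#' @param interval a [define_qtl_interval()] result, or any list with
#'   `chr`, `bp_start`, `bp_end`.
#' @param genes `data.frame` with columns `chrom`, `start`, `end`,
#'   `gene_id` (0-based half-open), e.g. from [read_gene_table()].
#' @return The overlapping rows of `genes`.
#' @export
genes_in_interval <- function(interval, genes) {
  sub <- genes[genes$chrom == interval$chr, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("no genes on chromosome ", interval$chr)
    return(genes[0, , drop = FALSE])
  }
  if (any(sub$start >= sub$end)) stop_invalid("gene start must be < end")
  # half-open -> 1-based closed for IRanges
  q <- IRanges::IRanges(start = interval$bp_start + 1L,
                        end = interval$bp_end)
  s <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
  hits <- IRanges::findOverlaps(s, q, minoverlap = 1L)
  sub[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Rank enrichment of a gene set
#'
#' Tests whether the member genes occupy unusually high positions
#' (small ranks) in a genome-wide gene ranking. The default is a
#' one-sided Wilcoxon rank-sum test of member ranks against all other
#' ranked genes; the resampling alternative compares the members' mean
#' rank with random same-size gene sets (exhaustively enumerated when
#' feasible, Monte Carlo with the add-one rule otherwise).
#'
#' @param gene_ids character vector of member genes (e.g. from
#'   [genes_in_interval()]).
#' @param ranking `data.frame` with columns `gene_id` and `rank`
#'   (unique positive integers; rank 1 = most implicated).
#' @param method `"ranksum"` or `"resampling"`.
#' @param n_resample Monte Carlo draws (also the enumeration budget).
#' @param seed integer seed or `NULL`.
#' @return Object of class `cc_enrichment`: list with `p`, `statistic`
#'   (rank-sum W or observed mean rank), `method`, `member_ranks`,
#'   `n_members`, `n_ranked`.
#' @export
rank_enrichment <- function(gene_ids, ranking,
                            method = c("ranksum", "resampling"),
                            n_resample = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (anyDuplicated(ranking$rank) || any(ranking$rank < 1))
    stop_invalid("ranks must be unique positive integers")
  member <- ranking$rank[ranking$gene_id %in% unique(gene_ids)]
  if (length(member) == 0L)
    stop_invalid("no member gene present in the ranking")
  other <- ranking$rank[!ranking$gene_id %in% unique(gene_ids)]
  G <- nrow(ranking)
  k <- length(member)
  if (length(other) == 0L) {
    return(structure(list(p = 1, statistic = mean(member), method = method,
                          member_ranks = sort(member), n_members = k,
                          n_ranked = G),
                     class = "cc_enrichment"))
  }
  if (method == "ranksum") {
    wt <- stats::wilcox.test(member, other, alternative = "less",
                             exact = FALSE, correct = FALSE)
    p <- wt$p.value
    stat <- unname(wt$statistic)
  } else {
    obs <- mean(member)
    all_ranks <- ranking$rank
    n_total <- choose(G, k)
    if (is.finite(n_total) && n_total <= n_resample) {
      combs <- utils::combn(all_ranks, k)
      p <- mean(colMeans(combs) <= obs + 1e-12)
    } else {
      p <- with_seed(seed, {
        hits <- sum(vapply(seq_len(n_resample), function(i)
          mean(all_ranks[sample.int(G, k)]) <= obs + 1e-12, logical(1)))
        (1 + hits) / (n_resample + 1)
      })
    }
    stat <- obs
  }
  structure(list(p = p, statistic = stat, method = method,
                 member_ranks = sort(member), n_members = k, n_ranked = G),
            class = "cc_enrichment")
}

#' @export
print.cc_enrichment <- function(x, ...) {
  cat("Rank enrichment (", x$method, "): ", x$n_members, " of ",
      x$n_ranked, " ranked genes\n", sep = "")
  cat("  one-sided P = ", format(x$p, digits = 3),
      "  (statistic = ", format(x$statistic, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Simulate a genome-wide gene table and ranking
#'
#' Synthetic gene annotation for end-to-end runs: genes laid down
#' uniformly along the physical genome implied by a genetic map, plus a
#' random implication ranking over them.
#'
#' @param map a [genetic_map()].
#' @param n_genes number of genes.
#' @param gene_bp gene length in bp.
#' @param seed integer seed or `NULL`.
#' @return List with `genes` (chrom, start, end, gene_id, strand) and
#'   `ranking` (gene_id, rank).
#' @export
simulate_gene_table <- function(map, n_genes = 1000L, gene_bp = 20000L,
                                seed = NULL) {
  with_seed(seed, {
    chrs <- chromosomes(map)
    span <- vapply(chrs, function(ch) max(map$bp[map$chr == ch]), numeric(1))
    chr_pick <- sample(chrs, n_genes, replace = TRUE,
                       prob = span / sum(span))
    start <- vapply(seq_len(n_genes), function(i)
      as.integer(floor(stats::runif(1, 0, max(1, span[chr_pick[i]] - gene_bp)))),
      integer(1))
    genes <- data.frame(chrom = chr_pick, start = start,
                        end = start + as.integer(gene_bp),
                        gene_id = sprintf("G%05d", seq_len(n_genes)),
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    genes <- genes[order(match(genes$chrom, chrs), genes$start), ]
    rownames(genes) <- NULL
    ranking <- data.frame(gene_id = genes$gene_id,
                          rank = sample.int(n_genes),
                          stringsAsFactors = FALSE)
    list(genes = genes, ranking = ranking)
  })
}
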