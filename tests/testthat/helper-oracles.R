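# Independent oracles, deliberately written without rank(), cor(),
# p.adjust() or anything from the package itself.

# average ranks: count-smaller + half the ties
oracle_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Pearson correlation from the explicit sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_rank(x), oracle_rank(y))
}

# BH step-up by hand: sort, scale by m/rank, cumulative min from the top,
# clip at 1, restore input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# all permutations of 1..n via Heap's algorithm (distinct from the
# package's recursive generator)
oracle_permutations <- function(n) {
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  a <- seq_len(n)
  generate <- function(k) {
    if (k == 1L) {
      row <<- row + 1L
      out[row, ] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      generate(k - 1L)
      if (k %% 2L == 0L) {
        tmp <- a[i]; a[i] <<- a[k]; a[k] <<- tmp
      } else {
        tmp <- a[1L]; a[1L] <<- a[k]; a[k] <<- tmp
      }
    }
  }
  generate(n)
  out
}

# exhaustive two-sided permutation p-value for Spearman at small n
oracle_perm_pvalue <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  obs <- oracle_pearson(rx, ry)
  perms <- oracle_permutations(length(x))
  vals <- apply(perms, 1, function(idx) oracle_pearson(rx, ry[idx]))
  mean(abs(vals) >= abs(obs) - 1e-12)
}

# small staged matrix with named genes for network/cluster toys
toy_matrix <- function(values, genes = NULL, stage = "averaged") {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  rownames(values) <- genes
  colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  count_matrix(values, stage = stage)
}

# annotation placing genes consecutively on one chromosome
toy_annotation <- function(genes, chrom = "chr1") {
  ann <- data.frame(gene_id = genes, chrom = chrom,
                    start = (seq_along(genes) - 1) * 2000,
                    end = (seq_along(genes) - 1) * 2000 + 1500,
                    strand = "+", stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
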