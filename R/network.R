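#' Network construction parameters
#'
#' Bundle of the thresholds used when calling co-expression edges.
#'
#' @param rho_threshold minimum Spearman coefficient an edge must strictly
#'   exceed (in absolute value when `polarity = "signed"`). 0.4 is the
#'   conventional choice for small functional cohorts; genome-wide top-k
#'   modules use the much stricter [module_params()] preset (0.86).
#' @param alpha Benjamini-Hochberg FDR level edges must beat (`q < alpha`).
#' @param k module size for [top_k_module()].
#' @param polarity `"positive_only"` keeps only positively co-expressed
#'   pairs; `"signed"` keeps both signs (used for activator/repressor
#'   scoring).
#' @param p_method raw p-value method, `"t_approx"` (default) or
#'   `"permutation"` (see [correlation_pvalue()]).
#' @return a `network_params` list.
#' @export
network_params <- function(rho_threshold = 0.4, alpha = 0.05, k = 10,
                           polarity = c("positive_only", "signed"),
                           p_method = c("t_approx", "permutation")) {
  polarity <- match.arg(polarity)
  p_method <- match.arg(p_method)
  if (rho_threshold < 0 || rho_threshold > 1)
    stop("rho_threshold must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  structure(list(rho_threshold = rho_threshold, alpha = alpha, k = as.integer(k),
                 polarity = polarity, p_method = p_method),
            class = "network_params")
}

#' @rdname network_params
#' @details `module_params()` is the preset used for genome-wide top-k
#'   modules around a focal gene: `rho_threshold = 0.86`, `alpha = 1e-6`,
#'   `k = 10`.
#' @export
module_params <- function(rho_threshold = 0.86, alpha = 1e-6, k = 10,
                          polarity = "positive_only") {
  network_params(rho_threshold = rho_threshold, alpha = alpha, k = k,
                 polarity = polarity)
}

#' Spearman rank correlation of two expression profiles
#'
#' Average-ranks both profiles (ties get the mean of the ranks they occupy)
#' and returns the Pearson correlation of the rank vectors. Constant
#' profiles have no defined rank correlation: the result is `NA` (flagged
#' not-computable), never a substitute number.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return a single coefficient in `[-1, 1]`, or `NA` if either profile is
#'   constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("profiles must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("profiles must not contain missing values", call. = FALSE)
  if (max(x) == min(x) || max(y) == min(y)) return(NA_real_)
  stats::cor(rank(x), rank(y))
}

# all permutations of 1..n as a (n! x n) matrix, in a fixed recursive order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Two-sided p-value for a Spearman coefficient
#'
#' `t_approx` uses the t statistic `rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom — the standard large-sample approximation.
#' `|rho| = 1` returns `p = 0` with a logged note, since the statistic
#' degenerates there.
#'
#' `permutation` computes the two-sided permutation p-value: exhaustive over
#' all `n!` orderings when `n <= 7`, otherwise Monte-Carlo with
#' `n_resamples` draws (seed the R RNG for reproducibility; the add-one
#' estimator `(1 + hits) / (B + 1)` is used). Supply `x` and `y` so tied
#' ranks shape the null; without data, untied ranks `1..n` are assumed.
#'
#' @param rho observed coefficient in `[-1, 1]`.
#' @param n number of paired observations (`n >= 4` for `t_approx`).
#' @param method `"t_approx"` or `"permutation"`.
#' @param x,y optional original profiles (for tie-aware permutation nulls).
#' @param n_resamples Monte-Carlo resamples when `n > 7`.
#' @return two-sided p-value in `[0, 1]`.
#' @export
correlation_pvalue <- function(rho, n, method = c("t_approx", "permutation"),
                               x = NULL, y = NULL, n_resamples = 10000L) {
  method <- match.arg(method)
  if (is.na(rho)) return(NA_real_)
  if (abs(rho) > 1 + 1e-12) stop("|rho| must be <= 1", call. = FALSE)
  if (method == "t_approx") {
    if (n < 4) stop("t approximation needs n >= 4", call. = FALSE)
    return(spearman_p_t(rho, n))
  }
  if (!is.null(x) && !is.null(y)) {
    rx <- rank(x); ry <- rank(y)
    obs <- stats::cor(rx, ry)
  } else {
    rx <- seq_len(n); ry <- seq_len(n)
    obs <- rho
  }
  if (n <= 7) {
    perms <- all_permutations(as.integer(n))
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    mean(abs(rhos) >= abs(obs) - 1e-12)
  } else {
    hits <- sum(vapply(seq_len(n_resamples), function(i) {
      abs(stats::cor(rx, sample(ry))) >= abs(obs) - 1e-12
    }, logical(1)))
    (1 + hits) / (n_resamples + 1)
  }
}

# vectorized t-approximation p-values; |rho| ~ 1 collapses to p = 0
spearman_p_t <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  degenerate <- !is.na(rho) & abs(rho) >= 1 - 1e-15
  if (any(degenerate))
    message(sum(degenerate),
            " coefficient(s) at |rho| = 1: t approximation returns p = 0")
  p[degenerate] <- 0
  ok <- !is.na(rho) & !degenerate
  tt <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) controlling the expected false
#' discovery proportion, in input order. Thin validated front-end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]` (`NA` allowed
#'   for not-computable tests and passed through).
#' @return q-values in `[0, 1]`, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Number of unordered gene pairs in a cohort
#'
#' @param n cohort size (`n >= 0`).
#' @return `n * (n - 1) / 2`.
#' @export
count_pairs <- function(n) {
  if (n < 0) stop("cohort size must be non-negative", call. = FALSE)
  as.numeric(n) * (n - 1) / 2
}

# ranks of each gene's profile across columns (rows = genes)
rank_rows <- function(m) {
  t(apply(m, 1, rank))
}

constant_rows <- function(m) {
  apply(m, 1, function(v) max(v) == min(v))
}

resolve_cohort <- function(mat, cohort, what = "cohort") {
  ids <- as.character(cohort)
  missing <- setdiff(ids, rownames(mat))
  if (length(missing))
    stop(what, " gene(s) missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids
}

edge_frame <- function(gene_a, gene_b, rho, p, q) {
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]; gene_a[swap] <- gene_b[swap]; gene_b[swap] <- tmp
  data.frame(gene_a = gene_a, gene_b = gene_b, rho = rho, p = p, q = q,
             sign = ifelse(rho >= 0, "+", "-"), stringsAsFactors = FALSE)
}

#' All-pairs co-expression edges within a gene cohort
#'
#' Computes Spearman coefficients and p-values for every unordered pair in
#' the cohort, BH-adjusts within exactly that family of tests, and retains
#' pairs with `q < alpha` whose coefficient strictly exceeds the threshold
#' (`rho > rho_threshold` for `positive_only`, `|rho| > rho_threshold` for
#' `signed`). Constant-profile genes have no defined rank correlation; they
#' are excluded up front and reported via a message and the
#' `excluded_constant` attribute.
#'
#' @param mat a [count_matrix()] with stage `"averaged"` (or
#'   `"normalized"`).
#' @param cohort character vector of gene IDs, all present in the matrix,
#'   with at least two usable (non-constant) members.
#' @param params a [network_params()].
#' @param keep_all return every evaluated pair (with its q-value) instead of
#'   only the retained edges.
#' @return edge data.frame (`gene_a`, `gene_b`, `rho`, `p`, `q`, `sign`)
#'   sorted lexicographically by pair, with attributes `n_candidates`
#'   (pairs evaluated) and `excluded_constant`.
#' @export
pairwise_edges <- function(mat, cohort, params = network_params(),
                           keep_all = FALSE) {
  assert_stage(mat, c("averaged", "normalized"))
  ids <- resolve_cohort(mat, cohort)
  sub <- unclass(mat)[ids, , drop = FALSE]
  const <- constant_rows(sub)
  if (any(const))
    message("excluding ", sum(const), " constant-profile gene(s): ",
            paste(ids[const], collapse = ", "))
  use <- sort(ids[!const])
  if (length(use) < 2L)
    stop("fewer than 2 usable (non-constant) cohort genes", call. = FALSE)
  R <- rank_rows(unclass(mat)[use, , drop = FALSE])
  C <- stats::cor(t(R))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  rho <- C[idx]
  p <- spearman_p_t(rho, ncol(R))
  q <- bh_adjust(p)
  edges <- edge_frame(use[idx[, 1]], use[idx[, 2]], rho, p, q)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  if (!keep_all) {
    pass <- if (params$polarity == "positive_only")
      edges$rho > params$rho_threshold else abs(edges$rho) > params$rho_threshold
    edges <- edges[pass & edges$q < params$alpha, , drop = FALSE]
    rownames(edges) <- NULL
  }
  attr(edges, "n_candidates") <- count_pairs(length(use))
  attr(edges, "excluded_constant") <- ids[const]
  edges
}

#' Co-expression of one focal gene against the whole matrix
#'
#' Computes the Spearman edge between a focal gene and every other
#' non-constant gene; the BH family is that full set of tests. All
#' evaluated edges are returned ranked by coefficient (descending) so that
#' callers can either inspect the genome-wide profile or cut a module with
#' [top_k_module()].
#'
#' @param mat a [count_matrix()] with stage `"averaged"` (or
#'   `"normalized"`).
#' @param focal gene ID present in the matrix; a constant focal profile is
#'   an error.
#' @param params a [network_params()] (recorded for downstream filtering).
#' @return edge data.frame as in [pairwise_edges()] but unfiltered, sorted
#'   by `rho` descending, with attributes `focal`, `params` and
#'   `excluded_constant`.
#' @export
all_vs_one <- function(mat, focal, params = network_params()) {
  assert_stage(mat, c("averaged", "normalized"))
  focal <- resolve_cohort(mat, focal, what = "focal")
  if (length(focal) != 1L) stop("exactly one focal gene", call. = FALSE)
  m <- unclass(mat)
  fv <- m[focal, ]
  if (max(fv) == min(fv))
    stop("focal gene has a constant profile; Spearman undefined", call. = FALSE)
  others <- setdiff(rownames(m), focal)
  sub <- m[others, , drop = FALSE]
  const <- constant_rows(sub)
  if (any(const))
    message("excluding ", sum(const), " constant-profile gene(s)")
  others <- others[!const]
  R <- rank_rows(m[others, , drop = FALSE])
  rho <- as.vector(stats::cor(rank(fv), t(R)))
  p <- spearman_p_t(rho, ncol(m))
  q <- bh_adjust(p)
  edges <- edge_frame(rep(focal, length(others)), others, rho, p, q)
  partner <- ifelse(edges$gene_a == focal, edges$gene_b, edges$gene_a)
  edges <- edges[order(-edges$rho, partner), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "focal") <- focal
  attr(edges, "params") <- params
  attr(edges, "excluded_constant") <- setdiff(rownames(m), c(focal, others))
  edges
}

#' Top-k co-expression module around a focal gene
#'
#' Filters the [all_vs_one()] edges to those passing `q < alpha` and the
#' coefficient threshold, then keeps the `k` largest by `rho`; ties at the
#' cut are broken lexicographically by partner ID so results are
#' deterministic across platforms. Fewer than `k` survivors yield a shorter
#' module with a logged note.
#'
#' @param edges result of [all_vs_one()].
#' @param k module size; defaults to `params$k`.
#' @param params a [network_params()]; defaults to the params recorded on
#'   `edges`.
#' @return a `coex_module`: list with `focal` and a `partners` data.frame
#'   (`partner`, `rho`, `q`) sorted by `rho` descending.
#' @export
top_k_module <- function(edges, k = NULL, params = NULL) {
  focal <- attr(edges, "focal")
  if (is.null(focal))
    stop("edges must come from all_vs_one() (focal attribute missing)",
         call. = FALSE)
  if (is.null(params)) params <- attr(edges, "params")
  if (is.null(params)) params <- network_params()
  if (is.null(k)) k <- params$k
  partner <- ifelse(edges$gene_a == focal, edges$gene_b, edges$gene_a)
  pass <- edges$q < params$alpha
  pass <- pass & (if (params$polarity == "positive_only")
    edges$rho > params$rho_threshold else abs(edges$rho) > params$rho_threshold)
  df <- data.frame(partner = partner[pass], rho = edges$rho[pass],
                   q = edges$q[pass], stringsAsFactors = FALSE)
  df <- df[order(-df$rho, df$partner), , drop = FALSE]
  if (nrow(df) < k)
    message("only ", nrow(df), " significant partner(s) available for a ",
            k, "-gene module around ", focal)
  df <- utils::head(df, k)
  rownames(df) <- NULL
  structure(list(focal = focal, partners = df), class = "coex_module")
}

#' @export
print.coex_module <- function(x, ...) {
  cat(sprintf("co-expression module around %s (%d partners)\n",
              x$focal, nrow(x$partners)))
  print(x$partners)
  invisible(x)
}

#' Score candidate regulators by signed embedding in a cohort network
#'
#' For each candidate regulator (typically a transcription-factor gene),
#' counts the cohort genes whose edge to the candidate is significantly
#' positive (`rho > rho_threshold`, `q < alpha`) or significantly negative
#' (`rho < -rho_threshold`, `q < alpha`). The BH family is all candidate x
#' cohort pairs evaluated in the call. Many positive connections mark a
#' putative activator of the cohort, many negative ones a putative
#' repressor. Candidates overlapping the cohort are removed with a warning.
#'
#' @param mat a [count_matrix()] with stage `"averaged"` (or
#'   `"normalized"`).
#' @param cohort gene IDs of the functional cohort (e.g. lignin-modifying
#'   enzymes).
#' @param candidates gene IDs of candidate regulators; must be non-empty
#'   after overlap removal.
#' @param params a [network_params()]; polarity is forced to `"signed"`.
#' @return data.frame (`regulator`, `n_positive`, `n_negative`,
#'   `cohort_size`) ranked by `max(n_positive, n_negative)` descending, ties
#'   broken by regulator ID.
#' @export
regulator_embedding <- function(mat, cohort, candidates,
                                params = network_params(polarity = "signed")) {
  assert_stage(mat, c("averaged", "normalized"))
  cohort <- resolve_cohort(mat, cohort)
  candidates <- resolve_cohort(mat, candidates, what = "candidate")
  overlap <- intersect(candidates, cohort)
  if (length(overlap)) {
    warning("candidate(s) overlapping the cohort removed: ",
            paste(overlap, collapse = ", "))
    candidates <- setdiff(candidates, overlap)
  }
  if (length(candidates) == 0L)
    stop("no candidate regulators left to score", call. = FALSE)
  m <- unclass(mat)
  coh_const <- constant_rows(m[cohort, , drop = FALSE])
  cand_const <- constant_rows(m[candidates, , drop = FALSE])
  if (any(coh_const) || any(cand_const))
    message("excluding ", sum(coh_const) + sum(cand_const),
            " constant-profile gene(s) from correlation")
  coh_use <- cohort[!coh_const]
  cand_use <- candidates[!cand_const]
  Rc <- rank_rows(m[coh_use, , drop = FALSE])
  Rt <- rank_rows(m[cand_use, , drop = FALSE])
  C <- stats::cor(t(Rt), t(Rc))          # candidates x cohort
  p <- spearman_p_t(as.vector(C), ncol(m))
  q <- matrix(bh_adjust(p), nrow = nrow(C))
  sig <- q < params$alpha
  n_pos <- rowSums(sig & C > params$rho_threshold)
  n_neg <- rowSums(sig & C < -params$rho_threshold)
  scores <- data.frame(regulator = cand_use,
                       n_positive = as.integer(n_pos),
                       n_negative = as.integer(n_neg),
                       cohort_size = length(cohort),
                       stringsAsFactors = FALSE)
  if (any(cand_const))
    scores <- rbind(scores,
                    data.frame(regulator = candidates[cand_const],
                               n_positive = 0L, n_negative = 0L,
                               cohort_size = length(cohort),
                               stringsAsFactors = FALSE))
  scores <- scores[order(-pmax(scores$n_positive, scores$n_negative),
                         scores$regulator), , drop = FALSE]
  rownames(scores) <- NULL
  scores
}
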