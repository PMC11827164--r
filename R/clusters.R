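#' Parameters for contiguous cluster detection
#'
#' @param min_size minimum number of co-expressed (qualifying) genes a run
#'   must contain to be called a cluster (default 3).
#' @param rho_threshold minimum Spearman coefficient for a qualifying link
#'   (default 0.4; comparisons are `rho >= rho_threshold`).
#' @param alpha BH-FDR level for link significance (default 0.05).
#' @param max_silent_interior maximum number of consecutive non-qualifying
#'   (silent) genes tolerated inside a cluster (default 1).
#' @param expression_floor genes whose maximum normalized expression falls
#'   below this value are treated as silent and can never qualify
#'   (default 0 = disabled).
#' @param extension_stat statistic summarising a candidate gene's
#'   correlation with the current cluster members: `"median"` (default,
#'   robust to one outlier member) or `"mean"`.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(min_size = 3, rho_threshold = 0.4, alpha = 0.05,
                           max_silent_interior = 1, expression_floor = 0,
                           extension_stat = c("median", "mean")) {
  extension_stat <- match.arg(extension_stat)
  if (min_size < 2) stop("min_size must be at least 2", call. = FALSE)
  if (max_silent_interior < 0)
    stop("max_silent_interior must be non-negative", call. = FALSE)
  if (rho_threshold < 0 || rho_threshold > 1)
    stop("rho_threshold must lie in [0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(min_size = as.integer(min_size),
                 rho_threshold = rho_threshold, alpha = alpha,
                 max_silent_interior = as.integer(max_silent_interior),
                 expression_floor = expression_floor,
                 extension_stat = extension_stat),
            class = "cluster_params")
}

#' Order genes along each chromosome
#'
#' @param annotation a `gene_annotation` from [read_annotation()].
#' @return named list (one element per chromosome, chromosomes sorted by
#'   name) of gene IDs sorted by start coordinate; ties broken by end
#'   coordinate (shorter span first) then gene ID.
#' @export
order_genes_by_position <- function(annotation) {
  if (nrow(annotation) == 0L) stop("empty annotation", call. = FALSE)
  chroms <- sort(unique(annotation$chrom))
  out <- lapply(chroms, function(ch) {
    sub <- annotation[annotation$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end, sub$gene_id), , drop = FALSE]
    sub$gene_id
  })
  names(out) <- chroms
  out
}

#' Detect contiguous co-expressed gene clusters along the genome
#'
#' Greedy seed-and-extend scan over each chromosome's positional gene
#' order. A cluster is seeded wherever two consecutive genes are
#' significantly co-expressed (`rho >= rho_threshold` with BH `q < alpha`)
#' and extended rightward while the next gene's median (or mean) Spearman
#' coefficient against the current qualifying members stays at or above the
#' threshold and its link to the nearest qualifying member is significant.
#' Up to `max_silent_interior` consecutive non-qualifying genes are
#' tolerated inside a cluster; silent genes are trimmed from the ends, so
#' emitted clusters always start and end with qualifying members. Clusters
#' are maximal, non-overlapping (left-to-right greedy) and must hold at
#' least `min_size` qualifying genes.
#'
#' The BH family on a chromosome is every gene pair within positional
#' distance `max_silent_interior + 1` among usable genes — exactly the
#' pairs the scan can ever test as seed or extension links — so q-values do
#' not depend on the scan path. Constant-profile genes (e.g. silent
#' all-zero genes) and genes below `expression_floor` can never qualify but
#' may sit inside a cluster as silent members. Matrix genes without
#' annotation (and vice versa) are skipped with a logged count.
#'
#' @param mat a [count_matrix()] with stage `"averaged"` (or
#'   `"normalized"`).
#' @param annotation a `gene_annotation`.
#' @param params a [cluster_params()].
#' @return list of cluster calls, each a list with `cluster_id`, `chrom`,
#'   `members` (ordered, qualifying + silent), `qualifying`, `silent`,
#'   `occupancy` and `span` (0-based half-open base pairs); attribute
#'   `n_unannotated` counts skipped matrix genes.
#' @export
detect_contiguous_clusters <- function(mat, annotation,
                                       params = cluster_params()) {
  assert_stage(mat, c("averaged", "normalized"))
  m <- unclass(mat)
  shared <- intersect(rownames(m), annotation$gene_id)
  if (length(shared) == 0L)
    stop("annotation and matrix share no genes", call. = FALSE)
  n_unannotated <- nrow(m) - length(shared)
  if (n_unannotated > 0)
    message(n_unannotated, " matrix gene(s) without annotation skipped")
  ann <- annotation[annotation$gene_id %in% shared, , drop = FALSE]
  ordering <- order_genes_by_position(ann)
  span_of <- stats::setNames(split(ann[c("start", "end")], seq_len(nrow(ann))),
                             ann$gene_id)
  s <- params$max_silent_interior
  calls <- list()
  counter <- 0L
  for (ch in names(ordering)) {
    genes <- ordering[[ch]]
    n <- length(genes)
    if (n < 2L) next
    sub <- m[genes, , drop = FALSE]
    eligible <- !constant_rows(sub)
    if (params$expression_floor > 0)
      eligible <- eligible & apply(sub, 1, max) >= params$expression_floor
    R <- rank_rows(sub)            # ranks even for ineligible rows; unused there
    # test family: pairs within positional distance s + 1, both eligible
    pa <- integer(0); pb <- integer(0)
    for (d in seq_len(s + 1L)) {
      i <- seq_len(n - d)
      keep <- eligible[i] & eligible[i + d]
      pa <- c(pa, i[keep]); pb <- c(pb, i[keep] + d)
    }
    sig <- new.env(hash = TRUE, parent = emptyenv())
    if (length(pa)) {
      rho <- vapply(seq_along(pa),
                    function(k) stats::cor(R[pa[k], ], R[pb[k], ]),
                    numeric(1))
      p <- spearman_p_t(rho, ncol(sub))
      q <- bh_adjust(p)
      ok <- rho >= params$rho_threshold & q < params$alpha
      for (k in seq_along(pa))
        assign(paste0(pa[k], ":", pb[k]), ok[k], envir = sig)
    }
    is_sig <- function(i, j) {
      key <- paste0(min(i, j), ":", max(i, j))
      if (!exists(key, envir = sig, inherits = FALSE)) return(FALSE)
      get(key, envir = sig, inherits = FALSE)
    }
    stat_fun <- if (params$extension_stat == "median") stats::median else mean
    i <- 1L
    while (i < n) {
      if (!(eligible[i] && eligible[i + 1L] && is_sig(i, i + 1L))) {
        i <- i + 1L
        next
      }
      qual <- c(i, i + 1L)
      j <- i + 2L
      silent_run <- 0L
      while (j <= n && silent_run < s + 1L) {
        joined <- FALSE
        if (eligible[j] && is_sig(max(qual), j)) {
          rhos <- stats::cor(R[j, ], t(R[qual, , drop = FALSE]))
          if (stat_fun(as.vector(rhos)) >= params$rho_threshold) {
            qual <- c(qual, j)
            silent_run <- 0L
            joined <- TRUE
          }
        }
        if (!joined) silent_run <- silent_run + 1L
        j <- j + 1L
      }
      occupancy <- length(qual)
      if (occupancy >= params$min_size) {
        counter <- counter + 1L
        members <- genes[min(qual):max(qual)]
        qual_ids <- genes[qual]
        silent_ids <- setdiff(members, qual_ids)
        starts <- ann$start[match(members, ann$gene_id)]
        ends <- ann$end[match(members, ann$gene_id)]
        calls[[counter]] <- list(cluster_id = sprintf("cluster_%d", counter),
                                 chrom = ch,
                                 members = members,
                                 qualifying = qual_ids,
                                 silent = silent_ids,
                                 occupancy = occupancy,
                                 span = c(min(starts), max(ends)))
        i <- max(qual) + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  attr(calls, "n_unannotated") <- n_unannotated
  calls
}

#' Re-test all pairwise co-expression within one cluster call
#'
#' Confirmation step: computes the full pairwise Spearman edge table among
#' a cluster's members (qualifying and silent), BH-adjusting within the
#' cluster, and flags members with zero significant edges — silent members
#' and spurious groupings show up here.
#'
#' @param call one element of the [detect_contiguous_clusters()] result.
#' @param mat the expression matrix the call was made on.
#' @param params a [network_params()] supplying the significance rule.
#' @return edge data.frame over all member pairs (attribute
#'   `flagged_members` lists members with no significant edge).
#' @export
confirm_cluster_coexpression <- function(call, mat,
                                         params = network_params()) {
  members <- call$members
  missing <- setdiff(members, rownames(mat))
  if (length(missing))
    stop("cluster member(s) missing from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  edges <- suppressMessages(
    pairwise_edges(mat, members, params = params, keep_all = TRUE))
  pass <- if (params$polarity == "positive_only")
    edges$rho > params$rho_threshold else abs(edges$rho) > params$rho_threshold
  sig <- edges[pass & edges$q < params$alpha, , drop = FALSE]
  connected <- unique(c(sig$gene_a, sig$gene_b))
  attr(edges, "flagged_members") <- setdiff(members, connected)
  edges
}

#' Summarize a set of cluster calls
#'
#' @param calls list of cluster calls.
#' @return list with `n_clusters`, `n_genes` (total qualifying genes) and
#'   the occupancy `min`/`max`/`median` (NA for an empty call list).
#' @export
summarize_clusters <- function(calls) {
  if (length(calls) == 0L)
    return(list(n_clusters = 0L, n_genes = 0L,
                occupancy = c(min = NA_real_, max = NA_real_,
                              median = NA_real_)))
  occ <- vapply(calls, function(cl) cl$occupancy, numeric(1))
  list(n_clusters = length(calls),
       n_genes = as.integer(sum(occ)),
       occupancy = c(min = min(occ), max = max(occ),
                     median = stats::median(occ)))
}
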