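#' Median-of-ratios size factors
#'
#' Library-size scaling factors in the DESeq2 style: the per-gene reference
#' is the geometric mean of its counts across samples, taken over genes with
#' strictly positive counts in every sample; each sample's factor is the
#' median over those genes of count/reference, rescaled so the factors have
#' geometric mean 1. The result is invariant under gene reordering, and
#' multiplying one sample's counts by a constant multiplies its factor by
#' the same constant.
#'
#' Only the size-factor estimator is provided here; dispersion estimation
#' and differential testing are deliberately out of scope.
#'
#' @param raw a [count_matrix()] with stage `"raw"`.
#' @return named numeric vector of positive factors, one per sample.
#' @export
median_of_ratios_size_factors <- function(raw) {
  assert_stage(raw, "raw")
  m <- unclass(raw)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    stop("no gene has positive counts in every sample; cannot form the ",
         "geometric-mean reference (pseudo-reference fallback is disabled)",
         call. = FALSE)
  sub <- m[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  sf <- apply(sub / ref, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))   # normalize to geometric mean 1
  stats::setNames(sf, colnames(m))
}

# round half away from zero (spreadsheet-style), the rule used when the
# averaged matrix is rounded back to whole counts
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalize counts by size factors
#'
#' @param raw a [count_matrix()] with stage `"raw"`.
#' @param size_factors optional named factor vector; computed with
#'   [median_of_ratios_size_factors()] when missing.
#' @return a [count_matrix()] with stage `"normalized"`.
#' @export
normalize_counts <- function(raw, size_factors = NULL) {
  assert_stage(raw, "raw")
  if (is.null(size_factors)) size_factors <- median_of_ratios_size_factors(raw)
  if (!all(colnames(raw) %in% names(size_factors)))
    stop("size factors missing for some samples", call. = FALSE)
  sf <- size_factors[colnames(raw)]
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factors must be positive and finite", call. = FALSE)
  count_matrix(sweep(unclass(raw), 2, sf, "/"), stage = "normalized")
}

#' Normalize, average replicates and round
#'
#' The full preprocessing step applied before any network construction:
#' counts are divided by median-of-ratios size factors, replicates within
#' each condition are averaged, and the averaged values are rounded half
#' away from zero to whole numbers. Conditions with a single sample pass
#' through unaveraged (apart from normalization and rounding). Output
#' columns are conditions in their order of first appearance in the sheet.
#'
#' @param raw a [count_matrix()] with stage `"raw"`.
#' @param sheet sample sheet data.frame (`sample_id`, `condition`,
#'   `replicate`); every matrix sample must be listed.
#' @param size_factors optional precomputed factors.
#' @param round whether to round the averaged matrix to integers
#'   (default TRUE).
#' @return a [count_matrix()] with stage `"averaged"`, columns = conditions.
#' @export
normalize_and_average <- function(raw, sheet, size_factors = NULL,
                                  round = TRUE) {
  assert_stage(raw, "raw")
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(colnames(raw), sheet$sample_id)
  if (length(missing))
    stop("samples absent from the sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  norm <- normalize_counts(raw, size_factors)
  conds <- unique(sheet$condition)
  out <- vapply(conds, function(cond) {
    ids <- sheet$sample_id[sheet$condition == cond]
    ids <- intersect(ids, colnames(norm))
    if (length(ids) == 0L)
      stop("condition with zero samples in the matrix: ", cond, call. = FALSE)
    rowMeans(unclass(norm)[, ids, drop = FALSE])
  }, numeric(nrow(raw)))
  if (round) out <- round_half_away(out)
  dimnames(out) <- list(rownames(raw), conds)
  count_matrix(out, stage = "averaged")
}

#' Expression-tier thresholds
#'
#' Fractions of the housekeeping reference a gene's peak expression must
#' strictly exceed to be called highly (default > 50 %), moderately
#' (> 5 %) or detectably (> 1 %) expressed.
#'
#' @param high,moderate,detectable fractions with
#'   `0 < detectable < moderate < high <= 1`.
#' @export
classification_thresholds <- function(high = 0.50, moderate = 0.05,
                                      detectable = 0.01) {
  if (!(0 < detectable && detectable < moderate && moderate < high &&
        high <= 1))
    stop("need 0 < detectable < moderate < high <= 1", call. = FALSE)
  structure(list(high = high, moderate = moderate, detectable = detectable),
            class = "classification_thresholds")
}

#' Default housekeeping reference genes
#'
#' Actin, beta-tubulin and glyceraldehyde-3-phosphate dehydrogenase —
#' stably, highly expressed genes whose per-condition mean anchors relative
#' expression tiers. IDs are the JGI protein IDs used by the *Fomes
#' fomentarius* annotation (`actA` 1265750, `tubB` 1188384, `gpdA` 1372934);
#' supply your own set for any other genome.
#'
#' @return character vector of gene IDs.
#' @export
default_housekeeping <- function() {
  c(actA = "1265750", tubB = "1188384", gpdA = "1372934")
}

#' Classify genes into expression tiers relative to a housekeeping mean
#'
#' For each condition the reference is the arithmetic mean of the
#' housekeeping genes' values in that condition; a gene's peak ratio is its
#' maximum over conditions of value/reference, i.e. expression relative to
#' housekeeping in at least one condition. The tier is the highest threshold
#' the peak ratio strictly exceeds, else `"below"`. Tiers are reported
#' disjoint; nested counts (">= x % in at least one condition") are in the
#' summary.
#'
#' @param avg a [count_matrix()] with stage `"averaged"`.
#' @param housekeeping gene IDs of the reference set (all must be present);
#'   default [default_housekeeping()].
#' @param thresholds a [classification_thresholds()].
#' @return data.frame (`gene_id`, `peak_ratio`, `tier`) with the thresholds
#'   attached as an attribute; `tier` is a factor with levels
#'   high/moderate/detectable/below.
#' @export
classify_expression <- function(avg, housekeeping = default_housekeeping(),
                                thresholds = classification_thresholds()) {
  assert_stage(avg, "averaged")
  housekeeping <- as.character(housekeeping)
  missing <- setdiff(housekeeping, rownames(avg))
  if (length(missing))
    stop("housekeeping gene(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(housekeeping) < 1L)
    stop("need at least one housekeeping gene", call. = FALSE)
  m <- unclass(avg)
  ref <- colMeans(m[housekeeping, , drop = FALSE])
  if (any(ref <= 0))
    stop("housekeeping reference is zero in condition(s): ",
         paste(colnames(m)[ref <= 0], collapse = ", "),
         " - silent housekeeping genes indicate a data problem", call. = FALSE)
  ratio <- sweep(m, 2, ref, "/")
  peak <- apply(ratio, 1, max)
  tier <- ifelse(peak > thresholds$high, "high",
          ifelse(peak > thresholds$moderate, "moderate",
          ifelse(peak > thresholds$detectable, "detectable", "below")))
  out <- data.frame(gene_id = rownames(m), peak_ratio = unname(peak),
                    tier = factor(tier, levels = c("high", "moderate",
                                                   "detectable", "below")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  class(out) <- c("expression_classification", "data.frame")
  out
}

#' Summarize an expression classification
#'
#' Nested counts answer "how many genes exceed x % of the housekeeping mean
#' in at least one condition" (the way tier totals are usually reported);
#' disjoint counts partition the genome across the four tiers.
#'
#' @param cls result of [classify_expression()].
#' @return list with `disjoint` and `nested` named count vectors and
#'   `n_genes`.
#' @export
classification_summary <- function(cls) {
  thr <- attr(cls, "thresholds")
  disjoint <- table(cls$tier)
  nested <- c(high = sum(cls$peak_ratio > thr$high),
              moderate = sum(cls$peak_ratio > thr$moderate),
              detectable = sum(cls$peak_ratio > thr$detectable))
  list(disjoint = c(disjoint), nested = nested, n_genes = nrow(cls))
}

#' log10 heat-map transform
#'
#' Transforms a normalized or averaged matrix to the log10 scale used for
#' expression heat maps: values of at least 1 map to `log10(v)`, values
#' below 1 (including silent zeros) map to 0, so the heat-map floor is 0
#' rather than minus infinity. The floor/ceiling of the rendering colour
#' scale are recorded as attributes; values are not clipped.
#'
#' @param x a [count_matrix()] with stage `"normalized"` or `"averaged"`.
#' @param floor,ceiling colour-scale bounds (must satisfy floor < ceiling);
#'   conventional scales are 0-10 and 4.5-10.
#' @return numeric matrix of log10 values with `floor`/`ceiling` attributes.
#' @export
log10_heatmap <- function(x, floor = 0, ceiling = 10) {
  assert_stage(x, c("normalized", "averaged"))
  if (floor >= ceiling)
    stop("heat-map floor must be below the ceiling", call. = FALSE)
  m <- unclass(x)
  out <- ifelse(m >= 1, log10(m), 0)
  dimnames(out) <- dimnames(m)
  attr(out, "floor") <- floor
  attr(out, "ceiling") <- ceiling
  out
}

#' Percentage of a whole, rounded as printed
#'
#' `100 * numerator / denominator`, rounded half away from zero to
#' `decimals` digits — the arithmetic behind printed summary percentages
#' such as secretome fractions or the transcribed-genome fraction.
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator`, `denominator > 0`.
#' @param decimals digits after the point (default 1).
#' @return the rounded percentage.
#' @export
proportion_percent <- function(numerator, denominator, decimals = 1) {
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  if (numerator < 0 || numerator > denominator)
    stop("need 0 <= numerator <= denominator", call. = FALSE)
  round_half_away(100 * numerator / denominator, decimals)
}

#' Exact sum of named category counts
#'
#' @param counts numeric vector of non-negative integer counts (possibly
#'   named); an empty vector sums to 0.
#' @return integer total.
#' @export
category_sum <- function(counts) {
  counts <- unlist(counts, use.names = TRUE)
  if (length(counts) == 0L) return(0L)
  if (any(counts < 0)) stop("negative category count", call. = FALSE)
  as.integer(sum(counts))
}
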