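#' Gene-by-sample count matrix
#'
#' Light container for an expression matrix: a numeric matrix with gene IDs
#' as row names, sample (or condition) IDs as column names, and a `stage`
#' attribute recording where the matrix sits in the pipeline:
#'
#' * `"raw"` — integer read counts straight from quantification;
#' * `"normalized"` — counts divided by per-sample size factors;
#' * `"averaged"` — normalized counts averaged over replicates within each
#'   condition and rounded back to integers (columns are conditions).
#'
#' @param values numeric matrix with unique, non-empty row and column names.
#'   No negative or missing entries; `stage = "raw"` additionally requires
#'   all entries to be whole numbers.
#' @param stage one of `"raw"`, `"normalized"`, `"averaged"`.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(values, stage = c("raw", "normalized", "averaged")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty count matrix (no genes or no samples)", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid) || any(!nzchar(gid)) || any(!nzchar(sid)))
    stop("count matrix needs non-empty gene (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene ID: ", paste(unique(gid[duplicated(gid)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ID: ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(values))
    stop("count matrix contains missing values", call. = FALSE)
  if (any(values < 0))
    stop("count matrix contains negative values", call. = FALSE)
  if (stage == "raw" && any(values != round(values)))
    stop("stage=\"raw\" requires integer counts; found non-integer entries",
         call. = FALSE)
  structure(values, stage = stage, class = c("count_matrix", "matrix", "array"))
}

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
matrix_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) stop("not a staged count matrix", call. = FALSE)
  s
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d genes x %d samples\n",
              matrix_stage(x), nrow(x), ncol(x)))
  n <- min(5L, nrow(x)); m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

# subsetting keeps the stage flag; drop defaults to FALSE so gene slices
# stay matrices
#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, stage = attr(x, "stage"),
                     class = c("count_matrix", "matrix", "array"))
  out
}

# internal: coerce + check stage
assert_stage <- function(x, allowed, what = deparse(substitute(x))) {
  s <- matrix_stage(x)
  if (!s %in% allowed)
    stop(sprintf("%s has stage \"%s\"; expected %s", what, s,
                 paste(dQuote(allowed, q = FALSE), collapse = " or ")),
         call. = FALSE)
  invisible(s)
}
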