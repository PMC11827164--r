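#' Read a gene-by-sample count matrix from TSV/CSV
#'
#' The first column holds gene IDs, the header row holds sample IDs, and the
#' body is numeric. Input row and column order are preserved. Duplicated
#' gene or sample IDs, negative cells and non-numeric cells are hard errors
#' that name the offending ID or cell.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"csv"`. Quoted IDs containing the
#'   delimiter are handled by the standard CSV quoting rules.
#' @param stage pipeline stage of the stored matrix; `"raw"` for integer
#'   counts (the default), `"normalized"`/`"averaged"` when reading back a
#'   processed matrix.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("tsv", "csv"),
                        stage = c("raw", "normalized", "averaged")) {
  format <- match.arg(format)
  stage <- match.arg(stage)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty count matrix in ", path, call. = FALSE)
  gid <- as.character(df[[1L]])
  if (anyDuplicated(gid))
    stop("duplicate gene ID in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric cell at gene \"%s\", sample \"%s\" in %s",
                     gid[bad[1L]], names(body)[j], path), call. = FALSE)
      col <- num
    }
    if (anyNA(col))
      stop(sprintf("missing cell at gene \"%s\", sample \"%s\" in %s",
                   gid[which(is.na(col))[1L]], names(body)[j], path),
           call. = FALSE)
    if (any(col < 0))
      stop(sprintf("negative cell at gene \"%s\", sample \"%s\" in %s",
                   gid[which(col < 0)[1L]], names(body)[j], path),
           call. = FALSE)
    body[[j]] <- col
  }
  m <- as.matrix(body)
  rownames(m) <- gid
  count_matrix(m, stage = stage)
}

#' Write a count matrix to TSV/CSV
#'
#' Inverse of [read_counts()]: first column `gene_id`, then one column per
#' sample. Round-trips bit-exactly on IDs and to full double precision on
#' values.
#'
#' @param x a [count_matrix()].
#' @inheritParams read_counts
#' @export
write_counts <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = format == "csv",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Three-column TSV mapping samples to conditions and replicate indices:
#' `sample_id`, `condition`, `replicate`. Every sample may appear only once
#' and every (condition, replicate) slot may hold only one sample.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `condition`, `replicate`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.integer(df$replicate)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet data.frame with the three sample-sheet columns.
#' @export
validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "), call. = FALSE)
  slot <- paste(sheet$condition, sheet$replicate, sep = "\r")
  if (anyDuplicated(slot))
    stop("a (condition, replicate) slot holds more than one sample",
         call. = FALSE)
  if (any(!is.finite(sheet$replicate)) || any(sheet$replicate < 1L))
    stop("replicate indices must be positive integers", call. = FALSE)
  sheet
}

#' Write a sample sheet
#' @inheritParams validate_sample_sheet
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read gene coordinates from GFF3, GTF or a plain table
#'
#' Keeps only records of one feature type (default `"gene"`) and stores
#' coordinates internally as 0-based half-open intervals, converting once at
#' this boundary from the 1-based inclusive convention the input formats use.
#' Records without a parseable gene ID are skipped with a warning that counts
#' them.
#'
#' @param path file path.
#' @param format `"gff3"`, `"gtf"` or `"table"`. The table format is a TSV
#'   with columns `gene_id`, `chrom`, `start`, `end` and optionally `strand`
#'   (1-based inclusive coordinates, like GFF); a missing strand column or
#'   empty strand becomes `"unknown"`.
#' @param feature_type feature type to keep for GFF3/GTF (default `"gene"`).
#' @param id_attribute attribute holding the gene ID; default `"ID"` for
#'   GFF3 and `"gene_id"` for GTF.
#' @return a `gene_annotation` data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and `strand` in `{+,-,unknown}`.
#' @export
read_annotation <- function(path, format = c("gff3", "gtf", "table"),
                            feature_type = "gene", id_attribute = NULL) {
  format <- match.arg(format)
  if (format == "table") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("annotation table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    strand <- if ("strand" %in% names(df)) as.character(df$strand)
              else rep(NA_character_, nrow(df))
    ann <- data.frame(gene_id = as.character(df$gene_id),
                      chrom = as.character(df$chrom),
                      start = as.numeric(df$start) - 1,
                      end = as.numeric(df$end),
                      strand = strand, stringsAsFactors = FALSE)
  } else {
    if (is.null(id_attribute))
      id_attribute <- if (format == "gff3") "ID" else "gene_id"
    gr <- rtracklayer::import(path, format = format)
    md <- as.data.frame(gr)
    keep <- !is.na(md$type) & as.character(md$type) == feature_type
    md <- md[keep, , drop = FALSE]
    if (!id_attribute %in% names(md))
      ids <- rep(NA_character_, nrow(md))
    else
      ids <- as.character(md[[id_attribute]])
    ann <- data.frame(gene_id = ids,
                      chrom = as.character(md$seqnames),
                      start = md$start - 1,
                      end = as.numeric(md$end),
                      strand = as.character(md$strand),
                      stringsAsFactors = FALSE)
  }
  no_id <- is.na(ann$gene_id) | !nzchar(ann$gene_id)
  if (any(no_id)) {
    warning(sum(no_id), " annotation record(s) without a parseable gene ID skipped")
    ann <- ann[!no_id, , drop = FALSE]
  }
  ann$strand[is.na(ann$strand) | !ann$strand %in% c("+", "-")] <- "unknown"
  if (any(ann$start >= ann$end))
    stop("annotation interval with start >= end after conversion for gene: ",
         paste(utils::head(ann$gene_id[ann$start >= ann$end], 3), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "),
         call. = FALSE)
  rownames(ann) <- NULL
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Write gene annotation as a plain table
#'
#' Emits the 1-based inclusive `table` format accepted by
#' [read_annotation()], converting back from the internal 0-based half-open
#' representation.
#'
#' @param ann a `gene_annotation`.
#' @param path file path.
#' @export
write_annotation_table <- function(ann, path) {
  out <- data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                    start = ann$start + 1, end = ann$end,
                    strand = ann$strand, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene cohort list
#'
#' Plain text, one gene ID per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @param name cohort name; defaults to the file name without extension.
#' @return character vector of unique gene IDs with a `name` attribute.
#' @export
read_cohort <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- lines[nzchar(lines)]
  if (anyDuplicated(ids)) {
    warning("duplicate cohort members dropped: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids <- unique(ids)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  structure(ids, name = name)
}

#' Write a co-expression network for Cytoscape
#'
#' Two formats:
#' * `sif` — simple interaction lines `geneA <pp|pn> geneB`, where `pp`
#'   marks a positive and `pn` a negative Spearman edge (Cytoscape's signed
#'   network convention);
#' * `edge_table` — TSV with columns `gene_a`, `gene_b`, `rho`, `p`, `q`,
#'   `sign`, loadable as a Cytoscape edge attribute table.
#'
#' One line per unordered pair, ordered lexicographically by (gene_a,
#' gene_b). An empty edge list yields an empty SIF file or a header-only
#' edge table.
#'
#' @param edges edge data.frame as returned by [pairwise_edges()] /
#'   [all_vs_one()].
#' @param path file path.
#' @param format `"sif"` or `"edge_table"`.
#' @export
write_network <- function(edges, path, format = c("sif", "edge_table")) {
  format <- match.arg(format)
  cols <- c("gene_a", "gene_b", "rho", "p", "q", "sign")
  if (nrow(edges)) {
    edges <- edges[order(edges$gene_a, edges$gene_b), cols, drop = FALSE]
  } else {
    edges <- edges[, cols, drop = FALSE]
  }
  if (format == "sif") {
    rel <- ifelse(edges$sign == "+", "pp", "pn")
    writeLines(if (nrow(edges)) paste(edges$gene_a, rel, edges$gene_b)
               else character(0), path)
  } else {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Read back an edge table written by [write_network()]
#' @param path file path to an `edge_table` TSV.
#' @return edge data.frame with columns `gene_a`, `gene_b`, `rho`, `p`, `q`,
#'   `sign`.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = c(gene_a = "character",
                                         gene_b = "character",
                                         rho = "numeric", p = "numeric",
                                         q = "numeric", sign = "character"),
                          stringsAsFactors = FALSE)
  df
}

#' Write a log10 heat-map table
#'
#' Applies the [log10_heatmap()] transform (values below 1 floor to 0) to a
#' normalized or averaged matrix and writes the result as genes x conditions
#' TSV, preserving shape. Raw matrices are refused: normalize first.
#'
#' @param x a [count_matrix()] with stage `normalized` or `averaged`.
#' @param path file path.
#' @param floor,ceiling rendering scale bounds recorded for downstream
#'   colour mapping (values are not clipped).
#' @export
write_heatmap_table <- function(x, path, floor = 0, ceiling = 10) {
  assert_stage(x, c("normalized", "averaged"))
  hm <- log10_heatmap(x, floor = floor, ceiling = ceiling)
  df <- data.frame(gene_id = rownames(hm), unclass(hm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write cluster calls as a BED-like table
#'
#' Columns: `chrom`, `start`, `end` (cluster span, 0-based half-open BED
#' convention), `cluster_id`, `occupancy`, comma-joined `members`, and
#' comma-joined `silent` members (`.` when none).
#'
#' @param calls list of cluster calls from [detect_contiguous_clusters()].
#' @param path file path.
#' @export
write_clusters_bed <- function(calls, path) {
  rows <- lapply(calls, function(cl) {
    data.frame(chrom = cl$chrom, start = cl$span[1], end = cl$span[2],
               cluster_id = cl$cluster_id, occupancy = cl$occupancy,
               members = paste(cl$members, collapse = ","),
               silent = if (length(cl$silent)) paste(cl$silent, collapse = ",")
                        else ".",
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(chrom = character(), start = numeric(),
                        end = numeric(), cluster_id = character(),
                        occupancy = integer(), members = character(),
                        silent = character(), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
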