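#' Gene cohorts and focal genes from the *Fomes fomentarius* study design
#'
#' `cell_wall_cohort()` returns the 13 highly conserved cell-wall
#' biosynthesis genes (JGI protein IDs): the alpha-1,3-glucan synthase
#' `agsA`, two beta-1,3-glucan synthases `fksA`/`fksB`, all nine putative
#' chitin synthases, and the Rho GTPase `rhoA`. `study_focal_genes()`
#' returns the positive-control focal genes used for module construction
#' (`erg11`, lanosterol demethylase, and `tubB`, beta-tubulin).
#'
#' @return named character vector of gene IDs.
#' @export
cell_wall_cohort <- function() {
  c(agsA = "1363000", fksA = "1313161", fksB = "1370413",
    chs1 = "1364985", chs2 = "1367937", chs3 = "1258680",
    chs4 = "1397629", chs5 = "1316987", chs6 = "1374350",
    chs7 = "1303258", chs8 = "1370108", chs9 = "682709",
    rhoA = "1396228")
}

#' @rdname cell_wall_cohort
#' @export
study_focal_genes <- function() {
  c(erg11 = "1348887", tubB = "1188384")
}

#' Recompute the headline co-expression results from a normalized matrix
#'
#' Runs the downstream pipeline on a replicate-averaged, normalized
#' 27-condition count matrix (genes x conditions, gene IDs in the first
#' column): expression-tier classification against the housekeeping
#' reference, the 13-gene cell-wall cohort network at `rho > 0.4` and BH
#' FDR `< 0.05`, and the top-10 modules around `erg11` and `tubB` at the
#' module preset (`rho > 0.86`, FDR `< 1e-6`).
#'
#' @param path path to the normalized matrix (TSV or CSV).
#' @param format `"csv"` (default, the distribution format) or `"tsv"`.
#' @return list with `classification` (nested tier counts), `cell_wall`
#'   (`n_pairs` candidate pairs and `n_edges` retained positive pairs) and
#'   `modules` (per focal gene, the partner table and its minimum rho).
#' @export
reproduce_study_matrix <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  avg <- read_counts(path, format = format, stage = "averaged")
  cls <- classify_expression(avg)
  cohort_edges <- pairwise_edges(avg, cell_wall_cohort(),
                                 params = network_params(rho_threshold = 0.4,
                                                         alpha = 0.05))
  modules <- lapply(study_focal_genes(), function(focal) {
    edges <- all_vs_one(avg, focal, params = module_params())
    mod <- top_k_module(edges)
    list(module = mod, min_rho = min(mod$partners$rho))
  })
  list(classification = classification_summary(cls),
       cell_wall = list(n_pairs = attr(cohort_edges, "n_candidates"),
                        n_edges = nrow(cohort_edges),
                        edges = cohort_edges),
       modules = modules)
}
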