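#' Simulation configuration
#'
#' Describes a synthetic condition-series RNA-seq experiment: a
#' negative-binomial count matrix over `n_conditions` cultivation
#' conditions with replicated samples, a small set of stable, highly
#' expressed housekeeping genes, and per-sample library size factors. The
#' defaults mirror a 27-condition, biological-duplicate design so that the
#' package's default thresholds are exercised at the sample size they were
#' meant for.
#'
#' Per gene `g` and condition `c` the log mean is
#' `baseline_g + sd_g * u_gc`, where `u_gc` is a standard normal condition
#' effect (shared latent factors for planted structures, see
#' [planted_module()] and friends), `sd_g = condition_sd` for ordinary
#' genes and `housekeeping_sd` for housekeeping genes. Counts for sample
#' `s` in condition `c` are drawn `NB(mean = exp(eta_gc) * sf_s,
#' dispersion = nb_dispersion)`.
#'
#' @param n_genes number of genes.
#' @param n_conditions number of conditions (default 27).
#' @param replicates_per_condition scalar or length-`n_conditions` vector
#'   of replicate counts (default 2; singleton conditions are allowed and
#'   pass through replicate averaging unaveraged).
#' @param nb_dispersion shared NB dispersion (variance
#'   `mu + dispersion * mu^2`; default 0.1).
#' @param mean_log_range interval for per-gene baseline natural-log means
#'   (default `c(1, 8)`, counts roughly 3-3000).
#' @param condition_sd standard deviation of condition effects on the
#'   natural-log scale (default 1.5, a wide dynamic range across diverse
#'   substrates).
#' @param n_housekeeping number of housekeeping genes, placed at the end of
#'   the gene index (default 3).
#' @param housekeeping_log_mean,housekeeping_sd baseline log mean (default
#'   9, counts around 8000) and near-zero condition effect SD (default
#'   0.05) of the housekeeping genes.
#' @param size_factor_sd SD of log-normal per-sample size factors
#'   (rescaled to geometric mean 1; default 0.15).
#' @param contig_size genes per synthetic contig in the generated
#'   annotation (default 500).
#' @param seed RNG seed; identical configs give bit-identical datasets.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes, n_conditions = 27,
                              replicates_per_condition = 2,
                              nb_dispersion = 0.1,
                              mean_log_range = c(1, 8),
                              condition_sd = 1.5,
                              n_housekeeping = 3,
                              housekeeping_log_mean = 9,
                              housekeeping_sd = 0.05,
                              size_factor_sd = 0.15,
                              contig_size = 500,
                              seed = 1) {
  if (n_genes < 1 || n_conditions < 1)
    stop("n_genes and n_conditions must be positive", call. = FALSE)
  if (nb_dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  reps <- as.integer(replicates_per_condition)
  if (length(reps) == 1L) reps <- rep(reps, n_conditions)
  if (length(reps) != n_conditions || any(reps < 1L))
    stop("replicates_per_condition must be a positive scalar or one value ",
         "per condition", call. = FALSE)
  if (n_housekeeping < 0 || n_housekeeping >= n_genes)
    stop("n_housekeeping must be in [0, n_genes)", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_conditions = as.integer(n_conditions),
                 replicates = reps,
                 nb_dispersion = nb_dispersion,
                 mean_log_range = mean_log_range,
                 condition_sd = condition_sd,
                 n_housekeeping = as.integer(n_housekeeping),
                 housekeeping_log_mean = housekeeping_log_mean,
                 housekeeping_sd = housekeeping_sd,
                 size_factor_sd = size_factor_sd,
                 contig_size = as.integer(contig_size),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Planted structures for the simulator
#'
#' `planted_module()` makes a set of genes share a Gaussian latent factor
#' with the given loading, so any two members have latent correlation
#' `loading^2` (use [loading_for_rho()] to target a population
#' coefficient). `planted_regulator()` gives one regulator gene its own
#' latent trajectory and couples each target to it with the signed
#' `coupling` (latent correlation regulator-target = coupling, negative for
#' repression). `planted_cluster()` is a module whose members must sit at
#' consecutive gene indices (hence adjacent on a synthetic contig);
#' `silent` marks interior members to silence entirely (all-zero counts).
#'
#' @param members,targets integer gene indices.
#' @param regulator integer gene index of the regulator.
#' @param loading latent-factor loading in `[0, 1]`.
#' @param coupling signed coupling strength in `[-1, 1]`.
#' @param silent integer indices (subset of `members`, interior) of genes
#'   to silence.
#' @return a `planted_structure` list.
#' @export
planted_module <- function(members, loading) {
  if (loading < 0 || loading > 1)
    stop("loading must lie in [0, 1]", call. = FALSE)
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  structure(list(kind = "module", members = as.integer(members),
                 loading = loading), class = "planted_structure")
}

#' @rdname planted_module
#' @export
planted_regulator <- function(regulator, targets, coupling) {
  if (abs(coupling) > 1) stop("|coupling| must be <= 1", call. = FALSE)
  if (regulator %in% targets)
    stop("regulator cannot be one of its targets", call. = FALSE)
  structure(list(kind = "regulator", regulator = as.integer(regulator),
                 members = as.integer(targets), coupling = coupling),
            class = "planted_structure")
}

#' @rdname planted_module
#' @export
planted_cluster <- function(members, loading, silent = integer(0)) {
  members <- as.integer(sort(members))
  if (length(members) < 2L) stop("need at least 2 members", call. = FALSE)
  if (!all(diff(members) == 1L))
    stop("cluster members must be consecutive gene indices", call. = FALSE)
  silent <- as.integer(silent)
  if (length(silent)) {
    if (!all(silent %in% members))
      stop("silent indices must be cluster members", call. = FALSE)
    if (any(silent %in% range(members)))
      stop("silent members must be interior (not at cluster edges)",
           call. = FALSE)
  }
  if (loading < 0 || loading > 1)
    stop("loading must lie in [0, 1]", call. = FALSE)
  structure(list(kind = "contiguous_cluster", members = members,
                 loading = loading, silent = silent),
            class = "planted_structure")
}

#' Loading that targets a population rank correlation between members
#'
#' Two module members with loading `l` have latent correlation `l^2`;
#' count noise attenuates the observed Spearman coefficient slightly below
#' that, so treat the result as an upper anchor.
#'
#' @param rho target population correlation in `[0, 1]`.
#' @return the loading `sqrt(rho)`.
#' @export
loading_for_rho <- function(rho) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  sqrt(rho)
}

#' Simulate a condition-series RNA-seq dataset with planted structure
#'
#' Draws, in a fixed order (baselines, condition effects, one latent factor
#' per planted structure in list order, size factors, counts), a raw count
#' matrix plus its sample sheet, a positional gene annotation, and a truth
#' record sufficient to recompute every expected detection outcome.
#' Identical config + planted lists give bit-identical outputs; the caller's
#' RNG state is restored on exit.
#'
#' Genes are laid on synthetic contigs in index order with fixed spacing
#' (2 kb starts, 1.5 kb gene bodies), so `planted_cluster()` members are
#' physically adjacent. Housekeeping genes occupy the last
#' `n_housekeeping` indices and may not be members of planted structures.
#'
#' @param config a [simulation_config()].
#' @param planted list of [planted_module()], [planted_regulator()],
#'   [planted_cluster()] structures; members of the same kind must be
#'   disjoint and within `n_genes`.
#' @param size_factors optional vector of true per-sample factors (one per
#'   sample, recycled per condition replicate layout); drawn log-normally
#'   when NULL.
#' @return a `coex_sim` list: `counts` (raw [count_matrix()]), `sheet`
#'   (sample sheet), `annotation` (`gene_annotation`) and `truth` (a
#'   `coex_truth` record).
#' @export
simulate_dataset <- function(config, planted = list(), size_factors = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  C <- config$n_conditions
  hk_idx <- if (config$n_housekeeping > 0)
    (n - config$n_housekeeping + 1L):n else integer(0)
  for (st in planted) {
    idx <- c(st$members, st$regulator)
    if (any(idx < 1L | idx > n))
      stop("planted member index out of range", call. = FALSE)
    if (any(idx %in% hk_idx))
      stop("planted structures may not use housekeeping gene indices",
           call. = FALSE)
  }
  for (kind in unique(vapply(planted, `[[`, "", "kind"))) {
    mem <- unlist(lapply(planted[vapply(planted, `[[`, "", "kind") == kind],
                         `[[`, "members"))
    if (anyDuplicated(mem))
      stop("planted structures of kind \"", kind,
           "\" must have disjoint members", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  gene_ids <- sprintf("g%05d", seq_len(n))
  baseline <- stats::runif(n, config$mean_log_range[1], config$mean_log_range[2])
  sd_g <- rep(config$condition_sd, n)
  if (length(hk_idx)) {
    baseline[hk_idx] <- config$housekeeping_log_mean
    sd_g[hk_idx] <- config$housekeeping_sd
  }
  U <- matrix(stats::rnorm(n * C), nrow = n, ncol = C)
  for (st in planted) {
    f <- stats::rnorm(C)
    if (st$kind == "regulator") {
      U[st$regulator, ] <- f
      k <- st$coupling
      U[st$members, ] <- k * rep(f, each = length(st$members)) +
        sqrt(1 - k^2) * U[st$members, , drop = FALSE]
    } else {
      l <- st$loading
      U[st$members, ] <- l * rep(f, each = length(st$members)) +
        sqrt(1 - l^2) * U[st$members, , drop = FALSE]
    }
    if (st$kind == "contiguous_cluster" && length(st$silent))
      baseline[st$silent] <- -Inf
  }
  eta <- baseline + sd_g * U      # n x C log means (recycled by column)

  reps <- config$replicates
  cond_labels <- sprintf("c%02d", seq_len(C))
  cond_of_sample <- rep(seq_len(C), reps)
  sample_ids <- unlist(lapply(seq_len(C), function(ci)
    sprintf("%s_r%d", cond_labels[ci], seq_len(reps[ci]))))
  S <- length(sample_ids)
  if (is.null(size_factors)) {
    sf <- exp(stats::rnorm(S, 0, config$size_factor_sd))
    sf <- sf / exp(mean(log(sf)))
  } else {
    sf <- rep_len(as.numeric(size_factors), S)
  }
  names(sf) <- sample_ids

  mu <- exp(eta)[, cond_of_sample, drop = FALSE] *
    rep(sf, each = n)
  counts <- matrix(stats::rnbinom(n * S, size = 1 / config$nb_dispersion,
                                  mu = as.vector(mu)),
                   nrow = n, ncol = S,
                   dimnames = list(gene_ids, sample_ids))
  sheet <- data.frame(sample_id = sample_ids,
                      condition = cond_labels[cond_of_sample],
                      replicate = unlist(lapply(reps, seq_len)),
                      stringsAsFactors = FALSE)

  gi <- seq_len(n) - 1L
  contig <- sprintf("contig_%d", gi %/% config$contig_size + 1L)
  pos <- gi %% config$contig_size
  ann <- data.frame(gene_id = gene_ids, chrom = contig,
                    start = pos * 2000, end = pos * 2000 + 1500,
                    strand = "+", stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")

  truth <- structure(list(
    seed = config$seed,
    n_genes = n, n_conditions = C, replicates = reps,
    gene_ids = gene_ids,
    housekeeping = gene_ids[hk_idx],
    baselines = stats::setNames(baseline, gene_ids),
    size_factors = sf,
    nb_dispersion = config$nb_dispersion,
    structures = lapply(planted, function(st) {
      out <- list(kind = st$kind, members = gene_ids[st$members])
      if (st$kind == "regulator") {
        out$regulator <- gene_ids[st$regulator]
        out$coupling <- st$coupling
      } else {
        out$loading <- st$loading
      }
      if (st$kind == "contiguous_cluster")
        out$silent <- gene_ids[st$silent]
      out
    })), class = "coex_truth")

  structure(list(counts = count_matrix(counts, stage = "raw"),
                 sheet = sheet, annotation = ann, truth = truth),
            class = "coex_sim")
}

#' Export a simulated dataset as plain-text fixture files
#'
#' Writes `counts.tsv` (raw matrix), `samples.tsv` (sample sheet),
#' `annotation.tsv` (positional table) and `truth.json` (machine-readable
#' truth record) into a directory, each readable back through the package's
#' readers. Existing files are a hard error unless `overwrite = TRUE`.
#'
#' @param sim a `coex_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param overwrite allow clobbering existing fixture files.
#' @return invisibly, the four file paths.
#' @export
export_fixture <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "coex_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "samples.tsv", "annotation.tsv",
                            "truth.json"))
  names(paths) <- c("counts", "samples", "annotation", "truth")
  if (!overwrite && any(file.exists(paths)))
    stop("fixture file(s) already exist in ", dir,
         " (use overwrite = TRUE)", call. = FALSE)
  write_counts(sim$counts, paths["counts"])
  write_sample_sheet(sim$sheet, paths["samples"])
  write_annotation_table(sim$annotation, paths["annotation"])
  truth <- unclass(sim$truth)
  # JSON has no -Inf: encode silenced baselines as null, restore on read;
  # named vectors go through as.list() so names survive as object keys
  bl <- ifelse(is.finite(truth$baselines), truth$baselines, NA_real_)
  names(bl) <- names(truth$baselines)
  truth$baselines <- as.list(bl)
  truth$size_factors <- as.list(truth$size_factors)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}

#' Read back a truth record written by [export_fixture()]
#' @param path path to `truth.json`.
#' @return a `coex_truth` list.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  bl <- vapply(raw$baselines, function(v) if (is.null(v)) -Inf else v,
               numeric(1))
  structure(list(
    seed = raw$seed,
    n_genes = raw$n_genes, n_conditions = raw$n_conditions,
    replicates = as.integer(unlist(raw$replicates)),
    gene_ids = as.character(unlist(raw$gene_ids)),
    housekeeping = as.character(unlist(raw$housekeeping)),
    baselines = bl,
    size_factors = unlist(raw$size_factors),
    nb_dispersion = raw$nb_dispersion,
    structures = lapply(raw$structures, function(st)
      lapply(st, function(v) if (is.list(v)) unlist(v) else v))),
    class = "coex_truth")
}
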