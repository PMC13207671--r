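# Synthetic single-cell proteome generator: two biological groups, two
# acquisition batches, intensity-dependent (left-censored) detection,
# planted fold-changes, batch effects and procedural blanks.

#' Configuration for the synthetic single-cell proteome generator
#'
#' Builds and validates the parameter set that defines a simulated
#' two-group, two-batch single-cell proteomics experiment. Defaults emulate
#' a 12 vs 12 coelomocyte-scale design: ~2500 simulated proteins of which
#' roughly 1000--2000 are detected per cell, a strongly up-shifted
#' differential landscape, and a small panel of procedural blanks carrying
#' only background contamination.
#'
#' @param n_per_group Cells per biological group (default 12).
#' @param n_blanks Procedural blank samples (default 3).
#' @param n_proteins Number of simulated proteins (default 2500).
#' @param frac_up,frac_down Fractions of proteins with planted positive /
#'   negative group effects. Defaults (0.30 / 0.05) mirror the up-dominant
#'   remodeling the pipeline is designed to detect while keeping a clear
#'   null majority.
#' @param fc_log2_range Interval for the magnitude of planted log2
#'   fold-changes; default `c(log2(1.5), 3)` starts at the pipeline's own
#'   fold-change calling threshold.
#' @param mu0,sigma0 Mean and SD of the baseline true log2 abundance
#'   across proteins (default 19, 2.2 -- typical DIA protein-group scale).
#' @param sigma_cell Within-group cell-to-cell SD on the log2 scale
#'   (default 0.5).
#' @param batch_gamma_sd SD of the additive per-(batch, protein) shift
#'   (default 0.4).
#' @param batch_delta_range Interval for the multiplicative residual scale
#'   per (batch, protein) (default `c(0.8, 1.25)`).
#' @param detect_x0,detect_s Location and scale of the logistic detection
#'   curve on the true log2 intensity. Defaults (18.5, 1.2) give ~1500
#'   detected proteins per cell under the default abundance model.
#' @param blank_frac Fraction of proteins carrying background
#'   contamination (default 0.08).
#' @param blank_level Mean log2 level of the contaminant background
#'   (default 15).
#' @param seed RNG seed; all randomness flows from it through a fixed
#'   stream-splitting scheme (see [generate_dataset()]).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_per_group = 12, n_blanks = 3, n_proteins = 2500,
                         frac_up = 0.30, frac_down = 0.05,
                         fc_log2_range = c(log2(1.5), 3),
                         mu0 = 19, sigma0 = 2.2, sigma_cell = 0.5,
                         batch_gamma_sd = 0.4,
                         batch_delta_range = c(0.8, 1.25),
                         detect_x0 = 18.5, detect_s = 1.2,
                         blank_frac = 0.08, blank_level = 15,
                         seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_blanks = as.integer(n_blanks),
              n_proteins = as.integer(n_proteins),
              frac_up = frac_up, frac_down = frac_down,
              fc_log2_range = as.numeric(fc_log2_range),
              mu0 = mu0, sigma0 = sigma0, sigma_cell = sigma_cell,
              batch_gamma_sd = batch_gamma_sd,
              batch_delta_range = as.numeric(batch_delta_range),
              detect_x0 = detect_x0, detect_s = detect_s,
              blank_frac = blank_frac, blank_level = blank_level,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$frac_up + cfg$frac_down >= 1)
    stop("invalid synth_config: frac_up + frac_down must be < 1")
  if (cfg$n_per_group < 2)
    stop("invalid synth_config: n_per_group must be >= 2")
  if (cfg$detect_s <= 0)
    stop("invalid synth_config: detect_s must be > 0")
  if (cfg$sigma0 <= 0 || cfg$sigma_cell <= 0 || cfg$batch_gamma_sd <= 0)
    stop("invalid synth_config: all SDs (sigma0, sigma_cell, batch_gamma_sd) must be > 0")
  if (cfg$fc_log2_range[1] < 0)
    stop("invalid synth_config: fc_log2_range lower bound must be >= 0")
  if (cfg$fc_log2_range[2] < cfg$fc_log2_range[1])
    stop("invalid synth_config: fc_log2_range must be non-decreasing")
  if (cfg$n_blanks < 0 || cfg$n_proteins < 1)
    stop("invalid synth_config: n_blanks >= 0 and n_proteins >= 1 required")
  if (cfg$blank_frac < 0 || cfg$blank_frac > 1)
    stop("invalid synth_config: blank_frac must be in [0, 1]")
  invisible(cfg)
}

# Sub-seeds for the generator's independent random streams. Keeping blanks
# on their own stream means adding/removing blanks never perturbs cell draws.
synth_streams <- function(seed) {
  base <- as.integer(seed) %% 2147480000L
  list(proteins = base, cells = base + 1L, blanks = base + 2L)
}

#' Generate a synthetic single-cell proteome dataset
#'
#' Draws per-protein baseline log2 abundances, plants up/down group effects
#' and per-(batch, protein) location--scale batch effects, then observes
#' each cell through a logistic detection filter so that low-abundance
#' values are preferentially missing (left-censored MNAR). Procedural
#' blanks contain only the contaminant background, which is also added (on
#' the linear scale) to cell samples so blank subtraction has real signal
#' to remove.
#'
#' Cells are assigned to the two acquisition batches by interleaving within
#' each group (cell 1, 3, 5, ... of a group in batch `b1`; cell 2, 4, ...
#' in batch `b2`), so batch is never confounded with group. Randomness is
#' split into three streams seeded from `config$seed` (protein-level
#' parameters, cell observations, blank observations).
#'
#' @param config A [synth_config()] object.
#' @return A list with elements `matrix` (proteins x samples linear
#'   intensities, `NA` = not detected), `metadata` (data.frame with
#'   `sample_id`, `group`, `batch`, `is_blank`), and `truth` (a
#'   `ground_truth` list: `true_class`, `true_log2fc`, `gamma`, `delta`,
#'   `contaminant`, plus slots filled by [generate_gene_sets()] /
#'   [generate_ppi()]).
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  P <- config$n_proteins
  n_cells <- 2L * config$n_per_group
  streams <- synth_streams(config$seed)

  protein_ids <- sprintf("P%04d", seq_len(P))

  ## stream 1: protein-level parameters
  set.seed(streams$proteins)
  mu <- stats::rnorm(P, config$mu0, config$sigma0)
  n_up <- round(config$frac_up * P)
  n_down <- round(config$frac_down * P)
  true_class <- rep("null", P)
  if (n_up + n_down > 0) {
    planted <- sample.int(P, n_up + n_down)
    if (n_up > 0) true_class[planted[seq_len(n_up)]] <- "up"
    if (n_down > 0) true_class[planted[n_up + seq_len(n_down)]] <- "down"
  }
  lo <- config$fc_log2_range[1]; hi <- config$fc_log2_range[2]
  true_log2fc <- numeric(P)
  true_log2fc[true_class == "up"] <- stats::runif(n_up, lo, hi)
  true_log2fc[true_class == "down"] <- -stats::runif(n_down, lo, hi)
  contaminant <- stats::runif(P) < config$blank_frac
  gamma <- matrix(stats::rnorm(2L * P, 0, config$batch_gamma_sd), nrow = 2L,
                  dimnames = list(c("b1", "b2"), protein_ids))
  delta <- matrix(stats::runif(2L * P, config$batch_delta_range[1],
                               config$batch_delta_range[2]), nrow = 2L,
                  dimnames = list(c("b1", "b2"), protein_ids))

  ## design: interleaved batch assignment within each group
  group <- rep(c("control", "storage"), each = config$n_per_group)
  batch <- rep(c("b1", "b2"), length.out = config$n_per_group)
  batch <- c(batch, batch)
  cell_ids <- sprintf("%s_%02d", ifelse(group == "control", "ctl", "sto"),
                      c(seq_len(config$n_per_group), seq_len(config$n_per_group)))

  ## stream 2: cell observations
  set.seed(streams$cells)
  eff <- ifelse(group == "storage", 1, 0)
  x_true <- matrix(0, P, n_cells)
  for (j in seq_len(n_cells)) {
    b <- if (batch[j] == "b1") 1L else 2L
    eps <- stats::rnorm(P, 0, config$sigma_cell)
    x_true[, j] <- mu + true_log2fc * eff[j] + gamma[b, ] + delta[b, ] * eps
  }
  p_det <- stats::plogis((x_true - config$detect_x0) / config$detect_s)
  detected <- matrix(stats::runif(P * n_cells), P, n_cells) < p_det
  signal <- ifelse(detected, 2^x_true, 0)
  bg_cells <- matrix(0, P, n_cells)
  if (any(contaminant)) {
    nb <- sum(contaminant)
    bg_cells[contaminant, ] <- 2^(config$blank_level +
      matrix(stats::rnorm(nb * n_cells, 0, 0.3), nb, n_cells))
  }
  cells <- signal + bg_cells
  cells[cells == 0] <- NA_real_

  ## stream 3: blank observations
  blanks <- NULL
  blank_ids <- character(0)
  if (config$n_blanks > 0) {
    set.seed(streams$blanks)
    blanks <- matrix(NA_real_, P, config$n_blanks)
    if (any(contaminant)) {
      nb <- sum(contaminant)
      blanks[contaminant, ] <- 2^(config$blank_level +
        matrix(stats::rnorm(nb * config$n_blanks, 0, 0.3), nb, config$n_blanks))
    }
    blank_ids <- sprintf("blank_%02d", seq_len(config$n_blanks))
  }

  m <- cbind(cells, blanks)
  dimnames(m) <- list(protein_ids, c(cell_ids, blank_ids))

  metadata <- data.frame(
    sample_id = c(cell_ids, blank_ids),
    group = c(group, rep(NA_character_, config$n_blanks)),
    batch = c(batch, rep(c("b1", "b2"), length.out = config$n_blanks)),
    is_blank = c(rep(FALSE, n_cells), rep(TRUE, config$n_blanks)),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    protein_ids = protein_ids,
    true_class = stats::setNames(true_class, protein_ids),
    true_log2fc = stats::setNames(true_log2fc, protein_ids),
    gamma = gamma, delta = delta,
    contaminant = stats::setNames(contaminant, protein_ids),
    planted_set = NULL, clique_nodes = NULL),
    class = "ground_truth")

  list(matrix = m, metadata = metadata, truth = truth)
}

#' Generate gene-set fixtures with one planted enriched set
#'
#' Produces a collection of `n_decoys + 1` protein sets: a "planted" set in
#' which a fraction `enrich_frac` of members are drawn from up-class
#' proteins (the remainder from nulls), and `n_decoys` decoy sets sampled
#' uniformly from all simulated proteins. The planted membership is
#' recorded in the returned truth object.
#'
#' @param truth A `ground_truth` object from [generate_dataset()].
#' @param n_decoys Number of decoy sets.
#' @param set_size Members per set.
#' @param enrich_frac Fraction of planted-set members taken from up-class
#'   proteins (0..1).
#' @param seed RNG seed.
#' @return A list with `collection` (a [gene_set_collection()]) and
#'   `truth` (input truth with `planted_set` filled in).
#' @export
generate_gene_sets <- function(truth, n_decoys = 10, set_size = 50,
                               enrich_frac = 0.8, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (enrich_frac < 0 || enrich_frac > 1)
    stop("enrich_frac must be in [0, 1]")
  ids <- truth$protein_ids
  if (set_size > length(ids))
    stop("set_size (", set_size, ") exceeds available proteins (",
         length(ids), ")")
  up <- ids[truth$true_class == "up"]
  null <- ids[truth$true_class == "null"]
  n_enr <- round(enrich_frac * set_size)
  if (n_enr > length(up))
    stop("not enough up-class proteins (", length(up),
         ") for enrich_frac * set_size = ", n_enr)
  if (set_size - n_enr > length(null))
    stop("not enough null proteins for the planted set remainder")
  set.seed(as.integer(seed) %% 2147480000L)
  planted <- c(sample(up, n_enr), sample(null, set_size - n_enr))
  sets <- list(planted_set = planted)
  if (n_decoys > 0) {
    for (i in seq_len(n_decoys))
      sets[[sprintf("decoy_%02d", i)]] <- sample(ids, set_size)
  }
  desc <- c("planted enriched set",
            if (n_decoys > 0) sprintf("uniform decoy set %d", seq_len(n_decoys)))
  names(desc) <- names(sets)
  truth$planted_set <- planted
  list(collection = gene_set_collection(sets, desc), truth = truth)
}

#' Generate a PPI graph with a planted clique
#'
#' Builds an undirected simple graph on `n_nodes` protein identifiers
#' containing one planted complete subgraph of `clique_size` nodes plus
#' Erdos-Renyi background edges with probability `edge_prob`. The planted
#' nodes are recorded in the returned truth object; because a k-clique
#' contributes (k-1)! to each member's Maximal Clique Centrality, the
#' planted nodes dominate MCC ranks in sparse backgrounds.
#'
#' @param truth A `ground_truth` object.
#' @param clique_size Planted clique size (>= 2).
#' @param n_nodes Nodes in the graph (<= number of simulated proteins).
#' @param edge_prob Background edge probability in [0, 1].
#' @param seed RNG seed.
#' @return A list with `graph` (a [ppi_graph()]) and `truth` (with
#'   `clique_nodes` filled in).
#' @export
generate_ppi <- function(truth, clique_size = 6, n_nodes = 60,
                         edge_prob = 0.02, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (clique_size < 2) stop("clique_size must be >= 2")
  if (clique_size > n_nodes) stop("clique_size must be <= n_nodes")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  if (n_nodes > length(truth$protein_ids))
    stop("n_nodes exceeds available proteins")
  set.seed(as.integer(seed) %% 2147480000L)
  nodes <- sort(sample(truth$protein_ids, n_nodes))
  clique <- sort(sample(nodes, clique_size))
  pairs <- utils::combn(nodes, 2)
  in_clique <- pairs[1, ] %in% clique & pairs[2, ] %in% clique
  keep <- in_clique | stats::runif(ncol(pairs)) < edge_prob
  edges <- data.frame(node1 = pairs[1, keep], node2 = pairs[2, keep],
                      score = ifelse(in_clique[keep], 0.9, 0.5),
                      stringsAsFactors = FALSE)
  truth$clique_nodes <- clique
  list(graph = ppi_graph(nodes, edges), truth = truth)
}

#' Write ground truth as TSV
#'
#' Per-protein table: class, planted log2 fold-change, contaminant flag.
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  df <- data.frame(protein_id = truth$protein_ids,
                   true_class = unname(truth$true_class),
                   true_log2fc = unname(truth$true_log2fc),
                   contaminant = unname(truth$contaminant),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}
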