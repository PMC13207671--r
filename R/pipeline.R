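# End-to-end orchestration: read -> blank subtraction -> depth filter ->
# detection filter -> log2 + median-center -> impute -> batch-correct ->
# differential table -> QC report -> ORA -> GSEA -> hubs -> category
# tally, with a JSON manifest of parameters, seeds and artifact digests.

PIPELINE_ARTIFACTS <- c(
  "qc_sample_counts.tsv", "qc_overlap.tsv", "qc_correlation.tsv",
  "matrix_filtered.tsv", "matrix_processed.tsv", "differential_table.tsv",
  "zscore_topk.tsv", "ora_results.tsv", "gsea_results.tsv",
  "hub_table.tsv", "category_tally.tsv", "manifest.json")

#' Pipeline configuration
#'
#' Collects input paths, stage toggles, thresholds and the seed for a full
#' run. Thresholds default to the analysis' canonical values: sample depth
#' 900 identifications, detection in >= 4 replicates of one group,
#' FDR < 0.05 with |FC| >= 1.5, ORA p < 0.05, GSEA FDR < 0.25, imputation
#' downshift 1.8 / width 0.3, top 10 hubs.
#'
#' @param matrix,metadata Paths to the intensity matrix and metadata TSVs.
#' @param gene_sets Optional GMT path (enables ORA/GSEA).
#' @param edge_list Optional edge-list TSV path (enables hub scoring).
#' @param annotations Optional protein->category TSV path (enables the
#'   category tally).
#' @param out_dir Output directory for run artifacts.
#' @param blank_subtraction,batch_correction,run_ora,run_gsea,run_hubs
#'   Stage toggles.
#' @param min_proteins,min_reps,fdr,fc,ora_p,gsea_fdr,shift,width,hub_k
#'   Thresholds (see description).
#' @param gsea_n_perm GSEA permutations (default 1000).
#' @param gsea_set_filter Optional regular expression; only GMT sets whose
#'   names match are scored by GSEA (e.g. `"mito"` to restrict to
#'   mitochondria-related sets).
#' @param min_score Minimum PPI edge score retained.
#' @param seed Seed for stochastic stages (imputation, GSEA); required
#'   when any stochastic stage is enabled.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix, metadata, gene_sets = NULL,
                            edge_list = NULL, annotations = NULL,
                            out_dir = "scpda_run",
                            blank_subtraction = TRUE,
                            batch_correction = TRUE,
                            run_ora = TRUE, run_gsea = TRUE,
                            run_hubs = TRUE,
                            min_proteins = 900, min_reps = 4,
                            fdr = 0.05, fc = 1.5, ora_p = 0.05,
                            gsea_fdr = 0.25, shift = 1.8, width = 0.3,
                            hub_k = 10, gsea_n_perm = 1000,
                            gsea_set_filter = NULL, min_score = 0.0,
                            seed = NULL) {
  cfg <- list(matrix = matrix, metadata = metadata, gene_sets = gene_sets,
              edge_list = edge_list, annotations = annotations,
              out_dir = out_dir,
              blank_subtraction = isTRUE(blank_subtraction),
              batch_correction = isTRUE(batch_correction),
              run_ora = isTRUE(run_ora), run_gsea = isTRUE(run_gsea),
              run_hubs = isTRUE(run_hubs),
              min_proteins = as.numeric(min_proteins),
              min_reps = as.numeric(min_reps),
              fdr = as.numeric(fdr), fc = as.numeric(fc),
              ora_p = as.numeric(ora_p), gsea_fdr = as.numeric(gsea_fdr),
              shift = as.numeric(shift), width = as.numeric(width),
              hub_k = as.numeric(hub_k),
              gsea_n_perm = as.numeric(gsea_n_perm),
              gsea_set_filter = gsea_set_filter,
              min_score = as.numeric(min_score),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$fdr <= 0 || cfg$fdr > 1) stop("fdr must be in (0, 1]")
  if (cfg$fc < 1) stop("fc must be >= 1")
  if (cfg$min_proteins < 0 || cfg$min_reps < 1)
    stop("min_proteins >= 0 and min_reps >= 1 required")
  if (cfg$ora_p <= 0 || cfg$ora_p > 1) stop("ora_p must be in (0, 1]")
  if (cfg$gsea_fdr <= 0 || cfg$gsea_fdr > 1) stop("gsea_fdr must be in (0, 1]")
  if (cfg$shift < 0 || cfg$width <= 0) stop("shift >= 0 and width > 0 required")
  if (cfg$hub_k < 1) stop("hub_k must be >= 1")
  stochastic <- TRUE  # imputation may always draw; GSEA when enabled
  if (stochastic && is.null(cfg$seed))
    stop("seed required: stochastic stages (imputation/GSEA) are enabled")
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order (blank subtraction cannot be permuted
#' after the detection filter), writes every intermediate table plus a
#' JSON manifest containing the applied thresholds, seeds, and an md5
#' digest per artifact, and a human-readable log. Identical config and
#' inputs give identical digests.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the output directory path. On stage failure the
#'   partial outputs are retained beside a `FAILED` marker naming the
#'   stage.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n",
                                    "scpda", paste0(...)),
                            file = log_path, append = TRUE)
  unlink(log_path)
  unlink(file.path(config$out_dir, "FAILED"))
  stage <- "read"
  result <- tryCatch({
    m <- read_protein_matrix(config$matrix)
    meta <- read_sample_metadata(config$metadata, sample_ids = colnames(m))
    logf("read matrix: ", nrow(m), " proteins x ", ncol(m), " samples")

    stage <- "blank_subtraction"
    if (config$blank_subtraction) {
      m <- subtract_blank_background(m, meta)
      logf("blank subtraction applied; ", ncol(m), " cell samples retained")
    } else {
      m <- m[, colnames(m) %in% meta$sample_id[!meta$is_blank],
             drop = FALSE]
      logf("blank subtraction skipped")
    }

    stage <- "sample_depth_filter"
    depth <- filter_samples_by_depth(m, config$min_proteins)
    m <- depth$matrix
    logf("depth filter: ", sum(depth$report$retained), "/",
         nrow(depth$report), " samples kept (min_proteins = ",
         config$min_proteins, ")")

    stage <- "detection_filter"
    m <- filter_proteins_by_detection(m, meta, config$min_reps)
    logf("detection filter: ", nrow(m), " proteins kept (min_reps = ",
         config$min_reps, ")")
    write_protein_matrix(m, file.path(config$out_dir, "matrix_filtered.tsv"))

    stage <- "qc"
    ov <- overlap_counts(m, meta)
    lm_raw <- log2_and_center(m)
    write_tsv(depth$report, file.path(config$out_dir, "qc_sample_counts.tsv"))
    write_tsv(data.frame(shared = ov$shared, only_a = ov$only_a,
                         only_b = ov$only_b,
                         group_a = ov$groups[1], group_b = ov$groups[2]),
              file.path(config$out_dir, "qc_overlap.tsv"))

    stage <- "normalize_impute"
    params <- estimate_global_params(lm_raw, config$shift, config$width)
    lm <- impute_left_censored(lm_raw, params, seed = config$seed)
    logf(sprintf("imputation: mu_obs=%.4f sigma_obs=%.4f mu_imp=%.4f sigma_imp=%.4f",
                 params$mu_obs, params$sigma_obs, params$mu_imp,
                 params$sigma_imp))

    stage <- "batch_correction"
    if (config$batch_correction) {
      bc <- combat_adjust(lm, meta)
      lm <- bc$matrix
      logf("batch correction: EB converged in ",
           paste(bc$params$iterations, collapse = "/"), " iterations")
    } else {
      lm <- lm[, cell_meta(lm, meta)$sample_id, drop = FALSE]
      logf("batch correction skipped")
    }
    write_protein_matrix(lm, file.path(config$out_dir, "matrix_processed.tsv"))

    stage <- "qc_correlation"
    cr <- correlation_matrix(lm, use = "all")
    crdf <- data.frame(sample_id = rownames(cr), cr, check.names = FALSE)
    write_tsv(crdf, file.path(config$out_dir, "qc_correlation.tsv"))

    stage <- "differential"
    tab <- differential_table(lm, meta, fdr_threshold = config$fdr,
                              fc_threshold = config$fc)
    write_tsv(tab, file.path(config$out_dir, "differential_table.tsv"))
    n_up <- sum(tab$class == "up"); n_down <- sum(tab$class == "down")
    logf("differential: ", n_up, " up, ", n_down, " down at FDR < ",
         config$fdr, " and |FC| >= ", config$fc)

    stage <- "zscore_topk"
    k <- min(60, sum(!is.na(tab$q)))
    zs <- zscore_top_k(lm, tab, k = k)
    zdf <- data.frame(protein_id = zs$order,
                      cluster_position = seq_along(zs$order),
                      zs$matrix, check.names = FALSE)
    write_tsv(zdf, file.path(config$out_dir, "zscore_topk.tsv"))

    up_ids <- tab$protein_id[tab$class == "up"]

    stage <- "ora"
    if (config$run_ora && !is.null(config$gene_sets) &&
        length(up_ids) > 0) {
      sets <- read_gmt(config$gene_sets)
      ora <- ora_hypergeometric(up_ids, tab$protein_id, sets,
                                p_threshold = config$ora_p)
      write_tsv(ora, file.path(config$out_dir, "ora_results.tsv"))
      logf("ORA: ", sum(ora$significant), " significant term(s) at p < ",
           config$ora_p)
    } else {
      write_tsv(data.frame(term = character(0)),
                file.path(config$out_dir, "ora_results.tsv"))
      logf("ORA skipped")
    }

    stage <- "gsea"
    if (config$run_gsea && !is.null(config$gene_sets)) {
      sets <- read_gmt(config$gene_sets)
      if (!is.null(config$gsea_set_filter)) {
        keep <- grepl(config$gsea_set_filter, names(sets$sets))
        sets <- gene_set_collection(sets$sets[keep],
                                    sets$descriptions[keep])
        logf("GSEA set filter '", config$gsea_set_filter, "': ",
             sum(keep), " set(s) retained")
      }
      o <- order(tab$t, decreasing = TRUE)
      gsea <- gsea_run(tab$protein_id[o], tab$t[o], sets,
                       n_perm = config$gsea_n_perm,
                       seed = config$seed + 1L,
                       fdr_threshold = config$gsea_fdr)
      write_tsv(gsea, file.path(config$out_dir, "gsea_results.tsv"))
      logf("GSEA: ", sum(gsea$significant), " significant term(s) at FDR < ",
           config$gsea_fdr)
    } else {
      write_tsv(data.frame(term = character(0)),
                file.path(config$out_dir, "gsea_results.tsv"))
      logf("GSEA skipped")
    }

    stage <- "hubs"
    if (config$run_hubs && !is.null(config$edge_list) &&
        length(up_ids) > 0) {
      g <- read_edge_list(config$edge_list, min_score = config$min_score)
      sub <- subgraph_on(g, up_ids)
      if (length(sub$nodes) == 0) {
        warning("no up-DEP overlaps the PPI network; hub table empty")
        hubs <- data.frame(node = character(0))
      } else {
        hubs <- mcc_scores(sub)
        logf("hubs: top ", min(config$hub_k, nrow(hubs)), " of ",
             nrow(hubs), " DEP-subnetwork nodes")
      }
      write_tsv(hubs, file.path(config$out_dir, "hub_table.tsv"))
    } else {
      write_tsv(data.frame(node = character(0)),
                file.path(config$out_dir, "hub_table.tsv"))
      logf("hub scoring skipped")
    }

    stage <- "category_tally"
    if (!is.null(config$annotations) && length(up_ids) > 0) {
      ann <- read_tsv(config$annotations, colClasses = "character")
      tally <- category_tally(up_ids, ann)
    } else {
      tally <- data.frame(category = character(0), count = integer(0),
                          fraction = numeric(0))
    }
    write_tsv(tally, file.path(config$out_dir, "category_tally.tsv"))

    stage <- "manifest"
    artifacts <- setdiff(PIPELINE_ARTIFACTS, "manifest.json")
    digests <- as.list(tools::md5sum(file.path(config$out_dir, artifacts)))
    names(digests) <- artifacts
    manifest <- list(
      package = "scpda",
      parameters = config[c("blank_subtraction", "batch_correction",
                            "run_ora", "run_gsea", "run_hubs",
                            "min_proteins", "min_reps", "fdr", "fc",
                            "ora_p", "gsea_fdr", "shift", "width",
                            "hub_k", "gsea_n_perm", "min_score")],
      seeds = list(imputation = config$seed,
                   gsea = if (config$run_gsea) config$seed + 1L else NULL),
      stage_order = c("read", "blank_subtraction", "sample_depth_filter",
                      "detection_filter", "log2_median_center",
                      "imputation", "batch_correction", "differential",
                      "qc", "ora", "gsea", "hubs", "category_tally"),
      digests = digests)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logf("done")
    config$out_dir
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
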