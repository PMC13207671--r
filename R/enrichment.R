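# Functional enrichment: GMT gene-set collections, hypergeometric
# over-representation, weighted-KS permutation GSEA, and annotation
# category tallies.

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique set names,
#'   non-empty members).
#' @param descriptions Optional named character vector of descriptions.
#' @return List of class `gene_set_collection` with `sets` and
#'   `descriptions`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  if (any(vapply(sets, length, integer(1)) == 0))
    stop("sets must be non-empty")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then tab-separated members. Duplicate
#' members within a set are deduplicated with a warning; duplicate set
#' names or lines with fewer than 3 fields are rejected.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    nm <- f[1]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate member(s) in set '", nm, "' deduplicated")
      members <- unique(members)
    }
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, counts K (annotated in population) and k (annotated in
#' the study set) after intersecting with the population, and reports the
#' upper-tail hypergeometric probability P(X >= k), fold enrichment
#' (k/n)/(K/N), and BH-adjusted q. Significance is flagged on the raw p
#' (p < `p_threshold`), mirroring the conventional ORA cutoff; q is
#' reported alongside.
#'
#' @param study Character vector, a subset of `population`.
#' @param population Background universe (e.g. all quantified proteins).
#' @param sets A `gene_set_collection`.
#' @param p_threshold Raw-p significance cutoff (default 0.05).
#' @return data.frame sorted by p then term: `term`, `N`, `K`, `n`, `k`,
#'   `fold_enrichment`, `p`, `q`, `significant`.
#' @export
ora_hypergeometric <- function(study, population, sets, p_threshold = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  study <- unique(study); population <- unique(population)
  stray <- setdiff(study, population)
  if (length(stray) > 0)
    stop("study ids not in population: ", paste(stray, collapse = ", "))
  if (length(population) == 0) stop("population is empty")
  N <- length(population); n <- length(study)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], population)
    K <- length(members)
    k <- length(intersect(members, study))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (K == 0 || n == 0) 0 else (k / n) / (K / N)
    data.frame(term = nm, N = N, K = K, n = n, k = k,
               fold_enrichment = fe, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < p_threshold
  out[order(out$p, out$term), , drop = FALSE]
}

#' GSEA weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: hits add `|score|^weight / sum_hits
#' |score|^weight`, misses subtract `1/(N - N_H)`. The enrichment score
#' is the maximum-magnitude deviation of the running sum (signed); the
#' leading edge comprises set members at or before the extremum (at or
#' after it, for a negative ES).
#'
#' @param ranked Character vector of protein ids in ranking order.
#' @param scores Numeric ranking scores aligned with `ranked`.
#' @param set Character vector of set members.
#' @param weight Score-weighting exponent (default 1; 0 = classic KS).
#' @return List `es`, `running` (length-N profile), `leading_edge`.
#' @export
gsea_enrichment_score <- function(ranked, scores, set, weight = 1) {
  N <- length(ranked)
  if (length(scores) != N) stop("scores must align with ranked ids")
  if (!all(is.finite(scores))) stop("ranking scores must be finite")
  hit <- ranked %in% set
  nh <- sum(hit)
  if (nh == 0 || nh == N)
    stop("set must hit a non-empty strict subset of the ranked list")
  w <- abs(scores)^weight
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - nh)
  running <- cumsum(inc)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (es >= 0) ranked[seq_len(i_max)][hit[seq_len(i_max)]]
             else ranked[i_max:N][hit[i_max:N]]
  list(es = es, running = running, leading_edge = leading)
}

# Fast ES for permutations: positions of hits given as an index vector.
es_from_hits <- function(w, hit_idx, N) {
  inc <- rep(-1 / (N - length(hit_idx)), N)
  inc[hit_idx] <- w[hit_idx] / sum(w[hit_idx])
  r <- cumsum(inc)
  r[which.max(abs(r))]
}

#' Permutation GSEA over a gene-set collection
#'
#' Computes each term's enrichment score on the ranked list, builds a
#' null ES distribution from `n_perm` permutations (random same-size
#' member sets in `gene_set` mode, or group-label permutations with the
#' ranking metric recomputed in `phenotype` mode), and reports the
#' add-one permutation p-value, NES (ES divided by the mean |null ES| of
#' matching sign), and a sign-stratified FDR over terms flagged at
#' `fdr_threshold`.
#'
#' @param ranked Character vector of protein ids in ranking order
#'   (descending score).
#' @param scores Ranking scores aligned with `ranked`.
#' @param sets A `gene_set_collection`.
#' @param n_perm Permutations (>= 100; default 1000).
#' @param perm_type `"gene_set"` (default) or `"phenotype"`.
#' @param seed RNG seed.
#' @param weight Score-weighting exponent (default 1).
#' @param fdr_threshold Significance cutoff on the FDR (default 0.25).
#' @param expr_matrix,meta Required for `perm_type = "phenotype"`: the
#'   complete log2 matrix and metadata used to recompute the t-statistic
#'   ranking under label permutations.
#' @return data.frame: `term`, `size`, `es`, `nes`, `p_perm`, `q`,
#'   `significant`, `leading_edge` (comma-separated).
#' @export
gsea_run <- function(ranked, scores, sets, n_perm = 1000,
                     perm_type = c("gene_set", "phenotype"), seed = 1L,
                     weight = 1, fdr_threshold = 0.25,
                     expr_matrix = NULL, meta = NULL) {
  perm_type <- match.arg(perm_type)
  stopifnot(inherits(sets, "gene_set_collection"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  N <- length(ranked)
  w <- abs(scores)^weight
  set.seed(as.integer(seed) %% 2147480000L)

  term_names <- names(sets$sets)
  obs <- lapply(term_names, function(nm) {
    members <- intersect(sets$sets[[nm]], ranked)
    if (length(members) == 0 || length(members) == N) return(NULL)
    r <- gsea_enrichment_score(ranked, scores, members, weight)
    list(term = nm, size = length(members), es = r$es,
         leading = r$leading_edge)
  })
  keep <- !vapply(obs, is.null, logical(1))
  if (any(!keep))
    warning("term(s) with degenerate overlap left unscored: ",
            paste(term_names[!keep], collapse = ", "))
  obs <- obs[keep]
  if (length(obs) == 0)
    stop("no scoreable terms after intersecting with the ranked list")

  sizes <- vapply(obs, function(o) o$size, integer(1))
  null_es <- matrix(NA_real_, length(obs), n_perm)
  if (perm_type == "gene_set") {
    for (p in seq_len(n_perm)) {
      for (t in seq_along(obs)) {
        null_es[t, p] <- es_from_hits(w, sample.int(N, sizes[t]), N)
      }
    }
  } else {
    if (is.null(expr_matrix) || is.null(meta))
      stop("phenotype permutation needs expr_matrix and meta")
    cm <- cell_meta(expr_matrix, meta)
    for (p in seq_len(n_perm)) {
      pm <- cm
      pm$group <- sample(pm$group)
      tab <- differential_table(expr_matrix[, pm$sample_id, drop = FALSE],
                                pm, welch = FALSE)
      o <- order(tab$t, decreasing = TRUE)
      r_ids <- tab$protein_id[o]
      r_w <- abs(tab$t[o])^weight
      for (t in seq_along(obs)) {
        hit_idx <- which(r_ids %in% sets$sets[[obs[[t]]$term]])
        null_es[t, p] <- es_from_hits(r_w, hit_idx, length(r_ids))
      }
    }
  }

  es <- vapply(obs, function(o) o$es, numeric(1))
  nes <- numeric(length(obs)); p_perm <- numeric(length(obs))
  null_nes <- null_es
  for (t in seq_along(obs)) {
    nulls <- null_es[t, ]
    same <- nulls[sign(nulls) == sign(es[t]) | nulls == 0]
    denom <- mean(abs(same))
    if (!is.finite(denom) || denom == 0) denom <- mean(abs(nulls))
    nes[t] <- es[t] / denom
    p_perm[t] <- (1 + sum(abs(same) >= abs(es[t]))) / (1 + length(same))
    pos <- null_es[t, ] >= 0
    mpos <- mean(null_es[t, pos]); mneg <- mean(abs(null_es[t, !pos]))
    null_nes[t, pos] <- if (is.finite(mpos) && mpos > 0)
      null_es[t, pos] / mpos else NA_real_
    null_nes[t, !pos] <- if (is.finite(mneg) && mneg > 0)
      null_es[t, !pos] / mneg else NA_real_
  }

  # sign-stratified FDR: pooled null NES of matching sign vs observed NES
  q <- vapply(seq_along(obs), function(t) {
    if (nes[t] >= 0) {
      pool <- null_nes[null_nes >= 0 & is.finite(null_nes)]
      num <- mean(pool >= nes[t])
      den <- mean(nes[nes >= 0] >= nes[t])
    } else {
      pool <- null_nes[null_nes < 0 & is.finite(null_nes)]
      num <- mean(pool <= nes[t])
      den <- mean(nes[nes < 0] <= nes[t])
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  data.frame(term = vapply(obs, function(o) o$term, character(1)),
             size = sizes, es = es, nes = nes, p_perm = p_perm, q = q,
             significant = q < fdr_threshold,
             leading_edge = vapply(obs, function(o)
               paste(o$leading, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}

#' Tally annotation categories over a study set
#'
#' Counts category assignments over the study proteins; a protein with
#' several categories contributes one count to each, and fractions are
#' computed over assignments (not proteins). Proteins without any
#' annotation are tallied as `"unannotated"`.
#'
#' @param study Character vector of protein ids.
#' @param annotation data.frame with columns `protein_id`, `category`
#'   (repeated rows allowed).
#' @return data.frame `category`, `count`, `fraction`, sorted by count
#'   descending then category.
#' @export
category_tally <- function(study, annotation) {
  stopifnot(all(c("protein_id", "category") %in% colnames(annotation)))
  study <- unique(study)
  if (length(study) == 0)
    return(data.frame(category = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  ann <- unique(annotation[annotation$protein_id %in% study, ,
                           drop = FALSE])
  unann <- setdiff(study, ann$protein_id)
  cats <- c(ann$category, rep("unannotated", length(unann)))
  tab <- table(cats)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction <- out$count / sum(out$count)
  out[order(-out$count, out$category), , drop = FALSE]
}
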