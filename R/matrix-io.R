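# Protein-group matrix and sample metadata I/O.
#
# Matrix dialect (DIA-NN protein-group style): tab-separated, first column
# protein ids, remaining columns sample ids, linear-scale intensities,
# empty field or 0 = not detected.

#' Read a protein quantification matrix
#'
#' Parses a proteins x samples TSV of linear intensities. Zeros and empty
#' fields become `NA` (not detected); row and column order are preserved.
#'
#' @param path Path to the TSV (first column protein id, header row of
#'   sample ids).
#' @return Numeric matrix with protein rownames and sample colnames; `NA`
#'   marks missing values.
#' @export
read_protein_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_tsv(path, colClasses = NA)
  if (ncol(df) < 2) stop("matrix file needs a protein id column plus >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein id: ", ids[duplicated(ids)][1])
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id: ", samples[duplicated(samples)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative intensity at protein '%s', sample '%s'",
                 ids[neg[1, 1]], samples[neg[1, 2]]))
  m[!is.na(m) & m == 0] <- NA_real_
  dimnames(m) <- list(ids, samples)
  m
}

#' Write a protein quantification matrix
#'
#' Inverse of [read_protein_matrix()]: missing values are written as empty
#' fields, numbers with full (round-trip safe) precision, UTF-8 with Unix
#' newlines.
#'
#' @param m Numeric matrix with protein rownames and sample colnames.
#' @param path Output path.
#' @param id_col Name of the leading id column (default "protein_id").
#' @export
write_protein_matrix <- function(m, path, id_col = "protein_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), stringsAsFactors = FALSE)
  names(df) <- id_col
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
  write_tsv(df, path)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' Required columns: `sample_id`, `group`, `batch`, `is_blank`. Blanks need
#' no group; non-blank samples must carry a group and a batch, and at most
#' two distinct group labels are allowed (two-group design).
#'
#' @param path Path to the metadata TSV.
#' @param sample_ids Optional character vector (e.g. matrix colnames);
#'   every one of these must be present in the metadata.
#' @return A data.frame with the four validated columns.
#' @export
read_sample_metadata <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read_tsv(path, colClasses = "character")
  validate_sample_metadata_df(df, sample_ids)
}

validate_sample_metadata_df <- function(df, sample_ids = NULL) {
  req <- c("sample_id", "group", "batch", "is_blank")
  miss <- setdiff(req, colnames(df))
  if (length(miss) > 0)
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  df$group[!is.na(df$group) & df$group == ""] <- NA_character_
  blank_raw <- toupper(as.character(df$is_blank))
  if (!all(blank_raw %in% c("TRUE", "FALSE", "T", "F", "0", "1")))
    stop("is_blank must be logical (TRUE/FALSE)")
  df$is_blank <- blank_raw %in% c("TRUE", "T", "1")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  cells <- df[!df$is_blank, , drop = FALSE]
  if (any(is.na(cells$group)))
    stop("non-blank sample(s) without group: ",
         paste(cells$sample_id[is.na(cells$group)], collapse = ", "))
  if (any(is.na(cells$batch) | cells$batch == ""))
    stop("non-blank sample(s) without batch: ",
         paste(cells$sample_id[is.na(cells$batch) | cells$batch == ""],
               collapse = ", "))
  groups <- unique(cells$group)
  if (length(groups) > 2)
    stop("two-group design required; found groups: ",
         paste(sort(groups), collapse = ", "))
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, df$sample_id)
    if (length(absent) > 0)
      stop("sample(s) in matrix absent from metadata: ",
           paste(absent, collapse = ", "))
  }
  df[, req]
}

#' Write a sample metadata table
#' @param meta Metadata data.frame (`sample_id`, `group`, `batch`,
#'   `is_blank`).
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  out <- meta[, c("sample_id", "group", "batch", "is_blank")]
  out$is_blank <- ifelse(out$is_blank, "TRUE", "FALSE")
  write_tsv(out, path)
  invisible(path)
}

# Non-blank metadata rows aligned to matrix columns.
cell_meta <- function(m, meta) {
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("sample(s) in matrix absent from metadata: ",
         paste(colnames(m)[is.na(meta$sample_id)], collapse = ", "))
  meta[!meta$is_blank, , drop = FALSE]
}

group_indices <- function(m, meta) {
  cm <- cell_meta(m, meta)
  groups <- sort(unique(cm$group))
  if (length(groups) != 2)
    stop("exactly two biological groups required; found: ",
         paste(groups, collapse = ", "))
  lapply(stats::setNames(groups, groups),
         function(g) match(cm$sample_id[cm$group == g], colnames(m)))
}
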