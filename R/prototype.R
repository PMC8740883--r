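#' Assemble and validate a prototype dataset
#'
#' A prototype dataset is the input to parameter estimation: a cells x PCs
#' embedding matrix together with per-cell metadata assigning every cell to a
#' sample, a processing batch, and a cluster (cell state). Embeddings are
#' unitless principal-component coordinates; clusters are opaque labels.
#'
#' @param embeddings Numeric matrix (cells x PCs) with rownames giving cell
#'   IDs, or a data frame with a `cell` column followed by PC columns.
#' @param meta Data frame with columns `cell`, `sample`, `batch`, `cluster`.
#'   Row order need not match `embeddings`; rows are matched by cell ID.
#'
#' @details Validation enforces: unique cell IDs; identical cell sets in
#' embeddings and metadata; at least 2 PCs and 2 clusters; no empty cluster;
#' and a nested batch structure in which every sample belongs to exactly one
#' batch.
#'
#' @return An object of class `proto_data`: a list with `embeddings` (matrix,
#'   rownames = cell IDs) and `meta` (tibble, one row per cell, same order).
#' @export
prototype_dataset <- function(embeddings, meta) {
  if (is.data.frame(embeddings)) {
    if (!"cell" %in% names(embeddings)) {
      abort("`embeddings` data frame must contain a `cell` column.")
    }
    m <- as.matrix(embeddings[setdiff(names(embeddings), "cell")])
    rownames(m) <- as.character(embeddings$cell)
    embeddings <- m
  }
  if (is.null(rownames(embeddings))) {
    abort("`embeddings` must carry cell IDs as rownames.")
  }
  storage.mode(embeddings) <- "double"
  meta <- as_tibble(meta)
  req <- c("cell", "sample", "batch", "cluster")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    abort(paste0("`meta` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  meta <- dplyr::mutate(meta, dplyr::across(dplyr::all_of(req), as.character))

  if (anyDuplicated(meta$cell)) abort("Duplicated cell IDs in `meta`.")
  if (anyDuplicated(rownames(embeddings))) abort("Duplicated cell IDs in `embeddings`.")
  if (!setequal(meta$cell, rownames(embeddings))) {
    abort("Cell IDs in `embeddings` and `meta` do not match.")
  }
  meta <- meta[match(rownames(embeddings), meta$cell), ]

  out <- structure(list(embeddings = embeddings, meta = meta),
                   class = "proto_data")
  validate_prototype(out)
  out
}

#' Validate a prototype dataset against its invariants
#'
#' @param x A `proto_data` object.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_prototype <- function(x) {
  stopifnot(inherits(x, "proto_data"))
  emb <- x$embeddings
  meta <- x$meta
  if (ncol(emb) < 2) abort("Prototype needs at least 2 PC dimensions.")
  if (nrow(emb) != nrow(meta)) abort("Embeddings and metadata disagree on cell count.")
  if (!identical(rownames(emb), meta$cell)) abort("Cell order mismatch between embeddings and metadata.")
  if (any(!is.finite(emb))) abort("Embeddings contain non-finite values.")
  if (dplyr::n_distinct(meta$cluster) < 2) abort("Prototype needs at least 2 clusters.")
  tab <- table(meta$cluster)
  if (any(tab == 0)) abort("Empty cluster in prototype.")
  sb <- dplyr::distinct(meta, .data$sample, .data$batch)
  dup <- sb$sample[duplicated(sb$sample)]
  if (length(dup)) {
    abort(paste0("Sample(s) mapped to more than one batch: ",
                 paste(unique(dup), collapse = ", ")))
  }
  invisible(x)
}

#' Read a prototype dataset from tabular files
#'
#' Reads a cells x PCs embedding table and a per-cell metadata table
#' (CSV or TSV, detected from content) and assembles a validated
#' [prototype_dataset()]. Tables are joined on the `cell` column, so row
#' order need not agree.
#'
#' A warning (not an error) is emitted when the prototype has fewer than 6
#' samples or any sample contributes fewer than 500 cells: variance and
#' frequency estimates from such small prototypes are unstable, and study
#' designs derived from them should be treated with caution.
#'
#' @param embeddings_path Path to a delimited table: `cell` column + one
#'   column per PC.
#' @param metadata_path Path to a delimited table with columns
#'   `cell`, `sample`, `batch`, `cluster`.
#' @return A `proto_data` object.
#' @export
read_prototype <- function(embeddings_path, metadata_path) {
  emb <- read_delim_auto(embeddings_path)
  meta <- read_delim_auto(metadata_path)
  if (!"cell" %in% names(emb)) abort("Embeddings table must have a `cell` column.")
  out <- prototype_dataset(emb, meta)
  check_prototype_size(out)
  out
}

check_prototype_size <- function(x) {
  n_per_sample <- table(x$meta$sample)
  if (length(n_per_sample) < 6 || any(n_per_sample < 500)) {
    warn(paste0(
      "Small prototype: ", length(n_per_sample), " sample(s), minimum ",
      min(n_per_sample), " cells/sample. Estimates are most reliable with at ",
      "least 6 samples of 500+ cells each."))
  }
  invisible(x)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Write a simulated (or prototype) dataset to disk
#'
#' Writes two TSV files under `dir`: `embeddings.tsv` (`cell` + PC columns)
#' and `meta.tsv` (all metadata columns). The pair is re-readable with
#' [read_simulated()] and round-trips values to full double precision.
#'
#' @param dataset A `sim_data` object from [simulate_dataset()] (a
#'   `proto_data` object is also accepted).
#' @param dir Output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
write_simulated <- function(dataset, dir) {
  if (!inherits(dataset, c("sim_data", "proto_data"))) {
    abort("`dataset` must be a `sim_data` or `proto_data` object.")
  }
  if (nrow(dataset$meta) == 0) abort("Refusing to write an empty dataset.")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory: ", dir))
  }
  emb_path <- file.path(dir, "embeddings.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  emb_df <- tibble(cell = rownames(dataset$embeddings)) |>
    dplyr::bind_cols(as_tibble(dataset$embeddings, .name_repair = "minimal"))
  readr::write_tsv(emb_df, emb_path, progress = FALSE)
  readr::write_tsv(dataset$meta, meta_path, progress = FALSE)
  invisible(c(embeddings = emb_path, meta = meta_path))
}

#' Read back a simulated dataset written by [write_simulated()]
#'
#' @param dir Directory containing `embeddings.tsv` and `meta.tsv`.
#' @return A `sim_data` object (embeddings matrix + metadata tibble).
#' @export
read_simulated <- function(dir) {
  emb <- read_delim_auto(file.path(dir, "embeddings.tsv"))
  meta <- read_delim_auto(file.path(dir, "meta.tsv"))
  m <- as.matrix(emb[setdiff(names(emb), "cell")])
  rownames(m) <- as.character(emb$cell)
  meta <- dplyr::mutate(meta, dplyr::across(dplyr::where(is.character), as.character))
  if (!setequal(meta$cell, rownames(m))) abort("Cell IDs in embeddings and meta files do not match.")
  meta <- meta[match(rownames(m), meta$cell), ]
  new_sim_data(m, as_tibble(meta))
}

new_sim_data <- function(embeddings, meta, target_cluster = NA_character_,
                         design = NULL) {
  structure(
    list(embeddings = embeddings, meta = meta,
         target_cluster = target_cluster, design = design),
    class = "sim_data")
}

#' @exportS3Method base::print
print.proto_data <- function(x, ...) {
  cat("<proto_data> ", nrow(x$embeddings), " cells x ", ncol(x$embeddings),
      " PCs; ", dplyr::n_distinct(x$meta$cluster), " clusters, ",
      dplyr::n_distinct(x$meta$sample), " samples, ",
      dplyr::n_distinct(x$meta$batch), " batches\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.sim_data <- function(x, ...) {
  cat("<sim_data> ", nrow(x$embeddings), " cells x ", ncol(x$embeddings),
      " PCs; target cluster: ", x$target_cluster, "\n", sep = "")
  invisible(x)
}
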