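#' Read a delimited numeric matrix
#'
#' Reads a TSV (or CSV, detected from the extension or `sep`) with row
#' identifiers in the first column and a header row of column identifiers —
#' the canonical on-disk layout for beta-value, fraction and p-value tables
#' (CpGs x samples or samples x cell types).
#'
#' @param path file path.
#' @param sep field separator; default inferred (`","` for `.csv`, else tab).
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input: ", path, " has no data rows")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- ids
  m
}

#' Write a numeric matrix as TSV
#'
#' Tab-separated, header row of column identifiers, first column `id` with
#' the row identifiers, full-precision values (round-trips bit-exactly
#' through [read_matrix()]).
#'
#' @param x matrix with dimnames (missing names are generated).
#' @param path output path.
#' @param id_name header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_name = "id") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("r%06d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("c%03d", seq_len(ncol(x)))
  df <- data.frame(rownames(x), format(x, digits = 17, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_name, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a reference panel to a directory
#'
#' Writes `mu.tsv`, `var.tsv`, `pooled_var.tsv` and a `manifest.json`
#' recording cell types, seed and hyperparameters.
#'
#' @param panel a `reference_panel`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(panel$mu, file.path(dir, "mu.tsv"), "CpG")
  write_matrix(panel$var, file.path(dir, "var.tsv"), "CpG")
  pv <- matrix(panel$pooled_var, ncol = 1,
               dimnames = list(panel$cpg_ids, "pooled_var"))
  write_matrix(pv, file.path(dir, "pooled_var.tsv"), "CpG")
  manifest <- list(cell_types = panel$cell_types,
                   n_pure = as.list(panel$n_pure),
                   pooling_types = panel$pooling_types,
                   mean_hyper = panel$mean_hyper, sd_hyper = panel$sd_hyper,
                   seed = panel$seed, format = "ctsdm-panel-1")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a serialized reference panel
#'
#' @param dir directory written by [write_panel()].
#' @return a `reference_panel` (empirical quantities restored at the printed
#'   precision; `sd_true` is not serialized).
#' @export
read_panel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mu <- read_matrix(file.path(dir, "mu.tsv"))
  v <- read_matrix(file.path(dir, "var.tsv"))
  pv <- read_matrix(file.path(dir, "pooled_var.tsv"))[, 1]
  structure(list(
    cpg_ids = rownames(mu), cell_types = manifest$cell_types,
    mu = mu, var = v, pooled_var = unname(pv), sd_true = NULL,
    n_pure = unlist(manifest$n_pure),
    pooling_types = manifest$pooling_types,
    mean_hyper = manifest$mean_hyper, sd_hyper = manifest$sd_hyper,
    seed = manifest$seed
  ), class = "reference_panel")
}

#' Serialize a simulated dataset to a directory
#'
#' Writes `bulk.tsv` (CpG x sample), `phenotype.tsv`, `fractions.tsv`
#' (sample x cell type), `truth.tsv` (0/1 CpG x cell type),
#' `effect_size.tsv` and `manifest.json` (seed and design).
#'
#' @param sim a `ctsdm_sim`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$bulk, file.path(dir, "bulk.tsv"), "CpG")
  ph <- matrix(sim$phenotype, ncol = 1,
               dimnames = list(colnames(sim$bulk), "phenotype"))
  write_matrix(ph, file.path(dir, "phenotype.tsv"), "sample")
  write_matrix(sim$fractions, file.path(dir, "fractions.tsv"), "sample")
  tr <- sim$effects$truth + 0
  rownames(tr) <- rownames(sim$bulk)
  write_matrix(tr, file.path(dir, "truth.tsv"), "CpG")
  es <- matrix(sim$effects$effect_size * sim$effects$sign, ncol = 1,
               dimnames = list(rownames(sim$bulk), "signed_effect_size"))
  write_matrix(es, file.path(dir, "effect_size.tsv"), "CpG")
  design <- sim$design
  manifest <- list(
    seed = sim$seed, panel_seed = sim$panel_seed,
    design = list(
      p = design$p, n = design$n, snr = design$snr,
      cell_types = design$cell_types,
      fraction_bounds = apply(design$fraction_bounds, 1, as.list),
      n_diff = as.list(design$n_diff),
      case_fraction = design$case_fraction,
      effect_sign = design$effect_sign,
      clip_output = design$clip_output, epsilon = design$epsilon
    ),
    format = "ctsdm-dataset-1"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a serialized simulated dataset
#'
#' @param dir directory written by [write_dataset()].
#' @return list with `bulk`, `phenotype`, `fractions`, `truth` (logical
#'   matrix), `effect_size` (signed), `manifest`.
#' @export
read_dataset <- function(dir) {
  bulk <- read_matrix(file.path(dir, "bulk.tsv"))
  phenotype <- as.integer(read_matrix(file.path(dir, "phenotype.tsv"))[, 1])
  fractions <- read_matrix(file.path(dir, "fractions.tsv"))
  truth <- read_matrix(file.path(dir, "truth.tsv")) > 0
  es <- read_matrix(file.path(dir, "effect_size.tsv"))[, 1]
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(bulk = bulk, phenotype = phenotype, fractions = fractions,
       truth = truth, effect_size = unname(es), manifest = manifest)
}

#' Read external method tables into a p-value cube
#'
#' Each file is a long TSV with columns `CpG`, `cell_type` and `p` (or
#' `posterior`), as produced by wrappers around external detection tools.
#'
#' @param paths named character vector of file paths (names become method
#'   labels).
#' @return a `pvalue_cube`.
#' @export
read_method_tables <- function(paths) {
  if (is.null(names(paths))) stop("'paths' must be named by method")
  tables <- list(); kinds <- character()
  for (m in names(paths)) {
    df <- utils::read.table(paths[[m]], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    valcol <- intersect(c("p", "posterior"), names(df))
    if (length(valcol) != 1L)
      stop("table '", m, "' needs exactly one of columns 'p'/'posterior'")
    mat <- stats::xtabs(df[[valcol]] ~ CpG + cell_type, data = df)
    mat <- matrix(mat, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    tables[[m]] <- mat
    kinds[m] <- if (valcol == "p") "p-value" else "posterior"
  }
  assemble_cube(tables, unname(kinds), names(paths))
}
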