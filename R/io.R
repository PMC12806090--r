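#' Construct an expression matrix container
#'
#' @param values G x n numeric matrix, genes in rows, spots in columns.
#' @param gene_ids,spot_ids unique identifiers; default to dimnames.
#' @param layer_tag what the values are: `"counts"`, `"cpm"`, `"log1p"`,
#'   `"anscombe"`, or `"residual"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              spot_ids = colnames(values),
                              layer_tag = "counts") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(ncol(values)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(spot_ids)) stop("duplicate spot ids")
  if (length(gene_ids) != nrow(values) || length(spot_ids) != ncol(values))
    stop("id lengths must match matrix dimensions")
  if (!all(is.finite(values))) stop("non-finite expression values")
  if (layer_tag == "counts" && any(values < 0))
    stop("counts layer must be nonnegative")
  dimnames(values) <- list(gene_ids, spot_ids)
  structure(list(values = values, gene_ids = gene_ids, spot_ids = spot_ids,
                 layer_tag = layer_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "spots; layer =", x$layer_tag, "\n")
  invisible(x)
}

#' Read an expression matrix from disk
#'
#' Dense TSV/CSV (first column = ids, header = other axis ids) or
#' MatrixMarket triplet with `features.tsv` / `barcodes.tsv` sidecars
#' (10x convention: one id per line, matrix rows = features). The result
#' is always in canonical genes x spots orientation.
#'
#' @param path matrix file (`.tsv`/`.csv`/`.mtx`).
#' @param format `"dense_tsv"` or `"mtx_triplet"`; guessed from the file
#'   extension by default.
#' @param orientation orientation of the file on disk.
#' @param features,barcodes sidecar paths for `mtx_triplet` (default:
#'   `features.tsv` and `barcodes.tsv` next to the matrix).
#' @param layer_tag layer annotation for the result.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = NULL,
                            orientation = c("genes_x_spots", "spots_x_genes"),
                            features = NULL, barcodes = NULL,
                            layer_tag = "counts") {
  orientation <- match.arg(orientation)
  if (is.null(format)) {
    format <- if (grepl("\\.mtx$", path)) "mtx_triplet" else "dense_tsv"
  }
  if (format == "dense_tsv") {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
  } else if (format == "mtx_triplet") {
    if (is.null(features)) features <- file.path(dirname(path), "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dirname(path), "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    feat <- utils::read.table(features, sep = "\t",
                              stringsAsFactors = FALSE)[, 1]
    bc <- utils::read.table(barcodes, sep = "\t",
                            stringsAsFactors = FALSE)[, 1]
    if (length(feat) != nrow(m) || length(bc) != ncol(m))
      stop("sidecar lengths (", length(feat), " features, ", length(bc),
           " barcodes) do not match matrix dimensions ", nrow(m), " x ",
           ncol(m))
    dimnames(m) <- list(feat, bc)
  } else stop("unknown format: ", format)
  if (orientation == "spots_x_genes") m <- t(m)
  expression_matrix(m, layer_tag = layer_tag)
}

#' Write an expression matrix as dense TSV
#'
#' Genes in rows, spots in columns, ids in the first column/header; the
#' exact inverse of [read_expression()] for dense TSV.
#'
#' @param em an `expression_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spot coordinates
#'
#' Accepts a TSV/CSV with columns `spot_id`, `x`, `y` (any order, by
#' name), or a file whose ids encode coordinates in the
#' `"<x>x<y>"` convention of classic Spatial Transcriptomics arrays
#' (e.g. `"12.5x10.2"`), in which case the coordinates are parsed from
#' the ids themselves.
#'
#' @param path coordinates file.
#' @param spot_ids optional ids (e.g. from the expression matrix) that the
#'   coordinates must cover; unmatched ids raise an error.
#' @return a [spot_set()] (ordered to `spot_ids` when given).
#' @export
read_coordinates <- function(path, spot_ids = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("spot_id", "x", "y") %in% names(df))) {
    ss <- spot_set(cbind(df$x, df$y), df$spot_id)
  } else {
    ids <- as.character(df[[1]])
    ok <- grepl("^[-+0-9.eE]+x[-+0-9.eE]+$", ids)
    if (!all(ok))
      stop("no x/y columns and ids not in '<x>x<y>' form, e.g.: ",
           paste(utils::head(ids[!ok], 5L), collapse = ", "))
    parts <- strsplit(ids, "x", fixed = TRUE)
    ss <- spot_set(cbind(as.numeric(vapply(parts, `[`, "", 1L)),
                         as.numeric(vapply(parts, `[`, "", 2L))), ids)
  }
  if (!is.null(spot_ids)) {
    miss <- setdiff(spot_ids, ss$spot_ids)
    if (length(miss))
      stop("coordinates missing for spot ids: ",
           paste(utils::head(miss, 10L), collapse = ", "))
    idx <- match(spot_ids, ss$spot_ids)
    ss <- spot_set(ss$coords[idx, , drop = FALSE], spot_ids)
  }
  ss
}

#' Write spot coordinates as TSV
#'
#' @param spots a [spot_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(spots, path) {
  utils::write.table(data.frame(spot_id = spots$spot_ids,
                                x = spots$coords[, 1], y = spots$coords[, 2]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter low-coverage spots and genes
#'
#' Drops spots detecting (count > 0) fewer than `min_genes_per_spot`
#' genes, then drops genes with fewer than `min_reads_per_gene` total
#' reads over the surviving spots. The spot-then-gene order is fixed and
#' matters: gene totals are recomputed after spot removal.
#'
#' @param em an `expression_matrix` on the counts layer.
#' @param min_genes_per_spot,min_reads_per_gene thresholds (kept when
#'   `>= threshold`... spots/genes strictly below are removed).
#' @return filtered `expression_matrix`.
#' @export
filter_spots_genes <- function(em, min_genes_per_spot = 100L,
                               min_reads_per_gene = 100L) {
  v <- em$values
  keep_spot <- colSums(v > 0) >= min_genes_per_spot
  v <- v[, keep_spot, drop = FALSE]
  keep_gene <- rowSums(v) >= min_reads_per_gene
  v <- v[keep_gene, , drop = FALSE]
  if (nrow(v) == 0L || ncol(v) == 0L)
    stop("filtering removed all spots or genes")
  expression_matrix(v, layer_tag = em$layer_tag)
}

#' Counts-per-million normalization
#'
#' Scales each spot column to a library size of one million.
#'
#' @param em counts-layer `expression_matrix` with no zero-total spot.
#' @return `expression_matrix` with `layer_tag = "cpm"`.
#' @export
cpm_normalize <- function(em) {
  tot <- colSums(em$values)
  if (any(tot == 0))
    stop("zero-total spot(s); run filter_spots_genes() first")
  expression_matrix(sweep(em$values, 2, tot, "/") * 1e6, layer_tag = "cpm")
}

#' log(1 + x) transform
#'
#' Natural-log transform of nonnegative expression values.
#'
#' @param em an `expression_matrix` with nonnegative values.
#' @return `expression_matrix` with `layer_tag = "log1p"`.
#' @export
log1p_transform <- function(em) {
  if (any(em$values < 0)) stop("log1p requires nonnegative values")
  expression_matrix(log1p(em$values), layer_tag = "log1p")
}

#' Anscombe variance-stabilizing transform
#'
#' Entry-wise `2 * sqrt(x + 3/8)`; approximately unit-variance for
#' Poisson-distributed counts.
#'
#' @param em an `expression_matrix` with nonnegative values.
#' @return `expression_matrix` with `layer_tag = "anscombe"`.
#' @export
anscombe_transform <- function(em) {
  if (any(em$values < 0)) stop("Anscombe transform requires nonnegative values")
  expression_matrix(2 * sqrt(em$values + 3 / 8), layer_tag = "anscombe")
}

#' Regress out per-spot total counts
#'
#' For each gene, replaces its values by the residuals of an ordinary
#' least-squares fit on (intercept, per-spot total), removing library-size
#' effects after a variance-stabilizing transform.
#'
#' @param em an `expression_matrix` (transformed layer).
#' @param totals per-spot totals to regress on; defaults to the column
#'   sums of `em`.
#' @return `expression_matrix` with `layer_tag = "residual"`.
#' @export
regress_out_totals <- function(em, totals = NULL) {
  v <- em$values
  if (is.null(totals)) totals <- colSums(v)
  if (length(totals) != ncol(v)) stop("totals must have one entry per spot")
  if (diff(range(totals)) == 0) {
    warning("constant totals; removing gene means only")
    res <- v - rowMeans(v)
  } else {
    X <- cbind(1, totals)
    beta <- solve(crossprod(X), crossprod(X, t(v)))   # 2 x G
    res <- v - t(X %*% beta)
  }
  out <- expression_matrix(res, layer_tag = "residual")
  out
}
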