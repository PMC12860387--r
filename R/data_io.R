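#' Spot-by-gene expression matrix
#'
#' Thin container around a dense or sparse spots x genes matrix of
#' non-negative values, with ordered spot and gene identifiers and a layer tag
#' recording whether the values are raw counts or library-size-normalised
#' log1p expression.
#'
#' @param values numeric matrix or `Matrix` sparse matrix, spots in rows.
#' @param spot_ids character vector of unique spot identifiers (row order).
#' @param gene_ids character vector of unique gene identifiers (column order).
#' @param layer `"counts"` or `"normalized"`.
#' @return an object of class `spot_matrix`.
#' @export
spot_matrix <- function(values, spot_ids, gene_ids, layer = c("counts", "normalized")) {
  layer <- match.arg(layer)
  if (length(spot_ids) != nrow(values))
    stop_arg("spot_ids length (", length(spot_ids), ") != number of rows (", nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop_arg("gene_ids length (", length(gene_ids), ") != number of columns (", ncol(values), ")")
  spot_ids <- trimws(as.character(spot_ids))
  gene_ids <- trimws(as.character(gene_ids))
  if (anyDuplicated(spot_ids)) stop_arg("duplicated spot ids: ",
    paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids)) stop_arg("duplicated gene ids: ",
    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  neg <- which(as_dense(values) < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop_arg("negative entry at (row ", neg[1, 1], ", col ", neg[1, 2], "): value ",
             as_dense(values)[neg[1, 1], neg[1, 2]])
  dimnames(values) <- list(spot_ids, gene_ids)
  structure(list(values = values, spot_ids = spot_ids, gene_ids = gene_ids,
                 layer = layer), class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("spot_matrix: %d spots x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.spot_matrix <- function(x) dim(x$values)

#' Read a spot-by-gene matrix from disk
#'
#' Supports a MatrixMarket triplet with sidecar gene/barcode lists (the 10x
#' convention stores genes in rows; orientation is auto-detected from the
#' sidecar lengths) and a dense CSV with spot ids in the first column and gene
#' ids in the header.
#'
#' @param path path to the `.mtx` file or dense CSV.
#' @param format `"auto"` (by extension), `"mtx"` or `"csv"`.
#' @param genes_file,barcodes_file optional explicit sidecar paths; by default
#'   `genes.tsv`/`features.tsv` and `barcodes.tsv` next to the `.mtx`.
#' @param orientation for a square MTX whose orientation is ambiguous,
#'   `"genes_in_rows"` or `"spots_in_rows"` must be given explicitly.
#' @param layer layer tag for the returned matrix.
#' @return a [spot_matrix] with spots in rows.
#' @export
read_spot_matrix <- function(path, format = c("auto", "mtx", "csv"),
                             genes_file = NULL, barcodes_file = NULL,
                             orientation = c("auto", "genes_in_rows", "spots_in_rows"),
                             layer = "counts") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_arg("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    return(spot_matrix(m, df[[1]], colnames(df)[-1], layer = layer))
  }
  dirn <- dirname(path)
  if (is.null(genes_file)) {
    for (cand in c("genes.tsv", "features.tsv")) {
      p <- file.path(dirn, cand)
      if (file.exists(p)) { genes_file <- p; break }
    }
  }
  barcodes_file <- barcodes_file %||% file.path(dirn, "barcodes.tsv")
  if (is.null(genes_file) || !file.exists(genes_file))
    stop_arg("gene list sidecar not found next to ", path)
  if (!file.exists(barcodes_file))
    stop_arg("barcode list sidecar not found: ", barcodes_file)
  genes <- read.delim(genes_file, header = FALSE, stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(barcodes_file, header = FALSE, stringsAsFactors = FALSE)[[1]]
  m <- as(Matrix::readMM(path), "CsparseMatrix")
  if (orientation == "auto") {
    if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
      if (nrow(m) == ncol(m) && length(genes) == length(barcodes))
        stop_arg("square matrix with equal sidecar lengths: pass orientation= explicitly")
      orientation <- "genes_in_rows"
    } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
      orientation <- "spots_in_rows"
    } else {
      stop_arg("matrix dimensions (", nrow(m), "x", ncol(m),
               ") match neither sidecar orientation")
    }
  }
  if (orientation == "genes_in_rows") m <- Matrix::t(m)
  spot_matrix(m, barcodes, genes, layer = layer)
}

#' Write a spot-by-gene matrix to disk
#'
#' `format = "mtx"` writes a MatrixMarket triplet (genes in rows, the 10x
#' convention) with `genes.tsv` and `barcodes.tsv` sidecars into a directory;
#' `format = "csv"` writes one dense CSV.
#'
#' @param m a [spot_matrix].
#' @param path target file (csv) or directory (mtx).
#' @param format `"csv"` or `"mtx"`.
#' @export
write_spot_matrix <- function(m, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "spot_matrix"))
  if (format == "csv") {
    df <- data.frame(spot_id = m$spot_ids, as_dense(m$values),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("spot_id", m$gene_ids)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sm <- methods::as(Matrix::t(methods::as(m$values, "CsparseMatrix")), "generalMatrix")
    Matrix::writeMM(sm, file.path(path, "matrix.mtx"))
    writeLines(m$gene_ids, file.path(path, "genes.tsv"))
    writeLines(m$spot_ids, file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read spot pixel coordinates
#'
#' Expects a CSV with spot id, x and y columns (header optional). Coordinates
#' are kept verbatim, in full-resolution image pixel units, in file order.
#'
#' @param path path to the CSV.
#' @return a `data.frame` with columns `spot_id`, `x`, `y`, class
#'   `spot_coords`.
#' @export
read_coordinates <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_arg("empty coordinates file: ", path)
  first <- strsplit(lines[1], ",")[[1]]
  # a header row has non-numeric entries in BOTH coordinate columns
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[2]))) &&
    is.na(suppressWarnings(as.numeric(first[3])))
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) stop_arg("no coordinate rows in ", path)
  ids <- character(0); xs <- numeric(0); ys <- numeric(0)
  for (i in seq(start, length(lines))) {
    f <- trimws(strsplit(lines[i], ",")[[1]])
    if (length(f) < 3) stop_arg("line ", i, ": expected id,x,y, got '", lines[i], "'")
    x <- suppressWarnings(as.numeric(f[2])); y <- suppressWarnings(as.numeric(f[3]))
    if (is.na(x) || is.na(y))
      stop_arg("line ", i, ": non-numeric coordinate in '", lines[i], "'")
    ids <- c(ids, f[1]); xs <- c(xs, x); ys <- c(ys, y)
  }
  spot_coords(ids, xs, ys)
}

#' Construct spot coordinates
#'
#' @param spot_id character spot identifiers (unique after whitespace trim).
#' @param x,y numeric pixel coordinates.
#' @return a `spot_coords` data.frame.
#' @export
spot_coords <- function(spot_id, x, y) {
  spot_id <- trimws(as.character(spot_id))
  if (anyDuplicated(spot_id))
    stop_arg("duplicated spot id: ", spot_id[duplicated(spot_id)][1])
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_arg("non-finite coordinate values")
  structure(data.frame(spot_id = spot_id, x = as.numeric(x), y = as.numeric(y),
                       stringsAsFactors = FALSE),
            class = c("spot_coords", "data.frame"))
}

#' Per-spot cell-type proportion matrix
#'
#' Rows live on the probability simplex: non-negative, summing to one within
#' 1e-6.
#'
#' @param values numeric matrix, spots x cell types.
#' @param type_names ordered unique cell-type names.
#' @param spot_ids optional spot identifiers.
#' @return an object of class `proportion_matrix` (a numeric matrix).
#' @export
proportion_matrix <- function(values, type_names = colnames(values),
                              spot_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(type_names)) type_names <- paste0("type", seq_len(ncol(values)))
  if (anyDuplicated(type_names)) stop_arg("duplicated type names")
  if (length(type_names) != ncol(values)) stop_arg("type_names length mismatch")
  if (any(values < -1e-12)) stop_arg("negative proportion entry")
  rs <- rowSums(values)
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad) > 0)
    stop_arg("row ", bad[1], " sums to ", rs[bad[1]], ", not 1 (tolerance 1e-6)")
  colnames(values) <- type_names
  if (!is.null(spot_ids)) rownames(values) <- trimws(as.character(spot_ids))
  class(values) <- c("proportion_matrix", class(values))
  values
}

#' One-hot per-spot pathology labels
#'
#' @param class_vec character/factor of per-spot classes, or an existing
#'   one-hot 0/1 matrix.
#' @param class_names optional ordered class names (levels).
#' @param spot_ids optional spot identifiers.
#' @return a 0/1 matrix of class `pathology_labels`, one 1 per row.
#' @export
pathology_labels <- function(class_vec, class_names = NULL, spot_ids = NULL) {
  if (is.matrix(class_vec)) {
    m <- class_vec
    if (!all(m %in% c(0, 1)) || any(rowSums(m) != 1))
      stop_arg("one-hot matrix must have exactly one 1 per row")
    if (!is.null(class_names)) colnames(m) <- class_names
  } else {
    class_vec <- as.character(class_vec)
    class_names <- class_names %||% sort(unique(class_vec))
    if (!all(class_vec %in% class_names)) stop_arg("class outside class_names")
    m <- outer(class_vec, class_names, `==`) * 1
    colnames(m) <- class_names
  }
  if (!is.null(spot_ids)) rownames(m) <- trimws(as.character(spot_ids))
  class(m) <- c("pathology_labels", class(m))
  m
}

#' Bundle the components of one ST dataset
#'
#' All present components must index the same spots in the same order (strict
#' string equality after whitespace trim).
#'
#' @param expression a [spot_matrix].
#' @param coords optional [spot_coords].
#' @param image optional RGB raster array (H x W x 3, values in `[0,1]`).
#' @param proportions optional [proportion_matrix] (planted truth).
#' @param pathology optional [pathology_labels].
#' @return an object of class `st_dataset`.
#' @export
st_dataset <- function(expression, coords = NULL, image = NULL,
                       proportions = NULL, pathology = NULL) {
  stopifnot(inherits(expression, "spot_matrix"))
  check_ids <- function(ids, what) {
    if (!identical(trimws(as.character(ids)), expression$spot_ids))
      stop_arg(what, " spot ids do not match expression spot ids (strict order)")
  }
  if (!is.null(coords)) check_ids(coords$spot_id, "coordinates")
  if (!is.null(proportions) && !is.null(rownames(proportions)))
    check_ids(rownames(proportions), "proportions")
  if (!is.null(pathology) && !is.null(rownames(pathology)))
    check_ids(rownames(pathology), "pathology")
  structure(list(expression = expression, coords = coords, image = image,
                 proportions = proportions, pathology = pathology),
            class = "st_dataset")
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf("st_dataset: %d spots x %d genes; coords: %s; image: %s; truth: %s; pathology: %s\n",
              nrow(x$expression$values), ncol(x$expression$values),
              !is.null(x$coords), !is.null(x$image),
              !is.null(x$proportions), !is.null(x$pathology)))
  invisible(x)
}

#' Restrict two expression matrices to a shared ordered gene space
#'
#' The shared list is the intersection in the gene order of `simulated`,
#' optionally reduced to the `n_top` genes with the highest variance computed
#' on the simulated matrix. Both domains must share one gene space so that a
#' single encoder can serve both.
#'
#' @param simulated,real [spot_matrix] objects.
#' @param n_top optional number of most-variable genes to keep (default all).
#' @return list with elements `simulated` and `real`, identically ordered.
#' @export
align_genes <- function(simulated, real, n_top = NULL) {
  stopifnot(inherits(simulated, "spot_matrix"), inherits(real, "spot_matrix"))
  shared <- simulated$gene_ids[simulated$gene_ids %in% real$gene_ids]
  if (length(shared) == 0) stop_arg("no shared genes")
  if (!is.null(n_top) && n_top < length(shared)) {
    v <- apply(as_dense(simulated$values[, shared, drop = FALSE]), 2L, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(n_top)]
    shared <- shared[sort(keep)]  # preserve original gene order among the top-N
  }
  list(
    simulated = spot_matrix(simulated$values[, shared, drop = FALSE],
                            simulated$spot_ids, shared, layer = simulated$layer),
    real = spot_matrix(real$values[, shared, drop = FALSE],
                       real$spot_ids, shared, layer = real$layer)
  )
}

#' Library-size normalise and log-transform counts
#'
#' Each row is scaled to sum to `target_sum` and then transformed by
#' `log(1 + x)`. All-zero rows pass through unchanged. Applied identically to
#' simulated and real matrices so the shared encoder sees a single scale.
#'
#' @param m a [spot_matrix] with `layer == "counts"`.
#' @param target_sum positive target library size (default 1e4).
#' @return a [spot_matrix] with `layer == "normalized"`.
#' @export
normalize_expression <- function(m, target_sum = 1e4) {
  stopifnot(inherits(m, "spot_matrix"))
  if (m$layer != "counts") stop_arg("normalize_expression expects layer 'counts'")
  if (!is.numeric(target_sum) || target_sum <= 0) stop_arg("target_sum must be > 0")
  v <- as_dense(m$values)
  rs <- rowSums(v)
  scale <- ifelse(rs > 0, target_sum / rs, 0)
  out <- log1p(v * scale)
  spot_matrix(out, m$spot_ids, m$gene_ids, layer = "normalized")
}

#' Write per-spot proportions to CSV
#'
#' One row per spot with a leading `spot_id` column and one column per cell
#' type; values survive a read-back to at least 8 significant digits.
#'
#' @param p a [proportion_matrix].
#' @param path target CSV path.
#' @export
write_proportions <- function(p, path) {
  stopifnot(inherits(p, "proportion_matrix"))
  ids <- rownames(p) %||% paste0("spot", seq_len(nrow(p)))
  df <- data.frame(spot_id = ids, format(unclass(p), digits = 15, trim = TRUE,
                                         scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("spot_id", colnames(p))
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_arg("cannot write proportions to ", path)
  invisible(path)
}

#' Read per-spot proportions from CSV
#'
#' @param path CSV written by [write_proportions()].
#' @return a [proportion_matrix].
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  # renormalise away the CSV formatting round-off (well below 1e-8)
  proportion_matrix(m / rowSums(m), colnames(df)[-1], df[[1]])
}

#' Write spot coordinates to CSV
#' @param coords a [spot_coords] data.frame.
#' @param path target CSV path.
#' @export
write_coordinates <- function(coords, path) {
  write.csv(as.data.frame(coords), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an RGB raster image (PNG or TIFF)
#'
#' @param path image path.
#' @return numeric array H x W x 3 with values in `[0,1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_arg("the 'tiff' package is required for TIFF input")
    img <- tiff::readTIFF(path)
  } else {
    img <- png::readPNG(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write an RGB raster image as PNG
#' @param image numeric array H x W x 3 in `[0,1]`.
#' @param path target PNG path.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
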