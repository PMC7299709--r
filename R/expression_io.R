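#' Read an expression matrix
#'
#' Reads a genes x samples matrix from delimited text (first column = gene
#' symbol, header row = sample IDs) or GCT 1.2. Row keys are preserved as
#' read, including duplicates -- collapsing duplicated symbols is a separate,
#' explicit step ([collapse_duplicates()]). Non-numeric cells become `NA`.
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"tsv"`, `"csv"`, `"gct"`.
#' @param sep Field separator override for delimited text.
#' @return Numeric matrix with gene symbols as rownames and sample IDs as
#'   colnames.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "csv", "gct"),
                                   sep = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct"
      else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  if (format == "gct") return(read_gct(path))
  if (is.null(sep)) sep <- if (format == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("empty expression matrix: ", path)
  finish_matrix(raw[[1L]], names(raw)[-1L],
                raw[, -1L, drop = FALSE], path)
}

read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || trimws(header[1L]) != "#1.2") {
    stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
  }
  dims <- as.integer(strsplit(header[2L], "\t", fixed = TRUE)[[1L]][1:2])
  raw <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                           quote = "", comment.char = "", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) stop("GCT body must have NAME, Description and data columns")
  body_genes <- nrow(raw)
  body_samples <- ncol(raw) - 2L
  if (body_genes != dims[1L] || body_samples != dims[2L]) {
    stop("GCT declared dims (", dims[1L], " x ", dims[2L],
         ") mismatch body (", body_genes, " x ", body_samples, ")")
  }
  finish_matrix(raw[[1L]], names(raw)[-(1:2)],
                raw[, -(1:2), drop = FALSE], path)
}

finish_matrix <- function(genes, samples, cells, path) {
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(cells)), nrow = length(genes),
           dimnames = list(trimws(genes), samples)))
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty expression matrix: ", path)
  message("read ", nrow(m), " genes x ", ncol(m), " samples (",
          sum(is.na(m)), " missing cells)")
  m
}

#' Read a sparse single-cell matrix (MTX triplet)
#'
#' Reads a MatrixMarket file plus sidecar text files listing gene symbols
#' (rows) and cell barcodes (columns), and densifies to the canonical
#' genes x samples layout.
#'
#' @param mtx_path MatrixMarket (.mtx) file.
#' @param genes_path,barcodes_path One-name-per-line text files; a
#'   tab-delimited genes file uses its last column as the symbol.
#' @return Dense numeric matrix, genes x cells.
#' @export
read_mtx_expression <- function(mtx_path, genes_path, barcodes_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- utils::read.table(genes_path, sep = "\t", colClasses = "character")
  genes <- trimws(genes[[ncol(genes)]])
  barcodes <- trimws(readLines(barcodes_path, warn = FALSE))
  if (length(genes) != nrow(m) || length(barcodes) != ncol(m)) {
    stop("sidecar lengths (", length(genes), " genes, ", length(barcodes),
         " barcodes) mismatch matrix dims ", nrow(m), " x ", ncol(m))
  }
  if (anyDuplicated(barcodes)) stop("duplicate sample IDs in ", barcodes_path)
  dimnames(m) <- list(genes, barcodes)
  message("read ", nrow(m), " genes x ", ncol(m), " cells (sparse triplet)")
  m
}

#' Write an expression matrix as TSV
#'
#' Full-precision tab-delimited output, gene symbols in the first column.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse duplicated gene symbols
#'
#' Resolves duplicated row keys so each gene symbol appears once. The
#' default keeps, per sample, the elementwise maximum across a symbol's
#' duplicate rows; `"max-mean-row"` instead keeps the single whole row with
#' the largest mean. Missing values are ignored when taking maxima (a cell
#' that is missing in every duplicate row stays missing).
#'
#' @param m Numeric matrix, genes x samples.
#' @param method `"elementwise-max"` (default) or `"max-mean-row"`.
#' @return Matrix with unique rownames, duplicate rows collapsed.
#' @export
collapse_duplicates <- function(m, method = c("elementwise-max", "max-mean-row")) {
  method <- match.arg(method)
  dup <- duplicated(rownames(m))
  if (!any(dup)) return(m)
  n_dup_symbols <- length(unique(rownames(m)[dup]))
  keep_order <- rownames(m)[!dup]
  safe_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  groups <- split(seq_len(nrow(m)), rownames(m))
  rows <- lapply(groups, function(idx) {
    if (length(idx) == 1L) return(m[idx, , drop = TRUE])
    sub <- m[idx, , drop = FALSE]
    if (method == "elementwise-max") {
      apply(sub, 2L, safe_max)
    } else {
      means <- rowMeans(sub, na.rm = TRUE)
      sub[which.max(means), ]
    }
  })
  out <- do.call(rbind, rows[keep_order])
  dimnames(out) <- list(keep_order, colnames(m))
  message("collapsed ", n_dup_symbols, " duplicated symbol(s) [", method, "]")
  out
}

#' Detected genes per sample
#'
#' Counts, per sample, the genes with value strictly greater than zero --
#' the usual library-complexity summary contrasting single-cell with bulk
#' profiles. Missing values never count as detected.
#'
#' @param m Numeric matrix, genes x samples.
#' @return List with `per_sample` (named integer vector), `mean` and `sd`
#'   (sample standard deviation across samples).
#' @export
detected_genes <- function(m) {
  per_sample <- colSums(m > 0, na.rm = TRUE)
  list(per_sample = per_sample,
       mean = mean(per_sample),
       sd = stats::sd(per_sample))
}
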