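#' Phyletic-age vocabulary
#'
#' The six ordered phyletic-age categories used to date human genes, from
#' most ancient to most recent. Genes whose families arose in the two oldest
#' eras ("cellular organisms", "Eukaryota") predate multicellularity and are
#' the candidate pool for the progenitor signature.
#'
#' @return Character vector of the six labels, ordered ancient to recent.
#' @export
phyletic_ages <- function() {
  c("cellular organisms", "Eukaryota", "Fungi/Metazoa group",
    "Metazoa", "Chordata", "Mammalia")
}

#' Parse phyletic-age labels
#'
#' Validates labels against the six-category vocabulary and returns an
#' ordered factor (ancient < ... < recent), so age comparisons are total.
#'
#' @param x Character vector of age labels.
#' @return Ordered factor with levels `phyletic_ages()`.
#' @export
#' @examples
#' phyletic_age(c("Eukaryota", "Mammalia"))
phyletic_age <- function(x) {
  x <- trimws(as.character(x))
  bad <- setdiff(unique(x), phyletic_ages())
  if (length(bad) > 0) {
    stop("unknown phyletic-age label(s): ", paste(sQuote(bad), collapse = ", "),
         "; expected one of: ", paste(phyletic_ages(), collapse = ", "))
  }
  factor(x, levels = phyletic_ages(), ordered = TRUE)
}

#' Construct a gene set
#'
#' @param name Set name (non-empty string).
#' @param symbols Character vector of gene symbols; whitespace-trimmed,
#'   deduplicated case-sensitively (first occurrence kept).
#' @param description Optional free-text description.
#' @return An object of class `gene_set`: a list with `name`, `description`
#'   and `symbols`.
#' @export
gene_set <- function(name, symbols, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  symbols <- trimws(as.character(symbols))
  symbols <- symbols[nzchar(symbols)]
  if (anyDuplicated(symbols)) {
    warning("gene set ", sQuote(name), ": ",
            sum(duplicated(symbols)), " duplicate symbol(s) collapsed")
    symbols <- symbols[!duplicated(symbols)]
  }
  structure(list(name = name, description = as.character(description)[1L],
                 symbols = symbols),
            class = "gene_set")
}

#' @export
#' @method print gene_set
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$symbols), " genes\n", sep = "")
  shown <- utils::head(x$symbols, 8L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$symbols) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Read a gene-age/essentiality table
#'
#' Reads an OGEE-style delimited table with one row per (gene, age,
#' essentiality) record. The delimiter is auto-detected from the file
#' extension (`.csv` comma, otherwise tab).
#'
#' @param path File path.
#' @param symbol_col,age_col,essential_col Column names holding the gene
#'   symbol, phyletic-age label and essentiality flag.
#' @return A data.frame with columns `symbol` (character), `age` (ordered
#'   factor) and `essential` (logical).
#' @export
read_gene_age_table <- function(path, symbol_col = "symbol",
                                age_col = "phyletic_age",
                                essential_col = "essential") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", check.names = FALSE)
  need <- c(symbol_col, age_col, essential_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("gene-age table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ess <- raw[[essential_col]]
  if (!is.logical(ess)) {
    ess <- tolower(trimws(as.character(ess))) %in% c("true", "t", "1", "yes", "y")
  }
  out <- data.frame(symbol = trimws(as.character(raw[[symbol_col]])),
                    age = phyletic_age(raw[[age_col]]),
                    essential = ess,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$symbol))) stop("gene-age table contains empty gene symbols")
  out
}

#' Curate the progenitor gene set
#'
#' Selects progenitor genes from a gene-age/essentiality table: genes flagged
#' essential whose phyletic age is "cellular organisms" or "Eukaryota" (the
#' two eras predating multicellular life). When a symbol appears in several
#' records with conflicting essentiality, it is treated as essential if any
#' record says so (inclusive OR; a warning reports the conflicts). Output
#' order is the input order of each symbol's first occurrence.
#'
#' @param table Data.frame as returned by [read_gene_age_table()], or any
#'   data.frame with columns `symbol`, `age`, `essential`.
#' @param name Name for the returned set.
#' @return A [gene_set] of the curated symbols.
#' @export
curate_progenitor_genes <- function(table, name = "progenitor") {
  if (!is.data.frame(table) || nrow(table) == 0) stop("empty gene-age table")
  stopifnot(all(c("symbol", "age", "essential") %in% names(table)))
  age <- phyletic_age(table$age)
  symbol <- trimws(as.character(table$symbol))
  if (any(!nzchar(symbol))) stop("gene-age table contains empty gene symbols")
  essential <- as.logical(table$essential)

  ess_any <- tapply(essential, symbol, any)
  conflict <- tapply(essential, symbol, function(e) length(unique(e)) > 1L)
  if (any(conflict)) {
    warning("conflicting essentiality for ",
            sum(conflict), " symbol(s) (treated as essential if any record ",
            "says so): ",
            paste(utils::head(names(conflict)[conflict], 5L), collapse = ", "))
  }
  ancient <- age <= phyletic_age("Eukaryota")
  keep <- ancient & ess_any[symbol]
  symbols <- symbol[keep]
  symbols <- symbols[!duplicated(symbols)]
  if (length(symbols) == 0) stop("no genes survive filter")
  message("curated ", length(symbols), " progenitor gene(s) from ",
          length(unique(symbol)), " unique symbols")
  gene_set(name, symbols,
           description = "essential genes of phyletic age cellular organisms or Eukaryota")
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then symbols, tab-separated.
#' Duplicate symbols within a line are collapsed with a warning.
#'
#' @param path GMT file path.
#' @return Named list of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, ": expected at least 3 tab-separated fields, got ",
           length(fields))
    }
    sets[[i]] <- gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$symbols), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' The packaged progenitor gene set
#'
#' Loads the 77-gene progenitor signature shipped with the package. The
#' packaged list is a synthetic stand-in: 77 human gene symbols drawn from
#' complexes whose members are essential and phyletically ancient
#' (proteasome, chaperonin, MCM replicative helicase, ribosome, spliceosome,
#' replication machinery), curated from the packaged synthetic gene-age
#' table with the same essential-AND-ancient rule applied to the real
#' signature.
#'
#' @return A [gene_set] with 77 symbols.
#' @export
progenitor_gene_set <- function() {
  path <- system.file("extdata", "progenitor_synthetic.gmt",
                      package = "progenitorness", mustWork = TRUE)
  read_gmt(path)[[1L]]
}
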