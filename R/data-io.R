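#' Read an expression matrix from a delimited text file
#'
#' Reads a TSV/CSV expression table into the canonical samples x genes
#' orientation used throughout the package. The first column must carry
#' sample identifiers (or gene identifiers when
#' `orientation = "genes_by_samples"`); the header carries the other axis.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file. The
#'   delimiter is inferred from the extension unless `sep` is given.
#' @param orientation Either `"samples_by_genes"` (default; rows are samples)
#'   or `"genes_by_samples"` (rows are genes; the matrix is transposed on
#'   read).
#' @param sep Optional field delimiter overriding the extension-based guess.
#' @return A numeric matrix, samples in rows and genes in columns, with
#'   sample identifiers as `rownames` and gene identifiers as `colnames`.
#'   Gene identifiers are kept as opaque strings (Entrez IDs are numerals
#'   but are never parsed as numbers).
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes", "genes_by_samples"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  df <- read_delim_table(path, sep)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("expression table at '", path, "' is empty or has no data columns")
  }
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    col <- vals[[j]]
    if (is.character(col) || is.factor(col)) {
      num <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop("non-numeric expression value at row '", ids[bad[1L]],
             "', column '", colnames(vals)[j], "'")
      }
      col <- num
    }
    m[, j] <- as.numeric(col)
  }
  if (orientation == "genes_by_samples") m <- t(m)
  as_expression_matrix(m)
}

#' Validate a samples x genes expression matrix
#'
#' @param m Numeric matrix with sample `rownames` and gene `colnames`.
#' @return The validated matrix (invisibly the same object).
#' @export
as_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs sample rownames and gene colnames")
  }
  dup_s <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_s)) stop("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  dup_g <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_g)) stop("duplicated gene ids: ", paste(dup_g, collapse = ", "))
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  if (ncol(m) < 2L) stop("need at least 2 genes")
  m
}

#' Write an expression matrix back to TSV at full precision
#'
#' Floats are serialized with 17 significant digits so a read/write/read
#' round trip is bit-identical.
#'
#' @param m Samples x genes numeric matrix.
#' @param path Output file path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(sample = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype (clinical covariate) table
#'
#' @param path TSV/CSV file, samples in rows; first column holds sample
#'   identifiers, remaining columns the clinical/demographic variables.
#' @param group_variable Name of the binary condition column (e.g. current
#'   smoking status).
#' @param sep Optional delimiter override.
#' @return A `data.frame` with sample ids as `rownames`, carrying the
#'   attribute `group_variable`. Character columns are kept as character
#'   (categorical); numeric columns as numeric.
#' @export
read_phenotype <- function(path, group_variable, sep = NULL) {
  df <- read_delim_table(path, sep)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("phenotype table at '", path, "' is empty or has no variable columns")
  }
  ids <- as.character(df[[1L]])
  ph <- df[, -1L, drop = FALSE]
  rownames(ph) <- ids
  as_phenotype_table(ph, group_variable)
}

#' Validate a phenotype table and its binary grouping variable
#'
#' @param ph `data.frame` with sample rownames.
#' @param group_variable Column name of the binary condition.
#' @return The validated `data.frame` with attribute `group_variable`.
#' @export
as_phenotype_table <- function(ph, group_variable) {
  if (!is.data.frame(ph)) stop("phenotype must be a data.frame")
  if (is.null(rownames(ph))) stop("phenotype table needs sample rownames")
  if (!group_variable %in% colnames(ph)) {
    stop("group variable '", group_variable, "' not found; columns: ",
         paste(colnames(ph), collapse = ", "))
  }
  g <- ph[[group_variable]]
  if (anyNA(g)) {
    stop("missing values in group variable for samples: ",
         paste(rownames(ph)[is.na(g)], collapse = ", "))
  }
  lev <- unique(as.character(g))
  if (length(lev) != 2L) {
    stop("group variable '", group_variable, "' has ", length(lev),
         " observed level(s); exactly 2 required (",
         paste(utils::head(lev, 5L), collapse = ", "), ")")
  }
  attr(ph, "group_variable") <- group_variable
  ph
}

#' Align expression and phenotype tables and split samples by condition
#'
#' Restricts both tables to their common samples (in expression order),
#' drops samples with missing covariate values (complete-case, with a
#' message stating the count), and dichotomizes the samples into Group A /
#' Group B on the binary condition. Unless levels are named explicitly the
#' lexicographically smaller level becomes Group A, so the sign of the
#' group coefficient downstream is deterministic.
#'
#' @param expr Samples x genes matrix (see [read_expression()]).
#' @param pheno Phenotype `data.frame` (see [read_phenotype()]).
#' @param group_a_level,group_b_level Optional explicit level labels.
#' @return A list of class `"aligned_data"` with elements `expr`, `pheno`,
#'   `assignment` (a `group_assignment`: integer index vectors `group_a`,
#'   `group_b` into the aligned rows, plus `levels`).
#' @export
align_and_split <- function(expr, pheno,
                            group_a_level = NULL, group_b_level = NULL) {
  expr <- as_expression_matrix(expr)
  gv <- attr(pheno, "group_variable")
  if (is.null(gv)) stop("phenotype table lacks a group_variable attribute; use as_phenotype_table()")
  common <- intersect(rownames(expr), rownames(pheno))
  if (length(common) == 0L) stop("no overlapping sample ids between expression and phenotype")
  n_only_expr <- nrow(expr) - length(common)
  n_only_ph <- nrow(pheno) - length(common)
  if (n_only_expr + n_only_ph > 0L) {
    message(n_only_expr, " expression-only and ", n_only_ph,
            " phenotype-only sample(s) dropped")
  }
  keep <- rownames(expr)[rownames(expr) %in% common]
  ph <- pheno[keep, , drop = FALSE]
  cc <- stats::complete.cases(ph)
  if (any(!cc)) {
    message(sum(!cc), " sample(s) dropped for missing covariate values")
    keep <- keep[cc]
    ph <- ph[keep, , drop = FALSE]
  }
  ex <- expr[keep, , drop = FALSE]

  g <- as.character(ph[[gv]])
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("group variable has ", length(lev), " level(s) after filtering; need 2")
  if (!is.null(group_a_level) || !is.null(group_b_level)) {
    if (is.null(group_a_level)) group_a_level <- setdiff(lev, group_b_level)
    if (is.null(group_b_level)) group_b_level <- setdiff(lev, group_a_level)
    if (!all(c(group_a_level, group_b_level) %in% lev) ||
        group_a_level == group_b_level) {
      stop("group levels must name the two observed values: ", paste(lev, collapse = ", "))
    }
    lev <- c(group_a_level, group_b_level)
  }
  ia <- which(g == lev[1L])
  ib <- which(g == lev[2L])
  if (length(ia) < 4L || length(ib) < 4L) {
    stop("each group needs >= 4 samples (leave-one-out re-estimation); got ",
         length(ia), " and ", length(ib))
  }
  # warn when a categorical covariate level is observed in only one group
  for (v in setdiff(colnames(ph), gv)) {
    if (is.character(ph[[v]]) || is.factor(ph[[v]])) {
      la <- unique(as.character(ph[[v]][ia]))
      lb <- unique(as.character(ph[[v]][ib]))
      only <- c(setdiff(la, lb), setdiff(lb, la))
      if (length(only)) {
        warning("covariate '", v, "' level(s) ", paste(only, collapse = ", "),
                " observed in one group only; group effect may be partially confounded")
      }
    }
  }
  assignment <- structure(
    list(group_a = ia, group_b = ib, levels = lev),
    class = "group_assignment")
  stopifnot(length(intersect(ia, ib)) == 0L,
            length(union(ia, ib)) == nrow(ex))
  attr(ph, "group_variable") <- gv
  structure(list(expr = ex, pheno = ph, assignment = assignment),
            class = "aligned_data")
}

#' Read a two-column gene-identifier mapping table
#'
#' @param path TSV/CSV with two columns: source id (e.g. Entrez), target id
#'   (e.g. symbol). A header row is expected.
#' @param sep Optional delimiter override.
#' @return Named character vector: `map[source] = target`.
#' @export
read_id_map <- function(path, sep = NULL) {
  df <- read_delim_table(path, sep)
  if (ncol(df) < 2L) stop("id map needs two columns (source, target)")
  src <- as.character(df[[1L]])
  if (anyDuplicated(src)) {
    stop("duplicated source ids in map: ",
         paste(unique(src[duplicated(src)]), collapse = ", "))
  }
  stats::setNames(as.character(df[[2L]]), src)
}

#' Rename gene identifiers through a mapping, passing unknowns through
#'
#' Missing mappings fall through to the source id unchanged (counted in a
#' warning); order is preserved. Typical use: Entrez IDs to gene symbols.
#'
#' @param ids Character vector of gene ids.
#' @param map Named character vector (see [read_id_map()]) or a two-column
#'   `data.frame`.
#' @return Character vector of the same length and order.
#' @export
rename_genes <- function(ids, map) {
  if (is.data.frame(map)) {
    map <- stats::setNames(as.character(map[[2L]]), as.character(map[[1L]]))
  }
  ids <- as.character(ids)
  hit <- ids %in% names(map)
  out <- ids
  out[hit] <- unname(map[ids[hit]])
  if (any(!hit)) {
    warning(sum(!hit), " gene id(s) had no mapping and were passed through")
  }
  out
}

# Delimiter from extension (.csv -> comma, else tab) unless declared.
read_delim_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}
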