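#' Gene-by-sample matrix with a declared data role
#'
#' The pipeline moves three kinds of gene x sample tables around: relative
#' copy numbers stored as log2(copies/ploidy + 1), CRISPR knockout gene-effect
#' scores (0 = non-essential, negative = loss of viability), and expression as
#' log2(TPM + 1). A `gene_matrix` is a plain numeric matrix with unique gene
#' symbols as row names, unique sample ids as column names, and a `role`
#' attribute recording which of the three it holds, so that downstream
#' functions can refuse a matrix of the wrong kind.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   row and column names set. `NA` cells are allowed; each downstream
#'   operation documents how it treats them.
#' @param role One of `"copy_number"`, `"gene_effect"`, `"expression"`.
#' @param entrez_ids Optional integer vector of numeric gene ids (parallel to
#'   rows), kept as metadata when reading DepMap-style `"SYMBOL (id)"` labels.
#'
#' @return A numeric matrix of class `gene_matrix` with attributes `role` and
#'   (optionally) `entrez_ids`.
#' @export
gene_matrix <- function(values, role = c("copy_number", "gene_effect", "expression"),
                        entrez_ids = NULL) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene row names and sample column names", call. = FALSE)
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (!is.null(entrez_ids) && length(entrez_ids) != nrow(values)) {
    stop("`entrez_ids` must have one entry per gene row", call. = FALSE)
  }
  structure(values,
            class = c("gene_matrix", class(values)),
            role = role, entrez_ids = entrez_ids)
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix role=%s: %d genes x %d samples>\n",
              attr(x, "role"), nrow(x), ncol(x)))
  invisible(x)
}

#' Role of a gene matrix
#' @param x A [gene_matrix()].
#' @return The role tag.
#' @export
matrix_role <- function(x) attr(x, "role")

assert_role <- function(x, role, arg = deparse(substitute(x))) {
  if (!inherits(x, "gene_matrix")) {
    stop("`", arg, "` must be a gene_matrix", call. = FALSE)
  }
  if (!identical(attr(x, "role"), role)) {
    stop("`", arg, "` must have role '", role, "', got '", attr(x, "role"), "'",
         call. = FALSE)
  }
  invisible(x)
}
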