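#' Read a gene x sample matrix from delimited text
#'
#' Accepts CSV/TSV exports in the DepMap dialect: a header row of sample ids,
#' a first column of gene labels, and numeric cells. Gene labels of the form
#' `"SYMBOL (1956)"` are reduced to `SYMBOL`, with the numeric id retained in
#' the `entrez_ids` attribute. Malformed input is rejected, never coerced:
#' duplicate identifiers and non-numeric cells are errors that name the
#' offending gene or cell. Empty cells become `NA` and are tracked as missing.
#'
#' @param path Path to a delimited text file.
#' @param role Data role of the matrix (see [gene_matrix()]).
#' @param sep Field separator; default `","`.
#' @return A [gene_matrix()].
#' @export
read_gene_matrix <- function(path, role, sep = ",") {
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = "character",
                          data.table = FALSE, na.strings = c("", "NA"))
  if (ncol(dt) < 2L) stop("matrix file needs a gene column plus >= 1 sample column", call. = FALSE)
  labels <- dt[[1L]]
  parsed <- parse_gene_labels(labels)
  samples <- colnames(dt)[-1L]
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) {
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  dup_g <- unique(parsed$symbol[duplicated(parsed$symbol)])
  if (length(dup_g)) {
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(dt), length(samples),
                 dimnames = list(parsed$symbol, samples))
  for (j in seq_along(samples)) {
    cell <- dt[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene %s, sample %s",
                   cell[bad[1L]], parsed$symbol[bad[1L]], samples[j]), call. = FALSE)
    }
    vals[, j] <- num
  }
  entrez <- if (all(is.na(parsed$entrez))) NULL else parsed$entrez
  gene_matrix(vals, role = role, entrez_ids = entrez)
}

# "EGFR (1956)" -> symbol EGFR, id 1956; plain symbols pass through with NA id
parse_gene_labels <- function(labels) {
  m <- regmatches(labels, regexec("^\\s*(\\S+)\\s*\\((\\d+)\\)\\s*$", labels))
  symbol <- labels
  entrez <- rep(NA_integer_, length(labels))
  hit <- lengths(m) == 3L
  symbol[hit] <- vapply(m[hit], `[[`, "", 2L)
  entrez[hit] <- as.integer(vapply(m[hit], `[[`, "", 3L))
  list(symbol = trimws(symbol), entrez = entrez)
}

#' Write a gene matrix to delimited text
#'
#' Inverse of [read_gene_matrix()]: first column `gene`, one column per
#' sample, full numeric precision so a read-back reproduces the values
#' bit for bit.
#'
#' @param x A [gene_matrix()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_gene_matrix <- function(x, path, sep = ",") {
  df <- data.frame(gene = rownames(x), format_full(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

# numeric -> shortest decimal string that round-trips through as.numeric
format_full <- function(x) {
  if (is.matrix(x)) {
    out <- matrix(formatC(x, digits = 17, format = "g"), nrow(x), ncol(x),
                  dimnames = dimnames(x))
    out[is.na(x)] <- ""
    return(out)
  }
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Read / write GMT gene-set collections
#'
#' Standard MSigDB GMT: one set per line, tab-separated fields
#' `name`, `description`, then the member genes. Used here for positional
#' (chromosome-band) gene sets and for coamplicon gene sets. Lines with
#' fewer than three fields (i.e. an empty member list) are rejected with
#' their line number; duplicate set names are rejected.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors; each element carries a
#'   `description` attribute with the second GMT field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields (empty gene set?)", call. = FALSE)
    }
    nms[i] <- fields[1L]
    members <- unique(fields[-(1:2)])
    attr(members, "description") <- fields[2L]
    sets[[i]] <- members
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) stop("duplicate gene-set names: ", paste(dup, collapse = ", "), call. = FALSE)
  names(sets) <- nms
  sets
}

#' @rdname read_gmt
#' @param collection Named list of character vectors (optionally with
#'   `description` attributes).
#' @export
write_gmt <- function(collection, path) {
  if (is.null(names(collection)) || any(!nzchar(names(collection)))) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (any(lengths(collection) == 0L)) {
    stop("empty gene sets cannot be written to GMT", call. = FALSE)
  }
  lines <- vapply(names(collection), function(nm) {
    desc <- attr(collection[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read the sample table
#'
#' Required columns: `sample_id` and `lineage`. Optional columns: `ploidy`
#' (defaulted to 2, the neutral diploid assumption, with a warning naming the
#' affected samples) and `source` (`cell_line` or `tumor`; default
#' `cell_line`).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `sample_id`, `lineage`, `ploidy`, `source`.
#' @export
read_sample_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  for (col in c("sample_id", "lineage")) {
    if (!col %in% colnames(df)) stop("sample table lacks required column '", col, "'", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample table", call. = FALSE)
  if (any(!nzchar(df$lineage) | is.na(df$lineage))) {
    stop("empty lineage values in sample table", call. = FALSE)
  }
  if (!"ploidy" %in% colnames(df)) df$ploidy <- NA_real_
  missing_p <- is.na(df$ploidy)
  if (any(missing_p)) {
    warning("ploidy missing for ", sum(missing_p),
            " sample(s); defaulting to 2 (diploid): ",
            paste(utils::head(df$sample_id[missing_p], 5L), collapse = ", "),
            call. = FALSE)
    df$ploidy[missing_p] <- 2
  }
  if (any(df$ploidy <= 0)) stop("ploidy must be positive", call. = FALSE)
  if (!"source" %in% colnames(df)) df$source <- "cell_line"
  bad_src <- setdiff(unique(df$source), c("cell_line", "tumor"))
  if (length(bad_src)) stop("unknown source values: ", paste(bad_src, collapse = ", "), call. = FALSE)
  df[, c("sample_id", "lineage", "ploidy", "source")]
}

#' Read target annotations (localization + ligandability)
#'
#' Required columns: `gene_id`, `localization` (one of membrane, secreted,
#' cytoplasm, nucleus, organelle, unknown) and `ligandability`, a
#' structure-based score on the CanSAR-style scale from -3 (low) to 3 (high),
#' or missing. Out-of-range scores are rejected.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `gene_id`, `localization`, `ligandability`.
#' @export
read_target_annotations <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  for (col in c("gene_id", "localization", "ligandability")) {
    if (!col %in% colnames(df)) stop("annotation table lacks required column '", col, "'", call. = FALSE)
  }
  allowed <- c("membrane", "secreted", "cytoplasm", "nucleus", "organelle", "unknown")
  bad <- setdiff(unique(df$localization), allowed)
  if (length(bad)) stop("unknown localization class: ", paste(bad, collapse = ", "), call. = FALSE)
  df$ligandability <- as.numeric(df$ligandability)
  out_of_range <- !is.na(df$ligandability) & (df$ligandability < -3 | df$ligandability > 3)
  if (any(out_of_range)) {
    stop("ligandability outside [-3, 3] for: ",
         paste(df$gene_id[out_of_range], collapse = ", "), call. = FALSE)
  }
  df[, c("gene_id", "localization", "ligandability")]
}

#' Write a results table with stable column order and full precision
#'
#' Numeric columns are serialized with enough digits that reading the file
#' back reproduces the doubles exactly; column order is preserved as given.
#'
#' @param records A data.frame.
#' @param path Output path (TSV).
#' @export
write_results_table <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) out[[j]] <- format_full(out[[j]])
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
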