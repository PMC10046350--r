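# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# the reference study-scale fixture: 2,000 genes x 200 lines, 30% amplified,
# planted delta = -0.5 against effect noise 0.2
default_bundle <- function() {
  if (is.null(.fixtures$bundle)) .fixtures$bundle <- simulate_bundle(sim_config())
  .fixtures$bundle
}

# a smaller bundle for fast end-to-end checks
small_config <- function(...) {
  args <- list(n_genes = 300, n_lines = 120, amplicon_span = c(101L, 110L),
               reference_index = 105L, dependent_genes = c(103L, 106L, 108L),
               dosage_genes = c(103L, 106L), band_size = 50L, n_tumors = 200)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

small_bundle <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- simulate_bundle(small_config())
  .fixtures$small
}

# tiny gene matrix with explicit values; existing dimnames win
toy_matrix <- function(values, role, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- rownames(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- colnames(values)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  gene_matrix(values, role)
}

# vector with exact sample Pearson correlation r against x
make_correlated <- function(x, r, seed = 1) {
  set.seed(seed)
  z <- rnorm(length(x))
  z <- residuals(lm(z ~ x))
  xs <- as.numeric(scale(x))
  zs <- as.numeric(scale(z))
  r * xs + sqrt(1 - r^2) * zs
}

# frequency-table pair (tumor, cell line) for one lineage with exact r
similarity_pair <- function(r, n_genes = 8, lineage = "lin1") {
  x <- seq_len(n_genes) / (2 * n_genes)        # frequencies in (0, 0.5]
  y <- make_correlated(x, r)
  y <- (y - min(y)) / (max(y) - min(y) + 1)    # affine into [0,1): r preserved
  genes <- sprintf("REF%d", seq_len(n_genes))
  list(
    tumor = data.frame(reference_gene = genes, lineage = lineage, frequency = x),
    cellline = data.frame(reference_gene = genes, lineage = lineage, frequency = y))
}
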