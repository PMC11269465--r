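# Small fixtures built in code, shared across test files.

# experiment with prescribed per-bin sizes when cut into `n_bins`
# equal-width bins over [0, length(sizes)]
ce_with_bin_sizes <- function(sizes, n_genes = 5, seed = 11) {
  set.seed(seed)
  pt <- unlist(lapply(seq_along(sizes), function(j) {
    if (sizes[j] == 0) return(numeric(0))
    lo <- j - 1
    hi <- j - if (j == length(sizes)) 0 else 0.02
    seq(lo, hi, length.out = sizes[j])
  }))
  n <- length(pt)
  counts <- matrix(rpois(n_genes * n, 5), n_genes, n)
  cell_experiment(counts, pt, rep("A", n))
}

# two-path experiment with uniform pseudotime
ce_two_paths <- function(n_per_path = 60, n_genes = 8, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_path
  counts <- matrix(rpois(n_genes * n, 10), n_genes, n)
  cell_experiment(counts,
                  pseudotime = rep(seq(0, 10, length.out = n_per_path), 2),
                  path = rep(c("A", "B"), each = n_per_path))
}

# binned experiment assembled directly from a pseudobulk matrix
binned_from_matrix <- function(pb, path, bin_index) {
  stopifnot(ncol(pb) == length(path), length(path) == length(bin_index))
  if (is.null(rownames(pb))) rownames(pb) <- paste0("g", seq_len(nrow(pb)))
  colnames(pb) <- paste0(path, "_bin", bin_index)
  cd <- S4Vectors::DataFrame(path = path, bin_index = bin_index,
                             bin_size = rep(1L, length(path)),
                             bin_total = colSums(pb),
                             row.names = colnames(pb))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pseudobulk = pb), colData = cd)
  sf <- size_factors(se)
  se$size_factor <- sf$size_factor
  se$offset <- sf$offset
  se
}

# simulate pseudobulk counts directly from the polynomial branch model
model_pseudobulk <- function(beta, theta = 10, n_bins_per_path = 13,
                             degree = 3, n_genes = 1, offset = NULL) {
  bm <- data.frame(path = rep(c("A", "B"), each = n_bins_per_path),
                   bin_index = rep(seq_len(n_bins_per_path), 2))
  X <- build_design(bm, degree = degree, reference_path = "A")
  stopifnot(length(beta) == ncol(X))
  if (is.null(offset)) offset <- rep(0, nrow(X))
  mu <- exp(drop(X %*% beta) + offset)
  pb <- t(vapply(seq_len(n_genes),
                 function(i) rnbinom(length(mu), mu = mu, size = theta),
                 numeric(length(mu))))
  list(pb = pb, bm = bm, X = X, mu = mu)
}
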