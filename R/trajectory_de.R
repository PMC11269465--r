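#' Workflow configuration
#'
#' Collects the tunable parameters of the two-stage selection procedure.
#' Defaults follow common practice for trajectory data: cubic polynomial,
#' 0.05 significance levels with Benjamini-Hochberg correction at the
#' screening stage, and an R-squared gate of 0.6.
#'
#' @param degree polynomial degree of the time trend (default 3).
#' @param alpha_screen screening significance level (default 0.05).
#' @param p_adjust multiple-testing method for screening p-values
#'   (`"BH"` default; `"none"` tests raw p-values).
#' @param alpha_step stepwise drop-one significance level (default 0.05).
#' @param rsq_threshold deviance-R-squared gate for selection (default 0.6).
#' @param family GLM family, see [fit_glm()].
#' @param use_offset include log-size-factor offsets (default `TRUE`;
#'   automatically disabled for the gaussian family, which is meant for
#'   pre-normalized values).
#' @param reference_path baseline path for the dummies (default: first).
#' @param workers gene-level parallel workers (results are identical to a
#'   serial run; fits use no randomness).
#' @param seed optional seed recorded for provenance.
#' @return a `WorkflowConfig` list.
#' @export
workflow_config <- function(degree = 3, alpha_screen = 0.05, p_adjust = "BH",
                            alpha_step = 0.05, rsq_threshold = 0.6,
                            family = "negative_binomial", use_offset = TRUE,
                            reference_path = NULL, workers = 1, seed = NULL) {
  stopifnot(degree >= 1,
            alpha_screen > 0, alpha_screen < 1,
            alpha_step > 0, alpha_step < 1,
            rsq_threshold >= 0, rsq_threshold <= 1)
  if (family == "gaussian") use_offset <- FALSE
  structure(list(degree = degree, alpha_screen = alpha_screen,
                 p_adjust = p_adjust, alpha_step = alpha_step,
                 rsq_threshold = rsq_threshold, family = family,
                 use_offset = use_offset, reference_path = reference_path,
                 workers = workers, seed = seed),
            class = "WorkflowConfig")
}

.binned_parts <- function(binned, config) {
  pb <- assay(binned, "pseudobulk")
  cd <- as.data.frame(colData(binned))
  X <- build_design(cd, degree = config$degree,
                    reference_path = config$reference_path)
  offset <- if (config$use_offset) {
    if (is.null(cd$offset))
      stop("binned experiment has no offsets; rerun aggregate_bins() or ",
           "set use_offset = FALSE")
    cd$offset
  } else rep(0, ncol(pb))
  if (ncol(pb) < ncol(X) + 1)
    stop("only ", ncol(pb), " bins for a ", ncol(X), "-column model; ",
         "lower the polynomial degree or the drop-factor k")
  list(pb = pb, cd = cd, X = X, offset = offset)
}

.gene_apply <- function(genes, fn, workers) {
  if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(genes, fn, mc.cores = workers)
  } else {
    lapply(genes, fn)
  }
}

# null fit matching the effective family/dispersion of a full fit
.null_fit <- function(y, offset, full, family) {
  if (family == "negative_binomial") {
    if (full$poisson_fallback)
      fit_glm(y, matrix(1, length(y), 1), offset, family = "poisson")
    else
      fit_glm(y, matrix(1, length(y), 1), offset,
              family = "negative_binomial", theta = full$theta)
  } else {
    fit_glm(y, matrix(1, length(y), 1), offset, family = family)
  }
}

#' Screen genes against the intercept-only model
#'
#' Stage one of the workflow: per gene, the full polynomial branch model is
#' fitted and compared with an intercept-only (plus offset) model by a
#' likelihood-ratio test; p-values are corrected for multiple testing.
#' Non-convergent or degenerate (all-zero) genes are recorded as `NA` and
#' excluded downstream.
#'
#' @param binned a binned experiment from [aggregate_bins()].
#' @param config a [workflow_config()].
#' @return data.frame with one row per gene: `gene`, `p_value`,
#'   `adjusted_p`, `theta`, `converged`, `screened`.
#' @export
p_vector <- function(binned, config = workflow_config()) {
  parts <- .binned_parts(binned, config)
  genes <- rownames(parts$pb)
  rows <- .gene_apply(seq_along(genes), function(i) {
    y <- parts$pb[i, ]
    full <- suppressWarnings(
      fit_glm(y, parts$X, parts$offset, family = config$family))
    if (full$degenerate || !full$converged)
      return(c(p = NA_real_, theta = NA_real_, conv = 0))
    null <- .null_fit(y, parts$offset, full, config$family)
    c(p = lrt_pvalue(full, null), theta = full$theta, conv = 1)
  }, config$workers)
  m <- do.call(rbind, rows)
  p <- m[, "p"]
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- if (config$p_adjust == "none") p[ok]
             else p.adjust(p[ok], method = config$p_adjust)
  data.frame(gene = genes, p_value = p, adjusted_p = adj,
             theta = m[, "theta"], converged = m[, "conv"] == 1,
             screened = !is.na(adj) & adj <= config$alpha_screen,
             stringsAsFactors = FALSE)
}

# drop-one LRT p-values for every non-intercept column of the current model
.drop_one <- function(y, X, cols, offset, family, theta, cur) {
  vapply(cols, function(j) {
    red <- setdiff(cols, j)
    f <- .refit(y, X, c(1L, red), offset, family, theta)
    lam <- max(0, 2 * (cur$loglik - f$loglik))
    .lrt_p(lam, 1, cur$n - cur$rank, "f")
  }, numeric(1))
}

.refit <- function(y, X, cols, offset, family, theta) {
  suppressWarnings(
    fit_glm(y, X[, cols, drop = FALSE], offset, family = family,
            theta = if (family == "negative_binomial") theta else NULL))
}

#' Backward stepwise refinement of screened genes
#'
#' Stage two: starting from the full model, repeatedly drop the
#' non-intercept term with the largest drop-one likelihood-ratio p-value
#' exceeding `alpha_step`, refit, and stop when every remaining term is
#' significant (or only the intercept is left). Exact p-value ties are
#' broken by dropping interaction terms before main effects and higher
#' powers before lower. The NB dispersion is estimated once per gene from
#' the full model and held fixed across the elimination so that nested
#' models stay comparable. The deviance R-squared is computed on the final
#' model.
#'
#' @param binned a binned experiment from [aggregate_bins()].
#' @param genes character vector of genes that passed [p_vector()].
#' @param config a [workflow_config()].
#' @return data.frame with one row per gene: `selected_terms` (semicolon
#'   separated), `term_pvalues`, `coefficients`, `r_squared`, `converged`,
#'   `classification` (`branch-dependent` / `time-only` /
#'   `not significant`).
#' @export
t_fit <- function(binned, genes, config = workflow_config()) {
  parts <- .binned_parts(binned, config)
  meta <- attr(parts$X, "term_meta")
  if (length(genes) == 0) {
    return(data.frame(gene = character(), selected_terms = character(),
                      term_pvalues = character(), coefficients = character(),
                      r_squared = numeric(), converged = logical(),
                      classification = character(), stringsAsFactors = FALSE))
  }
  stopifnot(all(genes %in% rownames(parts$pb)))
  # tie-break priority: interactions/path terms first, then higher powers
  prio <- order(-as.integer(!is.na(meta$path)), -meta$power)
  prio_rank <- match(seq_len(nrow(meta)), prio)

  fit_one <- function(g) {
    y <- parts$pb[g, ]
    full <- suppressWarnings(
      fit_glm(y, parts$X, parts$offset, family = config$family))
    theta <- if (full$poisson_fallback) NULL else full$theta
    family <- if (full$poisson_fallback) "poisson" else config$family
    cols <- setdiff(seq_len(ncol(parts$X)), 1L)  # non-intercept columns
    cur <- .refit(y, parts$X, c(1L, cols), parts$offset, family, theta)
    repeat {
      if (length(cols) == 0) break
      pj <- .drop_one(y, parts$X, cols, parts$offset, family, theta, cur)
      worst <- which(pj > config$alpha_step)
      if (length(worst) == 0) break
      # largest p; ties resolved by precedence rank
      cand <- worst[pj[worst] == max(pj[worst])]
      drop_j <- cols[cand][order(prio_rank[cols[cand]])][1]
      cols <- setdiff(cols, drop_j)
      cur <- .refit(y, parts$X, c(1L, cols), parts$offset, family, theta)
    }
    term_names <- colnames(parts$X)[cols]
    pj_final <- if (length(cols) > 0)
      .drop_one(y, parts$X, cols, parts$offset, family, theta, cur)
    else numeric(0)
    r2 <- if (length(cols) == 0) 0 else deviance_r2(cur)
    cls <- if (length(cols) == 0) "not significant"
           else if (any(!is.na(meta$path[cols]))) "branch-dependent"
           else "time-only"
    coefs <- cur$coefficients
    data.frame(
      gene = g,
      selected_terms = paste(term_names, collapse = ";"),
      term_pvalues = paste(sprintf("%s=%.6g", term_names, pj_final),
                           collapse = ";"),
      coefficients = paste(sprintf("%s=%.17g", names(coefs), coefs),
                           collapse = ";"),
      r_squared = r2,
      converged = cur$converged,
      classification = cls,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, .gene_apply(genes, fit_one, config$workers))
  rownames(res) <- NULL
  attr(res, "degree") <- config$degree
  attr(res, "reference_path") <- attr(parts$X, "reference_path")
  res
}

#' Run the full two-stage selection
#'
#' Convenience driver: [p_vector()] screening, then [t_fit()] on the
#' screened genes, merged into one result table covering every gene.
#' Screened-out genes carry empty term sets, `NA` R-squared and the
#' `not significant` label.
#'
#' @inheritParams p_vector
#' @return a result table (data.frame), one row per gene, suitable for
#'   [get_siggenes()], [cluster_trends()], the `evaluate` functions and
#'   [write_results()].
#' @export
run_trajectory_de <- function(binned, config = workflow_config()) {
  screen <- p_vector(binned, config)
  sig <- screen$gene[screen$screened]
  step <- t_fit(binned, sig, config)
  res <- merge(screen, step, by = "gene", all.x = TRUE, sort = FALSE)
  res <- res[match(screen$gene, res$gene), ]
  miss <- is.na(res$selected_terms)
  res$selected_terms[miss] <- ""
  res$term_pvalues[miss] <- ""
  res$coefficients[miss] <- ""
  res$classification[miss] <- "not significant"
  res$converged <- ifelse(miss, res$converged.x, res$converged.y)
  res$converged.x <- res$converged.y <- NULL
  rownames(res) <- NULL
  attr(res, "degree") <- config$degree
  attr(res, "reference_path") <- attr(step, "reference_path")
  attr(res, "alpha_screen") <- config$alpha_screen
  res
}

#' Partition selected genes
#'
#' Applies the R-squared gate on top of the screening significance and
#' splits the selected genes into branch-dependent genes (any retained
#' term involves a path dummy or interaction) and time-only genes.
#' Boundary-equal genes (R-squared exactly at the threshold) are kept.
#'
#' @param results a result table from [run_trajectory_de()] / [t_fit()].
#' @param rsq_threshold R-squared gate (default 0.6).
#' @return list with `selected`, `branch_dependent`, `time_only` gene id
#'   vectors and the subset `table`.
#' @export
get_siggenes <- function(results, rsq_threshold = 0.6) {
  ok <- results$screened & !is.na(results$r_squared) &
    results$r_squared >= rsq_threshold
  tab <- results[ok, , drop = FALSE]
  list(selected = tab$gene,
       branch_dependent = tab$gene[tab$classification == "branch-dependent"],
       time_only = tab$gene[tab$classification == "time-only"],
       table = tab)
}

.parse_named <- function(s) {
  if (is.na(s) || s == "") return(numeric(0))
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
           vapply(kv, `[[`, character(1), 1))
}

#' Cluster fitted gene trends
#'
#' Each selected gene's fitted curve (predicted log-mean per bin, both
#' paths concatenated in bin order, z-score standardized per gene) is
#' clustered by hierarchical agglomeration with 1 - Pearson correlation
#' distance and average linkage, cut at `n_clusters`. Constant curves
#' (zero variance) are handled without NaNs by assigning them maximal
#' distance to non-constant curves and zero distance to each other.
#'
#' @param results a result table from [run_trajectory_de()].
#' @param binned the binned experiment the results were computed on.
#' @param n_clusters number of clusters (must not exceed the number of
#'   selected genes).
#' @param rsq_threshold gate used to pick the genes to cluster.
#' @return list with `labels` (named integer vector), `curves` (genes x
#'   bins matrix of standardized fitted trends) and `trends` (per-cluster
#'   mean trend per bin, with path and bin metadata).
#' @export
cluster_trends <- function(results, binned, n_clusters,
                           rsq_threshold = 0.6) {
  sel <- get_siggenes(results, rsq_threshold)$table
  if (nrow(sel) < n_clusters)
    stop("n_clusters (", n_clusters, ") exceeds the ", nrow(sel),
         " selected gene(s)")
  degree <- attr(results, "degree")
  if (is.null(degree)) degree <- 3
  X <- build_design(colData(binned), degree = degree,
                    reference_path = attr(results, "reference_path"))
  curves <- matrix(0, nrow(sel), ncol = nrow(X),
                   dimnames = list(sel$gene, colnames(binned)))
  for (i in seq_len(nrow(sel))) {
    beta <- .parse_named(sel$coefficients[i])
    beta <- beta[!is.na(beta)]
    idx <- match(names(beta), colnames(X))
    eta <- drop(X[, idx, drop = FALSE] %*% beta)
    s <- stats::sd(eta)
    curves[i, ] <- if (is.finite(s) && s > 0) (eta - mean(eta)) / s
                   else rep(0, length(eta))
  }
  if (n_clusters == 1 || nrow(curves) == 1) {
    labels <- setNames(rep(1L, nrow(curves)), rownames(curves))
  } else {
    C <- suppressWarnings(cor(t(curves)))
    C[!is.finite(C)] <- 0
    const <- apply(curves, 1, function(v) all(v == 0))
    if (any(const)) C[const, const] <- 1   # zero distance among constants
    diag(C) <- 1
    hc <- hclust(as.dist(1 - C), method = "average")
    labels <- cutree(hc, k = n_clusters)
  }
  cd <- as.data.frame(colData(binned))
  trends <- do.call(rbind, lapply(sort(unique(labels)), function(k) {
    data.frame(cluster = k, bin = colnames(binned), path = cd$path,
               bin_index = cd$bin_index,
               mean_trend = colMeans(curves[labels == k, , drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(labels = labels, curves = curves, trends = trends)
}
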