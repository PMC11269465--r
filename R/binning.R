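#' Number of pseudotime bins for a path
#'
#' Histogram-rule bin count with a drop-factor `k`: the bracketed rule value
#' is ceiled, multiplied by `k`, and ceiled again, e.g. Sturges gives
#' `ceil(ceil(log2(N) + 1) * k)`. `k < 1` compresses the pseudotime axis
#' into fewer, larger bins (useful for very sparse data); `k > 1` refines
#' it. The result is floored at 2 bins (1 when fewer than 4 cells).
#'
#' @param n_cells number of cells on the path.
#' @param strategy one of `"sturges"` (default), `"rice"`, `"doane"`,
#'   `"freedman_diaconis"`, `"scott"`, `"sqrt"`.
#' @param k drop-factor, `k >= 0.3`.
#' @param x the pseudotime values themselves; required by the data-dependent
#'   rules (`doane`, `freedman_diaconis`, `scott`).
#' @return integer bin count.
#' @export
#' @examples
#' bin_count(1024)            # 11
#' bin_count(1024, k = 0.3)   # 4
bin_count <- function(n_cells, strategy = "sturges", k = 1, x = NULL) {
  stopifnot(n_cells >= 1)
  if (!is.numeric(k) || length(k) != 1 || k < 0.3)
    stop("drop-factor k must be a single number >= 0.3")
  strategy <- match.arg(strategy, c("sturges", "rice", "doane",
                                    "freedman_diaconis", "scott", "sqrt"))
  n <- as.numeric(n_cells)
  needs_x <- strategy %in% c("doane", "freedman_diaconis", "scott")
  if (needs_x && is.null(x))
    stop("strategy '", strategy, "' needs the pseudotime values (x)")
  base <- switch(strategy,
    sturges = log2(n) + 1,
    rice = 2 * n^(1/3),
    sqrt = sqrt(n),
    doane = {
      g1 <- .skewness(x)
      sg <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
      1 + log2(n) + log2(1 + abs(g1) / sg)
    },
    scott = {
      h <- 3.49 * stats::sd(x) * n^(-1/3)
      if (!is.finite(h) || h <= 0) 1 else diff(range(x)) / h
    },
    freedman_diaconis = {
      h <- 2 * stats::IQR(x) * n^(-1/3)
      if (!is.finite(h) || h <= 0) 1 else diff(range(x)) / h
    })
  b <- ceiling(ceiling(base) * k)
  floor_b <- if (n_cells < 4) 1L else 2L
  max(as.integer(b), floor_b)
}

.skewness <- function(x) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(0)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  (sqrt(n * (n - 1)) / (n - 2)) * mean((x - m)^3) / s^3
}

#' Assign cells to equal-width pseudotime bins
#'
#' Partitions `[min(t), max(t)]` into `n_bins` equal-width intervals,
#' left-closed and right-open except the last, which is closed on both
#' ends. Indices are 1-based ordinals, non-decreasing in pseudotime.
#' A zero pseudotime range yields a single bin.
#'
#' @param pseudotime numeric vector of finite values.
#' @param n_bins positive integer.
#' @return integer vector of bin indices.
#' @export
assign_bins <- function(pseudotime, n_bins) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  stopifnot(all(is.finite(pseudotime)))
  lo <- min(pseudotime); hi <- max(pseudotime)
  if (hi == lo || n_bins == 1) return(rep(1L, length(pseudotime)))
  width <- (hi - lo) / n_bins
  idx <- floor((pseudotime - lo) / width) + 1
  as.integer(pmin(idx, n_bins))
}

#' Discretize pseudotime into per-path bins
#'
#' The binning analogue of a pseudotime "squeeze": each branching path is
#' binned separately over its own pseudotime range, large bins are split by
#' equalization (and small bins optionally pruned), and empty bins are
#' dropped so that the remaining ordinals are consecutive.
#'
#' @param ce a validated `SingleCellExperiment` (see [cell_experiment()]).
#' @param strategy,drop_factor histogram rule and drop-factor, see
#'   [bin_count()].
#' @param n_bins optional integer (or named per-path vector) forcing the bin
#'   count and bypassing the histogram rule.
#' @param split_bin split bins larger than mu + sigma (default `TRUE`).
#' @param prune_bin remove bins smaller than mu - sigma (default `FALSE`;
#'   pruned cells are dropped, not reassigned).
#' @param drop_tails truncate every path to the bin count of the shortest
#'   path (default `FALSE`); see [drop_tails()].
#' @param max_iterations equalization iteration cap.
#' @return A `BinMap` object: per-path interval tables, per-cell bin
#'   assignments, and the binning configuration.
#' @export
bin_pseudotime <- function(ce, strategy = "sturges", drop_factor = 1,
                           n_bins = NULL, split_bin = TRUE,
                           prune_bin = FALSE, drop_tails = FALSE,
                           max_iterations = 10) {
  validate_cell_experiment(ce)
  cd <- colData(ce)
  cells <- data.frame(cell_id = colnames(ce),
                      path = as.character(cd$path),
                      pseudotime = as.numeric(cd$pseudotime),
                      bin = NA_integer_, stringsAsFactors = FALSE)
  paths <- unique(cells$path)
  state <- list()
  for (p in paths) {
    rows <- which(cells$path == p)
    pt <- cells$pseudotime[rows]
    b <- if (!is.null(n_bins)) {
      if (!is.null(names(n_bins)) && p %in% names(n_bins))
        as.integer(n_bins[[p]]) else as.integer(n_bins[[1]])
    } else bin_count(length(rows), strategy, drop_factor, x = pt)
    idx <- assign_bins(pt, b)
    ord <- order(pt)            # stable: ties keep input order
    groups <- split(rows[ord], idx[ord])
    state[[p]] <- unname(groups)  # drop empty bins implicitly
  }
  bm <- .as_bin_map(state, cells, strategy, drop_factor, n_dropped = 0L)
  bm <- equalize_bins(bm, split_large = split_bin, prune_small = prune_bin,
                      max_iterations = max_iterations)
  if (drop_tails) bm <- drop_tails(bm)
  bm
}

# internal: build a BinMap from per-path lists of cell-row groups
.as_bin_map <- function(state, cells, strategy, k, n_dropped) {
  cells$bin <- NA_integer_
  path_tabs <- list()
  for (p in names(state)) {
    groups <- state[[p]]
    sizes <- vapply(groups, length, 1L)
    pt_all <- cells$pseudotime
    lo_edge <- min(pt_all[cells$path == p])
    hi_edge <- max(pt_all[cells$path == p])
    lows <- ups <- numeric(length(groups))
    for (j in seq_along(groups)) {
      cells$bin[groups[[j]]] <- j
      lows[j] <- if (j == 1) lo_edge else
        (max(pt_all[groups[[j - 1]]]) + min(pt_all[groups[[j]]])) / 2
      ups[j] <- if (j == length(groups)) hi_edge else
        (max(pt_all[groups[[j]]]) + min(pt_all[groups[[j + 1]]])) / 2
    }
    path_tabs[[p]] <- data.frame(bin = seq_along(groups), lower = lows,
                                 upper = ups, size = sizes)
  }
  structure(list(paths = path_tabs, cells = cells, strategy = strategy,
                 k = k, n_dropped = n_dropped),
            class = "BinMap")
}

# internal: per-path list of cell-row groups from a BinMap
.bin_groups <- function(bin_map) {
  cells <- bin_map$cells
  out <- list()
  for (p in names(bin_map$paths)) {
    rows <- which(cells$path == p & !is.na(cells$bin))
    rows <- rows[order(cells$pseudotime[rows])]
    out[[p]] <- unname(split(rows, cells$bin[rows]))
  }
  out
}

#' Equalize bin sizes within each path
#'
#' Per path, the mean `mu` and population standard deviation `sigma` of the
#' bin sizes at entry establish the allowable range `[mu - sigma,
#' mu + sigma]`. Bins above the maximum are split into
#' `ceil(size / (mu + sigma))` sub-bins of near-equal cell count by
#' pseudotime rank; bins below the minimum are removed when `prune_small`
#' is on (their cells are dropped). The rules are re-applied against the
#' established criteria until every bin conforms or `max_iterations` is
#' reached. (The criteria are deliberately not recomputed from the
#' shrinking sizes at each pass: doing so lets each split lower the mean
#' and mark previously conforming bins as oversized, cascading uniform
#' data into single-digit bins and defeating the purpose of pseudo-bulk
#' aggregation.)
#'
#' @param bin_map a `BinMap`.
#' @param split_large,prune_small which rules to apply; with both `FALSE`
#'   the input is returned unchanged.
#' @param max_iterations iteration cap (default 10).
#' @return the equalized `BinMap`, ordinals re-assigned consecutively.
#' @export
equalize_bins <- function(bin_map, split_large = TRUE, prune_small = FALSE,
                          max_iterations = 10) {
  stopifnot(inherits(bin_map, "BinMap"))
  if (!split_large && !prune_small) return(bin_map)
  state <- .bin_groups(bin_map)
  dropped <- bin_map$n_dropped
  for (p in names(state)) {
    groups <- state[[p]]
    sizes0 <- vapply(groups, length, 1L)
    mu <- mean(sizes0)
    sigma <- sqrt(mean((sizes0 - mu)^2))
    hi <- mu + sigma; lo <- mu - sigma
    for (it in seq_len(max_iterations)) {
      changed <- FALSE
      new_groups <- list()
      for (g in groups) {
        sz <- length(g)
        if (split_large && sz > hi && sigma > 0) {
          nsub <- ceiling(sz / hi)
          sub_sizes <- rep(sz %/% nsub, nsub)
          extra <- sz %% nsub
          if (extra > 0) sub_sizes[seq_len(extra)] <- sub_sizes[seq_len(extra)] + 1L
          splits <- split(g, rep(seq_len(nsub), sub_sizes))
          new_groups <- c(new_groups, unname(splits))
          changed <- TRUE
        } else if (prune_small && sz < lo) {
          dropped <- dropped + sz
          changed <- TRUE
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      groups <- new_groups
      if (!changed) break
      if (length(groups) == 0)
        stop("equalization removed every bin on path '", p, "'")
    }
    state[[p]] <- groups
  }
  cells <- bin_map$cells
  cells$bin <- NA_integer_
  .as_bin_map(state, cells, bin_map$strategy, bin_map$k, dropped)
}

#' Truncate paths to the bin range of the shortest path
#'
#' Removes, on every path, bins whose ordinal index exceeds the maximum
#' index of the path with the fewest bins, restricting the analysis to the
#' pseudotime segment shared by all branches.
#'
#' @param bin_map a `BinMap` with at least 2 paths (single-path input is a
#'   no-op with a warning).
#' @return the truncated `BinMap`.
#' @export
drop_tails <- function(bin_map) {
  stopifnot(inherits(bin_map, "BinMap"))
  if (length(bin_map$paths) < 2) {
    warning("drop_tails needs >= 2 paths; returning input unchanged")
    return(bin_map)
  }
  max_idx <- min(vapply(bin_map$paths, function(tab) max(tab$bin), 1L))
  if (max_idx < 1) stop("a path would be empty after truncation")
  state <- .bin_groups(bin_map)
  dropped <- bin_map$n_dropped
  for (p in names(state)) {
    g <- state[[p]]
    if (length(g) > max_idx) {
      dropped <- dropped + sum(lengths(g[(max_idx + 1):length(g)]))
      state[[p]] <- g[seq_len(max_idx)]
    }
    if (length(state[[p]]) == 0)
      stop("path '", p, "' is empty after truncation")
  }
  cells <- bin_map$cells
  cells$bin <- NA_integer_
  .as_bin_map(state, cells, bin_map$strategy, bin_map$k, dropped)
}

#' Aggregate pseudo-bulk counts per (path, bin)
#'
#' Sums the counts of all member cells of every bin, separately per path,
#' and attaches per-bin metadata (path, ordinal binned-pseudotime index,
#' bin size, bin total, size factor and log-size-factor offset). Cells
#' without a bin (only possible after pruning) are excluded; total counts
#' over retained cells are conserved.
#'
#' @param ce the `SingleCellExperiment` the bin map was derived from.
#' @param bin_map a `BinMap` from [bin_pseudotime()].
#' @param compute_size_factors attach size factors/offsets (default `TRUE`).
#' @return A `SummarizedExperiment` with a `pseudobulk` assay (genes x
#'   bins) and the `BinMap` in its metadata.
#' @export
aggregate_bins <- function(ce, bin_map, compute_size_factors = TRUE) {
  stopifnot(inherits(bin_map, "BinMap"))
  cells <- bin_map$cells
  if (!identical(cells$cell_id, colnames(ce)))
    stop("bin_map was not derived from this experiment")
  excluded <- sum(is.na(cells$bin))
  if (excluded > 0)
    message(excluded, " cell(s) without a bin excluded from aggregation")
  cols <- list(); meta <- list()
  counts <- assay(ce, "counts")
  for (p in names(bin_map$paths)) {
    tab <- bin_map$paths[[p]]
    for (j in tab$bin) {
      members <- which(cells$path == p & !is.na(cells$bin) & cells$bin == j)
      cols[[length(cols) + 1L]] <-
        Matrix::rowSums(counts[, members, drop = FALSE])
      meta[[length(meta) + 1L]] <-
        data.frame(path = p, bin_index = j, bin_size = length(members),
                   stringsAsFactors = FALSE)
    }
  }
  pb <- round(do.call(cbind, cols))
  md <- do.call(rbind, meta)
  md$bin_total <- colSums(pb)
  colnames(pb) <- paste0(md$path, "_bin", md$bin_index)
  rownames(md) <- colnames(pb)
  se <- SummarizedExperiment(
    assays = list(pseudobulk = pb),
    colData = DataFrame(md),
    metadata = list(bin_map = bin_map, n_cells_excluded = excluded))
  if (compute_size_factors) {
    sf <- size_factors(se)
    se$size_factor <- sf$size_factor
    se$offset <- sf$offset
  }
  se
}

#' Per-bin size factors and offsets
#'
#' The size factor of bin `b` is its total count divided by the geometric
#' mean of all bin totals; the offset is its logarithm (so offsets average
#' to zero). Offsets enter the GLM linear predictor with coefficient fixed
#' at 1, normalizing for unequal bin depth.
#'
#' @param binned a binned experiment from [aggregate_bins()].
#' @return data.frame with columns `size_factor` and `offset`.
#' @export
size_factors <- function(binned) {
  totals <- colData(binned)$bin_total
  if (any(totals <= 0))
    stop("bin(s) with zero total counts; enable prune_bin to remove ",
         "under-populated bins")
  lt <- log(totals)
  offset <- lt - mean(lt)
  data.frame(size_factor = exp(offset), offset = offset,
             row.names = colnames(binned))
}
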