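test_that("screening flags genes with real trends and spares flat ones", {
  set.seed(21)
  # one strongly increasing gene, one branch-divergent, six flat
  beta_flat <- c(log(40), rep(0, 7))
  beta_time <- c(log(40), 0.25, 0, 0, 0, 0, 0, 0)
  beta_branch <- c(log(40), 0, 0, 0, 0, 0.25, 0, 0)
  mk <- function(b) model_pseudobulk(b, theta = 10)$pb
  pb <- rbind(mk(beta_time), mk(beta_branch),
              do.call(rbind, replicate(6, mk(beta_flat), simplify = FALSE)))
  rownames(pb) <- paste0("g", 1:8)
  bm <- model_pseudobulk(beta_flat)$bm
  be <- binned_from_matrix(pb, bm$path, bm$bin_index)
  sc <- p_vector(be, workflow_config(use_offset = FALSE))
  expect_true(all(sc$screened[1:2]))
  expect_lt(sc$p_value[1], 1e-3)
  expect_identical(sc$gene, rownames(pb))
})

test_that("too few bins for the requested degree errors helpfully", {
  pb <- matrix(rpois(32, 20), 4, 8)
  be <- binned_from_matrix(pb, rep(c("A", "B"), each = 4), rep(1:4, 2))
  expect_error(p_vector(be, workflow_config(degree = 3)), "degree")
})

test_that("stepwise keeps the generating terms and drops the rest", {
  set.seed(33)
  reps <- 12
  hit_time <- hit_inter <- 0
  for (r in seq_len(reps)) {
    sim_t <- model_pseudobulk(c(log(30), 0.3, 0, 0, 0, 0, 0, 0), theta = 20)
    be_t <- binned_from_matrix(sim_t$pb, sim_t$bm$path, sim_t$bm$bin_index)
    res_t <- t_fit(be_t, "g1", workflow_config(use_offset = FALSE))
    terms_t <- strsplit(res_t$selected_terms, ";")[[1]]
    if ("t" %in% terms_t && !any(grepl("z_B", terms_t))) hit_time <- hit_time + 1
    sim_i <- model_pseudobulk(c(log(30), 0, 0, 0, 0, 0.3, 0, 0), theta = 20)
    be_i <- binned_from_matrix(sim_i$pb, sim_i$bm$path, sim_i$bm$bin_index)
    res_i <- t_fit(be_i, "g1", workflow_config(use_offset = FALSE))
    # any retained time-by-path interaction marks branch dependence;
    # correlated polynomial terms make t:z vs t2:z interchangeable
    if (grepl("t[0-9]?:z_B", res_i$selected_terms)) hit_inter <- hit_inter + 1
  }
  expect_gte(hit_time, reps - 2)
  expect_gte(hit_inter, reps - 2)
})

test_that("a flat gene collapses to intercept-only with zero R-squared", {
  set.seed(9)
  sim <- model_pseudobulk(c(log(50), rep(0, 7)), theta = 50)
  be <- binned_from_matrix(sim$pb, sim$bm$path, sim$bm$bin_index)
  res <- t_fit(be, "g1", workflow_config(use_offset = FALSE))
  expect_identical(res$selected_terms, "")
  expect_identical(res$r_squared, 0)
  expect_identical(res$classification, "not significant")
})

test_that("an empty significant set flows through cleanly", {
  pb <- matrix(rpois(8 * 26, 30), 8, 26)
  bm <- model_pseudobulk(c(log(30), rep(0, 7)))$bm
  be <- binned_from_matrix(pb, bm$path, bm$bin_index)
  res <- t_fit(be, character(0), workflow_config(use_offset = FALSE))
  expect_identical(nrow(res), 0L)
  sel <- get_siggenes(data.frame(gene = character(), screened = logical(),
                                 r_squared = numeric(),
                                 classification = character()), 0.6)
  expect_length(sel$selected, 0)
})

test_that("selection applies both gates and partitions by term type", {
  res <- data.frame(
    gene = paste0("g", 1:5),
    screened = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    r_squared = c(0.7, 0.5, 0.8, 0.9, 0.6),
    classification = c("branch-dependent", "branch-dependent",
                       "time-only", "branch-dependent", "time-only"),
    stringsAsFactors = FALSE)
  sel <- get_siggenes(res, 0.6)
  expect_identical(sel$selected, c("g1", "g3", "g5"))   # boundary 0.6 kept
  expect_identical(sel$branch_dependent, "g1")
  expect_identical(sel$time_only, c("g3", "g5"))
  # raising the threshold never grows the set
  for (thr in seq(0, 1, by = 0.1)) {
    hi <- get_siggenes(res, min(thr + 0.1, 1))$selected
    lo <- get_siggenes(res, thr)$selected
    expect_true(all(hi %in% lo))
  }
})

test_that("end-to-end recovery on model-generated genes", {
  set.seed(55)
  # 30 genes: 10 time-linear, 10 interaction, 10 flat
  betas <- c(replicate(10, c(log(30), 0.3, 0, 0, 0, 0, 0, 0), simplify = FALSE),
             replicate(10, c(log(30), 0, 0, 0, 0, 0.3, 0, 0), simplify = FALSE),
             replicate(10, c(log(30), rep(0, 7)), simplify = FALSE))
  sims <- lapply(betas, function(b) model_pseudobulk(b, theta = 20)$pb)
  pb <- do.call(rbind, sims)
  rownames(pb) <- paste0("g", seq_len(nrow(pb)))
  bm <- model_pseudobulk(betas[[1]])$bm
  be <- binned_from_matrix(pb, bm$path, bm$bin_index)
  res <- run_trajectory_de(be, workflow_config(use_offset = FALSE))
  expect_gte(sum(res$screened[1:20]), 18)
  expect_lte(sum(res$screened[21:30]), 3)
  sel <- get_siggenes(res, 0.6)
  # stepwise occasionally keeps a stray term (per-term alpha 0.05 over 7
  # candidates), so classification purity is high but not perfect
  expect_gte(mean(sel$time_only %in% paste0("g", 1:10)), 0.7)
  expect_gte(mean(sel$branch_dependent %in% paste0("g", 11:20)), 0.7)
  expect_true(all(paste0("g", 11:20) %in% sel$branch_dependent))
  expect_gte(length(sel$selected), 15)
})

test_that("trend clustering separates distinct curve families", {
  set.seed(14)
  up <- c(log(30), 0.35, 0, 0, 0, 0, 0, 0)
  div <- c(log(30), 0, 0, 0, 0, -0.35, 0, 0)
  pb <- rbind(
    do.call(rbind, replicate(4, model_pseudobulk(up, theta = 80)$pb,
                             simplify = FALSE)),
    do.call(rbind, replicate(4, model_pseudobulk(div, theta = 80)$pb,
                             simplify = FALSE)))
  rownames(pb) <- paste0("g", 1:8)
  bm <- model_pseudobulk(up)$bm
  be <- binned_from_matrix(pb, bm$path, bm$bin_index)
  res <- run_trajectory_de(be, workflow_config(use_offset = FALSE))
  cl <- cluster_trends(res, be, n_clusters = 2, rsq_threshold = 0.3)
  lab <- cl$labels
  expect_identical(length(unique(lab[paste0("g", 1:4)])), 1L)
  expect_identical(length(unique(lab[paste0("g", 5:8)])), 1L)
  expect_false(lab[["g1"]] == lab[["g5"]])
  # single cluster mode
  cl1 <- cluster_trends(res, be, n_clusters = 1, rsq_threshold = 0.3)
  expect_true(all(cl1$labels == 1))
  expect_false(any(is.na(cl1$trends$mean_trend)))
  # more clusters than genes errors
  expect_error(cluster_trends(res, be, n_clusters = 50), "exceeds")
})

test_that("gene-parallel execution reproduces the serial result", {
  set.seed(61)
  pb <- matrix(rnbinom(20 * 26, mu = 25, size = 5), 20, 26)
  rownames(pb) <- paste0("g", 1:20)
  bm <- model_pseudobulk(c(log(30), rep(0, 7)))$bm
  be <- binned_from_matrix(pb, bm$path, bm$bin_index)
  serial <- run_trajectory_de(be, workflow_config(workers = 1))
  par2 <- run_trajectory_de(be, workflow_config(workers = 2))
  expect_identical(serial, par2)
})
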