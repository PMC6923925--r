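test_that("ANOVA F equals the brute-force SSB/SSW computation", {
  # hand-checkable case: {1,2,3} vs {4,5,6} -> F = 13.5
  x <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  ann <- suppressWarnings(sample_annotation(colnames(x),
                                            rep(c("A", "B"), each = 3)))
  tab <- anova_rank(x, ann)
  expect_equal(tab$F_statistic, 13.5)
  expect_lt(tab$p_value, 0.05)
  expect_true(tab$significant)

  # property: random small instances against the oracle and oneway.test
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(2:4, 1)
    reps <- sample(3:6, k, replace = TRUE)
    vals <- rnorm(sum(reps), 5, 2)
    group <- rep(paste0("t", seq_len(k)), reps)
    m <- matrix(vals, nrow = 1, dimnames = list("g", paste0("s", seq_along(vals))))
    ann <- suppressWarnings(sample_annotation(colnames(m), group))
    got <- anova_rank(m, ann)
    oracle <- brute_force_f(vals, group)
    expect_equal(got$F_statistic, oracle$F, tolerance = 1e-10)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
    ow <- oneway.test(vals ~ factor(group), var.equal = TRUE)
    expect_equal(got$F_statistic, unname(ow$statistic), tolerance = 1e-8)
  }
})

test_that("ANOVA ranking sorts by p, flags significance, handles degenerates", {
  ref <- tiny_reference()
  tab <- anova_rank(ref$expr, ref$annotation)
  expect_identical(nrow(tab), nrow(ref$expr))
  expect_false(is.unsorted(tab$p_value))
  expect_identical(tab$rank, seq_len(nrow(tab)))
  # markers dominate the significant set
  n_markers <- nrow(ref$markers)
  expect_gt(mean(ref$markers$gene_id %in%
                   tab$probe_id[tab$significant]), 0.99)

  # constant feature: p = 1, never selected
  expr <- ref$expr
  expr["gene00399", ] <- 5
  tab2 <- anova_rank(expr, ref$annotation)
  row <- tab2[tab2$probe_id == "gene00399", ]
  expect_equal(row$p_value, 1)
  expect_false(row$significant)
  expect_identical(row$rank, nrow(tab2))
})

test_that("ANOVA preconditions: <2 replicates or unannotated samples error", {
  x <- random_expr(5, 4)
  ann3 <- suppressWarnings(sample_annotation(colnames(x)[1:3],
                                             c("A", "A", "B")))
  expect_error(anova_rank(x[, 1:3, drop = FALSE], ann3), "< 2 replicates")
  expect_error(anova_rank(x, ann3), "unannotated")
})

test_that("condition number matches an independent full-SVD oracle", {
  expect_equal(condition_number(diag(3)), 1.0)
  expect_equal(condition_number(diag(c(2, 1))), 2.0)
  expect_identical(condition_number(matrix(c(1, 2, 2, 4), 2)), Inf)
  expect_error(condition_number(matrix(numeric(0), 0, 0)), "empty")

  for (seed in 1:20) {
    set.seed(seed)
    nr <- sample(5:200, 1); nc <- sample(2:50, 1)
    m <- matrix(rnorm(nr * nc), nr, nc)
    d <- svd(m)$d                       # full SVD as the oracle
    expect_equal(condition_number(m), max(d) / min(d), tolerance = 1e-9)
  }
})

test_that("condition scan minimizes kappa on the grid, first G wins ties", {
  ref <- tiny_reference(noise_sd = 0.5)
  tab <- anova_rank(ref$expr, ref$annotation)
  scan <- scan_optimal_G(tab, ref$expr, step = 40L)
  n_sig <- sum(tab$significant)
  expect_identical(scan$grid$G, as.integer(seq(40, n_sig, by = 40)))
  # oracle: evaluate every grid point independently and take the argmin
  oracle <- vapply(scan$grid$G, function(g) {
    m <- ref$expr[tab$probe_id[seq_len(g)], ]
    d <- svd(m)$d; max(d) / min(d)
  }, numeric(1))
  expect_equal(scan$grid$kappa, oracle, tolerance = 1e-9)
  expect_identical(scan$G_star, scan$grid$G[which.min(oracle)])
  expect_true(all(scan$kappa_star <= scan$grid$kappa))

  # fewer significant probes than the step: single grid point
  scan1 <- scan_optimal_G(tab, ref$expr, step = 10000L)
  expect_identical(nrow(scan1$grid), 1L)
  expect_identical(scan1$G_star, n_sig)

  # partial final bin only on request
  scan2 <- scan_optimal_G(tab, ref$expr, step = 40L, include_partial = TRUE)
  if (n_sig %% 40L != 0L) expect_identical(max(scan2$grid$G), n_sig)
})

test_that("per-type medians follow the sort-and-middle convention", {
  x <- matrix(c(1, 2, 9,  1, 3, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"),
                              c("T_rep1", "T_rep2", "T_rep3")))
  ann <- ann_from_colnames(x)
  med <- summarize_by_cell_type(x, ann)
  expect_equal(unname(med["gA", "T"]), 2)      # odd count: middle value
  x2 <- x[, 1:2]
  ann2 <- ann_from_colnames(x2)
  med2 <- summarize_by_cell_type(x2, ann2)
  expect_equal(unname(med2["gB", "T"]), 2)     # even count {1,3}: mean of pair

  # one replicate per type: medians equal the columns
  y <- random_expr(6, 3)
  colnames(y) <- c("A_rep1", "B_rep1", "C_rep1")
  anny <- suppressWarnings(sample_annotation(colnames(y), c("A", "B", "C"),
                                             min_replicates = 1L))
  expect_equal(unname(summarize_by_cell_type(y, anny)), unname(y))

  # duplicating every replicate of every type leaves medians unchanged
  ref <- tiny_reference(k = 3, r = 3, g = 60, m = 10)
  med_a <- summarize_by_cell_type(ref$expr, ref$annotation)
  dup_cols <- ref$expr
  colnames(dup_cols) <- paste0(colnames(dup_cols), "_dup")
  expr_dup <- cbind(ref$expr, dup_cols)
  ann_dup <- suppressWarnings(sample_annotation(
    c(ref$annotation$sample_id, colnames(dup_cols)),
    rep(ref$annotation$cell_type, 2), min_replicates = 2L))
  med_b <- summarize_by_cell_type(expr_dup, ann_dup)
  expect_equal(med_a, med_b)
})

test_that("probe collapsing keeps the highest-median probe per gene", {
  sig <- matrix(c(5, 6,  7, 8,  1, 2), nrow = 3, byrow = TRUE,
                dimnames = list(c("pA", "pB", "pC"), c("t1", "t2")))
  src <- matrix(c(5, 5, 5,  7, 7, 7,  1, 1, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("pA", "pB", "pC"), c("s1", "s2", "s3")))
  map <- data.frame(probe_id = c("pA", "pB", "pC"),
                    gene_symbol = c("G1", "G1", "G2"))
  out <- collapse_probes(sig, src, map)
  expect_identical(rownames(out), c("G1", "G2"))
  expect_equal(unname(out["G1", ]), c(7, 8))   # pB wins: median 7 > 5

  # one probe per gene: identity up to renaming
  map1 <- data.frame(probe_id = c("pA", "pB", "pC"),
                     gene_symbol = c("gA", "gB", "gC"))
  out1 <- collapse_probes(sig, src, map1)
  expect_equal(unname(out1[c("gA", "gB", "gC"), ]), unname(sig))

  # tie on the median: lexicographically first probe retained
  src_tie <- src; src_tie["pA", ] <- src_tie["pB", ]
  out_tie <- collapse_probes(sig, src_tie, map)
  expect_equal(unname(out_tie["G1", ]), c(5, 6))

  # unmapped probes dropped with a reported count
  map_part <- map[1:2, ]
  expect_message(out_p <- collapse_probes(sig, src, map_part), "1 probe")
  expect_identical(rownames(out_p), "G1")

  # gene count equals distinct mapped genes
  expect_identical(nrow(out), length(unique(map$gene_symbol)))
})

test_that("full signature build recovers marker structure", {
  ref <- tiny_reference()
  build <- build_signature(ref$expr, ref$annotation, step = 40L)
  sig <- build$signature
  expect_identical(colnames(sig), sort(unique(ref$annotation$cell_type)))
  # every selected marker gene peaks in its own type's column
  sel <- ref$markers[ref$markers$gene_id %in% rownames(sig), ]
  peak <- colnames(sig)[apply(sig[sel$gene_id, ], 1L, which.max)]
  expect_identical(peak, sel$cell_type)
  # the scan's chosen kappa is minimal over its grid
  expect_true(all(build$scan$kappa_star <= build$scan$grid$kappa))

  # probe->gene collapsing integrates into the build
  map <- data.frame(probe_id = rownames(ref$expr),
                    gene_symbol = sub("gene", "SYM", rownames(ref$expr)))
  build2 <- build_signature(ref$expr, ref$annotation, map = map, step = 40L)
  expect_identical(rownames(build2$signature),
                   sort(sub("gene", "SYM", build$selected_probes)))
})

test_that("two perfectly separating genes give a well-conditioned 2x2 signature", {
  x <- matrix(c(10, 10, 1, 1,
                1, 1, 10, 10), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"),
                              c("A_rep1", "A_rep2", "B_rep1", "B_rep2")))
  # add slight replicate jitter so variances are nonzero
  set.seed(4); x <- x + matrix(rnorm(8, 0, 0.01), 2)
  ann <- ann_from_colnames(x)
  build <- build_signature(x, ann, alpha = 0.05, step = 2L)
  expect_identical(dim(build$signature), c(2L, 2L))
  full_kappa <- condition_number(x)
  expect_lte(build$scan$kappa_star, full_kappa * (1 + 1e-12))
})

test_that("Fisher embedding separates classes and matches the closed form", {
  # two classes of identical points: class collapses to one coordinate
  x <- matrix(c(0, 0, 5, 5,
                0, 0, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"),
                              c("A_rep1", "A_rep2", "B_rep1", "B_rep2")))
  ann <- ann_from_colnames(x)
  proj <- suppressWarnings(lda_embed(x, ann, n_axes = 3))
  expect_identical(ncol(proj), 1L)            # k - 1 = 1 axis available
  expect_equal(proj["A_rep1", 1], proj["A_rep2", 1])
  expect_gt(abs(proj["A_rep1", 1] - proj["B_rep1", 1]), 0)

  # 2-feature 2-class toy with a known Fisher direction
  set.seed(21)
  n <- 30
  xa <- rbind(rnorm(n, 0, 1), rnorm(n, 0, 0.3))
  xb <- rbind(rnorm(n, 3, 1), rnorm(n, 1, 0.3))
  m <- cbind(xa, xb)
  dimnames(m) <- list(c("f1", "f2"),
                      c(paste0("A_rep", 1:n), paste0("B_rep", 1:n)))
  ann2 <- ann_from_colnames(m)
  proj2 <- lda_embed(m, ann2)
  dirs <- attr(proj2, "directions")[, 1]
  mu1 <- rowMeans(xa); mu2 <- rowMeans(xb)
  sw <- tcrossprod(xa - mu1) + tcrossprod(xb - mu2)
  w_oracle <- solve(sw, mu1 - mu2)
  cosang <- abs(sum(dirs * w_oracle)) /
    sqrt(sum(dirs^2) * sum(w_oracle^2))
  expect_gt(cosang, 1 - 1e-8)                 # collinear with S_W^-1 (mu1-mu2)

  # multi-class fixture: within-class distances smaller than between-class
  ref <- tiny_reference(k = 5, r = 6, g = 120, m = 15)
  proj3 <- suppressWarnings(lda_embed(ref$expr, ref$annotation, n_axes = 3))
  expect_identical(ncol(proj3), 3L)
  lab <- ref$annotation$cell_type[match(rownames(proj3),
                                        ref$annotation$sample_id)]
  d <- as.matrix(dist(proj3))
  same <- outer(lab, lab, "==") & upper.tri(d)
  diff <- outer(lab, lab, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})

test_that("signature build artifacts write and read back", {
  ref <- tiny_reference(k = 3, r = 3, g = 60, m = 10)
  build <- build_signature(ref$expr, ref$annotation, step = 10L)
  sig_f <- withr::local_tempfile(fileext = ".tsv")
  scan_f <- withr::local_tempfile(fileext = ".tsv")
  rank_f <- withr::local_tempfile(fileext = ".tsv")
  write_signature_build(build, sig_f, scan_f, rank_f, header = "build test")
  back <- read_signature_matrix(sig_f)
  expect_lt(max(abs(back - build$signature)), 1e-12)
  scan_back <- read.delim(scan_f, comment.char = "#")
  expect_equal(scan_back$kappa, build$scan$grid$kappa, tolerance = 1e-14)
})
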