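test_that("weighted Pearson reduces to ordinary Pearson", {
  set.seed(51)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(weighted_pearson(x, y, rep(1, 30)), cor(x, y))
  # affine relations give r = 1 under any positive weights
  w <- runif(30, 0.1, 2)
  expect_equal(weighted_pearson(x, 2 * x + 1, w), 1)
  # zero weight equals explicit removal
  y2 <- y; y2[5] <- 50
  w2 <- rep(1, 30); w2[5] <- 0
  expect_equal(weighted_pearson(x, y2, w2), cor(x[-5], y2[-5]))
  expect_error(weighted_pearson(x[1:2], y[1:2]), ">= 3")
})

test_that("weighted clustering recovers planted gene blocks", {
  set.seed(52)
  n <- 40
  base1 <- rnorm(10); base2 <- rnorm(10)
  block1 <- t(replicate(n, base1 + rnorm(10, 0, 0.3)))
  block2 <- t(replicate(n, base2 + rnorm(10, 0, 0.3)))
  m <- rbind(block1, block2)
  rownames(m) <- paste0("G", seq_len(2 * n))
  hc <- weighted_hcluster(m)
  cl <- cutree(hc, k = 2)
  # cut at k = 2 separates the blocks exactly
  expect_equal(length(unique(cl[1:n])), 1)
  expect_equal(length(unique(cl[(n + 1):(2 * n)])), 1)
  expect_false(cl[1] == cl[n + 1])
  # duplicate rows sit at distance zero and merge at height 0
  m2 <- rbind(m, G_dup = m[1, ])
  hc2 <- weighted_hcluster(m2)
  expect_equal(min(hc2$height), 0)
  # row permutation changes labels only, not the partition
  perm <- sample(nrow(m))
  hc3 <- weighted_hcluster(m[perm, ])
  cl3 <- cutree(hc3, k = 2)[rownames(m)]
  expect_true(all(table(cl, cl3) %in% c(0, n)))
})

test_that("down-weighting removes the duplicated-chromosome cluster", {
  st <- small_study(seed = 53, esr_base = 0)
  g <- st$genome
  strain1 <- st$strains[1]
  dupchr <- st$strain_chromosomes[[strain1]]
  dup_genes <- g$genes[g$chromosome == dupchr]
  sub_genes <- c(dup_genes, sample(setdiff(g$genes, dup_genes), 150))
  m <- st$protein[sub_genes, ]
  w <- weight_table(m, st$annotation, st$strain_chromosomes)
  # unweighted: duplicated genes form their own tight, pure cluster
  # (their shared +1 block dominates the correlation); with their cells
  # down-weighted to zero that structure disappears
  dup_block_score <- function(hc) {
    cl <- cutree(hc, k = 4)
    max(vapply(unique(cl), function(k) {
      members <- names(cl)[cl == k]
      coverage <- mean(dup_genes %in% members)
      purity <- mean(members %in% dup_genes)
      coverage * purity
    }, numeric(1)))
  }
  expect_gt(dup_block_score(weighted_hcluster(m)), 0.7)
  expect_lt(dup_block_score(weighted_hcluster(m, w)), 0.4)
})

test_that("threshold signature extraction recovers the planted APS", {
  st <- default_study()
  w <- weight_table(st$protein, st$annotation, st$strain_chromosomes)
  sig <- extract_consistent_up_signature(st$protein, w)
  recall <- mean(st$aps_genes %in% sig$genes)
  precision <- mean(sig$genes %in% st$aps_genes)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.8)
})

test_that("null matrices yield (almost) no signature genes", {
  set.seed(55)
  m <- matrix(rnorm(2000 * 6, 0, 0.2), 2000, 6,
              dimnames = list(paste0("G", 1:2000), paste0("s", 1:6)))
  suppressWarnings(
    sig <- extract_consistent_up_signature(m, min_log2 = 0.2,
                                           mean_floor = -Inf))
  # closed form: 2000 * P(N(0, 0.2) > 0.2)^6 = 2000 * 0.1587^6 = 0.03
  expect_lte(length(sig$genes), 2)
})

test_that("threshold-method null count matches its closed form", {
  set.seed(56)
  counts <- replicate(50, {
    m <- matrix(rnorm(500 * 5, 0, 0.2), 500, 5,
                dimnames = list(paste0("G", 1:500), paste0("s", 1:5)))
    suppressWarnings(
      length(extract_consistent_up_signature(m, min_log2 = 0,
                                             mean_floor = -Inf)$genes))
  })
  expected <- 500 * 0.5^5  # 15.625 genes per null study
  se <- sqrt(500 * 0.5^5 * (1 - 0.5^5) / 50)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("single-strain threshold keeps every positive gene", {
  m <- matrix(c(0.5, -0.1, 0.2, 0), 4, 1,
              dimnames = list(paste0("G", 1:4), "s1"))
  m <- cbind(m, m)  # extractor requires >= 2 strains
  colnames(m) <- c("s1", "s2")
  sig <- extract_consistent_up_signature(m, min_log2 = 0,
                                         mean_floor = -Inf,
                                         min_strains = 2)
  expect_setequal(sig$genes, c("G1", "G3"))
})

test_that("signature projection is exact, linear, and SEM-correct", {
  set.seed(57)
  m <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(paste0("G", 1:50), paste0("s", 1:4)))
  # single gene: the projection is that gene's row
  p1 <- signature_projection(m, "G1")
  expect_equal(p1$mean, unname(m["G1", ]))
  expect_true(all(is.na(p1$sem)))
  # linearity over matrices
  m2 <- matrix(rnorm(50 * 4), 50, 4, dimnames = dimnames(m))
  genes <- paste0("G", 1:10)
  expect_equal(signature_projection(m + m2, genes)$mean,
               signature_projection(m, genes)$mean +
                 signature_projection(m2, genes)$mean)
  # all-zero matrix projects to zero
  expect_true(all(signature_projection(m * 0, genes)$mean == 0))
  expect_equal(signature_projection(m, genes)$sem[1],
               sd(m[genes, 1]) / sqrt(10))
  expect_error(signature_projection(m, "nope"), "intersect")
})

test_that("signature intensity tracks duplicated-chromosome size", {
  sizes <- c(I = 100, II = 200, V = 300, VIII = 400)
  intensity <- setNames(sizes / 1000,
                        paste0("disome", names(sizes)))
  res <- intensity_size_correlation(intensity, sizes)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 1e-3)
  # permuted intensities lose the correlation
  set.seed(58)
  perm <- setNames(sample(unname(intensity)), names(intensity))
  expect_lt(abs(intensity_size_correlation(perm, sizes)$r), 1)
  # planted APS model in a full study: strong correlation
  st <- default_study()
  w <- weight_table(st$protein, st$annotation, st$strain_chromosomes)
  sig <- extract_consistent_up_signature(st$protein, w)
  res2 <- intensity_size_correlation(sig, table(st$annotation$chromosome),
                                     st$strain_chromosomes)
  expect_gte(res2$r, 0.9)
})

test_that("binned paired comparison detects uniform attenuation", {
  set.seed(59)
  genes <- paste0("G", 1:900)
  a <- matrix(c(rnorm(300, 1, 0.2), rnorm(300, 0, 0.2),
                rnorm(300, -1, 0.2)), ncol = 1,
              dimnames = list(genes, "disomeV"))
  # identical matrices: zero differences, p = 1
  same <- bin_and_compare(a, a)
  expect_true(all(same$mean_diff[same$n > 0] == 0))
  expect_true(all(same$p_value[same$n > 1] == 1))
  # uniform shrinkage moves both tails toward zero
  b <- a * 0.7
  res <- bin_and_compare(a, b)
  up <- res[res$bin == "up", ]
  down <- res[res$bin == "down", ]
  expect_lt(up$mean_b, up$mean_a)
  expect_gt(down$mean_b, down$mean_a)
  expect_lt(up$p_value, 1e-3)
  expect_lt(down$p_value, 1e-3)
  # empty bins are reported, untested
  a2 <- a; a2[a2 >= 0.4] <- 0
  res2 <- bin_and_compare(a2, a2 * 0.7)
  expect_equal(res2$n[res2$bin == "up"], 0)
  expect_true(is.na(res2$p_value[res2$bin == "up"]))
})

test_that("turnover slopes match the closed-form least squares", {
  tc <- matrix(c(0, 0.072, 0.24), 1, 3,
               dimnames = list("G1", c("t0", "t90", "t300")))
  fit <- fit_turnover_slope(tc, c(0, 90, 300))
  # slope = sum((t - 130)(y - 0.104)) / sum((t - 130)^2) = 37.92/47400
  expect_equal(fit$slopes$slope, 37.92 / 47400, tolerance = 1e-12)
  expect_equal(fit$slopes$slope, 8.0e-4, tolerance = 1e-10)
  # flat timecourse: slope 0
  flat <- matrix(0.3, 2, 3, dimnames = list(c("G1", "G2"), NULL))
  expect_equal(fit_turnover_slope(flat, c(0, 90, 300))$slopes$slope,
               c(0, 0))
  expect_error(fit_turnover_slope(tc, c(0, 90)), "match")
})

test_that("planted slopes are recovered and the group contrast is strong", {
  g <- small_genome()
  tr <- disome_truth(g, "II", noise_sd = 0.2, seed = 61)
  tt <- generate_turnover_truth(g, tr, slope_attenuated = 4.8e-4,
                                noise_sd = 0.02, seed = 62)
  fit <- fit_turnover_slope(tt$timecourse, tt$timepoints,
                            annotation = genome_annotation(g),
                            attenuated = tr$attenuated_genes,
                            background = setdiff(tr$duplicated_genes,
                                                 tr$attenuated_genes))
  # known-noise slope SE: 0.02 / sqrt(sum((t - mean(t))^2))
  se <- 0.02 / sqrt(sum((c(0, 90, 300) - 130)^2))
  err <- fit$slopes$slope - tt$slopes[fit$slopes$gene]
  expect_gte(mean(abs(err) <= 3 * se), 0.98)
  expect_lt(fit$contrast$p_value, 1e-3)
  expect_gt(fit$contrast$mean_attenuated, fit$contrast$mean_other)
})
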