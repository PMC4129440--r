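test_that("hypergeometric enrichment matches brute-force enumeration", {
  # small exhaustive sweep against subset enumeration
  for (N in c(5, 8, 10)) {
    bg <- paste0("G", seq_len(N))
    for (K in c(2, floor(N / 2))) {
      for (n in c(2, N - 1)) {
        att <- bg[seq_len(n)]
        target <- bg[seq_len(K)]
        res <- enrichment_test(att, target, bg)
        expect_equal(res$p_value,
                     enumerate_hyper_p(N, K, n, res$k),
                     tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("enrichment edge cases behave", {
  bg <- paste0("G", 1:10)
  # saturated: attenuated = target = background
  expect_equal(enrichment_test(bg, bg, bg)$p_value, 1)
  # N=10, K=5, n=4, k=4 -> C(5,4)/C(10,4) = 5/210
  res <- enrichment_test(paste0("G", 1:4), paste0("G", 1:5), bg)
  expect_equal(res$p_value, 5 / 210)
  expect_error(enrichment_test("G1", "G2", character()), "background")
})

test_that("planted complex-biased attenuation is strongly enriched", {
  st <- default_study()
  calls <- call_attenuated(st$protein, st$annotation,
                           strain_chromosomes = st$strain_chromosomes)
  ratios <- duplicated_gene_ratios(st$protein, st$annotation,
                                   st$strain_chromosomes)
  members <- unique(unlist(st$catalog))
  res <- enrichment_test(attenuated_genes(calls), members, names(ratios))
  expect_lt(res$p_value, 1e-10)
})

test_that("overlap analysis counts genes once and handles extremes", {
  mk_calls <- function(genes, att) {
    structure(list(calls = data.frame(
      gene = genes, strain = "disomeI", log2_ratio = 0,
      attenuated = genes %in% att), cutoff = 0.6,
      reference = "fixed_expected",
      reference_values = c(disomeI = 1)), class = "attenuation_calls")
  }
  genes <- paste0("G", 1:100)
  a <- mk_calls(genes, genes[1:50])
  expect_equal(overlap_analysis(a, a)$fraction_a, 1)
  b <- mk_calls(genes, genes[51:100])
  expect_equal(overlap_analysis(a, b)$jaccard, 0)
  # planted 60% overlap recovered exactly from the calls
  c_ <- mk_calls(genes, genes[21:70])
  ov <- overlap_analysis(a, c_)
  expect_equal(ov$fraction_a, 0.6)
  expect_equal(length(ov$intersection), 30)
})

test_that("complex summaries aggregate subunits and call attenuation", {
  catalog <- list(CA = c("G1", "G2", "G3"), CB = c("G4", "G5", "G6"),
                  CC = c("G7", "G8"))
  ds <- list(tmt = c(G1 = 0.3, G2 = 0.4, G3 = 0.5, G4 = 1.0, G5 = 1.0,
                     G6 = 0.5, G7 = 0.2, G8 = 0.9))
  res <- summarize_complexes(catalog, ds, min_subunits = 3)
  tab <- res$table
  # CC dropped by the 3-subunit quorum
  expect_setequal(tab$complex, c("CA", "CB"))
  expect_equal(tab$mean_tmt[tab$complex == "CA"], 0.4)
  expect_true(tab$attenuated_complex[tab$complex == "CA"])
  expect_equal(tab$n_attenuated_subunits[tab$complex == "CA"], 3)
  expect_equal(tab$mean_tmt[tab$complex == "CB"], mean(c(1, 1, 0.5)))
  expect_false(tab$attenuated_complex[tab$complex == "CB"])
  expect_equal(tab$n_attenuated_subunits[tab$complex == "CB"], 1)
  expect_equal(tab$n_stable_subunits[tab$complex == "CB"], 2)
  # attenuated and stable subunits partition the quantified members
  memb <- res$members$CB
  expect_setequal(memb$gene, c("G4", "G5", "G6"))
  expect_equal(sum(memb$attenuated) +
                 tab$n_stable_subunits[tab$complex == "CB"], 3)
})

test_that("complex summaries ignore catalog order and absent members", {
  catalog <- list(CA = c("G1", "G2", "G3", "GHOST"),
                  CB = c("G4", "G5", "G6"))
  ds <- list(d = c(G1 = 0.3, G2 = 0.4, G3 = 0.5, G4 = 1, G5 = 1,
                   G6 = 0.5))
  r1 <- summarize_complexes(catalog, ds)
  r2 <- summarize_complexes(rev(catalog), ds)
  expect_equal(r1$table[order(r1$table$complex), ],
               r2$table[order(r2$table$complex), ], ignore_attr = TRUE)
  # removing the non-quantified member changes nothing
  catalog2 <- list(CA = c("G1", "G2", "G3"), CB = c("G4", "G5", "G6"))
  r3 <- summarize_complexes(catalog2, ds)
  expect_equal(r1$table, r3$table)
  expect_error(summarize_complexes(list(), ds), "empty")
})

test_that("two-dataset quorum requires subunits in both", {
  catalog <- list(CA = c("G1", "G2", "G3"))
  ds <- list(a = c(G1 = 0.2, G2 = 0.3, G3 = 0.4),
             b = c(G1 = 0.2, G2 = 0.3))
  expect_equal(nrow(summarize_complexes(catalog, ds)$table), 0)
  expect_equal(nrow(summarize_complexes(catalog, ds,
                                        require_all_datasets = FALSE)$table),
               1)
})

test_that("Welch complex-vs-noncomplex contrast behaves under null and alt", {
  set.seed(41)
  x <- rnorm(200, 0.46, 0.25)
  y <- rnorm(200, 1.0, 0.25)
  ratios <- setNames(c(x, y), paste0("G", 1:400))
  res <- complex_vs_noncomplex_test(ratios, paste0("G", 1:200))
  expect_lt(res$p_value, 1e-10)
  expect_lt(res$mean_complex, res$mean_noncomplex)
  # identical groups: t = 0, p = 1
  same <- setNames(c(1, 2, 3, 1, 2, 3), paste0("G", 1:6))
  res0 <- complex_vs_noncomplex_test(same, paste0("G", 1:3))
  expect_equal(res0$p_value, 1)
  expect_equal(res0$t, 0)
  expect_error(complex_vs_noncomplex_test(same, paste0("G", 1:6)),
               "non-empty")
})

test_that("shuffled membership labels control the type-I error rate", {
  set.seed(42)
  vals <- rnorm(200, 0.7, 0.3)
  names(vals) <- paste0("G", 1:200)
  reject <- replicate(1000, {
    memb <- sample(names(vals), 100)
    complex_vs_noncomplex_test(vals, memb)$p_value < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("cross-condition correlation respects exclusions and nulls", {
  set.seed(43)
  shared <- paste0("G", 1:500)
  a <- setNames(rnorm(500), shared)
  expect_equal(cross_condition_correlation(a, a)$r, 1)
  b <- setNames(rnorm(500), shared)
  expect_lt(abs(cross_condition_correlation(a, b)$r), 0.1)
  # exclusions are removed before correlating
  a2 <- a; a2[1:10] <- 100
  b2 <- a; b2[1:10] <- -100
  res <- cross_condition_correlation(a2, b2,
                                     exclusions = list(shared[1:10]))
  expect_equal(res$n, 490)
  expect_equal(res$r, 1)
  expect_error(cross_condition_correlation(a[1:2], a[1:2]), ">= 3")
})

test_that("conditions sharing planted attenuation correlate as predicted", {
  # two platforms measure the same attenuation truth with independent
  # noise 0.2 and 0.35; for a 50/50 complex-member mixture separated by
  # 0.34 log2 the attenuation-signal variance is 0.25 * 0.34^2 = 0.0289,
  # giving r = 0.0289 / sqrt((0.0289 + 0.04) * (0.0289 + 0.1225)) = 0.28
  st <- default_study()
  members <- unique(unlist(st$catalog))
  truths35 <- lapply(st$truths, function(tr) { tr$noise_sd <- 0.35; tr })
  cols <- lapply(seq_along(st$strains), function(i)
    generate_disome_matrix(st$genome, truths35[[i]], "protein",
                           seed = 5000 + i, strain = st$strains[i]))
  silac <- do.call(cbind, cols)
  ra <- duplicated_gene_ratios(st$protein, st$annotation,
                               st$strain_chromosomes)
  rb <- duplicated_gene_ratios(silac, st$annotation,
                               st$strain_chromosomes)
  cx <- intersect(names(ra), members)
  res <- cross_condition_correlation(ra[cx], rb[cx],
                                     exclusions = st$genome$ribosomal_set)
  expect_gt(res$r, 0.15)
  expect_lt(res$r, 0.45)
})
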