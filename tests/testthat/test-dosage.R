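test_that("Pearson mode skewness matches hand computations", {
  expect_equal(mode_skewness(c(-1, 0, 1)), 0)
  # median 0, mean -0.8, sample SD 1.78885 -> +0.447214
  expect_equal(mode_skewness(c(0, 0, 0, 0, -4)), 0.8 / sd(c(0, 0, 0, 0, -4)))
  expect_equal(mode_skewness(c(0, 0, 0, 0, -4)), 0.4472136,
               tolerance = 1e-6)
  expect_error(mode_skewness(c(1, 2)), ">= 3")
  expect_error(mode_skewness(c(1, 1, 1)), "SD")
})

test_that("single-Gaussian histogram fit recovers mean, SD and high R2", {
  set.seed(21)
  v <- rnorm(10000, 0, 0.3)
  f <- fit_gaussian(v, 1)
  expect_lt(abs(f$means - 0), 0.02)
  expect_lt(abs(f$sds - 0.3), 0.03)
  expect_gte(f$r_squared, 0.98)
  expect_equal(f$n_components, 1)
})

test_that("two-component fit recovers planted mixture means", {
  set.seed(22)
  v <- c(rnorm(1807, 1.0, 0.25), rnorm(774, 0.46, 0.25))
  f <- fit_gaussian(v, 2, equal_sd = TRUE)
  expect_lt(abs(f$means[1] - 0.46), 0.07)
  expect_lt(abs(f$means[2] - 1.0), 0.07)
  # means reported sorted ascending
  expect_true(f$means[1] < f$means[2])
  expect_error(fit_gaussian(rnorm(30), 2), ">= 50")
})

test_that("histogram mixture fit agrees with an EM oracle", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(23)
  diffs <- replicate(20, {
    v <- c(rnorm(1400, 1.0, 0.25), rnorm(600, 0.46, 0.25))
    f <- fit_gaussian(v, 2, equal_sd = TRUE)
    em <- mclust::Mclust(v, G = 2, modelNames = "E", verbose = FALSE)
    max(abs(sort(f$means) - sort(as.numeric(em$parameters$mean))))
  })
  expect_lt(max(diffs), 0.05)
})

test_that("model comparison prefers the true component count", {
  set.seed(24)
  pure <- rnorm(2581, 0, 0.2)
  expect_equal(compare_models(pure, equal_sd = TRUE)$preferred, 1L)
  mix <- c(rnorm(1807, 1.0, 0.25), rnorm(774, 0.46, 0.25))
  cmp <- compare_models(mix, equal_sd = TRUE)
  expect_equal(cmp$preferred, 2L)
  expect_gte(cmp$delta_r2, 0.02)
  expect_gte(cmp$separation, 1)
})

test_that("attenuation calls use an inclusive boundary at ref - cutoff", {
  ann <- data.frame(gene = c("G1", "G2", "G3"), chromosome = "V",
                    position = 0:2)
  m <- matrix(c(0.40, 0.41, 1.2), ncol = 1,
              dimnames = list(ann$gene, "disomeV"))
  calls <- call_attenuated(m, ann, cutoff = 0.6,
                           reference = "fixed_expected",
                           expected_value = 1.0)
  expect_equal(calls$calls$attenuated, c(TRUE, FALSE, FALSE))
  # per-strain-mean reference shifts the threshold with the data
  calls2 <- call_attenuated(m + 0.5, ann, cutoff = 0.6,
                            reference = "per_strain_mean")
  expect_equal(calls2$reference_values[["disomeV"]],
               mean(m + 0.5))
  expect_error(call_attenuated(m, ann, cutoff = -1), "cutoff")
  colnames(m) <- "mystery"
  expect_error(call_attenuated(m, ann), "unknown duplicated chromosome")
})

test_that("calls are monotone in the cutoff and strain-label invariant", {
  st <- small_study(seed = 31)
  sc <- st$strain_chromosomes
  c1 <- call_attenuated(st$protein, st$annotation, cutoff = 0.6,
                        strain_chromosomes = sc)
  c2 <- call_attenuated(st$protein, st$annotation, cutoff = 0.8,
                        strain_chromosomes = sc)
  a1 <- which(c1$calls$attenuated)
  a2 <- which(c2$calls$attenuated)
  expect_true(all(a2 %in% a1))  # larger cutoff => subset of calls
  # relabeling strains relabels but does not change the calls
  m2 <- st$protein
  colnames(m2) <- paste0("strain", seq_len(ncol(m2)))
  sc2 <- setNames(unname(sc), colnames(m2))
  c3 <- call_attenuated(m2, st$annotation, cutoff = 0.6,
                        strain_chromosomes = sc2)
  expect_equal(c3$calls$attenuated, c1$calls$attenuated)
  expect_equal(c3$calls$gene, c1$calls$gene)
})

test_that("chromosome profiles order genes and summarise per chromosome", {
  st <- small_study(seed = 32)
  strain <- st$strains[1]
  dup <- st$strain_chromosomes[[strain]]
  prof <- chromosome_profile(st$protein, st$annotation, strain)
  # genes sorted by (chromosome, ordinal position)
  expect_true(all(diff(order(match(prof$profile$chromosome,
                                   unique(prof$profile$chromosome)),
                             prof$profile$position)) > 0))
  cs <- prof$chromosome_stats
  expect_lt(abs(cs$mean[cs$chromosome == dup] - 1.0), 0.15)
  expect_true(all(abs(cs$mean[cs$chromosome != dup]) < 0.15))
  # all-zero matrix gives all-zero chromosome means
  z <- matrix(0, nrow(st$protein), 1,
              dimnames = list(rownames(st$protein), strain))
  expect_true(all(chromosome_profile(z, st$annotation,
                                     strain)$chromosome_stats$mean == 0))
  expect_error(chromosome_profile(st$protein, st$annotation, "nope"),
               "strain")
})

test_that("layer comparison shows protein-specific attenuation", {
  st <- small_study(seed = 33)
  calls <- call_attenuated(st$protein, st$annotation,
                           strain_chromosomes = st$strain_chromosomes)
  res <- compare_layers(calls, list(protein = st$protein,
                                    mRNA = st$mRNA))
  s <- res$summary
  att_prot <- s$mean[s$layer == "protein" & s$group == "attenuated"]
  att_mrna <- s$mean[s$layer == "mRNA" & s$group == "attenuated"]
  # attenuated at the protein layer, full transcript response at mRNA
  expect_lt(att_prot, 0.5)
  expect_gt(att_mrna, 0.7)
  # identical matrices give identical summaries
  res2 <- compare_layers(calls, list(a = st$protein, b = st$protein))
  sa <- res2$summary[res2$summary$layer == "a", -1]
  sb <- res2$summary[res2$summary$layer == "b", -1]
  expect_equal(sa, sb, ignore_attr = TRUE)
})

test_that("empty attenuated sets are summarised with a warning", {
  st <- small_study(seed = 34)
  calls <- call_attenuated(st$protein, st$annotation, cutoff = 5,
                           strain_chromosomes = st$strain_chromosomes)
  expect_warning(res <- compare_layers(calls, list(protein = st$protein)),
                 "empty attenuated")
  expect_true(all(res$summary$group == "not_attenuated"))
})
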