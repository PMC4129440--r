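#' Duplicated-instance log2 ratios per gene
#'
#' For each strain, extracts the values of genes on that strain's
#' duplicated chromosome (the "duplicated instances"); a gene measured as
#' duplicated in several strains contributes the mean of its instances,
#' keeping genes equally weighted downstream.
#'
#' @param m genes x strains matrix.
#' @param annotation annotation data.frame (`gene`, `chromosome`).
#' @param strain_chromosomes named duplicated chromosome per strain
#'   (parsed from column names by default); `NA` strains are skipped.
#' @return named numeric vector: duplicated-instance log2 ratio per gene.
#' @export
duplicated_gene_ratios <- function(m, annotation,
                                   strain_chromosomes = NULL) {
  if (is.null(strain_chromosomes))
    strain_chromosomes <- strain_chromosome(colnames(m))
  chrom <- setNames(annotation$chromosome, annotation$gene)[rownames(m)]
  acc <- list()
  for (strain in colnames(m)) {
    dup <- strain_chromosomes[[strain]]
    if (is.na(dup)) next
    idx <- which(chrom == dup & is.finite(m[, strain]))
    if (length(idx))
      acc[[strain]] <- setNames(m[idx, strain], rownames(m)[idx])
  }
  all_ <- unlist(unname(acc))
  out <- tapply(all_, names(all_), mean)
  setNames(as.numeric(out), names(out))
}

#' Pooled duplicated-instance values across strains
#'
#' Like [duplicated_gene_ratios()] but without per-gene averaging: one
#' entry per measured (gene, strain) duplicated instance, the pooled
#' sample whose histogram is decomposed by [fit_gaussian()].
#'
#' @inheritParams duplicated_gene_ratios
#' @return numeric vector of log2 ratios, named by gene.
#' @export
duplicated_gene_values <- function(m, annotation,
                                   strain_chromosomes = NULL) {
  if (is.null(strain_chromosomes))
    strain_chromosomes <- strain_chromosome(colnames(m))
  chrom <- setNames(annotation$chromosome, annotation$gene)[rownames(m)]
  out <- list()
  for (strain in colnames(m)) {
    dup <- strain_chromosomes[[strain]]
    if (is.na(dup)) next
    idx <- which(chrom == dup & is.finite(m[, strain]))
    if (length(idx))
      out[[strain]] <- setNames(m[idx, strain], rownames(m)[idx])
  }
  unlist(unname(out))
}

#' Hypergeometric enrichment of a gene set among attenuated genes
#'
#' Upper-tail hypergeometric test: the probability of drawing at least
#' `k` members of `target_set` when sampling `n = |attenuated|` genes
#' without replacement from the `N`-gene background containing `K`
#' target genes. The background should be the duplicated-chromosome
#' genes actually detected in the data set, not the whole genome.
#'
#' @param attenuated attenuated gene set.
#' @param target_set gene set tested for enrichment (e.g. complex
#'   members).
#' @param background background gene universe; `attenuated` and
#'   `target_set` are intersected with it.
#' @return object of class `enrichment_result`: list with `k`, `n`,
#'   `K`, `N`, `p_value`.
#' @export
enrichment_test <- function(attenuated, target_set, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  attenuated <- intersect(unique(attenuated), background)
  target_set <- intersect(unique(target_set), background)
  k <- length(intersect(attenuated, target_set))
  n <- length(attenuated)
  K <- length(target_set)
  N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k = k, n = n, K = K, N = N, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %d of %d in set (%d of %d background), p = %.3g\n",
              x$k, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Overlap between two attenuation call sets
#'
#' Gene-level overlap (a gene counts once however many strains it was
#' called in) between the attenuated genes of two experiments.
#'
#' @param calls_a,calls_b `attenuation_calls` objects.
#' @return list with `intersection` (genes), `jaccard`, `fraction_a`
#'   (share of a's attenuated genes also in b), `fraction_b`, `n_a`,
#'   `n_b`.
#' @export
overlap_analysis <- function(calls_a, calls_b) {
  a <- attenuated_genes(calls_a)
  b <- attenuated_genes(calls_b)
  both <- intersect(a, b)
  uni <- union(a, b)
  list(intersection = both,
       jaccard = if (length(uni)) length(both) / length(uni) else NA_real_,
       fraction_a = if (length(a)) length(both) / length(a) else NA_real_,
       fraction_b = if (length(b)) length(both) / length(b) else NA_real_,
       n_a = length(a), n_b = length(b))
}

#' Per-complex attenuation summaries
#'
#' Pools each complex's duplicated-instance subunit ratios per data set.
#' Complexes are kept when at least `min_subunits` subunits are
#' quantified in every data set (or in any one, when
#' `require_all_datasets = FALSE`). A complex is called attenuated when
#' its mean subunit log2 ratio is <= `cutoff` in every data set; a
#' subunit is attenuated when its ratio (pooled across data sets) is
#' <= `cutoff`, i.e. an increase of ~1.5-fold or less instead of the
#' expected twofold.
#'
#' @param catalog named list: complex ID -> member genes.
#' @param datasets named list of named numeric vectors (gene ->
#'   duplicated-instance log2 ratio), e.g. from
#'   [duplicated_gene_ratios()] on each platform/condition.
#' @param min_subunits minimum quantified subunits (default 3).
#' @param require_all_datasets require the subunit quorum in every data
#'   set.
#' @param cutoff attenuation threshold on the log2 ratio (default 0.6).
#' @return list with `table` (one row per retained complex: per-dataset
#'   n and mean, `attenuated_complex`, subunit counts) and `members`
#'   (per complex: data.frame gene/pooled ratio/attenuated flag).
#' @export
summarize_complexes <- function(catalog, datasets, min_subunits = 3L,
                                require_all_datasets = TRUE,
                                cutoff = 0.6) {
  if (!length(catalog)) stop("empty complex catalog", call. = FALSE)
  if (!length(datasets)) stop("need >= 1 dataset", call. = FALSE)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  rows <- list(); members <- list()
  for (cx in names(catalog)) {
    genes <- unique(catalog[[cx]])
    per_ds <- lapply(datasets, function(d) d[intersect(genes, names(d))])
    ns <- vapply(per_ds, length, integer(1))
    quorum <- if (require_all_datasets) all(ns >= min_subunits)
              else any(ns >= min_subunits)
    if (!quorum) next
    ds_means <- vapply(per_ds, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1))
    quantified <- unique(unlist(lapply(per_ds, names)))
    pooled <- vapply(quantified, function(g) {
      vals <- unlist(lapply(per_ds, function(v) v[names(v) == g]))
      mean(vals)
    }, numeric(1))
    att_sub <- names(pooled)[pooled <= cutoff]
    stable_sub <- setdiff(names(pooled), att_sub)
    row <- data.frame(complex = cx, stringsAsFactors = FALSE)
    for (ds in names(datasets)) {
      row[[paste0("n_", ds)]] <- ns[[ds]]
      row[[paste0("mean_", ds)]] <- ds_means[[ds]]
    }
    row$attenuated_complex <- all(ds_means[!is.na(ds_means)] <= cutoff) &&
      any(!is.na(ds_means))
    row$n_attenuated_subunits <- length(att_sub)
    row$n_stable_subunits <- length(stable_sub)
    rows[[cx]] <- row
    members[[cx]] <- data.frame(gene = names(pooled),
                                pooled_ratio = unname(pooled),
                                attenuated = pooled <= cutoff,
                                stringsAsFactors = FALSE)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex = character())
  rownames(table) <- NULL
  list(table = table, members = members, cutoff = cutoff)
}

#' Welch's t test: complex members vs non-members
#'
#' Two-sided unequal-variance t test of duplicated-instance log2 ratios
#' between proteins annotated as complex members and the rest.
#'
#' @param ratios named numeric vector (gene -> log2 ratio).
#' @param membership character vector of complex-member genes, or a
#'   logical vector aligned with `ratios`.
#' @return list with `mean_complex`, `mean_noncomplex`, `n_complex`,
#'   `n_noncomplex`, `t`, `p_value`.
#' @export
complex_vs_noncomplex_test <- function(ratios, membership) {
  if (is.logical(membership)) {
    in_cx <- membership
  } else {
    in_cx <- names(ratios) %in% membership
  }
  x <- ratios[in_cx & is.finite(ratios)]
  y <- ratios[!in_cx & is.finite(ratios)]
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(mean_complex = mean(x), mean_noncomplex = mean(y),
       n_complex = length(x), n_noncomplex = length(y),
       t = unname(tt$statistic), p_value = tt$p.value)
}

#' Pearson correlation of subunit ratios across two conditions
#'
#' Correlates duplicated-instance log2 ratios of complex subunits
#' measured in two conditions (e.g. rich vs selective medium, or
#' disomes vs disomes-ubp6), optionally excluding dominant complexes
#' such as the ribosome and the nucleosome.
#'
#' @param ratios_a,ratios_b named numeric vectors (gene -> log2 ratio).
#' @param exclusions gene sets (character vector or list of vectors)
#'   removed before correlating.
#' @return list with `r`, `n`, `genes`.
#' @export
cross_condition_correlation <- function(ratios_a, ratios_b,
                                        exclusions = character()) {
  excl <- unique(unlist(exclusions, use.names = FALSE))
  shared <- setdiff(intersect(names(ratios_a), names(ratios_b)), excl)
  a <- ratios_a[shared]; b <- ratios_b[shared]
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3)
    stop("need >= 3 shared genes after exclusions", call. = FALSE)
  list(r = stats::cor(a[keep], b[keep]), n = sum(keep),
       genes = shared[keep])
}
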