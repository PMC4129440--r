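#' Run the full disome analysis pipeline
#'
#' Orchestrates an end-to-end run from a config (a list or a YAML file):
#' loads matrices, annotation and complex catalog; recenters the protein
#' matrix copy-number-awarely; builds per-strain chromosome profiles;
#' compares one- vs two-Gaussian models of the duplicated and
#' non-duplicated distributions; calls attenuated genes; summarises
#' complexes and tests complex enrichment; extracts and projects the
#' consistent up-signature and correlates its intensity with chromosome
#' size; and (when supplied) analyses turnover timecourses and a
#' perturbation (e.g. ubp6) matrix. Writes result TSVs and a JSON
#' summary to `out_dir`.
#'
#' Required config fields: `out_dir`, `protein`, `annotation`. Optional:
#' `mrna`, `catalog`, `gene_sets`, `ubp6_protein`, `strain_chromosomes`,
#' `cutoff` (0.6), `bin_width` (0.1), `expected_value` (1.0),
#' `signature` (list: `method`, `min_log2`, `mean_floor`,
#' `min_strains`), `condition`, `seed`. Matrix/annotation/catalog fields
#' may be file paths or in-memory objects.
#'
#' @param config list or path to a YAML config file.
#' @return (invisibly) a list of all stage results plus the `summary`
#'   written as JSON.
#' @export
run_study <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  for (field in c("out_dir", "protein", "annotation"))
    if (is.null(config[[field]]))
      stop("config is missing required field '", field, "'",
           call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cutoff <- config$cutoff %||% 0.6
  bin_width <- config$bin_width %||% 0.1
  expected <- config$expected_value %||% 1.0
  if (cutoff <= 0) stop("config field 'cutoff' must be > 0", call. = FALSE)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- list()
  load_matrix <- function(x, layer) {
    if (is.matrix(x)) x else read_quant_matrix(x, layer = layer)
  }
  inputs <- stage("load", {
    annotation <- if (is.data.frame(config$annotation)) config$annotation
    else read_gene_annotation(config$annotation)
    protein <- load_matrix(config$protein, "protein")
    mrna <- if (!is.null(config$mrna)) load_matrix(config$mrna, "mRNA")
    catalog <- if (is.null(config$catalog)) NULL
    else if (is.list(config$catalog)) config$catalog
    else read_complex_catalog(config$catalog)
    gene_sets <- if (is.null(config$gene_sets)) list()
    else if (is.list(config$gene_sets)) config$gene_sets
    else read_gene_sets(config$gene_sets)
    strain_chromosomes <- config$strain_chromosomes %||%
      strain_chromosome(colnames(protein))
    strain_chromosomes <- unlist(strain_chromosomes)
    list(annotation = annotation, protein = protein, mrna = mrna,
         catalog = catalog, gene_sets = gene_sets,
         strain_chromosomes = strain_chromosomes)
  })
  ann <- inputs$annotation
  sc <- inputs$strain_chromosomes

  protein <- stage("recenter", normalize_recenter(inputs$protein, ann, sc))
  attr(protein, "layer") <- "protein"

  res$profiles <- stage("profiles", {
    stats_ <- lapply(colnames(protein), function(s) {
      cs <- chromosome_profile(protein, ann, s)$chromosome_stats
      cbind(strain = s, cs)
    })
    tab <- do.call(rbind, stats_)
    utils::write.table(tab, file.path(out_dir, "chromosome_means.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  res$distributions <- stage("distributions", {
    dup_mask_for <- function(m) {
      chrom <- setNames(ann$chromosome, ann$gene)[rownames(m)]
      mask <- vapply(colnames(m), function(s) chrom == sc[[s]],
                     logical(nrow(m)))
      mask & !is.na(mask)
    }
    dup_mask <- dup_mask_for(protein)
    dup_vals <- protein[dup_mask & is.finite(protein)]
    nondup_vals <- protein[!dup_mask & is.finite(protein)]
    cmp <- compare_models(dup_vals, bin_width = bin_width)
    nondup_fit <- fit_gaussian(nondup_vals, 1L, bin_width)
    dist <- list(duplicated = cmp, nondup_fit = nondup_fit,
                 dup_values = dup_vals)
    if (!is.null(inputs$mrna)) {
      mr <- inputs$mrna[, intersect(colnames(inputs$mrna),
                                    colnames(protein)), drop = FALSE]
      mmask <- dup_mask_for(mr)
      dist$mrna_dup_fit <- fit_gaussian(mr[mmask & is.finite(mr)],
                                        1L, bin_width)
    }
    tab <- data.frame(
      distribution = c("duplicated_1c", "duplicated_2c_low",
                       "duplicated_2c_high", "non_duplicated"),
      mean = c(cmp$fits$one$means, cmp$fits$two$means, nondup_fit$means),
      sd = c(cmp$fits$one$sds, cmp$fits$two$sds, nondup_fit$sds),
      r_squared = c(cmp$fits$one$r_squared, rep(cmp$fits$two$r_squared, 2),
                    nondup_fit$r_squared))
    utils::write.table(tab, file.path(out_dir, "distribution_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dist
  })

  res$attenuation <- stage("attenuation", {
    calls <- call_attenuated(protein, ann, cutoff = cutoff,
                             reference = "fixed_expected",
                             expected_value = expected,
                             strain_chromosomes = sc)
    utils::write.table(calls$calls,
                       file.path(out_dir, "attenuation_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls
  })

  if (!is.null(inputs$catalog)) {
    res$complexes <- stage("complexes", {
      ratios <- duplicated_gene_ratios(protein, ann, sc)
      summ <- summarize_complexes(inputs$catalog,
                                  list(protein = ratios),
                                  require_all_datasets = TRUE,
                                  cutoff = cutoff)
      members <- unique(unlist(inputs$catalog, use.names = FALSE))
      enr <- enrichment_test(attenuated_genes(res$attenuation),
                             members, names(ratios))
      welch <- complex_vs_noncomplex_test(ratios, members)
      utils::write.table(summ$table,
                         file.path(out_dir, "complex_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(summary = summ, enrichment = enr, welch = welch,
           ratios = ratios)
    })
  }

  res$signature <- stage("signature", {
    sig_cfg <- config$signature %||% list()
    w <- weight_table(protein, ann, sc)
    sig <- extract_consistent_up_signature(
      protein, w,
      min_log2 = sig_cfg$min_log2 %||% 0,
      mean_floor = sig_cfg$mean_floor %||% 0.2,
      min_strains = sig_cfg$min_strains %||% ncol(protein),
      method = sig_cfg$method %||% "threshold")
    sizes <- table(ann$chromosome)
    size_cor <- if (length(sig$genes) && ncol(protein) >= 3)
      tryCatch(intensity_size_correlation(sig, sizes, sc),
               error = function(e) NULL)
    projections <- list(protein = sig$projection)
    if (!is.null(inputs$mrna) && length(sig$genes))
      projections$mrna <- signature_projection(inputs$mrna, sig$genes)
    for (set_name in names(inputs$gene_sets)) {
      gs <- intersect(inputs$gene_sets[[set_name]], rownames(protein))
      if (length(gs))
        projections[[set_name]] <- signature_projection(protein, gs)
    }
    writeLines(sig$genes, file.path(out_dir, "signature_genes.tsv"))
    proj_tab <- do.call(rbind, lapply(names(projections), function(nm)
      cbind(set = nm, projections[[nm]])))
    utils::write.table(proj_tab,
                       file.path(out_dir, "signature_projection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(signature = sig, size_correlation = size_cor,
         projections = projections)
  })

  if (!is.null(config$turnover)) {
    res$turnover <- stage("turnover", {
      tc <- if (is.matrix(config$turnover)) config$turnover
      else read_quant_matrix(config$turnover, layer = "protein")
      tp <- config$turnover_timepoints %||% c(0, 90, 300)
      fit <- fit_turnover_slope(tc, tp, annotation = ann,
                                attenuated =
                                  attenuated_genes(res$attenuation))
      utils::write.table(fit$slopes,
                         file.path(out_dir, "turnover_slopes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fit
    })
  }

  if (!is.null(config$ubp6_protein)) {
    res$ubp6 <- stage("ubp6", {
      ub <- load_matrix(config$ubp6_protein, "protein")
      ub <- normalize_recenter(ub, ann, sc[colnames(ub)])
      attr(ub, "layer") <- "protein"
      bins <- bin_and_compare(protein[, colnames(ub), drop = FALSE], ub)
      ratios_a <- duplicated_gene_ratios(protein, ann, sc)
      ratios_b <- duplicated_gene_ratios(ub, ann, sc[colnames(ub)])
      corr <- tryCatch(cross_condition_correlation(ratios_a, ratios_b),
                       error = function(e) NULL)
      utils::write.table(bins, file.path(out_dir, "ubp6_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(bins = bins, correlation = corr)
    })
  }

  summary <- stage("summary", {
    s <- list(
      n_genes = nrow(protein), n_strains = ncol(protein),
      condition = config$condition %||% attr(inputs$protein, "condition"),
      recenter_factors = as.list(attr(protein, "recenter_factors")),
      preferred_components_duplicated =
        res$distributions$duplicated$preferred,
      duplicated_two_component_means =
        res$distributions$duplicated$fits$two$means,
      duplicated_two_component_r2 =
        res$distributions$duplicated$fits$two$r_squared,
      duplicated_one_component_r2 =
        res$distributions$duplicated$fits$one$r_squared,
      duplicated_mode_skewness = res$distributions$duplicated$fits$one$skewness,
      n_attenuation_calls = nrow(res$attenuation$calls),
      n_attenuated_genes = length(attenuated_genes(res$attenuation)),
      signature_size = length(res$signature$signature$genes),
      signature_size_correlation_r =
        if (!is.null(res$signature$size_correlation))
          res$signature$size_correlation$r else NA)
    if (!is.null(res$complexes)) {
      s$n_complexes <- nrow(res$complexes$summary$table)
      s$n_attenuated_complexes <-
        sum(res$complexes$summary$table$attenuated_complex)
      s$enrichment_p <- res$complexes$enrichment$p_value
      s$enrichment_k <- res$complexes$enrichment$k
      s$enrichment_n <- res$complexes$enrichment$n
    }
    if (!is.null(res$turnover) && !is.null(res$turnover$contrast))
      s$turnover_contrast_p <- res$turnover$contrast$p_value
    if (!is.null(res$ubp6) && !is.null(res$ubp6$correlation))
      s$ubp6_correlation_r <- res$ubp6$correlation$r
    s$config <- config[setdiff(names(config),
                               c("protein", "mrna", "ubp6_protein",
                                 "turnover", "annotation", "catalog",
                                 "gene_sets"))]
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    s
  })
  res$summary <- summary
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
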