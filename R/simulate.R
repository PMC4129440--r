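#' Generate one strain column of log2 ratios from a disome truth
#'
#' Non-duplicated genes are centred at 0, duplicated non-attenuated genes
#' at `mu_full`, and (protein layer only) attenuated duplicated genes at
#' `mu_att`; mRNA and footprint layers carry no attenuation because the
#' compensation in disomic yeast is posttranscriptional. APS genes receive
#' an additive protein-layer shift of `aps_coefficient` times the
#' duplicated-chromosome gene count; ESR genes are shifted on all layers
#' by +/- 0.5 * `esr_scale`. Gaussian noise of SD `noise_sd` is added on
#' the log2 scale.
#'
#' @param genome a `genome_model`.
#' @param truth a `disome_truth` built from the same genome.
#' @param layer one of `"protein"`, `"mRNA"`, `"footprint"`.
#' @param seed integer seed.
#' @param strain column name; defaults to `"disome<chromosome>"`.
#' @param condition free-text condition tag stored on the result.
#' @return a one-column numeric matrix (genes x 1) with attributes
#'   `layer` and `condition`.
#' @export
generate_disome_matrix <- function(genome, truth,
                                   layer = c("protein", "mRNA", "footprint"),
                                   seed = 1L, strain = NULL,
                                   condition = "synthetic") {
  stopifnot(inherits(genome, "genome_model"), inherits(truth, "disome_truth"))
  layer <- match.arg(layer)
  if (!all(truth$duplicated_genes %in% genome$genes))
    stop("truth is not consistent with this genome", call. = FALSE)
  if (is.null(strain))
    strain <- paste0("disome", truth$duplicated_chromosome)

  mu <- setNames(rep(0, genome$n_genes), genome$genes)
  mu[truth$duplicated_genes] <- truth$mu_full
  if (layer == "protein" && length(truth$attenuated_genes))
    mu[truth$attenuated_genes] <- truth$mu_att
  if (layer == "protein" && length(truth$aps_genes))
    mu[truth$aps_genes] <- mu[truth$aps_genes] +
      truth$aps_coefficient *
      genome$chromosome_sizes[[truth$duplicated_chromosome]]
  if (truth$esr_scale != 0) {
    mu[genome$esr_up] <- mu[genome$esr_up] + 0.5 * truth$esr_scale
    mu[genome$esr_down] <- mu[genome$esr_down] - 0.5 * truth$esr_scale
  }
  values <- with_seed(seed,
    mu + stats::rnorm(genome$n_genes, 0, truth$noise_sd))
  m <- matrix(values, ncol = 1, dimnames = list(genome$genes, strain))
  attr(m, "layer") <- layer
  attr(m, "condition") <- condition
  m
}

#' Generate a complete multi-strain synthetic disome study
#'
#' Emulates the design of the disome proteome studies: 12 of 16
#' chromosomes each duplicated in one strain, protein and mRNA layers,
#' attenuation concentrated in complex subunits (protein layer only), a
#' planted APS whose per-strain intensity is proportional to the
#' duplicated chromosome's size, ESR shifts scaled with chromosome size,
#' and platform-appropriate noise.
#'
#' @param genome a `genome_model` (a default 4,800-gene genome is built
#'   from `seed` when omitted).
#' @param duplicated_chromosomes chromosomes duplicated (one strain each);
#'   defaults to all but III, IV, VI and VII, matching the 12-disome
#'   panel.
#' @param layers layers to generate.
#' @param mu_full_protein,mu_full_mrna expected duplicated-gene log2
#'   ratio per layer (mRNA default log2(1.9), the observed mean
#'   transcript increase).
#' @param mu_att attenuated-gene protein mean.
#' @param noise_sd log2 noise SD (0.2 TMT-like / 0.35 SILAC-like).
#' @param n_aps number of planted APS genes (drawn from never-duplicated
#'   chromosomes when possible, so the signature is independent of copy
#'   number).
#' @param aps_coefficient APS shift per duplicated-chromosome gene;
#'   default 0.4 / min(duplicated chromosome size), i.e. a shift of at
#'   least 0.4 log2 units in every strain.
#' @param esr_base ESR scale of an average-size duplication; per-strain
#'   scale is esr_base * size / mean(size).
#' @param condition condition tag (e.g. `"YEPD"`).
#' @param seed integer master seed; all sub-draws derive from it.
#' @inheritParams disome_truth
#' @return list with `genome`, `annotation`, `catalog`, `strains`,
#'   `strain_chromosomes`, `truths` (per strain), `aps_genes`, and one
#'   genes x strains matrix per requested layer (`protein`, `mRNA`, ...).
#' @export
generate_disome_study <- function(genome = NULL,
                                  duplicated_chromosomes = NULL,
                                  layers = c("protein", "mRNA"),
                                  mu_full_protein = 1.0,
                                  mu_full_mrna = log2(1.9),
                                  mu_att = 0.66, noise_sd = 0.2,
                                  attenuated_fraction_complex = 0.5,
                                  attenuated_fraction_noncomplex = 0.053,
                                  n_aps = 92L, aps_coefficient = NULL,
                                  esr_base = 0.3, condition = "YEPD",
                                  seed = 1L) {
  if (is.null(genome)) genome <- generate_genome(seed = substream_seed(seed, 1))
  chroms <- names(genome$chromosome_sizes)
  if (is.null(duplicated_chromosomes))
    duplicated_chromosomes <- setdiff(chroms, c("III", "IV", "VI", "VII"))
  duplicated_chromosomes <- intersect(chroms, duplicated_chromosomes)
  if (!length(duplicated_chromosomes))
    stop("no valid duplicated chromosomes", call. = FALSE)
  sizes <- genome$chromosome_sizes[duplicated_chromosomes]
  if (is.null(aps_coefficient)) aps_coefficient <- 0.4 / min(sizes)

  never_dup <- genome$genes[!(genome$chromosome %in% duplicated_chromosomes)]
  aps_pool <- if (length(never_dup) >= n_aps) never_dup else genome$genes
  aps_genes <- with_seed(substream_seed(seed, 2),
                         sort(sample(aps_pool, n_aps)))

  strains <- paste0("disome", duplicated_chromosomes)
  truths <- vector("list", length(strains))
  names(truths) <- strains
  for (i in seq_along(strains)) {
    chr <- duplicated_chromosomes[i]
    truths[[i]] <- disome_truth(
      genome, chr,
      mu_full = mu_full_protein, mu_att = mu_att, noise_sd = noise_sd,
      attenuated_fraction_complex = attenuated_fraction_complex,
      attenuated_fraction_noncomplex = attenuated_fraction_noncomplex,
      aps_genes = aps_genes, aps_coefficient = aps_coefficient,
      esr_scale = esr_base * sizes[[chr]] / mean(sizes),
      seed = substream_seed(seed, 10 + i))
  }

  out <- list(genome = genome, annotation = genome_annotation(genome),
              catalog = genome$complexes, strains = strains,
              strain_chromosomes = setNames(duplicated_chromosomes, strains),
              truths = truths, aps_genes = aps_genes,
              aps_coefficient = aps_coefficient, condition = condition,
              seed = seed)
  for (layer in layers) {
    cols <- lapply(seq_along(strains), function(i) {
      tr <- truths[[i]]
      if (layer != "protein") {
        # transcription scales with copy number: no attenuation, and the
        # mRNA mean increase is the observed ~1.9-fold
        tr$mu_att <- mu_full_mrna - 1e-9
        tr$mu_full <- mu_full_mrna
        tr$attenuated_genes <- character()
      }
      generate_disome_matrix(genome, tr, layer = layer,
                             seed = substream_seed(seed, 100 * match(layer, layers) + i),
                             strain = strains[i], condition = condition)
    })
    m <- do.call(cbind, cols)
    attr(m, "layer") <- layer
    attr(m, "condition") <- condition
    out[[layer]] <- m
  }
  out
}

#' Generate a synthetic peptide-level quantification table
#'
#' Produces SILAC rows (heavy/light signal-to-noise plus a heavy/light
#' ratio carrying multiplicative noise) or TMT rows (six
#' accumulation-time-normalised reporter intensities whose channel ratios
#' encode the true protein ratio). A fraction of rows is planted to
#' violate the platform's quality filters (SILAC signal-to-noise rule;
#' TMT intensity >= 20 rule) and flagged in `planted_bad` so filter code
#' can be verified against ground truth.
#'
#' @param protein_truth named numeric vector: true log2 ratio per protein.
#' @param peptides_per_protein peptides per protein (recycled).
#' @param platform `"SILAC"` or `"TMT"`.
#' @param noise_sd multiplicative (log2-scale) peptide noise SD.
#' @param bad_fraction fraction of rows planted to fail the filters.
#' @param channel_design TMT only: per-channel multiplier of the true
#'   log2 ratio; default `c(0, 1, 1, 1, 1, 1)` (channel 1 = reference).
#' @param seed integer seed.
#' @return data.frame with columns `peptide`, `protein`, `platform`,
#'   `true_log2`, `planted_bad`, and platform columns: SILAC
#'   `s2n_heavy`, `s2n_light`, `ratio_hl`; TMT `i1`..`i6` (normalised
#'   intensities), `accumulation_time`.
#' @export
generate_peptide_table <- function(protein_truth, peptides_per_protein = 10L,
                                   platform = c("SILAC", "TMT"),
                                   noise_sd = 0, bad_fraction = 0,
                                   channel_design = c(0, 1, 1, 1, 1, 1),
                                   seed = 1L) {
  platform <- match.arg(platform)
  if (!length(protein_truth) || is.null(names(protein_truth)))
    stop("`protein_truth` must be a non-empty named vector", call. = FALSE)
  if (any(peptides_per_protein < 1))
    stop("`peptides_per_protein` must be >= 1", call. = FALSE)
  npep <- rep_len(as.integer(peptides_per_protein), length(protein_truth))
  protein <- rep(names(protein_truth), npep)
  true_log2 <- rep(unname(protein_truth), npep)
  n <- length(protein)
  with_seed(seed, {
    bad <- stats::runif(n) < bad_fraction
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    base <- data.frame(
      peptide = sprintf("pep%05d", seq_len(n)), protein = protein,
      platform = platform, true_log2 = true_log2, planted_bad = bad,
      stringsAsFactors = FALSE)
    if (platform == "SILAC") {
      base$s2n_heavy <- stats::runif(n, 5, 50)
      base$s2n_light <- stats::runif(n, 5, 50)
      # planted failures: both channels below 2 (fails both clauses)
      base$s2n_heavy[bad] <- stats::runif(sum(bad), 0, 1.9)
      base$s2n_light[bad] <- stats::runif(sum(bad), 0, 1.9)
      base$ratio_hl <- 2^(true_log2 + noise)
    } else {
      denorm <- matrix(stats::runif(n, 100, 1000), n, 6) *
        2^(outer(true_log2 + noise, channel_design))
      # planted failures: reference channel below the >= 20 floor
      denorm[bad, 1] <- stats::runif(sum(bad), 0, 19)
      base$accumulation_time <- stats::runif(n, 0.5, 2)
      norm <- denorm / base$accumulation_time
      colnames(norm) <- paste0("i", 1:6)
      base <- cbind(base, as.data.frame(norm))
    }
    base
  })
}

#' Generate a turnover-inhibition timecourse with planted slopes
#'
#' Emulates short proteasome/vacuole-inhibition timecourses (0, 90 and
#' 300 s): each gene's log2 ratio is its baseline plus `slope * t` plus
#' noise. By default only attenuated duplicated genes have a positive
#' slope (their excess copies are rapidly degraded, so blocking
#' degradation makes them accumulate) while all other genes are flat.
#'
#' @param genome a `genome_model`.
#' @param truth a `disome_truth`.
#' @param slopes named vector of log2/s slopes; default
#'   `slope_attenuated` for attenuated genes, 0 elsewhere.
#' @param timepoints strictly increasing times in seconds.
#' @param slope_attenuated default slope of attenuated genes (log2/s);
#'   4.8e-4 gives ~+0.14 log2 (=10%) over 300 s.
#' @param noise_sd per-measurement log2 noise SD.
#' @param baseline optional named baseline log2 ratios; generated from
#'   `truth` when omitted.
#' @param seed integer seed.
#' @return list with `timecourse` (genes x timepoints matrix, attribute
#'   `timepoints`), `slopes` (planted), `baseline`, `timepoints`.
#' @export
generate_turnover_truth <- function(genome, truth, slopes = NULL,
                                    timepoints = c(0, 90, 300),
                                    slope_attenuated = 4.8e-4,
                                    noise_sd = 0.02, baseline = NULL,
                                    seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(truth, "disome_truth"))
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0))
    stop("`timepoints` must be >= 2 strictly increasing values",
         call. = FALSE)
  if (is.null(slopes)) {
    slopes <- setNames(rep(0, genome$n_genes), genome$genes)
    slopes[truth$attenuated_genes] <- slope_attenuated
  }
  slopes <- slopes[genome$genes]
  if (is.null(baseline)) {
    baseline <- generate_disome_matrix(genome, truth, "protein",
                                       seed = substream_seed(seed, 1))[, 1]
  }
  baseline <- baseline[genome$genes]
  tc <- with_seed(substream_seed(seed, 2), {
    m <- outer(slopes, timepoints) + baseline
    m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), ncol(m))
  })
  dimnames(tc) <- list(genome$genes, paste0("t", timepoints))
  attr(tc, "timepoints") <- timepoints
  list(timecourse = tc, slopes = slopes, baseline = baseline,
       timepoints = timepoints)
}

#' Write a complete synthetic study to a fixtures directory
#'
#' Materialises a synthetic disome study (matrices, annotation, complex
#' catalog, gene sets, config) as the TSV/YAML files consumed by
#' [run_study()], so a full pipeline run can be exercised through the
#' on-disk interface.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed passed to [generate_disome_study()].
#' @param ... further arguments to [generate_disome_study()].
#' @return (invisibly) the config list, whose fields name the written
#'   files; also written as `config.yaml` in `dir`.
#' @export
write_study_fixtures <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_disome_study(seed = seed, ...)
  p <- function(f) file.path(dir, f)
  write_quant_matrix(study$protein, p("protein.tsv"))
  if (!is.null(study$mRNA)) write_quant_matrix(study$mRNA, p("mrna.tsv"))
  write_gene_annotation(study$annotation, p("annotation.tsv"))
  write_complex_catalog(study$catalog, p("complexes.tsv"))
  sets <- list(aps_planted = study$aps_genes,
               esr_up = study$genome$esr_up,
               esr_down = study$genome$esr_down,
               ribosomal = study$genome$ribosomal_set)
  write_gene_sets(sets, p("gene_sets.tsv"))
  config <- list(
    out_dir = file.path(dir, "results"),
    protein = p("protein.tsv"),
    mrna = if (!is.null(study$mRNA)) p("mrna.tsv"),
    annotation = p("annotation.tsv"),
    catalog = p("complexes.tsv"),
    gene_sets = p("gene_sets.tsv"),
    condition = study$condition,
    cutoff = 0.6, bin_width = 0.1, seed = seed)
  config <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(config, p("config.yaml"))
  invisible(config)
}
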