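#' Generate a synthetic yeast-like genome model
#'
#' Builds a genome of `n_genes` genes spread over `n_chromosomes`
#' chromosomes whose gene counts span roughly a threefold range (mirroring
#' the size spread of the sixteen yeast chromosomes), together with a
#' protein-complex catalog covering about `complex_fraction` of all genes
#' (yeast-wide, about a third of the proteome is complex-bound), a
#' 79-member ribosome-like complex when the genome is large enough, and
#' environmental-stress-response (ESR) up/down gene sets.
#'
#' @param n_genes total number of genes.
#' @param n_chromosomes number of chromosomes (16 by default).
#' @param complex_fraction target fraction of genes belonging to at least
#'   one complex; the realised fraction is within ±0.02 of this.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param chromosome_sizes optional explicit per-chromosome gene counts
#'   (must sum to `n_genes`); overrides the random size draw.
#' @return an object of class `genome_model`: a list with elements
#'   `genes`, `chromosome` (named by gene), `position` (0-based ordinal
#'   within chromosome, named by gene), `chromosome_sizes` (named gene
#'   counts), `complexes` (named list of member-gene vectors),
#'   `ribosomal_set`, `esr_up`, `esr_down`, `complex_fraction`, `n_genes`.
#' @examples
#' g <- generate_genome(600, 16, 0.33, seed = 1)
#' length(unique(unlist(g$complexes))) / g$n_genes
#' @export
generate_genome <- function(n_genes = 4800L, n_chromosomes = 16L,
                            complex_fraction = 0.33, seed = 1L,
                            chromosome_sizes = NULL) {
  if (n_genes < 1 || n_chromosomes < 1)
    stop("`n_genes` and `n_chromosomes` must be positive", call. = FALSE)
  if (n_genes < n_chromosomes)
    stop("`n_genes` must be >= `n_chromosomes`", call. = FALSE)
  if (complex_fraction < 0 || complex_fraction > 1)
    stop("`complex_fraction` must be in [0, 1]", call. = FALSE)
  n_genes <- as.integer(n_genes)
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_names <- as.character(utils::as.roman(seq_len(n_chromosomes)))

  with_seed(seed, {
    if (is.null(chromosome_sizes)) {
      # sizes span ~3-fold smallest:largest; shuffled so size is not
      # monotone in chromosome number
      w <- sample(seq(1, 3, length.out = n_chromosomes))
      sizes <- rep(1L, n_chromosomes)
      extra <- n_genes - n_chromosomes
      if (extra > 0) {
        alloc <- floor(extra * w / sum(w))
        rem <- extra - sum(alloc)
        if (rem > 0) {
          frac <- extra * w / sum(w) - alloc
          alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
            alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
        }
        sizes <- sizes + as.integer(alloc)
      }
    } else {
      sizes <- as.integer(chromosome_sizes)
      if (length(sizes) != n_chromosomes || any(sizes < 1) ||
          sum(sizes) != n_genes)
        stop("`chromosome_sizes` must have one positive entry per ",
             "chromosome and sum to `n_genes`", call. = FALSE)
    }
    names(sizes) <- chrom_names

    genes <- sprintf("G%0*d", max(4L, nchar(n_genes)), seq_len(n_genes))
    chromosome <- setNames(rep(chrom_names, sizes), genes)
    position <- setNames(unlist(lapply(sizes, function(s) seq_len(s) - 1L),
                                use.names = FALSE), genes)

    # complex catalog: disjoint complexes, sizes 2-80, one ribosome-like
    # complex of 79 members when the membership budget allows it
    target <- round(complex_fraction * n_genes)
    pool <- sample(genes)
    complexes <- list()
    ribosomal_set <- character()
    if (target >= 79 && n_genes >= 79) {
      ribosomal_set <- pool[seq_len(79)]
      pool <- pool[-seq_len(79)]
      complexes[["CPX_RIBOSOME"]] <- sort(ribosomal_set)
    }
    used <- length(ribosomal_set)
    i <- 0L
    while (target - used >= 2 && length(pool) >= 2) {
      size <- 2L + stats::rpois(1L, 2)
      if (stats::runif(1) < 0.03) size <- size + sample(8:50, 1L)
      size <- min(size, 80L, target - used, length(pool))
      if (size < 2L) break
      i <- i + 1L
      complexes[[sprintf("CPX%03d", i)]] <- sort(pool[seq_len(size)])
      pool <- pool[-seq_len(size)]
      used <- used + size
    }

    # ESR gene sets sized like the canonical yeast stress-response program
    # (~5% induced, ~10% repressed); repressed set includes the ribosome
    non_member <- setdiff(genes, unlist(complexes, use.names = FALSE))
    n_up <- min(round(0.047 * n_genes), length(non_member))
    esr_up <- sort(sample(non_member, n_up))
    down_pool <- setdiff(genes, c(esr_up, ribosomal_set))
    n_down <- max(round(0.097 * n_genes) - length(ribosomal_set), 0)
    esr_down <- sort(c(ribosomal_set,
                       sample(down_pool, min(n_down, length(down_pool)))))

    structure(list(
      genes = genes, chromosome = chromosome, position = position,
      chromosome_sizes = sizes, complexes = complexes,
      ribosomal_set = sort(ribosomal_set), esr_up = esr_up,
      esr_down = esr_down, complex_fraction = complex_fraction,
      n_genes = n_genes, seed = seed
    ), class = "genome_model")
  })
}

#' Gene annotation table of a genome model
#'
#' @param genome a `genome_model`.
#' @return data.frame with columns `gene`, `chromosome`, `position`
#'   (0-based ordinal along the chromosome).
#' @export
genome_annotation <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  data.frame(gene = genome$genes,
             chromosome = unname(genome$chromosome[genome$genes]),
             position = unname(genome$position[genome$genes]),
             stringsAsFactors = FALSE)
}

#' @export
print.genome_model <- function(x, ...) {
  memb <- unique(unlist(x$complexes, use.names = FALSE))
  cat("genome_model:", x$n_genes, "genes on", length(x$chromosome_sizes),
      "chromosomes\n")
  cat("  chromosome sizes:", min(x$chromosome_sizes), "-",
      max(x$chromosome_sizes), "genes\n")
  cat("  complexes:", length(x$complexes), "covering", length(memb),
      sprintf("genes (%.1f%%)\n", 100 * length(memb) / x$n_genes))
  invisible(x)
}

#' Ground truth for one synthetic disome strain
#'
#' Defines the generative parameters for a single disomic strain: which
#' chromosome is duplicated, which duplicated genes are attenuated (fail to
#' scale with copy number), the two mixture means on the log2 scale, the
#' aneuploidy-signature (APS) and ESR perturbations, and the measurement
#' noise.
#'
#' Attenuated genes are drawn from the duplicated chromosome: a fraction
#' `attenuated_fraction_complex` of its complex members and
#' `attenuated_fraction_noncomplex` of its non-complex genes.
#'
#' @param genome a `genome_model`.
#' @param duplicated_chromosome chromosome ID (e.g. `"V"`).
#' @param mu_full expected log2 ratio of duplicated, non-attenuated genes
#'   (1.0 = twofold).
#' @param mu_att mean log2 ratio of attenuated duplicated genes; must be
#'   below `mu_full` (default 0.66 ~ 1.6-fold).
#' @param noise_sd additive log2-scale measurement noise SD (>= 0; 0.2 is
#'   TMT-like, 0.35 SILAC-like).
#' @param attenuated_fraction_complex fraction of duplicated complex
#'   members that are attenuated.
#' @param attenuated_fraction_noncomplex fraction of duplicated
#'   non-complex genes that are attenuated.
#' @param aps_genes genes carrying the aneuploidy protein signature shift.
#' @param aps_coefficient log2 units of APS shift per gene of the
#'   duplicated chromosome (protein layer only).
#' @param esr_scale multiplier of the ESR program (+0.5*scale for ESR-up,
#'   -0.5*scale for ESR-down genes, all layers).
#' @param seed integer seed for the attenuated-gene draw.
#' @return an object of class `disome_truth`.
#' @export
disome_truth <- function(genome, duplicated_chromosome,
                         mu_full = 1.0, mu_att = 0.66, noise_sd = 0.2,
                         attenuated_fraction_complex = 0.5,
                         attenuated_fraction_noncomplex = 0.053,
                         aps_genes = character(), aps_coefficient = 0,
                         esr_scale = 0, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (!duplicated_chromosome %in% names(genome$chromosome_sizes))
    stop("unknown chromosome: ", duplicated_chromosome, call. = FALSE)
  if (mu_att >= mu_full)
    stop("`mu_att` must be < `mu_full`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!all(aps_genes %in% genome$genes))
    stop("`aps_genes` must be genes of the genome", call. = FALSE)

  dup_genes <- genome$genes[genome$chromosome == duplicated_chromosome]
  members <- unique(unlist(genome$complexes, use.names = FALSE))
  dup_complex <- intersect(dup_genes, members)
  dup_noncx <- setdiff(dup_genes, members)
  attenuated <- with_seed(seed, {
    n_cx <- round(attenuated_fraction_complex * length(dup_complex))
    n_nc <- round(attenuated_fraction_noncomplex * length(dup_noncx))
    sort(c(if (n_cx > 0) sample(dup_complex, n_cx),
           if (n_nc > 0) sample(dup_noncx, n_nc)))
  })

  structure(list(
    duplicated_chromosome = duplicated_chromosome,
    duplicated_genes = dup_genes,
    attenuated_genes = attenuated,
    mixture_params = c(mu_full = mu_full, mu_att = mu_att,
                       sigma = noise_sd),
    mu_full = mu_full, mu_att = mu_att, noise_sd = noise_sd,
    aps_genes = aps_genes, aps_coefficient = aps_coefficient,
    esr_scale = esr_scale, seed = seed
  ), class = "disome_truth")
}

#' @export
print.disome_truth <- function(x, ...) {
  cat("disome_truth: chromosome", x$duplicated_chromosome, "duplicated;",
      length(x$duplicated_genes), "genes,", length(x$attenuated_genes),
      "attenuated\n")
  cat(sprintf("  mu_full=%.3g  mu_att=%.3g  noise_sd=%.3g  APS genes=%d\n",
              x$mu_full, x$mu_att, x$noise_sd, length(x$aps_genes)))
  invisible(x)
}
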