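#' Pearson mode skewness
#'
#' `(median - mean) / SD`, a robust asymmetry measure of a log2-ratio
#' distribution: negative values indicate a left tail, e.g. a
#' sub-population of attenuated proteins below the main mode.
#'
#' @param values numeric vector (>= 3 finite values, SD > 0).
#' @return scalar skewness.
#' @export
mode_skewness <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need >= 3 finite values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("SD is zero", call. = FALSE)
  (stats::median(values) - mean(values)) / s
}

gaussian_mixture_height <- function(x, means, sds, amps) {
  y <- 0
  for (k in seq_along(means))
    y <- y + amps[k] * exp(-(x - means[k])^2 / (2 * sds[k]^2))
  y
}

#' Fit a one- or two-Gaussian model to a binned log2-ratio distribution
#'
#' Histograms the values into bins of `bin_width` (relative frequencies)
#' and least-squares fits a sum of scaled Gaussian curves to the bin
#' heights, Prism-style. The two-component fit is multistarted from
#' pairs of data quantiles and the best converged start is returned.
#'
#' @param values numeric vector of log2 ratios (NA ignored; >= 50 finite
#'   values required for two components).
#' @param n_components 1 or 2.
#' @param bin_width histogram bin width in log2 units (default 0.1).
#' @param breaks optional explicit histogram breaks (otherwise the data
#'   range rounded out to multiples of `bin_width`).
#' @param equal_sd constrain both components to one common SD.
#' @param n_starts number of multistart initialisations (2 components).
#' @return object of class `gaussian_fit`: list with `n_components`,
#'   `means` (sorted ascending), `sds`, `amplitudes`, `r_squared`,
#'   `bin_width`, `skewness` (Pearson mode skewness of the raw values),
#'   `bins` (data.frame mid/freq/fitted), `n`.
#' @export
fit_gaussian <- function(values, n_components = 1L, bin_width = 0.1,
                         breaks = NULL, equal_sd = FALSE, n_starts = 8L) {
  values <- values[is.finite(values)]
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  if (!n_components %in% c(1L, 2L))
    stop("`n_components` must be 1 or 2", call. = FALSE)
  if (n_components == 2L && length(values) < 50)
    stop("need >= 50 finite values for a two-component fit", call. = FALSE)
  if (length(values) < 10)
    stop("need >= 10 finite values", call. = FALSE)

  if (is.null(breaks)) {
    lo <- floor(min(values) / bin_width) * bin_width
    hi <- ceiling(max(values) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts / length(values)
  sst <- sum((y - mean(y))^2)
  wmean <- sum(x * y) / sum(y)
  wsd <- sqrt(max(sum(y * (x - wmean)^2) / sum(y), (bin_width / 2)^2))

  fits <- list()
  if (n_components == 1L) {
    st <- list(a = max(y), m = wmean, s = wsd)
    fits[[1]] <- try_gauss_fit(x, y,
      y ~ a * exp(-(x - m)^2 / (2 * s^2)), st,
      lower = c(a = 0, m = min(x) - 1, s = bin_width / 10),
      upper = c(a = Inf, m = max(x) + 1, s = diff(range(x)) + bin_width))
  } else {
    qpairs <- list(c(.25, .75), c(.15, .85), c(.35, .65), c(.10, .50),
                   c(.50, .90), c(.20, .80), c(.30, .60), c(.40, .70))
    qpairs <- qpairs[seq_len(min(n_starts, length(qpairs)))]
    for (qp in qpairs) {
      ms <- stats::quantile(values, qp, names = FALSE)
      if (equal_sd) {
        st <- list(a1 = max(y) * 0.6, m1 = ms[1], a2 = max(y) * 0.6,
                   m2 = ms[2], s = wsd / 1.5)
        form <- y ~ a1 * exp(-(x - m1)^2 / (2 * s^2)) +
          a2 * exp(-(x - m2)^2 / (2 * s^2))
        lower <- c(a1 = 0, m1 = min(x) - 1, a2 = 0, m2 = min(x) - 1,
                   s = bin_width / 10)
        upper <- c(a1 = Inf, m1 = max(x) + 1, a2 = Inf, m2 = max(x) + 1,
                   s = diff(range(x)) + bin_width)
      } else {
        st <- list(a1 = max(y) * 0.6, m1 = ms[1], s1 = wsd / 1.5,
                   a2 = max(y) * 0.6, m2 = ms[2], s2 = wsd / 1.5)
        form <- y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
          a2 * exp(-(x - m2)^2 / (2 * s2^2))
        lower <- c(a1 = 0, m1 = min(x) - 1, s1 = bin_width / 10,
                   a2 = 0, m2 = min(x) - 1, s2 = bin_width / 10)
        upper <- c(a1 = Inf, m1 = max(x) + 1,
                   s1 = diff(range(x)) + bin_width,
                   a2 = Inf, m2 = max(x) + 1,
                   s2 = diff(range(x)) + bin_width)
      }
      fits[[length(fits) + 1]] <- try_gauss_fit(x, y, form, st, lower, upper)
    }
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("Gaussian fit failed to converge from any start (n = ",
         length(values), ", bins = ", length(x), ")", call. = FALSE)
  sse <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(sse)]]
  cf <- stats::coef(best)

  if (n_components == 1L) {
    means <- cf[["m"]]; sds <- cf[["s"]]; amps <- cf[["a"]]
  } else if (equal_sd) {
    means <- c(cf[["m1"]], cf[["m2"]]); sds <- rep(cf[["s"]], 2)
    amps <- c(cf[["a1"]], cf[["a2"]])
  } else {
    means <- c(cf[["m1"]], cf[["m2"]]); sds <- c(cf[["s1"]], cf[["s2"]])
    amps <- c(cf[["a1"]], cf[["a2"]])
  }
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; amps <- amps[ord]
  fitted <- gaussian_mixture_height(x, means, sds, amps)
  r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else NA_real_
  structure(list(
    n_components = n_components, means = means, sds = sds,
    amplitudes = amps, r_squared = max(min(r2, 1), 0),
    bin_width = bin_width, skewness = mode_skewness(values),
    bins = data.frame(mid = x, freq = y, fitted = fitted),
    n = length(values)
  ), class = "gaussian_fit")
}

try_gauss_fit <- function(x, y, formula, start, lower, upper) {
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data.frame(x = x, y = y), start = start,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  fit
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("gaussian_fit: %d component(s), n = %d, bin width %.3g\n",
              x$n_components, x$n, x$bin_width))
  for (k in seq_along(x$means))
    cat(sprintf("  mean = %.4f (%.2f-fold)  sd = %.4f  amplitude = %.4f\n",
                x$means[k], 2^x$means[k], x$sds[k], x$amplitudes[k]))
  cat(sprintf("  R^2 = %.4f  mode skewness = %.3f\n",
              x$r_squared, x$skewness))
  invisible(x)
}

#' Compare one- vs two-Gaussian models of a distribution
#'
#' Fits both models to the binned distribution and prefers the
#' two-component model only when it both improves R^2 by at least
#' `delta_r2_threshold` and resolves components separated by at least
#' `min_separation` pooled SDs (parsimony tie-break: ties go to one
#' component).
#'
#' @inheritParams fit_gaussian
#' @param delta_r2_threshold minimum R^2 improvement (default 0.02).
#' @param min_separation minimum |mean2 - mean1| in pooled-SD units.
#' @return list with `preferred` (1 or 2), `fits` (both models),
#'   `delta_r2`, `separation`.
#' @export
compare_models <- function(values, bin_width = 0.1, breaks = NULL,
                           delta_r2_threshold = 0.02, min_separation = 1,
                           equal_sd = FALSE, n_starts = 8L) {
  f1 <- fit_gaussian(values, 1L, bin_width, breaks)
  f2 <- tryCatch(fit_gaussian(values, 2L, bin_width, breaks,
                              equal_sd = equal_sd, n_starts = n_starts),
                 error = function(e) NULL)
  if (is.null(f2))
    return(list(preferred = 1L, fits = list(one = f1, two = NULL),
                delta_r2 = NA_real_, separation = NA_real_))
  delta <- f2$r_squared - f1$r_squared
  pooled <- sqrt(mean(f2$sds^2))
  separation <- abs(diff(f2$means)) / pooled
  preferred <- if (delta >= delta_r2_threshold &&
                   separation >= min_separation) 2L else 1L
  list(preferred = preferred, fits = list(one = f1, two = f2),
       delta_r2 = delta, separation = separation)
}

#' Call attenuated (dosage-compensated) duplicated genes
#'
#' Operates on duplicated-chromosome genes only. A gene is attenuated in
#' a strain when its log2 ratio is at least `cutoff` below the reference:
#' either the fixed expected duplication value (1.0 = twofold; the
#' stringent cutoff 0.6 = 3 x the wild-type/wild-type ratio SD of 0.2
#' puts the threshold at 0.4, boundary inclusive) or, for data sets whose
#' overall duplication response deviates from twofold, the strain's own
#' mean duplicated-gene ratio.
#'
#' @param m genes x strains log2-ratio matrix.
#' @param annotation annotation data.frame (`gene`, `chromosome`).
#' @param cutoff log2 distance below the reference (> 0; default 0.6).
#' @param reference `"fixed_expected"` or `"per_strain_mean"`.
#' @param expected_value reference value for `"fixed_expected"`.
#' @param strain_chromosomes named duplicated chromosome per strain;
#'   parsed from column names by default. Strains with unknown (`NA`)
#'   duplication are a configuration error.
#' @return object of class `attenuation_calls`: list with `calls`
#'   (data.frame gene/strain/log2_ratio/attenuated), `cutoff`,
#'   `reference`, `reference_values` (named per strain).
#' @export
call_attenuated <- function(m, annotation, cutoff = 0.6,
                            reference = c("fixed_expected",
                                          "per_strain_mean"),
                            expected_value = 1.0,
                            strain_chromosomes = NULL) {
  reference <- match.arg(reference)
  if (cutoff <= 0) stop("`cutoff` must be > 0", call. = FALSE)
  if (is.null(strain_chromosomes))
    strain_chromosomes <- strain_chromosome(colnames(m))
  missing_ <- setdiff(colnames(m), names(strain_chromosomes))
  if (length(missing_) || anyNA(strain_chromosomes[colnames(m)]))
    stop("unknown duplicated chromosome for strain(s): ",
         paste(c(missing_,
                 colnames(m)[is.na(strain_chromosomes[colnames(m)])]),
               collapse = ", "), call. = FALSE)
  chrom <- setNames(annotation$chromosome, annotation$gene)[rownames(m)]
  rows <- list()
  ref_values <- setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    strain <- colnames(m)[j]
    dup <- strain_chromosomes[[strain]]
    idx <- which(chrom == dup & is.finite(m[, j]))
    vals <- m[idx, j]
    ref <- if (reference == "fixed_expected") expected_value
           else mean(vals)
    ref_values[strain] <- ref
    rows[[j]] <- data.frame(
      gene = rownames(m)[idx], strain = strain, log2_ratio = vals,
      attenuated = vals <= ref - cutoff, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  structure(list(calls = calls, cutoff = cutoff, reference = reference,
                 reference_values = ref_values),
            class = "attenuation_calls")
}

#' Genes attenuated in at least one strain of a call set
#' @param x an `attenuation_calls` object.
#' @return character vector of gene IDs.
#' @export
attenuated_genes <- function(x) {
  stopifnot(inherits(x, "attenuation_calls"))
  sort(unique(x$calls$gene[x$calls$attenuated]))
}

#' @export
print.attenuation_calls <- function(x, ...) {
  cat(sprintf(
    "attenuation_calls: %d calls, %d attenuated (%.1f%%), cutoff %.2f (%s)\n",
    nrow(x$calls), sum(x$calls$attenuated),
    100 * mean(x$calls$attenuated), x$cutoff, x$reference))
  invisible(x)
}

#' Chromosome-ordered profile of one strain
#'
#' Returns the strain's log2 ratios sorted by chromosome and ordinal
#' gene position (the order in which duplications appear as a block),
#' plus per-chromosome mean and SD.
#'
#' @param m genes x strains matrix.
#' @param annotation annotation data.frame (`gene`, `chromosome`,
#'   `position`).
#' @param strain strain (column) name.
#' @return list with `profile` (data.frame gene/chromosome/position/
#'   value) and `chromosome_stats` (chromosome/n/mean/sd; empty
#'   chromosomes have `NA` mean).
#' @export
chromosome_profile <- function(m, annotation, strain) {
  if (!strain %in% colnames(m))
    stop("strain not in matrix: ", strain, call. = FALSE)
  ann <- annotation[, c("gene", "chromosome", "position")]
  chrom_levels <- unique(ann$chromosome)
  ann <- ann[order(match(ann$chromosome, chrom_levels), ann$position), ]
  v <- m[, strain][ann$gene]
  profile <- data.frame(ann, value = unname(v), stringsAsFactors = FALSE)
  rownames(profile) <- NULL
  stats_ <- do.call(rbind, lapply(chrom_levels, function(ch) {
    vals <- profile$value[profile$chromosome == ch]
    vals <- vals[is.finite(vals)]
    data.frame(chromosome = ch, n = length(vals),
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_)
  }))
  list(profile = profile, chromosome_stats = stats_)
}

#' Distribution summaries of attenuated vs non-attenuated genes by layer
#'
#' For each layer matrix and each group (attenuated, not attenuated; at
#' the measured duplicated instances of the called genes) returns n,
#' mean, SD and, when the group is large enough, a one-component
#' Gaussian histogram fit. In disomic yeast the attenuated set shows a
#' reduced mean only at the protein layer; mRNA and footprint layers
#' stay near the full duplication response.
#'
#' @param att_calls an `attenuation_calls` object.
#' @param layer_matrices named list of genes x strains matrices.
#' @param bin_width histogram bin width for the per-group fits.
#' @param min_fit_n minimum group size for fitting.
#' @return list with `summary` (data.frame layer/group/n/mean/sd/
#'   fit_mean/fit_sd/fit_r2) and `fits` (named list of `gaussian_fit`).
#' @export
compare_layers <- function(att_calls, layer_matrices, bin_width = 0.1,
                           min_fit_n = 50L) {
  stopifnot(inherits(att_calls, "attenuation_calls"))
  calls <- att_calls$calls
  if (!any(calls$attenuated))
    warning("empty attenuated set; summarising the complement only",
            call. = FALSE)
  groups <- list(attenuated = calls[calls$attenuated, ],
                 not_attenuated = calls[!calls$attenuated, ])
  rows <- list(); fits <- list()
  for (layer in names(layer_matrices)) {
    lm_ <- layer_matrices[[layer]]
    for (g in names(groups)) {
      gc <- groups[[g]]
      if (!nrow(gc)) next
      keep <- gc$gene %in% rownames(lm_) & gc$strain %in% colnames(lm_)
      vals <- lm_[cbind(gc$gene[keep], gc$strain[keep])]
      vals <- vals[is.finite(vals)]
      fit <- if (length(vals) >= min_fit_n)
        tryCatch(fit_gaussian(vals, 1L, bin_width), error = function(e) NULL)
      else NULL
      if (!is.null(fit)) fits[[paste(layer, g, sep = ".")]] <- fit
      rows[[length(rows) + 1]] <- data.frame(
        layer = layer, group = g, n = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
        fit_mean = if (!is.null(fit)) fit$means else NA_real_,
        fit_sd = if (!is.null(fit)) fit$sds else NA_real_,
        fit_r2 = if (!is.null(fit)) fit$r_squared else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, rows), fits = fits)
}
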