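#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_point geom_vline
#'   geom_hline labs theme_minimal after_stat
NULL

#' Plot the allele-effect direction distribution
#'
#' Histogram of the per-probeset allele effect (difference of group mean
#' log2 expression at the best locus, code-0 homozygotes minus carriers).
#' On an unbiased platform with no dominant true effects this distribution
#' is centered on zero; a rightward shift is the signature of probe
#' hybridization bias against the variant-carrying allele.
#'
#' @param object an `eqtl_result` from [eqtl_scan()].
#' @param bins histogram bin count.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot eqtl_result
#' @export
autoplot.eqtl_result <- function(object, bins = 40, ...) {
  ggplot(as_tibble(object), aes(x = .data$allele_effect_d)) +
    geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    geom_vline(xintercept = 0, linetype = 2, colour = "firebrick") +
    labs(x = "allele effect d (log2, homozygous - carrier)", y = "probesets",
         title = "Allele-effect direction at best loci") +
    theme_minimal()
}

#' Plot significance change against uncorrected strength
#'
#' Scatter of the change in eQTL statistical strength after probe masking
#' (`delta` on the -log10 p scale; negative = weakened) against the
#' uncorrected strength. A downward trend at high uncorrected strength
#' indicates that the strongest uncorrected signals were inflated by probe
#' bias.
#'
#' @param object a `run_comparison` from [compare_runs()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot run_comparison
#' @export
autoplot.run_comparison <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$neglog10p_uncorrected, y = .data$delta)) +
    geom_point(alpha = 0.4, size = 0.8) +
    geom_hline(yintercept = 0, linetype = 2, colour = "firebrick") +
    labs(x = "uncorrected strength (-log10 p)",
         y = "change after correction (-log10 p)",
         title = "eQTL strength change after probe masking") +
    theme_minimal()
}

#' Plot the per-probeset masking depth
#'
#' Histogram of the number of probes removed per probeset.
#'
#' @param object a `mask_report` from [equalize_annotation()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mask_report
#' @export
autoplot.mask_report <- function(object, ...) {
  ggplot(as_tibble(unclass(object)), aes(x = .data$n_probes_removed)) +
    geom_histogram(binwidth = 1, fill = "grey35", colour = "white") +
    labs(x = "probes removed per probeset", y = "probesets",
         title = "Masking depth") +
    theme_minimal()
}
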