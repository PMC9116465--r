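#' Descriptor and pyramid configuration
#'
#' Bundles every tunable of the feature extractor: the local-pattern
#' neighborhood (`P` sampling points at radius `R`), the joint-histogram
#' geometry (`M` pattern codes by `N` differential-excitation bins), the
#' number of equal-width bins for the three ternary-pattern channel
#' histograms, and the number of pyramid scales. The defaults reproduce the
#' standard 444-dimensional descriptor:
#' 3 scales x (10 x 10 joint histogram + 3 x 15 channel bins + 3 entropies).
#'
#' @param P Number of circular neighbors per pixel (default 8).
#' @param R Neighborhood radius in pixels (default 1; the 8 grid neighbors
#'   are used directly, non-integer radii are sampled bilinearly).
#' @param M Number of pattern-code bins of the joint histogram. Rotation-
#'   invariant uniform coding emits codes 0..P+1, so the default is `P + 2`.
#' @param N Number of absolute differential-excitation bins over \[0, pi/2\].
#' @param n_bins Bins of each ternary-channel histogram (default 15).
#' @param n_scales Pyramid depth including the original scale (default 3).
#' @return An object of class `"ceiqa_config"` (a validated list).
#' @examples
#' cfg <- ceiqa_config()
#' feature_length(cfg) # 444
#' @export
ceiqa_config <- function(P = 8L, R = 1, M = P + 2L, N = 10L,
                         n_bins = 15L, n_scales = 3L) {
  P <- as.integer(P); M <- as.integer(M); N <- as.integer(N)
  n_bins <- as.integer(n_bins); n_scales <- as.integer(n_scales)
  stopifnot(P >= 4L, R > 0, N >= 1L, n_bins >= 2L, n_scales >= 1L)
  if (M < P + 2L)
    stop("M must be at least P + 2 to hold pattern codes 0..P+1", call. = FALSE)
  structure(list(P = P, R = R, M = M, N = N,
                 n_bins = n_bins, n_scales = n_scales),
            class = "ceiqa_config")
}

#' Length of the feature vector implied by a configuration
#'
#' `n_scales * (M*N + 3*n_bins + 3)`; 444 at the defaults.
#'
#' @param config A [ceiqa_config()] object.
#' @return Integer feature count.
#' @export
feature_length <- function(config = ceiqa_config()) {
  with(config, n_scales * (M * N + 3L * n_bins + 3L))
}

#' Feature-layout fingerprint
#'
#' A short string identifying the feature layout a configuration produces.
#' Models store it at training time and refuse incompatible feature tables.
#'
#' @param config A [ceiqa_config()] object.
#' @return A single character string.
#' @export
config_fingerprint <- function(config = ceiqa_config()) {
  with(config, sprintf("ceiqa/1 P%d R%g M%d N%d B%d S%d D%d",
                       P, R, M, N, n_bins, n_scales, feature_length(config)))
}

#' Column names of the feature layout
#'
#' Per scale `s`: `s{s}_delbp_{000..}` (joint histogram, flattened by pattern
#' code then DE bin), `s{s}_up_*`, `s{s}_low_*`, `s{s}_mag_*` channel
#' histograms, then `s{s}_E_up`, `s{s}_E_low`, `s{s}_E_mag`.
#'
#' @param config A [ceiqa_config()] object.
#' @return Character vector of length `feature_length(config)`.
#' @export
feature_names <- function(config = ceiqa_config()) {
  unlist(lapply(seq_len(config$n_scales) - 1L, function(s) {
    c(sprintf("s%d_delbp_%03d", s, seq_len(config$M * config$N) - 1L),
      sprintf("s%d_up_%02d",  s, seq_len(config$n_bins) - 1L),
      sprintf("s%d_low_%02d", s, seq_len(config$n_bins) - 1L),
      sprintf("s%d_mag_%02d", s, seq_len(config$n_bins) - 1L),
      sprintf(c("s%d_E_up", "s%d_E_low", "s%d_E_mag"), s))
  }), use.names = FALSE)
}

#' @export
print.ceiqa_config <- function(x, ...) {
  cat("Descriptor configuration\n")
  cat(sprintf("  neighborhood: P = %d, R = %g\n", x$P, x$R))
  cat(sprintf("  joint histogram: %d pattern codes x %d DE bins\n", x$M, x$N))
  cat(sprintf("  channel histograms: %d bins\n", x$n_bins))
  cat(sprintf("  scales: %d  ->  %d features\n", x$n_scales, feature_length(x)))
  invisible(x)
}
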