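#' @keywords internal
"_PACKAGE"

## Shared small helpers. Kept internal.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(structure(class = c("adipomr_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("adipomr_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Inverse logit
#' @param x numeric vector on the log-odds scale
#' @return probabilities in (0,1)
#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

## z-quantile used for every 95% interval in the package; fixed at 1.96 so
## intervals are reproducible across R versions and match the reporting
## convention (estimate +/- 1.96*SE).
Z95 <- 1.96

ci95 <- function(est, se) c(est - Z95 * se, est + Z95 * se)

pval_norm <- function(est, se) 2 * stats::pnorm(-abs(est / se))

## Deterministic sub-seed derivation: keeps every stage's RNG stream
## reproducible from one top-level seed while staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 1117) %% 2147483647)
}
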