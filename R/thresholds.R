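# Three-axis physico-chemical classification thresholds.

#' Classification thresholds for the three monomer category axes
#'
#' Cutoffs used to assign every monomer one label per axis: hydrophobicity
#' (hydrophobic / polar / charged), charge (neutral / positive / negative) and
#' size (small / medium / large).  Defaults are the package's documented,
#' editable choices (they are not canonical constants of any one dataset):
#' capped-residue logP >= 1.0 is hydrophobic; formal net charge at pH 7 of
#' >= +0.5 is positive and <= -0.5 negative; free-monomer MW <= 120 Da is
#' small and >= 180 Da large.  The isoelectric-point cutoffs are a fallback
#' used only when net charge is unavailable.
#'
#' @param logp_hydrophobic_min logP at/above which a neutral monomer is
#'   hydrophobic.
#' @param logp_polar_max logP at/below which a monomer is unambiguously polar
#'   (informational boundary; everything below `logp_hydrophobic_min` that is
#'   not charged classifies polar).
#' @param charge_positive_min,charge_negative_max net-charge cutoffs at pH 7.
#' @param pi_positive_min,pi_negative_max isoelectric-point fallback cutoffs.
#' @param mw_small_max,mw_large_min molecular-weight cutoffs in Daltons.
#' @return object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(logp_hydrophobic_min = 1.0,
                                      logp_polar_max = -1.0,
                                      charge_positive_min = 0.5,
                                      charge_negative_max = -0.5,
                                      pi_positive_min = 8.0,
                                      pi_negative_max = 6.0,
                                      mw_small_max = 120,
                                      mw_large_min = 180) {
  th <- list(logp_hydrophobic_min = logp_hydrophobic_min,
             logp_polar_max = logp_polar_max,
             charge_positive_min = charge_positive_min,
             charge_negative_max = charge_negative_max,
             pi_positive_min = pi_positive_min,
             pi_negative_max = pi_negative_max,
             mw_small_max = mw_small_max,
             mw_large_min = mw_large_min)
  if (!(th$logp_hydrophobic_min > th$logp_polar_max &&
        th$charge_positive_min > th$charge_negative_max &&
        th$pi_positive_min > th$pi_negative_max &&
        th$mw_large_min > th$mw_small_max))
    pd_error("each threshold min must be strictly greater than its paired max",
             "pepmc_config_error")
  structure(th, class = "classification_thresholds")
}

#' Read / write classification thresholds as YAML
#'
#' @param path YAML file path.
#' @return `read_thresholds` returns a `classification_thresholds` object;
#'   `write_thresholds` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(classification_thresholds, vals)
}

#' @rdname read_thresholds
#' @param thresholds a `classification_thresholds` object.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}
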