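#' Run configuration
#'
#' Central registry of tunable parameters with documented defaults. Unknown
#' keys are rejected, so typos fail loudly rather than silently falling back
#' to a default.
#'
#' Parameters (units, default):
#' \describe{
#'   \item{bin_size}{bin width in bp (200,000).}
#'   \item{min_size}{minimum reportable CA size in bp (200,000); calls below
#'     it are filtered.}
#'   \item{depth}{mean mapped fragments per cell (285,000).}
#'   \item{dispersion}{negative-binomial variance inflation of bin counts,
#'     variance = dispersion x mean (2).}
#'   \item{bg_flip}{fraction of reads mapped to the wrong strand, background
#'     mapping noise (0.02).}
#'   \item{tag_frac}{fraction of reads carrying an informative haplotype tag
#'     (0.15).}
#'   \item{sce_mean}{mean sister-chromatid-exchange count per cell, Poisson,
#'     genome-wide (6).}
#'   \item{qc_min_fragments}{per-cell minimum fragment count; cells below it
#'     are QC-fail (50,000).}
#'   \item{penalty}{segmentation penalty multiplier; the per-changepoint
#'     penalty is `penalty * d * log(n)` for d signal dimensions and n bins
#'     (2).}
#'   \item{single_bin_alpha}{genome-wide false-positive budget of the
#'     single-bin refinement scan (0.05).}
#'   \item{cn_cap}{maximum total copy number in the segment state space (6);
#'     states at the cap are flagged.}
#'   \item{blacklist_frac}{bins whose population median coverage falls below
#'     this fraction of the genome median are masked (0.25).}
#'   \item{consensus_min_cells}{minimum cells required to build a consensus
#'     (3).}
#'   \item{chromothripsis_k}{minimum oscillating state switches for a
#'     chromothripsis call (5).}
#'   \item{whole_arm_frac}{arm fraction above which an isolated call gets the
#'     whole-arm annotation (0.9).}
#'   \item{iso_alpha}{per-event two-sided quasi-binomial alpha for the
#'     balanced Watson/Crick increment test of the isoacentric flag
#'     (0.005): a consistency guard, kept small so genuinely balanced
#'     gains essentially always retain the flag.}
#'   \item{reciprocity_min}{minimum template-strand reciprocity for a sister
#'     verdict (0.95).}
#'   \item{sce_tol_bins}{mirrored-SCE co-localization tolerance in bins (1).}
#'   \item{min_informative_frac}{genome fraction that must be informative for
#'     the SCE-free sister rule (0.9).}
#'   \item{seed}{default random seed (1).}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `sk_config`.
#' @examples
#' cfg <- sk_config(depth = 1e5)
#' @export
sk_config <- function(...) {
  defaults <- list(
    bin_size = 200000,
    min_size = 200000,
    depth = 285000,
    dispersion = 2,
    bg_flip = 0.02,
    tag_frac = 0.15,
    sce_mean = 6,
    qc_min_fragments = 50000,
    penalty = 1.5,
    single_bin_alpha = 0.05,
    cn_cap = 6,
    blacklist_frac = 0.25,
    consensus_min_cells = 3,
    chromothripsis_k = 5,
    whole_arm_frac = 0.9,
    iso_alpha = 0.005,
    reciprocity_min = 0.95,
    sce_tol_bins = 1,
    min_informative_frac = 0.9,
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      sk_parameter_error("config overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      sk_parameter_error(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
    defaults[names(over)] <- over
  }
  structure(defaults, class = "sk_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with a flat mapping of parameter overrides.
#' @return An [sk_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) sk_io_error(paste0("no such file: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(sk_config())
  do.call(sk_config, vals)
}

as_sk_config <- function(config) {
  if (is.null(config)) return(sk_config())
  if (inherits(config, "sk_config")) return(config)
  do.call(sk_config, as.list(config))
}
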