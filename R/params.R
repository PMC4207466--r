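# Per-subgroup generation parameters.
#
# The four anatomical subgroups (suprapyramidal/infrapyramidal blade x
# deep/superficial GCL depth) have distinct balancing factors, stem-count
# distributions, dendritic-field sizes and target-point quotas.  The
# balancing factors are fixed anatomical inputs (0.9 suprapyramidal deep,
# 1.35 suprapyramidal superficial, 1.22 infrapyramidal); the remaining
# metric parameters are calibrated so that the generated population
# reproduces the reference morphometric tables (see
# scripts/calibrate_growth.R in the source repository and the package
# vignette).

#' Default subgroup growth-parameter table
#'
#' One row per subgroup with columns:
#' `bf` (balancing factor), `max_reach` (maximum connection distance, um,
#' during wiring; see [grow_tree()]), `stem_lambda` (Poisson rate of the stem-count
#' sampler truncated to 1..4), `rt_mean`/`rt_sd` (transverse cone radius
#' distribution, um), `rl_ratio` (longitudinal/transverse radius ratio),
#' `n_nodes` (mean total target-point quota), `f_gcl`..`f_oml` (mean quota
#' fractions per layer), `size_cv` (coefficient of variation of the
#' per-cell size factor), `amp10`/`amp50` (jitter amplitudes, um, at the
#' 10 um and 50 um length constants), and the diameter-taper parameters
#' `dmax_mean`, `dmax_sd`, `dtip_mean`, `dtip_sd`, `taper_lambda` (um).
#'
#' @return data.frame with row names the four subgroup labels.
#' @export
default_subgroup_params <- function() {
  sg <- c("supra_superficial", "supra_deep",
          "infra_superficial", "infra_deep")
  tab <- data.frame(
    subgroup   = sg,
    bf         = c(1.35, 0.90, 1.22, 1.22),
    max_reach  = 50,
    z_exp      = c(2.2, 3, 2.2, 3),
    within_bias = 0,
    apex_offset = 40,
    stem_lambda = c(2.643, 0.896, 1.781, 0.726),
    rt_mean    = c(140, 125, 128, 112),
    rt_sd      = c(22, 20, 20, 18),
    rl_ratio   = c(0.56, 0.56, 0.56, 0.56),
    n_nodes    = c(45, 44, 39, 38),
    f_gcl      = 0.08, f_iml = 0.34, f_mml = 0.29, f_oml = 0.29,
    size_cv    = 0.15,
    amp10      = 2.5, amp50 = 12.0,
    dmax_mean  = 2.2, dmax_sd = 0.35,
    dtip_mean  = 0.75, dtip_sd = 0.10,
    taper_lambda = 5.0,
    stringsAsFactors = FALSE)
  rownames(tab) <- sg
  tab
}

#' Load / save a subgroup parameter table
#'
#' Round-trips the table through a human-readable YAML file so that runs
#' are reproducible from configuration alone.
#'
#' @param path file path
#' @param tab table as returned by [default_subgroup_params()]
#' @return `read_subgroup_params` returns the table.
#' @export
read_subgroup_params <- function(path) {
  y <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(y, function(row) as.data.frame(row)))
  rownames(tab) <- tab$subgroup
  tab
}

#' @rdname read_subgroup_params
#' @export
write_subgroup_params <- function(tab, path) {
  y <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
  names(y) <- tab$subgroup
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Mean of a Poisson distribution truncated to an integer range
#'
#' @param lambda Poisson rate
#' @param lo,hi inclusive truncation bounds
#' @export
trunc_pois_mean <- function(lambda, lo = 1, hi = 4) {
  k <- lo:hi
  p <- dpois(k, lambda)
  sum(k * p) / sum(p)
}

#' Sample from a truncated Poisson distribution
#'
#' @param n number of draws
#' @param lambda Poisson rate
#' @param lo,hi inclusive truncation bounds
#' @export
rtrunc_pois <- function(n, lambda, lo = 1, hi = 4) {
  k <- lo:hi
  p <- dpois(k, lambda)
  k[sample.int(length(k), n, replace = TRUE, prob = p)]
}

#' Solve for the truncated-Poisson rate giving a target mean
#'
#' @param target desired mean on `lo..hi`
#' @param lo,hi inclusive truncation bounds
#' @export
trunc_pois_lambda <- function(target, lo = 1, hi = 4) {
  if (target <= lo || target >= hi) stop("target mean outside open range")
  stats::uniroot(function(l) trunc_pois_mean(l, lo, hi) - target,
                 c(1e-6, 60), tol = 1e-10)$root
}
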