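#' Liability thresholds reproducing a target mean feather score
#'
#' Feather score is a three-level categorical trait (10 = intact plumage,
#' 15 = damaged feathers, 20 = bald patches) generated here by cutting a
#' standard-normal liability at two thresholds. The data the design emulates
#' report only the mean score per trait, not the category frequencies, so the
#' split between the two damaged categories is set by a fixed policy:
#' P(score 15) = `ratio` * P(score 20). Given a target mean, the category
#' probabilities then solve mean = 10 + 5 P(15) + 10 P(20).
#'
#' @param target_mean desired expected score, in (10, 20).
#' @param ratio P(15)/P(20) policy constant.
#' @return numeric length-2 vector of increasing standard-normal thresholds
#'   `c(t1, t2)`: score 10 below `t1`, 15 in `[t1, t2)`, 20 at or above `t2`.
#' @examples
#' th <- fs_thresholds(11.32)
#' p <- diff(c(0, pnorm(th), 1))
#' sum(p * c(10, 15, 20))  # 11.32
#' @export
fs_thresholds <- function(target_mean, ratio = 4) {
  stopifnot(target_mean > 10, target_mean < 20, ratio > 0)
  p20 <- (target_mean - 10) / (5 * ratio + 10)
  p15 <- ratio * p20
  if (p15 + p20 >= 1) stop("target mean too high for the P(15)/P(20) policy")
  stats::qnorm(c(1 - p15 - p20, 1 - p20))
}

#' Configuration of the recurrent-testing simulator
#'
#' Defines the half-sib cage design and the true (liability-scale) variance
#' components. Each test sire is mated to `dams_per_sire` unidentified dams
#' and has about `daughters_per_sire` daughters housed in `cages_per_sire`
#' all-half-sib cages. Cage sizes are drawn as `3 + Binomial(19, p)` with `p`
#' solved so the mean cage size equals `daughters_per_sire / cages_per_sire`,
#' keeping sizes inside `cage_size_range`.
#'
#' Because dams are unknown, the residual variance `sigma2_e` absorbs the dam
#' and Mendelian-sampling variation: on the individual liability scale the
#' phenotypic decomposition is `sigma2_S + sigma2_c + sigma2_e`, with the
#' full additive variance `sigma2_A = 4 * sigma2_S` of which `3/4 sigma2_A`
#' sits inside `sigma2_e`.
#'
#' @param n_sires number of test sires in the terminal generation.
#' @param pedigree_depth generations of sire-line ancestry (>= 1).
#' @param dams_per_sire,daughters_per_sire,cages_per_sire design constants
#'   d, n and m of the progeny test.
#' @param cage_size_range allowed cage sizes (min >= 3).
#' @param sigma2_S sire (transmitting-ability) variance of the feather-score
#'   liability.
#' @param sigma2_c random cage variance of the liability.
#' @param sigma2_e residual liability variance (includes 3/4 sigma2_A).
#' @param sigma2_S_surv sire variance of the survival liability.
#' @param r_g_fs_surv genetic correlation between the feather-score and
#'   survival liabilities, in [-1, 1]. Positive values mean that sires whose
#'   daughters feather badly also lose more daughters.
#' @param surv_rate_45,surv_rate_70 marginal survival probabilities at the
#'   two scoring ages (cumulative: dead at 45 wk implies dead at 70 wk).
#' @param fs_means named target mean scores used to calibrate the category
#'   thresholds (names BACK45, NECK45, BACK70, NECK70).
#' @param thresholds named list of length-2 threshold vectors per trait;
#'   computed from `fs_means` via [fs_thresholds()] when `NULL`.
#' @param rho_age correlation between the 45-wk and 70-wk residual
#'   liabilities of the same bird.
#' @param n_farms,n_rt_numbers,n_crosses,farms_per_batch,crosses_per_batch
#'   sizes of the cross-classified fixed-effect structure: each recurrent
#'   test batch (RT number) has one housing date and runs on a subset of
#'   farms with a subset of crosses.
#' @param sd_batch,sd_fdc standard deviations of the batch and
#'   farm-by-date-by-cross fixed effects on the liability scale.
#' @param feather_gene_freq allele frequency of the fast-feathering gene
#'   (scored per cage, as in the emulated records).
#' @param beta_feather_gene liability effect of the fast genotype.
#' @param seed integer seed governing all randomness.
#' @return object of class `rt_sim_config` (a validated list).
#' @export
sim_config <- function(n_sires = 200,
                       pedigree_depth = 4,
                       dams_per_sire = 20,
                       daughters_per_sire = 53,
                       cages_per_sire = 6,
                       cage_size_range = c(3, 22),
                       sigma2_S = 0.042,
                       sigma2_c = 0.15,
                       sigma2_e = 0.808,
                       sigma2_S_surv = 0.02,
                       r_g_fs_surv = 0.4,
                       surv_rate_45 = 0.98,
                       surv_rate_70 = 0.94,
                       fs_means = c(BACK45 = 11.32, NECK45 = 12.42,
                                    BACK70 = 13.98, NECK70 = 14.78),
                       thresholds = NULL,
                       rho_age = 0.5,
                       n_farms = 20,
                       n_rt_numbers = 8,
                       n_crosses = 4,
                       farms_per_batch = 5,
                       crosses_per_batch = 2,
                       sd_batch = 0.25,
                       sd_fdc = 0.15,
                       feather_gene_freq = 0.5,
                       beta_feather_gene = 0.15,
                       seed = 1) {
  cfg <- as.list(environment())
  if (is.null(thresholds)) {
    cfg$thresholds <- lapply(as.list(fs_means), fs_thresholds)
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_sires < 1) stop("invalid config: n_sires must be >= 1")
    if (pedigree_depth < 1) stop("invalid config: pedigree_depth must be >= 1")
    vars <- c(sigma2_S, sigma2_c, sigma2_e, sigma2_S_surv)
    if (any(vars < 0)) stop("invalid config: variances must be >= 0")
    if (abs(r_g_fs_surv) > 1) stop("invalid config: |r_g_fs_surv| must be <= 1")
    if (cage_size_range[1] < 3 || cage_size_range[2] < cage_size_range[1])
      stop("invalid config: cage_size_range must satisfy 3 <= min <= max")
    mean_size <- daughters_per_sire / cages_per_sire
    if (mean_size < cage_size_range[1] || mean_size > cage_size_range[2])
      stop("invalid config: mean cage size outside cage_size_range")
    if (any(surv_rate_45 <= 0, surv_rate_45 > 1, surv_rate_70 <= 0,
            surv_rate_70 > surv_rate_45))
      stop("invalid config: survival rates must satisfy 0 < s70 <= s45 <= 1")
  })
  for (th in cfg$thresholds) {
    if (length(th) != 2 || diff(th) <= 0)
      stop("invalid config: thresholds must be two increasing cutpoints")
  }
  structure(cfg, class = "rt_sim_config")
}

#' @export
print.rt_sim_config <- function(x, ...) {
  cat("Recurrent-testing simulation config\n")
  cat(sprintf("  %d sires x %d cages x ~%.1f birds (pedigree depth %d)\n",
              x$n_sires, x$cages_per_sire,
              x$daughters_per_sire / x$cages_per_sire, x$pedigree_depth))
  cat(sprintf("  liability variances: sire %.4g, cage %.4g, residual %.4g (sigma2_A = %.4g)\n",
              x$sigma2_S, x$sigma2_c, x$sigma2_e, 4 * x$sigma2_S))
  cat(sprintf("  survival: %.3g / %.3g, genetic correlation with FS %.2f\n",
              x$surv_rate_45, x$surv_rate_70, x$r_g_fs_surv))
  invisible(x)
}

#' Read a simulator configuration from a YAML-style key-value file
#'
#' Accepts a flat `key: value` file with the fields of [sim_config()];
#' unknown keys are an error. `fs_means` and `cage_size_range` may be given
#' as comma-separated values.
#'
#' @param path file to read.
#' @return `rt_sim_config` object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = ":"), ""))
  defaults <- formals(sim_config)
  bad <- setdiff(keys, names(defaults))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(trimws(v)))
    args[[keys[i]]] <- if (anyNA(num)) trimws(v) else num
  }
  if (!is.null(args$fs_means)) {
    names(args$fs_means) <- c("BACK45", "NECK45", "BACK70", "NECK70")
  }
  do.call(sim_config, args)
}
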