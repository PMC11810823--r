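#' Simulate a sire-line pedigree for the progeny test
#'
#' Builds `pedigree_depth` generations of sire-line ancestry: the terminal
#' generation holds the `n_sires` test sires, each earlier generation a pool
#' of males and females from which parents are drawn at random. With
#' `pedigree_depth = 1` the test sires are unrelated founders. Commercial
#' daughters are not included here; [extend_pedigree()] appends them with
#' unknown dams.
#'
#' @param config [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed`.
#' @return data.frame with columns `id`, `sire`, `dam`, `generation`,
#'   `is_test_sire`, ordered parents first.
#' @export
simulate_pedigree <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "rt_sim_config"))
  if (config$n_sires < 1) stop("invalid config: n_sires must be >= 1")
  set.seed(seed)
  depth <- config$pedigree_depth
  n_sires <- config$n_sires
  # ancestor pool sizes: enough for diversity, small relative to test sires
  n_pool <- max(5L, ceiling(n_sires / 4))
  ped <- list()
  prev_m <- prev_f <- character(0)
  if (depth > 1) {
    for (g in seq_len(depth - 1L)) {
      m_ids <- sprintf("G%dM%03d", g, seq_len(n_pool))
      f_ids <- sprintf("G%dF%03d", g, seq_len(n_pool))
      if (g == 1L) {
        sire_m <- dam_m <- rep(NA_character_, n_pool)
        sire_f <- dam_f <- rep(NA_character_, n_pool)
      } else {
        sire_m <- sample(prev_m, n_pool, replace = TRUE)
        dam_m <- sample(prev_f, n_pool, replace = TRUE)
        sire_f <- sample(prev_m, n_pool, replace = TRUE)
        dam_f <- sample(prev_f, n_pool, replace = TRUE)
      }
      ped[[g]] <- data.frame(
        id = c(m_ids, f_ids), sire = c(sire_m, sire_f), dam = c(dam_m, dam_f),
        generation = g, is_test_sire = FALSE, stringsAsFactors = FALSE)
      prev_m <- m_ids; prev_f <- f_ids
    }
  }
  s_ids <- sprintf("S%04d", seq_len(n_sires))
  if (depth > 1) {
    s_sire <- sample(prev_m, n_sires, replace = TRUE)
    s_dam <- sample(prev_f, n_sires, replace = TRUE)
  } else {
    s_sire <- s_dam <- rep(NA_character_, n_sires)
  }
  ped[[depth]] <- data.frame(id = s_ids, sire = s_sire, dam = s_dam,
                             generation = depth, is_test_sire = TRUE,
                             stringsAsFactors = FALSE)
  do.call(rbind, ped)
}

#' Append commercial daughters to a sire pedigree
#'
#' Daughters have a known sire and an unknown dam (single unidentified dam
#' line), so they enter the relationship matrix as non-inbred half-sibs.
#'
#' @param pedigree output of [simulate_pedigree()].
#' @param individuals individual records with `animal_id` and `sire_id`.
#' @return combined pedigree data.frame.
#' @export
extend_pedigree <- function(pedigree, individuals) {
  kids <- data.frame(id = individuals$animal_id, sire = individuals$sire_id,
                     dam = NA_character_,
                     generation = max(pedigree$generation) + 1L,
                     is_test_sire = FALSE, stringsAsFactors = FALSE)
  rbind(pedigree, kids)
}

# Breeding values down the pedigree: founders N(0, G0), offspring
# parent average + Mendelian sampling N(0, d_i G0); G0 is the 2x2 additive
# covariance of the FS and survival liabilities (animal scale).
sim_breeding_values <- function(pedigree, G0) {
  px <- ped_index(pedigree)
  n <- length(px$ids)
  F <- inbreeding(pedigree)
  # PSD square root (chol would reject zero-variance components)
  eg <- eigen(G0, symmetric = TRUE)
  rootG <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  bv <- matrix(0, n, 2)
  z <- matrix(stats::rnorm(2 * n), n, 2) %*% rootG
  for (i in seq_len(n)) {
    si <- px$sire[i]; di <- px$dam[i]
    pa <- c(0, 0)
    d_i <- 1
    if (!is.na(si) && !is.na(di)) {
      pa <- (bv[si, ] + bv[di, ]) / 2
      d_i <- 0.5 - 0.25 * (F[si] + F[di])
    } else if (!is.na(si)) {
      pa <- bv[si, ] / 2
      d_i <- 0.75 - 0.25 * F[si]
    } else if (!is.na(di)) {
      pa <- bv[di, ] / 2
      d_i <- 0.75 - 0.25 * F[di]
    }
    bv[i, ] <- pa + sqrt(d_i) * z[i, ]
  }
  rownames(bv) <- px$ids
  colnames(bv) <- c("fs", "surv")
  bv
}

# Shift two standard-normal cutpoints so that, averaged over the realized
# per-bird fixed-effect offsets, the expected category frequencies equal the
# targets implied by the config thresholds. Keeps realized trait means on
# target despite the extra between-group variance the fixed effects add.
calibrate_thresholds <- function(thresholds, offsets, sd_rand = 1) {
  p_hi <- stats::pnorm(thresholds[2], lower.tail = FALSE)      # P(score 20)
  p_mid_hi <- stats::pnorm(thresholds[1], lower.tail = FALSE)  # P(score >= 15)
  solve_cut <- function(p_target) {
    stats::uniroot(function(t) mean(stats::pnorm((t - offsets) / sd_rand,
                                                 lower.tail = FALSE)) - p_target,
                   interval = c(-15, 15) * max(1, sd_rand), tol = 1e-10)$root
  }
  c(solve_cut(p_mid_hi), solve_cut(p_hi))
}

#' Simulate the recurrent-test population
#'
#' For each test sire, daughters are placed in `cages_per_sire` all-half-sib
#' cages. Each bird's feather-score liability at a scoring age is the sum of
#' cage-level fixed effects (test batch, farm-by-date-by-cross, feathering
#' gene), the sire transmitting ability, a random cage effect and a residual;
#' the three-level score is obtained by cutting the liability at two
#' thresholds calibrated to the configured trait means. A survival liability
#' sharing sire effects with the feather score (genetic correlation
#' `r_g_fs_surv`) determines which birds are alive at 45 and 70 weeks;
#' mortality is cumulative and dead birds have missing scores at that age.
#'
#' @param config [sim_config()] object.
#' @param pedigree pedigree containing the test sires (see
#'   [simulate_pedigree()]).
#' @param seed integer seed; defaults to `config$seed + 1`.
#' @param keep_liability if `TRUE`, the latent continuous liabilities are
#'   kept as columns `liab_45` / `liab_70` (useful to fit models on a
#'   correctly specified Gaussian trait).
#' @return data.frame of individual records (one row per bird) with score
#'   columns `fs_BACK45` ... `fs_NECK70` (values 10/15/20 or NA when dead)
#'   and survival codes `surv_45`, `surv_70` (2 = alive, 1 = dead). True sire
#'   transmitting abilities, cage effects and the calibrated thresholds are
#'   attached as `attr(x, "truth")`.
#' @export
simulate_population <- function(config, pedigree, seed = config$seed + 1,
                                keep_liability = FALSE) {
  stopifnot(inherits(config, "rt_sim_config"))
  for (th in config$thresholds) {
    if (diff(th) <= 0) stop("invalid config: thresholds must be increasing")
  }
  set.seed(seed)
  sires <- pedigree$id[pedigree$is_test_sire]
  if (!length(sires)) stop("pedigree contains no test sires")
  n_sires <- length(sires)

  # true breeding values (animal scale) -> transmitting abilities
  sA_fs <- sqrt(4 * config$sigma2_S)
  sA_sv <- sqrt(4 * config$sigma2_S_surv)
  G0 <- matrix(c(sA_fs^2, config$r_g_fs_surv * sA_fs * sA_sv,
                 config$r_g_fs_surv * sA_fs * sA_sv, sA_sv^2), 2, 2)
  bv <- sim_breeding_values(pedigree, G0)
  ta_fs <- bv[sires, "fs"] / 2
  ta_sv <- bv[sires, "surv"] / 2

  # cage layout
  m <- config$cages_per_sire
  n_cages <- n_sires * m
  mean_size <- config$daughters_per_sire / m
  rng <- config$cage_size_range
  span <- rng[2] - rng[1]
  p_size <- (mean_size - rng[1]) / span
  cage_size <- rng[1] + stats::rbinom(n_cages, span, p_size)

  # cross-classified fixed structure: batch -> date, farms, crosses
  batches <- seq_len(config$n_rt_numbers)
  batch_date <- format(as.Date("2014-01-15") + (batches - 1) * 91)
  batch_farms <- lapply(batches, function(b)
    sample.int(config$n_farms, min(config$farms_per_batch, config$n_farms)))
  batch_crosses <- lapply(batches, function(b)
    sample.int(config$n_crosses, min(config$crosses_per_batch, config$n_crosses)))
  beta_batch <- stats::rnorm(length(batches), 0, config$sd_batch)

  cage_batch <- sample(batches, n_cages, replace = TRUE)
  cage_farm <- vapply(cage_batch, function(b) {
    f <- batch_farms[[b]]; f[sample.int(length(f), 1L)]
  }, 1L)
  cage_cross <- vapply(cage_batch, function(b) {
    cc <- batch_crosses[[b]]; cc[sample.int(length(cc), 1L)]
  }, 1L)
  cage_gene <- ifelse(stats::runif(n_cages) < config$feather_gene_freq,
                      "fast", "slow")
  fdc <- sprintf("F%02d.%s.X%d", cage_farm, batch_date[cage_batch], cage_cross)
  beta_fdc <- stats::rnorm(length(unique(fdc)), 0, config$sd_fdc)
  names(beta_fdc) <- unique(fdc)
  cage_offset <- beta_batch[cage_batch] + beta_fdc[fdc] +
    ifelse(cage_gene == "fast", config$beta_feather_gene, 0)
  cage_effect <- stats::rnorm(n_cages, 0, sqrt(config$sigma2_c))
  cage_sire <- rep(sires, each = m)
  cage_id <- sprintf("C%05d", seq_len(n_cages))

  # individual records
  n_birds <- sum(cage_size)
  bird_cage <- rep(seq_len(n_cages), cage_size)
  offsets <- cage_offset[bird_cage]
  e45 <- stats::rnorm(n_birds, 0, sqrt(config$sigma2_e))
  e70 <- config$rho_age * e45 +
    sqrt(1 - config$rho_age^2) * stats::rnorm(n_birds, 0, sqrt(config$sigma2_e))
  s_fs_bird <- ta_fs[cage_sire[bird_cage]]
  liab45 <- offsets + s_fs_bird + cage_effect[bird_cage] + e45
  liab70 <- offsets + s_fs_bird + cage_effect[bird_cage] + e70

  # survival: cumulative, shares sire genetics with FS
  sd_es <- sqrt(1 - config$sigma2_S_surv)
  s_sv_bird <- ta_sv[cage_sire[bird_cage]]
  l_s45 <- s_sv_bird + stats::rnorm(n_birds, 0, sd_es)
  l_s70 <- s_sv_bird + stats::rnorm(n_birds, 0, sd_es)
  alive45 <- l_s45 < stats::qnorm(config$surv_rate_45)
  alive70 <- alive45 &
    (l_s70 < stats::qnorm(config$surv_rate_70 / config$surv_rate_45))

  # score categories, thresholds recalibrated for realized fixed offsets
  sd_rand <- sqrt(config$sigma2_S + config$sigma2_c + config$sigma2_e)
  th_cal <- list()
  score_of <- function(liab, th) {
    c(10, 15, 20)[1L + findInterval(liab, th)]
  }
  ind <- data.frame(
    animal_id = sprintf("D%06d", seq_len(n_birds)),
    cage_id = cage_id[bird_cage],
    sire_id = cage_sire[bird_cage],
    rt_number = sprintf("RT%02d", cage_batch[bird_cage]),
    farm = sprintf("F%02d", cage_farm[bird_cage]),
    cross = sprintf("X%d", cage_cross[bird_cage]),
    housing_date = batch_date[cage_batch[bird_cage]],
    fdc = fdc[bird_cage],
    feather_gene = cage_gene[bird_cage],
    stringsAsFactors = FALSE)
  for (trait in names(config$thresholds)) {
    age <- if (grepl("45$", trait)) "45" else "70"
    liab <- if (age == "45") liab45 else liab70
    alive <- if (age == "45") alive45 else alive70
    th <- calibrate_thresholds(config$thresholds[[trait]], offsets, sd_rand)
    th_cal[[trait]] <- th
    sc <- score_of(liab, th)
    sc[!alive] <- NA_integer_
    ind[[paste0("fs_", trait)]] <- sc
  }
  ind$surv_45 <- ifelse(alive45, 2L, 1L)
  ind$surv_70 <- ifelse(alive70, 2L, 1L)
  if (keep_liability) {
    ind$liab_45 <- ifelse(alive45, liab45, NA_real_)
    ind$liab_70 <- ifelse(alive70, liab70, NA_real_)
  }
  attr(ind, "truth") <- list(
    sires = data.frame(sire_id = sires, s_fs = unname(ta_fs),
                       s_surv = unname(ta_sv), stringsAsFactors = FALSE),
    cages = data.frame(cage_id = cage_id, sire_id = cage_sire,
                       cage_effect = cage_effect, offset = cage_offset,
                       stringsAsFactors = FALSE),
    thresholds = th_cal)
  ind
}

#' Rebuild individual records from per-cage score counts
#'
#' The raw recurrent-test records give, for each cage, the number of birds
#' with each score rather than bird-level scores. Because all cage members
#' share the same pedigree (same sire, unknown dams, no offspring), assigning
#' the scores to random surviving members yields a dataset fully equivalent
#' for genetic analysis. Dead birds get a missing score.
#'
#' @param counts data.frame with columns `cage_id`, `n10`, `n15`, `n20`,
#'   `n_dead`; any additional columns (sire, fixed effects) are carried
#'   through to every member of the cage.
#' @param seed integer seed for the random allocation.
#' @return data.frame with one row per bird: `cage_id`, `member`, `fs`
#'   (10/15/20 or NA), `surv` (2 alive / 1 dead), plus carried columns.
#' @export
make_individual_dataset <- function(counts, seed = 1) {
  req <- c("cage_id", "n10", "n15", "n20", "n_dead")
  stopifnot(all(req %in% names(counts)))
  cnt <- as.matrix(counts[, c("n10", "n15", "n20", "n_dead")])
  if (any(cnt < 0)) stop("data error: negative score counts")
  set.seed(seed)
  extra <- setdiff(names(counts), c("n10", "n15", "n20", "n_dead"))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n_alive <- sum(cnt[i, 1:3])
    n_total <- n_alive + cnt[i, 4]
    scores <- rep(c(10L, 15L, 20L), cnt[i, 1:3])
    member_scores <- rep(NA_integer_, n_total)
    alive_members <- sample.int(n_total, n_alive)
    member_scores[alive_members] <- sample(scores, n_alive)
    out <- counts[rep(i, n_total), extra, drop = FALSE]
    out$member <- seq_len(n_total)
    out$fs <- member_scores
    out$surv <- ifelse(is.na(member_scores), 1L, 2L)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Tabulate per-cage score counts from individual records
#'
#' Inverse of [make_individual_dataset()]: collapses bird-level scores of one
#' trait into the count format of the raw records.
#'
#' @param individuals output of [simulate_population()].
#' @param trait one of `"BACK45"`, `"NECK45"`, `"BACK70"`, `"NECK70"`.
#' @return data.frame with `cage_id`, `sire_id`, `n10`, `n15`, `n20`,
#'   `n_dead`.
#' @export
tabulate_cage_scores <- function(individuals, trait = "BACK45") {
  fs <- individuals[[paste0("fs_", trait)]]
  if (is.null(fs)) stop("unknown trait: ", trait)
  cg <- factor(individuals$cage_id, levels = unique(individuals$cage_id))
  data.frame(
    cage_id = levels(cg),
    sire_id = individuals$sire_id[!duplicated(individuals$cage_id)],
    n10 = as.vector(tapply(fs, cg, function(x) sum(x == 10, na.rm = TRUE))),
    n15 = as.vector(tapply(fs, cg, function(x) sum(x == 15, na.rm = TRUE))),
    n20 = as.vector(tapply(fs, cg, function(x) sum(x == 20, na.rm = TRUE))),
    n_dead = as.vector(tapply(fs, cg, function(x) sum(is.na(x)))),
    stringsAsFactors = FALSE)
}

#' Build the cage-level working dataset
#'
#' One record per cage: the mean score of the survivors for every trait, the
#' survival fraction (birds alive at scoring / original cage size) at both
#' ages, and the id of one random cage member used by the cage-level animal
#' model. Cages with no survivors at an age keep their survival record but
#' have a missing mean score.
#'
#' @param individuals output of [simulate_population()] (or any data.frame
#'   with the same columns).
#' @param seed integer seed for drawing the representative member.
#' @return data.frame of cage records.
#' @export
make_cage_dataset <- function(individuals, seed = 1) {
  set.seed(seed)
  cg <- factor(individuals$cage_id, levels = unique(individuals$cage_id))
  first <- !duplicated(individuals$cage_id)
  keep_cols <- intersect(c("sire_id", "rt_number", "farm", "cross",
                           "housing_date", "fdc", "feather_gene"),
                         names(individuals))
  out <- data.frame(cage_id = levels(cg), stringsAsFactors = FALSE)
  out[keep_cols] <- individuals[first, keep_cols]
  out$n_original <- as.vector(table(cg))
  for (age in c("45", "70")) {
    sv <- individuals[[paste0("surv_", age)]]
    alive <- as.vector(tapply(sv == 2L, cg, sum))
    out[[paste0("n_alive_", age)]] <- alive
    out[[paste0("surv_frac_", age)]] <- alive / out$n_original
  }
  mean_cols <- grep("^(fs|liab)_", names(individuals), value = TRUE)
  for (col in mean_cols) {
    out[[paste0("mean_", col)]] <-
      as.vector(tapply(individuals[[col]], cg,
                       function(x) if (all(is.na(x))) NA_real_
                       else mean(x, na.rm = TRUE)))
  }
  # one random member per cage (for the cage-level animal model)
  idx <- split(seq_len(nrow(individuals)), cg)
  out$representative_animal_id <- vapply(idx[levels(cg)], function(i)
    individuals$animal_id[i[sample.int(length(i), 1L)]], "")
  out
}

#' Simulate a complete recurrent-test study
#'
#' Orchestrates pedigree, population and both working datasets from a single
#' config; the config seed is expanded into independent child seeds per
#' stage so stages are individually reproducible.
#'
#' @param config [sim_config()] object.
#' @param keep_liability see [simulate_population()].
#' @return list of class `rt_sim` with elements `config`, `pedigree`
#'   (including daughters), `individuals`, `cages`, `truth` and `seeds`.
#' @export
simulate_rt_data <- function(config = sim_config(), keep_liability = FALSE) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4L)
  ped <- simulate_pedigree(config, seed = seeds[1])
  ind <- simulate_population(config, ped, seed = seeds[2],
                             keep_liability = keep_liability)
  cages <- make_cage_dataset(ind, seed = seeds[3])
  structure(list(config = config, pedigree = extend_pedigree(ped, ind),
                 individuals = ind, cages = cages,
                 truth = attr(ind, "truth"), seeds = seeds),
            class = "rt_sim")
}

#' @export
print.rt_sim <- function(x, ...) {
  cat(sprintf("Recurrent-test simulation: %d birds in %d cages, %d test sires\n",
              nrow(x$individuals), nrow(x$cages),
              sum(x$pedigree$is_test_sire)))
  cat(sprintf("  realized survival: %.3f (45 wk), %.3f (70 wk)\n",
              mean(x$individuals$surv_45 == 2L),
              mean(x$individuals$surv_70 == 2L)))
  invisible(x)
}

#' Write the simulated datasets as CSV files
#'
#' @param sim `rt_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_rt_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("pedigree.csv", "individuals.csv", "cages.csv"))
  utils::write.csv(sim$pedigree, paths[1], row.names = FALSE)
  utils::write.csv(sim$individuals, paths[2], row.names = FALSE)
  utils::write.csv(sim$cages, paths[3], row.names = FALSE)
  invisible(paths)
}
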