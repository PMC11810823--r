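#' Assign cages to cross-validation folds
#'
#' Partitions the cages into `k` near-equal folds (sizes differ by at most
#' one). The assignment depends only on the cage list, `k` and `seed`, so it
#' is identical across all models and traits of one comparison.
#'
#' @param cages cage-level data.frame (or vector of cage ids).
#' @param k number of folds.
#' @param seed integer seed.
#' @return data.frame with `cage_id` and `fold`.
#' @export
assign_folds <- function(cages, k = 10, seed = 1) {
  ids <- if (is.data.frame(cages)) as.character(cages$cage_id)
         else as.character(cages)
  if (k < 2) stop("invalid k: need at least 2 folds")
  if (length(ids) < k) stop("fewer cages than folds")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(ids)))
  data.frame(cage_id = ids, fold = fold, stringsAsFactors = FALSE)
}

#' Pre-corrected cage phenotypes (validation proxies)
#'
#' Computes the cage-average residuals of a fixed-effects-only linear model
#' for one feather-score trait on the complete cage-level dataset. These
#' residuals serve as proxies for the true sire effects when validating
#' estimated sire effects against masked cages.
#'
#' @param cages complete (unmasked) cage-level dataset.
#' @param trait feather-score trait, e.g. `"BACK45"`.
#' @param fixed one-sided formula of fixed effects; default the standard
#'   structure (RT number, farm-by-date-by-cross, feathering gene).
#' @return data.frame with `cage_id` and `y_obs` (NA for cages without a
#'   defined mean score).
#' @export
precorrect <- function(cages, trait = "BACK45",
                       fixed = ~ rt_number + fdc + feather_gene) {
  cand <- c(paste0("mean_fs_", trait), paste0("mean_", trait), trait)
  col <- cand[cand %in% names(cages)][1]
  if (is.na(col)) stop("trait column not found for '", trait, "'")
  dat <- cages
  dat$.y <- dat[[col]]
  keep <- character(0)
  for (v in all.vars(fixed)) {
    dat[[v]] <- factor(dat[[v]])
    if (nlevels(dat[[v]]) > 1) keep <- c(keep, v)
  }
  fml <- if (length(keep)) {
    stats::reformulate(keep, response = ".y")
  } else {
    .y ~ 1
  }
  fit <- stats::lm(fml, data = dat, na.action = stats::na.exclude)
  data.frame(cage_id = as.character(cages$cage_id),
             y_obs = unname(stats::resid(fit)), stringsAsFactors = FALSE)
}

#' Correlation between true sire effects and cage proxies
#'
#' The fraction of variance in the pre-corrected cage-average phenotype
#' explained by the sire effect, under the half-sib cage design:
#' `r = sqrt( s2A/4 / (s2A/4 + s2c + (3/4 s2A + s2e) / n_bar) )`,
#' where `s2A/4` is the sire (transmitting-ability) variance common to all
#' cage members, and the dam plus Mendelian-sampling variance `3/4 s2A` and
#' the residual are averaged over the `n_bar` cage members.
#'
#' @param sigma2_A additive genetic variance (individual scale).
#' @param sigma2_c random cage variance.
#' @param sigma2_e individual residual variance (excluding `3/4 sigma2_A`).
#' @param n_bar mean cage size, computed from the realized data.
#' @return scalar in (0, 1].
#' @export
r_true_proxy <- function(sigma2_A, sigma2_c, sigma2_e, n_bar) {
  if (sigma2_A < 0 || sigma2_c < 0 || sigma2_e < 0)
    stop("variance components must be non-negative")
  if (sigma2_A + sigma2_c + sigma2_e == 0)
    stop("undefined: all variance components are zero")
  num <- sigma2_A / 4
  den <- num + sigma2_c + (0.75 * sigma2_A + sigma2_e) / n_bar
  sqrt(num / den)
}

# Map a fitted model's components onto r(s1, Ybar_obs). For individual-level
# fits this evaluates the half-sib formula; for cage-level fits the sire
# variance and cage-level residual already partition var(Ybar_obs) directly.
r_true_proxy_from_fit <- function(fit, n_bar) {
  g <- fit$varcomp$G0[1, 1]
  e <- fit$varcomp$R0[1, 1]
  cc <- if (!is.null(fit$varcomp$C0)) fit$varcomp$C0[1, 1] else 0
  if (fit$spec$level == "individual") {
    if (fit$spec$genetic == "animal") {
      r_true_proxy(g, cc, e - 0.75 * g, n_bar)
    } else {
      # sire parameterization: residual already contains 3/4 sigma2_A
      sqrt(g / (g + cc + e / n_bar))
    }
  } else {
    if (fit$spec$genetic == "animal") {
      # cage record on one member: sire share of its genetic variance is 1/4
      sqrt((g / 4) / (g + e))
    } else {
      sqrt(g / (g + e))
    }
  }
}

#' Per-fold accuracy ingredients
#'
#' Pearson correlation between estimated sire effects and the pre-corrected
#' phenotypes of the masked cages. Final accuracy is the marginal mean of
#' these correlations across folds divided by the marginal mean of
#' `r(s1, Ybar_obs)` (see [r_true_proxy()]).
#'
#' @param s_hat data.frame with `sire_id`, `s_hat` (from [sire_effects()]).
#' @param proxies data.frame with `cage_id`, `sire_id`, `y_obs` for the
#'   masked cages.
#' @return Pearson correlation over the masked cages, or NA if fewer than 3
#'   masked cages have a defined proxy.
#' @export
fold_accuracy <- function(s_hat, proxies) {
  m <- merge(proxies, s_hat, by = "sire_id")
  m <- m[!is.na(m$y_obs), ]
  if (nrow(m) < 3) return(NA_real_)
  stats::cor(m$s_hat, m$y_obs)
}

#' Dispersion of estimated sire effects
#'
#' Ordinary least-squares slope of the masked pre-corrected cage phenotypes
#' on the estimated sire effects. For correctly dispersed BLUP the expected
#' slope is one; slopes below one indicate over-dispersion of the estimates.
#'
#' @inheritParams fold_accuracy
#' @return OLS slope, or NA if the sire effects have no variance or fewer
#'   than 3 masked cages have a defined proxy.
#' @export
dispersion_slope <- function(s_hat, proxies) {
  m <- merge(proxies, s_hat, by = "sire_id")
  m <- m[!is.na(m$y_obs), ]
  if (nrow(m) < 3 || stats::sd(m$s_hat) == 0) return(NA_real_)
  unname(stats::coef(stats::lm(y_obs ~ s_hat, data = m))[2])
}

#' Expected (theoretical) accuracy of each model family
#'
#' Square root of the reliability implied by the estimated variance
#' components and the progeny-test design constants: `d` dams per sire, `n`
#' daughters per sire and `m` cages per sire (for cage-level models the
#' records are cage averages, so effectively n = m).
#'
#' Individual-level animal models:
#' `R2 = (s2A/4) / (s2A/4 + s2A/(4d) + s2A/(2n) + s2e/n + s2c/m)`.
#' Individual-level sire model (residual contains `3/4 s2A`):
#' `R2 = s2S / (s2S + s2S/d + 2 s2S/n + (s2e - 3 s2S)/n + s2c/m)`.
#' Cage-level animal model: `R2 = (s2A/4) / (s2A/4 + (3/4 s2A + s2e)/m)`.
#' Cage-level sire models: `R2 = s2S / (s2S + s2e/m)`.
#'
#' @param model model name or [model_spec()].
#' @param varcomp list with `G0`, optional `C0`, `R0` (as in an `rt_fit`),
#'   or an `rt_fit` object.
#' @param d,n,m design constants (defaults follow the emulated design).
#' @return expected accuracy `sqrt(R2)` in (0, 1).
#' @export
expected_accuracy <- function(model, varcomp, d = 20, n = 53, m = 6) {
  spec <- as_model_spec(model)
  if (inherits(varcomp, "rt_fit")) varcomp <- varcomp$varcomp
  if (any(c(d, n, m) <= 0)) stop("design constants d, n, m must be positive")
  g <- as.matrix(varcomp$G0)[1, 1]
  e <- as.matrix(varcomp$R0)[1, 1]
  cc <- if (!is.null(varcomp$C0)) as.matrix(varcomp$C0)[1, 1] else 0
  R2 <- if (spec$level == "individual") {
    if (spec$genetic == "animal") {
      (g / 4) / (g / 4 + g / (4 * d) + g / (2 * n) + e / n + cc / m)
    } else {
      res <- (e - 3 * g) / n
      if (e < 3 * g) stop("inconsistent components: sigma2_e < 3 sigma2_S")
      g / (g + g / d + 2 * g / n + res + cc / m)
    }
  } else {
    if (spec$genetic == "animal") {
      (g / 4) / (g / 4 + (0.75 * g + e) / m)
    } else {
      g / (g + e / m)
    }
  }
  sqrt(R2)
}

#' Ratio of total heritable variance to phenotypic variance
#'
#' `T2 = s2A / s2P` for animal models and `T2 = 4 s2S / s2P` for sire
#' models. The phenotypic variance is the sum of the genetic, cage (when
#' fitted) and residual components; because cage-level records average the
#' dam, Mendelian-sampling and residual parts over cage members, cage-level
#' phenotypic variances are smaller and their T2 larger.
#'
#' @param fit an `rt_fit` object (or list with `varcomp` and `spec`).
#' @return scalar T2 >= 0.
#' @export
total_heritable_ratio <- function(fit) {
  g <- fit$varcomp$G0[1, 1]
  e <- fit$varcomp$R0[1, 1]
  cc <- if (!is.null(fit$varcomp$C0)) fit$varcomp$C0[1, 1] else 0
  s2P <- g + cc + e
  if (s2P <= 0) stop("undefined: phenotypic variance is zero")
  if (fit$spec$genetic == "sire") 4 * g / s2P else g / s2P
}

#' Cage-masked k-fold cross-validation of the evaluation models
#'
#' Implements the validation design: cages are partitioned into `k` folds;
#' for each fold the phenotypes of its cages are masked (all traits), each
#' model is refitted on the training data, and the estimated sire effects
#' are compared to the masked cages' pre-corrected phenotypes. Per fold and
#' model this yields the correlation `r(s_hat, Ybar_obs)`, the dispersion
#' slope `b(Ybar_obs, s_hat)`, the total-heritable-variance ratio T2 and the
#' correction `r(s1, Ybar_obs)`; accuracy is the ratio of marginal means
#' (see [fold_accuracy()]).
#'
#' @param sim `rt_sim` object from [simulate_rt_data()].
#' @param models character vector of model names to compare.
#' @param trait feather-score trait.
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @param vc_source model whose per-fold variance components feed
#'   `r(s1, Ybar_obs)`: a model name (default `"IBAM"`, refitted per fold if
#'   not among `models`) or `"fit"` to reuse each model's own components
#'   (the choice shifts all models' accuracies by a common factor and does
#'   not affect their comparison).
#' @param d,n design constants reported alongside (defaults from the
#'   simulation config).
#' @return object of class `rt_validation`: `$folds` (per model x fold
#'   metrics), `$summary` (per-model marginal means via [emmean_compare()]),
#'   `$accuracy` (per-model accuracy estimates), `$n_bar`, `$fold_map`.
#' @export
cross_validate <- function(sim, models = "CUSiM", trait = "BACK45", k = 10,
                           seed = 1, vc_source = "IBAM",
                           d = sim$config$dams_per_sire,
                           n = sim$config$daughters_per_sire) {
  stopifnot(inherits(sim, "rt_sim"))
  fold_map <- assign_folds(sim$cages, k = k, seed = seed)
  proxies <- precorrect(sim$cages, trait)
  proxies$sire_id <- sim$cages$sire_id[match(proxies$cage_id,
                                             sim$cages$cage_id)]
  n_bar <- mean(sim$cages$n_original)
  sires <- sim$pedigree$id[sim$pedigree$is_test_sire]
  skipped <- 0L
  rows <- list()
  for (f in sort(unique(fold_map$fold))) {
    masked <- fold_map$cage_id[fold_map$fold == f]
    prox_f <- proxies[proxies$cage_id %in% masked & !is.na(proxies$y_obs), ]
    if (nrow(prox_f) < 3) { skipped <- skipped + 1L; next }
    train_ind <- sim$individuals[!sim$individuals$cage_id %in% masked, ]
    train_cage <- sim$cages[!sim$cages$cage_id %in% masked, ]
    fits <- list()
    fit_one <- function(mname) {
      spec <- model_spec(mname)
      dat <- if (spec$level == "cage") train_cage else train_ind
      reml_fit(dat, sim$pedigree, spec, trait, keep_ids = sires)
    }
    for (mname in models) fits[[mname]] <- fit_one(mname)
    r_s1 <- if (identical(vc_source, "fit")) {
      vapply(fits, r_true_proxy_from_fit, 1, n_bar = n_bar)
    } else {
      vc_fit <- if (vc_source %in% names(fits)) fits[[vc_source]]
                else fit_one(vc_source)
      rep(r_true_proxy_from_fit(vc_fit, n_bar), length(models))
    }
    for (i in seq_along(models)) {
      mname <- models[i]
      sh <- sire_effects(fits[[mname]], sires)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mname, fold = f,
        r_shat = fold_accuracy(sh, prox_f),
        slope = dispersion_slope(sh, prox_f),
        t2 = total_heritable_ratio(fits[[mname]]),
        r_s1 = r_s1[i], stringsAsFactors = FALSE)
    }
  }
  folds <- do.call(rbind, rows)
  acc <- accuracy_from_folds(folds)
  structure(list(folds = folds, accuracy = acc,
                 summary = list(
                   r_shat = emmean_compare(folds, "r_shat"),
                   slope = emmean_compare(folds, "slope", null = 1),
                   t2 = emmean_compare(folds, "t2")),
                 n_bar = n_bar, d = d, n = n, k = k,
                 fold_map = fold_map, skipped = skipped, trait = trait),
            class = "rt_validation")
}

accuracy_from_folds <- function(folds) {
  sp <- split(folds, folds$model)
  out <- do.call(rbind, lapply(sp, function(df) {
    data.frame(model = df$model[1],
               r_shat = mean(df$r_shat, na.rm = TRUE),
               r_s1 = mean(df$r_s1, na.rm = TRUE),
               accuracy = mean(df$r_shat, na.rm = TRUE) /
                 mean(df$r_s1, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Marginal-mean comparison of per-fold metrics across models
#'
#' Treats the fold as a blocking factor shared by all models (the training
#' sets are identical across models), fits `value ~ model + fold`, and
#' reports estimated marginal means per model with standard errors,
#' Tukey-adjusted pairwise comparisons and compact letter display. With
#' `null` given, each model mean is additionally tested against that value
#' (used for the dispersion slope's expected value of one).
#'
#' @param folds data.frame with columns `model`, `fold` and the metric.
#' @param metric name of the metric column.
#' @param null optional null value for one-sample contrasts per model.
#' @param alpha significance level for the letter grouping.
#' @return data.frame with `model`, `emmean`, `se`, `group` (letters) and,
#'   if `null` was given, `p_vs_null`.
#' @export
emmean_compare <- function(folds, metric = "r_shat", null = NULL,
                           alpha = 0.05) {
  df <- folds[!is.na(folds[[metric]]), c("model", "fold", metric)]
  names(df)[3] <- "value"
  df$model <- factor(df$model)
  df$fold <- factor(df$fold)
  if (nlevels(df$model) == 1L) {
    out <- data.frame(model = levels(df$model), emmean = mean(df$value),
                      se = stats::sd(df$value) / sqrt(nrow(df)),
                      group = "a", stringsAsFactors = FALSE)
    if (!is.null(null)) {
      tt <- stats::t.test(df$value, mu = null)
      out$p_vs_null <- tt$p.value
    }
    return(out)
  }
  fit <- stats::lm(value ~ model + fold, data = df)
  emm <- emmeans::emmeans(fit, "model")
  es <- as.data.frame(emm)
  prs <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "tukey"))
  out <- data.frame(model = as.character(es$model), emmean = es$emmean,
                    se = es$SE, stringsAsFactors = FALSE)
  out$group <- compact_letters(out$model, prs, alpha)
  if (!is.null(null)) {
    # one-sample contrast against the null per model, on the fold-to-fold
    # variability (the blocked-model SE only serves the model comparison)
    out$p_vs_null <- vapply(out$model, function(m)
      stats::t.test(df$value[df$model == m], mu = null)$p.value, 1)
  }
  out[order(out$model), , drop = FALSE]
}

# Compact letter display by the insert-and-absorb algorithm: models that do
# not differ significantly share at least one letter. `pairs_df` is the
# emmeans pairwise-contrast table (contrast strings "A - B").
compact_letters <- function(models, pairs_df, alpha = 0.05) {
  k <- length(models)
  sig <- matrix(FALSE, k, k, dimnames = list(models, models))
  cs <- strsplit(as.character(pairs_df$contrast), " - ", fixed = TRUE)
  for (i in seq_along(cs)) {
    a <- cs[[i]][1]; b <- cs[[i]][2]
    if (isTRUE(pairs_df$p.value[i] < alpha)) sig[a, b] <- sig[b, a] <- TRUE
  }
  groups <- list(models)
  for (a in models) for (b in models) {
    if (a < b && sig[a, b]) {
      hit <- vapply(groups, function(g) all(c(a, b) %in% g), TRUE)
      split_groups <- unlist(lapply(groups[hit], function(g)
        list(setdiff(g, a), setdiff(g, b))), recursive = FALSE)
      groups <- c(groups[!hit], split_groups)
      groups <- groups[lengths(groups) > 0]
      # absorb groups contained in (or duplicating) another group
      keep <- vapply(seq_along(groups), function(i)
        !any(vapply(seq_along(groups), function(j) {
          if (i == j) return(FALSE)
          sub <- all(groups[[i]] %in% groups[[j]])
          sub && (length(groups[[i]]) < length(groups[[j]]) || i > j)
        }, TRUE)), TRUE)
      groups <- groups[keep]
    }
  }
  groups <- groups[order(vapply(groups, function(g) match(g[1], models), 1))]
  out <- vapply(models, function(m) {
    paste(letters[which(vapply(groups, function(g) m %in% g, TRUE))],
          collapse = "")
  }, "")
  unname(out)
}

#' @export
print.rt_validation <- function(x, ...) {
  cat(sprintf("%d-fold cage-masked cross-validation, trait %s (n_bar = %.2f)\n",
              x$k, x$trait, x$n_bar))
  cat("\nAccuracy (EMMEAN r(s_hat, Y_obs) / EMMEAN r(s1, Y_obs)):\n")
  print(x$accuracy, row.names = FALSE)
  cat("\nDispersion slope (expected 1):\n")
  print(x$summary$slope, row.names = FALSE)
  invisible(x)
}
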