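# Dense-matrix REML oracle: builds V = ZGZ' + R explicitly and evaluates
# the restricted likelihood and GLS solutions by textbook formulas.
dense_oracle <- function(dat, ped, spec, trait, vc, fixed, trait2 = NULL) {
  A <- build_A(ped)
  n_tr <- if (spec$bivariate) 2 else 1
  ys <- cbind(dat[[trait]], if (n_tr == 2) dat[[trait2]])
  obs <- lapply(seq_len(n_tr), function(t) which(!is.na(ys[, t])))
  y <- unlist(lapply(seq_len(n_tr), function(t) ys[obs[[t]], t]))
  Xf <- model.matrix(fixed, dat)
  X <- as.matrix(Matrix::bdiag(lapply(obs, function(o) Xf[o, , drop = FALSE])))
  gcol <- if (spec$genetic == "sire") "sire_id" else "animal_id"
  gids <- rownames(A)
  gi <- match(dat[[gcol]], gids)
  Z <- as.matrix(Matrix::bdiag(lapply(obs, function(o) {
    Zt <- matrix(0, length(o), length(gids))
    Zt[cbind(seq_along(o), gi[o])] <- 1
    Zt
  })))
  V <- Z %*% kronecker(as.matrix(vc$G0), A) %*% t(Z)
  if (spec$cage_effect) {
    cg <- as.integer(factor(dat$cage_id))
    Zc <- as.matrix(Matrix::bdiag(lapply(obs, function(o) {
      Ct <- matrix(0, length(o), max(cg))
      Ct[cbind(seq_along(o), cg[o])] <- 1
      Ct
    })))
    V <- V + Zc %*% kronecker(as.matrix(vc$C0), diag(max(cg))) %*% t(Zc)
  }
  R0 <- as.matrix(vc$R0)
  n1 <- length(obs[[1]])
  Rm <- matrix(0, length(y), length(y))
  if (n_tr == 1) {
    diag(Rm) <- R0[1, 1]
  } else {
    for (i in seq_len(nrow(dat))) {
      p1 <- match(i, obs[[1]]); p2 <- n1 + match(i, obs[[2]])
      if (!is.na(p2)) Rm[p2, p2] <- R0[2, 2]
      if (!is.na(p1)) Rm[p1, p1] <- R0[1, 1]
      if (!is.na(p1) && !is.na(p2)) Rm[p1, p2] <- Rm[p2, p1] <- R0[1, 2]
    }
  }
  Vt <- V + Rm
  Vi <- solve(Vt)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  n <- length(y); p <- ncol(X)
  ll <- -0.5 * as.numeric(determinant(Vt, TRUE)$modulus +
                          determinant(XVX, TRUE)$modulus +
                          t(y) %*% P %*% y + (n - p) * log(2 * pi))
  b <- solve(XVX, t(X) %*% Vi %*% y)
  u <- kronecker(as.matrix(vc$G0), A) %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(loglik = ll, b = as.numeric(b), u = as.numeric(u), ids = gids)
}

biv_fixture <- function(seed = 7, n = 60) {
  set.seed(seed)
  ped <- data.frame(id = sprintf("S%d", 1:8),
                    sire = c(NA, NA, NA, "S1", "S1", "S2", "S2", "S3"),
                    dam = c(NA, NA, NA, "S3", "S3", NA, NA, NA))
  ped <- rbind(ped, data.frame(id = sprintf("A%02d", 1:n),
                               sire = sample(sprintf("S%d", 1:8), n, TRUE),
                               dam = NA))
  dat <- data.frame(animal_id = sprintf("A%02d", 1:n),
                    sire_id = ped$sire[match(sprintf("A%02d", 1:n), ped$id)],
                    cage_id = rep(sprintf("C%d", 1:12), length.out = n),
                    grp = rep(c("a", "b"), length.out = n),
                    stringsAsFactors = FALSE)
  dat$y1 <- rnorm(n) + ifelse(dat$grp == "a", 0, 0.5)
  dat$y2 <- rnorm(n) * 0.3 + 2
  dat$y1[sample(n, 10)] <- NA
  list(ped = ped, dat = dat,
       vc = list(G0 = matrix(c(0.3, 0.1, 0.1, 0.2), 2),
                 C0 = matrix(c(0.15, 0.03, 0.03, 0.1), 2),
                 R0 = matrix(c(1, 0.2, 0.2, 0.8), 2)))
}

test_that("restricted loglik matches a dense oracle (uni- and bivariate)", {
  fx <- biv_fixture()
  spec <- model_spec("IBSiM")
  ll <- restricted_loglik(fx$dat, fx$ped, spec, trait = "y1",
                          varcomp = fx$vc, fixed = ~grp, trait2 = "y2")
  orc <- dense_oracle(fx$dat, fx$ped, spec, "y1", fx$vc, ~grp, "y2")
  expect_equal(ll, orc$loglik, tolerance = 1e-10)

  # univariate animal model with cage effect
  vc1 <- list(G0 = matrix(0.25), C0 = matrix(0.1), R0 = matrix(0.9))
  spec1 <- model_spec("IUAM")
  dat1 <- fx$dat[!is.na(fx$dat$y1), ]
  ll1 <- restricted_loglik(dat1, fx$ped, spec1, trait = "y1",
                           varcomp = vc1, fixed = ~grp)
  orc1 <- dense_oracle(dat1, fx$ped, spec1, "y1", vc1, ~grp)
  expect_equal(ll1, orc1$loglik, tolerance = 1e-10)

  # permutation invariance
  perm <- sample(nrow(fx$dat))
  llp <- restricted_loglik(fx$dat[perm, ], fx$ped, spec, trait = "y1",
                           varcomp = fx$vc, fixed = ~grp, trait2 = "y2")
  expect_equal(ll, llp, tolerance = 1e-9)
})

test_that("MME solutions equal dense generalized least squares", {
  fx <- biv_fixture(seed = 3)
  spec <- model_spec("IBSiM")
  mme <- assemble_mme(fx$dat, fx$ped, spec, trait = "y1", varcomp = fx$vc,
                      fixed = ~grp, trait2 = "y2")
  orc <- dense_oracle(fx$dat, fx$ped, spec, "y1", fx$vc, ~grp, "y2")
  expect_equal(unname(unlist(mme$solution$fixed)), orc$b, tolerance = 1e-9)
  # compare on the ids the reduced model carries (oracle also predicts
  # effects for animals outside the sire model; BLUP is consistent on the
  # shared subset)
  ids <- names(mme$solution$genetic[[1]])
  pos <- c(match(ids, orc$ids), length(orc$ids) + match(ids, orc$ids))
  got_u <- c(mme$solution$genetic[[1]][ids], mme$solution$genetic[[2]][ids])
  expect_equal(unname(got_u), orc$u[pos], tolerance = 1e-9)
})

test_that("scalar MME shrinkage and the OLS limit hold", {
  ped <- data.frame(id = c("SA", "SB"), sire = NA, dam = NA)
  dat <- data.frame(cage_id = c("c1", "c2"), sire_id = c("SA", "SB"),
                    y = c(2, -1))
  vc <- list(G0 = matrix(1), R0 = matrix(1))
  mme <- assemble_mme(dat, ped, "CUSiM", trait = "y", varcomp = vc,
                      fixed = ~0)
  # lambda = 1: u = y / 2
  expect_equal(unname(mme$solution$genetic[[1]]), c(1, -0.5))

  # vanishing genetic variance: fixed solutions -> OLS
  fx <- biv_fixture(seed = 5)
  dat1 <- fx$dat[!is.na(fx$dat$y1), ]
  vc0 <- list(G0 = matrix(1e-10), R0 = matrix(1))
  mme0 <- assemble_mme(dat1, fx$ped, "CUSiM", trait = "y1", varcomp = vc0,
                       fixed = ~grp)
  ols <- coef(lm(y1 ~ grp, dat1))
  expect_equal(unname(mme0$solution$fixed[[1]]), unname(ols),
               tolerance = 1e-6)
})

test_that("REML equals the balanced one-way ANOVA estimator", {
  bs <- balanced_sire_data(s = 30, k = 10, seed = 2)
  fit <- reml_fit(bs$data, bs$pedigree, "CUSiM", trait = "y", fixed = ~1)
  ms <- anova(lm(y ~ sire_id, bs$data))$"Mean Sq"
  sigma2_P <- sum(fit$varcomp$G0[1, 1], fit$varcomp$R0[1, 1])
  expect_lt(abs(fit$varcomp$G0[1, 1] - (ms[1] - ms[2]) / 10),
            1e-4 * sigma2_P)
  expect_lt(abs(fit$varcomp$R0[1, 1] - ms[2]), 1e-4 * sigma2_P)
  expect_true(fit$converged)

  # the optimum really is an optimum
  ll_hat <- restricted_loglik(bs$data, bs$pedigree, "CUSiM", trait = "y",
                              varcomp = fit$varcomp, fixed = ~1)
  for (f in c(0.9, 1.1)) {
    vc <- list(G0 = fit$varcomp$G0 * f, R0 = fit$varcomp$R0 * f)
    expect_gte(ll_hat, restricted_loglik(bs$data, bs$pedigree, "CUSiM",
                                         trait = "y", varcomp = vc,
                                         fixed = ~1))
  }
})

test_that("null sire variance is estimated at the boundary", {
  for (seed in 1:3) {
    bs <- balanced_sire_data(s = 60, k = 8, sigma2_S = 0, seed = seed)
    fit <- reml_fit(bs$data, bs$pedigree, "CUSiM", trait = "y", fixed = ~1)
    expect_lt(fit$varcomp$G0[1, 1], 0.05 * fit$varcomp$R0[1, 1])
  }
})

test_that("in-sample BLUP solutions are shrunken, never over-dispersed", {
  bs <- balanced_sire_data(s = 40, k = 6, seed = 4)
  fit <- reml_fit(bs$data, bs$pedigree, "CUSiM", trait = "y", fixed = ~1)
  expect_lte(var(fit$genetic[[1]]), fit$varcomp$G0[1, 1] * (1 + 1e-8))
})

test_that("sire and animal parameterizations are equivalent", {
  sim <- small_sim()
  sires <- sim$pedigree$id[sim$pedigree$is_test_sire]
  f_s <- fit_model(sim, "CUSiM", "BACK45")
  f_a <- fit_model(sim, "CUAM", "BACK45")
  s_hat <- sire_effects(f_s, sires)$s_hat
  ebv <- sire_effects(f_a, sires, scale = "ebv")$s_hat
  expect_gte(cor(s_hat, ebv), 0.99)
  # animal EBVs are twice the sire effects; both regression directions
  expect_equal(unname(coef(lm(ebv ~ s_hat))[2]), 2, tolerance = 0.1)
  expect_equal(unname(coef(lm(s_hat ~ ebv))[2]), 0.5, tolerance = 0.05)
  # genetic variances map as sigma2_A ~= 4 sigma2_S
  expect_equal(f_a$varcomp$G0[1, 1] / f_s$varcomp$G0[1, 1], 4,
               tolerance = 0.25)
  # transmitting-ability scale agrees directly
  ta <- sire_effects(f_a, sires)$s_hat
  expect_equal(ta, ebv / 2, tolerance = 1e-12)
})

test_that("bivariate fits honor constraints and missing records", {
  sim <- small_sim()
  # cage-level bivariate sire model: residual covariance estimated freely
  f_cb <- fit_model(sim, "CBSiM", "BACK45", maxit = 80)
  expect_equal(dim(f_cb$varcomp$G0), c(2L, 2L))
  expect_true(all(eigen(f_cb$varcomp$G0, TRUE, TRUE)$values > -1e-10))

  # individual-level bivariate animal model: residual covariance fixed 0,
  # and dead birds keep their survival record
  ind <- sim$individuals
  f_ib <- reml_fit(ind, sim$pedigree, "IBAM", "BACK45", maxit = 30)
  expect_identical(f_ib$varcomp$R0[1, 2], 0)
  expect_equal(f_ib$n_obs[1], sum(!is.na(ind$fs_BACK45)))
  expect_equal(f_ib$n_obs[2], nrow(ind))
  expect_gt(f_ib$n_obs[2], f_ib$n_obs[1])
})

test_that("aliased fixed-effect levels are dropped, not fatal", {
  bs <- balanced_sire_data(s = 20, k = 5, seed = 6)
  bs$data$dup <- rep(c("u", "v"), length.out = nrow(bs$data))
  bs$data$dup2 <- bs$data$dup  # perfectly confounded copy
  fit <- reml_fit(bs$data, bs$pedigree, "CUSiM", trait = "y",
                  fixed = ~ dup + dup2)
  expect_equal(fit$aliased[1], 1L)
  expect_true(fit$converged)
})
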