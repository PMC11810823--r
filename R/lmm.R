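#' @importFrom Matrix Diagonal sparseMatrix crossprod t solve determinant
#' @importFrom methods as
NULL

# ---- design preparation ------------------------------------------------

# Resolve the response column(s) for a model/trait on a dataset.
resolve_response <- function(data, spec, trait, trait2 = NULL) {
  age <- if (grepl("45", trait)) "45" else "70"
  cand1 <- if (spec$level == "cage") {
    c(paste0("mean_fs_", trait), paste0("mean_", trait), trait)
  } else {
    c(paste0("fs_", trait), trait)
  }
  col1 <- cand1[cand1 %in% names(data)][1]
  if (is.na(col1)) stop("trait column not found for '", trait, "'")
  y <- cbind(as.numeric(data[[col1]]))
  tn <- trait
  if (spec$bivariate) {
    col2 <- if (!is.null(trait2)) trait2
            else if (spec$level == "cage") paste0("surv_frac_", age)
            else paste0("surv_", age)
    if (!col2 %in% names(data)) stop("survival column ", col2, " not found")
    y <- cbind(y, as.numeric(data[[col2]]))
    tn <- c(trait, col2)
  }
  colnames(y) <- tn
  y
}

genetic_id_column <- function(spec) {
  if (spec$genetic == "sire") "sire_id"
  else if (spec$level == "cage") "representative_animal_id"
  else "animal_id"
}

# Reduce a design matrix to full column rank; returns kept column indices.
full_rank_cols <- function(X, tol = 1e-8) {
  qr_x <- qr(X, LAPACK = TRUE)
  d <- abs(diag(qr_x$qr))
  r <- sum(d > tol * max(d, 1))
  sort(qr_x$pivot[seq_len(r)])
}

# Build all fixed/random incidence structures for one model fit.
# Returns an environment reused by every likelihood evaluation.
mm_prepare <- function(data, pedigree, spec, trait, keep_ids = NULL,
                       fixed = NULL, trait2 = NULL) {
  if (is.null(fixed)) fixed <- spec$fixed_formula
  y_all <- resolve_response(data, spec, trait, trait2)
  n_rec <- nrow(data)
  n_tr <- ncol(y_all)

  # genetic levels: animals/sires with records, forced ids, and ancestors
  gcol <- genetic_id_column(spec)
  if (!gcol %in% names(data)) stop("column ", gcol, " missing from data")
  gid <- as.character(data[[gcol]])
  keep <- unique(c(gid, as.character(keep_ids)))
  ped <- prune_pedigree(pedigree, keep)
  Ainv <- build_A_inverse(ped)
  ids <- rownames(Ainv)
  q <- length(ids)
  g_idx <- match(gid, ids)
  if (anyNA(g_idx)) stop("data references ids absent from the pedigree")

  # per-trait observation sets
  obs <- lapply(seq_len(n_tr), function(t) which(!is.na(y_all[, t])))
  n_t <- lengths(obs)
  if (any(n_t == 0)) stop("a trait has no observed records")

  # trait scaling for numerical balance
  sd_y <- vapply(seq_len(n_tr), function(t) stats::sd(y_all[obs[[t]], t]), 1)
  sd_y[sd_y <= 0 | !is.finite(sd_y)] <- 1

  # fixed-effects design, full-rank per trait block
  mf <- stats::model.frame(fixed, data = data, na.action = NULL)
  for (j in seq_along(mf)) mf[[j]] <- factor(mf[[j]])
  Xfull <- stats::model.matrix(fixed, mf)
  Xs <- list(); p_t <- integer(n_tr); aliased <- integer(n_tr)
  for (t in seq_len(n_tr)) {
    Xt <- Xfull[obs[[t]], , drop = FALSE]
    kc <- full_rank_cols(Xt)
    aliased[t] <- ncol(Xt) - length(kc)
    Xt <- Xt[, kc, drop = FALSE]
    p_t[t] <- ncol(Xt)
    Xs[[t]] <- methods::as(Matrix::Matrix(Xt, sparse = TRUE), "generalMatrix")
    attr(Xs[[t]], "colnames") <- colnames(Xfull)[kc]
  }

  # genetic and cage incidence per trait block
  Zg <- lapply(seq_len(n_tr), function(t)
    Matrix::sparseMatrix(i = seq_len(n_t[t]), j = g_idx[obs[[t]]],
                         x = 1, dims = c(n_t[t], q)))
  n_cage <- 0L; cage_lev <- character(0); Zc <- NULL
  if (spec$cage_effect) {
    cage <- factor(as.character(data$cage_id))
    cage_lev <- levels(cage)
    n_cage <- length(cage_lev)
    Zc <- lapply(seq_len(n_tr), function(t)
      Matrix::sparseMatrix(i = seq_len(n_t[t]),
                           j = as.integer(cage)[obs[[t]]],
                           x = 1, dims = c(n_t[t], n_cage)))
  }

  W <- cbind(Matrix::bdiag(Xs), Matrix::bdiag(Zg),
             if (spec$cage_effect) Matrix::bdiag(Zc))
  y <- unlist(lapply(seq_len(n_tr), function(t)
    y_all[obs[[t]], t] / sd_y[t]), use.names = FALSE)

  # coefficient partition
  off <- 0L
  idx_b <- list()
  for (t in seq_len(n_tr)) { idx_b[[t]] <- off + seq_len(p_t[t]); off <- off + p_t[t] }
  idx_u <- lapply(seq_len(n_tr), function(t) off + (t - 1L) * q + seq_len(q))
  off <- off + n_tr * q
  idx_c <- if (spec$cage_effect)
    lapply(seq_len(n_tr), function(t) off + (t - 1L) * n_cage + seq_len(n_cage))
  else list()

  # residual-structure bookkeeping (units observed on one or both traits)
  both <- if (n_tr == 2) intersect(obs[[1]], obs[[2]]) else integer(0)
  pos <- lapply(seq_len(n_tr), function(t) {
    p <- rep(NA_integer_, n_rec); p[obs[[t]]] <- seq_len(n_t[t]); p
  })
  list(spec = spec, trait = trait, y = y, W = W, Ainv = Ainv, ids = ids,
       q = q, n_tr = n_tr, n_t = n_t, n_rec = n_rec, n_cage = n_cage,
       cage_lev = cage_lev, p_t = p_t, idx_b = idx_b, idx_u = idx_u,
       idx_c = idx_c, obs = obs, both = both, pos = pos, sd_y = sd_y,
       aliased = aliased, g_idx = g_idx,
       xnames = lapply(Xs, attr, "colnames"),
       logdet_A = attr(Ainv, "logdet_A"))
}

# Sparse inverse residual covariance for the stacked observation vector.
build_Rinv <- function(prep, R0) {
  n_tr <- prep$n_tr
  if (n_tr == 1) {
    return(list(Rinv = Matrix::Diagonal(prep$n_t[1], 1 / R0[1, 1]),
                logdetR = prep$n_t[1] * log(R0[1, 1])))
  }
  only1 <- setdiff(prep$obs[[1]], prep$both)
  only2 <- setdiff(prep$obs[[2]], prep$both)
  i1 <- prep$pos[[1]][prep$both]
  i2 <- prep$n_t[1] + prep$pos[[2]][prep$both]
  Rb <- solve(R0)
  ii <- c(i1, i2, i1, i2,
          prep$pos[[1]][only1], prep$n_t[1] + prep$pos[[2]][only2])
  jj <- c(i1, i2, i2, i1,
          prep$pos[[1]][only1], prep$n_t[1] + prep$pos[[2]][only2])
  xx <- c(rep(Rb[1, 1], length(i1)), rep(Rb[2, 2], length(i2)),
          rep(Rb[1, 2], length(i1)), rep(Rb[2, 1], length(i2)),
          rep(1 / R0[1, 1], length(only1)), rep(1 / R0[2, 2], length(only2)))
  n_eq <- sum(prep$n_t)
  Rinv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_eq, n_eq))
  logdetR <- length(prep$both) * determinant(R0, logarithm = TRUE)$modulus +
    length(only1) * log(R0[1, 1]) + length(only2) * log(R0[2, 2])
  list(Rinv = Rinv, logdetR = as.numeric(logdetR))
}

# One evaluation of the mixed-model equations at given (scaled) components.
# Returns the pieces of -2 * restricted log-likelihood plus solutions.
mme_eval <- function(prep, G0, C0, R0, solve_only = FALSE) {
  rr <- build_Rinv(prep, R0)
  WtR <- Matrix::crossprod(prep$W, rr$Rinv)
  Clhs <- methods::as(WtR %*% prep$W, "generalMatrix")
  G0inv <- solve(G0)
  pen <- Matrix::kronecker(G0inv, prep$Ainv)
  blocks <- list(Matrix::Diagonal(sum(prep$p_t), 0), pen)
  logdetG <- prep$q * as.numeric(determinant(G0, TRUE)$modulus) +
    prep$n_tr * prep$logdet_A
  if (prep$spec$cage_effect) {
    C0inv <- solve(C0)
    blocks[[3]] <- Matrix::kronecker(C0inv, Matrix::Diagonal(prep$n_cage))
    logdetG <- logdetG +
      prep$n_cage * as.numeric(determinant(C0, TRUE)$modulus)
  }
  C <- Clhs + Matrix::bdiag(blocks)
  C <- Matrix::forceSymmetric(C)
  rhs <- as.numeric(WtR %*% prep$y)
  ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  if (solve_only) return(list(sol = sol, C = C, rhs = rhs))
  logdetC <- 2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
  yRy <- as.numeric(Matrix::crossprod(prep$y, rr$Rinv %*% prep$y))
  yPy <- yRy - sum(sol * rhs)
  list(logdetR = rr$logdetR, logdetG = logdetG, logdetC = logdetC,
       yPy = yPy, sol = sol, C = C, rhs = rhs,
       n_eq = sum(prep$n_t), p_tot = sum(prep$p_t))
}

neg2_reml <- function(ev) {
  ev$logdetR + ev$logdetG + ev$logdetC + ev$yPy +
    (ev$n_eq - ev$p_tot) * log(2 * pi)
}

# ---- parameterizations -------------------------------------------------

# log-Cholesky <-> covariance matrix (2x2 or 1x1); diag = constrain
# off-diagonal to zero (e.g. residual covariance fixed at 0).
theta_to_cov <- function(theta, dim, diag_only = FALSE) {
  if (dim == 1) return(matrix(exp(2 * theta[1]), 1, 1))
  if (diag_only) {
    L <- diag(exp(theta[1:2]))
  } else {
    L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  }
  L %*% t(L)
}

n_theta <- function(dim, diag_only) {
  if (dim == 1) 1L else if (diag_only) 2L else 3L
}

cov_to_theta <- function(V, diag_only = FALSE) {
  if (nrow(V) == 1) return(log(sqrt(V[1, 1])))
  if (diag_only) return(log(sqrt(diag(V))))
  L <- t(chol(V))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

# ---- public operations -------------------------------------------------

#' Assemble Henderson's mixed-model equations
#'
#' Builds the sparse coefficient matrix and right-hand side of the
#' mixed-model equations for one model, trait and set of variance
#' components: the genetic block is augmented by `A^-1 (x) G0^-1`, the cage
#' block by `C0^-1 (x) I`, and records missing a trait (dead birds' feather
#' score) contribute no equation for that trait.
#'
#' @param data individual- or cage-level records matching the model's level.
#' @param pedigree pedigree data.frame (`id`, `sire`, `dam`), parents first.
#' @param model model name or [model_spec()] object.
#' @param trait feather-score trait, e.g. `"BACK45"`.
#' @param fixed optional one-sided formula overriding the standard
#'   fixed-effect structure (used by reduced designs and tests).
#' @param trait2 optional column name overriding the default second
#'   (survival) response of bivariate models.
#' @param varcomp list with `G0` (genetic covariance, per-trait), optional
#'   `C0` (cage) and `R0` (residual), each a t x t matrix (or scalar for
#'   univariate models).
#' @return list with the coefficient matrix `C`, right-hand side `rhs`,
#'   `solution` of the system, and the coefficient `partition` (fixed,
#'   genetic, cage index sets).
#' @export
assemble_mme <- function(data, pedigree, model, trait = "BACK45", varcomp,
                         fixed = NULL, trait2 = NULL) {
  spec <- as_model_spec(model)
  prep <- mm_prepare(data, pedigree, spec, trait, fixed = fixed,
                     trait2 = trait2)
  vc <- scale_varcomp(varcomp_as_matrices(varcomp, prep), 1 / prep$sd_y)
  ev <- mme_eval(prep, vc$G0, vc$C0, vc$R0, solve_only = TRUE)
  sol <- unscale_solution(ev$sol, prep)
  list(C = ev$C, rhs = ev$rhs, solution = sol,
       partition = list(fixed = prep$idx_b, genetic = prep$idx_u,
                        cage = prep$idx_c))
}

varcomp_as_matrices <- function(varcomp, prep) {
  as_m <- function(x) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (!all(dim(x) == prep$n_tr)) stop("varcomp dimension mismatch")
    x
  }
  list(G0 = as_m(varcomp$G0),
       C0 = if (prep$spec$cage_effect) as_m(varcomp$C0) else NULL,
       R0 = as_m(varcomp$R0))
}

# rescale covariance matrices to the internally standardized trait scale
scale_varcomp <- function(vc, f) {
  D <- diag(f, length(f))
  sc <- function(V) if (is.null(V)) NULL else D %*% V %*% D
  list(G0 = sc(vc$G0), C0 = sc(vc$C0), R0 = sc(vc$R0))
}

unscale_solution <- function(sol, prep) {
  out <- list()
  for (t in seq_len(prep$n_tr)) {
    b <- sol[prep$idx_b[[t]]] * prep$sd_y[t]
    names(b) <- prep$xnames[[t]]
    out$fixed[[t]] <- b
    u <- sol[prep$idx_u[[t]]] * prep$sd_y[t]
    names(u) <- prep$ids
    out$genetic[[t]] <- u
    if (prep$spec$cage_effect) {
      cc <- sol[prep$idx_c[[t]]] * prep$sd_y[t]
      names(cc) <- prep$cage_lev
      out$cage[[t]] <- cc
    }
  }
  out
}

#' Restricted log-likelihood of a model at given variance components
#'
#' @inheritParams assemble_mme
#' @return scalar restricted log-likelihood (including the
#'   `-(n-p)/2 log(2*pi)` constant).
#' @export
restricted_loglik <- function(data, pedigree, model, trait = "BACK45",
                              varcomp, fixed = NULL, trait2 = NULL) {
  spec <- as_model_spec(model)
  prep <- mm_prepare(data, pedigree, spec, trait, fixed = fixed,
                     trait2 = trait2)
  vc <- varcomp_as_matrices(varcomp, prep)
  ok <- vapply(vc[!vapply(vc, is.null, TRUE)],
               function(V) all(eigen(V, TRUE, TRUE)$values > 0), TRUE)
  if (!all(ok)) stop("variance component matrices must be positive definite")
  vcs <- scale_varcomp(vc, 1 / prep$sd_y)
  ev <- mme_eval(prep, vcs$G0, vcs$C0, vcs$R0)
  # Jacobian of the internal trait standardisation, on the contrast space
  -0.5 * neg2_reml(ev) - sum((prep$n_t - prep$p_t) * log(prep$sd_y))
}

#' Fit a model by REML
#'
#' Estimates the variance components of one of the six evaluation models by
#' maximizing the restricted log-likelihood with a quasi-Newton search over
#' log-Cholesky-parameterized covariance blocks (the residual variance is
#' profiled out analytically for univariate models), then solves the
#' mixed-model equations at the estimates for fixed-effect and BLUP
#' solutions.
#'
#' @inheritParams assemble_mme
#' @param init optional starting values, as a `varcomp` list.
#' @param keep_ids ids that must stay in the pruned pedigree even without
#'   records (e.g. all test sires during cross-validation).
#' @param maxit maximum optimizer iterations.
#' @param reltol relative convergence tolerance on the objective.
#' @return object of class `rt_fit`: variance components (`$varcomp`,
#'   back on the observed trait scale), `$fixed`, `$genetic` and `$cage`
#'   solutions, `$loglik`, `$converged`, `$n_iter`, `$boundary` flag and
#'   bookkeeping (`$spec`, `$trait`, `$n_obs`, `$aliased`).
#' @export
reml_fit <- function(data, pedigree, model, trait = "BACK45", init = NULL,
                     keep_ids = NULL, maxit = 200, reltol = 1e-10,
                     fixed = NULL, trait2 = NULL) {
  spec <- as_model_spec(model)
  prep <- mm_prepare(data, pedigree, spec, trait, keep_ids = keep_ids,
                     fixed = fixed, trait2 = trait2)
  if (prep$n_tr == 1) {
    fit <- reml_fit_uni(prep, init, maxit, reltol)
  } else {
    fit <- reml_fit_biv(prep, init, maxit, reltol)
  }
  fit
}

# Univariate: optimize variance ratios, profile the residual variance.
reml_fit_uni <- function(prep, init, maxit, reltol) {
  has_c <- prep$spec$cage_effect
  lam0 <- if (!is.null(init)) {
    r0 <- as.matrix(init$R0)[1, 1] / prep$sd_y[1]^2
    c(log(as.matrix(init$G0)[1, 1] / prep$sd_y[1]^2 / r0),
      if (has_c) log(as.matrix(init$C0)[1, 1] / prep$sd_y[1]^2 / r0))
  } else c(log(0.1), if (has_c) log(0.1))
  obj <- function(lt) {
    G0 <- matrix(exp(lt[1]), 1, 1)
    C0 <- if (has_c) matrix(exp(lt[2]), 1, 1) else NULL
    ev <- tryCatch(mme_eval(prep, G0, C0, matrix(1, 1, 1)),
                   error = function(e) NULL)
    if (is.null(ev) || !is.finite(ev$yPy) || ev$yPy <= 0) return(1e10)
    df <- ev$n_eq - ev$p_tot
    s2 <- ev$yPy / df
    ev$logdetR + ev$logdetG + ev$logdetC + df * log(s2) + df +
      df * log(2 * pi)
  }
  lo <- rep(log(1e-8), length(lam0)); hi <- rep(log(1e8), length(lam0))
  opt <- stats::nlminb(lam0, obj, lower = lo, upper = hi,
                       control = list(iter.max = maxit, rel.tol = reltol))
  lt <- opt$par
  G0 <- matrix(exp(lt[1]), 1, 1)
  C0 <- if (has_c) matrix(exp(lt[2]), 1, 1) else NULL
  ev <- mme_eval(prep, G0, C0, matrix(1, 1, 1))
  df <- ev$n_eq - ev$p_tot
  s2 <- ev$yPy / df
  # back to observed scale
  f <- prep$sd_y[1]^2
  vc <- list(G0 = G0 * s2 * f, C0 = if (has_c) C0 * s2 * f, R0 = matrix(s2 * f, 1, 1))
  ev2 <- mme_eval(prep, G0 * s2, if (has_c) C0 * s2, matrix(s2, 1, 1))
  make_fit(prep, vc, ev2, opt, boundary = any(abs(lt - lo) < 1e-6))
}

# Bivariate: full log-Cholesky parameterization of every covariance block.
reml_fit_biv <- function(prep, init, maxit, reltol) {
  has_c <- prep$spec$cage_effect
  diag_R <- prep$spec$residual_cov == "fixed_zero"
  if (is.null(init)) {
    # start from univariate fits of each trait
    g0 <- c(0.1, 0.1); r0 <- c(0.9, 0.9); c0 <- c(0.1, 0.1)
    uni <- lapply(1:2, function(t) uni_start(prep, t))
    for (t in 1:2) {
      g0[t] <- uni[[t]]$g; r0[t] <- uni[[t]]$e
      if (has_c) c0[t] <- uni[[t]]$c
    }
    start_block <- function(v, r = 0.2, diag_only = FALSE) {
      V <- diag(v); V[1, 2] <- V[2, 1] <- r * sqrt(prod(v))
      cov_to_theta(V, diag_only)
    }
    theta <- c(start_block(g0, 0.3),
               if (has_c) start_block(c0, 0.1),
               start_block(r0, 0, diag_R))
  } else {
    sc <- scale_varcomp(varcomp_as_matrices(init, prep), 1 / prep$sd_y)
    theta <- c(cov_to_theta(sc$G0),
               if (has_c) cov_to_theta(sc$C0),
               cov_to_theta(sc$R0, diag_R))
  }
  split_theta <- function(th) {
    i <- 3L
    G0 <- theta_to_cov(th[1:3], 2)
    C0 <- NULL
    if (has_c) { C0 <- theta_to_cov(th[i + 1:3], 2); i <- i + 3L }
    nr <- n_theta(2, diag_R)
    R0 <- theta_to_cov(th[i + seq_len(nr)], 2, diag_R)
    list(G0 = G0, C0 = C0, R0 = R0)
  }
  obj <- function(th) {
    vc <- split_theta(th)
    ev <- tryCatch(mme_eval(prep, vc$G0, vc$C0, vc$R0),
                   error = function(e) NULL)
    if (is.null(ev) || !is.finite(ev$yPy) || ev$yPy <= 0) return(1e10)
    neg2_reml(ev)
  }
  np <- length(theta)
  is_ld <- log_diag_positions(has_c, diag_R)
  lo <- rep(-Inf, np); hi <- rep(Inf, np)
  lo[is_ld] <- log(1e-5); hi[is_ld] <- log(1e3)
  lo[!is_ld] <- -50; hi[!is_ld] <- 50
  opt <- stats::nlminb(theta, obj, lower = lo, upper = hi,
                       control = list(iter.max = maxit, rel.tol = reltol))
  vc_s <- split_theta(opt$par)
  ev <- mme_eval(prep, vc_s$G0, vc_s$C0, vc_s$R0)
  D <- diag(prep$sd_y)
  vc <- list(G0 = D %*% vc_s$G0 %*% D,
             C0 = if (has_c) D %*% vc_s$C0 %*% D,
             R0 = D %*% vc_s$R0 %*% D)
  make_fit(prep, vc, ev, opt,
           boundary = any(abs(opt$par[is_ld] - log(1e-5)) < 1e-6))
}

log_diag_positions <- function(has_c, diag_R) {
  pos <- c(TRUE, FALSE, TRUE)                      # genetic block
  if (has_c) pos <- c(pos, TRUE, FALSE, TRUE)      # cage block
  pos <- c(pos, if (diag_R) c(TRUE, TRUE) else c(TRUE, FALSE, TRUE))
  pos
}

# crude per-trait variance split for bivariate starting values (the traits
# are standardized internally, so total variance is ~1)
uni_start <- function(prep, t) {
  v <- stats::var(prep$y[(if (t == 1) seq_len(prep$n_t[1])
                          else prep$n_t[1] + seq_len(prep$n_t[2]))])
  list(g = 0.1 * v, c = 0.1 * v, e = 0.8 * v)
}

make_fit <- function(prep, vc, ev, opt, boundary) {
  sol <- unscale_solution(ev$sol, prep)
  # loglik on the observed trait scale
  ll <- -0.5 * neg2_reml(ev) - sum((prep$n_t - prep$p_t) * log(prep$sd_y))
  structure(list(
    varcomp = vc, fixed = sol$fixed, genetic = sol$genetic,
    cage = sol$cage, loglik = ll,
    converged = identical(opt$convergence, 0L), n_iter = opt$iterations,
    boundary = boundary, spec = prep$spec, trait = prep$trait,
    n_obs = prep$n_t, aliased = prep$aliased, ids = prep$ids,
    sd_y = prep$sd_y), class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("REML fit: %s, trait %s (%s records: %s)\n", x$spec$name,
              x$trait, x$spec$level, paste(x$n_obs, collapse = " + ")))
  vt <- varcomp_table(x)
  print(vt, row.names = FALSE)
  cat(sprintf("logLik %.3f, %sconverged in %d iterations%s\n", x$loglik,
              if (x$converged) "" else "NOT ", x$n_iter,
              if (x$boundary) " (boundary estimate)" else ""))
  invisible(x)
}

#' Tidy table of estimated variance components
#'
#' @param fit an `rt_fit` object.
#' @return data.frame with columns `component` and `estimate`.
#' @export
varcomp_table <- function(fit) {
  gname <- if (fit$spec$genetic == "sire") "sigma2_S" else "sigma2_A"
  rows <- list()
  add <- function(nm, v) rows[[length(rows) + 1L]] <<- data.frame(
    component = nm, estimate = v, stringsAsFactors = FALSE)
  tn <- c(fit$trait, "surv")
  for (t in seq_len(nrow(as.matrix(fit$varcomp$G0)))) {
    add(paste0(gname, "_", tn[t]), fit$varcomp$G0[t, t])
    if (!is.null(fit$varcomp$C0)) add(paste0("sigma2_c_", tn[t]),
                                      fit$varcomp$C0[t, t])
    add(paste0("sigma2_e_", tn[t]), fit$varcomp$R0[t, t])
  }
  if (nrow(as.matrix(fit$varcomp$G0)) == 2) {
    add("cov_g", fit$varcomp$G0[1, 2])
    if (!is.null(fit$varcomp$C0)) add("cov_c", fit$varcomp$C0[1, 2])
    add("cov_e", fit$varcomp$R0[1, 2])
  }
  do.call(rbind, rows)
}

#' Estimated sire (transmitting-ability) effects from a fit
#'
#' For sire models these are the genetic solutions directly; for animal
#' models the sire's estimated breeding value is halved, putting all models
#' on the transmitting-ability scale the validation compares.
#'
#' @param fit an `rt_fit` object.
#' @param sire_ids which sires to extract; default all ids in the fit whose
#'   id occurs as a `sire_id` level (sire models) or all ids (animal models).
#' @param scale `"ta"` (transmitting ability, default) or `"ebv"` (animal
#'   scale, twice the transmitting ability).
#' @return data.frame with `sire_id` and `s_hat`.
#' @export
sire_effects <- function(fit, sire_ids = NULL, scale = c("ta", "ebv")) {
  scale <- match.arg(scale)
  u <- fit$genetic[[1]]
  if (is.null(sire_ids)) sire_ids <- names(u)
  sire_ids <- as.character(sire_ids)
  missing_ids <- setdiff(sire_ids, names(u))
  if (length(missing_ids)) stop("ids not in fit: ",
                                paste(utils::head(missing_ids), collapse = ", "))
  val <- u[sire_ids]
  mult_ta <- if (fit$spec$genetic == "animal") 0.5 else 1
  val <- val * mult_ta
  if (scale == "ebv") val <- val * 2
  data.frame(sire_id = sire_ids, s_hat = unname(val),
             stringsAsFactors = FALSE)
}

#' Convenience wrapper: fit a model on a simulated study
#'
#' Picks the individual- or cage-level dataset required by the model from an
#' `rt_sim` object and calls [reml_fit()].
#'
#' @param sim output of [simulate_rt_data()].
#' @param model model name or [model_spec()].
#' @param trait feather-score trait.
#' @param ... passed to [reml_fit()].
#' @export
fit_model <- function(sim, model, trait = "BACK45", ...) {
  spec <- as_model_spec(model)
  data <- if (spec$level == "cage") sim$cages else sim$individuals
  reml_fit(data, sim$pedigree, spec, trait, ...)
}
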