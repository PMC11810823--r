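#' The six evaluation models
#'
#' Declarative catalogue of the compared linear mixed models for feather
#' score analysis of recurrent-test data:
#'
#' * `IBAM` — individual-level bivariate (FS + survival) animal model with a
#'   random cage effect; the residual covariance between FS and survival is
#'   fixed at zero (survivors all share the same survival code, leaving no
#'   information to estimate it).
#' * `IUAM` — individual-level univariate animal model with random cage
#'   effect.
#' * `CUAM` — cage-level univariate animal model; the cage-mean record is
#'   assigned to a single random member of the cage.
#' * `IBSiM` — individual-level bivariate sire model with random cage
#'   effect; residual covariance estimated freely.
#' * `CBSiM` — cage-level bivariate sire model.
#' * `CUSiM` — cage-level univariate sire model.
#'
#' The fixed-effect structure is identical across models: recurrent-test
#' batch number, the farm-by-housing-date-by-cross interaction (one combined
#' factor level per unique triple), and the fast-feathering gene genotype.
#'
#' @name rt_models
NULL

MODEL_NAMES <- c("IBAM", "IUAM", "CUAM", "IBSiM", "CBSiM", "CUSiM")

#' Specification of one evaluation model
#'
#' @param name one of `"IBAM"`, `"IUAM"`, `"CUAM"`, `"IBSiM"`, `"CBSiM"`,
#'   `"CUSiM"`.
#' @return object of class `rt_model_spec`: a list with `name`, `level`
#'   (`"individual"` or `"cage"`), `genetic` (`"animal"` or `"sire"`),
#'   `bivariate` (logical; FS + survival), `cage_effect` (logical random
#'   cage term, individual-level models only) and `residual_cov`
#'   (`"free"` or `"fixed_zero"`).
#' @examples
#' model_spec("CUSiM")
#' @export
model_spec <- function(name) {
  if (length(name) != 1 || !name %in% MODEL_NAMES) {
    stop("unknown model '", paste(name, collapse = ","),
         "'; valid models: ", paste(MODEL_NAMES, collapse = ", "))
  }
  spec <- switch(name,
    IBAM = list(level = "individual", genetic = "animal", bivariate = TRUE,
                cage_effect = TRUE, residual_cov = "fixed_zero"),
    IUAM = list(level = "individual", genetic = "animal", bivariate = FALSE,
                cage_effect = TRUE, residual_cov = "free"),
    CUAM = list(level = "cage", genetic = "animal", bivariate = FALSE,
                cage_effect = FALSE, residual_cov = "free"),
    IBSiM = list(level = "individual", genetic = "sire", bivariate = TRUE,
                 cage_effect = TRUE, residual_cov = "free"),
    CBSiM = list(level = "cage", genetic = "sire", bivariate = TRUE,
                 cage_effect = FALSE, residual_cov = "free"),
    CUSiM = list(level = "cage", genetic = "sire", bivariate = FALSE,
                 cage_effect = FALSE, residual_cov = "free"))
  structure(c(list(name = name), spec,
              list(fixed_formula = ~ rt_number + fdc + feather_gene)),
            class = "rt_model_spec")
}

#' @export
print.rt_model_spec <- function(x, ...) {
  cat(sprintf("%s: %s-level %s %s model%s%s\n", x$name, x$level,
              if (x$bivariate) "bivariate" else "univariate", x$genetic,
              if (x$cage_effect) ", random cage effect" else "",
              if (x$residual_cov == "fixed_zero")
                ", residual covariance fixed at 0" else ""))
  invisible(x)
}

#' @rdname model_spec
#' @export
model_names <- function() MODEL_NAMES

as_model_spec <- function(model) {
  if (inherits(model, "rt_model_spec")) model else model_spec(model)
}
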