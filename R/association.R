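# Case-control logistic association of a variant with disease under multiple
# genetic models, per stage and combined.

#' Code a genotype under a genetic model
#'
#' additive: 0/1/2 count of the effect allele. recessive: 1 for homozygous
#' effect-allele carriers, 0 otherwise (reference group is dosage 0 or 1).
#' genotype_contrast: homozygote-vs-homozygote contrast — heterozygotes are
#' coded NA and dropped from the analysis. The allelic model is an expansion
#' to 2N allele observations and is handled inside [fit_logistic_assoc()].
#'
#' @param dosage integer vector in {0, 1, 2}.
#' @param model `"additive"`, `"recessive"` or `"genotype_contrast"`.
#' @return Numeric design values (NA marks excluded subjects).
#' @export
code_genetic_model <- function(dosage,
                               model = c("additive", "recessive",
                                         "genotype_contrast")) {
  model <- match.arg(model)
  if (any(!dosage %in% 0:2)) stop("dosage values must be 0, 1 or 2")
  switch(model,
         additive = as.numeric(dosage),
         recessive = as.numeric(dosage == 2),
         genotype_contrast = ifelse(dosage == 1, NA_real_,
                                    as.numeric(dosage == 2)))
}

#' Multivariable logistic association for one genetic model
#'
#' Unconditional maximum-likelihood logistic regression of phenotype on
#' `[1, coded genotype, covariates]`. Reports `OR = exp(coef)` with Wald 95%
#' CI and two-sided Wald p. Under the allelic model each subject is expanded
#' to two allele observations with covariates duplicated. Separation (a
#' diverging coefficient or non-convergence) is an error — the fit is never
#' silently penalized.
#'
#' @param cohort data frame with phenotype (0/1), dosage (0/1/2) and the
#'   covariate columns.
#' @param model `"additive"`, `"recessive"`, `"allelic"` or
#'   `"genotype_contrast"`.
#' @param covariates character vector of covariate column names (default
#'   gender/age/smoking/drinking as available in the cohort).
#' @return One-row data frame of class `assoc_result`: model, or_, ci_low,
#'   ci_high, p, log_or, se, n_cases, n_controls, stage.
#' @export
fit_logistic_assoc <- function(cohort,
                               model = c("additive", "recessive", "allelic",
                                         "genotype_contrast"),
                               covariates = intersect(c("sex", "age",
                                                        "smoking", "drinking"),
                                                      names(cohort))) {
  model <- match.arg(model)
  if (anyNA(cohort$phenotype)) stop("missing phenotype")
  if (any(!cohort$dosage %in% 0:2)) stop("dosage values must be 0, 1 or 2")
  if (model == "allelic") {
    a1 <- as.numeric(cohort$dosage >= 1)
    a2 <- as.numeric(cohort$dosage == 2)
    d <- rbind(cohort, cohort)
    d$g <- c(a1, a2)
  } else {
    d <- cohort
    d$g <- code_genetic_model(cohort$dosage, model)
    d <- d[!is.na(d$g), , drop = FALSE]
  }
  if (length(unique(d$phenotype)) < 2)
    stop("both phenotype classes must be present")
  fml <- stats::reformulate(c("g", covariates), response = "phenotype")
  fit <- stats::glm(fml, data = d, family = stats::binomial())
  b <- stats::coef(fit)["g"]
  se <- sqrt(stats::vcov(fit)["g", "g"])
  if (!fit$converged || abs(b) > 15)
    stop("separation detected (|log OR| diverges); consider an exact or ",
         "penalized analysis")
  out <- data.frame(model = model, or_ = exp(b),
                    ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(b / se)),
                    log_or = unname(b), se = se,
                    n_cases = sum(cohort$phenotype == 1),
                    n_controls = sum(cohort$phenotype == 0),
                    stage = if (!is.null(cohort$stage))
                      paste(sort(unique(cohort$stage)), collapse = "+")
                    else NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' @export
print.assoc_result <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    lab <- if (!is.null(x$method)) paste0(x$model[i], "/", x$method[i])
    else x$model[i]
    cat(sprintf("%s: OR = %.3f (95%% CI %.3f-%.3f), P = %.3g  [%d cases / %d controls%s]\n",
                lab, x$or_[i], x$ci_low[i], x$ci_high[i], x$p[i],
                x$n_cases[i], x$n_controls[i],
                if (!is.na(x$stage[i])) paste0(", stage ", x$stage[i]) else ""))
  }
  invisible(x)
}

#' Combine association stages
#'
#' `pooled`: a single logistic re-fit on the concatenated subjects with stage
#' indicator covariates. `ivw_meta`: fixed-effect inverse-variance-weighted
#' mean of the per-stage log-ORs with combined Wald CI and p. Both are
#' legitimate combined analyses; they are labeled in the output.
#'
#' @param cohorts list of stage cohort data frames (as for
#'   [fit_logistic_assoc()]); each must carry a distinct `stage` value.
#' @param model genetic model, passed through.
#' @param method `"pooled"`, `"ivw_meta"`, or both.
#' @param covariates covariate columns, passed through.
#' @return `assoc_result` data frame with one row per method, plus attribute
#'   `stage_fits` (the per-stage results).
#' @export
combine_stages <- function(cohorts, model = "additive",
                           method = c("pooled", "ivw_meta"),
                           covariates = intersect(c("sex", "age", "smoking",
                                                    "drinking"),
                                                  names(cohorts[[1]]))) {
  method <- match.arg(method, several.ok = TRUE)
  if (length(cohorts) < 2) stop("need at least 2 stages")
  stage_fits <- lapply(cohorts, fit_logistic_assoc, model = model,
                       covariates = covariates)
  rows <- list()
  if ("pooled" %in% method) {
    all_d <- do.call(rbind, cohorts)
    all_d$stage <- factor(all_d$stage)
    r <- fit_logistic_assoc(all_d, model = model,
                            covariates = c(covariates,
                                           if (nlevels(all_d$stage) > 1) "stage"))
    r$method <- "pooled"
    rows <- c(rows, list(r))
  }
  if ("ivw_meta" %in% method) {
    b <- vapply(stage_fits, `[[`, 0, "log_or")
    se <- vapply(stage_fits, `[[`, 0, "se")
    w <- 1 / se^2
    bc <- sum(w * b) / sum(w)
    sec <- 1 / sqrt(sum(w))
    r <- data.frame(model = model, or_ = exp(bc),
                    ci_low = exp(bc - 1.96 * sec),
                    ci_high = exp(bc + 1.96 * sec),
                    p = 2 * stats::pnorm(-abs(bc / sec)),
                    log_or = bc, se = sec,
                    n_cases = sum(vapply(stage_fits, `[[`, 0, "n_cases")),
                    n_controls = sum(vapply(stage_fits, `[[`, 0, "n_controls")),
                    stage = "combined", method = "ivw_meta",
                    stringsAsFactors = FALSE)
    rows <- c(rows, list(r))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assoc_result", "data.frame")
  structure(out, stage_fits = stage_fits)
}
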