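#' Coefficient table of a fitted (or published) period model
#'
#' Lightweight container for fixed-effect estimates in the canonical term
#' vocabulary: `intercept`, the non-reference period labels (`pollution`,
#' `post1`, `post2`), the non-reference catchment (`Plesne`), period x
#' catchment interactions (`pollution:Plesne`, ...) and, for
#' increment-discrimination models, `delta13C` and its period interactions.
#' The reference levels (period `pre`, catchment `Certovo`) contribute zero
#' by construction and carry no row.
#'
#' @param terms `data.frame` with columns `term,estimate`.
#' @param response Response name.
#' @param r2m,r2c Marginal / conditional pseudo-R-squared (optional).
#' @param aic AIC of the selected model (optional).
#' @return Object of class `coefficient_table`.
#' @export
coefficient_table <- function(terms, response, r2m = NA_real_,
                              r2c = NA_real_, aic = NA_real_) {
  stopifnot(all(c("term", "estimate") %in% names(terms)))
  if (!"intercept" %in% terms$term) stop("intercept term required")
  structure(list(terms = terms[, c("term", "estimate")], response = response,
                 r2m = r2m, r2c = r2c, aic = aic),
            class = "coefficient_table")
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat(sprintf("coefficient_table: %s (AIC %.4g, R2m %.2f, R2c %.2f)\n",
              x$response, x$aic, x$r2m, x$r2c))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

# map lme4/lm coefficient names onto the canonical term vocabulary
.canonical_terms <- function(nm) {
  nm <- sub("^\\(Intercept\\)$", "intercept", nm)
  nm <- gsub("period", "", nm, fixed = TRUE)
  nm <- gsub("catchment", "", nm, fixed = TRUE)
  # order interactions as period:Plesne / period:delta13C
  vapply(strsplit(nm, ":", fixed = TRUE), function(parts) {
    if (length(parts) == 1L) return(parts)
    paste(sort(parts, decreasing = parts[1] == "delta13C"), collapse = ":")
  }, character(1))
}

.extract_coefficient_table <- function(fit, response) {
  fe <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  terms <- data.frame(term = .canonical_terms(names(fe)),
                      estimate = unname(fe))
  r2 <- if (inherits(fit, "merMod")) pseudo_r2(fit) else
    c(r2m = summary(fit)$r.squared, r2c = summary(fit)$r.squared)
  ct <- coefficient_table(terms, response, r2m = unname(r2[1]),
                          r2c = unname(r2[2]), aic = stats::AIC(fit))
  ct$fit <- fit
  ct
}

#' Fit and select a period mixed model
#'
#' Fits linear mixed models of one tree-period value per row with a random
#' intercept per tree and candidate fixed structures `{1}` (intercept
#' only), `{period}`, `{period + catchment}`, `{period * catchment}` (each
#' additionally with `covariate` when supplied). Candidates are compared by maximum-likelihood
#' AIC and the winner is refitted by REML for the reported estimates, the
#' convention under which AIC comparison across fixed structures is valid.
#' Reference levels are the first period and catchment `Certovo`. A singular
#' random-effect fit triggers a warning and a fallback to ordinary least
#' squares with the same fixed structure.
#'
#' @param data `data.frame` with `tree_id`, `period` (factor), `value`, and
#'   optionally `catchment` and a covariate column.
#' @param covariate Optional name of a covariate column.
#' @param response Response label for the returned table.
#' @return A [coefficient_table] with the fitted model in `$fit` and the
#'   ML AIC table in `$aic_table`.
#' @export
fit_period_model <- function(data, covariate = NULL, response = "value") {
  stopifnot(all(c("tree_id", "period", "value") %in% names(data)))
  if (length(unique(data$period)) < 2L) stop("need >= 2 periods")
  if (length(unique(data$tree_id)) < 5L) stop("need >= 5 trees")
  data$period <- droplevels(as.factor(data$period))
  has_catch <- "catchment" %in% names(data) &&
    length(unique(data$catchment)) > 1L
  if (has_catch)
    data$catchment <- stats::relevel(as.factor(data$catchment), "Certovo")
  fixed <- c("1", "period")
  if (has_catch) fixed <- c(fixed, "period + catchment", "period * catchment")
  if (!is.null(covariate))
    fixed <- c(fixed, paste(fixed, "+", covariate))
  forms <- paste("value ~", fixed, "+ (1 | tree_id)")
  ml <- lapply(forms, function(f)
    suppressMessages(lme4::lmer(stats::as.formula(f), data = data,
                                REML = FALSE)))
  aics <- vapply(ml, stats::AIC, numeric(1))
  best <- which.min(aics)
  fit <- suppressMessages(lme4::lmer(stats::as.formula(forms[best]),
                                     data = data, REML = TRUE))
  if (lme4::isSingular(fit)) {
    warning("singular random-effect fit; falling back to fixed-effects-only ",
            "least squares")
    fit <- stats::lm(stats::as.formula(paste("value ~", fixed[best])),
                     data = data)
  }
  ct <- .extract_coefficient_table(fit, response)
  ct$aic <- aics[best] # report the ML AIC used for selection
  ct$aic_table <- data.frame(fixed = fixed, aic = aics)
  ct
}

#' Tukey pairwise period comparisons with letter groupings
#'
#' All pairwise comparisons of period marginal means from a fitted period
#' model, single-step adjusted (Tukey), plus a compact letter display:
#' periods sharing no letter differ at `alpha`.
#'
#' @param model A fitted `merMod`/`lm` (e.g. `$fit` of
#'   [fit_period_model()]).
#' @param alpha Significance level for the letters (default 0.05).
#' @param adjust Multiplicity adjustment passed to emmeans (default
#'   `"tukey"`, the single-step studentized-range adjustment).
#' @return List with `emmeans` (`data.frame`), `contrasts` (`data.frame`
#'   of pairwise tests) and `letters` (named character vector).
#' @export
tukey_contrasts <- function(model, alpha = 0.05, adjust = "tukey") {
  em <- emmeans::emmeans(model, "period")
  prs <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = adjust))
  emd <- as.data.frame(em)
  lev <- as.character(emd$period)
  pmat <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_len(nrow(prs))) {
    ab <- strsplit(prs$contrast[i], " - ")[[1]]
    ab <- gsub("[()]", "", ab)
    pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- prs$p.value[i]
  }
  list(emmeans = emd, contrasts = prs,
       letters = compact_letters(pmat, alpha = alpha))
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: levels sharing a letter are not
#' significantly different; every significant pair shares no letter. The
#' assignment is transitive-consistent with the p-value matrix by
#' construction.
#'
#' @param pmat Symmetric matrix of pairwise p-values with dimnames.
#' @param alpha Significance level.
#' @return Named character vector of letter strings, one per level.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  lev <- rownames(pmat)
  sets <- list(lev)
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    a <- lev[i]; b <- lev[j]
    for (k in rev(seq_along(sets))) {
      s <- sets[[k]]
      if (a %in% s && b %in% s) {
        sets[[k]] <- setdiff(s, a)
        sets[[length(sets) + 1L]] <- setdiff(s, b)
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(sets))
    for (k in seq_along(sets)) for (l in seq_along(sets)) {
      if (k != l && keep[l] && all(sets[[k]] %in% sets[[l]]) &&
          length(sets[[k]]) < length(sets[[l]])) keep[k] <- FALSE
    }
    sets <- unique(sets[keep])
  }
  # order letters by first appearance in level order
  first <- vapply(sets, function(s) min(match(s, lev)), numeric(1))
  sets <- sets[order(first)]
  out <- stats::setNames(rep("", length(lev)), lev)
  for (k in seq_along(sets))
    out[sets[[k]]] <- paste0(out[sets[[k]]], letters[k])
  out
}

#' Marginal and conditional pseudo-R-squared of a random-intercept model
#'
#' Variance-partition R-squared for Gaussian mixed models: the marginal
#' value is the share of total variance (fixed + random intercept +
#' residual) attributable to the fixed-effect predictor, the conditional
#' value the share attributable to fixed plus random effects together.
#'
#' @param model A fitted `merMod`.
#' @return Named numeric vector `c(r2m, r2c)`.
#' @export
pseudo_r2 <- function(model) {
  stopifnot(inherits(model, "merMod"))
  var_f <- stats::var(as.vector(lme4::getME(model, "X") %*% lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  var_r <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(r2m = var_f / tot, r2c = (var_f + var_r) / tot)
}

#' Mixed model of biomass increment on discrimination by period
#'
#' Fits `increment ~ delta13C * period + (1 | tree_id)`: the within-period
#' slope of biomass increment on discrimination, allowed to differ between
#' periods. Used to test whether the increment-discrimination coupling was
#' lost during the pollution period (interaction offsetting the baseline
#' slope toward zero).
#'
#' @param data `data.frame` with `tree_id,period,increment,delta13C`.
#' @param response Response label.
#' @return A [coefficient_table] (fit in `$fit`) with a `$slopes` entry
#'   giving the per-period slope of increment on delta13C.
#' @export
fit_increment_vs_discrimination <- function(data,
                                            response = "biomass_increment") {
  stopifnot(all(c("tree_id", "period", "increment", "delta13C") %in%
                  names(data)))
  data$period <- droplevels(as.factor(data$period))
  data$value <- data$increment
  single <- length(unique(data$period)) < 2L
  form <- if (single) value ~ delta13C + (1 | tree_id) else
    value ~ delta13C * period + (1 | tree_id)
  # one observation per tree leaves the random intercept unidentifiable;
  # the model then reduces to ordinary least squares
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = data, REML = TRUE)),
    error = function(e) {
      message("random intercept not identifiable (", conditionMessage(e),
              "); fitting fixed effects only")
      stats::lm(lme4::nobars(form), data = data)
    })
  ct <- .extract_coefficient_table(fit, response)
  base <- ct$terms$estimate[ct$terms$term == "delta13C"]
  slopes <- stats::setNames(rep(base, nlevels(data$period)),
                            levels(data$period))
  for (lv in levels(data$period)[-1]) {
    tm <- paste0(lv, ":delta13C")
    if (tm %in% ct$terms$term)
      slopes[lv] <- base + ct$terms$estimate[ct$terms$term == tm]
  }
  ct$slopes <- slopes
  ct
}
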