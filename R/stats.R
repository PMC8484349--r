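#' Model specification for an experimental contrast
#'
#' Mirrors the study's analysis conventions: linear models (LM) for
#' offspring counts per dish, binomial GLM (GLM-b) for the parasitism rate,
#' binomial mixed models (GLMM-b) for offspring sex ratio, and linear or
#' Poisson mixed models (LMM / GLMM-p) for clutch size, with the Petri-dish
#' identifier as random intercept in all mixed models. Clutch sizes under a
#' Poisson family are shifted by minus one (support starts at 1) and
#' predictions shifted back for reporting.
#'
#' @param response One of \code{"total_offspring"}, \code{"parasitized"},
#'   \code{"sex"}, \code{"clutch_size"}.
#' @param family \code{"gaussian"}, \code{"binomial"} or \code{"poisson"}.
#' @param fixed Character vector of fixed-factor column names (possibly
#'   empty: intercept/null model).
#' @param random_dish Include a dish (founder) random intercept?
#' @param transform \code{"shift_minus_1"} or \code{"none"}; forced to
#'   \code{"shift_minus_1"} for Poisson clutch-size models.
#' @return A \code{model_spec} object.
#' @export
model_spec <- function(response = c("total_offspring", "parasitized",
                                    "sex", "clutch_size"),
                       family = c("gaussian", "binomial", "poisson"),
                       fixed = character(0), random_dish = FALSE,
                       transform = c("none", "shift_minus_1")) {
  response <- match.arg(response)
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (response == "clutch_size" && family == "poisson" &&
      transform != "shift_minus_1") {
    transform <- "shift_minus_1"
  }
  structure(list(response = response, family = family, fixed = fixed,
                 random_dish = random_dish, transform = transform),
            class = "model_spec")
}

# per-founder aggregation for dish-level responses
aggregate_founders <- function(tab, fixed) {
  sp <- split(tab, tab$founder_id)
  out <- do.call(rbind, lapply(sp, function(s) {
    native <- s[s$parasitized & s$host_species == "native", , drop = FALSE]
    row <- data.frame(founder_id = s$founder_id[1L],
                      total_offspring = sum(native$clutch_size))
    for (f in fixed) {
      v <- unique(s[[f]])
      if (length(v) > 1L)
        stop("fixed factor '", f, "' varies within founder ",
             s$founder_id[1L],
             "; dish-level responses need founder-constant factors",
             call. = FALSE)
      row[[f]] <- v
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Fit one model of the comparison battery
#'
#' Maximum-likelihood fits (mixed models by Laplace approximation via lme4;
#' linear mixed models with \code{REML = FALSE} so likelihood-ratio
#' comparisons are valid). Non-convergence is flagged on the returned
#' handle, never silent.
#'
#' @param tab Host-egg table (see [host_egg_schema]); fixed-factor columns
#'   must be present.
#' @param spec A [model_spec()].
#' @return A \code{fitted_contrast} handle: the fit, its log-likelihood,
#'   parameter count, coefficient table and a convergence flag.
#' @export
fit_model <- function(tab, spec) {
  stopifnot(inherits(spec, "model_spec"))
  validate_host_table(tab)
  miss <- setdiff(spec$fixed, names(tab))
  if (length(miss) > 0)
    stop("fixed factor column(s) missing from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rhs_fixed <- if (length(spec$fixed) > 0)
    paste(spec$fixed, collapse = " + ") else "1"

  if (spec$response == "total_offspring") {
    dat <- aggregate_founders(tab, spec$fixed)
    if (spec$random_dish)
      stop("total_offspring is a dish-level response; it has one row per ",
           "dish, so a dish random intercept is not identifiable",
           call. = FALSE)
    fit <- stats::lm(stats::as.formula(paste("total_offspring ~", rhs_fixed)),
                     data = dat)
    converged <- TRUE
  } else {
    if (spec$response == "parasitized") {
      dat <- tab
      dat$.y <- as.integer(dat$parasitized)
      lhs <- ".y"
      fam <- stats::binomial()
    } else if (spec$response == "sex") {
      dat <- tab[tab$parasitized, , drop = FALSE]
      if (nrow(dat) == 0L) stop("no parasitized rows", call. = FALSE)
      lhs <- "cbind(n_females, clutch_size - n_females)"
      fam <- stats::binomial()
    } else { # clutch_size
      dat <- tab[tab$parasitized, , drop = FALSE]
      if (nrow(dat) == 0L) stop("no parasitized rows", call. = FALSE)
      if (spec$transform == "shift_minus_1") {
        dat$.y <- dat$clutch_size - 1L
      } else dat$.y <- dat$clutch_size
      lhs <- ".y"
      fam <- switch(spec$family, poisson = stats::poisson(),
                    gaussian = stats::gaussian(), binomial =
                      stop("binomial family is not meaningful for clutch size",
                           call. = FALSE))
    }
    if (spec$random_dish) {
      form <- stats::as.formula(
        paste(lhs, "~", rhs_fixed, "+ (1 | founder_id)"))
      if (spec$family == "gaussian") {
        fit <- lme4::lmer(form, data = dat, REML = FALSE)
      } else {
        fit <- suppressMessages(
          lme4::glmer(form, data = dat, family = fam))
      }
      msgs <- fit@optinfo$conv$lme4$messages
      converged <- is.null(msgs) ||
        !any(grepl("failed to converge", msgs, ignore.case = TRUE))
    } else {
      form <- stats::as.formula(paste(lhs, "~", rhs_fixed))
      if (spec$family == "gaussian") {
        fit <- stats::lm(form, data = dat)
        converged <- TRUE
      } else {
        fit <- stats::glm(form, data = dat, family = fam)
        converged <- fit$converged
        if (!converged)
          warning("GLM did not converge (possible complete separation); ",
                  "treat coefficients with caution")
      }
    }
  }
  ll <- stats::logLik(fit)
  coefs <- tryCatch({
    s <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
    se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)))),
                   error = function(e) rep(NA_real_, length(s)))
    data.frame(term = names(s), estimate = as.numeric(s),
               std_error = as.numeric(se))
  }, error = function(e) NULL)
  structure(list(fit = fit, spec = spec, logLik = as.numeric(ll),
                 n_params = attr(ll, "df"), nobs = stats::nobs(fit),
                 coefficients = coefs, converged = converged),
            class = "fitted_contrast")
}

#' @export
print.fitted_contrast <- function(x, ...) {
  cat("Fitted contrast:", x$spec$response, "~",
      if (length(x$spec$fixed)) paste(x$spec$fixed, collapse = " + ")
      else "1",
      if (x$spec$random_dish) "+ (1 | dish)" else "", "\n")
  cat(sprintf("  family %s, logLik %.3f, %d parameters, n = %d%s\n",
              x$spec$family, x$logLik, x$n_params, x$nobs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' Twice the log-likelihood difference against a chi-square reference with
#' degrees of freedom equal to the parameter-count difference — the ANOVA
#' model-comparison convention for the battery. Numerically negative
#' statistics are clamped at zero with a warning.
#'
#' @param full,reduced \code{fitted_contrast} handles on the same data;
#'   \code{reduced} must be nested in \code{full}.
#' @return A \code{comparison_result}: statistic, df, p-value, the full
#'   model's coefficient table and convergence flags.
#' @export
lrt_compare <- function(full, reduced) {
  stopifnot(inherits(full, "fitted_contrast"),
            inherits(reduced, "fitted_contrast"))
  if (full$nobs != reduced$nobs)
    stop("models were fitted to different data (", full$nobs, " vs ",
         reduced$nobs, " observations)", call. = FALSE)
  if (full$spec$response != reduced$spec$response)
    stop("models have different responses; not nested", call. = FALSE)
  if (!all(reduced$spec$fixed %in% full$spec$fixed) ||
      (reduced$spec$random_dish && !full$spec$random_dish))
    stop("`reduced` is not nested in `full`", call. = FALSE)
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("`reduced` has more parameters than `full`", call. = FALSE)
  stat <- 2 * (full$logLik - reduced$logLik)
  if (stat < 0) {
    if (stat < -1e-6)
      warning("negative likelihood-ratio statistic (", format(stat),
              ") clamped to 0; check convergence")
    stat <- 0
  }
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 estimates = full$coefficients,
                 converged = full$converged && reduced$converged),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("LRT: chi-square(%d) = %.3f, p = %.4g%s\n", x$df, x$statistic,
              x$p_value, if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' 95% confidence interval for a group outcome
#'
#' Gaussian outcomes get a t interval; binomial proportions the exact
#' Clopper-Pearson interval; Poisson counts the exact chi-square-based
#' interval.
#'
#' @param values For \code{"gaussian"}: the raw observations. For
#'   \code{"binomial"}: \code{c(successes, trials)}. For \code{"poisson"}:
#'   \code{c(count)} or \code{c(count, exposure)}.
#' @param family \code{"gaussian"}, \code{"binomial"} or \code{"poisson"}.
#' @return Numeric \code{c(lower, upper)}.
#' @export
#' @examples
#' interval_95(c(5, 10), family = "binomial")  # 0.187 .. 0.813
interval_95 <- function(values, family = c("gaussian", "binomial",
                                           "poisson")) {
  family <- match.arg(family)
  if (length(values) == 0L) stop("no values supplied", call. = FALSE)
  switch(family,
    gaussian = {
      n <- length(values)
      if (n == 1L) {
        warning("single observation: interval width undefined")
        return(c(NA_real_, NA_real_))
      }
      m <- mean(values)
      half <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
      c(m - half, m + half)
    },
    binomial = {
      if (length(values) != 2L)
        stop("binomial interval needs c(successes, trials)", call. = FALSE)
      x <- values[1L]; n <- values[2L]
      if (n < 1 || x < 0 || x > n)
        stop("need 0 <= successes <= trials, trials >= 1", call. = FALSE)
      lower <- if (x == 0) 0 else stats::qbeta(0.025, x, n - x + 1)
      upper <- if (x == n) 1 else stats::qbeta(0.975, x + 1, n - x)
      c(lower, upper)
    },
    poisson = {
      x <- values[1L]
      exposure <- if (length(values) >= 2L) values[2L] else 1
      if (x < 0 || exposure <= 0)
        stop("need count >= 0 and exposure > 0", call. = FALSE)
      lower <- if (x == 0) 0 else stats::qchisq(0.025, 2 * x) / 2
      upper <- stats::qchisq(0.975, 2 * (x + 1)) / 2
      c(lower, upper) / exposure
    })
}

battery_row <- function(experiment, response, factor_name, cmp, note = "") {
  data.frame(experiment = experiment, response = response,
             factor = factor_name,
             statistic = if (is.null(cmp)) NA_real_ else cmp$statistic,
             df = if (is.null(cmp)) NA_integer_ else cmp$df,
             p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
             converged = if (is.null(cmp)) NA else cmp$converged,
             note = note)
}

run_one_contrast <- function(tab, response, family, factor_name,
                             random_dish) {
  full <- fit_model(tab, model_spec(response, family, fixed = factor_name,
                                    random_dish = random_dish))
  red <- fit_model(tab, model_spec(response, family, fixed = character(0),
                                   random_dish = random_dish))
  lrt_compare(full, red)
}

#' Run the full experimental comparison battery
#'
#' For each experiment table supplied, runs the study's contrast grid:
#' parasitism rate (GLM-b), offspring sex ratio (GLMM-b), clutch size
#' (GLMM-p with the minus-one shift), and per-dish offspring total (LM),
#' each against the experiment's design factor (substrate, choice vs
#' no-choice test type, or host-offer group). Mixed-effect models carry the
#' dish random intercept and are compared with null models holding the
#' random factor only. Missing groups skip their contrasts with an explicit
#' notice. No multiple-testing correction is applied (per-contrast
#' p-values); set \code{holm = TRUE} to add Holm-adjusted p-values.
#'
#' @param tables Named list of host-egg tables; recognised names:
#'   \code{no_choice} (three substrate arms), \code{choice} (the choice
#'   test; combined with \code{no_choice} for the test-type contrast),
#'   \code{fict} (fictitious-host experiment, groups \code{fict_host_mix},
#'   \code{low_density}, \code{high_density}).
#' @param holm Add a Holm-corrected p-value column?
#' @return data.frame, one row per contrast: experiment, response, factor,
#'   LRT statistic, df, p-value, convergence flag and notes.
#' @export
run_paper_battery <- function(tables, holm = FALSE) {
  out <- list()
  add <- function(row) out[[length(out) + 1L]] <<- row

  safe <- function(experiment, response, expr, factor_name) {
    res <- tryCatch(expr, error = function(e)
      structure(list(msg = conditionMessage(e)), class = "battery_skip"))
    if (inherits(res, "battery_skip")) {
      add(battery_row(experiment, response, factor_name, NULL,
                      note = paste("skipped:", res$msg)))
    } else add(battery_row(experiment, response, factor_name, res))
  }

  nc <- tables$no_choice
  if (!is.null(nc) && length(unique(nc$substrate)) >= 2) {
    safe("no_choice", "parasitized",
         run_one_contrast(nc, "parasitized", "binomial", "substrate", FALSE),
         "substrate")
    safe("no_choice", "sex",
         run_one_contrast(nc, "sex", "binomial", "substrate", TRUE),
         "substrate")
    safe("no_choice", "clutch_size",
         run_one_contrast(nc, "clutch_size", "poisson", "substrate", TRUE),
         "substrate")
    safe("no_choice", "total_offspring",
         run_one_contrast(nc, "total_offspring", "gaussian", "substrate",
                          FALSE), "substrate")
  } else if (!is.null(nc)) {
    add(battery_row("no_choice", "all", "substrate", NULL,
                    note = "skipped: fewer than two substrate groups"))
  }

  ch <- tables$choice
  if (!is.null(ch) && !is.null(nc)) {
    comb <- rbind(cbind(nc, test_type = "no_choice"),
                  cbind(ch, test_type = "choice"))
    safe("choice_vs_no_choice", "parasitized",
         run_one_contrast(comb, "parasitized", "binomial", "test_type",
                          FALSE), "test_type")
    safe("choice_vs_no_choice", "sex",
         run_one_contrast(comb, "sex", "binomial", "test_type", TRUE),
         "test_type")
    safe("choice_vs_no_choice", "clutch_size",
         run_one_contrast(comb, "clutch_size", "poisson", "test_type", TRUE),
         "test_type")
    safe("choice_vs_no_choice", "total_offspring",
         run_one_contrast(comb, "total_offspring", "gaussian", "test_type",
                          FALSE), "test_type")
  } else if (!is.null(ch)) {
    add(battery_row("choice_vs_no_choice", "all", "test_type", NULL,
                    note = "skipped: no no-choice table to compare against"))
  }

  ft <- tables$fict
  if (!is.null(ft)) {
    grs <- unique(ft$group)
    pairs <- list(c("fict_host_mix", "low_density"),
                  c("fict_host_mix", "high_density"))
    for (pr in pairs) {
      lab <- paste(pr, collapse = "_vs_")
      if (!all(pr %in% grs)) {
        add(battery_row(lab, "all", "group", NULL,
                        note = paste("skipped: missing group(s)",
                                     paste(setdiff(pr, grs),
                                           collapse = ", "))))
        next
      }
      sub <- ft[ft$group %in% pr, , drop = FALSE]
      safe(lab, "parasitized",
           run_one_contrast(sub, "parasitized", "binomial", "group", FALSE),
           "group")
      safe(lab, "sex",
           run_one_contrast(sub, "sex", "binomial", "group", TRUE), "group")
      safe(lab, "clutch_size",
           run_one_contrast(sub, "clutch_size", "poisson", "group", TRUE),
           "group")
      safe(lab, "total_offspring",
           run_one_contrast(sub, "total_offspring", "gaussian", "group",
                            FALSE), "group")
    }
  }

  rep_tab <- do.call(rbind, out)
  rownames(rep_tab) <- NULL
  if (holm) rep_tab$p_holm <- stats::p.adjust(rep_tab$p_value,
                                              method = "holm")
  rep_tab
}
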