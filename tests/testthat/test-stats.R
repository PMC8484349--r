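test_that("binomial GLM recovers the closed-form log-odds from a 2x2 table", {
  # 20/40 parasitized on one substrate, 30/40 on the other:
  # log-odds difference = log((30/10) / (20/20)) = log(3)
  mk <- function(substrate, n_par, n_tot, offset = 0) {
    par <- c(rep(TRUE, n_par), rep(FALSE, n_tot - n_par))
    data.frame(founder_id = paste0(substrate, "_", seq_len(n_tot) + offset),
               group = "g", substrate = substrate, host_species = "native",
               parasitized = par,
               clutch_size = ifelse(par, 1L, NA_integer_),
               n_females = ifelse(par, 0L, NA_integer_),
               emerged = par)
  }
  tab <- rbind(mk("usual_plant", 20, 40), mk("fictitious_plant", 30, 40))
  fit <- fit_model(tab, model_spec("parasitized", "binomial",
                                   fixed = "substrate"))
  slope <- fit$coefficients$estimate[
    grepl("substrate", fit$coefficients$term)]
  expect_equal(abs(slope), log(3), tolerance = 1e-6)
})

test_that("a constant response gives equal null and full log-likelihoods", {
  tab <- simulate_two_arm(p = c(1, 1), seed = 4)
  full <- suppressWarnings(
    fit_model(tab, model_spec("parasitized", "binomial",
                              fixed = "substrate")))
  red <- suppressWarnings(
    fit_model(tab, model_spec("parasitized", "binomial")))
  expect_equal(full$logLik, red$logLik, tolerance = 1e-8)
  cmp <- lrt_compare(full, red)
  expect_equal(cmp$statistic, 0, tolerance = 1e-6)
})

test_that("GLMM on dish-homogeneous data collapses to the GLM fit", {
  # generated with dish_sd = 0, so the random-intercept variance should hit
  # the boundary and fixed effects should match the plain GLM
  tab <- simulate_two_arm(p = c(0.4, 0.7), seed = 6, dish_sd = 0,
                          n_per_arm = 25)
  glmm <- fit_model(tab, model_spec("parasitized", "binomial",
                                    fixed = "substrate", random_dish = TRUE))
  glm_ <- fit_model(tab, model_spec("parasitized", "binomial",
                                    fixed = "substrate"))
  vc <- lme4::VarCorr(glmm$fit)
  expect_lt(sqrt(as.numeric(vc$founder_id)), 0.15)
  expect_equal(glmm$coefficients$estimate, glm_$coefficients$estimate,
               tolerance = 1e-2)
})

test_that("likelihood-ratio comparison enforces nesting and clamps at zero", {
  tab <- simulate_two_arm(p = c(0.4, 0.8), seed = 2)
  full <- fit_model(tab, model_spec("parasitized", "binomial",
                                    fixed = "substrate"))
  red <- fit_model(tab, model_spec("parasitized", "binomial"))
  cmp <- lrt_compare(full, red)
  expect_gte(cmp$statistic, 0)
  expect_identical(cmp$df, 1L)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  # identical model compared with itself: statistic 0, p = 1
  self <- lrt_compare(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # clutch-size and parasitism fits are not nested
  clutch <- fit_model(tab, model_spec("clutch_size", "poisson",
                                      fixed = "substrate",
                                      random_dish = TRUE))
  expect_error(lrt_compare(clutch, red), "different data|not nested")
})

test_that("statistics are invariant to row permutation", {
  tab <- simulate_two_arm(p = c(0.3, 0.7), seed = 9)
  shuffled <- tab[sample(nrow(tab)), ]
  for (resp in list(c("parasitized", "binomial", FALSE),
                    c("clutch_size", "poisson", TRUE))) {
    s_full <- model_spec(resp[1], resp[2], fixed = "substrate",
                         random_dish = as.logical(resp[3]))
    s_red <- model_spec(resp[1], resp[2],
                        random_dish = as.logical(resp[3]))
    c1 <- lrt_compare(fit_model(tab, s_full), fit_model(tab, s_red))
    c2 <- lrt_compare(fit_model(shuffled, s_full), fit_model(shuffled, s_red))
    expect_equal(c1$statistic, c2$statistic, tolerance = 1e-6)
  }
})

test_that("the Poisson clutch-size model applies the minus-one shift", {
  spec <- model_spec("clutch_size", "poisson", fixed = "substrate",
                     random_dish = TRUE)
  expect_identical(spec$transform, "shift_minus_1")
  # all-singleton clutches become all-zero counts: intercept -> -Inf guard
  tab <- simulate_two_arm(p = c(1, 1), seed = 3)
  tab$clutch_size[tab$parasitized] <- 1L
  tab$n_females[tab$parasitized] <- 0L
  fit <- suppressWarnings(fit_model(tab, model_spec("clutch_size", "poisson",
                                                    random_dish = FALSE)))
  expect_true(is.finite(fit$logLik))
})

test_that("confidence intervals use the exact forms per family", {
  # Clopper-Pearson closed form for 5 of 10
  ci <- interval_95(c(5, 10), family = "binomial")
  expect_equal(ci[1], qbeta(0.025, 5, 6), tolerance = 1e-12)
  expect_equal(ci[2], qbeta(0.975, 6, 5), tolerance = 1e-12)
  expect_equal(ci, c(0.187086, 0.812914), tolerance = 1e-5)
  # zero successes pins the lower bound at 0
  expect_equal(interval_95(c(0, 10), family = "binomial")[1], 0)
  expect_equal(interval_95(c(10, 10), family = "binomial")[2], 1)
  # gaussian t-interval
  x <- c(4, 6, 5, 7, 3)
  ci_g <- interval_95(x, family = "gaussian")
  half <- qt(0.975, 4) * sd(x) / sqrt(5)
  expect_equal(ci_g, c(mean(x) - half, mean(x) + half))
  expect_warning(interval_95(5, family = "gaussian"), "single observation")
  # exact Poisson interval
  ci_p <- interval_95(c(7), family = "poisson")
  expect_equal(ci_p[1], qchisq(0.025, 14) / 2)
  expect_equal(ci_p[2], qchisq(0.975, 16) / 2)
})

test_that("the comparison battery runs the contrast grid and skips missing groups", {
  params <- generator_params(dish_sd = 0.3)
  nc <- do.call(rbind, simulate_study(params, global_seed = 3,
    scenarios = c("no_choice_usual", "no_choice_fictplant",
                  "no_choice_control")))
  ch <- simulate_study(params, global_seed = 3, scenarios = "choice")$choice
  ft <- do.call(rbind, simulate_study(params, global_seed = 3,
    scenarios = c("fict_host_mix", "low_density")))
  rep_tab <- run_paper_battery(list(no_choice = nc, choice = ch, fict = ft),
                               holm = TRUE)
  expect_true(all(c("experiment", "response", "statistic", "df", "p_value")
                  %in% names(rep_tab)))
  done <- rep_tab[!is.na(rep_tab$p_value), ]
  expect_true(all(done$p_value >= 0 & done$p_value <= 1))
  expect_true(all(done$statistic >= 0))
  expect_true(any(grepl("skipped: missing group",
                        rep_tab$note[rep_tab$experiment ==
                          "fict_host_mix_vs_high_density"])))
  expect_true("p_holm" %in% names(rep_tab))
  # no-choice grid covers the four response families
  expect_setequal(
    rep_tab$response[rep_tab$experiment == "no_choice"],
    c("parasitized", "sex", "clutch_size", "total_offspring"))
})

test_that("dish-level response refuses a non-identifiable dish random effect", {
  tab <- simulate_two_arm(seed = 1)
  expect_error(fit_model(tab, model_spec("total_offspring", "gaussian",
                                         fixed = "substrate",
                                         random_dish = TRUE)),
               "not identifiable")
})
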