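# Gamma GLMM, Wald contrasts, fold-change ratios.

test_that("the GLMM recovers effects on zero-random-effect data", {
  tab <- gen_attachment_table(attachment_sim_spec(
    sd_sample = 0, sd_image = 0, gamma_shape = 400,
    n_flies_per_genotype = 15L, seed = 110))
  truth <- attr(tab, "truth")
  fit <- fit_gamma_glmm(tab)
  # variances at the zero boundary legitimately trip optimizer diagnostics,
  # so convergence is asserted on the regular fit below, not here
  for (g in c("closed", "ko", "double")) {
    j <- paste0("genotype", g)
    expect_lt(abs(fit$beta[[j]] - truth$beta[[g]]), 2 * fit$se_beta[[j]])
  }
  expect_lt(fit$var_sample, 0.005)
  expect_lt(fit$var_image, 0.005)
  expect_gt(fit$shape, 100)
})

test_that("single-coefficient contrasts reproduce the coefficient z test", {
  tab <- gen_attachment_table(attachment_sim_spec(seed = 111))
  fit <- fit_gamma_glmm(tab)
  expect_true(fit$converged)
  expect_true(fit$pd_hessian)
  j <- which(names(fit$beta) == "genotypeclosed")
  cv <- setNames(rep(0, length(fit$beta)), names(fit$beta))
  cv[j] <- 1
  res <- wald_contrasts(fit, list(closed = cv))
  expect_equal(res$estimate, unname(fit$beta[j]))
  expect_equal(res$se, unname(fit$se_beta[j]))
  expect_equal(res$z, unname(fit$beta[j] / fit$se_beta[j]))
  expect_equal(res$p_bonferroni, res$p_raw)  # m = 1
})

test_that("contrast machinery agrees with the multcomp reference", {
  # cross-check the Wald linear algebra on a fixed-effect gamma GLM, where
  # multcomp::glht applies directly
  tab <- gen_attachment_table(attachment_sim_spec(sd_sample = 0, sd_image = 0,
                                                  seed = 112))
  glm_fit <- stats::glm(length ~ genotype, data = tab,
                        family = stats::Gamma(link = "log"))
  shim <- structure(list(beta = coef(glm_fit),
                         se_beta = sqrt(diag(vcov(glm_fit))),
                         vcov_beta = as.matrix(vcov(glm_fit))),
                    class = "glmm_fit")
  K <- rbind(closed_vs_wt = c(0, 1, 0, 0),
             ko_vs_wt = c(0, 0, 1, 0),
             double_vs_additive = c(0, -1, -1, 1))
  ours <- wald_contrasts(shim, list(closed_vs_wt = K[1, ], ko_vs_wt = K[2, ],
                                    double_vs_additive = K[3, ]))
  ref <- summary(multcomp::glht(glm_fit, linfct = K),
                 test = multcomp::adjusted("none"))
  expect_equal(ours$estimate, unname(ref$test$coefficients), tolerance = 1e-8)
  expect_equal(ours$se, unname(ref$test$sigma), tolerance = 1e-8)
  expect_equal(ours$p_raw, unname(ref$test$pvalues), tolerance = 1e-6)
})

test_that("the fit agrees with an independent mixed-model engine", {
  tab <- gen_attachment_table(attachment_sim_spec(seed = 116))
  fit <- fit_gamma_glmm(tab)
  ref <- suppressWarnings(lme4::glmer(
    length ~ genotype + (1 | sample / image), data = tab,
    family = stats::Gamma(link = "log")))
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 5e-3)
  # and with the random effects dropped on zero-variance data the fixed
  # effects match a plain GLM closely
  flat <- gen_attachment_table(attachment_sim_spec(sd_sample = 0, sd_image = 0,
                                                   seed = 117))
  f1 <- fit_gamma_glmm(flat)
  f0 <- stats::glm(length ~ genotype, data = flat,
                   family = stats::Gamma(link = "log"))
  expect_lt(max(abs(f1$beta - coef(f0))), 1e-3)
})

test_that("responses rescaled by lambda shift only the intercept", {
  tab <- gen_attachment_table(attachment_sim_spec(seed = 113))
  fit1 <- fit_gamma_glmm(tab)
  tab2 <- tab; tab2$length <- tab2$length * 4.2
  fit2 <- fit_gamma_glmm(tab2)
  expect_equal(fit2$beta[["(Intercept)"]] - fit1$beta[["(Intercept)"]],
               log(4.2), tolerance = 1e-4)
  c1 <- wald_contrasts(fit1); c2 <- wald_contrasts(fit2)
  # bounded by the optimizer's convergence reproducibility (~2e-6)
  expect_lt(max(abs(c1$estimate - c2$estimate)), 1e-5)
})

test_that("Bonferroni adjustment is monotone and capped at 1", {
  tab <- gen_attachment_table(attachment_sim_spec(seed = 114))
  fit <- fit_gamma_glmm(tab)
  res <- wald_contrasts(fit)
  expect_true(all(res$p_bonferroni >= res$p_raw))
  expect_true(all(res$p_bonferroni <= 1))
  expect_equal(res$p_bonferroni, pmin(1, 3 * res$p_raw))
})

test_that("the epistasis contrast detects a planted interaction", {
  hits <- vapply(1:10, function(r) {
    tab <- gen_attachment_table(attachment_sim_spec(delta = 0.3, seed = 700 + r))
    cons <- wald_contrasts(fit_gamma_glmm(tab))
    cons$p_raw[cons$contrast == "double_vs_additive"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)  # power well above one half at delta = 0.3
})

test_that("input validation catches bad responses and broken nesting", {
  tab <- gen_attachment_table(attachment_sim_spec(seed = 115))
  bad <- tab; bad$length[1] <- -1
  expect_error(fit_gamma_glmm(bad), "positive")
  crossed <- tab
  crossed$image <- "shared_image"   # one image id across all samples
  expect_error(fit_gamma_glmm(crossed), "nesting")
})

test_that("fold-change ratios follow the defining arithmetic", {
  tab <- data.frame(lane = 1:3,
                    phospho_intensity = c(10, 10, 5),
                    total_intensity = c(20, 20, 20),
                    genotype = c("wt", "wt", "mut"))
  out <- fold_change_ratio(tab, "wt")
  expect_equal(out$ratio[out$genotype == "mut"], (5 / 10) / (20 / 20))  # 0.5
  expect_equal(mean(out$ratio[out$genotype == "wt"]), 1)
  # halving phospho in one genotype halves its ratio
  tab2 <- tab; tab2$phospho_intensity[3] <- 2.5
  out2 <- fold_change_ratio(tab2, "wt")
  expect_equal(out2$ratio[3], out$ratio[3] / 2)
  expect_error(fold_change_ratio(tab, "nope"), "not present")
  tab3 <- tab; tab3$total_intensity[2] <- 0
  expect_error(fold_change_ratio(tab3, "wt"), "positive")
})
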