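test_that("imputation-quality filter uses a strict < rule", {
  geno <- matrix(sample(0:2, 40, TRUE), 10, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  hc <- human_cohort(geno, r2 = c(0.9, 0.69, 0.70, 0.71),
                     outcome = rep(c(0, 1), 5))
  expect_message(f <- filter_by_imputation(hc), "1 SNV")
  expect_equal(colnames(f$geno), c("s1", "s3", "s4"))  # 0.70 kept
  hc2 <- human_cohort(geno, r2 = rep(1, 4), outcome = rep(c(0, 1), 5))
  expect_equal(ncol(filter_by_imputation(hc2)$geno), 4L)
  # randomized: exactly k below threshold removed
  set.seed(2)
  r2 <- runif(50)
  hc3 <- human_cohort(matrix(sample(0:2, 500, TRUE), 10, 50,
                             dimnames = list(NULL, paste0("x", 1:50))),
                      r2 = r2)
  expect_equal(ncol(suppressMessages(filter_by_imputation(hc3))$geno),
               sum(r2 >= 0.7))
})

test_that("CDA case labelling uses an inclusive 5-point drop at any time point", {
  expect_equal(label_cda_cases(60, 55), 1L)      # boundary drop is a case
  expect_equal(label_cda_cases(60, 55.5), 0L)    # 4.5 points: control
  base <- c(60, 62, 58, 65, 55, 70, 61, 59, 63, 64)
  fu <- base - c(5, 4, 6, 0, -2, 10, 4.9, 5.1, 2, 7)
  expect_equal(sum(label_cda_cases(base, fu)), 5L)  # hand count
  # any qualifying follow-up time point makes a case
  fu2 <- cbind(first6mo = c(58, 60), final = c(54, 59))
  expect_equal(label_cda_cases(c(60, 62), fu2), c(1L, 0L))
  # missing follow-up excludes the patient
  expect_message(lab <- label_cda_cases(c(60, 62), c(50, NA)), "excluded")
  expect_equal(lab, c(1L, NA_integer_))
})

test_that("genetic-model encodings follow the field's definitions", {
  d <- c(0, 1, 2)
  expect_equal(drop(encode_genetic_model(d, "dominant")), c(0, 1, 1))
  expect_equal(drop(encode_genetic_model(d, "recessive")), c(0, 0, 1))
  expect_equal(drop(encode_genetic_model(d, "overdominant")), c(0, 1, 0))
  expect_equal(drop(encode_genetic_model(d, "log-additive")), c(0, 1, 2))
  cod <- encode_genetic_model(d, "codominant")
  expect_equal(dim(cod), c(3L, 2L))
  expect_equal(cod[, "het"], c(0, 1, 0))
  expect_equal(cod[, "hom_alt"], c(0, 0, 1))
  # identity: log-additive = dominant + recessive, elementwise
  set.seed(4)
  dd <- sample(0:2, 100, TRUE)
  expect_equal(drop(encode_genetic_model(dd, "log-additive")),
               drop(encode_genetic_model(dd, "dominant")) +
                 drop(encode_genetic_model(dd, "recessive")))
  expect_error(encode_genetic_model(c(0, 3), "dominant"), "0/1/2")
})

test_that("single-SNV association matches closed-form 2x2 and saturated oracles", {
  # dominant 2x2 table: cases 10 exposed/10 unexposed, controls 5/20
  d <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 20))
  y <- c(rep(1, 20), rep(0, 25))
  res <- associate_snv(cbind(snvA = d), "snvA", model = "dominant",
                       outcome = y)
  expect_equal(res$or, (10 * 20) / (10 * 5), tolerance = 1e-6)
  expect_false(res$separated)
  # null SNV, balanced table -> OR ~ 1
  set.seed(10)
  g0 <- sample(0:2, 400, TRUE, prob = c(.49, .42, .09))
  y0 <- rep(c(0, 1), 200)
  res0 <- associate_snv(cbind(s = g0), "s", "log-additive", outcome = y0)
  expect_lt(abs(log(res0$or)), 0.35)
  expect_gt(res0$p, 0.001)
  # codominant model saturates a 2x3 table: fitted probabilities equal
  # per-genotype case fractions (brute-force MLE of the table)
  g <- rep(c(0, 1, 2), c(60, 80, 40))
  # per-genotype case fractions 0.2, 0.45, 0.7 laid out deterministically
  yc <- c(rep(c(1, 0), c(12, 48)), rep(c(1, 0), c(36, 44)),
          rep(c(1, 0), c(28, 12)))
  X <- encode_genetic_model(g, "codominant")
  fit <- stats::glm(yc ~ X, family = stats::binomial())
  fitted_by_geno <- tapply(stats::fitted(fit), g, mean)
  observed <- tapply(yc, g, mean)
  expect_equal(unname(fitted_by_geno), unname(observed), tolerance = 1e-6)
  resc <- associate_snv(cbind(s = g), "s", "codominant", outcome = yc)
  expect_equal(nrow(resc), 2L)             # het and hom-alt odds ratios
  expect_equal(resc$or[1L], (0.45 / 0.55) / (0.2 / 0.8), tolerance = 1e-3)
  # separation flagged and handled
  ds <- c(rep(0, 20), rep(2, 20))
  ys <- c(rep(0, 20), rep(1, 20))
  ress <- associate_snv(cbind(s = ds), "s", "log-additive", outcome = ys)
  expect_true(ress$separated)
  expect_true(is.finite(ress$or))
})

test_that("best_genetic_model flags the lowest-AIC encoding", {
  set.seed(15)
  g <- sample(0:2, 300, TRUE, prob = c(.49, .42, .09))
  y <- rbinom(300, 1, stats::plogis(-1 + 1.5 * (g == 1)))  # overdominant truth
  tab <- best_genetic_model(cbind(s = g), "s", outcome = y)
  expect_equal(sum(tab$chosen), 1L)
  expect_equal(tab$model[tab$chosen], "overdominant")
})

test_that("Youden cutoff equals the exhaustive sweep and obeys the tie rule", {
  res <- optimize_cutoff_youden(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(res$cutoff, 0.8)
  expect_equal(res$J, 1)
  set.seed(33)
  for (i in 1:10) {
    sc <- round(runif(40), 2)  # ties likely
    lb <- rbinom(40, 1, 0.4)
    if (length(unique(lb)) < 2) next
    mine <- optimize_cutoff_youden(sc, lb)
    orac <- oracle_youden(sc, lb)
    expect_equal(mine$J, orac$J, tolerance = 1e-12)
    expect_equal(mine$cutoff, orac$cutoff)
  }
  # random labels -> J near 0
  set.seed(34)
  jnull <- mean(replicate(100, {
    optimize_cutoff_youden(runif(100), rbinom(100, 1, 0.5))$J
  }))
  expect_lt(jnull, 0.25)
  expect_error(optimize_cutoff_youden(runif(5), rep(1, 5)), "both classes")
})

test_that("bootstrap selection is seeded, powered, and specific", {
  set.seed(50)
  n <- 336
  maf <- 0.3
  g_causal <- rbinom(n, 2, maf)
  geno <- cbind(causal = g_causal,
                matrix(rbinom(n * 30, 2, maf), n, 30,
                       dimnames = list(NULL, paste0("null", 1:30))))
  y <- rbinom(n, 1, stats::plogis(qlogis(0.3) + log(8) * (g_causal - 2 * maf)))
  sel <- bootstrap_select_snvs(geno, y, n_iter = 100, seed = 7)
  expect_true("causal" %in% sel$snv)
  expect_gte(sel$hits[sel$snv == "causal"], 50)
  # identical seed -> identical hit counts; different seed differs somewhere
  sel2 <- bootstrap_select_snvs(geno, y, n_iter = 100, seed = 7)
  expect_identical(attr(sel, "all_hits"), attr(sel2, "all_hits"))
  expect_error(bootstrap_select_snvs(geno, y, n_iter = 0, seed = 1), "n_iter")
  # null SNVs almost never reach 5 hits
  hits_null <- attr(sel, "all_hits")[-1L]
  expect_lte(sum(hits_null >= 5), 1L)
})

test_that("the lasso risk model matches its limits and is seed-stable", {
  set.seed(60)
  n <- 300
  geno <- matrix(rbinom(n * 8, 2, 0.3), n, 8,
                 dimnames = list(NULL, paste0("s", 1:8)))
  lp <- qlogis(0.3) + log(2.5) * (geno[, 1] - 0.6) + log(2.5) * (geno[, 2] - 0.6)
  y <- rbinom(n, 1, stats::plogis(lp))
  m <- fit_lasso_risk_model(geno, y, candidates = paste0("s", 1:8), seed = 3)
  m2 <- fit_lasso_risk_model(geno, y, candidates = paste0("s", 1:8), seed = 3)
  expect_identical(m$coef, m2$coef)
  expect_true(m$cutoff >= 0 && m$cutoff <= 1)
  expect_true(all(names(m$coef) %in% paste0("s", 1:8)))
  # lambda -> infinity: intercept-only
  big <- glmnet::glmnet(geno, y, family = "binomial", lambda = 10)
  expect_equal(sum(abs(as.numeric(big$beta))), 0)
  # lambda = 0 equals the unpenalized logistic fit
  g0 <- glmnet::glmnet(geno, y, family = "binomial", lambda = 0,
                       thresh = 1e-12)
  ref <- stats::glm(y ~ geno, family = stats::binomial())
  expect_equal(as.numeric(g0$beta), unname(stats::coef(ref))[-1L],
               tolerance = 1e-4)
  # single-candidate fallback is flagged
  m1 <- fit_lasso_risk_model(geno, y, candidates = "s1", seed = 3)
  expect_true(m1$single_candidate)
  expect_equal(m1$lambda, 0)
})

test_that("test-set evaluation is consistent and errors on missing SNVs", {
  set.seed(61)
  n <- 200
  geno <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
                 dimnames = list(NULL, paste0("s", 1:5)))
  y <- rbinom(n, 1, stats::plogis(-0.5 + 0.9 * (geno[, 1] - 0.6)))
  m <- fit_lasso_risk_model(geno, y, candidates = paste0("s", 1:5), seed = 5)
  self <- evaluate_on_test(m, geno, y)
  expect_equal(unname(self), unname(m$train_metrics), tolerance = 1e-12)
  mfix <- m
  mfix$snvs <- "s1"; mfix$coef <- c(s1 = 0.5)
  expect_error(evaluate_on_test(mfix, geno[, -1L, drop = FALSE], y), "lacks")
  # uninformative model on a balanced set -> AUC ~ 0.5
  mnull <- m; mnull$coef <- stats::setNames(numeric(0), character(0))
  mnull$snvs <- character(0)
  aucs <- evaluate_on_test(mnull, geno, rep(c(0, 1), 100))["auc"]
  expect_equal(unname(aucs), 0.5, tolerance = 1e-6)
})

test_that("VCF dosages are read with R2, missing and multi-allelic handling", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2\tP3",
    "1\t100\trs1\tA\tG\t.\tPASS\tR2=0.95\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\tR2=0.55\tGT\t0|1\t./.\t0/0",
    "1\t300\trs3\tG\tA,C\t.\tPASS\tR2=0.9\tGT\t0/0\t0/1\t0/0")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_warning(hc <- read_vcf_dosages(f), "multi-allelic")
  expect_equal(colnames(hc$geno), c("rs1", "rs2"))
  expect_equal(unname(hc$geno[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(hc$geno[, "rs2"]), c(1, NA, 0))
  expect_equal(unname(hc$r2), c(0.95, 0.55))
  expect_equal(rownames(hc$geno), c("P1", "P2", "P3"))
  # the R2 < 0.7 filter then drops rs2
  expect_equal(colnames(suppressMessages(filter_by_imputation(hc))$geno),
               "rs1")
})
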