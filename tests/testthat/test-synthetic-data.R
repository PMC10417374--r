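test_that("the default genome matches the stated marker density", {
  map <- default_genetic_map()
  expect_equal(nrow(map), 1499L)
  expect_equal(length(attr(map, "chromosomes")), 19L)
  expect_true(all(tapply(map$pos_cM, map$chr, max) == 70))
})

test_that("backcross genotype simulation is seeded and marginally fair", {
  map <- default_genetic_map(n_chr = 2L, chr_len_cM = 50, n_markers = 20L)
  b1 <- simulate_backcross_genotypes(map, 50, seed = 1)
  b2 <- simulate_backcross_genotypes(map, 50, seed = 1)
  expect_identical(b1$geno, b2$geno)
  b3 <- simulate_backcross_genotypes(map, 50, seed = 2)
  expect_false(identical(b1$geno, b3$geno))
  # per-marker heterozygote frequency ~ 0.5 within binomial 99% CI, n=2000
  big <- simulate_backcross_genotypes(map, 2000, seed = 9, missing_rate = 0)
  het <- colMeans(big$geno)
  ci <- 2.576 * sqrt(0.25 / 2000)
  expect_gt(mean(abs(het - 0.5) <= ci), 0.95)
  # adjacent-marker recombination fraction matches Haldane within 99% CI
  sel <- which(map$chr == "1")
  d <- diff(map$pos_cM[sel])
  for (j in seq_along(d)) {
    obs <- mean(big$geno[, sel[j]] != big$geno[, sel[j + 1L]])
    r <- map_to_recomb(d[j])
    expect_lt(abs(obs - r), 2.576 * sqrt(r * (1 - r) / 2000) + 1e-9)
  }
  # coincident markers never recombine
  map0 <- genetic_map(rep("1", 3), c("a", "b", "c"), c(5, 5, 5))
  b0 <- simulate_backcross_genotypes(map0, 100, seed = 3, missing_rate = 0)
  expect_true(all(b0$geno[, 1L] == b0$geno[, 2L] &
                    b0$geno[, 2L] == b0$geno[, 3L]))
  # missingness rate near its target
  expect_lt(abs(mean(is.na(simulate_backcross_genotypes(
    map, 500, seed = 4, missing_rate = 0.1)$geno)) - 0.1), 0.02)
})

test_that("IMP simulation places effects at the configured ipQTLs", {
  cfg <- simulation_config(seed = 21)
  bx <- simulate_backcross_genotypes(cfg$map, 2000, seed = 22,
                                     missing_rate = 0)
  imps <- simulate_imp_levels(bx, cfg, seed = 23)
  expect_identical(imps, simulate_imp_levels(bx, cfg, seed = 23))
  # group means at the first ipQTL differ by ~ its effect (1.0 SD)
  j <- which(bx$map$chr == "3")[which.min(abs(
    bx$map$pos_cM[bx$map$chr == "3"] - 35))]
  g <- bx$geno[, j]
  gap <- mean(imps[g == 1, "pP70S6K"]) - mean(imps[g == 0, "pP70S6K"])
  expect_lt(abs(gap - 1.0), 0.15)
  # a pure-noise molecule shows no significant linkage
  pr <- calc_genotype_probs(bx, step = Inf)
  s <- scan_hk(pr, imps[, "miR_21"])
  expect_lt(max(s$lod), 3)
})

test_that("pathophenotype simulation encodes mediation, age and arm structure", {
  cfg <- simulation_config(seed = 31)
  co <- simulate_mouse_cohort(cfg)
  expect_identical(co$pheno, simulate_mouse_cohort(cfg)$pheno)
  expect_equal(nrow(co$pheno), 130L)
  expect_equal(unname(table(co$pheno$arm)[c("doxorubicin", "combined")]),
               c(70L, 60L), ignore_attr = TRUE)
  expect_true(all(co$pheno$age_weeks >= 51 & co$pheno$age_weeks <= 114))
  expect_true(all(co$pheno$fibrosis_global >= 0 &
                    co$pheno$fibrosis_global <= 100))
  expect_true(all(co$pheno$cardiomyocyte_area > 0))
  # positive age-fibrosis correlation only in the combined arm (pooled
  # over seeds to beat sampling noise at n = 60/70)
  cors <- sapply(31:40, function(sd) {
    ph <- simulate_mouse_cohort(simulation_config(seed = sd))$pheno
    c(comb = cor(ph$age_weeks[ph$arm == "combined"],
                 ph$fibrosis_global[ph$arm == "combined"]),
      dox = cor(ph$age_weeks[ph$arm == "doxorubicin"],
                ph$fibrosis_global[ph$arm == "doxorubicin"]))
  })
  expect_gt(mean(cors["comb", ]), 0.15)
  expect_lt(abs(mean(cors["dox", ])), 0.12)
  # all-zero architecture -> fibrosis independent of genotype
  cfg0 <- simulation_config(
    ip_effects = data.frame(imp = character(), chr = character(),
                            pos = numeric(), effect = numeric()),
    cda_effects = data.frame(trait = character(), chr = character(),
                             pos = numeric(), effect = numeric()),
    mediation = stats::setNames(numeric(0), character(0)),
    seed = 41)
  co0 <- simulate_mouse_cohort(cfg0)
  pr0 <- calc_genotype_probs(co0$cross, step = Inf)
  s0 <- scan_hk(pr0, co0$pheno$fibrosis_global)
  expect_lt(max(s0$lod), 3.5)
})

test_that("pure mediation is visible at the IMP but weaker at the complex trait", {
  # no direct cdaQTL effect: the ipQTL must show a stronger LOD on the IMP
  # than on fibrosis (the mediated, diluted signal)
  ok <- sapply(1:20, function(sd) {
    cfg <- simulation_config(
      cda_effects = data.frame(trait = character(), chr = character(),
                               pos = numeric(), effect = numeric()),
      seed = 100 + sd)
    co <- simulate_mouse_cohort(cfg)
    pr <- calc_genotype_probs(co$cross, step = Inf)
    s_imp <- scan_hk(pr, co$imps[, "pP70S6K"])
    s_fib <- scan_hk(pr, co$pheno$fibrosis_global)
    at3 <- s_imp$chr == "3"
    c(imp_found = max(s_imp$lod[at3]) > 3,
      weaker = max(s_fib$lod[at3]) < max(s_imp$lod[at3]))
  })
  expect_gte(mean(ok["imp_found", ]), 0.7)
  expect_gte(mean(ok["weaker", ]), 0.7)
})

test_that("human cohort simulation obeys HWE, MAF and the logistic model", {
  hc <- simulate_human_cohort(n = 5000, n_snvs = 20, maf = 0.3,
                              causal_or = c(snv1 = 2), seed = 51)
  expect_identical(hc$geno,
                   simulate_human_cohort(n = 5000, n_snvs = 20, maf = 0.3,
                                         causal_or = c(snv1 = 2),
                                         seed = 51)$geno)
  # empirical allele frequency within 99% CI of MAF
  af <- colMeans(hc$geno) / 2
  ci <- 2.576 * sqrt(0.3 * 0.7 / (2 * 5000))
  expect_gt(mean(abs(af - 0.3) <= ci), 0.9)
  # HWE chi-square holds for null SNVs in >= 95% of runs
  hwe_p <- apply(hc$geno[, -1L], 2L, function(g) {
    n <- length(g); p <- mean(g) / 2
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    o <- tabulate(g + 1L, 3L)
    stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
  })
  expect_gte(mean(hwe_p > 0.01), 0.95)
  # all ORs = 1 -> association p-values uniform across SNVs
  hc0 <- simulate_human_cohort(n = 800, n_snvs = 150, maf = 0.3,
                               causal_or = stats::setNames(numeric(0),
                                                           character(0)),
                               seed = 52)
  pvals <- vapply(seq_len(150), function(j)
    associate_snv(hc0$geno, j, "log-additive", outcome = hc0$outcome)$p, 1)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_error(simulate_human_cohort(maf = 0.6, seed = 1), "MAF")
})

test_that("cohort CSV export round-trips through the path loader", {
  cfg <- simulation_config(map = default_genetic_map(n_chr = 3L,
                                                     chr_len_cM = 40,
                                                     n_markers = 30L),
                           ip_effects = data.frame(imp = "pP70S6K",
                                                   chr = "1", pos = 20,
                                                   effect = 1),
                           cda_effects = data.frame(trait = "fibrosis_global",
                                                    chr = "2", pos = 20,
                                                    effect = 1.2),
                           seed = 61)
  co <- simulate_mouse_cohort(cfg)
  d <- file.path(tempdir(), "cohort_csv")
  paths <- write_cohort_csv(co, d)
  expect_true(all(file.exists(paths)))
  co2 <- ipqtl:::.load_cohort_paths(list(cross = paths[["cross"]],
                                         pheno = paths[["pheno"]],
                                         imps = paths[["imps"]]))
  expect_equal(unname(co2$cross$geno), unname(co$cross$geno))
  expect_equal(co2$pheno$fibrosis_global, co$pheno$fibrosis_global,
               tolerance = 1e-12)
  expect_equal(unname(co2$imps), unname(co$imps), tolerance = 1e-12)
})
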