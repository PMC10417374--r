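#' Default simulated genome
#'
#' A marker map mirroring the density of the mouse cohort the framework
#' targets: 19 autosomes of 70 cM carrying 1499 equally spaced markers in
#' total (17 chromosomes with 79 markers, 2 with 78). The X chromosome is
#' excluded from simulation and scans.
#'
#' @param n_chr Number of autosomes (default 19).
#' @param chr_len_cM Chromosome length(s) in cM (default 70, recycled).
#' @param n_markers Total marker count (default 1499), distributed as
#'   evenly as possible.
#' @return A [genetic_map()].
#' @export
default_genetic_map <- function(n_chr = 19L, chr_len_cM = 70,
                                n_markers = 1499L) {
  chr_len_cM <- rep_len(chr_len_cM, n_chr)
  base <- n_markers %/% n_chr
  extra <- n_markers %% n_chr
  counts <- rep(base, n_chr) + c(rep(1L, extra), rep(0L, n_chr - extra))
  chr <- rep(as.character(seq_len(n_chr)), counts)
  pos <- unlist(lapply(seq_len(n_chr), function(i)
    seq(0, chr_len_cM[i], length.out = counts[i])))
  marker <- unlist(lapply(seq_len(n_chr), function(i)
    sprintf("c%dm%d", i, seq_len(counts[i]))))
  genetic_map(chr, marker, pos)
}

#' Simulate backcross genotypes
#'
#' Each individual's genotype along a chromosome is a two-state Markov
#' chain: the first marker is heterozygous with probability 1/2 (the
#' backcross expectation) and the state switches between adjacent markers
#' with probability equal to the recombination fraction of their map
#' distance.
#'
#' @param map A [genetic_map()].
#' @param n Number of individuals.
#' @param seed Integer seed (required).
#' @param missing_rate Fraction of genotypes masked to `NA`
#'   (default 0.02, exercising the HMM).
#' @param map_function Passed to [map_to_recomb()].
#' @return A [backcross()] object.
#' @export
simulate_backcross_genotypes <- function(map, n, seed, missing_rate = 0.02,
                                         map_function = "haldane") {
  stopifnot(inherits(map, "genetic_map"))
  if (missing(seed)) stop("seed is required")
  geno <- .with_seed(seed, {
    g <- matrix(NA_integer_, nrow = n, ncol = nrow(map))
    for (cc in attr(map, "chromosomes")) {
      sel <- which(map$chr == cc)
      r <- map_to_recomb(diff(map$pos_cM[sel]), map_function)
      cur <- stats::rbinom(n, 1L, 0.5)
      g[, sel[1L]] <- cur
      for (j in seq_along(r)) {
        flip <- stats::rbinom(n, 1L, r[j])
        cur <- as.integer(xor(cur, flip))
        g[, sel[j + 1L]] <- cur
      }
    }
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(g)) < missing_rate, nrow = n)
      g[mask] <- NA_integer_
    }
    g
  })
  backcross(map, geno)
}

#' Full simulation configuration
#'
#' Bundles the stated world of the synthetic cohorts: an F1BX cohort of
#' 130 mice (70 doxorubicin / 60 combined therapy) aged 51-114 weeks,
#' genotyped at ~1499 markers on 19 autosomes; intermediate molecular
#' phenotype (IMP) levels under ipQTL genetic control; fibrosis built
#' from direct cdaQTL effects plus IMP mediation, with a positive
#' age-fibrosis slope only in the combined-therapy arm; and human
#' case-control cohorts with Hardy-Weinberg SNVs and logistic CDA risk.
#'
#' Effect sizes are in units of the phenotype's residual SD; a backcross
#' locus with additive effect `a` contributes genetic variance `a^2/4`
#' (genotype variance 1/4).
#'
#' @param n_mice,arm_sizes Cohort size and therapy-arm split.
#' @param age_range Uniform age range in weeks.
#' @param map Genetic map (default [default_genetic_map()]).
#' @param ip_effects Data frame `imp`, `chr`, `pos`, `effect`: ipQTL
#'   effects on IMP levels (SD units).
#' @param imp_noise_sd Named residual SDs per IMP (default 1 for IMPs
#'   not listed).
#' @param extra_imps Names of pure-noise IMPs added to the panel.
#' @param cda_effects Data frame `trait`, `chr`, `pos`, `effect`: direct
#'   cdaQTL effects.
#' @param mediation Named numeric: coefficient of each mediating IMP in
#'   the fibrosis model.
#' @param age_slope Named per-arm slope of latent fibrosis on age
#'   (SD units per week); positive only in the combined arm by default.
#' @param arm_offset Latent offset of the combined arm.
#' @param fibrosis_base,fibrosis_sd_pct Mapping of the latent scale to
#'   percent fibrosis: `% = base + sd_pct * latent`, truncated to
#'   `[0, 100]`.
#' @param missing_rate Genotype missingness.
#' @param human Human-cohort settings: `n`, `n_snvs`, `maf`, `causal_or`
#'   (named vector over causal SNV indices), `prevalence`, and the beta
#'   parameters of the imputation-R2 distribution.
#' @param seed Integer seed (mandatory).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    n_mice = 130L,
    arm_sizes = c(doxorubicin = 70L, combined = 60L),
    age_range = c(51, 114),
    map = default_genetic_map(),
    ip_effects = data.frame(
      imp = c("pP70S6K", "pP70S6K", "pCREB"),
      chr = c("3", "9", "17"),
      pos = c(35, 35, 30),
      effect = c(1.0, 1.0, 0.8),
      stringsAsFactors = FALSE),
    imp_noise_sd = c(pP70S6K = 0.7),
    extra_imps = c("pJNK", "miR_21", "telomere_length"),
    cda_effects = data.frame(
      trait = "fibrosis_global", chr = "11", pos = 30, effect = 1.2,
      stringsAsFactors = FALSE),
    mediation = c(pP70S6K = 1.0),
    age_slope = c(doxorubicin = 0, combined = 0.03),
    arm_offset = 0.5,
    fibrosis_base = 8,
    fibrosis_sd_pct = 2.5,
    missing_rate = 0.02,
    human = list(n = 420L, n_snvs = 200L, maf = 0.3,
                 causal_or = stats::setNames(rep(2.0, 6L), paste0("snv", 1:6)),
                 prevalence = 0.3, r2_shape = c(8, 1.5)),
    seed) {
  if (missing(seed)) stop("seed is mandatory in a simulation config")
  if (sum(arm_sizes) != n_mice)
    stop("arm sizes must sum to n_mice")
  cfg <- list(n_mice = n_mice, arm_sizes = arm_sizes, age_range = age_range,
              map = map, ip_effects = ip_effects, imp_noise_sd = imp_noise_sd,
              extra_imps = extra_imps, cda_effects = cda_effects,
              mediation = mediation, age_slope = age_slope,
              arm_offset = arm_offset, fibrosis_base = fibrosis_base,
              fibrosis_sd_pct = fibrosis_sd_pct,
              missing_rate = missing_rate, human = human, seed = seed)
  if (!all(names(mediation) %in% c(ip_effects$imp, extra_imps)))
    stop("mediation coefficients reference unknown IMPs")
  structure(cfg, class = "simulation_config")
}

# genotype at the marker nearest (chr, pos); missing values replaced by
# the backcross prior 0.5 so simulated effects stay well-defined
.geno_at <- function(cross, chr, pos) {
  sel <- which(cross$map$chr == as.character(chr))
  j <- sel[which.min(abs(cross$map$pos_cM[sel] - pos))]
  g <- cross$geno[, j]
  ifelse(is.na(g), 0.5, as.numeric(g))
}

#' Simulate intermediate molecular phenotype levels
#'
#' `IMP_j = sum(effect * genotype at its ipQTLs) + Normal(0, sd_j)`;
#' molecules without listed effects are pure noise.
#'
#' @param cross A [backcross()].
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Individuals x molecules matrix.
#' @export
simulate_imp_levels <- function(cross, config, seed) {
  imps <- unique(c(config$ip_effects$imp, config$extra_imps))
  n <- nrow(cross$geno)
  .with_seed(seed, {
    panel <- matrix(0, nrow = n, ncol = length(imps),
                    dimnames = list(rownames(cross$geno), imps))
    for (m in imps) {
      eff <- config$ip_effects[config$ip_effects$imp == m, , drop = FALSE]
      mu <- 0
      if (nrow(eff)) for (i in seq_len(nrow(eff)))
        mu <- mu + eff$effect[i] * .geno_at(cross, eff$chr[i], eff$pos[i])
      sdj <- if (m %in% names(config$imp_noise_sd))
        config$imp_noise_sd[[m]] else 1
      panel[, m] <- mu + stats::rnorm(n, 0, sdj)
    }
    panel
  })
}

#' Simulate cardiotoxicity pathophenotypes
#'
#' Latent fibrosis = direct cdaQTL effects + mediated IMP contributions +
#' arm-specific age slope + arm offset + noise (unit residual SD); the
#' percent scale is `base + sd_pct * latent`, truncated to `[0, 100]`.
#' Subendocardial and subepicardial fibrosis are the global latent signal
#' plus zone noise; cardiomyocyte area (um^2) shares the direct genetic
#' effects at a smaller scale.
#'
#' @param cross A [backcross()].
#' @param imps IMP panel from [simulate_imp_levels()].
#' @param covars Data frame with `age_weeks` and `arm`.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return Data frame of pathophenotypes and covariates.
#' @export
simulate_cda_phenotypes <- function(cross, imps, covars, config, seed) {
  n <- nrow(cross$geno)
  stopifnot(nrow(covars) == n)
  .with_seed(seed, {
    direct <- rep(0, n)
    ce <- config$cda_effects[config$cda_effects$trait == "fibrosis_global", ,
                             drop = FALSE]
    if (nrow(ce)) for (i in seq_len(nrow(ce)))
      direct <- direct + ce$effect[i] * .geno_at(cross, ce$chr[i], ce$pos[i])
    med <- rep(0, n)
    for (m in names(config$mediation))
      med <- med + config$mediation[[m]] * imps[, m]
    slope <- config$age_slope[as.character(covars$arm)]
    age_c <- covars$age_weeks - mean(covars$age_weeks)
    offset <- ifelse(covars$arm == "combined", config$arm_offset, 0)
    latent <- direct + med + slope * age_c + offset + stats::rnorm(n)
    to_pct <- function(z) pmin(pmax(config$fibrosis_base +
                                      config$fibrosis_sd_pct * z, 0), 100)
    fib_global <- to_pct(latent)
    fib_subendo <- to_pct(latent + stats::rnorm(n, 0, 0.5))
    fib_subepi <- to_pct(latent + stats::rnorm(n, 0, 0.5))
    area <- pmax(300 + 25 * (0.7 * direct + stats::rnorm(n)), 1)
    data.frame(fibrosis_global = fib_global,
               fibrosis_subendo = fib_subendo,
               fibrosis_subepi = fib_subepi,
               cardiomyocyte_area = area,
               age_weeks = covars$age_weeks,
               arm = covars$arm,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full mouse backcross cohort
#'
#' Draws genotypes, IMP levels, covariates (ages uniform over the
#' configured range; therapy arms of the configured sizes) and
#' pathophenotypes, and attaches a ground-truth record from which every
#' simulated effect (and its expected percent variance, `a^2/4` over the
#' total variance) can be recomputed.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_cohort`: list with `cross`, `imps`, `pheno`
#'   (including `age_group` from [assign_age_groups()]) and `truth`.
#' @export
simulate_mouse_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  cross <- simulate_backcross_genotypes(config$map, config$n_mice,
                                        seed = seed,
                                        missing_rate = config$missing_rate)
  imps <- simulate_imp_levels(cross, config, seed = seed + 1L)
  covars <- .with_seed(seed + 2L, data.frame(
    age_weeks = stats::runif(config$n_mice, config$age_range[1L],
                             config$age_range[2L]),
    arm = rep(names(config$arm_sizes), config$arm_sizes),
    stringsAsFactors = FALSE))
  pheno <- simulate_cda_phenotypes(cross, imps, covars, config,
                                   seed = seed + 3L)
  pheno$age_group <- assign_age_groups(pheno$age_weeks)
  truth <- list(ip_effects = config$ip_effects,
                cda_effects = config$cda_effects,
                mediation = config$mediation,
                imp_noise_sd = config$imp_noise_sd,
                age_slope = config$age_slope,
                arm_offset = config$arm_offset,
                fibrosis_sd_pct = config$fibrosis_sd_pct,
                seed = config$seed)
  structure(list(cross = cross, imps = imps, pheno = pheno, truth = truth),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated backcross cohort\n")
  print(x$cross)
  cat("  IMP panel:", ncol(x$imps), "molecules;",
      "arms:", paste(names(table(x$pheno$arm)), table(x$pheno$arm),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a human case-control cohort
#'
#' SNV dosages are drawn under Hardy-Weinberg equilibrium at the
#' configured minor-allele frequencies; the binary CDA outcome follows a
#' logistic model with the configured per-SNV odds ratios (log-additive,
#' dosages centered at `2*MAF` so the baseline prevalence is preserved);
#' per-SNV imputation R2 is drawn from a beta distribution so the
#' quality filter is exercisable.
#'
#' @param n Individuals.
#' @param n_snvs SNV count.
#' @param maf Minor-allele frequency (scalar or per-SNV vector, in
#'   `(0, 0.5]`).
#' @param causal_or Named vector of odds ratios; names must be SNV ids
#'   (`snv1` ... `snv<n_snvs>`).
#' @param prevalence Baseline CDA prevalence.
#' @param r2_shape Beta parameters of the imputation-R2 distribution.
#' @param cohort Cohort tag.
#' @param seed Integer seed (required).
#' @return A [human_cohort()] with attribute `truth`.
#' @export
simulate_human_cohort <- function(n = 420L, n_snvs = 200L, maf = 0.3,
                                  causal_or = stats::setNames(rep(2, 6L),
                                                              paste0("snv", 1:6)),
                                  prevalence = 0.3, r2_shape = c(8, 1.5),
                                  cohort = "breast", seed) {
  if (missing(seed)) stop("seed is required")
  maf <- rep_len(maf, n_snvs)
  if (any(maf <= 0 | maf > 0.5)) stop("MAF must lie in (0, 0.5]")
  ids <- paste0("snv", seq_len(n_snvs))
  if (!all(names(causal_or) %in% ids))
    stop("causal_or names must be among ", ids[1L], "...", ids[n_snvs])
  .with_seed(seed, {
    geno <- sapply(seq_len(n_snvs), function(j)
      stats::rbinom(n, 2L, maf[j]))
    colnames(geno) <- ids
    lp <- rep(stats::qlogis(prevalence), n)
    for (s in names(causal_or)) {
      j <- match(s, ids)
      lp <- lp + log(causal_or[[s]]) * (geno[, j] - 2 * maf[j])
    }
    y <- stats::rbinom(n, 1L, stats::plogis(lp))
    r2 <- stats::rbeta(n_snvs, r2_shape[1L], r2_shape[2L])
    hc <- human_cohort(geno, r2 = r2, outcome = y, cohort = cohort)
    attr(hc, "truth") <- list(maf = maf, causal_or = causal_or,
                              prevalence = prevalence, seed = seed)
    hc
  })
}

#' Write simulated mouse data to CSV files
#'
#' Emits the cross file (see [write_cross_csv()]), a phenotype table, an
#' IMP table, and a JSON truth record into `dir`.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cross = file.path(dir, "cross.csv"),
             pheno = file.path(dir, "phenotypes.csv"),
             imps = file.path(dir, "imps.csv"),
             truth = file.path(dir, "truth.json"))
  write_cross_csv(cohort$cross, paths["cross"])
  utils::write.csv(cbind(individual = rownames(cohort$cross$geno),
                         cohort$pheno),
                   paths["pheno"], row.names = FALSE)
  utils::write.csv(cbind(individual = rownames(cohort$imps),
                         as.data.frame(cohort$imps)),
                   paths["imps"], row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
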