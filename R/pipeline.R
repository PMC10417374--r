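#' Run the mouse intermediate-phenotype QTL pipeline
#'
#' End-to-end analysis of a backcross cohort, per stratum (therapy arm x
#' age group): select IMPs associated with each pathophenotype, scan the
#' selected IMPs (ipQTLs) and the pathophenotypes (cdaQTLs), consolidate
#' peaks, and build multi-QTL genetic models extending the basal cdaQTL
#' model with up to `max_ipqtls` ipQTL loci, keeping extensions whose
#' added terms pass the drop-one p < `alpha` rule.
#'
#' @param cohort A `simulated_cohort` (from [simulate_mouse_cohort()]),
#'   a [simulation_config()] (simulated on the fly), or a list of paths
#'   `list(cross=, pheno=, imps=)` to CSV files.
#' @param traits Pathophenotypes to analyze (default global fibrosis).
#' @param method Scan method, `"hk"` (default) or `"em"`.
#' @param step,error_prob Grid settings for [calc_genotype_probs()].
#' @param significant,suggestive LOD thresholds.
#' @param alpha Selection / drop-one threshold.
#' @param max_ipqtls Maximum ipQTL loci added to a basal model
#'   (default 2, the largest published models).
#' @param min_stratum_n Strata below this size are skipped with a
#'   warning (default 20).
#' @param stratify Analyze arm x age-group strata (default) or the full
#'   cohort as one stratum.
#' @param outdir Optional directory: report tables are written as CSV
#'   plus a JSON manifest.
#' @return A `report_bundle` list: `scans`, `peaks`, `registry`,
#'   `imp_selection`, `models`, `log`.
#' @export
run_mouse_pipeline <- function(cohort, traits = "fibrosis_global",
                               method = c("hk", "em"),
                               step = 2.5, error_prob = 0.001,
                               significant = 3.0, suggestive = 1.5,
                               alpha = 0.05, max_ipqtls = 2L,
                               min_stratum_n = 20L, stratify = TRUE,
                               outdir = NULL) {
  method <- match.arg(method)
  if (inherits(cohort, "simulation_config"))
    cohort <- simulate_mouse_cohort(cohort)
  if (!inherits(cohort, "simulated_cohort")) {
    if (!is.list(cohort) || is.null(cohort$cross))
      stop("cohort must be a simulated_cohort, simulation_config, or path list")
    cohort <- .load_cohort_paths(cohort)
  }
  cross <- cohort$cross; imps <- cohort$imps; pheno <- cohort$pheno
  probs <- calc_genotype_probs(cross, step = step, error_prob = error_prob)
  scan_fun <- if (method == "hk") scan_hk else scan_em
  strata <- if (stratify)
    split(seq_len(nrow(pheno)),
          interaction(pheno$arm, pheno$age_group, drop = TRUE, sep = "|"))
  else list(all = seq_len(nrow(pheno)))
  scans <- list(); peaks <- list(); sel_tabs <- list(); model_tabs <- list()
  for (st in names(strata)) {
    idx <- strata[[st]]
    if (length(idx) < min_stratum_n) {
      warning("stratum ", st, " skipped (n = ", length(idx), ")")
      next
    }
    sprobs <- subset_genoprob(probs, idx)
    for (tr in traits) {
      y <- pheno[[tr]][idx]
      tag <- paste(tr, st, sep = "|")
      cda_scan <- scan_fun(sprobs, y, trait = tr)
      scans[[length(scans) + 1L]] <- tidy_scan(cda_scan, stratum = st)
      cda_peaks <- classify_peaks(cda_scan, significant, suggestive,
                                  condition = tag)
      if (nrow(cda_peaks)) cda_peaks$role <- "cdaQTL"
      peaks[[length(peaks) + 1L]] <- cda_peaks
      sel <- select_imps(imps[idx, , drop = FALSE], y, alpha_entry = alpha)
      if (nrow(sel$selected))
        sel_tabs[[length(sel_tabs) + 1L]] <-
          cbind(stratum = st, trait = tr, sel$selected)
      ip_peaks <- list()
      for (m in sel$selected$molecule) {
        is <- scan_fun(sprobs, imps[idx, m], trait = m)
        scans[[length(scans) + 1L]] <- tidy_scan(is, stratum = st)
        pk <- classify_peaks(is, significant, suggestive,
                             condition = paste(m, st, sep = "|"))
        if (nrow(pk)) {
          pk$role <- "ipQTL"
          ip_peaks[[length(ip_peaks) + 1L]] <- pk
          peaks[[length(peaks) + 1L]] <- pk
        }
      }
      mt <- .build_model_table(sprobs, y, cda_peaks,
                               if (length(ip_peaks)) do.call(rbind, ip_peaks)
                               else NULL,
                               alpha = alpha, max_ipqtls = max_ipqtls)
      if (!is.null(mt))
        model_tabs[[length(model_tabs) + 1L]] <-
          cbind(stratum = st, trait = tr, mt)
    }
  }
  all_peaks <- if (length(peaks)) do.call(rbind, peaks) else
    classify_peaks_empty()
  bundle <- list(
    scans = if (length(scans)) do.call(rbind, scans) else NULL,
    peaks = all_peaks,
    registry = consolidate_qtls(all_peaks),
    imp_selection = if (length(sel_tabs)) do.call(rbind, sel_tabs) else NULL,
    models = if (length(model_tabs)) do.call(rbind, model_tabs) else NULL,
    log = list(method = method, step = step, error_prob = error_prob,
               significant = significant, suggestive = suggestive,
               alpha = alpha, max_ipqtls = max_ipqtls,
               strata = vapply(strata, length, 1L),
               package_version = as.character(utils::packageVersion("ipqtl")),
               r_version = R.version.string))
  class(bundle) <- "report_bundle"
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

classify_peaks_empty <- function() {
  data.frame(chr = character(), pos = numeric(), lod = numeric(),
             class = character(), ci_lo = numeric(), ci_hi = numeric(),
             condition = character(), trait = character(),
             method = character(), role = character(),
             stringsAsFactors = FALSE)
}

# basal model = strongest cdaQTL peak; extensions = basal + every subset
# of distinct ipQTL loci up to max_ipqtls
.build_model_table <- function(probs, y, cda_peaks, ip_peaks, alpha,
                               max_ipqtls) {
  if (is.null(cda_peaks) || !nrow(cda_peaks)) return(NULL)
  best <- cda_peaks[which.max(cda_peaks$lod), ]
  basal <- fit_qtl_model(probs, y, qtl_model_spec(best$chr, best$pos))
  if (is.null(ip_peaks) || !nrow(ip_peaks)) {
    tab <- compare_models(basal, list(), alpha = alpha)
    return(tab)
  }
  # one locus per ipQTL peak, deduplicated, excluding the basal locus
  loci <- unique(ip_peaks[, c("chr", "pos")])
  loci <- loci[!(loci$chr == best$chr & abs(loci$pos - best$pos) < 1e-9), ,
               drop = FALSE]
  if (!nrow(loci)) return(compare_models(basal, list(), alpha = alpha))
  ext <- list()
  for (k in seq_len(min(max_ipqtls, nrow(loci)))) {
    combos <- utils::combn(nrow(loci), k, simplify = FALSE)
    for (cb in combos) {
      spec <- qtl_model_spec(c(best$chr, loci$chr[cb]),
                             c(best$pos, loci$pos[cb]))
      fit <- try(fit_qtl_model(probs, y, spec), silent = TRUE)
      if (!inherits(fit, "try-error")) ext[[length(ext) + 1L]] <- fit
    }
  }
  compare_models(basal, ext, alpha = alpha)
}

.load_cohort_paths <- function(paths) {
  cross <- read_cross_csv(paths$cross)
  pheno <- utils::read.csv(paths$pheno, stringsAsFactors = FALSE)
  imps <- utils::read.csv(paths$imps, stringsAsFactors = FALSE)
  rn <- imps$individual
  imps <- as.matrix(imps[, setdiff(colnames(imps), "individual"),
                         drop = FALSE])
  rownames(imps) <- rn
  if (!"age_group" %in% colnames(pheno) && "age_weeks" %in% colnames(pheno))
    pheno$age_group <- assign_age_groups(pheno$age_weeks)
  structure(list(cross = cross, imps = imps, pheno = pheno, truth = NULL),
            class = "simulated_cohort")
}

#' Write a report bundle to disk
#'
#' @param bundle A `report_bundle`.
#' @param outdir Output directory.
#' @return Paths written, invisibly.
#' @export
write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("scans", "peaks", "registry", "imp_selection", "models")) {
    if (!is.null(bundle[[nm]]) && is.data.frame(bundle[[nm]])) {
      p <- file.path(outdir, paste0(nm, ".csv"))
      utils::write.csv(bundle[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(bundle$risk_model)) {
    p <- file.path(outdir, "risk_model.json")
    jsonlite::write_json(.serialize_risk_model(bundle$risk_model), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  if (!is.null(bundle$metrics)) {
    p <- file.path(outdir, "metrics.csv")
    utils::write.csv(data.frame(set = rownames(bundle$metrics),
                                bundle$metrics, row.names = NULL), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(c(bundle$log, list(files = basename(paths))), mp,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}

.serialize_risk_model <- function(m) {
  list(snvs = m$snvs, coefficients = as.list(m$coef),
       intercept = m$intercept, lambda = m$lambda,
       lambda_rule = m$lambda_rule, cutoff = m$cutoff, youden = m$youden,
       hit_counts = as.list(m$hit_counts), seed = m$seed)
}

#' Run the human risk-score pipeline
#'
#' Filter poorly imputed SNVs, label CDA cases (when a cardiac-function
#' index is supplied instead of a ready outcome), split the cohort into
#' stratified training (80%) and testing (20%) sets, pre-select SNVs by
#' bootstrap on the training set only, fit the LASSO risk model with a
#' Youden-optimal cutoff on the training set, and evaluate once on the
#' held-out test set. No test individual influences selection, the
#' penalty, or the cutoff.
#'
#' @param cohort A [human_cohort()] (e.g. from
#'   [simulate_human_cohort()]).
#' @param seed Integer seed governing the split, the bootstrap and the
#'   CV folds.
#' @param r2_min Imputation-quality threshold (default 0.7; `NULL`
#'   skips filtering).
#' @param drop_threshold Cardiac-function drop defining a case
#'   (default 5 percentage points).
#' @param train_frac Training fraction (default 0.8).
#' @param n_iter,eval_frac,min_hits,alpha Bootstrap settings (see
#'   [bootstrap_select_snvs()]).
#' @param lambda_rule Passed to [fit_lasso_risk_model()].
#' @param outdir Optional output directory.
#' @return A `report_bundle` with `selection`, `risk_model`, `metrics`
#'   (train/test rows), `split`, `log`.
#' @export
run_human_pipeline <- function(cohort, seed, r2_min = 0.7,
                               drop_threshold = 5, train_frac = 0.8,
                               n_iter = 100L, eval_frac = 0.8,
                               min_hits = 5L, alpha = 0.05,
                               lambda_rule = "min", outdir = NULL) {
  stopifnot(inherits(cohort, "human_cohort"))
  if (missing(seed)) stop("seed is required")
  if (!is.null(r2_min) && !is.null(cohort$r2))
    cohort <- filter_by_imputation(cohort, r2_min)
  if (ncol(cohort$geno) == 0L)
    stop("empty SNV panel after imputation-quality filtering")
  outcome <- cohort$outcome
  if (is.null(outcome)) {
    if (is.null(cohort$baseline) || is.null(cohort$followup))
      stop("cohort carries neither an outcome nor cardiac-function measurements")
    outcome <- label_cda_cases(cohort$baseline, cohort$followup,
                               drop_threshold)
  }
  ok <- !is.na(outcome)
  geno <- cohort$geno[ok, , drop = FALSE]
  y <- outcome[ok]
  if (length(unique(y)) < 2L)
    stop("fewer than 2 outcome classes after case labelling")
  train_idx <- .with_seed(seed, .stratified_split(y, train_frac))
  test_idx <- setdiff(seq_along(y), train_idx)
  sel <- bootstrap_select_snvs(geno[train_idx, , drop = FALSE], y[train_idx],
                               n_iter = n_iter, eval_frac = eval_frac,
                               min_hits = min_hits, alpha = alpha,
                               seed = seed + 1L)
  model <- NULL
  metrics <- NULL
  if (nrow(sel)) {
    model <- fit_lasso_risk_model(geno[train_idx, , drop = FALSE],
                                  y[train_idx], candidates = sel$snv,
                                  seed = seed + 2L,
                                  lambda_rule = lambda_rule,
                                  hit_counts = stats::setNames(sel$hits,
                                                               sel$snv))
    test_m <- evaluate_on_test(model, geno[test_idx, , drop = FALSE],
                               y[test_idx])
    metrics <- rbind(train = model$train_metrics, test = test_m)
  } else {
    message("no SNV reached ", min_hits, " bootstrap hits; no risk model fitted")
  }
  bundle <- list(selection = sel, risk_model = model, metrics = metrics,
                 split = list(train = rownames(geno)[train_idx],
                              test = rownames(geno)[test_idx]),
                 log = list(seed = seed, r2_min = r2_min,
                            drop_threshold = drop_threshold,
                            train_frac = train_frac, n_iter = n_iter,
                            eval_frac = eval_frac, min_hits = min_hits,
                            alpha = alpha, lambda_rule = lambda_rule,
                            n_train = length(train_idx),
                            n_test = length(test_idx),
                            package_version =
                              as.character(utils::packageVersion("ipqtl")),
                            r_version = R.version.string))
  class(bundle) <- "report_bundle"
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("ipqtl report bundle\n")
  if (!is.null(x$peaks)) cat("  peaks:", nrow(x$peaks), "\n")
  if (!is.null(x$registry)) cat("  registry entries:", nrow(x$registry), "\n")
  if (!is.null(x$models)) cat("  model rows:", nrow(x$models), "\n")
  if (!is.null(x$selection)) cat("  selected SNVs:", nrow(x$selection), "\n")
  if (!is.null(x$metrics)) {
    cat("  metrics:\n")
    print(round(x$metrics, 3))
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic mouse cohort),
#' `mouse` (run the mouse pipeline), `human` (run the human risk-score
#' pipeline). A YAML or JSON config file supplies non-default settings.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status, invisibly.
#' @export
ipqtl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ipqtl <simulate|mouse|human> [--config FILE] [--seed INT]",
    "[--out DIR]")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- .parse_cli(args[-1L])
  seed <- as.integer(opts[["seed"]] %||% 1L)
  outdir <- opts[["out"]] %||% "ipqtl_run"
  cfg <- if (!is.null(opts[["config"]]))
    read_analysis_config(opts[["config"]]) else list()
  if (cmd == "simulate") {
    sc <- do.call(simulation_config, c(cfg$simulation %||% list(),
                                       list(seed = seed)))
    paths <- write_cohort_csv(simulate_mouse_cohort(sc), outdir)
    cat("wrote:", paste(paths, collapse = "\n       "), "\n")
  } else if (cmd == "mouse") {
    cohort <- if (!is.null(cfg$paths)) cfg$paths else
      simulate_mouse_cohort(do.call(simulation_config,
                                    c(cfg$simulation %||% list(),
                                      list(seed = seed))))
    bundle <- do.call(run_mouse_pipeline,
                      c(list(cohort = cohort, outdir = outdir),
                        cfg$mouse %||% list()))
    print(bundle)
  } else if (cmd == "human") {
    hc <- do.call(simulate_human_cohort,
                  c(cfg$human %||% list(), list(seed = seed)))
    bundle <- do.call(run_human_pipeline,
                      c(list(cohort = hc, seed = seed, outdir = outdir),
                        cfg$human_pipeline %||% list()))
    print(bundle)
  } else {
    cat(usage, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_cli <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3L)
      opts[[key]] <- if (i < length(args)) args[i + 1L] else TRUE
      i <- i + 2L
    } else i <- i + 1L
  }
  opts
}

#' Read an analysis configuration file
#'
#' @param path `.yaml`/`.yml` (requires the yaml package) or `.json`.
#' @return Nested list.
#' @export
read_analysis_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}
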