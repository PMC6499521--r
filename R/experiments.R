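#' Specification of a simulation scenario
#'
#' Bundles a genotype panel spec, a phenotype model spec and the evaluation
#' protocol: training-set size(s), number of replicates, methods to run and
#' clumping r2 grid. Genotypes are simulated once and reused across
#' replicates (each replicate redraws the phenotype), mirroring protocols
#' that reuse one real genotype panel.
#'
#' @param genotype_spec a [genotype_sim_spec].
#' @param phenotype_spec a [phenotype_sim_spec]; its seed is re-derived per
#'   replicate from `seed`.
#' @param train_size training-set size, or a vector of sizes to sweep; the
#'   test set is every individual not in the training set.
#' @param n_replicates phenotype replicates per train size.
#' @param methods subset of `c("ct", "plr", "plr3")`.
#' @param r2_grid clumping thresholds for the C+T method (default 0.2).
#' @param cmsa_k,patience,alpha_grid,n_lambda,dfmax CMSA settings for
#'   PLR/PLR3.
#' @param seed master seed; every replicate's seeds derive from it.
#' @param scenario_id free-text label.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(genotype_spec, phenotype_spec, train_size,
                          n_replicates = 10L,
                          methods = c("ct", "plr"),
                          r2_grid = 0.2,
                          cmsa_k = 10L, patience = 10L,
                          alpha_grid = c(1, 0.5, 0.05, 0.001),
                          n_lambda = 200L, dfmax = Inf,
                          seed = 1L, scenario_id = "s1") {
  stopifnot(inherits(genotype_spec, "genotype_sim_spec"),
            inherits(phenotype_spec, "phenotype_sim_spec"),
            all(train_size < genotype_spec$n_samples),
            n_replicates >= 1,
            all(methods %in% c("ct", "plr", "plr3")), length(methods) >= 1)
  structure(as.list(environment()), class = "scenario_spec")
}

.derive_seed <- function(master, i, j = 0L) {
  (as.integer(master) * 1009L + as.integer(i) * 101L + as.integer(j)) %%
    2147483562L + 1L
}

#' Run a simulation scenario
#'
#' For each replicate: draw a fresh phenotype on the shared genotype panel,
#' split into training rows and test rows (all remaining individuals), fit
#' each requested method on the training rows, score the test rows, and
#' record AUC, partial AUC and the number of predictors. Method failures
#' are caught and recorded; the run continues.
#'
#' @param spec a [scenario_spec].
#' @param verbose print one line per replicate.
#' @return A `scenario_result`: list with `rows` (one data.frame row per
#'   replicate x method x r2 where applicable), `summary` (per-method mean
#'   AUC with 2 x bootstrap SD), `spec`.
#' @export
run_scenario <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  dataset <- simulate_genotypes(spec$genotype_spec)
  n <- nrow(dataset$genotypes)
  rows <- list()
  for (ts_i in seq_along(spec$train_size)) {
    ts <- spec$train_size[ts_i]
    for (rep_i in seq_len(spec$n_replicates)) {
      ph_spec <- spec$phenotype_spec
      ph_spec$seed <- .derive_seed(spec$seed, 1000L * ts_i + rep_i, 1L)
      phen <- simulate_phenotype(dataset, ph_spec)
      split_seed <- .derive_seed(spec$seed, 1000L * ts_i + rep_i, 2L)
      old <- .Random.seed_save()
      set.seed(split_seed)
      train_rows <- sort(sample.int(n, ts))
      .Random.seed_restore(old)
      test_rows <- setdiff(seq_len(n), train_rows)
      fit_seed <- .derive_seed(spec$seed, 1000L * ts_i + rep_i, 3L)
      res <- evaluate_methods(dataset, phen$status, train_rows, test_rows,
                              methods = spec$methods, r2_grid = spec$r2_grid,
                              cmsa_k = spec$cmsa_k, patience = spec$patience,
                              alpha_grid = spec$alpha_grid,
                              n_lambda = spec$n_lambda, dfmax = spec$dfmax,
                              seed = fit_seed)
      res$replicate <- rep_i
      res$train_size <- ts
      res$seed <- fit_seed
      rows[[length(rows) + 1L]] <- res
      if (verbose)
        message(sprintf("train %d replicate %d: %s", ts, rep_i,
                        paste(sprintf("%s=%.3f", res$method, res$auc),
                              collapse = " ")))
    }
  }
  raw <- do.call(rbind, rows)
  structure(list(rows = raw, summary = .summarize_rows(raw), spec = spec),
            class = "scenario_result")
}

.summarize_rows <- function(raw) {
  ok <- raw[!is.na(raw$auc), , drop = FALSE]
  key <- interaction(ok$method, ok$train_size, drop = TRUE)
  do.call(rbind, lapply(split(ok, key), function(d) {
    data.frame(method = d$method[1], train_size = d$train_size[1],
               n_runs = nrow(d),
               mean_auc = mean(d$auc),
               auc_2sd = 2 * if (nrow(d) > 1)
                 bootstrap_sd_of_mean(d$auc, n_boot = 1e4, seed = 1L) else 0,
               mean_pauc = mean(d$pauc),
               mean_n_predictors = mean(d$n_predictors),
               stringsAsFactors = FALSE)
  }))
}

#' Fit and evaluate a set of PRS methods on one train/test split
#'
#' The shared engine behind [run_scenario()] and [monte_carlo_cv()].
#' C+T runs a GWAS on the training rows, clumps with the test rows as LD
#' reference (the published, deliberately optimistic protocol) and reports
#' the `max` variant per r2 threshold; PLR/PLR3 run CMSA on the training
#' rows only.
#'
#' @param dataset a [genotype_dataset] without missing values.
#' @param status full-length 0/1 phenotype.
#' @param train_rows,test_rows disjoint row index sets.
#' @param methods subset of `c("ct", "plr", "plr3")`.
#' @param r2_grid clumping thresholds for C+T.
#' @param cmsa_k,patience,alpha_grid,n_lambda,dfmax CMSA settings.
#' @param seed seed for the CMSA fold split.
#' @param family `"logistic"` or `"linear"`.
#' @return data.frame: one row per method (x r2 for C+T) with `method`,
#'   `r2_threshold`, `auc`, `pauc`, `n_predictors`, `error`.
#' @export
evaluate_methods <- function(dataset, status, train_rows, test_rows,
                             methods = c("ct", "plr"), r2_grid = 0.2,
                             cmsa_k = 10L, patience = 10L,
                             alpha_grid = c(1, 0.5, 0.05, 0.001),
                             n_lambda = 200L, dfmax = Inf, seed = 1L,
                             family = "logistic") {
  out <- list()
  add_row <- function(method, r2, auc, pauc, npred, err = NA_character_) {
    out[[length(out) + 1L]] <<- data.frame(
      method = method, r2_threshold = r2, auc = auc, pauc = pauc,
      n_predictors = npred, error = err, stringsAsFactors = FALSE)
  }
  ylab <- as.integer(status)
  if ("ct" %in% methods) {
    gw <- tryCatch(gwas(dataset, status, train_rows, family = family),
                   error = function(e) e)
    for (r2 in r2_grid) {
      res <- tryCatch({
        if (inherits(gw, "error")) stop(conditionMessage(gw))
        cl <- clump(gw, dataset, ld_rows = test_rows, r2_threshold = r2)
        ct <- ct_variants(gw, cl, dataset, test_rows, ylab)
        add_row("ct_max", r2, ct$max$auc, ct$max$pauc, ct$max$n_predictors)
        add_row("ct_all", r2, ct$all$auc, ct$all$pauc, ct$all$n_predictors)
        add_row("ct_stringent", r2, ct$stringent$auc, ct$stringent$pauc,
                ct$stringent$n_predictors)
      }, error = function(e) {
        add_row("ct_max", r2, NA_real_, NA_real_, NA_integer_,
                conditionMessage(e))
      })
    }
  }
  for (mth in intersect(methods, c("plr", "plr3"))) {
    enc <- if (mth == "plr3") "triple" else "additive"
    res <- tryCatch({
      fit <- plr_fit(dataset, status, train_rows, encoding = enc,
                     family = family, alpha_grid = alpha_grid, K = cmsa_k,
                     patience = patience, n_lambda = n_lambda, dfmax = dfmax,
                     seed = seed)
      sc <- predict(fit, if (enc == "triple")
        triple_encode(dataset)$matrix[test_rows, , drop = FALSE]
        else dataset$genotypes[test_rows, , drop = FALSE])
      add_row(mth, NA_real_, auc(sc, ylab[test_rows]),
              partial_auc(sc, ylab[test_rows]), fit$n_predictors)
    }, error = function(e) {
      add_row(mth, NA_real_, NA_real_, NA_real_, NA_integer_,
              conditionMessage(e))
    })
  }
  do.call(rbind, out)
}

#' Monte Carlo cross-validation on a fixed dataset
#'
#' Repeatedly draws a uniform training set of `train_size` individuals
#' (the rest form the test set), fits each method, and summarizes AUC,
#' partial AUC and predictor counts across the splits.
#'
#' @param dataset a [genotype_dataset] without missing values.
#' @param phenotype full-length 0/1 phenotype.
#' @param train_size training-set size.
#' @param n_splits number of random splits.
#' @param methods,r2_grid,cmsa_k,patience,alpha_grid,n_lambda,dfmax,family as in
#'   [evaluate_methods()].
#' @param seed master seed controlling all splits.
#' @return A `scenario_result` (rows + summary).
#' @export
monte_carlo_cv <- function(dataset, phenotype, train_size, n_splits = 10L,
                           methods = c("ct", "plr"), r2_grid = 0.2,
                           cmsa_k = 10L, patience = 10L,
                           alpha_grid = c(1, 0.5, 0.05, 0.001),
                           n_lambda = 200L, dfmax = Inf, seed = 1L,
                           family = "logistic") {
  n <- nrow(dataset$genotypes)
  stopifnot(train_size < n)
  rows <- list()
  for (i in seq_len(n_splits)) {
    old <- .Random.seed_save()
    set.seed(.derive_seed(seed, i, 2L))
    train_rows <- sort(sample.int(n, train_size))
    .Random.seed_restore(old)
    test_rows <- setdiff(seq_len(n), train_rows)
    res <- evaluate_methods(dataset, phenotype, train_rows, test_rows,
                            methods = methods, r2_grid = r2_grid,
                            cmsa_k = cmsa_k, patience = patience,
                            alpha_grid = alpha_grid, n_lambda = n_lambda,
                            dfmax = dfmax, seed = .derive_seed(seed, i, 3L),
                            family = family)
    res$replicate <- i
    res$train_size <- train_size
    res$seed <- seed
    rows[[i]] <- res
  }
  raw <- do.call(rbind, rows)
  structure(list(rows = raw, summary = .summarize_rows(raw), spec = NULL),
            class = "scenario_result")
}

#' Write scenario outputs
#'
#' Writes the raw per-replicate table, the per-method summary, and a
#' plain-text manifest (spec fields, seed, package version, wall clock) so
#' a run can be reproduced exactly.
#'
#' @param result a `scenario_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
report_scenario <- function(result, out_dir) {
  stopifnot(inherits(result, "scenario_result"), nrow(result$rows) > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$rows, file.path(out_dir, "raw.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  man <- c(sprintf("prsforge version: %s",
                   as.character(utils::packageVersion("prsforge"))),
           sprintf("written: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           if (!is.null(result$spec)) {
             s <- result$spec
             c(sprintf("scenario_id: %s", s$scenario_id),
               sprintf("seed: %d", s$seed),
               sprintf("n_samples: %d", s$genotype_spec$n_samples),
               sprintf("n_snps: %d", s$genotype_spec$n_snps),
               sprintf("train_size: %s", paste(s$train_size, collapse = ",")),
               sprintf("n_replicates: %d", s$n_replicates),
               sprintf("methods: %s", paste(s$methods, collapse = ",")),
               sprintf("h2: %g", s$phenotype_spec$heritability),
               sprintf("prevalence: %g", s$phenotype_spec$prevalence),
               sprintf("n_causal: %d", s$phenotype_spec$n_causal),
               sprintf("model: %s", s$phenotype_spec$model))
           })
  writeLines(man, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
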