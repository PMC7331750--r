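# End-to-end orchestration: simulate or load -> preprocess -> CFA model
# comparison -> twin models -> report bundle.

#' Build a generating model from a declarative list
#'
#' Maps the `generator` field of a pipeline config (as parsed from
#' YAML/JSON) to the corresponding generating-model constructor. Variance
#' components are given as 3-vectors `(a2, c2, e2)`.
#'
#' @param spec Named list with `type` (one of `"univariate"`,
#'   `"common_pathway"`, `"cholesky"`, `"hierarchical"`) and the
#'   constructor's fields.
#' @return A generating model object.
#' @export
generator_from_config <- function(spec) {
  vc <- function(x) variance_components(x[[1]], x[[2]], x[[3]])
  vcl <- function(x) if (is.list(x[[1]])) lapply(x, vc) else vc(x)
  switch(spec$type,
    univariate = vc(spec$ace),
    common_pathway = common_pathway_gen(vc(spec$common_ace),
                                        unlist(spec$loadings),
                                        vcl(spec$specific_ace),
                                        phenotypes = spec$phenotypes),
    cholesky = cholesky_gen(do.call(rbind, spec$a_paths),
                            do.call(rbind, spec$e_paths),
                            if (!is.null(spec$c_paths))
                              do.call(rbind, spec$c_paths),
                            phenotypes = spec$phenotypes),
    hierarchical = hierarchical_gen(vc(spec$common_ace),
                                    unlist(spec$factor_loadings),
                                    vcl(spec$factor_specific_ace),
                                    unlist(spec$loadings),
                                    unlist(spec$factor_map),
                                    vcl(spec$specific_ace),
                                    phenotypes = spec$phenotypes,
                                    factor_names = spec$factor_names),
    stop("unknown generator type: ", spec$type, call. = FALSE))
}

simulate_from_config <- function(spec, design) {
  gen <- generator_from_config(spec)
  cohort <- switch(spec$type,
    univariate = simulate_univariate_cohort(design, gen),
    common_pathway = simulate_common_pathway_cohort(design, gen),
    cholesky = simulate_cholesky_cohort(design, gen),
    hierarchical = simulate_hierarchical_cohort(design, gen))
  apply_covariates_and_missingness(cohort, design)
}

read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config must carry a seed", call. = FALSE)
  config
}

#' Run the full twin analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation from a generator
#' config or a wide CSV), preprocessing (residualization for age and sex,
#' one-twin-per-pair selection), descriptive screening, CFA model
#' comparison on the selected half-sample, and the requested twin models
#' on the full cohort. Every stage's outputs are written under `out_dir`
#' together with a run manifest; the whole run is determined by the config
#' seed.
#'
#' @param config Path to a YAML/JSON config, or an equivalent list. Fields:
#'   `seed` (mandatory); `input_csv` or `simulate` (a design plus a
#'   `generator` spec for [generator_from_config()]); optional `stages`
#'   (subset of `"describe"`, `"cfa"`, `"twin"`); `cfa_models` (named list
#'   of [cfa_model()] argument lists); `twin_models` (list of twin-model
#'   requests, each with a `model` field: `"univariate"`,
#'   `"sex_limitation"`, `"common_pathway"`, `"hierarchical"` or
#'   `"cholesky"`, plus that fitter's arguments).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the cohort, stage results and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_config(config)
  seed <- check_seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("describe", "cfa", "twin")

  # --- acquire cohort ---------------------------------------------------
  if (!is.null(config$input_csv)) {
    cohort <- read_twin_cohort(config$input_csv)
  } else if (!is.null(config$simulate)) {
    sim <- config$simulate
    design <- cohort_design(sim$n_mzm %||% 178, sim$n_mzf %||% 169,
                            sim$n_dzm %||% 325, sim$n_dzf %||% 260,
                            sim$n_dos %||% 398, seed = seed,
                            sex_effect = sim$sex_effect %||% 0,
                            age_effect = sim$age_effect %||% 0,
                            missing_rate = sim$missing_rate %||% 0)
    cohort <- simulate_from_config(sim$generator, design)
  } else stop("config needs 'input_csv' or 'simulate'", call. = FALSE)
  write_twin_cohort(cohort, file.path(out_dir, "cohort.csv"))

  # --- preprocess -------------------------------------------------------
  cohort <- residualize_standardize(cohort)
  halves <- select_one_per_pair(cohort, seed = seed + 1L)
  results <- list(cohort = cohort)

  # --- descriptives -----------------------------------------------------
  if ("describe" %in% stages) {
    desc <- do.call(rbind, lapply(phenotypes(cohort), function(p) {
      x <- halves$primary[[p]]
      dc <- distribution_check(x)
      sx <- sex_difference_r2(halves$primary[[p]], halves$primary$sex)
      data.frame(phenotype = p, n = sum(!is.na(x)),
                 skewness = dc$skewness, kurtosis = dc$kurtosis,
                 distribution_pass = dc$pass,
                 sex_r2 = sx$r2, male_higher = sx$direction > 0)
    }))
    utils::write.csv(desc, file.path(out_dir, "descriptives.csv"),
                     row.names = FALSE)
    results$descriptives <- desc
  }

  # --- CFA comparison ---------------------------------------------------
  if ("cfa" %in% stages && !is.null(config$cfa_models)) {
    X <- as.matrix(halves$primary[, phenotypes(cohort), drop = FALSE])
    X <- X[stats::complete.cases(X), , drop = FALSE]
    fits <- lapply(config$cfa_models, function(m)
      fit_cfa(stats::cov(X), nrow(X), do.call(cfa_model, m)))
    comp <- data.frame(model = names(fits),
                       T = vapply(fits, `[[`, 0, "T"),
                       df = vapply(fits, `[[`, 0, "df"),
                       cfi = vapply(fits, `[[`, 0, "cfi"),
                       tli = vapply(fits, `[[`, 0, "tli"),
                       rmsea = vapply(fits, `[[`, 0, "rmsea"),
                       srmr = vapply(fits, `[[`, 0, "srmr"),
                       aic = vapply(fits, `[[`, 0, "aic"))
    comp$akaike_weight <- if (nrow(comp) > 1L) aic_weights(comp$aic) else 1
    utils::write.csv(comp, file.path(out_dir, "cfa_comparison.csv"),
                     row.names = FALSE)
    results$cfa <- list(fits = fits, comparison = comp)
  }

  # --- twin models ------------------------------------------------------
  if ("twin" %in% stages && !is.null(config$twin_models)) {
    twin <- lapply(config$twin_models, function(tm) {
      switch(tm$model,
        univariate = fit_univariate_ace(cohort, tm$phenotype,
                                        tm$submodel %||% "ACE"),
        sex_limitation = fit_sex_limitation(cohort, tm$phenotype),
        common_pathway = fit_common_pathway(
          cohort, tm$indicators %||% phenotypes(cohort),
          tm$components %||% "ACE"),
        hierarchical = fit_hierarchical_model(cohort, tm$factors,
                                              tm$components %||% "AE"),
        cholesky = fit_cholesky(cohort, tm$phenotypes %||% phenotypes(cohort),
                                tm$components %||% "AE"),
        stop("unknown twin model: ", tm$model, call. = FALSE))
    })
    names(twin) <- vapply(config$twin_models, function(tm)
      paste0(tm$model, "_", tm$phenotype %||% "multi"), "")
    jsonlite::write_json(lapply(twin, twin_fit_record),
                         file.path(out_dir, "twin_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$twin <- twin
  }

  # --- report + manifest ------------------------------------------------
  write_report(results, out_dir)
  manifest <- list(package = "twinpath",
                   version = as.character(utils::packageVersion("twinpath")),
                   seed = seed, stages = stages, config = config,
                   convergence = if (!is.null(results$twin))
                     lapply(results$twin, function(f)
                       f$convergence %||% NA))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(results)
}

# flatten a twin fit into a JSON-friendly record
twin_fit_record <- function(f) {
  if (inherits(f, "sexlim_fit"))
    return(list(model = "sex_limitation", fits = lapply(f$fits, function(g)
      list(model = g$model, male = as.list(g$male), female = as.list(g$female),
           m2ll = g$m2ll, aic = g$aic)), lrt = f$lrt))
  out <- list(m2ll = f$m2ll, aic = f$aic, npar = f$npar,
              convergence = f$convergence)
  if (inherits(f, "ace_fit")) {
    out$model <- "univariate"; out$components <- as.list(f$components)
  } else if (inherits(f, "common_pathway_fit")) {
    out$model <- "common_pathway"; out$common <- as.list(f$common)
    out$loadings <- as.list(f$std_loadings)
    out$genetic_shares <- as.list(f$genetic_shares)
  } else if (inherits(f, "hierarchical_twin_fit")) {
    out$model <- "hierarchical"; out$second_order <- as.list(f$second_order)
    out$factor_r2 <- as.list(f$factor_r2)
    out$factor_genetic_shares <- as.list(f$factor_genetic_shares)
  } else if (inherits(f, "cholesky_fit")) {
    out$model <- "cholesky"
    out$genetic_shares <- apply(f$genetic_shares, 1, as.list)
    out$trait_components <- apply(f$trait_components, 1, as.list)
  }
  out
}

#' Write a plain-text analysis report
#'
#' Renders the stage outputs of [run_pipeline()] into `report.txt`; a pure
#' function of the results, so regenerating from the same stage outputs is
#' byte-identical.
#'
#' @param results Stage results as produced by [run_pipeline()].
#' @param out_dir Output directory.
#' @return The report path, invisibly.
#' @export
write_report <- function(results, out_dir) {
  lines <- c("Twin analysis report", strrep("=", 60))
  fmt <- function(x) formatC(x, digits = 3, format = "f")
  if (!is.null(results$descriptives)) {
    d <- results$descriptives
    lines <- c(lines, "", "Descriptives (selected half-sample)",
               sprintf("  %-12s n=%5d  skew=%s kurt=%s pass=%s  sex R2=%s",
                       d$phenotype, d$n, fmt(d$skewness), fmt(d$kurtosis),
                       d$distribution_pass, fmt(d$sex_r2)))
  } else lines <- c(lines, "", "Descriptives: stage skipped")
  if (!is.null(results$cfa)) {
    cc <- results$cfa$comparison
    lines <- c(lines, "", "CFA model comparison",
               sprintf("  %-16s T=%9s df=%3d CFI=%s TLI=%s RMSEA=%s SRMR=%s AIC=%11s w=%s",
                       cc$model, fmt(cc$T), cc$df, fmt(cc$cfi), fmt(cc$tli),
                       fmt(cc$rmsea), fmt(cc$srmr), fmt(cc$aic),
                       fmt(cc$akaike_weight)),
               sprintf("  (Akaike weights sum to %s)",
                       formatC(sum(cc$akaike_weight), digits = 3, format = "f")))
  } else lines <- c(lines, "", "CFA: stage skipped")
  if (!is.null(results$twin)) {
    lines <- c(lines, "", "Twin models")
    for (nm in names(results$twin)) {
      f <- results$twin[[nm]]
      lines <- c(lines, paste0("  ", nm, ":"))
      rec <- twin_fit_record(f)
      if (!is.null(rec$components))
        lines <- c(lines, sprintf("    a2=%s c2=%s e2=%s (-2lnL=%s)",
                                  fmt(rec$components$a2), fmt(rec$components$c2),
                                  fmt(rec$components$e2), fmt(rec$m2ll)))
      if (!is.null(rec$common))
        lines <- c(lines, sprintf("    common factor a2=%s c2=%s e2=%s (-2lnL=%s)",
                                  fmt(rec$common$a2), fmt(rec$common$c2),
                                  fmt(rec$common$e2), fmt(rec$m2ll)))
      if (!is.null(rec$second_order))
        lines <- c(lines, sprintf("    second-order a2=%s e2=%s (-2lnL=%s)",
                                  fmt(rec$second_order$a2),
                                  fmt(rec$second_order$e2), fmt(rec$m2ll)))
      if (inherits(f, "cholesky_fit"))
        lines <- c(lines, sprintf("    %s genetic shares: %s", rownames(f$genetic_shares),
                                  apply(f$genetic_shares, 1, function(r)
                                    paste(fmt(r), collapse = " "))))
      if (inherits(f, "sexlim_fit"))
        lines <- c(lines, sprintf("    %s: male a2=%s female a2=%s",
                                  vapply(f$fits, `[[`, "", "model"),
                                  fmt(vapply(f$fits, function(g) g$male[["a2"]], 0)),
                                  fmt(vapply(f$fits, function(g) g$female[["a2"]], 0))))
    }
  } else lines <- c(lines, "", "Twin models: stage skipped")
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
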