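# End-to-end study orchestration: simulate (or load) -> metrics -> join ->
# filter -> descriptives + VIF -> OLS -> Moran gate -> spatial lag & error
# fits -> report.

#' Variable roster of the study design
#'
#' The default predictor list: the six landscape metrics followed by the
#' seven socio-demographic/air-quality covariates.
#'
#' @return character vector of predictor names.
#' @export
predictor_roster <- function() {
  c("TreeCov", "TreeClus", "TreeAgr", "PrvtGrn", "GrnRec", "SemiGrn",
    covariate_names())
}

#' Default ground-truth coefficients for the synthetic outcome process
#'
#' Signs and magnitudes follow the fitted spatial-lag coefficients reported
#' for the Los Angeles County study region (canopy cover, patch size and
#' private greenspace protective; poverty, Black population share, child
#' population and pollution adverse), so synthetic studies reproduce the
#' qualitative structure of the real analysis. `TreeClus` is expressed per
#' squared raster unit.
#'
#' @return named numeric vector including `Constant`, aligned with
#'   [predictor_roster()].
#' @export
default_truth_beta <- function() {
  c(Constant = 7.586,
    TreeCov = -44.692, TreeClus = -0.034, TreeAgr = 15.687,
    PrvtGrn = -12.998, GrnRec = 3.876, SemiGrn = -1.567,
    PovRt = 0.172, EduAtn = -0.003, EtnGrp = 0.365, ChldPop = 0.843,
    SnrPop = -0.105, PM25 = 0.583, Ozone = 114.113)
}

#' Build a study configuration
#'
#' Collects every knob of a synthetic end-to-end study into one validated
#' list; [run_study()] is a pure function of this object, so a fixed
#' config regenerates its report byte-identically.
#'
#' @param n_rows,n_cols,tract_cells,cell_size partition geometry.
#' @param process outcome process: `"lag"`, `"error"` or `"none"`.
#' @param rho,lambda true spatial parameter for the chosen process.
#' @param beta named true coefficients (must cover `Constant` and every
#'   predictor); defaults to [default_truth_beta()].
#' @param sigma innovation standard deviation of the outcome process.
#' @param predictors predictor columns entering the models.
#' @param outcome outcome column name.
#' @param weights_type `"queen"` or `"rook"` contiguity.
#' @param connectivity patch connectivity (4 or 8).
#' @param scheme Moran inference scheme (`"normal"` or `"permutation"`).
#' @param n_perm permutations when `scheme = "permutation"`.
#' @param min_residential minimum residential land share for a tract to be
#'   retained (the no-residential exclusion rule).
#' @param n_no_residential tracts forced to a no-residential composition.
#' @param cover_mean,cover_sd,patch_intensity_range,patch_growth canopy
#'   generator settings (see [simulate_dataset()]).
#' @param seed master seed; mandatory in synthetic mode.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_rows = 15, n_cols = 15, tract_cells = 20,
                         cell_size = 1,
                         process = c("lag", "error", "none"),
                         rho = 0.541, lambda = 0.797,
                         beta = default_truth_beta(), sigma = 10,
                         predictors = predictor_roster(),
                         outcome = "Asthma",
                         weights_type = c("queen", "rook"),
                         connectivity = 8,
                         scheme = c("normal", "permutation"), n_perm = 999,
                         min_residential = 0.05, n_no_residential = 0,
                         cover_mean = 0.11, cover_sd = 0.06,
                         patch_intensity_range = c(0.01, 0.05),
                         patch_growth = 0.5,
                         seed = NULL) {
  process <- match.arg(process)
  weights_type <- match.arg(weights_type)
  scheme <- match.arg(scheme)
  if (is.null(seed)) stopf("seed is mandatory in synthetic mode")
  known <- c(predictor_roster(), covariate_names())
  unknown <- setdiff(predictors, known)
  if (length(unknown)) {
    stopf("unknown predictor name(s): %s", paste(unknown, collapse = ", "))
  }
  need <- c("Constant", predictors)
  if (!all(need %in% names(beta))) {
    stopf("beta must name: %s", paste(setdiff(need, names(beta)),
                                      collapse = ", "))
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, tract_cells = tract_cells,
         cell_size = cell_size, process = process, rho = rho,
         lambda = lambda, beta = beta[need], sigma = sigma,
         predictors = predictors, outcome = outcome,
         weights_type = weights_type, connectivity = connectivity,
         scheme = scheme, n_perm = n_perm,
         min_residential = min_residential,
         n_no_residential = n_no_residential,
         cover_mean = cover_mean, cover_sd = cover_sd,
         patch_intensity_range = patch_intensity_range,
         patch_growth = patch_growth,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Write a study configuration to JSON
#'
#' Canonical serialization: the named `beta` vector is stored as a JSON
#' object so names survive the round trip through [read_study_config()].
#'
#' @param config a `study_config`.
#' @param path output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  obj <- unclass(config)
  obj$beta <- as.list(obj$beta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return a validated [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$beta)) raw$beta <- unlist(raw$beta)
  do.call(study_config, raw)
}

#' Content digest of a study configuration
#'
#' md5 of the canonical JSON form; used to content-address output
#' directories so an unchanged config maps to the same location.
#'
#' @param config a `study_config`.
#' @return character md5 digest.
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "study_config"))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_study_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Filter the joined tract table before modelling
#'
#' Applies the exclusion rules mirroring the removal of uninhabited
#' (park/forest-only) tracts from the real analysis: tracts whose landscape
#' metrics are undefined (no tree patch for `TreeClus`, fewer than two for
#' `TreeAgr`), tracts below the residential land-share threshold, and rows
#' with missing values (complete-case analysis). Every exclusion carries a
#' reason.
#'
#' @param tab joined data.frame of metrics and covariates; must contain a
#'   `flags` column and, when the residential rule is active, a
#'   `residential_share` column.
#' @param min_residential threshold on residential share (`NULL` or 0
#'   disables the rule).
#' @param check_cols columns checked for missing values; defaults to all
#'   numeric columns.
#' @return list with `retained` (filtered data.frame) and `log`
#'   (data.frame of `tract_id`, `reason`).
#' @export
filter_tracts <- function(tab, min_residential = 0.05, check_cols = NULL) {
  stopifnot(is.data.frame(tab), "tract_id" %in% names(tab))
  drop_reason <- rep(NA_character_, nrow(tab))
  note <- function(idx, why) {
    fresh <- idx[is.na(drop_reason[idx])]
    drop_reason[fresh] <<- why
  }
  # uninhabited tracts are removed first, as in the study design; metric
  # flags only apply to tracts that survive the residential rule
  if (!is.null(min_residential) && min_residential > 0 &&
      "residential_share" %in% names(tab)) {
    note(which(tab$residential_share < min_residential), "no residential land")
  }
  if ("flags" %in% names(tab)) {
    flagged <- which(!is.na(tab$flags) & nzchar(tab$flags))
    for (i in flagged) note(i, tab$flags[i])
  }
  if (is.null(check_cols)) {
    check_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  }
  nas <- which(rowSums(is.na(tab[check_cols])) > 0)
  note(nas, "missing values")
  keep <- is.na(drop_reason)
  if (!any(keep)) stopf("all tracts excluded by the filtering rules")
  list(
    retained = tab[keep, , drop = FALSE],
    log = data.frame(tract_id = tab$tract_id[!keep],
                     reason = drop_reason[!keep],
                     stringsAsFactors = FALSE)
  )
}

#' Run the end-to-end synthetic study
#'
#' Executes the full analysis path: simulate the landscape and covariates,
#' compute the six per-tract landscape metrics, join, filter tracts, build
#' row-standardized contiguity weights on the retained tracts, draw the
#' outcome from the configured spatial process (truth recorded), then fit
#' OLS, test its residuals with Moran's I (advisory gate — both spatial
#' models are always fitted), screen with VIF, and fit the spatial lag and
#' spatial error models.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`: `config`, `truth`,
#'   `descriptives` (min/max/mean/sd/VIF per variable), `moran`, `fits`
#'   (named list `ols`, `lag`, `error`), `exclusions`, `metrics`, `data`
#'   (retained modelling table), `n_retained`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  ds <- simulate_dataset(
    n_rows = config$n_rows, n_cols = config$n_cols,
    tract_cells = config$tract_cells, cell_size = config$cell_size,
    cover_mean = config$cover_mean, cover_sd = config$cover_sd,
    patch_intensity_range = config$patch_intensity_range,
    patch_growth = config$patch_growth,
    n_no_residential = config$n_no_residential,
    seed = config$seed
  )
  metrics <- compute_tract_metrics(ds$canopy, ds$green, ds$landuse,
                                   ds$partition, config$connectivity)
  joined <- merge(metrics, ds$covariates, by = "tract_id", sort = FALSE)
  joined$residential_share <- ds$residential_share[joined$tract_id]
  flt <- filter_tracts(joined, config$min_residential,
                       check_cols = config$predictors)
  tab <- flt$retained
  exclusions <- flt$log

  # weights on the retained tracts; islands created by filtering are
  # excluded with their own logged reason
  W_all <- build_queen_weights(ds$partition, config$weights_type)
  keep_idx <- match(tab$tract_id, ds$partition$tract_id)
  W <- subset_weights(W_all, keep_idx)
  if (length(W$islands) > 0L) {
    isl_ids <- W$ids[W$islands]
    exclusions <- rbind(exclusions,
                        data.frame(tract_id = isl_ids,
                                   reason = "island after filtering",
                                   stringsAsFactors = FALSE))
    tab <- tab[!tab$tract_id %in% isl_ids, , drop = FALSE]
    W <- subset_weights(W_all, match(tab$tract_id, ds$partition$tract_id))
  }
  W <- suppressWarnings(row_standardize(W))

  X <- as.matrix(tab[config$predictors])
  truth <- synthetic_truth(
    process = config$process, rho = config$rho, lambda = config$lambda,
    beta = config$beta, sigma = config$sigma,
    seed = derive_seed(config$seed, 5L)
  )
  y <- simulate_outcome(cbind(Constant = 1, X), W, truth)
  tab[[config$outcome]] <- y

  vt <- vif(X)
  descr <- data.frame(
    variable = c(config$outcome, config$predictors),
    min = NA_real_, max = NA_real_, mean = NA_real_, sd = NA_real_,
    vif = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(descr))) {
    v <- tab[[descr$variable[i]]]
    descr$min[i] <- min(v); descr$max[i] <- max(v)
    descr$mean[i] <- mean(v); descr$sd[i] <- stats::sd(v)
  }
  descr$vif[match(vt$variable, descr$variable)] <- vt$vif

  ols <- fit_ols(X, y)
  moran <- morans_i(ols$residuals, W, scheme = config$scheme,
                    n_perm = config$n_perm,
                    seed = derive_seed(config$seed, 6L))
  lag <- fit_spatial_lag(X, y, W)
  err <- fit_spatial_error(X, y, W)

  structure(
    list(config = config, truth = truth, descriptives = descr,
         moran = moran, fits = list(ols = ols, lag = lag, error = err),
         exclusions = exclusions, metrics = metrics, data = tab,
         weights = W, n_retained = nrow(tab)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  writeLines(render_report(x))
  invisible(x)
}

fmt <- function(x, d = 4) formatC(x, format = "f", digits = d)

#' Render a study report as text
#'
#' Deterministic plain-text rendering (no timestamps): descriptive
#' statistics with VIF, the Moran gate, the three model columns with
#' coefficients, standardized coefficients, standard errors, z-values and
#' significance stars at the 0.10/0.05/0.01 two-tailed levels, the fit
#' statistics, and the tract exclusion log. In synthetic mode the recorded
#' truth is echoed beside the estimates.
#'
#' @param report a `study_report`.
#' @return character vector of lines.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "study_report"))
  out <- character(0)
  push <- function(...) out <<- c(out, ...)
  cfg <- report$config
  push("# Tree/greenspace spatial regression study report", "")
  push(sprintf("Tracts analysed: %d (excluded: %d)  |  weights: %s, style W",
               report$n_retained, nrow(report$exclusions),
               cfg$weights_type), "")

  push("## Descriptive statistics", "")
  d <- report$descriptives
  push(sprintf("%-10s %10s %10s %10s %10s %8s",
               "Variable", "Min", "Max", "Mean", "SD", "VIF"))
  for (i in seq_len(nrow(d))) {
    push(sprintf("%-10s %10s %10s %10s %10s %8s",
                 d$variable[i], fmt(d$min[i], 3), fmt(d$max[i], 3),
                 fmt(d$mean[i], 3), fmt(d$sd[i], 3),
                 ifelse(is.na(d$vif[i]), "-", fmt(d$vif[i], 3))))
  }
  push("")

  m <- report$moran
  push("## Moran's I on OLS residuals (spatial-model gate, advisory)", "")
  push(sprintf("I = %s, expected = %s, z = %s, p = %s [%s scheme]",
               fmt(m$I), fmt(m$expected), fmt(m$z, 3), fmt(m$p, 4),
               m$scheme), "")

  push("## Model estimates", "")
  for (kind in c("ols", "lag", "error")) {
    f <- report$fits[[kind]]
    label <- switch(kind, ols = "OLS model", lag = "Spatial lag model (ML)",
                    error = "Spatial error model (ML)")
    push(sprintf("### %s", label), "")
    push(sprintf("%-10s %12s %12s %10s %12s", "Variable", "Coef.",
                 "Standardized", "S.E.", "Z"))
    for (j in seq_along(f$coefficients)) {
      nm <- names(f$coefficients)[j]
      push(sprintf("%-10s %12s %12s %10s %12s",
                   nm, fmt(f$coefficients[j], 3),
                   ifelse(is.na(f$std_beta[j]), "-", fmt(f$std_beta[j], 3)),
                   ifelse(is.na(f$se[j]), "-", fmt(f$se[j], 3)),
                   ifelse(is.na(f$z[j]), "-",
                          paste0(sig_stars(f$p[j]), " ", fmt(f$z[j], 3)))))
    }
    if (kind == "lag") {
      push(sprintf("Lag coefficient (Rho): %s (S.E. %s)",
                   fmt(f$rho, 3), fmt(f$rho_se, 3)))
    }
    if (kind == "error") {
      push(sprintf("Lag coefficient (Lambda): %s (S.E. %s)",
                   fmt(f$lambda, 3), fmt(f$rho_se, 3)))
    }
    push(sprintf("R-squared: %s   Log likelihood: %s   AIC: %s",
                 fmt(f$pseudo_r2, 3), fmt(f$loglik, 3), fmt(f$aic, 1)), "")
  }
  push("Signif.: *** p<0.01, ** p<0.05, * p<0.10 (2-tailed)", "")

  tr <- report$truth
  push("## Synthetic truth (recorded beside the estimates)", "")
  par_line <- switch(tr$process,
                     lag = sprintf("process = lag, rho_true = %s", fmt(tr$rho, 3)),
                     error = sprintf("process = error, lambda_true = %s",
                                     fmt(tr$lambda, 3)),
                     none = "process = none")
  push(par_line, sprintf("sigma_true = %s, seed = %d", fmt(tr$sigma, 3),
                         tr$seed), "")
  bn <- tr$beta_names %||% paste0("b", seq_along(tr$beta))
  push(paste(sprintf("%s=%s", bn, fmt(tr$beta, 3)), collapse = ", "), "")

  push("## Tract exclusion log", "")
  if (nrow(report$exclusions) == 0L) {
    push("(no exclusions)")
  } else {
    cnt <- table(report$exclusions$reason)
    for (r in names(cnt)) push(sprintf("%4d  %s", cnt[[r]], r))
    push("", paste(sprintf("%s [%s]", report$exclusions$tract_id,
                           report$exclusions$reason), collapse = "; "))
  }
  out
}

#' Write the study outputs to a directory
#'
#' Writes `report.md` (the rendered report), `metrics.csv`,
#' `model_data.csv` (the retained table), `exclusions.csv`,
#' `fits.json` (coefficients and fit statistics of the three models),
#' `truth.json`, and `weights.gal`. Contents are deterministic functions of
#' the config.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing); defaults to a
#'   content-addressed name derived from [config_digest()].
#' @return the output directory, invisibly.
#' @export
write_study <- function(report, dir = NULL) {
  stopifnot(inherits(report, "study_report"))
  if (is.null(dir)) {
    dir <- file.path("study_out", config_digest(report$config))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(render_report(report), file.path(dir, "report.md"))
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$data, file.path(dir, "model_data.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  fits <- lapply(report$fits, function(f) {
    list(kind = f$kind, coefficients = as.list(f$coefficients),
         se = as.list(f$se), z = as.list(f$z), p = as.list(f$p),
         std_beta = as.list(f$std_beta), sigma2 = f$sigma2,
         rho = f$rho, lambda = f$lambda, spatial_se = f$rho_se,
         loglik = f$loglik, aic = f$aic, pseudo_r2 = f$pseudo_r2,
         n = f$n, converged = f$converged)
  })
  fits$moran <- unclass(report$moran)
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(unclass(report$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_gal(report$weights, file.path(dir, "weights.gal"))
  invisible(dir)
}
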