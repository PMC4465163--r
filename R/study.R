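#' Configuration for a full texture-outcome study
#'
#' Collects every knob of the end-to-end pipeline: input mode, the
#' synthetic cohort description, the segmentation thresholds to evaluate
#' (the first is the primary VOI definition, the second the stability
#' comparison), the endpoints, the T-stage subgroup rule, the texture
#' settings and the master seed.
#'
#' @param nPatients synthetic cohort size (default 45).
#' @param inputMode `"synthetic"` (default) or `"files"`.
#' @param volumePaths NIfTI paths (files mode).
#' @param outcomeTable outcome `data.frame` or CSV path (files mode), with
#'   the columns produced by [simulateOutcomes()] plus optionally
#'   `diameter_mm` and `dose_gy`.
#' @param thresholds SUV isocontour levels (default `c(2, 2.5)`); the
#'   first defines the analysis VOI.
#' @param endpoints subset of `c("LR", "LN", "DM", "DSS", "OS")`.
#' @param subgroupDiameterMm T1/T2 cut (default 30 mm; T1 <= cut < T2).
#' @param connectivity VOI component connectivity (default 26).
#' @param entropyLogBase entropy logarithm base (default 2).
#' @param glcmAggregation `"merged"` or `"averaged"`.
#' @param distribution a [cohortDistribution()] (synthetic mode).
#' @param outcome an [outcomeParams()] (synthetic mode).
#' @param doseRangeGy range of the independent dose stand-in covariate
#'   used in multivariate models (default `c(24, 45)`).
#' @param multivariateSet covariates of the restricted multivariate model,
#'   at most three of `"entropy"` (dichotomized high/low), `"mtv"`
#'   (log scale) and `"dose"`.
#' @param seed master integer seed.
#' @return validated list of class `StudyConfig`.
#' @seealso [runStudy()]
#' @export
studyConfig <- function(nPatients = 45L,
                        inputMode = c("synthetic", "files"),
                        volumePaths = NULL, outcomeTable = NULL,
                        thresholds = c(2.0, 2.5),
                        endpoints = c("LR", "LN", "DM", "DSS", "OS"),
                        subgroupDiameterMm = 30,
                        connectivity = 26L,
                        entropyLogBase = 2,
                        glcmAggregation = c("merged", "averaged"),
                        distribution = cohortDistribution(),
                        outcome = outcomeParams(),
                        doseRangeGy = c(24, 45),
                        multivariateSet = c("entropy", "mtv", "dose"),
                        seed = 1L) {
  inputMode <- match.arg(inputMode)
  glcmAggregation <- match.arg(glcmAggregation)
  if (length(thresholds) < 1L) stop("at least one threshold required")
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  if (length(endpoints) == 0L) stop("endpoints must be non-empty")
  if (length(multivariateSet) > 3L)
    stop("multivariate models are restricted to three covariates")
  if (inputMode == "files" && (is.null(volumePaths)))
    stop("files mode requires volumePaths")
  structure(list(nPatients = as.integer(nPatients), inputMode = inputMode,
                 volumePaths = volumePaths, outcomeTable = outcomeTable,
                 thresholds = thresholds, endpoints = endpoints,
                 subgroupDiameterMm = subgroupDiameterMm,
                 connectivity = as.integer(connectivity),
                 entropyLogBase = entropyLogBase,
                 glcmAggregation = glcmAggregation,
                 distribution = distribution, outcome = outcome,
                 doseRangeGy = doseRangeGy,
                 multivariateSet = multivariateSet,
                 seed = as.integer(seed)),
            class = "StudyConfig")
}

# recursively drop S3 classes so a config serializes as plain lists
stripClasses <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, stripClasses)
    attr(x, "class") <- NULL
  } else {
    x <- unclass(x)
  }
  x
}

# deterministic md5 of a config (serialized as canonical JSON)
configHash <- function(config) {
  js <- jsonlite::toJSON(stripClasses(config),
                         auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

# endpoint -> binary label vector
endpointLabel <- function(endpoint, outcomes) {
  switch(endpoint,
    LR  = outcomes$lr_event,
    LN  = outcomes$ln_event,
    DM  = outcomes$dm_event,
    DSS = as.integer(outcomes$death_cause == "disease"),
    OS  = outcomes$os_event,
    stop("unknown endpoint: ", endpoint))
}

# parameters analyzed in the report tables (+ CT-diameter analogue if known)
reportParameters <- function(features) {
  pars <- featureColumns()
  if (!is.null(features$diameter_mm) && !anyNA(features$diameter_mm))
    pars <- c(pars, "diameter_mm")
  pars
}

#' Run the full texture-outcome study
#'
#' Executes generate/ingest, isocontour segmentation at every configured
#' threshold, feature extraction, ROC per parameter and endpoint (whole
#' cohort, plus the T2 subgroup for local recurrence), cutoff-dichotomized
#' Kaplan-Meier/log-rank comparisons, univariate Cox for all parameters
#' and a restricted (three-covariate) multivariate Cox, threshold
#' stability and size-dependency correlations. Fully reproducible under
#' the master seed; identical configs give byte-identical written
#' reports.
#'
#' @param config a `StudyConfig` from [studyConfig()].
#' @return a [StudyReport-class].
#' @examples
#' \donttest{
#' rep <- runStudy(studyConfig(nPatients = 12, seed = 5))
#' rep
#' }
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  log <- character()
  warns <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # stage 1: inputs
  note("stage 1: %s input", config$inputMode)
  if (config$inputMode == "synthetic") {
    coh <- collect(generateCohort(config$nPatients, config$distribution,
                                  config$outcome, seed = config$seed,
                                  thresholdSUV = config$thresholds[1]))
    volumes <- coh$volumes
    outcomes <- coh$outcomes
    diameters <- coh$features$diameter_mm
  } else {
    volumes <- lapply(seq_along(config$volumePaths), function(i)
      readVolume(config$volumePaths[i], patientId = sprintf("P%03d", i)))
    outcomes <- config$outcomeTable
    if (is.character(outcomes))
      outcomes <- utils::read.csv(outcomes, stringsAsFactors = FALSE)
    if (is.null(outcomes)) stop("files mode requires an outcome table")
    if (nrow(outcomes) != length(volumes))
      stop("outcome table and volume list disagree in size")
    diameters <- if (!is.null(outcomes$diameter_mm))
      outcomes$diameter_mm else rep(NA_real_, nrow(outcomes))
  }
  n <- length(volumes)

  # stage 2: segmentation + features at every threshold
  note("stage 2: features at thresholds %s",
       paste(config$thresholds, collapse = ", "))
  featsBy <- lapply(config$thresholds, function(thr) {
    do.call(rbind, lapply(seq_len(n), function(i)
      collect(extractAllFeatures(volumes[[i]], thresholdSUV = thr,
                                 connectivity = config$connectivity,
                                 aggregation = config$glcmAggregation,
                                 entropyLogBase = config$entropyLogBase,
                                 diameter_mm = diameters[i]))))
  })
  features <- featsBy[[1]]
  if (is.null(outcomes$t_stage) || anyNA(outcomes$t_stage))
    outcomes$t_stage <- ifelse(diameters <= config$subgroupDiameterMm,
                               "T1", "T2")
  pars <- reportParameters(features)
  t2 <- outcomes$t_stage == "T2"

  # stage 3: ROC per parameter x endpoint (+ LR in the T2 subgroup)
  note("stage 3: ROC analysis")
  epCols <- c(config$endpoints,
              if ("LR" %in% config$endpoints && any(t2) && !all(t2)) "LR_T2")
  rocRows <- list()
  cutoffs <- list()
  for (par in pars) for (ep in epCols) {
    sub <- if (ep == "LR_T2") t2 else rep(TRUE, n)
    lab <- endpointLabel(sub("_T2$", "", ep), outcomes)[sub]
    row <- tryCatch({
      r <- collect(rocAnalysis(features[[par]][sub], lab))
      cutoffs[[paste(par, ep)]] <- r$optimal_cutoff
      data.frame(parameter = par, endpoint = ep, auc = r$auc,
                 ci_low = r$ci_low, ci_high = r$ci_high,
                 cutoff = r$optimal_cutoff, n_pos = r$n_pos, n_neg = r$n_neg,
                 significant = !is.na(r$ci_low) &&
                   (r$ci_low > 0.5 || r$ci_high < 0.5),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warns <<- c(warns, sprintf("ROC %s/%s: %s", par, ep,
                                 conditionMessage(e)))
      data.frame(parameter = par, endpoint = ep, auc = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, cutoff = NA_real_,
                 n_pos = NA_integer_, n_neg = NA_integer_,
                 significant = FALSE, stringsAsFactors = FALSE)
    })
    rocRows[[paste(par, ep)]] <- row
  }
  rocTable <- do.call(rbind, c(rocRows, list(make.row.names = FALSE)))

  # stage 4: cutoff-dichotomized KM / log-rank
  note("stage 4: survival analysis")
  survEndpoints <- intersect(c("LR_T2", "LR", "DSS", "OS"),
                             c(epCols, config$endpoints))
  survRows <- list()
  for (par in pars) for (ep in survEndpoints) {
    base <- sub("_T2$", "", ep)
    if (!base %in% c("LR", "DSS", "OS")) next
    sub <- if (ep == "LR_T2") t2 else rep(TRUE, n)
    tm <- if (base == "LR") outcomes$time_to_lr_months[sub] else
      outcomes$os_time_months[sub]
    ev <- endpointLabel(base, outcomes)[sub]
    cut <- cutoffs[[paste(par, ep)]]
    row <- tryCatch({
      if (is.null(cut) || !is.finite(cut)) stop("no usable cutoff")
      grp <- factor(ifelse(features[[par]][sub] >= cut, "high", "low"),
                    levels = c("low", "high"))
      if (any(table(grp) == 0L)) stop("degenerate dichotomization")
      km <- kmLogrank(tm, ev, grp)
      g <- km$groups
      data.frame(parameter = par, endpoint = ep, cutoff = cut,
                 n_low = g$n[1], events_low = g$events[1],
                 median_low = g$median[1], rmean_low = g$rmean[1],
                 n_high = g$n[2], events_high = g$events[2],
                 median_high = g$median[2], rmean_high = g$rmean[2],
                 logrank_p = km$logrank_p,
                 significant = !is.na(km$logrank_p) && km$logrank_p < 0.05,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warns <<- c(warns, sprintf("KM %s/%s: %s", par, ep, conditionMessage(e)))
      data.frame(parameter = par, endpoint = ep, cutoff = NA_real_,
                 n_low = NA, events_low = NA, median_low = NA, rmean_low = NA,
                 n_high = NA, events_high = NA, median_high = NA,
                 rmean_high = NA, logrank_p = NA_real_, significant = FALSE,
                 stringsAsFactors = FALSE)
    })
    survRows[[paste(par, ep)]] <- row
  }
  survivalTable <- do.call(rbind, c(survRows, list(make.row.names = FALSE)))

  # stage 5: Cox regression (univariate all parameters; restricted
  # multivariate: high-entropy vs log-MTV vs dose stand-in)
  note("stage 5: Cox regression")
  dose <- withSeed(config$seed + 1L,
                   stats::runif(n, config$doseRangeGy[1],
                                config$doseRangeGy[2]))
  coxRows <- list()
  for (ep in intersect(c("OS", "DSS"), config$endpoints)) {
    ev <- endpointLabel(ep, outcomes)
    tm <- outcomes$os_time_months
    for (par in pars) {
      cut <- cutoffs[[paste(par, ep)]]
      covName <- par
      cov <- if (par %in% c("mtv_ml", "diameter_mm")) features[[par]] else {
        covName <- paste0("high_", par)
        if (is.null(cut) || !is.finite(cut)) NULL else
          as.numeric(features[[par]] >= cut)
      }
      lt <- if (par == "mtv_ml") "mtv_ml" else character()
      row <- tryCatch({
        if (is.null(cov)) stop("no usable cutoff")
        cf <- data.frame(x = cov); names(cf) <- covName
        res <- coxFit(cf, tm, ev, logTransform = lt)
        data.frame(endpoint = ep, model = "univariate", covariate = covName,
                   hr = res$hr, ci_low = res$ci_low, ci_high = res$ci_high,
                   p = res$p, significant = res$p < 0.05,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warns <<- c(warns, sprintf("Cox %s/%s: %s", par, ep,
                                   conditionMessage(e)))
        data.frame(endpoint = ep, model = "univariate", covariate = covName,
                   hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   p = NA_real_, significant = FALSE, stringsAsFactors = FALSE)
      })
      coxRows[[paste(ep, "uni", par)]] <- row
    }
    # multivariate
    mv <- tryCatch({
      cols <- list()
      lt <- character()
      for (term in config$multivariateSet) {
        if (term == "entropy") {
          cut <- cutoffs[[paste("entropy", ep)]]
          if (is.null(cut) || !is.finite(cut)) stop("no entropy cutoff")
          cols[["high_entropy"]] <- as.numeric(features$entropy >= cut)
        } else if (term == "mtv") {
          cols[["mtv_ml"]] <- features$mtv_ml
          lt <- c(lt, "mtv_ml")
        } else if (term == "dose") {
          cols[["dose_gy"]] <- dose
        } else stop("unknown multivariate term: ", term)
      }
      res <- coxFit(as.data.frame(cols), tm, ev, logTransform = lt)
      data.frame(endpoint = ep, model = "multivariate",
                 covariate = res$covariate, hr = res$hr,
                 ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
                 significant = res$p < 0.05, stringsAsFactors = FALSE)
    }, error = function(e) {
      warns <<- c(warns, sprintf("Cox multivariate/%s: %s", ep,
                                 conditionMessage(e)))
      NULL
    })
    if (!is.null(mv)) coxRows[[paste(ep, "multi")]] <- mv
  }
  coxTable <- if (length(coxRows))
    do.call(rbind, c(coxRows, list(make.row.names = FALSE))) else
    data.frame(endpoint = character(), model = character(),
               covariate = character(), hr = numeric(), ci_low = numeric(),
               ci_high = numeric(), p = numeric(), significant = logical())

  # stage 6: stability across thresholds
  note("stage 6: threshold stability")
  stabilityTable <- if (length(config$thresholds) >= 2L)
    pearsonTable(featsBy[[1]], featsBy[[2]]) else
    data.frame()

  # stage 7: size dependency
  note("stage 7: size dependency")
  sizeTable <- sizeDependency(features)

  new("StudyReport", rocTable = rocTable, survivalTable = survivalTable,
      coxTable = coxTable, stabilityTable = stabilityTable,
      sizeTable = sizeTable,
      provenance = list(seed = config$seed, configHash = configHash(config),
                        packageVersion =
                          as.character(utils::packageVersion("pettex")),
                        config = stripClasses(config),
                        log = log, warnings = unique(warns)))
}

#' Write a study report to disk
#'
#' Writes the five tables as CSV, a single JSON bundle of the whole
#' report, and a plain-text stage log. Significant rows carry a boolean
#' `significant` column (two-sided p < 0.05). Nothing is written if the
#' output directory cannot be created.
#'
#' @param report a [StudyReport-class].
#' @param outdir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
writeReport <- function(report, outdir) {
  stopifnot(is(report, "StudyReport"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  tabs <- list(roc_table = report@rocTable,
               survival_table = report@survivalTable,
               cox_table = report@coxTable,
               stability_table = report@stabilityTable,
               size_table = report@sizeTable)
  files <- character()
  for (nm in names(tabs)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  bundle <- c(tabs, list(provenance = report@provenance))
  jf <- file.path(outdir, "report.json")
  jsonlite::write_json(bundle, jf, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  lf <- file.path(outdir, "study.log")
  writeLines(c(report@provenance$log,
               if (length(report@provenance$warnings))
                 paste("warning:", report@provenance$warnings)), lf)
  invisible(c(files, jf, lf))
}

#' Re-read a written study report
#'
#' @param path the `report.json` written by [writeReport()] (or its
#'   directory).
#' @return a [StudyReport-class].
#' @export
readReport <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("StudyReport",
      rocTable = as.data.frame(b$roc_table),
      survivalTable = as.data.frame(b$survival_table),
      coxTable = as.data.frame(b$cox_table),
      stabilityTable = as.data.frame(b$stability_table),
      sizeTable = as.data.frame(b$size_table),
      provenance = b$provenance)
}

#' Write or read a study configuration as YAML
#'
#' @param config a `StudyConfig`.
#' @param path destination / source path.
#' @return `writeConfig()` returns `path` invisibly; `readConfig()` a
#'   `StudyConfig` (synthetic-mode fields only).
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "StudyConfig"))
  yaml::write_yaml(stripClasses(config), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  studyConfig(nPatients = y$nPatients, inputMode = y$inputMode,
              volumePaths = y$volumePaths,
              thresholds = unlist(y$thresholds),
              endpoints = unlist(y$endpoints),
              subgroupDiameterMm = y$subgroupDiameterMm,
              connectivity = y$connectivity,
              entropyLogBase = y$entropyLogBase,
              glcmAggregation = y$glcmAggregation,
              distribution = do.call(cohortDistribution,
                                     lapply(y$distribution, unlist)),
              outcome = do.call(outcomeParams, lapply(y$outcome, unlist)),
              doseRangeGy = unlist(y$doseRangeGy),
              multivariateSet = unlist(y$multivariateSet),
              seed = y$seed)
}
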