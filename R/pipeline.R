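#' @include AllClasses.R utils.R synth-cohort.R confounds.R dualreg.R
#' @include similarity.R graph-metrics.R network-fc.R inference.R mediation.R
NULL

#' Default pipeline configuration
#'
#' All tunables of the end-to-end synthetic run: cohort size, acquisition
#' length (198 volumes at TR 2.5 s with the first 5 dropped), motion
#' screening thresholds, band-pass edges, the young-adult reference cutoff,
#' the graph threshold sweep, FDR level and bootstrap size. `simulate` may
#' carry overrides for any [defaultGroundTruth()] parameter.
#'
#' @param ... named overrides of any default entry.
#' @return a named list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    n_subjects = 129L,
    n_volumes = 198L,
    drop_volumes = 5L,
    tr_seconds = 2.5,
    seed = 1L,
    mean_fd = 0.2, frac_fd = 0.2, vol_fd = 0.2,
    bandpass_low = 0.01, bandpass_high = 0.1,
    reference_cutoff_age = 30,
    graph_thresholds = c(0.20, 0.25, 0.30, 0.35, 0.40),
    fdr_q = 0.05,
    n_boot = 10000L,
    use_full_parcellation = TRUE,
    use_dual_regression = FALSE,
    grid_dim = c(24L, 24L, 12L),
    stages = c("screen", "confounds", "similarity", "graph", "netfc",
               "mediate"),
    out_dir = NULL,
    simulate = list())
  dots <- list(...)
  stopIfNot(all(names(dots) %in% names(cfg)),
            paste("unknown config entries:",
                  paste(setdiff(names(dots), names(cfg)), collapse = ", ")))
  cfg[names(dots)] <- dots
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with top-level config keys (a `simulate:` block
#'   carries ground-truth overrides).
#' @return a config list merged over [defaultConfig()].
#' @export
readConfig <- function(path) {
  do.call(defaultConfig, yaml::read_yaml(path))
}

## Drop covariate columns that are constant over the analysed subjects
## (e.g. a single-sex subsample); NULL when none survive.
usableCovariates <- function(M) {
  M <- as.matrix(M)
  keep <- apply(M, 2L, stats::sd) > 0
  if (!any(keep)) return(NULL)
  M[, keep, drop = FALSE]
}

## Partial-correlation row of one measure against one variable, controlling
## the others, over included subjects with pairwise-complete values.
assocRow <- function(vals, dem, against, controls) {
  keep <- is.finite(vals)
  if (sum(keep) <= 2 + length(controls))
    return(list(r = NA_real_, p = NA_real_, n = sum(keep)))
  pc <- tryCatch(
    partialCorrelation(vals[keep], dem[[against]][keep],
                       covariates = usableCovariates(
                         dem[keep, controls, drop = FALSE])),
    error = function(e) NULL)       # degenerate (e.g. constant) variable
  if (is.null(pc)) return(list(r = NA_real_, p = NA_real_, n = sum(keep)))
  list(r = pc$r, p = pc$p, n = pc$n)
}

## Association table: every measure column vs age (controlling sex, ACE-R),
## sex (controlling age, ACE-R) and ACE-R (controlling age, sex), with
## per-column BH-FDR flags.
associationTable <- function(measures, dem, q) {
  vars <- list(age = c("sex", "ace_r_total"),
               sex = c("age", "ace_r_total"),
               ace_r_total = c("age", "sex"))
  out <- data.frame(measure = colnames(measures), stringsAsFactors = FALSE)
  for (v in names(vars)) {
    rows <- lapply(seq_len(ncol(measures)), function(j)
      assocRow(measures[, j], dem, v, vars[[v]]))
    out[[paste0("r_", v)]] <- vapply(rows, `[[`, numeric(1), "r")
    out[[paste0("p_", v)]] <- vapply(rows, `[[`, numeric(1), "p")
    pv <- out[[paste0("p_", v)]]
    flag <- rep(NA, length(pv))
    ok <- is.finite(pv)
    if (any(ok)) flag[ok] <- bhFdr(pv[ok], q)
    out[[paste0("fdr_", v)]] <- flag
  }
  out
}

## Long similarity table -> subjects x RSN wide matrix.
etaWide <- function(simTab, subjectIds) {
  labs <- unique(simTab$rsn_label)
  m <- matrix(NA_real_, length(subjectIds), length(labs),
              dimnames = list(subjectIds, labs))
  idx <- cbind(match(simTab$subject_id, subjectIds),
               match(simTab$rsn_label, labs))
  m[idx] <- simTab$eta_sq
  m
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate, motion screening, confound regression + band-pass
#' filtering, (optionally) dual regression, similarity analysis against a
#' young-adult reference, the graph-metric threshold sweep, network-level
#' connectivity, and bootstrap mediation — all from one config under one
#' master seed (per-stage child seeds make the run reproducible even when
#' stages are toggled). When `out_dir` is set, every stage table is written
#' as TSV together with a YAML provenance record.
#'
#' @param config list from [defaultConfig()] / [readConfig()], or a path to
#'   a YAML config.
#' @return list with elements `config`, `truth`, `subjects`, `screening`,
#'   `similarity` (table + associations + normality), `graph` (per-subject
#'   metrics + associations per threshold), `netfc` (cell table +
#'   associations), `mediation` (per-candidate paths with bootstrap z / p),
#'   as produced by the enabled stages.
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- do.call(defaultConfig, config[setdiff(names(config), "")])
  seed <- cfg$seed
  truth <- do.call(defaultGroundTruth,
                   c(list(seed = seed), cfg$simulate))
  parc <- defaultParcellation(includeOther = cfg$use_full_parcellation)
  res <- list(config = cfg, truth = truth)

  ## --- simulate -----------------------------------------------------------
  cohort <- generateCohort(cfg$n_subjects, truth)
  subjects <- cohort$subjects
  n <- nrow(subjects)
  Tn <- cfg$n_volumes

  traces <- lapply(seq_len(n), function(i)
    generateMotionTrace(subjects[i, ], truth, nVolumes = Tn,
                        seed = childSeed(seed, 1000L + i)))

  ## --- screen -------------------------------------------------------------
  if ("screen" %in% cfg$stages) {
    screening <- lapply(traces, function(tr)
      screenSubject(framewiseDisplacement(tr),
                    meanThr = cfg$mean_fd, fracThr = cfg$frac_fd,
                    volThr = cfg$vol_fd))
    subjects$included <- vapply(screening, `[[`, logical(1), "include")
    res$screening <- data.frame(
      subject_id = subjects$subject_id,
      mean_fd = vapply(screening, `[[`, numeric(1), "mean_fd"),
      frac_high = vapply(screening, `[[`, numeric(1), "frac_high"),
      included = subjects$included,
      reasons = vapply(screening, function(s)
        paste(s$reasons, collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
  } else subjects$included <- TRUE
  res$subjects <- subjects
  inc <- which(subjects$included)
  stopIfNot(length(inc) >= 4L, "fewer than 4 subjects survive screening")
  dem <- subjects[inc, , drop = FALSE]

  ## --- confounds: node time series, nuisance regression, band-pass --------
  needTs <- any(c("confounds", "graph", "netfc", "mediate") %in% cfg$stages)
  tsList <- NULL
  if (needTs) {
    tsList <- lapply(inc, function(i) {
      ts <- generateNodeTimeSeries(subjects[i, ], parc, truth,
                                   nVolumes = Tn,
                                   trSeconds = cfg$tr_seconds,
                                   seed = childSeed(seed, 2000L + i))
      if ("confounds" %in% cfg$stages) {
        drop <- cfg$drop_volumes
        ts <- dropInitialVolumes(ts, drop)
        tr <- new("MotionTrace",
                  params = traces[[i]]@params[-seq_len(drop), , drop = FALSE])
        nuis <- withSeed(childSeed(seed, 3000L + i),
                         matrix(stats::rnorm(nrow(ts@values) * 3),
                                ncol = 3))
        ts <- regressConfounds(ts, buildConfoundDesign(tr, nuis))
        ts <- bandpass(ts, cfg$bandpass_low, cfg$bandpass_high)
      }
      ts
    })
    names(tsList) <- subjects$subject_id[inc]
  }

  ## --- similarity ---------------------------------------------------------
  if ("similarity" %in% cfg$stages) {
    templates <- generateTemplates(gridDim = cfg$grid_dim,
                                   seed = childSeed(seed, 11L))
    subjectMaps <- lapply(seq_along(inc), function(j) {
      i <- inc[j]
      sm <- generateSpatialMaps(subjects[i, ], templates, truth,
                                seed = childSeed(seed, 4000L + i))
      if (cfg$use_dual_regression) {
        ## rebuild maps through the two-stage regression path: synthesize
        ## voxel data as maps x unit-variance courses + noise, then recover
        M <- mapMatrix(sm)
        K <- ncol(M)
        Td <- max(60L, cfg$n_volumes - cfg$drop_volumes)
        dat <- withSeed(childSeed(seed, 5000L + i), {
          S <- matrix(stats::rnorm(K * Td), K, Td)
          M %*% S + matrix(stats::rnorm(nrow(M) * Td, 0, 0.5),
                           nrow(M), Td)
        })
        tc <- dualRegressionStage1(dat, templates)
        sm <- dualRegressionStage2(dat, tc, templates)
      }
      sm
    })
    names(subjectMaps) <- subjects$subject_id[inc]
    ref <- buildReference(subjectMaps, dem,
                          cutoffAge = cfg$reference_cutoff_age)
    simTab <- similarityTable(subjectMaps, ref)
    eta <- etaWide(simTab, names(subjectMaps))
    normality <- lapply(colnames(eta), function(lab)
      tryCatch(ksNormality(eta[is.finite(eta[, lab]), lab]),
               error = function(e) list(statistic = NA, p = NA, reject = NA)))
    res$similarity <- list(
      table = simTab,
      reference_n = ref$n_reference_subjects,
      associations = associationTable(eta, dem, cfg$fdr_q),
      normality = data.frame(
        rsn_label = colnames(eta),
        ks_p = vapply(normality, function(x) as.numeric(x$p), numeric(1)),
        reject = vapply(normality, function(x) isTRUE(x$reject), logical(1)),
        stringsAsFactors = FALSE))
    res$similarity$eta_wide <- eta
  }

  ## --- connectivity matrices ----------------------------------------------
  needConn <- any(c("graph", "netfc", "mediate") %in% cfg$stages)
  connList <- NULL
  if (needConn && !is.null(tsList))
    connList <- lapply(tsList, buildConnectivity)

  ## --- graph metrics -------------------------------------------------------
  if ("graph" %in% cfg$stages && !is.null(connList)) {
    sweep <- do.call(rbind, lapply(seq_along(connList), function(j) {
      sw <- graphMetricsSweep(connList[[j]], cfg$graph_thresholds,
                              seed = childSeed(seed, 6000L + j))
      cbind(subject_id = names(connList)[j], sw,
            stringsAsFactors = FALSE)
    }))
    metricCols <- c("path_length", "global_efficiency", "mean_degree",
                    "mean_betweenness", "modularity_q", "hierarchy_beta")
    assoc <- do.call(rbind, lapply(cfg$graph_thresholds, function(thr) {
      sub <- sweep[sweep$threshold == thr, ]
      m <- as.matrix(sub[match(dem$subject_id, sub$subject_id), metricCols])
      a <- associationTable(m, dem, cfg$fdr_q)
      cbind(threshold = thr, a, stringsAsFactors = FALSE)
    }))
    res$graph <- list(metrics = sweep, associations = assoc)
  }

  ## --- network-level connectivity -----------------------------------------
  if ("netfc" %in% cfg$stages && !is.null(connList)) {
    cellTabs <- lapply(connList, networkFCTable, parc = parc)
    cells <- cellTabs[[1L]][, c("cell", "type", "network1", "network2",
                                "n_pairs")]
    vals <- vapply(cellTabs, function(tb) tb$value,
                   numeric(nrow(cells)))
    vals <- t(vals)                       # subjects x cells
    colnames(vals) <- cells$cell
    rownames(vals) <- names(connList)
    assoc <- associationTable(vals, dem, cfg$fdr_q)
    res$netfc <- list(cells = cells,
                      values = vals,
                      associations = cbind(cells[, c("type", "network1",
                                                     "network2")],
                                           assoc,
                                           stringsAsFactors = FALSE))
  }

  ## --- mediation -----------------------------------------------------------
  if ("mediate" %in% cfg$stages) {
    candidates <- list()
    addCand <- function(cands, name, vals) {
      keep <- is.finite(vals)
      if (sum(keep) <= 4) return(cands)
      sexCov <- usableCovariates(dem$sex[keep])
      pAge <- tryCatch(
        partialCorrelation(vals[keep], dem$age[keep], covariates = sexCov)$p,
        error = function(e) NA_real_)
      pAce <- tryCatch(
        partialCorrelation(vals[keep], dem$ace_r_total[keep],
                           covariates = sexCov)$p,
        error = function(e) NA_real_)
      if (isTRUE(pAge < 0.05) && isTRUE(pAce < 0.05))
        cands[[name]] <- vals
      cands
    }
    if (!is.null(res$similarity))
      for (lab in colnames(res$similarity$eta_wide))
        candidates <- addCand(candidates, paste0("eta_sq:", lab),
                              res$similarity$eta_wide[, lab])
    if (!is.null(res$netfc))
      for (cell in colnames(res$netfc$values))
        candidates <- addCand(candidates, paste0("netfc:", cell),
                              res$netfc$values[, cell])
    if (!is.null(res$graph)) {
      thr0 <- cfg$graph_thresholds[1L]
      sub <- res$graph$metrics[res$graph$metrics$threshold == thr0, ]
      for (mc in c("path_length", "global_efficiency", "mean_degree",
                   "mean_betweenness")) {
        v <- sub[[mc]][match(dem$subject_id, sub$subject_id)]
        candidates <- addCand(candidates,
                              sprintf("graph:%s@%.2f", mc, thr0), v)
      }
    }
    medRows <- lapply(names(candidates), function(nm) {
      v <- candidates[[nm]]
      keep <- is.finite(v)
      mr <- bootstrapMediation(dem$age[keep], v[keep],
                               dem$ace_r_total[keep],
                               covariates = usableCovariates(dem$sex[keep]),
                               nBoot = cfg$n_boot,
                               seed = childSeed(seed, 7000L +
                                                  which(names(candidates) == nm)))
      data.frame(measure = nm, t(mr@paths),
                 z_ab = mr@z["ab"], p_ab = mr@p["ab"],
                 z_a = mr@z["a"], p_a = mr@p["a"],
                 z_b = mr@z["b"], p_b = mr@p["b"],
                 z_cprime = mr@z["cprime"], p_cprime = mr@p["cprime"],
                 n_boot = mr@nBoot, row.names = NULL,
                 stringsAsFactors = FALSE)
    })
    res$mediation <- if (length(medRows)) do.call(rbind, medRows)
      else data.frame()
  }

  if (!is.null(cfg$out_dir)) writePipelineOutputs(res, cfg$out_dir)
  res
}

## Serialize every stage table as TSV plus a YAML provenance sidecar.
writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  writeTsv(res$subjects[, c("subject_id", "age", "sex", "ace_r_total",
                            "cognitive_pass", "included")],
           file.path(outDir, "demographics.tsv"))
  if (!is.null(res$screening))
    writeTsv(res$screening, file.path(outDir, "screening.tsv"))
  if (!is.null(res$similarity)) {
    writeTsv(res$similarity$table, file.path(outDir, "similarity.tsv"))
    writeTsv(res$similarity$associations,
             file.path(outDir, "similarity_associations.tsv"))
  }
  if (!is.null(res$graph)) {
    writeTsv(res$graph$metrics, file.path(outDir, "graph_metrics.tsv"))
    writeTsv(res$graph$associations,
             file.path(outDir, "graph_associations.tsv"))
  }
  if (!is.null(res$netfc))
    writeTsv(res$netfc$associations,
             file.path(outDir, "netfc_associations.tsv"))
  if (!is.null(res$mediation) && nrow(res$mediation))
    writeTsv(res$mediation, file.path(outDir, "mediation.tsv"))
  prov <- list(
    package = "connAge",
    version = as.character(utils::packageVersion("connAge")),
    seed = cfg$seed,
    n_subjects = cfg$n_subjects,
    stages = cfg$stages,
    config = cfg[setdiff(names(cfg), c("out_dir", "simulate"))])
  yaml::write_yaml(prov, file.path(outDir, "provenance.yaml"))
  invisible(outDir)
}
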