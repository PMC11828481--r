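#' Read and validate a run configuration
#'
#' YAML configuration for the pipeline commands. Recognized blocks/keys:
#' `inputs` (`manifest`, `fr_table`, `deg_table`, `census_per_type`,
#' `census_per_sample`, `gene_set_dir`), `params` (`correction_factor`, `k`,
#' `nmda_delay_ms`, `nmda_window_ms`, `preset`, `lfc_min`, `fdr_max`),
#' `seed` and `out_dir`. Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowedTop <- c("inputs", "params", "seed", "out_dir")
  unknown <- setdiff(names(cfg), allowedTop)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  allowedInputs <- c("manifest", "fr_table", "deg_table", "census_per_type",
                     "census_per_sample", "gene_set_dir")
  unknown <- setdiff(names(cfg$inputs), allowedInputs)
  if (length(unknown)) stop("unknown input keys: ", paste(unknown, collapse = ", "))
  allowedParams <- c("correction_factor", "k", "nmda_delay_ms",
                     "nmda_window_ms", "preset", "lfc_min", "fdr_max")
  unknown <- setdiff(names(cfg$params), allowedParams)
  if (length(unknown)) stop("unknown param keys: ", paste(unknown, collapse = ", "))
  cfg
}

.provenance <- function(params, seed = NULL) {
  list(package = "synphen",
       version = as.character(utils::packageVersion("synphen")),
       seed = seed,
       params = params)
}

.pairwiseBky <- function(values, groups, q = 0.05) {
  groups <- as.character(groups)
  lv <- unique(groups)
  pairs <- utils::combn(lv, 2L)
  p <- apply(pairs, 2L, function(pr) {
    suppressWarnings(stats::wilcox.test(values[groups == pr[1L]],
                                        values[groups == pr[2L]])$p.value)
  })
  bky <- bkyTwoStage(p, q)
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p = p,
             bky_rejected = bky$rejected, stringsAsFactors = FALSE)
}

#' Run the full electrophysiology analysis
#'
#' End-to-end matched EPSC analysis: reads sweeps (or takes in-memory
#' recordings, or a published per-cell failure-rate table), extracts EPSC
#' features and failure rates, applies the +50 mV correction and the
#' silent-synapse estimator, and runs the statistical battery (matched
#' two-way ANOVA on amplitudes and failure rates, Kruskal-Wallis plus BKY
#' pairwise tests on AMPA/NMDA ratios and failure-rate ratios, Sidak-adjusted
#' within-condition -90 vs +50 contrasts). Writes `features.tsv`,
#' `silent.tsv`, `summary.tsv` and `stats.json` when `outDir` is given.
#'
#' @param manifest path to a sweep manifest (see [readSweeps()]).
#' @param recordings in-memory list of [CellRecording-class] (alternative to
#'   `manifest`).
#' @param frTable per-cell failure-rate table (path or data.frame; see
#'   [silentFromTable()]); skips sweep analysis.
#' @param outDir output directory, or `NULL` to return results only.
#' @param correctionFactor +50 mV failure-rate correction (default 1.3).
#' @param k success/failure threshold in noise SDs.
#' @param nmdaDelay,nmdaWindow NMDA measurement window (seconds).
#' @return list with `features`, `silent` (per-cell), `summary`
#'   (per-condition) and `stats` (named list of test results).
#' @export
runEphysPipeline <- function(manifest = NULL, recordings = NULL,
                             frTable = NULL, outDir = NULL,
                             correctionFactor = 1.3, k = 3,
                             nmdaDelay = 40e-3, nmdaWindow = 5e-3) {
  if (is.null(manifest) && is.null(recordings) && is.null(frTable)) {
    stop("ephys pipeline needs a manifest, recordings, or a failure-rate table")
  }
  features <- NULL
  if (!is.null(manifest) || !is.null(recordings)) {
    if (is.null(recordings)) recordings <- readSweeps(manifest)
    if (length(recordings) == 0L) stop("no recordings found in the manifest")
    features <- epscFeatureTable(recordings, nmdaDelay = nmdaDelay,
                                 nmdaWindow = nmdaWindow, k = k)
    silent <- silentSynapseTable(recordings, correctionFactor = correctionFactor,
                                 k = k)
  } else {
    silent <- silentFromTable(frTable, correctionFactor = correctionFactor)$cells
  }
  summary <- conditionSummary(silent)

  statsOut <- list()
  if (!is.null(features)) {
    clean <- features[features$qc_flags == "" & is.finite(features$ampa_nmda_ratio), ]
    if (nrow(clean) >= 6L && length(unique(clean$condition)) >= 2L) {
      long <- rbind(
        data.frame(cell_id = clean$cell_id, condition = clean$condition,
                   measurement = "AMPA", value = clean$ampa_amplitude),
        data.frame(cell_id = clean$cell_id, condition = clean$condition,
                   measurement = "NMDA", value = clean$nmda_amplitude))
      statsOut$amplitude_anova <- twoWayMixedAnova(long)
      statsOut$ratio_kruskal <- kruskalWallis(clean$ampa_nmda_ratio,
                                              clean$condition)
      statsOut$ratio_pairwise_bky <- .pairwiseBky(clean$ampa_nmda_ratio,
                                                  clean$condition)
    }
  }
  okFr <- silent[silent$qc_flags == "", ]
  if (nrow(okFr) >= 6L && length(unique(okFr$condition)) >= 2L) {
    frLong <- rbind(
      data.frame(cell_id = okFr$cell_id, condition = okFr$condition,
                 measurement = "FRminus90", value = okFr$fr_minus90),
      data.frame(cell_id = okFr$cell_id, condition = okFr$condition,
                 measurement = "FRplus50", value = okFr$fr_plus50_corrected))
    statsOut$fr_anova <- twoWayMixedAnova(frLong, ggCorrection = TRUE)
    # within-condition -90 vs +50 contrasts, Sidak-adjusted across conditions
    conds <- unique(okFr$condition)
    pRaw <- vapply(conds, function(cond) {
      sub <- okFr[okFr$condition == cond, ]
      stats::t.test(sub$fr_minus90, sub$fr_plus50_corrected,
                    paired = TRUE)$p.value
    }, numeric(1L))
    statsOut$fr_contrasts_sidak <- data.frame(
      condition = conds, p = pRaw, p_sidak = sidakAdjust(pRaw),
      stringsAsFactors = FALSE)
    frr <- okFr[is.finite(okFr$frr), ]
    statsOut$frr_kruskal <- kruskalWallis(frr$frr, frr$condition)
    statsOut$frr_pairwise_bky <- .pairwiseBky(frr$frr, frr$condition)
  }

  out <- list(features = features, silent = silent, summary = summary,
              stats = statsOut,
              provenance = .provenance(list(
                correction_factor = correctionFactor, k = k,
                nmda_delay = nmdaDelay, nmda_window = nmdaWindow)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(features)) {
      writeFeatureTable(features, file.path(outDir, "features.tsv"))
    }
    writeFeatureTable(silent, file.path(outDir, "silent.tsv"))
    writeFeatureTable(summary, file.path(outDir, "summary.tsv"))
    jsonlite::write_json(
      list(stats = .statsToJson(statsOut), summary = summary,
           provenance = out$provenance),
      file.path(outDir, "stats.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, null = "null")
  }
  out
}

.statsToJson <- function(statsOut) {
  lapply(statsOut, function(x) {
    if (inherits(x, "synphen_test")) unclass(x) else x
  })
}

#' Run the cell-type DEG census and enrichment analysis
#'
#' Applies the DEG thresholds to a per-gene statistics table, tallies DEG
#' shares per class, computes conditional DEG probabilities against the
#' expressed-gene census, tests curated gene-set enrichment per class
#' (Yates chi-square, hypergeometric and the exact multi-set intersection for
#' all sets jointly), and compares per-type UMIs across conditions when a
#' per-sample census is provided. Writes `census_report.json` when `outDir`
#' is given.
#'
#' @param degTable per-gene statistics (data.frame or path; columns `gene`,
#'   `cell_type`, `log2fc`, `fdr`).
#' @param census per-type census (data.frame or path; columns `cell_type`,
#'   `class`, `n_genes_expressed`) or a census list from
#'   [censusFromCounts()].
#' @param geneSets named list of character vectors, or a directory of
#'   `*.txt` gene lists (one symbol per line).
#' @param classMap optional type-to-class map (defaults to the census
#'   `class` column).
#' @param preset DEG threshold preset (`"deg"` or `"overlap"`, see
#'   [filterDegs()]).
#' @param outDir output directory or `NULL`.
#' @return list with `degTable` (flagged), `shares`, `conditional`,
#'   `enrichment` (per class x set), `umi` (test results or `NULL`).
#' @export
runCensusPipeline <- function(degTable, census, geneSets = NULL,
                              classMap = NULL, preset = "deg",
                              outDir = NULL) {
  if (is.character(degTable)) degTable <- readFeatureTable(degTable)
  perSample <- NULL
  if (is.list(census) && !is.data.frame(census) && !is.null(census$perType)) {
    perSample <- census$perSample
    census <- census$perType
  } else if (is.character(census)) {
    census <- readFeatureTable(census)
  }
  if (is.null(classMap) && !is.null(census$class)) {
    classMap <- stats::setNames(census$class, census$cell_type)
  }
  if (is.character(geneSets)) {
    files <- list.files(geneSets, pattern = "\\.txt$", full.names = TRUE)
    if (length(files) == 0L) stop("no gene lists (*.txt) found in ", geneSets)
    geneSets <- stats::setNames(lapply(files, readGeneSet),
                                tools::file_path_sans_ext(basename(files)))
  }

  flagged <- filterDegs(degTable, preset = preset)
  degs <- flagged[flagged$is_deg, , drop = FALSE]
  shares <- degShareByClass(degs, classMap)
  conditional <- conditionalDegProbability(census, degs, classMap)

  enrichment <- NULL
  if (!is.null(geneSets)) {
    universe <- unique(degTable$gene)
    cls <- .classOf(degs$cell_type, classMap)
    rows <- list()
    for (cl in unique(cls)) {
      clDegs <- unique(degs$gene[cls == cl])
      for (setName in names(geneSets)) {
        res <- genesetOverlapTest(clDegs, geneSets[[setName]], universe)
        rows[[paste(cl, setName)]] <- data.frame(
          class = cl, gene_set = setName, n_degs = length(clDegs),
          n_set = length(geneSets[[setName]]), overlap = res$overlap,
          expected = res$expected, fold = res$fold,
          chisq_yates = if (is.null(res$chiSquare)) NA_real_ else res$chiSquare$statistic,
          chisq_p = if (is.null(res$chiSquare)) NA_real_ else res$chiSquare$p.value,
          hyper_p = res$hyperP, stringsAsFactors = FALSE)
      }
    }
    enrichment <- do.call(rbind, rows)
    rownames(enrichment) <- NULL
  }

  umi <- NULL
  if (!is.null(perSample)) {
    tab <- umiPerNucleusTable(perSample)
    mm <- tab$matchedMedians
    condCols <- setdiff(names(mm), "cell_type")
    if (nrow(mm) >= 5L && length(condCols) == 2L) {
      anova <- twoWayMixedAnova(tab$perSample, value = "median_umi",
                                cell = "sample", within = "cell_type",
                                between = "condition")
      wilcox <- tryCatch(
        wilcoxonMatchedPairs(mm[[condCols[1L]]], mm[[condCols[2L]]]),
        error = function(e) NULL)
      umi <- list(anova = anova, wilcoxon = wilcox, matched = mm)
    }
  }

  out <- list(degTable = flagged, shares = shares, conditional = conditional,
              enrichment = enrichment, umi = umi,
              provenance = .provenance(list(preset = preset)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(shares = as.list(shares),
           conditional = conditional,
           enrichment = enrichment,
           umi = if (is.null(umi)) NULL else list(
             anova = umi$anova,
             wilcoxon = if (is.null(umi$wilcoxon)) NULL else unclass(umi$wilcoxon)),
           provenance = out$provenance),
      file.path(outDir, "census_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE, null = "null")
  }
  out
}
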