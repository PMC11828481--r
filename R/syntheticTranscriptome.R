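#' Default cortical cell-type panel
#'
#' Seventeen motor-cortex cell types grouped into four classes: excitatory
#' intratelencephalically projecting pyramidal neurons (ExIT, by layer),
#' other excitatory projection classes (ExCT: extratelencephalic,
#' corticothalamic, L6b, near-projecting), inhibitory interneuron subclasses
#' (IN) and non-neuronal types.
#'
#' @return data.frame with columns `cell_type` and `class`.
#' @export
corticalTypePanel <- function() {
  data.frame(
    cell_type = c("L2/3 IT", "L4/5 IT", "L5 IT", "L6 IT",
                  "L5 ET", "L6 CT", "L6b", "NP",
                  "Pvalb", "Sst", "Vip", "Lamp5", "Sncg",
                  "Astro", "Oligo", "OPC", "Micro"),
    class = c(rep("ExIT", 4L), rep("ExCT", 4L), rep("IN", 5L),
              rep("NonNeuronal", 4L)),
    stringsAsFactors = FALSE)
}

#' Design of a synthetic single-nucleus dataset
#'
#' Parameters of the count-matrix generator: a cell-type panel, per-type cell
#' and expressed-gene budgets, a global UMI inflation applied to
#' sleep-deprived cells, and a planted-DEG scheme whose class shares default
#' to the ExIT-dominated distribution (0.69 ExIT, 0.17 IN, 0.05 ExCT, 0.09
#' non-neuronal). Reported per-gene statistics are the planted log2 fold
#' changes plus Gaussian estimation noise, with per-type BH-adjusted
#' p-values, so the reported table is internally consistent.
#'
#' @param types cell-type panel (data.frame `cell_type`, `class`).
#' @param nGenes total genes in the annotation.
#' @param nCellsPerType nuclei per type per condition.
#' @param nSamplesPerCondition biological samples per condition.
#' @param umiInflation multiplicative UMI increase in SD nuclei (>= 1).
#' @param nDeg total planted DEG (gene, type) rows.
#' @param classShares named shares of planted DEGs per class (sum to 1).
#' @param lfcNoise SD of the Gaussian estimation noise on reported log2FC.
#' @param dispersion negative-binomial size parameter of the counts.
#' @param exprRange per-class range of expressed genes per type (fractions of
#'   `nGenes`).
#' @param umiMedian named per-class median UMIs per nucleus (CS condition).
#' @return a `transcriptome_design` list.
#' @export
transcriptomeDesign <- function(types = corticalTypePanel(),
                                nGenes = 12000L,
                                nCellsPerType = 50L,
                                nSamplesPerCondition = 4L,
                                umiInflation = 1.15,
                                nDeg = 1500L,
                                classShares = c(ExIT = 0.69, IN = 0.17,
                                                ExCT = 0.05,
                                                NonNeuronal = 0.09),
                                lfcNoise = 0.02,
                                dispersion = 10,
                                exprRange = list(ExIT = c(0.58, 0.75),
                                                 ExCT = c(0.5, 0.62),
                                                 IN = c(0.42, 0.55),
                                                 NonNeuronal = c(0.33, 0.42)),
                                umiMedian = c(ExIT = 6000, ExCT = 5000,
                                              IN = 4000, NonNeuronal = 2000)) {
  stopifnot(sum(classShares) <= 1 + 1e-9, umiInflation >= 1,
            nGenes > 0, nCellsPerType > 0, nSamplesPerCondition > 0)
  if (!all(unique(types$class) %in% names(classShares))) {
    stop("classShares must cover every class in the type panel")
  }
  structure(list(types = types, nGenes = as.integer(nGenes),
                 nCellsPerType = as.integer(nCellsPerType),
                 nSamplesPerCondition = as.integer(nSamplesPerCondition),
                 umiInflation = umiInflation, nDeg = as.integer(nDeg),
                 classShares = classShares, lfcNoise = lfcNoise,
                 dispersion = dispersion, exprRange = exprRange,
                 umiMedian = umiMedian),
            class = "transcriptome_design")
}

#' Generate a synthetic single-nucleus dataset
#'
#' Draws a gene-by-cell negative-binomial count matrix for the design's
#' cell-type panel under two conditions (CS, SD), with SD library sizes
#' scaled by the design's UMI inflation; plants DEGs per the class shares and
#' emits both the ground-truth DEG table and a noisy reported statistics
#' table (log2FC plus estimation noise, per-type BH-adjusted p-values).
#' Deterministic under `seed`. Optionally writes a MatrixMarket triplet
#' (`counts.mtx`, `features.tsv`, `barcodes.tsv`) plus `cell_metadata.tsv`,
#' `census_per_type.tsv`, `census_per_sample.tsv`, `degs_truth.tsv` and
#' `degs_reported.tsv`.
#'
#' @param design a [transcriptomeDesign()].
#' @param seed integer seed.
#' @param dir output directory, or `NULL` to keep in memory.
#' @return list with `counts` (sparse gene x cell), `metadata` (per cell),
#'   `census` (from [censusFromCounts()]), `degTruth` and `degReported`.
#' @export
generateTranscriptome <- function(design = transcriptomeDesign(), seed = 1,
                                  dir = NULL) {
  stopifnot(inherits(design, "transcriptome_design"))
  set.seed(as.integer(seed))
  nGenes <- design$nGenes
  genes <- sprintf("Gene%05d", seq_len(nGenes))
  types <- design$types
  nTypes <- nrow(types)
  conds <- c("CS", "SD")
  samples <- lapply(conds, function(cond) {
    sprintf("%s_s%d", cond, seq_len(design$nSamplesPerCondition))
  })
  names(samples) <- conds

  # per-gene relative expression, long-tailed
  lambda <- rgamma(nGenes, shape = 0.4, rate = 1)
  lambda <- lambda / sum(lambda)

  # per-type expressed-gene support
  support <- vector("list", nTypes)
  nExpr <- integer(nTypes)
  for (i in seq_len(nTypes)) {
    rng <- design$exprRange[[types$class[i]]]
    nExpr[i] <- round(nGenes * runif(1, rng[1L], rng[2L]))
    support[[i]] <- sort(sample.int(nGenes, nExpr[i]))
  }

  # plant DEGs: distribute over classes then uniformly over the class's types
  degTruth <- NULL
  if (design$nDeg > 0L) {
    classPick <- sample(names(design$classShares), design$nDeg, replace = TRUE,
                        prob = design$classShares)
    typeIdx <- vapply(classPick, function(cl) {
      idxs <- which(types$class == cl)
      idxs[sample.int(length(idxs), 1L)]
    }, integer(1L))
    rows <- lapply(seq_len(design$nDeg), function(j) {
      ti <- typeIdx[j]
      g <- sample(support[[ti]], 1L)
      data.frame(gene = genes[g], cell_type = types$cell_type[ti],
                 log2fc = sample(c(-1, 1), 1L) * (0.2 + stats::rexp(1, 4)),
                 stringsAsFactors = FALSE)
    })
    degTruth <- do.call(rbind, rows)
    # a (gene, type) pair is one DEG row; drop collision re-draws
    degTruth <- degTruth[!duplicated(paste(degTruth$gene, degTruth$cell_type)), ]
    rownames(degTruth) <- NULL
  } else {
    degTruth <- data.frame(gene = character(), cell_type = character(),
                           log2fc = numeric(), stringsAsFactors = FALSE)
  }

  # counts
  cellBlocks <- list()
  metaBlocks <- list()
  cellCounter <- 0L
  for (i in seq_len(nTypes)) {
    sup <- support[[i]]
    pg <- lambda[sup] / sum(lambda[sup])
    medUmi <- design$umiMedian[[types$class[i]]]
    for (cond in conds) {
      nc <- design$nCellsPerType
      lib <- medUmi * exp(rnorm(nc, sd = 0.3))
      if (cond == "SD") lib <- lib * design$umiInflation
      sampleOf <- sample(rep_len(samples[[cond]], nc))
      mu <- outer(pg, lib)
      # planted DEGs shift the SD condition of their type
      if (cond == "SD" && nrow(degTruth) > 0L) {
        sel <- degTruth$cell_type == types$cell_type[i]
        if (any(sel)) {
          gi <- match(degTruth$gene[sel], genes[sup])
          ok <- !is.na(gi)
          mu[gi[ok], ] <- mu[gi[ok], , drop = FALSE] *
            2^degTruth$log2fc[sel][ok]
        }
      }
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = design$dispersion),
                    nrow = length(sup))
      block <- Matrix::sparseMatrix(
        i = rep(sup, ncol(cnt))[cnt > 0],
        j = rep(seq_len(ncol(cnt)), each = nrow(cnt))[cnt > 0],
        x = cnt[cnt > 0], dims = c(nGenes, nc))
      cellBlocks[[length(cellBlocks) + 1L]] <- block
      metaBlocks[[length(metaBlocks) + 1L]] <- data.frame(
        barcode = sprintf("cell%06d", cellCounter + seq_len(nc)),
        cell_type = types$cell_type[i], class = types$class[i],
        sample = sampleOf, condition = cond, stringsAsFactors = FALSE)
      cellCounter <- cellCounter + nc
    }
  }
  counts <- do.call(cbind, cellBlocks)
  metadata <- do.call(rbind, metaBlocks)
  rownames(metadata) <- NULL
  dimnames(counts) <- list(genes, metadata$barcode)

  # reported per-gene statistics for every expressed (gene, type) pair
  repBlocks <- vector("list", nTypes)
  for (i in seq_len(nTypes)) {
    sup <- support[[i]]
    lfc <- rep(0, length(sup))
    p <- runif(length(sup))
    sel <- degTruth$cell_type == types$cell_type[i]
    if (any(sel)) {
      gi <- match(degTruth$gene[sel], genes[sup])
      ok <- !is.na(gi)
      lfc[gi[ok]] <- degTruth$log2fc[sel][ok]
      p[gi[ok]] <- runif(sum(ok), 0, 1e-6)
    }
    if (design$lfcNoise > 0) lfc <- lfc + rnorm(length(sup), sd = design$lfcNoise)
    repBlocks[[i]] <- data.frame(
      gene = genes[sup], cell_type = types$cell_type[i],
      log2fc = lfc, fdr = stats::p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE)
  }
  degReported <- do.call(rbind, repBlocks)
  rownames(degReported) <- NULL

  census <- censusFromCounts(counts, metadata)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(counts, file.path(dir, "counts.mtx"))
    writeLines(genes, file.path(dir, "features.tsv"))
    writeLines(metadata$barcode, file.path(dir, "barcodes.tsv"))
    writeFeatureTable(metadata, file.path(dir, "cell_metadata.tsv"))
    writeFeatureTable(census$perType, file.path(dir, "census_per_type.tsv"))
    writeFeatureTable(census$perSample, file.path(dir, "census_per_sample.tsv"))
    writeFeatureTable(degTruth, file.path(dir, "degs_truth.tsv"))
    writeFeatureTable(degReported, file.path(dir, "degs_reported.tsv"))
  }

  list(counts = counts, metadata = metadata, census = census,
       degTruth = degTruth, degReported = degReported)
}

#' Cell-type census from a count matrix
#'
#' Tallies, per cell type: the number of expressed genes (detected with at
#' least `minCount` counts in at least `minFraction` of the type's nuclei,
#' with a floor of one nucleus) and per-sample nucleus counts and median
#' UMIs per nucleus.
#'
#' @param counts gene-by-cell sparse matrix.
#' @param metadata per-cell data.frame with `cell_type`, `sample`,
#'   `condition` (and optionally `class`), aligned to the columns.
#' @param minFraction minimum fraction of nuclei detecting a gene
#'   (default 0.01).
#' @param minCount minimum counts for detection (default 1).
#' @return list with `perType` (cell_type, class, n_nuclei,
#'   n_genes_expressed) and `perSample` (cell_type, class, sample, condition,
#'   n_nuclei, median_umi, total_umi).
#' @export
censusFromCounts <- function(counts, metadata, minFraction = 0.01,
                             minCount = 1) {
  counts <- methods::as(counts, "CsparseMatrix")
  if (nrow(metadata) != ncol(counts)) {
    stop("metadata rows must match the number of cells")
  }
  umi <- Matrix::colSums(counts)
  typeRows <- list()
  sampleRows <- list()
  for (ty in unique(metadata$cell_type)) {
    sel <- which(metadata$cell_type == ty)
    cls <- if (!is.null(metadata$class)) metadata$class[sel[1L]] else NA_character_
    sub <- counts[, sel, drop = FALSE]
    detected <- Matrix::rowSums(sub >= minCount)
    minCells <- max(1L, ceiling(minFraction * length(sel)))
    typeRows[[ty]] <- data.frame(
      cell_type = ty, class = cls, n_nuclei = length(sel),
      n_genes_expressed = sum(detected >= minCells),
      stringsAsFactors = FALSE)
    key <- paste(metadata$sample[sel], metadata$condition[sel])
    for (kk in unique(key)) {
      ss <- sel[key == kk]
      sampleRows[[paste(ty, kk)]] <- data.frame(
        cell_type = ty, class = cls,
        sample = metadata$sample[ss[1L]],
        condition = metadata$condition[ss[1L]],
        n_nuclei = length(ss),
        median_umi = stats::median(umi[ss]),
        total_umi = sum(umi[ss]),
        stringsAsFactors = FALSE)
    }
  }
  perType <- do.call(rbind, typeRows)
  perSample <- do.call(rbind, sampleRows)
  rownames(perType) <- rownames(perSample) <- NULL
  list(perType = perType, perSample = perSample)
}
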