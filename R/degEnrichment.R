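#' Pseudobulk aggregation of single-nucleus counts
#'
#' Sums counts over the nuclei of each cell type within each sample,
#' producing per-type gene-by-sample count matrices suitable for pseudobulk
#' differential testing. Cells whose type is missing/unknown are excluded
#' with a logged count; samples must be nested in conditions.
#'
#' @param counts gene-by-cell sparse matrix ([Matrix::dgCMatrix-class] or
#'   coercible); column names identify cells.
#' @param metadata data.frame with one row per cell, columns `cell_type`,
#'   `sample` and `condition` (rows aligned to `colnames(counts)` or to a
#'   `barcode` column).
#' @return named list (one entry per cell type) of gene-by-sample sparse
#'   matrices; each carries a `condition` attribute mapping samples to
#'   conditions.
#' @export
pseudobulkAggregate <- function(counts, metadata) {
  counts <- methods::as(counts, "CsparseMatrix")
  required <- c("cell_type", "sample", "condition")
  missingCols <- setdiff(required, names(metadata))
  if (length(missingCols)) {
    stop("metadata is missing columns: ", paste(missingCols, collapse = ", "))
  }
  if (nrow(metadata) != ncol(counts)) {
    stop("metadata rows must match the number of cells")
  }
  if (!is.null(metadata$barcode) && !is.null(colnames(counts))) {
    if (!all(metadata$barcode == colnames(counts))) {
      stop("metadata barcodes do not align with count matrix columns")
    }
  }
  condPerSample <- unique(metadata[, c("sample", "condition")])
  if (anyDuplicated(condPerSample$sample)) {
    stop("samples must be nested in conditions")
  }
  known <- !is.na(metadata$cell_type)
  nDropped <- sum(!known)
  if (nDropped > 0L) {
    message("pseudobulkAggregate: excluded ", nDropped,
            " cells with unknown cell type")
  }
  out <- list()
  for (ty in unique(metadata$cell_type[known])) {
    sel <- which(known & metadata$cell_type == ty)
    samples <- factor(metadata$sample[sel])
    ind <- Matrix::sparseMatrix(
      i = seq_along(sel), j = as.integer(samples), x = 1,
      dims = c(length(sel), nlevels(samples)),
      dimnames = list(NULL, levels(samples)))
    agg <- counts[, sel, drop = FALSE] %*% ind
    attr(agg, "condition") <- condPerSample$condition[
      match(levels(samples), condPerSample$sample)]
    out[[ty]] <- agg
  }
  out
}

#' Flag differentially expressed genes by effect size and FDR
#'
#' Applies the DEG definition to a per-gene statistics table: a (gene, cell
#' type) row is a DEG when its absolute log2 fold change and FDR meet the
#' thresholds. Two presets are available: `"deg"` (|log2FC| >= 0.1375, i.e. a
#' 10% change, and FDR <= 0.05; boundary values inclusive) and `"overlap"`
#' (|log2FC| > log2(1.23), i.e. more than a 23% change, and FDR < 0.05), used
#' for the curated gene-set overlaps.
#'
#' @param stats data.frame with columns `gene`, `cell_type`, `log2fc`, `fdr`.
#' @param lfcMin,fdrMax explicit thresholds (override the preset).
#' @param preset `"deg"` or `"overlap"`.
#' @return the input with a logical `is_deg` column appended.
#' @export
filterDegs <- function(stats, lfcMin = NULL, fdrMax = NULL, preset = "deg") {
  required <- c("gene", "cell_type", "log2fc", "fdr")
  missingCols <- setdiff(required, names(stats))
  if (length(missingCols)) {
    stop("DEG table is missing columns: ", paste(missingCols, collapse = ", "))
  }
  preset <- match.arg(preset, c("deg", "overlap"))
  if (preset == "deg") {
    if (is.null(lfcMin)) lfcMin <- 0.1375
    if (is.null(fdrMax)) fdrMax <- 0.05
    stats$is_deg <- abs(stats$log2fc) >= lfcMin & stats$fdr <= fdrMax
  } else {
    if (is.null(lfcMin)) lfcMin <- log2(1.23)
    if (is.null(fdrMax)) fdrMax <- 0.05
    stats$is_deg <- abs(stats$log2fc) > lfcMin & stats$fdr < fdrMax
  }
  stats
}

.classOf <- function(types, classMap) {
  if (is.data.frame(classMap)) {
    classMap <- stats::setNames(classMap$class, classMap$cell_type)
  }
  cls <- classMap[as.character(types)]
  if (anyNA(cls)) {
    stop("no class mapping for cell types: ",
         paste(unique(types[is.na(cls)]), collapse = ", "))
  }
  unname(cls)
}

#' Share of DEGs per cell-type class
#'
#' Proportion of all DEG rows falling in each class (e.g. ExIT, ExCT, IN,
#' non-neuronal). DEGs are counted per (gene, cell type) row, so a gene
#' differentially expressed in two types counts twice, matching per-type DEG
#' tallies. Proportions sum to 1.
#'
#' @param degTable output of [filterDegs()] (rows with `is_deg` used), or any
#'   table of DEG rows with a `cell_type` column.
#' @param classMap named character vector (type -> class) or data.frame with
#'   columns `cell_type`, `class`.
#' @return named numeric vector of class shares.
#' @export
degShareByClass <- function(degTable, classMap) {
  if ("is_deg" %in% names(degTable)) {
    degTable <- degTable[degTable$is_deg, , drop = FALSE]
  }
  if (nrow(degTable) == 0L) stop("no DEGs to tally")
  cls <- .classOf(degTable$cell_type, classMap)
  tab <- table(cls)
  prop <- as.numeric(tab) / sum(tab)
  stats::setNames(prop, names(tab))
}

#' Conditional probability of differential expression per cell type
#'
#' For each cell type, the probability that an expressed gene responded to
#' sleep deprivation: P(DEG | expressed in type) = nDEG(type) /
#' nExpressed(type). Class-level probabilities pool DEG and expressed-gene
#' counts within the class, and each class is compared to the strongest of
#' the other classes (`ratio_to_best_other`). This is the "given the number
#' of genes expressed" normalization of DEG occurrence; it depends only on
#' ratios, so duplicating a type's counts leaves it unchanged.
#'
#' @param census per-type table with columns `cell_type` and
#'   `n_genes_expressed` (a census list from [censusFromCounts()] is also
#'   accepted), optionally `class`.
#' @param degTable output of [filterDegs()] or table of DEG rows.
#' @param classMap optional type-to-class mapping (defaults to the census
#'   `class` column).
#' @return list with `perType` (cell_type, n_degs, n_genes_expressed,
#'   probability) and `perClass` (class, probability, ratio_to_best_other).
#' @export
conditionalDegProbability <- function(census, degTable, classMap = NULL) {
  if (is.list(census) && !is.data.frame(census) && !is.null(census$perType)) {
    census <- census$perType
  }
  if ("is_deg" %in% names(degTable)) {
    degTable <- degTable[degTable$is_deg, , drop = FALSE]
  }
  ok <- census$n_genes_expressed > 0
  if (any(!ok)) {
    warning("skipping cell types with zero expressed genes: ",
            paste(census$cell_type[!ok], collapse = ", "))
    census <- census[ok, , drop = FALSE]
  }
  nDeg <- vapply(census$cell_type,
                 function(ty) sum(degTable$cell_type == ty), numeric(1L))
  perType <- data.frame(
    cell_type = census$cell_type,
    n_degs = nDeg,
    n_genes_expressed = census$n_genes_expressed,
    probability = nDeg / census$n_genes_expressed,
    stringsAsFactors = FALSE)
  perClass <- NULL
  if (!is.null(classMap) || !is.null(census$class)) {
    cls <- if (!is.null(classMap)) .classOf(census$cell_type, classMap)
           else census$class
    agg <- do.call(rbind, lapply(unique(cls), function(cl) {
      sel <- cls == cl
      data.frame(class = cl,
                 n_degs = sum(perType$n_degs[sel]),
                 n_genes_expressed = sum(perType$n_genes_expressed[sel]),
                 stringsAsFactors = FALSE)
    }))
    agg$probability <- agg$n_degs / agg$n_genes_expressed
    agg$ratio_to_best_other <- vapply(seq_len(nrow(agg)), function(i) {
      agg$probability[i] / max(agg$probability[-i])
    }, numeric(1L))
    perClass <- agg
  }
  list(perType = perType, perClass = perClass)
}

#' Curated gene-set enrichment of a DEG set
#'
#' Tests whether a cell type's DEGs are enriched for a curated gene set
#' (e.g. autism risk genes, synaptic shaping components) within a gene
#' universe. Symbols are harmonized case-insensitively (collisions logged);
#' symbols outside the universe are dropped with a message. Reports the 2x2
#' table, fold enrichment (observed / expected overlap), the Yates-corrected
#' chi-square and the hypergeometric upper-tail p-value.
#'
#' @param degs character vector of DEG symbols for one cell type.
#' @param geneSet character vector of curated gene symbols.
#' @param universe character vector of background gene symbols.
#' @return list with `table` (2x2), `overlap`, `expected`, `fold`,
#'   `chiSquare` (a `synphen_test`, `NULL` when a margin is empty) and
#'   `hyperP`.
#' @export
genesetOverlapTest <- function(degs, geneSet, universe) {
  harmonize <- function(x, label) {
    up <- toupper(x)
    if (anyDuplicated(up)) {
      message(label, ": ", sum(duplicated(up)),
              " case-insensitive symbol collisions collapsed")
    }
    unique(up)
  }
  universe <- harmonize(universe, "universe")
  if (length(universe) == 0L) stop("empty gene universe")
  clip <- function(x, label) {
    x <- harmonize(x, label)
    out <- intersect(x, universe)
    if (length(out) < length(x)) {
      message(label, ": dropped ", length(x) - length(out),
              " symbols outside the universe")
    }
    out
  }
  degs <- clip(degs, "degs")
  geneSet <- clip(geneSet, "geneSet")
  N <- length(universe)
  a <- length(intersect(degs, geneSet))
  tab <- matrix(c(a, length(geneSet) - a,
                  length(degs) - a,
                  N - length(degs) - length(geneSet) + a),
                2L, 2L,
                dimnames = list(set = c("in", "out"), deg = c("in", "out")))
  expected <- length(degs) * length(geneSet) / N
  chi <- tryCatch(chiSquareYates(tab), error = function(e) NULL)
  hyperP <- stats::phyper(a - 1, length(geneSet), N - length(geneSet),
                          length(degs), lower.tail = FALSE)
  list(table = tab, overlap = a, expected = expected,
       fold = if (expected > 0) a / expected else NA_real_,
       chiSquare = chi, hyperP = hyperP)
}

#' Exact k-set intersection test
#'
#' Probability of observing at least the given k-way intersection when each
#' set is an independent uniform draw of its size from a universe of size
#' `universeSize`. The distribution of the total intersection size is built
#' by chaining hypergeometric kernels: the intersection of the first j sets,
#' of size s, intersects an independent set of size n as
#' Hypergeometric(N, s, n). For k = 2 this is exactly the hypergeometric
#' upper tail.
#'
#' @param sets list of k >= 2 character vectors, or an integer vector of set
#'   sizes (then `observed` is required).
#' @param universeSize size of the background universe.
#' @param observed observed intersection size (computed from `sets` when they
#'   are character vectors).
#' @return list with `observed`, `expected` (N * prod(n_i/N)) and `p.value`
#'   (P(X >= observed)).
#' @export
multisetIntersectionP <- function(sets, universeSize, observed = NULL) {
  if (is.list(sets)) {
    sizes <- lengths(sets)
    if (is.null(observed)) observed <- length(Reduce(intersect, sets))
  } else {
    sizes <- as.integer(sets)
    if (is.null(observed)) stop("observed intersection size required when only sizes are given")
  }
  k <- length(sizes)
  if (k < 2L) stop("need at least two sets")
  if (any(sizes > universeSize)) stop("a set is larger than the universe")
  N <- universeSize
  # pmf of the running intersection size
  pmf <- stats::dhyper(0:min(sizes[1:2]), sizes[1L], N - sizes[1L], sizes[2L])
  for (j in seq_len(k - 2L) + 2L) {
    n <- sizes[j]
    upper <- min(length(pmf) - 1L, n)
    newPmf <- numeric(upper + 1L)
    for (s in seq_along(pmf) - 1L) {
      if (pmf[s + 1L] <= 0) next
      i <- 0:min(s, n)
      newPmf[i + 1L] <- newPmf[i + 1L] +
        pmf[s + 1L] * stats::dhyper(i, s, N - s, n)
    }
    pmf <- newPmf
  }
  pv <- if (observed <= 0) 1 else {
    if (observed > length(pmf) - 1L) 0 else sum(pmf[(observed + 1L):length(pmf)])
  }
  list(observed = observed,
       expected = N * prod(sizes / N),
       p.value = min(1, pv))
}

#' Matched per-type UMI table for the sleep-condition comparison
#'
#' Extracts, per cell type and sample, the median UMIs per nucleus in a tidy
#' table matched across conditions, consumable by [twoWayMixedAnova()]
#' (samples as subjects, cell type as the within factor, condition between)
#' and, after per-type aggregation, by [wilcoxonMatchedPairs()]. Cell types
#' missing a condition are excluded with a warning.
#'
#' @param census a census list from [censusFromCounts()] or its `perSample`
#'   data.frame (columns `cell_type`, `sample`, `condition`, `median_umi`).
#' @return list with `perSample` (tidy matched table) and `matchedMedians`
#'   (per-type median of sample medians, one column per condition).
#' @export
umiPerNucleusTable <- function(census) {
  if (is.list(census) && !is.data.frame(census) && !is.null(census$perSample)) {
    census <- census$perSample
  }
  if (nrow(census) == 0L) {
    return(list(perSample = census,
                matchedMedians = data.frame(cell_type = character())))
  }
  conds <- sort(unique(census$condition))
  keep <- vapply(split(census$condition, census$cell_type),
                 function(x) all(conds %in% x), logical(1L))
  dropped <- names(keep)[!keep]
  if (length(dropped)) {
    warning("cell types missing a condition excluded: ",
            paste(dropped, collapse = ", "))
  }
  census <- census[census$cell_type %in% names(keep)[keep], , drop = FALSE]
  med <- do.call(rbind, lapply(split(census, census$cell_type), function(sub) {
    row <- data.frame(cell_type = sub$cell_type[1L], stringsAsFactors = FALSE)
    for (cond in conds) {
      row[[cond]] <- stats::median(sub$median_umi[sub$condition == cond])
    }
    row
  }))
  rownames(med) <- NULL
  list(perSample = census, matchedMedians = med)
}

#' Read a curated gene list
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
readGeneSet <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
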