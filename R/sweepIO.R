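#' Read a sweep manifest into CellRecording objects
#'
#' The manifest is a delimited text table with one row per sweep and columns
#' `file` (path to a two-column `time_s`/`current_pA` trace, relative paths
#' resolved against the manifest's directory), `cell_id`, `animal_id`,
#' `condition` (CS/SD/RS), `holding_potential` (mV), `sweep_index`,
#' `stimulus_onset_s`, `sweep_time_s` (experiment clock; stimuli are
#' delivered every 10 s) and `series_resistance_mohm` (may be empty).
#'
#' @param manifestPath path to the manifest file (tab- or comma-delimited).
#' @return a list of [CellRecording-class], one per cell, sweeps grouped by
#'   holding potential and ordered by `sweep_index`.
#' @details All sweeps of one cell at one potential must share the sampling
#'   interval and stimulus onset; a violation is a format error naming the
#'   cell. A missing trace file is an I/O error naming the manifest row.
#' @seealso [writeSweeps()] for the inverse operation.
#' @export
readSweeps <- function(manifestPath) {
  if (!file.exists(manifestPath)) {
    stop("manifest not found: ", manifestPath)
  }
  man <- data.table::fread(manifestPath, sep = "auto", data.table = FALSE)
  required <- c("file", "cell_id", "animal_id", "condition",
                "holding_potential", "sweep_index", "stimulus_onset_s")
  missingCols <- setdiff(required, names(man))
  if (length(missingCols)) {
    stop("manifest is missing columns: ", paste(missingCols, collapse = ", "))
  }
  if (nrow(man) == 0L) return(list())
  if (!"series_resistance_mohm" %in% names(man)) {
    man$series_resistance_mohm <- NA_real_
  }
  key <- paste(man$cell_id, man$holding_potential, man$sweep_index)
  if (anyDuplicated(key)) {
    stop("manifest has duplicated (cell_id, holding_potential, sweep_index) rows")
  }
  base <- dirname(manifestPath)
  sweepObjs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    path <- man$file[i]
    if (!file.exists(path)) path <- file.path(base, man$file[i])
    if (!file.exists(path)) {
      stop(sprintf("manifest row %d: sweep file not found: %s", i, man$file[i]))
    }
    tr <- data.table::fread(path, sep = "auto", data.table = FALSE)
    if (ncol(tr) < 2L) {
      stop(sprintf("manifest row %d: expected two columns (time_s, current_pA) in %s",
                   i, man$file[i]))
    }
    tt <- tr[[1L]]
    dt <- diff(tt)
    if (length(dt) && (max(dt) - min(dt)) > 1e-9 * max(dt)) {
      stop(sprintf("manifest row %d: non-uniform sampling in %s", i, man$file[i]))
    }
    sweepObjs[[i]] <- Sweep(
      cellId = man$cell_id[i],
      sweepIndex = man$sweep_index[i],
      holdingPotential = man$holding_potential[i],
      samplingInterval = if (length(dt)) stats::median(dt) else 1,
      stimulusOnset = man$stimulus_onset_s[i],
      current = tr[[2L]],
      seriesResistance = suppressWarnings(as.numeric(man$series_resistance_mohm[i]))
    )
  }
  out <- list()
  for (cid in unique(man$cell_id)) {
    sel <- man$cell_id == cid
    m90 <- which(sel & man$holding_potential == -90)
    p50 <- which(sel & man$holding_potential == 50)
    m90 <- m90[order(man$sweep_index[m90])]
    p50 <- p50[order(man$sweep_index[p50])]
    for (idx in list(m90, p50)) {
      if (length(idx) > 1L) {
        si <- vapply(sweepObjs[idx], slot, numeric(1L), "samplingInterval")
        if (diff(range(si)) > 1e-12 * max(si)) {
          stop("mixed sampling intervals within cell ", cid)
        }
      }
    }
    rec <- CellRecording(
      cellId = cid,
      condition = man$condition[sel][1L],
      sweepsMinus90 = sweepObjs[m90],
      sweepsPlus50 = sweepObjs[p50],
      animalId = as.character(man$animal_id[sel][1L])
    )
    out[[cid]] <- rec
  }
  out
}

#' Write CellRecording objects to sweep files plus a manifest
#'
#' Writes one two-column trace file per sweep (`time_s`, `current_pA`) and a
#' manifest readable by [readSweeps()]. The manifest's `sweep_time_s` column
#' records the experiment clock assuming one stimulus every
#' `stimulusCadence` seconds.
#'
#' @param recordings list of [CellRecording-class].
#' @param dir output directory (created if needed).
#' @param stimulusCadence inter-stimulus interval in seconds (default 10).
#' @return invisibly, the manifest path (`dir/manifest.tsv`).
#' @export
writeSweeps <- function(recordings, dir, stimulusCadence = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (rec in recordings) {
    for (grp in list(rec@sweepsMinus90, rec@sweepsPlus50)) {
      for (sw in grp) {
        fname <- sprintf("%s_vh%+d_%04d.tsv", sw@cellId,
                         as.integer(sw@holdingPotential), sw@sweepIndex)
        tt <- (seq_along(sw@current) - 1L) * sw@samplingInterval
        data.table::fwrite(
          data.frame(time_s = tt, current_pA = sw@current),
          file.path(dir, fname), sep = "\t")
        rows[[length(rows) + 1L]] <- data.frame(
          file = fname,
          cell_id = rec@cellId,
          animal_id = rec@animalId,
          condition = rec@condition,
          holding_potential = sw@holdingPotential,
          sweep_index = sw@sweepIndex,
          stimulus_onset_s = sw@stimulusOnset,
          sweep_time_s = sw@sweepIndex * stimulusCadence,
          series_resistance_mohm = sw@seriesResistance,
          stringsAsFactors = FALSE)
      }
    }
  }
  man <- if (length(rows)) do.call(rbind, rows) else data.frame(
    file = character(), cell_id = character(), animal_id = character(),
    condition = character(), holding_potential = numeric(),
    sweep_index = integer(), stimulus_onset_s = numeric(),
    sweep_time_s = numeric(), series_resistance_mohm = numeric())
  manifestPath <- file.path(dir, "manifest.tsv")
  data.table::fwrite(man, manifestPath, sep = "\t")
  invisible(manifestPath)
}

#' Write and read per-cell feature tables
#'
#' Feature tables (EPSC features, failure-rate results, silent-synapse
#' estimates) are delimited text with a fixed header and full double
#' precision, so that `readFeatureTable(writeFeatureTable(x))` round-trips
#' losslessly.
#'
#' @param features a data.frame of homogeneous records.
#' @param path output file path.
#' @return `path`, invisibly (`writeFeatureTable`); the data.frame
#'   (`readFeatureTable`).
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is.data.frame(features))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(features), collapse = "\t"), con)
  if (nrow(features)) {
    cols <- lapply(features, function(col) {
      if (is.double(col)) sprintf("%.17g", col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  data.table::fread(path, sep = "\t", data.table = FALSE, na.strings = c("NA", ""))
}
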