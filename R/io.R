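## File I/O: tidy trace CSVs, per-window work CSVs, multi-model PDB
## trajectories, JSON reports.

#' Validate a tidy trace table
#'
#' Checks the tidy long format used for all fluorescence/luminescence
#' series (`series_id`, `roi_id`, `time_s`, `value`): required columns
#' present, numeric time and value columns, and strictly increasing
#' times within each (series, ROI).  Violations are reported with the
#' offending column or rows.
#'
#' @param df A `data.frame`.
#' @return The validated `data.frame`, invisibly unchanged.
#' @export
validateTraceTable <- function(df) {
  need <- c("series_id", "roi_id", "time_s", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  for (col in c("time_s", "value")) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col))
    if (anyNA(df[[col]]))
      stop(sprintf("column '%s' contains NA at row(s) %s", col,
                   paste(utils::head(which(is.na(df[[col]])), 5),
                         collapse = ", ")))
  }
  key <- paste(df$series_id, df$roi_id, sep = "\r")
  for (k in unique(key)) {
    tt <- df$time_s[key == k]
    if (any(diff(tt) <= 0)) {
      bad <- which(key == k)[which(diff(tt) <= 0)[1] + 1L]
      stop(sprintf(
        "non-monotone time_s for series '%s', roi '%s' (row %d)",
        df$series_id[bad], df$roi_id[bad], bad))
    }
  }
  invisible(df)
}

#' Read a tidy trace CSV
#'
#' @param path CSV with columns `series_id`, `roi_id`, `time_s`, `value`.
#' @param stimulusTime,ionomycinTime Landmarks (seconds) attached to each
#'   trace.
#' @return A [TraceEnsemble] (conditions taken from `series_id`).
#' @export
readTraceCsv <- function(path, stimulusTime = NA_real_,
                         ionomycinTime = NA_real_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateTraceTable(df)
  key <- paste(df$series_id, df$roi_id, sep = "\r")
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  traces <- lapply(idx, function(i) {
    FluorescenceTrace(df$time_s[i], df$value[i],
                      roiId = df$roi_id[i[1]],
                      stimulusTime = stimulusTime,
                      ionomycinTime = ionomycinTime)
  })
  meta <- data.frame(
    roi_id = vapply(idx, function(i) df$roi_id[i[1]], character(1)),
    condition = vapply(idx, function(i) df$series_id[i[1]], character(1)),
    conc_molar = NA_real_, stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  TraceEnsemble(unname(traces), meta)
}

#' Write a [TraceEnsemble] as a tidy CSV
#'
#' @param ensemble A [TraceEnsemble].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeTraceCsv <- function(ensemble, path) {
  stopifnot(is(ensemble, "TraceEnsemble"))
  rows <- lapply(seq_along(ensemble@traces), function(i) {
    tr <- ensemble@traces[[i]]
    data.frame(series_id = ensemble@meta$condition[i],
               roi_id = tr@roiId, time_s = tr@times, value = tr@values,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read per-window work samples from a tidy CSV
#'
#' Expected columns: `window` (0-based index), `direction` (`"forward"`
#' or `"reverse"`), `work_kcal_mol`, `temperature_k`.
#'
#' @param path CSV path.
#' @return A [WindowWorkSamples].
#' @export
readWorkCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window", "direction", "work_kcal_mol", "temperature_k")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (!all(df$direction %in% c("forward", "reverse")))
    stop("direction must be 'forward' or 'reverse'")
  temps <- unique(df$temperature_k)
  if (length(temps) != 1L)
    stop("all samples must share one temperature_k")
  wins <- sort(unique(df$window))
  fwd <- lapply(wins, function(w)
    df$work_kcal_mol[df$window == w & df$direction == "forward"])
  rev <- lapply(wins, function(w)
    df$work_kcal_mol[df$window == w & df$direction == "reverse"])
  WindowWorkSamples(fwd, rev, temperature = temps)
}

#' Write [WindowWorkSamples] to a tidy CSV
#'
#' @param w A [WindowWorkSamples].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeWorkCsv <- function(w, path) {
  stopifnot(is(w, "WindowWorkSamples"))
  rows <- lapply(seq_along(w@forward), function(i) {
    rbind(
      data.frame(window = i - 1L, direction = "forward",
                 work_kcal_mol = w@forward[[i]],
                 temperature_k = w@temperature),
      data.frame(window = i - 1L, direction = "reverse",
                 work_kcal_mol = w@reverse[[i]],
                 temperature_k = w@temperature))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#'
#' Parses MODEL/ENDMDL blocks (via \pkg{bio3d}) into a
#' [TrajectoryFrames]; hydrogens are identified from the element symbol
#' (falling back to the atom-name convention when the element column is
#' blank).
#'
#' @param path PDB file path.
#' @return A [TrajectoryFrames].
#' @export
readTrajectoryPdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nAtoms <- ncol(xyz) / 3
  nF <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nF, nAtoms, 3))
  for (f in seq_len(nF)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  ele <- pdb$atom$elesy
  isH <- !is.na(ele) & ele == "H"
  blank <- is.na(ele) | ele == ""
  isH[blank] <- grepl("^[0-9]*H", trimws(pdb$atom$elety[blank]))
  atoms <- data.frame(chain = pdb$atom$chain, resno = pdb$atom$resno,
                      resname = pdb$atom$resid,
                      atomName = trimws(pdb$atom$elety),
                      isHydrogen = isH, stringsAsFactors = FALSE)
  TrajectoryFrames(coords, atoms)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj A [TrajectoryFrames].
#' @param path Output PDB path.
#' @return The path, invisibly.
#' @export
writeTrajectoryPdb <- function(traj, path) {
  stopifnot(is(traj, "TrajectoryFrames"))
  d <- dim(traj@coords)
  xyz <- matrix(NA_real_, nrow = d[1], ncol = d[2] * 3)
  for (f in seq_len(d[1])) {
    xyz[f, ] <- as.numeric(t(traj@coords[f, , ]))
  }
  at <- traj@atoms
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", d[2]),
                   resno = at$resno, resid = at$resname,
                   eleno = seq_len(d[2]), elety = at$atomName,
                   chain = at$chain)
  invisible(path)
}
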