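## In-silico binding arm: trajectory contact and RMSD statistics,
## free-energy estimators (exponential averaging and Bennett acceptance
## ratio), thermodynamic-cycle ddG, per-protomer aggregation and the
## affinity fold change.

#' Select atoms of a trajectory by chain/residue
#'
#' Returns the (1-based) atom indices matching the given chain and/or
#' residue numbers.  Hydrogens are excluded by default, matching the
#' heavy-atom convention of the contact statistics.
#'
#' @param traj A [TrajectoryFrames].
#' @param chain Character chain identifier(s), or NULL for any.
#' @param resno Integer residue number(s), or NULL for any.
#' @param heavyOnly Drop hydrogens (default TRUE).
#' @return Integer vector of atom indices.
#' @export
selectAtoms <- function(traj, chain = NULL, resno = NULL,
                        heavyOnly = TRUE) {
  stopifnot(is(traj, "TrajectoryFrames"))
  at <- traj@atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (heavyOnly) keep <- keep & !at$isHydrogen
  which(keep)
}

## Per-frame minimum inter-selection distance (vectorised all-pairs).
minInterDist <- function(a, b) {
  ## a: nA x 3, b: nB x 3
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Residue-contact fraction of a trajectory
#'
#' For each frame, the minimum heavy-atom distance between two atom
#' selections is computed; the frame counts as a contact iff that
#' distance is strictly below the cutoff (ties at exactly the cutoff are
#' non-contacts).  The contact fraction is the mean of the per-frame
#' indicator — the "percentage of simulation time in close contact"
#' statistic used to compare wild-type and mutant antibody engagement.
#'
#' @param traj A [TrajectoryFrames].
#' @param selA,selB Integer atom-index vectors (e.g. from
#'   [selectAtoms()]); must be non-empty and disjoint.  Hydrogens in the
#'   selections are ignored.
#' @param cutoff Contact cutoff in Angstrom (default 3.0).
#' @return A [ContactResult].
#' @export
contactFraction <- function(traj, selA, selB, cutoff = 3.0) {
  stopifnot(is(traj, "TrajectoryFrames"))
  hyd <- traj@atoms$isHydrogen
  selA <- setdiff(as.integer(selA), which(hyd))
  selB <- setdiff(as.integer(selB), which(hyd))
  if (!length(selA) || !length(selB))
    stop("both selections must contain at least one heavy atom")
  if (length(intersect(selA, selB)))
    stop("selections must be disjoint")
  nf <- dim(traj@coords)[1]
  dmin <- vapply(seq_len(nf), function(f) {
    minInterDist(matrix(traj@coords[f, selA, ], ncol = 3),
                 matrix(traj@coords[f, selB, ], ncol = 3))
  }, numeric(1))
  perFrame <- dmin < cutoff
  new("ContactResult",
      selectionA = sprintf("%d atoms", length(selA)),
      selectionB = sprintf("%d atoms", length(selB)),
      cutoff = cutoff, fraction = mean(perFrame), perFrame = perFrame,
      minDistances = dmin)
}

## Kabsch optimal superposition: rotate/translate `mobile` onto `fixed`.
## Both are n x 3 matrices.  Returns the transformed mobile coordinates.
kabschFit <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  x <- sweep(mobile, 2, cm); y <- sweep(fixed, 2, cf)
  s <- svd(crossprod(x, y))           # 3x3
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(x %*% t(rot), 2, cf, "+")
}

#' RMSD of each frame from a reference frame
#'
#' Root-mean-square deviation of every frame from the reference frame,
#' optionally after optimal rigid-body (Kabsch) superposition.  With
#' alignment enabled, the series is invariant under any rigid transform
#' of the whole trajectory; frame `reference` maps to 0 by construction.
#'
#' @param traj A [TrajectoryFrames].
#' @param reference Reference frame index (default 1, the initial
#'   structure).
#' @param align Superpose each frame onto the reference first
#'   (default TRUE).
#' @param atomIndices Atoms to use (default: all atoms).
#' @return Numeric vector of per-frame RMSD values, Angstrom.
#' @export
rmsdSeries <- function(traj, reference = 1L, align = TRUE,
                       atomIndices = NULL) {
  stopifnot(is(traj, "TrajectoryFrames"))
  nf <- dim(traj@coords)[1]
  if (nf < 2L) stop("need at least 2 frames")
  if (is.null(atomIndices)) atomIndices <- seq_len(dim(traj@coords)[2])
  ref <- matrix(traj@coords[reference, atomIndices, ], ncol = 3)
  if (align) {
    if (nrow(ref) < 3L) stop("alignment needs at least 3 atoms")
    cen <- sweep(ref, 2, colMeans(ref))
    if (qr(cen)$rank < 2L)
      stop("alignment needs at least 3 non-collinear atoms")
  }
  vapply(seq_len(nf), function(f) {
    m <- matrix(traj@coords[f, atomIndices, ], ncol = 3)
    if (align) m <- kabschFit(ref, m)
    sqrt(mean(rowSums((m - ref)^2)))
  }, numeric(1))
}

#' Exponential-averaging (Zwanzig) free-energy estimator
#'
#' One-sided free-energy estimate from work samples,
#' `dG = -RT log mean(exp(-W/RT))`, computed with log-sum-exp
#' stabilisation.  Kept as a cross-check for the two-sided Bennett
#' estimator.
#'
#' @param work Numeric work samples, kcal/mol.
#' @param temperature Kelvin.
#' @return Numeric scalar dG, kcal/mol.
#' @export
expEstimator <- function(work, temperature = 310) {
  if (!length(work)) stop("no work samples")
  rt <- RGAS * temperature
  -rt * (logSumExp(-work / rt) - log(length(work)))
}

## Bennett self-consistency residual g(dg); monotone increasing in dg.
barResidual <- function(dg, wf, wr, beta, M) {
  f <- function(x) stats::plogis(-x)   # 1 / (1 + exp(x))
  sum(f(beta * (wf - dg) + M)) - sum(f(beta * (wr + dg) - M))
}

barRoot <- function(wf, wr, beta, tol = 1e-12) {
  M <- log(length(wf) / length(wr))
  dg0 <- (mean(wf) - mean(wr)) / 2
  width <- max(1, stats::sd(c(wf, -wr)))
  lo <- dg0 - width; hi <- dg0 + width
  for (i in 1:80) {
    if (barResidual(lo, wf, wr, beta, M) < 0) break
    lo <- lo - width; width <- width * 2
  }
  width <- max(1, stats::sd(c(wf, -wr)))
  for (i in 1:80) {
    if (barResidual(hi, wf, wr, beta, M) > 0) break
    hi <- hi + width; width <- width * 2
  }
  rl <- barResidual(lo, wf, wr, beta, M)
  rh <- barResidual(hi, wf, wr, beta, M)
  if (!(rl < 0 && rh > 0)) return(NULL)
  stats::uniroot(barResidual, c(lo, hi), wf = wf, wr = wr, beta = beta,
                 M = M, tol = tol)$root
}

#' Bennett acceptance ratio (BAR) estimator for one window
#'
#' Solves the Bennett self-consistent equation
#' `sum_F f(beta (W_F - dG) + M) = sum_R f(beta (W_R + dG) - M)` with
#' `f` the logistic function and `M = log(n_F/n_R)` by bracketed
#' root-finding (tolerance 1e-9 kcal/mol), combining forward and reverse
#' work samples into the minimum-variance two-sided free-energy
#' estimate.  Uncertainty is a seeded bootstrap standard error.
#'
#' Non-overlapping work distributions leave the equation without a root
#' in any bracket; the estimate is then flagged divergent (`dg = NA`)
#' with a warning rather than an error.
#'
#' @param forwardWork,reverseWork Numeric work samples, kcal/mol.
#' @param temperature Kelvin.
#' @param nBoot Bootstrap resamples for the standard error (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return List with `dg`, `se` (kcal/mol) and `flagged`.
#' @export
barEstimator <- function(forwardWork, reverseWork, temperature = 310,
                         nBoot = 200L, seed = 1L) {
  stopifnot(length(forwardWork) >= 1L, length(reverseWork) >= 1L)
  beta <- 1 / (RGAS * temperature)
  dg <- barRoot(forwardWork, reverseWork, beta)
  if (is.null(dg)) {
    warning("BAR diverged: work distributions do not overlap")
    return(list(dg = NA_real_, se = NA_real_, flagged = TRUE))
  }
  set.seed(subSeed(seed, "bar-bootstrap"))
  boot <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    r <- barRoot(sample(forwardWork, replace = TRUE),
                 sample(reverseWork, replace = TRUE), beta)
    if (!is.null(r)) boot[b] <- r
  }
  list(dg = dg, se = stats::sd(boot, na.rm = TRUE), flagged = FALSE)
}

#' Estimate a full free-energy leg from per-window work samples
#'
#' Applies [barEstimator()] (or [expEstimator()] on the forward work) to
#' every lambda window and combines the windows with [combineLeg()].
#'
#' @param w A [WindowWorkSamples].
#' @param label Leg label, e.g. `"complex"` or `"free"`.
#' @param estimator `"bar"` (default) or `"exp"`.
#' @param nBoot,seed Bootstrap settings passed per window.
#' @return A [FreeEnergyLeg].
#' @export
estimateLeg <- function(w, label = "leg", estimator = c("bar", "exp"),
                        nBoot = 200L, seed = 1L) {
  stopifnot(is(w, "WindowWorkSamples"))
  estimator <- match.arg(estimator)
  nw <- length(w@forward)
  per <- lapply(seq_len(nw), function(i) {
    if (estimator == "bar") {
      r <- barEstimator(w@forward[[i]], w@reverse[[i]],
                        temperature = w@temperature, nBoot = nBoot,
                        seed = subSeed(seed, paste0(label, "-win", i)))
      if (r$flagged)
        stop(sprintf("window %d: BAR diverged (no distribution overlap)", i))
      r
    } else {
      list(dg = expEstimator(w@forward[[i]], w@temperature), se = NA_real_)
    }
  })
  combineLeg(per, label = label)
}

#' Combine per-window estimates into a leg total
#'
#' `dG = sum(dg_i)`; the windows are treated as independent, so
#' `se = sqrt(sum(se_i^2))`.
#'
#' @param perWindow List of lists with elements `dg` and `se`, or a
#'   `data.frame` with columns `dg`, `se`.
#' @param label Leg label.
#' @return A [FreeEnergyLeg].
#' @export
combineLeg <- function(perWindow, label = "leg") {
  if (is.data.frame(perWindow)) {
    df <- perWindow
  } else {
    if (!length(perWindow)) stop("empty window list")
    df <- data.frame(
      dg = vapply(perWindow, function(x) x$dg, numeric(1)),
      se = vapply(perWindow, function(x)
        if (is.null(x$se) || is.na(x$se)) 0 else x$se, numeric(1)))
  }
  if (!nrow(df)) stop("empty window list")
  df$window <- seq_len(nrow(df)) - 1L
  new("FreeEnergyLeg", label = label, dg = sum(df$dg),
      se = sqrt(sum(df$se^2)), perWindow = df[c("window", "dg", "se")])
}

#' Thermodynamic-cycle binding free-energy difference
#'
#' `ddG = dG_complex - dG_free` for the same alchemical mutation run in
#' the antibody-bound complex and in the free hemichannel.  Positive ddG
#' means the mutation weakens antibody binding.
#'
#' @param complexLeg,freeLeg [FreeEnergyLeg] objects for the two legs.
#' @return List with `ddg` and `se` (quadrature), kcal/mol.
#' @examples
#' cl <- combineLeg(data.frame(dg = 2.00, se = 0.1), "complex")
#' fr <- combineLeg(data.frame(dg = 0.68, se = 0.1), "free")
#' thermoCycle(cl, fr)$ddg  # 1.32
#' @export
thermoCycle <- function(complexLeg, freeLeg) {
  stopifnot(is(complexLeg, "FreeEnergyLeg"), is(freeLeg, "FreeEnergyLeg"))
  list(ddg = complexLeg@dg - freeLeg@dg,
       se = sqrt(complexLeg@se^2 + freeLeg@se^2))
}

#' Affinity fold change implied by a ddG
#'
#' `exp(ddG / RT)` with `R = 1.9872e-3 kcal/(mol K)`: the multiplicative
#' change in binding constant.  A positive ddG (weakened binding) gives
#' a fold > 1.
#'
#' @param ddg kcal/mol.
#' @param temperature Kelvin (default 310, the simulation thermostat).
#' @return Numeric scalar fold change.
#' @examples
#' foldChange(1.32, 310)  # ~8.52, i.e. an order-of-magnitude loss
#' @export
foldChange <- function(ddg, temperature = 310) {
  stopifnot(temperature > 0)
  exp(ddg / (RGAS * temperature))
}

#' Aggregate per-protomer ddG contributions
#'
#' The six protomers of the hexameric connexon carry one mutated residue
#' each; because the mutated sites do not interact, the total binding
#' free-energy difference is the sum of the six per-site contributions.
#' The affinity fold change `exp(total/RT)` and its nearest power of ten
#' are reported alongside.
#'
#' @param ddg Numeric length 6, per-protomer ddG values, kcal/mol.
#' @param se Numeric length 6, standard errors (default 0).
#' @param temperature Kelvin (default 310).
#' @return A [ProtomerContributions].
#' @export
aggregateProtomers <- function(ddg, se = rep(0, 6), temperature = 310) {
  if (length(ddg) != 6L)
    stop("exactly six per-protomer contributions are required")
  total <- sum(ddg)
  fold <- foldChange(total, temperature)
  new("ProtomerContributions", ddgPerProtomer = as.numeric(ddg),
      se = as.numeric(se), totalDdg = total, foldChange = fold,
      foldPowerOfTen = 10^round(log10(fold)), temperature = temperature)
}
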