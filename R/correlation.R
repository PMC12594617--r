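# Correlation analyses: tie-corrected Spearman tests, Benjamini-Hochberg
# FDR per analysis family, redundancy pruning of ROIs, hypothesised vs
# exploratory partition, and correlation-test power (closed form and
# simulation).

#' Spearman rank correlation test
#'
#' Rank correlation on average (tie-corrected) ranks. For `n > 8` (the
#' production regime; the cohort here is in the sixties) the p-value uses
#' the t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. For tiny samples (`n <= 8`, where the approximation
#' is visibly off) the exact permutation distribution of rho is enumerated
#' in full, which also handles ties; `exact` overrides the switch.
#'
#' @param x,y numeric vectors of equal length >= 4, finite, non-constant.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact logical or NULL (default: exact iff `n <= 8`).
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y, alternative = c("two.sided", "greater",
                                                "less"), exact = NULL) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (length(y) != n) stopf("x and y must have equal length")
  if (n < 4) stopf("need at least 4 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("non-finite values")
  if (var(x) == 0 || var(y) == 0)
    stopf("rho undefined for a constant vector")
  exact <- exact %||% (n <= 8)
  rho <- cor(x, y, method = "spearman")
  if (exact) {
    rx <- rank(x); ry <- rank(y)
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ry_mat <- matrix(ry[perms], nrow = nrow(perms))
    ryc <- ry_mat - mean(ry)
    num <- as.vector(ryc %*% rxc)
    den <- sqrt(sum(rxc^2) * rowSums(ryc^2))
    rhos <- num / den
    eps <- 1e-10
    p <- switch(alternative,
                two.sided = mean(abs(rhos) >= abs(rho) - eps),
                greater = mean(rhos >= rho - eps),
                less = mean(rhos <= rho + eps))
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  tstat <- if (abs(rho) >= 1) sign(rho) * Inf
           else rho * sqrt((n - 2) / (1 - rho^2))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(tstat), df = n - 2),
              greater = pt(tstat, df = n - 2, lower.tail = FALSE),
              less = pt(tstat, df = n - 2))
  list(rho = rho, p = min(p, 1), n = n, method = "t-approximation")
}

# All permutations of 1:n as an n! x n matrix (n <= 8 in practice).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment within one declared family of tests, in the input
#' order (delegates to [stats::p.adjust()] after range validation).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Statistical power of a correlation test (Fisher z)
#'
#' Closed-form power of the one- or two-tailed test for a population
#' correlation `rho` at level `alpha` with `n` pairs, via the Fisher
#' z-transform: `power = Phi(atanh(rho) * sqrt(n - 3) - z_{1 - alpha/tails})`.
#'
#' @param n sample size (>= 4).
#' @param rho population correlation in (0, 1).
#' @param alpha significance level in (0, 1).
#' @param tails 1 or 2.
#' @return power (scalar in (0, 1)).
#' @export
power_corr <- function(n, rho, alpha = 0.05, tails = 1) {
  assert_number(n, "n", lo = 4, integer = TRUE)
  assert_number(rho, "rho", lo = 1e-12, hi = 1 - 1e-12)
  assert_number(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  if (!tails %in% c(1, 2)) stopf("tails must be 1 or 2")
  pnorm(atanh(rho) * sqrt(n - 3) - qnorm(1 - alpha / tails))
}

#' Simulated power of a correlation test
#'
#' Draws `reps` bivariate-normal samples of size `n` with population
#' correlation `rho`, tests each with the t-approximation at level `alpha`,
#' and reports the rejection fraction. Agrees with [power_corr()] within
#' Monte-Carlo error.
#'
#' @inheritParams power_corr
#' @param reps number of simulated samples (default 20000).
#' @param seed optional integer seed.
#' @return rejection fraction (scalar).
#' @export
simulate_power <- function(n, rho, alpha = 0.05, tails = 1, reps = 20000,
                           seed = NULL) {
  assert_number(n, "n", lo = 4, integer = TRUE)
  assert_number(rho, "rho", lo = -1 + 1e-12, hi = 1 - 1e-12)
  assert_number(reps, "reps", lo = 1, integer = TRUE)
  with_seed(seed, {
    x <- matrix(rnorm(reps * n), reps, n)
    y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(reps * n), reps, n)
    xc <- x - rowMeans(x); yc <- y - rowMeans(y)
    r <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    rej <- if (tails == 1) tstat > qt(1 - alpha, n - 2)
           else abs(tstat) > qt(1 - alpha / 2, n - 2)
    mean(rej)
  })
}

#' Packaged structure centroids (synthetic/approximate)
#'
#' Approximate MNI centre-of-mass coordinates (mm) for the anatomical
#' structures used in the hypothesis map. These ship as an editable
#' plain-text table -- the package embeds no brain atlas -- and exist so
#' that redundancy pruning has a deterministic tie-break; replace them with
#' atlas-derived centroids for real analyses.
#'
#' @param path optional path to an alternative centroid CSV with columns
#'   `structure`, `x`, `y`, `z`.
#' @return data.frame of centroids.
#' @export
structure_centroids <- function(path = NULL) {
  path <- path %||% system.file("extdata",
                                "structure_centroids_synthetic.csv",
                                package = "painweights")
  if (!nzchar(path) || !file.exists(path)) stopf("centroid table not found")
  as.data.frame(data.table::fread(path))
}

roi_activity_matrix <- function(rois) {
  meta_cols <- c("structure", "hemisphere", "x", "y", "z", "window")
  missing <- setdiff(meta_cols, names(rois))
  if (length(missing))
    stopf("ROI table missing columns: %s", paste(missing, collapse = ", "))
  part_cols <- setdiff(names(rois), meta_cols)
  if (length(part_cols) == 0L) stopf("ROI table has no participant columns")
  as.matrix(rois[, part_cols, drop = FALSE])
}

#' Prune redundant ROIs within structure and window
#'
#' ROIs of the same anatomical structure and time window whose activities
#' correlate above `threshold` (Spearman, strict inequality) carry
#' redundant information; within each such pair the ROI farther from the
#' structure's centre of mass is dropped (distance ties drop the
#' later-listed ROI). Pairs are resolved greedily, highest correlation
#' first, until all survivors correlate at or below the threshold.
#'
#' @param rois ROI table: columns `structure`, `hemisphere`, `x`, `y`, `z`,
#'   `window`, then one activity column per participant.
#' @param centroids centroid table (default [structure_centroids()]).
#' @param threshold redundancy threshold (default 0.7).
#' @return the pruned ROI table.
#' @export
prune_redundant <- function(rois, centroids = structure_centroids(),
                            threshold = 0.7) {
  if (nrow(rois) == 0L) stopf("empty ROI table")
  act <- roi_activity_matrix(rois)
  keep <- rep(TRUE, nrow(rois))
  groups <- split(seq_len(nrow(rois)),
                  interaction(rois$structure, rois$window, drop = TRUE))
  for (g in groups) {
    if (length(g) < 2L) next
    st <- rois$structure[g[1]]
    ci <- match(st, centroids$structure)
    if (is.na(ci)) stopf("no centroid for structure '%s'", st)
    cen <- as.numeric(centroids[ci, c("x", "y", "z")])
    dist_to_cen <- sqrt(colSums((t(as.matrix(rois[g, c("x", "y", "z")])) -
                                   cen)^2))
    alive <- rep(TRUE, length(g))
    repeat {
      idx <- which(alive)
      if (length(idx) < 2L) break
      combs <- utils::combn(idx, 2)
      rhos <- apply(combs, 2, function(pr)
        cor(act[g[pr[1]], ], act[g[pr[2]], ], method = "spearman"))
      if (max(rhos) <= threshold) break
      pr <- combs[, which.max(rhos)]
      d1 <- dist_to_cen[pr[1]]; d2 <- dist_to_cen[pr[2]]
      drop_local <- if (d1 > d2) pr[1] else if (d2 > d1) pr[2] else {
        message(sprintf(
          "centroid-distance tie in '%s'/'%s': dropping later-listed ROI",
          st, rois$window[g[1]]))
        pr[2]
      }
      alive[drop_local] <- FALSE
    }
    keep[g[!alive]] <- FALSE
  }
  rois[keep, , drop = FALSE]
}

#' Hypothesis map for the correlation analyses
#'
#' Declares which parameter-target pairs are tested as hypothesised (and
#' so receive FDR correction); everything else is exploratory. Defaults:
#' the somatosensory weight against structures previously associated with
#' somatic processing; the cue weight and the (absolute) cue-uncertainty
#' scale against structures associated with cue processing; and the P2
#' amplitude against the somatosensory weight, the cue-uncertainty scale
#' and the bias mean.
#'
#' @param sensory_structures,cue_structures character vectors of structure
#'   labels.
#' @param roi_map named list: parameter -> structure labels tested as
#'   hypothesised (built from the two sets by default).
#' @param p2_params parameters hypothesised against the P2 amplitude.
#' @param abs_params parameters entered as absolute values (default
#'   `"eta"`, whose sign only encodes the direction of the uncertainty
#'   effect).
#' @return an object of class `hypothesis_map`.
#' @export
hypothesis_map <- function(
    sensory_structures = c("postcentral gyrus", "middle frontal gyrus",
                           "posterior cingulate", "inferior parietal"),
    cue_structures = c("subgenual cingulate", "middle frontal gyrus",
                       "superior frontal gyrus", "inferior frontal gyrus",
                       "inferior temporal gyrus", "orbitofrontal cortex"),
    roi_map = NULL,
    p2_params = c("w_stim", "eta", "mu"),
    abs_params = "eta") {
  roi_map <- roi_map %||% list(w_stim = sensory_structures,
                               w_cue = cue_structures,
                               eta = cue_structures)
  structure(list(roi_map = roi_map, p2_params = p2_params,
                 abs_params = abs_params),
            class = "hypothesis_map")
}

model_parameter_set <- function() c("w_stim", "eta", "w_cue", "mu", "w_bias")

param_values <- function(params_table, p, map) {
  v <- params_table[[p]]
  if (is.null(v)) stopf("parameter column '%s' missing", p)
  if (p %in% map$abs_params) abs(v) else v
}

roi_label <- function(rois, i) {
  sprintf("%s %s (%g, %g, %g)", rois$structure[i], rois$hemisphere[i],
          rois$x[i], rois$y[i], rois$z[i])
}

correlate_rows <- function(params_table, map, rois, p2, covariates,
                           select_hypothesised, alternative) {
  res <- list()
  add <- function(parameter, target, window, family, hypothesised, y) {
    x <- param_values(params_table, parameter, map)
    st <- spearman_test(x, y, alternative)
    res[[length(res) + 1L]] <<- data.frame(
      parameter = parameter, target = target, window = window,
      rho = st$rho, p_raw = st$p, p_adjusted = NA_real_, family = family,
      flag = if (hypothesised) "hypothesised" else "exploratory",
      stringsAsFactors = FALSE)
  }
  act <- if (!is.null(rois) && nrow(rois)) roi_activity_matrix(rois)
  for (p in model_parameter_set()) {
    if (!is.null(rois) && nrow(rois)) {
      hyp_structs <- map$roi_map[[p]] %||% character(0)
      for (i in seq_len(nrow(rois))) {
        hyp <- rois$structure[i] %in% hyp_structs
        if (hyp != select_hypothesised) next
        add(p, roi_label(rois, i), rois$window[i],
            paste0("roi_", rois$window[i]), hyp, act[i, ])
      }
    }
    if (!is.null(p2)) {
      hyp <- p %in% map$p2_params
      if (hyp == select_hypothesised)
        add(p, "P2 amplitude", "post_stimulation", "p2", hyp, p2$amplitude)
    }
    if (!is.null(covariates) && !select_hypothesised) {
      cov_cols <- setdiff(names(covariates), "participant_id")
      for (cc in cov_cols)
        add(p, cc, "none", "covariates", FALSE, covariates[[cc]])
    }
  }
  if (length(res) == 0L)
    return(data.frame(parameter = character(0), target = character(0),
                      window = character(0), rho = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      family = character(0), flag = character(0)))
  do.call(rbind, res)
}

#' Hypothesised correlation analysis
#'
#' Spearman-correlates each model parameter with the targets declared for
#' it in the [hypothesis_map()]: mapped ROI activities (one BH-FDR family
#' per time window) and, for the P2 trio, the P2 amplitude (its own
#' family). The cue-uncertainty scale enters as its absolute value.
#' Redundancy pruning ([prune_redundant()]) is assumed to have been applied
#' to the ROI table.
#'
#' @param params_table data.frame with `participant_id` and columns
#'   `w_stim`, `eta`, `w_cue`, `mu`, `w_bias` (e.g. from [fit_cohort()],
#'   or ground truth).
#' @param rois pruned ROI table (see [prune_redundant()]); NULL to skip.
#' @param p2 data.frame with `participant_id` and `amplitude`; NULL to
#'   skip.
#' @param map a [hypothesis_map()].
#' @param alternative test sidedness (default two-sided; the power claim is
#'   one-tailed, so `"greater"` is available).
#' @return data.frame: `parameter`, `target`, `window`, `rho`, `p_raw`,
#'   `p_adjusted` (BH within family), `family`, `flag`.
#' @export
run_hypothesised <- function(params_table, rois = NULL, p2 = NULL,
                             map = hypothesis_map(),
                             alternative = "two.sided") {
  check_alignment(params_table, rois, p2, NULL)
  out <- correlate_rows(params_table, map, rois, p2, NULL,
                        select_hypothesised = TRUE,
                        alternative = alternative)
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_adjusted[sel] <- bh_fdr(out$p_raw[sel])
  }
  out
}

#' Exploratory correlation analysis
#'
#' Every parameter-target pair *not* in the hypothesis map: unmapped ROI
#' tests, the remaining parameters against the P2 amplitude, and all
#' parameters against questionnaire covariates and the mean rating.
#' Uncorrected by design -- these are tentative, hypothesis-generating
#' tests -- so `p_adjusted` stays `NA`.
#'
#' @inheritParams run_hypothesised
#' @param covariates data.frame with `participant_id` plus numeric columns
#'   (questionnaire scores, mean rating); all tested exploratorily.
#' @return data.frame as in [run_hypothesised()] with `p_adjusted = NA`.
#' @export
run_exploratory <- function(params_table, rois = NULL, p2 = NULL,
                            covariates = NULL, map = hypothesis_map(),
                            alternative = "two.sided") {
  check_alignment(params_table, rois, p2, covariates)
  correlate_rows(params_table, map, rois, p2, covariates,
                 select_hypothesised = FALSE, alternative = alternative)
}

check_alignment <- function(params_table, rois, p2, covariates) {
  ids <- params_table$participant_id
  if (is.null(ids)) stopf("params_table needs a participant_id column")
  if (!is.null(rois) && nrow(rois)) {
    part_cols <- setdiff(names(rois),
                         c("structure", "hemisphere", "x", "y", "z",
                           "window"))
    if (!identical(part_cols, as.character(ids)))
      stopf("ROI participant columns do not align with params_table")
  }
  if (!is.null(p2) && !identical(as.character(p2$participant_id),
                                 as.character(ids)))
    stopf("p2 table does not align with params_table")
  if (!is.null(covariates) &&
      !identical(as.character(covariates$participant_id),
                 as.character(ids)))
    stopf("covariates do not align with params_table")
  invisible(TRUE)
}

#' Read / write ROI tables and correlation results
#'
#' Plain CSV; the ROI table has columns `structure`, `hemisphere`, `x`,
#' `y`, `z`, `window` followed by one activity column per participant.
#'
#' @param rois,results data.frames.
#' @param path file path.
#' @return read functions return the data.frame.
#' @export
write_rois <- function(rois, path) {
  data.table::fwrite(rois, path)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  rois <- as.data.frame(data.table::fread(path))
  roi_activity_matrix(rois)  # validates shape
  rois
}

#' @rdname write_rois
#' @export
write_correlation_results <- function(results, path) {
  data.table::fwrite(results, path)
  invisible(path)
}
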