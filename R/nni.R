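#' Nitrogen nutrition index
#'
#' `NNI = Nt / Nc`: the ratio of the measured N concentration to the critical
#' concentration at the observation's biomass. Values below 1 indicate
#' deficiency, about 1 optimal nutrition, above 1 luxury uptake.
#'
#' @param Nt measured N concentration (% dry mass), > 0; vectorized.
#' @param Nc critical N concentration (% dry mass), > 0; vectorized.
#' @return NNI, dimensionless.
#' @export
compute_nni <- function(Nt, Nc) {
  if (any(!is.finite(Nc)) || any(Nc <= 0))
    stop("Nc must be positive", call. = FALSE)
  if (any(!is.finite(Nt)) || any(Nt <= 0))
    stop("Nt must be positive", call. = FALSE)
  Nt / Nc
}

#' Per-observation NNI series for one basis
#'
#' Applies a dilution curve to every observation of the requested basis:
#' `Nc` is evaluated at the observation's own W, and the NNI is computed per
#' observation point (never averaged over treatments).
#'
#' @param ds an `nc_experiment` (already filtered).
#' @param curve an [nc_curve()] whose `basis` matches `basis`.
#' @param basis organ basis.
#' @return data.frame with columns `experiment_id, date_index, treatment_id,
#'   replicate, basis, W, Nt, Nc, NNI`.
#' @export
nni_series <- function(ds, curve, basis) {
  stopifnot(inherits(curve, "nc_curve"))
  basis <- match.arg(basis, BASES)
  if (curve$basis != basis)
    stop("curve basis '", curve$basis, "' does not match requested basis '",
         basis, "'", call. = FALSE)
  pairs <- basis_pairs(ds, basis)
  if (nrow(pairs) == 0) stop("no observations for basis", call. = FALSE)
  nc <- nc_value(curve, pairs$W)
  data.frame(
    experiment_id = pairs$experiment_id, date_index = pairs$date_index,
    treatment_id = pairs$treatment_id, replicate = pairs$replicate,
    basis = basis, W = pairs$W, Nt = pairs$N, Nc = nc,
    NNI = compute_nni(pairs$N, nc), stringsAsFactors = FALSE
  )
}

#' Biomass-weighted mean NNI of leaf and stem
#'
#' Combines the two organ indices with their biomass shares:
#' `(NNI_leaf * W_leaf + NNI_stem * W_stem) / (W_leaf + W_stem)`.
#'
#' @param nni_leaf,nni_stem organ NNI values; vectorized.
#' @param W_leaf,W_stem organ biomasses (t/ha), >= 0, not both zero.
#' @return weighted mean NNI.
#' @export
weighted_mean_nni <- function(nni_leaf, nni_stem, W_leaf, W_stem) {
  if (any(W_leaf < 0) || any(W_stem < 0) || any(W_leaf + W_stem <= 0))
    stop("organ biomass weights must be non-negative with a positive sum",
         call. = FALSE)
  (nni_leaf * W_leaf + nni_stem * W_stem) / (W_leaf + W_stem)
}

#' Agreement between two paired NNI series
#'
#' `RMSE = sqrt(mean((P - O)^2))` and `n-RMSE = RMSE / mean(O) x 100%`,
#' normalized by the mean of the *reference* series O (so n-RMSE is not
#' symmetric in its arguments, while RMSE is).
#'
#' @param O reference NNI vector (e.g. derived from the specific curve, or
#'   the shoot basis).
#' @param P comparison NNI vector, same length, paired by observation.
#' @return object of class `nc_agreement`: list with `rmse`, `nrmse_pct`,
#'   `n`.
#' @export
agreement <- function(O, P) {
  if (length(O) != length(P))
    stop("O and P must be paired vectors of equal length", call. = FALSE)
  if (length(O) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (mean(O) == 0) stop("mean of reference series is zero", call. = FALSE)
  rmse <- sqrt(mean((P - O)^2))
  structure(list(rmse = rmse, nrmse_pct = rmse / mean(O) * 100,
                 n = length(O)),
            class = "nc_agreement")
}

#' @export
print.nc_agreement <- function(x, ...) {
  cat(sprintf("<nc_agreement> RMSE = %.4f, n-RMSE = %.2f%%, n = %d\n",
              x$rmse, x$nrmse_pct, x$n))
  invisible(x)
}

#' Cross-basis NNI comparison against the shoot basis
#'
#' Computes per-observation NNI for each requested basis from its fitted
#' (or supplied) curve, pairs observations across bases on
#' (experiment, date, treatment, replicate), and reports RMSE / n-RMSE of
#' leaf, stem, LAI and the leaf+stem biomass-weighted mean against the shoot
#' basis (the reference series for normalization).
#'
#' @param ds an `nc_experiment` (already filtered).
#' @param curves named list of [nc_curve()]s with entries `leaf`, `stem`,
#'   `shoot` and optionally `lai` (e.g. via [as_nc_curve()] on converged
#'   fits).
#' @return list with `pairs` (wide data.frame of paired NNI per observation)
#'   and `stats` (data.frame: comparison, rmse, nrmse_pct, n).
#' @export
basis_crosswalk <- function(ds, curves) {
  need <- c("leaf", "stem", "shoot")
  if (!all(need %in% names(curves)))
    stop("curves must include at least leaf, stem and shoot", call. = FALSE)
  bases <- intersect(c("leaf", "stem", "shoot", "lai"), names(curves))
  series <- lapply(bases, function(b) {
    s <- nni_series(ds, curves[[b]], b)
    key <- paste(s$experiment_id, s$date_index, s$treatment_id, s$replicate,
                 sep = "|")
    data.frame(key = key, s, stringsAsFactors = FALSE)
  })
  names(series) <- bases
  common <- Reduce(intersect, lapply(series, `[[`, "key"))
  dropped <- unique(unlist(lapply(series, function(s)
    setdiff(s$key, common))))
  if (length(dropped) > 0)
    warning(length(dropped), " observation key(s) unmatched across bases ",
            "excluded from the crosswalk", call. = FALSE)
  if (length(common) < 2)
    stop("fewer than 2 observations matched across all bases", call. = FALSE)
  aligned <- lapply(series, function(s) s[match(common, s$key), ])
  pairs <- data.frame(
    key = common,
    nni_shoot = aligned$shoot$NNI,
    nni_leaf = aligned$leaf$NNI,
    nni_stem = aligned$stem$NNI,
    W_leaf = aligned$leaf$W,
    W_stem = aligned$stem$W,
    stringsAsFactors = FALSE
  )
  if ("lai" %in% bases) pairs$nni_lai <- aligned$lai$NNI
  pairs$nni_weighted <- weighted_mean_nni(pairs$nni_leaf, pairs$nni_stem,
                                          pairs$W_leaf, pairs$W_stem)
  comparisons <- c("leaf_vs_shoot", "stem_vs_shoot",
                   if ("lai" %in% bases) "lai_vs_shoot",
                   "weighted_vs_shoot")
  cols <- c(leaf_vs_shoot = "nni_leaf", stem_vs_shoot = "nni_stem",
            lai_vs_shoot = "nni_lai", weighted_vs_shoot = "nni_weighted")
  stats <- do.call(rbind, lapply(comparisons, function(cmp) {
    ag <- agreement(pairs$nni_shoot, pairs[[cols[[cmp]]]])
    data.frame(comparison = cmp, rmse = ag$rmse, nrmse_pct = ag$nrmse_pct,
               n = ag$n, stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, stats = stats)
}
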