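# Estimation of relative per-site selection coefficients beta(t) * s_i from
# aligned sequence sets at two or more time points: consensus binarization,
# minority frequencies, the -log(f_i / f_norm) estimator, ranked-curve
# normalization, and recovery of the intrinsic site density g(s).

#' Time-stamped alignment set
#'
#' Container for aligned sequences sampled at several time points, optionally
#' from several replicate populations. Sequences may be nucleotide or amino
#' acid; only the consensus / non-consensus distinction is used downstream.
#'
#' @param alignments list, one element per time point, each a character
#'   matrix (sequences x positions) or character vector of equal-length
#'   sequence strings.
#' @param times numeric vector of sampling times, same length as
#'   `alignments`.
#' @param replicates optional list of per-sequence replicate labels, one
#'   vector per time point.
#' @return An object of class `timepoint_alignment`.
#' @export
timepoint_alignment <- function(alignments, times, replicates = NULL) {
  stopifnot(length(alignments) == length(times), length(times) >= 1)
  mats <- lapply(alignments, function(a) {
    if (is.character(a) && !is.matrix(a)) {
      lens <- nchar(a)
      if (length(unique(lens)) != 1L)
        stop("sequences within a time point differ in length", call. = FALSE)
      a <- do.call(rbind, strsplit(a, ""))
    }
    a
  })
  widths <- vapply(mats, ncol, integer(1))
  if (length(unique(widths)) != 1L)
    stop("alignments at different time points differ in width", call. = FALSE)
  if (!is.null(replicates)) {
    stopifnot(length(replicates) == length(mats))
    for (i in seq_along(mats))
      stopifnot(length(replicates[[i]]) == nrow(mats[[i]]))
  }
  ord <- order(times)
  structure(list(alignments = mats[ord], times = as.numeric(times)[ord],
                 replicates = if (is.null(replicates)) NULL else replicates[ord]),
            class = "timepoint_alignment")
}

#' @export
print.timepoint_alignment <- function(x, ...) {
  cat(sprintf("Alignment set: %d time points (t = %s), width %d, %s sequences\n",
              length(x$times), paste(x$times, collapse = ", "),
              ncol(x$alignments[[1L]]),
              paste(vapply(x$alignments, nrow, integer(1)), collapse = "/")))
  invisible(x)
}

#' Consensus binarization of an alignment set
#'
#' Determines one consensus residue per position from all sequences pooled
#' across time points (a single reference frame, so estimates are comparable
#' across times), then maps the consensus residue to 0 and any minority
#' residue to 1. Columns containing a gap (`-` or `.`) in any sequence are
#' removed; their original indices are recorded in `dropped_columns`. Modal
#' ties are resolved by character order and flagged in `tied_columns`.
#'
#' @param aln a [timepoint_alignment()].
#' @return An object of class `binary_alignment`: list with `matrices` (one
#'   binary matrix per time point), `times`, `replicates`, `consensus`
#'   (character vector), `column_map` (kept original column indices),
#'   `dropped_columns`, `tied_columns`.
#' @export
consensus_binarize <- function(aln) {
  stopifnot(inherits(aln, "timepoint_alignment"))
  pooled <- do.call(rbind, aln$alignments)
  if (nrow(pooled) == 0L) stop("empty alignment", call. = FALSE)
  L <- ncol(pooled)
  has_gap <- vapply(seq_len(L), function(j)
    any(pooled[, j] %in% c("-", ".")), logical(1))
  keep <- which(!has_gap)
  if (length(keep) == 0L) stop("all columns contain gaps", call. = FALSE)

  consensus <- character(length(keep))
  tied <- logical(length(keep))
  for (jj in seq_along(keep)) {
    counts <- table(pooled[, keep[jj]])
    top <- counts == max(counts)
    tied[jj] <- sum(top) > 1L
    consensus[jj] <- sort(names(counts)[top])[1L]  # tie-break: character order
  }
  matrices <- lapply(aln$alignments, function(m) {
    bin <- t(t(m[, keep, drop = FALSE]) != consensus) * 1L
    bin
  })
  structure(list(matrices = matrices, times = aln$times,
                 replicates = aln$replicates, consensus = consensus,
                 column_map = keep, dropped_columns = which(has_gap),
                 tied_columns = keep[tied]),
            class = "binary_alignment")
}

#' Per-site minority-allele frequency
#'
#' Frequency of 1 (non-consensus) per site at one time point. With replicate
#' labels, `pooling = "pooled"` (default) treats all sequences as one sample,
#' approximating the ensemble average by combining independent populations;
#' `pooling = "mean"` averages per-replicate frequencies, weighting
#' populations equally regardless of sample size.
#'
#' @param bin a [consensus_binarize()] result.
#' @param timepoint a value of `bin$times`.
#' @param pooling `"pooled"` or `"mean"`.
#' @return numeric vector of frequencies, one per kept column.
#' @export
minority_frequency <- function(bin, timepoint, pooling = c("pooled", "mean")) {
  stopifnot(inherits(bin, "binary_alignment"))
  pooling <- match.arg(pooling)
  it <- match(timepoint, bin$times)
  if (is.na(it)) stop("no such time point: ", timepoint, call. = FALSE)
  m <- bin$matrices[[it]]
  if (pooling == "pooled" || is.null(bin$replicates))
    return(colMeans(m))
  reps <- bin$replicates[[it]]
  # rowsum and table both order groups by sort(unique(reps))
  per_rep <- rowsum(m, group = reps) / as.vector(table(reps))
  colMeans(per_rep)
}

#' Relative selection coefficient from a minority frequency
#'
#' The estimator `beta(t) * s_i = -log(f_i(t) / f_norm)`: positive where the
#' minority allele is rarer than the reference frequency `f_norm` (consensus
#' fitter), negative where it is commoner (anti-consensus allele fitter).
#' Returns `NA` where `f_i = 0` (site monomorphic at consensus: the estimate
#' diverges and the site is not estimable).
#'
#' @param f_i minority frequencies (vectorized).
#' @param f_norm positive reference frequency.
#' @return relative selection coefficients in units of `1/beta`.
#' @export
relative_selection <- function(f_i, f_norm) {
  stopifnot(f_norm > 0)
  out <- rep(NA_real_, length(f_i))
  ok <- !is.na(f_i) & f_i > 0
  out[ok] <- -log(f_i[ok] / f_norm)
  out
}

#' Rank sites by estimated selection coefficient
#'
#' Sorts per-site estimates in descending order, producing the monotone
#' ranked curve `s_rank(m)`; ties are broken by site index. The site-to-rank
#' permutation is retained so estimates can be mapped back to genomic
#' coordinates.
#'
#' @param beta_s numeric vector of per-site estimates (`NA` = non-estimable,
#'   excluded).
#' @return An object of class `rank_curve`: list with `s_rank` (descending
#'   values), `site_index` (original index per rank), `rank_of_site`
#'   (rank per original site, `NA` where not estimable).
#' @export
rank_sites <- function(beta_s) {
  est <- which(!is.na(beta_s))
  if (length(est) < 2L) stop("need at least 2 estimable sites", call. = FALSE)
  ord <- est[order(-beta_s[est], est)]
  rank_of_site <- rep(NA_integer_, length(beta_s))
  rank_of_site[ord] <- seq_along(ord)
  structure(list(s_rank = beta_s[ord], site_index = ord,
                 rank_of_site = rank_of_site),
            class = "rank_curve")
}

#' Determine the normalization frequency f_norm from two time points
#'
#' The estimator factorizes as `beta(t) * s_i`, so the ranked curves from two
#' times must intersect at the rank of the `s = 0` site, where the estimate
#' vanishes at every time. `find_fnorm` builds both ranked curves, locates
#' their first transversal crossing on the shared rank axis (linear
#' interpolation between rank positions), and fixes `f_norm` so that the
#' common value at the crossing is zero. Changing `f_norm` by a factor `c`
#' shifts every estimate by `+log(c)` without moving the crossing rank, so
#' the zero condition determines `f_norm` uniquely.
#'
#' Only sites estimable (frequency strictly inside `(0, 1)`) at both times
#' enter the curves. If the fixed point lies outside `(0, 1]`, `f_norm` is
#' clamped to 1 with a warning (it is a reference frequency, not a
#' probability, but frequencies above 1 are meaningless).
#'
#' @param bin a [consensus_binarize()] result.
#' @param t1,t2 two distinct time points present in `bin$times`.
#' @param pooling replicate pooling passed to [minority_frequency()].
#' @return An object of class `fnorm_result`: list with `f_norm`,
#'   `intersection_rank`, `residual` (|s_rank| gap at the crossing before
#'   zeroing, a transversality diagnostic), `sites_used`, `n_dropped`.
#' @export
find_fnorm <- function(bin, t1, t2, pooling = "pooled") {
  stopifnot(inherits(bin, "binary_alignment"))
  if (t1 == t2) stop("t1 and t2 must differ", call. = FALSE)
  fnorm_from_frequencies(minority_frequency(bin, t1, pooling),
                         minority_frequency(bin, t2, pooling))
}

#' @rdname find_fnorm
#' @param f1,f2 per-site minority frequencies at the two time points
#'   (same sites, same order).
#' @export
fnorm_from_frequencies <- function(f1, f2) {
  stopifnot(length(f1) == length(f2))
  usable <- f1 > 0 & f1 < 1 & f2 > 0 & f2 < 1
  if (sum(usable) < 3L)
    stop("fewer than 3 sites estimable at both time points", call. = FALSE)

  # provisional estimates with f_norm = 1: a_t(m) = -log f_(m); the true
  # curves are a_t(m) + log(f_norm), so the crossing rank is already final
  a1 <- sort(-log(f1[usable]), decreasing = TRUE)
  a2 <- sort(-log(f2[usable]), decreasing = TRUE)
  d <- a1 - a2
  if (all(abs(d) < 1e-12))
    stop("ranked curves coincide (no transversal crossing): time points are ",
         "degenerate or frequencies unchanged; use more sites or wider-spaced ",
         "times", call. = FALSE)
  sign_change <- which(d[-length(d)] * d[-1L] <= 0 &
                         (d[-length(d)] != 0 | d[-1L] != 0))
  if (length(sign_change) == 0L) {
    if (all(d > 0) || all(d < 0))
      stop("ranked curves do not cross within the shared rank range; the ",
           "estimator needs sites on both sides of s = 0 (more sites or time ",
           "points may help)", call. = FALSE)
    sign_change <- which(d == 0)
  }
  m_lo <- sign_change[1L]                      # first transversal crossing
  frac <- if (d[m_lo] == d[m_lo + 1L]) 0 else d[m_lo] / (d[m_lo] - d[m_lo + 1L])
  m_star <- m_lo + frac
  a_star <- a1[m_lo] + frac * (a1[m_lo + 1L] - a1[m_lo])
  f_norm <- exp(-a_star)                        # zero the curve: log f_norm = -a*
  clamped <- FALSE
  if (f_norm > 1) {
    warning("fixed point implies f_norm > 1; clamping to 1")
    f_norm <- 1
    clamped <- TRUE
  }
  a2_star <- a2[m_lo] + frac * (a2[m_lo + 1L] - a2[m_lo])
  structure(list(f_norm = f_norm, intersection_rank = m_star,
                 residual = abs(a_star - a2_star), clamped = clamped,
                 sites_used = sum(usable), n_dropped = sum(!usable)),
            class = "fnorm_result")
}

#' @export
print.fnorm_result <- function(x, ...) {
  cat(sprintf("f_norm = %.4g (intersection at rank %.2f, %d sites used, %d dropped)\n",
              x$f_norm, x$intersection_rank, x$sites_used, x$n_dropped))
  invisible(x)
}

#' Estimate the intrinsic site density from a ranked curve
#'
#' The intrinsic density is the inverse derivative of the ranked curve:
#' `g(s) = (delta s / delta m)^(-1)`, evaluated at midpoints between
#' successive ranks. Runs of tied estimates (zero difference) are merged
#' before inversion. The output is in sites per unit of relative `s`
#' (units of `beta`); dividing the `s` axis by `beta(t)` recovers absolute
#' units.
#'
#' @param ranked a [rank_sites()] result (or numeric vector of descending
#'   estimates).
#' @return data.frame with columns `s_mid`, `g_estimate`.
#' @export
estimate_intrinsic_density <- function(ranked) {
  s_rank <- if (inherits(ranked, "rank_curve")) ranked$s_rank else as.numeric(ranked)
  if (length(s_rank) < 3L) stop("need at least 3 ranked sites", call. = FALSE)
  s_unique <- unique(s_rank)                    # merge tied runs
  if (length(s_unique) < 2L)
    stop("all estimates tied: density not estimable", call. = FALSE)
  m_at <- match(s_unique, s_rank) +
    (tabulate(match(s_rank, s_unique)) - 1) / 2  # mean rank of each tied run
  ds <- diff(s_unique)                           # < 0: curve is descending
  dm <- diff(m_at)
  data.frame(s_mid = (s_unique[-1L] + s_unique[-length(s_unique)]) / 2,
             g_estimate = -dm / ds)
}

#' Full inference pipeline
#'
#' Binarize, compute per-site minority frequencies, determine `f_norm` from
#' the first and last time points (or a given pair), estimate
#' `beta(t) * s_i` per site and time, rank, and recover the intrinsic
#' density. With a single time point no fixed point exists; estimates are
#' then relative to `f_norm = max(f_i)` and a warning is issued.
#'
#' The method assumes directional, roughly constant selection and a
#' population that is adapting (well past its origin but far from
#' mutation-selection equilibrium); these are properties of the study system
#' that the data alone cannot verify.
#'
#' @param aln a [timepoint_alignment()].
#' @param t_pair length-2 vector of times used for the `f_norm` fixed point
#'   (default: first and last).
#' @param pooling replicate pooling, `"pooled"` or `"mean"`.
#' @return An object of class `dfewave_inference`: list with
#'   `estimates` (data.frame: `site` in original alignment coordinates, `f_`
#'   columns per time, `beta_s_` columns per time, `rank` at the reference
#'   time, `flag`), `fnorm` (an `fnorm_result` or fallback), `density`
#'   (data.frame `s_mid`, `g_estimate` at the latest time), `binary`
#'   (the `binary_alignment`).
#' @export
run_inference <- function(aln, t_pair = NULL, pooling = "pooled") {
  stopifnot(inherits(aln, "timepoint_alignment"))
  bin <- consensus_binarize(aln)
  times <- bin$times
  freqs <- vapply(times, function(t) minority_frequency(bin, t, pooling),
                  numeric(ncol(bin$matrices[[1L]])))
  freqs <- matrix(freqs, ncol = length(times))

  if (length(times) >= 2L) {
    if (is.null(t_pair)) t_pair <- c(times[1L], times[length(times)])
    fnorm <- find_fnorm(bin, t_pair[1L], t_pair[2L], pooling = pooling)
    f_norm <- fnorm$f_norm
  } else {
    warning("single time point: no fixed point available; using f_norm = max(f_i)")
    f_norm <- max(freqs[freqs > 0])
    fnorm <- list(f_norm = f_norm, intersection_rank = NA_real_,
                  residual = NA_real_, clamped = FALSE,
                  sites_used = sum(freqs > 0), n_dropped = sum(freqs == 0))
  }

  beta_s <- apply(freqs, 2, relative_selection, f_norm = f_norm)
  beta_s <- matrix(beta_s, ncol = length(times))
  t_ref <- times[length(times)]
  ranked <- rank_sites(beta_s[, length(times)])
  density <- estimate_intrinsic_density(ranked)

  flag <- rep("ok", nrow(freqs))
  flag[apply(freqs == 0, 1, any)] <- "monomorphic-consensus"
  flag[apply(freqs == 1, 1, any)] <- "monomorphic-minority"

  est <- data.frame(site = bin$column_map)
  for (k in seq_along(times)) est[[paste0("f_t", times[k])]] <- freqs[, k]
  for (k in seq_along(times)) est[[paste0("beta_s_t", times[k])]] <- beta_s[, k]
  est$rank <- ranked$rank_of_site
  est$flag <- flag

  structure(list(estimates = est, fnorm = fnorm, density = density,
                 t_ref = t_ref, binary = bin),
            class = "dfewave_inference")
}

#' @export
print.dfewave_inference <- function(x, ...) {
  cat(sprintf("Selection-coefficient inference: %d sites (%d estimable), f_norm = %.4g\n",
              nrow(x$estimates), sum(!is.na(x$estimates$rank)), x$fnorm$f_norm))
  invisible(x)
}
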