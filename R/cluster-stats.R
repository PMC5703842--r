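#' Stack per-trial maps into a trials x pixels matrix
#' @noRd
stack_maps <- function(maps) {
  mats <- lapply(maps, function(m) if (inherits(m, "tfr_map")) m$power else m)
  dims <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == dims), TRUE))) {
    stop("maps have mismatched grids")
  }
  list(M = do.call(rbind, lapply(mats, as.numeric)), dims = dims)
}

#' 5x5 (or k x k) box-mean smoothing with truncated edge windows
#' @noRd
box_smooth <- function(x, k = 5) {
  h <- k %/% 2
  nr <- nrow(x); nc <- ncol(x)
  # summed-area table with zero padding
  sat <- apply(apply(x, 2, cumsum), 1, cumsum)   # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  r1 <- pmax(seq_len(nr) - h, 1); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1); c2 <- pmin(seq_len(nc) + h, nc)
  sums <- sat[r2 + 1, c2 + 1, drop = FALSE] -
    sat[r1, c2 + 1, drop = FALSE] -
    sat[r2 + 1, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1, c2 - c1 + 1)
  sums / counts
}

#' Pixel-wise F map with locally smoothed variance
#'
#' For each (frequency, time) pixel, a two-sample F statistic comparing
#' the condition means of per-trial (decibel-scaled) maps:
#' `F = (mean_a - mean_b)^2 / (s2 (1/na + 1/nb))`, with the pooled
#' variance `s2` replaced by its mean over a 5 x 5 pixel neighbourhood
#' (truncated at the edges) to stabilize the estimate. The statistic is
#' the square of the pooled-variance t, so its null law is
#' F(1, na + nb - 2). A variance floor guards constant maps.
#'
#' @param maps_a,maps_b lists of per-trial `tfr_map`s (or matrices) on
#'   identical grids, at least 2 trials each.
#' @param smooth_px side of the square smoothing neighbourhood.
#' @param var_floor lower bound on the smoothed pooled variance.
#' @return object of class `pixel_stat_map`: list with `F` (matrix),
#'   `sign` (sign of mean_a - mean_b), `df`, `dims`.
#' @export
smoothed_f_map <- function(maps_a, maps_b, smooth_px = 5,
                           var_floor = 1e-10) {
  sa <- stack_maps(maps_a); sb <- stack_maps(maps_b)
  if (!all(sa$dims == sb$dims)) stop("maps have mismatched grids")
  na <- nrow(sa$M); nb <- nrow(sb$M)
  if (na < 2 || nb < 2) stop("need at least 2 trials per condition")
  st <- f_map_core(rbind(sa$M, sb$M), seq_len(na), sa$dims, smooth_px,
                   var_floor)
  structure(st, class = "pixel_stat_map")
}

#' Core F computation on a stacked trial matrix; `idx_a` indexes rows of
#' condition A. Shared by the observed fit and the permutation loop.
#' @noRd
f_map_core <- function(M, idx_a, dims, smooth_px = 5, var_floor = 1e-10) {
  n <- nrow(M)
  na <- length(idx_a); nb <- n - na
  a <- M[idx_a, , drop = FALSE]
  b <- M[-idx_a, , drop = FALSE]
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b^2) - nb * mb^2) / (nb - 1)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  s2m <- box_smooth(matrix(s2, dims[1], dims[2]), smooth_px)
  s2m <- pmax(s2m, var_floor)
  Fm <- matrix((ma - mb)^2, dims[1], dims[2]) / (s2m * (1 / na + 1 / nb))
  list(F = Fm, sign = matrix(sign(ma - mb), dims[1], dims[2]),
       df = c(1, na + nb - 2), dims = dims)
}

#' Decile thresholding and clustering of an F map
#'
#' Selects pixels whose F statistic falls in the uppermost or lowermost
#' decile of its null F(1, df2) law (tail probabilities `p_high = 0.9`
#' and `p_low = 0.1` of the CDF), groups contiguous selected pixels into
#' clusters per tail under the declared connectivity, and scores each
#' cluster by its mass, the summed `|log F|` over member pixels (log F is
#' positive throughout the upper-decile region and negative throughout
#' the lower, so the mass is positive in both tails).
#'
#' @param stat a `pixel_stat_map`.
#' @param p_low,p_high CDF thresholds defining the lower and upper tails.
#' @param connectivity 4 (edge-adjacent) or 8 (plus diagonals).
#' @return object of class `cluster_set`: list with `clusters`
#'   (data.frame: id, tail, mass, n_pixels), `labels` (integer matrix per
#'   tail), thresholds.
#' @export
threshold_clusters <- function(stat, p_low = 0.1, p_high = 0.9,
                               connectivity = 4) {
  cdf <- stats::pf(stat$F, stat$df[1], stat$df[2])
  logF <- log(pmax(stat$F, .Machine$double.xmin))
  out <- list()
  labels <- list()
  for (tail in c("upper", "lower")) {
    sel <- if (tail == "upper") cdf >= p_high else cdf <= p_low
    lab <- .label_components(sel, as.integer(connectivity))
    k <- max(lab)
    labels[[tail]] <- lab
    if (k > 0) {
      pos <- lab > 0
      mass <- as.numeric(rowsum(abs(logF[pos]), lab[pos]))
      npx <- tabulate(lab[pos], k)
      out[[tail]] <- data.frame(id = seq_len(k), tail = tail,
                                mass = mass, n_pixels = npx)
    }
  }
  clusters <- if (length(out)) do.call(rbind, out) else
    data.frame(id = integer(), tail = character(), mass = numeric(),
               n_pixels = integer())
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, labels = labels,
                 p_low = p_low, p_high = p_high,
                 connectivity = connectivity),
            class = "cluster_set")
}

#' Cluster-mass permutation test for a time-frequency contrast
#'
#' Scores the observed clusters of [threshold_clusters()] against a null
#' built by randomly shuffling the condition labels of the trials and
#' re-running the whole pipeline (smoothed F map, decile thresholding,
#' clustering) each time, recording the maximum cluster mass per tail.
#' Each observed cluster gets
#' `p = (1 + #\{null max mass >= observed mass\}) / (1 + n_perm)`, with
#' the null maximum taken over both tails of each permutation so a single
#' alpha controls the family-wise error rate over all pixels, clusters
#' and tails; clusters with `p < alpha` are retained.
#'
#' @inheritParams smoothed_f_map
#' @inheritParams threshold_clusters
#' @param n_perm number of label permutations (a warning is given below
#'   100).
#' @param alpha retention threshold, default 0.05.
#' @param seed RNG seed; results are deterministic given (data, seed,
#'   n_perm).
#' @return a `cluster_set` whose `clusters` table gains `p` and
#'   `retained`, plus `null_max` (per-tail permutation maxima).
#' @export
permutation_null <- function(maps_a, maps_b, n_perm = 1000, seed = 1L,
                             p_low = 0.1, p_high = 0.9, connectivity = 4,
                             smooth_px = 5, alpha = 0.05) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null")
  sa <- stack_maps(maps_a); sb <- stack_maps(maps_b)
  if (!all(sa$dims == sb$dims)) stop("maps have mismatched grids")
  M <- rbind(sa$M, sb$M)
  na <- nrow(sa$M); n <- nrow(M)
  dims <- sa$dims

  obs <- threshold_clusters(
    structure(f_map_core(M, seq_len(na), dims, smooth_px),
              class = "pixel_stat_map"),
    p_low, p_high, connectivity
  )

  # thresholding on the F CDF at fixed deciles equals thresholding F at
  # the corresponding null quantiles, computed once outside the loop
  df2 <- nrow(M) - 2
  f_hi <- stats::qf(p_high, 1, df2)
  f_lo <- stats::qf(p_low, 1, df2)
  max_mass <- function(Fm) {
    logF <- log(pmax(Fm, .Machine$double.xmin))
    out <- c(upper = 0, lower = 0)
    for (tail in c("upper", "lower")) {
      sel <- if (tail == "upper") Fm >= f_hi else Fm <= f_lo
      if (!any(sel)) next
      lab <- .label_components(sel, as.integer(connectivity))
      pos <- lab > 0
      out[tail] <- max(rowsum(abs(logF[pos]), lab[pos]))
    }
    out
  }

  set.seed(derive_seed(seed, "permnull"))
  null_max <- matrix(0, n_perm, 2, dimnames = list(NULL, c("upper", "lower")))
  for (b in seq_len(n_perm)) {
    st <- f_map_core(M, sample(n, na), dims, smooth_px)
    null_max[b, ] <- max_mass(st$F)
  }
  cl <- obs$clusters
  if (nrow(cl)) {
    # one family across both tails: compare to the per-permutation
    # maximum over tails, otherwise each tail spends the full alpha
    null_any <- pmax(null_max[, "upper"], null_max[, "lower"])
    cl$p <- vapply(seq_len(nrow(cl)), function(i) {
      (1 + sum(null_any >= cl$mass[i])) / (1 + n_perm)
    }, 0)
    cl$retained <- cl$p < alpha
  } else {
    cl$p <- numeric(); cl$retained <- logical()
  }
  obs$clusters <- cl
  obs$null_max <- null_max
  obs$n_perm <- n_perm
  obs
}
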