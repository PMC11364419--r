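#' Hartigan's dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and the closest unimodal CDF; large values indicate
#' departure from unimodality. Computed with the classic greatest-convex-
#' minorant / least-concave-majorant cycling algorithm on the sorted
#' sample, iteratively narrowing the candidate modal interval.
#'
#' Closed forms used to validate the implementation: a sample of distinct
#' equally spaced points has dip exactly `1/(2n)`, and a two-point sample
#' with masses `p` and `1 - p` has dip `min(p, 1 - p)/2`.
#'
#' @param x Numeric sample.
#' @return The dip statistic, in `[1/(2n), 1/4]` for non-degenerate
#'   samples; 0 for constant or length-< 2 samples.
#' @seealso [dip_test()]
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x[is.finite(x)]))
  n <- length(x)
  if (n < 2 || x[n] == x[1]) return(0)

  lo <- 1L; hi <- n
  dip <- 1 # in count units; divided by 2n at the end

  # One-off pointer arrays: mn[j] chains back through the touch points of
  # the greatest convex minorant, mj[j] forward through those of the least
  # concave majorant, of the empirical CDF of the full sample.
  mn <- integer(n); mj <- integer(n)
  mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  mj[n] <- n
  for (j in (n - 1L):1L) {
    mj[j] <- j + 1L
    repeat {
      mjj <- mj[j]
      if (mjj == n) break
      mjmjj <- mj[mjj]
      if ((x[j] - x[mjj]) * (mjj - mjmjj) <
          (x[mjj] - x[mjmjj]) * (j - mjj)) break
      mj[j] <- mjmjj
    }
  }

  repeat {
    # touch points of the two envelopes over the current [lo, hi]
    gcm <- hi
    while (gcm[length(gcm)] > lo) gcm <- c(gcm, mn[gcm[length(gcm)]])
    lcm <- lo
    while (lcm[length(lcm)] < hi) lcm <- c(lcm, mj[lcm[length(lcm)]])
    l_gcm <- length(gcm) # gcm[1] = hi ... gcm[l_gcm] = lo
    l_lcm <- length(lcm) # lcm[1] = lo ... lcm[l_lcm] = hi

    # largest vertical gap (in counts) between minorant and majorant
    ig <- l_gcm; ih <- l_lcm
    ix <- l_gcm - 1L; iv <- 2L
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]; lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv - 1L }
        } else {
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx >= d) { d <- dx; ig <- ix + 1L; ih <- iv }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1
    }
    if (d < dip) break

    # max deviation of the empirical CDF from the convex minorant fit
    dip_l <- 0
    if (ig < l_gcm) for (j in ig:(l_gcm - 1L)) {
      max_t <- 1
      jb <- gcm[j + 1L]; je <- gcm[j]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (jj in jb:je) {
          t <- (jj - jb + 1) - (x[jj] - x[jb]) * C
          if (t > max_t) max_t <- t
        }
      }
      if (max_t > dip_l) dip_l <- max_t
    }
    # and from the concave majorant fit
    dip_u <- 0
    if (ih < l_lcm) for (j in ih:(l_lcm - 1L)) {
      max_t <- 1
      jb <- lcm[j]; je <- lcm[j + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        for (jj in jb:je) {
          t <- (je - jj + 1) - (x[je] - x[jj]) * C
          if (t > max_t) max_t <- t
        }
      }
      if (max_t > dip_u) dip_u <- max_t
    }
    dip <- max(dip, dip_l, dip_u)

    if (lo == gcm[ig] && hi == lcm[ih]) break
    lo <- gcm[ig]; hi <- lcm[ih]
    if (hi - lo < 2L) break
  }
  dip / (2 * n)
}

#' Dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution using Hartigan's dip statistic. The p-value is Monte-Carlo,
#' simulated under the uniform distribution -- the asymptotically least
#' favourable unimodal null -- at the observed sample size.
#'
#' @param x Numeric sample.
#' @param n_sim Number of uniform null simulations.
#' @param seed Seed for the null simulations (fixed so the test is
#'   reproducible and does not disturb the caller's RNG state).
#' @return A list with `statistic` (the dip) and `p_value`.
#' @examples
#' dip_test(c(rnorm(100, -2, 0.4), rnorm(100, 2, 0.4)))$p_value # small
#' @export
dip_test <- function(x, n_sim = 1000L, seed = 20230517L) {
  d <- dip_statistic(x)
  n <- sum(is.finite(x))
  key <- sprintf("n%d_b%d_s%d", n, n_sim, seed)
  null_d <- .dip_null_cache[[key]]
  if (is.null(null_d)) {
    null_d <- withr::with_seed(seed, {
      vapply(seq_len(n_sim), function(i) dip_statistic(runif(n)), numeric(1))
    })
    .dip_null_cache[[key]] <- null_d
  }
  list(statistic = d, p_value = (1 + sum(null_d >= d)) / (n_sim + 1))
}

# session cache of simulated null dip distributions, keyed by sample size
.dip_null_cache <- new.env(parent = emptyenv())
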