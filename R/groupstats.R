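#' Condition contrast per channel-channel-frequency cell
#'
#' Two-tailed t-test of COOP vs IND band-mean coherence across dyads, one
#' test per cell. Paired by default (each dyad contributes both
#' conditions); a Welch unpaired test is available by flag. A dyad missing
#' either condition in a cell is dropped from that cell only; cells with
#' fewer than `min_dyads` complete dyads are flagged untested (`tested =
#' FALSE`) rather than propagating NaN.
#'
#' @param coop_means,ind_means numeric matrices, dyads x cells, aligned.
#' @param paired paired t-test across dyads (default TRUE).
#' @param min_dyads minimum complete dyads per cell (default 3).
#' @return data.frame, one row per cell: `n_dyads`, `mean_coop`,
#'   `mean_ind`, `t`, `p`, `direction` ("COOP>IND" / "COOP<IND"),
#'   `tested`.
#' @export
condition_contrast <- function(coop_means, ind_means, paired = TRUE,
                               min_dyads = 3) {
  coop_means <- as.matrix(coop_means); ind_means <- as.matrix(ind_means)
  if (!all(dim(coop_means) == dim(ind_means)))
    stop("condition_contrast: condition matrices must share one shape")
  m <- ncol(coop_means)
  out <- data.frame(n_dyads = integer(m), mean_coop = NA_real_,
                    mean_ind = NA_real_, t = NA_real_, p = NA_real_,
                    direction = NA_character_, tested = FALSE)
  for (j in seq_len(m)) {
    a <- coop_means[, j]; b <- ind_means[, j]
    ok <- is.finite(a) & is.finite(b)
    n <- sum(ok)
    out$n_dyads[j] <- n
    if (n < min_dyads) next
    a <- a[ok]; b <- b[ok]
    out$mean_coop[j] <- mean(a)
    out$mean_ind[j] <- mean(b)
    if (paired) {
      d <- a - b
      sdd <- stats::sd(d)
      if (sdd == 0) {
        tv <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      } else {
        tv <- mean(d) / (sdd / sqrt(n))
      }
      pv <- 2 * stats::pt(-abs(tv), n - 1)
    } else {
      tt <- stats::t.test(a, b)
      tv <- unname(tt$statistic); pv <- tt$p.value
    }
    out$t[j] <- tv
    out$p[j] <- pv
    out$direction[j] <- if (mean(a) >= mean(b)) "COOP>IND" else "COOP<IND"
    out$tested[j] <- TRUE
  }
  out
}

#' Storey's positive false discovery rate q-values
#'
#' Estimates the null proportion from the upper tail of the p-value
#' distribution, `pi0 = #\{p > lambda\} / (m (1 - lambda))` clipped to
#' (0, 1], then computes q-values
#' `q_(i) = min_(j >= i) pi0 m p_(j) / j` over the ascending order
#' statistics. Cells are significant at `q < 0.05` under the conventional
#' criterion.
#'
#' @param p p-values in \[0, 1\] (NA allowed; NA in, NA out).
#' @param lambda tuning constant for the pi0 estimate (default 0.5).
#' @return list of class `qvalue_result`: `q` (aligned to input),
#'   `pi0`, `lambda`.
#' @export
storey_fdr <- function(p, lambda = 0.5) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0) stop("storey_fdr: no p-values supplied")
  if (any(pv < 0 | pv > 1)) stop("storey_fdr: p-values outside [0, 1]")
  if (lambda <= 0 || lambda >= 1) stop("storey_fdr: lambda must be in (0,1)")
  m <- length(pv)
  pi0 <- sum(pv > lambda) / (m * (1 - lambda))
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(pv)
  ranked <- pi0 * m * pv[o] / seq_len(m)
  qo <- rev(cummin(rev(ranked)))
  qo <- pmin(qo, 1)
  q <- rep(NA_real_, length(p))
  qok <- numeric(m)
  qok[o] <- qo
  q[ok] <- qok
  structure(list(q = q, pi0 = pi0, lambda = lambda),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("<qvalue_result> m = %d, pi0 = %.3f (lambda = %g), %d cells q < 0.05\n",
              sum(!is.na(x$q)), x$pi0, x$lambda,
              sum(x$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Representative frequency band per channel pair
#'
#' Adjacent bands of one channel pair are highly correlated, so one band
#' represents each pair: the band with the smallest p-value (within an
#' optional frequency window), ties broken toward the lower band index.
#' Pairs with no tested band in scope are excluded.
#'
#' @param cells data.frame with columns `chA`, `chB`, `band`, `freq_hz`,
#'   `p`, `tested` (as produced by the pipeline's contrast stage).
#' @param f_window optional `c(f_lo, f_hi)` Hz restriction.
#' @return subset of `cells`, one row per channel pair.
#' @export
select_representative <- function(cells, f_window = NULL) {
  x <- cells[cells$tested & is.finite(cells$p), , drop = FALSE]
  if (!is.null(f_window))
    x <- x[x$freq_hz >= f_window[1] & x$freq_hz <= f_window[2], ,
           drop = FALSE]
  if (nrow(x) == 0) return(x)
  key <- paste(x$chA, x$chB, sep = "-")
  keep <- unlist(lapply(split(seq_len(nrow(x)), key), function(idx) {
    sub <- x[idx, ]
    idx[order(sub$p, sub$band)[1]]
  }), use.names = FALSE)
  out <- x[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate cells for the event-related GLM
#'
#' Cells with a significantly stronger coherence in COOP than IND
#' (two-tailed p below `p_threshold` with direction COOP>IND) inside the
#' social-interaction frequency window, reduced to one representative band
#' per channel pair (smallest p).
#'
#' @param cells contrast table (see [select_representative()]), needing
#'   additionally a `direction` column.
#' @param p_threshold selection threshold (default 0.001).
#' @param f_window frequency window in Hz (default c(0.03, 0.1)).
#' @param direction required direction (default "COOP>IND").
#' @return one row per candidate channel pair (possibly zero rows).
#' @export
glm_candidates <- function(cells, p_threshold = 0.001,
                           f_window = c(0.03, 0.1),
                           direction = "COOP>IND") {
  x <- cells[cells$tested & is.finite(cells$p) &
               cells$p < p_threshold & cells$direction == direction, ,
             drop = FALSE]
  select_representative(x, f_window)
}
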