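#' Modified Beer-Lambert law parameters
#'
#' Extinction coefficients for oxy- and deoxy-hemoglobin at the two
#' measurement wavelengths (695 and 830 nm), differential pathlength
#' factors, and source-detector distance. With `dpf = 1` the recovered
#' concentrations are in the relative mM x mm units conventional for
#' continuous-wave optical topography.
#'
#' Default molar extinction coefficients (1/(mM x cm)) are the published
#' values for human hemoglobin at 695 and 830 nm.
#'
#' @param extinction 2x2 matrix, rows = wavelengths (695, 830 nm),
#'   columns = chromophores (HbO, HbR), units 1/(mM x cm).
#' @param dpf differential pathlength factor per wavelength (default 1, 1).
#' @param distance_mm source-detector separation (default 30).
#' @return list of class `mbll_params`.
#' @export
mbll_params <- function(extinction = matrix(c(0.3123, 1.0507,
                                              1.7958, 0.7804),
                                            nrow = 2,
                                            dimnames = list(c("695", "830"),
                                                            c("HbO", "HbR"))),
                        dpf = c(1, 1), distance_mm = 30) {
  if (!is.matrix(extinction) || any(dim(extinction) != 2))
    stop("mbll_params: extinction must be a 2x2 matrix")
  if (kappa(extinction) >= 1e6)
    stop("mbll_params: extinction matrix is ill-conditioned")
  if (length(dpf) != 2 || any(dpf <= 0))
    stop("mbll_params: dpf must be two positive values")
  structure(list(extinction = extinction, dpf = dpf,
                 distance_mm = distance_mm),
            class = "mbll_params")
}

#' Optical density to hemoglobin concentration (modified Beer-Lambert law)
#'
#' Solves, per sample, the 2x2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`
#' for the concentration changes of the two chromophores.
#'
#' @param od_695,od_830 optical-density change series at 695 and 830 nm
#'   (equal length; may be matrices time x channel).
#' @param params an [mbll_params()].
#' @return list with `oxy` and `deoxy`, same shape as the inputs.
#' @export
mbll <- function(od_695, od_830, params = mbll_params()) {
  if (is.null(od_695) || is.null(od_830))
    stop("mbll: both wavelengths are required")
  if (length(od_695) != length(od_830))
    stop("mbll: optical-density series lengths differ")
  # distance in cm to match 1/(mM cm) extinction units
  A <- params$extinction * (params$dpf * params$distance_mm / 10)
  Ainv <- solve(A)
  oxy <- Ainv[1, 1] * od_695 + Ainv[1, 2] * od_830
  deoxy <- Ainv[2, 1] * od_695 + Ainv[2, 2] * od_830
  list(oxy = oxy, deoxy = deoxy)
}

# forward model used in tests and by the SNIRF intensity route
mbll_forward <- function(oxy, deoxy, params = mbll_params()) {
  A <- params$extinction * (params$dpf * params$distance_mm / 10)
  list(od_695 = A[1, 1] * oxy + A[1, 2] * deoxy,
       od_830 = A[2, 1] * oxy + A[2, 2] * deoxy)
}

#' Hemodynamic modality separation (HDMS)
#'
#' Decomposes oxy/deoxy hemoglobin series into a functional (cortical)
#' component, in which deoxy-Hb varies negatively proportionally to oxy-Hb
#' (`deoxy = k_f * oxy`, `k_f < 0`), and a systemic component in which they
#' vary positively proportionally (`deoxy = k_s * oxy`, `k_s > 0`). The
#' per-sample solve of `oxy = F + S`, `deoxy = k_f F + k_s S` removes
#' superficial/systemic blood-flow signals (e.g. skin blood flow driven by
#' interactive movement) before coherence analysis.
#'
#' @param oxy,deoxy equal-shape series or matrices.
#' @param k_f functional deoxy/oxy ratio, negative (default -0.6).
#' @param k_s systemic deoxy/oxy ratio, positive (default +0.5).
#' @return list with `functional_oxy` (F), `functional_deoxy` (k_f F),
#'   `systemic_oxy` (S), `systemic_deoxy` (k_s S).
#' @export
hdms <- function(oxy, deoxy, k_f = -0.6, k_s = 0.5) {
  if (!(k_f < 0) || !(k_s > 0))
    stop("hdms: require k_f < 0 < k_s")
  if (k_f == k_s) stop("hdms: k_f == k_s gives a singular system")
  if (length(oxy) != length(deoxy))
    stop("hdms: oxy and deoxy shapes differ")
  den <- k_s - k_f
  F <- (k_s * oxy - deoxy) / den
  S <- (deoxy - k_f * oxy) / den
  list(functional_oxy = F, functional_deoxy = k_f * F,
       systemic_oxy = S, systemic_deoxy = k_s * S)
}

#' Autoregressive pre-whitening
#'
#' Fits an AR(`order`) model by Yule-Walker (Levinson-Durbin) to the
#' mean-removed series and returns the one-step-ahead prediction residuals.
#' The default order 50 corresponds to 5 s of history at the 10 Hz Hb
#' sampling rate. The first `order` samples carry no residual and are
#' dropped, so the output has `length(x) - order` samples.
#'
#' @param x numeric series, length > 3 * order.
#' @param order AR model order (default 50).
#' @return residual series with attributes `ar_order` and `ar_coef`.
#' @export
prewhiten <- function(x, order = 50) {
  if (length(x) <= 3 * order)
    stop("prewhiten: series length must exceed 3 x order (",
         length(x), " <= ", 3 * order, ")")
  if (stats::sd(x) == 0) {
    res <- rep(0, length(x) - order)
    attr(res, "ar_order") <- order
    attr(res, "ar_coef") <- rep(0, order)
    return(res)
  }
  fit <- stats::ar(x, aic = FALSE, order.max = order,
                   method = "yule-walker", demean = TRUE)
  res <- as.numeric(fit$resid[-seq_len(order)])
  attr(res, "ar_order") <- order
  attr(res, "ar_coef") <- as.numeric(fit$ar)
  res
}

#' Pre-whiten every channel of a session
#'
#' Applies [prewhiten()] independently per channel and chromophore, then
#' left-trims the common `order` samples so all channels stay aligned on
#' one time base.
#'
#' @param hb an [hb_series].
#' @param order AR order.
#' @return an [hb_series] shortened by `order` samples.
#' @export
prewhiten_session <- function(hb, order = 50) {
  stopifnot(inherits(hb, "hb_series"))
  out <- hb
  for (chrom in c("oxy", "deoxy")) {
    M <- hb$data[[chrom]]
    R <- matrix(0, nrow(M) - order, ncol(M))
    for (j in seq_len(ncol(M))) R[, j] <- prewhiten(M[, j], order)
    colnames(R) <- colnames(M)
    out$data[[chrom]] <- R
  }
  out
}

#' Separate cortical from systemic hemodynamics for a whole session
#'
#' Runs [hdms()] on every channel and returns an [hb_series] holding the
#' functional (cortical) oxy/deoxy components, the substrate of all
#' downstream coherence analysis.
#'
#' @param hb an [hb_series].
#' @param k_f,k_s HDMS ratios, see [hdms()].
#' @return an [hb_series] with functional components in `oxy` / `deoxy`.
#' @export
hdms_session <- function(hb, k_f = -0.6, k_s = 0.5) {
  stopifnot(inherits(hb, "hb_series"))
  h <- hdms(hb$data$oxy, hb$data$deoxy, k_f, k_s)
  out <- hb
  out$data$oxy <- h$functional_oxy
  out$data$deoxy <- h$functional_deoxy
  out
}
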