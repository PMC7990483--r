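# Reduction of deformation-gradient histories to injury metrics: per-element
# maxima over time of first principal Green-Lagrange strain and its rate,
# threshold-exceedance volume fractions, and RMSE against observed contusion
# volume fractions.

#' Green-Lagrange strain tensor
#' @param F 3 x 3 deformation gradient, `det(F) > 0`.
#' @return Symmetric 3 x 3 strain tensor `E = (F'F - I) / 2`.
#' @export
green_lagrange <- function(F) {
  if (det(F) <= 0) stop("non-invertible deformation gradient (det <= 0)")
  (crossprod(F) - diag(3)) / 2
}

#' First principal strain (largest eigenvalue of a symmetric tensor)
#' @param E Symmetric 3 x 3 tensor.
#' @return Largest eigenvalue.
#' @export
first_principal <- function(E) {
  if (max(abs(E - t(E))) > 1e-10) stop("strain tensor is not symmetric")
  max(eigen((E + t(E)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# vectorised largest eigenvalue of symmetric 3x3 tensors given 6 components
# (trigonometric closed form)
.eigmax_sym6 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(p2 / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  ifelse(p > 0, q + 2 * p * cos(phi), q)
}

#' Reduce a simulation history to per-element strain metrics
#'
#' At every stored snapshot the first principal Green-Lagrange strain is
#' computed per element; the field keeps the maximum over time.  The strain
#' rate is the central finite difference of the principal strain series over
#' the snapshot interval (1/ms), again reduced to its maximum over time; the
#' alternative reading (largest principal value of the rate-of-deformation
#' tensor) is available via `rate_method = "rate_tensor"`.
#'
#' @param result A `sim_result` with at least 3 snapshots.
#' @param rate_method `"eps1_dot"` (default) or `"rate_tensor"`.
#' @return Object of class `strain_field`: data frame with element id,
#'   reference volume (mm^3), tissue, source voxel, `max_strain`, `max_rate`.
#' @export
reduce_history <- function(result, rate_method = c("eps1_dot", "rate_tensor")) {
  rate_method <- match.arg(rate_method)
  S <- length(result$times)
  if (S < 3) stop("insufficient history: need at least 3 snapshots")
  En <- dim(result$F_hist)[1]
  eps1 <- matrix(0, En, S)
  for (s in seq_len(S)) {
    Fm <- matrix(result$F_hist[, , s], ncol = 9)
    # C = F'F from columns F11,F21,F31,F12,...,F33
    c11 <- Fm[, 1]^2 + Fm[, 2]^2 + Fm[, 3]^2
    c22 <- Fm[, 4]^2 + Fm[, 5]^2 + Fm[, 6]^2
    c33 <- Fm[, 7]^2 + Fm[, 8]^2 + Fm[, 9]^2
    c12 <- Fm[, 1] * Fm[, 4] + Fm[, 2] * Fm[, 5] + Fm[, 3] * Fm[, 6]
    c13 <- Fm[, 1] * Fm[, 7] + Fm[, 2] * Fm[, 8] + Fm[, 3] * Fm[, 9]
    c23 <- Fm[, 4] * Fm[, 7] + Fm[, 5] * Fm[, 8] + Fm[, 6] * Fm[, 9]
    eps1[, s] <- .eigmax_sym6((c11 - 1) / 2, (c22 - 1) / 2, (c33 - 1) / 2,
                              c12 / 2, c13 / 2, c23 / 2)
  }
  max_strain <- apply(eps1, 1, max)
  dt_out <- diff(result$times)
  if (rate_method == "eps1_dot") {
    rate <- (eps1[, 3:S, drop = FALSE] - eps1[, 1:(S - 2), drop = FALSE]) /
      rep(dt_out[-1] + dt_out[-(S - 1)], each = En)
    max_rate <- apply(rate, 1, max)
  } else {
    max_rate <- rep(-Inf, En)
    for (s in 2:(S - 1)) {
      dF <- matrix(result$F_hist[, , s + 1] - result$F_hist[, , s - 1],
                   ncol = 9) /
        (result$times[s + 1] - result$times[s - 1])
      Fm <- matrix(result$F_hist[, , s], ncol = 9)
      # L = Fdot F^-1; D = sym(L)
      iF <- .inv3x3_rows(Fm)
      L <- .matmul_rows(dF, iF)
      max_rate <- pmax(max_rate,
                       .eigmax_sym6(L[, 1], L[, 5], L[, 9],
                                    (L[, 2] + L[, 4]) / 2,
                                    (L[, 3] + L[, 7]) / 2,
                                    (L[, 6] + L[, 8]) / 2))
    }
  }
  out <- data.frame(element = seq_len(En), volume = result$element_volumes,
                    tissue = result$hex_tissue, voxel = result$hex_voxel,
                    max_strain = max_strain, max_rate = max_rate)
  class(out) <- c("strain_field", "data.frame")
  out
}

# row-wise 3x3 inverse and multiply for E x 9 matrices (column-major layout)
.inv3x3_rows <- function(Fm) {
  F11 <- Fm[, 1]; F21 <- Fm[, 2]; F31 <- Fm[, 3]
  F12 <- Fm[, 4]; F22 <- Fm[, 5]; F32 <- Fm[, 6]
  F13 <- Fm[, 7]; F23 <- Fm[, 8]; F33 <- Fm[, 9]
  co11 <- F22 * F33 - F23 * F32; co12 <- F23 * F31 - F21 * F33
  co13 <- F21 * F32 - F22 * F31
  co21 <- F13 * F32 - F12 * F33; co22 <- F11 * F33 - F13 * F31
  co23 <- F12 * F31 - F11 * F32
  co31 <- F12 * F23 - F13 * F22; co32 <- F13 * F21 - F11 * F23
  co33 <- F11 * F22 - F12 * F21
  J <- F11 * co11 + F12 * co12 + F13 * co13
  cbind(co11, co21, co31, co12, co22, co32, co13, co23, co33) / J
}

.matmul_rows <- function(A, B) {
  out <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    out[, i + 3 * (j - 1)] <-
      A[, i] * B[, 1 + 3 * (j - 1)] +
      A[, i + 3] * B[, 2 + 3 * (j - 1)] +
      A[, i + 6] * B[, 3 + 3 * (j - 1)]
  }
  out
}

#' @export
print.strain_field <- function(x, ...) {
  cat("strain_field:", nrow(x), "elements; max principal strain",
      signif(max(x$max_strain), 3), "; max rate",
      signif(max(x$max_rate), 3), "/ms\n")
  invisible(x)
}

#' Brain volume fraction exceeding a threshold
#'
#' Fraction of brain-tissue volume (grey + white; CSF and ventricles are
#' excluded from both numerator and denominator) whose per-element maximum
#' strain or strain rate exceeds `threshold`.
#'
#' @param field A [reduce_history()] strain field.
#' @param quantity `"strain"` or `"strain_rate"`.
#' @param threshold Threshold value (dimensionless strain, or 1/ms).
#' @return Fraction in [0, 1].
#' @export
volume_fraction_above <- function(field, quantity = c("strain", "strain_rate"),
                                  threshold) {
  if (nrow(field) == 0) stop("empty strain field")
  quantity <- match.arg(quantity)
  brain <- field$tissue %in% c("grey", "white")
  vals <- if (quantity == "strain") field$max_strain else field$max_rate
  sum(field$volume[brain & vals > threshold]) / sum(field$volume[brain])
}

#' RMSE of predicted exceedance fractions against an observed mean
#'
#' @param predicted Numeric matrix (severities x thresholds) or vector of
#'   predicted volume fractions.
#' @param observed_mean Observed mean contusion volume fraction (scalar, or
#'   one value per severity).
#' @return Per-threshold root-mean-square error over severities.
#' @export
rmse_prediction <- function(predicted, observed_mean) {
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  if (length(observed_mean) != 1 &&
      length(observed_mean) != nrow(predicted)) {
    stop("observed_mean must be scalar or one value per severity (row)")
  }
  sqrt(colMeans((predicted - observed_mean)^2))
}

#' Write a strain field as CSV
#' @param field A `strain_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strain_field <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}
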