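# Nearly incompressible hyper-viscoelastic constitutive model.
#
# Deviatoric response: Ogden principal-stretch hyperelasticity on the
# isochoric stretches; volumetric response: penalty K*(J-1); time dependence:
# Prony-series shear relaxation applied to the deviatoric stress through the
# standard recursive exponential (hereditary-integral) update.
#
# Unit system g-mm-ms throughout: stress in MPa, density in g/mm^3, time in
# ms, so the small-strain shear relaxation modulus is
#   G(t) = G_inf + sum_k G_k exp(-t / tau_k),    G0 = sum_i mu_i alpha_i / 2,
# with G_k = g_k * G0 and G_inf = (1 - sum g_k) * G0.

#' Construct a material model
#'
#' @param rho Density, g/mm^3.
#' @param ogden_mu Ogden shear-like moduli, MPa (paired with `ogden_alpha`).
#' @param ogden_alpha Ogden exponents (dimensionless).
#' @param bulk_K Bulk modulus, MPa.
#' @param prony_g Relative relaxation weights g_k (dimensionless, sum < 1).
#' @param prony_tau Relaxation time constants, ms (all > 0).
#' @param scale_ratio Accumulated shear-spectrum scaling factor (book-keeping;
#'   see [scale_relaxation()]).
#' @param name Optional profile name.
#' @return Object of class `material_model`.
#' @export
material_model <- function(rho, ogden_mu, ogden_alpha, bulk_K,
                           prony_g = numeric(), prony_tau = numeric(),
                           scale_ratio = 1, name = "") {
  stopifnot(rho > 0, bulk_K > 0, length(ogden_mu) == length(ogden_alpha),
            length(prony_g) == length(prony_tau))
  if (length(prony_tau) > 0 && any(prony_tau <= 0)) {
    stop("prony_tau must be strictly positive")
  }
  if (sum(prony_g) >= 1) stop("sum of prony_g must be < 1")
  m <- structure(list(rho = rho, ogden_mu = as.numeric(ogden_mu),
                      ogden_alpha = as.numeric(ogden_alpha),
                      bulk_K = bulk_K, prony_g = as.numeric(prony_g),
                      prony_tau = as.numeric(prony_tau),
                      scale_ratio = scale_ratio, name = name),
                 class = "material_model")
  stopifnot(instantaneous_shear_modulus(m) > long_term_shear_modulus(m) ||
              length(prony_g) == 0)
  m
}

#' @export
print.material_model <- function(x, ...) {
  cat("material_model", if (nzchar(x$name)) paste0("'", x$name, "'"), ":\n")
  cat("  rho =", x$rho, "g/mm^3, K =", x$bulk_K, "MPa\n")
  cat("  Ogden mu =", paste(x$ogden_mu, collapse = ", "),
      "MPa, alpha =", paste(x$ogden_alpha, collapse = ", "), "\n")
  cat("  G0 =", signif(instantaneous_shear_modulus(x), 4),
      "MPa, Ginf =", signif(long_term_shear_modulus(x), 4), "MPa,",
      length(x$prony_g), "Prony term(s)\n")
  invisible(x)
}

#' Instantaneous and long-term small-strain shear moduli
#' @param material A `material_model`.
#' @return Modulus in MPa.
#' @export
instantaneous_shear_modulus <- function(material) {
  sum(material$ogden_mu * material$ogden_alpha) / 2
}

#' @rdname instantaneous_shear_modulus
#' @export
long_term_shear_modulus <- function(material) {
  instantaneous_shear_modulus(material) * (1 - sum(material$prony_g))
}

#' Shear relaxation modulus G(t)
#'
#' G(t) = G_inf + sum_k G_k exp(-t/tau_k), derived from the Ogden moduli
#' (instantaneous small-strain shear modulus) and the Prony weights.
#'
#' @param material A `material_model`.
#' @param t Time(s) since the step load, ms (>= 0, vectorised).
#' @return Modulus in MPa, same length as `t`.
#' @export
shear_relaxation <- function(material, t) {
  if (any(t < 0)) stop("negative time in shear_relaxation")
  g0 <- instantaneous_shear_modulus(material)
  ginf <- long_term_shear_modulus(material)
  gk <- material$prony_g * g0
  out <- rep(ginf, length(t))
  for (k in seq_along(gk)) {
    out <- out + gk[k] * exp(-t / material$prony_tau[k])
  }
  out
}

#' Scale the shear relaxation spectrum
#'
#' Multiplies every shear-stiffness quantity (each Ogden mu_i, hence G_inf and
#' every G_k) by `ratio`, leaving time constants, exponents, bulk modulus and
#' density unchanged.  This realises species scaling of the relaxation modulus
#' by the ratio of long-term shear moduli.
#'
#' @param material A `material_model`.
#' @param ratio Positive dimensionless factor.
#' @return The scaled `material_model`.
#' @export
scale_relaxation <- function(material, ratio) {
  if (ratio <= 0) stop("scale ratio must be > 0")
  material$ogden_mu <- material$ogden_mu * ratio
  material$scale_ratio <- material$scale_ratio * ratio
  material
}

#' Zeroed viscoelastic state for one integration point
#' @param material A `material_model`.
#' @return Object of class `visco_state`: per-Prony-term deviatoric
#'   overstress accumulators and the previous elastic deviatoric stress.
#' @export
visco_state <- function(material) {
  k <- length(material$prony_g)
  structure(list(H = replicate(k, matrix(0, 3, 3), simplify = FALSE),
                 S_prev = matrix(0, 3, 3)),
            class = "visco_state")
}

# deviatoric (traceless) instantaneous Ogden Cauchy stress from F,
# principal-stretch route valid for any alpha
.ogden_deviatoric <- function(material, F) {
  J <- det(F)
  b <- F %*% t(F)
  eb <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam_bar <- sqrt(pmax(eb$values, 0)) * J^(-1 / 3)
  tau_p <- numeric(3)
  for (p in seq_along(material$ogden_mu)) {
    pw <- lam_bar^material$ogden_alpha[p]
    tau_p <- tau_p + material$ogden_mu[p] * (pw - mean(pw))
  }
  V <- eb$vectors
  (V %*% diag(tau_p) %*% t(V)) / J
}

#' Cauchy stress with Prony viscoelastic update
#'
#' Volumetric part `K (J - 1) I` plus the isochoric Ogden deviatoric stress
#' attenuated by the Prony hereditary integral, advanced one time step with
#' the recursive exponential update
#' `H_k <- exp(-dt/tau_k) H_k + g_k exp(-dt/(2 tau_k)) (S - S_prev)`.
#'
#' @param material A `material_model`.
#' @param F 3 x 3 deformation gradient with `det(F) > 0`.
#' @param state A [visco_state()] (NULL for a state at rest).
#' @param dt Time step, ms (> 0).
#' @return List: `stress` (3 x 3 Cauchy stress, MPa) and `state` (updated).
#' @export
cauchy_stress <- function(material, F, state = NULL, dt = 1e-3) {
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) = ", signif(J, 4))
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(state)) state <- visco_state(material)
  S <- .ogden_deviatoric(material, F)
  g <- material$prony_g; tau <- material$prony_tau
  dev <- S * (1 - sum(g))
  for (k in seq_along(g)) {
    state$H[[k]] <- exp(-dt / tau[k]) * state$H[[k]] +
      g[k] * exp(-dt / (2 * tau[k])) * (S - state$S_prev)
    dev <- dev + state$H[[k]]
  }
  state$S_prev <- S
  sigma <- dev + diag(material$bulk_K * (J - 1), 3)
  list(stress = sigma, state = state)
}

#' Default per-tissue material profiles
#'
#' Grey and white matter share identical parameters (single-term Ogden with
#' alpha = 4, two Prony terms, rodent-scaled instantaneous shear modulus
#' 10 kPa, long-term 2 kPa); CSF and ventricles use the same framework with
#' shear moduli 100x lower and the same bulk modulus (soft-solid CSF).  The
#' `"desk"` profile uses K = 50 MPa for larger stable explicit time steps at
#' desk scale; `"physiological"` uses K = 2000 MPa.
#'
#' @param profile `"desk"` or `"physiological"`.
#' @return Named list of [material_model()]s: grey, white, csf, ventricle.
#' @export
default_materials <- function(profile = c("desk", "physiological")) {
  profile <- match.arg(profile)
  K <- if (profile == "desk") 50 else 2000
  brain <- material_model(rho = 1.04e-3, ogden_mu = 0.005, ogden_alpha = 4,
                          bulk_K = K, prony_g = c(0.5, 0.3),
                          prony_tau = c(0.08, 0.8), name = "brain")
  csf <- material_model(rho = 1.0e-3, ogden_mu = 5e-5, ogden_alpha = 4,
                        bulk_K = K, prony_g = c(0.5, 0.3),
                        prony_tau = c(0.08, 0.8), name = "csf")
  list(grey = brain, white = brain, csf = csf, ventricle = csf)
}
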