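# Synthetic per-animal, per-segment outcome tables with planted strain
# relationships (the statistical structure the mixed-effects stage assumes),
# plus the glial activation-classification rule on a toy cell table.

#' Effect specification for one outcome measure
#'
#' The generative model for an ipsilateral measurement is
#' `value = baseline + beta_strain * strain + beta_severity * 1[moderate] +
#' beta_interaction * strain * 1[moderate] + a_animal + s_segment + eps`,
#' with independent Gaussian random effects `a ~ N(0, sigma_animal^2)`,
#' `s ~ N(0, sigma_segment^2)` and residual `eps ~ N(0, sigma_resid^2)`.
#' A log link exponentiates the linear predictor.
#'
#' @param measure Measure name (e.g. `"FA"`, `"iba1_density"`).
#' @param beta_strain Fixed-effect slope per unit strain covariate.
#' @param beta_severity Offset of moderate relative to mild.
#' @param beta_interaction Strain-slope modifier for moderate.
#' @param sigma_animal SD of the animal random intercept.
#' @param sigma_segment SD of the segment random intercept.
#' @param sigma_resid Residual SD.
#' @param link `"identity"` or `"log"`.
#' @param baseline Contralateral (reference) mean; must be > 0 for log link.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(measure, beta_strain = 0, beta_severity = 0,
                        beta_interaction = 0, sigma_animal = 0,
                        sigma_segment = 0, sigma_resid = 0,
                        link = c("identity", "log"), baseline = 0) {
  link <- match.arg(link)
  stopifnot(sigma_animal >= 0, sigma_segment >= 0, sigma_resid >= 0)
  if (link == "log" && baseline <= 0) stop("log link requires baseline > 0")
  structure(list(measure = measure, beta_strain = beta_strain,
                 beta_severity = beta_severity,
                 beta_interaction = beta_interaction,
                 sigma_animal = sigma_animal, sigma_segment = sigma_segment,
                 sigma_resid = sigma_resid, link = link,
                 baseline = baseline),
            class = "effect_spec")
}

#' Default effect specifications
#'
#' Variance components are calibrated so that a strain-only mixed model on a
#' unit-variance standardised strain covariate has marginal R-squared 0.33
#' for the FA-like measure and 0.51 for the microglia-density-like measure
#' (slope 1 in magnitude, animal-intercept SD 0.8, no segment variance;
#' residual SD set by the targeted R-squared); the FA slope is negative
#' (higher strain lowers FA), the density slope positive.
#'
#' @return Named list of [effect_spec()]s.
#' @export
default_effect_specs <- function() {
  resid_for_r2 <- function(beta, r2, s_animal) {
    sqrt(beta^2 / r2 - beta^2 - s_animal^2)
  }
  list(
    FA = effect_spec("FA", beta_strain = -1, sigma_animal = 0.8,
                     sigma_resid = resid_for_r2(1, 0.33, 0.8)),
    iba1_density = effect_spec("iba1_density", beta_strain = 1,
                               sigma_animal = 0.8,
                               sigma_resid = resid_for_r2(1, 0.51, 0.8))
  )
}

#' Generate a synthetic outcome table
#'
#' One row per (animal, hemisphere, segment, measure).  The ipsilateral
#' strain covariates come from `strain_summary` (typically per-segment mean
#' maximum principal strain of the matching severity's CCI run, standardised
#' over the pooled ipsilateral segments); contralateral rows carry the
#' baseline plus random effects and noise only.
#'
#' @param strain_summary Data frame with columns `severity` (`"mild"` /
#'   `"moderate"`), `segment` (1-5), `strain` and optionally `strain_rate`:
#'   the ipsilateral segment covariates.
#' @param specs List of [effect_spec()]s.
#' @param n_mild,n_moderate Animals per severity group (> 1).
#' @param seed Integer seed (reproducible output).
#' @return Data frame of class `outcome_table`: animal, severity,
#'   hemisphere, segment, measure, value, strain, strain_rate.
#' @export
gen_outcomes <- function(strain_summary, specs = default_effect_specs(),
                         n_mild = 10, n_moderate = 11, seed = 1) {
  if (n_mild <= 1 || n_moderate <= 1) {
    stop("need more than one animal per severity group")
  }
  need <- expand.grid(severity = c("mild", "moderate"), segment = 1:5,
                      stringsAsFactors = FALSE)
  key <- paste(strain_summary$severity, strain_summary$segment)
  if (!all(paste(need$severity, need$segment) %in% key)) {
    stop("strain covariates required for all 10 ipsilateral segments")
  }
  if (is.null(strain_summary$strain_rate)) strain_summary$strain_rate <- NA
  set.seed(seed)
  animals <- data.frame(
    animal = seq_len(n_mild + n_moderate),
    severity = rep(c("mild", "moderate"), c(n_mild, n_moderate)))
  rows <- list()
  for (sp in specs) {
    a_int <- stats::rnorm(nrow(animals), 0, sp$sigma_animal)
    s_int <- stats::rnorm(5, 0, sp$sigma_segment)
    for (hemi in c("ipsi", "contra")) {
      grid <- merge(animals, data.frame(segment = 1:5))
      m <- match(paste(grid$severity, grid$segment), key)
      strain <- if (hemi == "ipsi") strain_summary$strain[m] else 0
      srate <- if (hemi == "ipsi") strain_summary$strain_rate[m] else 0
      mod <- as.numeric(grid$severity == "moderate")
      eta <- sp$baseline + sp$beta_strain * strain +
        (sp$beta_severity + sp$beta_interaction * strain) * mod * nzero(hemi) +
        a_int[grid$animal] + s_int[grid$segment] +
        stats::rnorm(nrow(grid), 0, sp$sigma_resid)
      value <- if (sp$link == "log") exp(eta) else eta
      rows[[paste(sp$measure, hemi)]] <-
        data.frame(animal = grid$animal, severity = grid$severity,
                   hemisphere = hemi, segment = grid$segment,
                   measure = sp$measure, value = value,
                   strain = if (hemi == "ipsi") strain else NA_real_,
                   strain_rate = if (hemi == "ipsi") srate else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$measure, out$animal, out$hemisphere, out$segment), ]
  class(out) <- c("outcome_table", "data.frame")
  out
}

# severity offsets act on the injured hemisphere only
nzero <- function(hemi) as.numeric(hemi == "ipsi")

#' Classify glial cells as activated and compute densities
#'
#' A cell is activated iff its process thickness strictly exceeds the
#' threshold (2.7 um by default).
#'
#' @param cells Data frame with at least `process_thickness` (um); optional
#'   `marker`.
#' @param area_mm2 Region area, mm^2 (> 0).
#' @param threshold Activation threshold on process thickness, um.
#' @return List: `activated` (subset of `cells`), `density_total` and
#'   `density_activated` (cells per mm^2).
#' @export
classify_activated <- function(cells, area_mm2, threshold = 2.7) {
  if (area_mm2 <= 0) stop("region area must be > 0")
  stopifnot(all(cells$process_thickness > 0))
  act <- cells[cells$process_thickness > threshold, , drop = FALSE]
  list(activated = act,
       density_total = nrow(cells) / area_mm2,
       density_activated = nrow(act) / area_mm2)
}

#' Ipsilateral change relative to a reference
#'
#' `paired_contra` subtracts the same animal's contralateral value segment by
#' segment (the diffusion-imaging convention); `naive_mean` subtracts the
#' per-segment mean of the contralateral values across all animals (the
#' histology convention, where the reference comes from uninjured controls).
#'
#' @param table An [gen_outcomes()] outcome table.
#' @param mode `"paired_contra"` or `"naive_mean"`.
#' @return Data frame: animal, severity, segment, measure, change, strain,
#'   strain_rate.
#' @export
ipsi_minus_reference <- function(table,
                                 mode = c("paired_contra", "naive_mean")) {
  mode <- match.arg(mode)
  ipsi <- table[table$hemisphere == "ipsi", ]
  contra <- table[table$hemisphere == "contra", ]
  if (mode == "paired_contra") {
    m <- match(paste(ipsi$animal, ipsi$segment, ipsi$measure),
               paste(contra$animal, contra$segment, contra$measure))
    if (any(is.na(m))) {
      stop("missing contralateral reference for ",
           sum(is.na(m)), " ipsilateral row(s)")
    }
    ref <- contra$value[m]
  } else {
    agg <- stats::aggregate(value ~ segment + measure, contra, mean)
    m <- match(paste(ipsi$segment, ipsi$measure),
               paste(agg$segment, agg$measure))
    if (any(is.na(m))) stop("missing contralateral group reference")
    ref <- agg$value[m]
  }
  data.frame(animal = ipsi$animal, severity = ipsi$severity,
             segment = ipsi$segment, measure = ipsi$measure,
             change = ipsi$value - ref, strain = ipsi$strain,
             strain_rate = ipsi$strain_rate)
}

#' Generate a toy glial-cell table
#'
#' Log-normal process thicknesses whose activated fraction rises with the
#' planted activation probability.
#'
#' @param n Number of cells.
#' @param p_activated Target fraction of activated cells.
#' @param marker `"IBA1"` or `"GFAP"`.
#' @param seed Integer seed.
#' @param threshold Activation threshold, um.
#' @return Data frame: cell id, marker, x, y, process_thickness,
#'   process_area, process_length.
#' @export
gen_glia_cells <- function(n = 200, p_activated = 0.3, marker = "IBA1",
                           seed = 1, threshold = 2.7) {
  set.seed(seed)
  act <- stats::runif(n) < p_activated
  thick <- ifelse(act,
                  threshold + stats::rlnorm(n, meanlog = -0.7, sdlog = 0.4),
                  threshold * stats::rbeta(n, 4, 2))
  data.frame(cell = seq_len(n), marker = marker,
             x = stats::runif(n), y = stats::runif(n),
             process_thickness = thick,
             process_area = thick * stats::rlnorm(n, 1.5, 0.3),
             process_length = stats::rlnorm(n, 1.8, 0.4))
}

#' Treat generated ipsilateral values as change data
#'
#' For calibration and parameter-recovery studies the generator's
#' ipsilateral linear predictor (with `baseline = 0`) *is* the injury
#' change, carrying the planted fixed effect, random-intercept and residual
#' variances directly; subtracting a noisy contralateral reference would
#' cancel the shared intercepts and double the residual variance, changing
#' the planted variance decomposition.
#'
#' @param table A [gen_outcomes()] outcome table.
#' @return Change table with the ipsilateral values as `change`.
#' @export
as_change_table <- function(table) {
  ipsi <- table[table$hemisphere == "ipsi", ]
  data.frame(animal = ipsi$animal, severity = ipsi$severity,
             segment = ipsi$segment, measure = ipsi$measure,
             change = ipsi$value, strain = ipsi$strain,
             strain_rate = ipsi$strain_rate)
}
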