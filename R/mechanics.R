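#' Esophageal-catheter occlusion validation
#'
#' During an expiratory occlusion, spontaneous (or externally applied)
#' effort changes airway and esophageal pressure identically when the
#' catheter reads pleural pressure faithfully; the ratio dPes/dPaw should
#' be close to unity. Placement passes if the ratio lies in [0.8, 1.2]
#' (boundaries inclusive).
#'
#' @param dPes,dPaw pressure swings during the occlusion, cmH2O.
#' @return A list with \code{ratio} and logical \code{pass}. Vectorized.
#' @export
validate_occlusion <- function(dPes, dPaw) {
  if (any(dPaw == 0)) stop("dPaw must be non-zero")
  ratio <- dPes / dPaw
  list(ratio = ratio, pass = ratio >= 0.8 & ratio <= 1.2)
}

#' Respiratory-system, chest-wall and lung elastance
#'
#' Classic occlusion formulas: \code{E_rs = (Paw_ei - PEEPtot) / VT},
#' \code{E_cw = (Pes_ei - Pes_ee) / VT}, \code{E_l = E_rs - E_cw}, with
#' pressures from 3-s end-inspiratory/end-expiratory holds (zero flow) and
#' VT in litres, so elastances are in cmH2O/L.
#'
#' @param Paw_ei end-inspiratory hold airway pressure, cmH2O.
#' @param PEEPtot total end-expiratory hold airway pressure, cmH2O.
#' @param Pes_ei,Pes_ee end-inspiratory/-expiratory esophageal pressure.
#' @param VT tidal volume in litres.
#' @return A list with \code{E_rs}, \code{E_cw}, \code{E_l}. Vectorized.
#' @export
elastances <- function(Paw_ei, PEEPtot, Pes_ei, Pes_ee, VT) {
  if (any(VT <= 0)) stop("VT must be positive (litres)")
  E_rs <- (Paw_ei - PEEPtot) / VT
  E_cw <- (Pes_ei - Pes_ee) / VT
  E_l <- E_rs - E_cw
  if (any(E_l < 0, na.rm = TRUE))
    warning("E_cw exceeds E_rs: negative lung elastance")
  list(E_rs = E_rs, E_cw = E_cw, E_l = E_l)
}

#' Absolute transpulmonary pressures from esophageal manometry
#'
#' \code{TPP_ei = Paw_ei - Pes_ei} (end-inspiratory lung stress, most
#' dependent regions) and \code{TPP_ee = PEEPtot - Pes_ee}.
#'
#' @inheritParams elastances
#' @return A list with \code{TPP_ei} and \code{TPP_ee}, cmH2O. Vectorized.
#' @export
transpulmonary <- function(Paw_ei, Pes_ei, PEEPtot, Pes_ee) {
  list(TPP_ei = Paw_ei - Pes_ei, TPP_ee = PEEPtot - Pes_ee)
}

#' Transpulmonary pressure by the elastance-ratio method
#'
#' \code{TPP_elast = Paw_ei x E_l / E_rs}: the share of the end-inspiratory
#' airway pressure borne by the lung, read as the stress of non-dependent
#' regions.
#'
#' @param Paw_ei end-inspiratory hold airway pressure, cmH2O.
#' @param E_l,E_rs lung and respiratory-system elastance, cmH2O/L.
#' @return TPP_elast in cmH2O. Vectorized.
#' @export
tpp_elastance_method <- function(Paw_ei, E_l, E_rs) {
  if (any(E_rs == 0)) stop("E_rs must be non-zero")
  Paw_ei * E_l / E_rs
}

#' Peak pressure across the lung
#'
#' \code{Ppeak_l = Ppeak_rs - Ppeak_cw}, the difference between the maxima
#' of airway and esophageal pressure over the breath.
#'
#' @param Ppeak_rs,Ppeak_cw peak airway / esophageal pressure, cmH2O.
#' @return Ppeak_l in cmH2O. Vectorized.
#' @export
peak_lung_pressure <- function(Ppeak_rs, Ppeak_cw) Ppeak_rs - Ppeak_cw

#' Mechanical power of ventilation
#'
#' Simplified-formula mechanical powers in J/min, with VT in litres and RR
#' in breaths/min (0.098 converts L.cmH2O/min to J/min):
#' \deqn{MP_{rs} = 0.098 \, VT \, RR \, (Ppeak_{rs} - (Paw_{ei} - Paw_{ee})/2)}
#' \deqn{MP_{lDep} = 0.098 \, VT \, RR \, (Ppeak_l - (TPP_{ei} - TPP_{ee})/2)}
#' \deqn{MP_{lnonDep} = 0.098 \, VT \, RR \, (Ppeak_l - (TPP_{elast} - TPP_{ee})/2)}
#' \code{Paw_ee} is the measured total end-expiratory hold pressure
#' (PEEPtot) when available.
#'
#' @param VT tidal volume, litres.
#' @param RR respiratory rate, breaths/min.
#' @param Ppeak_rs peak airway pressure, cmH2O.
#' @param Paw_ei,Paw_ee end-inspiratory/-expiratory airway pressures.
#' @param Ppeak_l peak transpulmonary pressure, cmH2O.
#' @param TPP_ei,TPP_ee,TPP_elast transpulmonary pressures, cmH2O.
#' @return A list with \code{MP_rs}, \code{MP_lDep}, \code{MP_lnonDep}
#'   (J/min). Vectorized.
#' @export
mechanical_power <- function(VT, RR, Ppeak_rs, Paw_ei, Paw_ee,
                             Ppeak_l, TPP_ei, TPP_ee, TPP_elast) {
  k <- 0.098 * VT * RR
  out <- list(
    MP_rs = k * (Ppeak_rs - (Paw_ei - Paw_ee) / 2),
    MP_lDep = k * (Ppeak_l - (TPP_ei - TPP_ee) / 2),
    MP_lnonDep = k * (Ppeak_l - (TPP_elast - TPP_ee) / 2)
  )
  if (any(unlist(out) < 0, na.rm = TRUE))
    warning("negative mechanical power: physically implausible inputs")
  out
}

#' Derive all respiratory-mechanics quantities from hold measurements
#'
#' Applies [elastances()], [transpulmonary()], [tpp_elastance_method()],
#' [peak_lung_pressure()], [mechanical_power()] and [validate_occlusion()]
#' to a per-period hold table and appends the derived columns. Tidal volume
#' is carried in mL in study tables (column \code{VT_ml}) and converted to
#' litres internally.
#'
#' @param holds data frame with columns \code{Paw_ei}, \code{PEEPtot},
#'   \code{Pes_ei}, \code{Pes_ee}, \code{Ppeak_rs}, \code{Ppeak_cw},
#'   \code{VT_ml}, \code{RR}, optionally \code{Paw_ee}, \code{dPes},
#'   \code{dPaw}.
#' @return The input with columns \code{E_rs}, \code{E_cw}, \code{E_l},
#'   \code{TPP_ei}, \code{TPP_ee}, \code{TPP_elast}, \code{Ppeak_l},
#'   \code{MP_rs}, \code{MP_lDep}, \code{MP_lnonDep}, and when occlusion
#'   deltas are present \code{occlusion_ratio}, \code{occlusion_pass}.
#' @export
compute_mechanics <- function(holds) {
  need <- c("Paw_ei", "PEEPtot", "Pes_ei", "Pes_ee", "Ppeak_rs",
            "Ppeak_cw", "VT_ml", "RR")
  miss <- setdiff(need, names(holds))
  if (length(miss)) stop("holds table missing column(s): ",
                         paste(miss, collapse = ", "))
  vt <- holds$VT_ml / 1000
  el <- elastances(holds$Paw_ei, holds$PEEPtot, holds$Pes_ei,
                   holds$Pes_ee, vt)
  tp <- transpulmonary(holds$Paw_ei, holds$Pes_ei, holds$PEEPtot,
                       holds$Pes_ee)
  tpe <- tpp_elastance_method(holds$Paw_ei, el$E_l, el$E_rs)
  ppl <- peak_lung_pressure(holds$Ppeak_rs, holds$Ppeak_cw)
  paw_ee <- if ("Paw_ee" %in% names(holds)) holds$Paw_ee else holds$PEEPtot
  mp <- mechanical_power(vt, holds$RR, holds$Ppeak_rs, holds$Paw_ei,
                         paw_ee, ppl, tp$TPP_ei, tp$TPP_ee, tpe)
  out <- cbind(holds,
               data.frame(E_rs = el$E_rs, E_cw = el$E_cw, E_l = el$E_l,
                          TPP_ei = tp$TPP_ei, TPP_ee = tp$TPP_ee,
                          TPP_elast = tpe, Ppeak_l = ppl,
                          MP_rs = mp$MP_rs, MP_lDep = mp$MP_lDep,
                          MP_lnonDep = mp$MP_lnonDep))
  if (all(c("dPes", "dPaw") %in% names(holds))) {
    occ <- validate_occlusion(holds$dPes, holds$dPaw)
    out$occlusion_ratio <- occ$ratio
    out$occlusion_pass <- occ$pass
  }
  out
}
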