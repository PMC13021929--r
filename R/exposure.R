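#' Drug exposure and total-dose arithmetic
#'
#' Experiment-design utility relating a concentration-duration pair to
#' its exposure product (exposure = concentration x time) and a per-dose
#' schedule to its cumulative dose (total dose = dose per administration
#' x number of administrations). A high-concentration intermittent
#' exposure of 100 nmol/L for 18 h and a low-concentration continuous
#' exposure of 20 nmol/L for 72 h give products of 1800 and 1440
#' nmol/L*hour, respectively.
#'
#' @param concentration drug concentration in nmol/L.
#' @param durationHours exposure duration in hours.
#' @param perDose dose per administration in mg/kg (optional).
#' @param nDoses number of administrations (optional).
#' @return data.frame with columns \code{concentration},
#'   \code{duration_hours}, \code{exposure} (nmol/L*hour) and, when a
#'   schedule is given, \code{per_dose}, \code{n_doses},
#'   \code{total_dose} (mg/kg).
#' @examples
#' exposureAndDose(100, 18)                    # exposure 1800
#' exposureAndDose(20, 72, perDose = 0.6, nDoses = 7)
#' @export
exposureAndDose <- function(concentration, durationHours,
                            perDose = NULL, nDoses = NULL) {
    if (any(concentration < 0) || any(durationHours < 0))
        stop("concentration and duration must be non-negative")
    out <- data.frame(concentration = concentration,
                      duration_hours = durationHours,
                      exposure = concentration * durationHours)
    if (!is.null(perDose) || !is.null(nDoses)) {
        if (is.null(perDose) || is.null(nDoses))
            stop("give both 'perDose' and 'nDoses' or neither")
        if (any(perDose < 0) || any(nDoses < 0))
            stop("doses must be non-negative")
        out$per_dose <- perDose
        out$n_doses <- nDoses
        out$total_dose <- perDose * nDoses
    }
    out
}
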