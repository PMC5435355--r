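# Metabolic-labeling arithmetic.
#
# Cultures are spiked with [32P] orthophosphate; every RNA then incorporates
# label in proportion to its phosphate content. Two closed forms matter for
# array work: the isotopic dilution of the spike into the medium's cold
# phosphate pool, and the expected number of 32P atoms a tRNA molecule
# carries (which must stay well below one for spot activity to be a linear
# proxy for molecule counts).

#' Metabolic-labeling parameters
#'
#' @param spike_uCi_per_ml radioactivity added to the culture, uCi/ml.
#' @param specific_activity_Ci_per_mmol specific activity of the spike,
#'   Ci/mmol; converts activity to molarity.
#' @param media_phosphate_mM cold phosphate concentration of the medium,
#'   mmol/L (22 mM for M9-style media).
#' @param trna_length_nt tRNA length in nucleotides; the number of labelable
#'   phosphates per molecule (phosphodiester plus 5'-terminal) is about the
#'   length.
#' @return a `labeling_params` list.
#' @export
labeling_params <- function(spike_uCi_per_ml = 10,
                            specific_activity_Ci_per_mmol = 1,
                            media_phosphate_mM = 22,
                            trna_length_nt = 76L) {
  stopifnot(spike_uCi_per_ml > 0, specific_activity_Ci_per_mmol > 0,
            media_phosphate_mM > 0, trna_length_nt > 0)
  structure(list(spike_uCi_per_ml = spike_uCi_per_ml,
                 specific_activity_Ci_per_mmol = specific_activity_Ci_per_mmol,
                 media_phosphate_mM = media_phosphate_mM,
                 trna_length_nt = as.integer(trna_length_nt)),
            class = "labeling_params")
}

#' Isotopic dilution factor
#'
#' Molar ratio of the medium's cold phosphate to the spiked radioactive
#' phosphate. The spike molarity in umol/L equals spike activity (uCi/ml)
#' divided by specific activity (Ci/mmol): 10 uCi/ml at 1 Ci/mmol is
#' 10 umol/L, so 22 mM cold phosphate gives a 2200-fold dilution. The
#' spike's own contribution to the total pool is neglected (it is three
#' orders of magnitude smaller).
#'
#' @param params a [labeling_params()] list.
#' @return dilution factor (fold), dimensionless.
#' @export
dilution_factor <- function(params = labeling_params()) {
  spike_umol_per_L <- params$spike_uCi_per_ml /
    params$specific_activity_Ci_per_mmol
  1000 * params$media_phosphate_mM / spike_umol_per_L
}

#' Expected 32P atoms per tRNA molecule
#'
#' Each of the ~`length` phosphates of a molecule is radioactive
#' independently with probability 1/dilution, so the label count is Poisson
#' with mean `lambda = length / dilution`. `p_multilabel` is the
#' probability of carrying two or more atoms, `1 - exp(-lambda) (1 +
#' lambda)`; at typical conditions it is ~1e-4 ("at most one atom per
#' molecule").
#'
#' @param length_nt tRNA length in nucleotides.
#' @param dilution isotopic dilution factor (> 0).
#' @return list: lambda, p_labeled (>= 1 atom), p_multilabel (>= 2 atoms).
#' @export
labels_per_molecule <- function(length_nt = 76L,
                                dilution = dilution_factor()) {
  stopifnot(dilution > 0, length_nt > 0)
  lambda <- length_nt / dilution
  list(lambda = lambda,
       p_labeled = 1 - exp(-lambda),
       p_multilabel = 1 - exp(-lambda) * (1 + lambda))
}

#' One-stop labeling report
#'
#' @param params a [labeling_params()] list.
#' @return list: dilution_factor, lambda, p_labeled, p_multilabel.
#' @export
labeling_report <- function(params = labeling_params()) {
  d <- dilution_factor(params)
  c(list(dilution_factor = d),
    labels_per_molecule(params$trna_length_nt, d))
}
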